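#' Read and write region-by-time signal matrices
#'
#' On disk, scans are tab-separated with a header row of region labels and
#' rows as time points; in memory, [region_ts()] stores regions in rows.
#' The reader transposes accordingly.
#'
#' @param path File path.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param age,sex,handedness Optional covariates attached on read.
#' @return [read_region_ts()] returns a [region_ts()];
#'   [write_region_ts()] returns `path` invisibly.
#' @export
read_region_ts <- function(path, subject_id = NULL, age = NA_real_,
                           sex = NA_character_, handedness = NA_character_) {
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "d"),
                        progress = FALSE)
  values <- t(as.matrix(df))
  region_ts(values, subject_id, age = age, sex = sex, handedness = handedness)
}

#' @rdname read_region_ts
#' @param ts A [region_ts()].
#' @export
write_region_ts <- function(ts, path) {
  stopifnot(inherits(ts, "region_ts"))
  m <- t(ts$values)
  labels <- colnames(m)
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(ncol(m)))
  df <- tibble::as_tibble(m, .name_repair = ~labels)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Tab-separated with columns `subject_id`, `age`, `sex`, `handedness`,
#' `t_scan` (extra columns pass through).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_subject_metadata <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  need <- c("subject_id", "age", "t_scan")
  if (!all(need %in% names(df))) {
    stop("metadata table must contain columns: ", paste(need, collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Write a synchrony series
#'
#' One tab-separated column named `synchrony`, one row per time point.
#'
#' @param s A synchrony vector.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_synchrony <- function(s, path) {
  readr::write_tsv(tibble::tibble(synchrony = as.numeric(s)), path,
                   progress = FALSE)
  invisible(path)
}

#' Connectome I/O
#'
#' Reads either a square tab-separated 0/1 adjacency matrix (with or
#' without header) or a two-column edge list; `format = "auto"` picks the
#' edge list when the file has exactly two columns and more rows than two.
#' Writing uses the edge-list form by default.
#'
#' @param path File path.
#' @param format `"auto"`, `"adjacency"` or `"edgelist"`.
#' @param n_nodes Required for edge lists (isolated nodes are invisible
#'   there); ignored for adjacency matrices.
#' @return A [connectome()].
#' @export
read_connectome <- function(path, format = c("auto", "adjacency", "edgelist"),
                            n_nodes = NULL) {
  format <- match.arg(format)
  m <- unname(as.matrix(utils::read.table(path, sep = "\t", header = FALSE)))
  if (format == "auto") {
    format <- if (ncol(m) == 2L && nrow(m) != 2L) "edgelist" else "adjacency"
  }
  if (format == "adjacency") {
    if (nrow(m) != ncol(m)) stop("adjacency matrix must be square")
    if (!isTRUE(all.equal(m, t(m)))) stop("adjacency matrix must be symmetric")
    idx <- which(m != 0 & upper.tri(m), arr.ind = TRUE)
    connectome(nrow(m), idx)
  } else {
    if (is.null(n_nodes)) n_nodes <- max(m)
    connectome(n_nodes, m)
  }
}

#' @rdname read_connectome
#' @param g A [connectome()].
#' @export
write_connectome <- function(g, path, format = c("edgelist", "adjacency")) {
  stopifnot(inherits(g, "connectome"))
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(g$edges, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    m <- matrix(0L, g$n_nodes, g$n_nodes)
    m[g$edges] <- 1L
    m[g$edges[, c(2, 1), drop = FALSE]] <- 1L
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Write a threshold calibration table
#'
#' Tab-separated audit table of `n_eff`, `lambda_c` and `s_star` (full
#' precision plus the two-decimal reporting value) for a set of effective
#' region counts.
#'
#' @param n_eff_values Integer vector.
#' @param path File path.
#' @return The table, invisibly.
#' @export
write_calibration_table <- function(n_eff_values, path) {
  tb <- tibble::tibble(
    n_eff = as.integer(n_eff_values),
    lambda_c = purrr::map_dbl(n_eff_values, critical_lambda),
    s_star = purrr::map_dbl(n_eff_values, calibrate_s_star),
    s_star_reported = round(.data$s_star, 2)
  )
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(tb)
}

#' Write an edge-removal trajectory and its run manifest
#'
#' The trajectory goes to a tab-separated table (round, n_edges,
#' avg_degree, pseg); the manifest is JSON with the configuration, seed,
#' threshold and Spearman correlation.
#'
#' @param traj A `removal_trajectory` from [edge_removal_experiment()].
#' @param path Trajectory file path.
#' @param manifest_path Optional JSON manifest path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, manifest_path = NULL) {
  stopifnot(inherits(traj, "removal_trajectory"))
  readr::write_tsv(traj$records, path, progress = FALSE)
  if (!is.null(manifest_path)) {
    cfg <- traj$config
    jsonlite::write_json(
      list(
        lam0 = cfg$lam0, n_steps = cfg$n_steps,
        flips_per_step = cfg$flips_per_step,
        removal_batch = cfg$removal_batch,
        removal_rounds = cfg$removal_rounds, burn_in = cfg$burn_in,
        seed = cfg$seed, s_star = traj$s_star,
        spearman_rho = traj$spearman_rho, p_value = traj$p_value
      ),
      manifest_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Write a JSON report of an effective-region-count scan
#'
#' @param scan A `neff_scan` from [select_neff()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_neff_report <- function(scan, path) {
  stopifnot(inherits(scan, "neff_scan"))
  jsonlite::write_json(
    list(best = scan$best, objective = scan$objective,
         scan = scan$scan),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
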