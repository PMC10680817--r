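#' Quality-control filter for a cohort
#'
#' Applies the study's inclusion rules to a subject metadata table: only
#' scans whose length equals the predominant (modal) scan length of the
#' cohort are kept, and subjects at or above the age cap are excluded
#' (ages become protected information at advanced ages, so exact values are
#' unavailable there). Every subject appears exactly once in the output,
#' flagged included or carrying its exclusion reason.
#'
#' @param metadata Data frame with at least `subject_id`, `age`, `t_scan`.
#' @param age_cap Exclude subjects with `age >= age_cap` (default 90);
#'   `Inf` disables the rule.
#' @return The metadata as a tibble with added `included` (logical) and
#'   `exclusion_reason` (`"none"`, `"scan_length"` or `"age_cap"`).
#' @export
qc_filter <- function(metadata, age_cap = 90) {
  metadata <- tibble::as_tibble(metadata)
  stopifnot(all(c("subject_id", "age", "t_scan") %in% names(metadata)),
            nrow(metadata) >= 1L)
  lengths <- table(metadata$t_scan)
  modal <- as.integer(names(lengths)[which.max(lengths)])
  metadata |>
    dplyr::mutate(
      exclusion_reason = dplyr::case_when(
        .data$t_scan != modal ~ "scan_length",
        .data$age >= age_cap ~ "age_cap",
        TRUE ~ "none"
      ),
      included = .data$exclusion_reason == "none"
    )
}

#' Fit one subject's coupling and segregation probability
#'
#' The per-subject pipeline: binarize the scan, compute synchrony and its
#' moments over all atlas regions, fit the mean-field coupling at the
#' data set's effective region count by moment matching, and compute the
#' empirical Pseg at the data set's calibrated threshold. A nonphysical
#' (negative) fitted coupling marks the subject excluded; its value is
#' kept as a diagnostic.
#'
#' @param ts A [region_ts()].
#' @param n_eff Effective region count of the data set.
#' @param s_star Calibrated threshold (see [calibrate_s_star()]).
#' @param sd_window Window length for the per-subject windowed Pseg
#'   standard deviation (`NULL` skips it; default 60 time points,
#'   non-overlapping).
#' @return One-row tibble: subject_id, age, sex, handedness, t_scan, m2,
#'   m4, lam_hat, pseg, pint, pseg_sd, included, exclusion_reason.
#' @export
fit_subject <- function(ts, n_eff, s_star, sd_window = 60L) {
  stopifnot(inherits(ts, "region_ts"))
  s <- synchrony(binarize(ts))
  mom <- empirical_moments(s)
  fit <- fit_lambda(mom$m2, n_eff)
  ps <- pseg_empirical(s, s_star)
  tibble::tibble(
    subject_id = ts$subject_id,
    age = ts$age,
    sex = ts$sex,
    handedness = ts$handedness,
    t_scan = ncol(ts$values),
    m2 = mom$m2,
    m4 = mom$m4,
    lam_hat = fit$lambda,
    pseg = ps$pseg,
    pint = ps$pint,
    pseg_sd = if (is.null(sd_window)) NA_real_ else
      pseg_windowed_sd(s, s_star, sd_window),
    included = !fit$excluded,
    exclusion_reason = if (fit$excluded) "negative_lambda" else "none"
  )
}

#' Fit a whole cohort
#'
#' Runs [qc_filter()] on the metadata, fits every QC-passing subject with
#' [fit_subject()], and returns one row per input subject: QC-excluded
#' subjects keep their exclusion reason with missing fit columns, so the
#' accounting of inclusions and exclusions is complete.
#'
#' @param subjects List of [region_ts()] objects (names or `subject_id`s
#'   must match the metadata).
#' @param metadata Subject metadata table (see [qc_filter()]).
#' @param n_eff Effective region count.
#' @param s_star Calibrated threshold; `NULL` calibrates for `n_eff`.
#' @param age_cap Passed to [qc_filter()].
#' @param sd_window Passed to [fit_subject()].
#' @return Tibble of subject fits, one row per subject.
#' @export
fit_cohort <- function(subjects, metadata, n_eff, s_star = NULL,
                       age_cap = 90, sd_window = 60L) {
  if (is.null(s_star)) s_star <- calibrate_s_star(n_eff)
  qc <- qc_filter(metadata, age_cap = age_cap)
  ids <- purrr::map_chr(subjects, "subject_id")
  fits <- purrr::map_dfr(seq_len(nrow(qc)), function(i) {
    row <- qc[i, ]
    if (!row$included) {
      return(tibble::tibble(
        subject_id = row$subject_id, age = row$age,
        sex = row[["sex"]] %||% NA_character_,
        handedness = row[["handedness"]] %||% NA_character_,
        t_scan = row$t_scan,
        m2 = NA_real_, m4 = NA_real_, lam_hat = NA_real_,
        pseg = NA_real_, pint = NA_real_, pseg_sd = NA_real_,
        included = FALSE, exclusion_reason = row$exclusion_reason
      ))
    }
    ts <- subjects[[match(row$subject_id, ids)]]
    if (is.null(ts)) stop("no scan found for subject ", row$subject_id)
    fit_subject(ts, n_eff, s_star, sd_window = sd_window)
  })
  attr(fits, "n_eff") <- n_eff
  attr(fits, "s_star") <- s_star
  fits
}

#' Age trend of segregation across a cohort
#'
#' The headline statistic is the Spearman correlation between age and Pseg
#' over all included subjects. Subjects are also summarized in 5-year age
#' bins (left-closed, anchored at the floor of the youngest age) by the
#' median Pseg with a standard error, and an additive OLS regression of
#' Pseg on age, sex and handedness quantifies the age effect with
#' covariates.
#'
#' @param fits Subject-fit tibble from [fit_cohort()] (or rows of
#'   [fit_subject()]); only rows with `included == TRUE` enter.
#' @param bin_width Age bin width in years (default 5).
#' @param se_method `"normal"` (1.2533 SD/sqrt(n), the large-sample SE of a
#'   median under approximate normality) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates when `se_method = "bootstrap"`.
#' @param outcome Column to trend, `"pseg"` (default) or `"pint"`;
#'   trending Pint flips the sign of the correlation exactly.
#' @return Object of class `age_trend`: list with `spearman_rho`,
#'   `p_value`, `n_included`, `bins` (tibble), `regression` (coefficient
#'   tibble), `outcome`.
#' @export
age_trend <- function(fits, bin_width = 5, se_method = c("normal", "bootstrap"),
                      boot_reps = 500L, outcome = c("pseg", "pint")) {
  se_method <- match.arg(se_method)
  outcome <- match.arg(outcome)
  fits <- tibble::as_tibble(fits)
  inc <- dplyr::filter(fits, .data$included)
  if (nrow(inc) < 3L) stop("age_trend needs at least 3 included subjects")
  y <- inc[[outcome]]

  ct <- suppressWarnings(
    stats::cor.test(inc$age, y, method = "spearman", exact = FALSE)
  )

  lo <- floor(min(inc$age))
  breaks <- seq(lo, max(inc$age) + bin_width, by = bin_width)
  med_se <- function(v) {
    if (length(v) < 2L) return(NA_real_)
    if (se_method == "normal") {
      1.2533 * stats::sd(v) / sqrt(length(v))
    } else {
      stats::sd(replicate(boot_reps,
                          stats::median(sample(v, replace = TRUE))))
    }
  }
  bins <- inc |>
    dplyr::mutate(bin = cut(.data$age, breaks = breaks, right = FALSE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mid = mean(.data$age),
      median = stats::median(.data[[outcome]]),
      se = med_se(.data[[outcome]]),
      .groups = "drop"
    )

  covars <- c("age",
              if (dplyr::n_distinct(inc$sex, na.rm = TRUE) > 1L) "sex",
              if (dplyr::n_distinct(inc$handedness, na.rm = TRUE) > 1L)
                "handedness")
  form <- stats::reformulate(covars, response = outcome)
  regression <- broom::tidy(stats::lm(form, data = inc))

  structure(
    list(spearman_rho = unname(ct$estimate), p_value = ct$p.value,
         n_included = nrow(inc), bins = bins, regression = regression,
         outcome = outcome, bin_width = bin_width),
    class = "age_trend"
  )
}

#' @export
print.age_trend <- function(x, ...) {
  cat("<age_trend> ", x$outcome, " vs age: Spearman rho = ",
      signif(x$spearman_rho, 3), " (p = ", format.pval(x$p_value, digits = 3),
      "), n = ", x$n_included, "\n", sep = "")
  print(x$bins, n = 6)
  invisible(x)
}

#' @rdname age_trend
#' @param x An `age_trend` object.
#' @param type `"bins"` (default) or `"regression"`.
#' @param ... Unused.
#' @method tidy age_trend
#' @export
tidy.age_trend <- function(x, type = c("bins", "regression"), ...) {
  switch(match.arg(type), bins = x$bins, regression = x$regression)
}

#' @rdname age_trend
#' @method glance age_trend
#' @export
glance.age_trend <- function(x, ...) {
  tibble::tibble(
    spearman_rho = x$spearman_rho,
    p_value = x$p_value,
    n_included = x$n_included,
    n_bins = nrow(x$bins),
    outcome = x$outcome
  )
}
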