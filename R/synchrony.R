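#' Construct a region-by-time signal object
#'
#' Bundles one subject's parcellated scan (regions in rows, time points in
#' columns) with its demographic covariates. This is the unit every
#' signal-level operation consumes; on-disk matrices store time in rows and
#' are transposed on read (see [read_region_ts()]).
#'
#' @param values Numeric matrix, `n_regions x t_scan`, continuous signal
#'   amplitude in arbitrary units. Row names, if present, are region labels.
#' @param subject_id Subject identifier (coerced to character).
#' @param age Age in years (optional).
#' @param sex,handedness Optional categorical covariates.
#' @return An object of class `region_ts`.
#' @export
region_ts <- function(values, subject_id, age = NA_real_, sex = NA_character_,
                      handedness = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) {
    stop("a region-time series needs at least 2 regions, got ", nrow(values))
  }
  if (ncol(values) < 3L) {
    stop("a region-time series needs at least 3 time points, got ", ncol(values))
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      age = as.numeric(age),
      sex = sex,
      handedness = handedness,
      values = values
    ),
    class = "region_ts"
  )
}

#' @export
print.region_ts <- function(x, ...) {
  cat(
    "<region_ts> subject", x$subject_id, "-",
    nrow(x$values), "regions x", ncol(x$values), "time points\n"
  )
  invisible(x)
}

#' Binarize a continuous scan into Ising spins
#'
#' Each region's continuous trace is reduced to a spin at every time step by
#' the sign of the slope between consecutive time points: an increasing
#' signal maps to +1, a decreasing one to -1. An exactly flat step maps to
#' +1 deterministically; real-valued signals make exact ties a measure-zero
#' event, and a deterministic rule keeps synthetic integer-valued inputs
#' unambiguous and runs reproducible.
#'
#' @param ts A [region_ts()] object.
#' @return An integer matrix of spins in \{-1, +1\}, `n_regions x (t_scan - 1)`.
#' @export
#' @examples
#' ts <- region_ts(rbind(c(1, 2, 1.5), c(0, -1, 3)), "s1")
#' binarize(ts)
binarize <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  v <- ts$values
  if (!all(is.finite(v))) {
    stop(
      "non-finite signal values in scan for subject '", ts$subject_id,
      "'; refusing to binarize"
    )
  }
  d <- v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
  spins <- matrix(1L, nrow = nrow(d), ncol = ncol(d),
                  dimnames = dimnames(d))
  spins[d < 0] <- -1L
  spins
}

assert_spins <- function(spins) {
  if (!is.matrix(spins) || !all(spins == 1L | spins == -1L)) {
    stop("spin matrix must contain only -1 and +1")
  }
  invisible(spins)
}

#' Brain-wide synchrony of a spin matrix
#'
#' Synchrony at time t is the mean spin over all regions: the Ising
#' magnetization per spin, in \[-1, 1\]. With N regions every value lies on
#' the parity grid \{-1, -1 + 2/N, ..., 1\}.
#'
#' @param spins Spin matrix from [binarize()] (or the synthetic generator).
#' @return Numeric vector of class `synchrony` with attribute `n_regions`.
#' @export
synchrony <- function(spins) {
  assert_spins(spins)
  s <- colMeans(spins)
  structure(s, n_regions = nrow(spins), class = "synchrony")
}

#' @export
print.synchrony <- function(x, ...) {
  cat("<synchrony> ", length(x), " time points over ",
      attr(x, "n_regions"), " regions\n", sep = "")
  print(unclass(x)[seq_len(min(10L, length(x)))])
  invisible(x)
}

#' Second and fourth moments of a synchrony series
#'
#' The second moment is the currency of the maximum-entropy coupling fit;
#' the fourth moment is the next even moment the fit does not constrain and
#' drives the effective-region-count scan. All time points are used; no
#' burn-in is trimmed from empirical scans.
#'
#' @param s Synchrony vector (any numeric in \[-1, 1\]).
#' @return One-row tibble with columns `m2`, `m4`, `t_used`.
#' @export
empirical_moments <- function(s) {
  if (length(s) == 0L) stop("cannot compute moments of an empty synchrony series")
  s <- as.numeric(s)
  tibble::tibble(m2 = mean(s^2), m4 = mean(s^4), t_used = length(s))
}

#' Empirical segregation probability
#'
#' Pseg is the fraction of time points whose absolute synchrony falls
#' strictly below the threshold `s_star`; boundary points count as
#' integrated. Pint = 1 - Pseg by construction.
#'
#' @param s Synchrony vector.
#' @param s_star Synchrony threshold in (0, 1), typically from
#'   [calibrate_s_star()].
#' @return One-row tibble with columns `pseg`, `pint`, `t_used`.
#' @export
pseg_empirical <- function(s, s_star) {
  if (length(s) == 0L) stop("cannot compute Pseg of an empty synchrony series")
  if (!is.numeric(s_star) || length(s_star) != 1L || s_star <= 0 || s_star >= 1) {
    stop("s_star must be a single number in (0, 1)")
  }
  p <- mean(abs(as.numeric(s)) < s_star)
  tibble::tibble(pseg = p, pint = 1 - p, t_used = length(s))
}

#' Windowed Pseg variability of one synchrony series
#'
#' Splits the series into non-overlapping windows, computes Pseg per window
#' and returns the standard deviation across windows. Used to track how
#' stable an individual's segregation level is across a scan.
#'
#' @param s Synchrony vector.
#' @param s_star Threshold in (0, 1).
#' @param window Window length in time points (default 60, non-overlapping).
#' @return Standard deviation of windowed Pseg, or `NA` if fewer than two
#'   complete windows fit.
#' @export
pseg_windowed_sd <- function(s, s_star, window = 60L) {
  n_win <- length(s) %/% window
  if (n_win < 2L) return(NA_real_)
  idx <- rep(seq_len(n_win), each = window)
  kept <- as.numeric(s)[seq_len(n_win * window)]
  stats::sd(tapply(abs(kept) < s_star, idx, mean))
}
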