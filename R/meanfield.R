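#' Mean-field Ising model of brain synchrony
#'
#' A fully connected pairwise maximum-entropy model over `n_eff` effective
#' units with coupling `lambda`. The total-spin variable n lives on the
#' parity grid \{-n_eff, -n_eff + 2, ..., n_eff\} with
#' P(n) = (1/Z) C(n_eff, (n_eff + n)/2) exp(lambda n^2 / n_eff^2).
#' `big_lambda = lambda - n_eff/2` rescales the coupling so that 0 sits at
#' the order-disorder critical point.
#'
#' @param n_eff Effective number of regions (integer >= 2).
#' @param lambda Coupling strength (dimensionless, may be negative for
#'   diagnostics).
#' @return Object of class `meanfield_model`.
#' @export
meanfield_model <- function(n_eff, lambda) {
  n_eff <- check_n_eff(n_eff)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  structure(
    list(n_eff = n_eff, lambda = lambda,
         big_lambda = lambda - n_eff / 2),
    class = "meanfield_model"
  )
}

#' @export
print.meanfield_model <- function(x, ...) {
  cat("<meanfield_model> n_eff =", x$n_eff,
      " lambda =", signif(x$lambda, 6),
      " (big_lambda =", signif(x$big_lambda, 6), ")\n")
  invisible(x)
}

check_n_eff <- function(n_eff) {
  if (!is.numeric(n_eff) || length(n_eff) != 1L || n_eff < 2 ||
      n_eff != round(n_eff)) {
    stop("n_eff must be a single integer >= 2")
  }
  as.integer(n_eff)
}

#' Exact mean-field synchrony distribution
#'
#' Computes P(n) on the parity grid in log space (binomial multiplicity via
#' `lchoose` plus the Boltzmann exponent), max-shifted before
#' exponentiation so any coupling is overflow-free.
#'
#' @inheritParams meanfield_model
#' @return A tibble of class `synchrony_pmf` with columns `n` (total spin),
#'   `s` (synchrony n/n_eff) and `prob`.
#' @export
#' @examples
#' synchrony_pmf(4, 0)  # fair spins: symmetric binomial
synchrony_pmf <- function(n_eff, lambda) {
  n_eff <- check_n_eff(n_eff)
  n <- seq(-n_eff, n_eff, by = 2)
  logw <- lchoose(n_eff, (n_eff + n) / 2) + lambda * n^2 / n_eff^2
  p <- exp(logw - max(logw))
  p <- p / sum(p)
  out <- tibble::tibble(n = n, s = n / n_eff, prob = p)
  class(out) <- c("synchrony_pmf", class(out))
  attr(out, "n_eff") <- n_eff
  attr(out, "lambda") <- lambda
  out
}

#' Synchrony moments implied by the mean-field model
#'
#' @inheritParams meanfield_model
#' @return One-row tibble with `m2` and `m4`, the second and fourth moments
#'   of synchrony s = n/n_eff under the exact pmf.
#' @export
meanfield_moments <- function(n_eff, lambda) {
  m <- mf_moments(check_n_eff(n_eff), lambda)
  tibble::tibble(m2 = m[[1]], m4 = m[[2]])
}

# bare-numeric moments, hot path of the fitter and the scan
mf_moments <- function(n_eff, lambda) {
  s <- seq(-n_eff, n_eff, by = 2) / n_eff
  logw <- lchoose(n_eff, n_eff * (1 + s) / 2) + lambda * s^2
  p <- exp(logw - max(logw))
  p <- p / sum(p)
  c(sum(p * s^2), sum(p * s^4))
}

#' Critical coupling of the mean-field model
#'
#' At lambda = n_eff/2 the quadratic term of the log-pmf vanishes (Gaussian
#' expansion of the binomial entropy cancels the Boltzmann exponent) and
#' the synchrony distribution turns from unimodal to bimodal.
#'
#' @inheritParams meanfield_model
#' @return The critical coupling, `n_eff / 2`.
#' @export
critical_lambda <- function(n_eff) {
  check_n_eff(n_eff) / 2
}

# Landau (critical-expansion) log-density of |s| on [0, 1]:
# expanding ln C(n_eff, n_eff(1+s)/2) around s = 0 gives
#   const - n_eff (s^2/2 + s^4/12 + ...),
# so with the Boltzmann exponent lambda s^2 the density of s is
#   exp(big_lambda s^2 - n_eff s^4 / 12),  big_lambda = lambda - n_eff/2.
# This is the continuum form the threshold calibration extrapolates to.
landau_mass <- function(n_eff, lambda, upper) {
  bl <- lambda - n_eff / 2
  g <- function(u) bl * u^2 - n_eff * u^4 / 12
  # shift by the max of g on [0,1] so the integrand never overflows
  u_star <- if (bl > 0) min(1, sqrt(6 * bl / n_eff)) else 0
  shift <- max(g(0), g(1), g(u_star))
  stats::integrate(function(u) exp(g(u) - shift), 0, upper,
                   rel.tol = 1e-12, abs.tol = 0)$value
}

#' Calibrate the synchrony threshold s*
#'
#' The threshold separating segregated from integrated time points is fixed
#' per effective region count by requiring Pseg = 1/2 exactly at the
#' critical point. The critical synchrony density is the quartic Landau
#' limit exp(-n_eff s^4 / 12) (the quadratic term cancels at criticality);
#' s* is its half-mass point on \[0, 1\]. The value is returned at full
#' precision; report it rounded to two decimals.
#'
#' @inheritParams meanfield_model
#' @return The threshold s* in (0, 1).
#' @export
#' @examples
#' round(calibrate_s_star(40), 2)
calibrate_s_star <- function(n_eff) {
  n_eff <- check_n_eff(n_eff)
  lam_c <- critical_lambda(n_eff)
  half <- landau_mass(n_eff, lam_c, 1) / 2
  stats::uniroot(
    function(x) landau_mass(n_eff, lam_c, x) - half,
    interval = c(1e-8, 1 - 1e-8), tol = 1e-12
  )$root
}

#' Model segregation probability
#'
#' Probability mass of the segregated state |s| < s* under the mean-field
#' model. The default `"landau"` method evaluates the continuum
#' critical-expansion density (the same convention as
#' [calibrate_s_star()]), so at the critical coupling with the calibrated
#' threshold it returns 1/2 by construction. `"grid"` sums the exact pmf
#' over grid points with |n| strictly below `n_eff * s_star` (non-integer
#' bounds truncated inward), matching the strict-inequality convention of
#' [pseg_empirical()].
#'
#' @param model A [meanfield_model()].
#' @param s_star Threshold in (0, 1).
#' @param method `"landau"` (continuum, calibration-consistent) or
#'   `"grid"` (exact parity-grid sum).
#' @return One-row tibble with `pseg` and `pint`.
#' @export
pseg_model <- function(model, s_star, method = c("landau", "grid")) {
  stopifnot(inherits(model, "meanfield_model"))
  method <- match.arg(method)
  if (!is.numeric(s_star) || length(s_star) != 1L || s_star <= 0 || s_star >= 1) {
    stop("s_star must be a single number in (0, 1)")
  }
  p <- switch(method,
    landau = landau_mass(model$n_eff, model$lambda, s_star) /
      landau_mass(model$n_eff, model$lambda, 1),
    grid = {
      d <- synchrony_pmf(model$n_eff, model$lambda)
      sum(d$prob[abs(d$n) < model$n_eff * s_star])
    }
  )
  tibble::tibble(pseg = p, pint = 1 - p)
}

#' Maximum-entropy coupling fit by moment matching
#'
#' The pairwise maximum-entropy distribution with a binomial prior and a
#' second-moment constraint has exactly the mean-field form, so fitting the
#' coupling reduces to solving meanfield_moments(n_eff, lambda)$m2 = m2_obs.
#' The root is bracketed by growing the interval geometrically and solved
#' by bisection. Observed second moments below the fair-spin value
#' 1/n_eff would need lambda < 0 — a nonphysical coupling; such subjects
#' are flagged excluded, with the negative root kept as a diagnostic.
#'
#' @param m2_obs Observed second moment of synchrony, in \[0, 1\].
#' @param n_eff Effective number of regions.
#' @param tol Bisection tolerance on the m2 residual (default 1e-10).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return Object of class `lambda_fit`: a list with `lambda`, `excluded`
#'   (TRUE when the root is negative), `m2_obs`, `n_eff`, `residual`.
#' @export
fit_lambda <- function(m2_obs, n_eff, tol = 1e-10, max_iter = 200L) {
  n_eff <- check_n_eff(n_eff)
  if (!is.numeric(m2_obs) || length(m2_obs) != 1L || !is.finite(m2_obs) ||
      m2_obs < 0 || m2_obs > 1) {
    stop("m2_obs must be a single number in [0, 1]")
  }
  f <- function(lam) mf_moments(n_eff, lam)[[1]] - m2_obs

  m2_fair <- 1 / n_eff
  if (abs(m2_obs - m2_fair) <= tol) {
    return(new_lambda_fit(0, FALSE, m2_obs, n_eff, 0))
  }
  negative <- m2_obs < m2_fair
  # grow the bracket geometrically from the fair-spin point
  lo <- 0
  hi <- if (negative) -1 else 1
  while (sign(f(hi)) == sign(f(lo))) {
    hi <- hi * 2
    if (abs(hi) > 1e6 * n_eff) stop("failed to bracket lambda for m2_obs = ", m2_obs)
  }
  if (negative) { tmp <- lo; lo <- hi; hi <- tmp }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  new_lambda_fit((lo + hi) / 2, negative, m2_obs, n_eff, f((lo + hi) / 2))
}

new_lambda_fit <- function(lambda, excluded, m2_obs, n_eff, residual) {
  structure(
    list(lambda = lambda, excluded = excluded, m2_obs = m2_obs,
         n_eff = n_eff, residual = residual),
    class = "lambda_fit"
  )
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("<lambda_fit> lambda =", signif(x$lambda, 6),
      if (x$excluded) "(negative: subject excluded)" else "",
      "\n  n_eff =", x$n_eff, " m2_obs =", signif(x$m2_obs, 6), "\n")
  invisible(x)
}

#' Select the effective region count by a fourth-moment scan
#'
#' For each candidate `n_eff`, fits the coupling of every subject from its
#' observed second moment, predicts the model fourth moment, and scores the
#' candidate by the error between observed and predicted fourth moments
#' across the cohort. The best candidate minimizes the objective. Subjects
#' whose fit is nonphysical (negative coupling) are dropped for that
#' candidate; a candidate losing all subjects gets a missing objective.
#'
#' @param moments Data frame with one row per subject and columns `m2`,
#'   `m4` (e.g. rows of [empirical_moments()] or the output of
#'   [fit_cohort()]).
#' @param candidates Integer vector of candidate effective region counts;
#'   defaults to multiples of 5 up to 200, optionally capped at the atlas
#'   size via `n_max`.
#' @param n_max Optional cap (e.g. the atlas region count).
#' @param objective `"cohort_rmse"` (root mean squared fourth-moment error
#'   over subjects, the default) or `"sum_abs"` (sum of per-subject
#'   absolute errors); the argmin is insensitive to this monotone
#'   reweighting in practice.
#' @return Object of class `neff_scan`: list with `scan` (tibble of
#'   `n_eff`, `objective`, `n_used`), `best`, `objective`.
#' @export
select_neff <- function(moments, candidates = seq(5L, 200L, by = 5L),
                        n_max = NULL,
                        objective = c("cohort_rmse", "sum_abs")) {
  objective <- match.arg(objective)
  moments <- tibble::as_tibble(moments)
  stopifnot(all(c("m2", "m4") %in% names(moments)))
  if (nrow(moments) < 2L) stop("the scan needs at least 2 subjects")
  if (length(candidates) == 0L) stop("empty candidate list")
  if (!is.null(n_max)) candidates <- candidates[candidates <= n_max]
  if (length(candidates) == 0L) stop("no candidates remain below n_max")

  scan <- purrr::map_dfr(candidates, function(ne) {
    fits <- purrr::map(moments$m2, fit_lambda, n_eff = ne)
    keep <- !purrr::map_lgl(fits, "excluded")
    if (!any(keep)) {
      return(tibble::tibble(n_eff = ne, objective = NA_real_, n_used = 0L))
    }
    m4_model <- purrr::map_dbl(fits[keep], function(f) {
      mf_moments(ne, f$lambda)[[2]]
    })
    err <- moments$m4[keep] - m4_model
    obj <- switch(objective,
      cohort_rmse = sqrt(mean(err^2)),
      sum_abs = sum(abs(err))
    )
    tibble::tibble(n_eff = ne, objective = obj, n_used = sum(keep))
  })
  ok <- which(!is.na(scan$objective))
  if (length(ok) == 0L) stop("all candidates lost every subject to exclusion")
  best <- scan$n_eff[ok[which.min(scan$objective[ok])]]
  structure(
    list(scan = scan, best = best, objective = objective),
    class = "neff_scan"
  )
}

#' @export
print.neff_scan <- function(x, ...) {
  cat("<neff_scan> best n_eff =", x$best,
      "over", nrow(x$scan), "candidates (", x$objective, ")\n")
  print(x$scan, n = 10)
  invisible(x)
}

#' @rdname select_neff
#' @param x A `neff_scan` object.
#' @param ... Unused.
#' @method tidy neff_scan
#' @export
tidy.neff_scan <- function(x, ...) x$scan

#' @rdname select_neff
#' @method glance neff_scan
#' @export
glance.neff_scan <- function(x, ...) {
  tibble::tibble(
    best_n_eff = x$best,
    min_objective = min(x$scan$objective, na.rm = TRUE),
    n_candidates = nrow(x$scan),
    objective = x$objective
  )
}
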