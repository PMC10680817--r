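#' Sample spin matrices from the mean-field model
#'
#' Draws the total spin n from the exact [synchrony_pmf()] by inverse CDF
#' at every time point, then assigns which of the `n_eff` exchangeable
#' units carry +1 uniformly at random. Columns are independent across
#' time: the moment-matching fit uses only marginal moments, so iid
#' samples are the right null for recovery experiments.
#'
#' @inheritParams meanfield_model
#' @param t Number of time points.
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @return Integer spin matrix, `n_eff x t`.
#' @export
sample_meanfield_spins <- function(n_eff, lambda, t, seed = NULL) {
  stopifnot(t >= 1L)
  gen <- function() {
    d <- synchrony_pmf(n_eff, lambda)
    cdf <- cumsum(d$prob)
    draws <- d$n[findInterval(stats::runif(t), cdf) + 1L]
    spins <- matrix(-1L, nrow = n_eff, ncol = t)
    for (j in seq_len(t)) {
      k <- (n_eff + draws[j]) / 2
      if (k > 0) spins[sample.int(n_eff, k), j] <- 1L
    }
    spins
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Expand meta-unit spins to an N-region continuous scan
#'
#' Realizes the premise that N atlas regions behave as a smaller number of
#' effective units: each meta-unit is copied to `floor(n_regions / n_eff)`
#' region channels (the remainder goes to the first meta-units, one extra
#' channel each), every copied spin flips sign independently with
#' probability `flip_noise`, and the continuous trace is rebuilt as the
#' cumulative sum of spin-signed positive increments (unit-mean uniform on
#' \[0.5, 1.5\], so traces are strictly monotone between flips and
#' [binarize()] recovers the noisy spins exactly).
#'
#' @param meta Spin matrix from [sample_meanfield_spins()], `n_eff x t`.
#' @param n_regions Atlas size (>= number of meta rows).
#' @param flip_noise Per-copy flip probability in \[0, 0.5\].
#' @param seed Optional integer seed.
#' @param subject_id,age,sex,handedness Metadata passed to [region_ts()].
#' @return A [region_ts()] with `t + 1` time points.
#' @export
expand_to_timeseries <- function(meta, n_regions, flip_noise = 0, seed = NULL,
                                 subject_id = "synthetic", age = NA_real_,
                                 sex = NA_character_,
                                 handedness = NA_character_) {
  assert_spins(meta)
  n_eff <- nrow(meta)
  t <- ncol(meta)
  stopifnot(n_regions >= n_eff, t >= 2L)
  if (flip_noise < 0 || flip_noise > 0.5) {
    stop("flip_noise must be in [0, 0.5]")
  }
  gen <- function() {
    copies <- rep(n_regions %/% n_eff, n_eff)
    rem <- n_regions %% n_eff
    if (rem > 0) copies[seq_len(rem)] <- copies[seq_len(rem)] + 1L
    spins <- meta[rep.int(seq_len(n_eff), copies), , drop = FALSE]
    if (flip_noise > 0) {
      flip <- matrix(stats::runif(length(spins)) < flip_noise,
                     nrow = n_regions)
      spins[flip] <- -spins[flip]
    }
    incr <- matrix(stats::runif(length(spins), 0.5, 1.5), nrow = n_regions)
    traces <- cbind(0, t(apply(spins * incr, 1L, cumsum)))
    rownames(traces) <- sprintf("R%03d", seq_len(n_regions))
    region_ts(traces, subject_id, age = age, sex = sex,
              handedness = handedness)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Specify a synthetic cohort
#'
#' Describes the statistical structure the analysis assumes: every subject
#' is a mean-field synchrony process with a planted effective region count,
#' expanded to the atlas size, with a coupling set by an age-dependent
#' schedule. Defaults emulate a 300-region atlas, a 490-time-point scan,
#' and adult ages 20-80.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; mandatory so a spec fully determines its bundle.
#' @param n_regions Atlas size.
#' @param n_eff_planted Planted effective region count.
#' @param t_scan Scan length in time points (the generated spin series has
#'   `t_scan - 1` columns so the continuous scan has `t_scan`).
#' @param age_range Numeric length-2, min and max age in years.
#' @param lambda_schedule A schedule from [lambda_schedule_linear()] or
#'   [lambda_schedule_constant()].
#' @param flip_noise Per-region-copy flip probability in \[0, 0.5\].
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, seed, n_regions = 300L,
                        n_eff_planted = 40L, t_scan = 490L,
                        age_range = c(20, 80),
                        lambda_schedule = lambda_schedule_linear(30, 8, age_range),
                        flip_noise = 0) {
  if (missing(seed)) stop("a cohort spec requires a seed")
  stopifnot(n_subjects >= 1L, n_regions >= n_eff_planted, t_scan >= 4L,
            length(age_range) == 2L, age_range[1] < age_range[2])
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         n_regions = as.integer(n_regions),
         n_eff_planted = as.integer(n_eff_planted),
         t_scan = as.integer(t_scan), age_range = as.numeric(age_range),
         lambda_schedule = lambda_schedule,
         flip_noise = flip_noise),
    class = "cohort_spec"
  )
}

#' Age-dependent coupling schedules
#'
#' `lambda_schedule_linear()` interpolates the coupling linearly from
#' `lambda_young` at the start of the age range to `lambda_old` at its end
#' (a planted weakening of connection strength with age);
#' `lambda_schedule_constant()` plants no age effect. Couplings must be
#' non-negative.
#'
#' @param lambda_young,lambda_old Couplings at the ends of the age range.
#' @param age_range Numeric length-2.
#' @return A function age -> lambda, tagged with its family for manifests.
#' @export
lambda_schedule_linear <- function(lambda_young, lambda_old,
                                   age_range = c(20, 80)) {
  stopifnot(lambda_young >= 0, lambda_old >= 0)
  f <- function(age) {
    w <- (age - age_range[1]) / (age_range[2] - age_range[1])
    lambda_young + w * (lambda_old - lambda_young)
  }
  structure(f, family = "linear",
            params = list(lambda_young = lambda_young, lambda_old = lambda_old,
                          age_range = age_range))
}

#' @rdname lambda_schedule_linear
#' @param lambda Constant coupling.
#' @export
lambda_schedule_constant <- function(lambda) {
  stopifnot(lambda >= 0)
  structure(function(age) rep(lambda, length(age)),
            family = "constant", params = list(lambda = lambda))
}

#' Generate a synthetic cohort bundle
#'
#' Ages are uniform over the age range; each subject's coupling comes from
#' the schedule; spin matrices are sampled from the planted mean-field
#' model and expanded to continuous region scans. Sex and handedness are
#' randomized with zero true effect, so covariate regressions on the bundle
#' are calibrated nulls. With `dir` set, the bundle is also written as the
#' tab-separated files the readers consume, plus a JSON manifest of the
#' spec and seed.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory to write the bundle to.
#' @return List with `subjects` (list of [region_ts()]) and `metadata`
#'   (tibble: subject_id, age, sex, handedness, t_scan, lambda_true).
#' @export
synth_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  bundle <- withr::with_seed(spec$seed, {
    ages <- stats::runif(spec$n_subjects, spec$age_range[1], spec$age_range[2])
    lambdas <- spec$lambda_schedule(ages)
    sexes <- sample(c("F", "M"), spec$n_subjects, replace = TRUE)
    hands <- sample(c("R", "L"), spec$n_subjects, replace = TRUE,
                    prob = c(0.9, 0.1))
    ids <- sprintf("SYN%04d", seq_len(spec$n_subjects))
    subjects <- purrr::map(seq_len(spec$n_subjects), function(i) {
      meta <- sample_meanfield_spins(spec$n_eff_planted, lambdas[i],
                                     spec$t_scan - 1L)
      expand_to_timeseries(meta, spec$n_regions, spec$flip_noise,
                           subject_id = ids[i], age = ages[i],
                           sex = sexes[i], handedness = hands[i])
    })
    list(
      subjects = subjects,
      metadata = tibble::tibble(
        subject_id = ids, age = ages, sex = sexes, handedness = hands,
        t_scan = spec$t_scan, lambda_true = lambdas
      )
    )
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    purrr::walk(bundle$subjects, function(ts) {
      write_region_ts(ts, file.path(dir, paste0(ts$subject_id, ".tsv")))
    })
    readr::write_tsv(bundle$metadata, file.path(dir, "metadata.tsv"))
    manifest <- list(
      n_subjects = spec$n_subjects, seed = spec$seed,
      n_regions = spec$n_regions, n_eff_planted = spec$n_eff_planted,
      t_scan = spec$t_scan, age_range = spec$age_range,
      lambda_schedule = c(list(family = attr(spec$lambda_schedule, "family")),
                          attr(spec$lambda_schedule, "params")),
      flip_noise = spec$flip_noise
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
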