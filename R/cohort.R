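#' Synthetic survival cohort specification
#'
#' Describes a cohort whose log hazard is linear in the core/shell
#' tract-length ratio (c/s ratio): subject i with ratio `cs_i` has event
#' hazard `baseline_hazard * exp(log_hazard_slope * cs_i)` (exponential
#' event times, so hazard ratios have closed form). A negative slope
#' makes a high c/s ratio protective, the direction observed clinically.
#' Censoring is independent exponential, its rate tuned so the expected
#' censored fraction matches `censoring_fraction`. The necrosis fraction
#' is linear in the c/s ratio with Gaussian noise
#' (`necrosis = necrosis_intercept - necrosis_slope * cs + eps`,
#' truncated to the unit interval), mirroring the observed anti-correlation.
#'
#' @param n_subjects cohort size (>= 2).
#' @param cs_mean,cs_sd c/s ratio distribution (normal, truncated > 0).
#' @param log_hazard_slope log-hazard change per unit c/s ratio.
#' @param baseline_hazard events per month at cs = 0.
#' @param censoring_fraction target expected censored fraction in [0, 1).
#' @param necrosis_intercept,necrosis_slope,necrosis_noise_sd necrosis
#'   model coefficients.
#' @param age_mean,age_sd,kps_levels,idh_rate covariate generators.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 62L, cs_mean = 1.0, cs_sd = 0.3,
                        log_hazard_slope = -1.5, baseline_hazard = 0.25,
                        censoring_fraction = 11 / 62,
                        necrosis_intercept = 0.8, necrosis_slope = 0.5,
                        necrosis_noise_sd = 0.03,
                        age_mean = 60, age_sd = 10,
                        kps_levels = seq(60, 100, by = 10),
                        idh_rate = 0.1, seed = 0L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must lie in [0, 1)")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  structure(list(n_subjects = as.integer(n_subjects), cs_mean = cs_mean,
                 cs_sd = cs_sd, log_hazard_slope = log_hazard_slope,
                 baseline_hazard = baseline_hazard,
                 censoring_fraction = censoring_fraction,
                 necrosis_intercept = necrosis_intercept,
                 necrosis_slope = necrosis_slope,
                 necrosis_noise_sd = necrosis_noise_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 kps_levels = kps_levels, idh_rate = idh_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# censoring rate rc with P(censored_i) = rc / (rc + h_i); tune the mean
# over subjects to the target fraction.
.censoring_rate <- function(hazards, target) {
  if (target <= 0) return(0)
  f <- function(rc) mean(rc / (rc + hazards)) - target
  stats::uniroot(f, c(1e-12, 1e6), tol = 1e-12)$root
}

#' Simulate a survival cohort with a c/s-ratio effect
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` with columns `time_months`, `event`, `cs_ratio`,
#'   `age`, `kps`, `idh`, `necrosis` (the cohort CSV schema).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_subjects
  cs <- stats::rnorm(n, spec$cs_mean, spec$cs_sd)
  while (any(cs <= 0))                              # truncate at 0
    cs[cs <= 0] <- stats::rnorm(sum(cs <= 0), spec$cs_mean, spec$cs_sd)
  hazard <- spec$baseline_hazard * exp(spec$log_hazard_slope * cs)
  t_event <- stats::rexp(n, hazard)
  if (spec$censoring_fraction > 0) {
    rc <- .censoring_rate(hazard, spec$censoring_fraction)
    t_cens <- stats::rexp(n, rc)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  necrosis <- spec$necrosis_intercept - spec$necrosis_slope * cs +
    stats::rnorm(n, sd = spec$necrosis_noise_sd)
  necrosis <- pmin(pmax(necrosis, 0), 1)
  data.frame(
    time_months = pmax(time, 1e-6),
    event = event,
    cs_ratio = cs,
    age = round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1),
    kps = sample(spec$kps_levels, n, replace = TRUE),
    idh = stats::rbinom(n, 1L, spec$idh_rate),
    necrosis = necrosis)
}

#' Simulate a two-group cohort at a fixed hazard ratio
#'
#' Generates `n_per_group` subjects per arm with exponential event times
#' whose group hazard ratio is exactly `hazard_ratio` (group "low" is the
#' higher-hazard arm, matching a low c/s ratio), plus independent
#' exponential censoring tuned to the target overall censored fraction.
#' Used for hazard-ratio recovery studies where the generating HR must be
#' known in closed form.
#'
#' @param n_per_group subjects per arm.
#' @param hazard_ratio generating hazard ratio (low vs high group).
#' @param baseline_hazard hazard of the better-surviving ("high") arm
#'   (events per month).
#' @param censoring_fraction target expected overall censored fraction.
#' @param seed RNG seed.
#' @return `data.frame` with `time_months`, `event` and `group`
#'   (factor, levels `"high"`, `"low"`).
#' @export
simulate_survival_groups <- function(n_per_group = 31L,
                                     hazard_ratio = 3.8,
                                     baseline_hazard = 0.03,
                                     censoring_fraction = 11 / 62,
                                     seed = 0L) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  h <- c(rep(baseline_hazard * hazard_ratio, n_per_group),
         rep(baseline_hazard, n_per_group))
  t_event <- stats::rexp(2L * n_per_group, h)
  if (censoring_fraction > 0) {
    rc <- .censoring_rate(h, censoring_fraction)
    t_cens <- stats::rexp(2L * n_per_group, rc)
  } else {
    t_cens <- rep(Inf, 2L * n_per_group)
  }
  data.frame(
    time_months = pmax(pmin(t_event, t_cens), 1e-6),
    event = as.integer(t_event <= t_cens),
    group = factor(rep(c("low", "high"), each = n_per_group),
                   levels = c("high", "low")))
}
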