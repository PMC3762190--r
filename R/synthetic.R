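# Truncated-normal utilities ------------------------------------------------

# Closed-form mean/variance of N(mu, sigma) truncated to [a, b]; vectorised
# over all arguments.
tn_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  dal <- dnorm(al); dbe <- dnorm(be)
  m <- mu + sigma * (dal - dbe) / z
  v <- sigma^2 * (1 + (al * dal - be * dbe) / z - ((dal - dbe) / z)^2)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

# Inverse-CDF sampler; `a`/`b` may be vectors (per-draw bounds).
rtn <- function(n, mu, sigma, a, b) {
  pa <- pnorm(a, mu, sigma)
  pb <- pnorm(b, mu, sigma)
  qnorm(pa + runif(n) * (pb - pa), mu, sigma)
}

# Find (mu, sigma) such that the truncated distribution has the target
# mean and sd. Plain truncation at the observed range biases the mean (a
# bound close to the mean pulls it away), so the underlying parameters are
# solved for, not copied from the targets.
calibrate_tn <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    m <- tn_moments(par[1], exp(par[2]), a, b)
    (m$mean - target_mean)^2 / target_sd^2 + (m$sd - target_sd)^2 / target_sd^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = a, upper = b,
       target_mean = target_mean, target_sd = target_sd)
}

# Log-normal truncated to [a, b], parameters solved so the truncated
# distribution has the target median and mean (right-skewed lab values).
calibrate_lnorm <- function(target_median, target_mean, a, b) {
  trunc_stats <- function(mu, sigma) {
    pa <- plnorm(a, mu, sigma); pb <- plnorm(b, mu, sigma)
    med <- qlnorm((pa + pb) / 2, mu, sigma)
    s2 <- sigma^2
    mn <- exp(mu + s2 / 2) *
      (pnorm((log(b) - mu - s2) / sigma) - pnorm((log(a) - mu - s2) / sigma)) /
      (pb - pa)
    c(median = med, mean = mn)
  }
  obj <- function(par) {
    s <- trunc_stats(par[1], exp(par[2]))
    (s["median"] - target_median)^2 + (s["mean"] - target_mean)^2
  }
  fit <- optim(c(log(target_median), log(0.5)), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = a, upper = b,
       target_median = target_median, target_mean = target_mean)
}

rlnorm_trunc <- function(n, cal) {
  pa <- plnorm(cal$lower, cal$mu, cal$sigma)
  pb <- plnorm(cal$upper, cal$mu, cal$sigma)
  qlnorm(pa + runif(n) * (pb - pa), cal$mu, cal$sigma)
}

# Diastolic pressure is drawn conditionally below the same patient's
# systolic pressure, which shifts its marginal moments; calibrate the
# underlying parameters against the *constrained* marginal, integrating the
# per-systolic truncated moments over the systolic distribution.
calibrate_dbp <- function(target_mean, target_sd, a, b, sbp_cal) {
  ngrid <- 400
  edges <- seq(sbp_cal$lower, sbp_cal$upper, length.out = ngrid + 1)
  mid <- (edges[-1] + edges[-(ngrid + 1)]) / 2
  pa <- pnorm(sbp_cal$lower, sbp_cal$mu, sbp_cal$sigma)
  pb <- pnorm(sbp_cal$upper, sbp_cal$mu, sbp_cal$sigma)
  w <- dnorm(mid, sbp_cal$mu, sbp_cal$sigma) * diff(edges) / (pb - pa)
  w <- w / sum(w)
  ub <- pmin(b, mid)
  obj <- function(par) {
    m <- tn_moments(par[1], exp(par[2]), a, ub)
    mean_marg <- sum(w * m$mean)
    m2 <- sum(w * (m$sd^2 + m$mean^2))
    sd_marg <- sqrt(m2 - mean_marg^2)
    (mean_marg - target_mean)^2 / target_sd^2 +
      (sd_marg - target_sd)^2 / target_sd^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = a, upper = b,
       target_mean = target_mean, target_sd = target_sd)
}

# Cohort specification -------------------------------------------------------

#' Synthetic cohort specification
#'
#' Distribution parameters for the synthetic CAP inpatient cohort. The
#' defaults reproduce the marginal structure of a published 95-patient
#' respiratory-admissions audit: a middle-aged cohort (mean age 58.8, sd
#' 18.75, range 17-96), 56.8% male, 28.4% confused on admission,
#' right-skewed urea (median 6.65, mean 7.9 mmol/L), and vital signs
#' consistent with acute pneumonia (respiratory rate 24.2 +/- 6.46,
#' systolic BP 130.8 +/- 27.0, diastolic BP 72.9 +/- 14.4, heart rate
#' 101.9 +/- 19.4, temperature 37.78 +/- 1.18). Outcome rates are
#' calibrated to about 8 deaths and 11-12 death-or-ICU composite events
#' per 95 patients, with death and ICU admission linked through a shared
#' latent severity burden and a shared patient-level frailty so that ICU
#' patients are also at high risk of death.
#'
#' Continuous variables are truncated normals (urea a truncated
#' log-normal) whose underlying parameters are solved numerically so that
#' the *truncated* distribution matches the target moments — plain
#' truncation at the observed range would bias every mean toward the
#' centre of the range. Diastolic pressure is additionally constrained
#' below the same patient's systolic pressure and calibrated against that
#' constrained marginal. Variables are otherwise independent: the source
#' table reports only marginals, and no joint structure is assumed beyond
#' the systolic/diastolic ordering and the outcome model.
#'
#' @param n Cohort size (default 95).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @param age,resp_rate,sbp,dbp,heart_rate,temperature Named lists
#'   `list(mean =, sd =, lower =, upper =)` overriding the defaults.
#' @param urea Named list `list(median =, mean =, lower =, upper =)`.
#' @param p_male,p_confusion Bernoulli rates.
#' @param outcome Named list with `slope` (log-odds per SD of latent
#'   burden), `frailty_sd` (SD of the shared patient-level log-odds
#'   frailty), `death_rate` (marginal death target) and `composite_rate`
#'   (death-or-ICU target, at least `death_rate`).
#' @param missing Named list of per-field missing-completely-at-random
#'   rates (fields `urea`, `confusion`).
#' @return A `cap_cohort_spec` object (list) with calibrated sampling
#'   parameters.
#' @examples
#' spec <- cohort_spec(n = 95, seed = 1)
#' cohort <- generate_cohort(spec)
#' @export
cohort_spec <- function(n = 95, seed = 1,
                        age = list(mean = 58.8, sd = 18.752, lower = 17, upper = 96),
                        p_male = 54 / 95,
                        p_confusion = 27 / 95,
                        urea = list(median = 6.65, mean = 7.9, lower = 1, upper = 30.9),
                        resp_rate = list(mean = 24.2, sd = 6.455, lower = 10, upper = 40),
                        sbp = list(mean = 130.8, sd = 26.995, lower = 75, upper = 208),
                        dbp = list(mean = 72.9, sd = 14.409, lower = 40, upper = 113),
                        heart_rate = list(mean = 101.86, sd = 19.38, lower = 56, upper = 170),
                        temperature = list(mean = 37.78, sd = 1.1756, lower = 33.4, upper = 40),
                        outcome = list(slope = 1.6, frailty_sd = 2,
                                       death_rate = 8 / 95,
                                       composite_rate = 11.5 / 95),
                        missing = list(urea = 0.01, confusion = 0.01)) {
  if (n < 1) abort("`n` must be at least 1")
  rates <- c(p_male, p_confusion, outcome$death_rate, outcome$composite_rate,
             missing$urea, missing$confusion)
  if (any(rates < 0 | rates > 1)) abort("All rates must lie in [0, 1]")
  for (v in list(age, urea, resp_rate, sbp, dbp, heart_rate, temperature)) {
    if (v$lower >= v$upper) abort("Truncation bounds must satisfy lower < upper")
  }
  sbp_cal <- calibrate_tn(sbp$mean, sbp$sd, sbp$lower, sbp$upper)
  structure(list(
    n = as.integer(n), seed = seed,
    p_male = p_male, p_confusion = p_confusion,
    age = calibrate_tn(age$mean, age$sd, age$lower, age$upper),
    urea = calibrate_lnorm(urea$median, urea$mean, urea$lower, urea$upper),
    resp_rate = calibrate_tn(resp_rate$mean, resp_rate$sd,
                             resp_rate$lower, resp_rate$upper),
    sbp = sbp_cal,
    dbp = calibrate_dbp(dbp$mean, dbp$sd, dbp$lower, dbp$upper, sbp_cal),
    heart_rate = calibrate_tn(heart_rate$mean, heart_rate$sd,
                              heart_rate$lower, heart_rate$upper),
    temperature = calibrate_tn(temperature$mean, temperature$sd,
                               temperature$lower, temperature$upper),
    outcome = outcome, missing = missing
  ), class = "cap_cohort_spec")
}

#' @export
print.cap_cohort_spec <- function(x, ...) {
  cat("<cap_cohort_spec> n =", x$n, " seed =", x$seed, "\n")
  cat(sprintf("  death rate %.3f, composite rate %.3f, burden slope %.2f, frailty sd %.2f\n",
              x$outcome$death_rate, x$outcome$composite_rate,
              x$outcome$slope, x$outcome$frailty_sd))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [cohort_spec()], attaches outcomes with
#' [attach_outcomes()], then applies missing-completely-at-random masking
#' to urea and confusion. Deterministic given the seed; all randomness
#' flows from one seeded generator and the global RNG state is restored
#' afterwards.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A tibble with one row per patient and the cohort columns (see
#'   [read_cohort()] for the schema).
#' @examples
#' generate_cohort(cohort_spec(n = 10, seed = 99))
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cap_cohort_spec"))
  n <- spec$n
  withr::with_seed(seed, {
    draw <- function(cal) rtn(n, cal$mu, cal$sigma, cal$lower, cal$upper)
    sbp <- draw(spec$sbp)
    cohort <- tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      age = round(draw(spec$age), 1),
      sex = ifelse(runif(n) < spec$p_male, "male", "female"),
      confusion = as.integer(runif(n) < spec$p_confusion),
      urea = rlnorm_trunc(n, spec$urea),
      resp_rate = as.integer(round(draw(spec$resp_rate))),
      sbp = sbp,
      dbp = rtn(n, spec$dbp$mu, spec$dbp$sigma, spec$dbp$lower,
                pmin(spec$dbp$upper, sbp)),
      heart_rate = draw(spec$heart_rate),
      temperature = draw(spec$temperature)
    )
    cohort <- attach_outcomes(cohort, spec)
    if (spec$missing$urea > 0) {
      cohort$urea[runif(n) < spec$missing$urea] <- NA_real_
    }
    if (spec$missing$confusion > 0) {
      cohort$confusion[runif(n) < spec$missing$confusion] <- NA_integer_
    }
    cohort
  })
}

#' Attach outcomes to a generated cohort
#'
#' Assigns 6-week death and ICU-admission indicators from a logistic model
#' in a latent severity burden: a fixed-weight standardised combination of
#' confusion, log-urea, respiratory rate, shock index and age — the
#' physiology the severity criteria are built on — plus a shared
#' patient-level frailty that correlates the two outcomes (severely ill
#' patients tend to contribute to both). Intercepts are calibrated on the
#' cohort at hand: the death intercept so the expected death count equals
#' `n * death_rate` exactly, and the ICU intercept so the expected
#' death-or-ICU composite count equals `n * composite_rate`; realised
#' counts are binomial around those targets.
#'
#' Consumes random draws, so call it inside a seeded context;
#' [generate_cohort()] does this automatically.
#'
#' @param cohort A cohort tibble (before missingness masking).
#' @param spec The [cohort_spec()] that generated it.
#' @return The cohort with integer columns `died_6wk` and `icu_6wk`.
#' @export
attach_outcomes <- function(cohort, spec) {
  z <- severity_burden(cohort)
  n <- nrow(cohort)
  oc <- spec$outcome
  if (oc$composite_rate < oc$death_rate) {
    abort("`composite_rate` cannot be below `death_rate`")
  }
  frailty <- stats::rnorm(n, 0, 1)
  eta <- oc$slope * z + oc$frailty_sd * frailty
  a_death <- calibrate_intercept(eta, oc$death_rate)
  p_death <- plogis(a_death + eta)
  # ICU intercept calibrated against the death-or-ICU composite rate:
  # E[death or ICU] = E[p_d + (1 - p_d) p_i] given the shared predictor
  a_icu <- if (oc$composite_rate == oc$death_rate) -Inf else {
    uniroot(function(a) {
      mean(p_death + (1 - p_death) * plogis(a + eta)) - oc$composite_rate
    }, lower = -40, upper = 40, tol = 1e-10)$root
  }
  cohort$died_6wk <- rbinom(n, 1, plogis(a_death + eta))
  cohort$icu_6wk <- rbinom(n, 1, plogis(a_icu + eta))
  cohort
}

# Latent severity burden: fixed reference standardisation (cohort-level
# targets, not sample moments) so the burden scale does not depend on n.
severity_burden <- function(cohort) {
  si <- cohort$heart_rate / cohort$sbp
  w <- c(confusion = 1.0, urea = 0.7, resp = 0.7, si = 0.7, age = 0.4)
  z <- w["confusion"] * (cohort$confusion - 0.284) / 0.45 +
    w["urea"] * (log(cohort$urea) - log(6.65)) / 0.55 +
    w["resp"] * (cohort$resp_rate - 24.2) / 6.46 +
    w["si"] * (si - 0.78) / 0.18 +
    w["age"] * (cohort$age - 58.8) / 18.75
  unname(z / sqrt(sum(w^2)))
}

# Solve the logistic intercept so the mean event probability over the
# cohort's linear predictors equals the target rate.
calibrate_intercept <- function(eta, rate) {
  if (rate == 0) return(-Inf)
  if (rate == 1) return(Inf)
  uniroot(function(a) mean(plogis(a + eta)) - rate,
          lower = -40, upper = 40, tol = 1e-10)$root
}
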