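# Shared fixtures and independent oracles.

# One cohort row with benign defaults; override any field.
make_record <- function(patient_id = "P1", age = 50, sex = "male",
                        confusion = 0L, urea = 5, resp_rate = 20L,
                        sbp = 130, dbp = 80, heart_rate = 80,
                        temperature = 37, died_6wk = 0L, icu_6wk = 0L) {
  tibble::tibble(
    patient_id = patient_id, age = age, sex = sex,
    confusion = as.integer(confusion), urea = urea,
    resp_rate = as.integer(resp_rate), sbp = sbp, dbp = dbp,
    heart_rate = heart_rate, temperature = temperature,
    died_6wk = as.integer(died_6wk), icu_6wk = as.integer(icu_6wk)
  )
}

# Brute-force continuity-corrected Wilson bounds: root of the CC score
# equation, found numerically. Independent of the closed form in the
# package.
wilson_cc_brute <- function(s, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- s / n
  lower <- if (s == 0) 0 else {
    uniroot(function(p) (phat - p - 1 / (2 * n)) - z * sqrt(p * (1 - p) / n),
            lower = 1e-12, upper = phat, tol = 1e-12)$root
  }
  upper <- if (s == n) 1 else {
    uniroot(function(p) (p - phat - 1 / (2 * n)) - z * sqrt(p * (1 - p) / n),
            lower = phat, upper = 1 - 1e-12, tol = 1e-12)$root
  }
  c(lower = max(0, lower), upper = min(1, upper))
}

# Brute-force exact two-sided signed-rank p-value: enumerate every sign
# assignment of the non-zero differences (midranks for ties).
wilcoxon_exact_brute <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
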