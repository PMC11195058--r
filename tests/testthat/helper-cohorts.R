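# Shared fixture builders: everything is generated in code at test time.

three_organ_config <- function(n = 500, seed = 11, ...) {
  simulation_config(
    n_subjects = n,
    organs = c("brain", "heart", "kidney"),
    n_proteins_per_organ = 8,
    n_organismal_proteins = 12,
    seed = seed, ...)
}

# Cohort with a single strong planted heart mortality effect; gamma/delta 0
# so the marginal per-SD HR of the heart gap equals the planted coefficient.
heart_hr_cohort <- function(n = 5000, hr = 1.8, baseline = 0.013, seed = 7) {
  cfg <- three_organ_config(
    n = n, seed = seed,
    hazard_specs = list(death = hazard_spec(
      c(heart = log(hr)), baseline_hazard = baseline,
      age_coef = 0, sex_coef = 0)))
  generate_cohort(cfg)
}

# Standardized matrix where one protein equals age exactly and the rest are
# pure noise; returns list(x, age).
perfect_signal_matrix <- function(n = 300, p_noise = 10, seed = 5) {
  with_seed_local(seed, {
    age <- runif(n, 40, 70)
    x <- cbind(signal = age,
               matrix(rnorm(n * p_noise), n,
                      dimnames = list(NULL, sprintf("noise%02d", 1:p_noise))))
    rownames(x) <- sprintf("S%04d", seq_len(n))
    list(x = x, age = age)
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Brute-force Cox partial log-likelihood (no ties) for the grid-search oracle.
cox_partial_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
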