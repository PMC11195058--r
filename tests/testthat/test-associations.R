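test_that("Cox log HR matches a grid-search partial-likelihood oracle", {
  time <- c(1, 2, 3, 4, 5, 6)
  status <- c(1, 0, 1, 1, 0, 1)
  x <- c(0.5, -1.2, 1.8, -0.3, 0.9, -1.5)
  rec <- data.frame(time = time, status = status)
  res <- cox_association(x, rec, covariates = character(0), name = "x")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               time = time, status = status, x = x)
  beta_oracle <- grid[which.max(ll)]
  expect_lt(abs(res$estimate - beta_oracle), 1e-3)
})

test_that("a planted per-SD hazard ratio of 1.8 is recovered", {
  ch <- heart_hr_cohort(n = 5000, hr = 1.8, seed = 50)
  rec <- data.frame(time = ch$events$death$time, status = ch$events$death$status,
                    age = ch$visits$age[ch$visits$visit == 1],
                    sex = ch$subjects$sex)
  expect_gt(mean(rec$status), 0.15); expect_lt(mean(rec$status), 0.3)
  res <- cox_association(gap_matrix(ch)[, "heart"], rec, name = "heart")
  expect_gt(res$hr, 1.65); expect_lt(res$hr, 1.96)
})

test_that("null Cox confidence intervals achieve nominal coverage", {
  covered <- vapply(1:200, function(r) {
    with_seed_local(1000 + r, {
      n <- 5000
      x <- rnorm(n)
      t_ev <- rexp(n, 0.05)
      rec <- data.frame(time = pmin(t_ev, 17),
                        status = as.integer(t_ev <= 17),
                        age = runif(n, 40, 70), sex = rbinom(n, 1, 0.5))
      res <- cox_association(x, rec, name = "null")
      res$ci_low <= 1 && res$ci_high >= 1
    })
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("categorical exposures are contrasted against the reference group", {
  with_seed_local(51, {
    n <- 3000
    grp <- factor(sample(c("normal", "aged"), n, TRUE, prob = c(0.7, 0.3)),
                  levels = c("normal", "aged"))
    lp <- log(2) * (grp == "aged")
    t_ev <- rexp(n, 0.03 * exp(lp))
    rec <- data.frame(time = pmin(t_ev, 17), status = as.integer(t_ev <= 17),
                      age = runif(n, 40, 70), sex = rbinom(n, 1, 0.5))
    res <- cox_association(grp, rec, name = "ageotype")
    expect_equal(res$exposure, "ageotype:aged")
    expect_gt(res$hr, 1.6); expect_lt(res$hr, 2.5)
  })
})

test_that("degenerate endpoints are flagged rather than estimated", {
  rec <- data.frame(time = 1:6, status = rep(0, 6),
                    age = rep(50, 6), sex = rep(0, 6))
  res <- cox_association(rnorm(6), rec, name = "x")
  expect_true(res$flagged)
  expect_true(is.na(res$estimate))
})

test_that("linear association recovers a planted exposure effect of 0.3", {
  with_seed_local(52, {
    n <- 10000
    age <- runif(n, 40, 70); sex <- rbinom(n, 1, 0.5)
    expos <- rnorm(n)
    gap <- 0.3 * expos + 0.05 * sex + rnorm(n)
    res <- linear_association(gap, expos,
                              covariates = data.frame(age = age, sex = sex))
    expect_lt(abs(res$estimate - 0.3), 0.03)
    # null exposure: CI covers 0
    res0 <- linear_association(gap, rnorm(n),
                               covariates = data.frame(age = age, sex = sex))
    expect_true(res0$ci_low <= 0 && res0$ci_high >= 0)
  })
})

test_that("two-predictor OLS matches the closed-form normal equations", {
  with_seed_local(53, {
    n <- 40
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- 1.5 * x1 - 0.7 * x2 + rnorm(n)
    res <- linear_association(y, data.frame(menopause = x1, estrogen = x2))
    X <- cbind(1, x1, x2)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(res$estimate, unname(beta[2:3]), tolerance = 1e-10)
  })
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  x <- rnorm(50)
  expect_error(
    linear_association(rnorm(50), data.frame(a = x, b = 2 * x)),
    "rank deficient.*b")
})

test_that("BH adjustment matches hand step-up arithmetic", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.037), 0.037)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  with_seed_local(54, {
    p <- runif(30)
    q <- adjust_bh(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
    expect_true(all(q <= 1))
  })
})

test_that("the Gini of log hazard ratios matches the pairwise oracle", {
  expect_equal(gini_of_log_hazards(c(0.5, 0.5, 0.5, 0.5))$gini, 0)
  expect_equal(gini_of_log_hazards(c(0, 0, 0, 1))$gini, 0.75)
  with_seed_local(55, {
    for (i in 1:5) {
      x <- runif(4)
      g <- gini_of_log_hazards(x)$gini
      # independent Lorenz-ordering oracle
      xs <- sort(x)
      oracle <- 2 * sum(seq_along(xs) * xs) / (length(xs) * sum(xs)) -
        (length(xs) + 1) / length(xs)
      expect_equal(g, oracle, tolerance = 1e-12)
      expect_equal(gini_of_log_hazards(2 * x)$gini, g, tolerance = 1e-12)
      expect_true(g >= 0 && g < 1)
    }
  })
  # negative values are clipped to zero before the ratio
  expect_equal(gini_of_log_hazards(c(-0.5, 0, 0, 1))$gini, 0.75)
  allneg <- gini_of_log_hazards(c(-1, -2))
  expect_true(allneg$flagged && is.na(allneg$gini))
  # mass concentrating on fewer organs raises G
  expect_gt(gini_of_log_hazards(c(0, 0, 0, 1))$gini,
            gini_of_log_hazards(c(0.25, 0.25, 0.25, 1))$gini)
})

test_that("a single-organ-driven endpoint has higher Gini than a systemic one", {
  organs <- default_organs()
  beta_sys <- setNames(rep(log(1.3), length(organs)), organs)
  cfg <- simulation_config(
    n_subjects = 4000, organs = organs, n_proteins_per_organ = 1,
    n_organismal_proteins = 1, seed = 56,
    hazard_specs = list(
      alzheimers = hazard_spec(c(brain = log(1.9)), baseline_hazard = 0.01),
      systemic = hazard_spec(beta_sys, baseline_hazard = 0.005)))
  ch <- generate_cohort(cfg)
  g <- gap_matrix(ch)
  base <- data.frame(age = ch$visits$age[ch$visits$visit == 1],
                     sex = ch$subjects$sex)
  gini_for <- function(endpoint) {
    rec <- cbind(ch$events[[endpoint]][, c("time", "status")], base)
    loghr <- vapply(organs, function(o)
      cox_association(g[, o], rec, name = o)$estimate, numeric(1))
    gini_of_log_hazards(loghr)$gini
  }
  expect_gt(gini_for("alzheimers"), gini_for("systemic"))
})

test_that("penalized mortality models rank feature sets by information content", {
  cfg <- simulation_config(
    n_subjects = 5000, organs = c("brain", "heart", "kidney"),
    n_proteins_per_organ = 1, n_organismal_proteins = 1, seed = 57,
    hazard_specs = list(death = hazard_spec(
      c(brain = log(1.5), heart = log(1.4), kidney = log(1.3)),
      baseline_hazard = 0.006)))
  ch <- generate_cohort(cfg)
  g <- gap_matrix(ch)
  with_seed_local(58, {
    dat <- data.frame(time = ch$events$death$time,
                      status = ch$events$death$status,
                      age = ch$visits$age[ch$visits$visit == 1],
                      sex = as.numeric(ch$subjects$sex == "male"),
                      brain = g[, "brain"], heart = g[, "heart"],
                      kidney = g[, "kidney"], noise = rnorm(5000))
    tr <- 1:3000; te <- 3001:5000
    cmp <- compare_mortality_models(
      dat, list(organ_gaps = c("brain", "heart", "kidney"), noise = "noise"),
      train_idx = tr, test_idx = te)
    cc <- cmp$concordance
    c_gaps <- cc$concordance_test[cc$model == "organ_gaps"]
    # oracle: concordance of the true linear predictor on the test split
    lp <- ch$truth$event_lp$death
    y_te <- survival::Surv(dat$time[te], dat$status[te])
    c_oracle <- survival::concordance(y_te ~ lp[te], reverse = TRUE)$concordance
    expect_lt(abs(c_gaps - c_oracle), 0.02)
    # age+sex-only baseline fitted directly; organ gaps must add signal
    base_fit <- survival::coxph(survival::Surv(time, status) ~ age + sex,
                                data = dat[tr, ])
    lp_base <- predict(base_fit, newdata = dat[te, ])
    c_base <- survival::concordance(y_te ~ lp_base, reverse = TRUE)$concordance
    expect_gt(c_gaps - c_base, 0.01)
    expect_error(compare_mortality_models(dat, list(empty = character(0)),
                                          tr, te), "non-empty")
  })
})

test_that("a pure-noise feature set has chance-level test concordance", {
  with_seed_local(59, {
    n <- 5000
    dat <- data.frame(time = pmin(t <- rexp(n, 0.05), 17),
                      status = as.integer(t <= 17),
                      age = rep(55, n), sex = rbinom(n, 1, 0.5),
                      noise = rnorm(n))
    # age constant and sex null -> only the noise feature can rank subjects
    cmp <- compare_mortality_models(dat, list(noise = "noise"),
                                    train_idx = 1:2500, test_idx = 2501:n,
                                    covariates = "sex")
    c_te <- cmp$concordance$concordance_test[1]
    expect_gt(c_te, 0.47); expect_lt(c_te, 0.53)
  })
})

test_that("Kaplan-Meier estimates match hand product-limit arithmetic", {
  rec <- data.frame(time = c(2, 3, 4, 5, 6), status = c(1, 0, 1, 0, 0))
  km <- km_curve(rec)
  s_at <- function(t) km$survival[km$time == t]
  expect_equal(s_at(2), 4 / 5)
  expect_equal(s_at(4), (4 / 5) * (2 / 3))
  expect_equal(km$cum_incidence, 1 - km$survival)
  # no events: survival stays 1
  rec0 <- data.frame(time = 1:5, status = rep(0, 5))
  expect_true(all(km_curve(rec0)$survival == 1))
  # censoring after the last event leaves S at event times unchanged
  rec2 <- data.frame(time = c(2, 3, 4, 50, 60), status = c(1, 0, 1, 0, 0))
  km2 <- km_curve(rec2)
  expect_equal(km2$survival[km2$time == 4], km$survival[km$time == 4])
  # per-group curves
  grp <- c("a", "a", "b", "b", "b")
  kmg <- km_curve(rec, grp)
  expect_setequal(unique(kmg$group), c("a", "b"))
})

test_that("per-SD Cox estimates are invariant to affine exposure rescaling", {
  ch <- heart_hr_cohort(n = 2000, hr = 1.5, seed = 60)
  rec <- data.frame(time = ch$events$death$time, status = ch$events$death$status,
                    age = ch$visits$age[ch$visits$visit == 1],
                    sex = ch$subjects$sex)
  x <- gap_matrix(ch)[, "heart"]
  z1 <- as.numeric(scale(x))
  z2 <- as.numeric(scale(100 + 7 * x))
  r1 <- cox_association(z1, rec, name = "a")
  r2 <- cox_association(z2, rec, name = "b")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
})
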