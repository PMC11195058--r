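test_that("a perfect-signal protein yields near-perfect age prediction", {
  d <- perfect_signal_matrix(n = 300, p_noise = 10, seed = 30)
  clock <- fit_clock(d$x, d$age, name = "toy", seed = 1)
  expect_true(clock$predictive)
  expect_true("signal" %in% names(clock$weights))
  d2 <- perfect_signal_matrix(n = 200, p_noise = 10, seed = 31)
  pred <- predict_age(clock, d2$x)
  expect_gte(cor(pred, d2$age), 0.99)
})

test_that("an all-noise panel is flagged non-predictive with gaps disabled", {
  with_seed_local(32, {
    x <- matrix(rnorm(200 * 15), 200, 15,
                dimnames = list(NULL, sprintf("n%02d", 1:15)))
    age <- runif(200, 40, 70)
    clock <- fit_clock(x, age, name = "noise", seed = 2)
    expect_false(clock$predictive)
    expect_error(compute_age_gaps(clock, predict_age(clock, x), age),
                 "non-predictive")
  })
})

test_that("the 95% rule picks a model at least as sparse as the CV optimum", {
  ch <- generate_cohort(three_organ_config(n = 500, seed = 33))
  x <- scale(ch$proteome[[1]])
  age <- ch$visits$age[ch$visits$visit == 1]
  tr <- 1:350; te <- 351:500
  clock95 <- fit_clock(x[tr, ], age[tr], name = "c95",
                       perf_fraction = 0.95, seed = 3)
  clock_opt <- fit_clock(x[tr, ], age[tr], name = "opt",
                         perf_fraction = 1.0, seed = 3)
  expect_lte(length(clock95$weights), length(clock_opt$weights))
  expect_gte(clock95$lambda, clock_opt$lambda)
  r2 <- function(cl) cor(predict_age(cl, x[te, ]), age[te])^2
  expect_gte(r2(clock95), 0.95 * r2(clock_opt) - 0.05)
})

test_that("sparsity is monotone non-increasing along the penalty path", {
  d <- perfect_signal_matrix(n = 250, p_noise = 12, seed = 34)
  clock <- fit_clock(d$x, d$age, seed = 4)
  rec <- clock$cv_record  # lambda decreasing down the path
  expect_true(all(diff(rec$nonzero) >= 0))
})

test_that("prediction is a deterministic linear combination", {
  cl <- clock_model("toy", weights = c(p1 = 2), intercept = 50)
  x <- matrix(c(3, 0), 2, 1, dimnames = list(c("a", "b"), "p1"))
  expect_equal(unname(predict_age(cl, x)), c(56, 50))
  # batch equals per-row
  x10 <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "p1"))
  batch <- predict_age(cl, x10)
  single <- vapply(1:10, function(i)
    predict_age(cl, x10[i, , drop = FALSE])[[1]], numeric(1))
  expect_equal(unname(batch), single)
  expect_error(predict_age(cl, matrix(0, 1, 1, dimnames = list(NULL, "q"))),
               "p1")
})

test_that("age gaps are residuals of predicted age on actual age", {
  age <- c(41, 45, 50, 55, 60, 68)
  # predicted = actual: all gaps zero
  cl <- clock_model("id", weights = c(p = 1), intercept = 0,
                    residualizer = c(0, 1))
  g0 <- compute_age_gaps(cl, age, age)
  expect_equal(g0$gap, rep(0, 6))
  # constant offset absorbed by the residualizer intercept
  cl5 <- clock_model("off", weights = c(p = 1), intercept = 0,
                     residualizer = c(5, 1))
  g5 <- compute_age_gaps(cl5, age + 5, age)
  expect_equal(g5$gap, rep(0, 6))
  # toy residualizer fitted here equals closed-form OLS residuals
  with_seed_local(35, {
    pred <- 0.8 * age + 12 + rnorm(6, 0, 2)
    b <- cov(pred, age) / var(age); a <- mean(pred) - b * mean(age)
    clt <- clock_model("t", weights = c(p = 1), intercept = 0,
                       residualizer = c(a, b))
    gt <- compute_age_gaps(clt, pred, age)
    expect_equal(gt$gap, pred - (a + b * age), tolerance = 1e-12)
    expect_lt(abs(sum(gt$gap)), 1e-9)
  })
})

test_that("training z-gaps are standardized and orthogonal to age", {
  ch <- generate_cohort(three_organ_config(n = 400, seed = 36))
  x <- scale(ch$proteome[[1]])
  age <- ch$visits$age[ch$visits$visit == 1]
  clock <- fit_clock(x, age, name = "brainish", seed = 5)
  g <- compute_age_gaps(clock, predict_age(clock, x), age)
  expect_lt(abs(mean(g$z_gap)), 1e-9)
  expect_lt(abs(sd(g$z_gap) - 1), 1e-9)
  expect_lt(abs(cor(g$gap, age)), 1e-6)
})

test_that("clocks recover latent gaps and degrade monotonically with noise", {
  r_for_noise <- function(noise_sd, seed) {
    cfg <- three_organ_config(n = 900, seed = seed,
                              protein_noise_sd = noise_sd)
    ch <- generate_cohort(cfg)
    x <- ch$proteome[[1]]
    age <- ch$visits$age[ch$visits$visit == 1]
    tr <- 1:600; te <- 601:900
    sc <- fit_scaler(x[tr, ])
    xs <- apply_scaler(sc, x)
    ld <- ch$truth$loadings
    clock <- fit_clock(xs[tr, ], age[tr],
                       panel = ld$protein[ld$organ == "heart"],
                       name = "heart", seed = 6)
    z <- compute_age_gaps(clock, predict_age(clock, xs[te, ]), age[te])$z_gap
    cor(z, gap_matrix(ch)[te, "heart"])
  }
  r_low <- r_for_noise(0.3, 37)
  r_high <- r_for_noise(2.5, 37)
  expect_gte(r_low, 0.7)
  expect_lt(r_high, r_low)
})

test_that("performance is stable across simulated train and test centres", {
  ch <- generate_cohort(three_organ_config(n = 1500, seed = 38))
  samples <- data.frame(sample_id = ch$subjects$subject_id,
                        center = ch$subjects$center)
  sp <- split_by_center(samples, sort(unique(samples$center))[1:10])
  pp <- preprocess(ch$proteome[[1]], sp)
  age <- setNames(ch$visits$age[ch$visits$visit == 1],
                  ch$subjects$subject_id)
  clock <- fit_clock(pp$train, age[rownames(pp$train)], name = "conv", seed = 7)
  r_tr <- cor(predict_age(clock, pp$train), age[rownames(pp$train)])
  r_te <- cor(predict_age(clock, pp$test), age[rownames(pp$test)])
  expect_lte(abs(r_tr - r_te), 0.05)
})

test_that("the meta-clock recovers planted organ-age weights", {
  with_seed_local(39, {
    n <- 800
    organ_ages <- cbind(organismal = runif(n, 40, 70),
                        brain = runif(n, 40, 70),
                        artery = runif(n, 40, 70))
    # conventional age identical to organismal -> all weight on organismal
    m1 <- fit_meta_clock(organ_ages, organ_ages[, "organismal"])
    expect_gte(m1$relative_weights[["organismal"]], 0.99)
    expect_gte(m1$r_squared, 0.999)
    # planted mixture recovered within 0.02
    target <- 0.7 * organ_ages[, "organismal"] + 0.2 * organ_ages[, "brain"] +
      0.1 * organ_ages[, "artery"]
    m2 <- fit_meta_clock(organ_ages, target)
    expect_lt(max(abs(unname(m2$relative_weights) - c(0.7, 0.2, 0.1))), 0.02)
    # permuting a non-contributing column leaves weights unchanged
    oa <- cbind(organ_ages, muscle = runif(n, 40, 70))
    m3 <- fit_meta_clock(oa, target)
    oa_p <- oa; oa_p[, "muscle"] <- sample(oa_p[, "muscle"])
    m4 <- fit_meta_clock(oa_p, target)
    expect_lt(max(abs(m3$relative_weights[1:3] - m4$relative_weights[1:3])),
              0.01)
    expect_error(fit_meta_clock(organ_ages[, 1, drop = FALSE], target), "2")
  })
})

test_that("distillation onto the parent's own proteins is retained near r=1", {
  d <- perfect_signal_matrix(n = 500, p_noise = 8, seed = 40)
  tr <- 1:350; te <- 351:500
  parent <- fit_clock(d$x[tr, ], d$age[tr], name = "parent", seed = 8)
  nz <- names(parent$weights)
  child <- distill_clock(parent, d$x[tr, ], d$age[tr], d$x[te, ], d$age[te],
                         reduced_panel = nz, seed = 9)
  expect_true(inherits(child, "clock_model") && child$retained)
  expect_gte(child$parent_cor, 0.999)
})

test_that("distillation onto pure noise is dropped with a record", {
  d <- perfect_signal_matrix(n = 400, p_noise = 6, seed = 41)
  tr <- 1:250; te <- 251:400
  parent <- fit_clock(d$x[tr, ], d$age[tr], name = "parent", seed = 10)
  with_seed_local(42, {
    noise <- matrix(rnorm(400 * 5), 400, 5,
                    dimnames = list(NULL, sprintf("junk%d", 1:5)))
    xall <- cbind(d$x, noise)
    drop <- distill_clock(parent, xall[tr, ], d$age[tr], xall[te, ], d$age[te],
                          reduced_panel = colnames(noise), seed = 11)
    expect_s3_class(drop, "distill_drop")
    expect_false(drop$retained)
    expect_lt(abs(drop$correlation), 0.5)
  })
})

test_that("distillation onto a reduced platform keeps fidelity with fewer features", {
  cfg <- three_organ_config(n = 1200, seed = 43, protein_noise_sd = 0.5)
  ch <- generate_cohort(cfg)
  x <- scale(ch$proteome[[1]])
  age <- ch$visits$age[ch$visits$visit == 1]
  tr <- 1:800; te <- 801:1200
  ld <- ch$truth$loadings
  panel <- ld$protein[ld$organ == "heart"]
  parent <- fit_clock(x[tr, ], age[tr], panel = panel, name = "heart", seed = 12)
  nz <- names(parent$weights)
  reduced <- union(nz[seq_len(ceiling(length(nz) / 2))],
                   ld$protein[ld$organ == "organismal"])
  child <- distill_clock(parent, x[tr, ], age[tr], x[te, ], age[te],
                         reduced_panel = reduced, seed = 13)
  expect_true(inherits(child, "clock_model") && child$retained)
  expect_gte(child$parent_cor, 0.8)
  expect_lte(sum(child$weights != 0), length(reduced))
  expect_error(distill_clock(parent, x[tr, ], age[tr], x[te, ], age[te],
                             reduced_panel = character(0)), "empty")
})

test_that("clock models survive a JSON round trip", {
  d <- perfect_signal_matrix(n = 200, p_noise = 5, seed = 44)
  clock <- fit_clock(d$x, d$age, name = "rt", seed = 14)
  path <- withr::local_tempfile(fileext = ".json")
  write_clock_json(clock, path)
  back <- read_clock_json(path)
  expect_equal(back$weights, clock$weights)
  expect_equal(back$residualizer, clock$residualizer)
  expect_equal(predict_age(back, d$x), predict_age(clock, d$x))
})
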