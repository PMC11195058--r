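#' Default organ list
#'
#' The eleven major organs modelled by the clocks, in alphabetical order.
#' @return Character vector of organ names.
#' @export
default_organs <- function() {
  c("adipose", "artery", "brain", "heart", "immune", "intestine",
    "kidney", "liver", "lung", "muscle", "pancreas")
}

#' Per-endpoint proportional-hazards specification
#'
#' Describes how one endpoint's event times are generated: a per-SD log hazard
#' ratio for each latent gap factor, a constant (exponential) baseline hazard,
#' log-linear age and sex terms, and an administrative censoring horizon.
#'
#' @param log_hr Named numeric vector of per-SD log hazard ratios; names must
#'   be latent factors of the cohort (organ names or `"organismal"`). Factors
#'   not named get coefficient 0.
#' @param baseline_hazard Constant baseline hazard rate (events per year) at
#'   the age reference; must be > 0.
#' @param horizon Administrative censoring horizon in years (default 17).
#' @param age_coef Log hazard ratio per year of baseline age (centred at
#'   `age_center`).
#' @param sex_coef Log hazard ratio for males versus females.
#' @param age_center Centring age in years for the age term.
#' @return An object of class `hazard_spec`.
#' @export
hazard_spec <- function(log_hr, baseline_hazard = 0.004, horizon = 17,
                        age_coef = 0.08, sex_coef = log(1.4), age_center = 55) {
  stopifnot(is.numeric(log_hr), !is.null(names(log_hr)) || length(log_hr) == 0)
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (horizon <= 0) stop("censoring horizon must be > 0")
  structure(list(log_hr = log_hr, baseline_hazard = baseline_hazard,
                 horizon = horizon, age_coef = age_coef, sex_coef = sex_coef,
                 age_center = age_center),
            class = "hazard_spec")
}

default_hazard_specs <- function(organs) {
  beta <- stats::setNames(rep(log(1.1), length(organs)), organs)
  if ("brain" %in% organs) beta[["brain"]] <- log(1.25)
  list(mortality = hazard_spec(beta))
}

#' Simulation configuration for a synthetic cohort
#'
#' Defines the statistical structure the downstream analysis assumes:
#' uniformly distributed recruitment ages, equicorrelated latent organ age
#' gaps (plus an organismal shared factor), stationary AR(1) gap persistence
#' across visits, a linear proteome emission model, proportional-hazards
#' endpoints, collection centres and completely-at-random missingness.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Recruitment age range in years, `c(low, high)`.
#' @param female_fraction Proportion of females.
#' @param n_centers Number of plasma collection centres (assigned uniformly).
#' @param organs Character vector of organ names.
#' @param n_proteins_per_organ Proteins emitted per organ panel.
#' @param n_organismal_proteins Proteins loading only on age and the shared
#'   organismal factor.
#' @param gap_correlation Pairwise correlation rho of the latent gaps
#'   (equicorrelation; default 0.21). Must satisfy rho > -1/(k-1) for the
#'   k = length(organs) + 1 latent factors.
#' @param gap_cor_matrix Optional full k x k correlation matrix (rows/columns
#'   in the order `c(organs, "organismal")`) overriding the equicorrelation.
#' @param gap_persistence Across-visit AR(1) correlation of the latent gaps
#'   (default 0.6).
#' @param n_visits Number of visits (1 to 3): baseline plus up to two
#'   follow-ups.
#' @param visit_intervals List of `c(mean, sd)` pairs, in years, for the gap
#'   between successive visits; defaults 9.1 (1.8) then 3.3 (1.6).
#' @param hazard_specs Named list of [hazard_spec()] objects, one per
#'   endpoint; default a single all-cause mortality endpoint.
#' @param protein_noise_sd Residual SD of each protein in abundance units.
#' @param age_slope_range Magnitude range of the per-protein age slope
#'   (abundance units per year; sign random).
#' @param gap_years_per_sd Years of apparent chronological aging produced by
#'   one SD of latent gap: each protein responds to the biological age
#'   `age + gap_years_per_sd * gap`, so its gap loading is
#'   `age_slope * gap_years_per_sd`. Setting 0 removes all gap signal.
#' @param sex_effect_sd SD of the per-protein sex effect.
#' @param missing_rate Completely-at-random missingness proportion.
#' @param seed Integer seed; all generator stages derive their streams from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 1000,
                              age_range = c(40, 70),
                              female_fraction = 0.5,
                              n_centers = 21,
                              organs = default_organs(),
                              n_proteins_per_organ = 10,
                              n_organismal_proteins = 30,
                              gap_correlation = 0.21,
                              gap_cor_matrix = NULL,
                              gap_persistence = 0.6,
                              n_visits = 1,
                              visit_intervals = list(c(9.1, 1.8), c(3.3, 1.6)),
                              hazard_specs = NULL,
                              protein_noise_sd = 1,
                              age_slope_range = c(0.02, 0.06),
                              gap_years_per_sd = 10,
                              sex_effect_sd = 0.2,
                              missing_rate = 0,
                              seed = 1) {
  stopifnot(n_subjects >= 1, length(age_range) == 2)
  if (!(age_range[1] < age_range[2])) stop("age_range low must be < high")
  stopifnot(female_fraction >= 0, female_fraction <= 1, n_centers >= 1)
  organs <- as.character(organs)
  if (anyDuplicated(organs)) stop("organ names must be unique")
  k <- length(organs) + 1L  # + organismal shared factor
  if (is.null(gap_cor_matrix)) {
    rho <- gap_correlation
    if (abs(rho) >= 1 || rho <= -1 / (k - 1)) {
      stop(sprintf(
        "gap correlation rho=%g does not give a positive-definite equicorrelation matrix for k=%d latent factors (need -1/(k-1) < rho < 1)",
        rho, k))
    }
  } else {
    if (!isTRUE(all.equal(dim(gap_cor_matrix), c(k, k))))
      stop(sprintf("gap_cor_matrix must be %d x %d (organs + organismal)", k, k))
    ev <- eigen(gap_cor_matrix, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop(sprintf("gap_cor_matrix is not positive definite for k=%d factors", k))
  }
  stopifnot(abs(gap_persistence) < 1)
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  n_visits <- as.integer(n_visits)
  if (n_visits < 1 || n_visits > length(visit_intervals) + 1)
    stop("n_visits must be between 1 and 1 + length(visit_intervals)")
  if (is.null(hazard_specs)) hazard_specs <- default_hazard_specs(organs)
  stopifnot(all(vapply(hazard_specs, inherits, logical(1), "hazard_spec")))
  structure(list(
    n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
    female_fraction = female_fraction, n_centers = as.integer(n_centers),
    organs = organs, n_proteins_per_organ = as.integer(n_proteins_per_organ),
    n_organismal_proteins = as.integer(n_organismal_proteins),
    gap_correlation = gap_correlation, gap_cor_matrix = gap_cor_matrix,
    gap_persistence = gap_persistence, n_visits = n_visits,
    visit_intervals = visit_intervals, hazard_specs = hazard_specs,
    protein_noise_sd = protein_noise_sd,
    age_slope_range = as.numeric(age_slope_range),
    gap_years_per_sd = gap_years_per_sd,
    sex_effect_sd = sex_effect_sd,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "simulation_config")
}

latent_factors <- function(config) c(config$organs, "organismal")

gap_chol <- function(config) {
  k <- length(latent_factors(config))
  S <- config$gap_cor_matrix
  if (is.null(S)) {
    rho <- config$gap_correlation
    S <- matrix(rho, k, k)
    diag(S) <- 1
  }
  chol(S)
}

#' Generate a synthetic cohort bundle
#'
#' Draws subjects (uniform ages within range, sex, uniformly assigned
#' centres), latent organ age gaps from the configured correlated normal with
#' stationary AR(1) persistence across visits, the proteome for every visit,
#' the event table for every configured endpoint, and injects missingness.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return An object of class `cohort_bundle`: a list with `subjects`
#'   (id, sex, center), `visits` (id, visit, age, years_since_baseline),
#'   `gaps` (long latent-gap table), `proteome` (list of matrices, one per
#'   visit, rows = subjects), `events` (named list of per-endpoint tables
#'   with `subject_id`, `time`, `status`), and `truth` (generator ground
#'   truth: loadings, linear predictors, config).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  ids <- sprintf("S%05d", seq_len(n))

  subjects <- with_seed(derive_seed(config$seed, 1), {
    data.frame(
      subject_id = ids,
      sex = ifelse(stats::runif(n) < config$female_fraction, "female", "male"),
      center = sprintf("C%02d", sample.int(config$n_centers, n, replace = TRUE)),
      stringsAsFactors = FALSE)
  })

  ages0 <- with_seed(derive_seed(config$seed, 2),
                     stats::runif(n, config$age_range[1], config$age_range[2]))

  # visit ages: baseline + cumulative positive intervals
  visits <- with_seed(derive_seed(config$seed, 3), {
    out <- data.frame(subject_id = ids, visit = 1L, age = ages0,
                      years_since_baseline = 0, stringsAsFactors = FALSE)
    elapsed <- rep(0, n)
    if (config$n_visits > 1) {
      for (v in 2:config$n_visits) {
        iv <- config$visit_intervals[[v - 1]]
        gap_years <- pmax(0.5, stats::rnorm(n, iv[1], iv[2]))
        elapsed <- elapsed + gap_years
        out <- rbind(out, data.frame(
          subject_id = ids, visit = as.integer(v), age = ages0 + elapsed,
          years_since_baseline = elapsed, stringsAsFactors = FALSE))
      }
    }
    out
  })

  # latent gaps: n x k per visit; stationary AR(1) with correlated innovations
  factors <- latent_factors(config)
  k <- length(factors)
  R <- gap_chol(config)
  phi <- config$gap_persistence
  gap_mats <- with_seed(derive_seed(config$seed, 4), {
    mats <- vector("list", config$n_visits)
    G <- matrix(stats::rnorm(n * k), n, k) %*% R
    mats[[1]] <- G
    if (config$n_visits > 1) {
      for (v in 2:config$n_visits) {
        innov <- matrix(stats::rnorm(n * k), n, k) %*% R
        G <- phi * G + sqrt(1 - phi^2) * innov
        mats[[v]] <- G
      }
    }
    lapply(mats, function(m) {
      dimnames(m) <- list(ids, factors)
      m
    })
  })

  gaps <- do.call(rbind, lapply(seq_along(gap_mats), function(v) {
    data.frame(subject_id = rep(ids, times = k),
               organ = rep(factors, each = n),
               visit = as.integer(v),
               true_gap = as.vector(gap_mats[[v]]),
               stringsAsFactors = FALSE)
  }))

  cohort <- structure(list(
    subjects = subjects, visits = visits, gaps = gaps,
    gap_matrices = gap_mats, proteome = NULL, events = NULL,
    truth = list(config = config)), class = "cohort_bundle")

  cohort$proteome <- generate_proteome(cohort, config)
  cohort$truth$loadings <- attr(cohort$proteome, "loadings")
  attr(cohort$proteome, "loadings") <- NULL

  cohort$events <- lapply(seq_along(config$hazard_specs), function(i) {
    generate_events(cohort, config$hazard_specs[[i]],
                    seed = derive_seed(config$seed, 100 + i))
  })
  names(cohort$events) <- names(config$hazard_specs)
  cohort$truth$event_lp <- lapply(cohort$events, attr, "linear_predictor")
  for (e in names(cohort$events)) attr(cohort$events[[e]], "linear_predictor") <- NULL

  if (config$missing_rate > 0) {
    cohort$proteome <- lapply(seq_along(cohort$proteome), function(v) {
      inject_missingness(cohort$proteome[[v]], config$missing_rate,
                         seed = derive_seed(config$seed, 200 + v))
    })
  }
  cohort
}

#' Latent gap matrix for one visit
#'
#' @param cohort A `cohort_bundle`.
#' @param visit Visit index.
#' @return Numeric matrix, subjects x latent factors.
#' @export
gap_matrix <- function(cohort, visit = 1) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  cohort$gap_matrices[[visit]]
}

#' Emit the proteome for every visit of a cohort
#'
#' Each organ-panel protein j is `a_j * age + b_j * gap(organ) + s_j * male +
#' noise`; organismal proteins load on age and the shared organismal factor
#' only. Loadings are drawn once (from the config seed) and returned as ground
#' truth in the `"loadings"` attribute.
#'
#' @param cohort A `cohort_bundle` with latent gaps present.
#' @param config The [simulation_config()].
#' @return List of matrices (one per visit, subjects x proteins) with a
#'   `"loadings"` attribute (data frame: protein, organ, age_slope,
#'   gap_loading, sex_effect).
#' @export
generate_proteome <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  organs <- config$organs
  m_org <- config$n_proteins_per_organ
  m_shared <- config$n_organismal_proteins
  prot_organ <- c(rep(organs, each = m_org), rep("organismal", m_shared))
  prot_names <- c(
    unlist(lapply(organs, function(o) sprintf("%s_p%02d", o, seq_len(m_org)))),
    sprintf("shared_p%02d", seq_len(m_shared)))
  p <- length(prot_names)

  with_seed(derive_seed(config$seed, 5), {
    loadings <- data.frame(
      protein = prot_names, organ = prot_organ,
      age_slope = sample(c(-1, 1), p, TRUE) *
        stats::runif(p, config$age_slope_range[1], config$age_slope_range[2]),
      sex_effect = stats::rnorm(p, 0, config$sex_effect_sd),
      stringsAsFactors = FALSE)
    # a gap acts as extra biological years, so the loading tracks the slope
    loadings$gap_loading <- loadings$age_slope * config$gap_years_per_sd

    male <- sex_indicator(cohort$subjects$sex)
    n <- nrow(cohort$subjects)
    out <- lapply(seq_len(config$n_visits), function(v) {
      age_v <- cohort$visits$age[cohort$visits$visit == v]
      G <- cohort$gap_matrices[[v]]
      X <- outer(age_v, loadings$age_slope) +
        G[, loadings$organ, drop = FALSE] %*% diag(loadings$gap_loading) +
        outer(male, loadings$sex_effect)
      if (config$protein_noise_sd > 0)
        X <- X + matrix(stats::rnorm(n * p, 0, config$protein_noise_sd), n, p)
      dimnames(X) <- list(cohort$subjects$subject_id, prot_names)
      X
    })
    attr(out, "loadings") <- loadings
    out
  })
}

#' Generate proportional-hazards event times for one endpoint
#'
#' Event times are drawn by inverse-transform sampling from
#' `h(t|x) = h0 * exp(sum_o beta_o * gap_o + gamma * (age - center) + delta * male)`
#' with a constant baseline hazard, then administratively censored at the
#' horizon. Hazards depend on baseline (visit 1) gaps and age.
#'
#' @param cohort A `cohort_bundle`.
#' @param spec A [hazard_spec()]; `names(spec$log_hr)` must be latent factors
#'   present in the cohort.
#' @param seed Integer seed.
#' @return Data frame `subject_id`, `time` (years from baseline draw),
#'   `status` (1 = event, 0 = censored), with the true linear predictor in the
#'   `"linear_predictor"` attribute.
#' @export
generate_events <- function(cohort, spec, seed = 1) {
  stopifnot(inherits(cohort, "cohort_bundle"), inherits(spec, "hazard_spec"))
  G <- cohort$gap_matrices[[1]]
  unknown <- setdiff(names(spec$log_hr), colnames(G))
  if (length(unknown))
    stop("hazard spec names unknown organ(s): ", paste(unknown, collapse = ", "))
  beta <- stats::setNames(rep(0, ncol(G)), colnames(G))
  beta[names(spec$log_hr)] <- spec$log_hr
  age0 <- cohort$visits$age[cohort$visits$visit == 1]
  male <- sex_indicator(cohort$subjects$sex)
  lp <- drop(G %*% beta) + spec$age_coef * (age0 - spec$age_center) +
    spec$sex_coef * male
  t_event <- with_seed(seed, {
    u <- stats::runif(nrow(G))
    -log(u) / (spec$baseline_hazard * exp(lp))
  })
  out <- data.frame(subject_id = cohort$subjects$subject_id,
                    time = pmin(t_event, spec$horizon),
                    status = as.integer(t_event <= spec$horizon),
                    stringsAsFactors = FALSE)
  attr(out, "linear_predictor") <- lp
  out
}

#' Set matrix entries missing completely at random
#'
#' @param matrix Numeric matrix.
#' @param rate Missingness proportion in \[0, 1).
#' @param seed Integer seed; the mask is deterministic given the seed.
#' @return The matrix with entries set to `NA` at the given rate.
#' @export
inject_missingness <- function(matrix, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("missing rate must be in [0, 1)")
  if (rate == 0) return(matrix)
  mask <- with_seed(seed, stats::runif(length(matrix)) < rate)
  matrix[mask] <- NA_real_
  matrix
}
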