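`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' One global seed fans out to per-stage seeds by a fixed affine derivation so
#' that pipeline stages are independently reproducible. The result always fits
#' in a 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param offset Integer stage offset (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(offset))
  as.integer((abs(as.numeric(seed)) + 7919 * (as.numeric(offset) + 1)) %% 2147483647)
}

# Evaluate expr with a local RNG state seeded at `seed`; the caller's RNG
# stream is restored afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# 1 for male, 0 for female; accepts "male"/"female" or 0/1 already.
sex_indicator <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  as.numeric(sex == "male")
}

#' Event rate of an endpoint table
#'
#' Fraction of records with an observed event. Used in pipeline logs and for
#' quoting incidence proportions.
#'
#' @param events Data frame with a 0/1 `status` column.
#' @return A list with `n`, `n_events` and `rate` (proportion in \[0,1\]).
#' @export
event_rate <- function(events) {
  stopifnot(is.data.frame(events), "status" %in% names(events))
  s <- events$status
  stopifnot(all(s %in% c(0, 1)))
  list(n = length(s), n_events = sum(s), rate = mean(s))
}
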