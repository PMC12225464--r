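#' Geometrically decaying category weights
#'
#' Enforcement effort is rarely spread evenly across categories: a few
#' regions, actors, and species absorb most patrols while many receive
#' well under 1% of effort. A geometric-decay profile over the scheme
#' order reproduces that concentration while keeping every minority class
#' present.
#'
#' @param n Number of levels.
#' @param decay Ratio between consecutive weights, in (0, 1\].
#' @return Numeric vector of length `n`, positive, summing to 1.
#' @export
geometric_weights <- function(n, decay = 0.8) {
  stopifnot(n >= 1L, decay > 0, decay <= 1)
  w <- decay^(seq_len(n) - 1L)
  w / sum(w)
}

#' Configuration of the synthetic patrol-record generator
#'
#' Bundles everything the generator needs: the ground-truth model
#' parameters, the category scheme, per-factor sampling weights, the
#' moments of the two continuous covariates, the number of records, and
#' the seed. Defaults for the continuous covariates mirror a national
#' enforcement programme: patrol time averaging 311.6 minutes (SD 217.9,
#' truncated above 0) and patrol groups averaging 2.0 enforcers (SD 1.1,
#' truncated at 1 and rounded to a whole count).
#'
#' @param scheme A [category_scheme()].
#' @param true_params A [model_params()] object over `scheme`.
#' @param n_records Number of records to simulate (>= 1).
#' @param seed Integer seed; one global seed drives independent
#'   substreams per variable, so adding a covariate does not perturb the
#'   draws of the others.
#' @param category_weights Named list of per-factor probability vectors
#'   (`region`, `actor`, `species`, `violation_type`, `year`); missing
#'   entries default to [geometric_weights()] with decays 0.95, 0.85,
#'   0.8, 0.85, 0.97 respectively.
#' @param time_mean,time_sd Patrol-time moments in minutes (truncation
#'   above 0 is applied after).
#' @param enforcers_mean,enforcers_sd Enforcer group-size moments.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(scheme, true_params, n_records, seed = 1L,
                             category_weights = list(),
                             time_mean = 311.6, time_sd = 217.9,
                             enforcers_mean = 2.0, enforcers_sd = 1.1) {
  stopifnot(inherits(scheme, "category_scheme"),
            inherits(true_params, "model_params"))
  if (!is.numeric(n_records) || n_records < 1) {
    abort("`n_records` must be at least 1.")
  }
  if (time_sd <= 0 || enforcers_sd <= 0) abort("SD values must be positive.")
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > .Machine$integer.max - 1000L) {
    abort("`seed` must be an integer (|seed| < 2^31 - 1000).")
  }

  default_decay <- c(region = 0.95, actor = 0.85, species = 0.8,
                     violation_type = 0.85, year = 0.97)
  weights <- list()
  for (col in unname(scheme_columns)) {
    lv_name <- names(scheme_columns)[scheme_columns == col]
    nl <- length(scheme[[lv_name]])
    w <- category_weights[[col]] %||% geometric_weights(nl, default_decay[[col]])
    if (length(w) != nl || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
      abort(sprintf(
        "`category_weights$%s` must be %d non-negative values summing to 1.",
        col, nl))
    }
    weights[[col]] <- w / sum(w)
  }

  structure(
    list(true_params = true_params, scheme = scheme,
         n_records = as.integer(n_records), seed = seed,
         category_weights = weights,
         time_mean = time_mean, time_sd = time_sd,
         enforcers_mean = enforcers_mean, enforcers_sd = enforcers_sd),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config: %d records, seed %d>\n", x$n_records,
              x$seed))
  print(x$scheme)
  invisible(x)
}

#' Ready-made generator configuration mirroring the study system
#'
#' Builds a [synthetic_config()] with the cardinalities of a national
#' fisheries enforcement dataset (by default 16 regions, 8 actors, 31
#' species groups, 7 violation types, years 2014-2020; reduced
#' cardinalities take the leading levels of [default_scheme()]) and
#' documented ground-truth effects: a strong positive patrol-time slope
#' (+1.79) and a negative group-size slope (-1.52) on the detection side,
#' all categorical coefficients drawn once from the `[-2.2, 2.2]` prior
#' box under the seed's substream, and intercepts `mu_p = -1.5`,
#' `mu_v = -0.7`, which put the marginal detected fraction near the 7%
#' typical of such programmes.
#'
#' @param n_records Number of records (the real dataset has 77,820;
#'   simulation studies in this package default to 5,000).
#' @param seed Integer seed.
#' @param n_regions,n_actors,n_species,n_violations Factor cardinalities
#'   (at most the defaults; at least 1).
#' @param years Integer vector of calendar years.
#' @param mu_p,mu_v,b1,b2 Ground-truth intercepts and continuous slopes.
#' @param ... Passed on to [synthetic_config()] (e.g. covariate moments).
#' @return A [synthetic_config()].
#' @export
#' @examples
#' cfg <- paper_like_config(n_records = 200, seed = 7)
#' recs <- simulate_records(cfg)
#' mean(recs$outcome)
paper_like_config <- function(n_records = 5000, seed = 1L,
                              n_regions = 16, n_actors = 8, n_species = 31,
                              n_violations = 7, years = 2014:2020,
                              mu_p = -1.5, mu_v = -0.7,
                              b1 = 1.79, b2 = -1.52, ...) {
  full <- default_scheme()
  take <- function(lv, k, what) {
    if (k < 1L || k > length(lv)) {
      abort(sprintf("`%s` must be between 1 and %d.", what, length(lv)))
    }
    lv[seq_len(k)]
  }
  scheme <- category_scheme(
    region_levels = take(full$region_levels, n_regions, "n_regions"),
    actor_levels = take(full$actor_levels, n_actors, "n_actors"),
    species_levels = take(full$species_levels, n_species, "n_species"),
    violation_levels = take(full$violation_levels, n_violations,
                            "n_violations"),
    year_levels = years
  )
  # categorical ground truth drawn once from the prior box, seed substream
  draw_block <- function(nl, offset) {
    if (nl <= 1L) return(NULL)
    withr_seed(seed + offset, runif(nl - 1L, -prior_bound, prior_bound))
  }
  true_params <- model_params(
    scheme, mu_p = mu_p, mu_v = mu_v, b1 = b1, b2 = b2,
    b3 = draw_block(length(scheme$region_levels), 101L),
    b4 = draw_block(length(scheme$actor_levels), 102L),
    b5 = draw_block(length(scheme$year_levels), 103L),
    b6 = draw_block(length(scheme$violation_levels), 104L),
    b7 = draw_block(length(scheme$species_levels), 105L)
  )
  synthetic_config(scheme, true_params, n_records = n_records, seed = seed,
                   ...)
}

# evaluate `expr` under a local RNG seed, restoring the global RNG state
withr_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# truncated-normal draws by analytic inverse-CDF truncation (lower bound)
rtruncnorm_lower <- function(n, mean, sd, lower) {
  plo <- pnorm(lower, mean, sd)
  u <- runif(n, plo, 1)
  qnorm(pmin(u, 1 - 1e-16), mean, sd)
}

#' Simulate the two-stage Bernoulli outcome process
#'
#' Given per-record violation probabilities `v` and conditional detection
#' probabilities `p`, draws the latent presence indicator
#' `s ~ Bernoulli(v)` and the observed outcome `y ~ Bernoulli(p * s)` -
#' the literal generative process of the observation model.
#'
#' @param v,p Probability vectors of equal length.
#' @param seed Optional integer seed (substreamed: `s` and `y` use
#'   independent substreams).
#' @return A tibble with columns `v`, `p`, `s`, `y`.
#' @export
simulate_outcomes <- function(v, p, seed = NULL) {
  stopifnot(length(v) == length(p), all(v >= 0 & v <= 1),
            all(p >= 0 & p <= 1))
  n <- length(v)
  s <- if (is.null(seed)) rbinom(n, 1L, v) else
    withr_seed(seed + 8L, rbinom(n, 1L, v))
  y <- if (is.null(seed)) rbinom(n, 1L, p * s) else
    withr_seed(seed + 9L, rbinom(n, 1L, p * s))
  tibble::tibble(v = v, p = p, s = s, y = y)
}

#' Simulate enforcement-patrol records from known ground truth
#'
#' Draws covariates (categoricals from the configured weights, patrol
#' time from a truncated normal above 0, enforcer counts from a truncated
#' normal at 1 rounded half-up to a whole count), evaluates the two
#' linear predictors under the ground-truth parameters on the min-max
#' scaled covariates, and then runs the two-stage Bernoulli process:
#' `s_i ~ Bernoulli(v_i)`, `y_i ~ Bernoulli(p_i * s_i)`. The latent truth
#' `(v_i, p_i, s_i)` is attached for use in recovery and calibration
#' tests; real data never has it.
#'
#' @param config A [synthetic_config()].
#' @return A records tibble with attributes `scheme`, `scaling`, and
#'   `truth` (a tibble `row_id`, `v`, `p`, `s`; see [latent_truth()]).
#' @export
simulate_records <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_records
  scheme <- config$scheme
  seed <- config$seed

  draw_cat <- function(col, offset) {
    lv_name <- names(scheme_columns)[scheme_columns == col]
    withr_seed(seed + offset,
               sample(scheme[[lv_name]], n, replace = TRUE,
                      prob = config$category_weights[[col]]))
  }
  records <- tibble::tibble(
    year = as.integer(draw_cat("year", 5L)),
    region = draw_cat("region", 1L),
    actor = draw_cat("actor", 2L),
    species = draw_cat("species", 3L),
    violation_type = draw_cat("violation_type", 4L),
    time_minutes = withr_seed(
      seed + 6L, rtruncnorm_lower(n, config$time_mean, config$time_sd, 0)),
    n_enforcers = withr_seed(
      seed + 7L,
      pmax(1L, as.integer(floor(rtruncnorm_lower(
        n, config$enforcers_mean, config$enforcers_sd, 1) + 0.5))))
  )

  records <- scale_continuous(records)
  v <- inv_logit(violation_logit(records, config$true_params))
  p <- inv_logit(detection_logit(records, config$true_params))
  out <- simulate_outcomes(v, p, seed = seed)
  records$outcome <- out$y

  structure(records,
            scheme = scheme,
            scaling = scaling_info(records),
            truth = tibble::tibble(row_id = seq_len(n), v = v, p = p,
                                   s = out$s))
}

#' Write the latent truth table of a simulated dataset
#'
#' Writes the `(row_id, v, p, s)` table attached by [simulate_records()]
#' as a CSV sibling of the records file, for test use only.
#'
#' @param records A simulated records tibble.
#' @param path Output CSV path.
#' @return The truth tibble, invisibly.
#' @export
write_truth <- function(records, path) {
  truth <- latent_truth(records)
  if (is.null(truth)) abort("`records` carries no latent truth table.")
  readr::write_csv(truth, path, progress = FALSE)
  invisible(truth)
}
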