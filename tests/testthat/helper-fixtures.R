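# Small shared fixtures, built in code. Fits are memoised so several test
# files can reuse them without re-running the sampler.

tiny_scheme <- function() {
  category_scheme(
    region_levels = c("North", "South"),
    actor_levels = c("Fisher", "Trader"),
    species_levels = c("Anchovy", "Hake"),
    violation_levels = c("Access", "Quota"),
    year_levels = 2014:2015
  )
}

# a records tibble with hand-set scaled covariates (bypasses scaling)
manual_records <- function(scheme, region, actor, species, violation, year,
                           time_scaled, enforcers_scaled, outcome) {
  n <- max(lengths(list(region, actor, species, violation, year,
                        time_scaled, enforcers_scaled, outcome)))
  structure(
    tibble::tibble(
      year = rep_len(as.integer(year), n),
      region = rep_len(region, n),
      actor = rep_len(actor, n),
      species = rep_len(species, n),
      violation_type = rep_len(violation, n),
      time_minutes = rep_len(time_scaled, n) * 100,
      n_enforcers = rep_len(2L, n),
      outcome = rep_len(as.integer(outcome), n),
      time_scaled = rep_len(time_scaled, n),
      enforcers_scaled = rep_len(enforcers_scaled, n)
    ),
    scheme = scheme
  )
}

# random parameters inside the prior box over a scheme
random_params <- function(scheme, seed) {
  set.seed(seed)
  rb <- function(nl) runif(nl - 1L, -2.2, 2.2)
  model_params(
    scheme,
    mu_p = runif(1, -2.2, 2.2), mu_v = runif(1, -2.2, 2.2),
    b1 = runif(1, -2.2, 2.2), b2 = runif(1, -2.2, 2.2),
    b3 = rb(length(scheme$region_levels)),
    b4 = rb(length(scheme$actor_levels)),
    b5 = rb(length(scheme$year_levels)),
    b6 = rb(length(scheme$violation_levels)),
    b7 = rb(length(scheme$species_levels))
  )
}

local({
  cache <- new.env(parent = emptyenv())
  # ground truth with named, test-visible effects: a +1.5 Trader effect on
  # detection, a -1.0 year-2015 effect, and moderate continuous slopes
  recovery_config <<- function() {
    scheme <- tiny_scheme()
    truth <- model_params(
      scheme, mu_p = -0.5, mu_v = 0.3, b1 = 1.0, b2 = -0.5,
      b3 = c(South = 0.8), b4 = c(Trader = 1.5), b5 = c("2015" = -1.0),
      b6 = c(Quota = 0.6), b7 = c(Hake = -0.9)
    )
    synthetic_config(scheme, truth, n_records = 4000, seed = 2024)
  }
  recovery_records <<- function() {
    if (is.null(cache$recs)) cache$recs <- simulate_records(recovery_config())
    cache$recs
  }
  recovery_fit <<- function() {
    if (is.null(cache$fit)) {
      cache$fit <- sample_posterior(recovery_records(), chains = 3,
                                    warmup = 400, iter = 800, seed = 77,
                                    save_loglik = TRUE, loglik_thin = 4)
    }
    cache$fit
  }
})

# a fit whose draws are all zero: every record then has v = p = 0.5
zero_draw_fit <- function(fit) {
  fit$draws[] <- 0
  fit
}
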