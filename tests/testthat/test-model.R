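test_that("linear predictors match their defining sums", {
  scheme <- tiny_scheme()

  # all covariates at reference / zero -> logit 0, probability 0.5
  ref <- manual_records(scheme, "North", "Fisher", "Anchovy", "Access",
                        2014L, 0, 0, 0)
  p0 <- model_params(scheme)
  expect_equal(detection_logit(ref, p0), 0)
  expect_equal(violation_logit(ref, p0), 0)
  expect_equal(plogis(detection_logit(ref, p0)), 0.5)

  # a unit scaled time with slope 1.79 moves the detection logit by 1.79
  pt <- model_params(scheme, b1 = 1.79)
  full_t <- manual_records(scheme, "North", "Fisher", "Anchovy", "Access",
                           2014L, 1, 0, 0)
  expect_equal(detection_logit(full_t, pt), 1.79)

  # a -2.2 species coefficient puts v at the prior box's ~10% edge
  ps <- model_params(scheme, b7 = c(Hake = -2.2))
  hake <- manual_records(scheme, "North", "Fisher", "Hake", "Access",
                         2014L, 0, 0, 0)
  expect_equal(plogis(violation_logit(hake, ps)), plogis(-2.2))
  expect_lt(plogis(violation_logit(hake, ps)), 0.11)
})

test_that("random parameters reproduce a hand-expanded dot product", {
  scheme <- tiny_scheme()
  for (seed in 1:20) {
    params <- random_params(scheme, seed)
    set.seed(seed + 1000)
    recs <- manual_records(
      scheme,
      sample(scheme$region_levels, 7, TRUE),
      sample(scheme$actor_levels, 7, TRUE),
      sample(scheme$species_levels, 7, TRUE),
      sample(scheme$violation_levels, 7, TRUE),
      sample(2014:2015, 7, TRUE),
      runif(7), runif(7), rbinom(7, 1, 0.5)
    )
    # brute-force expansion, record by record, term by term
    expected_p <- vapply(seq_len(7), function(i) {
      params$mu_p + params$b1 * recs$time_scaled[i] +
        params$b2 * recs$enforcers_scaled[i] +
        params$b3[[recs$region[i]]] + params$b4[[recs$actor[i]]] +
        params$b5[[as.character(recs$year[i])]]
    }, numeric(1))
    expected_v <- vapply(seq_len(7), function(i) {
      params$mu_v + params$b6[[recs$violation_type[i]]] +
        params$b7[[recs$species[i]]]
    }, numeric(1))
    expect_equal(detection_logit(recs, params), expected_p)
    expect_equal(violation_logit(recs, params), expected_v)
  }
})

test_that("marginal observation probability multiplies and degenerates", {
  expect_equal(marginal_obs_prob(v = 0.34, p = 0.18, y = 1), 0.0612)
  expect_equal(marginal_obs_prob(v = 0, p = 0.7, y = 1), 0)
  expect_equal(marginal_obs_prob(v = 1, p = 1, y = 0), 0)
  expect_equal(marginal_obs_prob(v = 0.5, p = 0.5, y = 0), 0.75)
  expect_error(marginal_obs_prob(v = 1.2, p = 0.5, y = 1), "\\[0, 1\\]")
  expect_error(marginal_obs_prob(v = 0.5, p = -0.1, y = 0), "\\[0, 1\\]")
  expect_error(marginal_obs_prob(v = 0.5, p = 0.5, y = 2), "binary")

  # log version agrees with the direct product and is finite near the edges
  v <- c(1e-12, 0.3, 1 - 1e-12)
  p <- c(1e-12, 0.9, 1 - 1e-12)
  expect_equal(marginal_obs_logprob(v, p, c(1, 1, 1)), log(v * p))
  expect_equal(marginal_obs_logprob(v, p, c(0, 0, 0)), log1p(-v * p))
  expect_true(all(is.finite(marginal_obs_logprob(v, p, c(0, 0, 0)))))
})

test_that("P(y=1) is symmetric in (v, p) and increasing in each", {
  set.seed(4)
  v <- runif(50)
  p <- runif(50)
  expect_equal(marginal_obs_prob(v, p, 1), marginal_obs_prob(p, v, 1))
  eps <- 1e-6
  expect_true(all(marginal_obs_prob(pmin(v + eps, 1), p, 1) >=
                    marginal_obs_prob(v, p, 1)))
  expect_true(all(marginal_obs_prob(v, pmin(p + eps, 1), 1) >=
                    marginal_obs_prob(v, p, 1)))
})

test_that("the prior is flat inside the closed box and -Inf outside", {
  scheme <- tiny_scheme()
  k_free <- 2 + 2 + 5  # two intercepts, two slopes, five 2-level factors
  expect_equal(log_prior(model_params(scheme)), -k_free * log(4.4))
  expect_equal(log_prior(model_params(scheme, mu_p = 2.2, b1 = -2.2)),
               -k_free * log(4.4))
  expect_identical(log_prior(c(0, 2.3)), -Inf)
  expect_identical(log_prior(c(2.2, -2.2)), -2 * log(4.4))
  expect_error(model_params(scheme, b1 = 2.3), "-2.2")
})

test_that("log-posterior equals prior plus exhaustive latent marginalisation", {
  scheme <- tiny_scheme()

  empty <- manual_records(scheme, character(0), character(0), character(0),
                          character(0), integer(0), numeric(0), numeric(0),
                          integer(0))
  p0 <- model_params(scheme)
  expect_equal(log_posterior(empty, p0), log_prior(p0))

  one <- manual_records(scheme, "North", "Fisher", "Anchovy", "Access",
                        2014L, 0, 0, 1)
  expect_equal(log_posterior(one, p0), log(0.25) + log_prior(p0))

  # 20-record set vs brute-force enumeration of each record's latent state
  for (seed in c(2, 3, 4)) {
    params <- random_params(scheme, seed)
    set.seed(seed + 500)
    recs <- manual_records(
      scheme,
      sample(scheme$region_levels, 20, TRUE),
      sample(scheme$actor_levels, 20, TRUE),
      sample(scheme$species_levels, 20, TRUE),
      sample(scheme$violation_levels, 20, TRUE),
      sample(2014:2015, 20, TRUE),
      runif(20), runif(20), rbinom(20, 1, 0.3)
    )
    enum <- vapply(seq_len(20), function(i) {
      row <- recs[i, ]
      # sum over s in {0, 1} of exp(complete-data log-likelihood)
      log(sum(vapply(0:1, function(s) {
        exp(complete_data_loglik(row, params, s))
      }, numeric(1))))
    }, numeric(1))
    expect_equal(log_posterior(recs, params), sum(enum) + log_prior(params),
                 tolerance = 1e-10)
  }
})

test_that("monte-carlo simulation of the latent process matches the marginal", {
  set.seed(99)
  for (i in 1:5) {
    v <- runif(1)
    p <- runif(1)
    out <- simulate_outcomes(rep(v, 100000), rep(p, 100000))
    target <- marginal_obs_prob(v, p, 1)
    se <- sqrt(target * (1 - target) / 100000)
    expect_lt(abs(mean(out$y) - target), 3 * se + 1e-12)
  }
})

test_that("parameters survive a JSON round-trip keyed by level names", {
  scheme <- tiny_scheme()
  params <- random_params(scheme, 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(params, path)
  back <- read_params_json(path, scheme)
  expect_equal(unclass(back)[], unclass(params)[], tolerance = 1e-12)

  # scheme and scaling serialisation round-trips too
  spath <- withr::local_tempfile(fileext = ".json")
  write_scheme_json(scheme, spath)
  expect_identical(read_scheme_json(spath), scheme)
})
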