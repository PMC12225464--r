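test_that("split Rhat matches a hand-computed between/within ratio", {
  # 2 chains x 8 draws, one parameter; oracle computed from the four
  # half-chains with the textbook formula
  x1 <- c(0.1, 0.4, 0.2, 0.3, 1.1, 1.5, 1.2, 1.4)
  x2 <- c(0.2, 0.5, 0.1, 0.4, 0.9, 1.3, 1.0, 1.2)
  draws <- array(NA_real_, c(2, 8, 1), dimnames = list(NULL, NULL, "theta"))
  draws[1, , 1] <- x1
  draws[2, , 1] <- x2

  halves <- list(x1[1:4], x1[5:8], x2[1:4], x2[5:8])
  n2 <- 4
  W <- mean(sapply(halves, var))
  B <- n2 * var(sapply(halves, mean))
  expected <- sqrt(((n2 - 1) / n2 * W + B / n2) / W)

  rep <- compute_rhat(draws)
  expect_equal(unname(rep$summary$rhat), expected, tolerance = 1e-12)
  expect_false(rep$pass)  # the half-chain means are far apart by design
})

test_that("Rhat is ~1 for well-mixed chains and large for disjoint ones", {
  set.seed(314)
  good <- array(rnorm(4 * 1000 * 2), c(4, 1000, 2),
                dimnames = list(NULL, NULL, c("a", "b")))
  rep_good <- compute_rhat(good)
  expect_true(all(abs(rep_good$summary$rhat - 1) < 0.02))
  expect_true(rep_good$pass)
  expect_true(all(rep_good$summary$ess > 1000))

  stuck <- good
  stuck[1, , ] <- stuck[1, , ] - 2
  stuck[2, , ] <- stuck[2, , ] + 2
  rep_bad <- compute_rhat(stuck)
  expect_true(all(rep_bad$summary$rhat > 1.5))
  expect_false(rep_bad$pass)

  expect_error(compute_rhat(good[1, , , drop = FALSE]), "2 chains")
  expect_error(compute_rhat(good[, 1:3, , drop = FALSE]), "4 draws")
})

test_that("WAIC reduces to -2*loglik at zero variance and matches hand math", {
  # constant log-likelihood across draws: no penalty
  ll_const <- matrix(rep(c(-1.2, -0.7), each = 5), nrow = 5)
  w0 <- compute_waic(ll_const)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * (-1.2 - 0.7))

  # 2 records x 3 draws toy table, lppd and penalty computed by hand
  ll <- matrix(c(-1.0, -1.5, -2.0,
                 -0.5, -0.6, -0.7), nrow = 3)
  w <- compute_waic(ll)
  lppd <- log(mean(exp(ll[, 1]))) + log(mean(exp(ll[, 2])))
  p <- var(ll[, 1]) + var(ll[, 2])
  expect_equal(w$lppd, lppd, tolerance = 1e-12)
  expect_equal(w$p_waic, p, tolerance = 1e-12)
  expect_equal(w$waic, -2 * (lppd - p), tolerance = 1e-12)

  llbad <- ll
  llbad[2, 2] <- -Inf
  expect_error(compute_waic(llbad), "record\\(s\\): 2")
})

test_that("the sampler is reproducible under its seed", {
  recs <- recovery_records()[1:400, ]
  f1 <- sample_posterior(recs, scheme = tiny_scheme(), chains = 2,
                         warmup = 100, iter = 150, seed = 5,
                         save_loglik = FALSE)
  f2 <- sample_posterior(recs, scheme = tiny_scheme(), chains = 2,
                         warmup = 100, iter = 150, seed = 5,
                         save_loglik = FALSE)
  expect_identical(f1$draws, f2$draws)
  f3 <- sample_posterior(recs, scheme = tiny_scheme(), chains = 2,
                         warmup = 100, iter = 150, seed = 6,
                         save_loglik = FALSE)
  expect_false(identical(f1$draws, f3$draws))

  # every stored draw respects the prior box
  expect_true(all(abs(f1$draws) <= 2.2))
})

test_that("a constant outcome warns and falls back to the prior", {
  recs <- recovery_records()[1:200, ]
  recs$outcome <- 0L
  expect_warning(
    fit <- sample_posterior(recs, scheme = tiny_scheme(), chains = 2,
                            warmup = 100, iter = 150, seed = 2,
                            save_loglik = FALSE),
    "identical")
  expect_s3_class(fit, "patrol_fit")
})

test_that("the recovery fit converges and covers its named true effects", {
  fit <- recovery_fit()
  conv <- compute_rhat(fit)
  expect_true(conv$pass)

  td <- tidy(fit)
  truth <- c("b4_actor[Trader]" = 1.5, "b5_year[2015]" = -1.0,
             "b1_time" = 1.0, "b3_region[South]" = 0.8,
             "b7_species[Hake]" = -0.9)
  for (nm in names(truth)) {
    row <- td[td$term == nm, ]
    expect_lt(abs(row$estimate - truth[[nm]]), 4 * row$std.error)
  }
  # sampled log-likelihoods agree with the R-side marginal likelihood
  flat <- fit$draws[1, 1, ]
  params <- patroldetect:::vector_to_params(flat, build_design(
    recovery_records(), scheme = tiny_scheme()))
  ll_r <- log_posterior(recovery_records(), params) - log_prior(params)
  ll_cpp <- sum(fit$loglik[1, 1, ])
  expect_equal(ll_cpp, ll_r, tolerance = 1e-8)
})

test_that("credible intervals shrink as the sample grows", {
  width <- function(n) {
    cfg <- paper_like_config(n_records = n, seed = 55, n_regions = 2,
                             n_actors = 2, n_species = 2, n_violations = 2,
                             years = 2014:2015)
    fit <- sample_posterior(simulate_records(cfg), chains = 2,
                            warmup = 250, iter = 500, seed = 60,
                            save_loglik = FALSE)
    td <- tidy(fit)
    mean(td$conf.high[td$term == "b1_time"] -
           td$conf.low[td$term == "b1_time"])
  }
  expect_lt(width(10000), width(1000))
})

test_that("the intercept product is identified even when intercepts are not", {
  # intercept-only truth: only v*p is identified by the data; the fitted
  # posterior of plogis(mu_v) * plogis(mu_p) must concentrate on the truth
  scheme <- tiny_scheme()
  truth <- model_params(scheme, mu_p = -0.4, mu_v = 0.6)
  cfg <- synthetic_config(scheme, truth, n_records = 8000, seed = 17)
  recs <- simulate_records(cfg)
  null_spec <- model_spec(character(0), character(0), name = "null")
  fit <- sample_posterior(recs, spec = null_spec, chains = 3,
                          warmup = 300, iter = 900, seed = 18,
                          save_loglik = FALSE)
  flat <- patroldetect:::flatten_draws(fit$draws)
  prod_draws <- plogis(flat[, "mu_p"]) * plogis(flat[, "mu_v"])
  true_prod <- plogis(-0.4) * plogis(0.6)
  ci <- quantile(prod_draws, c(0.025, 0.975))
  expect_lt(ci[1], true_prod)
  expect_gt(ci[2], true_prod)
  # and it is narrow relative to the prior's reach
  expect_lt(ci[2] - ci[1], 0.1)
})

test_that("the model ladder ranks the generating model above the null", {
  recs <- recovery_records()[1:1500, ]
  attr(recs, "scheme") <- tiny_scheme()
  ladder <- fit_model_ladder(
    recs,
    specs = list(null = model_spec(character(0), character(0), "null"),
                 full = model_spec(name = "full")),
    chains = 2, warmup = 300, iter = 600, seed = 9)
  expect_identical(ladder$model[1], "full")
  expect_lt(ladder$waic[ladder$model == "full"],
            ladder$waic[ladder$model == "null"])

  # a one-spec ladder is trivially ranked
  one <- fit_model_ladder(recs, specs = list(model_spec(name = "full")),
                          chains = 2, warmup = 150, iter = 300, seed = 9)
  expect_identical(nrow(one), 1L)

  # the alternative predictor assignment is expressible and runs
  alt <- model_spec(detection = c("time", "enforcers", "actor"),
                    violation = c("species", "violation_type", "region",
                                  "year"))
  fit_alt <- sample_posterior(recs[1:300, ], spec = alt, chains = 2,
                              warmup = 80, iter = 120, seed = 3,
                              save_loglik = FALSE)
  expect_true(any(startsWith(fit_alt$par_names, "b3_region")))
})

test_that("draws persist to tidy CSV and restore exactly", {
  fit <- recovery_fit()
  dir <- withr::local_tempdir()
  write_draws(fit, dir)
  back <- read_draws(dir)
  expect_equal(back$draws, fit$draws, tolerance = 1e-12)
  expect_identical(back$meta$n_chains, fit$meta$n_chains)
})
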