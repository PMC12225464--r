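test_that("the printed confusion matrix yields the reported scores", {
  # counts arranged as prediction rows x outcome columns
  tn <- 68737L; fp <- 169L; fn <- 275L; tp <- 4581L
  outcomes <- c(rep(0, tn), rep(0, fp), rep(1, fn), rep(1, tp))
  predictions <- c(rep(0, tn), rep(1, fp), rep(0, fn), rep(1, tp))
  sc <- confusion_and_scores(predictions, outcomes)

  expect_identical(sc$tn, tn)
  expect_identical(sc$fp, fp)
  expect_identical(sc$fn, fn)
  expect_identical(sc$tp, tp)
  expect_equal(round(100 * sc$recall), 94)
  expect_gte(sc$specificity, 0.99)
  expect_equal(round(sc$f1, 2), 0.95)
})

test_that("confusion counts match a brute-force loop on random vectors", {
  set.seed(77)
  predictions <- rbinom(200, 1, 0.3)
  outcomes <- rbinom(200, 1, 0.2)
  sc <- confusion_and_scores(predictions, outcomes)
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in 1:200) {
    counts[if (predictions[i] == 1 && outcomes[i] == 1) "tp"
           else if (predictions[i] == 1) "fp"
           else if (outcomes[i] == 1) "fn" else "tn"] <-
      counts[if (predictions[i] == 1 && outcomes[i] == 1) "tp"
             else if (predictions[i] == 1) "fp"
             else if (outcomes[i] == 1) "fn" else "tn"] + 1
  }
  expect_equal(c(sc$tp, sc$fp, sc$fn, sc$tn), as.vector(counts),
               ignore_attr = TRUE)

  # F1 always equals the harmonic-mean formula recomputed independently
  P <- counts[["tp"]] / (counts[["tp"]] + counts[["fp"]])
  R <- counts[["tp"]] / (counts[["tp"]] + counts[["fn"]])
  expect_equal(sc$f1, 2 * P * R / (P + R))

  # perfect prediction saturates every score
  perfect <- confusion_and_scores(outcomes, outcomes)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  expect_error(confusion_and_scores(c(0, 1), c(0, 1, 1)), "equal length")
  w <- capture_warnings(sc0 <- confusion_and_scores(rep(0, 5), rep(0, 5)))
  expect_true(any(grepl("undefined", w)))  # precision and recall both warn
  expect_true(is.na(sc0$f1))
})

test_that("classification thresholds behave at the boundary", {
  expect_identical(classify(c(0.24, 0.239, 0.9), 0.24), c(1L, 0L, 1L))
  expect_identical(classify(rep(0.9, 4), 0.999), rep(0L, 4))
  set.seed(12)
  probs <- runif(500)
  expect_identical(classify(probs, 0.24), as.integer(probs >= 0.24))
  expect_error(classify(probs, 0), "strictly inside")
  expect_error(classify(probs, 1), "strictly inside")
  expect_error(classify(c(-0.1, 0.5), 0.5), "\\[0, 1\\]")
})

test_that("the threshold sweep finds separable optima and counts its grid", {
  outcomes <- c(rep(1, 30), rep(0, 170))
  probs <- c(rep(0.9, 30), rep(0.1, 170))
  sw <- threshold_sweep(probs, outcomes)
  expect_equal(best_f1(sw), 1)
  expect_equal(best_threshold(sw), 0.11)  # smallest threshold above 0.1
  expect_identical(nrow(sw), 99L)

  # permutation invariance
  set.seed(5)
  idx <- sample(200)
  sw2 <- threshold_sweep(probs[idx], outcomes[idx])
  expect_equal(sw2$f1, sw$f1)
  expect_equal(best_threshold(sw2), best_threshold(sw))

  expect_warning(sw0 <- threshold_sweep(probs, rep(0, 200)), "No positive")
  expect_true(all(is.na(sw0$f1)))
  expect_true(is.na(best_f1(sw0)))

  expect_error(threshold_sweep(probs, outcomes, step = 0.6), "\\(0, 0.5\\]")
})

test_that("sweep F1 values match an independent tabulation oracle", {
  set.seed(31)
  probs <- runif(300)
  outcomes <- rbinom(300, 1, 0.25)  # outcomes independent of probs
  sw <- threshold_sweep(probs, outcomes, step = 0.05)
  for (i in seq_len(nrow(sw))) {
    t <- sw$threshold[i]
    tab <- table(factor(probs >= t, levels = c(FALSE, TRUE)),
                 factor(outcomes, levels = 0:1))
    tp <- tab["TRUE", "1"]; fp <- tab["TRUE", "0"]; fn <- tab["FALSE", "1"]
    f1 <- if (tp + fp == 0) NA_real_ else {
      P <- tp / (tp + fp); R <- tp / (tp + fn)
      if (P + R == 0) NA_real_ else 2 * P * R / (P + R)
    }
    expect_equal(sw$f1[i], f1)
  }
  # ties break toward the smallest threshold
  expect_identical(best_threshold(sw),
                   sw$threshold[which(sw$f1 == max(sw$f1, na.rm = TRUE))[1]])
})

test_that("posterior prediction averages the per-draw probabilities", {
  fit <- recovery_fit()
  recs <- recovery_records()[1:50, ]

  # all-zero draws -> v = p = 0.5 -> every record predicted at 0.25
  z <- zero_draw_fit(fit)
  preds0 <- posterior_predict(z, recs)
  expect_equal(preds0$.pred, rep(0.25, 50))
  expect_equal(preds0$.pred_detect, rep(0.5, 50))

  # two draws engineered to give record probabilities 0.1 and 0.3 -> 0.2
  two <- fit
  two$draws <- array(0, c(1, 2, length(fit$par_names)),
                     dimnames = list(NULL, NULL, fit$par_names))
  two$draws[1, 1, c("mu_p", "mu_v")] <- qlogis(sqrt(0.1))
  two$draws[1, 2, c("mu_p", "mu_v")] <- qlogis(sqrt(0.3))
  preds2 <- posterior_predict(two, recs)
  expect_equal(preds2$.pred, rep(0.2, 50), tolerance = 1e-10)

  # a level unseen at fit time is fatal and names the level
  alien <- recs
  alien$region[1] <- "Atlantis"
  expect_error(posterior_predict(fit, alien), "Atlantis")
})

test_that("predictions are calibrated in the large on synthetic data", {
  fit <- recovery_fit()
  recs <- recovery_records()
  preds <- posterior_predict(fit, recs, thin = 8)
  rate <- mean(recs$outcome)
  se <- sqrt(rate * (1 - rate) / nrow(recs))
  expect_lt(abs(mean(preds$.pred) - rate), 4 * se)

  # per-record product never exceeds either factor
  expect_true(all(preds$.pred <= preds$.pred_violation + 1e-12))
  expect_true(all(preds$.pred <= preds$.pred_detect + 1e-12))
})

test_that("sweeping can only improve on the conventional 0.5 threshold", {
  fit <- recovery_fit()
  recs <- recovery_records()
  preds <- posterior_predict(fit, recs, thin = 8)
  sw <- threshold_sweep(preds$.pred, recs$outcome)
  f1_at_half <- sw$f1[abs(sw$threshold - 0.5) < 1e-9]
  expect_gte(best_f1(sw), if (is.na(f1_at_half)) 0 else f1_at_half)
})

test_that("confusion reports write to CSV and text", {
  sc <- confusion_and_scores(c(1, 1, 0, 0), c(1, 0, 0, 0))
  dir <- withr::local_tempdir()
  paths <- write_confusion(sc, dir)
  tab <- readr::read_csv(paths[["csv"]], show_col_types = FALSE)
  expect_identical(sum(tab$count), 4)
  expect_true(any(grepl("precision", readLines(paths[["txt"]]))))
})
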