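#' Posterior-predictive probabilities for patrol records
#'
#' Scores records under a fitted model: for every retained draw the two
#' linear predictors are evaluated and the per-record violation
#' probability `v`, conditional detection probability `p`, and marginal
#' outcome probability `v * p` are averaged over draws. The fit's stored
#' scheme and scaling are applied, so held-out data is scored on the
#' training scale; a categorical level unseen at fit time is an error.
#'
#' @param fit A `patrol_fit`.
#' @param records A records tibble (defaults must be supplied; the fit
#'   does not retain its training data).
#' @param thin Use every `thin`-th retained draw (posterior means are
#'   insensitive to moderate thinning; it bounds memory and time).
#' @return A tibble with one row per record: `.row`, `.pred` (posterior
#'   mean of `v * p` - the probability the patrol records a violation),
#'   `.pred_violation` (mean of `v`), and `.pred_detect` (mean of `p`).
#' @export
posterior_predict <- function(fit, records, thin = 1L) {
  stopifnot(inherits(fit, "patrol_fit"))
  records <- scale_continuous(tibble::as_tibble(records),
                              scaling = fit$scaling)
  design <- build_design(records, scheme = fit$scheme, spec = fit$spec)
  flat <- flatten_draws(fit$draws)
  flat <- flat[seq(1L, nrow(flat), by = as.integer(thin)), , drop = FALSE]
  kp <- fit$n_detection_pars
  n <- nrow(records)
  S <- nrow(flat)

  sum_p <- sum_v <- sum_vp <- numeric(n)
  # chunk over draws to bound the n x chunk intermediate matrices
  chunk <- max(1L, floor(2e6 / n))
  for (start in seq(1L, S, by = chunk)) {
    idx <- start:min(start + chunk - 1L, S)
    p <- inv_logit(design$X_p %*% t(flat[idx, seq_len(kp), drop = FALSE]))
    v <- inv_logit(design$X_v %*% t(flat[idx, -seq_len(kp), drop = FALSE]))
    sum_p <- sum_p + rowSums(p)
    sum_v <- sum_v + rowSums(v)
    sum_vp <- sum_vp + rowSums(v * p)
  }
  tibble::tibble(
    .row = seq_len(n),
    .pred = sum_vp / S,
    .pred_violation = sum_v / S,
    .pred_detect = sum_p / S
  )
}

#' Threshold a probability vector into binary predictions
#'
#' A record is predicted "violation detected" when its probability is at
#' or above the threshold (ties classify as 1, a fixed documented
#' convention).
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param threshold A single value in (0, 1).
#' @return Integer vector of 0/1 predictions.
#' @export
classify <- function(probabilities, threshold) {
  stop_if_not_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly inside (0, 1).")
  }
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    abort("`probabilities` must lie in [0, 1].")
  }
  as.integer(probabilities >= threshold)
}

#' Confusion matrix and classification scores
#'
#' Cross-tabulates predictions against observed outcomes (rows are the
#' model's predictions, columns the dataset's outcomes) and computes
#' precision (`tp / (tp + fp)`), recall/sensitivity (`tp / (tp + fn)`),
#' specificity (`tn / (tn + fp)`), accuracy, and the F1 score
#' `2 * precision * recall / (precision + recall)`. A score whose
#' denominator is zero is reported as `NA` with a warning, never
#' silently as 0.
#'
#' @param predictions,outcomes Equal-length binary (0/1) vectors.
#' @return An object of class `confusion_scores`: list with counts `tn`,
#'   `fp`, `fn`, `tp`, the `matrix` (2 x 2, prediction rows x outcome
#'   columns), and the five scores.
#' @export
#' @examples
#' confusion_and_scores(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion_and_scores <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes)) {
    abort("`predictions` and `outcomes` must have equal length.")
  }
  if (any(!(predictions %in% c(0, 1))) || any(!(outcomes %in% c(0, 1)))) {
    abort("`predictions` and `outcomes` must be binary (0/1).")
  }
  tp <- sum(predictions == 1 & outcomes == 1)
  fp <- sum(predictions == 1 & outcomes == 0)
  fn <- sum(predictions == 0 & outcomes == 1)
  tn <- sum(predictions == 0 & outcomes == 0)

  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s is undefined (zero denominator); reported as NA.",
                   what))
      return(NA_real_)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  specificity <- ratio(tn, tn + fp, "specificity")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (!is.na(precision) && !is.na(recall)) {
      warn("F1 is undefined (precision + recall = 0); reported as NA.")
    }
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }

  m <- matrix(c(tn, fp, fn, tp), 2L, 2L,
              dimnames = list(prediction = c("Not detected", "Detected"),
                              outcome = c("Not detected", "Detected")))
  structure(
    list(tn = tn, fp = fp, fn = fn, tp = tp, matrix = m,
         precision = precision, recall = recall,
         specificity = specificity,
         accuracy = (tp + tn) / length(outcomes), f1 = f1),
    class = "confusion_scores"
  )
}

#' @export
print.confusion_scores <- function(x, ...) {
  cat("Model prediction (rows) vs dataset outcome (columns):\n")
  print(x$matrix)
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("precision = %s  recall = %s  specificity = %s  F1 = %s\n",
              fmt(x$precision), fmt(x$recall), fmt(x$specificity),
              fmt(x$f1)))
  invisible(x)
}

#' Write a confusion-score report to CSV and text
#'
#' Emits the 2 x 2 table (prediction rows, outcome columns) as CSV and a
#' human-readable text summary alongside it.
#'
#' @param scores A `confusion_scores` object.
#' @param dir Output directory (created if needed).
#' @return The file paths, invisibly.
#' @export
write_confusion <- function(scores, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- file.path(dir, "confusion.csv")
  txt_path <- file.path(dir, "confusion.txt")
  tab <- tibble::tibble(
    prediction = rownames(scores$matrix)[c(1, 1, 2, 2)],
    outcome = colnames(scores$matrix)[c(1, 2, 1, 2)],
    count = as.vector(t(scores$matrix))
  )
  readr::write_csv(tab, csv_path, progress = FALSE)
  txt <- utils::capture.output(print(scores))
  writeLines(txt, txt_path)
  invisible(c(csv = csv_path, txt = txt_path))
}

#' F1-maximising threshold sweep
#'
#' Evaluates the F1 score on a regular grid of classification thresholds
#' `{step, 2 step, ..., 1 - step}` and returns the best threshold. With
#' heavily imbalanced outcomes (detections are rare on patrol), the
#' F1-optimal threshold typically falls well below the conventional 0.5.
#' Ties are broken toward the smallest threshold.
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param outcomes Observed binary outcomes.
#' @param step Grid step in (0, 0.5\]; default 0.01 (99 thresholds).
#' @return A tibble of class `threshold_sweep` with columns `threshold`,
#'   `precision`, `recall`, `f1`, and attributes `best_threshold` and
#'   `best_f1` (both `NA` and flagged if no threshold has a defined F1,
#'   e.g. with no positive outcomes).
#' @export
threshold_sweep <- function(probabilities, outcomes, step = 0.01) {
  stop_if_not_scalar_number(step, "step")
  if (step <= 0 || step > 0.5) abort("`step` must lie in (0, 0.5].")
  if (length(probabilities) != length(outcomes)) {
    abort("`probabilities` and `outcomes` must have equal length.")
  }
  no_positives <- sum(outcomes == 1) == 0L
  if (no_positives) {
    warn("No positive outcomes: F1 is undefined at every threshold.")
  }
  grid <- seq(step, 1 - step / 2, by = step)
  grid <- grid[grid < 1]
  n_pos <- sum(outcomes == 1)
  eval1 <- function(t) {
    pred <- probabilities >= t
    tp <- sum(pred & outcomes == 1)
    fp <- sum(pred & outcomes == 0)
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    recall <- if (n_pos == 0) NA_real_ else tp / n_pos
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
      NA_real_ else 2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, f1 = f1)
  }
  res <- t(vapply(grid, eval1, numeric(3L)))
  out <- tibble::tibble(threshold = grid,
                        precision = res[, "precision"],
                        recall = res[, "recall"],
                        f1 = res[, "f1"])
  if (all(is.na(out$f1))) {
    best_t <- NA_real_
    best_f1 <- NA_real_
  } else {
    best_i <- which(out$f1 == max(out$f1, na.rm = TRUE))[1L]
    best_t <- out$threshold[best_i]
    best_f1 <- out$f1[best_i]
  }
  structure(out,
            class = c("threshold_sweep", class(out)),
            best_threshold = best_t, best_f1 = best_f1,
            no_positives = no_positives)
}

#' @rdname threshold_sweep
#' @param sweep A `threshold_sweep` tibble.
#' @return `best_threshold()` / `best_f1()` return the stored optimum.
#' @export
best_threshold <- function(sweep) attr(sweep, "best_threshold", exact = TRUE)

#' @rdname threshold_sweep
#' @export
best_f1 <- function(sweep) attr(sweep, "best_f1", exact = TRUE)

#' Plot an F1 threshold sweep
#'
#' @param object A `threshold_sweep`.
#' @param ... Unused.
#' @return A ggplot: F1 against threshold with the optimum marked.
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$f1)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(xintercept = attr(object, "best_threshold"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Classification threshold", y = "F1 score",
                  title = sprintf("Best F1 = %.3f at threshold %.2f",
                                  attr(object, "best_f1"),
                                  attr(object, "best_threshold"))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
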