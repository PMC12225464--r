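factor_block <- c(region = "b3", actor = "b4", year = "b5",
                  violation_type = "b6", species = "b7")

#' Posterior log-odds-ratio summaries per category
#'
#' For one categorical factor, summarises the posterior of each level's
#' coefficient - the log-odds ratio of that level against the factor's
#' reference category - as the posterior mean with an equal-tailed 95%
#' credible interval, together with the share of enforcement effort
#' (proportion of patrol records) falling in that level. The reference
#' level is reported as exactly 0 with a degenerate interval.
#'
#' @param fit A `patrol_fit`.
#' @param records The records the effort shares are computed over.
#' @param factor One of `"region"`, `"actor"`, `"year"` (detection side
#'   under the default assignment) or `"species"`,
#'   `"violation_type"` (violation side).
#' @param conf_level Credible-interval mass.
#' @return A tibble of class `category_summary`: `factor`, `level`,
#'   `estimate`, `conf.low`, `conf.high`, `effort_share`, `reference`.
#' @export
summarize_categories <- function(fit, records, factor,
                                 conf_level = 0.95) {
  stopifnot(inherits(fit, "patrol_fit"))
  if (!factor %in% names(factor_block)) {
    abort(sprintf("Unknown factor `%s`; expected one of %s.", factor,
                  paste(names(factor_block), collapse = ", ")))
  }
  block <- factor_block[[factor]]
  lv_name <- names(scheme_columns)[scheme_columns == predictor_column[[factor]]]
  levels <- fit$scheme[[lv_name]]
  prefix <- sprintf("%s_%s[", block, factor)
  par_idx <- startsWith(fit$par_names, prefix)
  if (!any(par_idx)) {
    abort(sprintf("Factor `%s` was not part of the fitted model.", factor))
  }
  flat <- flatten_draws(fit$draws)[, par_idx, drop = FALSE]
  par_levels <- sub("^.*\\[(.*)\\]$", "\\1", colnames(flat))
  alpha <- (1 - conf_level) / 2

  counts <- table(factor(as.character(records[[predictor_column[[factor]]]]),
                         levels = levels))
  share <- as.numeric(counts) / sum(counts)

  rows <- lapply(seq_along(levels), function(i) {
    lv <- levels[i]
    if (i == 1L) {
      tibble::tibble(factor = factor, level = lv, estimate = 0,
                     conf.low = 0, conf.high = 0,
                     effort_share = share[i], reference = TRUE)
    } else {
      x <- flat[, match(lv, par_levels)]
      tibble::tibble(factor = factor, level = lv, estimate = mean(x),
                     conf.low = unname(quantile(x, alpha)),
                     conf.high = unname(quantile(x, 1 - alpha)),
                     effort_share = share[i], reference = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("category_summary", class(out))
  out
}

#' Plot per-category posterior log-odds ratios
#'
#' Dot-and-interval display of a [summarize_categories()] result, with
#' each level's share of enforcement effort shown in parentheses after
#' its label, in the convention of category-effect figures for
#' enforcement data.
#'
#' @param object A `category_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.category_summary <- function(object, ...) {
  object$label <- sprintf("%s (%.1f%%)", object$level,
                          100 * object$effort_share)
  object$label <- factor(object$label, levels = rev(object$label))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Log-odds ratio vs reference (mean and 95% CI)",
                  y = NULL, title = unique(object$factor)) +
    ggplot2::theme_minimal()
}

#' Annual mean detectability series
#'
#' Averages the posterior-mean conditional detection probability `p_i`
#' over each year's realised patrols (marginal over the observed
#' covariate mix, not at reference covariates), giving the model's
#' estimate of how detectability moved over the study years. Years with
#' no records are omitted with a warning.
#'
#' @param fit A `patrol_fit`.
#' @param records The records to average over.
#' @param thin Draw thinning passed to [posterior_predict()].
#' @return A tibble of class `annual_detectability`: `year`,
#'   `detectability`, `n_records`.
#' @export
annual_detectability <- function(fit, records, thin = 1L) {
  preds <- posterior_predict(fit, records, thin = thin)
  years <- fit$scheme$year_levels
  have <- as.character(records$year)
  missing_years <- setdiff(years, have)
  if (length(missing_years)) {
    warn(sprintf("Year(s) with zero records omitted: %s.",
                 paste(missing_years, collapse = ", ")))
  }
  out <- tibble::tibble(year = as.integer(have),
                        p = preds$.pred_detect) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(detectability = mean(.data$p),
                     n_records = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$year)
  class(out) <- c("annual_detectability", class(out))
  out
}

#' @rdname annual_detectability
#' @param object An `annual_detectability` tibble.
#' @param ... Unused.
#' @return `autoplot()` returns a ggplot of the series.
#' @export
autoplot.annual_detectability <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$year, y = .data$detectability)) +
    ggplot2::geom_line(colour = "seagreen") +
    ggplot2::geom_point(colour = "seagreen") +
    ggplot2::scale_x_continuous(breaks = unique(object$year)) +
    ggplot2::labs(x = "Year", y = "Mean detectability",
                  title = "Detectability, as estimated by the model") +
    ggplot2::theme_minimal()
}

#' Headline probability summaries
#'
#' The three headline numbers of a fitted analysis: across records, the
#' mean (and SD) of the posterior-mean conditional detection probability
#' `p_i` ("detectability"), of the violation probability `v_i`, and of
#' the overall probability `v_i * p_i` that a patrol records a
#' violation. Per record the product is never larger than either factor,
#' so the overall probability is the narrowest of the three.
#'
#' @param fit A `patrol_fit`.
#' @param records The records to summarise over.
#' @param thin Draw thinning passed to [posterior_predict()].
#' @return A tibble with rows `detectability`, `violation`, `overall`
#'   and columns `quantity`, `mean`, `sd`.
#' @export
headline_summary <- function(fit, records, thin = 1L) {
  preds <- posterior_predict(fit, records, thin = thin)
  sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)  # spread of one value
  tibble::tibble(
    quantity = c("detectability", "violation", "overall"),
    mean = c(mean(preds$.pred_detect), mean(preds$.pred_violation),
             mean(preds$.pred)),
    sd = c(sd0(preds$.pred_detect), sd0(preds$.pred_violation),
           sd0(preds$.pred))
  )
}
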