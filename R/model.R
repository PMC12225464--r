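#' Prior half-width of the coefficient box
#'
#' Every intercept and coefficient carries an independent uniform prior on
#' the closed interval `[-2.2, 2.2]` on the log-odds scale. A log-odds
#' ratio of 2.2 corresponds to moving a probability from 50% to about 90%
#' (and -2.2 to about 10%), so the box spans the "-90% to +90%" range of
#' practically relevant effects while keeping the parameter space bounded.
#'
#' @format A single number, 2.2.
#' @export
prior_bound <- 2.2

#' Model parameters of the conditional detection model
#'
#' Bundles the two intercepts and seven coefficient blocks of the linked
#' logit submodels, on the log-odds scale:
#' \describe{
#'   \item{`mu_p`, `mu_v`}{intercepts of the detection and violation
#'     submodels;}
#'   \item{`b1`, `b2`}{slopes of scaled patrol time and scaled enforcer
#'     group size;}
#'   \item{`b3`--`b7`}{per-level coefficients for region, actor, year,
#'     violation type, and species, each a named vector over the scheme's
#'     levels with the reference level fixed at exactly 0.}
#' }
#' Every free entry must lie in the prior box `[-2.2, 2.2]`.
#'
#' @param scheme A [category_scheme()] defining the factor levels.
#' @param mu_p,mu_v,b1,b2 Scalars (default 0).
#' @param b3,b4,b5,b6,b7 Either `NULL` (all zero), a named numeric vector
#'   of non-reference levels (missing levels default to 0), or an unnamed
#'   vector of length `n_levels - 1` assigned to the non-reference levels
#'   in scheme order.
#' @return An object of class `model_params`.
#' @export
#' @examples
#' sc <- default_scheme()
#' model_params(sc, mu_p = -1.5, b1 = 1.79, b2 = -1.52,
#'              b4 = c("Restaurant" = 1.0))
model_params <- function(scheme, mu_p = 0, mu_v = 0, b1 = 0, b2 = 0,
                         b3 = NULL, b4 = NULL, b5 = NULL, b6 = NULL,
                         b7 = NULL) {
  stopifnot(inherits(scheme, "category_scheme"))
  for (nm in c("mu_p", "mu_v", "b1", "b2")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  block_levels <- list(
    b3 = scheme$region_levels, b4 = scheme$actor_levels,
    b5 = scheme$year_levels, b6 = scheme$violation_levels,
    b7 = scheme$species_levels
  )
  expand_block <- function(x, levels, nm) {
    out <- stats::setNames(rep(0, length(levels)), levels)
    if (is.null(x)) return(out)
    if (is.null(names(x))) {
      if (length(x) != length(levels) - 1L) {
        abort(sprintf("Unnamed `%s` must have length %d (non-reference levels).",
                      nm, length(levels) - 1L))
      }
      out[-1L] <- x
      return(out)
    }
    bad <- setdiff(names(x), levels)
    if (length(bad)) {
      abort(sprintf("`%s` names not in scheme: %s.", nm,
                    paste(bad, collapse = ", ")))
    }
    if (levels[1L] %in% names(x) && x[[levels[1L]]] != 0) {
      abort(sprintf("Reference level `%s` of `%s` must have coefficient 0.",
                    levels[1L], nm))
    }
    out[names(x)] <- x
    out
  }
  params <- list(mu_p = mu_p, mu_v = mu_v, b1 = b1, b2 = b2)
  for (nm in names(block_levels)) {
    params[[nm]] <- expand_block(get(nm), block_levels[[nm]], nm)
  }
  free <- c(params$mu_p, params$mu_v, params$b1, params$b2,
            unlist(lapply(params[names(block_levels)], `[`, -1L)))
  if (any(abs(free) > prior_bound)) {
    abort(sprintf("All coefficients must lie in [-%.1f, %.1f].",
                  prior_bound, prior_bound))
  }
  structure(params, scheme = scheme, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  mu_p = %.3f  mu_v = %.3f  b1(time) = %.3f  b2(enforcers) = %.3f\n",
              x$mu_p, x$mu_v, x$b1, x$b2))
  for (nm in c("b3", "b4", "b5", "b6", "b7")) {
    nz <- sum(x[[nm]] != 0)
    cat(sprintf("  %s: %d levels, %d non-zero\n", nm, length(x[[nm]]), nz))
  }
  invisible(x)
}

# map a model_params object onto a design's parameter vector
params_to_vector <- function(params, design) {
  get1 <- function(nm) {
    if (nm %in% c("mu_p", "mu_v")) return(params[[nm]])
    if (nm == "b1_time") return(params$b1)
    if (nm == "b2_enforcers") return(params$b2)
    block <- sub("_.*$", "", nm)          # e.g. "b3"
    level <- sub("^.*\\[(.*)\\]$", "\\1", nm)
    params[[block]][[level]]
  }
  stats::setNames(vapply(design$par_names, get1, numeric(1L)),
                  design$par_names)
}

# inverse of params_to_vector for a full-model design
vector_to_params <- function(theta, design) {
  scheme <- design$scheme
  pull_block <- function(block, pred) {
    nms <- grep(sprintf("^%s_%s\\[", block, pred), names(theta), value = TRUE)
    if (!length(nms)) return(NULL)
    stats::setNames(theta[nms], sub("^.*\\[(.*)\\]$", "\\1", nms))
  }
  model_params(
    scheme,
    mu_p = unname(theta[["mu_p"]]), mu_v = unname(theta[["mu_v"]]),
    b1 = if ("b1_time" %in% names(theta)) unname(theta[["b1_time"]]) else 0,
    b2 = if ("b2_enforcers" %in% names(theta))
      unname(theta[["b2_enforcers"]]) else 0,
    b3 = pull_block("b3", "region"), b4 = pull_block("b4", "actor"),
    b5 = pull_block("b5", "year"), b6 = pull_block("b6", "violation_type"),
    b7 = pull_block("b7", "species")
  )
}

# shared engine for the two linear predictors
submodel_logit <- function(records, params, scheme, preds, intercept) {
  eta <- rep(params[[intercept]], nrow(records))
  for (pred in preds) {
    if (pred == "time") {
      eta <- eta + params$b1 * records$time_scaled
    } else if (pred == "enforcers") {
      eta <- eta + params$b2 * records$enforcers_scaled
    } else {
      block <- params[[predictor_block[[pred]]]]
      x <- as.character(records[[predictor_column[[pred]]]])
      idx <- match(x, names(block))
      if (anyNA(idx)) {
        abort(sprintf("Record value(s) of `%s` not among fitted levels: %s.",
                      pred, paste(unique(x[is.na(idx)]), collapse = ", ")))
      }
      eta <- eta + unname(block[idx])
    }
  }
  eta
}

#' Linear predictors of the two submodels
#'
#' `detection_logit()` evaluates the detection-side linear predictor
#' `mu_p + b1*T + b2*N + b3[region] + b4[actor] + b5[year]` and
#' `violation_logit()` the violation-side predictor
#' `mu_v + b6[violation_type] + b7[species]`, for each record, under the
#' given [model_spec()] assignment (defaults shown). Continuous covariates
#' must already be scaled to \[0, 1\]; call [scale_continuous()] first
#' (done automatically if the scaled columns are missing).
#'
#' @param records A records tibble (scaled).
#' @param params A [model_params()] object.
#' @param spec A [model_spec()].
#' @return Numeric vector of log-odds, one per record.
#' @export
detection_logit <- function(records, params, spec = model_spec()) {
  if (any(c("time", "enforcers") %in% spec$detection) &&
      is.null(records$time_scaled)) {
    records <- scale_continuous(records, scaling = scaling_info(records))
  }
  submodel_logit(records, params, attr(params, "scheme"), spec$detection,
                 "mu_p")
}

#' @rdname detection_logit
#' @export
violation_logit <- function(records, params, spec = model_spec()) {
  if (any(c("time", "enforcers") %in% spec$violation) &&
      is.null(records$time_scaled)) {
    records <- scale_continuous(records, scaling = scaling_info(records))
  }
  submodel_logit(records, params, attr(params, "scheme"), spec$violation,
                 "mu_v")
}

#' Marginal probability of a patrol outcome
#'
#' The observation model is a two-stage Bernoulli process: a violation is
#' present with probability `v`, and, conditional on presence, detected
#' with probability `p`; a violation that is absent can never be detected.
#' Marginalising the latent presence indicator gives
#' `P(y = 1) = v * p` and `P(y = 0) = 1 - v * p`.
#' `marginal_obs_logprob()` is the numerically stable log version (uses
#' `log1p` for outcomes of 0).
#'
#' @param v Violation probabilities in \[0, 1\].
#' @param p Conditional detection probabilities in \[0, 1\].
#' @param y Binary outcomes (0/1), recycled against `v`/`p`.
#' @return Probabilities (or log-probabilities) of the observed outcomes.
#' @export
#' @examples
#' marginal_obs_prob(v = 0.34, p = 0.18, y = 1)  # 0.0612
marginal_obs_prob <- function(v, p, y) {
  check_prob <- function(x, nm) {
    if (any(!is.finite(x) | x < 0 | x > 1)) {
      abort(sprintf("`%s` must lie in [0, 1].", nm))
    }
  }
  check_prob(v, "v"); check_prob(p, "p")
  if (any(!(y %in% c(0, 1)))) abort("`y` must be binary (0/1).")
  ifelse(y == 1, v * p, 1 - v * p)
}

#' @rdname marginal_obs_prob
#' @export
marginal_obs_logprob <- function(v, p, y) {
  check_prob <- function(x, nm) {
    if (any(!is.finite(x) | x < 0 | x > 1)) {
      abort(sprintf("`%s` must lie in [0, 1].", nm))
    }
  }
  check_prob(v, "v"); check_prob(p, "p")
  if (any(!(y %in% c(0, 1)))) abort("`y` must be binary (0/1).")
  ifelse(y == 1, log(v) + log(p), log1p(-v * p))
}

# log-likelihood directly from the two linear predictors (stable)
loglik_from_logits <- function(eta_p, eta_v, y) {
  lp <- plogis(eta_p, log.p = TRUE)
  lv <- plogis(eta_v, log.p = TRUE)
  lvp <- lp + lv
  ifelse(y == 1, lvp, log1m_exp(lvp))
}

#' Log-prior density of the parameters
#'
#' Independent uniform priors on the closed box `[-2.2, 2.2]` for both
#' intercepts, both continuous slopes, and every non-reference categorical
#' coefficient (reference-level zeros carry no prior mass of their own).
#' Returns the exact log-density, `-k * log(4.4)` inside the box for `k`
#' free parameters, and `-Inf` outside.
#'
#' @param params A [model_params()] object, or a plain numeric vector of
#'   free parameters.
#' @return A single log-density value.
#' @export
log_prior <- function(params) {
  if (inherits(params, "model_params")) {
    free <- c(params$mu_p, params$mu_v, params$b1, params$b2,
              unlist(lapply(params[c("b3", "b4", "b5", "b6", "b7")],
                            `[`, -1L)))
  } else {
    free <- as.numeric(params)
  }
  if (any(abs(free) > prior_bound)) return(-Inf)
  -length(free) * log(2 * prior_bound)
}

#' Log-posterior density of the conditional detection model
#'
#' Sums the marginal log-likelihood of every record (the latent violation
#' indicator is marginalised analytically) and adds the box-uniform
#' log-prior. This is the target density the sampler explores.
#'
#' @inheritParams detection_logit
#' @return A single log-density value (`-Inf` outside the prior box).
#' @export
log_posterior <- function(records, params, spec = model_spec()) {
  lp <- log_prior(params)
  if (!is.finite(lp) || nrow(records) == 0L) return(lp)
  eta_p <- detection_logit(records, params, spec)
  eta_v <- violation_logit(records, params, spec)
  lp + sum(loglik_from_logits(eta_p, eta_v, records$outcome))
}

#' Complete-data log-likelihood given the latent violation indicators
#'
#' The unmarginalised counterpart of the observation model: given latent
#' presence indicators `s`, each record contributes
#' `P(s | v) * P(y | p, s)` with `P(y = 1 | p, s) = p * s`. Summing this
#' over the two values of each `s_i` recovers the marginal likelihood;
#' the function exists so that equivalence can be verified, the sampler
#' itself always uses the marginal form.
#'
#' @inheritParams detection_logit
#' @param s Integer vector of latent violation indicators (0/1).
#' @return A single log-likelihood value (no prior term).
#' @export
complete_data_loglik <- function(records, params, s, spec = model_spec()) {
  stopifnot(length(s) == nrow(records), all(s %in% c(0L, 1L)))
  v <- inv_logit(violation_logit(records, params, spec))
  p <- inv_logit(detection_logit(records, params, spec))
  y <- records$outcome
  py_given_s <- ifelse(y == 1, p * s, 1 - p * s)
  ps <- ifelse(s == 1, v, 1 - v)
  sum(log(py_given_s) + log(ps))
}

#' Serialize or restore model parameters as JSON
#'
#' Parameters are written keyed by factor level names (not positional
#' indices), so a fit is portable across schemes that share level labels.
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @param scheme A [category_scheme()] used to validate on read.
#' @return `write_params_json()` returns `params` invisibly;
#'   `read_params_json()` returns a [model_params()].
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  out <- list(
    mu_p = params$mu_p, mu_v = params$mu_v,
    b1 = params$b1, b2 = params$b2,
    b3 = as.list(params$b3), b4 = as.list(params$b4),
    b5 = as.list(params$b5), b6 = as.list(params$b6),
    b7 = as.list(params$b7)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(params)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path, scheme) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(
    scheme, mu_p = x$mu_p, mu_v = x$mu_v, b1 = x$b1, b2 = x$b2,
    b3 = unlist(x$b3), b4 = unlist(x$b4), b5 = unlist(x$b5),
    b6 = unlist(x$b6), b7 = unlist(x$b7)
  )
}
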