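#' Sample the posterior of the conditional detection model
#'
#' Runs multiple independent chains of componentwise adaptive random-walk
#' Metropolis over the box-uniform prior. Each chain starts from an
#' independent uniform draw over the prior box (dispersed initial
#' points), adapts its proposal scales during warmup toward 44%
#' acceptance, and freezes them for the sampling phase so retained draws
#' form a Markov chain. The latent violation indicators are marginalised
#' analytically, so the sampled state is just the intercepts and
#' coefficients. Defaults follow the analysis the package accompanies:
#' 3 chains, 600 warmup and 2400 sampling iterations.
#'
#' @param records A records tibble with binary `outcome`.
#' @param scheme A [category_scheme()]; defaults to the attached scheme.
#' @param spec A [model_spec()].
#' @param chains Number of chains (>= 1; >= 2 needed for Rhat).
#' @param warmup,iter Warmup and retained iterations per chain.
#' @param seed Master integer seed; per-chain seeds are derived from it.
#' @param save_loglik Keep the pointwise log-likelihood of each retained
#'   draw (needed for [compute_waic()]; memory scales with
#'   `chains * iter * nrow(records) / loglik_thin`).
#' @param loglik_thin Keep every `loglik_thin`-th draw's pointwise
#'   log-likelihood.
#' @return An object of class `patrol_fit`: a list with `draws` (a
#'   chains x iterations x parameters array), `loglik` (chains x kept
#'   iterations x records array, or `NULL`), `meta` (chains, warmup,
#'   sampling, seed), `par_names`, `accept_rate`, plus the `scheme`,
#'   `scaling`, and `spec` needed to score new data.
#' @export
#' @examples
#' recs <- simulate_records(paper_like_config(
#'   n_records = 300, seed = 1, n_regions = 2, n_actors = 2,
#'   n_species = 2, n_violations = 2, years = 2014:2015))
#' fit <- sample_posterior(recs, chains = 2, warmup = 100, iter = 200,
#'                         seed = 1, save_loglik = FALSE)
#' tidy(fit)
sample_posterior <- function(records, scheme = records_scheme(records),
                             spec = model_spec(), chains = 3,
                             warmup = 600, iter = 2400, seed = 1L,
                             save_loglik = TRUE, loglik_thin = 1L) {
  if (nrow(records) == 0L) abort("Cannot fit a model to zero records.")
  if (chains < 1L) abort("`chains` must be at least 1.")
  if (warmup < 1L || iter < 1L) {
    abort("`warmup` and `iter` must be positive.")
  }
  if (length(unique(records$outcome)) == 1L) {
    warn("All outcomes are identical; the posterior is prior-dominated.")
  }
  design <- build_design(records, scheme, spec)
  k <- length(design$par_names)
  kp <- ncol(design$X_p)

  chain_seeds <- withr_seed(seed,
                            sample.int(.Machine$integer.max - 10L, chains))
  run_chain <- function(cs) {
    withr_seed(cs, {
      init <- runif(k, -prior_bound, prior_bound)
      sample_chain_cpp(design$X_p, design$X_v, design$y, init,
                       as.integer(warmup), as.integer(iter), prior_bound,
                       save_loglik, as.integer(loglik_thin))
    })
  }
  runs <- lapply(chain_seeds, run_chain)

  draws <- array(NA_real_, c(chains, iter, k),
                 dimnames = list(NULL, NULL, design$par_names))
  for (c in seq_len(chains)) draws[c, , ] <- runs[[c]]$draws
  loglik <- NULL
  if (save_loglik) {
    n_saved <- nrow(runs[[1L]]$loglik)
    loglik <- array(NA_real_, c(chains, n_saved, nrow(records)))
    for (c in seq_len(chains)) loglik[c, , ] <- runs[[c]]$loglik
  }

  structure(
    list(
      draws = draws,
      loglik = loglik,
      meta = list(n_chains = as.integer(chains),
                  n_warmup = as.integer(warmup),
                  n_sampling = as.integer(iter),
                  seed = as.integer(seed),
                  loglik_thin = as.integer(loglik_thin)),
      par_names = design$par_names,
      n_detection_pars = kp,
      accept_rate = rowMeans(vapply(runs, function(r) r$accept_rate,
                                    numeric(k))),
      scheme = design$scheme,
      scaling = design$scaling,
      spec = design$spec,
      n_records = nrow(records)
    ),
    class = "patrol_fit"
  )
}

#' @export
print.patrol_fit <- function(x, ...) {
  cat(sprintf(
    "<patrol_fit: %d parameters, %d chains x %d draws (%d warmup), n = %d>\n",
    length(x$par_names), x$meta$n_chains, x$meta$n_sampling,
    x$meta$n_warmup, x$n_records))
  invisible(x)
}

# flatten a chains x iter x k array into (chains*iter) x k
flatten_draws <- function(draws) {
  k <- dim(draws)[3L]
  out <- matrix(aperm(draws, c(2L, 1L, 3L)),
                nrow = dim(draws)[1L] * dim(draws)[2L], ncol = k)
  colnames(out) <- dimnames(draws)[[3L]]
  out
}

#' Split-chain Gelman-Rubin diagnostics
#'
#' Splits every chain in half, computes the classic Gelman-Rubin
#' potential scale reduction factor (Rhat) per parameter from the
#' between- and within-half-chain variances, and an effective sample
#' size from the combined autocorrelation (Geyer initial-positive-pair
#' truncation). Convergence passes when every Rhat falls below the
#' threshold, 1.1 by convention.
#'
#' @param x A `patrol_fit` or a chains x iterations x parameters array.
#' @param threshold Rhat value below which a parameter counts as
#'   converged.
#' @return An object of class `convergence_report`: list with `summary`
#'   (tibble of `parameter`, `rhat`, `ess`), `pass` (all Rhat below
#'   threshold), `threshold`, and `max_rhat`.
#' @export
compute_rhat <- function(x, threshold = 1.1) {
  draws <- if (inherits(x, "patrol_fit")) x$draws else x
  if (length(dim(draws)) != 3L) {
    abort("`x` must be a patrol_fit or a chains x iterations x parameters array.")
  }
  m <- dim(draws)[1L]
  n <- dim(draws)[2L]
  if (m < 2L) {
    abort("Rhat needs at least 2 chains; re-run the sampler with `chains >= 2`.")
  }
  if (n < 4L) abort("Rhat needs at least 4 draws per chain.")
  n2 <- n %/% 2L
  pars <- dimnames(draws)[[3L]] %||% paste0("par", seq_len(dim(draws)[3L]))

  one_par <- function(j) {
    # split each chain into halves -> 2m sequences of length n2
    halves <- vector("list", 2L * m)
    for (c in seq_len(m)) {
      halves[[2L * c - 1L]] <- draws[c, seq_len(n2), j]
      halves[[2L * c]] <- draws[c, n2 + seq_len(n2), j]
    }
    mns <- vapply(halves, mean, numeric(1L))
    vars <- vapply(halves, var, numeric(1L))
    W <- mean(vars)
    B <- n2 * var(mns)
    var_hat <- (n2 - 1) / n2 * W + B / n2
    rhat <- if (W < .Machine$double.eps) {
      if (B < .Machine$double.eps) 1.0 else Inf
    } else {
      sqrt(var_hat / W)
    }

    ess <- if (W < .Machine$double.eps) NA_real_ else {
      lag_max <- min(n2 - 1L, 500L)
      acov <- vapply(halves, function(h) {
        stats::acf(h, lag.max = lag_max, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
      }, numeric(lag_max + 1L))
      rho <- 1 - (W - rowMeans(acov)) / var_hat  # rho[1] is lag 0
      # Geyer: sum initial positive pairs of autocorrelations
      tau <- 0
      t <- 2L
      prev <- Inf
      while (t + 1L <= length(rho)) {
        pair <- rho[t] + rho[t + 1L]
        if (pair < 0) break
        pair <- min(pair, prev)  # enforce monotone decrease
        tau <- tau + pair
        prev <- pair
        t <- t + 2L
      }
      min(2L * m * n2, 2L * m * n2 / (1 + 2 * tau))
    }
    c(rhat = rhat, ess = ess)
  }

  stats_mat <- vapply(seq_along(pars), one_par, numeric(2L))
  summary <- tibble::tibble(parameter = pars,
                            rhat = stats_mat["rhat", ],
                            ess = stats_mat["ess", ])
  structure(
    list(summary = summary,
         pass = all(summary$rhat < threshold),
         threshold = threshold,
         max_rhat = max(summary$rhat)),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report: max Rhat = %.4f, %s (threshold %.2f)>\n",
              x$max_rhat, if (x$pass) "PASS" else "FAIL", x$threshold))
  invisible(x)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Widely applicable information criterion
#'
#' Computes WAIC from the pointwise log-likelihood of the retained draws:
#' `lppd` is the sum over records of the log of the posterior-mean
#' likelihood, the effective-parameter penalty is the sum of pointwise
#' posterior variances of the log-likelihood (the variance-based pWAIC2
#' form), and `WAIC = -2 * (lppd - p_waic)`. Lower is better.
#'
#' @param x A `patrol_fit` fitted with `save_loglik = TRUE`, or a
#'   draws x records matrix of pointwise log-likelihoods.
#' @return An object of class `waic_result`: list with `waic`, `lppd`,
#'   `p_waic`, `elpd` (= `lppd - p_waic`), `n_draws`, and a `pointwise`
#'   tibble.
#' @export
compute_waic <- function(x) {
  if (inherits(x, "patrol_fit")) {
    if (is.null(x$loglik)) {
      abort("Fit has no pointwise log-likelihood; re-run with `save_loglik = TRUE`.")
    }
    ll <- matrix(aperm(x$loglik, c(2L, 1L, 3L)),
                 nrow = dim(x$loglik)[1L] * dim(x$loglik)[2L],
                 ncol = dim(x$loglik)[3L])
  } else {
    ll <- as.matrix(x)
  }
  bad <- which(!is.finite(ll), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("Non-finite log-likelihood for record(s): %s.",
                  paste(unique(bad[, 2L]), collapse = ", ")))
  }
  S <- nrow(ll)
  lppd_i <- apply(ll, 2L, log_sum_exp) - log(S)
  p_i <- apply(ll, 2L, var)
  if (S == 1L) p_i <- rep(0, ncol(ll))
  structure(
    list(waic = -2 * sum(lppd_i - p_i),
         lppd = sum(lppd_i),
         p_waic = sum(p_i),
         elpd = sum(lppd_i - p_i),
         n_draws = S,
         pointwise = tibble::tibble(record = seq_len(ncol(ll)),
                                    lppd = lppd_i, p_waic = p_i)),
    class = "waic_result"
  )
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("<waic_result: WAIC = %.2f (lppd = %.2f, p_waic = %.2f, %d draws)>\n",
              x$waic, x$lppd, x$p_waic, x$n_draws))
  invisible(x)
}

#' Fit a ladder of model specifications and rank them by WAIC
#'
#' Fits each supplied [model_spec()] to the same records (same sampler
#' settings and seed) and returns their WAIC ranking, lowest (best)
#' first. This is how the final predictor assignment is selected: start
#' from a null model, add predictors, and also try alternative
#' hypotheses such as moving the spatial and temporal predictors to the
#' violation side.
#'
#' @param records A records tibble.
#' @param specs Named list of [model_spec()] objects.
#' @param ... Passed to [sample_posterior()] (chains, warmup, iter, seed,
#'   ...). `save_loglik` is forced on.
#' @return A tibble with columns `model`, `waic`, `lppd`, `p_waic`,
#'   `max_rhat`, sorted by `waic`; the fitted objects (with pointwise
#'   log-likelihoods dropped to save memory) are attached as attribute
#'   `"fits"`.
#' @export
fit_model_ladder <- function(records, specs, ...) {
  if (!length(specs)) abort("`specs` must contain at least one model_spec.")
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- vapply(seq_along(specs), function(i) {
      specs[[i]]$name %||% paste0("model", i)
    }, character(1L))
  }
  args <- list(...)
  args$save_loglik <- TRUE
  rows <- vector("list", length(specs))
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    fit <- do.call(sample_posterior,
                   c(list(records = records, spec = specs[[i]]), args))
    w <- compute_waic(fit)
    conv <- compute_rhat(fit)
    rows[[i]] <- tibble::tibble(model = names(specs)[i], waic = w$waic,
                                lppd = w$lppd, p_waic = w$p_waic,
                                max_rhat = conv$max_rhat)
    fit$loglik <- NULL
    fits[[i]] <- fit
  }
  names(fits) <- names(specs)
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$waic)
  attr(out, "fits") <- fits
  out
}

#' Tidy posterior summaries of a fitted model
#'
#' @param x A `patrol_fit`.
#' @param conf_level Credible-interval mass (equal-tailed percentiles).
#' @param ... Unused.
#' @return A tibble with one row per sampled parameter: `term`,
#'   `estimate` (posterior mean), `std.error` (posterior SD),
#'   `conf.low`, `conf.high`, `rhat`, `ess`.
#' @export
tidy.patrol_fit <- function(x, conf_level = 0.95, ...) {
  flat <- flatten_draws(x$draws)
  alpha <- (1 - conf_level) / 2
  conv <- compute_rhat(x)
  tibble::tibble(
    term = x$par_names,
    estimate = colMeans(flat),
    std.error = apply(flat, 2L, sd),
    conf.low = apply(flat, 2L, quantile, probs = alpha),
    conf.high = apply(flat, 2L, quantile, probs = 1 - alpha),
    rhat = conv$summary$rhat,
    ess = conv$summary$ess
  )
}

#' One-row summary of a fitted model
#'
#' @param x A `patrol_fit`.
#' @param ... Unused.
#' @return A one-row tibble: record count, chain geometry, parameter
#'   count, max Rhat, convergence flag, and WAIC (NA when the pointwise
#'   log-likelihood was not kept).
#' @export
glance.patrol_fit <- function(x, ...) {
  conv <- compute_rhat(x)
  tibble::tibble(
    n_records = x$n_records,
    n_chains = x$meta$n_chains,
    n_warmup = x$meta$n_warmup,
    n_sampling = x$meta$n_sampling,
    n_parameters = length(x$par_names),
    max_rhat = conv$max_rhat,
    converged = conv$pass,
    waic = if (is.null(x$loglik)) NA_real_ else compute_waic(x)$waic
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Persist posterior draws as tidy CSV plus JSON metadata
#'
#' Writes the retained draws in long format (`chain`, `iter`,
#' `parameter`, `value`) alongside a JSON block with the chain geometry
#' and seed, so every reported interval can be recomputed from the files
#' alone. `read_draws()` restores the draws array and metadata.
#'
#' @param fit A `patrol_fit`.
#' @param dir Output directory (created if needed).
#' @return `write_draws()` returns the paths invisibly; `read_draws()` a
#'   list with `draws` and `meta`.
#' @export
write_draws <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- tidyr::pivot_longer(
    dplyr::bind_rows(lapply(seq_len(dim(fit$draws)[1L]), function(c) {
      d <- tibble::as_tibble(as.data.frame(fit$draws[c, , , drop = TRUE]))
      names(d) <- fit$par_names
      d$chain <- c
      d$iter <- seq_len(nrow(d))
      d
    })),
    cols = -c("chain", "iter"), names_to = "parameter",
    values_to = "value"
  )
  draws_path <- file.path(dir, "draws.csv")
  meta_path <- file.path(dir, "meta.json")
  readr::write_csv(long, draws_path, progress = FALSE)
  jsonlite::write_json(c(fit$meta, list(par_names = fit$par_names)),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(draws = draws_path, meta = meta_path))
}

#' @rdname write_draws
#' @export
read_draws <- function(dir) {
  long <- readr::read_csv(file.path(dir, "draws.csv"),
                          col_types = "iicd", progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pars <- meta$par_names
  chains <- sort(unique(long$chain))
  iters <- max(long$iter)
  draws <- array(NA_real_, c(length(chains), iters, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (c in chains) {
    sub <- long[long$chain == c, ]
    wide <- tidyr::pivot_wider(sub, names_from = "parameter",
                               values_from = "value")
    draws[c, , ] <- as.matrix(wide[pars])
  }
  list(draws = draws, meta = meta[setdiff(names(meta), "par_names")])
}
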