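predictor_names <- c("time", "enforcers", "region", "actor", "year",
                     "violation_type", "species")

# canonical coefficient block per predictor
predictor_block <- c(
  time = "b1", enforcers = "b2", region = "b3", actor = "b4", year = "b5",
  violation_type = "b6", species = "b7"
)

# record column carrying each categorical predictor
predictor_column <- c(region = "region", actor = "actor", year = "year",
                      violation_type = "violation_type", species = "species")

#' Specify which predictors enter which submodel
#'
#' The model has two linked logit submodels: one for the conditional
#' probability that a patrol detects a violation ("detection") and one for
#' the probability that a violation is present ("violation"). A model spec
#' assigns each predictor to at most one submodel. The default is the
#' full assignment used throughout the package: patrol time, enforcer
#' group size, region, actor, and year drive detection; species and
#' violation type drive violation occurrence. A null model (intercepts
#' only) is `model_spec(character(0), character(0))`.
#'
#' @param detection Character vector of predictors in the detection
#'   submodel, drawn from `"time"`, `"enforcers"`, `"region"`, `"actor"`,
#'   `"year"`, `"violation_type"`, `"species"`.
#' @param violation Character vector of predictors in the violation
#'   submodel (same choices; disjoint from `detection`).
#' @param name Optional label used in model-comparison tables.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec()                                   # the full assignment
#' model_spec(character(0), character(0), "null") # intercepts only
#' # alternative hypothesis: spatial/temporal structure on the violation side
#' model_spec(detection = c("time", "enforcers", "actor"),
#'            violation = c("species", "violation_type", "region", "year"))
model_spec <- function(detection = c("time", "enforcers", "region", "actor",
                                     "year"),
                       violation = c("species", "violation_type"),
                       name = NULL) {
  detection <- as.character(detection)
  violation <- as.character(violation)
  bad <- setdiff(c(detection, violation), predictor_names)
  if (length(bad)) {
    abort(sprintf("Unknown predictor(s): %s.", paste(bad, collapse = ", ")))
  }
  both <- intersect(detection, violation)
  if (length(both)) {
    abort(sprintf("Predictor(s) in both submodels: %s.",
                  paste(both, collapse = ", ")))
  }
  structure(list(detection = detection, violation = violation,
                 name = name %||% if (!length(c(detection, violation)))
                   "null" else "custom"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec: %s>\n  detection: %s\n  violation: %s\n",
              x$name,
              if (length(x$detection)) paste(x$detection, collapse = " + ")
              else "(intercept only)",
              if (length(x$violation)) paste(x$violation, collapse = " + ")
              else "(intercept only)"))
  invisible(x)
}

# one predictor -> its design columns (matrix with named columns)
predictor_design <- function(records, scheme, pred) {
  n <- nrow(records)
  if (pred == "time") {
    matrix(records$time_scaled, n, 1L, dimnames = list(NULL, "b1_time"))
  } else if (pred == "enforcers") {
    matrix(records$enforcers_scaled, n, 1L,
           dimnames = list(NULL, "b2_enforcers"))
  } else {
    col <- predictor_column[[pred]]
    lv_name <- names(scheme_columns)[scheme_columns == col]
    levels <- scheme[[lv_name]]
    x <- as.character(records[[col]])
    if (any(!(x %in% levels))) {
      abort(sprintf("Record value(s) of `%s` not in scheme: %s.", col,
                    paste(unique(setdiff(x, levels)), collapse = ", ")))
    }
    nonref <- levels[-1L]
    m <- matrix(0, n, length(nonref),
                dimnames = list(NULL, sprintf("%s_%s[%s]",
                                              predictor_block[[pred]],
                                              pred, nonref)))
    for (k in seq_along(nonref)) m[, k] <- as.numeric(x == nonref[k])
    m
  }
}

#' Build the two design matrices of the conditional model
#'
#' Expands a records tibble into the detection-side and violation-side
#' design matrices (reference-level treatment coding, intercept first),
#' ready for the sampler. Continuous covariates are min-max scaled if the
#' scaled columns are not already present.
#'
#' @param records A records tibble.
#' @param scheme A [category_scheme()]; defaults to the attached scheme.
#' @param spec A [model_spec()].
#' @return A list with elements `X_p` and `X_v` (design matrices with
#'   named columns, intercepts `mu_p` / `mu_v`), `y` (integer outcomes),
#'   `par_names` (all sampled parameters, detection block first),
#'   `scaling`, `scheme`, and `spec`.
#' @export
build_design <- function(records, scheme = records_scheme(records),
                         spec = model_spec()) {
  needs_cont <- any(c("time", "enforcers") %in%
                      c(spec$detection, spec$violation))
  if (needs_cont && is.null(records$time_scaled)) {
    records <- scale_continuous(records, scaling = scaling_info(records))
  }
  n <- nrow(records)
  if (n == 0L) abort("Cannot build a design from zero records.")

  side <- function(preds, intercept) {
    blocks <- c(list(matrix(1, n, 1L, dimnames = list(NULL, intercept))),
                lapply(preds, predictor_design,
                       records = records, scheme = scheme))
    do.call(cbind, blocks)
  }
  X_p <- side(spec$detection, "mu_p")
  X_v <- side(spec$violation, "mu_v")

  list(
    X_p = X_p, X_v = X_v,
    y = as.integer(records$outcome),
    par_names = c(colnames(X_p), colnames(X_v)),
    scaling = scaling_info(records),
    scheme = scheme,
    spec = spec
  )
}
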