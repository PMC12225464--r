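#' Read enforcement-patrol records from CSV
#'
#' Reads a CSV of patrol actions, one row per enforcement action, validates
#' every row, and attaches the category scheme in use. The file must have
#' the columns `year`, `region`, `actor`, `species`, `violation_type`,
#' `time_minutes`, `n_enforcers`, `outcome`. Rows that fail validation
#' (missing values, negative patrol time, fewer than one enforcer, an
#' outcome other than 0/1, or - under a fixed scheme - an unknown category
#' label) are dropped and counted in the attached drop report; a missing
#' column is an error.
#'
#' @param path Path to a CSV file.
#' @param scheme Optional [category_scheme()]. If `NULL`, levels are
#'   inferred from the data in order of first appearance.
#' @return A tibble of validated records with attributes `scheme`
#'   (the [category_scheme()] used) and `drop_report` (a list with
#'   `n_read`, `n_kept`, `invalid_rows`, and a per-reason count tibble),
#'   retrievable via [records_scheme()] and [drop_report()].
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' recs <- simulate_records(paper_like_config(n_records = 50, seed = 1))
#' write_records(recs, path)
#' again <- read_records(path)
#' drop_report(again)$invalid_rows
read_records <- function(path, scheme = NULL) {
  # a missing column is reported by the check below, not by the parser
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      year = readr::col_integer(),
      region = readr::col_character(),
      actor = readr::col_character(),
      species = readr::col_character(),
      violation_type = readr::col_character(),
      time_minutes = readr::col_double(),
      n_enforcers = readr::col_integer(),
      outcome = readr::col_integer()
    ),
    progress = FALSE
  ))
  missing_cols <- setdiff(record_columns, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("CSV is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[record_columns]
  validate_records(raw, scheme = scheme)
}

record_columns <- c("year", "region", "actor", "species", "violation_type",
                    "time_minutes", "n_enforcers", "outcome")

#' Validate a data frame of patrol records
#'
#' Applies the row-level validity rules used by [read_records()] to an
#' in-memory data frame: complete cases only, `time_minutes >= 0`,
#' `n_enforcers >= 1`, `outcome` in 0/1, and (under a fixed scheme)
#' category membership. Invalid rows are dropped and counted.
#'
#' @inheritParams read_records
#' @param records Data frame with the columns listed under [read_records()].
#' @return As [read_records()].
#' @export
validate_records <- function(records, scheme = NULL) {
  records <- tibble::as_tibble(records)[record_columns]
  records$year <- as.integer(records$year)
  n_read <- nrow(records)

  reasons <- character(0)
  bad <- rep(FALSE, n_read)
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    new <- cond & !bad
    if (any(new)) reasons <<- c(reasons, rep(why, sum(new)))
    bad <<- bad | cond
  }
  flag(!stats::complete.cases(records), "missing value")
  flag(records$time_minutes < 0, "negative time_minutes")
  flag(records$n_enforcers < 1, "n_enforcers < 1")
  flag(!(records$outcome %in% c(0L, 1L)), "outcome not 0/1")

  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "category_scheme"))
    for (nm in names(scheme_columns)) {
      col <- scheme_columns[[nm]]
      flag(!(as.character(records[[col]]) %in% scheme[[nm]]),
           sprintf("unknown %s", col))
    }
  }

  kept <- records[!bad, ]
  if (is.null(scheme)) {
    if (nrow(kept) == 0L) {
      abort("No valid records and no scheme supplied; cannot infer levels.")
    }
    scheme <- infer_scheme(kept)
  }

  report <- list(
    n_read = n_read,
    n_kept = nrow(kept),
    invalid_rows = n_read - nrow(kept),
    reasons = if (length(reasons)) {
      dplyr::count(tibble::tibble(reason = reasons), .data$reason, name = "n")
    } else {
      tibble::tibble(reason = character(0), n = integer(0))
    }
  )
  if (report$invalid_rows > 0) {
    warn(sprintf("Dropped %d invalid row(s) out of %d.",
                 report$invalid_rows, n_read))
  }
  structure(kept, scheme = scheme, drop_report = report)
}

#' Write patrol records to CSV
#'
#' Writes the canonical eight-column CSV that [read_records()] reads back.
#'
#' @param records A records tibble.
#' @param path Output file path.
#' @return `records`, invisibly.
#' @export
write_records <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records)[record_columns], path,
                   progress = FALSE)
  invisible(records)
}

#' Accessors for record attributes
#'
#' @param records A records tibble produced by [read_records()],
#'   [validate_records()], or [simulate_records()].
#' @return `records_scheme()` returns the attached [category_scheme()]
#'   (inferring one if absent); `drop_report()` the drop report list (or
#'   `NULL`); `latent_truth()` the simulated latent truth tibble (or
#'   `NULL` for real data).
#' @export
records_scheme <- function(records) {
  attr(records, "scheme", exact = TRUE) %||% infer_scheme(records)
}

#' @rdname records_scheme
#' @export
drop_report <- function(records) attr(records, "drop_report", exact = TRUE)

#' @rdname records_scheme
#' @export
latent_truth <- function(records) attr(records, "truth", exact = TRUE)

#' Collapse minority categories of a factor
#'
#' Relabels levels of one categorical covariate according to a mapping
#' (old label to new label), e.g. merging small-scale boats into
#' small-scale fishers, or pooling rare violation types into an "Other"
#' class. The record count is always conserved; only labels change. The
#' attached scheme is rebuilt with the collapsed level set (order of first
#' appearance in the updated scheme; the reference level keeps its
#' position unless itself remapped).
#'
#' @param records A records tibble.
#' @param factor One of `"region"`, `"actor"`, `"species"`,
#'   `"violation_type"`, `"year"`.
#' @param mapping Named character vector: names are existing labels,
#'   values their replacement. Targets may be existing levels or new
#'   labels.
#' @return The relabelled records tibble with an updated scheme attribute.
#' @export
#' @examples
#' recs <- simulate_records(paper_like_config(n_records = 20, seed = 1))
#' merged <- collapse_categories(recs, "violation_type",
#'                               c("Gear" = "Other", "Size limit" = "Other"))
#' nrow(merged) == nrow(recs)
collapse_categories <- function(records, factor, mapping) {
  factor <- match.arg(factor, unname(scheme_columns))
  scheme <- records_scheme(records)
  truth <- latent_truth(records)
  lv_name <- names(scheme_columns)[scheme_columns == factor]
  levels <- scheme[[lv_name]]

  if (length(mapping) == 0L) return(records)
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    abort("`mapping` must be a named character vector (old -> new).")
  }
  unknown <- setdiff(names(mapping), levels)
  if (length(unknown)) {
    abort(sprintf("Mapping source label(s) not in scheme: %s.",
                  paste(unknown, collapse = ", ")))
  }

  col <- as.character(records[[factor]])
  hit <- col %in% names(mapping)
  col[hit] <- unname(mapping[col[hit]])

  new_levels <- unique(ifelse(levels %in% names(mapping),
                              unname(mapping[levels]), levels))
  scheme[[lv_name]] <- new_levels
  scheme <- do.call(category_scheme, stats::setNames(
    scheme[names(scheme_columns)], names(scheme_columns)))

  records[[factor]] <- if (factor == "year") as.integer(col) else col
  structure(records, scheme = scheme, truth = truth,
            drop_report = drop_report(records))
}

#' Min-max scale the continuous covariates
#'
#' Scales `time_minutes` and `n_enforcers` to the unit interval via
#' `(x - min) / (max - min)`, appending `time_scaled` and
#' `enforcers_scaled` columns. The min/max used are stored in a
#' `scaling` attribute so the identical affine map can be applied to
#' held-out data (values beyond the training range are clipped to
#' \[0, 1\] with a warning). A constant column is an error: its scaling
#' would be degenerate.
#'
#' @param records A records tibble.
#' @param scaling Optional scaling list from a previous call (fields
#'   `time_min`, `time_max`, `enforcers_min`, `enforcers_max`). If `NULL`,
#'   the min/max of `records` are used.
#' @return `records` with the two scaled columns and a `scaling` attribute,
#'   retrievable via [scaling_info()].
#' @export
scale_continuous <- function(records, scaling = NULL) {
  if (is.null(scaling)) {
    scaling <- list(
      time_min = min(records$time_minutes),
      time_max = max(records$time_minutes),
      enforcers_min = min(records$n_enforcers),
      enforcers_max = max(records$n_enforcers)
    )
    if (scaling$time_max <= scaling$time_min) {
      abort("Cannot scale constant column `time_minutes` (min == max).")
    }
    if (scaling$enforcers_max <= scaling$enforcers_min) {
      abort("Cannot scale constant column `n_enforcers` (min == max).")
    }
  }
  scale1 <- function(x, lo, hi, name) {
    z <- (x - lo) / (hi - lo)
    if (any(z < 0 | z > 1)) {
      warn(sprintf("%d value(s) of `%s` outside the stored scaling range; clipped to [0, 1].",
                   sum(z < 0 | z > 1), name))
      z <- pmin(pmax(z, 0), 1)
    }
    z
  }
  records$time_scaled <- scale1(records$time_minutes, scaling$time_min,
                                scaling$time_max, "time_minutes")
  records$enforcers_scaled <- scale1(records$n_enforcers,
                                     scaling$enforcers_min,
                                     scaling$enforcers_max, "n_enforcers")
  attr(records, "scaling") <- scaling
  records
}

#' @rdname records_scheme
#' @export
scaling_info <- function(records) attr(records, "scaling", exact = TRUE)

#' Serialize or restore scaling information as JSON
#'
#' @param scaling A scaling list as attached by [scale_continuous()].
#' @param path File path.
#' @return `write_scaling_json()` returns `scaling` invisibly;
#'   `read_scaling_json()` returns the scaling list.
#' @export
write_scaling_json <- function(scaling, path) {
  jsonlite::write_json(scaling, path, auto_unbox = TRUE, digits = NA)
  invisible(scaling)
}

#' @rdname write_scaling_json
#' @export
read_scaling_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Screen design columns for collinearity
#'
#' Computes pairwise Pearson correlations between numeric design columns
#' and flags every pair with `|r|` above the threshold (default 0.7).
#' Which member of a flagged pair to drop is the caller's decision;
#' [drop_collinear()] implements the deterministic default of dropping
#' the later column.
#'
#' @param design A data frame (or matrix) of numeric columns.
#' @param threshold Absolute correlation above which a pair is flagged.
#' @return A tibble with columns `col_a`, `col_b`, `r`, one row per
#'   flagged pair. Zero-variance columns are excluded with a warning.
#' @export
collinearity_screen <- function(design, threshold = 0.7) {
  design <- as.data.frame(design)
  num <- vapply(design, is.numeric, logical(1L))
  design <- design[num]
  if (ncol(design) < 2L) abort("Need at least two numeric columns to screen.")
  vars <- vapply(design, function(x) stats::var(x), numeric(1L))
  if (any(vars == 0)) {
    warn(sprintf("Excluding zero-variance column(s) from screen: %s.",
                 paste(names(design)[vars == 0], collapse = ", ")))
    design <- design[vars > 0]
  }
  if (ncol(design) < 2L) {
    return(tibble::tibble(col_a = character(0), col_b = character(0),
                          r = numeric(0)))
  }
  cm <- stats::cor(as.matrix(design))
  idx <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  tibble::tibble(
    col_a = colnames(cm)[idx[, 1L]],
    col_b = colnames(cm)[idx[, 2L]],
    r = cm[idx]
  )
}

#' @rdname collinearity_screen
#' @param flagged The tibble returned by `collinearity_screen()`.
#' @return `drop_collinear()` returns `design` with, per flagged pair, the
#'   column appearing later in the design dropped.
#' @export
drop_collinear <- function(design, flagged) {
  if (nrow(flagged) == 0L) return(design)
  design <- as.data.frame(design)
  pos <- function(nm) match(nm, names(design))
  drop <- unique(ifelse(pos(flagged$col_b) > pos(flagged$col_a),
                        flagged$col_b, flagged$col_a))
  design[setdiff(names(design), drop)]
}
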