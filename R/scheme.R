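#' Category scheme for enforcement-patrol records
#'
#' A category scheme declares the admissible levels of the five categorical
#' covariates of a patrol record (region, actor targeted, species group,
#' violation type, and year) and, implicitly, the reference level of each:
#' the first element of each level vector. All model coefficients for a
#' categorical factor are log-odds ratios relative to that reference level,
#' whose coefficient is fixed at zero.
#'
#' @param region_levels,actor_levels,species_levels,violation_levels
#'   Character vectors of unique level labels, reference level first.
#' @param year_levels Integer (or integer-like) vector of unique calendar
#'   years, reference year first.
#' @return An object of class `category_scheme`: a named list of the five
#'   ordered level vectors (years stored as character).
#' @seealso [default_scheme()] for a ready-made scheme mirroring a national
#'   fisheries enforcement programme; [read_records()] which can infer a
#'   scheme from data.
#' @export
#' @examples
#' category_scheme(
#'   region_levels = c("North", "South"),
#'   actor_levels = c("Fisher", "Trader"),
#'   species_levels = c("Anchovy", "Hake"),
#'   violation_levels = c("Access", "Quota"),
#'   year_levels = 2014:2016
#' )
category_scheme <- function(region_levels, actor_levels, species_levels,
                            violation_levels, year_levels) {
  scheme <- list(
    region_levels = as.character(region_levels),
    actor_levels = as.character(actor_levels),
    species_levels = as.character(species_levels),
    violation_levels = as.character(violation_levels),
    year_levels = as.character(year_levels)
  )
  for (nm in names(scheme)) {
    lv <- scheme[[nm]]
    if (length(lv) < 1L) abort(sprintf("`%s` must have at least one level.", nm))
    if (anyDuplicated(lv)) {
      abort(sprintf("`%s` contains duplicated levels: %s.", nm,
                    paste(unique(lv[duplicated(lv)]), collapse = ", ")))
    }
    if (anyNA(lv)) abort(sprintf("`%s` contains NA.", nm))
  }
  structure(scheme, class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme>\n")
  for (nm in names(x)) {
    lv <- x[[nm]]
    cat(sprintf("  %-17s %d levels (ref: %s)\n",
                sub("_levels$", "", nm), length(lv), lv[1L]))
  }
  invisible(x)
}

#' Reference levels of a category scheme
#'
#' @param scheme A [category_scheme()].
#' @return Named character vector with the reference level of each factor.
#' @export
reference_levels <- function(scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  vapply(scheme, function(lv) lv[1L], character(1L))
}

# the record column each *_levels entry governs
scheme_columns <- c(
  region_levels = "region", actor_levels = "actor",
  species_levels = "species", violation_levels = "violation_type",
  year_levels = "year"
)

#' Default category scheme
#'
#' A scheme mirroring the structure of a national land-based fisheries
#' enforcement programme: 16 administrative regions (15 geographic regions
#' ordered north to south plus a mobile unit), 8 supply-chain actor
#' categories, 31 species groups, 7 violation types, and the years
#' 2014-2020. Reference levels are the Arica region, small-scale fishers,
#' anchovy, access violations, and 2014.
#'
#' @return A [category_scheme()].
#' @export
default_scheme <- function() {
  category_scheme(
    region_levels = c(
      "Arica", "Tarapaca", "Antofagasta", "Atacama", "Coquimbo",
      "Valparaiso", "Metropolitana", "OHiggins", "Maule", "Biobio",
      "Araucania", "Los Rios", "Los Lagos", "Aysen", "Magallanes",
      "Mobile Unit"
    ),
    actor_levels = c(
      "Small-scale fisher", "Industrial fisher", "Transporter",
      "Processor", "Marketer", "Restaurant", "No activity listed",
      "Other actor"
    ),
    species_levels = c(
      "Anchovy", "Sardine", "Jack mackerel", "Chub mackerel", "Hake",
      "Southern hake", "Conger eel", "Swordfish", "Tuna", "Shark",
      "Salmon", "Silverside", "Croaker", "Pomfret", "Toothfish", "Loco",
      "Keyhole limpet", "Sea urchin", "Octopus", "Squid", "Jumbo squid",
      "Crab", "King crab", "Shrimp", "Lobster", "Mussel", "Clam",
      "Razor clam", "Scallop", "Kelp", "Other species"
    ),
    violation_levels = c(
      "Access", "Quota", "Closed season", "Size limit", "Documentation",
      "Gear", "Other"
    ),
    year_levels = 2014:2020
  )
}

#' Serialize or restore a category scheme as JSON
#'
#' @param scheme A [category_scheme()].
#' @param path File path.
#' @return `write_scheme_json()` returns `scheme` invisibly;
#'   `read_scheme_json()` returns a [category_scheme()].
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "category_scheme"))
  jsonlite::write_json(unclass(scheme), path, pretty = TRUE)
  invisible(scheme)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  category_scheme(x$region_levels, x$actor_levels, x$species_levels,
                  x$violation_levels, x$year_levels)
}

# infer a scheme from records, levels in order of first appearance
infer_scheme <- function(records) {
  category_scheme(
    region_levels = unique(records$region),
    actor_levels = unique(records$actor),
    species_levels = unique(records$species),
    violation_levels = unique(records$violation_type),
    year_levels = unique(records$year)
  )
}
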