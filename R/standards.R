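#' Parameter standards registry
#'
#' A `wq_standards` object holds the metadata every index computation needs:
#' per-parameter permissible limits (BIS 2012 / WHO 2011 drinking-water
#' standards), the literature-assigned MWQI weights, ideal values for pH and
#' dissolved oxygen, Hakanson preindustrial reference values and
#' toxic-response coefficients, plus the membership of each index's
#' parameter set.
#'
#' Units follow the monitoring convention: cations, anions, BOD and DO in
#' mg/l; heavy metals, total phosphorus and chlorophyll-a in ug/l; electrical
#' conductivity in uS/cm; turbidity in NTU; Secchi depth in m.
#'
#' @param ph_standard Which BIS pH band to rate against: `"upper"` (8.5, the
#'   default; with ideal 7.0 a pH above neutral rates positively) or
#'   `"lower"` (6.5, for fidelity experiments -- note this makes the rating
#'   denominator negative).
#' @return A `wq_standards` object: a list with elements `parameters` (a
#'   tibble of per-parameter metadata), `mwqi_set`, `hpi_set`, `ri_set`,
#'   `tsi_set` (character vectors of parameter codes).
#' @examples
#' std <- default_standards()
#' std$parameters[std$parameters$code == "do", ]
#' @export
default_standards <- function(ph_standard = c("upper", "lower")) {
  ph_standard <- match.arg(ph_standard)
  p <- tibble::tibble(
    code = c("ph", "tds", "turbidity", "ec", "mg", "ca", "cl", "so4", "no3",
             "bod", "do", "zn", "cd", "pb", "ni", "cr", "fe", "sd", "chla",
             "tp"),
    name = c("pH", "Total dissolved solids", "Turbidity",
             "Electrical conductivity", "Magnesium", "Calcium", "Chloride",
             "Sulphate", "Nitrate", "Biological oxygen demand",
             "Dissolved oxygen", "Zinc", "Cadmium", "Lead", "Nickel",
             "Chromium", "Iron", "Secchi disk depth", "Chlorophyll-a",
             "Total phosphorus"),
    unit = c("pH units", "mg/l", "NTU", "uS/cm", "mg/l", "mg/l", "mg/l",
             "mg/l", "mg/l", "mg/l", "mg/l", "ug/l", "ug/l", "ug/l", "ug/l",
             "ug/l", "ug/l", "m", "ug/l", "ug/l"),
    permissible_limit = c(if (ph_standard == "upper") 8.5 else 6.5,
                          500, 1, 300, 30, 75, 250, 200, 45, 5, 6,
                          15000, 10, 50, 20, 50, 300, NA, NA, NA),
    assigned_weight = c(1, 1.79, 1.09, 1.78, 0.72, 0.8, 1.28, 1.60, 2.32,
                        1.72, 2.85, NA, NA, NA, NA, NA, NA, NA, NA, NA),
    ideal_value = c(7.0, NA, NA, NA, NA, NA, NA, NA, NA, NA, 14.6,
                    NA, NA, NA, NA, NA, NA, NA, NA, NA),
    reference_value = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                        175, 1.0, 70, NA, 90, NA, NA, NA, NA),
    toxic_response = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                       1, 30, 5, NA, 2, NA, NA, NA, NA),
    standard_source = c("BIS 2012", "WHO 2011", "BIS 2012", "BIS 2012",
                        "BIS 2012", "WHO 2011", "WHO 2011", "BIS 2012",
                        "WHO 2011", "BIS 2012", "BIS 2012", "BIS 2012",
                        "BIS 2012", "BIS 2012", "BIS 2012", "WHO 2011",
                        "WHO 2011", NA, NA, NA)
  )
  std <- structure(
    list(parameters = p,
         mwqi_set = c("ph", "tds", "turbidity", "ec", "mg", "ca", "cl",
                      "so4", "no3", "bod", "do"),
         hpi_set = c("zn", "cd", "pb", "ni", "cr", "fe"),
         ri_set = c("cd", "pb", "cr", "zn"),
         tsi_set = c("sd", "tp", "chla")),
    class = "wq_standards"
  )
  validate_standards(std)
}

#' Load a standards table from a YAML configuration
#'
#' Reads a human-editable YAML file describing every measured parameter
#' (limit, weight, ideal/reference values, index-set membership) and
#' validates it. With `path = NULL` the packaged defaults are returned.
#'
#' @param path Path to a YAML configuration, or `NULL` for defaults.
#' @inheritParams default_standards
#' @return A validated `wq_standards` object.
#' @seealso [write_standards()] for the inverse; the shipped default config
#'   is at `system.file("extdata", "standards.yaml", package = "riverwq")`.
#' @export
load_standards <- function(path = NULL, ph_standard = c("upper", "lower")) {
  if (is.null(path)) return(default_standards(ph_standard))
  cfg <- yaml::read_yaml(path)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chr_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  p <- tibble::tibble(
    code = vapply(cfg$parameters, function(x) x$code, character(1)),
    name = vapply(cfg$parameters, function(x) chr_or_na(x$name), character(1)),
    unit = vapply(cfg$parameters, function(x) chr_or_na(x$unit), character(1)),
    permissible_limit = vapply(cfg$parameters, function(x) num_or_na(x$permissible_limit), double(1)),
    assigned_weight = vapply(cfg$parameters, function(x) num_or_na(x$assigned_weight), double(1)),
    ideal_value = vapply(cfg$parameters, function(x) num_or_na(x$ideal_value), double(1)),
    reference_value = vapply(cfg$parameters, function(x) num_or_na(x$reference_value), double(1)),
    toxic_response = vapply(cfg$parameters, function(x) num_or_na(x$toxic_response), double(1)),
    standard_source = vapply(cfg$parameters, function(x) chr_or_na(x$standard_source), character(1))
  )
  std <- structure(
    list(parameters = p,
         mwqi_set = as.character(cfg$sets$mwqi),
         hpi_set = as.character(cfg$sets$hpi),
         ri_set = as.character(cfg$sets$ri),
         tsi_set = as.character(cfg$sets$tsi)),
    class = "wq_standards"
  )
  validate_standards(std)
}

#' Write a standards table to YAML
#'
#' Serialises a `wq_standards` object so that [load_standards()] reproduces
#' it exactly (round-trip identity).
#'
#' @param standards A `wq_standards` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_standards <- function(standards, path) {
  stopifnot(inherits(standards, "wq_standards"))
  p <- standards$parameters
  drop_na <- function(l) l[!vapply(l, function(x) is.na(x), logical(1))]
  params <- lapply(seq_len(nrow(p)), function(i) {
    drop_na(list(
      code = p$code[i], name = p$name[i], unit = p$unit[i],
      permissible_limit = p$permissible_limit[i],
      assigned_weight = p$assigned_weight[i],
      ideal_value = p$ideal_value[i],
      reference_value = p$reference_value[i],
      toxic_response = p$toxic_response[i],
      standard_source = p$standard_source[i]))
  })
  yaml::write_yaml(
    list(parameters = params,
         sets = list(mwqi = standards$mwqi_set, hpi = standards$hpi_set,
                     ri = standards$ri_set, tsi = standards$tsi_set)),
    path, precision = 15)
  invisible(path)
}

validate_standards <- function(std) {
  p <- std$parameters
  if (anyDuplicated(p$code))
    stop("duplicated parameter code in standards: ",
         paste(unique(p$code[duplicated(p$code)]), collapse = ", "))
  for (set_name in c("mwqi_set", "hpi_set", "ri_set", "tsi_set")) {
    missing <- setdiff(std[[set_name]], p$code)
    if (length(missing))
      stop("configuration error: ", set_name, " member(s) not in parameter ",
           "table: ", paste(missing, collapse = ", "))
  }
  idx <- match(std$mwqi_set, p$code)
  bad <- std$mwqi_set[is.na(p$assigned_weight[idx])]
  if (length(bad))
    stop("configuration error: mwqi_set member(s) lack assigned_weight: ",
         paste(bad, collapse = ", "))
  bad <- std$mwqi_set[is.na(p$permissible_limit[idx]) |
                        p$permissible_limit[idx] <= 0]
  if (length(bad))
    stop("configuration error: mwqi_set member(s) lack a positive ",
         "permissible_limit: ", paste(bad, collapse = ", "))
  idx <- match(std$hpi_set, p$code)
  bad <- std$hpi_set[is.na(p$permissible_limit[idx]) |
                       p$permissible_limit[idx] <= 0]
  if (length(bad))
    stop("configuration error: hpi_set member(s) lack a positive ",
         "permissible_limit: ", paste(bad, collapse = ", "))
  idx <- match(std$ri_set, p$code)
  bad <- std$ri_set[is.na(p$reference_value[idx]) |
                      p$reference_value[idx] <= 0 |
                      is.na(p$toxic_response[idx]) |
                      p$toxic_response[idx] <= 0]
  if (length(bad))
    stop("configuration error: ri_set member(s) lack positive ",
         "reference_value/toxic_response: ", paste(bad, collapse = ", "))
  aw <- p$assigned_weight[!is.na(p$assigned_weight)]
  if (any(aw <= 0)) stop("assigned_weight values must be > 0")
  std
}

#' @export
print.wq_standards <- function(x, ...) {
  cat("Water quality standards registry\n")
  cat("  parameters:", nrow(x$parameters), "\n")
  cat("  MWQI set (", length(x$mwqi_set), "): ",
      paste(x$mwqi_set, collapse = ", "), "\n", sep = "")
  cat("  HPI set  (", length(x$hpi_set), "): ",
      paste(x$hpi_set, collapse = ", "), "\n", sep = "")
  cat("  RI set   (", length(x$ri_set), "): ",
      paste(x$ri_set, collapse = ", "), "\n", sep = "")
  cat("  TSI set  (", length(x$tsi_set), "): ",
      paste(x$tsi_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate a sample against the registry
#'
#' Checks the physical invariants of one sample's measurement vector:
#' non-pH concentrations must be non-negative, pH must lie in \[0, 14\] and
#' Secchi depth must be positive when present. Parameters declared in an
#' index set but absent from the vector are reported via the
#' `"incomplete_indices"` attribute rather than silently zero-filled.
#'
#' @param values Named numeric vector of measurements (names are parameter
#'   codes from the registry).
#' @param standards A `wq_standards` object.
#' @return `values`, invisibly, with attribute `incomplete_indices` naming
#'   any index whose parameter set is not fully present.
#' @export
validate_sample <- function(values, standards) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  v <- values[!is.na(values)]
  if ("ph" %in% names(v) && (v[["ph"]] < 0 || v[["ph"]] > 14))
    stop("validation error: pH outside [0, 14]: ", v[["ph"]])
  neg <- setdiff(names(v)[v < 0], "ph")
  if (length(neg))
    stop("validation error: negative concentration for ",
         paste(neg, collapse = ", "))
  if ("sd" %in% names(v) && v[["sd"]] <= 0)
    stop("validation error: Secchi depth must be > 0")
  incomplete <- character(0)
  sets <- list(mwqi = standards$mwqi_set, hpi = standards$hpi_set,
               ri = standards$ri_set, tsi = standards$tsi_set)
  for (ix in names(sets)) {
    if (!all(sets[[ix]] %in% names(v)))
      incomplete <- c(incomplete, paste(ix, "incomplete"))
  }
  attr(values, "incomplete_indices") <- incomplete
  invisible(values)
}
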