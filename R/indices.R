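#' Relative weights for the weighted-arithmetic water quality index
#'
#' Normalises the literature-assigned weights of the MWQI parameter set so
#' they sum to one: `RW_i = AW_i / sum(AW)`.
#'
#' @param standards A `wq_standards` object.
#' @return Named numeric vector of relative weights over the MWQI set.
#' @examples
#' rw <- relative_weights(default_standards())
#' sum(rw)           # 1
#' rw[["do"]]        # 2.85 / 16.95
#' @export
relative_weights <- function(standards) {
  set <- standards$mwqi_set
  if (!length(set)) stop("configuration error: empty mwqi_set")
  p <- standards$parameters
  aw <- p$assigned_weight[match(set, p$code)]
  names(aw) <- set
  aw / sum(aw)
}

#' Quality rating of one parameter
#'
#' Rates a measured concentration against its permissible limit,
#' `Q_i = (C_i / S_i) * 100`, so that 100 means "exactly at the standard".
#' pH and dissolved oxygen are rated by deviation from their ideal values
#' (7.0 pH units; 14.6 mg/l, the 100% saturation concentration at 23 C)
#' relative to the standard's deviation:
#' `Q_i = (C_i - V_i) / (S_i - V_i) * 100`.
#'
#' @param code Parameter code (scalar).
#' @param value Measured concentration(s) in the registry unit; vectorised.
#' @param standards A `wq_standards` object.
#' @return Numeric rating(s).
#' @export
quality_rating <- function(code, value, standards) {
  p <- standards$parameters
  i <- match(code, p$code)
  if (is.na(i)) stop("unknown parameter code: ", code)
  s <- p$permissible_limit[i]
  v <- p$ideal_value[i]
  if (is.na(s)) stop("parameter ", code, " has no permissible limit")
  if (!is.na(v)) {
    if (s == v) stop("degenerate denominator: standard equals ideal value ",
                     "for ", code)
    (value - v) / (s - v) * 100
  } else {
    value / s * 100
  }
}

wq_index_result <- function(index, value, class_label, components) {
  structure(list(index = index, value = value, class_label = class_label,
                 components = components),
            class = "wq_index")
}

#' @export
print.wq_index <- function(x, ...) {
  cat(x$index, "=", round(x$value, 2), "->", x$class_label, "\n")
  invisible(x)
}

require_set <- function(values, set, index) {
  missing <- setdiff(set, names(values)[!is.na(values)])
  if (length(missing))
    stop("incomplete index ", index, ": missing parameter(s) ",
         paste(missing, collapse = ", "))
}

#' Modified Water Quality Index
#'
#' Weighted arithmetic index over 11 physico-chemical parameters:
#' `MWQI = sum(RW_i * Q_i)` with relative weights from
#' [relative_weights()] and ratings from [quality_rating()]. The
#' sub-indices `SI_i = RW_i * Q_i` are returned as components and sum
#' exactly to the index value.
#'
#' @param values Named numeric vector holding at least the 11 MWQI
#'   parameters (a phase-mean vector or a single sample).
#' @param standards A `wq_standards` object.
#' @return A `wq_index` object with elements `value`, `class_label` and
#'   `components` (the named sub-indices).
#' @examples
#' std <- default_standards()
#' means <- damodar_phase_stats()
#' pre <- setNames(means$mean[means$phase == "pre_lockdown"],
#'                 means$code[means$phase == "pre_lockdown"])
#' mwqi(pre, std)
#' @export
mwqi <- function(values, standards) {
  require_set(values, standards$mwqi_set, "MWQI")
  rw <- relative_weights(standards)
  q <- vapply(standards$mwqi_set,
              function(code) quality_rating(code, values[[code]], standards),
              double(1))
  si <- rw[standards$mwqi_set] * q
  value <- sum(si)
  wq_index_result("MWQI", value, classify_mwqi(value), si)
}

#' Heavy-metal pollution index
#'
#' Weighted mean of per-metal sub-indices with unit weights inversely
#' proportional to each metal's permissible limit:
#' `W_i = 1/S_i`, `Q_i = (M_i/S_i) * 100`,
#' `HPI = sum(W_i Q_i) / sum(W_i)`.
#'
#' @inheritParams mwqi
#' @return A `wq_index` object; components are the per-metal sub-indices
#'   `Q_i` (note these are weighted, so they do not sum to the value).
#' @export
hpi <- function(values, standards) {
  require_set(values, standards$hpi_set, "HPI")
  p <- standards$parameters
  s <- p$permissible_limit[match(standards$hpi_set, p$code)]
  m <- unlist(values[standards$hpi_set])
  w <- 1 / s
  q <- m / s * 100
  names(q) <- standards$hpi_set
  value <- sum(w * q) / sum(w)
  wq_index_result("HPI", value, classify_hmi(value), q)
}

#' Hakanson potential ecological risk index
#'
#' For each toxic metal the contamination factor is the measured
#' concentration over its preindustrial reference value,
#' `Cf_i = Cs_i / Cn_i`; the ecological risk factor scales it by the
#' metal's toxic-response coefficient, `Er_i = Tr_i * Cf_i`. The degree of
#' contamination is `C = sum(Cf_i)` and the total risk `RI = sum(Er_i)`.
#' Defaults use Cn = (Cd 1.0, Pb 70, Cr 90, Zn 175) ug/l and
#' Tr = (Cd 30, Pb 5, Cr 2, Zn 1).
#'
#' @inheritParams mwqi
#' @return A `wq_risk` object: a list with `breakdown` (tibble with one row
#'   per metal: concentration, reference, contamination_factor,
#'   toxic_response, risk_factor), `degree_of_contamination`, `value`
#'   (= RI), `class_label` and `components` (the named risk factors).
#' @examples
#' std <- default_standards()
#' ecological_risk(c(cd = 10.20, pb = 26.18, cr = 87.67, zn = 39845.45), std)
#' @export
ecological_risk <- function(values, standards) {
  require_set(values, standards$ri_set, "RI")
  p <- standards$parameters
  i <- match(standards$ri_set, p$code)
  cs <- unlist(values[standards$ri_set])
  cn <- p$reference_value[i]
  tr <- p$toxic_response[i]
  cf <- cs / cn
  er <- tr * cf
  names(er) <- standards$ri_set
  value <- sum(er)
  structure(
    list(index = "RI",
         breakdown = tibble::tibble(
           code = standards$ri_set, concentration = unname(cs),
           reference_value = cn, contamination_factor = unname(cf),
           toxic_response = tr, risk_factor = unname(er)),
         degree_of_contamination = sum(cf),
         value = value,
         class_label = classify_ri(value),
         components = er),
    class = c("wq_risk", "wq_index"))
}

#' Carlson trophic state index
#'
#' Averages log-transforms of Secchi-disk transparency, total phosphorus
#' and chlorophyll-a:
#' `TS(Sd) = 60.0 - 14.41 ln(Sd)`,
#' `TS(TP) = 14.42 ln(TP) + 4.15`,
#' `TS(Chla) = 30.6 + 9.81 ln(Chla)`,
#' `TSI = (TS(Sd) + TS(TP) + TS(Chla)) / 3`.
#'
#' @param sd_m Secchi disk depth in meters (> 0).
#' @param tp Total phosphorus in ug/l (> 0).
#' @param chla Chlorophyll-a in ug/l (> 0).
#' @return A `wq_index` object; components carry the three transforms.
#' @examples
#' tsi(2.24, 62.45, 76.09)
#' @export
tsi <- function(sd_m, tp, chla) {
  if (any(c(sd_m, tp, chla) <= 0) || any(is.na(c(sd_m, tp, chla))))
    stop("domain error: TSI inputs must be positive (logarithm undefined)")
  comp <- c(sd = 60.0 - 14.41 * log(sd_m),
            tp = 14.42 * log(tp) + 4.15,
            chla = 30.6 + 9.81 * log(chla))
  value <- mean(comp)
  wq_index_result("TSI", value, classify_tsi(value), comp)
}

#' Qualitative classification of index values
#'
#' Maps index values onto the published class schemes. MWQI and HPI/HMI
#' classes are lower-exclusive/upper-inclusive (honouring the inclusive
#' "excellent" anchor classes); RI and TSI classes are
#' lower-inclusive/upper-exclusive (honouring their strict "< 150" and
#' "< 30" anchors). Each scheme partitions its domain with no gaps or
#' overlaps. All classifiers are vectorised.
#'
#' * `classify_mwqi`: excellent (<= 50), good (50-100), poor (100-200),
#'   very poor (200-300), unfit for drinking (> 300).
#' * `classify_hmi`: excellent (0-25), good (25-50), poor (50-75),
#'   very poor (75-100), unfit for drinking (> 100).
#' * `classify_ri`: Practically uncontaminated (< 150), Moderately
#'   contaminated (150-300), Heavily contaminated (300-600), Extremely
#'   contaminated (>= 600).
#' * `classify_tsi`: low oligotrophic (< 30), high oligotrophic (30-40),
#'   mesotrophic (40-50), low eutrophic (50-60), medium eutrophic (60-70),
#'   high eutrophic (70-80), very high eutrophic (>= 80).
#'
#' @param value Numeric vector of index values.
#' @return Character vector of class labels.
#' @name classify
NULL

#' @rdname classify
#' @export
classify_mwqi <- function(value) {
  if (any(!is.finite(value)))
    stop("classification error: non-finite index value")
  as.character(cut(value, c(-Inf, 50, 100, 200, 300, Inf),
                   labels = c("excellent", "good", "poor", "very poor",
                              "unfit for drinking"),
                   right = TRUE))
}

#' @rdname classify
#' @export
classify_hmi <- function(value) {
  if (any(!is.finite(value)))
    stop("classification error: non-finite index value")
  if (any(value < 0)) stop("classification error: negative HPI value")
  as.character(cut(value, c(-Inf, 25, 50, 75, 100, Inf),
                   labels = c("excellent", "good", "poor", "very poor",
                              "unfit for drinking"),
                   right = TRUE))
}

#' @rdname classify
#' @export
classify_ri <- function(value) {
  if (any(!is.finite(value)))
    stop("classification error: non-finite index value")
  if (any(value < 0)) stop("classification error: negative RI value")
  as.character(cut(value, c(-Inf, 150, 300, 600, Inf),
                   labels = c("Practically uncontaminated",
                              "Moderately contaminated",
                              "Heavily contaminated",
                              "Extremely contaminated"),
                   right = FALSE))
}

#' @rdname classify
#' @export
classify_tsi <- function(value) {
  if (any(!is.finite(value)))
    stop("classification error: non-finite index value")
  as.character(cut(value, c(-Inf, 30, 40, 50, 60, 70, 80, Inf),
                   labels = c("low oligotrophic", "high oligotrophic",
                              "mesotrophic", "low eutrophic",
                              "medium eutrophic", "high eutrophic",
                              "very high eutrophic"),
                   right = FALSE))
}

#' Compute all four indices for every sample
#'
#' Applies [mwqi()], [hpi()], [ecological_risk()] and [tsi()] to each row
#' of a wide sample table. A sample missing any member of an index's
#' parameter set gets `NA` for that index (with a log entry) rather than a
#' renormalised value, because the assigned weights are global constants.
#'
#' @param samples Wide tibble/data frame: columns `site_id`, `phase`, then
#'   one column per parameter code.
#' @param standards A `wq_standards` object.
#' @return Tidy tibble with columns `site_id`, `phase`, `index`, `value`,
#'   `class_label`, plus attribute `log` (character vector of skipped
#'   index/sample combinations).
#' @export
compute_indices <- function(samples, standards) {
  stopifnot(all(c("site_id", "phase") %in% names(samples)))
  param_cols <- setdiff(names(samples), c("site_id", "phase", "collected"))
  log <- character(0)
  rows <- vector("list", nrow(samples) * 4L)
  k <- 0L
  for (i in seq_len(nrow(samples))) {
    v <- unlist(samples[i, param_cols])
    one <- function(fn_name, fn) {
      res <- tryCatch(fn(), error = function(e) conditionMessage(e))
      k <<- k + 1L
      if (is.character(res)) {
        log <<- c(log, paste0(samples$site_id[i], "/", samples$phase[i],
                              ": ", res))
        rows[[k]] <<- tibble::tibble(
          site_id = samples$site_id[i], phase = samples$phase[i],
          index = fn_name, value = NA_real_, class_label = NA_character_)
      } else {
        rows[[k]] <<- tibble::tibble(
          site_id = samples$site_id[i], phase = samples$phase[i],
          index = fn_name, value = res$value, class_label = res$class_label)
      }
    }
    one("MWQI", function() mwqi(v, standards))
    one("HPI", function() hpi(v, standards))
    one("RI", function() ecological_risk(v, standards))
    one("TSI", function() {
      require_set(v, standards$tsi_set, "TSI")
      tsi(v[["sd"]], v[["tp"]], v[["chla"]])
    })
  }
  out <- do.call(rbind, rows[seq_len(k)])
  attr(out, "log") <- log
  out
}
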