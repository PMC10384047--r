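#' Censored concentration values
#'
#' Broth-microdilution endpoints are interval data: a MIC of ">500" means
#' the endpoint was not reached at the top of the dilution grid. A
#' `censored` value carries the numeric bound plus a censoring state:
#' `"exact"`, `"gt"` (greater-than bound), `"lt"` (less-than bound) or
#' `"missing"`.
#'
#' @param value Numeric bound (ignored for `"missing"`).
#' @param censor One of `"exact"`, `"gt"`, `"lt"`, `"missing"`.
#' @return Object of class `censored`.
#' @export
censored <- function(value = NA_real_, censor = c("exact", "gt", "lt",
                                                  "missing")) {
  censor <- match.arg(censor)
  if (censor != "missing" && (!is.numeric(value) || !is.finite(value)))
    .stop_ampchem("non-missing censored values need a finite bound",
                  "ampchem_invalid_parameter")
  structure(list(value = as.numeric(value), censor = censor),
            class = "censored")
}

#' @rdname censored
#' @param x A string (`"8"`, `">500"`, `"<2"`, `"-"`), number or `NA`.
#' @export
parse_censored <- function(x) {
  if (inherits(x, "censored")) return(x)
  if (length(x) != 1L)
    .stop_ampchem("parse one value at a time", "ampchem_invalid_parameter")
  if (is.na(x)) return(censored(censor = "missing"))
  if (is.numeric(x)) return(censored(x, "exact"))
  s <- trimws(as.character(x))
  if (s %in% c("-", "", "NA")) return(censored(censor = "missing"))
  if (startsWith(s, ">")) return(censored(as.numeric(substring(s, 2)), "gt"))
  if (startsWith(s, "<")) return(censored(as.numeric(substring(s, 2)), "lt"))
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    .stop_ampchem(sprintf("cannot parse '%s' as a concentration", s),
                  "ampchem_parse_error")
  censored(v, "exact")
}

#' @export
format.censored <- function(x, ...) {
  switch(x$censor,
         exact = format(x$value, ...),
         gt = paste0(">", format(x$value, ...)),
         lt = paste0("<", format(x$value, ...)),
         missing = "-")
}

#' @export
print.censored <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Antimicrobial activity record
#'
#' @param compound,strain Labels.
#' @param gram `"positive"` or `"negative"`.
#' @param mic,mbc MIC and MBC in uM, as numbers, strings (`">500"`, `"-"`)
#'   or [censored()] objects.
#' @return Object of class `activity_record`. A warning is raised when both
#'   endpoints are exact but MBC < MIC.
#' @export
activity_record <- function(compound, strain, gram = c("positive", "negative"),
                            mic, mbc = censored(censor = "missing")) {
  gram <- match.arg(gram)
  mic <- parse_censored(mic)
  mbc <- parse_censored(mbc)
  if (mic$censor == "exact" && mbc$censor == "exact" && mbc$value < mic$value)
    .warn_ampchem("MBC below MIC: check transcription",
                  "ampchem_mbc_below_mic")
  structure(list(compound = compound, strain = strain, gram = gram,
                 mic = mic, mbc = mbc),
            class = "activity_record")
}

#' MBC/MIC ratio with censoring propagation
#'
#' A ratio of 1-2 marks bactericidal (rather than merely bacteriostatic)
#' action. The MIC must be exact; a censored MBC (">X") yields a censored
#' lower-bound ratio, a missing MBC a missing ratio.
#'
#' @param record An [activity_record()].
#' @return A [censored()] ratio.
#' @export
mbc_mic_ratio <- function(record) {
  stopifnot(inherits(record, "activity_record"))
  mic <- record$mic; mbc <- record$mbc
  if (mic$censor != "exact" || !is.finite(mic$value) || mic$value <= 0)
    .stop_ampchem("MIC must be exact and > 0 for a ratio",
                  "ampchem_undefined_ratio")
  if (mbc$censor == "missing") return(censored(censor = "missing"))
  censored(mbc$value / mic$value,
           if (mbc$censor == "exact") "exact" else mbc$censor)
}

#' Hemolysis concentration-response curve
#'
#' @param concentration Concentrations \[uM\], ascending.
#' @param hemolysis_pct Percent hemolysis relative to the fully lysed
#'   control, in \[0, 110\].
#' @param compound Label.
#' @return Object of class `hemolysis_curve`.
#' @export
hemolysis_curve <- function(concentration, hemolysis_pct, compound = "") {
  concentration <- as.numeric(concentration)
  hemolysis_pct <- as.numeric(hemolysis_pct)
  if (length(concentration) < 2L ||
      length(hemolysis_pct) != length(concentration))
    .stop_ampchem("need >= 2 points with equal-length arrays",
                  "ampchem_invalid_curve")
  if (is.unsorted(concentration, strictly = FALSE))
    .stop_ampchem("concentrations must be ascending",
                  "ampchem_invalid_curve")
  if (any(hemolysis_pct < 0) || any(hemolysis_pct > 110))
    .stop_ampchem("hemolysis must lie in [0, 110] percent",
                  "ampchem_invalid_curve")
  structure(list(concentration = concentration,
                 hemolysis_pct = hemolysis_pct, compound = compound),
            class = "hemolysis_curve")
}

#' HC50 from a hemolysis curve
#'
#' The concentration inducing 50% hemolysis, by piecewise-linear
#' interpolation of the first upward crossing of the 50% level. If the
#' maximum observed hemolysis stays below 50%, the result is censored
#' `"> c_max"`.
#'
#' @param curve A [hemolysis_curve()].
#' @return A [censored()] concentration \[uM\].
#' @export
hc50 <- function(curve) {
  stopifnot(inherits(curve, "hemolysis_curve"))
  x <- curve$concentration
  y <- curve$hemolysis_pct
  if (length(x) < 2L)
    .stop_ampchem("need at least 2 points to bracket a response",
                  "ampchem_insufficient_data")
  if (max(y) < 50) return(censored(max(x), "gt"))
  if (y[1] >= 50) return(censored(x[1], "lt"))
  i <- which(y[-length(y)] < 50 & y[-1] >= 50)[1]
  if (is.na(i))
    .stop_ampchem("no upward crossing of 50% found",
                  "ampchem_insufficient_data")
  censored(x[i] + (50 - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i]),
           "exact")
}

#' Selectivity (therapeutic window) index HC50/MIC
#'
#' @param hc50 HC50 as a [censored()] value (or parseable input).
#' @param mic MIC as a [censored()] value; must be exact.
#' @return A [censored()] ratio; a ">" HC50 gives a ">" (lower-bound) ratio.
#' @export
selectivity_index <- function(hc50, mic) {
  hc50 <- parse_censored(hc50)
  mic <- parse_censored(mic)
  if (mic$censor != "exact" || !is.finite(mic$value) || mic$value <= 0)
    .stop_ampchem("MIC must be exact and > 0 for a selectivity index",
                  "ampchem_undefined_ratio")
  if (hc50$censor == "missing") return(censored(censor = "missing"))
  censored(hc50$value / mic$value,
           if (hc50$censor == "exact") "exact" else hc50$censor)
}

#' Concentration unit conversion
#'
#' Converts between ug/mL and uM via the molar mass; same-unit conversion is
#' the identity (no molar mass needed).
#'
#' @param value Numeric value(s).
#' @param unit_in,unit_out `"ug/mL"` or `"uM"`.
#' @param molar_mass Molar mass \[g/mol\]; required for cross-unit
#'   conversion.
#' @return Converted value(s).
#' @examples
#' convert_concentration(1, "ug/mL", "uM", molar_mass = 500)  # 2 uM
#' @export
convert_concentration <- function(value, unit_in = c("uM", "ug/mL"),
                                  unit_out = c("uM", "ug/mL"),
                                  molar_mass = NULL) {
  unit_in <- match.arg(unit_in)
  unit_out <- match.arg(unit_out)
  if (unit_in == unit_out) return(value)
  if (is.null(molar_mass) || !.is_number(molar_mass) || molar_mass <= 0)
    .stop_ampchem("cross-unit conversion requires a positive molar mass",
                  "ampchem_conversion_error")
  if (unit_in == "ug/mL") value / molar_mass * 1000 else
    value * molar_mass / 1000
}

#' Snap a concentration onto a serial two-fold dilution grid
#'
#' The reported MIC of a broth microdilution assay is the smallest grid
#' concentration at or above the true endpoint. Values above the grid top
#' are censored `"> top"`. Grid values are fixed points. The default grid
#' reflects the usual 500 ... 2 uM series with its conventional rounding
#' (31, 62, 125 rather than 31.25, 62.5).
#'
#' @param true_value True endpoint concentration \[uM\].
#' @param grid Descending two-fold dilution grid \[uM\].
#' @return A [censored()] reported value.
#' @export
snap_to_dilution <- function(true_value,
                             grid = c(500, 250, 125, 62, 31, 16, 8, 4, 2)) {
  if (any(diff(grid) >= 0))
    .stop_ampchem("grid must be strictly descending",
                  "ampchem_invalid_parameter")
  if (true_value > grid[1]) return(censored(grid[1], "gt"))
  candidates <- grid[grid >= true_value]
  censored(min(candidates), "exact")
}

#' Read an antimicrobial activity table
#'
#' CSV with columns `compound, strain, gram, mic_uM, mbc_uM`; MIC/MBC cells
#' may be numeric, ">"-censored (`">500"`) or missing (`"-"`).
#'
#' @param path CSV path.
#' @return A list of [activity_record()]s.
#' @export
read_activity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("compound", "strain", "gram", "mic_uM", "mbc_uM")
  if (!all(need %in% names(df)))
    .stop_ampchem(sprintf("activity table needs columns: %s",
                          paste(need, collapse = ", ")),
                  "ampchem_parse_error")
  lapply(seq_len(nrow(df)), function(i)
    activity_record(df$compound[i], df$strain[i], df$gram[i],
                    mic = df$mic_uM[i], mbc = df$mbc_uM[i]))
}

#' Summarize MBC/MIC ratios across a table of records
#'
#' Reports the numeric ratio range over records with exact MIC and MBC and
#' whether any input carried a censoring bound. When ratios above 2 occur
#' (bacteriostatic-leaning combinations), the summary notes it rather than
#' enforcing the usual "1 to 2" bactericidal range.
#'
#' @param records List of [activity_record()]s.
#' @return List with `ratios` (data frame), `range`, `any_censored`,
#'   `exceeds_bactericidal_range`.
#' @export
summarize_mbc_mic <- function(records) {
  rows <- lapply(records, function(r) {
    ratio <- tryCatch(mbc_mic_ratio(r), error = function(e) NULL)
    data.frame(compound = r$compound, strain = r$strain,
               ratio = if (!is.null(ratio) && ratio$censor == "exact")
                 ratio$value else NA_real_,
               censored = is.null(ratio) ||
                 ratio$censor %in% c("gt", "lt"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  vals <- df$ratio[is.finite(df$ratio)]
  list(ratios = df,
       range = if (length(vals)) range(vals) else c(NA_real_, NA_real_),
       any_censored = any(df$censored),
       exceeds_bactericidal_range = any(vals > 2, na.rm = TRUE))
}
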