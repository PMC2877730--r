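# Internal-standard quantification: analyte/standard intensity ratios,
# unity-slope conversion to fmol per CC, and the inverse-concentration
# calibration diagnostic with linear-range detection.

#' Analyte/standard intensity ratio
#'
#' @param analyte,standard `peak_group` objects (from [assign_adducts()]).
#' @return Ratio of summed relative intensities.
#' @export
intensity_ratio <- function(analyte, standard) {
  stopifnot(inherits(analyte, "peak_group"), inherits(standard, "peak_group"))
  if (standard$summed_relative <= 0)
    stop("standard not detected", call. = FALSE)
  analyte$summed_relative / standard$summed_relative
}

#' Amount of internal standard co-crystallized with a sample
#'
#' nM x nl = amol, so fmol = concentration x volume / 1000.
#'
#' @param concentration_nM Standard concentration in the matrix (nM).
#' @param matrix_nl Matrix volume applied (nl).
#' @return Standard amount in fmol.
#' @export
#' @examples
#' standard_amount(400, 200)  # 80 fmol
standard_amount <- function(concentration_nM, matrix_nl) {
  if (concentration_nM <= 0 || matrix_nl <= 0)
    stop("concentration and volume must be > 0", call. = FALSE)
  concentration_nM * matrix_nl / 1000
}

#' Unity-slope conversion from ratio to amount
#'
#' Assumes a 1:1 intensity response between analyte and the chemically
#' identical heavy standard: amount = ratio x standard amount.
#'
#' @param ratio Analyte/standard intensity ratio (>= 0).
#' @param standard_fmol Standard amount (fmol).
#' @return Analyte amount in fmol.
#' @export
#' @examples
#' ratio_to_amount(2.175, 80)  # 174 fmol
ratio_to_amount <- function(ratio, standard_fmol) {
  if (any(ratio < 0)) stop("ratio must be >= 0", call. = FALSE)
  ratio * standard_fmol
}

#' Quantify one processed spectrum
#'
#' @param groups Peak groups from [process_spectrum()] /
#'   [assign_adducts()].
#' @param standard Name of the internal-standard species (default
#'   `"AKH*"`).
#' @param standard_nM,matrix_nl Standard concentration and matrix volume
#'   defining the spiked amount.
#' @param sample_id Identifier carried into the result.
#' @return A `quant_result`: `sample_id`, `standard_fmol`,
#'   `standard_detected`, and per-analyte `ratio`, `amount` (fmol),
#'   `detected`. When the standard is undetected, ratios and amounts are
#'   `NA` and the sample is meant to be excluded from summaries (QC-counted,
#'   not silently dropped).
#' @export
quantify_groups <- function(groups, standard = "AKH*", standard_nM = 400,
                            matrix_nl = 200, sample_id = "sample") {
  if (is.null(groups[[standard]]))
    stop("standard group '", standard, "' missing", call. = FALSE)
  std <- groups[[standard]]
  std_fmol <- standard_amount(standard_nM, matrix_nl)
  analytes <- setdiff(names(groups), standard)
  ok <- std$summed_relative > 0 && std$detected
  ratio <- vapply(analytes, function(a) {
    if (!ok) return(NA_real_)
    intensity_ratio(groups[[a]], std)
  }, 0)
  structure(list(
    sample_id = sample_id,
    standard_fmol = std_fmol,
    standard_detected = ok,
    ratio = ratio,
    amount = ratio_to_amount(ifelse(is.na(ratio), 0, ratio),
                             std_fmol) * ifelse(is.na(ratio), NA, 1),
    detected = vapply(analytes, function(a) groups[[a]]$detected, TRUE)
  ), class = "quant_result")
}

#' Process and quantify a simulated cohort
#'
#' @param cohort Output of [simulate_cohort()] (list of
#'   `list(spectrum, truth)`), or a plain list of spectra.
#' @param species List of [peptide_species()].
#' @param standard Internal standard species name.
#' @param ... Passed to [process_spectrum()].
#' @return List of `quant_result`, one per sample.
#' @export
quantify_cohort <- function(cohort, species = akh_species(),
                            standard = "AKH*", ...) {
  lapply(cohort, function(el) {
    spec <- if (inherits(el, "mass_spectrum")) el else el$spectrum
    truth <- if (inherits(el, "mass_spectrum")) NULL else el$truth
    groups <- process_spectrum(spec, species, ...)
    quantify_groups(
      groups, standard = standard,
      standard_nM = if (is.null(truth)) 400 else truth$standard_nM,
      matrix_nl = if (is.null(truth)) 200 else truth$matrix_nl,
      sample_id = if (is.null(spec$metadata$sample_id)) "sample"
                  else spec$metadata$sample_id)
  })
}

#' Flatten quantification results to a table
#'
#' @param results List of `quant_result`.
#' @return Data frame: `sample_id`, `species`, `ratio`, `amount`,
#'   `detected`, `standard_detected`, `standard_fmol`.
#' @export
quant_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id, species = names(r$ratio),
               ratio = unname(r$ratio), amount = unname(r$amount),
               detected = unname(r$detected),
               standard_detected = r$standard_detected,
               standard_fmol = r$standard_fmol, row.names = NULL)
  }))
}

#' Fit the internal-standard calibration diagnostic
#'
#' With the analyte held constant and the standard diluted, the intensity
#' ratio follows `ratio = k / concentration`; `k` estimates the analyte's
#' equivalent concentration. `k` is fitted by least squares of ratio
#' against 1/concentration through the origin. The detected linear range is
#' the maximal contiguous run of concentrations whose relative deviation
#' from `k/c` is within `tolerance`.
#'
#' @param concentration_nM Standard concentrations (>= 3 distinct values).
#' @param ratio Observed analyte/standard ratios.
#' @param tolerance Relative deviation tolerance (default 0.15).
#' @return Object of class `calibration_curve`: `k`, `points` (data frame
#'   with fitted values and deviations), `linear_range` (nM interval),
#'   `in_range` (logical per point).
#' @export
fit_calibration <- function(concentration_nM, ratio, tolerance = 0.15) {
  if (length(unique(concentration_nM)) < 3L)
    stop("need >= 3 distinct concentrations", call. = FALSE)
  stopifnot(length(concentration_nM) == length(ratio))
  o <- order(concentration_nM)
  conc <- concentration_nM[o]
  r <- ratio[o]
  x <- 1 / conc
  k <- sum(r * x) / sum(x^2)
  fitted <- k / conc
  deviation <- (r - fitted) / fitted
  ok <- abs(deviation) <= tolerance
  # maximal contiguous run of in-tolerance concentrations
  runs <- rle(ok)
  best <- NULL
  pos <- 1L
  for (j in seq_along(runs$lengths)) {
    len <- runs$lengths[j]
    if (runs$values[j] && (is.null(best) || len > best$len))
      best <- list(start = pos, len = len)
    pos <- pos + len
  }
  linear_range <- if (is.null(best)) c(NA_real_, NA_real_) else
    c(conc[best$start], conc[best$start + best$len - 1L])
  in_range <- rep(FALSE, length(conc))
  if (!is.null(best)) in_range[best$start:(best$start + best$len - 1L)] <- TRUE
  structure(list(
    k = k,
    points = data.frame(concentration_nM = conc, ratio = r, fitted = fitted,
                        deviation = deviation, in_range = in_range),
    linear_range = linear_range,
    tolerance = tolerance
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> k = %.4g nM; linear range %g-%g nM (tol %.0f%%)\n",
    x$k, x$linear_range[1], x$linear_range[2], 100 * x$tolerance))
  print(x$points)
  invisible(x)
}
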