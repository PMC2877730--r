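# Mass spectrum container: an (m/z, intensity) trace plus acquisition
# metadata. All processing stages take and return this object.

#' Construct a mass spectrum
#'
#' @param mz Numeric vector of m/z values (Da), strictly increasing.
#' @param intensity Numeric vector of intensities (arbitrary units, >= 0),
#'   same length as `mz`.
#' @param metadata Named list of acquisition metadata (sample id, seed,
#'   instrument parameters, `mode = "profile"|"centroid"`).
#' @return Object of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, metadata = list()) {
  x <- structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                      metadata = metadata),
                 class = "mass_spectrum")
  validate_spectrum(x)
  x
}

#' @rdname mass_spectrum
#' @param x A `mass_spectrum`.
#' @export
validate_spectrum <- function(x) {
  if (length(x$mz) != length(x$intensity))
    stop("mz and intensity differ in length", call. = FALSE)
  if (length(x$mz) > 1L && any(diff(x$mz) <= 0))
    stop("mz must be strictly increasing", call. = FALSE)
  if (any(!is.finite(x$intensity)) || any(x$intensity < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  invisible(x)
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %d points, m/z %.2f-%.2f, base peak %.3g\n",
              length(x$mz), min(x$mz), max(x$mz),
              if (length(x$intensity)) max(x$intensity) else NA_real_))
  if (!is.null(x$metadata$sample_id))
    cat("  sample:", x$metadata$sample_id, "\n")
  invisible(x)
}

#' Restrict a spectrum to an m/z window
#'
#' @param x A `mass_spectrum`.
#' @param range Numeric pair `c(lo, hi)` in Da.
#' @return The windowed `mass_spectrum`.
#' @export
crop_spectrum <- function(x, range) {
  keep <- x$mz >= range[1] & x$mz <= range[2]
  mass_spectrum(x$mz[keep], x$intensity[keep], x$metadata)
}
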