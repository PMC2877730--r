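# Raw profile -> per-species summed relative adduct intensities:
# top-hat baseline correction, S/N peak picking with parabolic apex
# refinement, greedy envelope de-isotoping, nearest-match adduct assignment.

#' Top-hat baseline correction
#'
#' Morphological opening (rolling minimum followed by rolling maximum over
#' the same window) estimates the baseline, which is subtracted and the
#' result clipped at zero. The window must be wider than the peak FWHM so
#' peaks are not eroded.
#'
#' @param spectrum A [mass_spectrum()].
#' @param window Structuring-element width in Da (default 5).
#' @return Baseline-corrected `mass_spectrum` (m/z unchanged).
#' @export
baseline_correct <- function(spectrum, window = 5) {
  validate_spectrum(spectrum)
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  if (length(spectrum$mz) < 3L) return(spectrum)
  step <- median(diff(spectrum$mz))
  w <- max(3L, as.integer(round(window / step)))
  if (w %% 2L == 0L) w <- w + 1L
  baseline <- .roll_max(.roll_min(spectrum$intensity, w), w)
  out <- spectrum
  out$intensity <- pmax(spectrum$intensity - baseline, 0)
  out$metadata$baseline_corrected <- TRUE
  out
}

# robust noise (sd scale) of a vector; stats::mad already applies 1.4826
.robust_noise <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  mad(x)
}

#' Detect peaks by local maxima and signal-to-noise
#'
#' Local maxima of a baseline-corrected profile are kept when their
#' signal-to-noise ratio reaches `snr`. Noise is the scaled median absolute
#' deviation (x 1.4826) of the signal-free intensities (points within
#' `exclusion` Da of any clear peak are excluded) in the
#' `noise_halfwidth`-wide tile flanking the apex; because the top-hat
#' baseline runs under the noise and leaves a positive pedestal, the apex
#' is measured from the tile's median level. The apex m/z is refined
#' by three-point parabolic
#' interpolation (on log intensities when possible, which is exact for a
#' Gaussian peak).
#'
#' The reported `intensity` is the area-equivalent integrated intensity
#' (apex height x fitted sigma x sqrt(2*pi)), not the raw apex height: on a
#' TOF instrument the peak width grows with m/z at constant resolving
#' power, so apex heights of equal-abundance species ~200 Da apart differ
#' by ~18%, which would bias cross-species intensity ratios. S/N still
#' uses the apex height.
#'
#' @param spectrum Baseline-corrected [mass_spectrum()].
#' @param snr Detection threshold on S/N (default 3).
#' @param noise_halfwidth Width (Da) of the noise-estimation tiles.
#' @param exclusion Half-width (Da) of the signal exclusion zone around
#'   each candidate apex.
#' @return Data frame (class `peak_list`) with `mz`, `intensity`, `snr`,
#'   sorted by m/z. Noise-free spectra yield infinite S/N.
#' @export
detect_peaks <- function(spectrum, snr = 3, noise_halfwidth = 15,
                         exclusion = 2.5) {
  validate_spectrum(spectrum)
  y <- spectrum$intensity
  mz <- spectrum$mz
  n <- length(y)
  if (n < 3L) stop("spectrum shorter than 3 points", call. = FALSE)

  empty <- data.frame(mz = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  class(empty) <- c("peak_list", "data.frame")

  i <- 2:(n - 1L)
  cand <- i[y[i] > y[i - 1L] & y[i] >= y[i + 1L] & y[i] > 0]
  if (length(cand) == 0L) return(empty)

  # provisional global noise keeps the candidate set small under noise;
  # it is zero for noise-free input so no true peak is lost
  sigma0 <- .robust_noise(y)
  cand <- cand[y[cand] >= snr * sigma0]
  if (length(cand) == 0L) return(empty)

  # mask points near clear signal so noise windows are signal-free; only
  # unambiguous peaks (>= 10 sigma) are masked, since excluding marginal
  # 3-sigma noise bumps and their neighborhoods would bias the MAD low
  masked <- rep(FALSE, n)
  strong <- if (sigma0 > 0) cand[y[cand] >= 10 * sigma0] else cand
  mlo <- findInterval(mz[strong] - exclusion, mz) + 1L
  mhi <- findInterval(mz[strong] + exclusion, mz)
  for (k in seq_along(strong)) {
    if (mlo[k] <= mhi[k]) masked[mlo[k]:mhi[k]] <- TRUE
  }
  # noise per tile of width noise_halfwidth over signal-free points only;
  # a candidate's flanking noise is its tile's estimate
  ntile <- max(1L, as.integer(ceiling((mz[n] - mz[1]) / noise_halfwidth)))
  tile <- pmin(pmax(ceiling((mz - mz[1] + 1e-9) / noise_halfwidth), 1L),
               ntile)
  bounds <- findInterval(mz[1] + (0:ntile) * noise_halfwidth + 1e-9, mz)
  bounds[1] <- 0L
  # per-tile noise scale and level: the top-hat baseline runs under the
  # noise, leaving a positive pedestal, so the apex is measured from the
  # tile's median level, not from zero
  noise_of <- rep(sigma0, ntile)
  level_of <- rep(0, ntile)
  for (t in seq_len(ntile)) {
    if (bounds[t] >= bounds[t + 1L]) next
    idx <- (bounds[t] + 1L):bounds[t + 1L]
    v <- y[idx][!masked[idx]]
    if (length(v) > 10L) {
      noise_of[t] <- .robust_noise(v)
      level_of[t] <- median(v)
    }
  }

  out_mz <- out_int <- out_snr <- numeric(length(cand))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    j <- cand[k]
    noise <- noise_of[tile[j]]
    s2n <- if (noise > 0) (y[j] - level_of[tile[j]]) / noise else Inf
    if (s2n < snr) next
    h <- mz[j + 1L] - mz[j]
    if (y[j - 1L] > 0 && y[j + 1L] > 0) {
      # log-parabola: exact position, sigma, and height for a Gaussian
      l1 <- log(y[j - 1L]); l0 <- log(y[j]); l2 <- log(y[j + 1L])
      curv <- 2 * l0 - l1 - l2
      if (curv > 0) {
        delta <- max(-0.5, min(0.5, 0.5 * (l2 - l1) / curv))
        sigma_hat <- h / sqrt(curv)
        height <- exp(l0 + curv * delta^2 / 2)
        out_mz[k] <- mz[j] + delta * h
        out_int[k] <- height * sigma_hat * sqrt(2 * pi)
      } else {
        out_mz[k] <- mz[j]
        out_int[k] <- y[j] * h
      }
    } else {
      # fallback for peaks with a zero neighbor: linear parabola
      denom <- y[j - 1L] - 2 * y[j] + y[j + 1L]
      delta <- if (denom < 0) 0.5 * (y[j - 1L] - y[j + 1L]) / denom else 0
      delta <- max(-0.5, min(0.5, delta))
      height <- y[j] - 0.25 * (y[j - 1L] - y[j + 1L]) * delta
      sigma_hat <- if (denom < 0) sqrt(-y[j] * h^2 / denom) else h
      out_mz[k] <- mz[j] + delta * h
      out_int[k] <- height * sigma_hat * sqrt(2 * pi)
    }
    out_snr[k] <- s2n
    keep[k] <- TRUE
  }
  out <- data.frame(mz = out_mz[keep], intensity = out_int[keep],
                    snr = out_snr[keep])
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Collapse isotopologue envelopes to monoisotopic peaks
#'
#' Peaks are chained greedily left-to-right into envelopes when consecutive
#' spacing is 1.00335 +/- `tolerance` Da (ties broken by the smaller spacing
#' error) and intensities are non-increasing after the envelope maximum.
#' Each chain is replaced by its first (monoisotopic) peak carrying the
#' chain's summed intensity; the S/N scales with the summed intensity.
#'
#' Before the envelope maximum the intensity may rise by at most
#' `max_step_up` per isotopologue: for CHNOS peptides in the processed
#' window (< 1.5 kDa, < ~75 carbons) consecutive isotopologue ratios stay
#' below ~0.9, so the cap only rejects implausible chains in which a noise
#' peak one unit below a real monoisotopic peak would otherwise swallow it.
#'
#' @param peaks A `peak_list` sorted by m/z (as from [detect_peaks()]).
#' @param tolerance Spacing tolerance in Da (default 0.05).
#' @param max_step_up Maximum allowed intensity rise factor between
#'   consecutive isotopologues before the envelope maximum.
#' @return A `peak_list` of monoisotopic peaks.
#' @export
deisotope <- function(peaks, tolerance = 0.05, max_step_up = 3) {
  n <- nrow(peaks)
  if (n == 0L) return(peaks)
  pmz <- peaks$mz
  pint <- peaks$intensity
  psnr <- peaks$snr
  used <- rep(FALSE, n)
  # peaks are sorted: successor windows precomputed in one pass
  lo_all <- findInterval(pmz + .ISO_SPACING - tolerance, pmz) + 1L
  hi_all <- findInterval(pmz + .ISO_SPACING + tolerance, pmz)
  res_mz <- res_int <- res_snr <- numeric(n)
  nres <- 0L
  for (i in seq_len(n)) {
    if (used[i]) next
    used[i] <- TRUE
    first <- last <- i
    total <- pint[i]
    decreasing <- FALSE
    repeat {
      target <- pmz[last] + .ISO_SPACING
      lo <- lo_all[last]
      hi <- hi_all[last]
      if (lo > hi) break
      ok <- lo:hi
      ok <- ok[!used[ok]]
      if (length(ok) == 0L) break
      nxt <- ok[which.min(abs(pmz[ok] - target))]
      if (decreasing && pint[nxt] > pint[last]) break
      if (!decreasing && pint[nxt] > max_step_up * pint[last]) break
      if (pint[nxt] < pint[last]) decreasing <- TRUE
      used[nxt] <- TRUE
      total <- total + pint[nxt]
      last <- nxt
    }
    s2n <- if (is.finite(psnr[first]) && pint[first] > 0)
      psnr[first] * total / pint[first] else psnr[first]
    nres <- nres + 1L
    res_mz[nres] <- pmz[first]
    res_int[nres] <- total
    res_snr[nres] <- s2n
  }
  out <- data.frame(mz = res_mz[seq_len(nres)],
                    intensity = res_int[seq_len(nres)],
                    snr = res_snr[seq_len(nres)])
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Assign monoisotopic peaks to species adducts
#'
#' Each species' candidate adduct m/z values ([M+H]+, [M+Na]+, [M+K]+ of
#' its monoisotopic mass) are matched to the nearest unassigned peak within
#' `tolerance`; every peak is assigned at most once and conflicts are
#' resolved by the smallest mass error. Relative intensity is the peak
#' intensity divided by the base-peak intensity of the processed spectrum;
#' a species' summed relative intensity is the sum over its assigned
#' adducts.
#'
#' @param peaks Monoisotopic `peak_list` (as from [deisotope()]).
#' @param species List of [peptide_species()].
#' @param tolerance Mass tolerance in Da (default 0.2).
#' @param snr Detection threshold: a species is `detected` when at least
#'   one assigned adduct peak has S/N >= `snr`.
#' @return Named list of `peak_group` objects, one per species, each with
#'   `species`, `adducts` (data frame: adduct, expected/observed m/z,
#'   intensity, snr, relative intensity), `summed_relative`, `detected`,
#'   and any `ambiguity` notes.
#' @export
assign_adducts <- function(peaks, species = akh_species(), tolerance = 0.2,
                           snr = 3) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  ad <- adduct_table()
  cands <- do.call(rbind, lapply(species, function(sp) {
    data.frame(species = sp$name, adduct = ad$name,
               expected = monoisotopic_mass(sp) + ad$shift)
  }))
  base_peak <- if (nrow(peaks) > 0) max(peaks$intensity) else NA_real_

  # all candidate-peak pairs within tolerance, best errors first
  pairs <- list()
  for (r in seq_len(nrow(cands))) {
    if (nrow(peaks) == 0L) break
    err <- abs(peaks$mz - cands$expected[r])
    hit <- which(err <= tolerance)
    if (length(hit))
      pairs[[length(pairs) + 1L]] <-
        data.frame(cand = r, peak = hit, err = err[hit])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(cand = integer(0), peak = integer(0), err = numeric(0))
  pairs <- pairs[order(pairs$err), , drop = FALSE]

  assigned_peak <- rep(NA_integer_, nrow(cands))
  peak_taken <- rep(FALSE, max(1L, nrow(peaks)))
  for (r in seq_len(nrow(pairs))) {
    ci <- pairs$cand[r]; pi <- pairs$peak[r]
    if (!is.na(assigned_peak[ci]) || peak_taken[pi]) next
    assigned_peak[ci] <- pi
    peak_taken[pi] <- TRUE
  }

  groups <- lapply(species, function(sp) {
    rows <- which(cands$species == sp$name)
    tab <- data.frame(adduct = cands$adduct[rows],
                      expected_mz = cands$expected[rows],
                      mz = NA_real_, intensity = 0, snr = 0,
                      relative = 0)
    notes <- character(0)
    for (k in seq_along(rows)) {
      pi <- assigned_peak[rows[k]]
      if (is.na(pi)) next
      tab$mz[k] <- peaks$mz[pi]
      tab$intensity[k] <- peaks$intensity[pi]
      tab$snr[k] <- peaks$snr[pi]
      tab$relative[k] <- peaks$intensity[pi] / base_peak
      # ambiguity: another species' candidate also within tolerance
      others <- which(abs(cands$expected - peaks$mz[pi]) <= tolerance &
                        cands$species != sp$name)
      if (length(others))
        notes <- c(notes, sprintf(
          "peak %.3f also matches %s",
          peaks$mz[pi],
          paste(unique(cands$species[others]), collapse = ", ")))
    }
    structure(list(species = sp$name, adducts = tab,
                   summed_relative = sum(tab$relative),
                   detected = any(tab$snr >= snr & tab$intensity > 0),
                   ambiguity = notes),
              class = "peak_group")
  })
  names(groups) <- vapply(species, function(sp) sp$name, "")
  groups
}

#' @export
print.peak_group <- function(x, ...) {
  cat(sprintf("<peak_group> %s: summed relative intensity %.4f (%s)\n",
              x$species, x$summed_relative,
              if (x$detected) "detected" else "not detected"))
  print(x$adducts)
  invisible(x)
}

#' Peak groups as a flat table
#'
#' @param groups Output of [assign_adducts()].
#' @return Data frame with one row per species x adduct: `species`,
#'   `adduct`, `expected_mz`, `mz`, `intensity`, `snr`, `relative`,
#'   `summed_relative`, `detected`.
#' @export
peak_groups_table <- function(groups) {
  do.call(rbind, lapply(groups, function(g) {
    cbind(species = g$species, g$adducts,
          summed_relative = g$summed_relative, detected = g$detected,
          row.names = NULL)
  }))
}

#' Process a raw spectrum into peak groups
#'
#' Convenience wrapper running the stage order used for quantification:
#' crop to the processed window (the low-mass gate upward), baseline
#' correction, peak detection, de-isotoping, adduct assignment.
#'
#' @param spectrum Raw [mass_spectrum()].
#' @param species List of [peptide_species()].
#' @param window Processed m/z window (Da), default `c(850, 1500)`.
#' @param baseline_window,snr,mass_tolerance,spacing_tolerance Stage
#'   parameters.
#' @return Named list of `peak_group` objects.
#' @export
process_spectrum <- function(spectrum, species = akh_species(),
                             window = c(850, 1500), baseline_window = 5,
                             snr = 3, mass_tolerance = 0.2,
                             spacing_tolerance = 0.05) {
  cropped <- crop_spectrum(spectrum,
                           c(max(window[1], min(spectrum$mz)),
                             min(window[2], max(spectrum$mz))))
  corrected <- baseline_correct(cropped, baseline_window)
  peaks <- detect_peaks(corrected, snr = snr)
  mono <- deisotope(peaks, tolerance = spacing_tolerance)
  assign_adducts(mono, species, tolerance = mass_tolerance, snr = snr)
}
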