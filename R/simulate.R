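# Synthetic direct-profiling spectra of single corpora cardiaca with known
# ground truth. The generator emulates the acquisition used for quantitative
# profiling: analytes plus a spiked heavy standard, H/Na/K adducts, full
# isotope envelopes, exponential chemical baseline, detector noise averaged
# over subspectra, a low-mass gate, and one shared per-spectrum ion
# suppression factor.

#' Instrument model for the spectrum simulator
#'
#' @param resolving_power m/dm at FWHM (unitless); reflectron-TOF default
#'   8000.
#' @param grid_step Profile grid spacing (Da).
#' @param mz_range Simulated m/z window (Da).
#' @param low_mass_gate Intensities below this m/z are zeroed (Da).
#' @param noise_sd Detector noise sd per subspectrum (intensity units).
#' @param baseline_amplitude,baseline_decay Chemical baseline
#'   `amplitude * exp(-(mz - min)/decay)`.
#' @param c_sat Saturation concentration (nM): effective concentration is
#'   `c / (1 + c/c_sat)`.
#' @param subspectra Number of averaged noise realizations (the "five
#'   subspectra of 50 shots" acquisition).
#' @param gain Signal area per nM of effective concentration.
#' @return Object of class `instrument_model`.
#' @export
instrument_model <- function(resolving_power = 8000, grid_step = 0.02,
                             mz_range = c(840, 1250), low_mass_gate = 850,
                             noise_sd = 2, baseline_amplitude = 20,
                             baseline_decay = 100, c_sat = 20000,
                             subspectra = 5L, gain = 1) {
  stopifnot(resolving_power > 0, grid_step > 0, low_mass_gate >= 0,
            subspectra >= 1L, c_sat > 0, noise_sd >= 0)
  structure(list(resolving_power = resolving_power, grid_step = grid_step,
                 mz_range = mz_range, low_mass_gate = low_mass_gate,
                 noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
                 baseline_decay = baseline_decay, c_sat = c_sat,
                 subspectra = as.integer(subspectra), gain = gain),
            class = "instrument_model")
}

#' Default adduct intensity partitions
#'
#' Generator conventions (not measured values): AKH and AKH* ionize almost
#' exclusively as Na/K adducts; the free-acid intermediate AKHGK also
#' protonates appreciably.
#'
#' @return Named list of fractions over `H`, `Na`, `K`, each summing to 1.
#' @export
default_adduct_fractions <- function() {
  list("AKH"   = c(H = 0.05, Na = 0.55, K = 0.40),
       "AKH*"  = c(H = 0.05, Na = 0.55, K = 0.40),
       "AKHGK" = c(H = 0.35, Na = 0.40, K = 0.25))
}

#' Ground truth for one simulated corpora cardiaca
#'
#' @param amounts_fmol Named vector of true analyte amounts per CC (fmol);
#'   names must match species names. The internal standard is specified by
#'   concentration, not amount.
#' @param matrix_nl Matrix volume applied per sample (nl).
#' @param standard_nM Internal standard concentration in the matrix (nM).
#' @param suppression_sigma Log-normal sigma of the shared per-spectrum ion
#'   suppression factor (factor has mean 1).
#' @param adduct_fractions Named list of H/Na/K fractions per species.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(amounts_fmol = c("AKH" = 178, "AKHGK" = 165),
                         matrix_nl = 200, standard_nM = 400,
                         suppression_sigma = 0.5,
                         adduct_fractions = default_adduct_fractions()) {
  if (any(amounts_fmol < 0)) stop("amounts must be >= 0", call. = FALSE)
  stopifnot(matrix_nl > 0, standard_nM >= 0, suppression_sigma >= 0)
  for (f in adduct_fractions) {
    if (abs(sum(f) - 1) > 1e-9)
      stop("adduct fractions must sum to 1", call. = FALSE)
  }
  structure(list(amounts_fmol = amounts_fmol, matrix_nl = matrix_nl,
                 standard_nM = standard_nM,
                 suppression_sigma = suppression_sigma,
                 adduct_fractions = adduct_fractions),
            class = "ground_truth")
}

# fmol per CC dissolved in the matrix droplet -> nM (1 fmol/nl = 1 uM)
.fmol_to_nM <- function(fmol, matrix_nl) 1000 * fmol / matrix_nl

# precompute centroid m/z and envelope abundance per species/adduct/isotopologue
.ion_table <- function(species, adduct_fractions, n_iso = 5L) {
  ad <- adduct_table()
  rows <- list()
  for (sp in species) {
    comp <- elemental_composition(sp)
    neutral <- .comp_mass(comp, .MONO_MASS)
    env <- isotope_envelope(comp, n_iso)
    frac <- adduct_fractions[[sp$name]]
    if (is.null(frac))
      stop("no adduct fractions for species ", sp$name, call. = FALSE)
    for (a in rownames(ad)) {
      if (frac[[a]] <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp$name, adduct = ad[a, "name"],
        mz = neutral + env$offset + ad[a, "shift"],
        weight = frac[[a]] * env$abundance
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate one direct-profiling spectrum
#'
#' Renders, for every species and adduct, a Gaussian profile peak per
#' isotopologue with FWHM = m/z / resolving power and area proportional to
#' effective concentration x adduct fraction x envelope abundance x the
#' shared suppression factor. Saturation makes concentration effective via
#' `c_eff = c / (1 + c/c_sat)`. An exponential chemical baseline and
#' Gaussian detector noise (averaged over `subspectra` realizations) are
#' added, intensities below the low-mass gate are zeroed, and negative
#' values are clipped at 0.
#'
#' @param truth A [ground_truth()].
#' @param species List of [peptide_species()]; defaults to [akh_species()].
#' @param instrument An [instrument_model()].
#' @param seed Integer seed; with a fixed seed the output is
#'   bit-reproducible.
#' @param sample_id Identifier stored in the metadata.
#' @param ions Optional precomputed ion table (internal, for cohort speed).
#' @return A [mass_spectrum()] with ground truth echoed in the metadata.
#' @export
#' @examples
#' sp <- simulate_spectrum(ground_truth(), seed = 1)
simulate_spectrum <- function(truth, species = akh_species(),
                              instrument = instrument_model(), seed,
                              sample_id = "sim", ions = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(instrument, "instrument_model"))
  if (any(truth$amounts_fmol < 0)) stop("amounts must be >= 0", call. = FALSE)
  if (is.null(ions)) ions <- .ion_table(species, truth$adduct_fractions)

  set.seed(as.integer(seed))
  sigma_s <- truth$suppression_sigma
  suppression <- if (sigma_s > 0)
    rlnorm(1, meanlog = -sigma_s^2 / 2, sdlog = sigma_s) else 1

  grid <- seq(instrument$mz_range[1], instrument$mz_range[2],
              by = instrument$grid_step)
  n <- length(grid)
  signal <- numeric(n)

  conc <- c(.fmol_to_nM(truth$amounts_fmol, truth$matrix_nl),
            "AKH*" = truth$standard_nM)
  c_eff <- conc / (1 + conc / instrument$c_sat)

  for (i in seq_len(nrow(ions))) {
    ci_idx <- match(ions$species[i], names(conc))
    if (is.na(ci_idx)) next  # species not present in this sample
    ci <- c_eff[[ci_idx]]
    if (is.na(ci) || ci <= 0) next
    area <- instrument$gain * ci * ions$weight[i] * suppression
    if (area <= 0) next
    mzc <- ions$mz[i]
    sd_peak <- (mzc / instrument$resolving_power) / 2.35482
    lo <- max(1L, ceiling((mzc - 6 * sd_peak - grid[1]) / instrument$grid_step) + 1L)
    hi <- min(n, floor((mzc + 6 * sd_peak - grid[1]) / instrument$grid_step) + 1L)
    if (lo > hi) next
    idx <- lo:hi
    signal[idx] <- signal[idx] + area * dnorm(grid[idx], mzc, sd_peak)
  }

  baseline <- instrument$baseline_amplitude *
    exp(-(grid - grid[1]) / instrument$baseline_decay)

  noise <- numeric(n)
  if (instrument$noise_sd > 0) {
    reps <- matrix(rnorm(n * instrument$subspectra, 0, instrument$noise_sd),
                   nrow = n)
    noise <- rowMeans(reps)
  }

  intensity <- pmax(signal + baseline + noise, 0)
  intensity[grid < instrument$low_mass_gate] <- 0

  mass_spectrum(grid, intensity, metadata = list(
    sample_id = sample_id, seed = as.integer(seed), mode = "profile",
    suppression = suppression, truth = truth, instrument = instrument))
}

#' Draw per-CC true amounts for a cohort
#'
#' Amounts are log-normal, moment-matched to the requested mean and sd
#' (support is positive, so no truncation is needed); `sd = 0` gives the
#' mean exactly.
#'
#' @param n Cohort size.
#' @param mean,sd Target mean and sd (fmol).
#' @return Numeric vector of length `n`.
#' @export
draw_cohort_amounts <- function(n, mean, sd) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a cohort of single-CC spectra
#'
#' @param n Number of flies (>= 1).
#' @param mean_fmol,sd_fmol Named vectors of per-species amount mean and sd
#'   (fmol per CC).
#' @param seed Integer master seed; per-sample seeds are derived with
#'   [derive_seed()].
#' @param species,instrument Passed to [simulate_spectrum()].
#' @param standard_nM,matrix_nl,suppression_sigma,adduct_fractions Passed to
#'   [ground_truth()].
#' @param fix_mean If `TRUE`, rescale the drawn amounts so the cohort's
#'   ground-truth sample mean equals `mean_fmol` exactly (per species); used
#'   when the cohort's true mean is the controlled quantity.
#' @param group Group label stored in sample ids.
#' @return List of length `n`; each element has `$spectrum` and `$truth`.
#' @export
#' @examples
#' cohort <- simulate_cohort(2, c(AKH = 178), c(AKH = 54), seed = 1)
simulate_cohort <- function(n, mean_fmol, sd_fmol, seed,
                            species = akh_species(),
                            instrument = instrument_model(),
                            standard_nM = 400, matrix_nl = 200,
                            suppression_sigma = 0.5,
                            adduct_fractions = default_adduct_fractions(),
                            fix_mean = FALSE, group = "cohort") {
  stopifnot(n >= 1)
  if (any(sd_fmol < 0)) stop("sd must be >= 0", call. = FALSE)
  set.seed(derive_seed(seed, paste0(group, ":amounts")))
  amounts <- vapply(names(mean_fmol), function(s) {
    a <- draw_cohort_amounts(n, mean_fmol[[s]], sd_fmol[[s]])
    if (fix_mean && mean(a) > 0) a <- a * mean_fmol[[s]] / mean(a)
    a
  }, numeric(n))
  amounts <- matrix(amounts, nrow = n,
                    dimnames = list(NULL, names(mean_fmol)))
  ions <- .ion_table(species, adduct_fractions)
  lapply(seq_len(n), function(i) {
    truth <- ground_truth(amounts_fmol = amounts[i, ], matrix_nl = matrix_nl,
                          standard_nM = standard_nM,
                          suppression_sigma = suppression_sigma,
                          adduct_fractions = adduct_fractions)
    spec <- simulate_spectrum(truth, species, instrument,
                              seed = derive_seed(seed, paste0(group, ":", i)),
                              sample_id = sprintf("%s_%02d", group, i),
                              ions = ions)
    list(spectrum = spec, truth = truth)
  })
}

#' Simulate a standard dilution series
#'
#' One spectrum per standard concentration, analyte amount held constant —
#' the acquisition behind the calibration curve.
#'
#' @param concentrations_nM Standard concentrations (nM), all > 0.
#' @param analyte_fmol Named vector of fixed analyte amounts (fmol).
#' @param seed Master seed.
#' @param species,instrument,matrix_nl,suppression_sigma,adduct_fractions
#'   As in [simulate_cohort()].
#' @return List with `$spectrum` and `$truth` per concentration.
#' @export
simulate_dilution_series <- function(concentrations_nM,
                                     analyte_fmol = c("AKH" = 38),
                                     seed,
                                     species = akh_species(),
                                     instrument = instrument_model(),
                                     matrix_nl = 200,
                                     suppression_sigma = 0.5,
                                     adduct_fractions = default_adduct_fractions()) {
  if (length(concentrations_nM) == 0L)
    stop("empty concentration list", call. = FALSE)
  if (any(concentrations_nM <= 0))
    stop("concentrations must be > 0", call. = FALSE)
  ions <- .ion_table(species, adduct_fractions)
  lapply(seq_along(concentrations_nM), function(i) {
    truth <- ground_truth(amounts_fmol = analyte_fmol, matrix_nl = matrix_nl,
                          standard_nM = concentrations_nM[i],
                          suppression_sigma = suppression_sigma,
                          adduct_fractions = adduct_fractions)
    spec <- simulate_spectrum(
      truth, species, instrument,
      seed = derive_seed(seed, paste0("dilution:", i)),
      sample_id = sprintf("std_%gnM", concentrations_nM[i]), ions = ions)
    list(spectrum = spec, truth = truth)
  })
}
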