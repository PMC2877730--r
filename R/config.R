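# Run configuration: JSON key-value file with documented schema. Every key
# has a default except `seed`; unknown keys are rejected so typos cannot
# silently fall back to defaults.

#' Default run configuration
#'
#' Schema (JSON object, all keys optional except `seed`):
#' \describe{
#'   \item{seed}{Integer master seed (required; may be supplied via the CLI
#'     `--seed` flag instead of the file).}
#'   \item{outdir}{Output directory.}
#'   \item{format}{Spectrum file format, `"tsv"` or `"mzml"`.}
#'   \item{standard_nM}{Internal standard concentration (default 400).}
#'   \item{matrix_nl}{Matrix volume per sample (default 200).}
#'   \item{suppression_sigma}{Log-normal sigma of per-spectrum ion
#'     suppression (default 0.5).}
#'   \item{instrument}{Sub-object with [instrument_model()] fields.}
#'   \item{groups}{Array of cohort specs: `label`, `n`, `mean` and `sd`
#'     (objects mapping species name to fmol).}
#'   \item{pairings}{Array of `{a, b}` group-label pairs to compare.}
#'   \item{tolerances}{`mass_tol` (0.2), `spacing_tol` (0.05), `snr` (3),
#'     `baseline_window` (5), `linearity` (0.15).}
#' }
#'
#' @return Named list of defaults (with `seed = NULL`).
#' @export
default_config <- function() {
  list(
    seed = NULL,
    outdir = "akh_run",
    format = "tsv",
    standard_nM = 400,
    matrix_nl = 200,
    suppression_sigma = 0.5,
    instrument = unclass(instrument_model()),
    groups = list(
      list(label = "control", n = 15,
           mean = list("AKH" = 177.25, "AKHGK" = 165),
           sd = list("AKH" = 53.3, "AKHGK" = 50)),
      list(label = "amon", n = 16,
           mean = list("AKH" = 21.6, "AKHGK" = 12),
           sd = list("AKH" = 9.6, "AKHGK" = 6))
    ),
    pairings = list(list(a = "control", b = "amon")),
    tolerances = list(mass_tol = 0.2, spacing_tol = 0.05, snr = 3,
                      baseline_window = 5, linearity = 0.15)
  )
}

.merge_checked <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]]) && k %in% c("instrument", "tolerances")) {
      defaults[[k]] <- .merge_checked(defaults[[k]], user[[k]],
                                      paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build a run configuration
#'
#' Merges user settings over [default_config()], rejecting unknown keys.
#'
#' @param ... Named settings (see [default_config()] for the schema).
#' @param seed Integer master seed (required here or in `...`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(..., seed = NULL) {
  user <- list(...)
  if (!is.null(seed)) user$seed <- seed
  cfg <- .merge_checked(default_config(), user)
  if (is.null(cfg$seed)) stop("config needs a seed", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$instrument <- do.call(instrument_model, cfg$instrument)
  structure(cfg, class = "run_config")
}

#' Read a configuration file
#'
#' @param path JSON file following the [default_config()] schema.
#' @param seed Optional seed overriding the file's value.
#' @return A `run_config`.
#' @export
read_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  if (!is.null(seed)) user$seed <- seed
  do.call(run_config, user)
}

# 31-based polynomial string hash mod 2^31 - 1 (exact in doubles)
.str_hash <- function(s) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% m
  h
}

#' Fingerprint of a configuration
#'
#' Stable hash of the canonical JSON serialization; logged with every run
#' so any output file is traceable to exactly one configuration.
#'
#' @param config A `run_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x))) x <- x[order(names(x))]
    if (is.list(x)) lapply(x, canon) else x
  }
  s <- as.character(jsonlite::toJSON(canon(unclass(config)),
                                     auto_unbox = TRUE, digits = NA))
  sprintf("%08x", .str_hash(s))
}

#' Derive a child seed for a pipeline stage
#'
#' All randomness flows from the single config seed: each stage (or sample)
#' gets `(seed + hash(label)) mod (2^31 - 1)`, keeping every seed a valid
#' 32-bit integer.
#'
#' @param seed Integer master seed.
#' @param label Stage/sample label, e.g. `"control:3"`.
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, label) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m + .str_hash(label)) %% m)
}
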