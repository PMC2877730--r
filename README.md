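# akhquant

Quantitative direct MALDI-TOF profiling of adipokinetic hormone (AKH) in
single insect corpora cardiaca (CC).

## The problem

AKH is the insect glucagon analog: an octapeptide
(pGlu-Leu-Thr-Phe-Ser-Pro-Asp-Trp-amide in *Drosophila*) released from the
corpora cardiaca to mobilize sugar and lipid stores. Its precursor is
matured by a signal peptidase, a PC2-type prohormone convertase that cuts
C-terminally to a dibasic site, a carboxypeptidase that trims the exposed
basic residues, and a glycine-consuming amidation, leaving a measurable
intermediate (AKHGK, the mature sequence with a C-terminal Gly-Lys
extension) along the way.

Whole dissected glands can be profiled directly by MALDI-TOF, but raw MALDI
signal intensities are not quantitative: analyte incorporation into the
matrix co-crystal and ion suppression vary spot to spot. The remedy
implemented here is isotope-dilution: a known amount of a chemically
identical, stable-isotope-labelled standard (AKH*, with
Leu as ^13C6,^15N; [M+H]+ = 982.5) is co-crystallized with every sample, and each
analyte is quantified from the ratio of summed adduct intensities

    amount = (I_analyte / I_standard) x n_standard        (unity slope)

where `I` sums the relative intensities of the [M+H]+, [M+Na]+ and [M+K]+
monoisotopic peaks of a species after baseline correction and
de-isotoping, and `n_standard` is the spiked amount (400 nM in 200 nl of
matrix = 80 fmol). Because the spectrum-wide suppression factor multiplies
analyte and standard alike, it cancels exactly in the ratio.

The package provides, as testable modules:

- **Peptide masses** — residue-level elemental compositions, monoisotopic
  and average masses, H/Na/K adduct m/z, isotope envelopes with exact
  handling of heavy-isotope labels, and the prohormone processing model
  that enumerates the expected species.
- **Synthetic spectra** — a ground-truth generator emulating single-CC
  direct profiles (Gaussian peaks at m/z / resolving-power width, full
  isotope envelopes, exponential chemical baseline, detector noise averaged
  over subspectra, 850 Da low-mass gate, per-spectrum log-normal ion
  suppression, saturation at high load).
- **Spectrum processing** — top-hat baseline correction, S/N-based peak
  detection with log-parabola apex refinement, greedy envelope
  de-isotoping, nearest-match adduct assignment.
- **Quantification** — intensity ratios, unity-slope amounts, and an
  inverse-concentration calibration diagnostic with linear-range detection.
- **Cohort statistics** — detection rates, median ratios, mean ± s.e.m.
  amounts, exact/approximate Mann-Whitney comparisons.
- **I/O and CLI** — mzML and two-column text spectra, JSON run configs,
  a four-stage pipeline (`simulate`, `process`, `quantify`, `compare`).

## Worked example

```r
library(akhquant)

## masses of the three profiled species
vapply(akh_species(), monoisotopic_mass, 0)
#>       AKH     AKHGK      AKH*
#>  974.4498 1160.5502  981.4669
round(adduct_mz(monoisotopic_mass(akh_species()[["AKH*"]]), "[M+H]+"), 1)
#> [1] 982.5

## simulate one control CC (174 fmol AKH) and quantify it
truth <- ground_truth(c(AKH = 174, AKHGK = 150))
spec  <- simulate_spectrum(truth, seed = 42)
grp   <- process_spectrum(spec)
intensity_ratio(grp[["AKH"]], grp[["AKH*"]])
#> [1] 2.109593
quantify_groups(grp)$amount
#>      AKH    AKHGK
#> 168.7674 145.3054
```

The ratio 2.11 x 80 fmol of standard recovers ~169 fmol against a true 174
fmol; the small shortfall is the documented saturation of the ~870 nM
analyte load relative to the 400 nM standard.

A full two-cohort comparison from the bundled day-5 configuration:

```r
cfg <- read_config(system.file("extdata", "table1_day5.json",
                               package = "akhquant"), seed = 11)
run_pipeline(cfg, "all")
read.csv(file.path(cfg$outdir, "comparison.csv"))
```

which reports the control vs convertase-mutant medians with a Mann-Whitney
`**` (p < 0.01) flag, mirroring the published day-5 contrast. The same
workflow is available from the shell:

```sh
Rscript -e 'akhquant::akh_cli(exit = TRUE)' all \
    --config inst/extdata/table1_day5.json --seed 11 --out day5_run
```

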