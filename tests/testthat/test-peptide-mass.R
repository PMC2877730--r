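# Masses, compositions, adducts, envelopes, and the prohormone processing
# chain, checked against the independent residue-sum oracle in
# helper-oracle.R.

test_that("residue table is internally consistent and complete", {
  tab <- residue_table()
  expect_setequal(rownames(tab), names(ORACLE_MONO))
  # stored residue masses agree with the independent literature values
  expect_equal(tab[names(ORACLE_MONO), "monoisotopic"],
               unname(ORACLE_MONO), tolerance = 1e-4)
})

test_that("elemental composition follows peptide-bond bookkeeping", {
  g <- elemental_composition(peptide_species("G", "G"))
  expect_equal(g[c("C", "H", "N", "O", "S")],
               c(C = 2, H = 5, N = 1, O = 2, S = 0))
  # GG = 2 x G - one water
  gg <- elemental_composition(peptide_species("GG", "GG"))
  expect_equal(unname(gg["H"]), 2 * 5 - 2)
  expect_equal(unname(gg["O"]), 2 * 2 - 1)
  expect_error(elemental_composition(peptide_species("bad", "GXZ")),
               "unknown residue code.*X")
})

test_that("heavy labels appear as distinct atoms", {
  comp <- elemental_composition(akh_species()[["AKH*"]])
  expect_equal(unname(comp["C13"]), 6)
  expect_equal(unname(comp["N15"]), 1)
  light <- elemental_composition(akh_species()[["AKH"]])
  expect_equal(unname(comp["C"]), unname(light["C"]) - 6)
  expect_equal(unname(comp["N"]), unname(light["N"]) - 1)
})

test_that("monoisotopic masses of the AKH species match the oracle", {
  sp <- akh_species()
  expect_equal(monoisotopic_mass(sp$AKH),
               oracle_mass("QLTFSPDW", pyroglu = TRUE, amide = TRUE),
               tolerance = 1e-4)
  expect_equal(monoisotopic_mass(sp$AKH), 974.4498, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(sp$AKHGK),
               oracle_mass("QLTFSPDWGK", pyroglu = TRUE), tolerance = 1e-4)
  expect_equal(monoisotopic_mass(sp$AKHGK), 1160.5502, tolerance = 1e-4)
  expect_equal(monoisotopic_mass(sp[["AKH*"]]),
               oracle_mass("QLTFSPDW", TRUE, TRUE, label = TRUE),
               tolerance = 1e-4)
  expect_equal(monoisotopic_mass(sp[["AKH*"]]), 981.4669, tolerance = 1e-4)
})

test_that("labelled standard protonates to the printed 982.5", {
  mh <- adduct_mz(monoisotopic_mass(akh_species()[["AKH*"]]), "[M+H]+")
  expect_equal(mh, 982.4742, tolerance = 1e-3)
  expect_equal(round(mh, 1), 982.5)
})

test_that("average masses use the average atomic weight table", {
  water <- average_mass(peptide_species("GG", "GG")) -
    2 * (average_mass(peptide_species("G", "G")) - 18.01528) - 18.01528
  expect_equal(water + 18.01528, 18.01528, tolerance = 2e-3)
  # label delta: labelled minus unlabelled
  sp <- akh_species()
  expect_equal(monoisotopic_mass(sp[["AKH*"]]) - monoisotopic_mass(sp$AKH),
               7.0172, tolerance = 5e-4)
  # average mass of the standard (composition-based; rules out the
  # "982.5 = average mass" reading)
  expect_equal(average_mass(sp[["AKH*"]]), 982.004, tolerance = 0.01)
})

test_that("adduct m/z values match cation arithmetic", {
  akh <- monoisotopic_mass(akh_species()$AKH)
  expect_equal(adduct_mz(akh, "[M+Na]+"), akh + ORACLE_NA, tolerance = 1e-4)
  expect_equal(adduct_mz(akh, "[M+Na]+"), 997.439, tolerance = 1e-3)
  expect_equal(adduct_mz(akh, "[M+K]+"), 1013.413, tolerance = 1e-3)
  gk <- monoisotopic_mass(akh_species()$AKHGK)
  expect_equal(adduct_mz(gk, "[M+H]+"), 1161.557, tolerance = 1e-3)
  expect_error(adduct_mz(1000, "[M+Cs]+"), "unknown adduct")
  expect_true(all(adduct_table()$shift > 0))
  expect_true(all(adduct_table()$charge == 1L))
})

test_that("mass additivity holds for random sequences", {
  set.seed(7)
  codes <- rownames(residue_table())
  for (i in 1:20) {
    a <- paste(sample(codes, sample(2:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(codes, sample(2:12, 1), replace = TRUE), collapse = "")
    m_ab <- monoisotopic_mass(peptide_species("ab", paste0(a, b)))
    m_a <- monoisotopic_mass(peptide_species("a", a))
    m_b <- monoisotopic_mass(peptide_species("b", b))
    expect_equal(m_ab, m_a + m_b - ORACLE_WATER, tolerance = 1e-4)
  }
})

test_that("isotope envelopes match element abundance arithmetic", {
  one_c <- isotope_envelope(c(C = 1), n_peaks = 2)
  expect_equal(one_c$abundance, c(0.9893, 0.0107))
  pure_heavy <- isotope_envelope(c(C13 = 10, N15 = 2), n_peaks = 3)
  expect_equal(pure_heavy$abundance, c(1, 0, 0))
  # second/mono ratio of AKH from first-order abundance arithmetic
  env <- isotope_envelope(elemental_composition(akh_species()$AKH), 5)
  expect_gt(env$abundance[2] / env$abundance[1], 0.55)
  expect_lt(env$abundance[2] / env$abundance[1], 0.60)
  expect_true(all(env$abundance >= 0))
  expect_lte(sum(env$abundance), 1)
  expect_error(isotope_envelope(c(C = 1), n_peaks = 1), "n_peaks")
})

test_that("labelled envelope is the light-atom envelope at shifted positions", {
  sp <- akh_species()
  env_star <- isotope_envelope(elemental_composition(sp[["AKH*"]]), 5)
  # positions: monoisotopic shifted by the label delta
  expect_equal(monoisotopic_mass(sp[["AKH*"]]) + env_star$offset,
               monoisotopic_mass(sp$AKH) + 7.0172 + env_star$offset,
               tolerance = 5e-4)
  # abundances equal those of the residual light-atom composition, and the
  # labelled envelope is narrower than the unlabelled one (fewer light C)
  light_only <- elemental_composition(sp[["AKH*"]])
  light_only["C13"] <- 0
  light_only["N15"] <- 0
  expect_equal(env_star$abundance,
               isotope_envelope(light_only, 5)$abundance)
  env_akh <- isotope_envelope(elemental_composition(sp$AKH), 5)
  expect_lt(env_star$abundance[2] / env_star$abundance[1],
            env_akh$abundance[2] / env_akh$abundance[1])
})

test_that("modification mass deltas equal their composition masses", {
  for (m in list(mod_pyroglutamate(), mod_amide(), mod_label_13C6_15N(2))) {
    direct <- sum(m$delta * c(C = 12, C13 = 13.0033548378,
                              H = 1.00782503207, N = 14.0030740048,
                              N15 = 15.0001088982, O = 15.9949146196,
                              S = 31.9720710015)[names(m$delta)])
    expect_equal(m$mass_delta, direct, tolerance = 1e-4)
  }
})

test_that("prohormone processing reproduces the maturation chain", {
  ann <- prohormone_annotation("MKLQLTFSPDWGKRAPE", 3, c(4, 11), c(12, 14),
                               c(15, 17))
  chain <- process_prohormone(ann)
  seqs <- vapply(chain, function(s) s$sequence, "")
  expect_equal(seqs, c("QLTFSPDWGKRAPE", "QLTFSPDWGKR", "QLTFSPDWGK",
                       "QLTFSPDWG", "QLTFSPDW"))
  # final species is amidated with pyroglutamate
  mature <- chain[[length(chain)]]
  expect_setequal(vapply(mature$modifications, function(m) m$name, ""),
                  c("amide", "pyroglutamate"))
  # cross-module: returned AKHGK and AKH masses match the direct species
  m <- vapply(chain, monoisotopic_mass, 0)
  expect_equal(m[3], monoisotopic_mass(akh_species()$AKHGK),
               tolerance = 1e-4)
  expect_equal(monoisotopic_mass(mature),
               monoisotopic_mass(akh_species()$AKH), tolerance = 1e-4)
  # masses strictly decrease along the carboxypeptidase chain
  expect_true(all(diff(m[2:5]) < 0))
})

test_that("processing handles edge cases", {
  # peptide not starting with Q: no pyroglutamate
  ann <- prohormone_annotation("MKLALTFSPDWGKRAPE", 3, c(4, 11), c(12, 14),
                               c(15, 17))
  mature <- tail(process_prohormone(ann), 1)[[1]]
  expect_false("pyroglutamate" %in%
                 vapply(mature$modifications, function(m) m$name, ""))
  # linker without a dibasic pair
  bad <- prohormone_annotation("MKLQLTFSPDWGAAAPE", 3, c(4, 11), c(12, 14),
                               c(15, 17))
  expect_error(process_prohormone(bad), "no PC site")
  # spans must tile
  expect_error(prohormone_annotation("MKLQLTFSPDWGKRAPE", 3, c(5, 11),
                                     c(12, 14), c(15, 17)), "contiguous")
})

test_that("species validation catches malformed input", {
  expect_error(peptide_species("x", ""), "non-empty")
  expect_error(peptide_species("x", "GG",
                               list(mod_amide(), mod_amide())),
               "at most one")
  expect_error(peptide_species("x", "GG", list(mod_label_13C6_15N(5))),
               "outside sequence")
})
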