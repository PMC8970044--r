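# Fragment matching, oxonium screening and fucose-topology calls.

test_that("planted diagnostic ions are recovered below 1 ppm", {
  ox <- oxonium_ions("HexNAc(1)Hex(1)Fuc(1)NeuAc(1)")
  sp <- ms2_spectrum("planted", 900, 2L, 10,
                     data.frame(mz = ox$mz, intensity = 100))
  hits <- screen_oxonium(sp, "HexNAc(1)Hex(1)Fuc(1)NeuAc(1)", tol_ppm = 20)
  expect_equal(nrow(hits), 8L)
  expect_true(all(abs(hits$error_ppm) < 1))
})

test_that("a 59 ppm offset peak is not matched at 20 ppm", {
  sp <- ms2_spectrum("off", 900, 2L, 10,
                     data.frame(mz = 512.23, intensity = 100))
  hits <- screen_oxonium(sp, "HexNAc(1)Hex(1)Fuc(1)", tol_ppm = 20)
  expect_false("HexNAcHexFuc" %in% hits$label)
  # the offset is ~ 59 ppm, so a 100 ppm tolerance does match
  hits2 <- screen_oxonium(sp, "HexNAc(1)Hex(1)Fuc(1)", tol_ppm = 100)
  expect_true("HexNAcHexFuc" %in% hits2$label)
})

test_that("non-fucosylated targets never match the 512.20 diagnostic", {
  gp <- glycopeptide("ELHHLQEQNVSNAFLDK", "HexNAc(5)Hex(6)NeuAc(3)")
  sp <- make_ms2(gp, seed = 5)
  hits <- screen_oxonium(sp, gp$glycan)
  expect_false("HexNAcHexFuc" %in% hits$label)
})

test_that("b/y ladders of a toy peptide are recovered against frozen values", {
  # frozen from an independent fragment-mass computation (charge 1)
  b_expected <- c(b2 = 227.1026, b3 = 324.1554, b4 = 425.2031,
                  b5 = 538.2871, b6 = 653.3141)
  y_expected <- c(y1 = 148.0604, y2 = 263.0874, y3 = 376.1714,
                  y4 = 477.2191, y5 = 574.2719, y6 = 703.3145)
  frags <- peptide_fragments("PEPTIDE", max_charge = 1L)
  got <- setNames(frags$mz, frags$label)
  expect_equal(got[names(b_expected)], b_expected, tolerance = 1e-4)
  expect_equal(got[names(y_expected)], y_expected, tolerance = 1e-4)
  # plant those peaks and confirm the matcher recovers the full ladder
  gp <- glycopeptide("PEPTIDE", glycan_composition())
  sp <- ms2_spectrum("ladder", 500, 2L, 5,
                     data.frame(mz = c(b_expected, y_expected),
                                intensity = 100))
  hits <- match_fragments(sp, gp, tol_ppm = 10, ion_types = c("b", "y"),
                          max_charge = 1L)
  expect_true(all(names(b_expected) %in% hits$label))
  expect_true(all(names(y_expected) %in% hits$label))
})

test_that("planted glycopeptide fragments are fully recovered with no false labels", {
  gp <- n762_gp()
  theo <- theoretical_fragments(gp, max_charge = 2L)
  sp <- make_ms2(gp, jitter_ppm = 0, n_noise = 40, seed = 9)
  hits <- match_fragments(sp, gp, tol_ppm = 10)
  # every planted ion recovered at ~0 ppm, nothing else labelled
  expect_equal(sort(paste(hits$label, hits$charge)),
               sort(paste(theo$label, theo$charge)))
  expect_true(all(abs(hits$error_ppm) < 1e-6))
})

test_that("peak-assignment collisions resolve to smaller ppm, tie to lower mass", {
  # two theoretical ions within tolerance of one peak
  ions <- rbind(
    data.frame(kind = "Y", label = "low", neutral_mass = 999.992724,
               charge = 1L, mz = 1001.000),
    data.frame(kind = "Y", label = "high", neutral_mass = 1000.002724,
               charge = 1L, mz = 1001.010))
  sp <- ms2_spectrum("c", 900, 2L, 1,
                     data.frame(mz = 1001.004, intensity = 10))
  got <- glycoPRM:::match_ion_table(sp, ions, tol_ppm = 20)
  expect_identical(got$label, "low")  # 4 ppm beats 6 ppm
  # exact tie in the absolute-tolerance regime: peak equidistant -> lower mass
  ions_abs <- rbind(
    data.frame(kind = "Y", label = "low", neutral_mass = 98.992724,
               charge = 1L, mz = 100),
    data.frame(kind = "Y", label = "high", neutral_mass = 298.992724,
               charge = 1L, mz = 300))
  sp_tie <- ms2_spectrum("t", 900, 2L, 1,
                         data.frame(mz = 200, intensity = 10))
  got_tie <- glycoPRM:::match_ion_table(sp_tie, ions_abs, tol_mz = 150)
  expect_identical(got_tie$label, "low")  # tie -> lower-mass ion
})

test_that("matching is deterministic and monotone in tolerance", {
  gp <- n762_gp()
  sp <- make_ms2(gp, jitter_ppm = 5, n_noise = 60, seed = 21)
  a <- call_fucose_topology(sp, gp)
  b <- call_fucose_topology(sp, gp)
  expect_identical(a, b)
  narrow <- match_fragments(sp, gp, tol_ppm = 5)
  wide <- match_fragments(sp, gp, tol_ppm = 20)
  expect_true(all(paste(narrow$label, narrow$charge) %in%
                    paste(wide$label, wide$charge)))
})

test_that("topology verdicts follow the diagnostic-ion evidence", {
  gp <- n762_gp()  # bi-fucosylated tri-antennary, site N762
  # planted 1287.61 (2+) and 512.20 -> both core and outer-arm
  ys <- y_ion_series(gp, 2L)
  core_mz <- ys$mz[ys$label == "pep+2HexNAc+Fuc" & ys$charge == 2L]
  outer_mz <- oxonium_ions(gp$glycan)
  outer_mz <- outer_mz$mz[outer_mz$label == "HexNAcHexFuc"]
  sp <- ms2_spectrum("both", precursor_mz(gp, 4L), 4L, 41.5,
                     data.frame(mz = c(core_mz, outer_mz),
                                intensity = c(100, 80)))
  call <- call_fucose_topology(sp, gp)
  expect_identical(call$verdict, "both")
  expect_true(call$core_fucosylated && call$outer_arm_fucosylated)
  expect_setequal(call$evidence, c("pep+2HexNAc+Fuc", "HexNAcHexFuc"))

  # non-fucosylated composition: verdict regardless of spurious peaks
  gp0 <- glycopeptide("ELHHLQEQNVSNAFLDK", "HexNAc(5)Hex(6)NeuAc(3)", 762)
  sp0 <- ms2_spectrum("nofuc", precursor_mz(gp0, 4L), 4L, 41.0,
                      data.frame(mz = c(512.1974, 204.0866),
                                 intensity = c(50, 100)))
  call0 <- call_fucose_topology(sp0, gp0)
  expect_identical(call0$verdict, "non_fucosylated")
  expect_length(call0$evidence, 0L)

  # mono-fucosylated with only the small core Y ion -> core
  gp1 <- glycopeptide("ELHHLQEQNVSNAFLDK", "HexNAc(5)Hex(6)Fuc(1)NeuAc(2)",
                      762)
  ys1 <- y_ion_series(gp1, 2L)
  mz1 <- ys1$mz[ys1$label == "pep+HexNAc+Fuc" & ys1$charge == 2L]
  sp1 <- ms2_spectrum("core", precursor_mz(gp1, 3L), 3L, 38.7,
                      data.frame(mz = mz1, intensity = 100))
  expect_identical(call_fucose_topology(sp1, gp1)$verdict, "core")

  # mono-fucosylated with the oxonium only -> outer_arm
  ox1 <- oxonium_ions(gp1$glycan)
  sp2 <- ms2_spectrum("outer", precursor_mz(gp1, 3L), 3L, 38.7,
                      data.frame(mz = ox1$mz[ox1$label == "HexNAcHexFuc"],
                                 intensity = 100))
  expect_identical(call_fucose_topology(sp2, gp1)$verdict, "outer_arm")

  # mono-fucosylated with BOTH evidence kinds: one fucose cannot occupy two
  # positions -> undetermined with conflict flag
  sp3 <- ms2_spectrum("conflict", precursor_mz(gp1, 3L), 3L, 38.7,
                      data.frame(mz = c(mz1, ox1$mz[ox1$label == "HexNAcHexFuc"]),
                                 intensity = c(100, 100)))
  call3 <- call_fucose_topology(sp3, gp1)
  expect_identical(call3$verdict, "undetermined")
  expect_true(call3$conflict)

  # fucosylated but no evidence at all -> undetermined, no conflict
  sp4 <- ms2_spectrum("none", precursor_mz(gp1, 3L), 3L, 38.7,
                      data.frame(mz = 204.0866, intensity = 100))
  call4 <- call_fucose_topology(sp4, gp1)
  expect_identical(call4$verdict, "undetermined")
  expect_false(call4$conflict)
})

test_that("evidence peaks below the relative-intensity floor are ignored", {
  gp <- glycopeptide("ELHHLQEQNVSNAFLDK", "HexNAc(5)Hex(6)Fuc(1)NeuAc(2)")
  ys <- y_ion_series(gp, 2L)
  mz1 <- ys$mz[ys$label == "pep+HexNAc+Fuc" & ys$charge == 2L]
  sp <- ms2_spectrum("weak", precursor_mz(gp, 3L), 3L, 10,
                     data.frame(mz = c(204.0866, mz1),
                                intensity = c(1e6, 100)))  # 0.01% of base
  expect_identical(call_fucose_topology(sp, gp)$verdict, "undetermined")
  expect_identical(call_fucose_topology(sp, gp,
                                        min_rel_intensity = 0)$verdict,
                   "core")
})

test_that("annotate_run pairs spectra with targets by precursor m/z", {
  tg <- ceru_targets()
  spectra <- lapply(c(4, 18), function(t) {
    gp <- glycopeptide(tg$peptide[t], tg$glycan[t], tg$glycosite[t])
    make_ms2(gp, precursor_charge = tg$precursor_charge[t],
             rt_min = tg$expected_rt_min[t], scan_id = paste0("s", t),
             seed = t)
  })
  ann <- annotate_run(spectra, tg)
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$verdict, "both")  # both planted targets are bi-fucosylated
})
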