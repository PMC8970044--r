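# XIC extraction, peak integration, normalization, and the fucosylation ratio.

gaussian_trace <- function(area = 100, center = 10, sd = 0.1,
                           half_width = 1, step = 0.02) {
  t <- seq(center - half_width, center + half_width, by = step)
  h <- area / (sd * sqrt(2 * pi))
  structure(data.frame(rt_min = t,
                       intensity = h * exp(-(t - center)^2 / (2 * sd^2))),
            class = c("xic_trace", "data.frame"))
}

test_that("extract_xic reproduces a planted elution profile exactly", {
  tg <- ceru_targets()[18, , drop = FALSE]
  run <- make_prm_run(tg, 100, seed = 1)
  gp <- glycopeptide(tg$peptide, tg$glycan, tg$glycosite)
  y1_mz <- ion_mz(glycoPRM:::backbone_mass(gp) + monosaccharide_masses("HexNAc"),
                  2L)
  trace <- extract_xic(run, y1_mz, tolerance = 0.05)
  truth <- gaussian_trace(100, tg$expected_rt_min, 0.1)
  expect_equal(trace$rt_min, truth$rt_min)
  expect_equal(trace$intensity, truth$intensity, tolerance = 1e-12)
  # m/z away from every peak: all-zero trace
  zero <- extract_xic(run, y1_mz + 5, tolerance = 0.05)
  expect_true(all(zero$intensity == 0))
})

test_that("co-eluting transitions separated by > 2x tolerance do not cross-talk", {
  sp <- lapply(seq(0, 1, by = 0.1), function(t) {
    ms2_spectrum(paste0("s", t), 500, 2L, t,
                 data.frame(mz = c(1000.00, 1000.20),
                            intensity = c(100, 900)))
  })
  run <- prm_run("x", sp)
  tr1 <- extract_xic(run, 1000.00, tolerance = 0.05)
  tr2 <- extract_xic(run, 1000.20, tolerance = 0.05)
  expect_true(all(tr1$intensity == 100))
  expect_true(all(tr2$intensity == 900))
})

test_that("integrate_peak matches closed forms", {
  # unit-height triangle over 1 min -> area 0.5
  tri <- data.frame(rt_min = c(9.5, 10, 10.5), intensity = c(0, 1, 0))
  expect_equal(integrate_peak(tri), 0.5)
  # planted Gaussian fully inside the boundaries -> h * s * sqrt(2*pi)
  tr <- gaussian_trace(area = 100)
  expect_equal(integrate_peak(tr), 100, tolerance = 0.01)
  # degenerate traces
  expect_equal(integrate_peak(data.frame(rt_min = 1:5,
                                         intensity = rep(0, 5))), 0)
  expect_warning(a <- integrate_peak(data.frame(rt_min = 1:2,
                                                intensity = c(1, 2))),
                 "fewer than 3")
  expect_equal(a, 0)
})

test_that("integration boundaries cut at the valley between co-eluting peaks", {
  t <- seq(9.5, 12, by = 0.02)
  y <- 1000 * exp(-(t - 10)^2 / (2 * 0.1^2)) +
    800 * exp(-(t - 11.5)^2 / (2 * 0.1^2))
  # apex belongs to the first peak; the valley near t = 10.75 bounds it
  area <- integrate_peak(data.frame(rt_min = t, intensity = y))
  expect_equal(area, 1000 * 0.1 * sqrt(2 * pi), tolerance = 0.01)
})

test_that("normalize_sample conserves unit total abundance", {
  rec <- data.frame(sample_id = "s", y1_area = c(1, 3))
  out <- normalize_sample(rec)
  expect_equal(out$relative_abundance, c(0.25, 0.75))
  one <- normalize_sample(data.frame(sample_id = "s", y1_area = 42))
  expect_equal(one$relative_abundance, 1.0)
  zero <- normalize_sample(data.frame(sample_id = "s", y1_area = c(0, 0, 0)))
  expect_true(attr(zero, "zero_total"))
  expect_equal(zero$relative_abundance, rep(0, 3))
})

test_that("quantify_prm recovers planted areas and abundances", {
  tg <- ceru_targets()
  areas <- seq(50, 220, by = 10)
  run <- make_prm_run(tg, areas, seed = 2)
  q <- quantify_prm(run, tg)
  expect_equal(q$y1_area, areas, tolerance = 0.02)
  expect_equal(sum(q$relative_abundance), 1, tolerance = 1e-9)
  expect_equal(q$relative_abundance, areas / sum(areas), tolerance = 0.02)
  # two-target relative abundance truth
  tg2 <- tg[c(1, 3), ]
  run2 <- make_prm_run(tg2, c(100, 300), seed = 3)
  q2 <- quantify_prm(run2, tg2)
  expect_equal(q2$relative_abundance, c(0.25, 0.75), tolerance = 0.001)
})

test_that("area recovery is unbiased under multiplicative noise", {
  tg <- ceru_targets()[1, , drop = FALSE]
  rec <- vapply(1:12, function(i) {
    run <- make_prm_run(tg, 100, noise_cv = 0.05, seed = 100 + i)
    quantify_prm(run, tg)$y1_area
  }, numeric(1))
  expect_equal(mean(rec), 100, tolerance = 0.02)
})

test_that("aggregate_charge_states sums areas across charges only", {
  ids <- data.frame(
    sample = "s1",
    peptide = c("PEPK", "PEPK", "PEPK", "AK"),
    glycosite = c(10L, 10L, 10L, 3L),
    glycan = c("HexNAc(4)Hex(5)", "HexNAc(4)Hex(5)", "HexNAc(5)Hex(6)",
               "HexNAc(4)Hex(5)"),
    charge = c(2L, 3L, 2L, 2L),
    xic_area = c(10, 5, 7, 3),
    stringsAsFactors = FALSE)
  out <- aggregate_charge_states(ids)
  expect_equal(nrow(out), 3L)  # charges merged, distinct glycans kept
  expect_equal(out$xic_area[out$peptide == "PEPK" &
                              out$glycan == "HexNAc(4)Hex(5)"], 15)
  expect_equal(sum(out$relative_abundance), 1)
  # mixed-case composition spellings of one glycan merge after parsing
  ids2 <- ids
  ids2$glycan[2] <- "HexNac(4)Gal(2)Man(3)"
  out2 <- aggregate_charge_states(ids2)
  expect_equal(nrow(out2), 3L)
})

test_that("fucosylation_ratio handles boundaries and is scale-invariant", {
  r <- fucosylation_ratio(5, 10)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$neg_log10_ratio, 0.3010, tolerance = 1e-4)
  expect_true(r$defined)
  # zero numerator: ratio 0, minus-log undefined
  r0 <- fucosylation_ratio(0, 10)
  expect_equal(r0$ratio, 0)
  expect_true(is.na(r0$neg_log10_ratio))
  # zero denominator: undefined, flagged for exclusion
  ru <- fucosylation_ratio(10, 0)
  expect_false(ru$defined)
  expect_true(is.na(ru$ratio))
  expect_error(fucosylation_ratio(-1, 5), "non-negative")
  set.seed(31)
  for (i in 1:20) {
    a <- runif(1, 0.1, 100); b <- runif(1, 0.1, 100)
    cc <- runif(1, 0.01, 1000)
    expect_equal(fucosylation_ratio(cc * a, cc * b)$ratio,
                 fucosylation_ratio(a, b)$ratio)
  }
})

test_that("ratio_table pairs targets within samples and counts exclusions", {
  tg <- ceru_targets()
  areas <- rep(100, 18)
  areas[tg$glycan == "HexNAc(5)Hex(6)Fuc(2)NeuAc(3)" &
          tg$glycosite == 762] <- 50
  run <- make_prm_run(tg, areas, seed = 4)
  q <- quantify_prm(run, tg)
  pairs <- ratio_pairs(tg)
  expect_equal(nrow(pairs), 8L)  # every fucosylated target has a partner
  rt <- ratio_table(q, pairs)
  target <- rt$glycosite == 762 & rt$glycan == "HexNAc(5)Hex(6)Fuc(2)NeuAc(3)"
  expect_equal(rt$ratio[target], 0.5, tolerance = 0.01)
  expect_equal(attr(rt, "n_undefined"), 0L)
  # a missing partner produces an undefined, counted record
  pairs2 <- pairs
  pairs2$partner_glycan[1] <- NA
  rt2 <- ratio_table(q, pairs2)
  expect_equal(attr(rt2, "n_undefined"), 1L)
  expect_false(rt2$defined[1])
})

test_that("filter_identifications enforces all four strict thresholds", {
  ids <- toy_identifications()
  out <- filter_identifications(ids)
  expect_equal(out$scan_id, c("scan1", "scan4"))  # hand-enumerated
  removed <- attr(out, "removed")
  expect_equal(unname(removed["byonic_score"]), 1L)  # row 2 at exactly 150
  # idempotence
  again <- filter_identifications(out)
  expect_equal(again$scan_id, out$scan_id)
  # empty and invalid inputs
  expect_equal(nrow(filter_identifications(ids[0, ])), 0L)
  expect_error(filter_identifications(ids[, names(ids) != "pep2d"]),
               "pep2d")
})

test_that("profile_distributions counts unique glycopeptides by class", {
  ids <- data.frame(
    sample = "s", scan_id = paste0("x", 1:5),
    peptide = c("AK", "CK", "DK", "EK", "AK"),
    glycosite = c(1L, 2L, 3L, 4L, 1L),
    glycan = c("HexNAc(4)Hex(5)", "HexNAc(4)Hex(5)Fuc(1)",
               "HexNAc(5)Hex(6)Fuc(1)NeuAc(1)", "HexNAc(6)Hex(7)Fuc(3)",
               "HexNAc(4)Hex(5)"),  # duplicate of row 1 (other charge)
    charge = c(2L, 2L, 3L, 3L, 3L),
    xic_area = 1, byonic_score = 200, delta_mod_score = 20,
    pep2d = 0.01, fdr2d = 0.001, stringsAsFactors = FALSE)
  prof <- profile_distributions(ids)
  expect_equal(prof$n_unique, 4L)
  ant <- setNames(prof$antennarity$percent, prof$antennarity$antennarity)
  expect_equal(unname(ant[c("bi", "tri", "tetra")]), c(50, 25, 25))
  # mono-fucosylated fraction among the fucosylated subset
  expect_equal(prof$n_fucosylated, 3L)
  fuc <- prof$fucose
  expect_equal(fuc$percent[fuc$fucose_count == 1], 100 * 2 / 3,
               tolerance = 1e-9)
  expect_equal(prof$n_sialylated, 1L)
})

test_that("compare_id_sets does set algebra on glycopeptide keys", {
  a <- data.frame(peptide = c("AK", "CK"), glycosite = c(1L, 2L),
                  glycan = c("HexNAc(4)Hex(5)", "HexNAc(5)Hex(6)"))
  b <- data.frame(peptide = c("CK", "DK"), glycosite = c(2L, 3L),
                  glycan = c("HexNAc(5)Hex(6)", "HexNAc(4)Hex(5)"))
  cmp <- compare_id_sets(a, b)
  expect_equal(cmp$union, 3L)
  expect_equal(cmp$intersection, 1L)
})

test_that("replicate_correlation is scale-invariant with a frozen example", {
  v <- c(a = 10, b = 20, c = 5)
  expect_equal(unname(replicate_correlation(list(r1 = v, r2 = v))[1, 2]), 1)
  expect_equal(unname(replicate_correlation(list(r1 = v, r2 = 2 * v))[1, 2]),
               1)
  # hand-computed 3-point Pearson: r = 11.333 / sqrt(4.667 * 28.667) = 0.97986
  m <- cbind(r1 = c(a = 1, b = 2, c = 4), r2 = c(a = 2, b = 3, c = 9))
  expect_equal(unname(replicate_correlation(m)[1, 2]), 0.9798637^2,
               tolerance = 1e-6)
  # a key missing from one replicate contributes 0
  out <- replicate_correlation(list(r1 = c(a = 1, b = 2, c = 4),
                                    r2 = c(a = 2, b = 3, c = 9, d = 1)))
  expect_equal(dim(out), c(2L, 2L))
  expect_warning(replicate_correlation(list(r1 = c(a = 1, b = 1),
                                            r2 = c(a = 1, b = 2))),
                 "constant")
})
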