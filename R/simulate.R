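# Synthetic-data generators with known ground truth: stepped-HCD MS2 spectra
# of glycopeptides, PRM runs with Gaussian elution peaks, and two-group
# patient cohorts. Every generator is deterministic under a fixed seed.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Simulate a stepped-HCD MS2 spectrum of a glycopeptide
#'
#' Plants peaks at the theoretical m/z of the glycopeptide's fragment ions
#' (by default all oxonium, glycosidic Y and b/y ions at charges
#' 1..`max_charge`), perturbed by Gaussian ppm jitter, plus uniform-random
#' noise peaks. Noise peaks are kept at least `noise_exclusion_factor` times
#' the matching tolerance away from every theoretical ion of the target, so
#' annotation on clean synthetic spectra has exact expected outcomes; set
#' `adversarial = TRUE` to allow noise inside the windows for robustness
#' testing.
#'
#' @param gp a [glycopeptide()].
#' @param precursor_charge precursor charge (default 3).
#' @param rt_min retention time label in minutes.
#' @param planted optional fragment-ion data.frame to plant (default: all
#'   theoretical fragments); a column `rel_intensity` may set per-ion
#'   relative intensities (default 1).
#' @param base_intensity intensity of a relative-intensity-1 planted peak.
#' @param n_noise number of noise peaks (default 50).
#' @param noise_intensity `c(min, max)` of noise peak intensities, as a
#'   fraction of `base_intensity` (default `c(0.001, 0.005)`, i.e. below the
#'   1% evidence floor).
#' @param jitter_ppm standard deviation of the m/z jitter in ppm (default 0).
#' @param tol_ppm matching tolerance the exclusion zone is scaled from
#'   (default 20 ppm).
#' @param noise_exclusion_factor noise must sit this many tolerances away
#'   from every theoretical ion (default 3).
#' @param adversarial allow noise peaks anywhere (default FALSE).
#' @param max_charge fragment charge range of the default planted set.
#' @param scan_id scan identifier.
#' @param seed RNG seed (restores the caller's RNG state).
#' @return An [ms2_spectrum()] with attribute `ground_truth` (the planted
#'   ion table).
#' @export
make_ms2 <- function(gp, precursor_charge = 3L, rt_min = 30,
                     planted = NULL, base_intensity = 1e5,
                     n_noise = 50L, noise_intensity = c(0.001, 0.005),
                     jitter_ppm = 0, tol_ppm = 20,
                     noise_exclusion_factor = 3, adversarial = FALSE,
                     max_charge = 2L, scan_id = "synthetic_1", seed = NULL) {
  stopifnot(inherits(gp, "glycopeptide"), jitter_ppm >= 0)
  with_seed(seed, {
    if (is.null(planted)) planted <- theoretical_fragments(gp, max_charge)
    if (is.null(planted$rel_intensity)) planted$rel_intensity <- 1
    if (any(planted$rel_intensity <= 0)) {
      stop("planted relative intensities must be positive")
    }
    mz <- planted$mz *
      (1 + stats::rnorm(nrow(planted), 0, jitter_ppm) * 1e-6)
    inten <- planted$rel_intensity * base_intensity
    # exclusion zones around every theoretical ion of the target
    theo <- theoretical_fragments(gp, max_charge)$mz
    lo <- 100
    hi <- max(c(theo, precursor_mz(gp, 1L) * 1.05))
    noise_mz <- numeric(0)
    guard <- 0L
    while (length(noise_mz) < n_noise && guard < 200L) {
      cand <- stats::runif(n_noise * 2L, lo, hi)
      if (!adversarial) {
        ok <- vapply(cand, function(m) {
          all(abs(m - theo) > noise_exclusion_factor * tol_ppm * 1e-6 * theo)
        }, logical(1))
        cand <- cand[ok]
      }
      noise_mz <- c(noise_mz, cand)
      guard <- guard + 1L
    }
    noise_mz <- noise_mz[seq_len(min(n_noise, length(noise_mz)))]
    noise_int <- stats::runif(length(noise_mz),
                              noise_intensity[1L], noise_intensity[2L]) *
      base_intensity
    sp <- ms2_spectrum(
      scan_id = scan_id,
      precursor_mz = precursor_mz(gp, precursor_charge),
      precursor_charge = precursor_charge,
      rt_min = rt_min,
      peaks = data.frame(mz = c(mz, noise_mz),
                         intensity = c(inten, noise_int)))
    attr(sp, "ground_truth") <- planted
    sp
  })
}

#' Simulate a PRM run with Gaussian elution peaks
#'
#' Generates a time series of targeted MS2 spectra for each target in the
#' list: at each point of a regular time grid inside the target's elution
#' window, a spectrum (precursor = the target's precursor m/z) containing the
#' Y1 ion at `y1_charge` with intensity following a Gaussian elution profile
#' of the specified area, optional multiplicative noise and additive
#' baseline. True areas are recorded as ground truth.
#'
#' @param targets a target list (see [read_target_list()]); elution peaks
#'   center on `expected_rt_min`.
#' @param true_areas numeric vector of true peak areas (intensity x minutes),
#'   one per target.
#' @param sample_id sample identifier.
#' @param peak_sd_min Gaussian elution peak sd in minutes (default 0.1).
#' @param sampling_interval_min time grid step in minutes (default 0.02).
#' @param window_half_width_min half-width of each target's acquisition
#'   window in minutes (default 1.0, i.e. 10 sd: the full peak).
#' @param noise_cv multiplicative intensity noise coefficient of variation
#'   (default 0: noise-free).
#' @param baseline additive baseline intensity (default 0).
#' @param y1_charge fragment charge of the planted Y1 ion (default 2).
#' @param seed RNG seed.
#' @return A [prm_run()] with attribute `ground_truth` (targets plus
#'   `true_area`).
#' @export
make_prm_run <- function(targets, true_areas, sample_id = "sample_1",
                         peak_sd_min = 0.1, sampling_interval_min = 0.02,
                         window_half_width_min = 1.0, noise_cv = 0,
                         baseline = 0, y1_charge = 2L, seed = NULL) {
  stopifnot(nrow(targets) == length(true_areas), all(true_areas >= 0),
            peak_sd_min > 0, sampling_interval_min > 0)
  with_seed(seed, {
    spectra <- list()
    sched <- list()
    for (t in seq_len(nrow(targets))) {
      gp <- glycopeptide(targets$peptide[t], targets$glycan[t],
                         targets$glycosite[t], targets$protein[t])
      y1_mz <- ion_mz(backbone_mass(gp) + .MONOSACCHARIDES[["HexNAc"]],
                      y1_charge)
      pmz <- precursor_mz(gp, targets$precursor_charge[t])
      rt0 <- targets$expected_rt_min[t]
      grid <- seq(rt0 - window_half_width_min, rt0 + window_half_width_min,
                  by = sampling_interval_min)
      height <- true_areas[t] / (peak_sd_min * sqrt(2 * pi))
      inten <- height * exp(-(grid - rt0)^2 / (2 * peak_sd_min^2)) + baseline
      if (noise_cv > 0) {
        inten <- inten * pmax(0, 1 + stats::rnorm(length(inten), 0, noise_cv))
      }
      sched[[t]] <- data.frame(rt = grid, target = t, mz = y1_mz,
                               intensity = inten, precursor = pmz)
    }
    sched <- do.call(rbind, sched)
    sched <- sched[order(sched$rt), , drop = FALSE]
    for (i in seq_len(nrow(sched))) {
      spectra[[i]] <- ms2_spectrum(
        scan_id = sprintf("%s_scan_%05d", sample_id, i),
        precursor_mz = sched$precursor[i],
        precursor_charge = targets$precursor_charge[sched$target[i]],
        rt_min = sched$rt[i],
        peaks = data.frame(mz = sched$mz[i], intensity = sched$intensity[i]))
    }
    run <- prm_run(sample_id, spectra,
                   metadata = list(gradient_min = 65,
                                   stepped_collision_energies = c(19, 26, 33)))
    truth <- targets
    truth$true_area <- true_areas
    attr(run, "ground_truth") <- truth
    run
  })
}

#' Simulate a two-group patient cohort
#'
#' Per-patient -log10 fucosylation ratios are Normal(mu_g, sigma^2) with the
#' disease group shifted by the standardized effect size d (mu_2 = mu_1 -
#' d * sigma: the ratio increases with disease, so its minus-log decreases).
#' AFP is log-normal with group-specific medians. Defaults mirror the
#' targeted study design: 35 cirrhosis versus 27 early HCC, d = 0.8, AFP
#' medians 3.7 and 32.4 ng/mL with log-scale spreads derived from the
#' clinical interquartile ranges.
#'
#' @param n1,n2 group sizes (cirrhosis, early HCC).
#' @param d standardized effect size on the -log10 ratio scale.
#' @param ratio_mu mean -log10 ratio of the reference (cirrhosis) group
#'   (default 0.6, i.e. a typical ratio near 0.25).
#' @param ratio_sigma sd of -log10 ratio (> 0; default 0.25).
#' @param afp_median `c(group1, group2)` AFP medians in ng/mL.
#' @param afp_sdlog `c(group1, group2)` log-normal sdlog parameters.
#' @param seed RNG seed.
#' @return A data.frame (`patient_id`, `group`, `afp_ng_ml`,
#'   `fucosylation_ratio`, `neg_log10_ratio`) with attribute `ground_truth`
#'   listing the generating parameters.
#' @export
make_cohort <- function(n1 = 35L, n2 = 27L, d = 0.8,
                        ratio_mu = 0.6, ratio_sigma = 0.25,
                        afp_median = c(3.7, 32.4),
                        afp_sdlog = c(1.243, 3.80), seed = NULL) {
  if (n1 < 2L || n2 < 2L) stop("group sizes must be >= 2")
  if (!is.finite(ratio_sigma) || ratio_sigma <= 0) {
    stop("ratio_sigma must be positive")
  }
  if (any(afp_median <= 0) || any(afp_sdlog <= 0)) {
    stop("AFP parameters must be positive")
  }
  with_seed(seed, {
    mu <- c(ratio_mu, ratio_mu - d * ratio_sigma)
    nl <- c(stats::rnorm(n1, mu[1L], ratio_sigma),
            stats::rnorm(n2, mu[2L], ratio_sigma))
    afp <- c(stats::rlnorm(n1, log(afp_median[1L]), afp_sdlog[1L]),
             stats::rlnorm(n2, log(afp_median[2L]), afp_sdlog[2L]))
    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n1 + n2)),
      group = rep(c("cirrhosis", "early_hcc"), c(n1, n2)),
      afp_ng_ml = afp,
      fucosylation_ratio = 10^(-nl),
      neg_log10_ratio = nl,
      stringsAsFactors = FALSE)
    attr(out, "ground_truth") <- list(
      n1 = n1, n2 = n2, d = d, mu = mu, sigma = ratio_sigma,
      afp_median = afp_median, afp_sdlog = afp_sdlog)
    out
  })
}
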