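# PRM-side quantification: XIC extraction, apex-anchored integration, Y1
# quantification, sample normalization and the fucosylation ratio.

#' Extract an ion chromatogram from a PRM run
#'
#' For each spectrum in the retention-time window (optionally restricted to
#' scans acquired for one targeted precursor), sums the intensity of peaks
#' within `mz_center` ± `tolerance`. Traces from non-overlapping windows have
#' zero cross-talk.
#'
#' @param run a [prm_run()].
#' @param mz_center fragment m/z to extract.
#' @param tolerance absolute extraction half-window in m/z (default 0.05,
#'   the targeted ion-match tolerance).
#' @param rt_window optional `c(min, max)` retention-time window in minutes.
#' @param precursor_mz optional targeted precursor m/z; only spectra whose
#'   precursor lies within `precursor_tol_mz` are used.
#' @param precursor_tol_mz precursor matching window (default 0.01 m/z).
#' @return A data.frame of class `xic_trace` with columns `rt_min`,
#'   `intensity`, and attributes `mz_center` and `tolerance`.
#' @export
extract_xic <- function(run, mz_center, tolerance = 0.05, rt_window = NULL,
                        precursor_mz = NULL, precursor_tol_mz = 0.01) {
  stopifnot(inherits(run, "prm_run"), tolerance > 0)
  rt <- numeric(0); inten <- numeric(0)
  for (s in run$spectra) {
    if (!is.null(rt_window) &&
        (s$rt_min < rt_window[1L] || s$rt_min > rt_window[2L])) next
    if (!is.null(precursor_mz) &&
        (is.na(s$precursor_mz) ||
         abs(s$precursor_mz - precursor_mz) > precursor_tol_mz)) next
    sel <- abs(s$peaks$mz - mz_center) <= tolerance
    rt <- c(rt, s$rt_min)
    inten <- c(inten, sum(s$peaks$intensity[sel]))
  }
  structure(data.frame(rt_min = rt, intensity = inten),
            class = c("xic_trace", "data.frame"),
            mz_center = mz_center, tolerance = tolerance)
}

#' Integrate a chromatographic peak
#'
#' Apex-anchored trapezoidal integration: the apex is the maximum-intensity
#' point of the trace; on each side the integration boundary is the deepest
#' valley (minimum-intensity point, ties resolved toward the apex) between
#' the apex and the trace edge, so an isolated peak integrates to the edges
#' of its extraction window while co-eluting peaks are cut at the valley
#' between them. Traces shorter than 3 points integrate to 0 with a warning.
#'
#' @param trace an [extract_xic()] trace (any data.frame with `rt_min` and
#'   `intensity` works).
#' @return Peak area in intensity x minutes (>= 0).
#' @export
integrate_peak <- function(trace) {
  y <- trace$intensity
  t <- trace$rt_min
  n <- length(y)
  if (n < 3L) {
    warning("trace has fewer than 3 points; area set to 0")
    return(0)
  }
  if (all(y == 0)) return(0)
  apex <- which.max(y)
  left <- y[1:apex]
  lo <- max(which(left == min(left)))       # valley closest to the apex
  right <- y[apex:n]
  hi <- apex - 1L + min(which(right == min(right)))
  idx <- lo:hi
  if (length(idx) < 2L) return(0)
  sum(diff(t[idx]) * (y[idx][-length(idx)] + y[idx][-1L]) / 2)
}

#' Quantify the Y1 transitions of a target list in a PRM run
#'
#' For each target, extracts the Y1 (peptide + HexNAc) ion chromatogram at
#' each fragment charge in `charges` within `expected_rt_min` ±
#' `rt_half_window`, integrates apex-anchored, and keeps the charge with the
#' maximal area (recorded per record). Missing targets get area 0 and remain
#' in the normalization denominator.
#'
#' @param run a [prm_run()].
#' @param targets a target list (see [read_target_list()]).
#' @param xic_tol absolute XIC tolerance in m/z (default 0.05).
#' @param rt_half_window half-width of the integration window in minutes
#'   (default 1.5).
#' @param charges Y1 fragment charges considered (default 1:2).
#' @param normalize compute within-sample relative abundances (default TRUE).
#' @return A data.frame of quantification records: `sample_id`, `peptide`,
#'   `glycosite`, `glycan`, `precursor_charge`, `y1_mz`, `y1_charge`,
#'   `y1_area`, and `relative_abundance` when `normalize` is TRUE.
#' @export
quantify_prm <- function(run, targets, xic_tol = 0.05, rt_half_window = 1.5,
                         charges = 1:2, normalize = TRUE) {
  stopifnot(inherits(run, "prm_run"))
  rows <- lapply(seq_len(nrow(targets)), function(t) {
    gp <- glycopeptide(targets$peptide[t], targets$glycan[t],
                       targets$glycosite[t], targets$protein[t])
    y1_neutral <- backbone_mass(gp) + .MONOSACCHARIDES[["HexNAc"]]
    pmz <- precursor_mz(gp, targets$precursor_charge[t])
    rt0 <- targets$expected_rt_min[t]
    best_area <- 0; best_z <- NA_integer_; best_mz <- NA_real_
    for (z in charges) {
      mz <- ion_mz(y1_neutral, z)
      trace <- extract_xic(run, mz, tolerance = xic_tol,
                           rt_window = c(rt0 - rt_half_window,
                                         rt0 + rt_half_window),
                           precursor_mz = pmz)
      area <- if (nrow(trace) >= 3L) integrate_peak(trace) else 0
      if (is.na(best_z) || area > best_area) {
        best_area <- area; best_z <- z; best_mz <- mz
      }
    }
    data.frame(sample_id = run$sample_id,
               peptide = targets$peptide[t],
               glycosite = targets$glycosite[t],
               glycan = targets$glycan[t],
               precursor_charge = targets$precursor_charge[t],
               y1_mz = best_mz, y1_charge = best_z, y1_area = best_area,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (normalize) out <- normalize_sample(out)
  out
}

#' Normalize quantification records within one sample
#'
#' Relative abundance of each target is its Y1 area divided by the sum of Y1
#' areas of all targets in the sample, so abundances sum to 1. A sample whose
#' total area is 0 gets all-zero abundances and is flagged via the
#' `zero_total` attribute.
#'
#' @param records quantification records for one sample (a `y1_area` column).
#' @return The records with a `relative_abundance` column.
#' @export
normalize_sample <- function(records) {
  stopifnot(nrow(records) >= 1L, "y1_area" %in% names(records))
  if (length(unique(records$sample_id)) > 1L) {
    stop("normalize_sample() expects records from a single sample; got ",
         length(unique(records$sample_id)))
  }
  total <- sum(records$y1_area)
  if (total > 0) {
    records$relative_abundance <- records$y1_area / total
    attr(records, "zero_total") <- FALSE
  } else {
    records$relative_abundance <- rep(0, nrow(records))
    attr(records, "zero_total") <- TRUE
  }
  records
}

#' Fucosylation ratio
#'
#' `ratio = fucosylated area / non-fucosylated area`, with
#' `-log10(ratio)` alongside (fucosylation ratios are below 1 in most
#' samples, so the minus-log scale is the plotting/combination scale). A zero
#' denominator leaves the ratio undefined (`NA`, `defined = FALSE`); such
#' records are excluded from group statistics rather than imputed. A zero
#' numerator gives ratio 0 with undefined `neg_log10_ratio`.
#'
#' @param fuc_area,nonfuc_area non-negative XIC areas (vectorized).
#' @return A data.frame with `ratio`, `neg_log10_ratio`, `defined`.
#' @examples
#' fucosylation_ratio(5, 10)   # ratio 0.5, -log10 = 0.301
#' @export
fucosylation_ratio <- function(fuc_area, nonfuc_area) {
  stopifnot(length(fuc_area) == length(nonfuc_area))
  if (any(fuc_area < 0, na.rm = TRUE) || any(nonfuc_area < 0, na.rm = TRUE)) {
    stop("XIC areas must be non-negative")
  }
  ratio <- ifelse(nonfuc_area > 0, fuc_area / nonfuc_area, NA_real_)
  neg_log10 <- ifelse(!is.na(ratio) & ratio > 0, -log10(ratio), NA_real_)
  data.frame(ratio = ratio, neg_log10_ratio = neg_log10,
             defined = !is.na(ratio))
}

#' Pair fucosylated targets with their non-fucosylated counterparts
#'
#' A fucosylated target's partner carries the same peptide, glycosite and
#' HexNAc/Hex/NeuAc counts with zero fucose. Fucosylated targets without a
#' partner in the list (e.g. the site-358 case) are reported with
#' `partner_glycan = NA` and yield undefined ratios downstream.
#'
#' @param targets a target list.
#' @return A data.frame with one row per fucosylated target: `peptide`,
#'   `glycosite`, `glycan`, `partner_glycan`.
#' @export
ratio_pairs <- function(targets) {
  comp <- lapply(targets$glycan, parse_glycan)
  fuc_idx <- which(vapply(comp, function(g) g[["Fuc"]] > 0L, logical(1)))
  rows <- lapply(fuc_idx, function(i) {
    g <- comp[[i]]
    partner <- NA_character_
    for (j in seq_along(comp)) {
      h <- comp[[j]]
      if (targets$peptide[j] == targets$peptide[i] &&
          targets$glycosite[j] == targets$glycosite[i] &&
          h[["Fuc"]] == 0L &&
          h[["HexNAc"]] == g[["HexNAc"]] && h[["Hex"]] == g[["Hex"]] &&
          h[["NeuAc"]] == g[["NeuAc"]]) {
        partner <- targets$glycan[j]
        break
      }
    }
    data.frame(peptide = targets$peptide[i], glycosite = targets$glycosite[i],
               glycan = targets$glycan[i], partner_glycan = partner,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), glycosite = integer(0),
                      glycan = character(0), partner_glycan = character(0))
  }
  unique(out)
}

#' Fucosylation ratios of quantified samples
#'
#' Joins each fucosylated/non-fucosylated target pair within each sample and
#' computes the fucosylation ratio from their Y1 areas. Pairs whose partner
#' is missing or has zero area yield undefined ratios, which are flagged and
#' counted (attribute `n_undefined`) and excluded from group statistics.
#'
#' @param quant quantification records (possibly several samples), as from
#'   [quantify_prm()].
#' @param pairs a [ratio_pairs()] table (default: derived from the records'
#'   own target set is not possible, so pass the target list's pairs).
#' @return A data.frame with one row per (sample, pair).
#' @export
ratio_table <- function(quant, pairs) {
  rows <- list()
  n_undef <- 0L
  for (s in unique(quant$sample_id)) {
    qs <- quant[quant$sample_id == s, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      fa <- qs$y1_area[qs$peptide == pairs$peptide[k] &
                       qs$glycan == pairs$glycan[k]]
      na <- if (is.na(pairs$partner_glycan[k])) numeric(0) else
        qs$y1_area[qs$peptide == pairs$peptide[k] &
                   qs$glycan == pairs$partner_glycan[k]]
      fa <- if (length(fa) > 0L) sum(fa) else NA_real_
      na <- if (length(na) > 0L) sum(na) else NA_real_
      if (is.na(fa) || is.na(na)) {
        r <- data.frame(ratio = NA_real_, neg_log10_ratio = NA_real_,
                        defined = FALSE)
      } else {
        r <- fucosylation_ratio(fa, na)
      }
      if (!r$defined) n_undef <- n_undef + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, peptide = pairs$peptide[k],
        glycosite = pairs$glycosite[k], glycan = pairs$glycan[k],
        partner_glycan = pairs$partner_glycan[k],
        fuc_area = fa, nonfuc_area = na,
        ratio = r$ratio, neg_log10_ratio = r$neg_log10_ratio,
        defined = r$defined, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_undefined") <- n_undef
  out
}
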