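# Fragment matching, diagnostic-ion screening and fucose-topology calling.

# Core matcher: assign theoretical ions to observed peaks within a tolerance.
# Each ion gets at most one peak and each peak at most one ion; candidate
# pairs are accepted greedily by increasing |ppm error|, ties broken toward
# the lower-mass ion. Tolerance is ppm by default, or absolute m/z when
# tol_mz is given (the targeted-trace regime).
match_ion_table <- function(spectrum, ions, tol_ppm = 20,
                            tol_mz = NULL, min_rel_intensity = 0) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  empty <- cbind(ions[0, , drop = FALSE],
                 data.frame(observed_mz = numeric(0),
                            observed_intensity = numeric(0),
                            error_ppm = numeric(0)))
  if (nrow(ions) == 0L || nrow(spectrum$peaks) == 0L) return(empty)
  peaks <- spectrum$peaks
  if (min_rel_intensity > 0 && nrow(peaks) > 0L) {
    peaks <- peaks[peaks$intensity >= min_rel_intensity * max(peaks$intensity), ,
                   drop = FALSE]
  }
  if (nrow(peaks) == 0L) return(empty)
  # candidate pairs within tolerance
  dm <- outer(peaks$mz, ions$mz, "-")            # peaks x ions
  tol <- if (is.null(tol_mz)) {
    outer(rep(1, nrow(peaks)), ions$mz * tol_ppm * 1e-6)
  } else {
    matrix(tol_mz, nrow(peaks), nrow(ions))
  }
  cand <- which(abs(dm) <= tol, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  err_ppm <- dm[cand] / ions$mz[cand[, 2L]] * 1e6
  # greedy acceptance by error (relative in ppm mode, absolute in m/z mode),
  # ties toward the lower-mass ion
  score <- if (is.null(tol_mz)) abs(err_ppm) else abs(dm[cand])
  ord <- order(score, ions$mz[cand[, 2L]])
  used_peak <- rep(FALSE, nrow(peaks))
  used_ion <- rep(FALSE, nrow(ions))
  keep <- integer(0)
  for (k in ord) {
    p <- cand[k, 1L]; io <- cand[k, 2L]
    if (used_peak[p] || used_ion[io]) next
    used_peak[p] <- TRUE; used_ion[io] <- TRUE
    keep <- c(keep, k)
  }
  out <- cbind(
    ions[cand[keep, 2L], , drop = FALSE],
    data.frame(observed_mz = peaks$mz[cand[keep, 1L]],
               observed_intensity = peaks$intensity[cand[keep, 1L]],
               error_ppm = err_ppm[keep])
  )
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen the diagnostic oxonium ions of a glycan in a spectrum
#'
#' Matches each diagnostic oxonium ion of the composition (see
#' [oxonium_ions()]) against the nearest peak within tolerance. At most one
#' peak per ion; unmatched ions are absent from the result.
#'
#' @param spectrum an [ms2_spectrum()].
#' @param glycan a [glycan_composition()] or composition string.
#' @param tol_ppm matching tolerance in ppm (default 20, the MS2 regime).
#' @param min_rel_intensity evidence floor as a fraction of the base peak
#'   (default 0: screen everything).
#' @return A data.frame of matched ions with `observed_mz`,
#'   `observed_intensity` and signed `error_ppm` columns.
#' @export
screen_oxonium <- function(spectrum, glycan, tol_ppm = 20,
                           min_rel_intensity = 0) {
  match_ion_table(spectrum, oxonium_ions(glycan), tol_ppm = tol_ppm,
                  min_rel_intensity = min_rel_intensity)
}

#' Match all theoretical fragments of a glycopeptide in a spectrum
#'
#' Annotates a centroided MS2 spectrum with the glycopeptide's diagnostic
#' oxonium ions, glycosidic Y series, and peptide b/y ladders (charges
#' 1..`max_charge`). Each observed peak is assigned to at most one
#' theoretical ion; when two theoretical ions fall within tolerance of the
#' same peak the smaller ppm error wins, ties going to the lower-mass ion.
#'
#' @inheritParams screen_oxonium
#' @param gp a [glycopeptide()].
#' @param ion_types subset of `c("oxonium", "Y", "b", "y")`.
#' @param max_charge highest fragment charge for Y/b/y ladders (default 2,
#'   the targeted-transition setting).
#' @param tol_mz optional absolute tolerance in m/z; when given it replaces
#'   the ppm tolerance (the 0.05 m/z targeted-trace regime).
#' @return A data.frame of matched ions.
#' @export
match_fragments <- function(spectrum, gp, tol_ppm = 20,
                            ion_types = c("oxonium", "Y", "b", "y"),
                            max_charge = 2L, tol_mz = NULL,
                            min_rel_intensity = 0) {
  ions <- theoretical_fragments(gp, max_charge = max_charge,
                                ion_types = ion_types)
  match_ion_table(spectrum, ions, tol_ppm = tol_ppm, tol_mz = tol_mz,
                  min_rel_intensity = min_rel_intensity)
}

#' Call core / outer-arm fucosylation topology from a spectrum
#'
#' Composition alone cannot place a fucose; the call is spectral. Core
#' fucosylation is evidenced by a fucose-retaining small Y ion
#' (`pep+HexNAc+Fuc` or `pep+2HexNAc+Fuc`, any charge up to `max_charge`);
#' larger fucosylated Y ions are ambiguous and not used as evidence.
#' Outer-arm fucosylation is evidenced by the HexNAc+Hex+Fuc oxonium ion at
#' m/z 512.20. A composition without fucose is `non_fucosylated` regardless
#' of spurious matches. The verdict `both` additionally requires at least two
#' fucoses in the composition; a mono-fucosylated glycopeptide with both
#' evidence kinds is `undetermined` with `conflict = TRUE` (one fucose cannot
#' occupy two positions). Evidence peaks must reach `min_rel_intensity` of
#' the base peak (default 1%) to guard against noise matches.
#'
#' @inheritParams match_fragments
#' @return A list of class `topology_call` with elements `verdict` (one of
#'   `core`, `outer_arm`, `both`, `undetermined`, `non_fucosylated`),
#'   `core_fucosylated`, `outer_arm_fucosylated`, `conflict`, and `evidence`
#'   (matched ion labels).
#' @export
call_fucose_topology <- function(spectrum, gp, tol_ppm = 20, max_charge = 2L,
                                 min_rel_intensity = 0.01) {
  stopifnot(inherits(gp, "glycopeptide"))
  fuc <- gp$glycan[["Fuc"]]
  matched <- match_fragments(spectrum, gp, tol_ppm = tol_ppm,
                             ion_types = c("oxonium", "Y"),
                             max_charge = max_charge,
                             min_rel_intensity = min_rel_intensity)
  core_labels <- c("pep+HexNAc+Fuc", "pep+2HexNAc+Fuc")
  core_hit <- matched$kind == "Y" & matched$label %in% core_labels
  outer_hit <- matched$kind == "oxonium" & matched$label == "HexNAcHexFuc"
  evidence <- unique(matched$label[core_hit | outer_hit])
  core <- any(core_hit)
  outer <- any(outer_hit)
  conflict <- FALSE
  if (fuc == 0L) {
    verdict <- "non_fucosylated"
    core <- outer <- FALSE
    evidence <- character(0)
  } else if (core && outer) {
    if (fuc >= 2L) {
      verdict <- "both"
    } else {
      verdict <- "undetermined"
      conflict <- TRUE
    }
  } else if (core) {
    verdict <- "core"
  } else if (outer) {
    verdict <- "outer_arm"
  } else {
    verdict <- "undetermined"
  }
  structure(list(
    verdict = verdict,
    core_fucosylated = core,
    outer_arm_fucosylated = outer,
    conflict = conflict,
    evidence = evidence
  ), class = "topology_call")
}

#' @export
print.topology_call <- function(x, ...) {
  cat("<topology call> ", x$verdict,
      if (x$conflict) " (conflicting evidence)",
      if (length(x$evidence)) paste0("  [", paste(x$evidence, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Annotate spectra against a target list
#'
#' Convenience wrapper: for every (spectrum, target) pair whose precursor m/z
#' matches the target within `precursor_tol_mz`, calls the fucose topology
#' and reports the verdict and evidence ions, one row per pair.
#'
#' @param spectra list of [ms2_spectrum()].
#' @param targets a target list (see [read_target_list()]).
#' @param tol_ppm fragment tolerance in ppm.
#' @param precursor_tol_mz precursor matching window in m/z (default 0.01).
#' @inheritParams call_fucose_topology
#' @return A data.frame, one row per matched (scan, target) pair.
#' @export
annotate_run <- function(spectra, targets, tol_ppm = 20,
                         precursor_tol_mz = 0.01, min_rel_intensity = 0.01) {
  rows <- list()
  for (t in seq_len(nrow(targets))) {
    gp <- glycopeptide(targets$peptide[t], targets$glycan[t],
                       targets$glycosite[t], targets$protein[t])
    pmz <- precursor_mz(gp, targets$precursor_charge[t])
    for (s in spectra) {
      if (is.na(s$precursor_mz) ||
          abs(s$precursor_mz - pmz) > precursor_tol_mz) next
      call <- call_fucose_topology(s, gp, tol_ppm = tol_ppm,
                                   min_rel_intensity = min_rel_intensity)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = s$scan_id,
        peptide = targets$peptide[t],
        glycosite = targets$glycosite[t],
        glycan = targets$glycan[t],
        precursor_charge = targets$precursor_charge[t],
        verdict = call$verdict,
        conflict = call$conflict,
        evidence = paste(call$evidence, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(scan_id = character(0), peptide = character(0),
                      glycosite = integer(0), glycan = character(0),
                      precursor_charge = integer(0), verdict = character(0),
                      conflict = logical(0), evidence = character(0)))
  }
  do.call(rbind, rows)
}
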