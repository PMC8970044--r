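# Spectrum and PRM-run containers.

#' Construct a centroided MS/MS spectrum
#'
#' Peaks are sorted by m/z on construction and peaks closer than 1e-5 Th are
#' merged (intensities summed). Precursor charge, when known, must lie in
#' 1..6 (the precursor charge range of this workflow); an unknown charge is
#' stored as `NA` and flagged for downstream handling.
#'
#' @param scan_id scan identifier string.
#' @param precursor_mz precursor m/z (Da/charge).
#' @param precursor_charge integer in 1..6, or `NA` when unknown.
#' @param rt_min retention time in minutes.
#' @param peaks data.frame (or 2-column matrix) with columns `mz`, `intensity`.
#' @return Object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(scan_id, precursor_mz, precursor_charge = NA_integer_,
                         rt_min = NA_real_, peaks = NULL) {
  if (is.null(peaks)) {
    peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
  }
  peaks <- as.data.frame(peaks)
  if (is.null(names(peaks)) || !all(c("mz", "intensity") %in% names(peaks))) {
    names(peaks) <- c("mz", "intensity")[seq_len(ncol(peaks))]
  }
  if (any(!is.finite(peaks$mz)) || any(peaks$mz <= 0)) {
    stop("spectrum '", scan_id, "': peak m/z must be positive and finite")
  }
  if (any(!is.finite(peaks$intensity)) || any(peaks$intensity < 0)) {
    stop("spectrum '", scan_id, "': peak intensities must be >= 0")
  }
  if (!is.na(precursor_charge) &&
      (precursor_charge < 1L || precursor_charge > 6L)) {
    stop("spectrum '", scan_id, "': precursor charge must be in 1..6 (got ",
         precursor_charge, ")")
  }
  peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
  peaks <- merge_close_peaks(peaks, 1e-5)
  structure(list(
    scan_id = as.character(scan_id),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    rt_min = as.numeric(rt_min),
    peaks = peaks
  ), class = "ms2_spectrum")
}

# Merge peaks closer than `tol` Th (assumes sorted mz); intensities summed,
# m/z intensity-weighted.
merge_close_peaks <- function(peaks, tol) {
  n <- nrow(peaks)
  if (n < 2L) return(peaks)
  grp <- cumsum(c(TRUE, diff(peaks$mz) > tol))
  if (max(grp) == n) {
    rownames(peaks) <- NULL
    return(peaks)
  }
  inten <- as.numeric(tapply(peaks$intensity, grp, sum))
  wsum <- as.numeric(tapply(peaks$mz * peaks$intensity, grp, sum))
  first <- as.numeric(tapply(peaks$mz, grp, function(z) z[1L]))
  mz <- ifelse(inten > 0, wsum / inten, first)
  data.frame(mz = mz, intensity = inten)
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2 spectrum> scan=", x$scan_id,
      " precursor=", format(x$precursor_mz, digits = 8),
      if (!is.na(x$precursor_charge)) paste0(" (", x$precursor_charge, "+)"),
      " rt=", format(x$rt_min, digits = 4), " min, ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Construct a PRM run
#'
#' A time-ordered collection of targeted MS/MS spectra from one sample.
#' Acquisition labels (gradient length, collision energies) are carried
#' opaquely in `metadata`.
#'
#' @param sample_id sample identifier.
#' @param spectra list of [ms2_spectrum()] with non-decreasing retention time.
#' @param metadata named list of acquisition labels.
#' @return Object of class `prm_run`.
#' @export
prm_run <- function(sample_id, spectra, metadata = list()) {
  stopifnot(is.list(spectra),
            all(vapply(spectra, inherits, logical(1), "ms2_spectrum")))
  rt <- vapply(spectra, function(s) s$rt_min, numeric(1))
  if (length(rt) > 1L && any(diff(rt) < 0)) {
    stop("PRM run '", sample_id, "': retention times must be non-decreasing")
  }
  structure(list(sample_id = as.character(sample_id), spectra = spectra,
                 metadata = metadata), class = "prm_run")
}

#' @export
print.prm_run <- function(x, ...) {
  rt <- vapply(x$spectra, function(s) s$rt_min, numeric(1))
  cat("<prm run> sample=", x$sample_id, ", ", length(x$spectra),
      " spectra, rt ", format(min(rt), digits = 4), "-",
      format(max(rt), digits = 4), " min\n", sep = "")
  invisible(x)
}
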