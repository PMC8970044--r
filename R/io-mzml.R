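# mzML reading (subset): centroided MS2 spectra with precursor metadata,
# through the Bioconductor mzR parser. Write support is deliberately absent;
# synthetic runs are written as MGF plus a run-index CSV.

#' Read centroided MS2 spectra from an mzML file
#'
#' Extracts scan id, precursor m/z and charge, retention time (converted to
#' minutes) and the centroided peak arrays from an mzML document. MS1 (and
#' other non-MS2) scans are skipped and counted; spectra flagged as
#' profile-mode are rejected with advice to centroid; MS2 scans without
#' precursor information are skipped with a warning. Vendor-specific extras
#' are ignored.
#'
#' @param path path to an mzML file.
#' @return A list of [ms2_spectrum()], with attribute `skipped_non_ms2`
#'   giving the number of non-MS2 scans ignored.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  handle <- tryCatch(
    mzR::openMSfile(path, backend = "pwiz"),
    error = function(e) {
      stop("cannot parse mzML file '", path, "': ", conditionMessage(e))
    })
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) {
    warning("mzML file contains no spectra: ", path)
    out <- list()
    attr(out, "skipped_non_ms2") <- 0L
    return(out)
  }
  is_ms2 <- hdr$msLevel == 2L
  n_skipped <- sum(!is_ms2)
  out <- list()
  n_no_precursor <- 0L
  for (i in which(is_ms2)) {
    if (!is.na(hdr$centroided[i]) && !hdr$centroided[i]) {
      stop("mzML spectrum ", hdr$seqNum[i], " in '", path,
           "' is profile-mode; centroid the data before reading")
    }
    prec_mz <- hdr$precursorMZ[i]
    if (is.na(prec_mz) || prec_mz <= 0) {
      n_no_precursor <- n_no_precursor + 1L
      next
    }
    chg <- hdr$precursorCharge[i]
    if (!is.na(chg) && chg == 0L) chg <- NA_integer_
    pk <- mzR::peaks(handle, hdr$seqNum[i])
    out[[length(out) + 1L]] <- ms2_spectrum(
      scan_id = if (!is.null(hdr$spectrumId)) hdr$spectrumId[i] else
        paste0("scan=", hdr$acquisitionNum[i]),
      precursor_mz = prec_mz,
      precursor_charge = chg,
      rt_min = hdr$retentionTime[i] / 60,
      peaks = data.frame(mz = pk[, 1], intensity = pk[, 2])
    )
  }
  if (n_no_precursor > 0L) {
    warning(n_no_precursor, " MS2 scan(s) without precursor information ",
            "skipped in ", path)
  }
  attr(out, "skipped_non_ms2") <- n_skipped
  out
}
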