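# MGF read/write. The dialect uses BEGIN IONS / END IONS blocks with TITLE,
# PEPMASS, CHARGE (e.g. "2+"), RTINSECONDS, and one "mz intensity" pair per
# line. Retention time is stored in minutes internally and converted on
# read/write.

#' Read an MGF file
#'
#' @param path path to an MGF file.
#' @return A list of [ms2_spectrum()]. Spectra lacking a CHARGE line get
#'   `precursor_charge = NA` (flagged downstream). An empty file yields an
#'   empty list with a warning. Malformed BEGIN/END IONS structure is an
#'   error naming the offending line.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("empty MGF file: ", path)
    return(list())
  }
  spectra <- list()
  in_block <- FALSE
  scan_id <- NULL; pepmass <- NA_real_; charge <- NA_integer_
  rt_min <- NA_real_; mzs <- numeric(0); ints <- numeric(0)
  begin_line <- NA_integer_
  for (i in idx) {
    ln <- lines[i]
    if (ln == "BEGIN IONS") {
      if (in_block) {
        stop("malformed MGF at line ", i, ": BEGIN IONS inside an open block ",
             "(block opened at line ", begin_line, ")")
      }
      in_block <- TRUE; begin_line <- i
      scan_id <- NULL; pepmass <- NA_real_; charge <- NA_integer_
      rt_min <- NA_real_; mzs <- numeric(0); ints <- numeric(0)
    } else if (ln == "END IONS") {
      if (!in_block) stop("malformed MGF at line ", i, ": END IONS without BEGIN IONS")
      in_block <- FALSE
      if (is.null(scan_id)) scan_id <- paste0("scan_", length(spectra) + 1L)
      spectra[[length(spectra) + 1L]] <- ms2_spectrum(
        scan_id, pepmass, charge, rt_min,
        data.frame(mz = mzs, intensity = ints))
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") scan_id <- val
      else if (key == "PEPMASS") pepmass <- as.numeric(strsplit(val, "\\s+")[[1]][1])
      else if (key == "CHARGE") charge <- as.integer(sub("\\+$", "", val))
      else if (key == "RTINSECONDS") rt_min <- as.numeric(val) / 60
    } else if (in_block) {
      parts <- strsplit(ln, "\\s+")[[1]]
      pk <- suppressWarnings(as.numeric(parts))
      if (length(pk) < 2L || any(is.na(pk[1:2]))) {
        stop("malformed MGF peak line ", i, ": '", ln, "'")
      }
      mzs <- c(mzs, pk[1]); ints <- c(ints, pk[2])
    } else {
      stop("malformed MGF at line ", i, ": content outside BEGIN/END IONS: '",
           ln, "'")
    }
  }
  if (in_block) {
    stop("malformed MGF: block opened at line ", begin_line,
         " has no END IONS")
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [ms2_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  stopifnot(is.list(spectra),
            all(vapply(spectra, inherits, logical(1), "ms2_spectrum")))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$scan_id), con)
    writeLines(paste0("PEPMASS=", sprintf("%.10g", s$precursor_mz)), con)
    if (!is.na(s$precursor_charge)) {
      writeLines(paste0("CHARGE=", s$precursor_charge, "+"), con)
    }
    if (!is.na(s$rt_min)) {
      writeLines(paste0("RTINSECONDS=", sprintf("%.10g", s$rt_min * 60)), con)
    }
    if (nrow(s$peaks) > 0L) {
      writeLines(sprintf("%.10g %.10g", s$peaks$mz, s$peaks$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
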