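# CSV table readers: PRM target lists, search-engine identification tables,
# and patient cohort tables. All readers validate and reject rather than
# silently coerce.

.GROUP_LEVELS <- c("cirrhosis", "early_hcc", "late_hcc")

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(what, " file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Read a PRM target list
#'
#' Columns: `protein`, `glycosite`, `peptide`, `glycan` (composition string),
#' `precursor_charge`, `expected_rt_min`. Composition strings are parsed and
#' canonicalized; duplicate (peptide, glycan, charge) triples are rejected.
#'
#' @param path CSV path.
#' @return A validated data.frame with canonical `glycan` strings.
#' @seealso [ceru_targets()] for the shipped 18-target ceruloplasmin fixture.
#' @export
read_target_list <- function(path) {
  df <- read_checked_csv(path, c("protein", "glycosite", "peptide", "glycan",
                                 "precursor_charge", "expected_rt_min"),
                         "target list")
  for (i in seq_len(nrow(df))) check_sequence(df$peptide[i])
  df$glycan <- vapply(df$glycan, function(g) format(parse_glycan(g)),
                      character(1), USE.NAMES = FALSE)
  df$glycosite <- as.integer(df$glycosite)
  df$precursor_charge <- as.integer(df$precursor_charge)
  if (any(is.na(df$precursor_charge)) ||
      any(df$precursor_charge < 1L | df$precursor_charge > 6L)) {
    stop("target list '", path, "': precursor charges must be in 1..6")
  }
  key <- paste(df$peptide, df$glycan, df$precursor_charge, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (peptide, glycan, charge) target(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  df
}

#' The shipped ceruloplasmin PRM target fixture
#'
#' An 18-row target list spanning the four ceruloplasmin glycosites
#' (N138, N358, N397, N762) used in the targeted workflow. The N762 peptide
#' (ELHHLQEQNVSNAFLDK) is the genuine tryptic glycopeptide of that site; the
#' other sequences are synthetic representative tryptic peptides (the study
#' does not print them), hence the `_synthetic` fixture name. Site N358
#' carries only non-fucosylated targets, so its fucosylation ratio is
#' undefined by design — it exercises the undefined-ratio path.
#'
#' @return The validated 18-row target list.
#' @export
ceru_targets <- function() {
  read_target_list(system.file("extdata", "ceru_targets_synthetic.csv",
                               package = "glycoPRM", mustWork = TRUE))
}

#' Read a search-engine identification table
#'
#' Columns: `sample`, `peptide`, `glycosite`, `glycan`, `charge`, `scan_id`,
#' `xic_area`, `byonic_score`, `delta_mod_score`, `pep2d`, `fdr2d`. Scores
#' must be finite; `pep2d` and `fdr2d` must lie in `[0, 1]`. Composition
#' strings are canonicalized.
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_identifications <- function(path) {
  df <- read_checked_csv(path, c("sample", "peptide", "glycosite", "glycan",
                                 "charge", "scan_id", "xic_area",
                                 "byonic_score", "delta_mod_score",
                                 "pep2d", "fdr2d"),
                         "identification table")
  df$glycan <- vapply(df$glycan, function(g) format(parse_glycan(g)),
                      character(1), USE.NAMES = FALSE)
  num <- c("xic_area", "byonic_score", "delta_mod_score", "pep2d", "fdr2d")
  for (col in num) {
    if (any(!is.finite(df[[col]]))) {
      stop("identification table '", path, "': non-finite values in ", col)
    }
  }
  for (col in c("pep2d", "fdr2d")) {
    if (any(df[[col]] < 0 | df[[col]] > 1)) {
      stop("identification table '", path, "': ", col, " must be in [0, 1]")
    }
  }
  df
}

#' Read a patient cohort table
#'
#' Columns: `patient_id`, `group` (one of `cirrhosis`, `early_hcc`,
#' `late_hcc`), `afp_ng_ml` (> 0), plus any per-target quantity columns,
#' which pass through untouched.
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_cohort <- function(path) {
  df <- read_checked_csv(path, c("patient_id", "group", "afp_ng_ml"),
                         "cohort table")
  bad <- setdiff(unique(df$group), .GROUP_LEVELS)
  if (length(bad) > 0L) {
    stop("cohort table '", path, "': unknown group label(s): ",
         paste(bad, collapse = ", "),
         " (expected: ", paste(.GROUP_LEVELS, collapse = ", "), ")")
  }
  if (any(!is.finite(df$afp_ng_ml)) || any(df$afp_ng_ml <= 0)) {
    stop("cohort table '", path, "': AFP must be positive")
  }
  if (anyDuplicated(df$patient_id)) {
    stop("cohort table '", path, "': duplicate patient_id")
  }
  df
}
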