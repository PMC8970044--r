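# DDA-side processing of search-engine identification tables: confidence
# filtering, charge-state aggregation, glycoform profiling and replicate
# correlation.

#' Filter identifications at the confidence thresholds
#'
#' Retains rows with Byonic score > 150, Delta modification score > 10,
#' PEP2D < 0.05 and FDR2D < 0.01 — all four strict inequalities, so a row at
#' any boundary (e.g. score exactly 150) is removed. Removal counts per
#' criterion are attached as attribute `removed` (a row failing several
#' criteria is counted under each). The filter is idempotent.
#'
#' @param ids an identification table (see [read_identifications()]).
#' @return The filtered table.
#' @export
filter_identifications <- function(ids) {
  required <- c("byonic_score", "delta_mod_score", "pep2d", "fdr2d")
  missing <- setdiff(required, names(ids))
  if (length(missing) > 0L) {
    stop("identification table lacks score column(s): ",
         paste(missing, collapse = ", "))
  }
  pass_byonic <- ids$byonic_score > 150
  pass_delta <- ids$delta_mod_score > 10
  pass_pep2d <- ids$pep2d < 0.05
  pass_fdr2d <- ids$fdr2d < 0.01
  keep <- pass_byonic & pass_delta & pass_pep2d & pass_fdr2d
  out <- ids[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(
    byonic_score = sum(!pass_byonic),
    delta_mod_score = sum(!pass_delta),
    pep2d = sum(!pass_pep2d),
    fdr2d = sum(!pass_fdr2d)
  )
  out
}

# Canonical unique-glycopeptide key: charge-collapsed.
glycopeptide_key <- function(ids) {
  paste(ids$peptide, ids$glycosite,
        vapply(ids$glycan, function(g) format(parse_glycan(g)), character(1),
               USE.NAMES = FALSE),
        sep = "|")
}

#' Aggregate identification areas over charge states
#'
#' A glycopeptide's abundance is the sum of its XIC areas over all observed
#' charge states of the same glycan at the same glycosite; the aggregated
#' areas are then normalized within each sample (relative abundance = area /
#' total area). Composition strings naming the same glycan (case or synonym
#' variants) merge after canonical parsing.
#'
#' @param ids an identification table with `xic_area`.
#' @return A data.frame with one row per (sample, peptide, glycosite, glycan)
#'   and columns `xic_area` and `relative_abundance`.
#' @export
aggregate_charge_states <- function(ids) {
  ids$glycan <- vapply(ids$glycan, function(g) format(parse_glycan(g)),
                       character(1), USE.NAMES = FALSE)
  key <- paste(ids$sample, ids$peptide, ids$glycosite, ids$glycan, sep = "|")
  agg <- stats::aggregate(ids$xic_area, by = list(key = key), FUN = sum)
  meta <- ids[!duplicated(key),
              c("sample", "peptide", "glycosite", "glycan"), drop = FALSE]
  meta$key <- key[!duplicated(key)]
  out <- merge(meta, agg, by = "key")
  names(out)[names(out) == "x"] <- "xic_area"
  out$key <- NULL
  out$relative_abundance <- NA_real_
  for (s in unique(out$sample)) {
    sel <- out$sample == s
    total <- sum(out$xic_area[sel])
    out$relative_abundance[sel] <-
      if (total > 0) out$xic_area[sel] / total else 0
  }
  out <- out[order(out$sample, out$peptide, out$glycosite, out$glycan), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Profile glycoform distributions of identified glycopeptides
#'
#' Counts unique glycopeptides — key (peptide, glycosite, canonical glycan),
#' charge-collapsed — by antennarity class, fucose count and sialic-acid
#' count, with percentages. The mono/di/tri/tetra-fucosylated percentages use
#' the fucosylated subset as denominator (the convention of per-fucose-count
#' distributions); antennarity and sialylation percentages use all unique
#' glycopeptides.
#'
#' @param ids an identification table (typically filtered).
#' @return A list with data.frames `antennarity`, `fucose`, `sialyl` and
#'   scalar counts `n_unique`, `n_fucosylated`, `n_sialylated`.
#' @export
profile_distributions <- function(ids) {
  key <- glycopeptide_key(ids)
  uniq <- ids[!duplicated(key), , drop = FALSE]
  cls <- lapply(uniq$glycan, classify_glycoform)
  ant <- factor(vapply(cls, `[[`, character(1), "antennarity"),
                levels = c("bi", "tri", "tetra", "other"))
  fuc <- vapply(cls, `[[`, integer(1), "fucose_count")
  sia <- vapply(cls, `[[`, integer(1), "sialyl_count")
  n <- nrow(uniq)
  ant_tab <- as.data.frame(table(antennarity = ant), stringsAsFactors = FALSE)
  names(ant_tab)[2L] <- "count"
  ant_tab$percent <- if (n > 0) 100 * ant_tab$count / n else 0
  fuc_sub <- fuc[fuc > 0]
  fuc_tab <- as.data.frame(table(fucose_count = fuc_sub),
                           stringsAsFactors = FALSE)
  names(fuc_tab)[2L] <- "count"
  fuc_tab$fucose_count <- as.integer(fuc_tab$fucose_count)
  fuc_tab$percent <- if (length(fuc_sub) > 0)
    100 * fuc_tab$count / length(fuc_sub) else numeric(0)
  sia_tab <- as.data.frame(table(sialyl_count = sia), stringsAsFactors = FALSE)
  names(sia_tab)[2L] <- "count"
  sia_tab$sialyl_count <- as.integer(sia_tab$sialyl_count)
  sia_tab$percent <- if (n > 0) 100 * sia_tab$count / n else numeric(0)
  list(antennarity = ant_tab, fucose = fuc_tab, sialyl = sia_tab,
       n_unique = n, n_fucosylated = length(fuc_sub),
       n_sialylated = sum(sia > 0))
}

#' Compare glycopeptide sets between run groups
#'
#' Set algebra over unique glycopeptide keys of two identification tables
#' (e.g. fractionated versus unfractionated runs).
#'
#' @param ids_a,ids_b identification tables.
#' @return A list with `n_a`, `n_b`, `union`, `intersection`, `only_a`,
#'   `only_b`.
#' @export
compare_id_sets <- function(ids_a, ids_b) {
  a <- unique(glycopeptide_key(ids_a))
  b <- unique(glycopeptide_key(ids_b))
  list(n_a = length(a), n_b = length(b),
       union = length(union(a, b)),
       intersection = length(intersect(a, b)),
       only_a = length(setdiff(a, b)),
       only_b = length(setdiff(b, a)))
}

#' Pairwise replicate correlation of abundance profiles
#'
#' Squared Pearson correlations between per-replicate relative-abundance (or
#' percentage) vectors over the union of glycopeptide keys; a key missing
#' from a replicate contributes 0. Constant vectors give `NA` entries with a
#' warning.
#'
#' @param profiles a named list of numeric vectors, each named by
#'   glycopeptide key, or a matrix with keys as rownames and replicates as
#'   columns.
#' @return A symmetric matrix of R-squared values (diagonal 1).
#' @export
replicate_correlation <- function(profiles) {
  if (is.list(profiles) && !is.data.frame(profiles)) {
    keys <- Reduce(union, lapply(profiles, names))
    if (is.null(keys)) stop("profile vectors must be named by glycopeptide key")
    m <- sapply(profiles, function(v) {
      out <- stats::setNames(rep(0, length(keys)), keys)
      out[names(v)] <- v
      out
    })
  } else {
    m <- as.matrix(profiles)
  }
  if (ncol(m) < 2L) stop("at least two replicates are required")
  const <- apply(m, 2L, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(const)) {
    warning("constant replicate vector(s): ",
            paste(colnames(m)[const], collapse = ", "),
            "; correlations set to NA")
  }
  r2 <- suppressWarnings(stats::cor(m)^2)
  diag(r2) <- 1
  r2
}
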