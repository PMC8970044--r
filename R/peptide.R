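# Peptide and glycopeptide mass engine.

.DEFAULT_FIXED_MODS <- c(C = 57.021464)  # carbamidomethyl

check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("peptide sequence must be non-empty")
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% names(.AA_RESIDUE_MASS))
  if (length(bad) > 0L) {
    stop("unknown residue '", aa[bad[1L]], "' at position ", bad[1L],
         " in sequence '", sequence, "'")
  }
  aa
}

# Normalize variable mods to a data.frame(position, delta).
check_variable_mods <- function(variable_mods, n_res) {
  if (is.null(variable_mods) || length(variable_mods) == 0L) {
    return(data.frame(position = integer(0), delta = numeric(0)))
  }
  if (is.list(variable_mods) && !is.data.frame(variable_mods)) {
    variable_mods <- do.call(rbind, lapply(variable_mods, function(v) {
      data.frame(position = v[[1L]], delta = v[[2L]])
    }))
  }
  stopifnot(is.data.frame(variable_mods),
            all(c("position", "delta") %in% names(variable_mods)))
  if (any(variable_mods$position < 1L | variable_mods$position > n_res)) {
    stop("variable modification position outside the peptide")
  }
  variable_mods
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water, plus fixed per-residue modification
#' deltas (applied to every occurrence of the named residue) and explicit
#' positional variable modifications.
#'
#' @param sequence amino-acid string (20 canonical residues).
#' @param fixed_mods named numeric vector of per-residue mass additions;
#'   default carbamidomethyl on C (+57.021464 Da).
#' @param variable_mods `NULL`, a `data.frame(position, delta)`, or a list of
#'   `c(position, delta)` pairs (e.g. oxidation +15.994915 on a given M).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("ELHHLQEQNVSNAFLDK")
#' peptide_mass("C")   # includes the carbamidomethyl fixed mod
#' @export
peptide_mass <- function(sequence, fixed_mods = .DEFAULT_FIXED_MODS,
                         variable_mods = NULL) {
  aa <- check_sequence(sequence)
  vm <- check_variable_mods(variable_mods, length(aa))
  fixed <- 0
  if (length(fixed_mods) > 0L) {
    stopifnot(!is.null(names(fixed_mods)))
    fixed <- sum(fixed_mods[aa], na.rm = TRUE)
  }
  sum(.AA_RESIDUE_MASS[aa]) + WATER_MASS + fixed + sum(vm$delta)
}

#' Construct a glycopeptide
#'
#' A peptide sequence carrying one N-glycan composition at a labelled
#' glycosite. The glycosite is a protein-coordinate label only and does not
#' affect mass computation.
#'
#' @param sequence amino-acid string.
#' @param glycan a [glycan_composition()] or composition string.
#' @param glycosite 1-based position within the protein (label).
#' @param protein optional protein label.
#' @inheritParams peptide_mass
#' @return An object of class `glycopeptide`.
#' @examples
#' glycopeptide("ELHHLQEQNVSNAFLDK", "HexNAc(5)Hex(6)Fuc(2)NeuAc(3)", 762, "CERU")
#' @export
glycopeptide <- function(sequence, glycan, glycosite = NA_integer_,
                         protein = NA_character_,
                         fixed_mods = .DEFAULT_FIXED_MODS,
                         variable_mods = NULL) {
  aa <- check_sequence(sequence)
  vm <- check_variable_mods(variable_mods, length(aa))
  structure(list(
    sequence = sequence,
    glycan = as_glycan(glycan),
    glycosite = as.integer(glycosite),
    protein = protein,
    fixed_mods = fixed_mods,
    variable_mods = vm
  ), class = "glycopeptide")
}

#' @export
print.glycopeptide <- function(x, ...) {
  cat("<glycopeptide> ", x$sequence,
      if (!is.na(x$glycosite)) paste0(" @N", x$glycosite),
      " + ", format(x$glycan), "\n", sep = "")
  invisible(x)
}

# Neutral peptide-backbone mass of a glycopeptide (mods included, no glycan).
backbone_mass <- function(gp) {
  stopifnot(inherits(gp, "glycopeptide"))
  peptide_mass(gp$sequence, gp$fixed_mods, gp$variable_mods)
}

#' Neutral mass and precursor m/z of a glycopeptide
#'
#' @param gp a [glycopeptide()].
#' @param charge precursor charge (1-6 in this workflow).
#' @return `glycopeptide_mass`: neutral mass in Da; `precursor_mz`: m/z.
#' @export
glycopeptide_mass <- function(gp) {
  backbone_mass(gp) + glycan_mass(gp$glycan)
}

#' @rdname glycopeptide_mass
#' @export
precursor_mz <- function(gp, charge) {
  ion_mz(glycopeptide_mass(gp), charge)
}

#' Glycosidic Y-ion series of a glycopeptide
#'
#' The small glycosidic Y ions used for identification, quantification and
#' fucose-topology calling: Y0 (bare peptide, label `"pep"`), Y1
#' (`"pep+HexNAc"` — the quantification transition), `"pep+HexNAc+Fuc"`,
#' `"pep+2HexNAc"` and `"pep+2HexNAc+Fuc"`, each at charges
#' `1..max_charge`. Ions whose monosaccharides the composition does not
#' contain are omitted (a composition without HexNAc yields only Y0; without
#' Fuc, no `+Fuc` ions). The fucose-retaining members (Y ions keeping at most
#' the chitobiose core) are the core-fucosylation diagnostics.
#'
#' @param gp a [glycopeptide()].
#' @param max_charge highest fragment charge to emit (>= 1); default 2.
#' @return A data.frame of fragment ions (`kind == "Y"`).
#' @examples
#' gp <- glycopeptide("ELHHLQEQNVSNAFLDK", "HexNAc(5)Hex(6)Fuc(2)NeuAc(3)")
#' y_ion_series(gp, max_charge = 2)
#' @export
y_ion_series <- function(gp, max_charge = 2L) {
  stopifnot(inherits(gp, "glycopeptide"), max_charge >= 1L)
  g <- gp$glycan
  pep <- backbone_mass(gp)
  hn <- .MONOSACCHARIDES[["HexNAc"]]
  fu <- .MONOSACCHARIDES[["Fuc"]]
  specs <- list(list(label = "pep", mass = pep))
  if (g[["HexNAc"]] >= 1L) {
    specs <- c(specs, list(list(label = "pep+HexNAc", mass = pep + hn)))
    if (g[["Fuc"]] >= 1L) {
      specs <- c(specs, list(list(label = "pep+HexNAc+Fuc", mass = pep + hn + fu)))
    }
  }
  if (g[["HexNAc"]] >= 2L) {
    specs <- c(specs, list(list(label = "pep+2HexNAc", mass = pep + 2 * hn)))
    if (g[["Fuc"]] >= 1L) {
      specs <- c(specs, list(list(label = "pep+2HexNAc+Fuc",
                                  mass = pep + 2 * hn + fu)))
    }
  }
  rows <- lapply(specs, function(s) {
    fragment_ion("Y", s$label, s$mass, seq_len(max_charge))
  })
  do.call(rbind, rows)
}

#' Peptide backbone b/y fragment ladders
#'
#' Standard b and y fragment ions of the peptide backbone at charges
#' `1..max_charge`, with fixed and variable modifications carried by the
#' residues each fragment retains. Labels follow the `b3`, `y5` convention.
#'
#' @param sequence amino-acid string, or a [glycopeptide()] (its backbone is
#'   used; the glycan is ignored for b/y ions).
#' @param max_charge highest fragment charge (default 2).
#' @param types subset of `c("b", "y")`.
#' @inheritParams peptide_mass
#' @return A data.frame of fragment ions.
#' @export
peptide_fragments <- function(sequence, max_charge = 2L, types = c("b", "y"),
                              fixed_mods = .DEFAULT_FIXED_MODS,
                              variable_mods = NULL) {
  if (inherits(sequence, "glycopeptide")) {
    gp <- sequence
    sequence <- gp$sequence
    fixed_mods <- gp$fixed_mods
    variable_mods <- gp$variable_mods
  }
  types <- match.arg(types, c("b", "y"), several.ok = TRUE)
  aa <- check_sequence(sequence)
  n <- length(aa)
  vm <- check_variable_mods(variable_mods, n)
  res <- .AA_RESIDUE_MASS[aa]
  if (length(fixed_mods) > 0L) {
    extra <- fixed_mods[aa]
    extra[is.na(extra)] <- 0
    res <- res + extra
  }
  if (nrow(vm) > 0L) {
    for (k in seq_len(nrow(vm))) {
      res[vm$position[k]] <- res[vm$position[k]] + vm$delta[k]
    }
  }
  csum <- cumsum(res)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    if ("b" %in% types) {
      rows[[length(rows) + 1L]] <-
        fragment_ion("b", paste0("b", i), csum[i], seq_len(max_charge))
    }
    if ("y" %in% types) {
      rows[[length(rows) + 1L]] <-
        fragment_ion("y", paste0("y", i), csum[n] - csum[n - i] + WATER_MASS,
                     seq_len(max_charge))
    }
  }
  do.call(rbind, rows)
}

#' All theoretical fragment ions of a glycopeptide
#'
#' Union of the diagnostic oxonium ions of the glycan, the glycosidic Y
#' series, and the peptide b/y ladders, as matched by [match_fragments()].
#'
#' @inheritParams y_ion_series
#' @param ion_types subset of `c("oxonium", "Y", "b", "y")`.
#' @return A data.frame of fragment ions.
#' @export
theoretical_fragments <- function(gp, max_charge = 2L,
                                  ion_types = c("oxonium", "Y", "b", "y")) {
  stopifnot(inherits(gp, "glycopeptide"))
  ion_types <- match.arg(ion_types, c("oxonium", "Y", "b", "y"),
                         several.ok = TRUE)
  rows <- list()
  if ("oxonium" %in% ion_types) rows$ox <- oxonium_ions(gp$glycan)
  if ("Y" %in% ion_types) rows$y_glyco <- y_ion_series(gp, max_charge)
  by <- intersect(c("b", "y"), ion_types)
  if (length(by) > 0L) {
    rows$by <- peptide_fragments(gp, max_charge = max_charge, types = by)
  }
  do.call(rbind, unname(rows))
}
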