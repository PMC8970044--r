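#' Glycan composition
#'
#' A complex-type N-glycan composition: counts of HexNAc, Hex, Fuc and NeuAc
#' residues. Compositions carry no topology; they are the unit of all glycan
#' mass arithmetic and of glycoform classification.
#'
#' @param hexnac,hex,fuc,neuac non-negative integer residue counts.
#' @return An object of class `glycan_composition` (a named integer vector).
#' @examples
#' glycan_composition(hexnac = 5, hex = 6, fuc = 2, neuac = 3)
#' @seealso [parse_glycan()], [glycan_mass()], [classify_glycoform()]
#' @export
glycan_composition <- function(hexnac = 0L, hex = 0L, fuc = 0L, neuac = 0L) {
  x <- c(HexNAc = unname(hexnac), Hex = unname(hex), Fuc = unname(fuc),
         NeuAc = unname(neuac))
  if (any(is.na(x)) || any(x < 0) || any(x != as.integer(x))) {
    stop("monosaccharide counts must be non-negative integers")
  }
  structure(as.integer(x), names = names(x), class = "glycan_composition")
}

# Synonyms accepted on parse (figure captions use HexNac, Gal, Glc, Man).
.GLYCAN_SYNONYMS <- c(
  hexnac = "HexNAc", glcnac = "HexNAc",
  hex = "Hex", gal = "Hex", man = "Hex", glc = "Hex",
  fuc = "Fuc", dhex = "Fuc",
  neuac = "NeuAc", sia = "NeuAc"
)

#' Parse a glycan composition string
#'
#' Parses the `HexNAc(a)Hex(b)Fuc(c)NeuAc(d)` convention. Zero-count terms
#' may be omitted; term order is free; the synonyms `HexNac`, `GlcNAc`,
#' `Gal`/`Man`/`Glc` (for Hex) and `Sia` are accepted case-insensitively.
#' An empty string parses to the empty composition.
#'
#' @param x a single composition string.
#' @return A [glycan_composition()].
#' @examples
#' parse_glycan("HexNAc(5)Hex(6)Fuc(2)NeuAc(3)")
#' parse_glycan("HexNac(1)Gal(1)Fuc(1)")   # caption-style synonyms
#' @export
parse_glycan <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (nchar(x) == 0L) return(glycan_composition())
  m <- gregexpr("([A-Za-z]+)\\((\\d+)\\)", x, perl = TRUE)[[1]]
  if (m[1L] == -1L) stop("cannot parse glycan composition: '", x, "'")
  tokens <- regmatches(x, gregexpr("([A-Za-z]+)\\((\\d+)\\)", x, perl = TRUE))[[1]]
  if (sum(nchar(tokens)) != nchar(gsub("\\s", "", x))) {
    stop("cannot parse glycan composition: '", x,
         "' (unrecognized text outside Name(count) terms)")
  }
  counts <- c(HexNAc = 0L, Hex = 0L, Fuc = 0L, NeuAc = 0L)
  for (tok in tokens) {
    name <- tolower(sub("\\(.*$", "", tok))
    n <- as.integer(sub("^.*\\((\\d+)\\)$", "\\1", tok))
    if (!name %in% names(.GLYCAN_SYNONYMS)) {
      stop("unknown monosaccharide '", sub("\\(.*$", "", tok),
           "' in composition '", x, "'")
    }
    counts[.GLYCAN_SYNONYMS[[name]]] <- counts[.GLYCAN_SYNONYMS[[name]]] + n
  }
  glycan_composition(counts[["HexNAc"]], counts[["Hex"]],
                     counts[["Fuc"]], counts[["NeuAc"]])
}

#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0L]
  if (length(nz) == 0L) return("")
  paste0(names(nz), "(", nz, ")", collapse = "")
}

#' @export
as.character.glycan_composition <- function(x, ...) format(x)

#' @export
print.glycan_composition <- function(x, ...) {
  cat("<glycan composition> ", format(x), "\n", sep = "")
  invisible(x)
}

# Coerce a composition given as string or glycan_composition.
as_glycan <- function(x) {
  if (inherits(x, "glycan_composition")) return(x)
  if (is.character(x)) return(parse_glycan(x))
  stop("expected a glycan_composition or a composition string")
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum of count times residue mass over the four monosaccharides. The empty
#' composition has mass 0; the function is linear in the composition.
#'
#' @param glycan a [glycan_composition()] or composition string.
#' @return Mass in Da.
#' @examples
#' glycan_mass("HexNAc(5)Hex(6)Fuc(2)NeuAc(3)")
#' @export
glycan_mass <- function(glycan) {
  g <- as_glycan(glycan)
  sum(as.numeric(g) * .MONOSACCHARIDES[names(g)])
}

#' Classify a glycan composition into a glycoform class
#'
#' Antennarity follows the chitobiose-core convention for non-bisected
#' complex-type N-glycans: antenna count = HexNAc - 2, so HexNAc 4/5/6 map
#' to bi/tri/tetra-antennary; anything else (including high-mannose-like
#' compositions with HexNAc < 2, which are flagged) is "other". Fucose and
#' sialic-acid counts are copied from the composition; core versus outer-arm
#' fucose position is a spectral (topology) call, not a composition call —
#' see [call_fucose_topology()].
#'
#' @param glycan a [glycan_composition()] or composition string.
#' @return A list with `antennarity` (one of `"bi"`, `"tri"`, `"tetra"`,
#'   `"other"`), `fucose_count`, `sialyl_count`, and `below_complex_core`
#'   (TRUE when HexNAc < 2).
#' @examples
#' classify_glycoform("HexNAc(5)Hex(6)Fuc(2)NeuAc(3)")  # tri-antennary
#' @export
classify_glycoform <- function(glycan) {
  g <- as_glycan(glycan)
  hexnac <- g[["HexNAc"]]
  antennarity <- switch(as.character(hexnac),
                        "4" = "bi", "5" = "tri", "6" = "tetra", "other")
  list(
    antennarity = antennarity,
    fucose_count = g[["Fuc"]],
    sialyl_count = g[["NeuAc"]],
    below_complex_core = hexnac < 2L
  )
}

# Diagnostic oxonium recipe table. The two HexNAc secondary fragments are
# fixed published values (dehydration / cross-ring products with no simple
# residue-sum form); all other ions are computed as residue sums + proton.
.OXONIUM_RECIPES <- list(
  list(label = "HexNAc-frag1", requires = c(HexNAc = 1L), fixed_mz = 138.05),
  list(label = "HexNAc-frag2", requires = c(HexNAc = 1L), fixed_mz = 168.05),
  list(label = "HexNAc",           requires = c(HexNAc = 1L)),
  list(label = "NeuAc-H2O",        requires = c(NeuAc = 1L), minus_water = TRUE),
  list(label = "NeuAc",            requires = c(NeuAc = 1L)),
  list(label = "HexNAcHex",        requires = c(HexNAc = 1L, Hex = 1L)),
  list(label = "HexNAcHexFuc",     requires = c(HexNAc = 1L, Hex = 1L, Fuc = 1L)),
  list(label = "HexNAcHexNeuAc",   requires = c(HexNAc = 1L, Hex = 1L, NeuAc = 1L))
)

#' Diagnostic oxonium ions of a glycan composition
#'
#' Returns the subset of the eight diagnostic oxonium ions whose constituent
#' monosaccharides are present in the composition. All oxonium ions are
#' singly charged. Six are computed as monosaccharide residue-mass sums plus
#' a proton (the NeuAc-H2O ion additionally loses one water); the two HexNAc
#' secondary fragments at m/z 138.05 and 168.05 are fixed published values
#' (see [glyco_constants()]).
#'
#' The m/z 512.20 ion (HexNAc+Hex+Fuc) is the outer-arm fucosylation
#' diagnostic; it requires at least one of each of HexNAc, Hex and Fuc.
#'
#' @param glycan a [glycan_composition()] or composition string.
#' @return A data.frame of fragment ions with columns `kind`, `label`,
#'   `neutral_mass`, `charge`, `mz`.
#' @examples
#' oxonium_ions("HexNAc(1)Hex(1)Fuc(1)NeuAc(1)")  # all eight diagnostics
#' oxonium_ions("HexNAc(2)Hex(3)")                # no Fuc/NeuAc ions
#' @export
oxonium_ions <- function(glycan) {
  g <- as_glycan(glycan)
  rows <- lapply(.OXONIUM_RECIPES, function(r) {
    if (any(g[names(r$requires)] < r$requires)) return(NULL)
    if (!is.null(r$fixed_mz)) {
      neutral <- r$fixed_mz - PROTON_MASS
    } else {
      neutral <- sum(.MONOSACCHARIDES[names(r$requires)] * r$requires)
      if (isTRUE(r$minus_water)) neutral <- neutral - WATER_MASS
    }
    fragment_ion("oxonium", r$label, neutral, 1L)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- fragment_ion(character(0), character(0), numeric(0), integer(0))
  }
  out
}
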