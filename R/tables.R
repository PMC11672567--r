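#' Van der Waals radii (Bondi-type element table)
#'
#' Element radii in Angstrom used for SASA computation. Values follow the
#' Bondi (1964) compilation with the common extensions for metals seen in
#' protein structures. The table is pinned so that SASA results are
#' reproducible; alternative tables can be supplied to [read_structure()].
#'
#' @return Named numeric vector, names are element symbols, values radii in
#'   Angstrom.
#' @export
#' @examples
#' vdw_radii()[["C"]]
vdw_radii <- function() {
  c(
    H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
    P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    SE = 1.90, B = 1.92,
    # common ions/metals in crystal structures
    "NA" = 2.27, MG = 1.73, K = 2.75, CA = 2.31, ZN = 1.39,
    FE = 1.94, MN = 1.97, CU = 1.40, NI = 1.63, CO = 1.53
  )
}

# default radius when the element cannot be resolved (generic heavy atom)
.default_vdw_radius <- 1.70

#' Black-Mould normalized hydrophobicity scale
#'
#' Per-amino-acid hydrophobicity indices normalized to the unit interval
#' (Phe = 1.000 most hydrophobic, Arg = 0.000 least), as tabulated by Black
#' and Mould (1991). Multiplying a residue's solvent-accessible surface area
#' by this index gives the surface-hydrophobicity score used throughout the
#' package.
#'
#' @return An object of class `hydrophobicity_scale`: list with `name` and
#'   `index` (named numeric vector over the 20 standard one-letter codes).
#' @export
#' @examples
#' black_mould_scale()$index[["W"]]
black_mould_scale <- function() {
  idx <- c(
    A = 0.616, R = 0.000, N = 0.236, D = 0.028, C = 0.680,
    Q = 0.251, E = 0.043, G = 0.501, H = 0.165, I = 0.943,
    L = 0.943, K = 0.283, M = 0.738, F = 1.000, P = 0.711,
    S = 0.359, T = 0.450, W = 0.878, Y = 0.880, V = 0.825
  )
  structure(list(name = "black_mould", index = idx,
                 normalization = "unit interval, Phe = 1, Arg = 0"),
            class = "hydrophobicity_scale")
}

#' Reference maximal residue SASA (Gly-X-Gly tripeptide)
#'
#' Theoretical maximum solvent-accessible surface areas per residue type in
#' an extended Gly-X-Gly tripeptide (Tien et al. 2013, theoretical column),
#' in Angstrom squared. Used as the denominator of relative solvent exposure.
#'
#' @return Named numeric vector over one-letter codes (Angstrom squared).
#' @export
max_sasa_gxg <- function() {
  c(
    A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
  )
}

#' Kabat CDR boundary table
#'
#' Default Kabat-scheme CDR boundaries for heavy and light variable domains.
#' Positions are Kabat numbers; insertion letters (e.g. 35A, 100C) inherit
#' the region of their parent number. Everything before CDR1 is FR1, between
#' CDRs FR2/FR3, after CDR3 up to the end of the variable domain FR4.
#'
#' @return Data frame with columns `chain` ("H"/"L"), `region`
#'   (CDR1/CDR2/CDR3), `start`, `end` (integer Kabat positions).
#' @export
kabat_cdr_boundaries <- function() {
  data.frame(
    chain  = c("H", "H", "H", "L", "L", "L"),
    region = c("CDR1", "CDR2", "CDR3", "CDR1", "CDR2", "CDR3"),
    start  = c(31L, 50L, 95L, 24L, 50L, 89L),
    end    = c(35L, 65L, 102L, 34L, 56L, 97L),
    stringsAsFactors = FALSE
  )
}

# variable-domain end (Kabat) used to separate FR4 from the constant domain
.kabat_vdomain_end <- c(H = 113L, L = 107L)

#' Assign a Kabat region to a scheme label
#'
#' Maps Kabat labels such as `"H97"`, `"L93"` or `"H100A"` to their region
#' (FR1-FR4, CDR1-CDR3, or "constant" past the variable domain).
#'
#' @param label Character vector of scheme labels: chain letter (H/L)
#'   followed by the Kabat number and an optional insertion letter.
#' @param boundaries CDR boundary table, defaults to [kabat_cdr_boundaries()].
#' @return Character vector of region labels.
#' @export
#' @examples
#' kabat_region(c("H97", "L93", "H31", "H49", "L120"))
kabat_region <- function(label, boundaries = kabat_cdr_boundaries()) {
  m <- regmatches(label, regexec("^([HL])([0-9]+)([A-Za-z]?)$", label))
  vapply(seq_along(label), function(i) {
    parts <- m[[i]]
    if (length(parts) != 4L) return("other")
    ch <- parts[2]; num <- as.integer(parts[3])
    if (num > .kabat_vdomain_end[[ch]]) return("constant")
    b <- boundaries[boundaries$chain == ch, , drop = FALSE]
    hit <- which(num >= b$start & num <= b$end)
    if (length(hit) == 1L) return(b$region[hit])
    # framework index = 1 + number of CDRs fully before this position
    fr <- 1L + sum(num > b$end)
    paste0("FR", fr)
  }, character(1))
}

# 3-letter -> 1-letter amino acid lookup, standard residues only
.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Default modified-residue alias table
#'
#' Maps common modified 3-letter residue names to their parent one-letter
#' code (e.g. MSE selenomethionine to M). Used by [extract_chain_sequence()]
#' when `strict = FALSE`.
#'
#' @return Named character vector (3-letter name to 1-letter code).
#' @export
modified_residue_aliases <- function() {
  c(MSE = "M", SEC = "C", PYL = "K", HYP = "P", MLY = "K",
    CSO = "C", PTR = "Y", SEP = "S", TPO = "T")
}
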