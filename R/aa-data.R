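# Constant tables shared across the package: amino-acid codes, van der Waals
# radii, the reference free-residue SASA table, and the helix-propensity scale.

#' @keywords internal
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' @keywords internal
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Convert between 3-letter and 1-letter amino-acid codes
#'
#' @param x character vector of residue codes.
#' @return character vector of converted codes; unknown codes give `NA`.
#' @export
aa_321 <- function(x) .AA1[match(toupper(x), .AA3)]

#' @rdname aa_321
#' @export
aa_123 <- function(x) .AA3[match(toupper(x), .AA1)]

# Residue names treated as solvent water.
.WATER_NAMES <- c("HOH", "WAT", "SOL", "TIP3", "H2O")

# Atom names that belong to the peptide backbone (N, CA, C, O and their
# attached hydrogens).  OXT covers carboxy termini in external files.
.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT",
                     "H", "H1", "H2", "H3", "HN", "HA", "HA2", "HA3")

# van der Waals radii (Bondi 1964), Angstrom.  Used by the SASA engine.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.VDW_DEFAULT <- 1.70

#' Reference solvent-accessible surface of free amino acids
#'
#' Per-residue SASA of the isolated amino acid in solution (Angstrom^2), used
#' to convert an observed residue SASA into a relative (percent) exposure.
#' The shipped values are the theoretical maximum-ASA normalization constants
#' of Tien et al. (2013); any complete 20-residue table can be substituted via
#' the `ref_sasa` argument of the functions that consume it (the exposure
#' classification is robust to the choice of normalization table).
#'
#' @return named numeric vector, names are 3-letter residue codes.
#' @export
reference_sasa <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
    GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
    LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
    SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)
}

#' Helix-propensity penalty scale
#'
#' Free-energy penalty (kJ/mol) for placing each amino acid inside an
#' alpha-helix, relative to alanine (the zero reference).  Values follow the
#' Pace & Scholtz consensus scale converted from kcal/mol; proline carries the
#' dominant penalty (13.22 kJ/mol) reflecting helix breakage.
#'
#' @return named numeric vector keyed by 1-letter code, kJ/mol.
#' @export
helix_propensity_scale <- function() {
  c(A = 0.00, L = 0.88, R = 0.88, M = 1.00, K = 1.09,
    Q = 1.63, E = 1.67, I = 1.72, W = 2.05, S = 2.09,
    Y = 2.22, F = 2.26, V = 2.55, H = 2.55, N = 2.72,
    T = 2.76, C = 2.85, D = 2.89, G = 4.18, P = 13.22)
}

# Sidechain atoms carrying a formal charge, used for salt-bridge detection.
.ACIDIC_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.BASIC_N  <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                  HIS = c("ND1", "NE2"))

#' @keywords internal
vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}
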