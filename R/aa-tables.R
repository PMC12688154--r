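# Shared alphabets and lookup tables. Every module indexes amino acids through
# these constants so column order never depends on file layout.

#' Amino-acid alphabets and category tables
#'
#' `aa_alphabet()` returns the 20 standard one-letter codes in the
#' profile-matrix column order (A R N D C Q E G H I L K M F P S T W Y V),
#' the single ordering used for PSSM columns, substitution matrices and
#' one-hot encodings throughout the package. `aa_categories()` returns the
#' membership table of the eight physicochemical categories. The four
#' charge/polarity categories (uncharged polar, positively charged,
#' negatively charged, nonpolar) partition the 20 amino acids; the other
#' four (aromatic, aliphatic, heterocyclic, sulfur-containing) overlap them.
#'
#' @return `aa_alphabet()`: a character vector of length 20.
#'   `aa_categories()`: a tibble with columns `category` and `aa`
#'   (list-column of member letters).
#' @examples
#' aa_alphabet()
#' aa_categories()
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# category memberships: first four partition the alphabet, last four overlap
.aa_category_members <- list(
  uncharged_polar    = c("S", "T", "N", "Q", "C", "Y"),
  positively_charged = c("K", "R", "H"),
  negatively_charged = c("D", "E"),
  nonpolar           = c("G", "A", "V", "L", "I", "P", "F", "M", "W"),
  aromatic           = c("F", "W", "Y", "H"),
  aliphatic          = c("G", "A", "V", "L", "I"),
  heterocyclic       = c("H", "P", "W"),
  sulfur_containing  = c("C", "M")
)

#' @rdname aa_alphabet
#' @export
aa_categories <- function() {
  tibble::tibble(
    category = names(.aa_category_members),
    aa = unname(.aa_category_members)
  )
}

.aa3_to_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.aa1_to_3 <- stats::setNames(names(.aa3_to_1), unname(.aa3_to_1))

aa3_to_aa1 <- function(x) {
  out <- unname(.aa3_to_1[toupper(x)])
  out[is.na(out)] <- "X"
  out
}
aa1_to_aa3 <- function(x) {
  out <- unname(.aa1_to_3[toupper(x)])
  if (anyNA(out)) stop("unknown one-letter amino acid code: ",
                       paste(x[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

# van der Waals radii by element (Angstrom); fallback 1.7 for unknowns
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, SE = 1.90)

vdw_radius <- function(element) {
  r <- unname(.vdw_radii[toupper(element)])
  r[is.na(r)] <- 1.70
  r
}

# Theoretical maximum accessible surface area per residue (Angstrom^2),
# Tien et al. 2013 theoretical values; denominator for relative accessibility.
.max_asa <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

#' Maximum accessible surface area reference table
#'
#' Theoretical maximum solvent-accessible surface area per amino acid
#' (square Angstrom), used as the denominator of relative solvent
#' accessibility.
#'
#' @return Named numeric vector over the 20 standard amino acids.
#' @export
max_asa_table <- function() .max_asa

# residues counted as hydrophobic for cluster detection
.hydrophobic_aa <- c("A", "V", "L", "I", "M", "F", "W", "C")

# Secondary-structure classes, fixed order used by every encoder
.ss_classes <- c("three_ten_helix", "alpha_helix", "pi_helix", "turn",
                 "beta_strand", "beta_bridge", "bend", "loop")

#' Secondary-structure classes
#'
#' The eight-state secondary-structure vocabulary used throughout the
#' package: 3-10 helix, alpha helix, pi helix, helix-turn, extended beta
#' strand, beta bridge, bend, and other/loop. DSSP letters map onto these
#' classes as G, H, I, T, E, B, S and blank respectively.
#'
#' @return Character vector of the eight class names, in canonical order.
#' @export
ss_classes <- function() .ss_classes

.dssp_ss_map <- c(G = "three_ten_helix", H = "alpha_helix", I = "pi_helix",
                  T = "turn", E = "beta_strand", B = "beta_bridge",
                  S = "bend")

dssp_letter_to_class <- function(letter) {
  out <- unname(.dssp_ss_map[letter])
  out[is.na(out)] <- "loop"
  out
}

# (phi, psi) region table for the dihedral-based eight-state classifier.
# Rows are checked top to bottom; first match wins; no match -> loop.
# Boundaries are an explicit, overridable package choice, not a DSSP clone.
.rama_regions <- tibble::tibble(
  class    = c("pi_helix", "alpha_helix", "three_ten_helix",
               "beta_strand", "beta_bridge", "bend", "turn"),
  phi_min  = c(-140, -140, -140, -180, -180, -180,   30),
  phi_max  = c( -30,  -30,  -30,  -90,  -90,  -90,  100),
  psi_min  = c( -95,  -55,  -25,   85,   50,  -60,  -60),
  psi_max  = c( -55,  -25,    5,  180,   85,   30,   60)
)

#' Ramachandran region table for the dihedral-based classifier
#'
#' The (phi, psi) rectangles mapped to the eight secondary-structure
#' classes by [assign_secondary_structure()] when no DSSP report is
#' supplied. Rows are applied in order and the first match wins; dihedral
#' pairs outside every region are labelled `loop`.
#'
#' @return A tibble with columns `class`, `phi_min`, `phi_max`, `psi_min`,
#'   `psi_max` (degrees).
#' @export
rama_region_table <- function() .rama_regions

# Pharmacophore typing: (resname, atom name) -> set of classes.
# Untyped carbons fall back to hydrophobic, anything else to neutral.
.pharm_classes <- c("hydrophobic", "positive", "negative", "acceptor",
                    "donor", "aromatic", "sulphur", "neutral")

.pharm_table <- list(
  ARG = list(NE = c("positive", "donor"), NH1 = c("positive", "donor"),
             NH2 = c("positive", "donor")),
  LYS = list(NZ = c("positive", "donor")),
  HIS = list(ND1 = c("aromatic", "donor", "acceptor"),
             NE2 = c("aromatic", "donor", "acceptor"),
             CG = c("aromatic", "hydrophobic"),
             CD2 = c("aromatic", "hydrophobic"),
             CE1 = c("aromatic", "hydrophobic")),
  ASP = list(OD1 = c("negative", "acceptor"), OD2 = c("negative", "acceptor")),
  GLU = list(OE1 = c("negative", "acceptor"), OE2 = c("negative", "acceptor")),
  ASN = list(OD1 = "acceptor", ND2 = "donor"),
  GLN = list(OE1 = "acceptor", NE2 = "donor"),
  SER = list(OG = c("donor", "acceptor")),
  THR = list(OG1 = c("donor", "acceptor")),
  TYR = list(OH = c("donor", "acceptor"),
             CG = c("aromatic", "hydrophobic"), CD1 = c("aromatic", "hydrophobic"),
             CD2 = c("aromatic", "hydrophobic"), CE1 = c("aromatic", "hydrophobic"),
             CE2 = c("aromatic", "hydrophobic"), CZ = c("aromatic", "hydrophobic")),
  PHE = list(CG = c("aromatic", "hydrophobic"), CD1 = c("aromatic", "hydrophobic"),
             CD2 = c("aromatic", "hydrophobic"), CE1 = c("aromatic", "hydrophobic"),
             CE2 = c("aromatic", "hydrophobic"), CZ = c("aromatic", "hydrophobic")),
  TRP = list(NE1 = c("aromatic", "donor"),
             CG = c("aromatic", "hydrophobic"), CD1 = c("aromatic", "hydrophobic"),
             CD2 = c("aromatic", "hydrophobic"), CE2 = c("aromatic", "hydrophobic"),
             CE3 = c("aromatic", "hydrophobic"), CZ2 = c("aromatic", "hydrophobic"),
             CZ3 = c("aromatic", "hydrophobic"), CH2 = c("aromatic", "hydrophobic")),
  CYS = list(SG = "sulphur"),
  MET = list(SD = "sulphur")
)

# atoms carrying formal charge at physiological pH, for ionic / pi-cation edges
.cation_atoms <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
.anion_atoms  <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# aromatic ring member atoms, for centroid-based pi interactions
.ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# interaction geometric cutoffs (Angstrom); configurable via interaction_network()
.interaction_defaults <- c(
  hydrogen_bond = 3.5, disulfide = 2.5, ionic = 4.0,
  vdw_slack = 0.5, pi_cation = 5.0, pi_pi = 6.5
)

.interaction_types <- c("hydrogen_bond", "disulfide", "ionic", "vdw",
                        "pi_cation", "pi_pi")
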