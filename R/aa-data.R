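#' Amino acid reference tables
#'
#' Small per-residue constant tables used across the package: mean residue
#' volumes, maximal solvent-accessible surface areas, and one/three letter
#' code conversion.
#'
#' @details
#' * `aa_volumes()` returns mean amino-acid volumes in cubic Angstroms
#'   (Zamyatnin-type mean residue volumes), used for the Heaviside-split
#'   packing/cavity terms.
#' * `aa_max_asa()` returns the theoretical maximum accessible surface area
#'   per residue type (Tien et al. 2013, theoretical values, square
#'   Angstroms), the denominator of relative solvent accessibility.
#'
#' Both tables are deliberately exposed so users can swap alternatives via
#' [ms_config()].
#'
#' @return A named numeric vector keyed by one-letter amino acid code.
#' @export
#' @examples
#' aa_volumes()[["W"]] - aa_volumes()[["A"]] # tryptophan is much larger
aa_volumes <- function() {
  c(
    A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
    Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
    S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0
  )
}

#' @rdname aa_volumes
#' @export
aa_max_asa <- function() {
  c(
    A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
  )
}

#' One-letter amino acid codes in canonical order
#' @return Character vector of the 20 canonical one-letter codes.
#' @export
aa_codes <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# three-letter -> one-letter map for PDB residue names
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

aa_one_to_three <- stats::setNames(names(aa_three_to_one), aa_three_to_one)

# van der Waals radii (Angstrom) by element, for surface-area computation
element_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
default_radius <- 1.80

#' Default backbone torsion-domain partition
#'
#' A first-match partition of the (phi, psi) plane into six named regions:
#' right-handed helical, left-handed helical, extended beta, polyproline II,
#' epsilon, and a catch-all "other". Residues without both torsion angles
#' (chain termini, broken backbones) are labelled `"undefined"` downstream.
#'
#' @return A tibble with columns `domain`, `phi_min`, `phi_max`, `psi_min`,
#'   `psi_max` (degrees; intervals are half-open `[min, max)`, tried in row
#'   order, first match wins; `psi` rows may wrap around +/-180).
#' @export
torsion_domains <- function() {
  tibble::tribble(
    ~domain,     ~phi_min, ~phi_max, ~psi_min, ~psi_max,
    "helical",     -160,      -20,     -120,      50,
    "helical_L",     20,      125,      -45,      90,
    "extended",    -180,     -100,       90,     180,
    "extended",    -180,     -100,     -180,    -120,
    "ppii",        -100,      -20,       90,     180,
    "epsilon",       20,      180,       90,     180,
    "epsilon",       20,      180,     -180,     -90
  )
}

#' Torsion-domain labels (including the catch-all)
#' @return Character vector of domain labels usable as structure elements.
#' @export
torsion_domain_labels <- function() {
  unique(c(torsion_domains()$domain, "other"))
}
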