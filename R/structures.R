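#' Read one chain of a PDB file as a structure object
#'
#' Parses the ATOM records of a single chain into the residue-level
#' representation consumed by the descriptor and potential machinery.
#' Only the 20 canonical amino acids are kept; waters, hetero groups and
#' hydrogens are dropped. For alternate locations the highest-occupancy
#' conformer is kept (ties resolved toward altloc "A"). Residues missing
#' any of the N, CA, C backbone atoms are retained but flagged, and later
#' receive an `"undefined"` torsion domain.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier (single character).
#' @param id Structure identifier; defaults to the file name.
#' @param tm_wild Optional wild-type melting temperature (degrees C)
#'   attached to the structure (used by temperature-dependent potentials).
#' @param resolution Optional crystallographic resolution (Angstrom).
#' @return An object of class `ms_structure`: a list with `id`, `chain`,
#'   `tm_wild`, `resolution`, an `atoms` tibble (`residue_index`, `name`,
#'   `element`, `x`, `y`, `z`) and a `residues` tibble (`index` 0-based,
#'   `author` author-numbering string including any insertion code, `aa`,
#'   `has_backbone`).
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' s0 <- generate_structures(synth_spec(n_structures = 1, seed = 1))[[1]]
#' write_structure_pdb(s0, pdb)
#' s <- read_structure(pdb, chain = "A")
#' n_residues(s)
read_structure <- function(path, chain, id = basename(path),
                           tm_wild = NULL, resolution = NULL) {
  stopifnot(file.exists(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!chain %in% unique(at$chain)) {
    stop("chain '", chain, "' not found in ", path,
         " (available: ", paste(unique(at$chain), collapse = ", "), ")")
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at <- at[at$resid %in% names(aa_three_to_one), , drop = FALSE]
  # element from atom name; drop hydrogens
  elem <- sub("[0-9'].*$", "", sub("^[0-9]+", "", at$elety))
  elem <- substr(elem, 1, 1)
  keep <- elem %in% c("C", "N", "O", "S")
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0) stop("no parsable residues in chain '", chain, "' of ", path)

  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  author <- paste0(at$resno, ins)
  key <- paste(author, at$resid)

  # altloc: per (residue, atom name), keep highest occupancy; ties -> "A";
  # the dedup pass must not disturb file order, which defines chain order
  alt <- ifelse(is.na(at$alt) | at$alt == "", "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  pref <- order(key, at$elety, -occ, alt)
  dup_sorted <- duplicated(paste(key, at$elety)[pref])
  keep_rows <- sort(pref[!dup_sorted])
  at <- at[keep_rows, , drop = FALSE]
  elem <- elem[keep_rows]
  author <- author[keep_rows]
  key <- key[keep_rows]

  ukey <- unique(key)
  res_index <- match(key, ukey) - 1L
  atoms <- tibble::tibble(
    residue_index = res_index,
    name = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z
  )
  stopifnot(all(is.finite(c(atoms$x, atoms$y, atoms$z))))

  res_aa <- unname(aa_three_to_one[at$resid[!duplicated(key)]])
  res_author <- author[!duplicated(key)]
  has_bb <- vapply(seq_along(ukey) - 1L, function(i) {
    nm <- atoms$name[atoms$residue_index == i]
    all(c("N", "CA", "C") %in% nm)
  }, logical(1))

  residues <- tibble::tibble(
    index = seq_along(ukey) - 1L,
    author = res_author,
    aa = res_aa,
    has_backbone = has_bb
  )
  if (nrow(residues) < 2) stop("structure must contain at least 2 residues")

  new_ms_structure(id = id, chain = chain, atoms = atoms, residues = residues,
                   tm_wild = tm_wild, resolution = resolution)
}

new_ms_structure <- function(id, chain, atoms, residues,
                             tm_wild = NULL, resolution = NULL) {
  structure(
    list(id = id, chain = chain, atoms = atoms, residues = residues,
         tm_wild = tm_wild, resolution = resolution),
    class = "ms_structure"
  )
}

#' @export
print.ms_structure <- function(x, ...) {
  cat(sprintf("<ms_structure> %s chain %s: %d residues, %d atoms%s\n",
              x$id, x$chain, nrow(x$residues), nrow(x$atoms),
              if (!is.null(x$tm_wild)) sprintf(", Tm = %.1f C", x$tm_wild) else ""))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure An `ms_structure`.
#' @return Integer residue count (the chain length `N_r`).
#' @export
n_residues <- function(structure) nrow(structure$residues)

# backbone atom coordinates for residue i (or NULL)
bb_atom <- function(structure, i, name) {
  a <- structure$atoms
  row <- which(a$residue_index == i & a$name == name)
  if (length(row) == 0) return(NULL)
  c(a$x[row[1]], a$y[row[1]], a$z[row[1]])
}

#' Shrake-Rupley accessible surface area
#'
#' Computes per-atom solvent-accessible surface area by placing a
#' deterministic spiral lattice of test points on each atom's expanded
#' sphere (van der Waals radius + probe) and counting points not buried in
#' any neighbouring atom's expanded sphere.
#'
#' @param xyz Numeric matrix (n x 3) of heavy-atom coordinates (Angstrom).
#' @param elements Character vector of element symbols (C, N, O, S).
#' @param probe_radius Probe radius in Angstroms.
#' @param n_points Test points per atom.
#' @return Numeric vector of per-atom areas (square Angstroms).
#' @export
shrake_rupley <- function(xyz, elements, probe_radius = 1.4, n_points = 960) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) == length(elements))
  n <- nrow(xyz)
  radii <- unname(element_radii[elements])
  radii[is.na(radii)] <- default_radius
  rad_exp <- radii + probe_radius
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  # neighbour lists via squared distances
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (rad_exp[i] + rad_exp)^2
    nbr <- which(d2[i, ] < cutoff2)
    nbr <- nbr[nbr != i]
    p <- pts * rad_exp[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, n_points)
    for (j in nbr) {
      if (!any(accessible)) break
      dx <- p[accessible, 1] - xyz[j, 1]
      dy <- p[accessible, 2] - xyz[j, 2]
      dz <- p[accessible, 3] - xyz[j, 3]
      buried <- (dx * dx + dy * dy + dz * dz) < rad_exp[j]^2
      accessible[accessible] <- !buried
    }
    areas[i] <- 4 * pi * rad_exp[i]^2 * sum(accessible) / n_points
  }
  areas
}

# max-ASA table derived from the package's own extended Gly-X-Gly reference
# in the reduced (N, CA, C, O, CB) representation; memoised per parameters
.computed_asa_cache <- new.env(parent = emptyenv())

computed_max_asa <- function(probe_radius = 1.4, n_sphere_points = 960) {
  key <- paste(probe_radius, n_sphere_points)
  if (!is.null(.computed_asa_cache[[key]])) return(.computed_asa_cache[[key]])
  vals <- vapply(aa_codes(), function(aa) {
    s <- build_backbone(c("G", aa, "G"),
                        phi = rep(-139, 3), psi = rep(135, 3))
    xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
    area <- shrake_rupley(xyz, s$atoms$element,
                          probe_radius = probe_radius,
                          n_points = n_sphere_points)
    sum(area[s$atoms$residue_index == 1L])
  }, numeric(1))
  .computed_asa_cache[[key]] <- vals
  vals
}

#' Per-residue sequence/structure descriptors
#'
#' Computes, for every residue of a parsed structure: relative solvent
#' accessibility (percent of the per-amino-acid maximal area), the backbone
#' torsion domain from (phi, psi), the accessibility bin label, and the
#' side-chain centroid (geometric mean of side-chain heavy atoms; CA for
#' glycine). Chain termini and residues with incomplete backbones get
#' torsion domain `"undefined"`. Deterministic: same file and configuration
#' give bit-identical output.
#'
#' @param structure An `ms_structure`.
#' @param config An [ms_config()].
#' @return A tibble with columns `index`, `author`, `aa`, `rsa`,
#'   `torsion_domain`, `acc_bin`, `cx`, `cy`, `cz`.
#' @export
residue_descriptors <- function(structure, config = ms_config()) {
  res <- structure$residues
  atoms <- structure$atoms
  n <- nrow(res)

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  area <- shrake_rupley(xyz, atoms$element,
                        probe_radius = config$probe_radius,
                        n_points = config$n_sphere_points)
  res_area <- vapply(res$index, function(i) sum(area[atoms$residue_index == i]),
                     numeric(1))
  rsa <- 100 * res_area / unname(config$max_asa[res$aa])
  rsa <- pmin(pmax(rsa, 0), 100)

  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    i <- res$index[k]
    if (!res$has_backbone[k]) next
    Ni <- bb_atom(structure, i, "N"); CAi <- bb_atom(structure, i, "CA")
    Ci <- bb_atom(structure, i, "C")
    if (k > 1 && res$has_backbone[k - 1]) {
      Cprev <- bb_atom(structure, res$index[k - 1], "C")
      phi[k] <- dihedral_angle(Cprev, Ni, CAi, Ci)
    }
    if (k < n && res$has_backbone[k + 1]) {
      Nnext <- bb_atom(structure, res$index[k + 1], "N")
      psi[k] <- dihedral_angle(Ni, CAi, Ci, Nnext)
    }
  }
  tdom <- assign_torsion_domain(phi, psi, config$domains)

  centroid <- t(vapply(seq_len(n), function(k) {
    i <- res$index[k]
    rows <- atoms$residue_index == i &
      !(atoms$name %in% c("N", "CA", "C", "O", "OXT"))
    if (!any(rows)) rows <- atoms$residue_index == i & atoms$name == "CA"
    if (!any(rows)) rows <- atoms$residue_index == i
    colMeans(as.matrix(atoms[rows, c("x", "y", "z")]))
  }, numeric(3)))

  tibble::tibble(
    index = res$index, author = res$author, aa = res$aa,
    rsa = rsa, torsion_domain = tdom,
    acc_bin = acc_bin(rsa, config),
    cx = centroid[, 1], cy = centroid[, 2], cz = centroid[, 3]
  )
}

# vectorised first-match lookup in the torsion-domain table
assign_torsion_domain <- function(phi, psi, domains = torsion_domains()) {
  out <- rep("other", length(phi))
  undef <- is.na(phi) | is.na(psi)
  assigned <- rep(FALSE, length(phi))
  for (r in seq_len(nrow(domains))) {
    hit <- !undef & !assigned &
      phi >= domains$phi_min[r] & phi < domains$phi_max[r] &
      psi >= domains$psi_min[r] & psi < domains$psi_max[r]
    out[hit] <- domains$domain[r]
    assigned <- assigned | hit
  }
  out[undef] <- "undefined"
  out
}

#' In-range residue pairs with binned side-chain distances
#'
#' Enumerates residue pairs `(i, j)` with `i < j`, sequence separation at
#' least `config$min_separation`, and side-chain centroid distance inside
#' the configured `[d_min, d_max)` window; each gets a 0-based uniform
#' distance-bin index. Out-of-range pairs are excluded entirely.
#'
#' @param structure An `ms_structure`.
#' @param config An [ms_config()].
#' @param descriptors Optional precomputed [residue_descriptors()] output
#'   (recomputed when missing).
#' @return A tibble with columns `i`, `j` (0-based residue indices),
#'   `distance` (Angstrom) and `bin` (0-based).
#' @export
residue_pairs <- function(structure, config = ms_config(),
                          descriptors = NULL) {
  if (is.null(descriptors)) descriptors <- residue_descriptors(structure, config)
  cen <- as.matrix(descriptors[, c("cx", "cy", "cz")])
  n <- nrow(cen)
  if (n < 2) {
    return(tibble::tibble(i = integer(), j = integer(),
                          distance = numeric(), bin = integer()))
  }
  dm <- as.matrix(stats::dist(cen))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  i <- descriptors$index[idx[, 1]]
  j <- descriptors$index[idx[, 2]]
  d <- dm[idx]
  keep <- abs(j - i) >= config$min_separation &
    d >= config$d_min & d < config$d_max
  tibble::tibble(
    i = i[keep], j = j[keep], distance = d[keep],
    bin = distance_bin(d[keep], config)
  )
}

#' Attach descriptors and pairs to a structure
#'
#' Convenience wrapper computing [residue_descriptors()] and
#' [residue_pairs()] once and caching them on the object together with the
#' configuration hash, so potential derivation and featurization reuse
#' them.
#'
#' @inheritParams residue_descriptors
#' @return The structure with `$descriptors`, `$pairs` and `$config_hash`
#'   fields set.
#' @export
describe_structure <- function(structure, config = ms_config()) {
  h <- config_hash(config)
  if (!is.null(structure$config_hash) && identical(structure$config_hash, h)) {
    return(structure)
  }
  structure$descriptors <- residue_descriptors(structure, config)
  structure$pairs <- residue_pairs(structure, config, structure$descriptors)
  structure$config_hash <- h
  structure
}
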