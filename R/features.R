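# Turning one point mutation on a wild-type structure into the model's
# input vector. Mutant energies are evaluated on unchanged wild-type
# geometry: only the mutated position's sequence element changes, so every
# potential term not touching that position cancels exactly in the
# difference and is never computed.

#' Heaviside-split residue volume change
#'
#' The volume difference `dV = V(mut) - V(wt)` (cubic Angstroms, from the
#' configured residue-volume table) split into its positive part (packing
#' stress added) and negative part (cavity created); exactly one of the
#' two is nonzero unless `dV = 0`.
#'
#' @param wt,mut One-letter amino acid codes (vectorized).
#' @param volumes Named volume table, defaults to [aa_volumes()].
#' @return A tibble with columns `dv_plus`, `dv_minus` (both >= 0).
#' @export
#' @examples
#' volume_terms("A", "W") # large positive dv_plus, zero dv_minus
volume_terms <- function(wt, mut, volumes = aa_volumes()) {
  if (!all(wt %in% names(volumes)) || !all(mut %in% names(volumes))) {
    bad <- setdiff(c(wt, mut), names(volumes))
    stop("unknown amino acid(s): ", paste(bad, collapse = ", "))
  }
  dv <- unname(volumes[mut] - volumes[wt])
  tibble::tibble(dv_plus = pmax(dv, 0), dv_minus = pmax(-dv, 0))
}

# energy lookup helper: rows of labels -> energies (0 for any NA label)
lookup_energy <- function(energy, labels) {
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1)
  if (nrow(labels) == 0) return(numeric(0))
  dn <- dimnames(energy)
  idx <- vapply(seq_along(dn), function(k) match(labels[, k], dn[[k]]),
                integer(nrow(labels)))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  ok <- stats::complete.cases(idx)
  out <- numeric(nrow(labels))
  out[ok] <- energy[idx[ok, , drop = FALSE]]
  out
}

# change in one potential's total energy when residue p's amino acid is
# switched wt -> mut, everything else fixed. `desc` must be the wild-type
# descriptor table, `touch` the precomputed pairs touching p (columns
# `other` = partner residue row, `db` = distance-bin label).
delta_energy_one <- function(pot, desc, touch, p_row, wt, mut) {
  if (!is.null(pot$components)) {
    return(sum(vapply(pot$components, delta_energy_one, numeric(1),
                      desc = desc, touch = touch, p_row = p_row,
                      wt = wt, mut = mut)))
  }
  e <- pot$energy
  ab <- desc$acc_bin
  td <- ifelse(desc$torsion_domain == "undefined", NA_character_,
               desc$torsion_domain)
  ap <- ab[p_row]
  tp <- td[p_row]
  o <- touch$other
  db <- touch$db
  diff_sum <- function(mut_labels, wt_labels) {
    sum(lookup_energy(e, mut_labels)) - sum(lookup_energy(e, wt_labels))
  }
  switch(pot$id,
    sa = if (is.na(ap)) 0 else diff_sum(c(mut, ap), c(wt, ap)),
    st = if (is.na(tp)) 0 else diff_sum(c(mut, tp), c(wt, tp)),
    sd = diff_sum(cbind(mut, db), cbind(wt, db)),
    sds = diff_sum(rbind(cbind(mut, db, desc$aa[o]),
                         cbind(desc$aa[o], db, mut)),
                   rbind(cbind(wt, db, desc$aa[o]),
                         cbind(desc$aa[o], db, wt))),
    sad = diff_sum(cbind(mut, ap, db), cbind(wt, ap, db)),
    std = diff_sum(cbind(mut, tp, db), cbind(wt, tp, db)),
    saa = diff_sum(cbind(mut, ap, ab[o]), cbind(wt, ap, ab[o])),
    stt = diff_sum(cbind(mut, tp, td[o]), cbind(wt, tp, td[o])),
    sst = diff_sum(rbind(cbind(mut, desc$aa[o], td[o]),
                         cbind(desc$aa[o], mut, tp)),
                   rbind(cbind(wt, desc$aa[o], td[o]),
                         cbind(desc$aa[o], wt, tp))),
    stop("unknown potential id: ", pot$id)
  )
}

#' Per-potential energy changes for one mutation
#'
#' For every potential of a set, computes the difference between the
#' structure's total energy with the mutated position's sequence element
#' set to the mutant amino acid and its wild-type total, on fixed
#' wild-type geometry. Terms whose sequence slots do not involve the
#' mutated position cancel exactly and are skipped.
#'
#' @param structure An `ms_structure` (descriptors are computed/cached).
#' @param position Author-numbering position string of the mutated
#'   residue.
#' @param wt,mut Wild-type and mutant one-letter amino acid codes.
#' @param set An `ms_potentials`.
#' @param config The [ms_config()] the set was derived with.
#' @return Named numeric vector of delta-delta-W values (kT), one per
#'   potential id in the set.
#' @export
mutation_delta_energy <- function(structure, position, wt, mut, set,
                                  config = ms_config()) {
  structure <- describe_structure(structure, config)
  if (!identical(structure$config_hash, set$config_hash)) {
    warning("potential set and descriptor configuration hashes differ")
  }
  desc <- structure$descriptors
  p_row <- which(desc$author == as.character(position))
  if (length(p_row) != 1) {
    stop("position ", position, " not found in ", structure$id,
         " chain ", structure$chain, " (author numbering)")
  }
  if (desc$aa[p_row] != wt) {
    stop("wild-type mismatch at author position ", position, " of ",
         structure$id, ": structure has ", desc$aa[p_row], ", record says ", wt)
  }
  pr <- structure$pairs
  p_idx <- desc$index[p_row]
  hit <- pr$i == p_idx | pr$j == p_idx
  other_idx <- ifelse(pr$i[hit] == p_idx, pr$j[hit], pr$i[hit])
  touch <- list(other = match(other_idx, desc$index),
                db = paste0("d", pr$bin[hit] + 1L))
  vapply(set$potentials, delta_energy_one, numeric(1),
         desc = desc, touch = touch, p_row = p_row, wt = wt, mut = mut)
}

#' Featurize a table of point mutations
#'
#' Turns each mutation record into the prediction models' input vector:
#' the nine standard-potential energy changes, the five mesostable and
#' five thermostable grouped-potential energy changes (when those sets are
#' supplied), the Heaviside volume terms, the wild-type residue's relative
#' solvent accessibility `acc`, the chain length `n_res`, and `tm_wild`.
#'
#' @param mutations Tibble with columns `protein_id`, `chain`, `position`,
#'   `wt`, `mut`, and optionally `tm_wild` plus any metadata columns
#'   (carried through unchanged).
#' @param structures Named list of `ms_structure` keyed by `protein_id`
#'   (an unnamed list is keyed by each structure's `id`).
#' @param std Standard `ms_potentials` (9 potentials).
#' @param meso,thermo Optional temperature-dependent `ms_potentials`
#'   (5 grouped potentials each).
#' @param config The [ms_config()] shared by descriptors and potentials.
#' @return The input tibble with feature columns appended: `ddw_<id>` for
#'   the standard forms, `ddw_meso_<id>` / `ddw_thermo_<id>` for the
#'   grouped forms, `dv_plus`, `dv_minus`, `acc`, `n_res`, `tm_wild`.
#' @export
featurize_mutations <- function(mutations, structures, std,
                                meso = NULL, thermo = NULL,
                                config = ms_config()) {
  stopifnot(all(c("protein_id", "position", "wt", "mut") %in%
                  names(mutations)))
  if (is.null(names(structures)) || any(names(structures) == "")) {
    names(structures) <- vapply(structures, function(s) s$id, character(1))
  }
  missing_ids <- setdiff(unique(mutations$protein_id), names(structures))
  if (length(missing_ids) > 0) {
    stop("no structure supplied for: ", paste(missing_ids, collapse = ", "))
  }
  structures <- lapply(structures, describe_structure, config = config)

  sets <- list(std = std)
  if (!is.null(meso)) sets$meso <- meso
  if (!is.null(thermo)) sets$thermo <- thermo

  feat_rows <- purrr::pmap(
    list(mutations$protein_id, mutations$position, mutations$wt,
         mutations$mut),
    function(pid, pos, wt, mut) {
      s <- structures[[pid]]
      out <- list()
      for (nm in names(sets)) {
        dd <- mutation_delta_energy(s, pos, wt, mut, sets[[nm]], config)
        prefix <- if (nm == "std") "ddw_" else paste0("ddw_", nm, "_")
        names(dd) <- paste0(prefix, names(dd))
        out <- c(out, as.list(dd))
      }
      p_row <- which(s$descriptors$author == as.character(pos))
      out$acc <- s$descriptors$rsa[p_row]
      out$n_res <- n_residues(s)
      tibble::as_tibble(out)
    })
  feats <- dplyr::bind_cols(mutations, dplyr::bind_rows(feat_rows))
  vt <- volume_terms(mutations$wt, mutations$mut, config$volumes)
  feats$dv_plus <- vt$dv_plus
  feats$dv_minus <- vt$dv_minus
  if (!"tm_wild" %in% names(feats)) {
    feats$tm_wild <- vapply(feats$protein_id, function(pid) {
      tm <- structures[[pid]]$tm_wild
      if (is.null(tm)) NA_real_ else tm
    }, numeric(1))
  }
  feats
}

# feature column names expected by each model
hot_feature_cols <- function() {
  c(paste0("ddw_", standard_potential_ids()), "dv_plus", "dv_minus")
}

tm_hot_feature_cols <- function() {
  list(meso = paste0("ddw_meso_", t_dependent_potential_ids()),
       thermo = paste0("ddw_thermo_", t_dependent_potential_ids()),
       vol = c("dv_plus", "dv_minus"))
}
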