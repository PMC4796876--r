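#' Specification for synthetic benchmark data
#'
#' Collects every knob of the synthetic generator: structures are built
#' with ideal backbone geometry as a configurable mix of helical and
#' extended segments, sequences are drawn with a controllable
#' sequence-structure coupling, and mutation datasets are generated from a
#' planted prediction model plus Gaussian noise. Everything is
#' deterministic under `seed`.
#'
#' @param n_structures Number of structures to generate.
#' @param chain_length_range Integer `(min, max)` residues per chain.
#' @param coupling Real in `[0, 1]`: 0 draws amino acids independently of
#'   local structure; 1 always draws them from a torsion-domain-biased
#'   distribution.
#' @param tm_range `(min, max)` wild-type melting temperatures (degrees C)
#'   assigned to the structures.
#' @param noise_sd Gaussian noise (degrees C) added to planted delta-Tm
#'   targets.
#' @param n_mutations Number of mutations for [generate_mutations()].
#' @param seed Integer seed; identical specs give byte-identical output.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_structures = 10, chain_length_range = c(30, 60),
                       coupling = 0.5, tm_range = c(40, 90),
                       noise_sd = 2, n_mutations = 500, seed = 42) {
  stopifnot(n_structures >= 1, length(chain_length_range) == 2,
            chain_length_range[1] <= chain_length_range[2],
            chain_length_range[1] >= 5,
            coupling >= 0, coupling <= 1,
            tm_range[1] <= tm_range[2], noise_sd >= 0, n_mutations >= 1)
  structure(list(n_structures = as.integer(n_structures),
                 chain_length_range = as.integer(chain_length_range),
                 coupling = coupling, tm_range = tm_range,
                 noise_sd = noise_sd, n_mutations = as.integer(n_mutations),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# ideal peptide geometry constants (Angstrom / degrees)
.geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, dih_cb = -122.6
)

# canonical (phi, psi) per secondary-structure state
ideal_phi_psi <- function(state) {
  switch(state,
         helix = c(-57, -47),
         strand = c(-139, 135),
         stop("unknown state: ", state))
}

#' Build a polypeptide with ideal backbone geometry
#'
#' Constructs N, CA, C, O atoms plus a CB pseudo-side-chain atom (omitted
#' for glycine) from per-residue (phi, psi) torsions using standard bond
#' lengths and angles, with omega fixed at 180 degrees.
#'
#' @param sequence Character vector of one-letter amino acids.
#' @param phi,psi Numeric vectors of torsions in degrees (phi of the first
#'   and psi of the last residue only orient terminal atoms).
#' @param id,chain Identifier and chain label for the resulting structure.
#' @param tm_wild Optional melting temperature annotation (degrees C).
#' @param gly_cb Give glycine a CB pseudo-atom too (default TRUE): the CB
#'   here is a pseudo-side-chain centroid, not a chemical atom, and a
#'   uniform representation keeps the geometry independent of the
#'   sequence (so decoupled corpora really are decoupled).
#' @return An `ms_structure`.
#' @export
build_backbone <- function(sequence, phi, psi, id = "model", chain = "A",
                           tm_wild = NULL, gly_cb = TRUE) {
  n <- length(sequence)
  stopifnot(n >= 2, length(phi) == n, length(psi) == n,
            all(sequence %in% aa_codes()))
  g <- .geom
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         g$c_n, g$ang_ca_c_n, psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          g$n_ca, g$ang_c_n_ca, 180)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         g$ca_c, g$ang_n_ca_c, phi[i])
  }
  rows <- list()
  for (i in seq_len(n)) {
    O <- place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o,
                    psi[i] + 180)
    res_atoms <- rbind(
      data.frame(name = "N", element = "N", x = N[[i]][1], y = N[[i]][2], z = N[[i]][3]),
      data.frame(name = "CA", element = "C", x = CA[[i]][1], y = CA[[i]][2], z = CA[[i]][3]),
      data.frame(name = "C", element = "C", x = C[[i]][1], y = C[[i]][2], z = C[[i]][3]),
      data.frame(name = "O", element = "O", x = O[1], y = O[2], z = O[3])
    )
    if (sequence[i] != "G" || gly_cb) {
      CB <- place_atom(C[[i]], N[[i]], CA[[i]], g$ca_cb, g$ang_n_ca_cb,
                       g$dih_cb)
      res_atoms <- rbind(res_atoms,
                         data.frame(name = "CB", element = "C",
                                    x = CB[1], y = CB[2], z = CB[3]))
    }
    res_atoms$residue_index <- i - 1L
    rows[[i]] <- res_atoms
  }
  atoms <- dplyr::bind_rows(rows)
  atoms <- tibble::as_tibble(atoms[, c("residue_index", "name", "element",
                                       "x", "y", "z")])
  residues <- tibble::tibble(index = seq_len(n) - 1L,
                             author = as.character(seq_len(n)),
                             aa = sequence, has_backbone = TRUE)
  new_ms_structure(id = id, chain = chain, atoms = atoms,
                   residues = residues, tm_wild = tm_wild)
}

# torsion-domain-biased amino acid distributions used when coupling > 0
.biased_aa <- list(
  helix = c(A = 4, L = 4, E = 3, K = 3, M = 2, Q = 2, R = 2),
  strand = c(V = 4, I = 4, F = 3, Y = 3, T = 2, W = 2, C = 1)
)

sample_sequence <- function(states, coupling) {
  n <- length(states)
  aa <- character(n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < coupling) {
      w <- .biased_aa[[states[i]]]
      pool <- names(w)
      aa[i] <- sample(pool, 1, prob = w)
    } else {
      aa[i] <- sample(aa_codes(), 1)
    }
  }
  aa
}

#' Generate synthetic protein structures
#'
#' Each structure is a single chain of alternating helical and extended
#' segments (segment lengths 6-14 residues) built with ideal geometry and
#' small torsion jitter (sd 8 degrees), carrying a melting-temperature
#' annotation drawn uniformly from `spec$tm_range`. With `coupling = 0`
#' amino acid types are independent of the local backbone state, which
#' makes all derived mean-force potentials vanish in the large-sample
#' limit.
#'
#' @param spec A [synth_spec()].
#' @return A list of `ms_structure` objects.
#' @export
#' @examples
#' ss <- generate_structures(synth_spec(n_structures = 2, seed = 7))
#' vapply(ss, n_residues, integer(1))
generate_structures <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_structures), function(k) {
      lens <- seq(spec$chain_length_range[1], spec$chain_length_range[2])
      len <- lens[sample.int(length(lens), 1)]
      states <- character(0)
      cur <- sample(c("helix", "strand"), 1)
      while (length(states) < len) {
        seg <- sample(6:14, 1)
        states <- c(states, rep(cur, seg))
        cur <- if (cur == "helix") "strand" else "helix"
      }
      states <- states[seq_len(len)]
      base <- vapply(states, ideal_phi_psi, numeric(2))
      phi <- base[1, ] + stats::rnorm(len, 0, 8)
      psi <- base[2, ] + stats::rnorm(len, 0, 8)
      aa <- sample_sequence(states, spec$coupling)
      tm <- stats::runif(1, spec$tm_range[1], spec$tm_range[2])
      build_backbone(aa, phi, psi, id = sprintf("synth%03d", k),
                     tm_wild = tm)
    })
  })
}

#' Write a structure as a PDB file
#'
#' @param structure An `ms_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  a <- structure$atoms
  res <- structure$residues
  resno <- res$index[match(a$residue_index, res$index)] + 1L
  resid <- unname(aa_one_to_three[res$aa[match(a$residue_index, res$index)]])
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = resno, resid = resid,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = rep(structure$chain, nrow(a)),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}

#' Generate a planted-model mutation dataset
#'
#' Samples random single-point mutations over the supplied structures,
#' featurizes them against the supplied potential sets, computes the
#' noiseless planted delta-Tm with the truth model, and adds Gaussian
#' noise of sd `spec$noise_sd`. Metadata columns (resolution, monomeric,
#' denaturant, two-state flags, pH) are set so that [filter_mutations()]
#' keeps every record.
#'
#' @param structures List of `ms_structure` (with `tm_wild` set).
#' @param truth A `ms_hot_params` or `ms_tm_hot_params` truth model.
#' @param std,meso,thermo Potential sets from [derive_potentials()] /
#'   [derive_t_potentials()], derived from the same structures.
#' @param spec A [synth_spec()] (`n_mutations`, `noise_sd`, `seed` used).
#' @param config The [ms_config()] the potentials were derived with.
#' @return A tibble: one row per mutation with record columns
#'   (`protein_id`, `chain`, `position`, `wt`, `mut`, `dtm_true`,
#'   `dtm_exp`, `tm_wild`, `ph`, `resolution`, flags) and all feature
#'   columns from [featurize_mutations()].
#' @export
generate_mutations <- function(structures, truth, std, meso = NULL,
                               thermo = NULL, spec = synth_spec(),
                               config = ms_config()) {
  stopifnot(inherits(spec, "synth_spec"))
  names(structures) <- vapply(structures, function(s) s$id, character(1))
  muts <- withr::with_seed(spec$seed + 1000003L, {
    ids <- sample(names(structures), spec$n_mutations, replace = TRUE)
    purrr::map2_dfr(ids, seq_len(spec$n_mutations), function(id, k) {
      s <- structures[[id]]
      pos <- sample(seq_len(n_residues(s)), 1)
      wt <- s$residues$aa[pos]
      mut <- sample(setdiff(aa_codes(), wt), 1)
      tibble::tibble(protein_id = id, chain = s$chain,
                     position = s$residues$author[pos], wt = wt, mut = mut,
                     tm_wild = s$tm_wild, ph = 7, resolution = 1.8,
                     monomeric = TRUE, no_denaturant = TRUE,
                     two_state = TRUE, n_sites = 1L)
    })
  })
  feats <- featurize_mutations(muts, structures, std = std, meso = meso,
                               thermo = thermo, config = config)
  dtm_true <- predict_planted(truth, feats)
  noise <- withr::with_seed(spec$seed + 2000003L,
                            stats::rnorm(nrow(feats), 0, spec$noise_sd))
  feats$dtm_true <- dtm_true
  feats$dtm_exp <- dtm_true + noise
  feats
}

# evaluate the planted truth model on a feature table
predict_planted <- function(truth, features) {
  if (inherits(truth, "ms_hot_params")) {
    predict_hot(truth, features)
  } else if (inherits(truth, "ms_tm_hot_params")) {
    predict_tm_hot(truth, features)
  } else {
    stop("truth must be ms_hot_params or ms_tm_hot_params")
  }
}

#' Moderate planted truth models for synthetic benchmarks
#'
#' Random but moderate parameter draws used as the planted model of
#' synthetic mutation datasets: sigmoid steepness around 0.1 per percent
#' accessibility so that core and surface weights differ visibly, weight
#' amplitudes of order 1.
#'
#' @param seed Integer seed.
#' @return `planted_hot_params()`: an `ms_hot_params`;
#'   `planted_tm_hot_params()`: an `ms_tm_hot_params`.
#' @export
planted_hot_params <- function(seed = 1) {
  withr::with_seed(seed, {
    w <- cbind(phi = stats::rnorm(12, 0, 1),
               r = stats::rnorm(12, 0, 1),
               omega = stats::runif(12, 0.05, 0.15),
               b = stats::runif(12, 20, 60))
    hot_params(weights = w, a = 1, c = stats::rnorm(1, 0, 0.5))
  })
}

#' @rdname planted_hot_params
#' @export
planted_tm_hot_params <- function(seed = 1) {
  withr::with_seed(seed, {
    mk <- function(n) cbind(phi = stats::rnorm(n, 0, 1),
                            r = stats::rnorm(n, 0, 1),
                            omega = stats::runif(n, 0.05, 0.15),
                            b = stats::runif(n, 20, 60))
    f <- rbind(M = c(0.5, 0.004, 0, 2, 0.01),
               T = c(0.5, 0.004, 0, 2, 0.01),
               V = c(0.3, 0.002, 0, 1, 0.005))
    colnames(f) <- paste0("q", 0:4)
    tm_hot_params(meso_weights = mk(5), thermo_weights = mk(5),
                  vol_ind_weights = mk(3), f_coef = f)
  })
}
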