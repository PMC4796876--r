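# Knowledge-based mean-force potentials.
#
# A potential is a table of effective energies (kT units, with kT set to 1;
# all absolute scaling is supplied downstream by the trained weights) over
# tuples of sequence elements s (amino acid type) and structure elements:
# binned side-chain distance d, accessibility bin a, torsion domain t.
# Energies are minus the log of a sparse-corrected ratio of observed to
# expected tuple frequencies counted over a structure set.

# element types for each potential form; "s" axes are sequence slots
potential_elements <- list(
  sd  = c("s", "d"),
  sds = c("s", "d", "s"),
  sad = c("s", "a", "d"),
  std = c("s", "t", "d"),
  sa  = c("s", "a"),
  saa = c("s", "a", "a"),
  st  = c("s", "t"),
  stt = c("s", "t", "t"),
  sst = c("s", "s", "t")
)

#' Potential identifiers
#' @return `standard_potential_ids()`: the 9 temperature-independent
#'   potential form ids; `t_dependent_potential_ids()`: the 5 grouped
#'   temperature-dependent potential ids.
#' @export
standard_potential_ids <- function() names(potential_elements)

#' @rdname standard_potential_ids
#' @export
t_dependent_potential_ids <- function() c("sd", "sds", "sad", "acc", "tors")

element_levels <- function(type, config) {
  switch(type,
         s = aa_codes(),
         d = d_bin_labels(config),
         a = acc_bin_labels(config),
         t = torsion_domain_labels(),
         stop("unknown element type: ", type))
}

# per-structure contribution label matrix for one potential form; each row
# is one counted tuple. Pair-based forms contribute both ordered directions
# of every in-range pair; residues with undefined structure elements are
# skipped for forms that need them.
contribution_labels <- function(id, desc, pairs, config) {
  aa <- desc$aa
  ab <- desc$acc_bin
  td <- ifelse(desc$torsion_domain == "undefined", NA_character_,
               desc$torsion_domain)
  i <- match(pairs$i, desc$index)
  j <- match(pairs$j, desc$index)
  db <- paste0("d", pairs$bin + 1L)
  m <- switch(id,
    sa  = cbind(aa, ab),
    st  = cbind(aa, td),
    sd  = rbind(cbind(aa[i], db), cbind(aa[j], db)),
    sds = rbind(cbind(aa[i], db, aa[j]), cbind(aa[j], db, aa[i])),
    sad = rbind(cbind(aa[i], ab[i], db), cbind(aa[j], ab[j], db)),
    std = rbind(cbind(aa[i], td[i], db), cbind(aa[j], td[j], db)),
    saa = rbind(cbind(aa[i], ab[i], ab[j]), cbind(aa[j], ab[j], ab[i])),
    stt = rbind(cbind(aa[i], td[i], td[j]), cbind(aa[j], td[j], td[i])),
    sst = rbind(cbind(aa[i], aa[j], td[j]), cbind(aa[j], aa[i], td[i])),
    stop("unknown potential id: ", id)
  )
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Count sequence/structure element associations over a structure set
#'
#' Accumulates the joint occurrence counts of one potential form's element
#' tuples over all residues (per-residue forms) or all in-range residue
#' pairs, both ordered directions (pair forms), across a list of
#' structures. All marginals needed by the mean-force formulas are derived
#' from the returned joint array.
#'
#' @param structures List of `ms_structure` objects.
#' @param id Potential form id, one of [standard_potential_ids()].
#' @param config An [ms_config()].
#' @return An object of class `ms_freq`: list with `id`, `elements`,
#'   `counts` (named array) and `n_total`.
#' @export
count_frequencies <- function(structures, id, config = ms_config()) {
  stopifnot(length(structures) >= 1)
  elements <- potential_elements[[id]]
  if (is.null(elements)) stop("unknown potential id: ", id)
  lv <- lapply(elements, element_levels, config = config)
  labs <- lapply(structures, function(s) {
    s <- describe_structure(s, config)
    contribution_labels(id, s$descriptors, s$pairs, config)
  })
  m <- do.call(rbind, labs)
  fs <- lapply(seq_along(lv), function(k) factor(m[, k], levels = lv[[k]]))
  counts <- do.call(table, fs)
  counts <- array(as.numeric(counts), dim = dim(counts),
                  dimnames = stats::setNames(lv, elements_axis_names(elements)))
  structure(list(id = id, elements = elements, counts = counts,
                 n_total = sum(counts)),
            class = "ms_freq")
}

# unique axis names for dimnames (repeated element types get suffixes)
elements_axis_names <- function(elements) {
  make.unique(elements, sep = "")
}

#' Shrink an observed frequency ratio toward 1 for sparse data
#'
#' With few observations the raw observed/expected ratio is unreliable;
#' it is replaced by a pseudocount-weighted average of the raw ratio and
#' the uninformative value 1, so the corresponding energy shrinks toward 0.
#'
#' @param raw_ratio Observed/expected frequency ratio (non-negative).
#' @param n_eff Number of observations behind the ratio.
#' @param n0 Pseudocount weight (default 10).
#' @return `(n_eff * raw_ratio + n0) / (n_eff + n0)`.
#' @export
#' @examples
#' sparse_correct(2, n_eff = 10, n0 = 10) # 1.5
#' sparse_correct(2, n_eff = 0)           # 1: no data, prior wins
sparse_correct <- function(raw_ratio, n_eff, n0 = 10) {
  stopifnot(all(n_eff >= 0))
  if (n0 == 0) return(raw_ratio)
  (n_eff * raw_ratio + n0) / (n_eff + n0)
}

#' Mean-force energy table from a frequency table
#'
#' For a two-element form the energy is `-ln(F(c,s) / (F(c) F(s)))`; for a
#' three-element form it is minus the log of
#' `F(x,y,z) F(x) F(y) F(z) / (F(x,y) F(y,z) F(x,z))` (joint times singles
#' over pairs), all relative frequencies taken from the joint count array.
#' The ratio is sparse-corrected with the configured pseudocount before the
#' log, which keeps every energy finite (a cell with zero observations gets
#' ratio 1, energy 0).
#'
#' @param freq An `ms_freq` from [count_frequencies()].
#' @param config An [ms_config()]; `config$pseudocount` is the n0 weight.
#' @param correct Apply the sparse-data correction (default TRUE). With
#'   `FALSE`, empty cells produce infinite energies.
#' @return A numeric array of energies (kT), same shape as `freq$counts`.
#' @export
pmf_table <- function(freq, config = ms_config(), correct = TRUE) {
  n <- freq$counts
  N <- sum(n)
  stopifnot(N > 0)
  nd <- length(dim(n))
  if (nd == 2) {
    n1 <- rowSums(n)
    n2 <- colSums(n)
    expected <- outer(n1, n2) / N
    raw <- n / expected
  } else if (nd == 3) {
    d <- dim(n)
    n1 <- apply(n, 1, sum); n2 <- apply(n, 2, sum); n3 <- apply(n, 3, sum)
    n12 <- apply(n, c(1, 2), sum)
    n13 <- apply(n, c(1, 3), sum)
    n23 <- apply(n, c(2, 3), sum)
    i1 <- slice.index(n, 1); i2 <- slice.index(n, 2); i3 <- slice.index(n, 3)
    num <- n * n1[i1] * n2[i2] * n3[i3]
    den <- N * array(n12[cbind(as.vector(i1), as.vector(i2))], d) *
      array(n23[cbind(as.vector(i2), as.vector(i3))], d) *
      array(n13[cbind(as.vector(i1), as.vector(i3))], d)
    raw <- num / den
  } else {
    stop("only 2- and 3-element forms are supported")
  }
  raw[n == 0] <- 0
  raw[!is.finite(raw)] <- 0
  ratio <- if (correct) sparse_correct(raw, n, config$pseudocount) else raw
  e <- -log(ratio)
  dimnames(e) <- dimnames(n)
  e
}

#' Smooth a potential along its distance axis
#'
#' Convolves the energies of a distance-type potential with a symmetric
#' triangular window along the distance-bin axis (edge-renormalized so a
#' constant table is unchanged); all other axes, and potentials without a
#' distance axis, are untouched.
#'
#' @param energy Numeric array of energies with named axes.
#' @param elements Element-type vector of the potential form (to locate
#'   the `"d"` axis).
#' @param halfwidth Window half-width in bins; 0 is the identity.
#' @return The smoothed array.
#' @export
smooth_distance_potential <- function(energy, elements, halfwidth = 2) {
  axis <- which(elements == "d")
  if (length(axis) == 0 || halfwidth == 0) return(energy)
  w <- (halfwidth + 1) - abs(seq(-halfwidth, halfwidth))
  nb <- dim(energy)[axis]
  sm <- function(v) {
    out <- numeric(nb)
    for (b in seq_len(nb)) {
      lo <- max(1L, b - halfwidth); hi <- min(nb, b + halfwidth)
      ww <- w[(lo - b + halfwidth + 1):(hi - b + halfwidth + 1)]
      out[b] <- sum(v[lo:hi] * ww) / sum(ww)
    }
    out
  }
  others <- setdiff(seq_along(dim(energy)), axis)
  res <- apply(energy, others, sm)
  perm <- order(c(axis, others))
  out <- aperm(res, perm)
  dimnames(out) <- dimnames(energy)
  out
}

new_potential <- function(id, elements, counts, energy) {
  list(id = id, elements = elements, counts = counts, energy = energy)
}

new_potential_set <- function(name, potentials, config, structures) {
  structure(list(
    name = name, potentials = potentials,
    config_hash = config_hash(config),
    n_structures = length(structures),
    structure_ids = vapply(structures, function(s) s$id, character(1))
  ), class = "ms_potentials")
}

#' @export
print.ms_potentials <- function(x, ...) {
  cat(sprintf("<ms_potentials> %s: %s\n  from %d structures; config %s\n",
              x$name, paste(names(x$potentials), collapse = ", "),
              x$n_structures, x$config_hash))
  invisible(x)
}

#' Derive the nine standard statistical potentials
#'
#' Builds the full temperature-independent potential set (forms sd, sds,
#' sad, std, sa, saa, st, stt, sst) from a structure set: counting,
#' mean-force energies with sparse correction, and triangular smoothing of
#' the distance axis of distance-type forms. Deterministic for a given
#' structure set and configuration; the configuration hash is recorded so
#' derive-time and lookup-time settings can be checked for identity.
#'
#' @param structures List of `ms_structure` objects.
#' @param config An [ms_config()].
#' @return An `ms_potentials` with the 9 potential tables.
#' @export
derive_potentials <- function(structures, config = ms_config()) {
  stopifnot(length(structures) >= 1)
  structures <- lapply(structures, describe_structure, config = config)
  pots <- lapply(standard_potential_ids(), function(id) {
    fr <- count_frequencies(structures, id, config)
    e <- pmf_table(fr, config)
    e <- smooth_distance_potential(e, fr$elements, config$smooth_halfwidth)
    new_potential(id, fr$elements, fr$counts, e)
  })
  names(pots) <- standard_potential_ids()
  new_potential_set("standard", pots, config, structures)
}

#' Derive mesostable and thermostable potential sets
#'
#' Splits a melting-temperature-annotated structure set at `tm_threshold`
#' (default 65 degrees C: below = mesostable, at or above = thermostable)
#' and derives from each subset the temperature-dependent potential forms,
#' grouped into exactly five potentials: `sd`, `sds`, `sad`, an
#' accessibility group (`sa` + `saa`) and a torsion group (`st` + `stt` +
#' `sst`); the `std` form is not part of the temperature-dependent set.
#' Grouped potentials are evaluated as the sum of their components'
#' energies.
#'
#' @param structures List of `ms_structure`, each with `tm_wild` set.
#' @param tm_threshold Split temperature in degrees C.
#' @param config An [ms_config()].
#' @return A list with elements `meso` and `thermo`, each an
#'   `ms_potentials` exposing the 5 grouped potentials.
#' @export
derive_t_potentials <- function(structures, tm_threshold = 65,
                                config = ms_config()) {
  tms <- vapply(structures, function(s) {
    if (is.null(s$tm_wild)) stop("structure ", s$id, " lacks tm_wild")
    s$tm_wild
  }, numeric(1))
  meso_set <- structures[tms < tm_threshold]
  thermo_set <- structures[tms >= tm_threshold]
  if (length(meso_set) == 0) stop("mesostable subset is empty (all Tm >= ",
                                  tm_threshold, ")")
  if (length(thermo_set) == 0) stop("thermostable subset is empty (all Tm < ",
                                    tm_threshold, ")")
  list(meso = derive_grouped(meso_set, "meso", config),
       thermo = derive_grouped(thermo_set, "thermo", config))
}

t_dependent_groups <- list(
  sd = "sd", sds = "sds", sad = "sad",
  acc = c("sa", "saa"), tors = c("st", "stt", "sst")
)

derive_grouped <- function(structures, name, config) {
  base <- derive_potentials(structures, config)
  pots <- lapply(names(t_dependent_groups), function(g) {
    comp <- base$potentials[t_dependent_groups[[g]]]
    if (length(comp) == 1) comp[[1]]
    else list(id = g, components = comp)
  })
  names(pots) <- names(t_dependent_groups)
  new_potential_set(name, pots, config, structures)
}

#' Largest absolute energy in a potential set
#'
#' Convenience diagnostic: the maximum `|energy|` over all (component)
#' tables of a set. Under sequence-structure independence this tends to 0
#' as the structure corpus grows.
#'
#' @param set An `ms_potentials`.
#' @return A single non-negative number (kT).
#' @export
max_abs_energy <- function(set) {
  mx <- 0
  for (p in set$potentials) {
    comps <- if (!is.null(p$components)) p$components else list(p)
    for (cp in comps) mx <- max(mx, max(abs(cp$energy)))
  }
  mx
}

#' Serialize / read a potential set bundle
#'
#' Potentials round-trip through a documented JSON bundle (per-potential
#' element types, axis labels, flattened count and energy arrays, set
#' provenance and configuration hash).
#'
#' @param set An `ms_potentials`.
#' @param path Output (or input) JSON file path.
#' @return `write_potentials()`: `path` invisibly; `read_potentials()`:
#'   the restored `ms_potentials`.
#' @export
write_potentials <- function(set, path) {
  ser_pot <- function(p) {
    if (!is.null(p$components)) {
      list(id = p$id, grouped = TRUE,
           components = lapply(p$components, ser_pot))
    } else {
      list(id = p$id, grouped = FALSE, elements = p$elements,
           dim = dim(p$energy), dimnames = dimnames(p$energy),
           counts = as.vector(p$counts), energy = as.vector(p$energy))
    }
  }
  obj <- list(name = set$name, config_hash = set$config_hash,
              n_structures = set$n_structures,
              structure_ids = set$structure_ids,
              potentials = lapply(set$potentials, ser_pot))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_potentials
#' @export
read_potentials <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  de_pot <- function(p) {
    if (isTRUE(p$grouped)) {
      list(id = p$id, components = lapply(p$components, de_pot))
    } else {
      dn <- p$dimnames
      new_potential(p$id, unlist(p$elements),
                    array(p$counts, dim = unlist(p$dim), dimnames = dn),
                    array(p$energy, dim = unlist(p$dim), dimnames = dn))
    }
  }
  structure(list(name = obj$name,
                 potentials = lapply(obj$potentials, de_pot),
                 config_hash = obj$config_hash,
                 n_structures = obj$n_structures,
                 structure_ids = unlist(obj$structure_ids)),
            class = "ms_potentials")
}
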