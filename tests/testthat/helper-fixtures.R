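# Shared fixtures, all built in code.

# small deterministic structure set (cached per session)
fixture_structures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ss <- generate_structures(
        synth_spec(n_structures = 4, chain_length_range = c(20, 30),
                   coupling = 0.6, seed = 11))
      # fixed Tm annotations so both temperature subsets are non-empty
      tms <- c(45, 55, 75, 85)
      for (k in seq_along(ss)) ss[[k]]$tm_wild <- tms[k]
      cache <<- ss
    }
    cache
  }
})

fixture_config <- function() ms_config()

# a described single structure
fixture_structure <- function() fixture_structures()[[1]]

# standard + T-dependent potentials over the fixture set (cached)
fixture_potentials <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ss <- fixture_structures()
      cfg <- fixture_config()
      tp <- derive_t_potentials(ss, 65, cfg)
      cache <<- list(std = derive_potentials(ss, cfg),
                     meso = tp$meso, thermo = tp$thermo)
    }
    cache
  }
})

# brute-force mean-force energies recomputed from raw count arrays by an
# independent route (plain frequency arithmetic, no shared code path)
oracle_pmf <- function(counts, n0) {
  N <- sum(counts)
  nd <- length(dim(counts))
  out <- array(0, dim(counts), dimnames = dimnames(counts))
  idx_grid <- expand.grid(lapply(dim(counts), seq_len))
  for (row in seq_len(nrow(idx_grid))) {
    ii <- as.integer(idx_grid[row, ])
    n_joint <- counts[matrix(ii, 1)]
    if (nd == 2) {
      f_joint <- n_joint / N
      f1 <- sum(counts[ii[1], ]) / N
      f2 <- sum(counts[, ii[2]]) / N
      raw <- if (f1 > 0 && f2 > 0) f_joint / (f1 * f2) else 0
    } else {
      f_joint <- n_joint / N
      f1 <- sum(counts[ii[1], , ]) / N
      f2 <- sum(counts[, ii[2], ]) / N
      f3 <- sum(counts[, , ii[3]]) / N
      f12 <- sum(counts[ii[1], ii[2], ]) / N
      f23 <- sum(counts[, ii[2], ii[3]]) / N
      f13 <- sum(counts[ii[1], , ii[3]]) / N
      raw <- if (f12 > 0 && f23 > 0 && f13 > 0) {
        f_joint * f1 * f2 * f3 / (f12 * f23 * f13)
      } else 0
    }
    corrected <- (n_joint * raw + n0) / (n_joint + n0)
    out[matrix(ii, 1)] <- -log(corrected)
  }
  out
}

# brute-force total energy of a structure under one (ungrouped) potential,
# enumerating every contribution from descriptors/pairs independently of
# the package's delta-only evaluation
oracle_total_energy <- function(pot, desc, pairs, aa_override = NULL) {
  aa <- desc$aa
  if (!is.null(aa_override)) aa[aa_override$row] <- aa_override$aa
  td <- ifelse(desc$torsion_domain == "undefined", NA, desc$torsion_domain)
  ab <- desc$acc_bin
  e <- pot$energy
  val <- function(labels) {
    if (any(is.na(labels))) return(0)
    dn <- dimnames(e)
    idx <- vapply(seq_along(dn), function(k) match(labels[k], dn[[k]]),
                  integer(1))
    e[matrix(idx, 1)]
  }
  total <- 0
  if (pot$id %in% c("sa", "st")) {
    for (k in seq_len(nrow(desc))) {
      lab <- switch(pot$id, sa = c(aa[k], ab[k]), st = c(aa[k], td[k]))
      total <- total + val(lab)
    }
    return(total)
  }
  for (p in seq_len(nrow(pairs))) {
    i <- match(pairs$i[p], desc$index)
    j <- match(pairs$j[p], desc$index)
    db <- paste0("d", pairs$bin[p] + 1)
    labs <- switch(pot$id,
      sd = list(c(aa[i], db), c(aa[j], db)),
      sds = list(c(aa[i], db, aa[j]), c(aa[j], db, aa[i])),
      sad = list(c(aa[i], ab[i], db), c(aa[j], ab[j], db)),
      std = list(c(aa[i], td[i], db), c(aa[j], td[j], db)),
      saa = list(c(aa[i], ab[i], ab[j]), c(aa[j], ab[j], ab[i])),
      stt = list(c(aa[i], td[i], td[j]), c(aa[j], td[j], td[i])),
      sst = list(c(aa[i], aa[j], td[j]), c(aa[j], aa[i], td[i]))
    )
    for (lab in labs) total <- total + val(lab)
  }
  total
}

# planted-model mutation dataset at configurable size/noise (cached by key)
fixture_dataset <- local({
  cache <- list()
  function(n = 200, noise_sd = 2, seed = 21) {
    key <- paste(n, noise_sd, seed)
    if (is.null(cache[[key]])) {
      ss <- fixture_structures()
      pots <- fixture_potentials()
      spec <- synth_spec(n_structures = 4, chain_length_range = c(20, 30),
                        coupling = 0.6, noise_sd = noise_sd,
                        n_mutations = n, seed = seed)
      cache[[key]] <<- generate_mutations(ss, planted_hot_params(1),
                                          pots$std, pots$meso, pots$thermo,
                                          spec, fixture_config())
    }
    cache[[key]]
  }
})
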