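#' Descriptor and potential configuration
#'
#' One configuration object governs every geometric and binning choice so
#' that potentials derived at training time and looked up at prediction
#' time are verifiably identical (compare `config_hash()`).
#'
#' @param d_min,d_max Side-chain centroid distance range in Angstroms;
#'   pairs outside `[d_min, d_max)` are ignored.
#' @param d_bin Distance bin width in Angstroms (uniform, half-open bins).
#' @param min_separation Minimum sequence separation `|i - j|` for a
#'   residue pair to be counted (default 1: only self-pairs excluded).
#' @param acc_breaks Breakpoints (percent accessibility) defining the
#'   accessibility bins used when accessibility acts as a structure
#'   element; `[0, 100]` is partitioned into `length(acc_breaks) + 1`
#'   half-open bins.
#' @param probe_radius Solvent probe radius in Angstroms.
#' @param n_sphere_points Number of surface test points per atom for the
#'   Shrake-Rupley accessible-surface computation.
#' @param max_asa Named numeric vector of per-amino-acid maximal accessible
#'   areas (square Angstroms) used to normalise relative accessibility, or
#'   the string `"computed"` to derive them from the package's own extended
#'   Gly-X-Gly reference conformation in its reduced atom representation
#'   (self-consistent for synthetic structures).
#' @param domains Torsion-domain partition table, see [torsion_domains()].
#' @param volumes Named numeric vector of residue volumes, see
#'   [aa_volumes()].
#' @param pseudocount Sparse-data pseudocount weight `n0`: observed
#'   frequency ratios are shrunk toward 1 (energies toward 0) with weight
#'   `n0` relative to the number of observations.
#' @param smooth_halfwidth Half-width, in distance bins, of the triangular
#'   smoothing window applied along the distance axis of distance-type
#'   potentials (0 disables smoothing).
#'
#' @return A list of class `ms_config`.
#' @export
#' @examples
#' cfg <- ms_config(d_bin = 0.5)
#' cfg$d_bin
ms_config <- function(d_min = 3.0, d_max = 8.0, d_bin = 0.2,
                      min_separation = 1,
                      acc_breaks = c(20, 40, 60, 80),
                      probe_radius = 1.4, n_sphere_points = 960,
                      max_asa = aa_max_asa(),
                      domains = torsion_domains(),
                      volumes = aa_volumes(),
                      pseudocount = 10,
                      smooth_halfwidth = 2) {
  stopifnot(d_max > d_min, d_bin > 0, min_separation >= 1,
            probe_radius > 0, n_sphere_points >= 10, pseudocount >= 0,
            smooth_halfwidth >= 0)
  if (identical(max_asa, "computed")) max_asa <- computed_max_asa(
    probe_radius = probe_radius, n_sphere_points = n_sphere_points)
  stopifnot(all(aa_codes() %in% names(max_asa)),
            all(aa_codes() %in% names(volumes)))
  cfg <- list(
    d_min = d_min, d_max = d_max, d_bin = d_bin,
    n_d_bins = as.integer(ceiling((d_max - d_min) / d_bin - 1e-9)),
    min_separation = as.integer(min_separation),
    acc_breaks = acc_breaks,
    probe_radius = probe_radius,
    n_sphere_points = as.integer(n_sphere_points),
    max_asa = max_asa[aa_codes()],
    domains = domains,
    volumes = volumes[aa_codes()],
    pseudocount = pseudocount,
    smooth_halfwidth = as.integer(smooth_halfwidth)
  )
  structure(cfg, class = "ms_config")
}

#' @export
print.ms_config <- function(x, ...) {
  cat("<ms_config>\n")
  cat(sprintf("  distance bins: [%.1f, %.1f) A, width %.2f (%d bins), min |i-j| = %d\n",
              x$d_min, x$d_max, x$d_bin, x$n_d_bins, x$min_separation))
  cat(sprintf("  accessibility bins: %d; torsion domains: %s\n",
              length(x$acc_breaks) + 1L,
              paste(unique(x$domains$domain), collapse = ", ")))
  cat(sprintf("  SASA: probe %.2f A, %d points; pseudocount n0 = %g; smoothing hw = %d\n",
              x$probe_radius, x$n_sphere_points, x$pseudocount,
              x$smooth_halfwidth))
  cat(sprintf("  hash: %s\n", config_hash(x)))
  invisible(x)
}

#' Stable fingerprint of a configuration
#'
#' @param config An [ms_config()] object.
#' @return A short hash string; potentials record it so mismatched
#'   derive/lookup configurations are detectable.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "ms_config"))
  rlang::hash(lapply(unclass(config), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }))
}

# distance -> 0-based bin index; NA when out of [d_min, d_max)
distance_bin <- function(d, config) {
  b <- floor((d - config$d_min) / config$d_bin)
  b[d < config$d_min | d >= config$d_max] <- NA_real_
  as.integer(b)
}

# accessibility percent -> bin label "acc1".."accK"
acc_bin <- function(a, config) {
  idx <- findInterval(a, config$acc_breaks, left.open = FALSE) + 1L
  idx[is.na(a)] <- NA_integer_
  ifelse(is.na(idx), NA_character_, paste0("acc", idx))
}

acc_bin_labels <- function(config) paste0("acc", seq_len(length(config$acc_breaks) + 1L))

d_bin_labels <- function(config) paste0("d", seq_len(config$n_d_bins))
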