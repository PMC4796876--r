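# Dataset curation rules and evaluation metrics.

#' Annotate mutation records with curation decisions
#'
#' Applies the dataset-selection rules in a fixed order and labels every
#' record with the first failing rule: crystallographic resolution must be
#' below 2.5 Angstrom, |delta-Tm| must not exceed 20 degrees C (larger
#' changes likely involve structural rearrangements outside the model's
#' scope), the protein must be monomeric, the measurement made without
#' chemical denaturants, the transition two-state, and the mutation a
#' single-site substitution. Missing metadata columns are treated as
#' passing.
#'
#' @param records Mutation tibble; recognised columns: `dtm_exp`,
#'   `resolution`, and logicals `monomeric`, `no_denaturant`, `two_state`,
#'   plus integer `n_sites`.
#' @param max_abs_dtm Magnitude cut for `dtm_exp` (degrees C).
#' @param max_resolution Exclusive resolution cut (Angstrom).
#' @return The input tibble with logical `keep` and character
#'   `reject_reason` (`NA` for kept records) columns appended.
#' @export
filter_mutations <- function(records, max_abs_dtm = 20,
                             max_resolution = 2.5) {
  n <- nrow(records)
  col <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else rep(default, n)
  }
  checks <- list(
    resolution = !is.na(col("resolution", NA_real_)) &
      col("resolution", NA_real_) >= max_resolution,
    dtm_magnitude = !is.na(col("dtm_exp", NA_real_)) &
      abs(col("dtm_exp", NA_real_)) > max_abs_dtm,
    monomeric = !col("monomeric", TRUE),
    denaturant = !col("no_denaturant", TRUE),
    two_state = !col("two_state", TRUE),
    multi_site = col("n_sites", 1L) > 1L
  )
  reason <- rep(NA_character_, n)
  for (nm in names(checks)) {
    bad <- checks[[nm]] & is.na(reason)
    bad[is.na(bad)] <- FALSE
    reason[bad] <- nm
  }
  records$keep <- is.na(reason)
  records$reject_reason <- reason
  records
}

#' Merge duplicate mutation measurements
#'
#' Duplicates are records sharing (`protein_id`, `chain`, `position`,
#' `wt`, `mut`). Within each group, only the entries measured at pH
#' closest to 7 are retained (within `ph_tol` units of the closest;
#' records without a pH are treated as pH 7), and their experimental
#' delta-Tm values are averaged with equal weights. One merged row per
#' group is returned, with `n_merged` recording the group size used.
#'
#' @param records Mutation tibble with `dtm_exp` and optionally `ph`.
#' @param ph_tol Tolerance (pH units) around the closest-to-7 entry.
#' @return A tibble with one row per unique mutation.
#' @export
merge_duplicate_mutations <- function(records, ph_tol = 0.5) {
  stopifnot(all(c("protein_id", "position", "wt", "mut") %in% names(records)))
  if (!"chain" %in% names(records)) records$chain <- "A"
  if (!"ph" %in% names(records)) records$ph <- 7
  records$ph[is.na(records$ph)] <- 7
  records |>
    dplyr::group_by(.data$protein_id, .data$chain, .data$position,
                    .data$wt, .data$mut) |>
    dplyr::group_modify(function(g, key) {
      dist <- abs(g$ph - 7)
      sel <- g[dist <= min(dist) + ph_tol, , drop = FALSE]
      out <- sel[1, , drop = FALSE]
      out$dtm_exp <- mean(sel$dtm_exp)
      out$n_merged <- nrow(sel)
      out
    }) |>
    dplyr::ungroup()
}

trim_indices <- function(err, trim_frac) {
  n_trim <- floor(trim_frac * length(err))
  if (n_trim == 0) return(seq_along(err))
  drop <- order(-abs(err))[seq_len(n_trim)]
  setdiff(seq_along(err), drop)
}

safe_cor <- function(x, y) {
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Prediction-error report with trimming and accessibility strata
#'
#' Computes the root-mean-square deviation `sigma` and Pearson
#' correlation `r` between predictions and experimental values, their
#' outlier-trimmed versions (the `floor(trim_frac * n)` points with the
#' largest absolute error are removed; ties broken by dataset order), and,
#' when accessibilities are supplied, the same metrics per burial class -
#' core (`A < 15`), partially buried (`15 <= A < 50`) and surface
#' (`A >= 50`) - including `sigma` normalized by the experimental
#' delta-Tm standard deviation of the stratum.
#'
#' @param pred,obs Numeric vectors (degrees C), equal length, `n >= 2`.
#' @param accessibility Optional numeric vector of percent solvent
#'   accessibilities.
#' @param trim_frac Fraction of points to trim (default 0.10).
#' @return A tibble with one row per stratum (`"all"` first) and columns
#'   `stratum`, `n`, `sigma`, `r`, `sigma_trimmed`, `r_trimmed`,
#'   `sigma_over_sd`. Correlations over degenerate inputs are `NA`.
#' @export
#' @examples
#' evaluate_dtm(c(1, 2, 3, 4), c(1.5, 2.5, 2.8, 4.2))
evaluate_dtm <- function(pred, obs, accessibility = NULL, trim_frac = 0.10) {
  stopifnot(length(pred) == length(obs), length(pred) >= 2)
  err <- pred - obs
  keep <- trim_indices(err, trim_frac)
  all_row <- tibble::tibble(
    stratum = "all", n = length(pred),
    sigma = sqrt(mean(err^2)), r = safe_cor(pred, obs),
    sigma_trimmed = sqrt(mean(err[keep]^2)),
    r_trimmed = safe_cor(pred[keep], obs[keep]),
    sigma_over_sd = sqrt(mean(err^2)) / stats::sd(obs)
  )
  if (is.null(accessibility)) return(all_row)
  stopifnot(length(accessibility) == length(pred))
  classes <- cut(accessibility, breaks = c(-Inf, 15, 50, Inf),
                 labels = c("core", "partial", "surface"), right = FALSE)
  strata <- lapply(levels(classes), function(cl) {
    idx <- which(classes == cl)
    if (length(idx) == 0) {
      return(tibble::tibble(stratum = cl, n = 0L, sigma = NA_real_,
                            r = NA_real_, sigma_trimmed = NA_real_,
                            r_trimmed = NA_real_, sigma_over_sd = NA_real_))
    }
    e <- err[idx]
    tibble::tibble(
      stratum = cl, n = length(idx), sigma = sqrt(mean(e^2)),
      r = safe_cor(pred[idx], obs[idx]),
      sigma_trimmed = NA_real_, r_trimmed = NA_real_,
      sigma_over_sd = sqrt(mean(e^2)) / stats::sd(obs[idx])
    )
  })
  dplyr::bind_rows(all_row, dplyr::bind_rows(strata))
}
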