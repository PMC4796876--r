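# The two delta-Tm model structures. Both are shallow networks whose
# "activation functions" are sigmoids of the mutated residue's solvent
# accessibility: each input term nu carries a 4-parameter weight
#   alpha_nu(A) = phi_nu + r_nu / (1 + exp(-omega_nu (A - b_nu))),
# a smooth interpolation between a core weight and a surface weight.

#' Sigmoid accessibility weight
#'
#' @param phi Offset (weight in the `A -> -Inf` limit direction).
#' @param r Amplitude of the core-to-surface transition.
#' @param omega Steepness, per percent accessibility.
#' @param b Transition center, percent accessibility.
#' @param A Solvent accessibility in percent (vectorized).
#' @return `phi + r / (1 + exp(-omega * (A - b)))`.
#' @export
#' @examples
#' sigmoid_weight(0, 1, 0.1, 50, 70) # ~0.881
sigmoid_weight <- function(phi, r, omega, b, A) {
  phi + r / (1 + exp(-omega * (A - b)))
}

hot_term_names <- function() c(standard_potential_ids(), "dv_plus",
                               "dv_minus", "independent")

check_weight_matrix <- function(w, n, what) {
  stopifnot(is.matrix(w), nrow(w) == n, ncol(w) == 4)
  if (is.null(colnames(w))) colnames(w) <- c("phi", "r", "omega", "b")
  stopifnot(identical(colnames(w), c("phi", "r", "omega", "b")),
            all(is.finite(w)))
  w
}

#' Temperature-independent model parameters
#'
#' The Tm-free model writes delta-Tm as a global affine transform of a
#' length-normalized sum of twelve sigmoid-weighted contributions: the
#' nine standard-potential energy changes, the two volume terms, and an
#' accessibility-only "independent" term. 12 weights x 4 sigmoid
#' parameters + the global scale `a` and offset `c` = 50 free parameters.
#'
#' @param weights 12 x 4 matrix (columns `phi`, `r`, `omega`, `b`; rows in
#'   the order sd, sds, sad, std, sa, saa, st, stt, sst, dv_plus,
#'   dv_minus, independent).
#' @param a Global scale.
#' @param c Global offset (degrees C).
#' @return An object of class `ms_hot_params`.
#' @export
hot_params <- function(weights, a = 1, c = 0) {
  weights <- check_weight_matrix(weights, 12, "weights")
  rownames(weights) <- hot_term_names()
  structure(list(weights = weights, a = a, c = c), class = "ms_hot_params")
}

#' Temperature-dependent model parameters
#'
#' The Tm-aware model combines three sigmoid-weighted perceptron sums
#' (mesostable potentials, thermostable potentials, volume + independent
#' terms) with polynomial output weights `F_M`, `F_T`, `F_V` in the
#' wild-type melting temperature and chain length. (5 + 5 + 3) weights x 4
#' sigmoid parameters + 3 x 5 polynomial coefficients = 67 free
#' parameters.
#'
#' @param meso_weights,thermo_weights 5 x 4 sigmoid-parameter matrices
#'   (rows in the order sd, sds, sad, acc, tors).
#' @param vol_ind_weights 3 x 4 matrix (rows dv_plus, dv_minus,
#'   independent).
#' @param f_coef 3 x 5 matrix of polynomial coefficients (rows `M`, `T`,
#'   `V`; columns `q0`..`q4`), see [poly_factor()].
#' @return An object of class `ms_tm_hot_params`.
#' @export
tm_hot_params <- function(meso_weights, thermo_weights, vol_ind_weights,
                          f_coef) {
  meso_weights <- check_weight_matrix(meso_weights, 5, "meso")
  thermo_weights <- check_weight_matrix(thermo_weights, 5, "thermo")
  vol_ind_weights <- check_weight_matrix(vol_ind_weights, 3, "vol_ind")
  rownames(meso_weights) <- rownames(thermo_weights) <- t_dependent_potential_ids()
  rownames(vol_ind_weights) <- c("dv_plus", "dv_minus", "independent")
  stopifnot(is.matrix(f_coef), nrow(f_coef) == 3, ncol(f_coef) == 5,
            all(is.finite(f_coef)))
  rownames(f_coef) <- c("M", "T", "V")
  colnames(f_coef) <- paste0("q", 0:4)
  structure(list(meso_weights = meso_weights,
                 thermo_weights = thermo_weights,
                 vol_ind_weights = vol_ind_weights,
                 f_coef = f_coef),
            class = "ms_tm_hot_params")
}

#' Flatten model parameters to a numeric vector
#'
#' The canonical free-parameter vector used by the trainer; its length is
#' the model's free parameter count (50 for the Tm-free model, 67 for the
#' Tm-aware one).
#'
#' @param params An `ms_hot_params` or `ms_tm_hot_params`.
#' @return A named numeric vector.
#' @export
params_vector <- function(params) UseMethod("params_vector")

#' @export
params_vector.ms_hot_params <- function(params) {
  w <- params$weights
  v <- c(as.vector(t(w)), params$a, params$c)
  names(v) <- c(paste(rep(rownames(w), each = 4), colnames(w), sep = "."),
                "a", "c")
  v
}

#' @export
params_vector.ms_tm_hot_params <- function(params) {
  nm <- function(w, tag) paste(tag, rep(rownames(w), each = 4),
                               colnames(w), sep = ".")
  v <- c(as.vector(t(params$meso_weights)),
         as.vector(t(params$thermo_weights)),
         as.vector(t(params$vol_ind_weights)),
         as.vector(t(params$f_coef)))
  names(v) <- c(nm(params$meso_weights, "meso"),
                nm(params$thermo_weights, "thermo"),
                nm(params$vol_ind_weights, "vol"),
                paste("F", rep(rownames(params$f_coef), each = 5),
                      colnames(params$f_coef), sep = "."))
  v
}

# inverse of params_vector
vector_to_params <- function(v, model = c("hot", "tm_hot")) {
  model <- match.arg(model)
  if (model == "hot") {
    stopifnot(length(v) == 50)
    w <- matrix(v[1:48], nrow = 12, ncol = 4, byrow = TRUE,
                dimnames = list(hot_term_names(),
                                c("phi", "r", "omega", "b")))
    hot_params(w, a = unname(v[49]), c = unname(v[50]))
  } else {
    stopifnot(length(v) == 67)
    mk <- function(x, n, rn) matrix(x, nrow = n, ncol = 4, byrow = TRUE,
                                    dimnames = list(rn, c("phi", "r", "omega", "b")))
    f <- matrix(v[53:67], nrow = 3, ncol = 5, byrow = TRUE,
                dimnames = list(c("M", "T", "V"), paste0("q", 0:4)))
    tm_hot_params(mk(v[1:20], 5, t_dependent_potential_ids()),
                  mk(v[21:40], 5, t_dependent_potential_ids()),
                  mk(v[41:52], 3, c("dv_plus", "dv_minus", "independent")),
                  f)
  }
}

# n x k matrix of sigmoid weights for a k x 4 weight matrix
weight_matrix_at <- function(w, A) {
  n <- length(A)
  out <- matrix(0, n, nrow(w))
  for (k in seq_len(nrow(w))) {
    out[, k] <- sigmoid_weight(w[k, "phi"], w[k, "r"], w[k, "omega"],
                               w[k, "b"], A)
  }
  colnames(out) <- rownames(w)
  out
}

hot_feature_matrix <- function(features) {
  cols <- hot_feature_cols()
  missing <- setdiff(cols, names(features))
  if (length(missing) > 0) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  cbind(as.matrix(features[, cols]), independent = 1)
}

#' Predict delta-Tm with the temperature-independent model
#'
#' `dTm = c + a * (sum_nu alpha_nu(A) x_nu) / N_r`, where the twelve
#' contributions `x_nu` are the nine standard-potential energy changes,
#' the two volume terms and a constant 1 (the accessibility-only
#' independent term), each weighted by its accessibility sigmoid. The
#' division by the chain length follows the small-perturbation picture
#' (the proportionality coefficient scales like 1/enthalpy, and the
#' folding enthalpy grows with chain length); it can be disabled.
#'
#' @param params An `ms_hot_params`.
#' @param features Feature tibble from [featurize_mutations()] (needs the
#'   nine `ddw_*` columns, `dv_plus`, `dv_minus`, `acc`, `n_res`).
#' @param length_normalize Divide the weighted sum by `n_res`
#'   (default TRUE).
#' @return Numeric vector of predicted delta-Tm (degrees C).
#' @export
predict_hot <- function(params, features, length_normalize = TRUE) {
  stopifnot(inherits(params, "ms_hot_params"))
  X <- hot_feature_matrix(features)
  alpha <- weight_matrix_at(params$weights, features$acc)
  s <- rowSums(alpha * X)
  scale <- if (length_normalize) features$n_res else rep(1, nrow(X))
  params$c + params$a * s / scale
}

#' Polynomial output weight of the Tm-aware model
#'
#' `F(Tm, N_r) = q0 + q1 Tm + q2 Tm^2 + q3 / N_r + q4 Tm / N_r`, the
#' output-perceptron weight applied to each hidden sum; the terms in
#' `1/N_r` capture the inverse-enthalpy scaling of the
#' stability-to-melting-temperature conversion.
#'
#' @param q Numeric length-5 coefficient vector (q0..q4).
#' @param tm_wild Wild-type melting temperature (degrees C, vectorized).
#' @param n_res Chain length (vectorized).
#' @return Numeric vector of factor values.
#' @export
poly_factor <- function(q, tm_wild, n_res) {
  stopifnot(length(q) == 5, all(n_res >= 1))
  q[1] + q[2] * tm_wild + q[3] * tm_wild^2 + q[4] / n_res +
    q[5] * tm_wild / n_res
}

tm_hot_blocks <- function(features) {
  cols <- tm_hot_feature_cols()
  need <- c(cols$meso, cols$thermo, cols$vol)
  missing <- setdiff(need, names(features))
  if (length(missing) > 0) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  list(M = as.matrix(features[, cols$meso]),
       T = as.matrix(features[, cols$thermo]),
       V = cbind(as.matrix(features[, cols$vol]), independent = 1))
}

#' Predict delta-Tm with the Tm-aware model
#'
#' Three sigmoid-weighted perceptron sums - over the five mesostable
#' potentials, the five thermostable potentials, and the volume +
#' independent terms - are combined with polynomial weights in the
#' wild-type melting temperature and chain length:
#' `dTm = F_M S_M + F_T S_T + F_V S_V`.
#'
#' @param params An `ms_tm_hot_params`.
#' @param features Feature tibble (needs the `ddw_meso_*` and
#'   `ddw_thermo_*` columns, `dv_plus`, `dv_minus`, `acc`, `n_res`,
#'   `tm_wild`).
#' @return Numeric vector of predicted delta-Tm (degrees C).
#' @export
predict_tm_hot <- function(params, features) {
  stopifnot(inherits(params, "ms_tm_hot_params"))
  if (!"tm_wild" %in% names(features) || anyNA(features$tm_wild)) {
    stop("tm_wild is required for the Tm-aware model; use predict_hot() ",
         "for mutations without a wild-type melting temperature")
  }
  bl <- tm_hot_blocks(features)
  A <- features$acc
  sM <- rowSums(weight_matrix_at(params$meso_weights, A) * bl$M)
  sT <- rowSums(weight_matrix_at(params$thermo_weights, A) * bl$T)
  sV <- rowSums(weight_matrix_at(params$vol_ind_weights, A) * bl$V)
  fM <- poly_factor(params$f_coef["M", ], features$tm_wild, features$n_res)
  fT <- poly_factor(params$f_coef["T", ], features$tm_wild, features$n_res)
  fV <- poly_factor(params$f_coef["V", ], features$tm_wild, features$n_res)
  fM * sM + fT * sT + fV * sV
}

#' Combined (averaged) delta-Tm prediction
#'
#' The final prediction is the arithmetic mean of the two model outputs.
#' Rows whose `tm_wild` is missing fall back to the Tm-free model alone
#' (with a warning), mirroring a tool that accepts the wild-type melting
#' temperature only "when available".
#'
#' @param hot An `ms_hot_params`.
#' @param tmhot An `ms_tm_hot_params`.
#' @param features Feature tibble.
#' @return Numeric vector of predicted delta-Tm (degrees C).
#' @export
predict_final <- function(hot, tmhot, features) {
  p1 <- predict_hot(hot, features)
  has_tm <- if ("tm_wild" %in% names(features)) {
    !is.na(features$tm_wild)
  } else {
    rep(FALSE, nrow(features))
  }
  if (!any(has_tm)) {
    warning("tm_wild missing for all mutations; returning the Tm-free ",
            "prediction only")
    return(p1)
  }
  out <- p1
  if (any(!has_tm)) {
    warning(sum(!has_tm), " mutation(s) lack tm_wild; falling back to the ",
            "Tm-free prediction for those")
  }
  sub <- features[has_tm, , drop = FALSE]
  out[has_tm] <- (p1[has_tm] + predict_tm_hot(tmhot, sub)) / 2
  out
}

#' Write / read model parameters as JSON
#'
#' Parameters round-trip through a named-block JSON file; reading asserts
#' the printed free-parameter counts (50 and 67).
#'
#' @param params An `ms_hot_params` or `ms_tm_hot_params`.
#' @param path JSON file path.
#' @return `write_params()`: `path` invisibly; `read_params()`: restored
#'   parameter object.
#' @export
write_params <- function(params, path) {
  if (inherits(params, "ms_hot_params")) {
    obj <- list(model = "hot", values = as.list(params_vector(params)))
  } else if (inherits(params, "ms_tm_hot_params")) {
    obj <- list(model = "tm_hot", values = as.list(params_vector(params)))
  } else stop("unsupported parameter object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- unlist(obj$values)
  expected <- if (obj$model == "hot") 50L else 67L
  if (length(v) != expected) {
    stop("parameter file holds ", length(v), " scalars; ", obj$model,
         " model requires exactly ", expected)
  }
  vector_to_params(v, obj$model)
}

#' @export
print.ms_hot_params <- function(x, ...) {
  cat("<ms_hot_params> 50 free parameters (12 sigmoid weights + a, c)\n")
  invisible(x)
}

#' @export
print.ms_tm_hot_params <- function(x, ...) {
  cat("<ms_tm_hot_params> 67 free parameters",
      "(13 sigmoid weights + 3 x 5 polynomial coefficients)\n")
  invisible(x)
}
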