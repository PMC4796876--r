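#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted delta-Tm model
#'
#' @param x An `ms_dtm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `block` (weight
#'   group), `term` (input the weight multiplies), `parameter` (sigmoid or
#'   polynomial coefficient name) and `estimate`.
#' @exportS3Method generics::tidy
tidy.ms_dtm_fit <- function(x, ...) {
  v <- params_vector(x$params)
  parts <- strsplit(names(v), ".", fixed = TRUE)
  if (x$model == "hot") {
    tibble::tibble(
      block = ifelse(lengths(parts) == 1, "global", "weights"),
      term = vapply(parts, function(p) p[1], character(1)),
      parameter = vapply(parts, function(p) p[length(p)], character(1)),
      estimate = unname(v)
    )
  } else {
    tibble::tibble(
      block = vapply(parts, function(p) p[1], character(1)),
      term = vapply(parts, function(p) p[2], character(1)),
      parameter = vapply(parts, function(p) p[3], character(1)),
      estimate = unname(v)
    )
  }
}

#' Glance at a fitted delta-Tm model
#'
#' @param x An `ms_dtm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `n_params`, `n_train`,
#'   `sigma_train`, `sigma_valid`, `n_restarts_ok`.
#' @exportS3Method generics::glance
glance.ms_dtm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_params = length(params_vector(x$params)),
    n_train = x$n_train,
    sigma_train = x$sigma_train,
    sigma_valid = x$sigma_valid,
    n_restarts_ok = sum(x$restarts$ok)
  )
}

#' Tidy a cross-validation result
#'
#' @param x An `ms_dtm_cv`.
#' @param ... Unused.
#' @return The per-fold metric tibble (`fold`, `n`, `sigma`, `r`).
#' @exportS3Method generics::tidy
tidy.ms_dtm_cv <- function(x, ...) x$folds

#' Glance at a cross-validation result
#'
#' @param x An `ms_dtm_cv`.
#' @param ... Unused.
#' @return A one-row tibble with the pooled out-of-fold metrics: `model`,
#'   `k`, `n`, `sigma`, `r`, `sigma_trimmed`, `r_trimmed`.
#' @exportS3Method generics::glance
glance.ms_dtm_cv <- function(x, ...) {
  all_row <- x$pooled[x$pooled$stratum == "all", ]
  tibble::tibble(model = x$model, k = x$k, n = all_row$n,
                 sigma = all_row$sigma, r = all_row$r,
                 sigma_trimmed = all_row$sigma_trimmed,
                 r_trimmed = all_row$r_trimmed)
}
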