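# Parameter identification: batch gradient descent on the mean-squared
# delta-Tm error with analytic gradients, random restarts, and early
# stopping on a validation set.

#' Training configuration
#'
#' @param n_restarts Independent random initializations; the restart with
#'   the lowest validation error wins (default 30).
#' @param max_iter Maximum gradient iterations per restart.
#' @param learning_rate Step size (fixed for plain gradient descent; the
#'   base rate for Adam).
#' @param early_stop_patience Stop a restart after this many iterations
#'   without validation improvement; parameters are returned from the
#'   best-validation iteration, not the last one.
#' @param optimizer `"gd"` (plain fixed-step batch gradient descent, the
#'   default) or `"adam"` (adaptive moments; useful when feature scales
#'   differ strongly).
#' @param lr_decay Hyperbolic learning-rate decay: the step size at
#'   iteration t is `learning_rate / (1 + lr_decay * t)` (0 = constant).
#' @param polish_iter Number of Levenberg-Marquardt refinement steps run
#'   after the descent phase of each restart (0 = off, the default). The
#'   model is a smooth least-squares problem with an exact Jacobian, so a
#'   short Gauss-Newton polish sharpens the optimum far beyond what a
#'   fixed-step method reaches; the early-stopping contract still applies
#'   (polish iterates are only kept while validation error improves).
#' @param seed Integer seed controlling initializations and data splits.
#' @return A list of class `train_control`.
#' @export
train_control <- function(n_restarts = 30, max_iter = 2000,
                          learning_rate = 1e-3, early_stop_patience = 50,
                          optimizer = c("gd", "adam"), lr_decay = 0,
                          polish_iter = 0, seed = 1) {
  stopifnot(n_restarts >= 1, max_iter >= 1, learning_rate > 0,
            early_stop_patience >= 1, lr_decay >= 0, polish_iter >= 0)
  structure(list(n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 optimizer = match.arg(optimizer),
                 lr_decay = lr_decay,
                 polish_iter = as.integer(polish_iter),
                 seed = as.integer(seed)),
            class = "train_control")
}

# precomputed design pieces for fast repeated prediction/gradient calls
build_train_data <- function(features, model) {
  if (model == "hot") {
    list(model = model,
         X = hot_feature_matrix(features),
         A = features$acc,
         scale = features$n_res)
  } else {
    bl <- tm_hot_blocks(features)
    if (anyNA(features$tm_wild)) stop("tm_wild required for the Tm-aware model")
    list(model = model, blocks = bl, A = features$acc,
         basis = cbind(1, features$tm_wild, features$tm_wild^2,
                       1 / features$n_res,
                       features$tm_wild / features$n_res))
  }
}

# sigmoid pieces for one weight matrix: value, and partials wrt the 4
# parameters (each an n x k matrix)
sigmoid_pieces <- function(w, A) {
  k <- nrow(w)
  n <- length(A)
  val <- dphi <- dr <- domega <- db <- matrix(0, n, k)
  for (j in seq_len(k)) {
    z <- w[j, "omega"] * (A - w[j, "b"])
    sig <- 1 / (1 + exp(-z))
    val[, j] <- w[j, "phi"] + w[j, "r"] * sig
    dphi[, j] <- 1
    dr[, j] <- sig
    ss <- w[j, "r"] * sig * (1 - sig)
    domega[, j] <- ss * (A - w[j, "b"])
    db[, j] <- -ss * w[j, "omega"]
  }
  list(val = val, dphi = dphi, dr = dr, domega = domega, db = db)
}

# interleave per-term partials into params_vector column order
# (term1.phi, term1.r, term1.omega, term1.b, term2.phi, ...)
interleave_jac <- function(pieces, X, outer_factor) {
  k <- ncol(X)
  n <- nrow(X)
  J <- matrix(0, n, 4 * k)
  for (j in seq_len(k)) {
    base <- (j - 1) * 4
    xf <- outer_factor * X[, j]
    J[, base + 1] <- xf * pieces$dphi[, j]
    J[, base + 2] <- xf * pieces$dr[, j]
    J[, base + 3] <- xf * pieces$domega[, j]
    J[, base + 4] <- xf * pieces$db[, j]
  }
  J
}

# prediction and full Jacobian (n x n_params) at parameter vector v
predict_with_jacobian <- function(v, data) {
  if (data$model == "hot") {
    p <- vector_to_params(v, "hot")
    pieces <- sigmoid_pieces(p$weights, data$A)
    s <- rowSums(pieces$val * data$X)
    u <- s / data$scale
    pred <- p$c + p$a * u
    J <- cbind(interleave_jac(pieces, data$X, p$a / data$scale), u, 1)
    list(pred = pred, jac = J)
  } else {
    p <- vector_to_params(v, "tm_hot")
    blocks <- list(M = list(w = p$meso_weights, X = data$blocks$M),
                   T = list(w = p$thermo_weights, X = data$blocks$T),
                   V = list(w = p$vol_ind_weights, X = data$blocks$V))
    f <- list(M = as.vector(data$basis %*% p$f_coef["M", ]),
              T = as.vector(data$basis %*% p$f_coef["T", ]),
              V = as.vector(data$basis %*% p$f_coef["V", ]))
    pred <- 0
    Jw <- list()
    Jf <- list()
    for (nm in c("M", "T", "V")) {
      pieces <- sigmoid_pieces(blocks[[nm]]$w, data$A)
      s <- rowSums(pieces$val * blocks[[nm]]$X)
      pred <- pred + f[[nm]] * s
      Jw[[nm]] <- interleave_jac(pieces, blocks[[nm]]$X, f[[nm]])
      Jf[[nm]] <- data$basis * s
    }
    list(pred = pred, jac = cbind(Jw$M, Jw$T, Jw$V, Jf$M, Jf$T, Jf$V))
  }
}

# gradient of the mean-squared-error cost at v
mse_gradient <- function(v, data, y) {
  pj <- predict_with_jacobian(v, data)
  e <- pj$pred - y
  list(loss = mean(e^2),
       grad = as.vector(2 * crossprod(pj$jac, e) / length(y)))
}

predict_vector <- function(v, data) predict_with_jacobian(v, data)$pred

rand_init <- function(model) {
  if (model == "hot") {
    w <- c(rbind(stats::rnorm(12, 0, 0.3),        # phi
                 stats::rnorm(12, 0, 0.3),        # r
                 stats::runif(12, 0.02, 0.2),     # omega
                 stats::runif(12, 10, 90)))       # b
    c(w, 1 + stats::rnorm(1, 0, 0.1), stats::rnorm(1, 0, 0.3))
  } else {
    mkw <- function(k) c(rbind(stats::rnorm(k, 0, 0.3),
                               stats::rnorm(k, 0, 0.3),
                               stats::runif(k, 0.02, 0.2),
                               stats::runif(k, 10, 90)))
    q <- function() c(stats::rnorm(1, 0, 0.3), stats::rnorm(1, 0, 0.01),
                      stats::rnorm(1, 0, 1e-4), stats::rnorm(1, 0, 1),
                      stats::rnorm(1, 0, 0.01))
    c(mkw(5), mkw(5), mkw(3), q(), q(), q())
  }
}

rmse <- function(pred, obs) sqrt(mean((pred - obs)^2))

# one restart of gradient descent with early stopping; returns best-found
# parameters by validation error (or NULL on numerical failure)
run_restart <- function(v, data, y, vdata, vy, control) {
  adam <- control$optimizer == "adam"
  m <- rep(0, length(v)); s <- rep(0, length(v))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_sigma <- rmse(predict_vector(v, vdata), vy)
  best_v <- v
  stall <- 0L
  for (t in seq_len(control$max_iter)) {
    g <- mse_gradient(v, data, y)
    if (!is.finite(g$loss) || any(!is.finite(g$grad))) return(NULL)
    lr <- control$learning_rate / (1 + control$lr_decay * t)
    if (adam) {
      m <- b1 * m + (1 - b1) * g$grad
      s <- b2 * s + (1 - b2) * g$grad^2
      mh <- m / (1 - b1^t); sh <- s / (1 - b2^t)
      v <- v - lr * mh / (sqrt(sh) + eps)
    } else {
      v <- v - lr * g$grad
    }
    if (any(!is.finite(v))) return(NULL)
    sigma_v <- rmse(predict_vector(v, vdata), vy)
    if (is.finite(sigma_v) && sigma_v < best_sigma - 1e-12) {
      best_sigma <- sigma_v
      best_v <- v
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > control$early_stop_patience) break
    }
  }
  if (control$polish_iter > 0) {
    lam <- 1e-3
    v <- best_v
    for (t in seq_len(control$polish_iter)) {
      pj <- predict_with_jacobian(v, data)
      e <- y - pj$pred
      jtj <- crossprod(pj$jac)
      dj <- diag(jtj)
      # Marquardt damping plus an absolute ridge: flat directions (e.g.
      # steepness/center of a weight whose amplitude is ~0) keep the
      # system solvable
      ridge <- lam * (mean(dj) + 1e-8)
      step <- tryCatch(
        solve(jtj + lam * diag(dj) + ridge * diag(length(dj)),
              crossprod(pj$jac, e)),
        error = function(err) NULL)
      if (is.null(step)) {
        lam <- lam * 10
        if (lam > 1e10) break
        next
      }
      v_new <- v + as.vector(step)
      loss_new <- mean((predict_vector(v_new, data) - y)^2)
      if (is.finite(loss_new) && loss_new < mean(e^2)) {
        v <- v_new
        lam <- max(lam / 3, 1e-12)
        sigma_v <- rmse(predict_vector(v, vdata), vy)
        if (is.finite(sigma_v) && sigma_v < best_sigma - 1e-15) {
          best_sigma <- sigma_v
          best_v <- v
        }
      } else {
        lam <- lam * 5
        if (lam > 1e10) break
      }
    }
  }
  list(v = best_v, sigma_valid = best_sigma,
       sigma_train = rmse(predict_vector(best_v, data), y))
}

#' Fit a delta-Tm model by gradient descent with restarts
#'
#' Minimizes the mean squared deviation between experimental and
#' predicted delta-Tm by batch gradient descent with analytic gradients.
#' Each of `control$n_restarts` restarts draws random initial weights,
#' descends with early stopping on the validation set (the best-validation
#' iterate is kept), and the restart reaching the lowest validation error
#' is returned. Restarts that diverge numerically are dropped (an error is
#' raised only if all fail). When no validation set is given, the training
#' set doubles as one.
#'
#' @param features Feature tibble (from [featurize_mutations()] or
#'   [generate_mutations()]) with the target column.
#' @param model `"hot"` (Tm-free, 50 parameters) or `"tm_hot"` (Tm-aware,
#'   67 parameters).
#' @param control A [train_control()].
#' @param validation Optional feature tibble used for early stopping and
#'   restart selection.
#' @param target Name of the target column (degrees C).
#' @return An object of class `ms_dtm_fit` with elements `model`,
#'   `params`, `sigma_train`, `sigma_valid`, `restarts` (per-restart
#'   tibble) and `control`. Supports [predict()][predict.ms_dtm_fit],
#'   `tidy()` and `glance()`.
#' @export
fit_dtm <- function(features, model = c("hot", "tm_hot"),
                    control = train_control(), validation = NULL,
                    target = "dtm_exp") {
  model <- match.arg(model)
  stopifnot(target %in% names(features), nrow(features) >= 1)
  y <- features[[target]]
  stopifnot(all(is.finite(y)))
  data <- build_train_data(features, model)
  if (is.null(validation)) {
    vdata <- data; vy <- y
  } else {
    vdata <- build_train_data(validation, model)
    vy <- validation[[target]]
  }
  inits <- withr::with_seed(control$seed,
                            lapply(seq_len(control$n_restarts),
                                   function(i) rand_init(model)))
  results <- lapply(inits, run_restart, data = data, y = y,
                    vdata = vdata, vy = vy, control = control)
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all ", control$n_restarts, " restarts failed numerically")
  restarts <- tibble::tibble(
    restart = seq_len(control$n_restarts),
    ok = ok,
    sigma_valid = vapply(results, function(r) if (is.null(r)) NA_real_ else r$sigma_valid, numeric(1)),
    sigma_train = vapply(results, function(r) if (is.null(r)) NA_real_ else r$sigma_train, numeric(1))
  )
  best <- which.min(restarts$sigma_valid)
  structure(list(model = model,
                 params = vector_to_params(results[[best]]$v, model),
                 sigma_train = restarts$sigma_train[best],
                 sigma_valid = restarts$sigma_valid[best],
                 restarts = restarts,
                 control = control,
                 n_train = nrow(features)),
            class = "ms_dtm_fit")
}

#' @export
print.ms_dtm_fit <- function(x, ...) {
  cat(sprintf("<ms_dtm_fit> %s model: %d parameters, %d/%d restarts ok\n",
              x$model, length(params_vector(x$params)),
              sum(x$restarts$ok), nrow(x$restarts)))
  cat(sprintf("  sigma(train) = %.3f C, sigma(validation) = %.3f C\n",
              x$sigma_train, x$sigma_valid))
  invisible(x)
}

#' Predict from a fitted delta-Tm model
#'
#' @param object An `ms_dtm_fit`.
#' @param newdata Feature tibble.
#' @param ... Unused.
#' @return Numeric vector of predicted delta-Tm (degrees C).
#' @export
predict.ms_dtm_fit <- function(object, newdata, ...) {
  if (object$model == "hot") predict_hot(object$params, newdata)
  else predict_tm_hot(object$params, newdata)
}

#' Nested cross-validation of a delta-Tm model
#'
#' Splits the mutations into `k` disjoint test folds. For each fold the
#' remaining data are further split 8:1 into an inner training set and a
#' validation set for early stopping, the model is fitted with restarts,
#' and the prediction error is computed on the untouched test fold.
#' Splits are by mutation. Pooled metrics concatenate the out-of-fold
#' predictions.
#'
#' @inheritParams fit_dtm
#' @param k Number of folds (default 5).
#' @return An object of class `ms_dtm_cv`: `folds` (per-fold metric
#'   tibble), `predictions` (out-of-fold tibble with `row`, `fold`,
#'   `pred`, `obs`, `acc`), `pooled` (an [evaluate_dtm()] report) and
#'   `model`. Supports `tidy()`, `glance()` and `autoplot()`.
#' @export
crossvalidate_dtm <- function(features, model = c("hot", "tm_hot"),
                              control = train_control(), k = 5,
                              target = "dtm_exp") {
  model <- match.arg(model)
  n <- nrow(features)
  stopifnot(n >= k, k >= 2)
  fold_of <- withr::with_seed(control$seed,
                              sample(rep(seq_len(k), length.out = n)))
  preds <- vector("list", k)
  fold_stats <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    rest_idx <- which(fold_of != f)
    val_idx <- withr::with_seed(control$seed + 7919L * f, {
      sample(rest_idx, max(1L, floor(length(rest_idx) / 9)))
    })
    train_idx <- setdiff(rest_idx, val_idx)
    fit <- fit_dtm(features[train_idx, , drop = FALSE], model,
                   control = control,
                   validation = features[val_idx, , drop = FALSE],
                   target = target)
    p <- predict(fit, features[test_idx, , drop = FALSE])
    obs <- features[[target]][test_idx]
    preds[[f]] <- tibble::tibble(row = test_idx, fold = f, pred = p,
                                 obs = obs, acc = features$acc[test_idx])
    fold_stats[[f]] <- tibble::tibble(
      fold = f, n = length(test_idx), sigma = rmse(p, obs),
      r = if (length(obs) >= 2) suppressWarnings(stats::cor(p, obs)) else NA_real_
    )
  }
  predictions <- dplyr::bind_rows(preds)
  pooled <- evaluate_dtm(predictions$pred, predictions$obs,
                         accessibility = predictions$acc)
  structure(list(folds = dplyr::bind_rows(fold_stats),
                 predictions = predictions, pooled = pooled,
                 model = model, k = k, control = control),
            class = "ms_dtm_cv")
}

#' @export
print.ms_dtm_cv <- function(x, ...) {
  all_row <- x$pooled[x$pooled$stratum == "all", ]
  cat(sprintf("<ms_dtm_cv> %s model, %d folds, %d mutations\n",
              x$model, x$k, sum(x$folds$n)))
  cat(sprintf("  pooled sigma = %.2f C, r = %.2f (trimmed: %.2f C, %.2f)\n",
              all_row$sigma, all_row$r, all_row$sigma_trimmed,
              all_row$r_trimmed))
  invisible(x)
}
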