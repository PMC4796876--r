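# feature generator decoupled from structures, for trainer-only tests
random_features <- function(n, seed = 1) {
  withr::with_seed(seed, {
    f <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(stats::rnorm(n * 9), n)),
      paste0("ddw_", standard_potential_ids())))
    for (id in t_dependent_potential_ids()) {
      f[[paste0("ddw_meso_", id)]] <- stats::rnorm(n)
      f[[paste0("ddw_thermo_", id)]] <- stats::rnorm(n)
    }
    f$dv_plus <- pmax(stats::rnorm(n), 0)
    f$dv_minus <- pmax(stats::rnorm(n), 0)
    f$acc <- stats::runif(n, 0, 100)
    f$n_res <- sample(50:200, n, replace = TRUE)
    f$tm_wild <- stats::runif(n, 40, 90)
    f
  })
}

test_that("analytic gradients match central differences at random points", {
  f <- random_features(30, seed = 2)
  y <- withr::with_seed(3, stats::rnorm(30, 0, 3))
  for (model in c("hot", "tm_hot")) {
    data <- meltshift:::build_train_data(f, model)
    worst <- 0
    withr::with_seed(4, {
      for (rep in seq_len(50)) {
        v <- meltshift:::rand_init(model)
        g <- meltshift:::mse_gradient(v, data, y)$grad
        num <- vapply(seq_along(v), function(k) {
          h <- 1e-5 * max(1, abs(v[k]))
          vp <- v; vp[k] <- v[k] + h
          vm <- v; vm[k] <- v[k] - h
          (mean((meltshift:::predict_vector(vp, data) - y)^2) -
             mean((meltshift:::predict_vector(vm, data) - y)^2)) / (2 * h)
        }, numeric(1))
        worst <- max(worst, max(abs(g - num) / pmax(1, abs(g), abs(num))))
      }
    })
    expect_lt(worst, 1e-5)
  }
})

test_that("training fits a noiseless flat-weight planted model to ~0", {
  truth <- withr::with_seed(31, {
    w <- cbind(phi = stats::rnorm(12, 0, 1), r = 0, omega = 0.1, b = 50)
    hot_params(w, a = 1, c = 0.3)
  })
  f <- random_features(200, seed = 5)
  f$dtm_exp <- predict_hot(truth, f)
  ctrl <- train_control(n_restarts = 3, max_iter = 500,
                        learning_rate = 0.03, early_stop_patience = 200,
                        optimizer = "adam", polish_iter = 120, seed = 6)
  fit <- fit_dtm(f, "hot", ctrl)
  expect_lte(fit$sigma_train, 1e-3)
  # same seed -> identical selected parameters
  fit2 <- fit_dtm(f, "hot", ctrl)
  expect_identical(params_vector(fit$params), params_vector(fit2$params))
  # degenerate all-zero targets are fitted to ~0 everywhere
  f0 <- f
  f0$dtm_exp <- 0
  fit0 <- fit_dtm(f0, "hot", ctrl)
  expect_lt(fit0$sigma_train, 1e-3)
})

test_that("early stopping returns the best-validation iterate", {
  f <- random_features(150, seed = 7)
  truth <- planted_hot_params(2)
  f$dtm_exp <- predict_hot(truth, f) + withr::with_seed(8, rnorm(150, 0, 1))
  val <- f[1:30, ]
  train <- f[31:150, ]
  ctrl <- train_control(n_restarts = 2, max_iter = 300,
                        learning_rate = 0.02, early_stop_patience = 30,
                        optimizer = "adam", seed = 9)
  fit <- fit_dtm(train, "hot", ctrl, validation = val)
  # reported validation sigma is reproduced by the returned parameters
  expect_equal(meltshift:::rmse(predict(fit, val), val$dtm_exp),
               fit$sigma_valid, tolerance = 1e-12)
  expect_equal(fit$sigma_valid, min(fit$restarts$sigma_valid, na.rm = TRUE))
})

test_that("cross-validation folds partition the data deterministically", {
  f <- random_features(100, seed = 10)
  f$dtm_exp <- predict_hot(planted_hot_params(2), f)
  ctrl <- train_control(n_restarts = 1, max_iter = 50,
                        learning_rate = 0.02, early_stop_patience = 20,
                        optimizer = "adam", seed = 11)
  cv <- crossvalidate_dtm(f, "hot", ctrl, k = 5)
  expect_equal(sort(cv$predictions$row), 1:100)
  expect_equal(unname(table(cv$predictions$fold)), rep(20L, 5),
               ignore_attr = TRUE)
  cv2 <- crossvalidate_dtm(f, "hot", ctrl, k = 5)
  expect_identical(cv$predictions, cv2$predictions)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 5)
})

test_that("planted-model recovery approaches the noise floor in CV", {
  d <- fixture_dataset(n = 600, noise_sd = 2, seed = 21)
  ctrl <- train_control(n_restarts = 2, max_iter = 500,
                        learning_rate = 0.03, early_stop_patience = 150,
                        optimizer = "adam", polish_iter = 60, seed = 6)
  cv <- crossvalidate_dtm(d, "hot", ctrl, k = 5)
  g <- glance(cv)
  expect_lt(g$sigma, 2.6)
  expect_gt(g$sigma, 1.7)
  # out-of-fold predictions track the noiseless planted truth
  expect_gt(cor(cv$predictions$pred, d$dtm_true[cv$predictions$row]), 0.95)
})

test_that("curation rules reject records with the first failing reason", {
  rec <- tibble::tibble(
    protein_id = "p", chain = "A", position = as.character(1:7),
    wt = "A", mut = "G",
    dtm_exp = c(1, 25, -1, 2, 3, -21, 4),
    resolution = c(1.8, 1.8, 2.8, 1.8, 1.8, 2.6, NA),
    monomeric = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    no_denaturant = TRUE,
    two_state = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    n_sites = c(1L, 1L, 1L, 1L, 1L, 1L, 2L)
  )
  out <- filter_mutations(rec)
  expect_equal(out$keep, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reject_reason,
               c(NA, "dtm_magnitude", "resolution", "monomeric", "two_state",
                 "resolution", "multi_site"))
  # all-rejected is a valid outcome
  all_bad <- rec[rep(3, 3), ]
  expect_true(all(!filter_mutations(all_bad)$keep))
  # missing metadata columns are treated as passing
  slim <- rec[1, c("protein_id", "chain", "position", "wt", "mut", "dtm_exp")]
  expect_true(filter_mutations(slim)$keep)
})

test_that("duplicate merging keeps near-neutral-pH entries and averages", {
  rec <- tibble::tibble(
    protein_id = c("p", "p", "p", "p", "q"),
    chain = "A",
    position = c("5", "5", "5", "9", "5"),
    wt = "A", mut = "G",
    dtm_exp = c(-3, -1, -2, 7, 1),
    ph = c(6.0, 7.0, 7.2, 7.0, 5.0)
  )
  out <- merge_duplicate_mutations(rec)
  m5 <- out[out$protein_id == "p" & out$position == "5", ]
  # pH 6.0 is outside 0.5 units of the closest (7.0); average of -1, -2
  expect_equal(m5$dtm_exp, -1.5)
  expect_equal(m5$n_merged, 2)
  # singletons unchanged
  expect_equal(out$dtm_exp[out$protein_id == "q"], 1)
  expect_equal(nrow(out), 3)
  # equal-pH duplicates use the plain mean
  rec2 <- rec[1:2, ]
  rec2$ph <- c(7, 7)
  rec2$dtm_exp <- c(-2, -4)
  expect_equal(merge_duplicate_mutations(rec2)$dtm_exp, -3)
})

test_that("evaluation trims exactly floor(0.1 n) largest errors", {
  # 20 points, errors all 0 except two of 10
  obs <- rep(0, 20)
  pred <- obs
  pred[c(4, 17)] <- 10
  rep_tbl <- evaluate_dtm(pred, obs)
  expect_equal(rep_tbl$sigma, sqrt(mean(pred^2)))
  expect_equal(rep_tbl$sigma_trimmed, 0)
  # shifted predictions: sigma = shift, perfect correlation
  obs2 <- seq(-5, 5, length.out = 30)
  rep2 <- evaluate_dtm(obs2 + 1, obs2)
  expect_equal(rep2$sigma, 1)
  expect_equal(rep2$r, 1)
  expect_lte(rep2$sigma_trimmed, rep2$sigma)
  # trimming never increases sigma (random cases)
  withr::with_seed(13, {
    for (rep in 1:20) {
      n <- sample(10:60, 1)
      p <- rnorm(n); o <- rnorm(n)
      ev <- evaluate_dtm(p, o)
      expect_lte(ev$sigma_trimmed, ev$sigma)
    }
  })
  # degenerate observations give NA correlation, no warning
  expect_true(is.na(evaluate_dtm(c(1, 2, 3), c(0, 0, 0))$r))
})

test_that("accessibility strata mirror the burial classes", {
  acc <- c(5, 10, 20, 40, 60, 90)
  obs <- c(1, -1, 2, -2, 3, -3)
  pred <- obs + c(1, 1, 2, 2, 3, 3)
  ev <- evaluate_dtm(pred, obs, accessibility = acc)
  expect_equal(ev$stratum, c("all", "core", "partial", "surface"))
  expect_equal(ev$n, c(6L, 2L, 2L, 2L))
  expect_equal(ev$sigma[ev$stratum == "core"], 1)
  expect_equal(ev$sigma[ev$stratum == "partial"], 2)
  expect_equal(ev$sigma[ev$stratum == "surface"], 3)
  expect_equal(ev$sigma_over_sd[ev$stratum == "core"],
               1 / stats::sd(c(1, -1)))
})
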