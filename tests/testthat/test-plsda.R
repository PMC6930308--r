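test_that("dummy coding is exact one-hot", {
  labs <- c("a", "c", "b", "c")
  Y <- dummy_code(labs, c("a", "b", "c"))
  expect_equal(dim(Y), c(4, 3))
  expect_equal(rowSums(Y), rep(1, 4))
  expect_equal(Y[2, ], c(a = 0, b = 0, c = 1))
  expect_equal(Y[cbind(1:4, match(labs, colnames(Y)))], rep(1, 4))

  six <- dummy_code(rep(c("v1", "v2", "v3", "v4", "v5", "v6"), 5),
                    paste0("v", 1:6))
  expect_equal(ncol(six), 6)
  expect_error(dummy_code(c("a", "z"), c("a", "b")), "z")
})

test_that("rank-1 X yields one exhaustive component, then a rank error", {
  with_seed_local(21, {
    t1 <- rnorm(12)
    p1 <- rnorm(6)
    # rank-1 centered X: scores proportional to the centered t1
    Xc <- outer(t1 - mean(t1), p1)
    Y <- cbind(rnorm(12), rnorm(12))
  })
  Yc <- scale(Y, scale = FALSE)
  fit <- fit_pls2(Xc, Yc, 1)
  resid <- Xc - fit$T %*% t(fit$P)
  expect_lt(sum(resid^2), 1e-16 * sum(Xc^2))  # LV1 explains all X variance
  expect_error(fit_pls2(Xc, Yc, 2), "rank")
})

test_that("full-rank PLS equals the least-squares oracle", {
  with_seed_local(33, {
    X <- matrix(rnorm(20 * 5), 20, 5)
    Y <- matrix(rnorm(20 * 2), 20, 2)
  })
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  fit <- fit_pls2(Xc, Yc, 5)
  W <- fit$W; P <- fit$P; Q <- fit$Q
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  # normal-equations oracle
  B_ls <- solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_equal(Xc %*% B, Xc %*% B_ls, tolerance = 1e-6)
})

test_that("single-response fit reduces to PLS-1", {
  with_seed_local(44, {
    X <- matrix(rnorm(10 * 8), 10, 8)
    y <- matrix(rnorm(10), 10, 1)
  })
  Xc <- scale(X, scale = FALSE); yc <- scale(y, scale = FALSE)
  fit <- fit_pls2(Xc, yc, 3)
  # closed form: the first PLS-1 weight is X'y normalized
  w1 <- crossprod(Xc, yc)[, 1]
  w1 <- w1 / sqrt(sum(w1^2))
  expect_equal(abs(sum(fit$W[, 1] * w1)), 1, tolerance = 1e-10)

  if (requireNamespace("mixOmics", quietly = TRUE)) {
    ref <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE, mode = "regression")
    for (a in 1:3) {
      r <- abs(cor(fit$T[, a], ref$variates$X[, a]))
      expect_equal(r, 1, tolerance = 1e-6,
                   info = paste("score direction, component", a))
    }
  }
})

test_that("scores are orthogonal and training error non-increasing in LVs", {
  leaves <- tiny_leaves(seed = 19)
  pp <- preprocess_chain(leaves, preprocess_config(mean_center = FALSE))$spectra
  Y <- dummy_code(pp$labels, class_levels(pp))
  Xc <- scale(pp$x, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  fit <- fit_pls2(Xc, Yc, 8)
  G <- crossprod(fit$T)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-8 * max(diag(G)))

  errs <- vapply(1:8, function(a) {
    model <- fit_plsda(pp, n_lv = a)
    mean(predict(model, pp)$assigned != pp$labels)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("adding a constant to every spectrum leaves predictions unchanged", {
  sp <- separable_spectra()
  m1 <- fit_plsda(sp, n_lv = 2)
  shifted <- replace_matrix_for_test(sp, sp$x + 5)
  m2 <- fit_plsda(shifted, n_lv = 2)
  expect_equal(predict(m1, sp)$y_hat, predict(m2, shifted)$y_hat,
               tolerance = 1e-8)
})

test_that("CV selects the smallest LV count at minimum error", {
  sp <- separable_spectra(n_per_class = 10)
  folds <- venetian_blinds(sp$sample_id, n_splits = 5)
  sel <- select_n_lv(sp, c("a", "b"), folds, max_lv = 6)
  expect_equal(min(sel$error_by_lv), 0)
  expect_equal(sel$n_lv, min(which(sel$error_by_lv == 0)))

  sel1 <- select_n_lv(sp, c("a", "b"), folds, max_lv = 1)
  expect_equal(sel1$n_lv, 1L)
})

test_that("uninformative labels give chance-level CV error", {
  errs <- vapply(1:5, function(s) {
    with_seed_local(100 + s, {
      X <- matrix(rnorm(40 * 12), 40, 12)
      lab <- rep(c("a", "b", "c", "d"), 10)
      sp <- as_spectra(X, labels = lab)
      folds <- venetian_blinds(sp$sample_id, n_splits = 5)
      sel <- select_n_lv(sp, unique(lab), folds, max_lv = 3)
      mean(sel$assignments[sp$sample_id] != sp$labels)
    })
  }, numeric(1))
  # chance error for 4 balanced classes is 0.75; allow binomial noise and
  # the slight optimism of picking the best-looking LV count
  expect_gt(mean(errs), 0.65)
  expect_lt(mean(errs), 0.85)
})

test_that("prediction recovers separable classes and near-dummy scores", {
  sp <- separable_spectra(n_per_class = 12, seed = 9)
  model <- fit_plsda(sp, n_lv = 3)
  pred <- predict(model, sp)
  expect_equal(unname(pred$assigned), sp$labels)  # 100% on training
  Y <- dummy_code(sp$labels, model$class_order)
  expect_lt(max(abs(pred$y_hat - Y)), 0.2)  # values near 1 / 0

  dup <- subset_samples(sp, c(1, 1))
  pd <- predict(model, dup)
  expect_identical(pd$y_hat[1, ], pd$y_hat[2, ])

  wrong_axis <- as_spectra(sp$x[, -1], axis = sp$axis[-1], labels = sp$labels)
  expect_error(predict(model, wrong_axis), "axis")
})

test_that("thresholds minimize calibration misclassifications", {
  y_hat <- cbind(a = c(0.8, 0.9, 0.1, 0.2), b = c(0.2, 0.1, 0.9, 0.8))
  labels <- c("a", "a", "b", "b")
  thr <- estimate_thresholds(y_hat, labels, c("a", "b"))
  expect_equal(unname(thr["a"]), 0.5)  # midpoint of 0.2 and 0.8

  # overlapping scores: compare against an exhaustive scan oracle
  with_seed_local(55, {
    s <- c(rnorm(20, 1, 0.8), rnorm(30, 0, 0.8))
  })
  labs <- c(rep("x", 20), rep("y", 30))
  y2 <- cbind(x = s, y = -s)
  thr2 <- estimate_thresholds(y2, labs, c("x", "y"))
  err_at <- function(th) sum(labs == "x" & s < th) + sum(labs != "x" & s >= th)
  grid_err <- min(vapply(sort(s) + 1e-9, err_at, numeric(1)),
                  err_at(min(s) - 1))
  expect_equal(err_at(thr2["x"]), grid_err)
  expect_gt(thr2["x"], min(s))
  expect_lt(thr2["x"], max(s))

  expect_error(estimate_thresholds(y_hat, labels, c("a", "b", "c")), "absent")
})

test_that("fitted models persist and reload for prediction", {
  sp <- separable_spectra()
  model <- fit_plsda(sp, n_lv = 2)
  dir <- withr::local_tempdir()
  write_plsda_model(model, dir)
  back <- read_plsda_model(dir)
  expect_equal(back$n_lv, model$n_lv)
  expect_equal(back$class_order, model$class_order)
  expect_equal(predict(back, sp)$y_hat, predict(model, sp)$y_hat,
               tolerance = 1e-10)
})
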