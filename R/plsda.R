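#' One-hot (dummy) coding of class labels
#'
#' Builds the PLS-DA response block: one column per class, a 1 where the
#' sample belongs to that class and 0 elsewhere, so each row sums to 1.
#'
#' @param labels character vector of class labels.
#' @param class_order ordered vector of class names (columns of the
#'   result).
#' @return numeric matrix `length(labels)` x `length(class_order)` with
#'   column names `class_order`.
#' @export
dummy_code <- function(labels, class_order) {
  labels <- as.character(labels)
  unknown <- setdiff(labels, class_order)
  if (length(unknown)) {
    stop("labels not in class_order: ", paste(unique(unknown), collapse = ", "))
  }
  Y <- matrix(0, length(labels), length(class_order),
              dimnames = list(NULL, class_order))
  Y[cbind(seq_along(labels), match(labels, class_order))] <- 1
  Y
}

#' NIPALS PLS-2 decomposition
#'
#' Fits `n_lv` latent variables to centered blocks `Xc` (spectra) and
#' `Yc` (centered dummy responses) by the NIPALS algorithm with
#' X-deflation only. Each component maximizes covariance between an
#' X-score and the response block.
#'
#' @param Xc centered predictor matrix (n x p).
#' @param Yc centered response matrix (n x m).
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n - 1, p)`.
#' @param tol convergence tolerance on the relative change of the X-score
#'   within a component (default 1e-12).
#' @param max_iter inner-loop iteration cap per component (default 10000).
#' @return list with matrices `W` (p x a, unit-norm X-weights), `T`
#'   (n x a scores), `P` (p x a X-loadings), `Q` (m x a Y-loadings).
#' @export
fit_pls2 <- function(Xc, Yc, n_lv, tol = 1e-12, max_iter = 10000L) {
  Xc <- as.matrix(Xc); Yc <- as.matrix(Yc)
  n <- nrow(Xc); p <- ncol(Xc); m <- ncol(Yc)
  if (n_lv < 1) stop("n_lv must be at least 1")
  if (n_lv > min(n - 1, p)) {
    stop("n_lv exceeds min(n_samples - 1, n_variables)")
  }
  W <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv)
  P <- matrix(0, p, n_lv); Q <- matrix(0, m, n_lv)
  E <- Xc
  x_ss0 <- sum(Xc^2)
  for (a in seq_len(n_lv)) {
    if (sum(E^2) <= 1e-12 * max(x_ss0, 1)) {
      stop("X block exhausted: rank lower than the requested ", n_lv,
           " latent variables (component ", a, ")")
    }
    u <- Yc[, which.max(colSums(Yc^2)), drop = FALSE]
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tt <- E %*% w
      q <- crossprod(Yc, tt)[, 1] / sum(tt^2)
      u <- Yc %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) {
        converged <- TRUE
        break
      }
      t_old <- tt
    }
    if (!converged) {
      stop("NIPALS inner loop did not converge within ", max_iter,
           " iterations (component ", a, ")")
    }
    tt_ss <- sum(tt^2)
    if (tt_ss <= 1e-12 * max(x_ss0, 1)) {
      stop("degenerate score in component ", a, "; reduce n_lv")
    }
    pp <- crossprod(E, tt)[, 1] / tt_ss
    E <- E - tt %*% t(pp)
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- pp; Q[, a] <- q
  }
  list(W = W, T = Tm, P = P, Q = Q)
}

# regression coefficients from a NIPALS decomposition truncated to `a`
# components: B = W_a (P_a' W_a)^-1 Q_a'
pls_coefficients <- function(fit, a = ncol(fit$W)) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  Q <- fit$Q[, seq_len(a), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  R %*% t(Q)
}

#' Fit a multi-class PLS-DA model
#'
#' Takes preprocessed (SNV + SG derivative), uncentered calibration
#' spectra; fits the per-wavenumber centering, dummy-codes the labels,
#' runs NIPALS PLS-2 and stores the regression coefficients for the
#' selected number of latent variables. When `n_lv` is `NULL` it is
#' selected by venetian-blinds cross-validation via [select_n_lv()].
#'
#' @param train a `spectra_set` of calibration spectra (uncentered).
#' @param class_order ordered class names; default the classes present.
#' @param n_lv number of latent variables, or `NULL` to select by CV.
#' @param max_lv largest candidate when selecting (default 20).
#' @param folds a [venetian_blinds()] assignment; default 10 folds of
#'   thickness 1 over the calibration samples ordered by class.
#' @return an object of class `plsda_model`.
#' @export
fit_plsda <- function(train, class_order = NULL, n_lv = NULL, max_lv = 20,
                      folds = NULL) {
  stopifnot(inherits(train, "spectra_set"))
  if (is.null(class_order)) class_order <- class_levels(train)
  Y <- dummy_code(train$labels, class_order)
  centering <- fit_mean_center(train)
  Xc <- sweep(train$x, 2, centering$column_means)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  max_lv <- min(max_lv, nrow(Xc) - 1L, ncol(Xc))
  cv <- NULL
  if (is.null(n_lv)) {
    if (is.null(folds)) folds <- venetian_blinds(train$sample_id)
    cv <- select_n_lv(train, class_order, folds, max_lv)
    n_lv <- cv$n_lv
  }
  fit <- fit_pls2(Xc, Yc, n_lv)
  B <- pls_coefficients(fit, n_lv)
  dimnames(B) <- list(format_wavenumber(train$axis), class_order)
  model <- structure(
    list(W = fit$W, T = fit$T, P = fit$P, Q = fit$Q, B = B,
         n_lv = as.integer(n_lv), class_order = class_order,
         centering = centering, y_means = y_means,
         axis = train$axis, sample_type = train$sample_type,
         thresholds = NULL, cv = cv),
    class = "plsda_model"
  )
  cal_pred <- predict(model, train)
  model$thresholds <- estimate_thresholds(cal_pred$y_hat, train$labels,
                                          class_order)
  model
}

#' @export
print.plsda_model <- function(x, ...) {
  cat("<plsda_model> ", length(x$class_order), " classes, ",
      x$n_lv, " latent variables, ", nrow(x$B), " wavenumbers\n", sep = "")
  invisible(x)
}

#' Select the number of latent variables by cross-validation
#'
#' For each candidate count the venetian-blinds folds are left out in
#' turn; centering (X column means and Y means) and the PLS-2 model are
#' refit on the in-fold calibration samples, so no information leaks from
#' the held-out blind. The classification error is the mean over classes
#' of the per-class error of the pooled out-of-fold hard (argmax)
#' assignments; the smallest count achieving the minimum error wins.
#'
#' @param train a `spectra_set` of calibration spectra (uncentered).
#' @param class_order ordered class names.
#' @param folds a [venetian_blinds()] assignment over `train$sample_id`.
#' @param max_lv largest candidate count.
#' @return list with `n_lv` (selected), `error_by_lv` (mean per-class CV
#'   error per candidate) and `assignments` (pooled out-of-fold class
#'   assignments at the selected count, named by sample id).
#' @export
select_n_lv <- function(train, class_order, folds, max_lv) {
  stopifnot(inherits(folds, "cv_folds"))
  if (max_lv < 1) stop("max_lv must be at least 1")
  ids <- names(folds$fold_of)
  if (!setequal(ids, train$sample_id)) {
    stop("fold assignment does not cover the calibration samples")
  }
  pos <- match(ids, train$sample_id)
  Y <- dummy_code(train$labels, class_order)
  n_fold <- folds$n_splits
  assigned <- matrix(NA_character_, length(ids), max_lv,
                     dimnames = list(ids, NULL))
  for (f in seq_len(n_fold)) {
    held <- which(folds$fold_of == f)
    tr <- pos[-held]; te <- pos[held]
    xm <- colMeans(train$x[tr, , drop = FALSE])
    ym <- colMeans(Y[tr, , drop = FALSE])
    Xc <- sweep(train$x[tr, , drop = FALSE], 2, xm)
    Yc <- sweep(Y[tr, , drop = FALSE], 2, ym)
    a_max <- min(max_lv, length(tr) - 1L, ncol(Xc))
    fit <- fit_pls2(Xc, Yc, a_max)
    Xte <- sweep(train$x[te, , drop = FALSE], 2, xm)
    for (a in seq_len(max_lv)) {
      Bf <- pls_coefficients(fit, min(a, a_max))
      yh <- sweep(Xte %*% Bf, 2, ym, "+")
      assigned[held, a] <- class_order[max.col(yh, ties.method = "first")]
    }
  }
  truth <- train$labels[pos]
  error_by_lv <- vapply(seq_len(max_lv), function(a) {
    per_class <- vapply(class_order, function(cls) {
      in_cls <- truth == cls
      mean(assigned[in_cls, a] != cls)
    }, numeric(1))
    mean(per_class)
  }, numeric(1))
  n_lv <- which.min(error_by_lv)  # first index: smallest count at the minimum
  list(n_lv = as.integer(n_lv), error_by_lv = error_by_lv,
       assignments = stats::setNames(assigned[, n_lv], ids))
}

#' Predict classes for preprocessed spectra
#'
#' Centers the spectra with the model's calibration means, applies the
#' regression coefficients and adds back the response means; the class is
#' the column with the largest prediction value (ties resolved toward the
#' earliest class in `class_order`).
#'
#' @param object a `plsda_model`.
#' @param spectra a `spectra_set` on the model's training axis
#'   (preprocessed, uncentered).
#' @param ... unused.
#' @return list with `y_hat` (n x classes continuous predictions) and
#'   `assigned` (character vector of class assignments).
#' @export
predict.plsda_model <- function(object, spectra, ...) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (length(spectra$axis) != length(object$axis) ||
      any(spectra$axis != object$axis)) {
    stop("spectra axis does not match the model's training axis")
  }
  Xc <- sweep(spectra$x, 2, object$centering$column_means)
  y_hat <- sweep(Xc %*% object$B, 2, object$y_means, "+")
  rownames(y_hat) <- spectra$sample_id
  assigned <- object$class_order[max.col(y_hat, ties.method = "first")]
  list(y_hat = y_hat, assigned = stats::setNames(assigned, spectra$sample_id))
}

#' Per-class decision thresholds on the prediction values
#'
#' For each class, scans the midpoints between consecutive distinct
#' calibration prediction values and returns the threshold minimizing the
#' in-class-vs-rest misclassification count (score >= threshold means
#' "in class"). Among equally good candidates the one with the widest
#' margin to the nearest observed value is kept. These thresholds are
#' diagnostics; hard class assignment remains argmax.
#'
#' @param y_hat calibration prediction matrix (n x classes, named
#'   columns).
#' @param labels true calibration labels.
#' @param class_order ordered class names.
#' @return named numeric vector of per-class thresholds.
#' @export
estimate_thresholds <- function(y_hat, labels, class_order) {
  missing_cls <- setdiff(class_order, labels)
  if (length(missing_cls)) {
    stop("class absent from calibration predictions: ",
         paste(missing_cls, collapse = ", "))
  }
  thr <- stats::setNames(numeric(length(class_order)), class_order)
  for (cls in class_order) {
    s <- y_hat[, cls]
    in_cls <- labels == cls
    vals <- sort(unique(s))
    if (length(vals) < 2) {
      stop("degenerate prediction values for class ", cls)
    }
    cand <- (vals[-1] + vals[-length(vals)]) / 2
    err <- vapply(cand, function(th) {
      sum(in_cls & s < th) + sum(!in_cls & s >= th)
    }, numeric(1))
    margin <- vapply(cand, function(th) min(abs(s - th)), numeric(1))
    best <- which(err == min(err))
    thr[cls] <- cand[best[which.max(margin[best])]]
  }
  thr
}

#' Persist / load a fitted PLS-DA model as a directory
#'
#' Writes `coefficients.csv` (wavenumber x class regression coefficients),
#' `centering.csv` (wavenumber, mean), `y_means.csv`, `thresholds.csv` and
#' a flat `metadata.txt` (`key: value` lines for n_lv, sample_type and
#' class order). `read_plsda_model()` reconstructs a model sufficient for
#' prediction and reporting (score matrices are not persisted).
#'
#' @param model a `plsda_model`.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly / a `plsda_model`.
#' @export
write_plsda_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(wavenumber = model$axis, model$B,
                              check.names = FALSE),
                   file.path(dir, "coefficients.csv"), row.names = FALSE)
  write_centering(model$centering, file.path(dir, "centering.csv"))
  utils::write.csv(data.frame(class = model$class_order,
                              y_mean = unname(model$y_means),
                              threshold = unname(model$thresholds)),
                   file.path(dir, "y_means.csv"), row.names = FALSE)
  writeLines(c(paste("n_lv:", model$n_lv),
               paste("sample_type:", model$sample_type),
               paste("class_order:", paste(model$class_order, collapse = ","))),
             file.path(dir, "metadata.txt"))
  if (!is.null(model$W)) {
    # decomposition matrices, needed to recompute importance indicators
    utils::write.csv(as.data.frame(model$W),
                     file.path(dir, "x_weights.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(model$P),
                     file.path(dir, "x_loadings.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(model$T),
                     file.path(dir, "x_scores.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(model$Q),
                     file.path(dir, "y_loadings.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_plsda_model
#' @export
read_plsda_model <- function(dir) {
  meta <- readLines(file.path(dir, "metadata.txt"))
  get_val <- function(key) {
    line <- grep(paste0("^", key, ":"), meta, value = TRUE)
    trimws(sub(paste0("^", key, ":"), "", line))
  }
  class_order <- strsplit(get_val("class_order"), ",")[[1]]
  co <- utils::read.csv(file.path(dir, "coefficients.csv"), check.names = FALSE)
  ym <- utils::read.csv(file.path(dir, "y_means.csv"))
  B <- as.matrix(co[, class_order, drop = FALSE])
  rownames(B) <- format_wavenumber(co$wavenumber)
  read_mat <- function(name) {
    path <- file.path(dir, name)
    if (file.exists(path)) unname(as.matrix(utils::read.csv(path))) else NULL
  }
  structure(
    list(W = read_mat("x_weights.csv"), T = read_mat("x_scores.csv"),
         P = read_mat("x_loadings.csv"), Q = read_mat("y_loadings.csv"),
         B = B,
         n_lv = as.integer(get_val("n_lv")), class_order = class_order,
         centering = read_centering(file.path(dir, "centering.csv")),
         y_means = stats::setNames(ym$y_mean, ym$class),
         axis = co$wavenumber,
         sample_type = get_val("sample_type"),
         thresholds = stats::setNames(ym$threshold, ym$class), cv = NULL),
    class = "plsda_model"
  )
}
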