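#' Variable importance in projection (VIP)
#'
#' Per-wavenumber VIP for a multi-response PLS-DA model:
#' `VIP_j = sqrt(p * sum_a ssy_a * (w_aj / ||w_a||)^2 / sum_a ssy_a)`
#' where `p` is the number of wavenumbers, `w_a` the a-th X-weight vector
#' and `ssy_a = (q_a' q_a)(t_a' t_a)` the response variance captured by
#' component a (summed over the dummy columns). The scores satisfy
#' `sum(VIP^2) = p`; values close to or greater than 1 mark relevant
#' variables.
#'
#' @param model a fitted `plsda_model` (with score/weight matrices).
#' @return numeric vector of VIP scores, one per wavenumber.
#' @export
vip_scores <- function(model) {
  if (is.null(model$W)) stop("model lacks the decomposition matrices")
  a <- model$n_lv
  W <- model$W[, seq_len(a), drop = FALSE]
  Tm <- model$T[, seq_len(a), drop = FALSE]
  Q <- model$Q[, seq_len(a), drop = FALSE]
  ssy <- colSums(Q^2) * colSums(Tm^2)
  if (sum(ssy) <= 0) stop("model explains no response variance")
  Wn2 <- sweep(W^2, 2, colSums(W^2), "/")   # (w_aj/||w_a||)^2
  p <- nrow(W)
  vip <- sqrt(p * as.vector(Wn2 %*% ssy) / sum(ssy))
  stats::setNames(vip, rownames(model$B))
}

#' Target-projection selectivity ratio
#'
#' Projects the centered spectra onto the direction of one class's
#' regression-coefficient vector (the target-projected component
#' `t_TP = Xc b / ||b||`), reconstructs the explained part of each
#' spectral variable from that single component
#' (`p_TP = Xc' t_TP / (t_TP' t_TP)`), and returns the per-variable ratio
#' of explained to residual variance. Large ratios mark variables useful
#' for predicting that class. Residual variances below `1e-12` of the
#' variable's total variance are treated as zero and the ratio is capped.
#'
#' @param model a fitted `plsda_model`.
#' @param Xc centered calibration spectra (the matrix the model was
#'   fitted on).
#' @param class_index class column (integer index or class name).
#' @param cap ceiling for ratios with (near-)zero residual (default 1e12).
#' @return numeric vector of selectivity ratios, one per wavenumber.
#' @export
selectivity_ratio <- function(model, Xc, class_index, cap = 1e12) {
  if (is.character(class_index)) {
    class_index <- match(class_index, model$class_order)
  }
  if (is.na(class_index) || class_index < 1 ||
      class_index > length(model$class_order)) {
    stop("invalid class_index")
  }
  b <- model$B[, class_index]
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("zero regression vector for class ",
                    model$class_order[class_index])
  t_tp <- as.vector(Xc %*% (b / nb))
  p_tp <- as.vector(crossprod(Xc, t_tp)) / sum(t_tp^2)
  explained <- outer(t_tp, p_tp)
  resid <- Xc - explained
  v_exp <- colSums(explained^2)
  v_res <- colSums(resid^2)
  total <- v_exp + v_res
  sr <- ifelse(v_res <= 1e-12 * pmax(total, .Machine$double.eps),
               cap, v_exp / pmax(v_res, .Machine$double.xmin))
  pmin(stats::setNames(sr, rownames(model$B)), cap)
}

#' Regression-coefficient vector for one class
#'
#' @param model a fitted `plsda_model`.
#' @param class_index class column (integer index or class name).
#' @return the class's column of the coefficient matrix B; its magnitude
#'   is the third variable-importance indicator.
#' @export
regression_vector <- function(model, class_index) {
  if (is.character(class_index)) {
    class_index <- match(class_index, model$class_order)
  }
  if (is.na(class_index) || class_index < 1 ||
      class_index > length(model$class_order)) {
    stop("invalid class_index")
  }
  model$B[, class_index]
}

#' All three importance indicators on one axis
#'
#' Computes VIP, per-class selectivity ratios (aggregated across classes
#' by the elementwise maximum) and per-class absolute regression
#' coefficients for a fitted model, together with the spectral cut point
#' used for truncation (defaults: 6700 cm^-1 for dried, 7500 cm^-1 for
#' fresh — the low-wavenumber side is retained).
#'
#' @param model a fitted `plsda_model`.
#' @param train the calibration `spectra_set` the model was fitted on
#'   (uncentered).
#' @param cut_wavenumber upper bound of the retained window; `NULL` picks
#'   the default for the model's sample type.
#' @return an `importance_profile`: list with `axis`, `vip`, `sr` (matrix
#'   wavenumber x class), `sr_aggregated`, `reg_vector` (matrix), and
#'   `cut_wavenumber`.
#' @export
importance_profile <- function(model, train, cut_wavenumber = NULL) {
  stopifnot(inherits(train, "spectra_set"))
  if (is.null(cut_wavenumber)) {
    cut_wavenumber <- default_cut(model$sample_type)
  }
  Xc <- sweep(train$x, 2, model$centering$column_means)
  sr <- vapply(seq_along(model$class_order),
               function(ci) selectivity_ratio(model, Xc, ci),
               numeric(length(model$axis)))
  colnames(sr) <- model$class_order
  structure(
    list(axis = model$axis,
         vip = vip_scores(model),
         sr = sr,
         sr_aggregated = apply(sr, 1, max),
         reg_vector = model$B,
         cut_wavenumber = cut_wavenumber),
    class = "importance_profile"
  )
}

#' Default spectral cut point per sample type
#' @param sample_type `"fresh"` or `"dried"`.
#' @return wavenumber (cm^-1) above which variables are discarded:
#'   6700 for dried-powdered leaves, 7500 for fresh leaves.
#' @export
default_cut <- function(sample_type = c("dried", "fresh")) {
  switch(match.arg(sample_type), dried = 6700, fresh = 7500)
}

#' Truncate spectra to the informative low-wavenumber window
#'
#' Keeps the wavenumbers `<= cut_wavenumber`, preserving order. The
#' high-wavenumber region (7500-10000 cm^-1) of leaf spectra carries no
#' class-discriminating bands and is discarded before refitting.
#'
#' @param spectra a `spectra_set`.
#' @param cut_wavenumber upper bound in cm^-1.
#' @return the truncated `spectra_set`.
#' @export
truncate_spectra <- function(spectra, cut_wavenumber) {
  stopifnot(inherits(spectra, "spectra_set"))
  keep <- spectra$axis <= cut_wavenumber
  if (!any(keep)) {
    stop("cut at ", cut_wavenumber, " cm^-1 removes every wavenumber")
  }
  replace_matrix(spectra, spectra$x[, keep, drop = FALSE],
                 axis = spectra$axis[keep])
}

#' Export an importance profile as CSV
#'
#' Columns: wavenumber, vip, sr_aggregated, then `abs_b_<class>` per
#' class, suitable for plotting the three indicator profiles.
#'
#' @param profile an `importance_profile`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_importance <- function(profile, path) {
  df <- data.frame(wavenumber = profile$axis,
                   vip = unname(profile$vip),
                   sr_aggregated = unname(profile$sr_aggregated))
  ab <- abs(profile$reg_vector)
  colnames(ab) <- paste0("abs_b_", colnames(ab))
  utils::write.csv(cbind(df, ab), path, row.names = FALSE)
  invisible(path)
}
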