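#' Kennard-Stone subset selection
#'
#' Deterministic max-min selection of `k` representative rows of `X`:
#' the pair with the largest Euclidean distance is selected first, then
#' each step adds the candidate whose minimum distance to the selected
#' set is largest. Ties are broken toward the lowest row index.
#'
#' @param X numeric matrix (samples x variables) for one class.
#' @param k number of rows to select, `2 <= k <= nrow(X)`.
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone_select <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2) stop("Kennard-Stone requires k >= 2")
  if (k > n) stop("cannot select more rows than available")
  D <- as.matrix(stats::dist(X))
  # seed pair: maximal pairwise distance, lowest indices on ties
  best <- c(1L, 2L)
  best_d <- -Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (D[i, j] > best_d) {
        best_d <- D[i, j]
        best <- c(i, j)
      }
    }
  }
  selected <- best
  if (k > 2) {
    mind <- pmin(D[, selected[1]], D[, selected[2]])
    for (step in 3:k) {
      mind[selected] <- -Inf
      cand <- which.max(mind)  # which.max takes the first (lowest index) tie
      selected <- c(selected, cand)
      mind <- pmin(mind, D[, cand])
    }
  }
  as.integer(selected)
}

#' Calibration/test split, per class
#'
#' Splits a spectra set into calibration and test subsets class by class,
#' with `round(fraction * class size)` calibration samples per class
#' (half-up rounding). The Kennard-Stone distances are computed on the
#' supplied spectra as-is; the pipeline passes SNV + SG-preprocessed,
#' uncentered spectra.
#'
#' @param spectra a `spectra_set` (one row per leaf).
#' @param fraction calibration proportion in (0, 1] (default 0.7).
#' @param method `"kennard_stone"` (deterministic) or `"random"`.
#' @param seed RNG seed for the random method.
#' @return a `split_index`: list with `calibration_ids`, `test_ids`,
#'   `method`, `fraction`.
#' @export
split_per_class <- function(spectra, fraction = 0.7,
                            method = c("kennard_stone", "random"),
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(spectra, "spectra_set"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (anyDuplicated(spectra$sample_id)) {
    stop("split requires one row per sample; average replicates first")
  }
  classes <- class_levels(spectra)
  cal <- character(0)
  for (cls in classes) {
    rows <- which(spectra$labels == cls)
    n <- length(rows)
    if (n < 3) stop("class '", cls, "' has fewer than 3 samples")
    k <- floor(fraction * n + 0.5)  # half-up
    k <- max(0L, min(n, k))
    if (k == n) {
      pick <- seq_len(n)
    } else if (method == "kennard_stone") {
      pick <- kennard_stone_select(spectra$x[rows, , drop = FALSE], k)
    } else {
      pick <- with_rng(seed + match(cls, classes), sample(n, k))
    }
    cal <- c(cal, spectra$sample_id[rows[sort(pick)]])
  }
  test <- setdiff(spectra$sample_id, cal)
  if (length(test) == 0) warning("empty test set (fraction = ", fraction, ")")
  structure(list(calibration_ids = cal, test_ids = test,
                 method = method, fraction = fraction),
            class = "split_index")
}

#' Venetian-blinds cross-validation folds
#'
#' Assigns the sample at ordered position `i` (0-based) to fold
#' `floor(i / thickness) %% n_splits`. With thickness 1 this interleaves
#' consecutive samples across all folds.
#'
#' @param ids ordered vector of calibration sample ids.
#' @param n_splits number of folds (default 10).
#' @param thickness samples per blind (default 1).
#' @return a `cv_folds`: list with `fold_of` (named integer vector of
#'   1-based fold indices) and `n_splits`.
#' @export
venetian_blinds <- function(ids, n_splits = 10, thickness = 1) {
  if (n_splits < 2) stop("n_splits must be at least 2")
  if (thickness < 1) stop("thickness must be at least 1")
  if (length(ids) < n_splits) {
    stop("fewer calibration samples (", length(ids),
         ") than folds (", n_splits, ")")
  }
  i <- seq_along(ids) - 1L
  fold <- (i %/% thickness) %% n_splits + 1L
  structure(list(fold_of = stats::setNames(as.integer(fold), ids),
                 n_splits = as.integer(n_splits),
                 thickness = as.integer(thickness)),
            class = "cv_folds")
}

#' Write a split (or fold) assignment as two-column CSV
#' @param split a `split_index` or `cv_folds`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_assignment <- function(split, path) {
  df <- if (inherits(split, "split_index")) {
    data.frame(sample_id = c(split$calibration_ids, split$test_ids),
               assignment = c(rep("calibration", length(split$calibration_ids)),
                              rep("test", length(split$test_ids))))
  } else {
    data.frame(sample_id = names(split$fold_of),
               assignment = unname(split$fold_of))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
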