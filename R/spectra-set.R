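#' Spectra container for NIR leaf measurements
#'
#' A `spectra_set` bundles a sample-by-wavenumber matrix with its spectral
#' axis and the sample metadata used throughout the pipeline: class labels
#' (variety), tree and replicate identifiers, and the sample type
#' ("fresh" or "dried").
#'
#' @param x numeric matrix, one row per spectrum, one column per wavenumber.
#'   Values are absorbance (log10(1/R)) unless `unit = "reflectance"`.
#' @param axis numeric vector of wavenumbers in cm^-1, strictly monotone
#'   (descending by instrument convention), length equal to `ncol(x)`.
#' @param labels character or factor of class labels, one per row.
#' @param sample_id character vector of per-leaf sample identifiers.
#' @param tree_id optional character/integer vector of tree identifiers.
#' @param replicate_id optional integer vector of instrument-replicate
#'   indices; `NULL` once replicates have been averaged.
#' @param sample_type one of `"fresh"`, `"dried"`.
#' @param unit `"absorbance"` or `"reflectance"`.
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `x`, `axis`, `labels`, `sample_id`, `tree_id`, `replicate_id`,
#'   `sample_type`, `unit`.
#' @export
spectra_set <- function(x, axis, labels, sample_id,
                        tree_id = NULL, replicate_id = NULL,
                        sample_type = c("fresh", "dried"),
                        unit = c("absorbance", "reflectance")) {
  sample_type <- match.arg(sample_type)
  unit <- match.arg(unit)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  axis <- as.numeric(axis)
  if (ncol(x) != length(axis)) {
    stop("number of spectral columns (", ncol(x),
         ") does not match axis length (", length(axis), ")")
  }
  d <- diff(axis)
  if (length(axis) > 1 && !(all(d > 0) || all(d < 0))) {
    stop("wavenumber axis must be strictly monotone")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("spectral matrix contains missing or non-finite values")
  }
  labels <- as.character(labels)
  sample_id <- as.character(sample_id)
  n <- nrow(x)
  if (length(labels) != n || length(sample_id) != n) {
    stop("labels and sample_id must have one entry per spectrum")
  }
  if (!is.null(tree_id) && length(tree_id) != n) {
    stop("tree_id must have one entry per spectrum")
  }
  if (!is.null(replicate_id) && length(replicate_id) != n) {
    stop("replicate_id must have one entry per spectrum")
  }
  colnames(x) <- format_wavenumber(axis)
  rownames(x) <- NULL
  structure(
    list(x = x, axis = axis, labels = labels, sample_id = sample_id,
         tree_id = if (is.null(tree_id)) NULL else as.character(tree_id),
         replicate_id = if (is.null(replicate_id)) NULL else as.integer(replicate_id),
         sample_type = sample_type, unit = unit),
    class = "spectra_set"
  )
}

format_wavenumber <- function(axis) {
  # integer-looking wavenumbers print without decimals in CSV headers
  ifelse(axis == round(axis), format(axis, trim = TRUE, scientific = FALSE),
         format(axis, trim = TRUE, scientific = FALSE, digits = 10))
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$x), " spectra x ", length(x$axis),
      " wavenumbers (", x$sample_type, ", ", x$unit, ")\n", sep = "")
  cat("  axis: ", max(x$axis), " .. ", min(x$axis), " cm^-1\n", sep = "")
  cat("  classes: ", paste(class_levels(x), collapse = ", "), "\n", sep = "")
  if (!is.null(x$replicate_id)) {
    cat("  replicates per leaf: up to ", max(x$replicate_id), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$x)

#' Class labels present in a spectra set, in order of first appearance
#' @param spectra a `spectra_set`
#' @return character vector of class names
#' @export
class_levels <- function(spectra) unique(spectra$labels)

#' Subset a spectra set by sample
#'
#' @param spectra a `spectra_set`
#' @param i integer or logical row index
#' @return a `spectra_set` with the selected spectra
#' @export
subset_samples <- function(spectra, i) {
  spectra_set(spectra$x[i, , drop = FALSE], spectra$axis,
              spectra$labels[i], spectra$sample_id[i],
              tree_id = if (is.null(spectra$tree_id)) NULL else spectra$tree_id[i],
              replicate_id = if (is.null(spectra$replicate_id)) NULL else spectra$replicate_id[i],
              sample_type = spectra$sample_type, unit = spectra$unit)
}

#' Replace the spectral matrix, keeping metadata
#'
#' Internal helper used by the preprocessing stages; `axis` may shrink
#' (derivative edge trimming, spectral truncation).
#' @noRd
replace_matrix <- function(spectra, x, axis = spectra$axis, unit = spectra$unit) {
  spectra_set(x, axis, spectra$labels, spectra$sample_id,
              tree_id = spectra$tree_id, replicate_id = spectra$replicate_id,
              sample_type = spectra$sample_type, unit = unit)
}

# run code with a private RNG stream; the global .Random.seed is untouched
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
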