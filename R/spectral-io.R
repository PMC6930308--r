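#' Write a spectra set to CSV
#'
#' Layout: columns `sample_id`, `class`, `tree_id`, `replicate_id`,
#' `sample_type`, then one column per wavenumber named by its value in
#' cm^-1 (e.g. "12000", "11996", ...). One row per spectrum. Numbers are
#' written at full double precision so a write/read round trip is
#' lossless.
#'
#' @param spectra a `spectra_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  n <- nrow(spectra$x)
  meta <- data.frame(
    sample_id = spectra$sample_id,
    class = spectra$labels,
    tree_id = if (is.null(spectra$tree_id)) rep(NA_character_, n) else spectra$tree_id,
    replicate_id = if (is.null(spectra$replicate_id)) rep(NA_integer_, n) else spectra$replicate_id,
    sample_type = rep(spectra$sample_type, n),
    stringsAsFactors = FALSE
  )
  spec_cols <- as.data.frame(spectra$x)
  names(spec_cols) <- format_wavenumber(spectra$axis)
  df <- cbind(meta, spec_cols)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectra set from CSV
#'
#' Expects the layout written by [write_spectra()]; `tree_id` and
#' `replicate_id` columns may be absent (the file is then treated as one
#' replicate per sample). The wavenumber axis is parsed from the column
#' headers and must be strictly monotone.
#'
#' @param path CSV file path.
#' @param expected_type `"fresh"`, `"dried"` or `"any"`; when not `"any"`,
#'   a file with a different `sample_type` raises an error.
#' @param unit unit of the stored values (`"absorbance"` default).
#' @return a `spectra_set`.
#' @export
read_spectra <- function(path, expected_type = c("any", "fresh", "dried"),
                         unit = c("absorbance", "reflectance")) {
  expected_type <- match.arg(expected_type)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "class", "sample_type")
  if (!all(required %in% names(df))) {
    stop("spectra CSV must contain columns: ", paste(required, collapse = ", "))
  }
  meta_cols <- intersect(c("sample_id", "class", "tree_id", "replicate_id",
                           "sample_type"), names(df))
  axis_names <- setdiff(names(df), meta_cols)
  axis <- suppressWarnings(as.numeric(axis_names))
  if (anyNA(axis)) {
    stop("non-numeric wavenumber column headers: ",
         paste(utils::head(axis_names[is.na(axis)], 3), collapse = ", "))
  }
  d <- diff(axis)
  if (length(axis) > 1 && !(all(d > 0) || all(d < 0))) {
    stop("wavenumber columns are not in monotone order")
  }
  x <- as.matrix(df[, axis_names, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("spectral matrix contains missing values")
  stype <- unique(df$sample_type)
  if (length(stype) != 1) stop("mixed sample_type values in one file")
  if (expected_type != "any" && stype != expected_type) {
    stop("file contains '", stype, "' spectra but '", expected_type,
         "' was expected")
  }
  tree_id <- if ("tree_id" %in% names(df) && !all(is.na(df$tree_id))) df$tree_id else NULL
  replicate_id <- if ("replicate_id" %in% names(df) && !all(is.na(df$replicate_id))) {
    as.integer(df$replicate_id)
  } else NULL
  spectra_set(x, axis, df$class, df$sample_id, tree_id = tree_id,
              replicate_id = replicate_id, sample_type = stype, unit = unit)
}

#' Convert reflectance spectra to absorbance
#'
#' Applies the instrument transform `A = log10(1/R)` elementwise.
#'
#' @param spectra a `spectra_set` in reflectance units, all values > 0.
#' @return the same set in absorbance units.
#' @export
reflectance_to_absorbance <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (spectra$unit != "reflectance") {
    stop("spectra are not in reflectance units")
  }
  bad <- which(apply(spectra$x <= 0, 1, any))
  if (length(bad)) {
    stop("non-positive reflectance in sample(s): ",
         paste(utils::head(spectra$sample_id[bad], 5), collapse = ", "))
  }
  replace_matrix(spectra, log10(1 / spectra$x), unit = "absorbance")
}

#' Average instrument replicates to one spectrum per leaf
#'
#' Arithmetic mean of the replicate scans of each `sample_id`, computed on
#' the stored unit (the pipeline averages absorbance, after log(1/R)).
#' Metadata is carried over; `replicate_id` is dropped.
#'
#' @param spectra a `spectra_set` with (possibly) repeated `sample_id`s.
#' @return a `spectra_set` with one row per unique `sample_id`, in first
#'   appearance order.
#' @export
average_replicates <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  ids <- unique(spectra$sample_id)
  idx <- split(seq_along(spectra$sample_id),
               factor(spectra$sample_id, levels = ids))
  for (id in ids) {
    g <- idx[[id]]
    if (length(unique(spectra$labels[g])) != 1) {
      stop("inconsistent class label within replicate group: ", id)
    }
  }
  xm <- t(vapply(idx, function(g) colMeans(spectra$x[g, , drop = FALSE]),
                 numeric(length(spectra$axis))))
  first <- vapply(idx, `[`, integer(1), 1L)
  spectra_set(xm, spectra$axis, spectra$labels[first], ids,
              tree_id = if (is.null(spectra$tree_id)) NULL else spectra$tree_id[first],
              replicate_id = NULL,
              sample_type = spectra$sample_type, unit = spectra$unit)
}
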