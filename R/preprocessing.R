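#' Preprocessing configuration
#'
#' The pre-treatment chain is SNV, then a Savitzky-Golay derivative, then
#' mean centering — the combination found optimal for leaf spectra:
#' a 15-point window with a second-order polynomial and first derivative.
#'
#' @param apply_snv apply standard normal variate row scaling.
#' @param sg_window Savitzky-Golay window length in points (odd, default 15).
#' @param sg_polyorder local polynomial order (default 2).
#' @param sg_deriv derivative order (default 1); 0 disables the stage.
#' @param mean_center subtract per-wavenumber training means.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(apply_snv = TRUE, sg_window = 15,
                              sg_polyorder = 2, sg_deriv = 1,
                              mean_center = TRUE) {
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2 == 0 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder")
  }
  if (sg_deriv > sg_polyorder) {
    stop("sg_deriv must not exceed sg_polyorder")
  }
  structure(list(apply_snv = apply_snv, sg_window = sg_window,
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = as.integer(sg_deriv),
                 mean_center = mean_center),
            class = "preprocess_config")
}

#' Standard normal variate (SNV) scaling
#'
#' Centers and scales each spectrum (row) to mean 0 and unit standard
#' deviation, correcting additive baseline shifts and multiplicative
#' scatter. The sample (n-1) standard deviation is used.
#'
#' @param spectra a `spectra_set`.
#' @return the SNV-scaled `spectra_set`.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  mu <- rowMeans(spectra$x)
  s <- apply(spectra$x, 1, stats::sd)
  degenerate <- which(s == 0)
  if (length(degenerate)) {
    stop("constant spectrum cannot be SNV-scaled: ",
         paste(utils::head(spectra$sample_id[degenerate], 5), collapse = ", "))
  }
  replace_matrix(spectra, (spectra$x - mu) / s)
}

# central-point Savitzky-Golay convolution coefficients: derivative of the
# local least-squares polynomial, per index step
sg_coefficients <- function(window, polyorder, deriv) {
  signal::sgolay(p = polyorder, n = window, m = deriv)[(window + 1) %/% 2, ]
}

#' Savitzky-Golay derivative filter
#'
#' Smoothed numerical derivative by local least-squares polynomial fits in
#' a sliding window. The derivative is reported per index step (the axis
#' is uniform, so this differs from the per-cm^-1 derivative only by a
#' constant factor). Half a window, `(sg_window - 1) / 2` points, is
#' trimmed from each end of the axis rather than extrapolated.
#'
#' @param spectra a `spectra_set`.
#' @param config a [preprocess_config()] supplying window, polynomial
#'   order and derivative order.
#' @return a `spectra_set` on the trimmed axis.
#' @export
sg_derivative <- function(spectra, config = preprocess_config()) {
  stopifnot(inherits(spectra, "spectra_set"))
  w <- config$sg_window
  p <- length(spectra$axis)
  if (p < w) stop("spectral axis shorter than the Savitzky-Golay window")
  h <- (w - 1L) %/% 2L
  co <- sg_coefficients(w, config$sg_polyorder, config$sg_deriv)
  keep <- (h + 1L):(p - h)
  out <- matrix(0, nrow(spectra$x), length(keep))
  for (k in seq_len(w)) {
    out <- out + co[k] * spectra$x[, keep + (k - h - 1L), drop = FALSE]
  }
  replace_matrix(spectra, out, axis = spectra$axis[keep])
}

#' Fit per-wavenumber means on a training set
#'
#' @param train a `spectra_set` (calibration spectra).
#' @return a `centering_model`: list with `axis` and `column_means`.
#' @export
fit_mean_center <- function(train) {
  stopifnot(inherits(train, "spectra_set"))
  structure(list(axis = train$axis, column_means = colMeans(train$x)),
            class = "centering_model")
}

#' Subtract training column means
#'
#' Test spectra are always centered with the calibration means, never
#' their own.
#'
#' @param spectra a `spectra_set`.
#' @param model a `centering_model` fitted on the calibration set.
#' @return the centered `spectra_set`.
#' @export
apply_center <- function(spectra, model) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(model, "centering_model"))
  if (length(model$axis) != length(spectra$axis) ||
      any(model$axis != spectra$axis)) {
    stop("centering model axis does not match the spectra axis")
  }
  replace_matrix(spectra, sweep(spectra$x, 2, model$column_means))
}

#' Full preprocessing chain: SNV, SG derivative, mean centering
#'
#' Applies the stages in fixed order. When no centering model is supplied
#' one is fitted on the input (calibration use); supplying a model centers
#' with its means (test use).
#'
#' @param spectra a `spectra_set`.
#' @param config a [preprocess_config()].
#' @param centering optional `centering_model` from the calibration chain.
#' @return list with elements `spectra` (processed set) and `centering`
#'   (the model used; `NULL` when centering is disabled).
#' @export
preprocess_chain <- function(spectra, config = preprocess_config(),
                             centering = NULL) {
  out <- spectra
  if (config$apply_snv) out <- snv(out)
  if (config$sg_deriv > 0) out <- sg_derivative(out, config)
  model <- centering
  if (config$mean_center) {
    if (is.null(model)) model <- fit_mean_center(out)
    out <- apply_center(out, model)
  } else {
    model <- NULL
  }
  list(spectra = out, centering = model)
}

#' Write / read a centering model as two-column CSV
#' @param model a `centering_model`.
#' @param path file path (columns `wavenumber`, `mean`).
#' @return `path` invisibly / the model.
#' @export
write_centering <- function(model, path) {
  utils::write.csv(data.frame(wavenumber = model$axis,
                              mean = unname(model$column_means)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centering
#' @export
read_centering <- function(path) {
  df <- utils::read.csv(path)
  structure(list(axis = df$wavenumber,
                 column_means = stats::setNames(df$mean,
                                                format_wavenumber(df$wavenumber))),
            class = "centering_model")
}
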