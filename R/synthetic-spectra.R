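#' Default absorption-band layout for synthetic leaf spectra
#'
#' Returns the Gaussian band table used by [generate_spectra()]. Fresh
#' leaves are dominated by two broad water bands (the O-H combination band
#' near 5000 cm^-1 and the first O-H stretching overtone near 7000 cm^-1)
#' plus a C-H combination band between 4000 and 4500 cm^-1. Dried-powdered
#' leaves lose the water dominance and instead show richer, narrower
#' carbohydrate/protein band structure spread over 4000-7500 cm^-1 and a
#' weak C-H second-overtone band between 8000 and 9000 cm^-1. The region
#' above 7500 cm^-1 carries no class-dependent bands in either mode,
#' emulating the low-information zone of real leaf spectra.
#'
#' @param sample_type `"fresh"` or `"dried"`.
#' @return A data frame with one row per band and columns `center` (cm^-1),
#'   `width` (Gaussian sigma, cm^-1), `base_amplitude` (absorbance units)
#'   and `informative` (logical; whether the band amplitude is modulated
#'   per class by [generate_spectra()]).
#' @export
default_band_table <- function(sample_type = c("fresh", "dried")) {
  sample_type <- match.arg(sample_type)
  tab <- switch(sample_type,
    fresh = data.frame(
      center         = c(5000, 7000, 4300, 5600, 8500),
      width          = c(350, 300, 120, 150, 250),
      base_amplitude = c(0.90, 0.60, 0.35, 0.20, 0.05),
      informative    = c(TRUE, TRUE, TRUE, TRUE, FALSE)
    ),
    dried = data.frame(
      center         = c(4300, 4700, 5200, 5800, 6200, 6600, 7200, 8500),
      width          = c(100, 120, 130, 140, 120, 100, 150, 250),
      base_amplitude = c(0.30, 0.28, 0.25, 0.22, 0.18, 0.15, 0.10, 0.04),
      informative    = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
    )
  )
  validate_band_table(tab)
  tab
}

validate_band_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("center", "width", "base_amplitude", "informative") %in% names(tab)))
  if (any(tab$width <= 0)) stop("band widths must be positive")
  if (any(tab$base_amplitude < 0)) stop("band amplitudes must be non-negative")
  invisible(tab)
}

#' Configuration for the synthetic leaf-spectrum generator
#'
#' Encodes the sampling design the generator emulates: six genetically
#' close varieties, fifty leaves per variety collected from ten trees,
#' each leaf scanned in triplicate on an FT-NIR instrument covering
#' 12000-3800 cm^-1 at 4 cm^-1 resolution.
#'
#' @param n_classes number of varieties (default 6).
#' @param n_trees_per_class trees sampled per variety (default 10).
#' @param n_leaves_per_class leaves per variety (default 50); must be
#'   divisible by `n_trees_per_class`.
#' @param n_replicates instrument scans per leaf (default 3).
#' @param sample_type `"fresh"` or `"dried"`.
#' @param axis_max,axis_min,axis_step spectral axis in cm^-1 (defaults
#'   12000, 3800, 4; axis stored descending, 2051 points).
#' @param band_table Gaussian band layout; default [default_band_table()].
#' @param class_effect half-range of the per-class amplitude multipliers on
#'   informative bands (default 0.08, i.e. multipliers drawn uniformly in
#'   [0.92, 1.08]). Set to 0 for classes with no spectral difference.
#' @param tree_sd,leaf_sd SDs of the tree- and leaf-level additive
#'   absorbance offsets (shared within tree / leaf respectively).
#' @param band_jitter_sd SD of the per-leaf multiplicative jitter on band
#'   amplitudes (dimensionless); the within-class chemistry variation.
#' @param replicate_sd SD of independent per-point instrument noise.
#' @param baseline_offset_sd,baseline_slope_sd SDs of the per-scan additive
#'   baseline (offset, and slope over the axis rescaled to [-1, 1]).
#' @param gain_sd SD of the per-scan multiplicative gain around 1,
#'   emulating multiplicative scatter (what SNV is meant to correct).
#' @param class_names optional variety names; defaults to six almond
#'   variety names when `n_classes == 6`.
#' @param seed integer RNG seed; equal seeds give bit-identical spectra.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_classes = 6, n_trees_per_class = 10,
                             n_leaves_per_class = 50, n_replicates = 3,
                             sample_type = c("dried", "fresh"),
                             axis_max = 12000, axis_min = 3800, axis_step = 4,
                             band_table = NULL,
                             class_effect = 0.08,
                             tree_sd = 0.02, leaf_sd = 0.01,
                             band_jitter_sd = 0.02,
                             replicate_sd = 0.002,
                             baseline_offset_sd = 0.02, baseline_slope_sd = 0.01,
                             gain_sd = 0.05,
                             class_names = NULL, seed = 1L) {
  sample_type <- match.arg(sample_type)
  if (axis_max <= axis_min) stop("axis_max must exceed axis_min")
  if (axis_step <= 0) stop("axis_step must be positive")
  sds <- c(tree_sd, leaf_sd, band_jitter_sd, replicate_sd,
           baseline_offset_sd, baseline_slope_sd, gain_sd)
  if (any(sds < 0)) stop("variance components must be non-negative")
  if (class_effect < 0) stop("class_effect must be non-negative")
  if (n_leaves_per_class %% n_trees_per_class != 0) {
    stop("n_leaves_per_class must be divisible by n_trees_per_class")
  }
  if (is.null(band_table)) band_table <- default_band_table(sample_type)
  validate_band_table(band_table)
  if (is.null(class_names)) {
    class_names <- if (n_classes == 6) {
      c("Avijor", "Guara", "Isabelona", "Marta", "Pentacebas", "Soleta")
    } else {
      paste0("class", seq_len(n_classes))
    }
  }
  if (length(class_names) != n_classes) {
    stop("class_names must have length n_classes")
  }
  structure(
    list(n_classes = n_classes, n_trees_per_class = n_trees_per_class,
         n_leaves_per_class = n_leaves_per_class, n_replicates = n_replicates,
         sample_type = sample_type,
         axis_max = axis_max, axis_min = axis_min, axis_step = axis_step,
         band_table = band_table, class_effect = class_effect,
         tree_sd = tree_sd, leaf_sd = leaf_sd,
         band_jitter_sd = band_jitter_sd, replicate_sd = replicate_sd,
         baseline_offset_sd = baseline_offset_sd,
         baseline_slope_sd = baseline_slope_sd, gain_sd = gain_sd,
         class_names = class_names, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Per-class amplitude multipliers for a band table
#'
#' Multipliers for informative bands are drawn once per class, uniformly in
#' `1 +/- class_effect`, from the configuration seed; non-informative bands
#' keep multiplier 1 for every class, so no class signal exists above the
#' informative region.
#'
#' @param config a `generator_config`.
#' @return numeric matrix `n_classes` x `nrow(band_table)`.
#' @export
class_multipliers <- function(config) {
  tab <- config$band_table
  m <- matrix(1, config$n_classes, nrow(tab),
              dimnames = list(config$class_names, NULL))
  if (config$class_effect > 0 && any(tab$informative)) {
    with_rng(config$seed + 1000003L, {
      for (ci in seq_len(config$n_classes)) {
        draws <- stats::runif(sum(tab$informative),
                              1 - config$class_effect, 1 + config$class_effect)
        m[ci, tab$informative] <- draws
      }
    })
  }
  m
}

#' Generate replicate-level synthetic NIR leaf spectra
#'
#' Each spectrum is a sum of Gaussian absorption bands (amplitudes
#' modulated per class and jittered per leaf), scaled by a per-scan gain,
#' plus a random linear baseline, additive tree- and leaf-level offsets
#' (shared within tree and leaf), and independent per-point instrument
#' noise. The hierarchy mirrors a field sampling design of
#' `n_trees_per_class` trees each contributing
#' `n_leaves_per_class / n_trees_per_class` leaves, every leaf scanned
#' `n_replicates` times.
#'
#' @param config a [generator_config()].
#' @return A [spectra_set()] in absorbance units with
#'   `n_classes * n_leaves_per_class * n_replicates` rows.
#' @export
generate_spectra <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("config must be a generator_config")
  }
  axis <- seq(config$axis_max, config$axis_min, by = -config$axis_step)
  p <- length(axis)
  tab <- config$band_table
  nb <- nrow(tab)
  # bands x wavenumbers Gaussian profiles
  G <- exp(-outer(tab$center, axis, function(cen, w) (w - cen)^2) /
             (2 * tab$width^2))
  u <- (axis - mean(axis)) / (diff(range(axis)) / 2)  # slope carrier in [-1,1]
  mult <- class_multipliers(config)

  leaves_per_tree <- config$n_leaves_per_class / config$n_trees_per_class
  n_rows <- config$n_classes * config$n_leaves_per_class * config$n_replicates
  X <- matrix(0, n_rows, p)
  labels <- character(n_rows)
  sample_id <- character(n_rows)
  tree_id <- character(n_rows)
  replicate_id <- integer(n_rows)

  with_rng(config$seed, {
    row <- 0L
    for (ci in seq_len(config$n_classes)) {
      cls <- config$class_names[ci]
      leaf_in_class <- 0L
      for (ti in seq_len(config$n_trees_per_class)) {
        e_tree <- stats::rnorm(1, 0, config$tree_sd)
        for (li in seq_len(leaves_per_tree)) {
          leaf_in_class <- leaf_in_class + 1L
          e_leaf <- stats::rnorm(1, 0, config$leaf_sd)
          jitter <- stats::rnorm(nb, 0, config$band_jitter_sd)
          amps <- tab$base_amplitude * mult[ci, ] * (1 + jitter)
          signal <- as.vector(amps %*% G)
          leaf_name <- sprintf("%s_T%02d_L%02d", cls, ti, leaf_in_class)
          for (ri in seq_len(config$n_replicates)) {
            gain <- 1 + stats::rnorm(1, 0, config$gain_sd)
            off <- stats::rnorm(1, 0, config$baseline_offset_sd)
            slope <- stats::rnorm(1, 0, config$baseline_slope_sd)
            eps <- stats::rnorm(p, 0, config$replicate_sd)
            row <- row + 1L
            X[row, ] <- gain * signal + off + slope * u +
              e_tree + e_leaf + eps
            labels[row] <- cls
            sample_id[row] <- leaf_name
            tree_id[row] <- sprintf("%s_T%02d", cls, ti)
            replicate_id[row] <- ri
          }
        }
      }
    }
  })

  spectra_set(X, axis, labels, sample_id, tree_id = tree_id,
              replicate_id = replicate_id, sample_type = config$sample_type,
              unit = "absorbance")
}

#' Convert absorbance spectra to reflectance
#'
#' Inverts the log10(1/R) transform: `R = 10^(-A)`. Values lie in (0, 1]
#' whenever the absorbance is non-negative.
#'
#' @param spectra a `spectra_set` in absorbance units.
#' @return the same set in reflectance units.
#' @export
to_reflectance <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (spectra$unit != "absorbance") {
    stop("spectra are not in absorbance units")
  }
  replace_matrix(spectra, 10^(-spectra$x), unit = "reflectance")
}
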