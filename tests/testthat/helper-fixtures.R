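# Shared fixtures: built in code at test time, sized for speed.

# small generator: 3 varieties x 12 leaves (4 trees) x 2 replicates on a
# coarse axis -- exercises every stage in well under a second
tiny_config <- function(seed = 11, sample_type = "dried", ...) {
  generator_config(n_classes = 3, n_trees_per_class = 4,
                   n_leaves_per_class = 12, n_replicates = 2,
                   axis_step = 40, sample_type = sample_type,
                   seed = seed, ...)
}

tiny_leaves <- function(seed = 11, ...) {
  average_replicates(generate_spectra(tiny_config(seed = seed, ...)))
}

# a deterministic spectra_set wrapper around an arbitrary matrix
as_spectra <- function(x, axis = seq(ncol(as.matrix(x)), 1),
                       labels = rep("a", nrow(as.matrix(x)))) {
  x <- as.matrix(x)
  spectra_set(x, axis, labels, sample_id = paste0("s", seq_len(nrow(x))),
              sample_type = "dried")
}

# 2-class linearly separable spectra: class signal on a handful of variables,
# tiny noise -- used for PLS-DA selection/prediction contracts
separable_spectra <- function(n_per_class = 12, p = 30, seed = 5) {
  with_seed_local(seed, {
    lab <- rep(c("a", "b"), each = n_per_class)
    X <- matrix(rnorm(2 * n_per_class * p, sd = 0.01), 2 * n_per_class, p)
    X[lab == "b", 1:3] <- X[lab == "b", 1:3] + 1
    as_spectra(X, labels = lab)
  })
}

# re-wrap a matrix with the metadata of an existing set
replace_matrix_for_test <- function(spectra, x) {
  spectra_set(x, spectra$axis, spectra$labels, spectra$sample_id,
              tree_id = spectra$tree_id, replicate_id = spectra$replicate_id,
              sample_type = spectra$sample_type)
}

# local seed scope so helpers never disturb the suite's RNG state
with_seed_local <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# the full default dried study run is expensive (~1 min); compute once per
# test session and share across test files
default_dried_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- pipeline_config(generator = generator_config(sample_type = "dried",
                                                          seed = 20191224),
                             seed = 20191224)
      cache <<- run_nirs_pipeline(cfg)
    }
    cache
  }
})

# independent Kennard-Stone oracle: explicit loops, no shared code with the
# implementation's distance bookkeeping
ks_oracle <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  edist <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- NULL; best_d <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (edist(i, j) > best_d) { best_d <- edist(i, j); best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand_best <- NA; cand_d <- -Inf
    for (i in setdiff(seq_len(n), sel)) {
      mind <- min(vapply(sel, function(s) edist(i, s), numeric(1)))
      if (mind > cand_d) { cand_d <- mind; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

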