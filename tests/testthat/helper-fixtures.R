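# Shared fixtures. Everything is generated in code; cohorts are kept small so
# the whole suite stays fast, and cached within a session because several test
# files reuse the same cohort.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_masks <- function(shape = c(10, 10, 10)) {
  cached(paste0("masks_", paste(shape, collapse = "x")),
         generate_masks(shape))
}

# Two-group cohort with one planted 40-voxel effect in the first group.
binary_cohort <- function(loading = 1.1, n_per = 8, n_volumes = 120, seed = 7,
                          shape = c(10, 10, 10), clinical_model = NULL) {
  key <- sprintf("bin_%g_%d_%d_%d_%s", loading, n_per, n_volumes, seed,
                 paste(unlist(clinical_model), collapse = "_"))
  cached(key, {
    masks <- generate_masks(shape)
    eff <- list(effect_spec(region_blob(masks, n_voxels = 40),
                            c(DET = loading, HC = 0), clinical = TRUE))
    args <- list(group_sizes = c(DET = n_per, HC = n_per),
                 grid_shape = shape, n_volumes = n_volumes,
                 effects = eff, seed = seed)
    if (!is.null(clinical_model)) args$clinical_model <- clinical_model
    cohort <- generate_cohort(do.call(cohort_config, args))
    attr(cohort, "effect_region") <- eff[[1]]$region
    cohort
  })
}

# The same cohort taken through preprocessing and GBC mapping.
binary_features <- function(...) {
  args <- list(...)
  key <- paste0("feat_", paste(unlist(args), collapse = "_"))
  cached(key, {
    cohort <- do.call(binary_cohort, args)
    pp <- compute_gbc_maps(preprocess_cohort(cohort))
    attr(pp, "effect_region") <- attr(cohort, "effect_region")
    pp
  })
}

# Single-group cohort whose planted region drives the depression score; used
# by the clinical-correlation tests (only the one group is needed there).
clinical_cohort <- function(slope, noise_sd, n = 20, seed = 31) {
  key <- sprintf("clin_%g_%g_%d_%d", slope, noise_sd, n, seed)
  cached(key, {
    masks <- generate_masks(c(12, 12, 12))
    eff <- list(effect_spec(region_blob(masks, n_voxels = 40), c(DET = 1.1),
                            clinical = TRUE))
    cfg <- cohort_config(group_sizes = c(DET = n), grid_shape = c(12, 12, 12),
                         n_volumes = 240, effects = eff, seed = seed,
                         subject_loading_sd = 0.3,
                         clinical_model = list(intercept = 11, slope = slope,
                                               noise_sd = noise_sd))
    pp <- compute_gbc_maps(preprocess_cohort(generate_cohort(cfg)))
    attr(pp, "effect_region") <- eff[[1]]$region
    pp
  })
}

# Pure-noise feature matrix (no structure at all) for null calibration.
noise_features <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  rownames(x) <- sprintf("n%02d", seq_len(n))
  x
}

# Construct three time series with exact pairwise correlations: cor(a, b) =
# r_ab, and c orthogonal to both (used for the closed-form GBC example).
exact_correlation_triplet <- function(r_ab, nt = 64, seed = 42) {
  set.seed(seed)
  raw <- matrix(rnorm(nt * 3), nt, 3)
  q <- qr.Q(qr(scale(raw, scale = FALSE)))   # orthonormal, zero-mean columns
  a <- q[, 1]
  b <- r_ab * q[, 1] + sqrt(1 - r_ab^2) * q[, 2]
  c <- q[, 3]
  cbind(a = a, b = b, c = c)
}

# Independent connected-component oracle built on igraph.
oracle_label_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(array(0L, dims))
  co <- arrayInd(idx, .dim = dims)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lookup <- stats::setNames(seq_along(idx), key(co))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1), ,
             drop = FALSE]
  from <- integer(0)
  to <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- sweep(co, 2, off[k, ], "+")
    hit <- unname(lookup[key(nb)])
    ok <- !is.na(hit)
    from <- c(from, which(ok))
    to <- c(to, hit[ok])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, as.vector(rbind(from, to)))
  comp <- igraph::components(g)$membership
  out <- array(0L, dims)
  out[idx] <- comp
  out
}
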