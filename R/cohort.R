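#' 4D time-series image
#'
#' Lightweight container for a 4D BOLD-like image: a voxel grid observed over
#' time, with voxel size and repetition time. Values must be finite and at
#' least two volumes are required.
#'
#' @param data 4D numeric array, `dim = c(nx, ny, nz, n_volumes)`.
#' @param voxel_size_mm Isotropic voxel edge length in millimetres.
#' @param tr_s Repetition time in seconds.
#' @return An object of class `ts_image`.
#' @export
ts_image <- function(data, voxel_size_mm = 3, tr_s = 2) {
  if (length(dim(data)) != 4L) abort("`data` must be a 4D array (x, y, z, time).")
  if (dim(data)[4] < 2L) abort("A time-series image needs at least 2 volumes.")
  if (!all(is.finite(data))) abort("`data` must be finite everywhere.")
  if (voxel_size_mm <= 0 || tr_s <= 0) abort("`voxel_size_mm` and `tr_s` must be positive.")
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s),
    class = "ts_image"
  )
}

#' @export
print.ts_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ts_image> %d x %d x %d voxels (%g mm), %d volumes, TR %g s\n",
    d[1], d[2], d[3], x$voxel_size_mm, d[4], x$tr_s
  ))
  invisible(x)
}

#' @export
dim.ts_image <- function(x) dim(x$data)

n_volumes <- function(img) dim(img$data)[4]

#' Planted connectivity effect
#'
#' Describes one group-dependent connectivity effect: a set of gray-matter
#' voxels that share a band-limited latent signal, with a per-group loading.
#' Groups with a larger loading show stronger within-region correlation and
#' therefore higher downstream global brain connectivity (GBC) in the region.
#'
#' @param region Integer vector of linear voxel indices (into the image grid);
#'   must lie inside the gray-matter mask of the cohort it is used with.
#' @param loadings Named numeric vector, one loading per group label.
#' @param latent_band_hz Frequency band of the shared latent signal (Hz).
#'   Kept inside the analysis band-pass so planted structure survives
#'   filtering.
#' @param clinical If `TRUE`, subject-level loading on this effect drives the
#'   depression score (HDRS-17) through the cohort's clinical model.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(region, loadings, latent_band_hz = c(0.01, 0.08),
                        clinical = FALSE) {
  region <- as.integer(region)
  if (length(region) == 0L) abort("`region` must contain at least one voxel.")
  if (is.null(names(loadings)) || any(!nzchar(names(loadings)))) {
    abort("`loadings` must be a named vector (one entry per group label).")
  }
  structure(
    list(region = region, loadings = loadings,
         latent_band_hz = latent_band_hz, clinical = isTRUE(clinical)),
    class = "effect_spec"
  )
}

#' Cohort generator configuration
#'
#' Study-design constants for the synthetic resting-state cohort. Defaults
#' emulate the four-group design this package targets: depressed essential
#' tremor (DET), non-depressed essential tremor (ET), primary depression (DP)
#' and healthy controls (HC), 240 volumes at TR 2 s on a 3 mm grid.
#'
#' @param group_sizes Named integer vector of subjects per group (all >= 2).
#' @param grid_shape Three integers, voxels per axis (each >= 4).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param n_volumes Volumes per run (> 10; the first 10 are later discarded).
#' @param tr_s Repetition time in seconds.
#' @param effects List of [effect_spec()] objects (may be empty).
#' @param background_loading Base loading of the octant background latents
#'   shared by all groups. Parcels receive graded multiples (0.7x to 1.8x) of
#'   this value, so some act as connectivity hubs and the baseline degree map
#'   has stable spatial structure.
#' @param noise_sd Standard deviation of i.i.d. voxel noise (> 0).
#' @param subject_loading_sd SD of the per-subject multiplier applied to each
#'   effect loading (biological variability between subjects).
#' @param motion_level Scale (mm) of the random-walk motion increments.
#' @param clinical_model List with `intercept`, `slope`, `noise_sd`: for
#'   subjects of a group with a clinical effect, HDRS-17 =
#'   `intercept + slope * subject_loading + noise`.
#' @param seed Master seed; deterministically spawns per-subject streams.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(DET = 41, ET = 49, DP = 45, HC = 43),
                          grid_shape = c(12, 12, 12),
                          voxel_size_mm = 3,
                          n_volumes = 240,
                          tr_s = 2,
                          effects = list(),
                          background_loading = 0.5,
                          noise_sd = 1,
                          subject_loading_sd = 0.15,
                          motion_level = 0.05,
                          clinical_model = list(intercept = 11, slope = 8, noise_sd = 3),
                          seed = 1) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    abort("`group_sizes` must be a named vector of group counts.")
  }
  if (any(group_sizes < 2)) abort("Every group needs at least 2 subjects.")
  if (length(grid_shape) != 3L || any(grid_shape < 4)) {
    abort("`grid_shape` must be 3 integers, each >= 4.")
  }
  if (n_volumes <= 10) abort("`n_volumes` must exceed 10.")
  if (noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (motion_level < 0) abort("`motion_level` must be non-negative.")
  ok_effects <- all(vapply(effects, inherits, logical(1), "effect_spec"))
  if (!ok_effects) abort("`effects` must be a list of effect_spec objects.")
  structure(
    list(group_sizes = group_sizes, grid_shape = as.integer(grid_shape),
         voxel_size_mm = voxel_size_mm, n_volumes = as.integer(n_volumes),
         tr_s = tr_s, effects = effects,
         background_loading = background_loading, noise_sd = noise_sd,
         subject_loading_sd = subject_loading_sd, motion_level = motion_level,
         clinical_model = clinical_model, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Tissue masks for a synthetic brain
#'
#' Builds three disjoint compartments on the voxel grid inside an ellipsoidal
#' "brain" centred in the grid: the innermost 5 % of brain voxels (by radius)
#' form a CSF core, the next 25 % a white-matter shell, and the remaining
#' 70 % the gray-matter shell (always the largest). Radius-rank splitting
#' keeps all three compartments non-empty on any grid large enough to hold a
#' few brain voxels.
#'
#' @param grid_shape Three integers, voxels per axis (each >= 4).
#' @return A list with logical 3D arrays `gm`, `wm`, `csf` and `brain`
#'   (their union), plus `grid_shape`.
#' @export
generate_masks <- function(grid_shape) {
  if (length(grid_shape) != 3L || any(grid_shape < 4)) {
    abort("Grid too small: need 3 axes with at least 4 voxels each.")
  }
  dims <- as.integer(grid_shape)
  co <- grid_coords(dims)
  ctr <- (dims + 1) / 2
  u <- sweep(co, 2, ctr, "-")
  u <- sweep(u, 2, (dims - 1) / 2, "/")
  r <- sqrt(rowSums(u^2))
  brain_idx <- which(r <= 0.95)
  if (length(brain_idx) < 6) {
    abort("Grid too small to host CSF, WM and GM compartments.")
  }
  ord <- brain_idx[order(r[brain_idx])]
  n <- length(ord)
  n_csf <- max(1L, round(0.05 * n))
  n_wm <- max(1L, round(0.25 * n))
  csf <- array(FALSE, dims); csf[ord[seq_len(n_csf)]] <- TRUE
  wm <- array(FALSE, dims); wm[ord[n_csf + seq_len(n_wm)]] <- TRUE
  gm <- array(FALSE, dims); gm[ord[(n_csf + n_wm + 1):n]] <- TRUE
  list(gm = gm, wm = wm, csf = csf, brain = gm | wm | csf,
       grid_shape = dims)
}

#' Pick a compact gray-matter region
#'
#' Selects the `n_voxels` gray-matter voxels nearest to a target point, giving
#' a compact blob usable as a planted effect region.
#'
#' @param masks Output of [generate_masks()].
#' @param center Grid coordinates (3 numbers) of the target point; defaults to
#'   a point on the positive-x side of the gray-matter shell.
#' @param n_voxels Number of voxels in the region.
#' @return Integer vector of linear voxel indices, all inside the GM mask.
#' @export
region_blob <- function(masks, center = NULL, n_voxels = 40) {
  dims <- masks$grid_shape
  gm_idx <- which(masks$gm)
  if (n_voxels > length(gm_idx)) abort("Region larger than the gray-matter mask.")
  if (is.null(center)) center <- c(dims[1] * 0.85, dims[2] / 2, dims[3] / 2)
  co <- arrayInd(gm_idx, .dim = dims)
  d2 <- rowSums(sweep(co, 2, center, "-")^2)
  gm_idx[order(d2)][seq_len(n_voxels)]
}

#' Default planted effects for a cohort
#'
#' One compact 40-voxel GM region per group, loaded only in that group, placed
#' at well-separated points of the gray-matter shell. The first group's region
#' is flagged as the clinical (HDRS-coupled) effect.
#'
#' @param masks Output of [generate_masks()].
#' @param groups Character vector of group labels.
#' @param loading Loading given to each group on its own region.
#' @param n_voxels Region size in voxels.
#' @return List of [effect_spec()] objects.
#' @export
default_effects <- function(masks, groups, loading = 1, n_voxels = 40) {
  dims <- masks$grid_shape
  ctr <- dims / 2
  rad <- dims * 0.35
  anchors <- list(
    c(ctr[1] + rad[1], ctr[2], ctr[3]),
    c(ctr[1] - rad[1], ctr[2], ctr[3]),
    c(ctr[1], ctr[2] + rad[2], ctr[3]),
    c(ctr[1], ctr[2] - rad[2], ctr[3]),
    c(ctr[1], ctr[2], ctr[3] + rad[3]),
    c(ctr[1], ctr[2], ctr[3] - rad[3])
  )
  if (length(groups) > length(anchors)) abort("At most 6 default effect regions are supported.")
  purrr::imap(groups, function(g, i) {
    lo <- setNames(rep(0, length(groups)), groups)
    lo[g] <- loading
    effect_spec(region_blob(masks, anchors[[i]], n_voxels), lo,
                clinical = (i == 1))
  })
}

#' Simulate a realignment motion trace
#'
#' Six rigid-body parameters per volume (3 translations in mm, then 3
#' rotations in radians), as a smooth random walk scaled by `level`; the first
#' volume is the all-zero reference. Rotation increments are scaled down by
#' 100 so translations and rotations contribute comparably to framewise
#' displacement at the 50 mm reference radius.
#'
#' @param n_volumes Number of volumes (>= 2).
#' @param level Scale (mm) of the translation random-walk increments; 0 gives
#'   a perfectly still subject.
#' @param seed Integer seed.
#' @return Numeric matrix `n_volumes x 6`, columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @export
generate_motion_trace <- function(n_volumes, level = 0.05, seed = 1) {
  if (n_volumes < 2) abort("`n_volumes` must be at least 2.")
  if (level < 0) abort("`level` must be non-negative.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  inc <- cbind(
    matrix(rnorm((n_volumes - 1) * 3, sd = level), ncol = 3),
    matrix(rnorm((n_volumes - 1) * 3, sd = level / 100), ncol = 3)
  )
  m <- rbind(rep(0, 6), matrix(apply(inc, 2, cumsum), ncol = 6))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  rownames(m) <- NULL
  m
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Group-wise clinical score distributions (mean, sd) used for groups whose
# depression score is not driven by a planted effect. Values loosely follow
# typical clinic samples for the four default labels; unknown labels fall back
# to the control row.
.clinical_table <- list(
  DET = list(hdrs17 = c(18.98, 6.35), hars14 = c(7.56, 3.47),
             mmse = c(26.00, 1.40), age = c(47.85, 15.66), edu = c(14.73, 4.17)),
  ET  = list(hdrs17 = c(3.27, 1.60), hars14 = c(3.73, 1.90),
             mmse = c(26.67, 1.71), age = c(46.16, 14.52), edu = c(12.18, 3.95)),
  DP  = list(hdrs17 = c(25.31, 7.12), hars14 = c(9.29, 4.93),
             mmse = c(25.67, 1.77), age = c(45.20, 13.25), edu = c(11.95, 4.40)),
  HC  = list(hdrs17 = c(2.09, 1.19), hars14 = c(2.02, 1.18),
             mmse = c(28.70, 1.35), age = c(46.60, 13.45), edu = c(12.28, 3.49))
)

clinical_params_for <- function(group) {
  .clinical_table[[group]] %||% .clinical_table$HC
}

#' Generate a synthetic multi-group resting-state cohort
#'
#' Simulates, per subject, a 4D time-series image, a realignment motion trace
#' and clinical scores. Every gray-matter voxel's series is a weighted sum of
#' band-limited latent signals plus i.i.d. Gaussian noise: octant-wise
#' background latents (shared by all groups) create baseline connectivity, and
#' each [effect_spec()] adds a group-loaded latent on its region, so voxels
#' with larger loadings acquire higher global brain connectivity. For subjects
#' of a group carrying a `clinical` effect with non-zero loading, the HDRS-17
#' depression score is a linear function of the subject-level loading, which
#' plants a GBC-severity correlation.
#'
#' @param config A [cohort_config()].
#' @return A tibble (class `gbc_cohort`) with one row per subject: columns
#'   `subject_id`, `group`, `hdrs17`, `hars14`, `mmse`, `age`,
#'   `education_years`, and list-columns `image` ([ts_image()]) and `motion`
#'   (matrix). The tissue masks and the config are attached as attributes
#'   `masks` and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config.")
  masks <- generate_masks(config$grid_shape)
  groups <- names(config$group_sizes)
  gm_idx <- which(masks$gm)
  for (ef in config$effects) {
    if (!all(ef$region %in% gm_idx)) {
      abort("An effect region extends outside the gray-matter mask.")
    }
    if (!all(groups %in% names(ef$loadings))) {
      abort("Every effect must define a loading for every group.")
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  dims <- config$grid_shape
  nvox <- prod(dims)
  nt <- config$n_volumes
  n_total <- sum(config$group_sizes)
  group_vec <- rep(groups, times = config$group_sizes)
  ids <- sprintf("S%03d", seq_len(n_total))

  # octant background parcels over GM with graded loadings: some parcels act
  # as connectivity hubs (within-parcel r above the usual 0.25 edge
  # threshold), others stay subthreshold, so baseline degree maps carry
  # stable spatial structure -- as real GBC maps do. Without that structure
  # the across-mask standardization would be dominated by any planted region
  # and would cancel its amplitude.
  co <- grid_coords(dims)
  ctr <- (dims + 1) / 2
  oct <- 1L + (co[, 1] > ctr[1]) + 2L * (co[, 2] > ctr[2]) + 4L * (co[, 3] > ctr[3])
  parcel <- oct[gm_idx]
  parcel_loading <- config$background_loading * (0.7 + 1.1 * (0:7) / 7)
  # planted circuit regions take their connectivity from the circuit latent
  # alone: carrying a background latent as well would let the extra effect
  # variance dilute their background edges and cancel the planted degree gain
  voxel_bg <- parcel_loading[parcel]
  effect_union <- unique(unlist(lapply(config$effects, function(e) e$region)))
  voxel_bg[match(effect_union, gm_idx)] <- 0

  clinical_idx <- which(vapply(config$effects, function(e) e$clinical, logical(1)))
  wm_idx <- which(masks$wm)
  csf_idx <- which(masks$csf)
  out_idx <- which(!masks$brain)

  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- group_vec[i]
    set.seed(derive_seed(config$seed, i))

    # latent signals
    s_bg <- replicate(8, band_limited_signal(nt, config$tr_s))
    s_wm <- band_limited_signal(nt, config$tr_s)
    s_csf <- band_limited_signal(nt, config$tr_s)
    s_eff <- lapply(config$effects, function(e)
      band_limited_signal(nt, config$tr_s, e$latent_band_hz))
    mult <- 1 + rnorm(length(config$effects), sd = config$subject_loading_sd)

    dat <- array(rnorm(nvox * nt, sd = config$noise_sd), dim = c(dims, nt))
    dm <- matrix(dat, nrow = nvox)
    # background structure in GM
    dm[gm_idx, ] <- dm[gm_idx, ] +
      voxel_bg * t(s_bg)[parcel, , drop = FALSE]
    # planted effects
    for (k in seq_along(config$effects)) {
      e <- config$effects[[k]]
      lo <- e$loadings[[g]] * mult[k]
      if (lo != 0) {
        dm[e$region, ] <- dm[e$region, ] +
          matrix(lo * s_eff[[k]], nrow = length(e$region), ncol = nt, byrow = TRUE)
      }
    }
    dm[wm_idx, ] <- dm[wm_idx, ] +
      matrix(0.7 * s_wm, nrow = length(wm_idx), ncol = nt, byrow = TRUE)
    dm[csf_idx, ] <- dm[csf_idx, ] +
      matrix(0.7 * s_csf, nrow = length(csf_idx), ncol = nt, byrow = TRUE)
    dm[out_idx, ] <- 0.05 * dm[out_idx, ]
    dat <- array(dm, dim = c(dims, nt))

    motion <- generate_motion_trace(nt, config$motion_level,
                                    seed = derive_seed(config$seed, 100000L + i))

    # clinical scores
    cp <- clinical_params_for(g)
    drive <- FALSE
    if (length(clinical_idx) == 1L) {
      e <- config$effects[[clinical_idx]]
      if (e$loadings[[g]] != 0) {
        lo_i <- e$loadings[[g]] * mult[clinical_idx]
        cm <- config$clinical_model
        hdrs <- cm$intercept + cm$slope * lo_i + rnorm(1, sd = cm$noise_sd)
        drive <- TRUE
      }
    }
    if (!drive) hdrs <- rnorm(1, cp$hdrs17[1], cp$hdrs17[2])
    hdrs <- max(0, hdrs)

    rows[[i]] <- tibble(
      subject_id = ids[i], group = g,
      hdrs17 = hdrs,
      hars14 = max(0, rnorm(1, cp$hars14[1], cp$hars14[2])),
      mmse = min(30, max(0, rnorm(1, cp$mmse[1], cp$mmse[2]))),
      age = max(18, rnorm(1, cp$age[1], cp$age[2])),
      education_years = max(0, rnorm(1, cp$edu[1], cp$edu[2])),
      image = list(ts_image(dat, config$voxel_size_mm, config$tr_s)),
      motion = list(motion)
    )
  }

  cohort <- dplyr::bind_rows(rows)
  cohort$group <- factor(cohort$group, levels = groups)
  attr(cohort, "masks") <- masks
  attr(cohort, "config") <- config
  class(cohort) <- c("gbc_cohort", class(cohort))
  cohort
}

#' Tissue masks attached to a cohort
#'
#' @param cohort A cohort from [generate_cohort()] or [load_dataset()].
#' @return The mask list (see [generate_masks()]).
#' @export
cohort_masks <- function(cohort) {
  m <- attr(cohort, "masks")
  if (is.null(m)) abort("This cohort carries no mask attribute (was it subset by a verb that drops attributes?).")
  m
}
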