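#' Write a cohort to disk
#'
#' Persists a cohort in the standard on-disk layout: one 4D NIfTI-1 image and
#' one six-column whitespace-delimited motion text file (translations mm, then
#' rotations rad; one row per volume) per subject, 3D NIfTI-1 tissue masks, a
#' subjects table (TSV with `subject_id`, `group`, `hdrs17`, `hars14`, `mmse`,
#' `age`, `education_years`) and a JSON manifest tying them together.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  masks <- cohort_masks(cohort)
  vox <- cohort$image[[1]]$voxel_size_mm
  tr <- cohort$image[[1]]$tr_s

  for (nm in c("gm", "wm", "csf")) {
    RNifti::writeNifti(
      RNifti::asNifti(array(as.numeric(masks[[nm]]), dim(masks[[nm]])),
                      pixdim = rep(vox, 3)),
      file.path(dir, paste0("mask_", nm, ".nii"))
    )
  }

  img_files <- character(nrow(cohort))
  mot_files <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    img_files[i] <- paste0(id, "_bold.nii")
    mot_files[i] <- paste0("rp_", id, ".txt")
    img <- cohort$image[[i]]
    RNifti::writeNifti(
      RNifti::asNifti(img$data, pixdim = c(rep(img$voxel_size_mm, 3), img$tr_s)),
      file.path(dir, img_files[i])
    )
    utils::write.table(cohort$motion[[i]], file.path(dir, mot_files[i]),
                       row.names = FALSE, col.names = FALSE)
  }

  subjects <- as.data.frame(cohort[, c("subject_id", "group", "hdrs17", "hars14",
                                       "mmse", "age", "education_years")])
  utils::write.table(subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  manifest <- list(
    subjects_table = "subjects.tsv",
    masks = list(gm = "mask_gm.nii", wm = "mask_wm.nii", csf = "mask_csf.nii"),
    voxel_size_mm = vox, tr_s = tr,
    subjects = purrr::pmap(
      list(cohort$subject_id, img_files, mot_files),
      function(id, f, m) list(subject_id = id, image = f, motion = m)
    )
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

read_motion_file <- function(path, rotations_in_degrees = FALSE) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6) abort(sprintf("Motion file %s must have 6 columns.", basename(path)))
  if (rotations_in_degrees) m[, 4:6] <- m[, 4:6] * pi / 180
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

#' Load a cohort dataset from a manifest
#'
#' Reads back the layout written by [write_cohort()], validating that every
#' referenced file exists, subject ids are unique, and all images share one
#' grid geometry.
#'
#' @param manifest Path to a `manifest.json`.
#' @param rotations_in_degrees Convert motion-file rotations from degrees.
#' @return A cohort tibble with masks attached (see [generate_cohort()]).
#' @export
load_dataset <- function(manifest, rotations_in_degrees = FALSE) {
  dir <- dirname(manifest)
  mf <- jsonlite::read_json(manifest)
  subjects <- utils::read.table(file.path(dir, mf$subjects_table),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  ids <- vapply(mf$subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate subject id in manifest: %s", ids[duplicated(ids)][1]))
  }

  read_mask <- function(f) {
    arr <- as.array(RNifti::readNifti(file.path(dir, f)))
    array(arr > 0.5, dim(arr))
  }
  gm <- read_mask(mf$masks$gm)
  masks <- list(gm = gm, wm = read_mask(mf$masks$wm), csf = read_mask(mf$masks$csf))
  masks$brain <- masks$gm | masks$wm | masks$csf
  masks$grid_shape <- dim(gm)

  rows <- vector("list", length(mf$subjects))
  geom <- NULL
  for (i in seq_along(mf$subjects)) {
    s <- mf$subjects[[i]]
    ipath <- file.path(dir, s$image)
    mpath <- file.path(dir, s$motion)
    if (!file.exists(ipath)) abort(sprintf("Missing image for subject %s: %s", s$subject_id, s$image))
    if (!file.exists(mpath)) abort(sprintf("Missing motion file for subject %s: %s", s$subject_id, s$motion))
    arr <- as.array(RNifti::readNifti(ipath))
    if (is.null(geom)) geom <- dim(arr)[1:3]
    if (!identical(dim(arr)[1:3], geom)) {
      abort(sprintf("Geometry mismatch: subject %s has grid %s, expected %s.",
                    s$subject_id, paste(dim(arr)[1:3], collapse = "x"),
                    paste(geom, collapse = "x")))
    }
    motion <- read_motion_file(mpath, rotations_in_degrees)
    srow <- subjects[subjects$subject_id == s$subject_id, , drop = FALSE]
    if (nrow(srow) != 1) abort(sprintf("Subject %s missing from the subjects table.", s$subject_id))
    rows[[i]] <- tibble(
      subject_id = s$subject_id, group = srow$group,
      hdrs17 = srow$hdrs17, hars14 = srow$hars14, mmse = srow$mmse,
      age = srow$age, education_years = srow$education_years,
      image = list(ts_image(arr, mf$voxel_size_mm, mf$tr_s)),
      motion = list(motion)
    )
  }
  if (!identical(dim(gm), geom)) abort("Mask geometry does not match the images.")
  cohort <- dplyr::bind_rows(rows)
  cohort$group <- factor(cohort$group, levels = unique(cohort$group))
  attr(cohort, "masks") <- masks
  class(cohort) <- c("gbc_cohort", class(cohort))
  cohort
}

#' Write a GBC (or weight/p) map as 3D NIfTI-1 with a JSON sidecar
#'
#' @param map A `gbc_map`.
#' @param path Output path (`.nii`); the parameter sidecar is written next to
#'   it as `.json`.
#' @return `path`, invisibly.
#' @export
write_gbc_map <- function(map, path) {
  dat <- map$data
  dat[is.na(dat)] <- 0
  RNifti::writeNifti(
    RNifti::asNifti(dat, pixdim = rep(map$voxel_size_mm, 3)), path
  )
  side <- list(subject_id = map$subject_id, params = unclass(map$params))
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
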