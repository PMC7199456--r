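#' Specification for a synthetic multimodal phantom
#'
#' Describes a synthetic "patient": a spherical brain region embedded in a
#' zero background, carrying one or more tumors built as unions of
#' overlapping ellipsoids.  Each imaging channel receives its own tumor
#' intensity offset (emulating the differing tumor contrast of FLAIR, T2,
#' T1 and T1ce sequences) plus additive Gaussian noise inside the brain.
#' The seed fully determines the generated volume.
#'
#' @param volume_shape integer triple, voxels per axis (each >= 16).
#' @param n_modalities number of imaging channels.
#' @param brain_radius_fraction brain sphere radius as a fraction of half the
#'   smallest volume extent, in (0, 1].
#' @param tumor_count number of disjoint tumors (0 allowed: empty mask).
#' @param tumor_radii_range range (min, max) of ellipsoid semi-axes, voxels.
#' @param tumor_contrast per-channel additive intensity of tumor tissue over
#'   brain tissue (arbitrary units); recycled to \code{n_modalities}.  The
#'   first channel is the contrast-bearing channel used by the region-grow
#'   baseline.
#' @param noise_sd standard deviation of the additive Gaussian noise applied
#'   inside the brain, intensity units.
#' @param brain_mean baseline brain-tissue intensity (must be nonzero so the
#'   brain is distinguishable from the exactly-zero background).
#' @param max_lobes tumors are unions of 1..max_lobes overlapping ellipsoids,
#'   so their shapes are not box-aligned.
#' @param seed integer seed; identical specs regenerate bit-identical output.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 64L),
                         n_modalities = 4L,
                         brain_radius_fraction = 0.8,
                         tumor_count = 1L,
                         tumor_radii_range = c(6, 12),
                         tumor_contrast = c(1.5, 1.2, -0.4, 0.8),
                         noise_sd = 0.2,
                         brain_mean = 1,
                         max_lobes = 3L,
                         seed = 1L) {
  volume_shape <- check_int3(volume_shape, "volume_shape")
  if (any(volume_shape < 16L)) stopf("each volume_shape extent must be >= 16")
  if (brain_radius_fraction <= 0 || brain_radius_fraction > 1)
    stopf("brain_radius_fraction must lie in (0, 1]")
  if (tumor_count < 0) stopf("tumor_count must be >= 0")
  if (length(tumor_radii_range) != 2L || tumor_radii_range[1] > tumor_radii_range[2] ||
      tumor_radii_range[1] < 1)
    stopf("tumor_radii_range must be an increasing pair >= 1")
  brain_radius <- brain_radius_fraction * min(volume_shape) / 2
  if (tumor_radii_range[2] >= brain_radius)
    stopf("tumor radii (max %g) must be strictly smaller than the brain radius (%g)",
          tumor_radii_range[2], brain_radius)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (brain_mean == 0) stopf("brain_mean must be nonzero")
  tumor_contrast <- rep_len(tumor_contrast, n_modalities)
  structure(list(volume_shape = volume_shape,
                 n_modalities = as.integer(n_modalities),
                 brain_radius_fraction = brain_radius_fraction,
                 brain_radius = brain_radius,
                 tumor_count = as.integer(tumor_count),
                 tumor_radii_range = as.numeric(tumor_radii_range),
                 tumor_contrast = as.numeric(tumor_contrast),
                 noise_sd = noise_sd,
                 brain_mean = brain_mean,
                 max_lobes = as.integer(max_lobes),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# logical mask of the lattice points inside an axis-aligned ellipsoid,
# accumulated into `mask` (0-based center coordinates)
add_ellipsoid <- function(mask, center, radii) {
  shape <- dim(mask)
  lo <- pmax(floor(center - radii), 0)
  hi <- pmin(ceiling(center + radii), shape - 1)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- ((xs - center[1]) / radii[1])^2
  gy <- ((ys - center[2]) / radii[2])^2
  gz <- ((zs - center[3]) / radii[3])^2
  sub <- outer(outer(gx, gy, `+`), gz, `+`) <= 1
  mask[xs + 1, ys + 1, zs + 1] <- mask[xs + 1, ys + 1, zs + 1] | sub
  mask
}

#' Generate one synthetic multimodal volume with a known tumor mask
#'
#' Draws tumor geometry and noise from the spec's seed and renders a
#' 4-channel (by default) volume.  Voxels outside the brain sphere are
#' exactly 0 in every channel; brain voxels take \code{brain_mean}, tumor
#' voxels additionally receive the per-channel \code{tumor_contrast}, and
#' Gaussian noise is added inside the brain only.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return a list with elements \code{volume} (a
#'   \code{\link{multimodal_volume}}) and \code{mask} (logical 3D array,
#'   the ground-truth tumor mask).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("'spec' must be a phantom_spec")
  shape <- spec$volume_shape
  bc <- (shape - 1) / 2
  rb <- spec$brain_radius
  with_seed(spec$seed, {
    mask <- array(FALSE, shape)
    centers <- list()
    tumors <- list()
    for (t in seq_len(spec$tumor_count)) {
      # primary ellipsoid: rejection-sample a center leaving room for lobes
      repeat {
        radii <- runif(3, spec$tumor_radii_range[1], spec$tumor_radii_range[2])
        extent <- 1.4 * max(radii)   # lobes stay within 1.4x the primary radii
        ctr <- bc + runif(3, -rb, rb)
        ok <- sqrt(sum((ctr - bc)^2)) + extent <= rb - 1
        if (ok && length(centers) > 0) {
          dists <- vapply(centers, function(p)
            sqrt(sum((ctr - p$ctr)^2)), numeric(1))
          seps <- vapply(centers, function(p) p$extent, numeric(1))
          ok <- all(dists > seps + extent + 3)
        }
        if (ok) break
      }
      centers[[length(centers) + 1L]] <- list(ctr = ctr, extent = extent)
      mask <- add_ellipsoid(mask, ctr, radii)
      lobes <- list(list(center = ctr, radii = radii))
      n_lobes <- sample.int(spec$max_lobes, 1L)
      for (l in seq_len(n_lobes - 1L)) {
        off <- runif(3, -0.6, 0.6) * radii     # lobe center inside the primary
        lr <- runif(3, 0.5, 0.8) * radii
        mask <- add_ellipsoid(mask, ctr + off, lr)
        lobes[[length(lobes) + 1L]] <- list(center = ctr + off, radii = lr)
      }
      tumors[[length(tumors) + 1L]] <- lobes
    }
    brain <- array(FALSE, shape)
    brain <- add_ellipsoid(brain, bc, rep(rb, 3))
    if (any(mask & !brain)) stopf("internal error: tumor escaped the brain region")

    vol <- array(0, c(shape, spec$n_modalities))
    nb <- sum(brain)
    for (ch in seq_len(spec$n_modalities)) {
      v <- array(0, shape)
      v[brain] <- spec$brain_mean
      v[mask] <- spec$brain_mean + spec$tumor_contrast[ch]
      if (spec$noise_sd > 0) v[brain] <- v[brain] + rnorm(nb, 0, spec$noise_sd)
      vol[, , , ch] <- v
    }
    list(volume = multimodal_volume(vol, spacing = c(1, 1, 1),
                                    patient_id = sprintf("phantom-%d", spec$seed)),
         mask = mask,
         tumors = tumors,   # drawn geometry: per tumor, a list of lobes
         brain = list(center = bc, radius = rb))
  })
}

#' Generate a reproducible cohort of phantoms
#'
#' Per-patient tumor size, position, lobe structure and contrast vary through
#' seeded randomization of the template spec; the cohort is reproducible from
#' \code{seed} alone.
#'
#' @param n_patients number of phantoms (>= 1).
#' @param spec_template a \code{\link{phantom_spec}} providing the shared
#'   geometry and intensity settings.
#' @param seed cohort-level integer seed.
#' @return list of \code{list(volume, mask)} pairs, one per patient.
#' @export
generate_cohort <- function(n_patients, spec_template = phantom_spec(), seed = 1L) {
  if (n_patients < 1) stopf("n_patients must be >= 1")
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max, n_patients),
    contrast_jitter = runif(n_patients, 0.8, 1.2)
  ))
  lapply(seq_len(n_patients), function(i) {
    sp <- spec_template
    sp$seed <- draws$seeds[i]
    sp$tumor_contrast <- sp$tumor_contrast * draws$contrast_jitter[i]
    ph <- generate_phantom(sp)
    ph$volume$patient_id <- sprintf("phantom-%03d", i)
    ph
  })
}

#' Write a phantom cohort to disk as NIfTI files plus a JSON manifest
#'
#' One \code{.nii.gz} file per modality plus one mask file per patient;
#' the manifest lists relative file paths and the cohort seed.
#'
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @param seed cohort seed recorded in the manifest.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(cohort), function(i) {
    pid <- cohort[[i]]$volume$patient_id
    paths <- write_volume(cohort[[i]]$volume, dir)
    mask_path <- file.path(dir, sprintf("%s_mask.nii.gz", pid))
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(cohort[[i]]$mask),
                            dim(cohort[[i]]$mask)),
                      pixdim = cohort[[i]]$volume$spacing),
      mask_path)
    list(patient_id = pid, modalities = as.list(basename(unlist(paths))),
         mask = basename(mask_path))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, n_patients = length(cohort),
                            modality_order = modality_names(),
                            patients = entries),
                       manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
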