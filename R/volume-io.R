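#' Fixed modality channel order
#'
#' Channels of a multimodal volume are always stored in this order.
#' @return character vector \code{c("FLAIR", "T2", "T1", "T1ce")}.
#' @export
modality_names <- function() c("FLAIR", "T2", "T1", "T1ce")

#' Construct a multimodal 3D volume
#'
#' The per-patient unit of study: co-registered intensity channels sharing
#' one spatial grid, with physical voxel spacing in millimetres.
#'
#' @param intensities numeric 4D array, dim \code{(X, Y, Z, channels)}.  A 3D
#'   array is promoted to a single channel.
#' @param spacing positive mm triple.
#' @param patient_id identifier string.
#' @return object of class \code{multimodal_volume}.
#' @export
multimodal_volume <- function(intensities, spacing = c(1, 1, 1),
                              patient_id = "patient") {
  if (length(dim(intensities)) == 3L)
    dim(intensities) <- c(dim(intensities), 1L)
  if (length(dim(intensities)) != 4L)
    stopf("'intensities' must be a (X, Y, Z, channel) array")
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stopf("'spacing' must be a strictly positive mm triple")
  structure(list(intensities = intensities,
                 spacing = as.numeric(spacing),
                 patient_id = as.character(patient_id)),
            class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("multimodal_volume '%s': %dx%dx%d voxels, %d channel(s), spacing %s mm\n",
              x$patient_id, d[1], d[2], d[3], d[4],
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

volume_shape <- function(vol) dim(vol$intensities)[1:3]
n_channels <- function(vol) dim(vol$intensities)[4]

#' Read a multimodal volume from one NIfTI file per modality
#'
#' @param paths character vector of file paths, either named by modality or
#'   given in the fixed \code{\link{modality_names}} order.
#' @param patient_id identifier attached to the volume.
#' @return a \code{\link{multimodal_volume}} with channels ordered
#'   (FLAIR, T2, T1, T1ce) and spacing taken from the NIfTI header.
#' @export
read_volume <- function(paths, patient_id = "patient") {
  want <- modality_names()
  if (!is.null(names(paths)) && all(nzchar(names(paths)))) {
    missing <- setdiff(want, names(paths))
    if (length(missing))
      stopf("missing modality file(s): %s", paste(missing, collapse = ", "))
    paths <- paths[want]
  } else if (length(paths) != length(want)) {
    stopf("expected %d files (%s), got %d", length(want),
          paste(want, collapse = ", "), length(paths))
  }
  imgs <- lapply(paths, RNifti::readNifti)
  shapes <- vapply(imgs, function(im) paste(dim(im)[1:3], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stopf("modality shapes disagree: %s", paste(shapes, collapse = " vs "))
  spac <- lapply(imgs, function(im) RNifti::pixdim(im)[1:3])
  if (max(vapply(spac, function(s) max(abs(s - spac[[1]])), 0)) > 1e-6)
    stopf("modality voxel spacings disagree")
  arr <- array(0, c(dim(imgs[[1]])[1:3], length(imgs)))
  for (i in seq_along(imgs)) arr[, , , i] <- as.array(imgs[[i]])
  multimodal_volume(arr, spacing = spac[[1]], patient_id = patient_id)
}

#' Write a multimodal volume as one NIfTI file per modality
#'
#' @param vol a \code{\link{multimodal_volume}}.
#' @param dir output directory.
#' @return named list of written file paths, invisibly.
#' @export
write_volume <- function(vol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- modality_names()[seq_len(n_channels(vol))]
  paths <- lapply(seq_along(nm), function(i) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", vol$patient_id, nm[i]))
    RNifti::writeNifti(
      RNifti::asNifti(vol$intensities[, , , i], pixdim = vol$spacing), p)
    p
  })
  names(paths) <- nm
  invisible(paths)
}

#' Z-score normalization over brain voxels
#'
#' Per channel, mean and standard deviation are estimated over the brain
#' area only -- the voxels with nonzero value, excluding the black background
#' outside the brain -- and the brain voxels are transformed to zero mean and
#' unit variance.  Background voxels remain exactly 0.  The population
#' (divide-by-n) standard deviation is used.
#'
#' @param vol a \code{\link{multimodal_volume}}.
#' @return the normalized volume.
#' @export
normalize_volume <- function(vol) {
  arr <- vol$intensities
  for (ch in seq_len(n_channels(vol))) {
    v <- arr[, , , ch]
    brain <- v != 0
    nb <- sum(brain)
    if (nb < 2L) stopf("channel %d has fewer than 2 nonzero voxels", ch)
    m <- mean(v[brain])
    s <- sqrt(mean((v[brain] - m)^2))
    if (s < 1e-12)
      stopf("channel %d has constant brain intensity; cannot normalize", ch)
    v[brain] <- (v[brain] - m) / s
    arr[, , , ch] <- v
  }
  vol$intensities <- arr
  vol
}

#' Axis-aligned 3D box annotation
#'
#' A box splits the volume into the unlabeled region S1 (inside, where the
#' tumor resides) and the positive region S0 (outside, known background).
#' Coordinates are 0-based with the half-open convention: voxel v is inside
#' iff \code{low <= v < high} on every axis.
#'
#' @param low inclusive lower corner (integer triple, 0-based).
#' @param high exclusive upper corner.
#' @param patient_id optional identifier.
#' @return object of class \code{box_annotation}.
#' @export
box_annotation <- function(low, high, patient_id = NULL) {
  low <- check_int3(low, "low"); high <- check_int3(high, "high")
  if (any(low >= high)) stopf("'low' must be < 'high' on every axis")
  if (any(low < 0)) stopf("'low' must be >= 0")
  structure(list(low = low, high = high, patient_id = patient_id),
            class = "box_annotation")
}

#' @export
print.box_annotation <- function(x, ...) {
  cat(sprintf("box_annotation [%s) - [%s): %d voxels inside (S1)\n",
              paste(x$low, collapse = ","), paste(x$high, collapse = ","),
              prod(x$high - x$low)))
  invisible(x)
}

box_volume <- function(box) prod(box$high - box$low)

check_box_in_bounds <- function(box, shape) {
  if (any(box$high > shape))
    stopf("box exceeds the volume bounds (%s)", paste(shape, collapse = "x"))
  invisible(TRUE)
}

# is each 0-based voxel row of `pts` (n x 3) inside the box?
in_box <- function(pts, box) {
  pts[, 1] >= box$low[1] & pts[, 1] < box$high[1] &
  pts[, 2] >= box$low[2] & pts[, 2] < box$high[2] &
  pts[, 3] >= box$low[3] & pts[, 3] < box$high[3]
}

#' Tight bounding box of a binary mask
#'
#' Returns the smallest axis-aligned box containing every positive voxel,
#' optionally expanded by a symmetric margin (clamped at the volume bounds).
#' This is how box annotations are derived from reference masks: the box is
#' only used in place of the mask at training time.
#'
#' @param mask logical/binary 3D array with at least one positive voxel.
#' @param margin non-negative integer margin added on every face.
#' @param patient_id optional identifier.
#' @return a \code{\link{box_annotation}} (0-based, half-open).
#' @export
box_from_mask <- function(mask, margin = 0L, patient_id = NULL) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stopf("mask has no positive voxels")
  shape <- dim(mask)
  low <- pmax(apply(idx, 2, min) - 1L - margin, 0L)          # to 0-based
  high <- pmin(apply(idx, 2, max) + margin, shape)           # half-open
  box_annotation(low, high, patient_id = patient_id)
}

#' Class prior of the positive (background) class
#'
#' The proportion of voxels outside the box: pi_p = n0 / (n0 + n1), where n1
#' is the box volume and n0 the rest of the volume.  This is the fraction of
#' positively-labeled (non-tumor) voxels under box supervision.
#'
#' @param box a \code{\link{box_annotation}}.
#' @param volume_shape integer triple.
#' @return object of class \code{class_prior} with fields \code{pi_p},
#'   \code{n0}, \code{n1}.
#' @export
class_prior <- function(box, volume_shape) {
  volume_shape <- check_int3(volume_shape, "volume_shape")
  check_box_in_bounds(box, volume_shape)
  n1 <- box_volume(box)
  n0 <- prod(volume_shape) - n1
  if (n0 <= 0) stopf("box covers the whole volume; class prior would be 0")
  structure(list(pi_p = n0 / (n0 + n1), n0 = n0, n1 = n1),
            class = "class_prior")
}

#' @export
print.class_prior <- function(x, ...) {
  cat(sprintf("class_prior pi_p = %.4f (n0 = %d outside, n1 = %d inside)\n",
              x$pi_p, x$n0, x$n1))
  invisible(x)
}

#' Write or read a box annotation as JSON
#'
#' @param box a \code{\link{box_annotation}}.
#' @param path JSON file path.
#' @return \code{write_box}: the path, invisibly; \code{read_box}: the box.
#' @export
write_box <- function(box, path) {
  jsonlite::write_json(list(low = box$low, high = box$high,
                            patient_id = box$patient_id),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_box
#' @export
read_box <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  box_annotation(x$low, x$high, patient_id = x$patient_id)
}
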