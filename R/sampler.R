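#' Configuration of the box-supervised patch sampler
#'
#' Candidate patch centers are drawn uniformly over the volume, tagged by
#' the region holding the center (S1 = inside the box, S0 = outside), and
#' subsampled to \code{n_selected} patches with an exact \code{fraction_s1}
#' / \code{1 - fraction_s1} split between the two regions.
#'
#' @param patch_size cubic patch side d in voxels (48 at full scale; 16 is
#'   the desk-scale default).
#' @param scale_factor size ratio of the context patch that provides the
#'   second, coarser scale of the network input.
#' @param n_candidates number of random candidate centers per patient.
#' @param n_selected number of patches kept per patient.
#' @param fraction_s1 fraction of selected patches whose center lies in S1,
#'   strictly inside (0, 1).
#' @param min_nonzero_fraction optional rejection filter: candidate centers
#'   whose native-scale patch holds a smaller fraction of nonzero (brain)
#'   voxels are discarded.  0 disables the filter.
#' @param seed integer seed making the selection reproducible.
#' @return object of class \code{sampler_config}.
#' @export
sampler_config <- function(patch_size = 16L, scale_factor = 2L,
                           n_candidates = 40000L, n_selected = 200L,
                           fraction_s1 = 0.8, min_nonzero_fraction = 0,
                           seed = 1L) {
  if (patch_size < 2) stopf("patch_size must be >= 2")
  if (scale_factor < 1) stopf("scale_factor must be >= 1")
  if (fraction_s1 <= 0 || fraction_s1 >= 1)
    stopf("fraction_s1 must lie strictly inside (0, 1)")
  if (n_selected > n_candidates) stopf("n_selected must be <= n_candidates")
  if (min_nonzero_fraction < 0 || min_nonzero_fraction > 1)
    stopf("min_nonzero_fraction must lie in [0, 1]")
  structure(list(patch_size = as.integer(patch_size),
                 scale_factor = as.integer(scale_factor),
                 n_candidates = as.integer(n_candidates),
                 n_selected = as.integer(n_selected),
                 fraction_s1 = fraction_s1,
                 min_nonzero_fraction = min_nonzero_fraction,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Draw stratified patch centers from the two box regions
#'
#' Exactly \code{round(n_selected * fraction_s1)} centers carry tag S1
#' (center inside the box) and the remainder tag S0.  Candidates are drawn
#' uniformly over the full volume; selection takes the first candidates of
#' each tag in draw order (stratified uniform subsampling).
#'
#' @param shape volume shape, integer triple.
#' @param box a \code{\link{box_annotation}}.
#' @param cfg a \code{\link{sampler_config}}.
#' @param volume optional \code{\link{multimodal_volume}}, required when
#'   \code{min_nonzero_fraction > 0}.
#' @return data.frame with 0-based integer columns \code{x, y, z} and a
#'   character column \code{tag} ("S1"/"S0").
#' @export
sample_centers <- function(shape, box, cfg, volume = NULL) {
  shape <- check_int3(shape, "shape")
  check_box_in_bounds(box, shape)
  n_s1 <- as.integer(round(cfg$n_selected * cfg$fraction_s1))
  n_s0 <- cfg$n_selected - n_s1
  if (n_s1 < 1L || n_s0 < 1L)
    stopf("n_selected and fraction_s1 must yield at least one patch per region")
  with_seed(cfg$seed, {
    cand <- cbind(x = sample.int(shape[1], cfg$n_candidates, replace = TRUE) - 1L,
                  y = sample.int(shape[2], cfg$n_candidates, replace = TRUE) - 1L,
                  z = sample.int(shape[3], cfg$n_candidates, replace = TRUE) - 1L)
    keep <- rep(TRUE, nrow(cand))
    if (cfg$min_nonzero_fraction > 0) {
      if (is.null(volume)) stopf("'volume' is required for the nonzero filter")
      keep <- apply(cand, 1, function(ctr) {
        p <- cpp_extract_window(volume$intensities, as.integer(ctr), cfg$patch_size)
        mean(p[, , , 1] != 0) >= cfg$min_nonzero_fraction
      })
    }
    inside <- in_box(cand, box)
    i_s1 <- which(inside & keep)
    i_s0 <- which(!inside & keep)
    if (length(i_s1) < n_s1)
      stopf("only %d S1 candidates for %d requested patches; enlarge n_candidates",
            length(i_s1), n_s1)
    if (length(i_s0) < n_s0)
      stopf("region S0 yielded only %d candidate centers for %d requested patches",
            length(i_s0), n_s0)
    sel <- c(i_s1[seq_len(n_s1)], i_s0[seq_len(n_s0)])
    data.frame(x = cand[sel, 1], y = cand[sel, 2], z = cand[sel, 3],
               tag = rep(c("S1", "S0"), c(n_s1, n_s0)),
               stringsAsFactors = FALSE)
  })
}

#' Extract a cubic intensity patch around a center
#'
#' The window of side d has its low corner at \code{center - floor(d/2)}
#' (the floor-center convention for even d); voxels falling outside the
#' volume are filled with 0.
#'
#' @param vol a \code{\link{multimodal_volume}}.
#' @param center 0-based voxel triple, inside the volume.
#' @param d patch side.
#' @return numeric array of dim \code{(d, d, d, channels)}.
#' @export
extract_patch <- function(vol, center, d) {
  center <- check_int3(center, "center")
  shape <- volume_shape(vol)
  if (any(center < 0) || any(center >= shape))
    stopf("center (%s) outside the volume", paste(center, collapse = ","))
  if (d > 2 * max(shape)) stopf("patch side %d exceeds twice the volume extent", d)
  cpp_extract_window(vol$intensities, center, as.integer(d))
}

#' Box-indicator label volume for a patch window
#'
#' A voxel of the window is labeled 1 iff its absolute coordinate lies
#' inside the box; all other voxels -- including padding beyond the volume
#' -- are 0.  This realizes zero-padding of the label where a patch from S1
#' reaches beyond the boxed area.
#'
#' @param center 0-based patch center.
#' @param d patch side.
#' @param box a \code{\link{box_annotation}}.
#' @return numeric \code{(d, d, d)} array of 0/1.
#' @export
label_patch <- function(center, d, box) {
  center <- check_int3(center, "center")
  w0 <- center - d %/% 2L
  lab <- array(0, c(d, d, d))
  lo <- pmax(box$low, w0) - w0          # window-relative, 0-based
  hi <- pmin(box$high, w0 + d) - w0
  if (all(lo < hi))
    lab[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], (lo[3] + 1):hi[3]] <- 1
  lab
}

#' Build the two-scale network input for one patch
#'
#' Channels 1..C are the native patch of side d per modality; channels
#' C+1..2C are a \code{scale_factor * d} context window at the same center,
#' resized down to side d by trilinear interpolation.  With 4 modalities
#' this yields the 8-channel input the network consumes.
#'
#' @param vol a \code{\link{multimodal_volume}}.
#' @param center 0-based voxel triple.
#' @param cfg a \code{\link{sampler_config}}.
#' @return numeric array of dim \code{(d, d, d, 2 * channels)}.
#' @export
build_multiscale_input <- function(vol, center, cfg) {
  d <- cfg$patch_size
  fine <- extract_patch(vol, center, d)
  coarse <- extract_patch(vol, center, cfg$scale_factor * d)
  coarse <- cpp_resize3(coarse, d)
  out <- array(0, c(d, d, d, 2L * n_channels(vol)))
  out[, , , seq_len(n_channels(vol))] <- fine
  out[, , , n_channels(vol) + seq_len(n_channels(vol))] <- coarse
  out
}

# Assemble a feature/label batch for a set of centers.  S0-tagged patches
# get an all-zero label volume (patches from S0 carry the patch-level label
# 0); S1-tagged patches get the box-indicator labels.
make_patch_batch <- function(vol, box, centers, cfg) {
  d <- cfg$patch_size
  n <- nrow(centers)
  nc <- n_channels(vol)
  feats <- array(0, c(d, d, d, 2L * nc, n))
  labs <- array(0, c(d, d, d, n))
  for (i in seq_len(n)) {
    ctr <- c(centers$x[i], centers$y[i], centers$z[i])
    feats[, , , , i] <- build_multiscale_input(vol, ctr, cfg)
    if (centers$tag[i] == "S1") labs[, , , i] <- label_patch(ctr, d, box)
  }
  list(features = feats, labels = labs, tags = centers$tag)
}
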