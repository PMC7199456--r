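#' Dice overlap coefficient
#'
#' \code{2|A n B| / (|A| + |B|)} between two binary masks of the same
#' shape.  Two empty masks agree perfectly by convention (1.0); an empty
#' prediction against a nonempty truth scores 0.
#'
#' @param a,b binary/logical arrays of identical shape.
#' @return unitless score in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("mask shapes differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

# binary mask -> n x 3 matrix of voxel coordinates (grid units)
mask_points <- function(m) {
  if (is.matrix(m) && ncol(m) == 3L) return(m)
  which(m != 0, arr.ind = TRUE) * 1.0
}

# foreground voxels with at least one 6-neighbour outside the mask
# (or on the volume border)
surface_voxels <- function(m) {
  m <- m != 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, src) acc & src
  pad <- function(along, dir) {
    out <- array(FALSE, d)
    if (along == 1) {
      if (dir > 0) out[-d[1], , ] <- m[-1, , ] else out[-1, , ] <- m[-d[1], , ]
    } else if (along == 2) {
      if (dir > 0) out[, -d[2], ] <- m[, -1, ] else out[, -1, ] <- m[, -d[2], ]
    } else {
      if (dir > 0) out[, , -d[3]] <- m[, , -1] else out[, , -1] <- m[, , -d[3]]
    }
    out
  }
  for (along in 1:3) for (dir in c(-1, 1))
    interior <- shift_and(interior, pad(along, dir))
  m & !interior
}

directed_nn <- function(a_pts, b_pts, spacing) {
  cpp_nn_dists(a_pts, b_pts, as.numeric(spacing))
}

as_points <- function(x, surface) {
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  mask_points(if (surface) surface_voxels(x) else x)
}

#' Directed Hausdorff distance
#'
#' \code{max_{a in A} min_{b in B} d(a, b)} in millimetres: the farthest
#' any point of A lies from its nearest point of B.
#'
#' @param a,b binary masks or n x 3 voxel-coordinate matrices.
#' @param spacing mm voxel spacing triple.
#' @param surface compare surface voxels only (identical result for solid
#'   masks, cheaper for large ones).
#' @return distance in mm, or \code{NA} when either set is empty (an
#'   undefined distance is recorded as missing, never as 0).
#' @export
directed_hausdorff <- function(a, b, spacing = c(1, 1, 1), surface = FALSE) {
  pa <- as_points(a, surface); pb <- as_points(b, surface)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(NA_real_)
  max(directed_nn(pa, pb, spacing))
}

#' Symmetric Hausdorff distance
#'
#' The maximum of the two directed distances.  (The directed distance is
#' taken to the *nearest* point of the other set; the max-over-both-sets
#' reading would be the set diameter and is not a segmentation distance.)
#'
#' @inheritParams directed_hausdorff
#' @return distance in mm, or \code{NA} for empty input.
#' @export
hausdorff <- function(a, b, spacing = c(1, 1, 1), surface = FALSE) {
  pa <- as_points(a, surface); pb <- as_points(b, surface)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(NA_real_)
  max(max(directed_nn(pa, pb, spacing)), max(directed_nn(pb, pa, spacing)))
}

#' 95th-percentile Hausdorff distance
#'
#' Robust variant: each directed value is the 95th percentile (linear
#' interpolation between order statistics) of the nearest-neighbour
#' distances from one set to the other; the reported value is the larger of
#' the two directions.  Always \code{<=} the plain Hausdorff distance.
#'
#' @inheritParams directed_hausdorff
#' @param p percentile in (0, 1].
#' @return distance in mm, or \code{NA} for empty input.
#' @export
hausdorff95 <- function(a, b, spacing = c(1, 1, 1), p = 0.95, surface = FALSE) {
  pa <- as_points(a, surface); pb <- as_points(b, surface)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(NA_real_)
  max(quantile(directed_nn(pa, pb, spacing), p, names = FALSE, type = 7),
      quantile(directed_nn(pb, pa, spacing), p, names = FALSE, type = 7))
}

#' Fill interior cavities of a binary mask
#'
#' Background components (6-connectivity) not connected to the volume
#' border become foreground; foreground is never removed, so the output
#' always contains the input and the operation is idempotent.
#'
#' @param mask logical/binary 3D array.
#' @return logical array of the same shape.
#' @export
fill_holes <- function(mask) {
  m <- mask != 0
  storage.mode(m) <- "logical"
  cpp_fill_holes(m)
}

#' Region-growing baseline segmentation
#'
#' A learning-free reference: 6-connected flood fill from a seed point over
#' the normalized contrast channel, admitting a neighbour whenever its
#' absolute intensity difference from the running region mean is strictly
#' below \code{threshold} (default 0.5, the gray-scale discontinuity
#' threshold).
#'
#' @param vol a \code{\link{multimodal_volume}} (normalized).
#' @param seed_point 0-based voxel triple inside the volume; conventionally
#'   the center of the box annotation, keeping the baseline weakly
#'   supervised.
#' @param threshold gray-level discontinuity threshold.
#' @param channel contrast-bearing channel index (1 = FLAIR).
#' @return logical mask: one 6-connected component containing the seed.
#' @export
region_grow_baseline <- function(vol, seed_point, threshold = 0.5, channel = 1L) {
  seed_point <- check_int3(seed_point, "seed_point")
  shape <- volume_shape(vol)
  if (any(seed_point < 0) || any(seed_point >= shape))
    stopf("seed point outside the volume")
  img <- vol$intensities[, , , channel]
  if (img[seed_point[1] + 1, seed_point[2] + 1, seed_point[3] + 1] == 0)
    stopf("seed point lies on zero background")
  cpp_region_grow(img, seed_point, threshold)
}

#' Fold-aggregated cohort evaluation
#'
#' Draws \code{n_folds} seeded random splits holding out \code{1 - split}
#' of the patients, computes Dice, Hausdorff and Hausdorff95 on each
#' held-out set (after hole filling of the thresholded predictions), and
#' reports per-fold and across-fold mean and standard deviation.  Undefined
#' distances (empty masks) are excluded from fold means, with the excluded
#' count reported.
#'
#' @param predictions list of probability volumes or binary masks, one per
#'   patient.
#' @param ground_truths list of binary reference masks, same order.
#' @param spacing mm spacing triple shared by the cohort.
#' @param n_folds number of random splits.
#' @param split training fraction (the evaluation set is the remainder).
#' @param seed split seed.
#' @param threshold probability threshold applied to probability inputs.
#' @param post_process fill holes before scoring.
#' @param surface compute distances on surface voxels only.
#' @return object of class \code{metrics_report}: \code{per_patient},
#'   \code{per_fold} and \code{summary} data frames.
#' @export
evaluate_cohort <- function(predictions, ground_truths, spacing = c(1, 1, 1),
                            n_folds = 5L, split = 0.8, seed = 1L,
                            threshold = 0.5, post_process = TRUE,
                            surface = FALSE) {
  n <- length(predictions)
  if (n != length(ground_truths)) stopf("prediction/truth counts differ")
  if (n < 5L) stopf("cohort evaluation needs at least 5 patients")
  masks <- lapply(predictions, function(p) {
    m <- if (is.logical(p)) p else p >= threshold
    if (post_process) fill_holes(m) else m
  })
  per_patient <- data.frame(
    patient = seq_len(n),
    dice = vapply(seq_len(n), function(i) dice(masks[[i]], ground_truths[[i]]), 0),
    hausdorff = vapply(seq_len(n), function(i)
      hausdorff(masks[[i]], ground_truths[[i]], spacing, surface = surface), 0),
    hausdorff95 = vapply(seq_len(n), function(i)
      hausdorff95(masks[[i]], ground_truths[[i]], spacing, surface = surface), 0))

  n_eval <- max(1L, round((1 - split) * n))
  folds <- with_seed(seed, lapply(seq_len(n_folds), function(f)
    sort(sample.int(n, n_eval))))
  per_fold <- do.call(rbind, lapply(seq_along(folds), function(f) {
    idx <- folds[[f]]
    has_tumor <- vapply(idx, function(i) sum(ground_truths[[i]]) > 0, TRUE)
    if (!any(has_tumor)) {
      warning(sprintf("fold %d holds no tumor-bearing volume; skipped", f))
      return(NULL)
    }
    rows <- per_patient[idx[has_tumor], ]
    data.frame(fold = f, n_eval = nrow(rows),
               dice = mean(rows$dice),
               hausdorff = mean(rows$hausdorff, na.rm = TRUE),
               hausdorff95 = mean(rows$hausdorff95, na.rm = TRUE),
               n_missing_distance = sum(is.na(rows$hausdorff)))
  }))
  metric_summary <- data.frame(
    metric = c("dice", "hausdorff", "hausdorff95"),
    mean = c(mean(per_fold$dice), mean(per_fold$hausdorff),
             mean(per_fold$hausdorff95)),
    sd = c(sd(per_fold$dice), sd(per_fold$hausdorff),
           sd(per_fold$hausdorff95)))
  structure(list(per_patient = per_patient, per_fold = per_fold,
                 summary = metric_summary, folds = folds),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: %d patients, %d folds\n",
              nrow(x$per_patient), nrow(x$per_fold)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Write a metrics report as JSON and CSV
#'
#' @param report a \code{metrics_report}.
#' @param json_path,csv_path output paths (NULL to skip either).
#' @return the report, invisibly.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(summary = report$summary,
                              per_fold = report$per_fold),
                         json_path, auto_unbox = TRUE, pretty = TRUE,
                         dataframe = "rows", na = "null")
  if (!is.null(csv_path))
    utils::write.csv(report$per_patient, csv_path, row.names = FALSE)
  invisible(report)
}
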