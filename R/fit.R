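#' Training configuration
#'
#' Mini-batch ADAM optimization of either the non-negative PU objective
#' (\code{mode = "pu"}) or the naive box-supervised cross-entropy
#' (\code{mode = "naive"}).  The PU schedule follows the gradient-switching
#' rule: while the empirical correction term stays above \code{-beta} the
#' optimizer descends the full clamped objective with step scale \code{eta};
#' when it falls below, the step descends the negated correction with the
#' discounted scale \code{gamma * eta}.
#'
#' @param batch_size patches per mini-batch (>= 2; 64 at full scale, 8 at
#'   desk scale).
#' @param epochs passes over the patch set (>= 1).
#' @param learning_rate base ADAM step size, scaled by \code{eta}.
#' @param pu a \code{\link{pu_loss_config}}.
#' @param mode \code{"pu"} or \code{"naive"}.
#' @param seed seed for epoch shuffling.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(batch_size = 8L, epochs = 3L, learning_rate = 1e-3,
                         pu = pu_loss_config(), mode = c("pu", "naive"),
                         seed = 1L) {
  mode <- match.arg(mode)
  if (batch_size < 2) stopf("batch_size must be >= 2")
  if (epochs < 1) stopf("epochs must be >= 1")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, pu = pu, mode = mode,
                 seed = as.integer(seed)),
            class = "train_config")
}

# forward/backward passes run over micro-batches of this many patches;
# a larger configured batch_size is accumulated across micro-batches
MICRO_BATCH <- 8L

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

# one ADAM update; `scale` multiplies the base step size (eta or gamma*eta)
adam_step <- function(theta, grad, state, lr, scale,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - scale * lr * mhat / (sqrt(vhat) + eps), state = state)
}

# compose one stratified mini-batch index set: every batch carries both
# S1 and S0 patches so each voxel batch contains both label classes
plan_batches <- function(tags, batch_size, frac_s1) {
  n <- length(tags)
  steps <- n %/% batch_size
  n_s1b <- min(max(1L, as.integer(round(batch_size * frac_s1))), batch_size - 1L)
  list(steps = steps, n_s1b = n_s1b, n_s0b = batch_size - n_s1b)
}

#' Train a segmentation network from box-annotated patches
#'
#' Implements the PU optimization schedule: per mini-batch the three
#' empirical risk components are computed from the voxel logits and labels;
#' if \code{r_u_minus - pi_p * r_p_minus >= -beta} the ADAM optimizer steps
#' on the gradient of the full non-negative objective with step scale
#' \code{eta}, otherwise on the gradient of
#' \code{pi_p * r_p_minus - r_u_minus} with the discounted scale
#' \code{gamma * eta}.  In \code{"naive"} mode the branch logic is bypassed
#' and plain mean cross-entropy on the box labels is minimized.  Mini-batches
#' are stratified (each contains both S1- and S0-tagged patches, in the
#' pool's proportion) so that both label classes are always present; the
#' patch order is reshuffled per epoch from the training seed.
#'
#' @param patients list of per-patient lists with elements \code{volume} (a
#'   normalized \code{\link{multimodal_volume}}), \code{box} (a
#'   \code{\link{box_annotation}}) and \code{centers} (from
#'   \code{\link{sample_centers}}).
#' @param network a \code{unet3d} from \code{\link{build_network}}.
#' @param cfg a \code{\link{train_config}}.
#' @param sampler a \code{\link{sampler_config}} (patch geometry).
#' @param precomputed optional patch pool from \code{\link{extract_pool}},
#'   allowing several fits (e.g. PU and naive on identical patches) to
#'   share one extraction pass.
#' @return list with \code{network} (trained parameters) and \code{history}
#'   (one data.frame row per optimization step: epoch, step, the three risk
#'   components, objective, branch flag).
#' @export
train <- function(patients, network, cfg, sampler = sampler_config(),
                  precomputed = NULL) {
  pc <- precomputed %||% extract_pool(patients, sampler)
  pool <- pc$pool; feats <- pc$features; labs <- pc$labels
  if (!any(pool$tag == "S1") || !any(pool$tag == "S0"))
    stopf("the patch pool must contain both S1 and S0 patches")
  frac_s1 <- mean(pool$tag == "S1")
  plan <- plan_batches(pool$tag, cfg$batch_size, frac_s1)
  if (plan$steps < 1) stopf("fewer patches than one batch")

  theta <- flatten_params(network$params)
  state <- adam_init(length(theta))
  pu <- cfg$pu
  hist <- vector("list", plan$steps * cfg$epochs)
  k <- 0L
  s1_rows <- which(pool$tag == "S1")
  s0_rows <- which(pool$tag == "S0")

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      s1_q <- sample(s1_rows)
      s0_q <- sample(s0_rows)
      p1 <- 0L; p0 <- 0L
      for (step in seq_len(plan$steps)) {
        if (p1 + plan$n_s1b > length(s1_q)) { s1_q <- sample(s1_rows); p1 <- 0L }
        if (p0 + plan$n_s0b > length(s0_q)) { s0_q <- sample(s0_rows); p0 <- 0L }
        rows <- c(s1_q[p1 + seq_len(plan$n_s1b)], s0_q[p0 + seq_len(plan$n_s0b)])
        p1 <- p1 + plan$n_s1b; p0 <- p0 + plan$n_s0b

        network$params <- unflatten_params(theta, network$params)
        # forward in micro-batches (gradient accumulation): the objective,
        # its branch and the gradient are those of the full mini-batch
        chunks <- split(seq_along(rows), ceiling(seq_along(rows) / MICRO_BATCH))
        fwds <- lapply(chunks, function(pos)
          unet_forward_cached(network, feats[, , , , rows[pos], drop = FALSE]))
        logits <- unlist(lapply(fwds, `[[`, "logits"), use.names = FALSE)
        batch_labels <- labs[, , , rows, drop = FALSE]

        if (cfg$mode == "naive") {
          objective <- naive_risk(logits, batch_labels)
          comps <- list(r_p_plus = NA_real_, r_u_minus = NA_real_,
                        r_p_minus = NA_real_)
          branch <- NA
          dlog <- risk_grad_logits(logits, batch_labels, pu, "naive")
          scale <- pu$eta
        } else {
          comps <- risk_components(logits, batch_labels, averaging = pu$averaging)
          nn <- nn_pu_risk(comps, pu)
          objective <- nn$risk
          branch <- nn$correction_negative
          if (!branch) {
            dlog <- risk_grad_logits(logits, batch_labels, pu, "pu")
            scale <- pu$eta
          } else {
            dlog <- risk_grad_logits(logits, batch_labels, pu, "correction")
            scale <- pu$gamma * pu$eta
          }
        }
        if (!is.finite(objective))
          stopf("non-finite objective at epoch %d step %d (components: %s)",
                epoch, step, paste(signif(unlist(comps), 4), collapse = ", "))

        vpp <- length(dlog) %/% length(rows)    # voxels per patch
        gflat <- 0
        for (ci in seq_along(chunks)) {
          sel <- rep((chunks[[ci]] - 1L) * vpp, each = vpp) + seq_len(vpp)
          gflat <- gflat + flatten_params(unet_backward(fwds[[ci]], dlog[sel]))
        }
        upd <- adam_step(theta, gflat, state, cfg$learning_rate, scale)
        theta <- upd$theta; state <- upd$state

        # bound the allocation garbage of past steps; without this the
        # collector can let several GB of dead batch arrays accumulate
        if (k %% 40L == 0L) gc(FALSE)

        k <- k + 1L
        hist[[k]] <- data.frame(epoch = epoch, step = k,
                                r_p_plus = comps$r_p_plus,
                                r_u_minus = comps$r_u_minus,
                                r_p_minus = comps$r_p_minus,
                                objective = objective, branch = branch,
                                step_scale = scale)
      }
    }
  })
  network$params <- unflatten_params(theta, network$params)
  list(network = network, history = do.call(rbind, hist))
}

#' Extract the full training patch pool of a patient collection
#'
#' Builds the multiscale feature and box-label arrays for every sampled
#' center of every patient, once.  \code{\link{train}} calls this
#' internally; extracting explicitly lets several fits on the same patches
#' (e.g. the PU and naive objectives) share the work.
#'
#' @param patients as in \code{\link{train}}.
#' @param sampler a \code{\link{sampler_config}}.
#' @return list with \code{pool} (patch index data.frame), \code{features}
#'   and \code{labels} arrays.
#' @export
extract_pool <- function(patients, sampler) {
  pool <- do.call(rbind, lapply(seq_along(patients), function(i) {
    ctr <- patients[[i]]$centers
    data.frame(patient = i, row = seq_len(nrow(ctr)), tag = ctr$tag,
               stringsAsFactors = FALSE)
  }))
  d <- sampler$patch_size
  nc_in <- 2L * n_channels(patients[[1]]$volume)
  feats <- array(0, c(d, d, d, nc_in, nrow(pool)))
  labs <- array(0, c(d, d, d, nrow(pool)))
  for (i in seq_len(nrow(pool))) {
    p <- patients[[pool$patient[i]]]
    one <- make_patch_batch(p$volume, p$box, p$centers[pool$row[i], ], sampler)
    feats[, , , , i] <- one$features[, , , , 1]
    labs[, , , i] <- one$labels[, , , 1]
  }
  list(pool = pool, features = feats, labels = labs)
}

#' Whole-volume sliding-window inference
#'
#' Tiles the (normalized) volume with overlapping multiscale patches at
#' stride \code{d/2}, applies the network, and averages the sigmoid
#' probabilities where tiles overlap.
#'
#' @param network a trained \code{unet3d}.
#' @param vol a normalized \code{\link{multimodal_volume}}.
#' @param sampler a \code{\link{sampler_config}} (patch geometry must match
#'   the training geometry).
#' @param stride tile stride, voxels; default \code{d/2}.
#' @param tile_batch tiles evaluated per forward pass.
#' @return probability array (values in [0, 1]) of the volume's shape.
#' @export
predict_volume <- function(network, vol, sampler = sampler_config(),
                           stride = NULL, tile_batch = 32L) {
  d <- sampler$patch_size
  shape <- volume_shape(vol)
  if (any(shape < d)) stopf("volume (%s) smaller than the %d-voxel patch",
                            paste(shape, collapse = "x"), d)
  stride <- as.integer(stride %||% (d %/% 2L))
  starts <- lapply(shape, function(s) unique(c(seq(0L, s - d, by = stride), s - d)))
  grid <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  prob <- array(0, shape)
  cnt <- array(0, shape)
  half <- d %/% 2L
  for (i0 in seq(1L, nrow(grid), by = tile_batch)) {
    idx <- i0:min(i0 + tile_batch - 1L, nrow(grid))
    feats <- array(0, c(d, d, d, 2L * n_channels(vol), length(idx)))
    for (j in seq_along(idx))
      feats[, , , , j] <- build_multiscale_input(vol, grid[idx[j], ] + half, sampler)
    logits <- unet_forward(network, feats)
    p <- 1 / (1 + exp(-logits))
    for (j in seq_along(idx)) {
      s <- grid[idx[j], ]
      xs <- (s[1] + 1):(s[1] + d); ys <- (s[2] + 1):(s[2] + d); zs <- (s[3] + 1):(s[3] + d)
      prob[xs, ys, zs] <- prob[xs, ys, zs] + p[, , , 1, j]
      cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1
    }
  }
  prob / cnt
}

#' Fit a box-supervised segmentation model
#'
#' The main entry point: takes a cohort of multimodal volumes with either
#' voxel masks (from which tight boxes are derived -- the masks themselves
#' are never used for gradients) or box annotations, normalizes intensities,
#' draws box-stratified training patches, and trains the segmentation
#' network under the chosen objective.
#'
#' @param cohort list of per-patient lists; each needs \code{volume} (a
#'   \code{\link{multimodal_volume}}) and either \code{box} (a
#'   \code{\link{box_annotation}}) or \code{mask} (binary array).
#' @param mode \code{"pu"} for non-negative positive-unlabeled training,
#'   \code{"naive"} for plain box supervision.
#' @param sampler a \code{\link{sampler_config}}.
#' @param net a \code{\link{network_config}}; its \code{patch_size} and
#'   \code{in_channels} must match the sampler and modality count.
#' @param control a \code{\link{train_config}}; its \code{mode} is
#'   overridden by \code{mode}.
#' @param normalize z-score the volumes over brain voxels first (disable
#'   only if the cohort is already normalized).
#' @param box_margin symmetric voxel margin added when deriving boxes from
#'   masks ("roughly covering" rather than tight boxes).  The class prior
#'   of the PU objective refers to the background fraction of the box
#'   interior, so the margin should be generous enough that this fraction
#'   is at least \code{pi_p}; ignored for entries that provide a box
#'   directly.
#' @param seed master seed: initial network parameters, per-patient patch
#'   selection and epoch shuffling all derive from it.
#' @return object of class \code{puboxseg}: the trained network, the
#'   training history, the per-patient boxes, and all configurations.
#' @seealso \code{\link{predict.puboxseg}}, \code{\link{evaluate_cohort}}
#' @export
puboxseg <- function(cohort, mode = c("pu", "naive"),
                     sampler = sampler_config(),
                     net = network_config(patch_size = sampler$patch_size),
                     control = train_config(), normalize = TRUE,
                     box_margin = 0L, seed = 1L) {
  mode <- match.arg(mode)
  if (net$patch_size != sampler$patch_size)
    stopf("network patch_size (%d) must match sampler patch_size (%d)",
          net$patch_size, sampler$patch_size)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(cohort) + 2L))
  patients <- lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]
    if (is.null(p$volume)) stopf("cohort entry %d lacks a volume", i)
    vol <- if (normalize) normalize_volume(p$volume) else p$volume
    box <- p$box %||% box_from_mask(p$mask, margin = box_margin,
                                    patient_id = vol$patient_id)
    check_box_in_bounds(box, volume_shape(vol))
    scfg <- sampler; scfg$seed <- seeds[i]
    centers <- sample_centers(volume_shape(vol), box, scfg, volume = vol)
    list(volume = vol, box = box, centers = centers)
  })
  if (2L * n_channels(patients[[1]]$volume) != net$in_channels)
    stopf("network expects %d input channels but volumes provide %d",
          net$in_channels, 2L * n_channels(patients[[1]]$volume))
  network <- build_network(net, seed = seeds[length(cohort) + 1L])
  control$mode <- mode
  control$seed <- seeds[length(cohort) + 2L]
  fitted <- train(patients, network, control, sampler = sampler)
  structure(list(network = fitted$network, history = fitted$history,
                 boxes = lapply(patients, `[[`, "box"),
                 patient_ids = vapply(patients, function(p) p$volume$patient_id, ""),
                 mode = mode, sampler = sampler, net = net,
                 control = control, seed = as.integer(seed),
                 call = match.call()),
            class = "puboxseg")
}

#' @export
print.puboxseg <- function(x, ...) {
  h <- x$history
  cat(sprintf("puboxseg model (mode = %s)\n", x$mode))
  cat(sprintf("  %d patients, %d training steps over %d epoch(s)\n",
              length(x$patient_ids), nrow(h), max(h$epoch)))
  cat(sprintf("  final objective: %.4f", tail(h$objective, 1)))
  if (x$mode == "pu")
    cat(sprintf("  (discounted-branch steps: %d/%d)", sum(h$branch), nrow(h)))
  cat("\n")
  invisible(x)
}

#' @export
summary.puboxseg <- function(object, ...) {
  h <- object$history
  per_epoch <- aggregate(h["objective"], by = list(epoch = h$epoch), FUN = mean)
  out <- list(mode = object$mode, n_patients = length(object$patient_ids),
              steps = nrow(h), per_epoch = per_epoch,
              n_branch = if (object$mode == "pu") sum(h$branch) else NA_integer_,
              pi_p = object$control$pu$pi_p, n_params = n_params(object$net))
  class(out) <- "summary.puboxseg"
  out
}

#' @export
print.summary.puboxseg <- function(x, ...) {
  cat(sprintf("Box-supervised segmentation fit (mode = %s, pi_p = %.2f, %d parameters)\n",
              x$mode, x$pi_p, x$n_params))
  cat(sprintf("  %d patients, %d steps; mean objective per epoch:\n", x$n_patients, x$steps))
  for (i in seq_len(nrow(x$per_epoch)))
    cat(sprintf("    epoch %d: %.4f\n", x$per_epoch$epoch[i], x$per_epoch$objective[i]))
  if (!is.na(x$n_branch))
    cat(sprintf("  discounted-branch steps: %d\n", x$n_branch))
  invisible(x)
}

#' @export
coef.puboxseg <- function(object, ...) flatten_params(object$network$params)

#' Predict a tumor probability map or mask for a volume
#'
#' @param object a fitted \code{\link{puboxseg}} model.
#' @param newdata a \code{\link{multimodal_volume}}.
#' @param type \code{"prob"} for the probability volume, \code{"mask"} for
#'   the thresholded binary mask (after optional hole filling).
#' @param threshold probability threshold for \code{type = "mask"}.
#' @param post_process fill interior cavities of the thresholded mask.
#' @param normalize z-score \code{newdata} first.
#' @param ... unused.
#' @return numeric probability array or logical mask, volume-shaped.
#' @export
predict.puboxseg <- function(object, newdata, type = c("prob", "mask"),
                             threshold = 0.5, post_process = TRUE,
                             normalize = TRUE, ...) {
  type <- match.arg(type)
  vol <- if (normalize) normalize_volume(newdata) else newdata
  prob <- predict_volume(object$network, vol, sampler = object$sampler)
  if (type == "prob") return(prob)
  mask <- prob >= threshold
  if (post_process) mask <- fill_holes(mask)
  mask
}

#' Plot the training objective trace
#'
#' @param x a fitted \code{\link{puboxseg}} model.
#' @param ... passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.puboxseg <- function(x, ...) {
  h <- x$history
  graphics::plot(h$step, h$objective, type = "l", xlab = "step",
                 ylab = "objective (nats)",
                 main = sprintf("%s training objective", x$mode), ...)
  if (x$mode == "pu" && any(h$branch, na.rm = TRUE))
    graphics::points(h$step[h$branch], h$objective[h$branch],
                     pch = 4, col = "red3")
  invisible(x)
}
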