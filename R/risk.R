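#' PU loss configuration
#'
#' Hyperparameters of the positive-unlabeled training objective.  The class
#' prior \code{pi_p} is the proportion of positive-class (background)
#' voxels; it defaults to the fixed operating value 0.75 but can be
#' recomputed from box annotations via \code{\link{class_prior}}.  When the
#' empirical correction term drops below \code{-beta}, the optimizer takes a
#' gradient step *against* the correction with step size scaled by
#' \code{gamma * eta} instead of \code{eta}.
#'
#' @param pi_p class prior of the positive class, in (0, 1); default 0.75.
#' @param beta non-negativity slack, in \code{[0, pi_p]}; default 0 so the
#'   clamped objective is used exactly as written.
#' @param gamma step discount for correction steps, in (0, 1]; default 1.
#' @param eta multiplicative scale on the optimizer's step size; default 0.5.
#' @param averaging \code{"group"} averages each empirical risk term over
#'   its own label group (the convention of the non-negative PU estimator);
#'   \code{"shared"} divides every term by the full batch voxel count.
#' @return object of class \code{pu_loss_config}.
#' @export
pu_loss_config <- function(pi_p = 0.75, beta = 0, gamma = 1, eta = 0.5,
                           averaging = c("group", "shared")) {
  averaging <- match.arg(averaging)
  if (pi_p <= 0 || pi_p >= 1) stopf("pi_p must lie strictly inside (0, 1)")
  if (beta < 0 || beta > pi_p) stopf("beta must lie in [0, pi_p]")
  if (gamma <= 0 || gamma > 1) stopf("gamma must lie in (0, 1]")
  if (eta <= 0) stopf("eta must be > 0")
  structure(list(pi_p = pi_p, beta = beta, gamma = gamma, eta = eta,
                 averaging = averaging),
            class = "pu_loss_config")
}

#' Numerically stable per-voxel cross-entropy
#'
#' With predicted probability \code{sigma(logit)} for class 1 (tumor; the
#' negative class in PU vocabulary), the loss is \code{-log sigma(logit)}
#' for target 1 and \code{-log(1 - sigma(logit))} for target 0, evaluated in
#' softplus form so that arbitrarily large logits neither overflow nor lose
#' the loss to rounding.
#'
#' @param logit real-valued logit(s).
#' @param target 0/1 target class, recycled against \code{logit}.
#' @return loss in nats, same length as \code{logit}.
#' @export
voxel_ce <- function(logit, target) {
  # softplus(x) = log(1 + exp(x)), stable form
  sp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
  n <- max(length(logit), length(target))
  logit <- rep_len(as.numeric(logit), n)
  target <- rep_len(as.numeric(target), n)
  out <- sp(logit)                # target 0: -log(1 - sigma(logit))
  neg <- target == 1
  out[neg] <- sp(-logit[neg])     # target 1: -log sigma(logit)
  out
}

#' Empirical PU risk components of a voxel batch
#'
#' Splits the batch by its box-derived voxel labels (0 = positive /
#' background, 1 = unlabeled / inside box) and returns the three empirical
#' means from which both PU objectives are assembled: \code{r_p_plus}
#' (positive-class loss on positive voxels), \code{r_u_minus}
#' (negative-class loss on unlabeled voxels) and \code{r_p_minus}
#' (negative-class loss on positive voxels).
#'
#' @param logits numeric vector/array of per-voxel logits.
#' @param labels matching 0/1 voxel labels.
#' @param averaging see \code{\link{pu_loss_config}}.
#' @return object of class \code{risk_components} with the three risk terms
#'   (nats) and the voxel counts \code{n_pos}, \code{n_unl}.
#' @export
risk_components <- function(logits, labels, averaging = c("group", "shared")) {
  averaging <- match.arg(averaging)
  logits <- as.numeric(logits); labels <- as.numeric(labels)
  if (length(logits) != length(labels)) stopf("logits/labels length mismatch")
  pos <- labels == 0
  n_pos <- sum(pos); n_unl <- length(labels) - n_pos
  if (n_pos == 0L || n_unl == 0L)
    stopf(paste("batch contains a single label class; PU risk needs both --",
                "mix S1 and S0 patches at the sampler level"))
  denom_p <- if (averaging == "group") n_pos else length(labels)
  denom_u <- if (averaging == "group") n_unl else length(labels)
  structure(list(
    r_p_plus = sum(voxel_ce(logits[pos], 0)) / denom_p,
    r_u_minus = sum(voxel_ce(logits[!pos], 1)) / denom_u,
    r_p_minus = sum(voxel_ce(logits[pos], 1)) / denom_p,
    n_pos = n_pos, n_unl = n_unl, averaging = averaging),
    class = "risk_components")
}

#' @export
print.risk_components <- function(x, ...) {
  cat(sprintf("risk_components: r_p_plus = %.4f, r_u_minus = %.4f, r_p_minus = %.4f (n_pos = %d, n_unl = %d)\n",
              x$r_p_plus, x$r_u_minus, x$r_p_minus, x$n_pos, x$n_unl))
  invisible(x)
}

#' Unbiased PU risk
#'
#' \code{pi_p * r_p_plus + r_u_minus - pi_p * r_p_minus}: an unbiased
#' estimate of the fully supervised risk built from positive and unlabeled
#' voxels only.  May be negative on flexible models, which is the
#' overfitting signal the non-negative variant clamps away.
#'
#' @param comps a \code{\link{risk_components}}.
#' @param cfg a \code{\link{pu_loss_config}}.
#' @return scalar risk (nats).
#' @export
pu_risk <- function(comps, cfg = pu_loss_config()) {
  cfg$pi_p * comps$r_p_plus + comps$r_u_minus - cfg$pi_p * comps$r_p_minus
}

#' Non-negative PU risk
#'
#' \code{pi_p * r_p_plus + max(0, r_u_minus - pi_p * r_p_minus)}.  The flag
#' reports whether the correction term fell below \code{-beta}, i.e.
#' whether a training step should instead descend the negated correction
#' with the discounted step size.
#'
#' @inheritParams pu_risk
#' @return list with \code{risk} (scalar, >= 0 when \code{beta = 0}) and
#'   \code{correction_negative} (logical branch flag).
#' @export
nn_pu_risk <- function(comps, cfg = pu_loss_config()) {
  corr <- comps$r_u_minus - cfg$pi_p * comps$r_p_minus
  list(risk = cfg$pi_p * comps$r_p_plus + max(0, corr),
       correction_negative = corr < -cfg$beta)
}

#' Naive box-supervised risk
#'
#' Plain mean cross-entropy over all voxels with the box-derived labels
#' treated as ground truth -- the baseline that over-segments toward the
#' box because background voxels inside it carry the wrong label.
#'
#' @param logits per-voxel logits.
#' @param labels matching 0/1 labels.
#' @return scalar mean loss (nats).
#' @export
naive_risk <- function(logits, labels) {
  mean(voxel_ce(as.numeric(logits), as.numeric(labels)))
}

# d(objective)/d(logit) for each voxel of a batch.
# branch "pu": gradient of the full unbiased objective
#   pi_p * r_p_plus + (r_u_minus - pi_p * r_p_minus)
# branch "correction": gradient of (pi_p * r_p_minus - r_u_minus)
# branch "naive": gradient of the plain mean cross-entropy.
# Uses d/dlogit[-log(1-sigma)] = sigma and d/dlogit[-log sigma] = sigma - 1.
risk_grad_logits <- function(logits, labels, cfg, branch) {
  sig <- 1 / (1 + exp(-as.numeric(logits)))
  labels <- as.numeric(labels)
  pos <- labels == 0
  n <- length(labels)
  g <- numeric(n)
  if (branch == "naive") {
    g[pos] <- sig[pos] / n
    g[!pos] <- (sig[!pos] - 1) / n
  } else {
    n_pos <- sum(pos); n_unl <- n - n_pos
    denom_p <- if (cfg$averaging == "group") n_pos else n
    denom_u <- if (cfg$averaging == "group") n_unl else n
    if (branch == "pu") {
      # pi_p * (ce(.,0) - ce(.,1)) on positives: sigma - (sigma - 1) = 1
      g[pos] <- cfg$pi_p / denom_p
      g[!pos] <- (sig[!pos] - 1) / denom_u
    } else if (branch == "correction") {
      g[pos] <- cfg$pi_p * (sig[pos] - 1) / denom_p
      g[!pos] <- -(sig[!pos] - 1) / denom_u
    } else stopf("unknown branch '%s'", branch)
  }
  dim(g) <- dim(logits)
  g
}
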