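# Independent oracles used across tests; deliberately naive implementations
# that share no code with the package internals.

# plain-formula cross-entropy (safe for |logit| <= ~35 in double)
ce_oracle <- function(logit, target) {
  p <- 1 / (1 + exp(-logit))
  if (target == 1) -log(p) else -log(1 - p)
}

# per-voxel loop versions of the risk terms
risk_oracle <- function(logits, labels, pi_p = 0.75) {
  sp <- su <- sm <- 0
  n_pos <- n_unl <- 0L
  for (i in seq_along(logits)) {
    if (labels[i] == 0) {
      sp <- sp + ce_oracle(logits[i], 0)
      sm <- sm + ce_oracle(logits[i], 1)
      n_pos <- n_pos + 1L
    } else {
      su <- su + ce_oracle(logits[i], 1)
      n_unl <- n_unl + 1L
    }
  }
  r_p_plus <- sp / n_pos; r_u_minus <- su / n_unl; r_p_minus <- sm / n_pos
  list(r_p_plus = r_p_plus, r_u_minus = r_u_minus, r_p_minus = r_p_minus,
       pu = pi_p * r_p_plus + r_u_minus - pi_p * r_p_minus,
       nn_pu = pi_p * r_p_plus + max(0, r_u_minus - pi_p * r_p_minus))
}

naive_oracle <- function(logits, labels) {
  s <- 0
  for (i in seq_along(logits)) s <- s + ce_oracle(logits[i], labels[i])
  s / length(logits)
}

# exhaustive double-loop Hausdorff machinery on coordinate matrices
pair_dists <- function(A, B, spacing) {
  d <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      d[i, j] <- sqrt(sum(((A[i, ] - B[j, ]) * spacing)^2))
  d
}
directed_hd_oracle <- function(A, B, spacing = c(1, 1, 1))
  max(apply(pair_dists(A, B, spacing), 1, min))
hd_oracle <- function(A, B, spacing = c(1, 1, 1))
  max(directed_hd_oracle(A, B, spacing), directed_hd_oracle(B, A, spacing))
hd95_oracle <- function(A, B, spacing = c(1, 1, 1)) {
  da <- apply(pair_dists(A, B, spacing), 1, min)
  db <- apply(pair_dists(B, A, spacing), 1, min)
  max(quantile(da, 0.95, names = FALSE), quantile(db, 0.95, names = FALSE))
}

# number of 6-connected foreground components (BFS over an index queue)
n_components_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  comp <- 0L
  idx <- which(mask != 0, arr.ind = TRUE)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    if (lab[v[1], v[2], v[3]] > 0) next
    comp <- comp + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- comp
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(6)) {
        w <- cur + offs[o, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] != 0 && lab[w[1], w[2], w[3]] == 0L) {
          lab[w[1], w[2], w[3]] <- comp
          queue[[length(queue) + 1L]] <- w
        }
      }
    }
  }
  comp
}

# random small binary mask with at least one foreground voxel
random_mask <- function(side, p = 0.1) {
  repeat {
    m <- array(runif(side^3) < p, rep(side, 3))
    if (any(m)) return(m)
  }
}

# small, fast phantom settings for tests
tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(volume_shape = c(32L, 32L, 32L), tumor_radii_range = c(4, 6),
         seed = seed),
    list(...))
  do.call(phantom_spec, args)
}
tiny_sampler <- function(seed = 1L, n_selected = 20L)
  sampler_config(patch_size = 8L, n_candidates = 2000L,
                 n_selected = n_selected, seed = seed)
tiny_net <- function(...) network_config(in_channels = 8L, base_filters = 2L,
                                         depth = 2L, patch_size = 8L, ...)

# independent inside-box predicate on 0-based coordinates
in_box_pts <- function(pts, box) {
  pts[, 1] >= box$low[1] & pts[, 1] < box$high[1] &
  pts[, 2] >= box$low[2] & pts[, 2] < box$high[2] &
  pts[, 3] >= box$low[3] & pts[, 3] < box$high[3]
}
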