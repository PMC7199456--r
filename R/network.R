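#' Configuration of the volumetric segmentation network
#'
#' An encoder-decoder 3D U-Net with skip connections, one down-sampling
#' stage fewer than the reference architecture (two stages by default):
#' aggressive down-sampling erases the edge features of small structures.
#' Each stage is two 3x3x3 convolution + instance-norm + ReLU units; 2x max
#' pooling between encoder stages, nearest-neighbour up-sampling plus skip
#' concatenation between decoder stages, and a final 1x1x1 convolution to a
#' single logit channel at input resolution.
#'
#' @param in_channels input channel count (8 for 4 modalities at 2 scales).
#' @param base_filters filters of the first stage; doubled per stage.
#' @param depth number of down-sampling stages; \code{patch_size} must be
#'   divisible by \code{2^depth}.
#' @param patch_size cubic input side d.
#' @param precision \code{"single"} (default) or \code{"double"} arithmetic
#'   for the network forward/backward passes.  The algorithm is identical;
#'   double precision is mainly useful for numerical gradient verification.
#' @param norm per-unit feature normalization: \code{"none"} (default) or
#'   \code{"instance"}.  Instance normalization standardizes every channel
#'   within each patch, which discards the patch's absolute intensity level;
#'   on inputs whose foreground is distinguished mainly by a global
#'   intensity shift (z-scored MR, piecewise-constant phantoms) that cue is
#'   load-bearing, so plain conv + ReLU blocks are the default.
#' @return object of class \code{network_config}.
#' @export
network_config <- function(in_channels = 8L, base_filters = 8L,
                           depth = 2L, patch_size = 16L,
                           precision = c("single", "double"),
                           norm = c("none", "instance")) {
  precision <- match.arg(precision)
  norm <- match.arg(norm)
  if (depth < 1) stopf("depth must be >= 1")
  if (patch_size %% (2^depth) != 0)
    stopf("patch_size %d is not divisible by 2^depth = %d", patch_size, 2^depth)
  if (patch_size %/% (2^depth) < 2)
    stopf("patch_size too small for depth %d", depth)
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 patch_size = as.integer(patch_size),
                 precision = precision, norm = norm),
            class = "network_config")
}

# channel bookkeeping shared with the C++ side (stages are 1-based here)
enc_channels <- function(cfg, st)
  list(cin = if (st == 1) cfg$in_channels else cfg$base_filters * 2^(st - 2),
       cout = cfg$base_filters * 2^(st - 1))
dec_channels <- function(cfg, st) {
  below <- if (st == cfg$depth) cfg$base_filters * 2^cfg$depth
           else cfg$base_filters * 2^st
  list(cin = cfg$base_filters * 2^(st - 1) + below,
       cout = cfg$base_filters * 2^(st - 1))
}

unet_param_shapes <- function(cfg) {
  shapes <- list()
  with_norm <- identical(cfg$norm, "instance")
  block <- function(pre, cin, cout) {
    shapes[[paste0(pre, "c1_W")]] <<- c(3L, 3L, 3L, cin, cout)
    shapes[[paste0(pre, "c1_b")]] <<- cout
    if (with_norm) {
      shapes[[paste0(pre, "n1_g")]] <<- cout
      shapes[[paste0(pre, "n1_b")]] <<- cout
    }
    shapes[[paste0(pre, "c2_W")]] <<- c(3L, 3L, 3L, cout, cout)
    shapes[[paste0(pre, "c2_b")]] <<- cout
    if (with_norm) {
      shapes[[paste0(pre, "n2_g")]] <<- cout
      shapes[[paste0(pre, "n2_b")]] <<- cout
    }
  }
  for (st in seq_len(cfg$depth)) {
    ch <- enc_channels(cfg, st)
    block(paste0("e", st), ch$cin, ch$cout)
  }
  block("b", cfg$base_filters * 2^(cfg$depth - 1), cfg$base_filters * 2^cfg$depth)
  for (st in seq_len(cfg$depth)) {
    ch <- dec_channels(cfg, st)
    block(paste0("d", st), ch$cin, ch$cout)
  }
  shapes[["f_W"]] <- c(cfg$base_filters, 1L)
  shapes[["f_b"]] <- 1L
  shapes
}

#' Build a segmentation network with seeded initialization
#'
#' Convolution weights use He-normal initialization (sd
#' \code{sqrt(2 / fan_in)}); biases start at 0, instance-norm gains at 1.
#' The final 1x1x1 logit head starts at exactly zero by default, so every
#' voxel begins at probability 0.5: the initial prediction carries no
#' seed-dependent skew, which matters for the PU schedule whose branch
#' decisions respond to the early logit distribution.  Two builds with the
#' same seed are identical.
#'
#' @param cfg a \code{\link{network_config}}.
#' @param seed integer seed for the initial parameters.
#' @param head_init \code{"zero"} (default) or \code{"random"} (He-normal)
#'   initialization of the final logit layer.
#' @return object of class \code{unet3d} with elements \code{config} and
#'   \code{params} (named list of parameter arrays).
#' @export
build_network <- function(cfg, seed = 1L, head_init = c("zero", "random")) {
  head_init <- match.arg(head_init)
  shapes <- unet_param_shapes(cfg)
  params <- with_seed(seed, {
    lapply(seq_along(shapes), function(i) {
      nm <- names(shapes)[i]; shp <- shapes[[i]]
      if (identical(nm, "f_W") && head_init == "zero") {
        array(0, shp)
      } else if (grepl("_W$", nm)) {
        fan_in <- prod(shp[-length(shp)])
        array(rnorm(prod(shp), 0, sqrt(2 / fan_in)), shp)
      } else if (grepl("n[12]_g$", nm)) {
        rep(1, shp)
      } else if (identical(nm, "f_b")) 0 else rep(0, shp)
    })
  })
  names(params) <- names(shapes)
  structure(list(config = cfg, params = params, seed = as.integer(seed),
                 head_init = head_init),
            class = "unet3d")
}

#' Total trainable parameter count
#' @param net a \code{unet3d} or \code{network_config}.
#' @return integer.
#' @export
n_params <- function(net) {
  cfg <- if (inherits(net, "unet3d")) net$config else net
  sum(vapply(unet_param_shapes(cfg), prod, numeric(1)))
}

#' @export
print.unet3d <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("3D U-Net: %d input channels, depth %d, %d base filters, d = %d (%d parameters)\n",
              cfg$in_channels, cfg$depth, cfg$base_filters, cfg$patch_size,
              n_params(cfg)))
  invisible(x)
}

# coerce a feature array to the (d,d,d,C,N) batch layout
as_batch <- function(x, cfg) {
  dm <- dim(x)
  d <- cfg$patch_size
  if (length(dm) == 4L) dm <- c(dm, 1L)
  if (length(dm) != 5L || any(dm[1:3] != d) || dm[4] != cfg$in_channels)
    stopf("input must have dim (%d, %d, %d, %d[, N])", d, d, d, cfg$in_channels)
  dim(x) <- dm
  x
}

#' Forward pass: per-voxel tumor logits
#'
#' Deterministic given parameters and input (evaluation mode); the sigmoid
#' is applied downstream, inside losses and probability maps.
#'
#' @param net a \code{unet3d} from \code{\link{build_network}}.
#' @param x feature array of dim \code{(d, d, d, in_channels)} or
#'   \code{(d, d, d, in_channels, N)}.
#' @return logit array of dim \code{(d, d, d, 1, N)}.
#' @export
unet_forward <- function(net, x) {
  cfg <- net$config
  x <- as_batch(x, cfg)
  n <- dim(x)[5]
  out <- cpp_unet_forward(net$params, x, cfg$patch_size, cfg$in_channels,
                          cfg$base_filters, cfg$depth,
                          use_norm = identical(cfg$norm, "instance"),
                          single = cfg$precision == "single")
  dim(out) <- c(cfg$patch_size, cfg$patch_size, cfg$patch_size, 1L, n)
  out
}

# forward pass keeping layer caches alive for one backward call;
# returns list(logits, cache)
unet_forward_cached <- function(net, x) {
  cfg <- net$config
  x <- as_batch(x, cfg)
  n <- dim(x)[5]
  out <- cpp_unet_fwd_cached(net$params, x, cfg$patch_size, cfg$in_channels,
                             cfg$base_filters, cfg$depth,
                             use_norm = identical(cfg$norm, "instance"),
                             single = cfg$precision == "single")
  dim(out$logits) <- c(cfg$patch_size, cfg$patch_size, cfg$patch_size, 1L, n)
  out
}

# parameter gradients from a cached forward pass and d(loss)/d(logit)
unet_backward <- function(fwd, dlogits) {
  cpp_unet_bwd_cached(fwd$cache, as.numeric(dlogits))
}

# convenience: forward + backward in one go
unet_grad <- function(net, x, dlogits) {
  fwd <- unet_forward_cached(net, x)
  list(grads = unet_backward(fwd, dlogits), logits = fwd$logits)
}

flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(flat, template) {
  out <- template
  pos <- 0L
  for (i in seq_along(template)) {
    n <- length(template[[i]])
    v <- flat[pos + seq_len(n)]
    if (!is.null(dim(template[[i]]))) dim(v) <- dim(template[[i]])
    out[[i]] <- v
    pos <- pos + n
  }
  out
}
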