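# VGG-16 convolutional widths up to the Conv4_3 tap: three 2x max-poolings
# precede it, so a 72-pixel input leaves a 9x9 spatial map with 512 channels.
vgg16_plan <- function(tap = "conv4_3") {
  widths <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                 c(512, 512, 512), c(512, 512, 512))
  names(widths) <- paste0("block", 1:5)
  m <- regmatches(tap, regexec("^conv([1-5])_([1-3])$", tap))[[1]]
  if (!length(m)) stop("unknown tap layer: ", tap)
  blk <- as.integer(m[2]); lay <- as.integer(m[3])
  if (lay > length(widths[[blk]])) stop("unknown tap layer: ", tap)
  chans <- integer(); pool <- logical()
  for (b in seq_len(blk)) {
    upto <- if (b == blk) lay else length(widths[[b]])
    for (l in seq_len(upto)) {
      chans <- c(chans, widths[[b]][l])
      pool <- c(pool, b > 1 && l == 1)  # pool before first conv of block 2+
    }
  }
  list(channels = chans, pool_before = pool,
       n_pool = sum(pool), tap = tap)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Build a feature backbone
#'
#' The feature extractor embeds each 72x72 window image as one pooled
#' convolutional vector. Three kinds are available:
#'
#' * `"vgg16-random"` (default): the VGG-16 architecture up to the tap
#'   layer with seed-deterministic He-initialized weights. Same contract as
#'   the pretrained net (512 channels on a 9x9 map for `conv4_3` at 72-pixel
#'   input), fully offline and reproducible.
#' * `"vgg16-pretrained"`: identical architecture with ImageNet weights
#'   supplied by the user as an RDS file (`weights_path`) holding a list of
#'   `list(W, b)` per conv layer, `W` of shape `[C_out x C_in*9]` with
#'   column order `c_in * 9 + k`, kernel offset `k = (dx+1)*3 + (dy+1)`.
#' * `"blockmean"`: a backbone-free baseline that averages the image over
#'   a 9x9 grid of 8x8 pixel blocks, giving 81-dimensional vectors; useful
#'   for fast smoke tests, not equivalent to the convolutional features.
#'
#' @param kind One of `"vgg16-random"`, `"vgg16-pretrained"`, `"blockmean"`.
#' @param seed Integer seed for the random weights.
#' @param tap Tap layer name (default `"conv4_3"`).
#' @param input_side Expected image side (default 72).
#' @param weights_path RDS file with pretrained weights (required for
#'   `"vgg16-pretrained"`).
#' @param preprocess `"imagenet"` (default) subtracts the per-channel
#'   ImageNet means from the 0..255 input; `"raw"` feeds 0..255 unchanged.
#' @return A `feature_backbone` object with the declared output contract
#'   in `$channels` and `$spatial_side`.
#' @export
build_backbone <- function(kind = c("vgg16-random", "vgg16-pretrained",
                                    "blockmean"),
                           seed = 1L, tap = "conv4_3", input_side = 72L,
                           weights_path = NULL,
                           preprocess = c("imagenet", "raw")) {
  kind <- match.arg(kind)
  preprocess <- match.arg(preprocess)
  if (kind == "blockmean") {
    return(structure(list(kind = kind, input_side = as.integer(input_side),
                          block = 8L,
                          channels = (input_side %/% 8L)^2, spatial_side = 1L,
                          preprocess = "raw", seed = NULL, layers = NULL),
                     class = "feature_backbone"))
  }
  plan <- vgg16_plan(tap)
  if (input_side %% 2^plan$n_pool != 0)
    stop("input side must be divisible by ", 2^plan$n_pool, " for tap ", tap)
  layers <- vector("list", length(plan$channels))
  if (kind == "vgg16-pretrained") {
    if (is.null(weights_path) || !file.exists(weights_path))
      stop("pretrained weights unavailable: supply weights_path ",
           "(RDS list of W/b per conv layer) or use kind = \"vgg16-random\"")
    wts <- readRDS(weights_path)
    if (length(wts) < length(layers)) stop("weights file has too few layers")
  }
  c_in <- 3L
  for (l in seq_along(layers)) {
    c_out <- plan$channels[l]
    if (kind == "vgg16-random") {
      W <- with_seed(seed + l,
        matrix(stats::rnorm(c_out * c_in * 9L, sd = sqrt(2 / (c_in * 9))),
               c_out, c_in * 9L))
      b <- numeric(c_out)
    } else {
      W <- wts[[l]]$W; b <- wts[[l]]$b
      if (!all(dim(W) == c(c_out, c_in * 9L)))
        stop("weights layer ", l, " has wrong shape")
    }
    layers[[l]] <- list(W = W, b = as.numeric(b), pool = plan$pool_before[l])
    c_in <- c_out
  }
  structure(list(kind = kind, input_side = as.integer(input_side),
                 tap = tap,
                 channels = plan$channels[length(plan$channels)],
                 spatial_side = as.integer(input_side %/% 2^plan$n_pool),
                 preprocess = preprocess, seed = as.integer(seed),
                 layers = layers),
            class = "feature_backbone")
}

# channel-wise ImageNet means on the 0..255 scale, RGB order
IMAGENET_MEANS <- c(123.68, 116.779, 103.939)

# images [side x side x 3 x n] -> matrix [3*side^2 x n], channel fastest
stage_images <- function(images, backbone) {
  d <- dim(images)
  if (d[1] != backbone$input_side || d[2] != backbone$input_side)
    stop("image side ", d[1], " does not match backbone contract ",
         backbone$input_side)
  x <- aperm(images, c(3, 1, 2, 4)) * 1.0
  if (backbone$preprocess == "imagenet") x <- x - IMAGENET_MEANS
  dim(x) <- c(3 * d[1] * d[2], d[4])
  x
}

#' Extract pooled convolutional features from a window stack
#'
#' Runs each window image through the backbone to the tap layer and
#' compresses the resulting feature map by global average pooling (the mean
#' over all spatial positions per channel), giving one 512-dimensional
#' vector per window for the default Conv4_3 tap.
#'
#' @param stack A `window_stack` with encoded images (see [make_windows()]).
#' @param backbone A `feature_backbone` from [build_backbone()].
#' @param batch_size Images per forward batch; results are independent of
#'   this value.
#' @return Numeric matrix `[n_windows x n_channels]` with attribute
#'   `backbone` recording provenance.
#' @export
extract_features <- function(stack, backbone, batch_size = 256L) {
  stopifnot(inherits(stack, "window_stack"), !is.null(stack$images),
            inherits(backbone, "feature_backbone"))
  images <- stack$images
  n <- dim(images)[4]
  if (backbone$kind == "blockmean") {
    feats <- t(vapply(seq_len(n), function(i) {
      g <- images[, , 1, i] / 255
      s <- backbone$block
      k <- dim(g)[1] %/% s
      as.vector(vapply(seq_len(k), function(bx)
        vapply(seq_len(k), function(by)
          mean(g[(by - 1) * s + 1:s, (bx - 1) * s + 1:s]), 0), numeric(k)))
    }, numeric(backbone$channels)))
  } else {
    feats <- matrix(0, n, backbone$channels)
    for (i0 in seq(1L, n, by = batch_size)) {
      i1 <- min(i0 + batch_size - 1L, n)
      x <- stage_images(images[, , , i0:i1, drop = FALSE], backbone)
      out <- vgg_forward_cpp(x, backbone$layers, backbone$input_side, 3L,
                             FALSE)
      feats[i0:i1, ] <- t(out$features)
    }
  }
  if (!all(is.finite(feats))) stop("non-finite feature values")
  attr(feats, "backbone") <- backbone[c("kind", "tap", "seed", "preprocess")]
  feats
}

#' Tap-layer feature maps for a few images
#'
#' Returns the full (un-pooled) tap-layer activations, mainly to inspect
#' the output contract and to validate pooling; intended for small subsets
#' only.
#'
#' @inheritParams extract_features
#' @param index Window indices to run.
#' @return Array `[channels x spatial x spatial x length(index)]`.
#' @export
extract_feature_maps <- function(stack, backbone, index = 1L) {
  stopifnot(inherits(backbone, "feature_backbone"),
            backbone$kind != "blockmean")
  x <- stage_images(stack$images[, , , index, drop = FALSE], backbone)
  out <- vgg_forward_cpp(x, backbone$layers, backbone$input_side, 3L, TRUE)
  s <- backbone$spatial_side
  array(out$maps, dim = c(backbone$channels, s, s, length(index)))
}
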