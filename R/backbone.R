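# Frozen convolutional backbones --------------------------------------------
#
# Two kinds of entry live in the registry:
#
#   * "tiny"  - a small randomly-initialised 3-block conv net implemented
#     here in full (forward pass via im2col + BLAS).  It is the runnable
#     feature extractor used for training, testing and Grad-CAM; being
#     frozen, its random weights are an instance of the untrained-extractor
#     regime and need no downloads.
#
#   * architecture descriptors for the published ImageNet backbones
#     (EfficientNetV2B2 reference, plus the ablation alternatives).  These
#     record the layer geometry (kernel / stride / padding per
#     spatial-reduction stage and final channel width) so the feature-map
#     shape contract can be computed and checked without any weights; their
#     numerical forward pass is not reimplemented here.
#
# A backbone maps a preprocessed H x W x 3 tensor to a spatial feature map;
# for EfficientNetV2B2 on 128 x 128 x 3 input that map is 4 x 4 x 1408.

.backbone_registry <- new.env(parent = emptyenv())

#' Register a backbone
#'
#' @param id Backbone identifier (lower case).
#' @param entry A list describing the backbone (see `R/backbone.R`).
#' @export
register_backbone <- function(id, entry) {
  assign(tolower(id), entry, envir = .backbone_registry)
  invisible(id)
}

#' @rdname register_backbone
#' @export
list_backbones <- function() sort(ls(.backbone_registry))

get_backbone <- function(id) {
  id <- tolower(id)
  if (!exists(id, envir = .backbone_registry, inherits = FALSE)) {
    stop("unregistered backbone: '", id, "' (see list_backbones())")
  }
  get(id, envir = .backbone_registry, inherits = FALSE)
}

# layer: list(kernel, stride, padding = "same"|"valid", is pooling ignored
# for shape purposes)
trace_spatial <- function(n, layers) {
  for (ly in layers) {
    n <- if (identical(ly$padding, "valid")) {
      floor((n - ly$kernel) / ly$stride) + 1L
    } else {
      ceiling(n / ly$stride)
    }
  }
  as.integer(n)
}

#' Feature-map shape of a backbone
#'
#' Traces the backbone's spatial-reduction layers (stride / kernel /
#' padding) over the input size and returns the pre-flatten feature tensor
#' shape.  The reference EfficientNetV2B2 on a `128 x 128 x 3` input gives
#' `c(4, 4, 1408)`.
#'
#' @param id Registered backbone id.
#' @param input_shape `c(height, width, channels)`.
#' @return Integer `c(height, width, channels)` of the feature map.
#' @examples
#' backbone_feature_shape("efficientnetv2b2", c(128, 128, 3))
#' @export
backbone_feature_shape <- function(id, input_shape = c(128L, 128L, 3L)) {
  bb <- get_backbone(id)
  c(trace_spatial(input_shape[1], bb$layers),
    trace_spatial(input_shape[2], bb$layers),
    as.integer(bb$out_channels))
}

same3 <- function(stride) list(kernel = 3L, stride = stride, padding = "same")
valid3 <- function(stride) list(kernel = 3L, stride = stride, padding = "valid")

# ---- descriptor entries ----------------------------------------------------

register_descriptor_backbones <- function() {
  # EfficientNetV2B2: stem s2; six stages with first-block strides
  # 1,2,2,2,1,2 (all 'same'); 1x1 top conv widens to 1408 channels.
  register_backbone("efficientnetv2b2", list(
    kind = "descriptor",
    layers = c(list(same3(2L)),
               lapply(c(1L, 2L, 2L, 2L, 1L, 2L), same3)),
    out_channels = 1408L))
  # ResNet50: 7x7 s2 stem, 3x3 s2 maxpool, stages s1,2,2,2; 2048 channels.
  register_backbone("resnet50", list(
    kind = "descriptor",
    layers = c(list(list(kernel = 7L, stride = 2L, padding = "same"),
                    same3(2L)),
               lapply(c(1L, 2L, 2L, 2L), same3)),
    out_channels = 2048L))
  # DenseNet201: same reduction ladder as ResNet; 1920 channels.
  register_backbone("densenet201", list(
    kind = "descriptor",
    layers = c(list(list(kernel = 7L, stride = 2L, padding = "same"),
                    same3(2L)),
               lapply(c(1L, 2L, 2L, 2L), same3)),
    out_channels = 1920L))
  # MobileNetV2: stem s2 + stage strides 1,2,2,2,1,2,1; 1x1 top to 1280.
  register_backbone("mobilenetv2", list(
    kind = "descriptor",
    layers = c(list(same3(2L)),
               lapply(c(1L, 2L, 2L, 2L, 1L, 2L, 1L), same3)),
    out_channels = 1280L))
  # VGG16: five 'same' 2x2 maxpools; 512 channels.
  register_backbone("vgg16", list(
    kind = "descriptor",
    layers = lapply(rep(2L, 5L), function(s)
      list(kernel = 2L, stride = s, padding = "same")),
    out_channels = 512L))
  # InceptionV3: valid-padded stem and two grid reductions; 2048 channels.
  register_backbone("inceptionv3", list(
    kind = "descriptor",
    layers = list(valid3(2L), valid3(1L), same3(1L), valid3(2L),
                  list(kernel = 1L, stride = 1L, padding = "valid"),
                  valid3(1L), valid3(2L), valid3(2L), valid3(2L)),
    out_channels = 2048L))
  # Xception: valid 3x3 s2 + 3x3 s1 stem, four 'same' stride-2 blocks.
  register_backbone("xception", list(
    kind = "descriptor",
    layers = c(list(valid3(2L), valid3(1L)),
               lapply(rep(2L, 4L), same3)),
    out_channels = 2048L))
}

# ---- tiny runnable backbone ------------------------------------------------

TINY_CHANNELS <- c(16L, 32L, 64L)

#' Initialise the tiny test backbone
#'
#' Three conv(3x3, 'same') + ReLU + maxpool(2) blocks with 16/32/64 output
#' channels, followed by a 2x2 average pool; He-initialised from `seed`,
#' then frozen.  On a `128 x 128 x 3` input the feature map is
#' `8 x 8 x 64`.
#'
#' @param seed Integer seed for the (frozen) random weights.
#' @return A list of conv weight matrices and biases of class
#'   `tiny_backbone`.
#' @export
tiny_backbone_weights <- function(seed = 0L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  in_ch <- c(3L, TINY_CHANNELS[-length(TINY_CHANNELS)])
  layers <- lapply(seq_along(TINY_CHANNELS), function(i) {
    fan_in <- 9L * in_ch[i]
    list(W = matrix(stats::rnorm(fan_in * TINY_CHANNELS[i],
                                 sd = sqrt(2 / fan_in)),
                    fan_in, TINY_CHANNELS[i]),
         b = rep(0, TINY_CHANNELS[i]))
  })
  structure(list(layers = layers, seed = as.integer(seed)),
            class = "tiny_backbone")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# 3x3 'same' convolution via im2col; x is H x W x Cin.
im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  cols <- matrix(0, H * W, 9L * C)
  k <- 1L
  for (c in seq_len(C)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        cols[, k] <- as.vector(xp[di + seq_len(H), dj + seq_len(W), c])
        k <- k + 1L
      }
    }
  }
  cols
}

conv3_relu <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  out <- im2col3(x) %*% W
  out <- sweep(out, 2L, b, `+`)
  out[out < 0] <- 0
  array(out, c(H, Wd, ncol(W)))
}

maxpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  a <- pmax(x[seq(1L, H, 2L), , , drop = FALSE],
            x[seq(2L, H, 2L), , , drop = FALSE])
  pmax(a[, seq(1L, W, 2L), , drop = FALSE],
       a[, seq(2L, W, 2L), , drop = FALSE])
}

avgpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  a <- (x[seq(1L, H, 2L), , , drop = FALSE] +
          x[seq(2L, H, 2L), , , drop = FALSE]) / 2
  (a[, seq(1L, W, 2L), , drop = FALSE] +
     a[, seq(2L, W, 2L), , drop = FALSE]) / 2
}

#' Tiny backbone forward pass
#'
#' @param weights A `tiny_backbone` from [tiny_backbone_weights()].
#' @param x Preprocessed `H x W x 3` array (H, W divisible by 16).
#' @return The `H/16 x W/16 x 64` feature map.
#' @export
tiny_backbone_forward <- function(weights, x) {
  stopifnot(inherits(weights, "tiny_backbone"))
  for (ly in weights$layers) {
    x <- maxpool2(conv3_relu(x, ly$W, ly$b))
  }
  avgpool2(x)
}

register_tiny_backbone <- function() {
  register_backbone("tiny", list(
    kind = "tiny",
    layers = lapply(rep(2L, 4L), function(s)
      list(kernel = 2L, stride = s, padding = "same")),
    out_channels = TINY_CHANNELS[length(TINY_CHANNELS)]))
}

.onLoad <- function(libname, pkgname) {
  register_descriptor_backbones()
  register_tiny_backbone()
}
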