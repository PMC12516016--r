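# Grad-CAM saliency per subband branch --------------------------------------
#
# Channel-importance weights are the spatially averaged gradients of the
# model's final (fused, pre-sigmoid) output with respect to the chosen
# branch's backbone feature map; the map is the ReLU of the weighted
# feature sum, min-max normalised and bilinearly upsampled to the input
# size.  Gradients target the fused output rather than the branch's own
# sigmoid so that the map explains the model's actual decision.

#' Grad-CAM saliency map for one subband branch
#'
#' @param model Trained `wavefrac_model` with a runnable (tiny) backbone.
#' @param branch Subband label, one of the model's subbands.
#' @param image Input image array of the model's input shape.
#' @return List of class `saliency_map`: `heatmap` (input-sized matrix in
#'   `[0, 1]`), `branch`, `target_layer`, `weights` (channel importances),
#'   `probability` (the fused model output for this image).
#' @export
gradcam <- function(model, branch, image) {
  stopifnot(inherits(model, "wavefrac_model"))
  if (!branch %in% model$subbands) {
    stop("branch '", branch, "' is not in the model's subband subset (",
         paste(model$subbands, collapse = ","), ")")
  }
  out <- model_features(model, list(image), keep_maps = TRUE)
  feats <- apply_feature_norm(out$features, model$feature_norm)
  fmap <- out$maps[[branch]][[1]]
  fwd <- model_forward(model, feats, training = FALSE)
  # d(final logit)/d(branch feature), inference mode (all layers linear or
  # piecewise linear, so the chain is exact)
  dlogit <- 1
  fb <- fusion_backward(dlogit, fwd$fusion_cache, model$fusion)
  j <- match(branch, model$subbands)
  br <- model$branches[[branch]]
  hb <- head_backward(fb$dP[, j], fwd$heads[[branch]]$cache,
                      br$head$params, br$head$state, need_dx = TRUE)
  dX <- as.vector(hb$dX)
  if (!is.null(model$feature_norm)) {    # chain through the z-scoring
    dX <- dX / model$feature_norm[[branch]]$sd
  }
  grad <- array(dX, dim(fmap))
  weights <- apply(grad, 3L, mean)
  cam <- matrix(0, dim(fmap)[1], dim(fmap)[2])
  for (c in seq_along(weights)) cam <- cam + weights[c] * fmap[, , c]
  cam[cam < 0] <- 0
  cam <- normalise01(cam)
  heat <- resize_channel(cam, model$input_shape[1], model$input_shape[2])
  heat <- pmin(pmax(heat, 0), 1)
  structure(list(heatmap = heat, branch = branch,
                 target_layer = "backbone_feature_map",
                 weights = weights, probability = fwd$h[1]),
            class = "saliency_map")
}

#' Overlay a saliency heatmap on an image
#'
#' @param image `M x N x 3` array (or matrix) in `[0, 1]`.
#' @param map `M x N` heatmap in `[0, 1]` (e.g. from [gradcam()]).
#' @param alpha Blend weight: 0 = original image, 1 = pure colour-mapped
#'   heatmap.
#' @param path Optional PNG output path.
#' @return The blended `M x N x 3` array (invisibly if written to `path`).
#' @export
overlay <- function(image, map, alpha = 0.4, path = NULL) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (!all(dim(image)[1:2] == dim(map))) {
    stop("image and heatmap shapes do not match")
  }
  cmap <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))(
    as.vector(map)) / 255
  heat_rgb <- array(cmap, c(dim(map), 3L))
  blend <- (1 - alpha) * image + alpha * heat_rgb
  blend <- pmin(pmax(blend, 0), 1)
  if (!is.null(path)) {
    write_image_png(blend, path)
    return(invisible(blend))
  }
  blend
}
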