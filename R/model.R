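# Multiband fusion classifier ------------------------------------------------
#
# One branch per subband: frozen backbone -> flatten -> two
# dense-BN-dropout blocks -> sigmoid score P_band.  The per-subband scores
# are concatenated into the probability vector P = [P_LL, P_LH, P_HL, P_HH]
# (restricted to the configured subset, order fixed), fused by a
# dense(128, ReLU) layer and a final sigmoid.  Training minimises binary
# cross-entropy end-to-end with Adam; the backbone never receives updates.

#' Branch configuration
#'
#' @param backbone_id Registered backbone (see [list_backbones()]).  Only
#'   `"tiny"` has a runnable forward pass in this package; the ImageNet
#'   backbones are registered as architecture descriptors for shape
#'   contracts.
#' @param frozen Must be `TRUE`: backbone weights are never trained.
#' @param dense_units Widths of the two dense blocks.
#' @param dropout Dropout rates of the two blocks, each in `[0, 1)`.
#' @return List of class `branch_config`.
#' @export
branch_config <- function(backbone_id = "tiny", frozen = TRUE,
                          dense_units = c(256L, 128L),
                          dropout = c(0.3, 0.3)) {
  stopifnot(length(dense_units) == 2L, all(dense_units >= 1L),
            length(dropout) == 2L, all(dropout >= 0), all(dropout < 1))
  if (!isTRUE(frozen)) stop("backbones are frozen by contract")
  get_backbone(backbone_id)   # fails early on unregistered ids
  structure(list(backbone_id = tolower(backbone_id), frozen = TRUE,
                 dense_units = as.integer(dense_units),
                 dropout = as.numeric(dropout)),
            class = "branch_config")
}

#' Training configuration
#'
#' Defaults mirror the reference training recipe: Adam with initial
#' learning rate 0.001, batch size 32, at most 50 epochs, early stopping
#' when validation accuracy has not improved for 5 consecutive epochs.
#'
#' @param learning_rate Adam initial learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience, in epochs, on validation
#'   accuracy; must be smaller than `max_epochs`.
#' @param seed Integer seed driving shuffling and dropout.
#' @param subbands Nonempty subset of `c("LL","LH","HL","HH")`.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L,
                         max_epochs = 50L, patience = 5L, seed = 0L,
                         subbands = SUBBAND_NAMES) {
  subbands <- match.arg(subbands, SUBBAND_NAMES, several.ok = TRUE)
  if (length(subbands) == 0L) stop("subband subset must be nonempty")
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 subbands = SUBBAND_NAMES[SUBBAND_NAMES %in% subbands]),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' `L = -(1/m) * sum(y*log(h) + (1-y)*log(1-h))` with predictions clipped
#' into `[eps, 1-eps]`, `eps = 1e-7`.
#'
#' @param y Binary labels (0/1).
#' @param h Predicted probabilities in `[0, 1]`.
#' @return Nonnegative scalar loss.
#' @examples
#' bce_loss(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
bce_loss <- function(y, h) {
  if (length(y) != length(h)) stop("labels and predictions differ in length")
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)")
  eps <- 1e-7
  h <- pmin(pmax(h, eps), 1 - eps)
  -mean(y * log(h) + (1 - y) * log(1 - h))
}

# He-style initialisation of one branch head.
init_head <- function(feature_dim, dense_units) {
  u1 <- dense_units[1]; u2 <- dense_units[2]
  params <- list(
    W1 = matrix(stats::rnorm(feature_dim * u1, sd = sqrt(2 / feature_dim)),
                feature_dim, u1),
    b1 = rep(0, u1), gamma1 = rep(1, u1), beta1 = rep(0, u1),
    W2 = matrix(stats::rnorm(u1 * u2, sd = sqrt(2 / u1)), u1, u2),
    b2 = rep(0, u2), gamma2 = rep(1, u2), beta2 = rep(0, u2),
    w3 = matrix(stats::rnorm(u2, sd = sqrt(1 / u2)), u2, 1L),
    b3 = 0)
  state <- list(rm1 = rep(0, u1), rv1 = rep(1, u1),
                rm2 = rep(0, u2), rv2 = rep(1, u2))
  list(params = params, state = state)
}

init_fusion <- function(n_branches, units = 128L) {
  list(Wf = matrix(stats::rnorm(n_branches * units,
                                sd = sqrt(2 / n_branches)),
                   n_branches, units),
       bf = rep(0, units),
       wo = matrix(stats::rnorm(units, sd = sqrt(1 / units)), units, 1L),
       bo = 0)
}

#' Build one subband branch
#'
#' A branch maps one full-size subband image tensor to a score in (0, 1):
#' frozen backbone, flatten, two dense-BN-dropout blocks, sigmoid.
#'
#' @param config A [branch_config()].
#' @param input_shape `c(height, width, channels)` of the subband tensor.
#' @param seed Seed for the frozen backbone weights and the head
#'   initialisation.
#' @return Object of class `wavefrac_branch`.
#' @export
build_branch <- function(config = branch_config(),
                         input_shape = c(128L, 128L, 3L), seed = 0L) {
  stopifnot(inherits(config, "branch_config"))
  bb <- get_backbone(config$backbone_id)
  feature_shape <- backbone_feature_shape(config$backbone_id, input_shape)
  if (bb$kind != "tiny") {
    stop("backbone '", config$backbone_id, "' is registered as an ",
         "architecture descriptor only; use backbone_feature_shape() for ",
         "its shape contract, or backbone_id = 'tiny' for a runnable branch")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  backbone <- tiny_backbone_weights(seed)
  head <- init_head(prod(feature_shape), config$dense_units)
  structure(list(config = config, input_shape = as.integer(input_shape),
                 feature_shape = feature_shape,
                 feature_dim = prod(feature_shape),
                 backbone = backbone, head = head, seed = as.integer(seed)),
            class = "wavefrac_branch")
}

# Per-band preprocessing: min-max rescale the (signed) subband tensor into
# the backbone's expected input range.
preprocess_band <- function(x) normalise01(x)

branch_features <- function(branch, band_tensor, keep_map = FALSE) {
  if (!all(dim(band_tensor) == branch$input_shape)) {
    stop("subband tensor has shape ", paste(dim(band_tensor), collapse = "x"),
         ", expected ", paste(branch$input_shape, collapse = "x"))
  }
  fmap <- tiny_backbone_forward(branch$backbone, preprocess_band(band_tensor))
  if (keep_map) list(map = fmap, flat = as.vector(fmap)) else as.vector(fmap)
}

#' Score one subband tensor with a branch
#'
#' Inference-mode forward pass; deterministic (no dropout).
#'
#' @param branch A `wavefrac_branch`.
#' @param band_tensor Subband image tensor of the branch's input shape.
#' @return A probability in (0, 1).
#' @export
branch_score <- function(branch, band_tensor) {
  x <- matrix(branch_features(branch, band_tensor), 1L)
  head_forward(x, branch$head$params, branch$head$state,
               rates = c(0, 0), training = FALSE)$s[1]
}

# ---- head + fusion forward/backward ---------------------------------------

head_forward <- function(X, p, st, rates, training) {
  z1 <- add_bias(X %*% p$W1, p$b1)
  if (training) {
    bn1 <- bn_forward_train(z1, p$gamma1, p$beta1, st$rm1, st$rv1)
    a1 <- bn1$out
  } else {
    a1 <- bn_forward_infer(z1, p$gamma1, p$beta1, st$rm1, st$rv1)
    bn1 <- NULL
  }
  r1 <- pmax(a1, 0)
  m1 <- if (training) dropout_mask(nrow(X), ncol(r1), rates[1]) else NULL
  d1 <- apply_mask(r1, m1)
  z2 <- add_bias(d1 %*% p$W2, p$b2)
  if (training) {
    bn2 <- bn_forward_train(z2, p$gamma2, p$beta2, st$rm2, st$rv2)
    a2 <- bn2$out
  } else {
    a2 <- bn_forward_infer(z2, p$gamma2, p$beta2, st$rm2, st$rv2)
    bn2 <- NULL
  }
  r2 <- pmax(a2, 0)
  m2 <- if (training) dropout_mask(nrow(X), ncol(r2), rates[2]) else NULL
  d2 <- apply_mask(r2, m2)
  s <- sigmoid(drop(add_bias(d2 %*% p$w3, p$b3)))
  list(s = s,
       cache = list(X = X, a1 = a1, m1 = m1, d1 = d1, a2 = a2, m2 = m2,
                    d2 = d2, s = s, bn1 = bn1, bn2 = bn2, training = training),
       new_state = if (training) {
         list(rm1 = bn1$run_mean, rv1 = bn1$run_var,
              rm2 = bn2$run_mean, rv2 = bn2$run_var)
       } else st)
}

# ds: dL/ds (length n).  Returns parameter grads and, optionally, dX.
head_backward <- function(ds, cache, p, st, need_dx = FALSE) {
  s <- cache$s
  dlogit <- matrix(ds * s * (1 - s), ncol = 1L)
  dw3 <- crossprod(cache$d2, dlogit)
  db3 <- sum(dlogit)
  dd2 <- dlogit %*% t(p$w3)
  dr2 <- apply_mask(dd2, cache$m2)
  da2 <- dr2 * (cache$a2 > 0)
  if (cache$training) {
    bnb2 <- bn_backward(da2, cache$bn2$cache)
    dz2 <- bnb2$dx; dgamma2 <- bnb2$dgamma; dbeta2 <- bnb2$dbeta
  } else {
    scale2 <- p$gamma2 / sqrt(st$rv2 + BN_EPS)
    dz2 <- sweep(da2, 2L, scale2, `*`)
    dgamma2 <- rep(0, length(p$gamma2)); dbeta2 <- rep(0, length(p$beta2))
  }
  dW2 <- crossprod(cache$d1, dz2)
  db2 <- colSums(dz2)
  dd1 <- dz2 %*% t(p$W2)
  dr1 <- apply_mask(dd1, cache$m1)
  da1 <- dr1 * (cache$a1 > 0)
  if (cache$training) {
    bnb1 <- bn_backward(da1, cache$bn1$cache)
    dz1 <- bnb1$dx; dgamma1 <- bnb1$dgamma; dbeta1 <- bnb1$dbeta
  } else {
    scale1 <- p$gamma1 / sqrt(st$rv1 + BN_EPS)
    dz1 <- sweep(da1, 2L, scale1, `*`)
    dgamma1 <- rep(0, length(p$gamma1)); dbeta1 <- rep(0, length(p$beta1))
  }
  dW1 <- crossprod(cache$X, dz1)
  db1 <- colSums(dz1)
  list(grads = list(W1 = dW1, b1 = db1, gamma1 = dgamma1, beta1 = dbeta1,
                    W2 = dW2, b2 = db2, gamma2 = dgamma2, beta2 = dbeta2,
                    w3 = dw3, b3 = db3),
       dX = if (need_dx) dz1 %*% t(p$W1) else NULL)
}

fusion_forward <- function(P, fp) {
  zf <- add_bias(P %*% fp$Wf, fp$bf)
  Fh <- pmax(zf, 0)
  h <- sigmoid(drop(add_bias(Fh %*% fp$wo, fp$bo)))
  list(h = h, cache = list(P = P, zf = zf, Fh = Fh, h = h))
}

# dlogit_out: dL/d(final pre-sigmoid logit), length n.
fusion_backward <- function(dlogit_out, cache, fp) {
  dlo <- matrix(dlogit_out, ncol = 1L)
  dwo <- crossprod(cache$Fh, dlo)
  dbo <- sum(dlo)
  dF <- dlo %*% t(fp$wo)
  dzf <- dF * (cache$zf > 0)
  dWf <- crossprod(cache$P, dzf)
  dbf <- colSums(dzf)
  list(grads = list(Wf = dWf, bf = dbf, wo = dwo, bo = dbo),
       dP = dzf %*% t(fp$Wf))
}

# ---- model -----------------------------------------------------------------

#' Assemble the multiband classifier from per-subband branches
#'
#' Branch scores are concatenated in canonical order (LL, LH, HL, HH,
#' restricted to the supplied subset) into the probability vector, then
#' fused by a dense(128, ReLU) + sigmoid output.
#'
#' @param branches Named list of `wavefrac_branch` objects; names are
#'   subband labels.
#' @param method,spec,ranges Decomposition settings the model will apply to
#'   raw images (see [decompose()]).
#' @param seed Seed for the fusion-layer initialisation.
#' @param fusion_units Width of the fusion dense layer.
#' @return Object of class `wavefrac_model`.
#' @export
assemble_model <- function(branches, method = "dwt2",
                           spec = wavelet_spec("haar"),
                           ranges = default_eigentriple_ranges(),
                           seed = 0L, fusion_units = 128L) {
  if (length(branches) == 0L) stop("at least one branch is required")
  if (is.null(names(branches)) ||
      !all(names(branches) %in% SUBBAND_NAMES)) {
    stop("branches must be named by subband (LL/LH/HL/HH)")
  }
  subbands <- SUBBAND_NAMES[SUBBAND_NAMES %in% names(branches)]
  branches <- branches[subbands]
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  structure(list(branches = branches, subbands = subbands,
                 fusion = init_fusion(length(subbands), fusion_units),
                 decomposition = list(method = method,
                                      family = spec$family,
                                      ranges = ranges),
                 input_shape = branches[[1]]$input_shape,
                 seed = as.integer(seed), trained = FALSE),
            class = "wavefrac_model")
}

#' Build the full model from configuration
#'
#' Convenience wrapper: one [build_branch()] per selected subband (all
#' sharing the same frozen backbone weights, mirroring a shared pre-trained
#' block) plus [assemble_model()].
#'
#' @inheritParams assemble_model
#' @param config A [branch_config()].
#' @param subbands Subband subset, canonical order enforced.
#' @param input_shape Model input shape.
#' @param seed One seed for backbone, heads and fusion.
#' @return A `wavefrac_model`.
#' @export
build_model <- function(config = branch_config(),
                        subbands = SUBBAND_NAMES,
                        method = "dwt2", spec = wavelet_spec("haar"),
                        ranges = default_eigentriple_ranges(),
                        input_shape = c(128L, 128L, 3L), seed = 0L) {
  subbands <- SUBBAND_NAMES[SUBBAND_NAMES %in% subbands]
  if (length(subbands) == 0L) stop("subband subset must be nonempty")
  branches <- lapply(seq_along(subbands), function(i) {
    build_branch(config, input_shape, seed = seed + (i - 1L))
  })
  # shared frozen extractor across branches
  for (i in seq_along(branches)) branches[[i]]$backbone <- branches[[1]]$backbone
  names(branches) <- subbands
  assemble_model(branches, method = method, spec = spec, ranges = ranges,
                 seed = seed)
}

#' @export
print.wavefrac_model <- function(x, ...) {
  cat(sprintf(
    "<wavefrac_model> %s backbone, subbands [%s], %s/%s decomposition, %s\n",
    x$branches[[1]]$config$backbone_id, paste(x$subbands, collapse = ","),
    x$decomposition$method, x$decomposition$family,
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Decompose images and run the frozen backbone once per subband; features
# are constant during training because the backbone is frozen.
model_features <- function(model, images, keep_maps = FALSE) {
  spec <- if (model$decomposition$method == "svd") wavelet_spec("haar") else
    wavelet_spec(model$decomposition$family)
  n <- length(images)
  feats <- lapply(model$subbands, function(b)
    matrix(0, n, model$branches[[b]]$feature_dim))
  names(feats) <- model$subbands
  maps <- if (keep_maps) stats::setNames(vector("list", length(model$subbands)),
                                         model$subbands) else NULL
  for (i in seq_len(n)) {
    sb <- decompose(images[[i]], model$decomposition$method, spec,
                    model$decomposition$ranges)
    for (b in model$subbands) {
      out <- branch_features(model$branches[[b]], sb[[b]], keep_map = keep_maps)
      if (keep_maps) {
        feats[[b]][i, ] <- out$flat
        maps[[b]][[i]] <- out$map
      } else {
        feats[[b]][i, ] <- out
      }
    }
  }
  if (keep_maps) list(features = feats, maps = maps) else feats
}

# Per-dimension z-scoring of the frozen backbone features, fitted on the
# training set.  Conditions the dense heads (raw activations have strongly
# heterogeneous scales) and makes batch-norm running moments track faster.
fit_feature_norm <- function(feats) {
  lapply(feats, function(f) {
    list(mu = colMeans(f),
         sd = pmax(apply(f, 2L, stats::sd), 1e-6))
  })
}

apply_feature_norm <- function(feats, norm) {
  if (is.null(norm)) return(feats)
  out <- lapply(names(feats), function(b) {
    sweep(sweep(feats[[b]], 2L, norm[[b]]$mu, `-`), 2L, norm[[b]]$sd, `/`)
  })
  names(out) <- names(feats)
  out
}

model_forward <- function(model, feats, training = FALSE) {
  heads <- lapply(model$subbands, function(b) {
    br <- model$branches[[b]]
    head_forward(feats[[b]], br$head$params, br$head$state,
                 rates = br$config$dropout, training = training)
  })
  names(heads) <- model$subbands
  P <- do.call(cbind, lapply(heads, `[[`, "s"))
  if (is.vector(P)) P <- matrix(P, nrow = 1L)
  colnames(P) <- model$subbands
  fus <- fusion_forward(P, model$fusion)
  list(h = fus$h, P = P, heads = heads, fusion_cache = fus$cache)
}

collect_params <- function(model) {
  list(heads = lapply(model$branches, function(br) br$head$params),
       fusion = model$fusion)
}

set_params <- function(model, params) {
  for (b in names(params$heads)) {
    model$branches[[b]]$head$params <- params$heads[[b]]
  }
  model$fusion <- params$fusion
  model
}

snapshot_states <- function(model)
  lapply(model$branches, function(br) br$head$state)

set_states <- function(model, states) {
  for (b in names(states)) model$branches[[b]]$head$state <- states[[b]]
  model
}

#' Train the multiband classifier
#'
#' End-to-end minimisation of binary cross-entropy over the trainable head
#' and fusion parameters with Adam; the frozen backbone is evaluated once
#' per image and subband, and its weights are untouched.  Early stopping
#' restores the parameters of the epoch with the best validation accuracy.
#'
#' @param model A `wavefrac_model` from [build_model()].
#' @param train_set,val_set Lists with elements `images` (list of
#'   `M x N x C` arrays) and `labels` (binary vector), e.g. from
#'   [generate_dataset()] or [load_dataset()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with the trained `model` and a per-epoch `history`
#'   data frame (epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_model <- function(model, train_set, val_set,
                        config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "wavefrac_model"), inherits(config, "train_config"))
  if (length(train_set$images) == 0L || length(val_set$images) == 0L) {
    stop("training and validation sets must be nonempty")
  }
  y_tr <- as.numeric(train_set$labels)
  y_va <- as.numeric(val_set$labels)
  if (!all(c(y_tr, y_va) %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (!setequal(model$subbands, config$subbands)) {
    stop("train_config subbands (", paste(config$subbands, collapse = ","),
         ") do not match the model's (", paste(model$subbands, collapse = ","),
         ")")
  }

  f_tr <- model_features(model, train_set$images)
  f_va <- model_features(model, val_set$images)
  model$feature_norm <- fit_feature_norm(f_tr)
  f_tr <- apply_feature_norm(f_tr, model$feature_norm)
  f_va <- apply_feature_norm(f_va, model$feature_norm)
  n <- length(y_tr)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)

  params <- collect_params(model)
  opt <- adam_state(params)
  best <- list(acc = -Inf, params = params, states = snapshot_states(model))
  wait <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        train_acc = numeric(), val_loss = numeric(),
                        val_acc = numeric())

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0; ep_correct <- 0L
    for (s0 in starts) {
      bidx <- idx[s0:min(s0 + config$batch_size - 1L, n)]
      Xb <- lapply(f_tr, function(f) f[bidx, , drop = FALSE])
      yb <- y_tr[bidx]
      model <- set_params(model, params)
      fwd <- model_forward(model, Xb, training = TRUE)
      # persist batch-norm running moments
      for (b in model$subbands) {
        model$branches[[b]]$head$state <- fwd$heads[[b]]$new_state
      }
      loss <- bce_loss(yb, fwd$h)
      ep_loss <- ep_loss + loss * length(bidx)
      ep_correct <- ep_correct + sum((fwd$h >= 0.5) == yb)
      dlogit <- (fwd$h - yb) / length(bidx)
      fb <- fusion_backward(dlogit, fwd$fusion_cache, params$fusion)
      head_grads <- lapply(seq_along(model$subbands), function(j) {
        b <- model$subbands[j]
        head_backward(fb$dP[, j], fwd$heads[[b]]$cache,
                      params$heads[[b]], model$branches[[b]]$head$state)$grads
      })
      names(head_grads) <- model$subbands
      step <- adam_step(params, list(heads = head_grads, fusion = fb$grads),
                        opt, lr = config$learning_rate)
      params <- step$params
      opt <- step$state
    }
    model <- set_params(model, params)
    va <- model_forward(model, f_va, training = FALSE)
    val_loss <- bce_loss(y_va, va$h)
    val_acc <- mean((va$h >= 0.5) == y_va)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = val_loss, val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, ep_loss / n, ep_correct / n, val_loss, val_acc))
    }
    if (val_acc > best$acc + 1e-12) {
      best <- list(acc = val_acc, params = params,
                   states = snapshot_states(model))
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model <- set_params(model, best$params)
  model <- set_states(model, best$states)
  model$trained <- TRUE
  model$train_config <- config
  list(model = model, history = history)
}

#' Predict fracture probabilities and labels
#'
#' @param model Trained `wavefrac_model`.
#' @param images List of image arrays (model input shape).
#' @param threshold Decision threshold; label 1 (fracture) iff probability
#'   is greater than or equal to it.
#' @return List with `probabilities`, `labels` and the per-subband score
#'   matrix `P`.
#' @export
predict_model <- function(model, images, threshold = 0.5) {
  feats <- apply_feature_norm(model_features(model, images),
                              model$feature_norm)
  fwd <- model_forward(model, feats, training = FALSE)
  list(probabilities = fwd$h,
       labels = as.integer(fwd$h >= threshold),
       P = fwd$P)
}

#' Checksum of the frozen backbone weights
#'
#' MD5 of the serialised weights; used to assert the frozen-backbone
#' contract before/after training.
#'
#' @param model A `wavefrac_model` (or a `wavefrac_branch`).
#' @return Character MD5 string.
#' @export
backbone_checksum <- function(model) {
  w <- if (inherits(model, "wavefrac_branch")) model$backbone else
    lapply(model$branches, function(br) br$backbone)
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(w, f, version = 2L, compress = FALSE)
  unname(tools::md5sum(f))
}
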