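# Synthetic long-bone radiograph generator ----------------------------------
#
# Emulates the statistical structure the multiband method exploits: a
# bright, smoothly shaded elongated "bone" (anti-aliased capsule with a
# transverse and longitudinal intensity profile) on a dark background, plus
# Gaussian noise.  Fracture images additionally carry a dark, jagged
# transverse crack (piecewise-linear polyline) crossing the bone, which
# injects localised high-frequency (HH) energy.  All smooth parts are
# locally near-linear in the pixel grid, so a clean non-fracture image has
# essentially no Haar HH energy.

#' Synthetic dataset specification
#'
#' @param image_size Square image side in pixels.
#' @param n_fracture,n_nonfracture Class counts.
#' @param bone_width Range of bone widths (pixels).
#' @param bone_curvature Range of centreline bow (pixels).
#' @param crack_width Range of crack widths (pixels).
#' @param crack_contrast Fractional intensity drop inside the crack,
#'   in (0, 1]; the default 0.6 gives the strongly separable regime.
#' @param noise_sd Gaussian pixel noise standard deviation (intensity
#'   units, images live in `[0, 1]`).
#' @param seed Integer master seed; every image's own seed derives from it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = 128L, n_fracture = 100L,
                           n_nonfracture = 100L,
                           bone_width = c(18, 30),
                           bone_curvature = c(0, 6),
                           crack_width = c(2, 4),
                           crack_contrast = 0.6,
                           noise_sd = 0.02, seed = 0L) {
  stopifnot(n_fracture >= 0, n_nonfracture >= 0, crack_contrast > 0,
            crack_contrast <= 1, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 n_fracture = as.integer(n_fracture),
                 n_nonfracture = as.integer(n_nonfracture),
                 bone_width = bone_width, bone_curvature = bone_curvature,
                 crack_width = crack_width, crack_contrast = crack_contrast,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Squared distance from all pixels (px, py) to segment (a, b).
seg_dist2 <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(pmax(((px - a[1]) * abx + (py - a[2]) * aby) / len2, 0), 1)
  (px - (a[1] + t * abx))^2 + (py - (a[2] + t * aby))^2
}

#' Generate one synthetic radiograph
#'
#' Deterministic for a fixed `(spec, fracture, seed)` triple.
#'
#' @param spec A [synthetic_spec()].
#' @param fracture Logical: add the crack discontinuity?
#' @param seed Integer seed for this image.
#' @return `image_size x image_size x 3` array in `[0, 1]` (identical
#'   channels).
#' @export
generate_image <- function(spec, fracture, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  S <- spec$image_size
  px <- rep(seq_len(S), each = S)    # x = column
  py <- rep(seq_len(S), times = S)   # y = row

  centre <- S / 2 + stats::runif(2, -0.1 * S, 0.1 * S)
  theta <- stats::runif(1, 0, pi)
  d <- c(cos(theta), sin(theta))
  nv <- c(-d[2], d[1])
  len <- stats::runif(1, 0.7, 0.95) * S
  w <- stats::runif(1, spec$bone_width[1], spec$bone_width[2]) / 2
  bow <- stats::runif(1, spec$bone_curvature[1], spec$bone_curvature[2])

  # distance to the (mildly bowed) capsule, computed in the bone frame:
  # longitudinal coordinate t in [-1, 1] along d, transverse offset u
  # relative to the bent centreline; beyond the ends the rounded cap adds
  # the longitudinal overshoot in quadrature.
  rx <- px - centre[1]; ry <- py - centre[2]
  t_raw <- (rx * d[1] + ry * d[2]) / (len / 2)
  tcl <- pmin(pmax(t_raw, -1), 1)
  u <- rx * nv[1] + ry * nv[2] - bow * (1 - tcl^2)
  over <- pmax(abs(t_raw) - 1, 0) * (len / 2)
  dist <- sqrt(u^2 + over^2)

  edge <- 6                                  # soft capsule boundary (px)
  inside <- smoothstep((w - dist) / edge + 0.5)
  transverse <- 1 - 0.25 * pmin(dist / w, 1)^2
  tproj <- pmin(pmax(((px - centre[1]) * d[1] + (py - centre[2]) * d[2]) /
                       (len / 2), -1), 1)
  longitudinal <- 0.85 + 0.15 * (tproj + 1) / 2
  img <- 0.05 + 0.75 * inside * transverse * longitudinal

  if (isTRUE(fracture)) {
    t0 <- stats::runif(1, -0.5, 0.5)
    p0 <- centre + t0 * len / 2 * d + bow * (1 - t0^2) * nv
    cw <- stats::runif(1, spec$crack_width[1], spec$crack_width[2])
    uu <- seq(-1.3 * w - edge, 1.3 * w + edge, length.out = 7L)
    jit <- stats::runif(length(uu), -0.2 * w, 0.2 * w)
    nodes <- cbind(p0[1] + uu * nv[1] + jit * d[1],
                   p0[2] + uu * nv[2] + jit * d[2])
    cd2 <- rep(Inf, S * S)
    for (k in seq_len(nrow(nodes) - 1L)) {
      cd2 <- pmin(cd2, seg_dist2(px, py, nodes[k, ], nodes[k + 1L, ]))
    }
    cmask <- smoothstep((cw / 2 - sqrt(cd2)) / 1.5 + 0.5)
    img <- img * (1 - spec$crack_contrast * cmask)
  }

  if (spec$noise_sd > 0) {
    img <- img + stats::rnorm(S * S, sd = spec$noise_sd)
  }
  img <- matrix(pmin(pmax(img, 0), 1), S, S)  # px fast over rows? see below
  # img vector is ordered with py (row) varying fastest -> matrix(S, S) is
  # already row-major-consistent: element (row=py, col=px)
  array(rep(img, 3L), c(S, S, 3L))
}

#' Generate a labelled synthetic dataset
#'
#' Draws one sub-seed per image from the master seed, generates
#' `n_fracture` crack images and `n_nonfracture` clean images, and (if
#' `dir` is given) writes them as PNG under `fracture/` and
#' `non_fracture/` class folders with a `manifest.csv`
#' (filename, label, seed).  Regeneration from the same spec is
#' byte-identical.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory, or `NULL` to keep the images in memory
#'   only.
#' @return (Invisibly for on-disk use) a list with `images`, `labels`
#'   (1 = fracture), and the `manifest` data frame.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_fracture + spec$n_nonfracture
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else integer(0)
  labels <- rep(c(1L, 0L), c(spec$n_fracture, spec$n_nonfracture))
  fnames <- ifelse(labels == 1L,
                   sprintf("fracture/frac_%04d.png", seq_len(n)),
                   sprintf("non_fracture/nonf_%04d.png", seq_len(n)))
  images <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- generate_image(spec, fracture = labels[i] == 1L,
                                  seed = seeds[i])
  }
  manifest <- data.frame(filename = fnames, label = labels, seed = seeds)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "fracture"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "non_fracture"), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_image_png(images[[i]], file.path(dir, fnames[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(list(images = images, labels = labels, manifest = manifest))
}
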