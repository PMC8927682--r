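# Synthetic fundus phantoms: dark branching curvilinear structures on a
# bright, slowly varying background inside a circular field of view, with
# pixel-exact vessel masks. Each "patient" (class) gets its own geometry
# seeded by (seed, class_index), so patches from one image correlate while
# images differ.

#' Specification for the synthetic vessel-image generator
#'
#' @param n_classes number of synthetic patients/images (default 10).
#' @param image_size square image side in pixels (default 160).
#' @param n_branches integer range c(lo, hi): number of vessel branches per
#'   image (default c(3, 6)).
#' @param width_range vessel diameter range in pixels, wide trunks tapering
#'   to thin tips (default c(2, 10)).
#' @param background_level mean background intensity of the green plane
#'   (default 0.72).
#' @param background_amplitude amplitude of the low-frequency background
#'   field (default 0.08).
#' @param vessel_contrast fractional darkening of vessel pixels relative to
#'   the local background (default 0.45).
#' @param noise_sd additive Gaussian noise standard deviation (default 0.02).
#' @param fov_radius field-of-view disc radius as a fraction of the image
#'   side (default 0.48).
#' @param seed integer base seed; class k is generated from (seed, k).
#' @return object of class \code{fv_synthetic_spec}.
#' @export
fv_synthetic_spec <- function(n_classes = 10L, image_size = 160L,
                              n_branches = c(3L, 6L), width_range = c(2, 10),
                              background_level = 0.72,
                              background_amplitude = 0.08,
                              vessel_contrast = 0.45, noise_sd = 0.02,
                              fov_radius = 0.48, seed = 1L) {
  if (image_size < 32) stop("image_size too small for a plausible phantom")
  if (any(width_range <= 0)) stop("width_range must be positive")
  if (n_branches[1] < 1) stop("need at least one vessel branch")
  structure(list(n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 n_branches = as.integer(n_branches),
                 width_range = width_range,
                 background_level = background_level,
                 background_amplitude = background_amplitude,
                 vessel_contrast = vessel_contrast, noise_sd = noise_sd,
                 fov_radius = fov_radius, seed = as.integer(seed)),
            class = "fv_synthetic_spec")
}

# Run expr under a derived seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derived per-class seed, kept inside 32-bit integer range.
fv_class_seed <- function(seed, class_index) {
  as.integer((as.numeric(seed) * 7919 + class_index * 104729) %% 2147483647)
}

# Smooth low-frequency scalar field on an n x n grid.
fv_low_freq_field <- function(n, amplitude, n_waves = 3L) {
  xs <- seq(0, 1, length.out = n)
  f <- matrix(0, n, n)
  for (i in seq_len(n_waves)) {
    fx <- runif(1, 0.5, 2); fy <- runif(1, 0.5, 2)
    ph <- runif(2, 0, 2 * pi)
    a <- runif(1, 0.3, 1)
    f <- f + a * outer(cos(2 * pi * fx * xs + ph[1]),
                       cos(2 * pi * fy * xs + ph[2]))
  }
  f / max(abs(f)) * amplitude
}

# Stamp a disc of given diameter at (r, c) into a logical mask.
fv_stamp <- function(mask, r, c, diameter) {
  n <- nrow(mask)
  rad <- max(diameter / 2, 0.5)
  ir <- max(1, floor(r - rad)):min(n, ceiling(r + rad))
  ic <- max(1, floor(c - rad)):min(n, ceiling(c + rad))
  for (cc in ic) {
    dy2 <- (cc - c)^2
    for (rr in ir) {
      if ((rr - r)^2 + dy2 <= rad^2) mask[rr, cc] <- TRUE
    }
  }
  mask
}

# Trace one vessel branch as a momentum random walk with tapering width;
# returns the updated mask and a queue of spawned child branches.
fv_trace_branch <- function(mask, start, angle, width, spec, depth) {
  n <- spec$image_size
  ctr <- (n + 1) / 2
  rad <- spec$fov_radius * n
  len <- round(runif(1, 0.3, 0.7) * n)
  pos <- start
  children <- list()
  w_end <- max(spec$width_range[1], width * runif(1, 0.3, 0.6))
  for (step in seq_len(len)) {
    w <- width + (w_end - width) * step / len
    mask <- fv_stamp(mask, pos[1], pos[2], w)
    angle <- angle + rnorm(1, 0, 0.09)
    pos <- pos + c(sin(angle), cos(angle))
    if (sqrt(sum((pos - ctr)^2)) > rad - 2) break
    if (depth < 2 && runif(1) < 0.015 && step > 10) {
      children[[length(children) + 1L]] <-
        list(start = pos, angle = angle + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
             width = w * 0.7, depth = depth + 1L)
    }
  }
  list(mask = mask, children = children)
}

#' Generate one synthetic annotated fundus image
#'
#' Deterministic in \code{(spec$seed, class_index)}: the same pair always
#' yields bit-identical output, and different classes get different vessel
#' geometry and background fields.
#'
#' @param spec an \code{\link{fv_synthetic_spec}}.
#' @param class_index positive integer identifying the synthetic patient.
#' @return list with \code{image} (H x W x 3 RGB in [0, 1]), \code{vessel}
#'   (binary matrix, pixel-exact rasterization), \code{fov} (binary disc),
#'   and \code{id} (e.g. \code{"synth03"}).
#' @export
fv_generate_class <- function(spec, class_index) {
  stopifnot(inherits(spec, "fv_synthetic_spec"))
  with_seed(fv_class_seed(spec$seed, class_index), {
    n <- spec$image_size
    ctr <- (n + 1) / 2
    rad <- spec$fov_radius * n
    idx <- seq_len(n)
    dist2 <- outer((idx - ctr)^2, (idx - ctr)^2, "+")
    fov <- (dist2 <= rad^2) * 1

    vessel <- matrix(FALSE, n, n)
    n_br <- sample(seq(spec$n_branches[1], spec$n_branches[2]), 1)
    queue <- list()
    for (b in seq_len(n_br)) {
      th <- runif(1, 0, 2 * pi)
      start <- c(ctr + 0.9 * rad * sin(th), ctr + 0.9 * rad * cos(th))
      queue[[length(queue) + 1L]] <-
        list(start = start, angle = th + pi + rnorm(1, 0, 0.4),
             width = runif(1, 0.45, 0.95) * spec$width_range[2], depth = 0L)
    }
    while (length(queue)) {
      br <- queue[[1]]; queue <- queue[-1]
      res <- fv_trace_branch(vessel, br$start, br$angle, br$width, spec,
                             br$depth)
      vessel <- res$mask
      queue <- c(queue, res$children)
    }
    vessel <- vessel & (fov > 0)

    green <- spec$background_level +
      fv_low_freq_field(n, spec$background_amplitude)
    green[vessel] <- green[vessel] * (1 - spec$vessel_contrast)
    green <- green + matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
    green <- pmin(pmax(green, 0), 1)
    red <- pmin(green * 1.25 + 0.05, 1)
    blue <- green * 0.45
    img <- array(0, c(n, n, 3))
    img[, , 1] <- red * fov
    img[, , 2] <- green * fov
    img[, , 3] <- blue * fov

    list(image = img, vessel = vessel * 1, fov = fov,
         id = sprintf("synth%02d", class_index))
  })
}

#' Generate a synthetic class library
#'
#' Runs \code{\link{fv_generate_class}} for every class, preprocesses each
#' image with the standard chain and cuts it into overlapping patches, so
#' the result plugs directly into episode sampling.
#'
#' @param spec an \code{\link{fv_synthetic_spec}}.
#' @param grid an \code{\link{fv_patch_grid}} matching
#'   \code{spec$image_size}; default: 64-px template, stride 48.
#' @param gamma,clip_limit,tile_grid preprocessing parameters.
#' @return an \code{fv_class_library} (see \code{\link{fv_class_library}}).
#' @export
fv_generate_library <- function(spec,
                                grid = fv_patch_grid(
                                  c(spec$image_size, spec$image_size),
                                  template = 64L, stride = 48L),
                                gamma = 1.2, clip_limit = 2,
                                tile_grid = c(8, 8)) {
  if (spec$n_classes == 0L) {
    warning("empty synthetic spec: returning an empty library")
    return(structure(list(classes = list(), grid = grid),
                     class = "fv_class_library"))
  }
  gens <- lapply(seq_len(spec$n_classes), function(k)
    fv_generate_class(spec, k))
  fv_class_library(images = lapply(gens, `[[`, "image"),
                   vessel_masks = lapply(gens, `[[`, "vessel"),
                   fov_masks = lapply(gens, `[[`, "fov"),
                   ids = vapply(gens, `[[`, "", "id"),
                   grid = grid, gamma = gamma, clip_limit = clip_limit,
                   tile_grid = tile_grid)
}
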