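#' Gamma-correct a fundus image
#'
#' Applies per-pixel power-law brightening/darkening, \code{out = in^gamma},
#' with the result clipped to \eqn{[0, 1]}. \code{gamma = 1} is the identity;
#' values below 1 brighten, values above 1 darken mid-tones.
#'
#' @param image numeric array (H x W x 3) or matrix with values in [0, 1].
#' @param gamma positive exponent; default 1.2 (mild mid-tone compression,
#'   common practice for fundus photographs).
#' @return array of the same shape, values in [0, 1].
#' @export
fv_gamma_correct <- function(image, gamma = 1.2) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a single positive number")
  out <- pmin(pmax(image, 0), 1)^gamma
  out[out > 1] <- 1
  out
}

#' Extract the green channel
#'
#' Vessel/background contrast is strongest in the green channel of a fundus
#' photograph, so segmentation pipelines routinely work on that plane alone.
#'
#' @param image numeric array H x W x 3 (RGB).
#' @return H x W matrix, the green plane unchanged.
#' @export
fv_green_channel <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("`image` must be an H x W x 3 RGB array")
  image[, , 2]
}

#' Contrast-limited adaptive histogram equalization
#'
#' Thin wrapper around \code{EBImage::clahe} keeping this package's
#' conventions (matrix in, matrix out, values in [0, 1]). A constant plane
#' comes back constant; the output is a deterministic function of the input
#' and the parameters.
#'
#' @param plane H x W matrix, values in [0, 1].
#' @param clip_limit positive contrast-limiting factor (default 2).
#' @param tile_grid integer vector of length 2, tiles along x and y
#'   (default \code{c(8, 8)}).
#' @return H x W matrix with values in [0, 1].
#' @export
fv_clahe <- function(plane, clip_limit = 2, tile_grid = c(8, 8)) {
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L || clip_limit <= 0)
    stop("`clip_limit` must be a single positive number")
  if (length(tile_grid) != 2L || any(tile_grid < 1))
    stop("`tile_grid` must be two positive integers")
  if (diff(range(plane)) < .Machine$double.eps) return(plane)
  out <- EBImage::clahe(EBImage::Image(plane), nx = tile_grid[1],
                        ny = tile_grid[2], limit = clip_limit)
  out <- as.matrix(EBImage::imageData(out))
  pmin(pmax(out, 0), 1)
}

#' Zero out pixels outside the field of view
#'
#' @param plane H x W matrix.
#' @param fov H x W binary matrix; 1 inside the circular retinal region.
#' @return plane with out-of-FOV pixels set to 0.
#' @export
fv_apply_field_mask <- function(plane, fov) {
  if (!identical(dim(plane), dim(fov)))
    stop("plane and field-of-view mask have different shapes")
  plane * (fov > 0)
}

#' Overlapping patch grid
#'
#' Top-left origins (0-based) of a sliding square template. Origins advance
#' by \code{stride} along each axis; when the last stride position does not
#' land flush with the border, one extra border-flush origin is appended per
#' axis so every pixel is covered.
#'
#' @param extent integer vector c(H, W) of the image.
#' @param template patch side in pixels (default 224).
#' @param stride step between consecutive origins (default 64, i.e. an
#'   overlap of \code{template - stride} = 160 at the defaults).
#' @return object of class \code{fv_patch_grid} with fields \code{origins}
#'   (n x 2 matrix of 0-based row/col), \code{template}, \code{stride},
#'   \code{extent}.
#' @export
fv_patch_grid <- function(extent, template = 224L, stride = 64L) {
  extent <- as.integer(extent)
  template <- as.integer(template)
  stride <- as.integer(stride)
  if (any(extent < template))
    stop("image extent (", paste(extent, collapse = "x"),
         ") smaller than patch template ", template)
  axis_origins <- function(n) {
    o <- seq.int(0L, n - template, by = stride)
    if (o[length(o)] != n - template) o <- c(o, n - template)
    o
  }
  rows <- axis_origins(extent[1])
  cols <- axis_origins(extent[2])
  origins <- cbind(rep(rows, times = length(cols)),
                   rep(cols, each = length(rows)))
  colnames(origins) <- c("row", "col")
  structure(list(origins = origins, template = template, stride = stride,
                 extent = extent),
            class = "fv_patch_grid")
}

#' @export
print.fv_patch_grid <- function(x, ...) {
  cat(sprintf("Patch grid: %d patches of %dx%d, stride %d, image %dx%d\n",
              nrow(x$origins), x$template, x$template, x$stride,
              x$extent[1], x$extent[2]))
  invisible(x)
}

#' Extract overlapping patches and their annotation crops
#'
#' Windows are half-open \code{[r, r + template) x [c, c + template)} in
#' 0-based coordinates. The annotation is cropped identically (no
#' resampling, so binary masks stay binary).
#'
#' @param plane H x W matrix (a preprocessed image plane).
#' @param mask H x W binary matrix (vessel annotation), or NULL.
#' @param grid an \code{\link{fv_patch_grid}}.
#' @return list of patches; each element has \code{patch}, \code{mask}
#'   (NULL if no annotation) and \code{origin} (0-based row/col).
#' @export
fv_extract_patches <- function(plane, mask, grid) {
  if (!inherits(grid, "fv_patch_grid")) stop("`grid` must be an fv_patch_grid")
  if (!identical(dim(plane), as.integer(grid$extent)))
    stop("plane extent does not match the grid")
  if (!is.null(mask) && !identical(dim(mask), dim(plane)))
    stop("mask and plane have different shapes")
  t <- grid$template
  lapply(seq_len(nrow(grid$origins)), function(i) {
    r <- grid$origins[i, 1]
    c <- grid$origins[i, 2]
    list(patch = plane[r + seq_len(t), c + seq_len(t)],
         mask = if (is.null(mask)) NULL else mask[r + seq_len(t), c + seq_len(t)],
         origin = grid$origins[i, ])
  })
}

#' Reassemble overlapping probability patches into a full-image map
#'
#' Each pixel takes the arithmetic mean of every patch covering it.
#'
#' @param patches list of H_t x W_t matrices, one per grid origin (same
#'   order as \code{grid$origins}).
#' @param grid the \code{\link{fv_patch_grid}} used for extraction.
#' @return matrix of the grid's extent.
#' @export
fv_reassemble <- function(patches, grid) {
  if (length(patches) != nrow(grid$origins))
    stop("got ", length(patches), " patches for ", nrow(grid$origins),
         " grid origins")
  acc <- matrix(0, grid$extent[1], grid$extent[2])
  cnt <- matrix(0, grid$extent[1], grid$extent[2])
  t <- grid$template
  for (i in seq_along(patches)) {
    r <- grid$origins[i, 1]
    c <- grid$origins[i, 2]
    acc[r + seq_len(t), c + seq_len(t)] <-
      acc[r + seq_len(t), c + seq_len(t)] + patches[[i]]
    cnt[r + seq_len(t), c + seq_len(t)] <-
      cnt[r + seq_len(t), c + seq_len(t)] + 1
  }
  acc / pmax(cnt, 1)
}

#' Full preprocessing chain for one fundus image
#'
#' gamma correction -> green-channel separation -> CLAHE -> field-of-view
#' masking, in that order.
#'
#' @param image H x W x 3 RGB array in [0, 1].
#' @param fov H x W binary field-of-view mask.
#' @param gamma,clip_limit,tile_grid see \code{\link{fv_gamma_correct}} and
#'   \code{\link{fv_clahe}}.
#' @return H x W matrix ready for patch extraction.
#' @export
fv_preprocess <- function(image, fov, gamma = 1.2, clip_limit = 2,
                          tile_grid = c(8, 8)) {
  plane <- fv_green_channel(fv_gamma_correct(image, gamma))
  plane <- fv_clahe(plane, clip_limit, tile_grid)
  fv_apply_field_mask(plane, fov)
}

# Normalise a mask read from disk (0/255 or 0/1, possibly multi-channel).
fv_as_binary_mask <- function(x) {
  if (length(dim(x)) == 3L) x <- x[, , 1]
  (x > max(x) / 2) * 1
}

#' Resize a binary mask to a feature-map grid
#'
#' Bilinear interpolation followed by thresholding at 0.5, so the result is
#' strictly binary at the coarser scale.
#'
#' @param mask H x W binary matrix.
#' @param h_out,w_out target grid size.
#' @return h_out x w_out binary matrix.
#' @export
fv_resize_mask <- function(mask, h_out, w_out) {
  m <- mask
  dim(m) <- c(dim(mask), 1L)
  r <- bilinear_fwd(m, h_out, w_out)[, , 1, drop = FALSE]
  matrix((r > 0.5) * 1, h_out, w_out)
}
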