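# Image and manifest IO. Images are PNG/TIFF/JPEG rasters read to [0, 1]
# arrays; masks may be 0/255 or 0/1 and are auto-normalised.

#' Read an image file to a numeric array in [0, 1]
#'
#' @param path PNG, TIFF or JPEG file.
#' @return H x W x C array (C = 3 for RGB) or H x W matrix for grayscale.
#' @export
fv_read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores (x, y, c); transpose to row/col (y, x, c)
  if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
}

#' Read a binary mask file
#'
#' @param path single-channel PNG/TIFF with values 0/255 or 0/1.
#' @return H x W binary matrix.
#' @export
fv_read_mask <- function(path) fv_as_binary_mask(fv_read_image(path))

#' Write a matrix or RGB array as PNG
#'
#' Values are clipped to [0, 1] and stored at 8-bit depth (the precision
#' limit of the PNG writer available here); probability maps needing full
#' precision should be kept as R objects or CSV.
#'
#' @param x H x W matrix or H x W x 3 array, values in [0, 1].
#' @param path output file.
#' @export
fv_write_png <- function(x, path) {
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}

#' Write patch fixtures with a sidecar manifest
#'
#' Saves every patch (and its annotation crop, when present) as PNG plus a
#' CSV manifest recording the image id, 0-based origin row/col, template
#' and stride — enough to reassemble or replay the extraction.
#'
#' @param plane preprocessed image plane.
#' @param mask binary vessel annotation or NULL.
#' @param grid an \code{\link{fv_patch_grid}}.
#' @param dir output directory.
#' @param id image identifier used in file names.
#' @return the manifest path, invisibly.
#' @export
fv_write_patches <- function(plane, mask, grid, dir, id = "img") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  patches <- fv_extract_patches(plane, mask, grid)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    pf <- sprintf("%s_patch%03d.png", id, i)
    fv_write_png(p$patch, file.path(dir, pf))
    mf <- NA_character_
    if (!is.null(p$mask)) {
      mf <- sprintf("%s_mask%03d.png", id, i)
      fv_write_png(p$mask, file.path(dir, mf))
    }
    data.frame(id = id, patch_file = pf, mask_file = mf,
               origin_row = p$origin[1], origin_col = p$origin[2],
               template = grid$template, stride = grid$stride)
  })
  man <- file.path(dir, paste0(id, "_patches.csv"))
  utils::write.csv(do.call(rbind, rows), man, row.names = FALSE)
  invisible(man)
}

#' Write a synthetic corpus to disk
#'
#' One PNG triple (image, vessel mask, field-of-view mask) per class plus a
#' JSON manifest, in the layout the library builder reads back, so
#' synthetic and real corpora are interchangeable.
#'
#' @param spec an \code{\link{fv_synthetic_spec}}.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
fv_write_corpus <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_len(spec$n_classes), function(k) {
    g <- fv_generate_class(spec, k)
    fv_write_png(g$image, file.path(dir, paste0(g$id, "_image.png")))
    fv_write_png(g$vessel, file.path(dir, paste0(g$id, "_vessel.png")))
    fv_write_png(g$fov, file.path(dir, paste0(g$id, "_fov.png")))
    list(id = g$id, image = paste0(g$id, "_image.png"),
         vessel = paste0(g$id, "_vessel.png"),
         fov = paste0(g$id, "_fov.png"))
  })
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = spec$seed, image_size = spec$image_size,
                            classes = entries),
                       man, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Build a class library from a corpus directory
#'
#' Reads the manifest written by \code{\link{fv_write_corpus}} (or an
#' equivalently laid out real-data directory).
#'
#' @param dir corpus directory containing \code{manifest.json}.
#' @param grid an \code{\link{fv_patch_grid}}.
#' @param gamma,clip_limit,tile_grid preprocessing parameters.
#' @return an \code{fv_class_library}.
#' @export
fv_read_corpus <- function(dir, grid, gamma = 1.2, clip_limit = 2,
                           tile_grid = c(8, 8)) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(man_path)
  cls <- man$classes
  if (length(cls) && !is.null(cls$id)) cls <- list(cls)
  fv_class_library(
    images = lapply(cls, function(e) {
      img <- fv_read_image(file.path(dir, e$image))
      if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
      if (dim(img)[3] > 3) img <- img[, , 1:3]
      img
    }),
    vessel_masks = lapply(cls, function(e)
      fv_read_mask(file.path(dir, e$vessel))),
    fov_masks = lapply(cls, function(e) fv_read_mask(file.path(dir, e$fov))),
    ids = vapply(cls, function(e) e$id, ""),
    grid = grid, gamma = gamma, clip_limit = clip_limit,
    tile_grid = tile_grid)
}
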