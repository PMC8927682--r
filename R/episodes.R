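# Scene-to-episode transformation: every annotated image is a few-shot
# "class", its overlapping patches are the class members, and training
# tasks are C-way K-shot episodes sampled from disjoint support/query
# members within each class.

#' Build a few-shot class library from annotated images
#'
#' Each image is preprocessed (gamma -> green channel -> CLAHE -> FOV mask),
#' cut into overlapping patches, and stored as one class whose members are
#' (patch, patch-mask, patch-fov) triples.
#'
#' @param images list of H x W x 3 RGB arrays in [0, 1].
#' @param vessel_masks list of binary vessel annotations (same extents).
#' @param fov_masks list of binary field-of-view masks.
#' @param ids character vector of class ids; defaults to img01, img02, ...
#' @param grid an \code{\link{fv_patch_grid}}.
#' @param gamma,clip_limit,tile_grid preprocessing parameters.
#' @return object of class \code{fv_class_library}: a list with
#'   \code{classes} (per class: \code{id}, \code{members}, \code{plane},
#'   \code{vessel}, \code{fov}) and \code{grid}.
#' @export
fv_class_library <- function(images, vessel_masks, fov_masks, ids = NULL,
                             grid = fv_patch_grid(dim(images[[1]])[1:2]),
                             gamma = 1.2, clip_limit = 2,
                             tile_grid = c(8, 8)) {
  n <- length(images)
  if (n == 0L) {
    warning("no images supplied: returning an empty library")
    return(structure(list(classes = list(), grid = grid),
                     class = "fv_class_library"))
  }
  if (length(vessel_masks) != n || length(fov_masks) != n)
    stop("every image needs a vessel annotation and a field-of-view mask")
  if (is.null(ids)) ids <- sprintf("img%02d", seq_len(n))
  classes <- lapply(seq_len(n), function(i) {
    vm <- fv_as_binary_mask(vessel_masks[[i]])
    fm <- fv_as_binary_mask(fov_masks[[i]])
    plane <- fv_preprocess(images[[i]], fm, gamma, clip_limit, tile_grid)
    patches <- fv_extract_patches(plane, vm, grid)
    fovs <- fv_extract_patches(fm, NULL, grid)
    members <- lapply(seq_along(patches), function(j)
      list(patch = patches[[j]]$patch, mask = patches[[j]]$mask,
           fov = fovs[[j]]$patch, origin = patches[[j]]$origin))
    list(id = ids[i], members = members, plane = plane, vessel = vm,
         fov = fm)
  })
  names(classes) <- ids
  structure(list(classes = classes, grid = grid),
            class = "fv_class_library")
}

#' @export
print.fv_class_library <- function(x, ...) {
  nm <- if (length(x$classes)) length(x$classes[[1]]$members) else 0L
  cat(sprintf("Few-shot class library: %d classes x %d members (%dx%d patches)\n",
              length(x$classes), nm, x$grid$template, x$grid$template))
  invisible(x)
}

#' Split class ids into train/validation/test sets
#'
#' @param library an \code{fv_class_library}.
#' @param n_train,n_valid number of training and validation classes; the
#'   remainder becomes the test set.
#' @param seed integer seed controlling the shuffle.
#' @return list with \code{train_ids}, \code{valid_ids}, \code{test_ids}.
#' @export
fv_split <- function(library, n_train, n_valid, seed = 1L) {
  ids <- names(library$classes)
  if (n_train + n_valid > length(ids))
    stop("split larger than the library")
  perm <- with_seed(seed, sample(ids))
  list(train_ids = perm[seq_len(n_train)],
       valid_ids = perm[n_train + seq_len(n_valid)],
       test_ids = perm[-seq_len(n_train + n_valid)])
}

#' Sample one C-way K-shot episode
#'
#' Draws C classes without replacement, then K support and K query members
#' per class, disjoint within the class. Reproducible under a fixed seed.
#'
#' @param library an \code{fv_class_library}.
#' @param C way count (number of classes per episode).
#' @param K shot count (support members per class; the query set also holds
#'   K members per class so the \eqn{1/(CK)} loss normalisation is exact).
#' @param class_ids optional pool of class ids to draw from (e.g. the
#'   training split); default all classes.
#' @param seed optional integer; when given the draw is made under it
#'   (caller RNG state is preserved), otherwise the current RNG is used.
#' @return object of class \code{fv_episode}: list of \code{classes}
#'   (each with \code{id}, \code{support}, \code{query} member lists),
#'   plus \code{C}, \code{K}.
#' @export
fv_sample_episode <- function(library, C, K, class_ids = NULL, seed = NULL) {
  pool <- if (is.null(class_ids)) names(library$classes) else class_ids
  if (length(pool) < C)
    stop("need at least C = ", C, " classes, have ", length(pool))
  draw <- function() {
    chosen <- sample(pool, C)
    classes <- lapply(chosen, function(id) {
      members <- library$classes[[id]]$members
      if (length(members) < 2 * K)
        stop("class ", id, " has ", length(members),
             " members; need at least 2K = ", 2 * K)
      sel <- sample(length(members), 2 * K)
      list(id = id,
           support = members[sel[seq_len(K)]],
           support_idx = sel[seq_len(K)],
           query = members[sel[K + seq_len(K)]],
           query_idx = sel[K + seq_len(K)])
    })
    names(classes) <- chosen
    structure(list(classes = classes, C = C, K = K), class = "fv_episode")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Fixed shared support for test-time inference
#'
#' Test classes are unseen, so their queries are guided by prototypes from
#' a fixed support set drawn from the validation split; the same support is
#' shared across every test class.
#'
#' @param library an \code{fv_class_library}.
#' @param valid_ids validation class ids to draw the shared support from.
#' @param test_ids test class ids to map.
#' @param K shots per shared support set.
#' @param seed integer seed for the (single, fixed) support draw.
#' @return named list mapping each test class id to the same list of K
#'   support members.
#' @export
fv_test_support_provider <- function(library, valid_ids, test_ids, K,
                                     seed = 1L) {
  if (length(valid_ids) == 0L)
    stop("validation split is empty: no support to share")
  if (length(test_ids) == 0L) return(setNames(list(), character(0)))
  support <- with_seed(seed, {
    id <- if (length(valid_ids) == 1L) valid_ids else sample(valid_ids, 1L)
    members <- library$classes[[id]]$members
    members[sample(length(members), min(K, length(members)))]
  })
  setNames(rep(list(support), length(test_ids)), test_ids)
}

#' Serialize an episode manifest
#'
#' Records class ids and member patch origins (not pixels), enough to
#' replay the episode exactly against the same library.
#'
#' @param episode an \code{fv_episode}.
#' @param path file to write JSON to; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
fv_episode_manifest <- function(episode, path = NULL) {
  man <- list(C = episode$C, K = episode$K,
              classes = lapply(episode$classes, function(cl)
                list(id = cl$id,
                     support = lapply(cl$support, function(m)
                       as.integer(m$origin)),
                     query = lapply(cl$query, function(m)
                       as.integer(m$origin)))))
  js <- jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
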