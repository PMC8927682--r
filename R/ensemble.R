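# Integrated framework: pixel-wise indicator voting over several
# independently trained members, then max/min probability fusion. A pixel
# is voted vessel when strictly more than T1 members assign it probability
# strictly above T; voted pixels take the maximum member probability,
# unvoted pixels the minimum.

#' Ensemble configuration
#'
#' @param members list of \code{fsvs_model} objects (N1 >= 2).
#' @param T probability threshold for a member's per-pixel vote
#'   (default 0.5).
#' @param T1 vote-count threshold; a pixel is foreground when the number of
#'   member votes strictly exceeds T1. Default \code{floor(N1 / 2)}, which
#'   is 1 for the three-member setting (i.e. "at least 2 of 3").
#' @return object of class \code{fv_ensemble}.
#' @export
fv_ensemble <- function(members, T = 0.5, T1 = floor(length(members) / 2)) {
  if (length(members) < 2) stop("an ensemble needs at least 2 members")
  if (T <= 0 || T >= 1) stop("T must lie strictly inside (0, 1)")
  if (T1 < 0 || T1 >= length(members))
    stop("T1 must satisfy 0 <= T1 < number of members")
  structure(list(members = members, T = T, T1 = T1),
            class = "fv_ensemble")
}

#' @export
print.fv_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d members (T = %g, T1 = %g)\n",
              length(x$members), x$T, x$T1))
  invisible(x)
}

#' Per-member probability maps for one or more queries
#'
#' Each member encodes the shared support once and then predicts every
#' query patch from its cached prototypes.
#'
#' @param members list of \code{fsvs_model} objects.
#' @param query_patch a query patch matrix, or a list of them.
#' @param support shared support member list.
#' @return for a single patch, a list of probability matrices (one per
#'   member, in member order); for a list of patches, a per-member list of
#'   per-query probability matrices.
#' @export
fv_member_predict <- function(members, query_patch, support) {
  single <- !is.list(query_patch)
  queries <- if (single) list(query_patch) else query_patch
  out <- lapply(seq_along(members), function(i) {
    m <- members[[i]]
    tryCatch({
      pv <- fv_prototype_values(m$weights, m$model_config, support)
      lapply(queries, function(q)
        fv_predict_cached(m$weights, m$model_config, q, pv))
    }, error = function(e) stop("ensemble member ", i, " failed: ",
                                conditionMessage(e)))
  })
  if (single) lapply(out, `[[`, 1L) else out
}

#' Pixel-wise majority vote
#'
#' \code{vote[m,n] = 1} iff the number of members with probability
#' strictly above \code{T} at (m, n) strictly exceeds \code{T1}.
#'
#' @param maps list of equally shaped probability matrices.
#' @param T per-member probability threshold (default 0.5).
#' @param T1 vote-count threshold (default 1, the three-member majority).
#' @return binary matrix of votes.
#' @export
fv_vote <- function(maps, T = 0.5, T1 = 1) {
  d <- dim(maps[[1]])
  for (m in maps) if (!identical(dim(m), d)) stop("member map shape mismatch")
  votes <- Reduce(`+`, lapply(maps, function(m) (m > T) * 1))
  (votes > T1) * 1
}

#' Max/min probability fusion
#'
#' Voted pixels take the maximum member probability, unvoted pixels the
#' minimum, so the fused map stays consistent with the vote: fused values
#' binarized at \code{T} reproduce the vote map exactly.
#'
#' @param maps list of member probability matrices.
#' @param vote_map binary matrix from \code{\link{fv_vote}}.
#' @return fused probability matrix.
#' @export
fv_fuse <- function(maps, vote_map) {
  d <- dim(maps[[1]])
  if (!identical(dim(vote_map), d)) stop("vote map shape mismatch")
  mx <- Reduce(pmax, maps)
  mn <- Reduce(pmin, maps)
  mx * (vote_map > 0) + mn * (vote_map == 0)
}

#' Fused ensemble prediction for a query patch
#'
#' Runs every member, votes pixel-wise and fuses by max/min.
#'
#' @param ensemble an \code{\link{fv_ensemble}}.
#' @param query_patch query patch matrix.
#' @param support shared support member list.
#' @return list with \code{fused} (probability matrix), \code{vote}
#'   (binary matrix) and \code{members} (per-member maps).
#' @export
predict.fv_ensemble <- function(object, query_patch, support, ...) {
  maps <- fv_member_predict(object$members, query_patch, support)
  v <- fv_vote(maps, object$T, object$T1)
  list(fused = fv_fuse(maps, v), vote = v, members = maps)
}
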