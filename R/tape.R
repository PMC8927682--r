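# Minimal reverse-mode autodiff tape.
#
# A node is an environment holding $v (value), $g (accumulated gradient,
# lazily initialised), $bk (closure propagating an upstream gradient to the
# node's parents) and $id (creation order). Operations append nodes to the
# active tape; tp_backward() walks the tape in reverse creation order.
# Heavy kernels (convolution, pooling, resampling) live in src/ops.cpp;
# everything here is bookkeeping.

.fv <- new.env(parent = emptyenv())

# Tapes form a stack so a helper that opens its own tape (e.g. prototype
# precomputation) can run while an outer tape is active.
tp_begin <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  if (is.null(.fv$stack)) .fv$stack <- list()
  .fv$stack[[length(.fv$stack) + 1L]] <- tape
  invisible(tape)
}

tp_end <- function() {
  n <- length(.fv$stack)
  if (n > 0L) .fv$stack[[n]] <- NULL
  invisible(NULL)
}

tp_active <- function() {
  n <- length(.fv$stack)
  if (n == 0L) stop("no active tape; call tp_begin() first")
  .fv$stack[[n]]
}

# Create a node. `bk` receives the upstream gradient and must return a list
# of gradients aligned with `parents` (NULL entries allowed for constants).
tp_node <- function(value, parents = list(), bk = NULL) {
  tape <- tp_active()
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$bk <- bk
  nd$parents <- parents
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

tp_const <- function(value) tp_node(value)

tp_accum <- function(node, g) {
  if (is.null(node$bk) && is.null(node$is_param)) return(invisible(NULL))
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible(NULL)
}

tp_param <- function(value) {
  nd <- tp_node(value)
  nd$is_param <- TRUE
  nd
}

tp_backward <- function(loss_node) {
  tape <- tp_active()
  loss_node$g <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$g) || is.null(nd$bk)) next
    gs <- nd$bk(nd$g)
    for (j in seq_along(gs)) {
      if (!is.null(gs[[j]])) tp_accum(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}
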