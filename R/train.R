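# Episodic training: Adam on the binary cross-entropy objective over
# C-way K-shot episodes, with per-epoch validation and best-accuracy
# checkpoint retention.

#' Numerically stable logistic link
#'
#' \eqn{p = 1 / (1 + e^{-x})}, element-wise, safe for |x| up to well beyond
#' 1e3 (extreme logits saturate to 0/1 without overflow).
#'
#' @param x numeric vector/matrix/array of logits.
#' @return object of the same shape with values in [0, 1].
#' @export
fv_sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  out[!pos] <- exp(x[!pos]) / (1 + exp(x[!pos]))
  out
}

#' Episode binary cross-entropy
#'
#' Mean over the C x K prediction maps of the pixel-mean binary
#' cross-entropy, with probabilities clamped to [eps, 1 - eps] before the
#' logarithms. For a single map this is the usual
#' \eqn{-mean[y log p + (1-y) log(1-p)]}.
#'
#' @param prob_maps list of probability matrices (or a single matrix).
#' @param truths list of binary masks matching \code{prob_maps}.
#' @param eps clamping constant (default 1e-7).
#' @return non-negative scalar loss.
#' @export
fv_bce_loss <- function(prob_maps, truths, eps = 1e-7) {
  if (!is.list(prob_maps)) prob_maps <- list(prob_maps)
  if (!is.list(truths)) truths <- list(truths)
  if (length(prob_maps) != length(truths))
    stop("prediction and truth counts differ")
  terms <- vapply(seq_along(prob_maps), function(i) {
    p <- pmin(pmax(prob_maps[[i]], eps), 1 - eps)
    y <- truths[[i]]
    if (!identical(dim(p), dim(y))) stop("map ", i, ": shape mismatch")
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }, 0)
  mean(terms)
}

#' Training configuration
#'
#' Defaults follow the production setting (Adam, learning rate 1e-4,
#' 30 epochs of 100 episodes); desk-scale runs shrink epochs/iterations and
#' raise the learning rate to suit the reduced-width network.
#'
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param iterations_per_epoch episodes sampled per epoch.
#' @param C,K way and shot counts for the sampled episodes.
#' @param seed integer seed governing initialization and episode sampling.
#' @param val_episodes validation episodes evaluated after each epoch.
#' @return object of class \code{fv_train_config}.
#' @export
fv_train_config <- function(learning_rate = 1e-4, epochs = 30L,
                            iterations_per_epoch = 100L, C = 3L, K = 3L,
                            seed = 1L, val_episodes = 2L) {
  stopifnot(learning_rate > 0, epochs >= 1, iterations_per_epoch >= 1,
            C >= 1, K >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 C = as.integer(C), K = as.integer(K), seed = as.integer(seed),
                 val_episodes = as.integer(val_episodes)),
            class = "fv_train_config")
}

fv_adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

fv_adam_step <- function(weights, grads, state, lr, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

# One optimisation step on a fixed episode; returns loss and new weights.
fv_train_step <- function(weights, cfg, episode, adam, lr) {
  tp_begin()
  on.exit(tp_end())
  p <- fv_param_nodes(weights)
  loss <- fv_episode_loss(p, cfg, episode)
  tp_backward(loss)
  grads <- lapply(p, function(nd) nd$g)
  if (!is.finite(loss$v))
    stop("non-finite training loss (", loss$v, "); aborting")
  upd <- fv_adam_step(weights, grads, adam, lr)
  list(loss = loss$v, weights = upd$weights, adam = upd$state)
}

# Micro-averaged metrics of one evaluation episode under given weights.
fv_eval_episode <- function(weights, cfg, episode) {
  counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  probs <- list(); truths <- list(); fovs <- list()
  for (cl in episode$classes) {
    pv <- fv_prototype_values(weights, cfg, cl$support)
    for (q in cl$query) {
      pr <- fv_predict_cached(weights, cfg, q$patch, pv)
      probs[[length(probs) + 1L]] <- pr
      truths[[length(truths) + 1L]] <- q$mask
      fovs[[length(fovs) + 1L]] <- q$fov
      cc <- fv_confusion(pr, q$mask, q$fov)
      counts <- counts + unlist(cc)[c("tp", "tn", "fp", "fn")]
    }
  }
  m <- fv_metrics(as.list(counts))
  m$auc <- suppressWarnings(
    fv_auc(do.call(c, lapply(probs, as.numeric)),
           do.call(c, lapply(truths, as.numeric)),
           do.call(c, lapply(fovs, as.numeric))))
  m
}

#' Fit a few-shot vessel segmentation model
#'
#' Episodic training of the baseline or upgraded prototype-guided network:
#' each iteration samples a C-way K-shot episode from the training classes,
#' builds the support prototypes, predicts the query patches and takes one
#' Adam step on the binary cross-entropy. After every epoch the model is
#' scored on validation episodes and the weights with the best validation
#' accuracy are retained.
#'
#' @param library an \code{fv_class_library}.
#' @param variant \code{"baseline"} or \code{"upgraded"}.
#' @param split list with \code{train_ids} and \code{valid_ids} (see
#'   \code{\link{fv_split}}); when NULL all classes are used for both.
#' @param config an \code{\link{fv_train_config}}.
#' @param model_config an \code{\link{fv_model_config}}; the variant field
#'   is overridden by \code{variant}.
#' @param verbose print per-epoch progress.
#' @return object of class \code{fsvs_model} with elements \code{weights}
#'   (best by validation accuracy), \code{final_weights}, \code{config},
#'   \code{model_config}, \code{history} (one row per iteration),
#'   \code{val_history} (one row per epoch) and \code{split}.
#' @export
fsvs_fit <- function(library, variant = c("upgraded", "baseline"),
                     split = NULL, config = fv_train_config(),
                     model_config = fv_model_config(variant),
                     verbose = FALSE) {
  variant <- match.arg(variant)
  model_config$variant <- variant
  if (is.null(split)) {
    ids <- names(library$classes)
    split <- list(train_ids = ids, valid_ids = ids)
  }
  weights <- fv_init_weights(model_config, seed = config$seed)
  adam <- fv_adam_init(weights)
  history <- data.frame()
  val_history <- data.frame()
  best <- list(acc = -Inf, weights = weights)
  with_seed(config$seed + 1L, {
    val_eps <- lapply(seq_len(config$val_episodes), function(i)
      fv_sample_episode(library, min(config$C, length(split$valid_ids)),
                        config$K, split$valid_ids))
    for (epoch in seq_len(config$epochs)) {
      for (it in seq_len(config$iterations_per_epoch)) {
        ep <- fv_sample_episode(library, config$C, config$K, split$train_ids)
        st <- fv_train_step(weights, model_config, ep, adam,
                            config$learning_rate)
        weights <- st$weights
        adam <- st$adam
        history <- rbind(history, data.frame(epoch = epoch, iteration = it,
                                             loss = st$loss))
      }
      vm <- lapply(val_eps, function(e) fv_eval_episode(weights,
                                                        model_config, e))
      vrow <- data.frame(epoch = epoch,
                         acc = mean(vapply(vm, `[[`, 0, "acc")),
                         sen = mean(vapply(vm, `[[`, 0, "sen")),
                         spe = mean(vapply(vm, `[[`, 0, "spe")),
                         f1 = mean(vapply(vm, `[[`, 0, "f1")))
      val_history <- rbind(val_history, vrow)
      if (is.finite(vrow$acc) && vrow$acc > best$acc)
        best <- list(acc = vrow$acc, weights = weights)
      if (verbose)
        message(sprintf(
          "epoch %d/%d  loss %.4f  val acc %.4f  val f1 %.4f", epoch,
          config$epochs, mean(utils::tail(history$loss,
                                          config$iterations_per_epoch)),
          vrow$acc, vrow$f1))
    }
  })
  structure(list(weights = best$weights, final_weights = weights,
                 config = config, model_config = model_config,
                 history = history, val_history = val_history,
                 split = split),
            class = "fsvs_model")
}

#' @export
print.fsvs_model <- function(x, ...) {
  cat(sprintf("Few-shot vessel segmentation model (%s variant)\n",
              x$model_config$variant))
  cat(sprintf("  %d-way %d-shot, %d epochs x %d episodes, lr %g\n",
              x$config$C, x$config$K, x$config$epochs,
              x$config$iterations_per_epoch, x$config$learning_rate))
  cat(sprintf("  channel scale %g (encoder widths %s)\n",
              x$model_config$channel_scale,
              paste(x$model_config$enc_widths, collapse = ", ")))
  if (nrow(x$val_history))
    cat(sprintf("  best validation accuracy %.4f (epoch %d)\n",
                max(x$val_history$acc), which.max(x$val_history$acc)))
  invisible(x)
}

#' @export
summary.fsvs_model <- function(object, ...) {
  h <- object$history
  ep_loss <- tapply(h$loss, h$epoch, mean)
  out <- list(variant = object$model_config$variant,
              epoch_loss = ep_loss, val_history = object$val_history,
              n_parameters = sum(vapply(object$weights, length, 0L)))
  class(out) <- "summary.fsvs_model"
  out
}

#' @export
print.summary.fsvs_model <- function(x, ...) {
  cat(sprintf("%s variant, %d trainable parameters\n", x$variant,
              x$n_parameters))
  cat("Per-epoch mean training loss:\n")
  print(round(x$epoch_loss, 4))
  cat("Validation history:\n")
  print(x$val_history, row.names = FALSE)
  invisible(x)
}

#' @export
plot.fsvs_model <- function(x, ...) {
  h <- x$history
  ep_loss <- tapply(h$loss, h$epoch, mean)
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  plot(seq_along(ep_loss), ep_loss, type = "b", xlab = "epoch",
       ylab = "mean episode loss", main = "Training loss", ...)
  if (nrow(x$val_history))
    plot(x$val_history$epoch, x$val_history$acc, type = "b", xlab = "epoch",
         ylab = "validation accuracy", main = "Validation accuracy", ...)
  invisible(x)
}

#' Predict vessel probabilities with a fitted model
#'
#' For a single patch, returns its probability map. For a full image plane,
#' extracts overlapping patches on the model's grid, predicts each and
#' averages the overlaps back into a full-resolution map.
#'
#' @param object an \code{fsvs_model}.
#' @param patch side x side matrix (side divisible by 16), or NULL.
#' @param plane full preprocessed image plane (used when patch is NULL).
#' @param support support member list guiding the prototypes.
#' @param grid \code{\link{fv_patch_grid}} for whole-plane prediction.
#' @param ... unused.
#' @return probability matrix matching the input extent.
#' @export
predict.fsvs_model <- function(object, patch = NULL, plane = NULL,
                               support = NULL, grid = NULL, ...) {
  if (is.null(support)) stop("a support set is required for prediction")
  if (!is.null(patch))
    return(fv_predict_patch(object$weights, object$model_config, patch,
                            support))
  if (is.null(plane)) stop("supply `patch` or `plane`")
  if (is.null(grid))
    grid <- fv_patch_grid(dim(plane), template = 64L, stride = 48L)
  patches <- fv_extract_patches(plane, NULL, grid)
  pv <- fv_prototype_values(object$weights, object$model_config, support)
  probs <- lapply(patches, function(pp)
    fv_predict_cached(object$weights, object$model_config, pp$patch, pv))
  fv_reassemble(probs, grid)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the weights, both configuration
#' objects and the training history.
#'
#' @param model an \code{fsvs_model}.
#' @param path file path.
#' @return \code{fv_load_model} returns the restored \code{fsvs_model}.
#' @export
fv_save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname fv_save_model
#' @export
fv_load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "fsvs_model")) stop("not an fsvs_model checkpoint")
  m
}

#' Evaluate a fitted model on held-out classes with shared support
#'
#' Test classes are unseen; their query patches are guided by a fixed
#' support set drawn from the validation split (support sharing). Counts
#' are micro-averaged over all test queries.
#'
#' @param model an \code{fsvs_model}.
#' @param library the class library.
#' @param test_ids held-out class ids.
#' @param support shared support member list (see
#'   \code{\link{fv_test_support_provider}}).
#' @param n_query query patches per test class (default: all members).
#' @param seed seed for the query subsample.
#' @return list of micro-averaged metrics (sen, spe, acc, f1, auc) plus
#'   the raw counts.
#' @export
fv_evaluate_heldout <- function(model, library, test_ids, support,
                                n_query = NULL, seed = 1L) {
  counts <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  probs <- c(); truths <- c(); fovs <- c()
  pv <- fv_prototype_values(model$weights, model$model_config, support)
  with_seed(seed, {
    for (id in test_ids) {
      members <- library$classes[[id]]$members
      sel <- if (is.null(n_query)) seq_along(members)
             else sample(length(members), min(n_query, length(members)))
      for (j in sel) {
        q <- members[[j]]
        pr <- fv_predict_cached(model$weights, model$model_config, q$patch,
                                pv)
        counts <- counts +
          unlist(fv_confusion(pr, q$mask, q$fov))[c("tp", "tn", "fp", "fn")]
        inside <- q$fov > 0
        probs <- c(probs, pr[inside])
        truths <- c(truths, q$mask[inside])
        fovs <- c(fovs, rep(1, sum(inside)))
      }
    }
  })
  m <- fv_metrics(as.list(counts))
  m$auc <- fv_auc(probs, truths, fovs)
  m$counts <- as.list(counts)
  m
}
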