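# Shared fixtures. Expensive artefacts (training runs) are computed once
# per test session and cached in this environment so several test files
# can reuse them.

.fx <- new.env(parent = emptyenv())

fx_small_library <- function(n_classes = 4L, seed = 1L) {
  key <- sprintf("lib_%d_%d", n_classes, seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- fv_generate_library(
      fv_synthetic_spec(n_classes = n_classes, seed = seed))
  .fx[[key]]
}

fx_tiny_episode <- function(side = 32L, C = 1L, K = 1L, seed = 7L) {
  set.seed(seed)
  mk <- function() list(patch = matrix(runif(side * side), side, side),
                        mask = matrix(rbinom(side * side, 1, 0.2), side, side),
                        fov = matrix(1, side, side))
  classes <- lapply(seq_len(C), function(j)
    list(id = paste0("c", j),
         support = replicate(K, mk(), simplify = FALSE),
         query = replicate(K, mk(), simplify = FALSE)))
  names(classes) <- paste0("c", seq_len(C))
  structure(list(classes = classes, C = C, K = K), class = "fv_episode")
}

# Desk-scale training protocol: 10 synthetic classes (160 px images,
# 64-px patches), channel_scale 0.125, 3-way 3-shot, 10 epochs x 20
# episodes. Returns per-seed held-out metrics and the epoch-mean loss
# trajectory.
fx_protocol_run <- function(variant, seed) {
  key <- sprintf("run_%s_%d", variant, seed)
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  lib <- fx_small_library(n_classes = 10L, seed = 11L)
  split <- fv_split(lib, n_train = 3, n_valid = 3, seed = 11L)
  tc <- fv_train_config(learning_rate = 1e-3, epochs = 10L,
                        iterations_per_epoch = 20L, C = 3L, K = 3L,
                        seed = seed, val_episodes = 1L)
  mc <- fv_model_config(variant, channel_scale = 0.125)
  fit <- fsvs_fit(lib, variant, split, tc, mc)
  sup <- fv_test_support_provider(lib, split$valid_ids, split$test_ids,
                                  K = 3L, seed = seed)
  m <- fv_evaluate_heldout(fit, lib, split$test_ids, sup[[1]], n_query = 6L,
                           seed = seed)
  ep_loss <- as.numeric(tapply(fit$history$loss, fit$history$epoch, mean))
  .fx[[key]] <- list(f1 = m$f1, auc = m$auc, acc = m$acc,
                     ep_loss = ep_loss)
  .fx[[key]]
}

fx_protocol_seeds <- c(101L, 202L, 303L)
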