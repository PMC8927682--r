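# Prototype-guided encoder/decoder segmentation network.
#
# The encoder is the first four convolution blocks of a VGG16-style net
# (ordinary 3x3 kernels, 2x2 max-pooling); the five feature positions are
# the four block outputs before their pooling (l = 1..4) plus the map after
# the fourth pooling (l = 5), giving spatial sides s, s/2, s/4, s/8, s/16
# and channel widths 64, 128, 256, 512, 512 at channel_scale = 1.
# Class prototypes come from mask average pooling of support features;
# query inference applies each prototype as a 1x1 inner-product kernel.
# The baseline uses the l = 5 prototype only; the upgraded variant extracts
# prototypes at all five scales, fuses guidance maps with skip-connected
# query features down the decoder, and applies two-scale non-local
# attention to the deepest query features.

#' Model configuration
#'
#' @param variant \code{"baseline"} (single deep prototype) or
#'   \code{"upgraded"} (multi-scale prototypes, skip fusion, two-scale
#'   non-local attention).
#' @param channel_scale factor in (0, 1] uniformly shrinking all layer
#'   widths; the architecture graph is unchanged. 1 is the full-width
#'   configuration; 0.125 is the desk-scale test setting.
#' @param attention_scales integer down-sampling factors for the non-local
#'   attention block at the deepest layer (default \code{c(1, 2)}).
#' @param in_channels input image planes (1 for the preprocessed green
#'   channel).
#' @return object of class \code{fv_model_config}.
#' @export
fv_model_config <- function(variant = c("upgraded", "baseline"),
                            channel_scale = 1, attention_scales = c(1L, 2L),
                            in_channels = 1L) {
  variant <- match.arg(variant)
  if (channel_scale <= 0 || channel_scale > 1)
    stop("channel_scale must be in (0, 1]")
  w <- function(n) max(1L, as.integer(round(n * channel_scale)))
  structure(list(variant = variant, channel_scale = channel_scale,
                 attention_scales = as.integer(attention_scales),
                 in_channels = as.integer(in_channels),
                 enc_widths = c(w(64), w(128), w(256), w(512), w(512)),
                 dec_widths = c(w(512), w(256), w(256), w(128), w(128),
                                w(64), w(64), w(32), 3L, 1L)),
            class = "fv_model_config")
}

# Layer table: name, kind (conv3/conv1), input and output channels.
fv_layer_table <- function(cfg) {
  cw <- cfg$enc_widths
  dw <- cfg$dec_widths
  up <- cfg$variant == "upgraded"
  enc <- list(
    c("e1_1", cfg$in_channels, cw[1]), c("e1_2", cw[1], cw[1]),
    c("e2_1", cw[1], cw[2]), c("e2_2", cw[2], cw[2]),
    c("e3_1", cw[2], cw[3]), c("e3_2", cw[3], cw[3]), c("e3_3", cw[3], cw[3]),
    c("e4_1", cw[3], cw[4]), c("e4_2", cw[4], cw[4]), c("e4_3", cw[4], cw[4]))
  gd <- function(skip) if (up) skip + 1L else 0L  # skip feature + guidance
  dec <- list(
    c("d1", cw[5] + 1L + gd(cw[4]), dw[1]), c("d2", dw[1], dw[2]),
    c("d3", dw[2] + gd(cw[3]), dw[3]), c("d4", dw[3], dw[4]),
    c("d5", dw[4] + gd(cw[2]), dw[5]), c("d6", dw[5], dw[6]),
    c("d7", dw[6] + gd(cw[1]), dw[7]), c("d8", dw[7], dw[8]),
    c("d9", dw[8], dw[9]), c("d10", dw[9], dw[10]))
  layers <- c(enc, dec)
  data.frame(name = vapply(layers, `[`, "", 1),
             cin = as.integer(vapply(layers, `[`, "", 2)),
             cout = as.integer(vapply(layers, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Initialize model weights
#'
#' He-normal initialization (sd = sqrt(2 / fan_in)), zero biases.
#'
#' @param cfg an \code{\link{fv_model_config}}.
#' @param seed integer seed for the draw.
#' @return named list of weight arrays.
#' @export
fv_init_weights <- function(cfg, seed = 1L) {
  with_seed(seed, {
    w <- list()
    tab <- fv_layer_table(cfg)
    for (i in seq_len(nrow(tab))) {
      fan_in <- 9L * tab$cin[i]
      w[[paste0(tab$name[i], ".k")]] <-
        matrix(rnorm(fan_in * tab$cout[i], 0, sqrt(2 / fan_in)),
               fan_in, tab$cout[i])
      w[[paste0(tab$name[i], ".b")]] <- numeric(tab$cout[i])
    }
    if (cfg$variant == "upgraded") {
      c5 <- cfg$enc_widths[5]
      ci <- max(1L, c5 %/% 2L)
      for (si in seq_along(cfg$attention_scales)) {
        pre <- sprintf("msa%d.", si)
        for (nm in c("th", "ph", "g"))
          w[[paste0(pre, nm)]] <- matrix(rnorm(c5 * ci, 0, sqrt(2 / c5)),
                                         c5, ci)
        w[[paste0(pre, "o")]] <- matrix(rnorm(ci * c5, 0, sqrt(2 / ci)),
                                        ci, c5)
      }
      w[["msaf.k"]] <- matrix(rnorm(c5 * c5, 0, sqrt(2 / c5)), c5, c5)
      w[["msaf.b"]] <- numeric(c5)
    }
    w
  })
}

# Wrap weights in parameter nodes on the active tape (once per step).
fv_param_nodes <- function(weights) lapply(weights, tp_param)

fv_conv_relu <- function(x, p, name) {
  ad_relu(ad_conv3(x, p[[paste0(name, ".k")]], p[[paste0(name, ".b")]]))
}

#' Encoder forward pass (tape nodes)
#'
#' @param p parameter node list from \code{fv_param_nodes}.
#' @param x input node, (side x side x in_channels), side divisible by 16.
#' @return list of five feature-map nodes f1..f5.
#' @keywords internal
fv_encode_nodes <- function(p, x) {
  side <- dim(x$v)[1]
  if (side %% 16L != 0L)
    stop("patch side ", side, " is not divisible by 16")
  f1 <- fv_conv_relu(fv_conv_relu(x, p, "e1_1"), p, "e1_2")
  x2 <- ad_maxpool2(f1)
  f2 <- fv_conv_relu(fv_conv_relu(x2, p, "e2_1"), p, "e2_2")
  x3 <- ad_maxpool2(f2)
  f3 <- fv_conv_relu(fv_conv_relu(fv_conv_relu(x3, p, "e3_1"), p, "e3_2"),
                     p, "e3_3")
  x4 <- ad_maxpool2(f3)
  f4 <- fv_conv_relu(fv_conv_relu(fv_conv_relu(x4, p, "e4_1"), p, "e4_2"),
                     p, "e4_3")
  f5 <- ad_maxpool2(f4)
  list(f1, f2, f3, f4, f5)
}

# Two-scale non-local attention (embedded Gaussian) on the deepest query
# feature map: per scale, average-pool, softmax-normalised pairwise
# affinities over all positions, value aggregation, output projection,
# residual add, bilinear up-sample; scale outputs are summed and passed
# through one 1x1 convolution.
fv_msa_nodes <- function(p, cfg, f5) {
  d <- dim(f5$v)
  outs <- vector("list", length(cfg$attention_scales))
  for (si in seq_along(cfg$attention_scales)) {
    s <- cfg$attention_scales[si]
    if (d[1] < s || d[2] < s)
      stop("feature side ", d[1], " smaller than attention scale ", s)
    xs <- if (s > 1L) ad_avgpool(f5, s) else f5
    ds <- dim(xs$v)
    xm <- ad_reshape_mat(xs)
    pre <- sprintf("msa%d.", si)
    th <- ad_matmul(xm, p[[paste0(pre, "th")]])
    ph <- ad_matmul(xm, p[[paste0(pre, "ph")]])
    gg <- ad_matmul(xm, p[[paste0(pre, "g")]])
    aff <- ad_softmax_rows(ad_matmul(th, ph, transb = TRUE))
    y <- ad_matmul(ad_matmul(aff, gg), p[[paste0(pre, "o")]])
    z <- ad_add(ad_reshape_cube(y, ds[1], ds[2]), xs)
    outs[[si]] <- if (s > 1L) ad_bilinear(z, d[1], d[2]) else z
  }
  acc <- outs[[1]]
  if (length(outs) > 1)
    for (i in 2:length(outs)) acc <- ad_add(acc, outs[[i]])
  ad_conv1(acc, p[["msaf.k"]], p[["msaf.b"]])
}

# Multi-shot class prototypes from the support set. Returns a list indexed
# by level l (positions with no prototype are NULL). Empty vessel masks are
# allowed: mask average pooling then yields a zero prototype.
fv_support_prototypes <- function(p, cfg, support, levels) {
  per_level <- vector("list", 5L)
  shot_protos <- lapply(support, function(m) {
    x <- tp_const(as_cube(m$patch))
    feats <- fv_encode_nodes(p, x)
    side <- dim(m$patch)[1]
    sapply(levels, function(l) {
      sl <- side %/% 2L^(l - 1L)
      msk <- if (l == 1L) (m$mask > 0.5) * 1 else fv_resize_mask(m$mask, sl, sl)
      ad_mask_avg_pool(feats[[l]], msk)
    }, simplify = FALSE)
  })
  for (i in seq_along(levels)) {
    per_level[[levels[i]]] <-
      ad_mean_nodes(lapply(shot_protos, `[[`, i))
  }
  per_level
}

# Query forward pass to logits, given per-level prototypes.
# `ablate_guidance` zeroes the l = 1..4 guidance maps (upgraded variant
# only), reducing the pass to a baseline-like single-prototype decoder.
fv_forward_query <- function(p, cfg, query_patch, protos,
                             ablate_guidance = FALSE) {
  up <- cfg$variant == "upgraded"
  x <- tp_const(as_cube(query_patch))
  side <- dim(x$v)[1]
  feats <- fv_encode_nodes(p, x)
  f5 <- if (up) fv_msa_nodes(p, cfg, feats[[5]]) else feats[[5]]
  guide <- function(l, f) {
    g <- ad_proto_dot(f, protos[[l]])
    if (ablate_guidance && l < 5L) g <- ad_scale(g, 0)
    g
  }
  state <- ad_concat(list(f5, guide(5L, f5)))
  dc <- function(x, name) fv_conv_relu(x, p, name)
  for (stage in 1:4) {
    so <- side %/% 2L^(4L - stage)
    state <- ad_bilinear(state, so, so)
    if (up) {
      l <- 5L - stage
      state <- ad_concat(list(state, feats[[l]], guide(l, feats[[l]])))
    }
    state <- dc(dc(state, sprintf("d%d", 2L * stage - 1L)),
                sprintf("d%d", 2L * stage))
  }
  state <- dc(state, "d9")
  ad_conv3(state, p[["d10.k"]], p[["d10.b"]])  # logits, no activation
}

# Episode loss graph: support prototypes per class, then pixel-mean BCE
# over the C x K query maps, averaged with the 1/(C*K) normalisation.
fv_episode_loss <- function(p, cfg, episode, ablate_guidance = FALSE) {
  levels <- if (cfg$variant == "upgraded") 1:5 else 5L
  terms <- list()
  for (cl in episode$classes) {
    protos <- fv_support_prototypes(p, cfg, cl$support, levels)
    for (q in cl$query) {
      logits <- fv_forward_query(p, cfg, q$patch, protos, ablate_guidance)
      terms[[length(terms) + 1L]] <-
        ad_bce_logits(logits, as_cube((q$mask > 0.5) * 1))
    }
  }
  ad_mean_scalars(terms)
}

# Numeric per-level prototype vectors for a support set (no gradients).
# Evaluation loops compute these once per support set and reuse them
# across many query patches.
fv_prototype_values <- function(weights, cfg, support) {
  tp_begin()
  on.exit(tp_end())
  p <- fv_param_nodes(weights)
  levels <- if (cfg$variant == "upgraded") 1:5 else 5L
  protos <- fv_support_prototypes(p, cfg, support, levels)
  lapply(protos, function(n) if (is.null(n)) NULL else n$v)
}

# Forward pass from precomputed prototype vectors.
fv_predict_cached <- function(weights, cfg, query_patch, proto_values,
                              ablate_guidance = FALSE) {
  force(proto_values)  # evaluate any helper-opened tape before ours
  tp_begin()
  on.exit(tp_end())
  p <- fv_param_nodes(weights)
  protos <- lapply(proto_values, function(v)
    if (is.null(v)) NULL else tp_const(v))
  logits <- fv_forward_query(p, cfg, query_patch, protos, ablate_guidance)
  fv_sigmoid(logits$v[, , 1])
}

#' Segment a query patch guided by a support set
#'
#' Runs one forward pass of the configured variant: support features are
#' mask-average-pooled into class prototypes, which guide the decoding of
#' the query patch into a per-pixel vessel probability map.
#'
#' @param weights named weight list (see \code{\link{fv_init_weights}}).
#' @param cfg an \code{\link{fv_model_config}}.
#' @param query_patch side x side matrix (side divisible by 16).
#' @param support list of support members, each with \code{patch} and
#'   \code{mask}.
#' @param ablate_guidance zero the shallow (l < 5) guidance maps of the
#'   upgraded variant; ignored for the baseline.
#' @return side x side matrix of vessel probabilities in [0, 1].
#' @export
fv_predict_patch <- function(weights, cfg, query_patch, support,
                             ablate_guidance = FALSE) {
  fv_predict_cached(weights, cfg, query_patch,
                    fv_prototype_values(weights, cfg, support),
                    ablate_guidance)
}
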