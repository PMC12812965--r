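#' 3D feature map container
#'
#' Channels-first activation tensor (C x D x H x W) emitted by the volumetric
#' encoder and consumed by the cross-modal fusion layer.
#'
#' @param tensor 4D numeric array with dims (channels, depth, height, width).
#' @param patient_id patient identifier string.
#' @return An object of class `feature_map3d`.
#' @export
feature_map3d <- function(tensor, patient_id = "unknown") {
  assert_that(is.array(tensor) && length(dim(tensor)) == 4,
              "feature map must be a 4D array", "gliofuse_dimension_error")
  assert_that(all(dim(tensor) >= 1), "all feature-map dims must be >= 1",
              "gliofuse_dimension_error")
  assert_that(all(is.finite(tensor)), "feature map contains non-finite values",
              "gliofuse_value_error")
  structure(list(tensor = tensor, patient_id = as.character(patient_id)),
            class = "feature_map3d")
}

#' @export
print.feature_map3d <- function(x, ...) {
  cat(sprintf("<feature_map3d> %s  %s\n", x$patient_id,
              paste(dim(x$tensor), collapse = "x")))
  invisible(x)
}

#' Volumetric encoder configuration
#'
#' A densely connected 3D convolutional encoder: a 7x7x7 stride-2 stem with
#' 3x3x3 stride-2 max pooling, `length(block_layers)` dense blocks separated
#' by compressing transition layers (1x1x1 convolution halving the channels,
#' then 2x2x2 average pooling), and a final stage of adaptive average pooling
#' to `pooled_side^3` followed by a 1x1x1 convolution to `out_channels`.
#' Within a dense block every layer applies batch-norm -> ReLU -> 3x3x3
#' convolution emitting `growth_rate` channels, consuming the concatenation of
#' all previous feature maps.
#'
#' @param block_layers integer vector, layers per dense block
#'   (default `c(6, 12, 24, 16)`).
#' @param growth_rate channels added by each dense layer (default 32).
#' @param init_channels stem output channels (default 64).
#' @param dropout dropout rate applied after each dense block during training
#'   (default 0.2; inactive in eval mode).
#' @param pooled_side spatial side of the output grid (default 7).
#' @param out_channels channels of the output feature map (default 256).
#' @param seed RNG seed for He-normal weight initialization.
#' @return An object of class `densenet_config`.
#' @export
densenet_config <- function(block_layers = c(6L, 12L, 24L, 16L),
                            growth_rate = 32L, init_channels = 64L,
                            dropout = 0.2, pooled_side = 7L,
                            out_channels = 256L, seed = 42L) {
  assert_that(length(block_layers) >= 1 && all(block_layers >= 0),
              "block_layers must be a non-empty vector of counts >= 0")
  assert_that(growth_rate >= 1, "growth_rate must be >= 1")
  assert_that(pooled_side >= 1, "pooled_side must be >= 1")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(block_layers = as.integer(block_layers),
                 growth_rate = as.integer(growth_rate),
                 init_channels = as.integer(init_channels),
                 dropout = dropout, pooled_side = as.integer(pooled_side),
                 out_channels = as.integer(out_channels),
                 seed = as.integer(seed)),
            class = "densenet_config")
}

#' Desk-scale volumetric encoder preset
#'
#' Two blocks of two layers, growth rate 8, 32 output channels on a 2^3 grid:
#' sized for side-16 synthetic volumes and second-scale CPU tests.
#'
#' @param seed RNG seed for weight initialization.
#' @return A [densenet_config].
#' @export
tiny_densenet_config <- function(seed = 42L) {
  densenet_config(block_layers = c(2L, 2L), growth_rate = 8L,
                  init_channels = 16L, dropout = 0, pooled_side = 2L,
                  out_channels = 32L, seed = seed)
}

bn_params <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

# He-normal conv weights: fan_in = Cin * k^3.
conv_params <- function(cout, cin, k) {
  list(w = he_normal(c(cout, cin, k, k, k), fan_in = cin * k^3),
       b = rep(0, cout))
}

#' Initialize the volumetric encoder
#'
#' Builds the full weight set (He-normal, seeded) for the encoder described
#' by `cfg`.
#'
#' @param cfg a [densenet_config].
#' @return An object of class `mri_encoder` holding config and weights.
#' @export
init_mri_encoder <- function(cfg = densenet_config()) {
  with_seed(cfg$seed, {
    stem <- list(conv = conv_params(cfg$init_channels, 1L, 7L),
                 bn = bn_params(cfg$init_channels))
    ch <- cfg$init_channels
    blocks <- list()
    transitions <- list()
    for (b in seq_along(cfg$block_layers)) {
      layers <- list()
      L <- cfg$block_layers[b]
      if (L > 0) for (l in seq_len(L)) {
        layers[[l]] <- list(bn = bn_params(ch),
                            conv = conv_params(cfg$growth_rate, ch, 3L))
        ch <- ch + cfg$growth_rate
      }
      blocks[[b]] <- layers
      if (b < length(cfg$block_layers)) {
        ch_out <- ch %/% 2L  # compression 0.5
        transitions[[b]] <- list(bn = bn_params(ch),
                                 conv = conv_params(ch_out, ch, 1L))
        ch <- ch_out
      }
    }
    final <- list(bn = bn_params(ch),
                  conv = conv_params(cfg$out_channels, ch, 1L))
    structure(list(cfg = cfg, stem = stem, blocks = blocks,
                   transitions = transitions, final = final,
                   final_in_channels = ch),
              class = "mri_encoder")
  })
}

dense_layer_fwd <- function(x, layer) {
  h <- batchnorm3d(x, layer$bn$gamma, layer$bn$beta)
  h <- relu(h)
  conv3d(h, layer$conv$w, layer$conv$b, stride = 1L, pad = 1L)
}

#' Forward pass through one dense block
#'
#' Each layer consumes the channel-wise concatenation of the block input and
#' all previous layer outputs and emits `growth_rate` new channels, so a block
#' of L layers grows the channel count from c0 to c0 + L * growth_rate at
#' unchanged spatial size. An empty block (L = 0) is the identity.
#'
#' @param input a [feature_map3d].
#' @param layers number of dense layers L (used when `weights` is `NULL`).
#' @param growth_rate channels emitted per layer k (used when `weights` is
#'   `NULL`).
#' @param weights optional pre-built list of layer weights (as stored in an
#'   [init_mri_encoder] block); when `NULL`, seeded He-normal weights are
#'   created.
#' @param seed RNG seed for ad-hoc weight creation.
#' @return A [feature_map3d] with `c0 + L * growth_rate` channels. The
#'   channel count after each layer is attached as attribute
#'   `"channel_trajectory"`.
#' @export
dense_block_forward <- function(input, layers, growth_rate, weights = NULL,
                                seed = 42L) {
  x <- input$tensor
  c0 <- dim(x)[1]
  if (is.null(weights)) {
    weights <- with_seed(seed, {
      ch <- c0
      lapply(seq_len(layers), function(l) {
        w <- list(bn = bn_params(ch), conv = conv_params(growth_rate, ch, 3L))
        ch <<- ch + growth_rate
        w
      })
    })
  }
  traj <- c0
  for (layer in weights) {
    new <- dense_layer_fwd(x, layer)
    x <- abind_channels(x, new)
    traj <- c(traj, dim(x)[1])
  }
  out <- feature_map3d(x, input$patient_id)
  attr(out, "channel_trajectory") <- traj
  out
}

# Channel-wise concatenation of two (C,D,H,W) arrays.
abind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

transition_fwd <- function(x, tr) {
  h <- batchnorm3d(x, tr$bn$gamma, tr$bn$beta)
  h <- relu(h)
  h <- conv3d(h, tr$conv$w, tr$conv$b, stride = 1L, pad = 0L)
  pool3d(h, k = 2L, stride = 2L, type = "avg")
}

#' Trace encoder shapes without running it
#'
#' Propagates the (channels, spatial side) bookkeeping through every stage of
#' the encoder arithmetically: the stem halves the side twice, each dense
#' layer adds `growth_rate` channels, each transition halves the channels
#' (floor) and the side, and the final stage emits
#' `out_channels x pooled_side^3`.
#'
#' @param cfg a [densenet_config].
#' @param input_side input cube side in voxels.
#' @return A data.frame with one row per stage (`stage`, `channels`, `side`);
#'   the final row is the output shape.
#' @export
encoder_shape_trace <- function(cfg, input_side) {
  rows <- list()
  side <- conv_out_len(input_side, 7L, 2L, 3L)
  side <- conv_out_len(side, 3L, 2L, 1L)
  ch <- cfg$init_channels
  rows[[1]] <- data.frame(stage = "stem", channels = ch, side = side)
  for (b in seq_along(cfg$block_layers)) {
    ch <- ch + cfg$block_layers[b] * cfg$growth_rate
    rows[[length(rows) + 1]] <-
      data.frame(stage = sprintf("block%d", b), channels = ch, side = side)
    if (b < length(cfg$block_layers)) {
      ch <- ch %/% 2L
      side <- side %/% 2L
      rows[[length(rows) + 1]] <-
        data.frame(stage = sprintf("transition%d", b), channels = ch,
                   side = side)
    }
  }
  rows[[length(rows) + 1]] <-
    data.frame(stage = "output", channels = cfg$out_channels,
               side = cfg$pooled_side)
  out <- do.call(rbind, rows)
  if (any(out$side < 1)) {
    min_side <- min_input_side(cfg)
    stop_gliofuse(sprintf(
      "input side %d too small for this encoder; minimum is %d voxels",
      input_side, min_side), "gliofuse_size_error")
  }
  out
}

# Smallest input side for which every stage keeps >= 1 voxel per axis.
min_input_side <- function(cfg) {
  n_trans <- length(cfg$block_layers) - 1L
  side <- 8L
  repeat {
    ok <- tryCatch({
      s <- conv_out_len(side, 7L, 2L, 3L)
      s <- conv_out_len(s, 3L, 2L, 1L)
      for (i in seq_len(n_trans)) s <- s %/% 2L
      s >= 1
    }, error = function(e) FALSE)
    if (ok) return(side)
    side <- side + 1L
  }
}

#' Encode an MRI volume into a spatial feature map
#'
#' Runs the full volumetric encoder forward pass: stem, dense blocks with
#' transitions, then adaptive average pooling to `pooled_side^3` and a 1x1x1
#' projection to `out_channels`. Deterministic given fixed weights and input
#' (dropout is inactive in eval mode).
#'
#' @param volume a preprocessed [volume_image] (cubic grid).
#' @param encoder an [init_mri_encoder] model.
#' @param training logical; enables post-block dropout.
#' @return A [feature_map3d] of shape `out_channels x pooled_side^3`, with the
#'   per-stage channel counts attached as attribute `"stage_channels"`.
#' @export
encode_mri <- function(volume, encoder, training = FALSE) {
  cfg <- encoder$cfg
  d <- dim(volume$data)
  assert_that(length(unique(d)) == 1,
              "encode_mri expects a cubic (preprocessed) volume",
              "gliofuse_dimension_error")
  encoder_shape_trace(cfg, d[1])  # raises a size error if too small
  x <- array(volume$data, dim = c(1, d))
  x <- conv3d(x, encoder$stem$conv$w, encoder$stem$conv$b,
              stride = 2L, pad = 3L)
  x <- relu(batchnorm3d(x, encoder$stem$bn$gamma, encoder$stem$bn$beta))
  x <- pool3d(x, k = 3L, stride = 2L, pad = 1L, type = "max")
  stage_channels <- c(stem = dim(x)[1])
  for (b in seq_along(encoder$blocks)) {
    fm <- dense_block_forward(feature_map3d(x, volume$id),
                              layers = length(encoder$blocks[[b]]),
                              growth_rate = cfg$growth_rate,
                              weights = encoder$blocks[[b]])
    x <- fm$tensor
    x <- dropout_tensor(x, cfg$dropout, training)
    stage_channels[sprintf("block%d", b)] <- dim(x)[1]
    if (b < length(encoder$blocks)) {
      x <- transition_fwd(x, encoder$transitions[[b]])
      stage_channels[sprintf("transition%d", b)] <- dim(x)[1]
    }
  }
  x <- relu(batchnorm3d(x, encoder$final$bn$gamma, encoder$final$bn$beta))
  x <- adaptive_avg_pool3d(x, cfg$pooled_side)
  x <- conv3d(x, encoder$final$conv$w, encoder$final$conv$b)
  out <- feature_map3d(x, volume$id)
  attr(out, "stage_channels") <- stage_channels
  out
}

#' Save / load model checkpoints
#'
#' Checkpoints are single-file RDS containers with a `version` field, holding
#' the model class, its configuration and all weights.
#'
#' @param model any gliofuse model object (encoder, fusion block, head, or a
#'   trained pipeline model).
#' @param path checkpoint file path.
#' @return `path` invisibly (save); the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = 1L, class = class(model), model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  assert_that(identical(obj$version, 1L),
              sprintf("unsupported checkpoint version: %s", obj$version),
              "gliofuse_value_error")
  obj$model
}
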