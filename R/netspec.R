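#' Network architecture configuration
#'
#' Describes the dual-path (or single-path) 3-D CNN. Each encoding path
#' applies, per level, two 3x3x3 same-padded convolutions with ReLU, a
#' dropout layer between the convolutions, and a 2x2x2 max-pooling; filter
#' counts double after each pooling. The paths' final feature blocks are
#' flattened, concatenated and fed to three fully connected layers with
#' dropout after the first two, ending in a softmax over the two grades.
#'
#' @param path_filters length-2 integer: first-level filter counts for the
#'   T1-CE and FLAIR encoding paths. The asymmetric default is `c(18, 2)`;
#'   the symmetric comparison variant is `c(10, 10)`.
#' @param levels encoder depth (number of conv-conv-pool blocks), default 3.
#' @param dropout_rate dropout probability (default 0.3).
#' @param fc_widths widths of the three fully connected layers; the last
#'   must equal `n_classes`. Default `c(256, 64, 2)`.
#' @param input_shape voxels per axis of the network input ROI; every axis
#'   must be divisible by `2^levels`.
#' @param n_classes number of output classes (2).
#' @param mode `"dual_path"` or `"single_path"`.
#' @param single_path_channels for single-path mode, which channels feed the
#'   one encoder: `"T1CE"`, `"FLAIR"` or `"both"`.
#' @param single_path_filters first-level filter count of the single-path
#'   encoder; defaults to `sum(path_filters)` (capacity parity with the
#'   dual-path net's first level).
#' @return a `net_config` object.
#' @export
net_config <- function(path_filters = c(18L, 2L), levels = 3L,
                       dropout_rate = 0.3, fc_widths = c(256L, 64L, 2L),
                       input_shape = c(64L, 64L, 64L), n_classes = 2L,
                       mode = c("dual_path", "single_path"),
                       single_path_channels = c("T1CE", "FLAIR", "both"),
                       single_path_filters = NULL) {
  mode <- match.arg(mode)
  single_path_channels <- match.arg(single_path_channels)
  path_filters <- as.integer(path_filters)
  levels <- as.integer(levels)
  input_shape <- as.integer(input_shape)
  if (length(input_shape) == 1L) input_shape <- rep(input_shape, 3L)
  if (mode == "dual_path" && (length(path_filters) != 2L ||
                              any(path_filters < 1L)))
    stop("net_config: dual_path needs two filter counts >= 1")
  if (levels < 1L) stop("net_config: levels must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("net_config: dropout_rate must be in [0, 1)")
  fc_widths <- as.integer(fc_widths)
  if (utils::tail(fc_widths, 1) != n_classes)
    stop("net_config: last fully connected width must equal n_classes")
  if (any(input_shape %% (2L^levels) != 0L))
    stop("net_config: input_shape must be divisible by 2^levels ",
         "on every axis (got ", paste(input_shape, collapse = "x"),
         " with ", levels, " levels)")
  if (is.null(single_path_filters)) single_path_filters <- sum(path_filters)
  structure(list(path_filters = path_filters, levels = levels,
                 kernel = c(3L, 3L, 3L), pool = c(2L, 2L, 2L),
                 dropout_rate = dropout_rate, fc_widths = fc_widths,
                 input_shape = input_shape, n_classes = as.integer(n_classes),
                 mode = mode, single_path_channels = single_path_channels,
                 single_path_filters = as.integer(single_path_filters)),
            class = "net_config")
}

#' Per-level filter counts for each encoding path
#'
#' Level `l` (0-based) holds `first_level * 2^l` filters: the channel count
#' doubles after each max-pooling. In dual-path mode the two paths are
#' allocated independently, so an 18:2 first level yields `[18, 36, 72]`
#' and `[2, 4, 8]` at depth 3.
#'
#' @param config a [net_config()].
#' @return a named list of integer vectors, one per path (`t1ce`/`flair`
#'   in dual mode, `single` otherwise).
#' @export
filter_allocation <- function(config) {
  stopifnot(inherits(config, "net_config"))
  grow <- function(f0) as.integer(f0 * 2L^(0:(config$levels - 1L)))
  if (config$mode == "dual_path")
    list(t1ce = grow(config$path_filters[1]),
         flair = grow(config$path_filters[2]))
  else
    list(single = grow(config$single_path_filters))
}

#' Glorot (Xavier) initialization standard deviation
#'
#' `sqrt(2 / (fan_in + fan_out))`, the nominal SD of the truncated normal
#' the weights are drawn from. For a convolution the fans are channel counts
#' times the kernel volume.
#'
#' @param fan_in,fan_out positive unit counts of the weight tensor.
#' @return the standard deviation.
#' @export
glorot_std <- function(fan_in, fan_out) {
  if (!is.finite(fan_in) || !is.finite(fan_out) || fan_in <= 0 ||
      fan_out <= 0)
    stop("glorot_std: fans must be positive")
  sqrt(2 / (fan_in + fan_out))
}

## SD shrinkage of a normal truncated at +/- 2 nominal SDs:
## Var = sigma^2 * (1 - 2*a*phi(a) / (2*Phi(a) - 1)) with a = 2.
TRUNC2_SD_FACTOR <- local({
  a <- 2
  sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1))
})

## number of input channels entering the (first conv of the) network
input_channels <- function(config) {
  if (config$mode == "dual_path") c(t1ce = 1L, flair = 1L)
  else c(single = if (config$single_path_channels == "both") 2L else 1L)
}

encoder_layers <- function(path, in_ch, filters, shape, dropout) {
  layers <- list()
  kvol <- 27L
  for (l in seq_along(filters)) {
    f <- filters[l]
    conv <- function(ci, co, tag) {
      list(name = sprintf("%s_l%d_%s", path, l, tag), kind = "conv3d",
           in_channels = ci, out_channels = co,
           fan_in = ci * kvol, fan_out = co * kvol, shape = shape)
    }
    layers <- c(layers, list(
      conv(in_ch, f, "conv1"),
      list(name = sprintf("%s_l%d_relu1", path, l), kind = "relu"),
      list(name = sprintf("%s_l%d_drop", path, l), kind = "dropout",
           rate = dropout),
      conv(f, f, "conv2"),
      list(name = sprintf("%s_l%d_relu2", path, l), kind = "relu"),
      list(name = sprintf("%s_l%d_pool", path, l), kind = "maxpool3d",
           in_shape = shape, out_shape = shape %/% 2L)
    ))
    if (any(shape %% 2L != 0L) || any(shape %/% 2L < 1L))
      stop("build_network: pooling underflow at level ", l,
           " (shape ", paste(shape, collapse = "x"), ")")
    shape <- shape %/% 2L
    in_ch <- f
  }
  list(layers = layers, out_shape = shape, out_channels = in_ch)
}

#' Build the ordered layer list of the network
#'
#' Expands a [net_config()] into an explicit sequence of layer
#' specifications with channel/width chaining, spatial shapes and
#' initialization fans, suitable both for audit and for instantiating
#' weights.
#'
#' @param config a [net_config()].
#' @return a `net_arch` object: list with `layers`, `feature_length`
#'   (flattened concatenated encoder output), and the originating `config`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "net_config"))
  alloc <- filter_allocation(config)
  inch <- input_channels(config)
  shape0 <- config$input_shape
  if (any(shape0 %/% (2L^config$levels) < 1L))
    stop("build_network: input too small for ", config$levels, " levels")
  encs <- mapply(function(path, f, ci) {
    encoder_layers(path, ci, f, shape0, config$dropout_rate)
  }, names(alloc), alloc, inch[names(alloc)], SIMPLIFY = FALSE)
  layers <- list()
  feat_len <- 0L
  for (p in names(encs)) {
    layers <- c(layers, encs[[p]]$layers)
    flat <- as.integer(prod(encs[[p]]$out_shape) * encs[[p]]$out_channels)
    layers <- c(layers, list(list(name = paste0(p, "_flatten"),
                                  kind = "flatten", out_width = flat)))
    feat_len <- feat_len + flat
  }
  if (config$mode == "dual_path")
    layers <- c(layers, list(list(name = "concat", kind = "concat",
                                  out_width = feat_len)))
  widths <- c(feat_len, config$fc_widths)
  nfc <- length(config$fc_widths)
  for (i in seq_len(nfc)) {
    layers <- c(layers, list(list(
      name = paste0("fc", i), kind = "dense",
      in_width = widths[i], out_width = widths[i + 1],
      fan_in = widths[i], fan_out = widths[i + 1])))
    if (i < nfc)
      layers <- c(layers, list(list(name = paste0("fc", i, "_drop"),
                                    kind = "dropout",
                                    rate = config$dropout_rate)))
  }
  layers <- c(layers, list(list(name = "softmax", kind = "softmax")))
  structure(list(layers = layers, feature_length = feat_len,
                 config = config,
                 encoder_out = lapply(encs, function(e)
                   list(shape = e$out_shape, channels = e$out_channels))),
            class = "net_arch")
}

layer_param_count <- function(ly) {
  if (ly$kind == "conv3d") ly$in_channels * 27L * ly$out_channels +
    ly$out_channels
  else if (ly$kind == "dense") ly$in_width * ly$out_width + ly$out_width
  else 0L
}

#' @export
print.net_arch <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Human-readable architecture summary table
#' @param x a `net_arch`.
#' @param ... unused.
#' @export
format.net_arch <- function(x, ...) {
  rows <- vapply(x$layers, function(ly) {
    shape <- if (!is.null(ly$shape)) paste(ly$shape, collapse = "x")
             else if (!is.null(ly$out_width)) as.character(ly$out_width)
             else ""
    sprintf("%-18s %-10s %8s %10.0f", ly$name, ly$kind, shape,
            layer_param_count(ly))
  }, character(1))
  c(sprintf("%-18s %-10s %8s %10s", "layer", "kind", "shape", "params"),
    rows,
    sprintf("total parameters: %.0f",
            sum(vapply(x$layers, layer_param_count, numeric(1)))))
}
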