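## Network instantiation and the forward/backward execution engine.
## Activations live as C x (N*B) matrices (N voxels per sample, B samples,
## voxel order x-fastest), convolutions run as im2col + GEMM in C++,
## everything else is plain R linear algebra. All stochasticity (weight
## init, dropout masks) flows through R's global RNG so a single set.seed
## makes runs reproducible.

## truncated normal on +/- 2 nominal SDs via inverse-CDF sampling
rtruncnorm2 <- function(n, sd) {
  lo <- stats::pnorm(-2)
  hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

weighted_layers <- function(arch) {
  Filter(function(ly) ly$kind %in% c("conv3d", "dense"), arch$layers)
}

#' Instantiate network weights
#'
#' Draws every conv kernel and dense matrix from a zero-centred truncated
#' normal (truncation at two nominal SDs) with Glorot SD
#' `sqrt(2/(fan_in+fan_out))`; biases start at zero. Uses the current R RNG
#' state: call `set.seed()` first for reproducibility.
#'
#' @param arch a `net_arch` from [build_network()], or a [net_config()].
#' @return a `cnn_model`: list with `arch` and `params` (per weighted layer,
#'   `W` and `b`). Conv weights are `out_channels x (in_channels*27)`
#'   matrices; dense weights are `out_width x in_width`.
#' @export
init_model <- function(arch) {
  if (inherits(arch, "net_config")) arch <- build_network(arch)
  stopifnot(inherits(arch, "net_arch"))
  params <- list()
  for (ly in weighted_layers(arch)) {
    sd <- glorot_std(ly$fan_in, ly$fan_out)
    if (ly$kind == "conv3d") {
      W <- matrix(rtruncnorm2(ly$out_channels * ly$in_channels * 27L, sd),
                  nrow = ly$out_channels)
      b <- numeric(ly$out_channels)
    } else {
      W <- matrix(rtruncnorm2(ly$out_width * ly$in_width, sd),
                  nrow = ly$out_width)
      b <- numeric(ly$out_width)
    }
    params[[ly$name]] <- list(W = W, b = b)
  }
  structure(list(arch = arch, params = params), class = "cnn_model")
}

## split a batch of ROI arrays [dx,dy,dz,2] into per-path C x (N*B) matrices
batch_to_paths <- function(xlist, config) {
  b <- length(xlist)
  ch_mat <- function(channels) {
    do.call(cbind, lapply(xlist, function(a) {
      m <- matrix(0, nrow = length(channels), ncol = prod(dim(a)[1:3]))
      for (i in seq_along(channels)) m[i, ] <- as.vector(a[, , , channels[i]])
      m
    }))
  }
  if (config$mode == "dual_path") {
    list(t1ce = ch_mat(1L), flair = ch_mat(2L))
  } else {
    chans <- switch(config$single_path_channels,
                    T1CE = 1L, FLAIR = 2L, both = c(1L, 2L))
    list(single = ch_mat(chans))
  }
}

dropout_mask <- function(n, rate) {
  if (rate <= 0) return(NULL)
  (stats::runif(n) >= rate) / (1 - rate)
}

## forward pass through one encoder path; returns output + caches for backprop
path_forward <- function(path, params, X, dims, nb, dropout_rate, training) {
  caches <- list()
  filters <- path$filters
  for (l in seq_along(filters)) {
    cache <- list(dims = dims)
    nm1 <- sprintf("%s_l%d_conv1", path$name, l)
    K1 <- im2col3d(X, dims, nb)
    Z1 <- params[[nm1]]$W %*% K1 + params[[nm1]]$b
    R1 <- Z1 > 0
    A1 <- Z1 * R1
    D <- if (training) dropout_mask(length(A1), dropout_rate) else NULL
    if (!is.null(D)) A1 <- A1 * D
    nm2 <- sprintf("%s_l%d_conv2", path$name, l)
    K2 <- im2col3d(A1, dims, nb)
    Z2 <- params[[nm2]]$W %*% K2 + params[[nm2]]$b
    R2 <- Z2 > 0
    A2 <- Z2 * R2
    pool <- maxpool3d_fwd(A2, dims, nb)
    cache$K1 <- K1; cache$R1 <- R1; cache$D <- D
    cache$K2 <- K2; cache$R2 <- R2; cache$argmax <- pool$argmax
    caches[[l]] <- cache
    X <- pool$values
    dims <- dims %/% 2L
  }
  list(out = X, dims = dims, caches = caches)
}

path_backward <- function(path, params, dX, fwd, nb) {
  grads <- list()
  for (l in rev(seq_along(path$filters))) {
    cache <- fwd$caches[[l]]
    dims <- cache$dims
    dA2 <- maxpool3d_bwd(dX, cache$argmax, dims, nb)
    dZ2 <- dA2 * cache$R2
    nm2 <- sprintf("%s_l%d_conv2", path$name, l)
    grads[[nm2]] <- list(W = dZ2 %*% t(cache$K2), b = rowSums(dZ2))
    dA1 <- col2im3d(t(params[[nm2]]$W) %*% dZ2, nrow(cache$R1), dims, nb)
    if (!is.null(cache$D)) dA1 <- dA1 * cache$D
    dZ1 <- dA1 * cache$R1
    nm1 <- sprintf("%s_l%d_conv1", path$name, l)
    grads[[nm1]] <- list(W = dZ1 %*% t(cache$K1), b = rowSums(dZ1))
    dX <- col2im3d(t(params[[nm1]]$W) %*% dZ1,
                   ncol(params[[nm1]]$W) %/% 27L, dims, nb)
  }
  grads
}

path_descr <- function(config) {
  alloc <- filter_allocation(config)
  lapply(names(alloc), function(nm) list(name = nm, filters = alloc[[nm]]))
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

## full forward pass; returns probabilities (n_classes x B) and caches
nn_forward <- function(model, xlist, training = FALSE) {
  config <- model$arch$config
  params <- model$params
  nb <- length(xlist)
  dims0 <- as.integer(dim(xlist[[1]])[1:3])
  if (!all(dims0 == config$input_shape))
    stop("nn_forward: ROI shape ", paste(dims0, collapse = "x"),
         " does not match config input_shape ",
         paste(config$input_shape, collapse = "x"))
  inputs <- batch_to_paths(xlist, config)
  paths <- path_descr(config)
  fwd <- list()
  feats <- list()
  for (p in paths) {
    f <- path_forward(p, params, inputs[[p$name]], dims0, nb,
                      config$dropout_rate, training)
    fwd[[p$name]] <- f
    # flatten per sample: channel fastest within voxel, sample blocks contig
    P <- prod(f$dims)
    feats[[p$name]] <- matrix(f$out, nrow = nrow(f$out) * P, ncol = nb)
  }
  Fmat <- do.call(rbind, feats)
  nfc <- length(config$fc_widths)
  fc_cache <- list()
  A <- Fmat
  for (i in seq_len(nfc)) {
    nm <- paste0("fc", i)
    Z <- params[[nm]]$W %*% A + params[[nm]]$b
    D <- NULL
    if (i < nfc && training) {
      D <- dropout_mask(length(Z), config$dropout_rate)
      if (!is.null(D)) Z <- Z * D
    }
    fc_cache[[i]] <- list(input = A, D = D)
    A <- Z
  }
  probs <- softmax_cols(A)
  list(probs = probs, logits = A, fc_cache = fc_cache, fwd = fwd,
       inputs = inputs, feats = feats, dims0 = dims0, nb = nb)
}

## backward pass from softmax cross-entropy; y is 0/1 (1 = Grade II)
nn_backward <- function(model, fw, y) {
  config <- model$arch$config
  params <- model$params
  nb <- fw$nb
  Y <- rbind(1 - y, y)
  dZ <- (fw$probs - Y) / nb
  grads <- list()
  nfc <- length(config$fc_widths)
  for (i in rev(seq_len(nfc))) {
    nm <- paste0("fc", i)
    cache <- fc_cache_get(fw, i)
    if (!is.null(cache$D)) dZ <- dZ * cache$D
    grads[[nm]] <- list(W = dZ %*% t(cache$input), b = rowSums(dZ))
    dZ <- t(params[[nm]]$W) %*% dZ
  }
  # split feature gradient back into paths
  offset <- 0L
  paths <- path_descr(config)
  for (p in paths) {
    f <- fw$fwd[[p$name]]
    C <- nrow(f$out); P <- prod(f$dims)
    len <- C * P
    dF <- dZ[(offset + 1):(offset + len), , drop = FALSE]
    offset <- offset + len
    dOut <- matrix(dF, nrow = C)
    pg <- path_backward(p, params, dOut, f, nb)
    grads <- c(grads, pg)
  }
  grads
}

fc_cache_get <- function(fw, i) fw$fc_cache[[i]]

## mean cross-entropy of a probability matrix (n_classes x B) vs labels 0/1
cross_entropy <- function(probs, y) {
  p <- pmax(probs[cbind(y + 1L, seq_along(y))], 1e-12)
  -mean(log(p))
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[slot]]
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] +
        (1 - beta2) * g^2
      mhat <- state$m[[nm]][[slot]] / bc1
      vhat <- state$v[[nm]][[slot]] / bc2
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Predict grade probabilities for one ROI
#'
#' Deterministic inference (dropout disabled). The second element is the
#' Grade II probability.
#'
#' @param model a `cnn_model`.
#' @param roi a `roi_tensor` or a 4-D array shaped like the config's
#'   `input_shape` with 2 channels.
#' @return named numeric `c(I = ., II = .)` summing to 1.
#' @export
predict_roi <- function(model, roi) {
  a <- if (inherits(roi, "roi_tensor")) roi$values else roi
  fw <- nn_forward(model, list(a), training = FALSE)
  p <- as.vector(fw$probs)
  names(p) <- c("I", "II")
  p
}

## batched eval-mode probabilities of Grade II
predict_batch_p2 <- function(model, xlist) {
  if (length(xlist) == 0) return(numeric(0))
  fw <- nn_forward(model, xlist, training = FALSE)
  as.vector(fw$probs[2, ])
}
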