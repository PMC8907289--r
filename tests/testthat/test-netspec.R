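# Architecture description, initialization, forward contract, and a
# finite-difference check of the backward pass.

test_that("filter_allocation doubles per level and per path", {
  asym <- net_config(path_filters = c(18L, 2L))
  expect_equal(filter_allocation(asym),
               list(t1ce = c(18L, 36L, 72L), flair = c(2L, 4L, 8L)))
  sym <- net_config(path_filters = c(10L, 10L))
  expect_equal(filter_allocation(sym),
               list(t1ce = c(10L, 20L, 40L), flair = c(10L, 20L, 40L)))
  one <- net_config(path_filters = c(1L, 1L), levels = 1L,
                    input_shape = c(8L, 8L, 8L))
  expect_equal(filter_allocation(one), list(t1ce = 1L, flair = 1L))
  # capacity parity at level 1: 18 + 2 = 10 + 10
  expect_equal(sum(vapply(filter_allocation(asym), `[`, integer(1), 1)),
               sum(vapply(filter_allocation(sym), `[`, integer(1), 1)))
})

test_that("build_network propagates shapes against an independent oracle", {
  cfg <- net_config(input_shape = c(64L, 64L, 64L))
  arch <- build_network(cfg)
  # oracle: same-padded convs keep the extent, each pool halves it
  oracle_shape <- function(input, levels) input %/% 2L^levels
  expect_equal(arch$encoder_out$t1ce$shape, oracle_shape(rep(64L, 3), 3))
  expect_equal(arch$encoder_out$flair$shape, oracle_shape(rep(64L, 3), 3))
  expect_equal(arch$encoder_out$t1ce$channels, 72L)
  expect_equal(arch$encoder_out$flair$channels, 8L)
  expect_equal(arch$feature_length, 8^3 * 72 + 8^3 * 8)
  # layer chaining: consecutive convs have compatible channels
  kinds <- vapply(arch$layers, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "conv3d"), 12)    # 2 paths x 3 levels x 2 convs
  expect_equal(sum(kinds == "dense"), 3)
  expect_equal(utils::tail(kinds, 1), "softmax")
  # single-path both-channels: first conv takes 2 input channels
  sp <- build_network(net_config(mode = "single_path",
                                 single_path_channels = "both",
                                 input_shape = c(16L, 16L, 16L), levels = 2L))
  first_conv <- Filter(function(l) l$kind == "conv3d", sp$layers)[[1]]
  expect_equal(first_conv$in_channels, 2L)
  # pooling underflow
  expect_error(net_config(levels = 7L, input_shape = c(64L, 64L, 64L)),
               "divisible")
  expect_gt(length(format(arch)), 10)  # audit table renders
})

test_that("glorot_std matches the closed form and the conv fan oracle", {
  expect_equal(glorot_std(100, 100), 0.1)
  expect_equal(glorot_std(1, 1), 1.0)
  expect_error(glorot_std(0, 5), "positive")
  # conv fans = channels x kernel volume
  cfg <- net_config(path_filters = c(18L, 2L), input_shape = c(8L, 8L, 8L),
                    levels = 1L)
  arch <- build_network(cfg)
  conv2 <- Filter(function(l) l$kind == "conv3d" &&
                    l$name == "t1ce_l1_conv2", arch$layers)[[1]]
  expect_equal(glorot_std(conv2$fan_in, conv2$fan_out),
               sqrt(2 / (18 * 27 + 18 * 27)))
  expect_equal(glorot_std(18 * 27, 36 * 27), sqrt(2 / (18 * 27 + 36 * 27)))
})

test_that("empirical init SD matches glorot_std with truncation shrinkage", {
  # truncation at +/-2 nominal SDs shrinks the SD by a known factor
  shrink <- duopath:::TRUNC2_SD_FACTOR
  expect_equal(shrink, 0.8796, tolerance = 1e-3)
  cfg <- net_config(path_filters = c(18L, 2L), input_shape = c(16L, 16L, 16L),
                    levels = 2L, fc_widths = c(256L, 64L, 2L))
  set.seed(61)
  model <- init_model(cfg)
  w <- model$params[["fc1"]]$W            # > 1e5 weights
  expect_gt(length(w), 1e5)
  ly <- Filter(function(l) !is.null(l$name) && l$name == "fc1",
               model$arch$layers)[[1]]
  nominal <- glorot_std(ly$fan_in, ly$fan_out)
  expect_lt(abs(stats::sd(w) - nominal * shrink) / (nominal * shrink), 0.05)
  expect_true(all(abs(w) <= 2 * nominal))  # hard truncation bound
  expect_true(all(model$params[["fc1"]]$b == 0))
})

test_that("predict_roi yields normalized, deterministic probabilities", {
  cfg <- net_config(path_filters = c(4L, 2L), levels = 2L,
                    input_shape = c(8L, 8L, 8L), fc_widths = c(16L, 8L, 2L))
  set.seed(62)
  model <- init_model(cfg)
  roi <- array(rnorm(8 * 8 * 8 * 2), dim = c(8, 8, 8, 2))
  p <- predict_roi(model, roi)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_named(p, c("I", "II"))
  # inference is dropout-free: duplicate input -> identical output
  expect_identical(p, predict_roi(model, roi))
  # shape mismatch
  expect_error(predict_roi(model, array(0, c(4, 4, 4, 2))), "shape")
  # init symmetry: mean Grade-II probability near 1/2 on random inputs
  set.seed(63)
  p2 <- vapply(1:100, function(i)
    predict_roi(model, array(rnorm(1024), dim = c(8, 8, 8, 2)))["II"],
    numeric(1))
  expect_gt(mean(p2), 0.3)
  expect_lt(mean(p2), 0.7)
})

test_that("backward pass agrees with finite differences", {
  cfg <- net_config(path_filters = c(3L, 2L), levels = 1L,
                    fc_widths = c(5L, 2L), input_shape = c(4L, 4L, 4L),
                    dropout_rate = 0)
  set.seed(64)
  model <- init_model(cfg)
  x <- list(array(rnorm(128), dim = c(4, 4, 4, 2)),
            array(rnorm(128), dim = c(4, 4, 4, 2)))
  y <- c(0L, 1L)
  fw <- duopath:::nn_forward(model, x, training = FALSE)
  gr <- duopath:::nn_backward(model, fw, y)
  loss_at <- function(params) {
    m2 <- model; m2$params <- params
    f <- duopath:::nn_forward(m2, x, training = FALSE)
    duopath:::cross_entropy(f$probs, y)
  }
  eps <- 1e-6
  for (nm in names(gr)) for (slot in c("W", "b")) {
    n_par <- length(model$params[[nm]][[slot]])
    for (i in sample(n_par, min(3, n_par))) {
      p <- model$params
      p[[nm]][[slot]][i] <- p[[nm]][[slot]][i] + eps
      up <- loss_at(p)
      p[[nm]][[slot]][i] <- p[[nm]][[slot]][i] - 2 * eps
      dn <- loss_at(p)
      num <- (up - dn) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][[slot]][i]) /
                  max(1e-6, abs(num) + abs(gr[[nm]][[slot]][i])), 1e-5)
    }
  }
})

test_that("single-path variants run the same forward contract", {
  for (ch in c("T1CE", "FLAIR", "both")) {
    cfg <- net_config(mode = "single_path", single_path_channels = ch,
                      levels = 1L, input_shape = c(4L, 4L, 4L),
                      fc_widths = c(8L, 2L))
    set.seed(65)
    model <- init_model(cfg)
    p <- predict_roi(model, array(rnorm(128), dim = c(4, 4, 4, 2)))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
})
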