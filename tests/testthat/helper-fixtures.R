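# Shared fixtures: all data is built in code at test time.

# desk-scale phantom: 32^3 grid with proportionally scaled tumor radii
small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(grid_shape = 32L, tumor_radius_range_mm = c(5, 8),
                 seed = seed, ...)
}

# benchmark-scale phantom for training runs (20^3 grid, 12^3 ROI)
bench_phantom_config <- function(seed = 1L, ...) {
  phantom_config(grid_shape = 20L, tumor_radius_range_mm = c(3.5, 5.5),
                 seed = seed, ...)
}

# tiny network for fast training tests
tiny_net_config <- function(...) {
  net_config(levels = 2L, input_shape = c(12L, 12L, 12L),
             fc_widths = c(64L, 16L, 2L), ...)
}

# analytic sphere mask: radius in mm on an isotropic grid
sphere_mask <- function(shape, spacing, radius_mm, role = "MASK") {
  shape <- rep(shape, length.out = 3)
  ctr <- (shape - 1) / 2
  ijk <- as.matrix(expand.grid(0:(shape[1] - 1), 0:(shape[2] - 1),
                               0:(shape[3] - 1)))
  d2 <- rowSums(sweep(ijk, 2, ctr)^2) * spacing^2
  vals <- array(as.numeric(d2 <= radius_mm^2), dim = shape)
  vol3d(vals, spacing = rep(spacing, 3), role = role)
}

# Mann-Whitney AUC by brute-force pairwise comparison (ties count 1/2)
auc_mann_whitney <- function(p, labels) {
  pos <- p[labels == "II"]
  neg <- p[labels == "I"]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# baseline classifier oracle on handcrafted features: intratumoral SD of
# channel 1 and boundary surface-to-volume ratio of the tumor mask
baseline_oracle_auc <- function(subjects) {
  feats <- t(vapply(subjects, function(s) {
    m <- s$t1ce_mask$values
    d <- dim(m)
    shift <- function(a, ax, k) {
      i <- pmin(pmax(seq_len(d[ax]) + k, 1), d[ax])
      if (ax == 1) a[i, , ] else if (ax == 2) a[, i, ] else a[, , i]
    }
    interior <- shift(m, 1, 1) * shift(m, 1, -1) * shift(m, 2, 1) *
      shift(m, 2, -1) * shift(m, 3, 1) * shift(m, 3, -1)
    c(sd = stats::sd(s$t1ce$values[m > 0]),
      sv = sum(m > 0 & interior == 0) / sum(m))
  }, numeric(2)))
  y <- vapply(subjects, function(s) s$grade, character(1))
  fit <- suppressWarnings(stats::glm((y == "II") ~ feats[, 1] + feats[, 2],
                                     family = stats::binomial))
  auc_mann_whitney(stats::fitted(fit), y)
}

# quick subject batch with alternating grades
make_subjects <- function(config, n, grades = NULL) {
  if (is.null(grades))
    grades <- rep(c("I", "II"), length.out = n)
  lapply(seq_len(n), function(i)
    generate_subject(config, grades[i], sprintf("s%03d", i)))
}
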