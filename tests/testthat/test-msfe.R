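test_that("elu matches its closed form", {
  expect_identical(elu(0), 0)
  expect_identical(elu(2.5), 2.5)
  expect_equal(elu(-1), exp(-1) - 1, tolerance = 1e-12)  # ~ -0.63212
  x <- seq(-4, 4, by = 0.01)
  y <- elu(x)
  expect_true(all(diff(y) > 0))                 # monotone
  expect_equal(y[x >= 0], x[x >= 0])            # identity branch
  expect_equal(y[x < 0], exp(x[x < 0]) - 1)     # exponential branch
})

test_that("msfe output shape follows the pooling arithmetic", {
  # default config, 22 channels, T = 1000: floor(floor(1000/8)/7) = 17
  blk <- build_msfe(msfe_config(), C = 22L, seed = 1)
  x <- array(rnorm(22 * 1000), dim = c(22, 1000, 1))
  y <- msfe_forward(blk, x)
  expect_equal(dim(y), c(16, 17, 1))
  # too-short input names the failing pool
  expect_error(msfe_forward(blk, array(0, dim = c(22, 4, 1))), "pool")
  # channel mismatch is a shape error naming C
  expect_error(msfe_forward(blk, array(0, dim = c(3, 1000, 1))), "C=22")
})

test_that("all-zero input stays zero through the block at init", {
  # zero-weight path: batch-norm starts at identity running stats, ELU(0)=0
  blk <- build_msfe(scaled_msfe_config(), C = 3L, seed = 2)
  y <- msfe_forward(blk, array(0, dim = c(3, scaled_T, 2)))
  expect_true(all(y == 0))
})

test_that("msfe is deterministic in inference mode despite dropout config", {
  blk <- build_msfe(scaled_msfe_config(), C = 3L, seed = 3)
  x <- array(rnorm(3 * scaled_T * 2), dim = c(3, scaled_T, 2))
  set.seed(1); y1 <- msfe_forward(blk, x, training = FALSE)
  set.seed(99); y2 <- msfe_forward(blk, x, training = FALSE)
  expect_identical(y1, y2)
  # training mode with dropout differs between RNG states
  set.seed(1); t1 <- msfe_forward(blk, x, training = TRUE)
  set.seed(2); t2 <- msfe_forward(blk, x, training = TRUE)
  expect_false(identical(t1, t2))
})

test_that("branch outputs concatenate independently", {
  ns <- asNamespace("msatnet")
  blk <- build_msfe(msfe_config(branch_kernel_lengths = c(8, 4),
                                n_temporal_filters = 2, pool1_length = 2,
                                pool2_length = 2, fusion_filters = 4,
                                fusion_kernel_length = 3, dropout_p = 0),
                    C = 2L, seed = 4)
  x <- array(rnorm(2 * 64 * 3), dim = c(2, 64, 3))
  # zero branch 2's parameters: pre-fusion concat = [branch-1 features, zeros]
  br2 <- blk$branches[[2]]
  for (mod in ns$collect_modules(br2))
    for (p in mod$param_names)
      if (p %in% c("W", "gamma")) mod[[p]] <- mod[[p]] * 0
  y1 <- ns$mod_forward(blk$branches[[1]], x, FALSE)
  y2 <- ns$mod_forward(br2, x, FALSE)
  expect_true(all(y2 == 0))
  expect_gt(max(abs(y1)), 0)
})

test_that("pooled features are equivariant to aligned shifts of a periodic input", {
  # periodic fixture, tiny config; shift by pool1*pool2 samples and compare
  # the pooled features away from the zero-padded borders
  cfg <- msfe_config(branch_kernel_lengths = c(8, 4), n_temporal_filters = 2,
                     pool1_length = 2, pool2_length = 2, fusion_filters = 3,
                     fusion_kernel_length = 3, dropout_p = 0)
  blk <- build_msfe(cfg, C = 2L, seed = 5)
  T <- 64L
  shift <- 4L  # pool1 * pool2
  base <- sin(2 * pi * 4 * (seq_len(T + shift) - 1) / 16) +
    0.5 * cos(2 * pi * 2 * (seq_len(T + shift) - 1) / 16)
  x1 <- rbind(base[seq_len(T)], base[seq_len(T)] * 0.5)
  x2 <- rbind(base[shift + seq_len(T)], base[shift + seq_len(T)] * 0.5)
  y1 <- msfe_forward(blk, array(x1, dim = c(2, T, 1)))
  y2 <- msfe_forward(blk, array(x2, dim = c(2, T, 1)))
  # y2 should equal y1 shifted by one pooled step, in the interior
  # margin of 3 pooled steps clears the zero-padding halo of both convolutions
  inner <- 4:(dim(y1)[2] - 2)
  expect_equal(y2[, inner - 1, 1], y1[, inner, 1], tolerance = 1e-8)
})

test_that("count_parameters matches closed forms and the audit sums", {
  ns <- asNamespace("msatnet")
  dense <- ns$make_dense(3, 2)
  expect_equal(count_parameters(dense), 8)       # 3*2 + 2
  conv <- ns$make_tconv(16, 64)
  expect_equal(count_parameters(conv), 1024)     # no bias (batch-norm follows)
  convb <- ns$make_conv1d(1, 16, 64, bias = TRUE)
  expect_equal(count_parameters(convb), 16 * 64 + 16)
  blk <- build_msfe(msfe_config(), C = 22L, seed = 1)
  audit <- parameter_audit(blk)
  expect_equal(sum(audit$count), count_parameters(blk))
})

test_that("literal stride-1 pooling reading is available", {
  cfg <- msfe_config(branch_kernel_lengths = c(8, 4), n_temporal_filters = 2,
                     pool1_length = 4, pool2_length = 4, fusion_filters = 2,
                     fusion_kernel_length = 3, pool_stride = "one",
                     dropout_p = 0)
  blk <- build_msfe(cfg, C = 2L, seed = 6)
  y <- msfe_forward(blk, array(rnorm(2 * 32), dim = c(2, 32, 1)))
  expect_equal(dim(y)[2], (32 - 4 + 1) - 4 + 1)  # barely downsamples
})

test_that("per-branch second-conv reading doubles the feature count", {
  cfg <- msfe_config(branch_kernel_lengths = c(8, 4), n_temporal_filters = 2,
                     pool1_length = 2, pool2_length = 2, fusion_filters = 3,
                     fusion_kernel_length = 3, second_conv = "branch",
                     dropout_p = 0)
  blk <- build_msfe(cfg, C = 2L, seed = 7)
  y <- msfe_forward(blk, array(rnorm(2 * 64), dim = c(2, 64, 1)))
  expect_equal(dim(y)[1], 6)  # n_branches * fusion_filters
})
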