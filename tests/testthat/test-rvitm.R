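test_that("Sylvester Hadamard probes have the prescribed structure", {
  p2 <- hadamard_probes(2)
  expect_identical(p2$hadamard, matrix(c(1, 1, 1, -1), 2, byrow = TRUE))
  expect_identical(p2$patterns[1:2, ], matrix(c(1L, 1L, 1L, 0L), 2,
                                              byrow = TRUE))
  expect_identical(p2$patterns[3:4, ], matrix(c(0L, 0L, 0L, 1L), 2,
                                              byrow = TRUE))

  p4 <- hadamard_probes(4)
  expect_identical(unname(p4$hadamard %*% t(p4$hadamard)),
                   diag(4) * 4) # mutual orthogonality under +-1 encoding
  # first H1 pattern all-ON, first H2 pattern all-OFF
  expect_true(all(p4$patterns[1, ] == 1))
  expect_true(all(p4$patterns[5, ] == 0))
  # complementary pairs OR to all-ON
  for (k in 1:4) {
    expect_true(all((p4$patterns[k, ] | p4$patterns[4 + k, ]) == 1))
  }
  expect_error(hadamard_probes(12), "power of 2")
})

test_that("characterisation preserves probe order and handles edge cases", {
  tm <- sample_tm(8, 1, seed = 2)
  probes <- hadamard_probes(8)
  stack <- characterize(tm_measure(tm), probes)
  expect_equal(dim(stack), c(1, 16))
  # all-OFF probe (first H2 pattern) gives a zero column in noiseless mode
  expect_equal(stack[1, 9], 0)
  # stack equals the per-pattern loop
  tm2 <- sample_tm(8, 8, seed = 3)
  m <- tm_measure(tm2)
  batch <- characterize(m, probes)
  for (k in c(1, 5, 16)) {
    expect_equal(batch[, k], propagate(tm2, probes$patterns[k, ])$intensity,
                 tolerance = 1e-12)
  }
  # callback failure is attributed to the failing probe
  bad <- function(pats) stop("camera dropout")
  expect_error(characterize(bad, probes), "probe 1")
})

test_that("reconstructed rvit values equal the amplitude-cosine truth exactly", {
  tm <- sample_tm(64, 32, seed = 4)
  probes <- hadamard_probes(64)
  target <- 17
  stack <- characterize(tm_measure(tm, rows = target), probes)
  row <- compute_rvitm(stack, probes, 1)
  truth <- truth_rvit(tm, target)
  expect_gt(cor(row$values, truth), 0.999)
  expect_lt(max(abs(row$values - truth)) / max(abs(truth)), 1e-10)
  # homogeneity: doubling all intensities doubles every rvit value
  row2 <- compute_rvitm(2 * stack, probes, 1)
  expect_equal(row2$values, 2 * row$values, tolerance = 1e-12)
  expect_error(compute_rvitm(stack[, 1:10, drop = FALSE], probes, 1),
               "2N")
})

test_that("the N = 2 case reproduces the hand enumeration", {
  # medium row t = (1, 1): probe intensities 4, 1 (H1) and 0, 1 (H2)
  tm <- sample_tm(2, 2, seed = 5)
  tm$elements[1, ] <- c(1 + 0i, 1 + 0i)
  probes <- hadamard_probes(2)
  stack <- characterize(tm_measure(tm, rows = 1), probes)
  expect_equal(as.vector(stack), c(4, 1, 0, 1))
  row <- compute_rvitm(stack, probes, 1)
  expect_equal(row$values, c(2, 2)) # equal, positive
})

test_that("top-P masks rank correctly and match the oracle at P = 50", {
  expect_identical(mask_top_p(c(3, 1, -2, -5), 50), c(1L, 1L, 0L, 0L))
  expect_true(all(mask_top_p(rnorm(32), 100) == 1))
  expect_error(mask_top_p(1:4, 0), "p")
  expect_error(mask_top_p(1:4, 150), "p")
  # round-half-up ON count
  expect_equal(sum(mask_top_p(1:10, 25)), 3) # 2.5 -> 3
  # stable index tie-break
  expect_identical(mask_top_p(c(1, 1, 1, 1), 50), c(1L, 1L, 0L, 0L))

  # noiseless positive-rvit set equals the oracle pi/2 mask, and the top-50%
  # mask differs from it only by the |ON-count - N/2| rank-boundary mirrors
  for (s in 6:8) {
    tm <- sample_tm(64, 16, seed = s)
    probes <- hadamard_probes(64)
    target <- 7
    row <- compute_rvitm(characterize(tm_measure(tm, rows = target), probes),
                         probes, 1)
    omask <- oracle_mask(tm, target, pi / 2)
    expect_identical(as.integer(row$values > 0), omask)
    expect_equal(sum(mask_top_p(row, 50) != omask), abs(sum(omask) - 32L))
  }
})

test_that("characterisation costs exactly 2N displays", {
  tm <- sample_tm(32, 8, seed = 8)
  m <- tm_measure(tm, rows = 3)
  characterize(m, hadamard_probes(32))
  expect_identical(measurement_count(m), 64L)
})

test_that("the P-sweep reports per-P scores and the argmax", {
  tm <- sample_tm(64, 256, seed = 9)
  target <- central_target(tm)
  probes <- hadamard_probes(64)
  row <- compute_rvitm(characterize(tm_measure(tm, rows = target), probes),
                       probes, 1)
  sweep <- p_sweep(row, tm_measure(tm), target, p_grid = seq(10, 100, 10))
  expect_equal(nrow(sweep), 10)
  expect_equal(attr(sweep, "argmax_p"),
               sweep$p[which.max(sweep$pbr)])
  # peak intensity is non-decreasing in P up to 50% (every added mirror has
  # positive rvit, hence adds constructively on average)
  upto50 <- sweep$peak[sweep$p <= 50]
  expect_true(all(diff(upto50) > -1e-9))
  # degenerate one-point grid
  one <- p_sweep(row, tm_measure(tm), target, p_grid = 30)
  expect_equal(nrow(one), 1)
})

test_that("rvit signs survive measurement noise at SNR 3.33", {
  sign_agreement <- sapply(1:3, function(s) {
    tm <- sample_tm(256, 16, seed = 100 + s)
    target <- 5
    probes <- hadamard_probes(256)
    noisy <- tm_measure(tm, rows = target,
                        noise = noise_model(3.33, seed = s))
    row <- compute_rvitm(characterize(noisy, probes), probes, 1)
    truth <- truth_rvit(tm, target)
    mean(sign(row$values) == sign(truth))
  })
  # at this SNR the noise std is 30% of the mean frame intensity, which
  # flips the sign of roughly one mirror in ten (those with the smallest
  # |rvit|); those mirrors sit at the ranking boundary where they matter
  # least, which is why the PBR itself stays within 10% (see the noise
  # robustness check)
  expect_gt(mean(sign_agreement), 0.85)
  # at the experimentally estimated SNR the signs are essentially intact
  agree_high <- {
    tm <- sample_tm(256, 16, seed = 104)
    probes <- hadamard_probes(256)
    noisy <- tm_measure(tm, rows = 5, noise = noise_model(33.3, seed = 9))
    row <- compute_rvitm(characterize(noisy, probes), probes, 1)
    mean(sign(row$values) == sign(truth_rvit(tm, 5)))
  }
  expect_gt(agree_high, 0.95)
})
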