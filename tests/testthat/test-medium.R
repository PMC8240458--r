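test_that("sampled media have the prescribed dimensions, support and determinism", {
  tm <- sample_tm(16, 16, rayleigh_scale = 0.3, seed = 7)
  expect_s3_class(tm, "transmission_matrix")
  expect_equal(dim(tm$elements), c(16, 16))
  expect_true(all(Mod(tm$elements) >= 0 & Mod(tm$elements) <= 1))
  expect_true(all(Arg(tm$elements) > -pi & Arg(tm$elements) <= pi))

  tm2 <- sample_tm(16, 16, rayleigh_scale = 0.3, seed = 7)
  expect_identical(tm$elements, tm2$elements)
  tm3 <- sample_tm(16, 16, rayleigh_scale = 0.3, seed = 8)
  expect_false(identical(tm$elements, tm3$elements))

  one <- sample_tm(1, 1, rayleigh_scale = 0.5, seed = 1)
  expect_equal(dim(one$elements), c(1, 1))
  expect_true(Mod(one$elements[1, 1]) <= 1)

  expect_error(sample_tm(0, 4, seed = 1), "positive")
  expect_error(sample_tm(4, 4, rayleigh_scale = -1, seed = 1), "positive")
  expect_error(sample_tm(4, 4), "seed")
})

test_that("sampled phases are uniform (KS) and amplitudes Rayleigh-shaped", {
  tm <- sample_tm(256, 512, seed = 11)
  ph <- Arg(tm$elements)
  ks <- suppressWarnings(stats::ks.test(ph, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
  # amplitude distribution matches the (renormalised) Rayleigh CDF on [0,1]
  amp <- Mod(tm$elements)
  pr <- function(q) (1 - exp(-q^2 / (2 * 0.09))) / (1 - exp(-1 / (2 * 0.09)))
  ks2 <- suppressWarnings(stats::ks.test(amp, pr))
  expect_gt(ks2$p.value, 0.01)
})

test_that("propagation matches the element-wise double-loop oracle", {
  tm <- sample_tm(8, 16, seed = 3)
  set.seed(4)
  pattern <- rbinom(8, 1, 0.5)
  out <- propagate(tm, pattern)
  # brute-force loop
  for (m in 1:16) {
    f <- 0 + 0i
    for (n in 1:8) if (pattern[n] == 1) f <- f + tm$elements[m, n]
    expect_equal(out$field[m], f, tolerance = 1e-12)
    expect_equal(out$intensity[m], Mod(f)^2, tolerance = 1e-12)
  }
})

test_that("propagation handles degenerate patterns and bad shapes", {
  tm <- sample_tm(8, 16, seed = 3)
  off <- propagate(tm, rep(0, 8))
  expect_true(all(off$field == 0) && all(off$intensity == 0))
  single <- propagate(tm, c(1, rep(0, 7)))
  expect_equal(single$intensity, Mod(tm$elements[, 1])^2, tolerance = 1e-12)
  expect_error(propagate(tm, rep(1, 7)), "length")
  expect_error(propagate(tm, c(2, rep(1, 7))), "0 or 1")
})

test_that("propagation is additive over disjoint patterns", {
  tm <- sample_tm(16, 32, seed = 5)
  set.seed(6)
  for (i in 1:10) {
    a <- integer(16); b <- integer(16)
    idx <- sample(16, 10)
    a[idx[1:5]] <- 1L
    b[idx[6:10]] <- 1L
    expect_equal(
      propagate(tm, a)$field + propagate(tm, b)$field,
      propagate(tm, as.integer(a | b))$field,
      tolerance = 1e-12
    )
  }
})

test_that("measurement noise has the advertised scale and clips at zero", {
  nm <- noise_model(33.3, seed = 2)
  x <- rep(5, 1e5)
  y <- add_noise(x, nm)
  expect_equal(sd(y - x), 5 / 33.3, tolerance = 0.05)
  expect_true(all(y >= 0))

  # near-infinite SNR leaves the record essentially unchanged
  quiet <- add_noise(x, noise_model(1e12, seed = 1))
  expect_equal(quiet, x, tolerance = 1e-6)

  # dark frame stays dark (clipping contract)
  expect_identical(add_noise(rep(0, 100), nm), rep(0, 100))

  expect_error(noise_model(0), "positive")
  expect_error(noise_model(-3), "positive")

  # deterministic given seed and draw index, independent across draws
  a1 <- add_noise(x[1:100], nm, draw = 1)
  a2 <- add_noise(x[1:100], nm, draw = 1)
  a3 <- add_noise(x[1:100], nm, draw = 2)
  expect_identical(a1, a2)
  expect_false(identical(a1, a3))
})

test_that("PBR has its closed-form values and invariances", {
  expect_equal(pbr(rep(3, 10), 4), 1)
  expect_equal(pbr(c(50, rep(2, 9)), 1), 25)
  # invariant to global rescaling
  set.seed(8)
  i <- rexp(64)
  expect_equal(pbr(i, 10), pbr(7.3 * i, 10))
  expect_error(pbr(c(1, 0, 0), 1), "zero")
  expect_error(pbr(5, 1), "one pixel")
  expect_error(pbr(rep(1, 4), 9), "target")
  # 2-D exclusion window removes the focus halo from the background
  img <- matrix(1, 8, 8)
  img[4, 4] <- 100; img[4, 5] <- 50
  t_idx <- 4 + 3 * 8
  expect_gt(pbr(img, t_idx, exclusion_radius = 1), pbr(img, t_idx))
})

test_that("reference field matches closed forms and all-ON propagation", {
  tm <- sample_tm(2, 1, seed = 1)
  tm$elements[1, ] <- c(1 + 0i, 1i)
  ref <- reference_field(tm, 1)
  expect_equal(ref$amplitude, sqrt(2))
  expect_equal(ref$phase, pi / 4)

  tm$elements[1, ] <- c(2 + 0i, 0.5 + 0i)
  expect_equal(reference_field(tm, 1)$phase, 0)

  tm2 <- sample_tm(32, 8, seed = 9)
  all_on <- propagate(tm2, rep(1, 32))$field
  for (m in c(1, 5)) {
    ref <- reference_field(tm2, m)
    expect_equal(ref$amplitude, Mod(all_on[m]), tolerance = 1e-12)
    expect_equal(ref$phase, Arg(all_on[m]), tolerance = 1e-12)
  }
})

test_that("oracle mask selects exactly the phase window around phi_R", {
  # hand-built 8-mirror row: phases chosen so phi_R = 0 and the pi/2 window
  # keeps mirrors 1:4
  phases <- c(0, 0.3, -0.4, 1.2, 1.8, -2.0, 2.9, -3.0)
  tm <- tm_from_phases(phases)
  ref <- reference_field(tm, 1)
  expected <- as.integer(abs(wrap_phase(phases - ref$phase)) < pi / 2)
  expect_identical(oracle_mask(tm, 1, pi / 2), expected)

  tm2 <- sample_tm(1024, 4, seed = 10)
  expect_true(all(oracle_mask(tm2, 2, pi) == 1))
  frac <- mean(oracle_mask(tm2, 2, pi / 2))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1024)) # binomial 3 sigma
  expect_error(oracle_mask(tm2, 2, 0), "phase_bound")
  expect_error(oracle_mask(tm2, 2, 4), "phase_bound")
})

test_that("measurement callbacks count patterns and honour row restriction", {
  tm <- sample_tm(8, 16, seed = 1)
  m_full <- tm_measure(tm)
  m_row <- tm_measure(tm, rows = 5)
  pats <- hadamard_probes(8)$patterns
  full <- m_full(pats)
  row <- m_row(pats)
  expect_equal(dim(full), c(16, 16))
  expect_equal(as.vector(full[5, ]), as.vector(row))
  expect_equal(measurement_count(m_full), 16L)
  expect_equal(measurement_count(m_row), 16L)
  m_row(pats[1, ])
  expect_equal(measurement_count(m_row), 17L)
})
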