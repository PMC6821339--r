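test_that("index scores are the b'X projection, row-wise over populations", {
  expect_identical(score_index(c(1, 0), c(3.2, 99)), 3.2)
  expect_identical(score_index(c(0, 0), c(5, 7)), 0)
  expect_equal(score_index(c(0.4, 0.2), c(1, 1)), 0.6)
  X <- rbind(c(1, 1), c(2, 0))
  expect_equal(score_index(c(0.4, 0.2), X), c(0.6, 0.8))
  expect_error(score_index(c(1, 2, 3), c(1, 2)), "length")
})

test_that("Smith-Hazel weights solve P b = G a", {
  ip <- identity_params(2L)
  expect_equal(unname(smith_hazel_weights(ip$params, c(1, 0))), c(1, 0))

  uni <- trait_panel("x", "u", 1, reference = "x")
  pu <- genetic_parameters(uni, matrix(0.5), matrix(1.0))
  expect_equal(unname(smith_hazel_weights(pu, 1)), 0.5)  # b = h2

  tt <- two_trait_params()
  expect_equal(unname(smith_hazel_weights(tt$params, c(1, 1))),
               c(0.4, 0.2), tolerance = 1e-12)
})

test_that("full desired-gains weights solve G b = Q and match the restricted form", {
  ip <- identity_params(3L)
  Q <- c(1.5, -2, 0.3)
  expect_equal(unname(desired_gain_weights_full(ip$params, Q)), Q)

  uni <- trait_panel("x", "u", 1, reference = "x")
  pu <- genetic_parameters(uni, matrix(0.25), matrix(1.0))
  expect_equal(unname(desired_gain_weights_full(pu, 0.5)), 2)

  # reduction: mask = all traits collapses Eq. (4) to Eq. (3)
  for (seed in 1:5) {
    rp <- random_params(4L, seed)
    Q <- rnorm(4)
    expect_equal(restricted_gain_weights(rp$params, Q, 1:4),
                 desired_gain_weights_full(rp$params, Q),
                 tolerance = 1e-8)
  }
})

test_that("restricted weights achieve the desired gains and minimize index variance", {
  ip <- identity_params(2L)
  b <- restricted_gain_weights(ip$params, 2, mask = 1L)
  expect_equal(unname(b), c(2, 0))
  expect_equal(unname(correlated_responses(ip$params, b)), c(2, 0))
  expect_equal(index_sd_and_intensity(ip$params, b)$sigma_I, 2)

  tt <- two_trait_params()
  b2 <- restricted_gain_weights(tt$params, 0.4, mask = "t1")
  expect_equal(unname(b2), c(1.076923, -0.307692), tolerance = 1e-6)
  expect_equal(correlated_responses(tt$params, b2)[["t1"]], 0.4)
  # matches the constrained-minimum-variance oracle
  expect_equal(unname(b2),
               kkt_oracle(tt$params$P, tt$params$G[, 1, drop = FALSE], 0.4),
               tolerance = 1e-10)
})

test_that("gain achievement holds on random PSD instances", {
  for (seed in 1:20) {
    n <- sample(3:8, 1)
    rp <- random_params(n, seed = 100 + seed)
    m <- sample(seq_len(n - 1L), 1)
    mask <- sort(sample(n, m))
    Q <- rnorm(m)
    b <- restricted_gain_weights(rp$params, Q, mask)
    resp <- correlated_responses(rp$params, b)
    expect_equal(unname(resp[mask]), Q, tolerance = 1e-8)
  }
})

test_that("restricted weights equal the independent constrained-QP oracle", {
  for (seed in 1:20) {
    n <- sample(2:6, 1)
    rp <- random_params(n, seed = 200 + seed)
    m <- sample(seq_len(n), 1)
    mask <- sort(sample(n, m))
    Q <- rnorm(m)
    b <- restricted_gain_weights(rp$params, Q, mask)
    b_oracle <- kkt_oracle(rp$params$P,
                           rp$params$G[, mask, drop = FALSE], Q)
    expect_equal(unname(b), b_oracle, tolerance = 1e-6)
  }
})

test_that("economic values and Smith-Hazel weights are an exact inverse pair", {
  tt <- two_trait_params()
  expect_equal(implied_economic_values(tt$params,
                                       smith_hazel_weights(tt$params,
                                                           c(2, -1))),
               stats::setNames(c(2, -1), c("t1", "t2")), tolerance = 1e-10)
  for (seed in 1:5) {
    rp <- random_params(5L, seed = 300 + seed)
    b <- rnorm(5)
    a <- implied_economic_values(rp$params, b)
    expect_equal(unname(smith_hazel_weights(rp$params, a)), b,
                 tolerance = 1e-8)
  }
  # G = P makes the matrices cancel: a = b
  ip <- identity_params(3L)
  expect_equal(unname(implied_economic_values(ip$params, c(1, 2, 3))),
               c(1, 2, 3))
})

test_that("weights are scale-equivariant in economic values and sigma_I is homogeneous", {
  rp <- random_params(4L, seed = 42)
  a <- rnorm(4)
  b1 <- smith_hazel_weights(rp$params, a)
  b3 <- smith_hazel_weights(rp$params, 3 * a)
  expect_equal(b3, 3 * b1, tolerance = 1e-10)
  expect_equal(index_sd_and_intensity(rp$params, -2 * b1)$sigma_I,
               2 * index_sd_and_intensity(rp$params, b1)$sigma_I)
  # ranking of a population is invariant to positive rescaling
  set.seed(7)
  X <- matrix(rnorm(40), 10, 4)
  expect_identical(order(score_index(as.numeric(b1), X)),
                   order(score_index(as.numeric(3 * b1), X)))
})

test_that("index SD is sqrt(b'Pb) and the univariate case matches the breeder's equation", {
  ip <- identity_params(2L)
  expect_equal(index_sd_and_intensity(ip$params, c(3, 4))$sigma_I, 5)

  uni <- trait_panel("x", "u", 1, reference = "x")
  pu <- genetic_parameters(uni, matrix(0.25), matrix(1.0))
  b <- desired_gain_weights_full(pu, 0.5)
  s <- index_sd_and_intensity(pu, b)
  expect_equal(unname(b), 2)
  expect_equal(s$sigma_I, 2)
  # i = R / (h2 * sigma_P) with R = 0.5, h2 = 0.25, sigma_P = 1
  expect_equal(s$i, 0.5 / (0.25 * 1))
  expect_equal(index_sd_and_intensity(ip$params, c(0, 0))$sigma_I, 0)
})

test_that("economic-value ratios normalize to the reference and print like table footnotes", {
  a <- c(t1 = 4.4, t2 = 2.0)
  expect_equal(unname(normalize_economic_values(a, "t2")), c(2.2, 1))
  expect_equal(normalize_economic_values(5 * a, "t2"),
               normalize_economic_values(a, "t2"))
  expect_error(normalize_economic_values(c(t1 = 1, t2 = 0), "t2"), "zero")
  expect_identical(format_econ_ratios(c(-180.4, 72.2, 1, 2.24)),
                   c("-180", "72", "1.0", "2.2"))
})

test_that("correlated responses and relative changes follow G b and the panel means", {
  rp <- random_params(3L, seed = 9)
  expect_equal(unname(correlated_responses(rp$params, c(0, 0, 0))),
               c(0, 0, 0))
  ip <- identity_params(3L)
  expect_equal(unname(correlated_responses(ip$params, c(1, 2, 3))),
               c(1, 2, 3))

  panel <- trait_panel(c("DOYFS1", "DryMatter"), c("d", "g"),
                       c(221.21, 1065.47))
  pct <- relative_change(c(DOYFS1 = 44.00, DryMatter = 213.00), panel)
  expect_equal(round(unname(pct), 1), c(19.9, 20.0))
  expect_equal(relative_change(c(DOYFS1 = 0), panel)[["DOYFS1"]], 0)
  zp <- trait_panel("z", "u", 0, reference = "z")
  expect_error(relative_change(c(z = 1), zp), "zero")
})
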