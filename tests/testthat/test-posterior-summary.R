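test_that("gradient assignment partitions CGs by ascending solution", {
  sol <- setNames(as.numeric(1:10), 1:10)
  gr <- assign_gradients(sol, k = 5)
  expect_equal(gr$levels$X, c(1.5, 3.5, 5.5, 7.5, 9.5))
  expect_equal(gr$levels$n_cgs, rep(2L, 5))

  # degenerate: all equal solutions still partition validly
  gr <- assign_gradients(setNames(rep(1, 6), 1:6), k = 3)
  expect_equal(gr$levels$X, rep(1, 3))
  expect_equal(as.integer(table(gr$assignment$level)), c(2L, 2L, 2L))

  expect_error(assign_gradients(setNames(1:3, 1:3), k = 5), "fewer")
})

test_that("23 CGs split 5/5/5/4/4 and match a sort-and-split oracle", {
  set.seed(31)
  sol <- setNames(rnorm(23), sample(letters, 23))
  gr <- assign_gradients(sol, k = 5)
  expect_equal(gr$levels$n_cgs, c(5L, 5L, 5L, 4L, 4L))
  # brute-force oracle: sort, then cut into the same sizes
  srt <- sort(sol)
  sizes <- c(5, 5, 5, 4, 4)
  idx <- rep(seq_len(5), sizes)
  expect_equal(gr$levels$X, as.numeric(tapply(srt, idx, mean)))
  expect_false(is.unsorted(gr$levels$X))
})

test_that("covariance function evaluates the quadratic form", {
  G <- gen_cov(100, 25, 20)
  expect_identical(additive_variance_at(0, G), 100)
  expect_equal(additive_variance_at(2, G), 280, tolerance = 1e-12)
  # singular G: minimum of the quadratic touches zero at X = -sigma_il/sigma2_l
  expect_equal(additive_variance_at(-2, gen_cov(4, 1, 2)), 0,
               tolerance = 1e-12)
})

test_that("additive variance is non-negative for any PSD G", {
  set.seed(77)
  for (rep in 1:50) {
    L <- matrix(rnorm(4), 2)
    M <- L %*% t(L)
    G <- gen_cov(M[1, 1], M[2, 2], M[1, 2])
    expect_true(all(additive_variance_at(seq(-50, 50, by = 2.5), G) >= -1e-9))
  }
})

test_that("genetic correlation: identities, hand values, and degeneracy", {
  G <- gen_cov(100, 25, 20)
  expect_equal(genetic_correlation(1.3, 1.3, G), 1, tolerance = 1e-12)
  expect_equal(genetic_correlation(0, 2, gen_cov(100, 25, 0)),
               100 / sqrt(100 * 200), tolerance = 1e-12)
  # no G x E: correlation is exactly 1 everywhere
  flat <- gen_cov(100, 0, 0)
  for (x in c(-3, 0, 1, 7)) {
    expect_identical(genetic_correlation(x, 5, flat), 1)
  }
  expect_warning(r <- genetic_correlation(-2, 1, gen_cov(4, 1, 2)), "zero")
  expect_true(is.na(r))
})

test_that("genetic correlation is exchangeable and scale-invariant", {
  set.seed(13)
  G <- gen_cov(100, 25, 20)
  for (rep in 1:20) {
    x <- rnorm(1, 0, 5); y <- rnorm(1, 0, 5)
    expect_equal(genetic_correlation(x, y, G), genetic_correlation(y, x, G))
    c0 <- runif(1, 0.1, 10)
    Gs <- gen_cov(100 * c0, 25 * c0, 20 * c0)
    expect_equal(genetic_correlation(x, y, Gs), genetic_correlation(x, y, G),
                 tolerance = 1e-12)
  }
})

test_that("correlation decays with environmental distance on one side", {
  G <- gen_cov(100, 25, 20)
  xs <- seq(0, 10, by = 0.5)
  r <- genetic_correlation(rep(0.5, length(xs)), 0.5 + xs, G)
  expect_true(all(diff(r) <= 1e-12))
})

# minimal hand-built fit object for draw-wise summaries
fake_fit <- function(G, s2pe, s2e, cg = NULL) {
  S <- length(s2e)
  structure(list(G = cbind(sigma2_i = G[, 1], sigma_il = G[, 2],
                           sigma2_l = G[, 3]),
                 sigma2_pe = s2pe, sigma2_e = s2e,
                 cg = cg), class = "rn_fit")
}

test_that("heritability is computed draw-wise", {
  # single draw, sigma2_pe = 0, sigma2_e = sigma2_a(X): h2 = 0.5 exactly
  f <- fake_fit(cbind(100, 0, 0), s2pe = 0, s2e = 100)
  h <- heritability_at(0, f)
  expect_equal(h$mean, 0.5)
  expect_equal(h$sd, 0)

  # identical draws: SD = 0
  f <- fake_fit(cbind(c(100, 100), 0, 0), s2pe = c(0, 0), s2e = c(100, 100))
  expect_equal(heritability_at(0, f)$sd, 0)

  # 1,000 synthetic draws match a direct per-draw recomputation
  set.seed(55)
  G <- cbind(rgamma(1000, 50, .5), rnorm(1000, 5, 2), rgamma(1000, 20, .8))
  s2pe <- rgamma(1000, 10, .3); s2e <- rgamma(1000, 80, .4)
  f <- fake_fit(G, s2pe, s2e)
  X <- 1.7
  va <- pmax(G[, 1] + X^2 * G[, 3] + 2 * X * G[, 2], 0)
  ref <- va / (va + s2pe + s2e)
  h <- heritability_at(X, f)
  expect_equal(h$mean, mean(ref), tolerance = 1e-12)
  expect_equal(h$sd, sd(ref), tolerance = 1e-12)
  expect_true(all(h$draws >= 0 & h$draws <= 1))
})

test_that("gradient_summary ties the pieces together coherently", {
  set.seed(21)
  S <- 200; q <- 15
  cg_draws <- matrix(rnorm(S * q, rep(seq(-6, 6, length.out = q), each = S), 0.3),
                     S, q, dimnames = list(NULL, paste0("g", 1:q)))
  G <- cbind(rgamma(S, 400, 4), rnorm(S, 10, 1), rgamma(S, 100, 8))
  f <- fake_fit(G, s2pe = rgamma(S, 30, 1), s2e = rgamma(S, 200, 1),
                cg = cg_draws)
  gs <- gradient_summary(f, k = 5)
  expect_equal(nrow(gs$levels), 5)
  expect_false(is.unsorted(gs$levels$X))
  expect_equal(diag(gs$r_g), rep(1, 5), ignore_attr = TRUE)
  expect_true(isSymmetric(gs$r_g))
  expect_true(all(gs$r_g >= -1 & gs$r_g <= 1))
  expect_true(all(gs$levels$sigma2_a_mean >= 0))
  expect_true(all(gs$levels$h2_mean >= 0 & gs$levels$h2_mean <= 1))
})
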