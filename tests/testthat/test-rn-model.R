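test_that("configuration guards", {
  expect_error(rn_config(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(rn_config(thin = 0), "thin")
  expect_error(rn_config(nu_G = 2), "nu_G")
})

test_that("saved-draw count follows floor((n - burn)/thin) exactly", {
  s <- small_sim(seed = 14)
  d <- s$sim$phenotypes
  for (cmb in list(c(500, 100, 7), c(301, 50, 10), c(240, 0, 1))) {
    fit <- fit_reaction_norm(d, s$pedigree,
                             rn_config(n_iterations = cmb[1], burn_in = cmb[2],
                                       thin = cmb[3], seed = 2))
    expect_equal(nrow(fit$G), (cmb[1] - cmb[2]) %/% cmb[3])
  }
})

test_that("same seed and data give bit-identical posteriors", {
  s <- small_sim(seed = 15)
  cfg <- rn_config(n_iterations = 800, burn_in = 200, thin = 4, seed = 77)
  f1 <- fit_reaction_norm(s$sim$phenotypes, s$pedigree, cfg)
  f2 <- fit_reaction_norm(s$sim$phenotypes, s$pedigree, cfg)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$a, f2$a)
  expect_identical(f1$cg, f2$cg)
})

test_that("fit validates its inputs", {
  s <- small_sim(seed = 16)
  d <- s$sim$phenotypes
  bad <- d
  bad$animal[1] <- 999999
  expect_error(fit_reaction_norm(bad, s$pedigree, rn_config(200, 50, 1)),
               "absent from pedigree")
  one_cg <- d
  one_cg$cg <- 1
  expect_error(fit_reaction_norm(one_cg, s$pedigree, rn_config(200, 50, 1)),
               "at least 2 contemporary groups")
})

test_that("every saved genetic covariance draw is positive definite", {
  s <- small_sim(seed = 17)
  fit <- fit_reaction_norm(s$sim$phenotypes, s$pedigree,
                           rn_config(n_iterations = 2000, burn_in = 500,
                                     thin = 5, seed = 5))
  dets <- fit$G[, "sigma2_i"] * fit$G[, "sigma2_l"] - fit$G[, "sigma_il"]^2
  expect_true(all(fit$G[, "sigma2_i"] > 0))
  expect_true(all(fit$G[, "sigma2_l"] > 0))
  expect_true(all(dets > 0))
})

test_that("with slopes frozen the sampler matches a REML animal-model oracle", {
  cfg <- sim_config(n_founders = 160, n_generations = 2, n_cgs = 30,
                    cg_mean_size = 15, true_G = gen_cov(100, 0, 0),
                    sigma2_cg = 150, sigma2_pe = 30, sigma2_e = 200,
                    seed = 21)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, cfg)
  fit <- fit_reaction_norm(sim$phenotypes, ped,
                           rn_config(n_iterations = 6000, burn_in = 1500,
                                     thin = 5, seed = 3, fix_slopes = TRUE,
                                     prior = "flat"))
  reml <- animal_model_reml(sim$phenotypes, ped)
  post <- cbind(sigma2_a = fit$G[, "sigma2_i"], sigma2_cg = fit$sigma2_cg,
                sigma2_pe = fit$sigma2_pe, sigma2_e = fit$sigma2_e)
  for (p in colnames(post)) {
    ci <- quantile(post[, p], c(0.025, 0.975))
    expect_gt(reml[p], ci[1] - 1e-8)
    expect_lt(reml[p], ci[2] + 1e-8)
  }
})

test_that("geweke diagnostic: degenerate, calibrated, and trend-sensitive", {
  expect_error(geweke_diagnostic(rnorm(50)), "at least 100")
  g <- geweke_diagnostic(rep(3, 500))
  expect_true(g$degenerate)
  expect_true(is.na(g$z))

  # iid normal chains: |z| approximately standard normal
  set.seed(88)
  rej <- mean(replicate(400, {
    abs(geweke_diagnostic(rnorm(2000))$z) > qnorm(0.975)
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)

  # 2-SD linear trend start-to-end is flagged
  set.seed(12)
  trended <- rnorm(5000) + seq(0, 2, length.out = 5000)
  expect_gt(abs(geweke_diagnostic(trended)$z), qnorm(0.975))

  # cross-check against the classical implementation
  skip_if_not_installed("coda")
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = 0.6), 5000))
  ours <- geweke_diagnostic(x)$z
  ref <- coda::geweke.diag(coda::mcmc(x), frac1 = 0.1, frac2 = 0.5)$z
  expect_equal(unname(ours), unname(ref), tolerance = 0.15)
})

test_that("geweke_table covers all dispersion parameters", {
  s <- small_sim(seed = 19)
  fit <- fit_reaction_norm(s$sim$phenotypes, s$pedigree,
                           rn_config(n_iterations = 1500, burn_in = 300,
                                     thin = 2, seed = 6))
  gt <- geweke_table(fit)
  expect_setequal(gt$parameter,
                  c("sigma2_i", "sigma_il", "sigma2_l", "sigma2_cg",
                    "sigma2_pe", "sigma2_e"))
})

test_that("sire slope extraction counts progeny and filters", {
  s <- small_sim(seed = 20)
  d <- s$sim$phenotypes
  fit <- fit_reaction_norm(d, s$pedigree,
                           rn_config(n_iterations = 1000, burn_in = 200,
                                     thin = 4, seed = 8))
  sl <- sire_slopes(fit, d, min_progeny = 3)
  expect_true(all(sl$n_progeny >= 3))
  cnt <- table(d$sire[d$sire != 0])
  expect_setequal(sl$sire, names(cnt)[cnt >= 3])
  # posterior means agree with direct recomputation from the draw matrix
  expect_equal(sl$mean_slope, unname(colMeans(fit$b[, sl$sire])),
               tolerance = 1e-12)
})
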