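test_that("configuration validation", {
  expect_error(sim_config(n_founders = 1), "at least 2")
  expect_error(gen_cov(-1, 1), "non-negative")
  expect_error(gen_cov(1, 1, 2), "positive semidefinite")
  expect_silent(gen_cov(4, 1, 2))  # boundary: singular but PSD
})

test_that("founder-only and seeded pedigree simulation", {
  cfg <- sim_config(n_founders = 2, n_generations = 0, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 2)
  expect_true(all(ped$sire == 0 & ped$dam == 0))

  cfg <- sim_config(n_founders = 10, n_generations = 2, n_cgs = 4,
                    cg_mean_size = 10, seed = 33)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
})

test_that("pedigrees are topologically ordered (full scan)", {
  set.seed(2)
  for (seed in 1:5) {
    cfg <- sim_config(n_founders = 20, n_generations = 3, n_cgs = 6,
                      cg_mean_size = 10, seed = seed)
    ped <- simulate_pedigree(cfg)
    pos <- seq_len(nrow(ped))
    for (col in c("sire", "dam")) {
      p <- ped[[col]]
      known <- p != 0
      expect_true(all(match(p[known], ped$animal) < pos[known]))
    }
  }
})

test_that("noise-free phenotypes decompose exactly", {
  cfg <- sim_config(n_founders = 30, n_generations = 1, n_cgs = 4,
                    cg_mean_size = 10, sigma2_pe = 0, sigma2_e = 0,
                    mu = 0, beta_age = c(0, 0), seed = 9)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, cfg)
  tr <- sim$truth
  d <- sim$phenotypes
  expected <- tr$true_intercepts[as.character(d$animal)] +
    (1 + tr$true_slopes[as.character(d$animal)]) *
    tr$true_cg_effects[as.character(d$cg)]
  expect_equal(d$value, unname(expected), tolerance = 1e-12)
})

test_that("degenerate G gives all-zero slopes", {
  cfg <- sim_config(n_founders = 20, n_generations = 1, n_cgs = 3,
                    cg_mean_size = 8, true_G = gen_cov(50, 0, 0), seed = 4)
  sim <- simulate_phenotypes(simulate_pedigree(cfg), cfg)
  expect_equal(unname(sim$truth$true_slopes), rep(0, length(sim$truth$true_slopes)))
})

test_that("founder breeding values converge to true_G", {
  cfg <- sim_config(n_founders = 10000, n_generations = 0,
                    true_G = gen_cov(100, 25, 20), seed = 12)
  ped <- simulate_pedigree(cfg)
  cfg2 <- cfg; cfg2$n_generations <- 1L; cfg2$n_cgs <- 10L
  # use one generation so phenotypes exist, but test the founder subset
  ped2 <- simulate_pedigree(cfg2)
  sim <- simulate_phenotypes(ped2, cfg2)
  f <- as.character(ped2$animal[ped2$generation == 0])
  a <- sim$truth$true_intercepts[f]
  b <- sim$truth$true_slopes[f]
  # sampling error of a variance at n = 10,000: SE ~ sqrt(2/n) * sigma2
  expect_lt(abs(var(a) - 100), 3 * sqrt(2 / 10000) * 100)
  expect_lt(abs(var(b) - 25), 3 * sqrt(2 / 10000) * 25)
  expect_lt(abs(cov(a, b) - 20), 3 * sqrt((100 * 25 + 20^2) / 10000))
})

test_that("parent-offspring intercept covariance is half the variance", {
  cfg <- sim_config(n_founders = 4000, n_generations = 1, n_cgs = 100,
                    cg_mean_size = 40, true_G = gen_cov(100, 25, 20),
                    seed = 8)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, cfg)
  a <- sim$truth$true_intercepts[as.character(ped$animal)]
  off <- which(ped$sire != 0)
  cv <- cov(a[off], a[match(ped$sire[off], ped$animal)])
  se <- sqrt((100 * 100 + 50^2) / length(off))
  expect_lt(abs(cv - 50), 3 * se)
})

test_that("seeded phenotype simulation is reproducible and writable", {
  s1 <- small_sim(seed = 5)
  s2 <- small_sim(seed = 5)
  expect_identical(s1$sim, s2$sim)
  dir <- withr::local_tempdir()
  paths <- write_simulation(s1$pedigree, s1$sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(nrow(back), nrow(s1$sim$phenotypes))
  expect_equal(back$value, s1$sim$phenotypes$value, tolerance = 1e-10)
})
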