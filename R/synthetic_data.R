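#' Intercept/slope genetic covariance matrix
#'
#' Container for the 2x2 additive (co)variance matrix of the reaction-norm
#' intercept and slope: `sigma2_i` (trait units squared), `sigma2_l`
#' (trait units squared per environmental unit squared) and their covariance
#' `sigma_il`.
#'
#' @param sigma2_i intercept additive variance, >= 0.
#' @param sigma2_l slope additive variance, >= 0.
#' @param sigma_il intercept-slope covariance; must satisfy
#'   `sigma_il^2 <= sigma2_i * sigma2_l`.
#' @return an object of class `gen_cov`.
#' @export
gen_cov <- function(sigma2_i, sigma2_l, sigma_il = 0) {
  stopifnot(is.numeric(sigma2_i), is.numeric(sigma2_l), is.numeric(sigma_il))
  if (sigma2_i < 0 || sigma2_l < 0) {
    stop("variances must be non-negative")
  }
  if (sigma_il^2 > sigma2_i * sigma2_l * (1 + 1e-12)) {
    stop("sigma_il^2 exceeds sigma2_i * sigma2_l: G not positive semidefinite")
  }
  structure(list(sigma2_i = sigma2_i, sigma2_l = sigma2_l,
                 sigma_il = sigma_il),
            class = "gen_cov")
}

#' @export
as.matrix.gen_cov <- function(x, ...) {
  matrix(c(x$sigma2_i, x$sigma_il, x$sigma_il, x$sigma2_l), 2, 2,
         dimnames = list(c("intercept", "slope"), c("intercept", "slope")))
}

#' @export
print.gen_cov <- function(x, ...) {
  cat("Genetic covariance (intercept/slope):\n")
  print(as.matrix(x))
  invisible(x)
}

#' Simulation configuration
#'
#' Defaults describe a multi-herd zebu-like population: contemporary groups
#' (herd-year-season-sex) with their own variance, cow age at calving with
#' linear and quadratic effects (population mean 72.63, SD 36.65 months,
#' truncated at 24 months), correlated intercept/slope breeding values
#' structured by the pedigree, maternal permanent environment effects and
#' Gaussian residuals. The default variance set
#' (100, 25, 20, 150, 30, 200) for
#' (sigma2_i, sigma2_l, sigma_il, sigma2_cg, sigma2_pe, sigma2_e) is the
#' package's reference parameter-recovery condition.
#'
#' Offspring per generation is `n_cgs * cg_mean_size / n_generations`, so
#' the phenotyped population size is `n_cgs * cg_mean_size`.
#'
#' @param n_founders number of founder animals (>= 2), split equally into
#'   males and females.
#' @param n_generations number of descendant generations (>= 0).
#' @param n_cgs total number of contemporary groups across generations.
#' @param cg_mean_size mean number of records per contemporary group.
#' @param true_G [gen_cov()] of the intercept/slope breeding values.
#' @param sigma2_cg variance of contemporary-group environmental effects.
#' @param sigma2_pe variance of maternal permanent environment effects.
#' @param sigma2_e residual variance.
#' @param mu overall trait mean (trait units).
#' @param beta_age linear and quadratic cow-age coefficients (age centered
#'   at its mean before applying them).
#' @param age_mean_sd mean and SD of cow age at calving, months.
#' @param age_min lower truncation for cow age, months.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 400, n_generations = 2, n_cgs = 100,
                       cg_mean_size = 20,
                       true_G = gen_cov(100, 25, 20),
                       sigma2_cg = 150, sigma2_pe = 30, sigma2_e = 200,
                       mu = 180, beta_age = c(0.5, -0.003),
                       age_mean_sd = c(72.63, 36.65), age_min = 24,
                       seed = NULL) {
  stopifnot(inherits(true_G, "gen_cov"), length(beta_age) == 2,
            length(age_mean_sd) == 2)
  if (n_founders < 2) stop("n_founders must be at least 2 to form matings")
  if (n_generations < 0) stop("n_generations must be >= 0")
  if (n_cgs < 1 || cg_mean_size < 1) stop("counts must be >= 1")
  if (sigma2_cg < 0 || sigma2_pe < 0 || sigma2_e < 0) {
    stop("variances must be non-negative")
  }
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_cgs = as.integer(n_cgs),
                 cg_mean_size = cg_mean_size,
                 true_G = true_G, sigma2_cg = sigma2_cg,
                 sigma2_pe = sigma2_pe, sigma2_e = sigma2_e,
                 mu = mu, beta_age = beta_age,
                 age_mean_sd = age_mean_sd, age_min = age_min,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random-mating multi-generation pedigree
#'
#' Founders (generation 0) have unknown parents; each later generation is
#' produced by random mating among the previous generation (one progeny per
#' mating event, sires drawn from males, dams from females, both with
#' replacement). No selection and no assortative mating. Offspring sex is
#' Bernoulli(0.5) with at least one animal of each sex forced per
#' generation so mating can continue.
#'
#' @param config a [sim_config()].
#' @return data frame (animal, sire, dam, sex, generation), topologically
#'   ordered, with sex in `c("M", "F")`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nf <- config$n_founders
  sex <- rep(c("M", "F"), length.out = nf)
  ped <- data.frame(animal = seq_len(nf), sire = 0L, dam = 0L,
                    sex = sex, generation = 0L,
                    stringsAsFactors = FALSE)
  if (config$n_generations == 0) return(ped)
  total_off <- round(config$n_cgs * config$cg_mean_size)
  per_gen <- diff(round(seq(0, total_off, length.out = config$n_generations + 1)))
  next_id <- nf + 1L
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (length(males) == 0 || length(females) == 0) {
      stop("generation ", g - 1L, " lacks one sex; cannot mate")
    }
    n_g <- per_gen[g]
    sires <- sample(males, n_g, replace = TRUE)
    dams <- sample(females, n_g, replace = TRUE)
    osex <- ifelse(rbinom(n_g, 1, 0.5) == 1, "M", "F")
    if (g < config$n_generations && n_g >= 2) {
      # guarantee both sexes so the next generation can be produced
      if (!any(osex == "M")) osex[1] <- "M"
      if (!any(osex == "F")) osex[1] <- "F"
    }
    ped <- rbind(ped, data.frame(animal = next_id + seq_len(n_g) - 1L,
                                 sire = sires, dam = dams, sex = osex,
                                 generation = g, stringsAsFactors = FALSE))
    next_id <- next_id + n_g
  }
  rownames(ped) <- NULL
  ped
}

# Draw correlated (a, b) breeding values down the pedigree: founders
# MVN(0, G); descendants parental average plus Mendelian sampling with
# covariance G * d_i, d_i = 0.5 - 0.25 (F_s + F_d) (unknown-parent F = -1).
draw_breeding_values <- function(ped, G, f) {
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal, nomatch = 0L)
  d <- match(ped$dam, ped$animal, nomatch = 0L)
  dd <- mendelian_d(s, d, f)
  Gm <- as.matrix(G)
  # lower Cholesky-like factor tolerant of singular G
  ev <- eigen(Gm, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  z <- matrix(rnorm(2 * n), n, 2) %*% rt  # unit-variance bivariate draws
  a <- numeric(n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    ma <- mb <- 0
    if (s[i] > 0) { ma <- ma + a[s[i]] / 2; mb <- mb + b[s[i]] / 2 }
    if (d[i] > 0) { ma <- ma + a[d[i]] / 2; mb <- mb + b[d[i]] / 2 }
    sc <- sqrt(dd[i])
    a[i] <- ma + sc * z[i, 1]
    b[i] <- mb + sc * z[i, 2]
  }
  list(a = a, b = b)
}

rtruncnorm_lower <- function(n, mean, sd, lower) {
  p0 <- pnorm(lower, mean, sd)
  stats::qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Simulate phenotypes on a pedigree
#'
#' One record per non-founder animal:
#' `y = mu + beta1 * age_c + beta2 * age_c^2 + (1 + b_i) * cg_effect +
#'  a_i + pm(dam) + e`, with `age_c` the cow age centered at its simulated
#' mean. Contemporary groups are nested within generation and sex (the
#' herd-year-season-sex structure collapses to an exchangeable grouping with
#' variance `sigma2_cg`); animals are assigned at random to the groups of
#' their generation-sex stratum.
#'
#' @param pedigree output of [simulate_pedigree()] (needs `sex` and
#'   `generation` columns).
#' @param config the same [sim_config()].
#' @return list with `phenotypes` (data frame animal, sire, dam, cg,
#'   cow_age, value) and `truth` (true intercepts, slopes, CG effects,
#'   maternal permanent environment effects, and the simulated betas).
#' @export
simulate_phenotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  as_pedigree(pedigree[c("animal", "sire", "dam")])
  if (!all(c("sex", "generation") %in% names(pedigree))) {
    stop("pedigree must carry sex and generation columns (see simulate_pedigree)")
  }
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  Gm <- as.matrix(config$true_G)
  ev <- eigen(Gm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("true_G is not positive semidefinite")

  f <- compute_inbreeding(pedigree[c("animal", "sire", "dam")])
  u <- draw_breeding_values(pedigree, config$true_G, as.numeric(f))

  off <- pedigree[pedigree$generation > 0, , drop = FALSE]
  if (nrow(off) == 0) {
    stop("no non-founder animals to phenotype; increase n_generations")
  }

  # allot CGs to generation-sex strata proportionally to stratum size
  strata <- interaction(off$generation, off$sex, drop = TRUE)
  n_str <- table(strata)
  n_cgs <- max(config$n_cgs, length(n_str))
  alloc <- pmax(1L, round(n_cgs * as.numeric(n_str) / nrow(off)))
  while (sum(alloc) != n_cgs) {
    k <- if (sum(alloc) > n_cgs) which.max(alloc) else which.min(alloc)
    alloc[k] <- alloc[k] + sign(n_cgs - sum(alloc))
  }
  cg_of <- integer(nrow(off))
  first <- 1L
  for (k in seq_along(n_str)) {
    rows <- which(strata == names(n_str)[k])
    cg_of[rows] <- sample(first:(first + alloc[k] - 1L), length(rows),
                          replace = TRUE)
    first <- first + alloc[k]
  }
  cg_effects <- rnorm(n_cgs, 0, sqrt(config$sigma2_cg))

  dams <- sort(unique(off$dam[off$dam > 0]))
  pe <- setNames(rnorm(length(dams), 0, sqrt(config$sigma2_pe)), dams)

  age <- rtruncnorm_lower(nrow(off), config$age_mean_sd[1],
                          config$age_mean_sd[2], config$age_min)
  age_c <- age - mean(age)
  idx <- match(off$animal, pedigree$animal)
  pm_of <- ifelse(off$dam > 0, pe[as.character(off$dam)], 0)
  eps <- rnorm(nrow(off), 0, sqrt(config$sigma2_e))
  value <- config$mu + config$beta_age[1] * age_c +
    config$beta_age[2] * age_c^2 +
    u$a[idx] + (1 + u$b[idx]) * cg_effects[cg_of] + pm_of + eps

  phen <- data.frame(animal = off$animal, sire = off$sire, dam = off$dam,
                     cg = cg_of, cow_age = age, value = value,
                     stringsAsFactors = FALSE)
  truth <- list(true_intercepts = setNames(u$a, pedigree$animal),
                true_slopes = setNames(u$b, pedigree$animal),
                true_cg_effects = setNames(cg_effects, seq_len(n_cgs)),
                true_pe_effects = pe,
                beta = c(mu = config$mu, age_lin = config$beta_age[1],
                         age_quad = config$beta_age[2]))
  list(phenotypes = phen, truth = truth)
}

#' Write a simulated population to plain-text files
#'
#' Pedigree as 3-column TSV (animal, sire, dam; 0 = unknown), phenotypes as
#' TSV with header (animal, sire, dam, cg, cow_age, value), and the truth
#' bundle as CSV files for test harnesses.
#'
#' @param pedigree,sim outputs of [simulate_pedigree()] and
#'   [simulate_phenotypes()].
#' @param dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(pedigree, sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "pedigree.tsv")
  utils::write.table(pedigree[c("animal", "sire", "dam")], p1, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  p2 <- file.path(dir, "phenotypes.tsv")
  utils::write.table(sim$phenotypes, p2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  tr <- sim$truth
  p3 <- file.path(dir, "truth_animals.csv")
  utils::write.csv(data.frame(animal = names(tr$true_intercepts),
                              true_intercept = unname(tr$true_intercepts),
                              true_slope = unname(tr$true_slopes)),
                   p3, row.names = FALSE)
  p4 <- file.path(dir, "truth_effects.csv")
  utils::write.csv(rbind(data.frame(effect = "cg", id = names(tr$true_cg_effects),
                                    value = unname(tr$true_cg_effects)),
                         data.frame(effect = "pe", id = names(tr$true_pe_effects),
                                    value = unname(tr$true_pe_effects))),
                   p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
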