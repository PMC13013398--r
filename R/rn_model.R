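#' Chain and prior configuration for the reaction-norm sampler
#'
#' Defaults mirror common practice for this model class: 200,000 Gibbs
#' iterations with a 20,000-cycle burn-in and thinning every 10 cycles.
#'
#' Two prior families are available for the dispersion parameters.
#' `prior = "proper"` (the default) uses an inverse-Wishart with `nu_G`
#' degrees of freedom for the 2x2 intercept/slope covariance and scaled
#' inverse chi-squares with `nu_scalar` degrees of freedom for the scalar
#' variances, with scales set from `prior_frac` times the phenotypic
#' variance unless given explicitly. `prior = "flat"` places a constant
#' prior on the genetic covariance matrix and on each scalar variance, the
#' convention of the standard animal-breeding Gibbs samplers; beware that
#' when the slope variance is large the environmental scale of the
#' one-step model is only weakly identified and fully flat variance priors
#' can make the posterior improper along that direction (see the package
#' vignette). Chain start values for the variances are
#' `prior_frac * var(y)` in both families (start values, not priors).
#'
#' @param n_iterations total Gibbs iterations.
#' @param burn_in discarded initial cycles (must be < `n_iterations`).
#' @param thin save every `thin`-th post-burn-in draw (>= 1).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param prior `"flat"` or `"proper"` (see above).
#' @param nu_G inverse-Wishart degrees of freedom of the proper prior
#'   (> 3 so the prior mean exists for a 2x2 matrix).
#' @param nu_scalar degrees of freedom of the proper scalar variance priors.
#' @param S_G optional 2x2 inverse-Wishart scale matrix for the proper
#'   prior; `NULL` = derived from var(y).
#' @param s2_cg,s2_pe,s2_e optional proper-prior scale for the
#'   contemporary-group, permanent-environment and residual variances;
#'   `NULL` = derived.
#' @param prior_frac fraction of var(y) used for derived prior scales and
#'   for chain start values.
#' @param fix_slopes if `TRUE`, freeze all slopes at zero; the sampler then
#'   reduces exactly to a standard additive animal model with random
#'   contemporary groups.
#' @param report print current variance draws every `report` iterations
#'   (0 = silent).
#' @return object of class `rn_config`.
#' @export
rn_config <- function(n_iterations = 200000, burn_in = 20000, thin = 10,
                      seed = NULL, prior = c("proper", "flat"),
                      nu_G = 4, nu_scalar = 4, S_G = NULL,
                      s2_cg = NULL, s2_pe = NULL, s2_e = NULL,
                      prior_frac = 0.25, fix_slopes = FALSE, report = 0) {
  prior <- match.arg(prior)
  if (burn_in >= n_iterations) stop("burn_in must be smaller than n_iterations")
  if (thin < 1) stop("thin must be >= 1")
  if (nu_G <= 3) stop("nu_G must exceed 3 for a proper 2x2 inverse-Wishart mean")
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 prior = prior,
                 nu_G = nu_G, nu_scalar = nu_scalar, S_G = S_G,
                 s2_cg = s2_cg, s2_pe = s2_pe, s2_e = s2_e,
                 prior_frac = prior_frac,
                 fix_slopes = isTRUE(fix_slopes),
                 report = as.integer(report)),
            class = "rn_config")
}

#' Fit the hierarchical one-step reaction norm model
#'
#' Gibbs sampler for
#' `y = x'beta + cg_j + a_i + b_i * cg_j + pm_dam + e`, where the
#' contemporary-group effects `cg_j ~ N(0, sigma2_cg)` serve simultaneously
#' as random environmental effects and as the environmental covariate of
#' the animal-specific reaction-norm slope (the "one-step" formulation:
#' the current draw of `cg_j` is the covariate, so environmental effects
#' and reaction norms are estimated jointly). The intercept/slope vector
#' `(a, b)` carries the bivariate pedigree prior `N(0, G (x) A)` built from
#' the sparse inverse numerator relationship matrix; `pm` is a maternal
#' permanent environment effect indexed by dam. Fixed effects are an
#' intercept plus linear and quadratic cow-age terms (age centered at its
#' sample mean); their prior is flat.
#'
#' The environmental origin is identified by the zero-mean prior on the
#' contemporary-group effects (no hard sum-to-zero constraint is imposed),
#' so `a_i` is interpreted as the breeding value at the average
#' environment and the posterior mean of the group effects is close to,
#' but not exactly, zero.
#'
#' @param records phenotype data frame (animal, sire, dam, cg, cow_age,
#'   value), normally after [apply_edits()]. Every animal must appear in
#'   the pedigree; at least 2 contemporary groups are required.
#' @param pedigree pedigree accepted by [as_pedigree()].
#' @param config an [rn_config()].
#' @return object of class `rn_fit`: matrices of saved draws (`beta`, `cg`,
#'   `a`, `b`, `pm`, `G` with columns sigma2_i/sigma_il/sigma2_l,
#'   `sigma2_cg`, `sigma2_pe`, `sigma2_e`), plus `meta` (id maps, the age
#'   centering constant, chain settings).
#' @export
fit_reaction_norm <- function(records, pedigree, config = rn_config(),
                              init = NULL) {
  stopifnot(inherits(config, "rn_config"))
  ped <- as_pedigree(pedigree)
  need <- c("animal", "cg", "cow_age", "value")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) stop("records missing column(s): ",
                             paste(miss, collapse = ", "))
  if (nrow(records) == 0) stop("no records to fit")
  anim_idx <- match(records$animal, ped$animal)
  if (anyNA(anim_idx)) {
    stop("record animal(s) absent from pedigree: ",
         paste(unique(records$animal[is.na(anim_idx)])[1:3], collapse = ", "))
  }
  cg_levels <- sort(unique(records$cg))
  if (length(cg_levels) < 2) stop("need at least 2 contemporary groups")
  cg_idx <- match(records$cg, cg_levels)

  dam_col <- if ("dam" %in% names(records)) records$dam else {
    ped$dam[anim_idx]
  }
  dam_known <- !(dam_col %in% c(0, "0", NA))
  dam_levels <- sort(unique(dam_col[dam_known]))
  dam_idx <- ifelse(dam_known, match(dam_col, dam_levels), 0L)

  age_center <- mean(records$cow_age)
  age_c <- records$cow_age - age_center
  Xf <- cbind(intercept = 1, age_lin = age_c, age_quad = age_c^2)

  vy <- var(records$value)
  pf <- config$prior_frac
  if (config$prior == "flat") {
    # constant prior on G and on each scalar variance: the posterior scale
    # carries only the data sums of squares (needs a handful of levels per
    # random term so the chi-square degrees of freedom stay positive)
    nu_G <- -3
    S_G <- matrix(0, 2, 2)
    nu_sc <- -2
    s2_cg <- s2_pe <- s2_e <- 0
    if (length(cg_levels) < 5) stop("flat prior needs at least 5 contemporary groups")
  } else {
    nu_G <- config$nu_G
    nu_sc <- config$nu_scalar
    S_G <- config$S_G
    if (is.null(S_G)) {
      # prior mean pf*vy for both diagonal components: S = mean * (nu - p - 1)
      S_G <- diag(c(pf * vy, pf * vy)) * (config$nu_G - 3)
    }
    if (any(dim(S_G) != c(2, 2)) ||
        min(eigen(S_G, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("prior scale S_G must be 2x2 positive definite")
    }
    s2_cg <- if (is.null(config$s2_cg)) pf * vy else config$s2_cg
    s2_pe <- if (is.null(config$s2_pe)) pf * vy else config$s2_pe
    s2_e <- if (is.null(config$s2_e)) pf * vy else config$s2_e
  }

  Ainv <- build_a_inverse(ped)
  trip <- Matrix::mat2triplet(as(Ainv, "generalMatrix"))

  if (is.null(init)) {
    init <- list(a = numeric(nrow(ped)), b = numeric(nrow(ped)),
                 lj = numeric(length(cg_levels)),
                 pm = numeric(length(dam_levels)),
                 G11 = pf * vy, G12 = 0,
                 G22 = if (config$fix_slopes) 0 else pf * vy,
                 s2cg = pf * vy, s2pe = pf * vy, s2e = pf * vy)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  raw <- gibbs_rn_cpp(as.numeric(records$value), Xf,
                      as.integer(cg_idx), as.integer(anim_idx),
                      as.integer(dam_idx),
                      nrow(ped), length(cg_levels), length(dam_levels),
                      as.integer(trip$i), as.integer(trip$j),
                      as.numeric(trip$x),
                      config$n_iterations, config$burn_in, config$thin,
                      nu_G, S_G,
                      nu_sc, s2_cg,
                      nu_sc, s2_pe,
                      nu_sc, s2_e,
                      config$fix_slopes, config$report, init)

  colnames(raw$beta) <- colnames(Xf)
  colnames(raw$cg) <- as.character(cg_levels)
  colnames(raw$a) <- as.character(ped$animal)
  colnames(raw$b) <- as.character(ped$animal)
  if (length(dam_levels) > 0) colnames(raw$pm) <- as.character(dam_levels)
  colnames(raw$G) <- c("sigma2_i", "sigma_il", "sigma2_l")

  structure(c(raw,
              list(meta = list(animal_ids = ped$animal, cg_ids = cg_levels,
                               dam_ids = dam_levels,
                               age_center = age_center,
                               n_records = nrow(records),
                               config = config))),
            class = "rn_fit")
}

#' @export
print.rn_fit <- function(x, ...) {
  cfg <- x$meta$config
  cat("One-step reaction norm fit:", x$meta$n_records, "records,",
      length(x$meta$animal_ids), "animals,", length(x$meta$cg_ids),
      "contemporary groups\n")
  cat(sprintf("Chain: %d iterations, burn-in %d, thin %d (%d saved draws)\n",
              cfg$n_iterations, cfg$burn_in, cfg$thin, nrow(x$G)))
  pm <- colMeans(x$G)
  cat(sprintf("Posterior means: sigma2_i=%.3g sigma2_l=%.3g sigma_il=%.3g\n",
              pm["sigma2_i"], pm["sigma2_l"], pm["sigma_il"]))
  cat(sprintf("  sigma2_cg=%.3g sigma2_pe=%.3g sigma2_e=%.3g\n",
              mean(x$sigma2_cg), mean(x$sigma2_pe), mean(x$sigma2_e)))
  invisible(x)
}

# AR-smoothed spectral density at frequency zero (Heidelberger/Geweke
# convention): fit an AR model by AIC, s0 = innovation variance /
# (1 - sum(phi))^2.
spectrum0_ar <- function(x) {
  if (length(unique(x)) == 1) return(0)
  fit <- ar(x, aic = TRUE)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `first_frac` of a chain with the mean of
#' the last `last_frac` using standard errors from AR-estimated spectral
#' densities at frequency zero; under stationarity z is asymptotically
#' standard normal, and |z| > 1.96 flags non-convergence at the 5% level.
#'
#' @param chain numeric vector of MCMC draws (length >= 100).
#' @param first_frac,last_frac fractions of the chain compared (defaults
#'   0.1 and 0.5; must sum to <= 1).
#' @param alpha significance level for the flag.
#' @return list with `z`, `p`, `converged` (logical), `degenerate`
#'   (TRUE when the chain has zero variance, in which case no z is
#'   reported).
#' @export
geweke_diagnostic <- function(chain, first_frac = 0.1, last_frac = 0.5,
                              alpha = 0.05) {
  if (length(chain) < 100) stop("chain must have at least 100 draws")
  if (first_frac <= 0 || last_frac <= 0 || first_frac + last_frac > 1) {
    stop("need first_frac > 0, last_frac > 0 and first_frac + last_frac <= 1")
  }
  n <- length(chain)
  x1 <- chain[seq_len(floor(first_frac * n))]
  x2 <- chain[seq.int(n - floor(last_frac * n) + 1, n)]
  if (var(chain) == 0) {
    return(list(z = NA_real_, p = NA_real_, converged = NA,
                degenerate = TRUE))
  }
  s1 <- spectrum0_ar(x1)
  s2 <- spectrum0_ar(x2)
  se <- sqrt(s1 / length(x1) + s2 / length(x2))
  if (se == 0) {
    return(list(z = NA_real_, p = NA_real_, converged = NA,
                degenerate = TRUE))
  }
  z <- (mean(x1) - mean(x2)) / se
  list(z = z, p = 2 * pnorm(-abs(z)), converged = abs(z) <= qnorm(1 - alpha / 2),
       degenerate = FALSE)
}

#' Geweke diagnostics for all variance components of a fit
#'
#' @param fit an [rn_fit][fit_reaction_norm()].
#' @param ... passed to [geweke_diagnostic()].
#' @return data frame with one row per dispersion parameter.
#' @export
geweke_table <- function(fit, ...) {
  stopifnot(inherits(fit, "rn_fit"))
  chains <- cbind(fit$G, sigma2_cg = fit$sigma2_cg,
                  sigma2_pe = fit$sigma2_pe, sigma2_e = fit$sigma2_e)
  res <- lapply(colnames(chains), function(nm) {
    g <- geweke_diagnostic(chains[, nm], ...)
    data.frame(parameter = nm, z = g$z, p = g$p, converged = g$converged)
  })
  do.call(rbind, res)
}
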