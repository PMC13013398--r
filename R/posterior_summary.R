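#' Cut contemporary groups into environmental gradient levels
#'
#' Contemporary groups are sorted in ascending order of their posterior
#' mean solutions and split into `k` quantile levels of as-equal-as-possible
#' group counts (largest remainders first, so the lower levels take the
#' extra groups). The environmental descriptor `X` of a level is the mean
#' of its member solutions; level 1 holds the environments with the lowest
#' solutions, level `k` the highest. Ties in solutions are broken by group
#' id order for determinism.
#'
#' @param cg_solutions named numeric vector of posterior mean
#'   contemporary-group effects.
#' @param k number of levels (default 5, i.e. 20% of the distribution per
#'   level).
#' @return object of class `rn_gradients`: list with `assignment`
#'   (data frame cg, solution, level) and `levels` (data frame level, X,
#'   n_cgs).
#' @export
assign_gradients <- function(cg_solutions, k = 5) {
  if (k < 2) stop("k must be at least 2")
  q <- length(cg_solutions)
  if (q < k) stop("fewer contemporary groups (", q, ") than levels (", k, ")")
  if (is.null(names(cg_solutions))) names(cg_solutions) <- seq_len(q)
  ord <- order(cg_solutions, names(cg_solutions))
  base <- q %/% k
  extra <- q %% k
  sizes <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
  level <- rep(seq_len(k), times = sizes)
  assignment <- data.frame(cg = names(cg_solutions)[ord],
                           solution = unname(cg_solutions[ord]),
                           level = level, stringsAsFactors = FALSE)
  levels <- data.frame(level = seq_len(k),
                       X = as.numeric(tapply(assignment$solution,
                                             assignment$level, mean)),
                       n_cgs = as.integer(sizes))
  structure(list(assignment = assignment, levels = levels),
            class = "rn_gradients")
}

#' Additive genetic variance along the environmental gradient
#'
#' Evaluates the covariance function
#' `sigma2_a(X) = sigma2_i + X^2 sigma2_l + 2 X sigma_il`.
#'
#' @param X environmental value(s) on the contemporary-group solution
#'   scale; vectorized.
#' @param G a [gen_cov()].
#' @return additive variance at each `X` (non-negative whenever `G` is
#'   positive semidefinite).
#' @export
additive_variance_at <- function(X, G) {
  stopifnot(inherits(G, "gen_cov"))
  G$sigma2_i + X^2 * G$sigma2_l + 2 * X * G$sigma_il
}

#' Genetic correlation between two environments
#'
#' From the same covariance function:
#' `cov(Xx, Xy) = sigma2_i + (Xx + Xy) sigma_il + Xx Xy sigma2_l`, divided
#' by the geometric mean of the two additive variances. Clipped to
#' `[-1, 1]` only against floating-point overshoot (tolerance 1e-12).
#'
#' @param Xx,Xy environmental values (vectorized in parallel).
#' @param G a [gen_cov()].
#' @return genetic correlation(s); `NA` with a warning where either
#'   variance is zero (degenerate environment).
#' @export
genetic_correlation <- function(Xx, Xy, G) {
  stopifnot(inherits(G, "gen_cov"))
  vx <- additive_variance_at(Xx, G)
  vy <- additive_variance_at(Xy, G)
  cv <- G$sigma2_i + (Xx + Xy) * G$sigma_il + Xx * Xy * G$sigma2_l
  out <- rep(NA_real_, length(cv))
  ok <- vx > 0 & vy > 0
  if (any(!ok)) warning("zero additive variance at some environment(s); NA returned")
  r <- cv[ok] / sqrt(vx[ok] * vy[ok])
  r[r > 1 & r <= 1 + 1e-12] <- 1
  r[r < -1 & r >= -1 - 1e-12] <- -1
  out[ok] <- r
  out
}

gen_cov_from_draw <- function(gdraw) {
  gen_cov(gdraw[["sigma2_i"]], gdraw[["sigma2_l"]], gdraw[["sigma_il"]])
}

#' Draw-wise heritability at an environmental value
#'
#' For every saved draw, `h2(X) = sigma2_a(X) / (sigma2_a(X) + sigma2_pe +
#' sigma2_e)`; the contemporary-group variance is excluded from the
#' denominator because the environment is the gradient itself, not noise
#' (set `include_cg = TRUE` for the wider denominator). Summaries are
#' evaluated draw-wise, not at posterior means.
#'
#' @param X environmental value (scalar).
#' @param fit an [rn_fit][fit_reaction_norm()].
#' @param include_cg include `sigma2_cg` in the denominator?
#' @return list with `mean`, `sd` and the per-draw vector `draws`.
#' @export
heritability_at <- function(X, fit, include_cg = FALSE) {
  stopifnot(inherits(fit, "rn_fit"), length(X) == 1)
  va <- fit$G[, "sigma2_i"] + X^2 * fit$G[, "sigma2_l"] +
    2 * X * fit$G[, "sigma_il"]
  va <- pmax(va, 0)  # guard against tiny negative draws of singular G
  denom <- va + fit$sigma2_pe + fit$sigma2_e
  if (include_cg) denom <- denom + fit$sigma2_cg
  h2 <- va / denom
  list(mean = mean(h2), sd = if (length(h2) > 1) sd(h2) else 0, draws = h2)
}

#' Gradient-wise genetic parameter summary
#'
#' Builds the environmental gradient levels from the posterior mean
#' contemporary-group solutions, then evaluates, draw by draw, the additive
#' variance and heritability at each level's descriptor `X` and the genetic
#' correlations between all level pairs.
#'
#' @param fit an [rn_fit][fit_reaction_norm()].
#' @param k number of gradient levels (default 5).
#' @param include_cg passed to [heritability_at()].
#' @return object of class `rn_gradient_summary`: `levels` (data frame
#'   level, X, n_cgs, sigma2_a_mean, sigma2_a_sd, h2_mean, h2_sd),
#'   `r_g` (posterior mean k x k correlation matrix), `gradients` (the
#'   [assign_gradients()] object).
#' @export
gradient_summary <- function(fit, k = 5, include_cg = FALSE) {
  stopifnot(inherits(fit, "rn_fit"))
  sol <- colMeans(fit$cg)
  gr <- assign_gradients(sol, k)
  Xs <- gr$levels$X
  nd <- nrow(fit$G)
  va <- sapply(Xs, function(X) pmax(fit$G[, "sigma2_i"] +
                                      X^2 * fit$G[, "sigma2_l"] +
                                      2 * X * fit$G[, "sigma_il"], 0))
  h2 <- lapply(Xs, function(X) heritability_at(X, fit, include_cg))
  r_g <- matrix(1, k, k, dimnames = list(paste0("L", seq_len(k)),
                                         paste0("L", seq_len(k))))
  for (x in seq_len(k - 1)) {
    for (y in seq.int(x + 1, k)) {
      cv <- fit$G[, "sigma2_i"] + (Xs[x] + Xs[y]) * fit$G[, "sigma_il"] +
        Xs[x] * Xs[y] * fit$G[, "sigma2_l"]
      denom <- sqrt(va[, x] * va[, y])
      ok <- denom > 0
      r_g[x, y] <- r_g[y, x] <- mean(pmin(pmax(cv[ok] / denom[ok], -1), 1))
    }
  }
  levels <- cbind(gr$levels,
                  sigma2_a_mean = colMeans(va),
                  sigma2_a_sd = apply(va, 2, sd),
                  h2_mean = vapply(h2, `[[`, numeric(1), "mean"),
                  h2_sd = vapply(h2, `[[`, numeric(1), "sd"))
  structure(list(levels = levels, r_g = r_g, gradients = gr),
            class = "rn_gradient_summary")
}

#' @export
print.rn_gradient_summary <- function(x, ...) {
  cat("Environmental gradient summary (", nrow(x$levels), " levels)\n", sep = "")
  print(format(x$levels, digits = 4), row.names = FALSE)
  cat("\nPosterior mean genetic correlations between levels:\n")
  print(round(x$r_g, 3))
  invisible(x)
}
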