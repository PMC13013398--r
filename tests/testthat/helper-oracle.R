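# REML animal-model oracle via lme4's modular API: the additive effect with
# covariance sigma2_a * A is reparameterised as Z* v with Z* = Z U', where
# U is the upper Cholesky factor of the relationship matrix restricted to
# phenotyped animals (their marginal covariance), so v is iid and lmer can
# fit it.
animal_model_reml <- function(records, pedigree) {
  requireNamespace("lme4")
  d <- records
  d$age_c <- as.numeric(scale(d$cow_age))
  d$age_c2 <- as.numeric(scale(d$age_c^2))
  A <- relationship_matrix(pedigree)
  ph <- as.character(d$animal)
  U <- chol(A[ph, ph])
  d$animal_f <- factor(d$animal, levels = d$animal)
  d$cg_f <- factor(d$cg)
  d$dam_f <- factor(d$dam)
  lf <- lme4::lFormula(
    value ~ age_c + age_c2 + (1 | animal_f) + (1 | cg_f) + (1 | dam_f),
    data = d,
    control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                check.nobs.vs.nRE = "ignore"))
  nm <- names(lf$reTrms$cnms)
  sizes <- vapply(lf$reTrms$Ztlist, nrow, 1L)
  ofs <- c(0L, cumsum(sizes))
  ai <- which(nm == "animal_f")
  idx <- (ofs[ai] + 1L):ofs[ai + 1L]
  # rows of the animal block follow levels(d$animal_f) = d$animal order,
  # which matches the rows/cols of U
  lf$reTrms$Zt[idx, ] <- U %*% lf$reTrms$Zt[idx, ]
  devf <- do.call(lme4::mkLmerDevfun, lf)
  opt <- lme4::optimizeLmer(devf)
  fit <- lme4::mkMerMod(environment(devf), opt, lf$reTrms, fr = lf$fr)
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- setNames(vc$vcov, vc$grp)
  c(sigma2_a = unname(out["animal_f"]), sigma2_cg = unname(out["cg_f"]),
    sigma2_pe = unname(out["dam_f"]), sigma2_e = unname(out["Residual"]))
}
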