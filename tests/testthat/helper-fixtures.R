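# Shared fixture builders: tiny pedigrees and a random-pedigree fuzzer used
# across the unit and acceptance tests.

trio_pedigree <- function() {
  data.frame(animal = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
}

# random topologically ordered pedigree: each animal gets parents drawn
# among earlier animals (or unknown), allowing inbreeding
random_pedigree <- function(n, p_unknown = 0.3) {
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) > p_unknown) {
      pick <- sample(i - 1L, 2)
      sire[i] <- pick[1]
      dam[i] <- pick[2]
    }
  }
  data.frame(animal = seq_len(n), sire = sire, dam = dam)
}

small_sim <- function(seed = 42, ...) {
  cfg <- sim_config(n_founders = 60, n_generations = 2, n_cgs = 12,
                    cg_mean_size = 16, seed = seed, ...)
  ped <- simulate_pedigree(cfg)
  list(config = cfg, pedigree = ped,
       sim = simulate_phenotypes(ped, cfg))
}

# brute-force reference for the editing rules: literal repeated filtering
brute_force_edits <- function(records, min_cg_size = 5, min_progeny = 3) {
  repeat {
    n0 <- nrow(records)
    cg_n <- table(records$cg)
    records <- records[cg_n[as.character(records$cg)] >= min_cg_size, ,
                       drop = FALSE]
    known <- records$sire != 0
    if (any(known)) {
      s_n <- table(records$sire[known])
      drop <- known & s_n[as.character(records$sire)] < min_progeny
      drop[is.na(drop)] <- FALSE
      records <- records[!drop, , drop = FALSE]
    }
    if (nrow(records) == n0) return(records)
  }
}
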