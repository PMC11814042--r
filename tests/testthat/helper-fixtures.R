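# Shared fixtures, all generated in code.

# small fixed two-source world used by several receptor tests
tiny_world <- function(n = 40, noise_cv = 0.05, seed = 5) {
  F_true <- rbind(a = c(E1 = 10, E2 = 1, E3 = 0.2, E4 = 5),
                  b = c(E1 = 0.5, E2 = 8, E3 = 4, E4 = 1))
  cfg <- synthetic_config(n_samples = n, elements = colnames(F_true),
                          profile_matrix = F_true, noise_cv = noise_cv,
                          mdl = 0.001, seed = seed)
  generate_dataset(cfg)
}

# adjusted Rand index, direct contingency-table implementation
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Tucker congruence coefficient between loading columns
tucker_phi <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

quiet_hq <- function(...) {
  withCallingHandlers(hazard_quotients(...),
                      sourcerisk_missing_route = function(w) invokeRestart("muffleWarning"))
}
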