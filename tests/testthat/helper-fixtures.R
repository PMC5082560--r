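# Shared fixtures built in code.

# three uncorrelated variants with hand-set association estimates
toy_summary <- function() {
  summary_data(variant_id = c("rs1", "rs2", "rs3"),
               beta_exposure = c(0.08, 0.05, 0.10),
               se_exposure = c(0.010, 0.011, 0.009),
               beta_outcome = c(0.040, 0.020, 0.055),
               se_outcome = c(0.012, 0.010, 0.015))
}

# small deterministic genotype matrix with all three genotype classes
toy_genotypes <- function(n = 60, k = 4, seed = 42) {
  set.seed(seed)
  matrix(rbinom(n * k, 2, 0.4), n, k, dimnames = list(NULL, paste0("g", 1:k)))
}

# reference-model moments used by several oracles
pop_var_x <- function(alpha, k = 20, maf = 0.3) 2 + 2 * k * alpha^2 * maf * (1 - maf)
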