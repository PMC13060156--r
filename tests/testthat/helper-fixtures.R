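# Shared fixture builders for the test suite. Everything is generated in
# code; no data files are read.

# key helper mirroring the package's internal cell naming
key3 <- function(strain, temp, cross) paste(strain, temp, cross, sep = "|")
key2 <- function(strain, temp) paste(strain, temp, sep = "|")

# A compact two-strain, two-temperature, two-cross design.
small_design <- function(reps = 30) {
  build_design(list(strains = c("wA", "wB"), temperatures = c(20, 26),
                    cross_types = c("compatible", "ci"),
                    replicates_per_cell = reps))
}

# Logit table for the small design: moderate CI in wA, strong in wB,
# temperature-sensitive in wA only.
small_logits <- function(design = small_design()) {
  cell_logits_from_or(
    design, compat_logit = 1.4,
    or_ci = setNames(c(0.05, 0.5, 0.01, 0.01),
                     c("wA|20", "wA|26", "wB|20", "wB|26")))
}

small_params <- function(design = small_design(), ...) {
  default_sim_params(design, cell_logit_mean = small_logits(design), ...)
}

# Independent brute-force simulator for the logit-normal-binomial mixture
# (deliberately different code path from simulate_crosses).
brute_hatch_fractions <- function(n_rep, eggs, eta, sigma, pi0, seed) {
  set.seed(seed)
  out <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    if (runif(1) < pi0) {
      out[i] <- 0
    } else {
      p <- 1 / (1 + exp(-(eta + rnorm(1, 0, sigma))))
      out[i] <- rbinom(1, eggs, p) / eggs
    }
  }
  out
}
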