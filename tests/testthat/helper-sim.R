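# Shared fixture builders (all data generated in code at test time).

# random multi-generation pedigree with known parents for animals > n_founders
random_pedigree <- function(n, n_founders = 20, seed = 1) {
  set.seed(seed)
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    anc <- sample(i - 1, 2)
    sire[i] <- paste0("A", anc[1])
    dam[i] <- paste0("A", anc[2])
  }
  data.frame(animal = paste0("A", seq_len(n)), sire = sire, dam = dam,
             birth_year = 2000 + (seq_len(n) %/% 10), sex = "F",
             stringsAsFactors = FALSE)
}

# small simulated dataset for fast mixed-model tests
quick_dataset <- function(seed, cows_per_generation = 150, ...) {
  cfg <- sim_config(seed = seed, n_founders = 60, n_generations = 3,
                    cows_per_generation = cows_per_generation, ...)
  simulate_dataset(cfg)
}

# fast-converging control for small fits
quick_control <- list(rel_tol = 1e-8)
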