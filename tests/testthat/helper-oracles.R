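# Independent sort-and-split n-tile oracle: partition sorted positions into
# n balanced chunks, then give every tie group the lowest chunk it touches.
oracle_ntile <- function(x, n) {
  N <- length(x)
  sizes <- diff(round(seq(0, N, length.out = n + 1)))
  bin_of_pos <- rep(seq_len(n), sizes)
  bin <- integer(N)
  bin[order(x)] <- bin_of_pos
  for (v in unique(x)) bin[x == v] <- min(bin[x == v])
  bin
}

# Brute-force Cox partial likelihood maximizer for a single covariate with
# untied event times (Breslow = Efron when no ties).
oracle_cox_beta <- function(time, event, x) {
  nll <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      rs <- time >= time[i]
      s <- s - (b * x[i] - log(sum(exp(b * x[rs]))))
    }
    s
  }
  stats::optimize(nll, c(-10, 10), tol = 1e-10)$minimum
}

# One fully specified intake row; override any field by name.
make_profile <- function(...) {
  row <- data.frame(
    subject_id = "T1", visit = 1,
    vegetables = 2.5, fruit = 2, whole_grains = 2.5, nuts_legumes = 0.5,
    legumes = 0.3, nuts = 0.3, red_processed_meat = 0.75, fish = 0.3,
    ssb = 0.5, lowfat_dairy = 1, cereal = 1,
    alcohol_g = 2.5, sodium_mg = 2224.5, epa_dha_mg = 125,
    pct_energy_carb = 0.5, pct_energy_protein_total = 0.17,
    pct_energy_protein_animal = 0.11, pct_energy_protein_veg = 0.06,
    pct_energy_fat_total = 0.33, pct_energy_fat_animal = 0.2,
    pct_energy_fat_veg = 0.13, pct_energy_pufa = 0.06,
    pct_energy_trans = 0.0225, mufa_sfa_ratio = 1,
    energy_kcal = 2000, bmi = 27, stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) row[[nm]] <- over[[nm]]
  row
}

# Small person-period table from the observational generator.
make_sim_pp <- function(n = 500, seed = 7, ...) {
  person_periods_from_sim(
    generate_observational_cohort(sim_config(n, seed = seed, ...)))
}
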