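# Shared fixture builders. Everything is generated in code; no files.

ARCHES <- make_archetypes(check = FALSE)

# A random valid parameter set: one of the archetypes, jittered.
random_params <- function() {
  a <- ARCHES[[sample(length(ARCHES), 1)]]
  p <- a$params * stats::runif(45, 0.7, 1.3)
  he <- hill_exponent_names()
  p[he] <- pmax(p[he], 1)
  p
}

random_state <- function() {
  c(M1 = stats::runif(1, 0, 30), M2 = stats::runif(1, 0, 30),
    IL1 = stats::runif(1, 0, 50), IL12 = stats::runif(1, 0, 50),
    IL10 = stats::runif(1, 0, 80), IL4 = stats::runif(1, 0, 20),
    D = stats::runif(1, 0, 30))
}

# Production pathways reduced to a negligible level (positivity keeps the
# parameter set valid); the system then decays exponentially from any
# initial condition with a single seeded compartment.
pure_decay_params <- function(mu_M1 = 0.05, eps = 1e-12) {
  p <- ARCHES$cluster1$params
  p[c("s_mr", "k_tbase", "k_pn1", "k_pn12", "k_pn10", "k_pn4",
      "k_tn10", "k_tn4", "alpha_n12", "alpha_n1", "r_M1")] <- eps
  p["mu_M1"] <- mu_M1
  p
}

# A binned table whose means are exactly the model's values at the bin
# centers, with prescribed relative spread. Offsets shift the means away
# from the model by `offset` (same length as the bin set, recycled).
manufactured_binned <- function(params, init, sd_frac = 0.1, n = 20,
                                offset = 0) {
  traj <- simulate_model(params, init, times = seq(0, 120, by = 1))
  amap <- analyte_states()
  rows <- lapply(names(amap), function(an) {
    v <- traj[[amap[[an]]]][match(bin_centers(), traj$time_h)]
    data.frame(analyte = an, bin_center_h = bin_centers(),
               mean = v + offset, sd = pmax(sd_frac * abs(v), 0.05),
               se = pmax(sd_frac * abs(v), 0.05) / sqrt(n), n = n)
  })
  do.call(rbind, rows)
}

# Small cytokine table written to a temp CSV.
write_temp_table <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}
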