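# Independent second transcription of the model equations, written
# directly in the u^n / (K^n + u^n) form (the package's own code uses the
# reciprocal overflow-safe form and shares no code with this file), plus
# a fixed-step classical RK4 integrator. These serve as oracles only.

oracle_hill <- function(u, K, n) {
  if (u <= 0) return(0)
  u^n / (K^n + u^n)
}

oracle_rhs <- function(state, p) {
  M1 <- state[["M1"]]; M2 <- state[["M2"]]
  IL1 <- state[["IL1"]]; IL12 <- state[["IL12"]]
  IL10 <- state[["IL10"]]; IL4 <- state[["IL4"]]
  D <- state[["D"]]

  Rm1 <- oracle_hill(p[["k_n1"]] * IL1 + p[["k_n12"]] * IL12,
                     p[["b_n"]], p[["x_n"]]) /
    (1 + ((IL10 + IL4) / p[["a_inf1"]])^2)
  Rm2 <- oracle_hill(p[["k_n4"]] * IL4 + p[["k_n10"]] * IL10,
                     p[["y_n"]], p[["z_n"]])
  Rms <- oracle_hill(p[["tau_n4"]] * IL4 + p[["tau_n10"]] * IL10,
                     p[["m_n"]], p[["g_n"]])
  Rp <- (p[["k_M1base"]] * M1 +
           M1 * oracle_hill(IL12 + p[["kcd"]] * D, p[["v_n"]], p[["h_n"]])) /
    (1 + ((IL10 + IL4) / p[["a_inf1"]])^2)
  Rt <- (p[["k_tbase"]] +
           oracle_hill(IL4 + p[["k_tn12"]] * IL12, p[["r_n"]], p[["c_n"]])) /
    (1 + (IL10 / p[["a_inf2"]])^2)
  Ra <- (p[["k_M2base"]] * M2 +
           M2 * oracle_hill(p[["kc4"]] * IL4, p[["w_n"]], p[["q_n"]])) /
    (1 + (IL10 / p[["a_inf2"]])^2)
  mr <- p[["s_mr"]] / (Rm1 + Rm2 + p[["mu_mr"]])

  c(M1 = Rm1 * mr - Rms * M1 - p[["mu_M1"]] * M1,
    M2 = Rm2 * mr + Rms * M1 - p[["mu_M2"]] * M2,
    IL1 = p[["k_pn1"]] * Rp - p[["mu_n1"]] * IL1,
    IL12 = p[["k_pn12"]] * Rp - p[["mu_n12"]] * IL12,
    IL10 = p[["k_tn10"]] * Rt + p[["k_pn10"]] * Ra - p[["mu_n10"]] * IL10,
    IL4 = p[["k_tn4"]] * Rt + p[["k_pn4"]] * Ra - p[["mu_n4"]] * IL4,
    D = (p[["alpha_n12"]] * IL12 + p[["alpha_n1"]] * IL1) /
      (1 + (IL10 / p[["a_inf2"]])^2) +
      p[["r_M1"]] * M1 - p[["gamma_M1"]] * M1 * D -
      p[["gamma_M2"]] * M2 * D)
}

# Classical fixed-step 4th-order Runge-Kutta on a uniform fine grid,
# reporting states at the requested output times (which must lie on the
# fine grid).
oracle_rk4 <- function(params, init, out_times, dt = 0.01) {
  y <- init
  t <- 0
  out <- matrix(NA_real_, nrow = length(out_times), ncol = length(init),
                dimnames = list(NULL, names(init)))
  oi <- 1L
  if (out_times[1] == 0) {
    out[1, ] <- y
    oi <- 2L
  }
  n_steps <- round(max(out_times) / dt)
  for (s in seq_len(n_steps)) {
    k1 <- oracle_rhs(y, params)
    k2 <- oracle_rhs(y + dt / 2 * k1, params)
    k3 <- oracle_rhs(y + dt / 2 * k2, params)
    k4 <- oracle_rhs(y + dt * k3, params)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- s * dt
    while (oi <= length(out_times) &&
           abs(out_times[oi] - t) < dt / 2) {
      out[oi, ] <- y
      oi <- oi + 1L
    }
  }
  out
}
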