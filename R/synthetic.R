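#' Cluster archetype parameter sets
#'
#' Three ground-truth parameterizations emulating the qualitative
#' phenotypes of the study's patient clusters:
#' \describe{
#'   \item{cluster1}{high inflammatory load, unfavorable outcome:
#'     prolonged, elevated microglial expression (small `mu_M1`), slow
#'     IL-10 decay from a high start, strong IL-1b/IL-12 release
#'     (`k_pn1`, `k_pn12`), IL-10 largely ineffective at suppressing
#'     pro-inflammation (large `a_inf2`).}
#'   \item{cluster2A}{low load, favorable outcome: faster M1 than M2
#'     decay, M2:M1 near 1 rising above 1, slowly growing
#'     pro-inflammatory cytokines, effective IL-10 inhibition (small
#'     `a_inf2`), the least end-of-course tissue damage.}
#'   \item{cluster2B}{low load, unfavorable outcome: the most transient
#'     microglial response (large `mu_M1`, `mu_M2`), rapidly decaying
#'     IL-10 and IL-4, and the highest end-of-course tissue damage.}
#' }
#' Absolute magnitudes are model-unit choices; only the ordinal
#' relations between clusters (see [archetype_relations()]) and the
#' trajectory phenotypes are contractual.
#'
#' @param check Verify the ordinal parameter relations and simulated
#'   trajectory phenotypes at build time (default `TRUE`).
#' @return Named list of three archetypes, each a list with `name`,
#'   `params`, `init`.
#' @export
make_archetypes <- function(check = TRUE) {
  base <- c(
    s_mr = 3.5, mu_mr = 0.5,
    k_n1 = 0.5, k_n12 = 0.5, b_n = 5, x_n = 2, a_inf1 = 40,
    k_n4 = 0.3, k_n10 = 0.05, y_n = 30, z_n = 3,
    tau_n4 = 0.5, tau_n10 = 0.15, m_n = 60, g_n = 2,
    mu_M1 = 0.02, mu_M2 = 0.06,
    k_tbase = 0.2, k_tn12 = 0.5, r_n = 5, c_n = 2,
    k_M1base = 0.1, kcd = 0.1, v_n = 60, h_n = 3,
    k_pn1 = 1.2, k_pn12 = 0.9, mu_n1 = 0.1, mu_n12 = 0.15,
    k_M2base = 0.05, kc4 = 1, w_n = 5, q_n = 2, a_inf2 = 60,
    k_tn10 = 1, k_tn4 = 0.5, k_pn10 = 0.2, k_pn4 = 0.1,
    mu_n10 = 0.02, mu_n4 = 0.35,
    alpha_n12 = 0.02, alpha_n1 = 0.01,
    gamma_M1 = 0.005, gamma_M2 = 0.01, r_M1 = 0.02
  )
  override <- function(p, ...) {
    ov <- c(...)
    p[names(ov)] <- ov
    p
  }
  arch <- list(
    cluster1 = list(
      name = "cluster1",
      params = base,
      init = c(M1 = 20, M2 = 5, IL1 = 10, IL12 = 3, IL10 = 60, IL4 = 4,
               D = 1)
    ),
    cluster2A = list(
      name = "cluster2A",
      params = override(base,
        s_mr = 1.5, b_n = 4,
        k_n4 = 0.6, k_n10 = 0.1, y_n = 6, z_n = 2,
        mu_M1 = 0.15, mu_M2 = 0.06,
        k_M1base = 0.2, v_n = 20, h_n = 2,
        k_pn1 = 0.5, k_pn12 = 0.2, mu_n12 = 0.03,
        a_inf2 = 8, k_tn10 = 0.4, k_tn4 = 0.25, k_pn10 = 0.1,
        mu_n10 = 0.12, mu_n4 = 0.05, r_M1 = 0.01),
      init = c(M1 = 10, M2 = 9.5, IL1 = 2, IL12 = 2, IL10 = 8, IL4 = 3,
               D = 1)
    ),
    cluster2B = list(
      name = "cluster2B",
      params = override(base,
        s_mr = 1.4,
        mu_M1 = 0.25, mu_M2 = 0.2,
        v_n = 40, h_n = 1.5,
        k_pn1 = 0.5, k_pn12 = 0.6, mu_n12 = 0.04,
        a_inf2 = 20, k_tn10 = 1.8, mu_n10 = 0.15, mu_n4 = 0.5,
        r_M1 = 0.01),
      init = c(M1 = 16, M2 = 4, IL1 = 6, IL12 = 2, IL10 = 14, IL4 = 4,
               D = 1)
    )
  )
  for (a in arch) validate_params(a$params)
  if (check) check_archetypes(arch)
  arch
}

#' Ordinal parameter relations between cluster archetypes
#'
#' The pairwise parameter orderings the archetypes must satisfy, one row
#' per relation: for `pair = "cluster1_vs_cluster2A"` these are the five
#' disparate parameters of that contrast (`a_inf2`, `k_pn12`, `mu_M1`,
#' `mu_n10`, `k_pn1`); the other pairs carry the orderings described for
#' their contrasts.
#'
#' @return Data frame with columns `pair`, `parameter`, `larger_in`.
#' @export
archetype_relations <- function() {
  rel <- rbind(
    data.frame(pair = "cluster1_vs_cluster2A",
               parameter = c("a_inf2", "k_pn12", "mu_M1", "mu_n10", "k_pn1"),
               larger_in = c("cluster1", "cluster1", "cluster2A",
                             "cluster2A", "cluster1")),
    data.frame(pair = "cluster1_vs_cluster2B",
               parameter = c("mu_M1", "mu_M2", "mu_n10", "h_n", "mu_n12",
                             "k_pn1", "k_pn12"),
               larger_in = c("cluster2B", "cluster2B", "cluster2B",
                             "cluster1", "cluster1", "cluster1",
                             "cluster1")),
    data.frame(pair = "cluster2A_vs_cluster2B",
               parameter = c("mu_M2", "k_pn12", "a_inf2"),
               larger_in = c("cluster2B", "cluster2B", "cluster2B"))
  )
  rel
}

archetype_error <- function(msg) {
  stop(errorCondition(msg,
                      class = c("tbinflam_archetype_error", "error")))
}

#' Trajectory phenotype summaries used to vet the archetypes
#'
#' For each archetype simulates \[0, 120\] h and reports: the time for M1
#' to fall to half its peak (`Inf` if it never does), end-of-course
#' damage `D(120)`, and the M2:M1 ratio at 0 and 120 h.
#'
#' @param archetypes Output of [make_archetypes()].
#' @return Data frame with one row per archetype.
#' @export
archetype_phenotypes <- function(archetypes) {
  rows <- lapply(archetypes, function(a) {
    traj <- simulate_model(a$params, a$init, times = seq(0, 120, by = 0.5))
    m1 <- traj$M1
    ipk <- which.max(m1)
    after <- which(seq_along(m1) > ipk & m1 <= m1[ipk] / 2)
    data.frame(
      name = a$name,
      m1_half_persistence_h = if (length(after)) {
        traj$time_h[after[1]]
      } else Inf,
      d_end = traj$D[nrow(traj)],
      ratio_start = traj$M2[1] / traj$M1[1],
      ratio_end = traj$M2[nrow(traj)] / traj$M1[nrow(traj)],
      m_floor = min(pmin(traj$M1, traj$M2))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Verify archetype contracts
#'
#' Checks (1) every ordinal parameter relation in
#' [archetype_relations()], and (2) the simulated trajectory phenotypes:
#' M1 half-peak persistence longest for cluster1 and shortest for
#' cluster2B; `D(120)` largest for cluster2B and smallest for cluster2A;
#' cluster2A's M2:M1 ratio near 1 initially and above 1 at 120 h;
#' clusters 1 and 2B near 1:4 initially and lower at 120 h. Violations
#' raise a construction error (class `tbinflam_archetype_error`).
#'
#' @param archetypes Output of [make_archetypes()].
#' @return `TRUE` invisibly on success.
#' @export
check_archetypes <- function(archetypes) {
  rel <- archetype_relations()
  for (i in seq_len(nrow(rel))) {
    members <- strsplit(rel$pair[i], "_vs_")[[1]]
    smaller <- setdiff(members, rel$larger_in[i])
    v_big <- archetypes[[rel$larger_in[i]]]$params[[rel$parameter[i]]]
    v_small <- archetypes[[smaller]]$params[[rel$parameter[i]]]
    if (!(v_big > v_small)) {
      archetype_error(sprintf(
        "relation violated: %s should be larger in %s (%s)",
        rel$parameter[i], rel$larger_in[i], rel$pair[i]))
    }
  }
  ph <- archetype_phenotypes(archetypes)
  get <- function(name, col) ph[[col]][ph$name == name]
  if (!(get("cluster1", "m1_half_persistence_h") >
        get("cluster2A", "m1_half_persistence_h") &&
        get("cluster2A", "m1_half_persistence_h") >
        get("cluster2B", "m1_half_persistence_h"))) {
    archetype_error("M1 half-peak persistence not ordered cluster1 > 2A > 2B")
  }
  if (!(get("cluster2B", "d_end") > get("cluster1", "d_end") &&
        get("cluster1", "d_end") > get("cluster2A", "d_end"))) {
    archetype_error("end damage not ordered cluster2B > cluster1 > cluster2A")
  }
  r0 <- get("cluster2A", "ratio_start")
  if (r0 < 0.7 || r0 > 1.3 || get("cluster2A", "ratio_end") <= 1) {
    archetype_error("cluster2A M2:M1 ratio must start near 1 and end above 1")
  }
  for (nm in c("cluster1", "cluster2B")) {
    r0 <- get(nm, "ratio_start")
    if (r0 < 0.15 || r0 > 0.35 || get(nm, "ratio_end") >= r0) {
      archetype_error(paste0(
        nm, " M2:M1 ratio must start near 0.25 and decrease"))
    }
  }
  invisible(TRUE)
}

#' Cohort sampling specification
#'
#' Defaults emulate the study's structure: 29 / 28 / 32 patients in
#' clusters 1 / 2A / 2B, CSF draws nominally twice daily near 7 AM and
#' 7 PM (hours 7, 19, 31, ... post-injury) for 5 days, Gaussian timing
#' jitter, independent per-draw dropout with probability 0.36 (so the
#' expected total draw count is about 567), and multiplicative lognormal
#' measurement noise with a coefficient of variation of 0.3.
#'
#' @param n_per_cluster Named counts for `cluster1`, `cluster2A`,
#'   `cluster2B`.
#' @param horizon_h Observation horizon (h).
#' @param first_sample_h,sample_interval_h Nominal draw schedule.
#' @param jitter_sd_h SD of Gaussian jitter on draw times (h).
#' @param missing_prob Per-scheduled-draw dropout probability.
#' @param noise_cv Lognormal coefficient of variation of measurement
#'   noise; 0 disables noise.
#' @param seed Integer seed making the cohort reproducible.
#' @return A list of class `tbinflam_cohort_spec`.
#' @export
cohort_spec <- function(n_per_cluster = c(cluster1 = 29, cluster2A = 28,
                                          cluster2B = 32),
                        horizon_h = 120, first_sample_h = 7,
                        sample_interval_h = 12, jitter_sd_h = 1,
                        missing_prob = 0.36, noise_cv = 0.3, seed = 1) {
  if (missing_prob < 0 || missing_prob >= 1 || noise_cv < 0 ||
      jitter_sd_h < 0 || any(n_per_cluster < 1)) {
    stop("invalid cohort specification", call. = FALSE)
  }
  structure(list(n_per_cluster = n_per_cluster, horizon_h = horizon_h,
                 first_sample_h = first_sample_h,
                 sample_interval_h = sample_interval_h,
                 jitter_sd_h = jitter_sd_h, missing_prob = missing_prob,
                 noise_cv = noise_cv, seed = seed),
            class = "tbinflam_cohort_spec")
}

#' Simulate a synthetic patient cohort
#'
#' For each patient of each cluster, draws sample times from the nominal
#' twice-daily schedule with Gaussian jitter (clamped to the horizon),
#' thins them by the dropout probability, reads the four modeled
#' cytokines off the cluster archetype's trajectory at those times, and
#' applies multiplicative lognormal noise calibrated to the requested
#' coefficient of variation. Reproducible given `spec$seed`.
#'
#' @param archetypes Output of [make_archetypes()].
#' @param spec A [cohort_spec()].
#' @return List with `table` (tidy data frame in the
#'   [read_cytokine_table()] dialect), `truth` (manifest: per-cluster
#'   true parameters, initial conditions and trajectories, the spec, and
#'   the seed), and `n_draws` (number of CSF draws generated).
#' @export
simulate_cohort <- function(archetypes, spec = cohort_spec()) {
  if (!inherits(spec, "tbinflam_cohort_spec")) {
    stop("`spec` must come from cohort_spec()", call. = FALSE)
  }
  set.seed(spec$seed)
  sigma <- if (spec$noise_cv > 0) sqrt(log(1 + spec$noise_cv^2)) else 0
  nominal <- seq(spec$first_sample_h, spec$horizon_h,
                 by = spec$sample_interval_h)
  amap <- analyte_states()
  grid <- seq(0, spec$horizon_h, by = 0.25)
  trajs <- lapply(archetypes, function(a) {
    simulate_model(a$params, a$init, times = grid)
  })
  rows <- list()
  n_draws <- 0L
  pid <- 0L
  for (cl in names(spec$n_per_cluster)) {
    traj <- trajs[[cl]]
    for (k in seq_len(spec$n_per_cluster[[cl]])) {
      pid <- pid + 1L
      tt <- nominal + stats::rnorm(length(nominal), 0, spec$jitter_sd_h)
      tt <- pmin(pmax(tt, 0), spec$horizon_h)
      keep <- stats::runif(length(tt)) >= spec$missing_prob
      tt <- tt[keep]
      if (!length(tt)) next
      n_draws <- n_draws + length(tt)
      for (an in names(amap)) {
        true_v <- stats::approx(traj$time_h, traj[[amap[[an]]]],
                                xout = tt)$y
        noise <- if (sigma > 0) {
          exp(stats::rnorm(length(tt), 0, sigma))
        } else 1
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("P%03d", pid),
          cluster = cl,
          time_h = tt,
          analyte = an,
          concentration_pg_ml = true_v * noise
        )
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  truth <- list(
    seed = spec$seed,
    spec = unclass(spec),
    clusters = lapply(archetypes, function(a) {
      list(params = a$params, init = a$init)
    }),
    trajectories = trajs
  )
  list(table = table, truth = truth, n_draws = n_draws)
}

#' Write a cohort's ground-truth manifest as JSON
#'
#' Records the generator seed, the sampling spec, and each cluster's
#' true parameters and initial conditions (trajectories are omitted;
#' they are reproducible from the recorded inputs).
#'
#' @param cohort Output of [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(cohort, path) {
  tr <- cohort$truth
  jsonlite::write_json(list(
    seed = tr$seed,
    spec = tr$spec,
    n_draws = cohort$n_draws,
    clusters = lapply(tr$clusters, function(cl) {
      list(params = as.list(cl$params), init = as.list(cl$init))
    })
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
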