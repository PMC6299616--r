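test_that("histogram overlap hits its closed-form anchor cases", {
  x <- c(1, 2, 3, 4, 5)
  same <- bhattacharyya(x, x)
  expect_equal(same$bc, 1)
  expect_equal(same$bd, 0)

  disjoint <- bhattacharyya(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disjoint$bc, 0)
  expect_true(is.na(disjoint$bd))

  # constructed proportions on two shared bins: (0.5, 0.5) vs (0.98, 0.02)
  a <- c(rep(0.5, 50), rep(1.5, 50))
  b <- c(rep(0.5, 98), rep(1.5, 2))
  m <- bhattacharyya(a, b, bins = c(0, 1, 2))
  expect_equal(m$bc, sqrt(0.5 * 0.98) + sqrt(0.5 * 0.02))
  expect_equal(m$bc, 0.8, tolerance = 1e-12)
  expect_equal(m$bd, -log(0.8), tolerance = 1e-12)

  expect_error(bhattacharyya(1, c(1, 2)), "at least 2")
})

test_that("gaussian closed form matches hand-plugged values", {
  # equal mean and variance
  m0 <- gaussian_bhattacharyya(c(1, 2, 3), c(2, 1, 3))
  expect_equal(m0$bd, 0)
  expect_equal(m0$bc, 1)
  # unit variances, means 2 apart: bd = 0.5
  m1 <- gaussian_bhattacharyya(c(0, 1, 2), c(2, 3, 4))
  expect_equal(m1$bd, 0.5)
  expect_equal(m1$bc, exp(-0.5))
  # sd 2 vs 1, equal means: bd = ln(25/16)/4
  m2 <- gaussian_bhattacharyya(c(-2, 0, 2), c(-1, 0, 1))
  expect_equal(m2$bd, 0.25 * log(25 / 16))
  expect_error(gaussian_bhattacharyya(c(1, 1), c(1, 2)), "variance")
})

test_that("overlap is symmetric and invariant to monotone rebinning", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(60, 0, 1)
    b <- rnorm(60, 1, 2)
    m_ab <- bhattacharyya(a, b)
    m_ba <- bhattacharyya(b, a)
    expect_equal(m_ab$bc, m_ba$bc)
  }
  # strictly monotone relabeling of values and shared edges keeps bin
  # memberships, hence bc
  a <- runif(80, 1, 9)
  b <- runif(80, 2, 10)
  edges <- seq(0, 10, by = 1)
  f <- function(x) x^3 + 2 * x
  expect_equal(bhattacharyya(f(a), f(b), bins = f(edges))$bc,
               bhattacharyya(a, b, bins = edges)$bc)
})

test_that("histogram overlap approaches the gaussian closed form for large samples", {
  set.seed(22)
  a <- rnorm(1e4, 0, 1)
  b <- rnorm(1e4, 1.2, 1)
  hist_bc <- bhattacharyya(a, b, bins = 30)$bc
  gauss_bc <- gaussian_bhattacharyya(a, b)$bc
  expect_lt(abs(hist_bc - gauss_bc), 0.05)
})

test_that("printed overlap/distance pairs are mutually consistent via bd = -ln(bc)", {
  pairs <- data.frame(bc = c(0.2, 0.134, 0.245, 0.379, 0.209, 0.045, 0.3),
                      bc_dec = c(1, 3, 3, 3, 3, 3, 1),
                      bd = c(1.61, 2.01, 1.41, 0.971, 1.56, 3.11, 1.2),
                      bd_dec = c(2, 2, 2, 3, 2, 2, 1))
  for (i in seq_len(nrow(pairs))) {
    # interval of -ln(bc) over the printed rounding width of bc
    half <- 0.5 * 10^(-pairs$bc_dec[i])
    lo <- -log(pairs$bc[i] + half)
    hi <- -log(pairs$bc[i] - half)
    bd_half <- 0.5 * 10^(-pairs$bd_dec[i])
    expect_gte(pairs$bd[i] + bd_half, lo)
    expect_lte(pairs$bd[i] - bd_half, hi)
    # at face value the relation holds within the propagated precision
    expect_lt(abs(-log(pairs$bc[i]) - pairs$bd[i]),
              bd_half + half / pairs$bc[i])
  }
})

make_wide <- function(n, shift = 0, seed = 1) {
  set.seed(seed)
  cols <- lapply(param_names(), function(pn) runif(n, 1, 2) + shift)
  names(cols) <- param_names()
  data.frame(member = seq_len(n), error = 1, cols, check.names = FALSE)
}

test_that("an ensemble compared with itself shows full overlap everywhere", {
  df <- make_wide(40)
  cmp <- compare_ensembles(df, df)
  expect_true(all(cmp$bc == 1))
  expect_true(all(cmp$bd == 0))
  expect_false(any(cmp$passes_bhatt))
  expect_false(any(cmp$disparate))
})

test_that("disjoint, sensitive parameters rank first and pass the gate", {
  df_a <- make_wide(40, seed = 2)
  df_b <- make_wide(40, seed = 3)
  df_b$mu_M1 <- df_b$mu_M1 + 10          # disjoint support
  df_b$k_pn1 <- df_b$k_pn1 + 0.5         # partial overlap
  sens <- data.frame(parameter = param_names(), summary = 0.1,
                     exceeds_threshold = FALSE)
  sens$summary[sens$parameter == "mu_M1"] <- 5
  sens$exceeds_threshold <- sens$summary > 2
  attr(sens, "threshold") <- 2
  cmp <- compare_ensembles(df_a, df_b, sens, sens)
  expect_equal(cmp$parameter[1], "mu_M1")
  expect_equal(cmp$bc[cmp$parameter == "mu_M1"], 0)
  expect_true(is.na(cmp$bd[cmp$parameter == "mu_M1"]))
  expect_true(cmp$disparate[cmp$parameter == "mu_M1"])
  # k_pn1 overlaps partially but fails the sensitivity gate
  expect_false(cmp$disparate[cmp$parameter == "k_pn1"])
  # ranking: ascending bc, undefined bd (bc = 0) first
  expect_true(all(diff(cmp$bc) >= 0))
})

test_that("rank order matches a hand-sorted oracle on constructed overlaps", {
  df_a <- make_wide(60, seed = 4)
  df_b <- make_wide(60, seed = 5)
  shifts <- c(mu_M1 = 10, k_pn1 = 1.2, mu_n10 = 0.6, a_inf2 = 0.2)
  for (pn in names(shifts)) df_b[[pn]] <- df_b[[pn]] + shifts[[pn]]
  cmp <- compare_ensembles(df_a, df_b)
  oracle_bc <- vapply(param_names(), function(pn) {
    bhattacharyya(df_a[[pn]], df_b[[pn]])$bc
  }, numeric(1))
  expect_equal(cmp$parameter,
               param_names()[order(oracle_bc,
                                   -ifelse(oracle_bc == 0, Inf,
                                           -log(oracle_bc)))])
  expect_equal(which(cmp$parameter == "mu_M1"), 1L)
})

test_that("mismatched parameter sets are rejected", {
  df_a <- make_wide(10)
  df_b <- df_a[, setdiff(names(df_a), "mu_M1")]
  expect_error(compare_ensembles(df_a, df_b), "mu_M1")
})

test_that("undefined distances serialize as n/a", {
  df_a <- make_wide(20, seed = 6)
  df_b <- make_wide(20, seed = 7)
  df_b$mu_M1 <- df_b$mu_M1 + 10
  cmp <- compare_ensembles(df_a, df_b)
  path <- tempfile(fileext = ".csv")
  write_comparison_csv(cmp, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$bd[back$parameter == "mu_M1"], "n/a")
})
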