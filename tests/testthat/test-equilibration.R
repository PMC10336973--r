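test_that("the molecular charge residual is sum(q) - Q", {
  expect_equal(molecular_charge_error(c(0.5, -0.5), 0), 0)
  expect_equal(molecular_charge_error(c(0.10, -0.05, 0.05), 0), 0.10)
  expect_equal(molecular_charge_error(c(0.3, 0.3, 0.3), 1), -0.1)
  expect_error(molecular_charge_error(numeric(0)), "at least one")
})

test_that("weight kernels reproduce hand-computed values for water", {
  syms <- c("O", "H", "H")
  st <- default_error_stats()

  expect_equal(assign_weights(1, c("C", "H", "O", "N")), rep(0.25, 4))

  # sigma-proportional: w = (0.0111, 0.00898, 0.00898) / 0.02906
  w6 <- assign_weights(6, syms)
  expect_equal(w6, c(0.0111, 0.00898, 0.00898) / 0.02906, tolerance = 1e-12)
  expect_equal(w6[1], 0.38197, tolerance = 1e-4)
  expect_equal(w6[2], 0.30901, tolerance = 1e-4)

  # |mu|-proportional: w_O = 1.97 / (1.97 + 2 * 2.98)
  w7 <- assign_weights(7, syms)
  expect_equal(w7[1], 1.97e-4 / (1.97e-4 + 2 * 2.98e-4), tolerance = 1e-12)
  expect_equal(w7[1], 0.24842, tolerance = 1e-4)

  # |q|-proportional collapses to uniform for equal-magnitude charges
  expect_equal(assign_weights(2, syms, q_pred = c(0.4, -0.4, 0.4)),
               rep(1 / 3, 3))

  # electron-count scheme: w prop Z - q
  q <- c(-0.6, 0.3, 0.3)
  w3 <- assign_weights(3, syms, q_pred = q)
  z <- c(8, 1, 1)
  expect_equal(w3, (z - q) / sum(z - q), tolerance = 1e-14)

  # electronegativity schemes against the constants table
  tab <- element_table()
  chi_s <- tab[c("O", "H", "H"), "chi_S"]
  expect_equal(assign_weights(4, syms), chi_s / sum(chi_s), tolerance = 1e-14)
  chi_p <- tab[c("O", "H", "H"), "chi_P"]
  expect_equal(assign_weights(5, syms), chi_p / sum(chi_p), tolerance = 1e-14)
})

test_that("composite mu/sigma/Z/r kernels follow their formulas", {
  syms <- c("O", "H", "N")
  q <- c(-0.4, 0.1, 0.3)
  st <- default_error_stats()
  tab <- element_table()
  mu <- abs(st$mu[syms]); sg <- st$sigma[syms]
  z <- tab[syms, "Z"]; r <- tab[syms, "r_cov"]
  raw <- list(`8` = mu * sg,
              `9` = mu * (z - q) / r,
              `10` = mu * (z - q),
              `11` = mu * sg * (z - q) / r)
  for (s in names(raw)) {
    w <- assign_weights(as.integer(s), syms, q_pred = q)
    expect_equal(w, unname(raw[[s]] / sum(raw[[s]])), tolerance = 1e-14)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
  expect_error(assign_weights(12, syms), "unknown equilibration scheme")
  expect_error(assign_weights(2, syms), "requires per-atom predicted charges")
})

test_that("degenerate kernels fall back to uniform weights with a warning", {
  syms <- c("H", "H", "H")
  expect_warning(w <- assign_weights(2, syms, q_pred = c(0, 0, 0)),
                 "uniform")
  expect_equal(w, rep(1 / 3, 3))
  # unphysical huge positive charge makes Z - q nonpositive
  expect_warning(w3 <- assign_weights(3, syms, q_pred = c(2, 0, 0)), "uniform")
  expect_equal(w3, rep(1 / 3, 3))
})

test_that("equilibration applies eta = w * dQ and conserves Q", {
  cs <- equilibrate(c(0.10, -0.05, 0.05), 0, rep(1 / 3, 3))
  expect_equal(cs$q_corr, c(0.10, -0.05, 0.05) - 0.10 / 3)
  expect_equal(sum(cs$q_corr), 0, tolerance = 1e-15)

  cs2 <- equilibrate(c(0.2, 0.2, 0.2), 0, c(0.5, 0.3, 0.2))
  expect_equal(cs2$eta, c(0.30, 0.18, 0.12))
  expect_equal(cs2$q_corr, c(-0.10, 0.02, 0.08))

  # zero residual is the identity
  q <- c(0.25, -0.5, 0.25)
  cs3 <- equilibrate(q, 0, c(0.2, 0.5, 0.3))
  expect_identical(cs3$q_corr, q)

  expect_error(equilibrate(c(1, 2), 0, c(1)), "does not match")
  expect_error(equilibrate(c(1, 2), 0, c(0.7, 0.6)), "sum to 1")
})

test_that("scheme 1 equals the closed form q - dQ/N bitwise", {
  q <- c(0.5, -0.25, 0.125, 0.25)  # exact binary fractions
  cs <- run_equilibration(q, 0, c("C", "H", "O", "N"),
                          equilibration_settings(CEQ = 1))
  dq <- sum(q)
  expect_identical(cs$q_corr, q - rep(1 / length(q), length(q)) * dq)
})

test_that("all schemes conserve the molecular charge on randomized inputs", {
  set.seed(404)
  st <- default_error_stats()
  for (k in 1:120) {
    case <- random_charge_case(seed = 7000 + k)
    Q <- sample(c(-1, 0, 0, 1), 1)
    scheme <- sample(1:13, 1)
    n <- case$mol$N
    cs <- suppressWarnings(run_equilibration(
      case$q, Q, case$mol$symbols,
      equilibration_settings(CEQ = scheme, Qtoler = 1e-3, seed = k,
                             max_iter = 2000)))
    expect_lte(abs(sum(cs$q_corr) - Q), 1e-10 * max(1, n))
    expect_equal(cs$q_corr, case$q - cs$eta)
  }
})

test_that("weights are normalized and corrections monotone in the weights", {
  set.seed(505)
  for (scheme in 1:11) {
    case <- random_charge_case(seed = 8000 + scheme)
    w <- suppressWarnings(assign_weights(scheme, case$mol$symbols,
                                         q_pred = case$q))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
    # fixed dQ > 0: larger weight receives a larger correction
    cs <- equilibrate(case$q, sum(case$q) - 0.4, w)
    expect_equal(order(cs$eta), order(w))
  }
})

test_that("re-equilibrating an equilibrated set is idempotent", {
  set.seed(606)
  case <- random_charge_case(seed = 9001)
  for (scheme in c(1, 3, 6, 11)) {
    w <- assign_weights(scheme, case$mol$symbols, q_pred = case$q)
    cs <- equilibrate(case$q, 0, w)
    w2 <- assign_weights(scheme, case$mol$symbols, q_pred = cs$q_corr)
    cs2 <- equilibrate(cs$q_corr, 0, w2)
    expect_lte(max(abs(cs2$q_corr - cs$q_corr)), 1e-10)
  }
})

test_that("equilibration is permutation-equivariant", {
  case <- random_charge_case(seed = 9100)
  set.seed(77)
  perm <- sample(case$mol$N)
  for (scheme in c(2, 5, 6, 9)) {
    cs <- equilibrate(case$q, 0,
                      assign_weights(scheme, case$mol$symbols, q_pred = case$q))
    csp <- equilibrate(case$q[perm], 0,
                       assign_weights(scheme, case$mol$symbols[perm],
                                      q_pred = case$q[perm]))
    expect_equal(csp$eta, cs$eta[perm], tolerance = 1e-14)
    expect_equal(csp$q_corr, cs$q_corr[perm], tolerance = 1e-14)
  }
})

test_that("iterative equilibration honors Qtoler, seeds and early exit", {
  syms <- c("O", "H", "H")
  q0 <- toy_charges(water_molecule())
  q <- q0 + 0.1 / 3  # dQ = 0.1
  for (ceq in c(12L, 13L)) {
    s <- equilibration_settings(CEQ = ceq, Qtoler = 1e-3, seed = 42)
    cs <- iterative_equilibrate(q, 0, syms, settings = s)
    expect_lte(abs(sum(cs$q_corr)), 1e-10 * 3)
    expect_gt(cs$iterations, 0)
    cs2 <- iterative_equilibrate(q, 0, syms, settings = s)
    expect_identical(cs$q_corr, cs2$q_corr)
    # already within tolerance: unchanged, zero iterations
    cs0 <- iterative_equilibrate(q0, 0, syms, settings = s)
    expect_equal(cs0$iterations, 0L)
    expect_equal(cs0$q_corr, q0 - sum(q0) / 3)
  }
  expect_error(equilibration_settings(CEQ = 12, Qtoler = 0), "Qtoler")
  expect_error(equilibration_settings(CEQ = 12, Sigma = 0), "Sigma")
  expect_error(
    iterative_equilibrate(c(0.1), 0, "P",
                          settings = equilibration_settings(CEQ = 12)),
    "unsupported element|no error statistics")
})

test_that("custom plug-in schemes are loaded and validated", {
  f <- withr::local_tempfile(fileext = ".R")
  writeLines(c("assign_custom_weights <- function(symbols, q_pred, stats, elements) {",
               "  rep(1 / length(symbols), length(symbols))",
               "}"), f)
  fn <- load_custom_scheme(f)
  case <- random_charge_case(seed = 9200)
  w <- fn(case$mol$symbols, case$q)
  expect_equal(w, rep(1 / case$mol$N, case$mol$N))
  # equivalent to CEQ = 1 end to end
  cs_custom <- run_equilibration(case$q, 0, case$mol$symbols,
                                 equilibration_settings(CEQ = -1, custom_path = f))
  cs_uniform <- run_equilibration(case$q, 0, case$mol$symbols,
                                  equilibration_settings(CEQ = 1))
  expect_identical(cs_custom$q_corr, cs_uniform$q_corr)

  writeLines(c("assign_custom_weights <- function(symbols, q_pred, stats, elements) {",
               "  rep(0.9 / length(symbols), length(symbols))",
               "}"), f)
  expect_error(load_custom_scheme(f)(case$mol$symbols, case$q), "sum to 1")
  expect_error(load_custom_scheme(tempfile()), "not found")
  expect_error(equilibration_settings(CEQ = -1), "custom")
})

test_that("CEQ 0 disables equilibration", {
  q <- c(0.3, -0.1)
  cs <- run_equilibration(q, 0, c("C", "H"), equilibration_settings(CEQ = 0))
  expect_identical(cs$q_corr, q)
  expect_identical(cs$eta, c(0, 0))
})
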