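# Shared fixtures and independent oracles for the test suite.

# A gas-phase water geometry (Angstrom), experimental-like bond/angle.
water_molecule <- function() {
  molecule(c("O", "H", "H"),
           rbind(c(0, 0, 0),
                 c(0.9572, 0, 0),
                 c(-0.2400, 0.9266, 0)))
}

# Random proper rotation + translation (optionally a reflection).
random_rigid_motion <- function(mol, reflect = FALSE) {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if ((det(R) < 0) != reflect) R[, 1] <- -R[, 1]
  t_vec <- stats::rnorm(3, sd = 5)
  molecule(mol$symbols, mol$coords %*% R + rep(t_vec, each = mol$N), Q = mol$Q)
}

# Brute-force ACSF oracle: naive loops transliterated from the functional
# forms, independent of the package's vectorized implementation.
naive_fc <- function(r, Rc) if (r > Rc) 0 else 0.5 * (cos(pi * r / Rc) + 1)

naive_aev <- function(mol, config) {
  n <- mol$N
  d <- function(i, j) sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
  lapply(seq_len(n), function(i) {
    el <- mol$symbols[i]
    out <- numeric(0)
    rad <- config$radial[config$radial$center == el, , drop = FALSE]
    for (p in seq_len(nrow(rad))) {
      s <- 0
      for (j in seq_len(n)) {
        if (j != i && mol$symbols[j] == rad$neighbor[p]) {
          r <- d(i, j)
          s <- s + exp(-rad$eta[p] * (r - rad$Rs[p])^2) * naive_fc(r, rad$Rc[p])
        }
      }
      out <- c(out, s)
    }
    ang <- config$angular[config$angular$center == el, , drop = FALSE]
    for (p in seq_len(nrow(ang))) {
      s <- 0
      for (j in seq_len(n)) {
        for (k in seq_len(n)) {
          if (j < k && j != i && k != i &&
              ((mol$symbols[j] == ang$n1[p] && mol$symbols[k] == ang$n2[p]) ||
               (mol$symbols[j] == ang$n2[p] && mol$symbols[k] == ang$n1[p]))) {
            rij <- d(i, j); rik <- d(i, k); rjk <- d(j, k)
            cosang <- sum((mol$coords[j, ] - mol$coords[i, ]) *
                            (mol$coords[k, ] - mol$coords[i, ])) / (rij * rik)
            cosang <- min(1, max(-1, cosang))
            afac <- max(0, 1 + ang$lambda[p] * cosang)^ang$zeta[p]
            if (ang$variant[p] == "narrow") {
              term <- afac *
                exp(-ang$eta[p] * ((rij - ang$Rs[p])^2 + (rik - ang$Rs[p])^2 +
                                     (rjk - ang$Rs[p])^2)) *
                naive_fc(rij, ang$Rc[p]) * naive_fc(rik, ang$Rc[p]) *
                naive_fc(rjk, ang$Rc[p])
            } else {
              term <- afac *
                exp(-ang$eta[p] * ((rij - ang$Rs[p])^2 + (rik - ang$Rs[p])^2)) *
                naive_fc(rij, ang$Rc[p]) * naive_fc(rik, ang$Rc[p])
            }
            s <- s + term
          }
        }
      }
      out <- c(out, 2^(1 - ang$zeta[p]) * s)
    }
    out
  })
}

# Loop-based metrics oracle.
naive_metrics <- function(pred, ref) {
  n <- length(pred)
  sae <- 0; sse <- 0
  for (i in seq_len(n)) {
    sae <- sae + abs(pred[i] - ref[i])
    sse <- sse + (pred[i] - ref[i])^2
  }
  mp <- sum(pred) / n; mr <- sum(ref) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (pred[i] - mp) * (ref[i] - mr)
    sxx <- sxx + (pred[i] - mp)^2
    syy <- syy + (ref[i] - mr)^2
  }
  list(mae = sae / n, rmse = sqrt(sse / n), r = sxy / sqrt(sxx * syy))
}

# A small ACSF set (single element pair coverage) for fast featurizer tests.
tiny_acsf_config <- function(elements = c("C", "H", "O", "N"), Rc = 4) {
  default_acsf_config(elements, Rc = Rc, radial_shifts = c(1, 2),
                      radial_eta = 2, angular_eta = 0.2, zeta = 1)
}

# Random CHON molecule + charges for property tests.
random_charge_case <- function(seed) {
  spec <- fixture_spec(
    composition = c(C = sample(0:3, 1), H = sample(1:4, 1),
                    O = sample(0:2, 1), N = sample(0:2, 1)),
    seed = seed)
  if (sum(spec$composition) < 2) spec$composition["H"] <- 2
  mol <- generate_molecule(spec, seed = seed)
  q <- stats::rnorm(mol$N, sd = 0.3)
  list(mol = mol, q = q)
}
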