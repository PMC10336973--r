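# Synthetic CHON fixtures: random packed geometries plus an analytic,
# exactly charge-conserving per-atom charge function. These stand in for
# quantum-chemical reference charges so featurization, training, prediction,
# equilibration and metrics can all be exercised without external data.

#' Fixture generation settings
#'
#' @param composition Named integer vector: atoms per element, e.g.
#'   `c(C = 2, H = 4, O = 1, N = 1)`.
#' @param n_molecules Number of molecules to generate.
#' @param geometry_scale Typical nearest-neighbor distance (Angstrom); new
#'   atoms are placed at roughly this distance from an existing atom, so
#'   geometries form connected clusters.
#' @param min_separation Clash threshold: minimum allowed pairwise distance
#'   (Angstrom, > 0).
#' @param noise_level Standard deviation of per-atom Gaussian noise added by
#'   [perturb_charges()] (electrons).
#' @param offset Deliberate residual molecular charge injected by
#'   [perturb_charges()] (electrons).
#' @param seed Integer RNG seed.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(composition = c(C = 2, H = 4, O = 1, N = 1),
                         n_molecules = 1L, geometry_scale = 1.3,
                         min_separation = 0.9, noise_level = 0.01,
                         offset = 0, seed = 1L) {
  if (is.null(names(composition)) || any(composition < 0) ||
      sum(composition) < 1) {
    stop("composition must be a named count vector with at least one atom")
  }
  if (min_separation <= 0) stop("min_separation must be > 0")
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  if (noise_level < 0) stop("noise_level must be >= 0")
  list(composition = composition, n_molecules = as.integer(n_molecules),
       geometry_scale = geometry_scale, min_separation = min_separation,
       noise_level = noise_level, offset = offset, seed = as.integer(seed))
}

#' Generate a random clash-free molecule
#'
#' Atoms are placed sequentially: each new atom sits at a distance around
#' `geometry_scale` (uniform in `[0.9, 1.3] * geometry_scale`) from a
#' randomly chosen placed atom, in a random direction, rejecting positions
#' closer than `min_separation` to any placed atom. Deterministic given the
#' spec's seed. Element order is shuffled so compositions do not imprint a
#' fixed atom ordering.
#'
#' @param spec A [fixture_spec()].
#' @param seed Optional seed overriding `spec$seed` (used when generating
#'   many molecules from one spec).
#' @return A [molecule()] whose pairwise distances all exceed
#'   `min_separation`.
#' @export
generate_molecule <- function(spec = fixture_spec(), seed = spec$seed) {
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  symbols <- rep(names(spec$composition), times = spec$composition)
  n <- length(symbols)
  symbols <- symbols[sample.int(n)]
  coords <- matrix(0, n, 3L)
  max_tries <- 200L
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      anchor <- coords[sample.int(i - 1L, 1L), ]
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      r <- spec$geometry_scale * stats::runif(1, 0.9, 1.3)
      cand <- anchor + r * u
      d <- sqrt(rowSums((coords[seq_len(i - 1L), , drop = FALSE] -
                           rep(cand, each = i - 1L))^2))
      if (all(d >= spec$min_separation)) {
        coords[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place atom ", i, " after ", max_tries,
           " attempts; reduce min_separation or increase geometry_scale")
    }
  }
  molecule(symbols, coords)
}

#' Analytic per-atom reference charges
#'
#' A deliberately simple, smooth stand-in for real-space reference charges:
#' `q_A = kappa * (chi_bar - chi_A) * g_A`, where `chi_A` is the atom's
#' Pauling electronegativity, `chi_bar` the molecular mean, and
#' `g_A = sum_B fc(R_AB) / R_AB` a positive coordination-like factor over
#' neighbors inside `cutoff`. A constant shift then makes the charges sum
#' to zero exactly. The function is deterministic, continuous in the
#' coordinates and invariant under rigid motions; electron-rich elements
#' (higher electronegativity) come out negative, as for water's oxygen.
#'
#' @param mol A [molecule()].
#' @param elements Element constants table.
#' @param kappa Overall charge scale (electrons).
#' @param cutoff Neighbor cutoff for the geometry factor (Angstrom).
#' @return Numeric per-atom charges (electrons) summing to 0.
#' @export
toy_charges <- function(mol, elements = element_table(), kappa = 0.15,
                        cutoff = 4) {
  stopifnot(inherits(mol, "molecule"))
  chi <- vapply(mol$symbols, function(s) lookup_element(s, elements)$chi_P,
                numeric(1), USE.NAMES = FALSE)
  chi_bar <- mean(chi)
  dmat <- mol_distance_matrix(mol)
  g <- vapply(seq_len(mol$N), function(i) {
    r <- dmat[i, -i]
    if (length(r) == 0) return(0)
    sum(cutoff_function(r, cutoff) / r)
  }, numeric(1))
  q <- kappa * (chi_bar - chi) * g
  q - mean(q)
}

#' Perturb charges to emulate model error
#'
#' Adds per-atom Gaussian noise of standard deviation `spec$noise_level`
#' plus a uniformly distributed systematic component chosen so that
#' `sum(q_pred) - sum(q)` equals `spec$offset` exactly, emulating the
#' accumulation of per-atom prediction errors into a molecular-charge
#' residual. Deterministic given the seed.
#'
#' @param q Per-atom reference charges (electrons).
#' @param spec A [fixture_spec()] (`noise_level`, `offset`, `seed`).
#' @param seed Optional seed overriding `spec$seed`.
#' @return Perturbed charges with the constructed residual.
#' @export
perturb_charges <- function(q, spec = fixture_spec(), seed = spec$seed) {
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- length(q)
  noise <- stats::rnorm(n, sd = spec$noise_level)
  q + noise + (spec$offset - sum(noise)) / n
}

#' Generate labeled fixture frames
#'
#' Produces `spec$n_molecules` random molecules with their analytic
#' reference charges, as `labeled_molecule` objects ready for
#' [build_dataset()] or [write_xyz()] (extended XYZ) export. Per-molecule
#' seeds are derived from `spec$seed` so frames are independent but the set
#' is reproducible.
#'
#' @param spec A [fixture_spec()].
#' @param elements Element constants table.
#' @param kappa,cutoff Passed to [toy_charges()].
#' @return List of `labeled_molecule` objects.
#' @export
generate_fixture_frames <- function(spec = fixture_spec(),
                                    elements = element_table(),
                                    kappa = 0.15, cutoff = 4) {
  lapply(seq_len(spec$n_molecules), function(k) {
    mol <- generate_molecule(spec, seed = spec$seed + k - 1L)
    structure(list(molecule = mol,
                   targets = toy_charges(mol, elements, kappa, cutoff),
                   units = "electrons"),
              class = "labeled_molecule")
  })
}

#' Write fixture frames as extended XYZ
#'
#' @param frames List of `labeled_molecule` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_frames <- function(frames, path) {
  if (file.exists(path)) file.remove(path)
  for (k in seq_along(frames)) {
    write_xyz(frames[[k]]$molecule, path,
              comment = sprintf("fixture frame %d", k),
              targets = frames[[k]]$targets, append = TRUE)
  }
  invisible(path)
}
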