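# Charge equilibration: redistribute the residual molecular charge across
# atoms so the corrected charges reconstruct the molecular charge exactly.
#
# The correction is linear: eta_A = w_A * dQ with the weights w summing to
# one, so sum(q_pred - eta) = sum(q_pred) - dQ = Q by construction. The
# weight kernels (scheme ids 1-11) trade off chemical and statistical
# information; two iterative noise-draw variants (12-13) and a user plug-in
# (-1) complete the set. This is a post-hoc rescaling of ML predictions,
# not an electronegativity-equalization charge computation.

CEQ_NONE <- 0L
CEQ_SCHEMES <- 1:11
CEQ_ITERATIVE <- c(12L, 13L)
CEQ_CUSTOM <- -1L

#' Residual molecular charge
#'
#' The excess or deficiency of electrons in a set of predicted charges:
#' `dQ = sum(q_pred) - Q`. For neutral molecules (`Q = 0`) this is simply
#' the sum of the predictions.
#'
#' @param q_pred Per-atom predicted charges (electrons).
#' @param Q Target total molecular charge (electrons).
#' @return The residual, electrons.
#' @export
molecular_charge_error <- function(q_pred, Q = 0) {
  if (length(q_pred) < 1) stop("need at least one atomic charge")
  sum(q_pred) - Q
}

#' Construct an equilibrated charge set
#'
#' @param q_pred Per-atom predicted charges (electrons).
#' @param Q Target molecular charge (electrons).
#' @param eta Per-atom corrections (electrons).
#' @param iterations Iteration count (iterative schemes; 0 otherwise).
#' @return An object of class `charge_set` with fields `q_pred`, `Q`,
#'   `delta_Q` (`sum(q_pred) - Q`), `eta`, `q_corr` (`q_pred - eta`) and
#'   `iterations`.
#' @export
charge_set <- function(q_pred, Q, eta, iterations = 0L) {
  if (length(eta) != length(q_pred)) stop("eta length does not match q_pred")
  q_corr <- q_pred - eta
  structure(list(q_pred = q_pred, Q = Q,
                 delta_Q = sum(q_pred) - Q,
                 eta = eta, q_corr = q_corr,
                 iterations = iterations),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("charge set: %d atoms, Q = %g e, dQ before %.3e e, after %.3e e\n",
              length(x$q_pred), x$Q, x$delta_Q, sum(x$q_corr) - x$Q))
  invisible(x)
}

uniform_weights <- function(n) rep(1 / n, n)

normalize_or_uniform <- function(raw, scheme) {
  s <- sum(raw)
  if (!all(is.finite(raw)) || any(raw < 0) || s <= 1e-15) {
    warning("scheme ", scheme, ": degenerate weight terms; falling back to ",
            "uniform weights")
    return(uniform_weights(length(raw)))
  }
  raw / s
}

#' Assign per-atom equilibration weights
#'
#' Computes the weight vector of the chosen deterministic scheme,
#' normalized to sum to one:
#' 1. uniform, `1/N`;
#' 2. proportional to `|q_A|`;
#' 3. proportional to the electron count `Z_A - q_A`;
#' 4. proportional to the Sanderson electronegativity `chi_S`;
#' 5. proportional to the Pauling electronegativity `chi_P`;
#' 6. proportional to the element's prediction-error spread `sigma_A`;
#' 7. proportional to `|mu_A|`, the magnitude of the element's mean error;
#' 8. proportional to `|mu_A| * sigma_A`;
#' 9. proportional to `|mu_A| * (Z_A - q_A) / r_A`;
#' 10. proportional to `|mu_A| * (Z_A - q_A)`;
#' 11. proportional to `|mu_A| * sigma_A * (Z_A - q_A) / r_A`.
#'
#' Degenerate inputs (all-zero terms, or a nonpositive electron count in
#' schemes 3/9/10/11) fall back to uniform weights with a warning.
#'
#' @param scheme Integer scheme id in 1..11.
#' @param symbols Per-atom element symbols.
#' @param q_pred Per-atom predicted charges (electrons); used by schemes
#'   2, 3, 9, 10, 11.
#' @param stats An `error_stats` object (schemes 6-11).
#' @param elements Element constants table from [element_table()].
#' @return Numeric weight vector: nonnegative, summing to 1.
#' @export
assign_weights <- function(scheme, symbols, q_pred = NULL,
                           stats = default_error_stats(),
                           elements = element_table()) {
  if (!scheme %in% CEQ_SCHEMES) {
    stop("unknown equilibration scheme id: ", scheme, " (expected 1..11)")
  }
  symbols <- canonical_symbol(symbols)
  n <- length(symbols)
  if (n < 1) stop("need at least one atom")
  if (scheme %in% c(2, 3, 9, 10, 11)) {
    if (is.null(q_pred) || length(q_pred) != n) {
      stop("scheme ", scheme, " requires per-atom predicted charges")
    }
  }
  per_atom <- function(field) {
    vapply(symbols, function(s) lookup_element(s, elements)[[field]], numeric(1),
           USE.NAMES = FALSE)
  }
  if (scheme %in% 6:11) {
    st <- stats_for_symbols(stats, symbols, what = paste("scheme", scheme))
  }
  if (scheme %in% c(3, 9, 10, 11)) {
    ecount <- per_atom("Z") - q_pred
    if (any(ecount <= 0)) {
      warning("scheme ", scheme, ": nonpositive electron count Z - q; ",
              "falling back to uniform weights")
      return(uniform_weights(n))
    }
  }
  raw <- switch(as.character(scheme),
    "1" = rep(1, n),
    "2" = abs(q_pred),
    "3" = ecount,
    "4" = per_atom("chi_S"),
    "5" = per_atom("chi_P"),
    "6" = st$sigma,
    "7" = abs(st$mu),
    "8" = abs(st$mu) * st$sigma,
    "9" = abs(st$mu) * ecount / per_atom("r_cov"),
    "10" = abs(st$mu) * ecount,
    "11" = abs(st$mu) * st$sigma * ecount / per_atom("r_cov"))
  normalize_or_uniform(raw, scheme)
}

#' Equilibrate charges with a weight vector
#'
#' Applies the linear correction `eta_A = w_A * dQ`, `q_corr = q_pred - eta`.
#' Because the weights sum to one, the corrected charges sum to `Q` up to
#' floating-point roundoff.
#'
#' @param q_pred Per-atom predicted charges (electrons).
#' @param Q Target molecular charge (electrons).
#' @param weights Weight vector summing to 1 (see [assign_weights()]).
#' @return A [charge_set()].
#' @export
equilibrate <- function(q_pred, Q, weights) {
  if (length(weights) != length(q_pred)) {
    stop("weights length (", length(weights), ") does not match charges (",
         length(q_pred), ")")
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1 (got ", format(sum(weights)), ")")
  }
  if (any(weights < 0)) stop("weights must be nonnegative")
  dQ <- molecular_charge_error(q_pred, Q)
  charge_set(q_pred, Q, eta = weights * dQ)
}

#' Equilibration settings
#'
#' @param CEQ Scheme id: 0 disables equilibration, 1-11 are the
#'   deterministic kernels of [assign_weights()], 12-13 the iterative
#'   noise-draw variants, and -1 a custom plug-in (see
#'   [load_custom_scheme()]).
#' @param Sigma Multiplier on each element's error standard deviation when
#'   drawing iterative noise (unitless, > 0).
#' @param Qtoler Maximum tolerated residual molecular charge in the
#'   iterative schemes (electrons, > 0).
#' @param seed Integer seed for the iterative draws.
#' @param max_iter Iteration cap (>= 1).
#' @param custom_path Path to the plug-in file when `CEQ = -1`.
#' @return A validated `equilibration_settings` list.
#' @export
equilibration_settings <- function(CEQ = 1L, Sigma = 1, Qtoler = 1e-4,
                                   seed = 1L, max_iter = 10000L,
                                   custom_path = NULL) {
  CEQ <- as.integer(CEQ)
  if (!CEQ %in% c(CEQ_NONE, CEQ_SCHEMES, CEQ_ITERATIVE, CEQ_CUSTOM)) {
    stop("CEQ must be -1, 0, 1..11, 12 or 13 (got ", CEQ, ")")
  }
  if (Sigma <= 0) stop("Sigma must be > 0")
  if (Qtoler <= 0) stop("Qtoler must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (CEQ == CEQ_CUSTOM && is.null(custom_path)) {
    stop("CEQ = -1 requires a custom plug-in path")
  }
  list(CEQ = CEQ, Sigma = Sigma, Qtoler = Qtoler, seed = as.integer(seed),
       max_iter = as.integer(max_iter), custom_path = custom_path)
}

#' Iterative noise-draw equilibration
#'
#' Repeatedly proposes corrections drawn from each element's error
#' distribution `Normal(mu_e, (Sigma * sigma_e)^2)`, accepting a proposal
#' only when it strictly reduces the residual `|dQ|`. Two variants are
#' exposed: `CEQ = 12` draws independently per atom; `CEQ = 13` draws one
#' shared standard-normal deviate per iteration, scaled by each element's
#' `Sigma * sigma_e` around `mu_e`. Iteration stops when `|dQ| <= Qtoler`
#' or after `max_iter` proposals; any remaining residual is then removed by
#' a uniform redistribution so the corrected charges sum to `Q` exactly
#' (up to roundoff). Identical seeds give identical output.
#'
#' @param q_pred Per-atom predicted charges (electrons).
#' @param Q Target molecular charge (electrons).
#' @param symbols Per-atom element symbols.
#' @param stats An `error_stats` object covering all elements present.
#' @param settings An [equilibration_settings()] with `CEQ` 12 or 13.
#' @return A [charge_set()]; `iterations` counts accepted and rejected
#'   proposals together.
#' @export
iterative_equilibrate <- function(q_pred, Q, symbols,
                                  stats = default_error_stats(),
                                  settings = equilibration_settings(CEQ = 12L)) {
  if (!settings$CEQ %in% CEQ_ITERATIVE) {
    stop("iterative equilibration requires CEQ = 12 or 13")
  }
  if (length(symbols) != length(q_pred)) stop("symbols length does not match charges")
  st <- stats_for_symbols(stats, symbols, what = "iterative equilibration")
  n <- length(q_pred)
  scale <- settings$Sigma * st$sigma

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(settings$seed)

  q_cur <- q_pred
  dq <- molecular_charge_error(q_cur, Q)
  iter <- 0L
  while (abs(dq) > settings$Qtoler && iter < settings$max_iter) {
    iter <- iter + 1L
    draw <- if (settings$CEQ == 12L) {
      stats::rnorm(n, mean = st$mu, sd = scale)
    } else {
      st$mu + stats::rnorm(1L) * scale
    }
    q_prop <- q_cur - draw
    dq_prop <- molecular_charge_error(q_prop, Q)
    if (abs(dq_prop) < abs(dq)) {
      q_cur <- q_prop
      dq <- dq_prop
    }
  }
  # deterministic cleanup: spread whatever residual remains uniformly
  q_final <- q_cur - dq / n
  charge_set(q_pred, Q, eta = q_pred - q_final, iterations = iter)
}

#' Load a custom weight-assignment plug-in
#'
#' Sources an R file that must define a function
#' `assign_custom_weights(symbols, q_pred, stats, elements)` returning a
#' per-atom weight vector. The returned procedure validates its output on
#' every call: weights must be numeric of the right length, nonnegative and
#' sum to 1 (within 1e-8).
#'
#' @param path Path to the plug-in R file.
#' @return A function with signature
#'   `(symbols, q_pred, stats, elements) -> weights`.
#' @export
load_custom_scheme <- function(path) {
  if (!file.exists(path)) stop("custom scheme file not found: ", path)
  env <- new.env(parent = globalenv())
  sys.source(path, envir = env)
  fn <- env$assign_custom_weights
  if (!is.function(fn)) {
    fns <- Filter(is.function, as.list(env))
    if (length(fns) == 1L) fn <- fns[[1L]]
    else stop(path, " must define a function 'assign_custom_weights'")
  }
  function(symbols, q_pred, stats = default_error_stats(),
           elements = element_table()) {
    w <- fn(symbols, q_pred, stats, elements)
    if (!is.numeric(w) || length(w) != length(symbols)) {
      stop("custom scheme returned ", length(w), " weights for ",
           length(symbols), " atoms")
    }
    if (any(w < 0)) stop("custom scheme returned negative weights")
    if (abs(sum(w) - 1) > 1e-8) {
      stop("custom scheme weights must sum to 1 (got ", format(sum(w)), ")")
    }
    w
  }
}

#' Run charge equilibration per settings
#'
#' Dispatch over the full scheme vocabulary: `CEQ = 0` returns the
#' predictions unchanged (with zero corrections), 1-11 apply
#' [assign_weights()] + [equilibrate()], 12-13 run
#' [iterative_equilibrate()], and -1 uses the plug-in at
#' `settings$custom_path`.
#'
#' @param q_pred Per-atom predicted charges (electrons).
#' @param Q Target molecular charge (electrons).
#' @param symbols Per-atom element symbols.
#' @param settings An [equilibration_settings()].
#' @param stats An `error_stats` object.
#' @param elements Element constants table.
#' @return A [charge_set()].
#' @export
run_equilibration <- function(q_pred, Q, symbols,
                              settings = equilibration_settings(),
                              stats = default_error_stats(),
                              elements = element_table()) {
  if (settings$CEQ == CEQ_NONE) {
    return(charge_set(q_pred, Q, eta = rep(0, length(q_pred))))
  }
  if (settings$CEQ %in% CEQ_ITERATIVE) {
    return(iterative_equilibrate(q_pred, Q, symbols, stats, settings))
  }
  w <- if (settings$CEQ == CEQ_CUSTOM) {
    load_custom_scheme(settings$custom_path)(symbols, q_pred, stats, elements)
  } else {
    assign_weights(settings$CEQ, symbols, q_pred, stats, elements)
  }
  equilibrate(q_pred, Q, w)
}
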