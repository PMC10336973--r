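# Symmetry-function calculator: atom-centered symmetry functions (ACSF) and
# per-atom atomic environment vectors (AEVs).
#
# Functional forms are the canonical descriptor family: cosine cutoff,
# Gaussian radial functions (G2) and narrow (G4) / wide (G5) angular
# functions. All distances in Angstrom; descriptors are unitless. Open
# boundaries only (no periodic images).

#' Construct an ACSF configuration
#'
#' The configuration fixes, per center element, the ordered list of radial
#' and angular symmetry-function parameters; its file order defines the AEV
#' slot order (all radial slots first, then all angular slots).
#'
#' @param element_types Character vector of supported element symbols.
#' @param radial Data frame with columns `center`, `neighbor`, `Rc` (cutoff,
#'   Angstrom), `eta` (width, 1/Angstrom^2), `Rs` (shift, Angstrom).
#' @param angular Data frame with columns `center`, `n1`, `n2` (the neighbor
#'   element pair), `Rc`, `eta`, `zeta` (>= 1), `lambda` (+1 or -1),
#'   `variant` (`"narrow"` for G4 or `"wide"` for G5) and optional `Rs`
#'   (radial shift, default 0).
#' @return An object of class `acsf_config`.
#' @export
acsf_config <- function(element_types, radial, angular) {
  element_types <- canonical_symbol(element_types)
  if (anyDuplicated(element_types)) stop("duplicate element in element_types")
  radial <- as.data.frame(radial, stringsAsFactors = FALSE)
  angular <- as.data.frame(angular, stringsAsFactors = FALSE)
  need_rad <- c("center", "neighbor", "Rc", "eta", "Rs")
  if (!all(need_rad %in% names(radial))) {
    stop("radial parameters need columns: ", paste(need_rad, collapse = ", "))
  }
  if (!"Rs" %in% names(angular)) angular$Rs <- 0
  need_ang <- c("center", "n1", "n2", "Rc", "eta", "zeta", "lambda", "variant", "Rs")
  if (!all(need_ang %in% names(angular))) {
    stop("angular parameters need columns: ",
         paste(setdiff(need_ang, names(angular)), collapse = ", "))
  }
  radial$center <- canonical_symbol(radial$center)
  radial$neighbor <- canonical_symbol(radial$neighbor)
  angular$center <- canonical_symbol(angular$center)
  angular$n1 <- canonical_symbol(angular$n1)
  angular$n2 <- canonical_symbol(angular$n2)
  for (col in c(radial$center, radial$neighbor, angular$center, angular$n1, angular$n2)) {
    if (!all(col %in% element_types)) {
      stop("unknown element in ACSF parameters: ",
           paste(setdiff(col, element_types), collapse = ", "))
    }
  }
  if (any(radial$Rc <= 0) || any(angular$Rc <= 0)) stop("all cutoffs must be > 0")
  if (any(angular$zeta < 1)) stop("zeta must be >= 1")
  if (!all(angular$lambda %in% c(-1, 1))) stop("lambda must be +1 or -1")
  if (!all(angular$variant %in% c("narrow", "wide"))) {
    stop("angular variant must be 'narrow' (G4) or 'wide' (G5)")
  }
  radial <- radial[need_rad]
  angular <- angular[need_ang]
  rownames(radial) <- NULL
  rownames(angular) <- NULL
  structure(list(element_types = element_types, radial = radial,
                 angular = angular),
            class = "acsf_config")
}

#' @export
print.acsf_config <- function(x, ...) {
  cat(sprintf("ACSF configuration: elements %s; %d radial, %d angular records\n",
              paste(x$element_types, collapse = " "),
              nrow(x$radial), nrow(x$angular)))
  for (el in x$element_types) {
    cat(sprintf("  %-2s AEV length %d (%d radial + %d angular)\n", el,
                aev_length(x, el), sum(x$radial$center == el),
                sum(x$angular$center == el)))
  }
  invisible(x)
}

#' AEV length for a center element
#'
#' @param config An [acsf_config()].
#' @param element Center element symbol.
#' @return Integer descriptor length (radial + angular slot count).
#' @export
aev_length <- function(config, element) {
  element <- canonical_symbol(element)
  sum(config$radial$center == element) + sum(config$angular$center == element)
}

read_param_lines <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  which_keep <- which(lines != "")
  list(fields = strsplit(lines[which_keep], "[[:space:]]+"), lineno = which_keep)
}

num_field <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    stop(sprintf("%s: line %d: non-numeric %s '%s'", path, lineno, what,
                 x[which(is.na(v))[1]]))
  }
  v
}

#' Parse ACSF parameter files
#'
#' Reads the three plain-text parameter files defining a symmetry-function
#' set. All files are whitespace-separated with `#` comments:
#' * `input.type` — the supported element symbols;
#' * `input.rad` — one radial record per line:
#'   `center neighbor Rc eta Rs`;
#' * `input.ang` — one angular record per line:
#'   `center n1 n2 Rc eta zeta lambda variant [Rs]`.
#'
#' @param rad_path,ang_path,type_path Paths to `input.rad`, `input.ang` and
#'   `input.type`.
#' @return An [acsf_config()]; file order fixes AEV slot order.
#' @export
parse_acsf_config <- function(rad_path, ang_path, type_path) {
  for (p in c(rad_path, ang_path, type_path)) {
    if (!file.exists(p)) stop("ACSF parameter file not found: ", p)
  }
  types <- unlist(read_param_lines(type_path)$fields)
  if (length(types) == 0) stop(type_path, ": no element types found")

  rl <- read_param_lines(rad_path)
  radial <- do.call(rbind, lapply(seq_along(rl$fields), function(i) {
    f <- rl$fields[[i]]
    if (length(f) != 5L) {
      stop(sprintf("%s: line %d: expected 5 fields (center neighbor Rc eta Rs), got %d",
                   rad_path, rl$lineno[i], length(f)))
    }
    v <- num_field(f[3:5], rad_path, rl$lineno[i], "radial parameter")
    data.frame(center = f[1], neighbor = f[2], Rc = v[1], eta = v[2], Rs = v[3],
               stringsAsFactors = FALSE)
  }))

  al <- read_param_lines(ang_path)
  angular <- do.call(rbind, lapply(seq_along(al$fields), function(i) {
    f <- al$fields[[i]]
    if (!length(f) %in% c(8L, 9L)) {
      stop(sprintf("%s: line %d: expected 8 or 9 fields (center n1 n2 Rc eta zeta lambda variant [Rs]), got %d",
                   ang_path, al$lineno[i], length(f)))
    }
    v <- num_field(f[4:7], ang_path, al$lineno[i], "angular parameter")
    rs <- if (length(f) == 9L) num_field(f[9], ang_path, al$lineno[i], "Rs") else 0
    data.frame(center = f[1], n1 = f[2], n2 = f[3], Rc = v[1], eta = v[2],
               zeta = v[3], lambda = v[4], variant = f[8], Rs = rs,
               stringsAsFactors = FALSE)
  }))
  if (is.null(radial)) radial <- data.frame(center = character(), neighbor = character(),
                                            Rc = numeric(), eta = numeric(), Rs = numeric())
  if (is.null(angular)) angular <- data.frame(center = character(), n1 = character(),
                                              n2 = character(), Rc = numeric(),
                                              eta = numeric(), zeta = numeric(),
                                              lambda = numeric(), variant = character(),
                                              Rs = numeric())
  acsf_config(types, radial, angular)
}

#' Write ACSF parameter files
#'
#' Inverse of [parse_acsf_config()]; used when persisting a model bundle.
#'
#' @param config An [acsf_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_acsf_config <- function(config, dir) {
  stopifnot(inherits(config, "acsf_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(c("# supported element types", paste(config$element_types, collapse = " ")),
             file.path(dir, "input.type"))
  r <- config$radial
  writeLines(c("# center neighbor Rc eta Rs",
               sprintf("%s %s %.12g %.12g %.12g", r$center, r$neighbor, r$Rc, r$eta, r$Rs)),
             file.path(dir, "input.rad"))
  a <- config$angular
  writeLines(c("# center n1 n2 Rc eta zeta lambda variant Rs",
               sprintf("%s %s %s %.12g %.12g %.12g %d %s %.12g", a$center, a$n1, a$n2,
                       a$Rc, a$eta, a$zeta, as.integer(a$lambda), a$variant, a$Rs)),
             file.path(dir, "input.ang"))
  invisible(dir)
}

# Canonical text form of a config; bundle persistence compares these to
# detect ACSF files edited after training.
acsf_fingerprint <- function(config) {
  r <- config$radial
  a <- config$angular
  paste(c(paste(config$element_types, collapse = " "),
          sprintf("R %s %s %.12g %.12g %.12g", r$center, r$neighbor, r$Rc, r$eta, r$Rs),
          sprintf("A %s %s %s %.12g %.12g %.12g %d %s %.12g", a$center, a$n1, a$n2,
                  a$Rc, a$eta, a$zeta, as.integer(a$lambda), a$variant, a$Rs)),
        collapse = "\n")
}

#' Default ACSF configuration for CHON molecules
#'
#' A compact general-purpose set: per neighbor element, Gaussian radial
#' functions on a ladder of shifts, plus narrow (G4) angular functions for
#' every unordered neighbor-element pair at both angular parities.
#'
#' @param elements Element symbols to support.
#' @param Rc Cutoff radius, Angstrom.
#' @param radial_shifts Radial Gaussian centers `Rs`, Angstrom.
#' @param radial_eta Radial Gaussian width, 1/Angstrom^2.
#' @param angular_eta Angular Gaussian width, 1/Angstrom^2.
#' @param zeta Angular sharpness exponent.
#' @return An [acsf_config()].
#' @export
default_acsf_config <- function(elements = c("C", "H", "O", "N"), Rc = 4.5,
                                radial_shifts = c(0.8, 1.15, 1.5, 2.0, 2.8),
                                radial_eta = 4, angular_eta = 0.25, zeta = 1) {
  elements <- canonical_symbol(elements)
  radial <- expand.grid(center = elements, neighbor = elements,
                        Rs = radial_shifts, stringsAsFactors = FALSE)
  radial <- radial[order(match(radial$center, elements),
                         match(radial$neighbor, elements), radial$Rs), ]
  radial$Rc <- Rc
  radial$eta <- radial_eta
  pairs <- expand.grid(i = seq_along(elements), j = seq_along(elements))
  pairs <- pairs[pairs$i <= pairs$j, ]
  angular <- do.call(rbind, lapply(elements, function(ce) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
      data.frame(center = ce, n1 = elements[pairs$i[p]], n2 = elements[pairs$j[p]],
                 Rc = Rc, eta = angular_eta, zeta = zeta, lambda = c(1, -1),
                 variant = "narrow", Rs = 0, stringsAsFactors = FALSE)
    }))
  }))
  acsf_config(elements, radial, angular)
}

#' Cosine cutoff function
#'
#' Smoothly damps neighbor contributions to zero at the cutoff radius:
#' `0.5 * (cos(pi * r / Rc) + 1)` for `r <= Rc`, exactly 0 beyond.
#'
#' @param r Distance(s), Angstrom (vectorized).
#' @param Rc Cutoff radius, Angstrom.
#' @return Unitless damping value(s) in `[0, 1]`.
#' @export
cutoff_function <- function(r, Rc) {
  if (any(r < 0)) stop("distances must be nonnegative")
  if (Rc <= 0) stop("cutoff radius must be positive")
  ifelse(r <= Rc, 0.5 * (cos(pi * r / Rc) + 1), 0)
}

mol_distance_matrix <- function(mol) {
  d <- as.matrix(stats::dist(mol$coords))
  dimnames(d) <- NULL
  d
}

#' Radial symmetry function (G2)
#'
#' Sum over neighbors `j` of the requested element (excluding the center) of
#' `exp(-eta * (R_ij - Rs)^2) * fc(R_ij)`.
#'
#' @param mol A [molecule()].
#' @param center 1-based atom index of the center atom.
#' @param param One-row data frame (or list) with fields `center`,
#'   `neighbor`, `Rc`, `eta`, `Rs`.
#' @param dmat Optional precomputed distance matrix.
#' @return Unitless scalar.
#' @export
radial_sf <- function(mol, center, param, dmat = mol_distance_matrix(mol)) {
  if (center < 1 || center > mol$N) stop("center index out of bounds")
  if (canonical_symbol(param$center) != mol$symbols[center]) {
    stop("parameter center element (", param$center,
         ") does not match atom ", center, " (", mol$symbols[center], ")")
  }
  j <- which(mol$symbols == canonical_symbol(param$neighbor))
  j <- j[j != center]
  if (length(j) == 0) return(0)
  r <- dmat[center, j]
  if (any(r == 0)) stop("degenerate geometry: zero-length interatomic distance")
  sum(exp(-param$eta * (r - param$Rs)^2) * cutoff_function(r, param$Rc))
}

angular_neighbor_pairs <- function(symbols, center, n1, n2) {
  if (n1 == n2) {
    idx <- which(symbols == n1)
    idx <- idx[idx != center]
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    list(j = cmb[1, ], k = cmb[2, ])
  } else {
    i1 <- which(symbols == n1); i1 <- i1[i1 != center]
    i2 <- which(symbols == n2); i2 <- i2[i2 != center]
    if (length(i1) == 0 || length(i2) == 0) return(NULL)
    g <- expand.grid(j = i1, k = i2)
    list(j = g$j, k = g$k)
  }
}

#' Angular symmetry function (G4 narrow / G5 wide)
#'
#' Sum over unordered neighbor pairs `(j, k)` matching the configured
#' element pair of
#' `2^(1-zeta) * (1 + lambda*cos(theta_jik))^zeta *
#'  exp(-eta*((R_ij-Rs)^2 + (R_ik-Rs)^2 + (R_jk-Rs)^2)) *
#'  fc(R_ij) * fc(R_ik) * fc(R_jk)`
#' for the narrow (G4) variant; the wide (G5) variant omits the `R_jk`
#' Gaussian term and its cutoff factor. `theta_jik` is the angle at the
#' center atom.
#'
#' @inheritParams radial_sf
#' @param param One-row data frame (or list) with fields `center`, `n1`,
#'   `n2`, `Rc`, `eta`, `zeta`, `lambda`, `variant`, `Rs`.
#' @return Unitless scalar.
#' @export
angular_sf <- function(mol, center, param, dmat = mol_distance_matrix(mol)) {
  if (center < 1 || center > mol$N) stop("center index out of bounds")
  prs <- angular_neighbor_pairs(mol$symbols, center,
                                canonical_symbol(param$n1), canonical_symbol(param$n2))
  if (is.null(prs)) return(0)
  rij <- dmat[center, prs$j]
  rik <- dmat[center, prs$k]
  rjk <- dmat[cbind(prs$j, prs$k)]
  if (any(rij == 0) || any(rik == 0)) {
    stop("degenerate geometry: zero-length bond at the center atom")
  }
  vj <- mol$coords[prs$j, , drop = FALSE] - rep(mol$coords[center, ], each = length(prs$j))
  vk <- mol$coords[prs$k, , drop = FALSE] - rep(mol$coords[center, ], each = length(prs$k))
  cosang <- rowSums(vj * vk) / (rij * rik)
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- pmax(0, 1 + param$lambda * cosang)^param$zeta
  fc_ij <- cutoff_function(rij, param$Rc)
  fc_ik <- cutoff_function(rik, param$Rc)
  if (param$variant == "narrow") {
    gauss <- exp(-param$eta * ((rij - param$Rs)^2 + (rik - param$Rs)^2 + (rjk - param$Rs)^2))
    fcs <- fc_ij * fc_ik * cutoff_function(rjk, param$Rc)
  } else {
    gauss <- exp(-param$eta * ((rij - param$Rs)^2 + (rik - param$Rs)^2))
    fcs <- fc_ij * fc_ik
  }
  2^(1 - param$zeta) * sum(ang * gauss * fcs)
}

#' Compute atomic environment vectors
#'
#' Assembles one AEV per atom: all radial slots for the atom's element in
#' configuration order, then all angular slots. AEVs are invariant under
#' rigid motions and reflections of the molecule and equivariant under atom
#' relabeling; atoms beyond every configured cutoff contribute exactly zero.
#'
#' @param mol A [molecule()].
#' @param config An [acsf_config()] covering every element in `mol`.
#' @return A list of length `mol$N`; each entry is a numeric descriptor
#'   vector with attribute `"element"` set to the owning atom's symbol.
#' @export
compute_aev <- function(mol, config) {
  stopifnot(inherits(mol, "molecule"), inherits(config, "acsf_config"))
  missing <- setdiff(unique(mol$symbols), config$element_types)
  if (length(missing) > 0) {
    stop("unsupported element(s) not in ACSF configuration: ",
         paste(missing, collapse = ", "))
  }
  dmat <- mol_distance_matrix(mol)
  lapply(seq_len(mol$N), function(i) {
    el <- mol$symbols[i]
    rad <- config$radial[config$radial$center == el, , drop = FALSE]
    ang <- config$angular[config$angular$center == el, , drop = FALSE]
    v_rad <- if (nrow(rad) > 0) {
      vapply(seq_len(nrow(rad)), function(p) {
        radial_sf(mol, i, rad[p, ], dmat = dmat)
      }, numeric(1))
    } else numeric(0)
    v_ang <- if (nrow(ang) > 0) {
      vapply(seq_len(nrow(ang)), function(p) {
        angular_sf(mol, i, ang[p, ], dmat = dmat)
      }, numeric(1))
    } else numeric(0)
    structure(c(v_rad, v_ang), element = el)
  })
}
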