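# Molecular geometry containers and XYZ / extended-XYZ / .nnaim file I/O.
# Coordinates are Cartesian, in Angstrom; atom order is never permuted.

#' Construct a molecule
#'
#' @param symbols Character vector of element symbols, in atom order.
#' @param coords Numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param Q Target total molecular charge in electrons (default 0).
#' @return An object of class `molecule` with fields `symbols`, `coords`,
#'   `Q` and atom count `N`.
#' @export
molecule <- function(symbols, coords, Q = 0) {
  symbols <- canonical_symbol(symbols)
  coords <- as.matrix(coords)
  if (length(symbols) < 1L) stop("a molecule needs at least one atom")
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) != length(symbols)) {
    stop("coords must be a numeric matrix with one row of 3 per atom")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (length(Q) != 1L || !is.finite(Q)) stop("Q must be a single finite number")
  dimnames(coords) <- NULL
  structure(list(symbols = symbols, coords = coords, Q = Q,
                 N = length(symbols)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s), Q = %g e\n", x$N,
              paste(sort(unique(x$symbols)), collapse = ""), x$Q))
  invisible(x)
}

parse_xyz_frame <- function(lines, start, path, frame, n_extra = 0L) {
  if (start > length(lines)) return(NULL)
  count_line <- trimws(lines[start])
  if (count_line == "") return(NULL)
  n <- suppressWarnings(as.integer(count_line))
  if (is.na(n) || n < 1L) {
    stop(sprintf("%s: line %d: expected a positive atom count, got '%s'",
                 path, start, count_line))
  }
  comment <- if (start + 1L <= length(lines)) lines[start + 1L] else
    stop(sprintf("%s: frame %d: truncated after the count line", path, frame))
  body_end <- start + 1L + n
  if (body_end > length(lines)) {
    stop(sprintf("%s: frame %d: declares %d atoms but the file ends after %d atom line(s)",
                 path, frame, n, length(lines) - start - 1L))
  }
  symbols <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  extras <- if (n_extra > 0L) matrix(NA_real_, n, n_extra) else NULL
  for (i in seq_len(n)) {
    lineno <- start + 1L + i
    fields <- strsplit(trimws(lines[lineno]), "[[:space:]]+")[[1]]
    if (length(fields) < 4L + n_extra) {
      stop(sprintf("%s: frame %d, line %d: expected %d fields (symbol x y z%s), got %d",
                   path, frame, lineno, 4L + n_extra,
                   if (n_extra > 0L) " + per-atom value(s)" else "",
                   length(fields)))
    }
    symbols[i] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[2:(4L + n_extra)]))
    if (any(is.na(vals))) {
      stop(sprintf("%s: frame %d, line %d: unparsable numeric field", path, frame, lineno))
    }
    coords[i, ] <- vals[1:3]
    if (n_extra > 0L) extras[i, ] <- vals[4:(3L + n_extra)]
  }
  # Consistency guard: the next non-empty line (if any) must be a new count
  # line, otherwise the declared count did not match the body.
  nxt <- body_end + 1L
  if (nxt <= length(lines) && trimws(lines[nxt]) != "") {
    nxt_fields <- strsplit(trimws(lines[nxt]), "[[:space:]]+")[[1]]
    if (length(nxt_fields) != 1L ||
        is.na(suppressWarnings(as.integer(nxt_fields[1])))) {
      stop(sprintf("%s: frame %d: count line declares %d atoms but line %d continues the frame",
                   path, frame, n, nxt))
    }
  }
  list(symbols = symbols, coords = coords, extras = extras,
       comment = comment, next_start = nxt)
}

# Parse "charge=<int>" (case-insensitive) from an XYZ comment line.
charge_from_comment <- function(comment) {
  m <- regmatches(comment, regexpr("charge=[-+]?[0-9]+", comment, ignore.case = TRUE))
  if (length(m) == 0) return(NULL)
  as.numeric(sub("(?i)charge=", "", m[1], perl = TRUE))
}

#' Read a molecule from an XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then one
#' `symbol x y z` line per atom (coordinates in Angstrom). The total
#' molecular charge defaults to 0; a `charge=<int>` token on the comment
#' line overrides it, and the `Q` argument overrides both.
#'
#' @param path File path.
#' @param Q Optional molecular charge (electrons) overriding the file.
#' @return A [molecule()].
#' @export
read_xyz <- function(path, Q = NULL) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0 || all(trimws(lines) == "")) {
    stop(path, ": empty file, expected XYZ format")
  }
  fr <- parse_xyz_frame(lines, 1L, path, 1L)
  lookups <- vapply(unique(fr$symbols), function(s) {
    lookup_element(s)
    TRUE
  }, logical(1))
  q <- if (!is.null(Q)) Q else {
    qc <- charge_from_comment(fr$comment)
    if (is.null(qc)) 0 else qc
  }
  molecule(fr$symbols, fr$coords, Q = q)
}

#' Read labeled frames from an extended XYZ file
#'
#' Extended XYZ: concatenated XYZ frames whose atom lines carry one trailing
#' per-atom property value after the coordinates. Used as training input.
#'
#' @param path File path.
#' @param units Units string recorded on each frame's targets (metadata only).
#' @return A list of `labeled_molecule` objects, each a list with fields
#'   `molecule` and `targets` (numeric, one value per atom).
#' @export
read_extended_xyz <- function(path, units = "electrons") {
  if (!file.exists(path)) stop("extended XYZ file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  start <- 1L
  frame <- 1L
  while (start <= length(lines) && trimws(lines[start]) != "") {
    fr <- parse_xyz_frame(lines, start, path, frame, n_extra = 1L)
    if (is.null(fr)) break
    qc <- charge_from_comment(fr$comment)
    mol <- molecule(fr$symbols, fr$coords, Q = if (is.null(qc)) 0 else qc)
    frames[[frame]] <- structure(
      list(molecule = mol, targets = as.numeric(fr$extras[, 1]), units = units),
      class = "labeled_molecule")
    start <- fr$next_start
    frame <- frame + 1L
  }
  if (length(frames) == 0) stop(path, ": empty file, expected extended XYZ format")
  frames
}

#' Write a molecule as XYZ
#'
#' @param mol A [molecule()].
#' @param path Output file path.
#' @param comment Comment line; a `charge=<Q>` token is appended when the
#'   molecular charge is nonzero so it round-trips through [read_xyz()].
#' @param targets Optional per-atom values appended as a trailing column
#'   (extended XYZ).
#' @param append Append to the file instead of overwriting (multi-frame).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = "", targets = NULL, append = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  if (!is.null(targets) && length(targets) != mol$N) {
    stop("targets length (", length(targets), ") does not match atom count (", mol$N, ")")
  }
  if (mol$Q != 0 && !grepl("charge=", comment, ignore.case = TRUE)) {
    comment <- trimws(paste(comment, sprintf("charge=%g", mol$Q)))
  }
  body <- if (is.null(targets)) {
    sprintf("%-3s %17.10f %17.10f %17.10f", mol$symbols,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  } else {
    sprintf("%-3s %17.10f %17.10f %17.10f %17.10g", mol$symbols,
            mol$coords[, 1], mol$coords[, 2], mol$coords[, 3], targets)
  }
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(c(as.character(mol$N), comment, body), con)
  invisible(path)
}

#' Write per-atom prediction results (.nnaim table)
#'
#' Writes a human-readable whitespace-separated table with a commented
#' header: 1-based atom index, element symbol, raw predicted value and,
#' when supplied, the equilibrated (corrected) value.
#'
#' @param mol A [molecule()].
#' @param raw Per-atom raw predictions (length `mol$N`).
#' @param corrected Optional per-atom corrected values (length `mol$N`).
#' @param path Output file path (conventionally `.nnaim`).
#' @param property Name of the property, for the header.
#' @param units Units of the property, for the header.
#' @return `path`, invisibly.
#' @export
write_nnaim <- function(mol, raw, corrected = NULL, path,
                        property = "atomic charge", units = "electrons") {
  stopifnot(inherits(mol, "molecule"))
  if (length(raw) != mol$N) {
    stop("raw values length (", length(raw), ") does not match atom count (", mol$N, ")")
  }
  if (!is.null(corrected) && length(corrected) != mol$N) {
    stop("corrected values length (", length(corrected),
         ") does not match atom count (", mol$N, ")")
  }
  idx <- seq_len(mol$N)
  if (is.null(corrected)) {
    header <- sprintf("# %s [%s]", property, units)
    cols <- "# index symbol raw"
    body <- sprintf("%5d %-3s %15.8g", idx, mol$symbols, raw)
  } else {
    header <- sprintf("# %s [%s]; corrected = after charge equilibration", property, units)
    cols <- "# index symbol raw corrected"
    body <- sprintf("%5d %-3s %15.8g %15.8g", idx, mol$symbols, raw, corrected)
  }
  writeLines(c(header, cols, body), path)
  invisible(path)
}
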