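# Per-element physical constants and prediction-error statistics.

.aimcharge_cache <- new.env(parent = emptyenv())

element_data_path <- function() {
  system.file("extdata", "element_data.tsv", package = "aimcharge", mustWork = TRUE)
}

#' Table of per-element constants
#'
#' Returns the table of per-element constants shipped with the package:
#' atomic number `Z`, Sanderson electronegativity `chi_S`, Pauling
#' electronegativity `chi_P` and covalent radius `r_cov` (Angstrom), together
#' with the default per-element prediction-error statistics `mu` and `sigma`
#' (electrons). These constants feed the charge-equilibration weight kernels.
#'
#' @param path Optional path to an alternative tab-separated table with the
#'   same columns; defaults to the file shipped under `extdata`.
#' @return A data.frame with one row per element and columns `symbol`, `Z`,
#'   `chi_S`, `chi_P`, `r_cov`, `mu`, `sigma`.
#' @export
element_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.aimcharge_cache$element_table)) {
      return(.aimcharge_cache$element_table)
    }
    path <- element_data_path()
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  required <- c("symbol", "Z", "chi_S", "chi_P", "r_cov", "mu", "sigma")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("element table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(tab$Z < 1) || any(tab$chi_S <= 0) || any(tab$chi_P <= 0) ||
      any(tab$r_cov <= 0) || any(tab$sigma < 0)) {
    stop("element table violates constraints (Z >= 1, chi > 0, r_cov > 0, sigma >= 0)")
  }
  rownames(tab) <- toupper(tab$symbol)
  if (cache) .aimcharge_cache$element_table <- tab
  tab
}

canonical_symbol <- function(symbol) {
  s <- as.character(symbol)
  paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, nchar(s))))
}

#' Look up one element's constants
#'
#' Case-insensitive lookup of a single element in [element_table()].
#'
#' @param symbol Element symbol, e.g. `"C"` or `"h"`.
#' @param table Optional table from [element_table()].
#' @return A one-row list with fields `symbol` (canonicalized), `Z`, `chi_S`,
#'   `chi_P`, `r_cov`, `mu`, `sigma`.
#' @export
lookup_element <- function(symbol, table = element_table()) {
  stopifnot(length(symbol) == 1L)
  key <- toupper(as.character(symbol))
  if (!key %in% rownames(table)) {
    stop("unsupported element: '", symbol, "'")
  }
  row <- table[key, , drop = FALSE]
  list(symbol = canonical_symbol(row$symbol), Z = as.integer(row$Z),
       chi_S = row$chi_S, chi_P = row$chi_P, r_cov = row$r_cov,
       mu = row$mu, sigma = row$sigma)
}

#' Default per-element error statistics
#'
#' Gaussian parameters (mean `mu`, standard deviation `sigma`, in electrons)
#' of the per-element charge-prediction error distributions shipped as
#' defaults, as obtained from normal fits to validation errors of the
#' reference CHON charge models. Used by the error-statistics-weighted
#' equilibration kernels and by the iterative noise-draw schemes.
#'
#' @return An object of class `error_stats`: a list with named numeric
#'   vectors `mu` and `sigma` (electrons), indexed by element symbol.
#' @export
default_error_stats <- function() {
  tab <- element_table()
  error_stats(mu = stats::setNames(tab$mu, canonical_symbol(tab$symbol)),
              sigma = stats::setNames(tab$sigma, canonical_symbol(tab$symbol)))
}

#' Construct per-element error statistics
#'
#' @param mu Named numeric vector of mean prediction errors (electrons).
#' @param sigma Named numeric vector of error standard deviations (electrons),
#'   with the same element names as `mu`.
#' @return An `error_stats` object.
#' @export
error_stats <- function(mu, sigma) {
  if (is.null(names(mu)) || is.null(names(sigma))) {
    stop("mu and sigma must be named by element symbol")
  }
  names(mu) <- canonical_symbol(names(mu))
  names(sigma) <- canonical_symbol(names(sigma))
  if (!setequal(names(mu), names(sigma))) {
    stop("mu and sigma must cover the same elements")
  }
  sigma <- sigma[names(mu)]
  if (any(sigma < 0)) stop("sigma must be >= 0 for every element")
  structure(list(mu = mu, sigma = sigma), class = "error_stats")
}

#' Read per-element error statistics from file
#'
#' Reads a whitespace-separated table with columns `symbol`, `mu`, `sigma`
#' (comment lines start with `#`), so tailor-made models can supply the
#' validation statistics of their own networks.
#'
#' @param path File path.
#' @return An `error_stats` object.
#' @export
read_error_stats <- function(path) {
  if (!file.exists(path)) stop("error-statistics file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  required <- c("symbol", "mu", "sigma")
  if (!all(required %in% names(tab))) {
    stop("error-statistics file must have columns: ", paste(required, collapse = ", "))
  }
  error_stats(mu = stats::setNames(tab$mu, tab$symbol),
              sigma = stats::setNames(tab$sigma, tab$symbol))
}

#' Write per-element error statistics to file
#'
#' @param stats An `error_stats` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_error_stats <- function(stats, path) {
  stopifnot(inherits(stats, "error_stats"))
  lines <- c("symbol mu sigma",
             sprintf("%s %.17g %.17g", names(stats$mu), stats$mu,
                     stats$sigma[names(stats$mu)]))
  writeLines(lines, path)
  invisible(path)
}

# Fetch mu/sigma for a vector of symbols, erroring with context if absent.
stats_for_symbols <- function(stats, symbols, what = "equilibration") {
  stopifnot(inherits(stats, "error_stats"))
  syms <- canonical_symbol(symbols)
  missing <- setdiff(unique(syms), names(stats$mu))
  if (length(missing) > 0) {
    stop("no error statistics for element(s) ", paste(missing, collapse = ", "),
         " required by ", what)
  }
  list(mu = unname(stats$mu[syms]), sigma = unname(stats$sigma[syms]))
}

#' @export
print.error_stats <- function(x, ...) {
  cat("Per-element prediction-error statistics (electrons)\n")
  print(data.frame(symbol = names(x$mu), mu = unname(x$mu),
                   sigma = unname(x$sigma), row.names = NULL))
  invisible(x)
}
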