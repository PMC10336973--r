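# Per-element model pipeline: dataset construction from labeled frames,
# standardization, training, prediction and bundle persistence.

#' Build a per-element training dataset
#'
#' Featurizes every frame and partitions the (AEV, target) pairs by the
#' atom's element, the layout the per-element networks train on. Every atom
#' of every frame contributes exactly one pair.
#'
#' @param frames List of `labeled_molecule` objects
#'   (see [read_extended_xyz()]).
#' @param config An [acsf_config()] covering every element present.
#' @param property Name of the target property.
#' @param units Units of the target property.
#' @return An object of class `aim_dataset`: per-element feature matrices
#'   `X` and target vectors `y`, plus the configuration and its fingerprint.
#' @export
build_dataset <- function(frames, config, property = "atomic charge",
                          units = "electrons") {
  stopifnot(inherits(config, "acsf_config"))
  if (length(frames) == 0) {
    per_element <- list()
  } else {
    rows <- lapply(frames, function(fr) {
      stopifnot(inherits(fr, "labeled_molecule"))
      if (length(fr$targets) != fr$molecule$N) {
        stop("frame has ", length(fr$targets), " targets for ",
             fr$molecule$N, " atoms")
      }
      aevs <- compute_aev(fr$molecule, config)
      list(symbols = fr$molecule$symbols, aevs = aevs, targets = fr$targets)
    })
    symbols <- unlist(lapply(rows, `[[`, "symbols"))
    targets <- unlist(lapply(rows, `[[`, "targets"))
    aevs <- do.call(c, lapply(rows, `[[`, "aevs"))
    per_element <- lapply(stats::setNames(nm = sort(unique(symbols))), function(el) {
      idx <- which(symbols == el)
      list(X = do.call(rbind, lapply(aevs[idx], as.numeric)), y = targets[idx])
    })
  }
  structure(list(per_element = per_element, property = property, units = units,
                 config = config, fingerprint = acsf_fingerprint(config)),
            class = "aim_dataset")
}

#' @export
print.aim_dataset <- function(x, ...) {
  n <- vapply(x$per_element, function(e) nrow(e$X), integer(1))
  cat(sprintf("dataset: %s [%s]; %d atoms (%s)\n", x$property, x$units,
              sum(n), paste(sprintf("%s: %d", names(n), n), collapse = ", ")))
  invisible(x)
}

#' Default training hyperparameters
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param activation Hidden activation (`"tanh"`, `"relu"` or `"sigmoid"`).
#' @param learning_rate Adam learning rate on standardized data.
#' @param epochs Maximum full-batch epochs.
#' @param validation_fraction Fraction of each element's atoms held out for
#'   early stopping; must lie strictly between 0 and 1.
#' @param patience Epochs without validation improvement before stopping.
#' @return A named list of hyperparameters.
#' @export
default_hyperparams <- function(hidden = c(64, 64), activation = "tanh",
                                learning_rate = 0.01, epochs = 2000,
                                validation_fraction = 0.1, patience = 300) {
  list(hidden = hidden, activation = activation, learning_rate = learning_rate,
       epochs = epochs, validation_fraction = validation_fraction,
       patience = patience)
}

# z-scoring helpers; zero-variance slots get unit scale so standardization
# is always invertible.
feature_stats <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = m, scale = s)
}

standardize <- function(X, st) {
  sweep(sweep(X, 2, st$mean, "-"), 2, st$scale, "/")
}

#' Train per-element feed-forward networks
#'
#' Trains one independent network per element on z-scored features and
#' targets (statistics taken from the training split), minimizing the
#' mean-squared error with full-batch Adam and early stopping on a held-out
#' validation split. The seed fixes weight initialization and the
#' train/validation shuffle, so identical inputs give identical bundles.
#'
#' @param dataset An [build_dataset()] result; must be nonempty for every
#'   element it contains.
#' @param hyperparams See [default_hyperparams()].
#' @param seed Integer RNG seed.
#' @param verbose Print a per-element summary line while training.
#' @return An object of class `model_bundle` holding the per-element
#'   networks, the standardization statistics, the ACSF configuration and
#'   the target property metadata.
#' @export
train_model <- function(dataset, hyperparams = default_hyperparams(),
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(dataset, "aim_dataset"))
  if (length(dataset$per_element) == 0) stop("cannot train on an empty dataset")
  vf <- hyperparams$validation_fraction
  if (!is.numeric(vf) || length(vf) != 1L || vf <= 0 || vf >= 1) {
    stop("validation_fraction must lie strictly between 0 and 1")
  }
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  networks <- lapply(stats::setNames(nm = names(dataset$per_element)), function(el) {
    d <- dataset$per_element[[el]]
    n <- nrow(d$X)
    if (n < 2) stop("element ", el, " has fewer than 2 training atoms")
    perm <- sample.int(n)
    n_val <- max(1L, floor(vf * n))
    val_idx <- perm[seq_len(n_val)]
    train_idx <- perm[-seq_len(n_val)]
    x_st <- feature_stats(d$X[train_idx, , drop = FALSE])
    y_mean <- mean(d$y[train_idx])
    y_scale <- stats::sd(d$y[train_idx])
    if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
    Xs <- standardize(d$X, x_st)
    ys <- (d$y - y_mean) / y_scale
    fit <- mlp_train(Xs[train_idx, , drop = FALSE], ys[train_idx],
                     Xs[val_idx, , drop = FALSE], ys[val_idx],
                     hidden = hyperparams$hidden,
                     activation = hyperparams$activation,
                     lr = hyperparams$learning_rate,
                     epochs = hyperparams$epochs,
                     patience = hyperparams$patience)
    if (verbose) {
      message(sprintf("  %-2s n=%d  val RMSE (std.) %.4f  epochs %d",
                      el, n, sqrt(fit$val_loss), fit$epochs_run))
    }
    list(net = fit$net, x_mean = x_st$mean, x_scale = x_st$scale,
         y_mean = y_mean, y_scale = y_scale,
         n_train = length(train_idx), n_val = n_val, val_idx = val_idx,
         val_rmse_std = sqrt(fit$val_loss))
  })
  structure(list(networks = networks, config = dataset$config,
                 fingerprint = dataset$fingerprint,
                 property = dataset$property, units = dataset$units,
                 hyperparams = hyperparams, seed = seed),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model bundle: %s [%s]; elements %s\n", x$property, x$units,
              paste(names(x$networks), collapse = " ")))
  invisible(x)
}

#' Predict per-atom properties
#'
#' Featurizes the molecule with the bundle's ACSF configuration and runs
#' each atom's descriptor through its element's network, destandardizing
#' the output to property units. Deterministic.
#'
#' @param mol A [molecule()].
#' @param bundle A [train_model()] or [load_bundle()] result.
#' @return Numeric vector of per-atom values in the bundle's property units.
#' @export
predict_properties <- function(mol, bundle) {
  stopifnot(inherits(mol, "molecule"), inherits(bundle, "model_bundle"))
  for (i in seq_len(mol$N)) {
    if (!mol$symbols[i] %in% names(bundle$networks)) {
      stop("no trained network for atom ", i, " ('", mol$symbols[i], "')")
    }
  }
  aevs <- compute_aev(mol, bundle$config)
  vapply(seq_len(mol$N), function(i) {
    nw <- bundle$networks[[mol$symbols[i]]]
    x <- (as.numeric(aevs[[i]]) - nw$x_mean) / nw$x_scale
    yhat <- mlp_forward(nw$net, matrix(x, nrow = 1L))
    yhat * nw$y_scale + nw$y_mean
  }, numeric(1))
}

# Doubles are persisted as %.17g strings: 17 significant digits round-trip
# IEEE doubles exactly, so loaded bundles predict bit-identically.
enc_num <- function(x) sprintf("%.17g", x)
dec_num <- function(s) as.numeric(s)
enc_mat <- function(m) list(nrow = nrow(m), data = enc_num(as.numeric(m)))
dec_mat <- function(l) matrix(dec_num(l$data), nrow = l$nrow)

#' Save a model bundle to a folder
#'
#' The folder is self-describing: the ACSF parameter files (`input.rad`,
#' `input.ang`, `input.type`), one `network_<element>.json` per element with
#' layer weights and standardization statistics (full double precision), and
#' a `manifest.json` naming the target property, units and the configuration
#' fingerprint recorded at training time.
#'
#' @param bundle A `model_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_acsf_config(bundle$config, dir)
  manifest <- list(property = bundle$property, units = bundle$units,
                   fingerprint = bundle$fingerprint,
                   elements = names(bundle$networks),
                   hyperparams = bundle$hyperparams, seed = bundle$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (el in names(bundle$networks)) {
    nw <- bundle$networks[[el]]
    payload <- list(element = el, sizes = nw$net$sizes,
                    activation = nw$net$activation,
                    W = stats::setNames(lapply(nw$net$W, enc_mat),
                                        paste0("layer", seq_along(nw$net$W))),
                    b = stats::setNames(lapply(nw$net$b, enc_num),
                                        paste0("layer", seq_along(nw$net$b))),
                    x_mean = enc_num(nw$x_mean), x_scale = enc_num(nw$x_scale),
                    y_mean = enc_num(nw$y_mean), y_scale = enc_num(nw$y_scale),
                    n_train = nw$n_train, n_val = nw$n_val,
                    val_idx = nw$val_idx, val_rmse_std = nw$val_rmse_std)
    jsonlite::write_json(payload, file.path(dir, paste0("network_", el, ".json")),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Load a model bundle from a folder
#'
#' Inverse of [save_bundle()]. The ACSF parameter files in the folder are
#' re-parsed and their fingerprint compared with the one recorded in the
#' manifest at training time; editing them after saving is an error, since
#' the networks are only valid for the descriptors they were trained on.
#' `load_bundle(save_bundle(b))` reproduces predictions bit-identically.
#'
#' @param dir Bundle directory.
#' @return A `model_bundle`.
#' @export
load_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("model folder not found: ", dir)
  needed <- c("manifest.json", "input.rad", "input.ang", "input.type")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing) > 0) {
    stop("model folder ", dir, " is missing: ", paste(missing, collapse = ", "))
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  config <- parse_acsf_config(file.path(dir, "input.rad"),
                              file.path(dir, "input.ang"),
                              file.path(dir, "input.type"))
  fp <- acsf_fingerprint(config)
  if (!identical(fp, manifest$fingerprint)) {
    stop("ACSF files in ", dir, " do not match the fingerprint recorded at ",
         "training time; the bundle's descriptors have been edited")
  }
  net_files <- file.path(dir, paste0("network_", manifest$elements, ".json"))
  missing_nets <- manifest$elements[!file.exists(net_files)]
  if (length(missing_nets) > 0) {
    stop("model folder ", dir, " is missing network file(s) for: ",
         paste(missing_nets, collapse = ", "))
  }
  networks <- lapply(stats::setNames(net_files, manifest$elements), function(f) {
    p <- jsonlite::read_json(f, simplifyVector = TRUE)
    list(net = list(W = unname(lapply(p$W, dec_mat)),
                    b = unname(lapply(p$b, dec_num)),
                    activation = p$activation, sizes = as.integer(p$sizes)),
         x_mean = dec_num(p$x_mean), x_scale = dec_num(p$x_scale),
         y_mean = dec_num(p$y_mean), y_scale = dec_num(p$y_scale),
         n_train = p$n_train, n_val = p$n_val,
         val_idx = as.integer(p$val_idx), val_rmse_std = p$val_rmse_std)
  })
  structure(list(networks = networks, config = config, fingerprint = fp,
                 property = manifest$property, units = manifest$units,
                 hyperparams = manifest$hyperparams, seed = manifest$seed),
            class = "model_bundle")
}
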