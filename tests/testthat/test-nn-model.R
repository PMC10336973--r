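# A hand-built one-element bundle around a known affine map.
handmade_bundle <- function(cfg, element, w, b0, x_mean = NULL, x_scale = NULL,
                            y_mean = 0, y_scale = 1) {
  d <- aev_length(cfg, element)
  if (is.null(x_mean)) x_mean <- rep(0, d)
  if (is.null(x_scale)) x_scale <- rep(1, d)
  net <- list(W = list(matrix(w, d, 1)), b = list(b0),
              activation = "tanh", sizes = c(d, 1L))
  structure(list(networks = stats::setNames(
    list(list(net = net, x_mean = x_mean, x_scale = x_scale,
              y_mean = y_mean, y_scale = y_scale,
              n_train = 0L, n_val = 0L, val_idx = integer(0),
              val_rmse_std = NA_real_)), element),
    config = cfg, fingerprint = aimcharge:::acsf_fingerprint(cfg),
    property = "atomic charge", units = "electrons",
    hyperparams = default_hyperparams(), seed = 1L),
    class = "model_bundle")
}

test_that("datasets partition atoms by element with exact counts", {
  cfg <- tiny_acsf_config()
  water <- water_molecule()
  frames <- lapply(1:10, function(k) {
    structure(list(molecule = water, targets = toy_charges(water),
                   units = "electrons"), class = "labeled_molecule")
  })
  ds <- build_dataset(frames, cfg)
  expect_named(ds$per_element, c("H", "O"))
  expect_equal(nrow(ds$per_element$O$X), 10L)
  expect_equal(nrow(ds$per_element$H$X), 20L)
  expect_equal(ncol(ds$per_element$H$X), aev_length(cfg, "H"))

  empty <- build_dataset(list(), cfg)
  expect_length(empty$per_element, 0L)
  expect_error(train_model(empty), "empty dataset")

  s_frame <- structure(list(molecule = molecule("S", matrix(0, 1, 3)),
                            targets = 0, units = "electrons"),
                       class = "labeled_molecule")
  expect_error(build_dataset(list(s_frame), cfg), "unsupported element")
})

test_that("hand-built networks reproduce known affine maps", {
  cfg <- tiny_acsf_config()
  mol <- water_molecule()
  aevs <- compute_aev(mol, cfg)
  d <- aev_length(cfg, "H")

  # all-zero weights: every prediction is the element's target mean
  b0 <- handmade_bundle(cfg, "H", w = rep(0, d), b0 = 0, y_mean = 0.42,
                        y_scale = 2)
  mol_h <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0.8, 0, 0)))
  expect_equal(predict_properties(mol_h, b0), c(0.42, 0.42))

  # single linear layer: prediction is the hand-computed affine map
  w <- seq_len(d) / d
  b1 <- handmade_bundle(cfg, "H", w = w, b0 = 0.25, y_mean = -0.1,
                        y_scale = 3)
  got <- predict_properties(mol_h, b1)
  aev_h <- compute_aev(mol_h, cfg)
  want <- vapply(aev_h, function(v) {
    (sum(as.numeric(v) * w) + 0.25) * 3 - 0.1
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-14)

  # element without a network
  expect_error(predict_properties(water_molecule(), b1),
               "no trained network for atom 1 \\('O'\\)")
})

test_that("training learns a constant and rejects bad fractions", {
  cfg <- tiny_acsf_config()
  frames <- generate_fixture_frames(fixture_spec(
    composition = c(O = 1, H = 2), n_molecules = 30, seed = 50))
  for (k in seq_along(frames)) frames[[k]]$targets <- rep(0.37, 3)
  ds <- build_dataset(frames, cfg)
  hp <- default_hyperparams(hidden = c(8, 8), epochs = 300)
  b <- train_model(ds, hp, seed = 3)
  pred <- predict_properties(frames[[1]]$molecule, b)
  expect_equal(pred, rep(0.37, 3), tolerance = 1e-3)

  expect_error(train_model(ds, default_hyperparams(validation_fraction = 1.5)),
               "validation_fraction")
  expect_error(train_model(ds, default_hyperparams(validation_fraction = 0)),
               "validation_fraction")
})

test_that("training recovers a linear function of the descriptors", {
  cfg <- tiny_acsf_config()
  # 100 five-atom hydrogen clusters: 500 atoms for one element's network
  frames <- generate_fixture_frames(fixture_spec(composition = c(H = 5),
                                                 n_molecules = 100, seed = 60))
  ds <- build_dataset(frames, cfg)
  dat <- ds$per_element$H
  expect_equal(nrow(dat$X), 500L)
  set.seed(61)
  beta <- stats::rnorm(ncol(dat$X), sd = 0.05)
  dat$y <- as.numeric(dat$X %*% beta) + 0.02
  ds$per_element$H <- dat
  b <- train_model(ds, default_hyperparams(hidden = c(32, 32), epochs = 800),
                   seed = 62)
  nw <- b$networks$H
  val <- nw$val_idx
  # least-squares oracle: the target is exactly representable
  df_train <- data.frame(y = dat$y[-val], dat$X[-val, , drop = FALSE])
  fit <- suppressWarnings(stats::lm(y ~ ., data = df_train))
  df_val <- data.frame(dat$X[val, , drop = FALSE])
  lm_pred <- suppressWarnings(stats::predict(fit, newdata = df_val))
  expect_lt(mean(abs(lm_pred - dat$y[val])), 1e-8)
  # the network approaches the oracle: MAE below 5% of the target spread
  Xs <- aimcharge:::standardize(dat$X[val, , drop = FALSE],
                                list(mean = nw$x_mean, scale = nw$x_scale))
  nn_pred <- aimcharge:::mlp_forward(nw$net, Xs) * nw$y_scale + nw$y_mean
  expect_lt(mean(abs(nn_pred - dat$y[val])), 0.05 * stats::sd(dat$y))
})

test_that("training is seed-reproducible and standardization invertible", {
  cfg <- tiny_acsf_config()
  frames <- generate_fixture_frames(fixture_spec(
    composition = c(C = 1, H = 3), n_molecules = 15, seed = 70))
  ds <- build_dataset(frames, cfg)
  hp <- default_hyperparams(hidden = c(8, 8), epochs = 40, patience = 40)
  b1 <- train_model(ds, hp, seed = 123)
  b2 <- train_model(ds, hp, seed = 123)
  expect_identical(b1$networks, b2$networks)
  b3 <- train_model(ds, hp, seed = 124)
  expect_false(identical(b3$networks, b1$networks))

  # standardize-then-destandardize is the identity
  nw <- b1$networks$H
  y <- stats::rnorm(20)
  expect_equal((y - nw$y_mean) / nw$y_scale * nw$y_scale + nw$y_mean, y,
               tolerance = 1e-12)
  X <- ds$per_element$H$X
  st <- list(mean = nw$x_mean, scale = nw$x_scale)
  back <- sweep(sweep(aimcharge:::standardize(X, st), 2, st$scale, "*"),
                2, st$mean, "+")
  expect_equal(back, X, tolerance = 1e-12)
})

test_that("predictions inherit rigid-motion invariance", {
  cfg <- tiny_acsf_config()
  frames <- generate_fixture_frames(fixture_spec(
    composition = c(O = 1, H = 2), n_molecules = 10, seed = 80))
  ds <- build_dataset(frames, cfg)
  b <- train_model(ds, default_hyperparams(hidden = c(8, 8), epochs = 60,
                                           patience = 60), seed = 5)
  mol <- frames[[1]]$molecule
  set.seed(81)
  moved <- random_rigid_motion(mol)
  expect_equal(predict_properties(moved, b), predict_properties(mol, b),
               tolerance = 1e-8)
})

test_that("bundles persist losslessly and guard their descriptor files", {
  cfg <- tiny_acsf_config()
  frames <- generate_fixture_frames(fixture_spec(
    composition = c(N = 1, H = 3), n_molecules = 12, seed = 90))
  ds <- build_dataset(frames, cfg)
  b <- train_model(ds, default_hyperparams(hidden = c(8, 8), epochs = 50,
                                           patience = 50), seed = 9)
  dir <- withr::local_tempdir()
  save_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c("input.rad", "input.ang",
                                               "input.type", "manifest.json")))))
  b2 <- load_bundle(dir)
  mol <- frames[[3]]$molecule
  expect_identical(predict_properties(mol, b2), predict_properties(mol, b))

  # missing piece
  file.remove(file.path(dir, "input.type"))
  expect_error(load_bundle(dir), "missing: input.type")

  # edited descriptors break the fingerprint
  dir2 <- withr::local_tempdir()
  save_bundle(b, dir2)
  rad <- readLines(file.path(dir2, "input.rad"))
  rad[2] <- sub("^(\\S+ \\S+ )\\S+", "\\13.9", rad[2])
  writeLines(rad, file.path(dir2, "input.rad"))
  expect_error(load_bundle(dir2), "fingerprint")

  expect_error(load_bundle(file.path(tempdir(), "no-such-bundle")), "not found")
})
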