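toy_classes <- function(n_per = 4, sigma = 0) {
  grid <- seq(1000, 1400, 4)
  protos <- list(a = exp(-((grid - 1100) / 20)^2),
                 b = exp(-((grid - 1300) / 20)^2))
  rows <- do.call(rbind, lapply(names(protos), function(cl) {
    t(replicate(n_per, protos[[cl]] + rnorm(length(grid), 0, sigma)))
  }))
  spectra_matrix(rows, grid,
                 labels = tibble::tibble(molecule = rep(names(protos),
                                                        each = n_per)))
}

test_that("spectra tables round-trip values, grid and labels", {
  d <- toy_classes()
  expect_equal(length(spectra_grid(d)), 101)
  expect_equal(dim(spectra_values(d)), c(8, 101))
  expect_error(spectra_matrix(matrix(1, 2, 3), 1:2), "grid")
})

test_that("PCA scores separate disjoint classes and decompose exactly", {
  d <- toy_classes()
  p <- pca_scores(d, n_components = 2)
  s1 <- p$scores$PC1
  cls <- p$scores$molecule
  expect_true(all(s1[cls == "a"] * s1[cls == "b"][1] < 0))
  # identical rows -> zero variance
  same <- spectra_matrix(matrix(1, 3, 10), 1:10)
  expect_lt(sum(pca_scores(same, 1)$explained_variance), 1e-20)
  # variance partition is exact
  x <- spectra_values(d)
  expect_equal(sum(pca_scores(d, 2)$explained_variance),
               sum(apply(x, 2, var)), tolerance = 1e-10)
  expect_error(pca_scores(d[1, ]), "at least 2")
})

test_that("linear SVM separates synthetic molecules perfectly when separable", {
  set.seed(1)
  d <- toy_classes(n_per = 10, sigma = 0.01)
  cls <- train_classifier(d, split_fraction = 0.8, cost = 1, seed = 0)
  expect_equal(cls$test_accuracy, 1)
  expect_length(intersect(cls$split$train, cls$split$test), 0)
  # train/test split sizes follow the 80/20 rule per class
  expect_equal(length(cls$split$train), 16)
  expect_error(train_classifier(d[1:10, ]), "2 classes")
})

test_that("NNLS unmixing is exact on linear mixtures and scale-equivariant", {
  grid <- seq(1500, 1750, 2)
  r1 <- exp(-((grid - 1657) / 20)^2)
  r2 <- exp(-((grid - 1550) / 25)^2)
  refs <- spectra_matrix(rbind(r1, r2), grid,
                         labels = tibble::tibble(ref = c("bsa", "blg")))
  mix <- seira_spectrum(grid, 0.8 * r1 + 0.2 * r2, kind = "difference")
  um <- nnls_unmix(mix, refs)
  expect_equal(unname(um$weights), c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(um$mse, 0, tolerance = 1e-24)
  # pure reference
  um1 <- nnls_unmix(seira_spectrum(grid, r1, "difference"), refs)
  expect_equal(unname(um1$weights), c(1, 0), tolerance = 1e-12)
  # scale equivariance
  um3 <- nnls_unmix(seira_spectrum(grid, 3 * (0.8 * r1 + 0.2 * r2),
                                   "difference"), refs)
  expect_equal(unname(um3$weights), 3 * c(0.8, 0.2), tolerance = 1e-10)
  # constant offset cannot be absorbed and shows up as residual MSE
  umo <- nnls_unmix(seira_spectrum(grid, 0.8 * r1 + 0.2 * r2 + 0.01,
                                   "difference"), refs)
  expect_gt(umo$mse, 0)
  expect_lte(umo$mse, 1e-4 + 1e-12)
  bad <- spectra_matrix(rbind(r1[-1], r2[-1]), grid[-1])
  expect_error(nnls_unmix(mix, bad), "grid")
})

test_that("titration sets unmix to their mixing weights through the pipeline", {
  tdat <- simulate_titration_dataset(
    n_per_ratio = 25, noise = noise_model(sigma = 0.01, seed = 0),
    ratios = tibble::tibble(bsa = c(100, 80, 50, 20, 0),
                            blg = c(0, 20, 50, 80, 100)))
  res <- unmix_titration(tdat)
  expect_lt(max(abs(res$weight_bsa - res$conc_bsa / 100)), 0.03)
  # noiseless 4:1 set is recovered almost exactly
  t41 <- simulate_titration_dataset(
    n_per_ratio = 2, noise = noise_model(0, 0, 0),
    ratios = tibble::tibble(bsa = c(100, 80, 0), blg = c(0, 20, 100)))
  r41 <- unmix_titration(t41)
  expect_equal(r41$weight_bsa[r41$conc_bsa == 80], 0.8, tolerance = 0.01)
})

test_that("concentration regression: linear backend is exact, network learns", {
  grid <- seq(1500, 1750, 2)
  b1 <- exp(-((grid - 1657) / 20)^2)
  b2 <- exp(-((grid - 1550) / 25)^2)
  set.seed(3)
  conc <- cbind(runif(40, 10, 100), runif(40, 10, 100))
  rows <- conc %*% rbind(b1, b2)
  d <- spectra_matrix(rows, grid,
                      labels = tibble::tibble(conc_bsa = conc[, 1],
                                              conc_blg = conc[, 2]))
  lin <- regress_concentrations(d, backend = "linear", seed = 0)
  expect_lt(lin$mape, 1e-8)
  # deterministic contract: same seed, bit-identical error
  lin2 <- regress_concentrations(d, backend = "linear", seed = 0)
  expect_identical(lin$mape, lin2$mape)
})

test_that("network backend reaches the noise floor on the titration set", {
  tdat <- simulate_titration_dataset(n_per_ratio = 50,
                                     noise = noise_model(sigma = 0.01, seed = 0))
  mod <- regress_concentrations(tdat, backend = "network", seed = 0)
  expect_lte(mod$mape, 10)
  mod2 <- regress_concentrations(tdat, backend = "network", seed = 0)
  expect_identical(mod$mape, mod2$mape)
})

test_that("secondary-structure fractions partition the Amide-I lobes", {
  d2g <- seq(1580, 1720, 0.5)
  single <- secondary_structure(
    seira_spectrum(d2g, -dnorm(d2g, 1655, 4), "derivative2"))
  expect_equal(
    single$band_fractions$fraction[single$band_fractions$structure == "alpha_helix"],
    1, tolerance = 1e-6)
  double <- secondary_structure(
    seira_spectrum(d2g, -dnorm(d2g, 1655, 4) - dnorm(d2g, 1630, 4),
                   "derivative2"))
  bf <- double$band_fractions
  expect_equal(bf$fraction[bf$structure == "alpha_helix"], 0.5, tolerance = 0.02)
  expect_equal(bf$fraction[bf$structure == "beta_sheet"], 0.5, tolerance = 0.02)
  expect_equal(sum(bf$fraction), 1, tolerance = 1e-12)
  # synthetic BSA: dominant 1657 band -> alpha-helix largest
  grid <- default_grid()
  sp <- simulate_measurement(make_system("OC-Hmu", "BSA"), grid,
                             noise_model(0, 0, 1))
  da <- extract_difference(sp)
  d2 <- derivative_spectrum(da, derivative_config(order = 2))
  ss <- secondary_structure(d2)
  top <- ss$band_fractions$structure[which.max(ss$band_fractions$fraction)]
  expect_identical(top, "alpha_helix")
  expect_error(secondary_structure(
    seira_spectrum(seq(1700, 1800, 2), rnorm(51), "derivative2")), "Amide")
})
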