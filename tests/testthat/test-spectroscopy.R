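test_that("the MRE conversion applies the measured-parameter formula pointwise", {
  wl <- seq(200, 250, 5)
  z <- cd_spectrum(wl, rep(0, length(wl)), "mdeg",
                   path_cm = 0.1, conc_mg_ml = 0.62, mw_kda = 16.6)
  expect_true(all(to_mre(z)$value == 0))

  s <- cd_spectrum(wl, rep(-5, length(wl)), "mdeg",
                   path_cm = 0.1, conc_mg_ml = 0.62, mw_kda = 16.6)
  m <- to_mre(s)
  expect_equal(m$value, rep(-5 * 16.6 / (10 * 0.1 * 0.62), length(wl)),
               tolerance = 1e-9)
  expect_equal(m$value[1], -133.87, tolerance = 1e-4)
  expect_identical(attr(m, "unit"), "MRE")

  # doubling the concentration halves every value
  m2 <- to_mre(s, conc_mg_ml = 1.24)
  expect_equal(m2$value, m$value / 2, tolerance = 1e-12)

  expect_error(to_mre(s, path_cm = 0), "positive")
  expect_error(to_mre(m), "not in mdeg")
})

test_that("averaging subtracts the baseline then takes the pointwise mean", {
  wl <- 200:210
  mk <- function(v) cd_spectrum(wl, v, "mdeg")
  same <- mk(sin(wl))
  avg <- average_and_correct(list(same, same, same), mk(rep(0, 11)))
  expect_equal(avg$value, same$value, tolerance = 1e-12)

  opp <- average_and_correct(list(mk(rep(1, 11)), mk(rep(-1, 11))))
  expect_true(all(opp$value == 0))

  # three spectra with a nonzero baseline, against hand arithmetic
  s1 <- mk(wl * 0 + 3); s2 <- mk(wl * 0 + 6); s3 <- mk(wl * 0 + 9)
  bl <- mk(wl * 0 + 2)
  got <- average_and_correct(list(s1, s2, s3), bl)
  expect_equal(got$value, rep((1 + 4 + 7) / 3, 11), tolerance = 1e-12)

  bad <- cd_spectrum(201:211, rep(1, 11), "mdeg")
  expect_error(average_and_correct(list(s1, bad)), "grid")
})

test_that("Savitzky-Golay smoothing is exact on cubics and reduces noise", {
  wl <- seq(200, 250, 0.5)
  cub <- 2 - 0.3 * wl + 0.004 * wl^2 - 1e-5 * wl^3
  s <- cd_spectrum(wl, cub, "MRE")
  expect_equal(smooth_spectrum(s, 3, 9)$value, cub, tolerance = 1e-10)

  const <- cd_spectrum(wl, rep(7, length(wl)), "MRE")
  expect_equal(smooth_spectrum(const)$value, rep(7, length(wl)),
               tolerance = 1e-10)

  set.seed(15)
  noisy <- cd_spectrum(wl, cub + rnorm(length(wl), 0, 5), "MRE")
  resid_in <- noisy$value - cub
  resid_out <- smooth_spectrum(noisy)$value - cub
  expect_lt(var(resid_out), var(resid_in))

  irregular <- cd_spectrum(c(200, 201, 203, 204, 206, 207, 209, 210, 212, 213),
                           rnorm(10), "MRE")
  expect_error(smooth_spectrum(irregular), "uniform")
  expect_error(smooth_spectrum(s, order = 3, window = 8), "odd")
  expect_error(smooth_spectrum(s, order = 3, window = 3), "odd|larger")
})

test_that("noiseless mixtures deconvolve exactly and permutation-equivariantly", {
  basis <- synthetic_basis()
  f_true <- c(helix = 0.4, strand = 0.1, coil = 0.5)
  sp <- gen_cd_spectrum(f_true, basis, noise_sd = 0)
  fit <- deconvolve_cd(sp, basis)
  expect_lt(max(abs(fit$fractions[names(f_true)] - f_true)), 1e-8)
  expect_lt(fit$rmsd_kmre, 1e-8)
  expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)

  # single-component spectrum
  one <- gen_cd_spectrum(c(helix = 0, strand = 1, coil = 0), basis, 0)
  fit1 <- deconvolve_cd(one, basis)
  expect_equal(unname(fit1$fractions["strand"]), 1, tolerance = 1e-8)

  # relabeling the basis permutes the fractions identically
  perm <- basis
  perm$components <- basis$components[, c("coil", "helix", "strand")]
  fitp <- deconvolve_cd(sp, perm)
  expect_equal(fitp$fractions[names(f_true)], fit$fractions[names(f_true)],
               tolerance = 1e-8)
})

test_that("noisy mixtures deconvolve close to truth after smoothing", {
  basis <- synthetic_basis()
  f_true <- c(helix = 0.4, strand = 0.1, coil = 0.5)
  sigma <- 0.02 * max(abs(basis$components))
  errs <- vapply(1:10, function(s) {
    sp <- gen_cd_spectrum(f_true, basis, noise_sd = sigma, seed = s)
    fit <- deconvolve_cd(smooth_spectrum(sp), basis)
    max(abs(fit$fractions[names(f_true)] - f_true))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("basis selection ranks candidates by post-scaling RMSD", {
  basis <- synthetic_basis()
  wrong <- basis
  wrong$name <- "distorted"
  wrong$components <- basis$components[nrow(basis$components):1, ]
  sp <- gen_cd_spectrum(c(helix = 0.5, strand = 0.2, coil = 0.3), basis, 0)
  sel <- select_basis(sp, list(wrong, basis))
  expect_identical(sel$best$name, basis$name)
  expect_identical(nrow(sel$table), 2L)
  expect_lt(sel$table$rmsd_kmre[2], sel$table$rmsd_kmre[1])

  only <- select_basis(sp, list(basis))
  expect_identical(only$best$name, basis$name)

  # two-candidate RMSD ranking against a hand-computed RMSD for a
  # fixed fraction fit: the winning candidate's reported rmsd must
  # equal the residual of its own reconstruction
  recon <- as.numeric(basis$components %*% sel$fit$fractions)
  hand <- sqrt(mean((sel$fit$scale * sp$value - recon)^2)) / 1000
  expect_equal(sel$fit$rmsd_kmre, hand, tolerance = 1e-12)
})

test_that("class grouping preserves totals and flags unmapped classes", {
  basis <- synthetic_basis()
  f <- c(helix = 0.4, strand = 0.1, coil = 0.5)
  g <- group_classes(f, basis)
  expect_equal(unname(g), unname(f[c("helix", "strand", "coil")]))

  # six-component basis summing pairwise into the three classes
  wl <- seq(200, 250, 5)
  comp <- matrix(rnorm(length(wl) * 6), length(wl), 6,
                 dimnames = list(NULL, c("h1", "h2", "s1", "s2", "c1", "c2")))
  map <- c(h1 = "helix", h2 = "helix", s1 = "strand", s2 = "strand",
           c1 = "coil", c2 = "coil")
  b6 <- cd_basis(wl, comp, map)
  f6 <- c(h1 = 0.2, h2 = 0.1, s1 = 0.15, s2 = 0.05, c1 = 0.3, c2 = 0.2)
  g6 <- group_classes(f6, b6)
  expect_equal(unname(g6), c(0.3, 0.2, 0.5), tolerance = 1e-12)
  expect_equal(sum(g6), 1, tolerance = 1e-12)

  expect_error(group_classes(c(mystery = 1), basis), "no grouping")
})

test_that("spectrum files round-trip with their YAML sidecar", {
  wl <- seq(200, 250, 0.5)
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(wavelength_nm = wl, value = sin(wl)),
                     tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("unit: mdeg", "path_cm: 0.1", "conc_mg_ml: 0.62",
               "mw_kda: 16.6"), paste0(tmp, ".yaml"))
  sp <- read_cd_spectrum(tmp)
  expect_equal(sp$value, sin(wl), tolerance = 1e-12)
  expect_identical(attr(sp, "unit"), "mdeg")
  expect_equal(attr(sp, "conc_mg_ml"), 0.62)
})
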