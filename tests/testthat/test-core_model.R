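test_that("kabsch superposition recovers rigid motions exactly", {
  set.seed(101)
  m <- matrix(rnorm(30), 10, 3)
  expect_lt(kabsch_superpose(m, m)$rmsd, 1e-12)
  for (i in 1:5) {
    mv <- mutadyn:::random_rigid_motion()
    expect_lt(kabsch_superpose(mv(m), m)$rmsd, 1e-10)
  }
})

test_that("kabsch RMSD matches an independent least-squares solution", {
  # small 4-point sets; oracle = closed-form quaternion method, with a
  # numerically refined rotation search as a second, cruder check
  set.seed(7)
  for (i in 1:10) {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    got <- kabsch_superpose(a, b)$rmsd
    expect_equal(got, quaternion_rmsd(a, b), tolerance = 1e-9)
  }
  # refined grid/optim search over Euler angles agrees to optimizer tol
  a <- matrix(c(0, 0, 0, 1.2, 0.1, 0, 0.3, 1.5, 0.2, 1, 1, 1), 4, 3, byrow = TRUE)
  b <- matrix(c(0.1, 0, 0, 1.3, 0, 0.2, 0.2, 1.4, 0, 0.9, 1.1, 0.8), 4, 3, byrow = TRUE)
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  obj <- function(ang) mean(rowSums((ac %*% t(rot(ang)) - bc)^2))
  best <- Inf
  for (s1 in seq(0, 2 * pi, length.out = 7))
    for (s2 in seq(0, pi, length.out = 4))
      for (s3 in seq(0, 2 * pi, length.out = 7)) {
        o <- optim(c(s1, s2, s3), obj, method = "BFGS",
                   control = list(reltol = 1e-15))
        best <- min(best, o$value)
      }
  expect_equal(kabsch_superpose(a, b)$rmsd, sqrt(best), tolerance = 1e-6)
})

test_that("degenerate fit selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
  two <- matrix(rnorm(6), 2, 3)
  expect_error(kabsch_superpose(two, two), "at least 3")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3, 3),
                                matrix(rnorm(12), 4, 3)), "equal")
})

test_that("rmsd_series is zero for rigid motions and composes the single-frame fit", {
  hel <- make_helix(8)
  mv1 <- mutadyn:::with_seed(3, mutadyn:::random_rigid_motion())
  mv2 <- mutadyn:::with_seed(4, mutadyn:::random_rigid_motion())
  same <- frames_to_trajectory(list(hel, hel, hel))
  expect_true(all(rmsd_series(same, hel)$value < 1e-10))
  moved <- frames_to_trajectory(list(
    structure3d(hel$atoms, mv1(hel$xyz)), structure3d(hel$atoms, mv2(hel$xyz))))
  expect_true(all(rmsd_series(moved, hel)$value < 1e-10))

  set.seed(55)
  f1 <- structure3d(hel$atoms, hel$xyz + matrix(rnorm(nrow(hel$xyz) * 3, 0, 0.3),
                                                ncol = 3))
  f2 <- structure3d(hel$atoms, hel$xyz + matrix(rnorm(nrow(hel$xyz) * 3, 0, 0.3),
                                                ncol = 3))
  toy <- frames_to_trajectory(list(f1, f2))
  ca <- atom_select(hel, name = "CA")
  got <- rmsd_series(toy, hel, fit_sel = ca)$value
  exp1 <- kabsch_superpose(f1$xyz[ca, ], hel$xyz[ca, ])$rmsd
  exp2 <- kabsch_superpose(f2$xyz[ca, ], hel$xyz[ca, ])$rmsd
  expect_equal(got, c(exp1, exp2), tolerance = 1e-12)
})

test_that("RMSD is symmetric and rigid-motion invariant", {
  set.seed(9)
  a <- matrix(rnorm(21), 7, 3)
  b <- matrix(rnorm(21), 7, 3)
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-10)
  mv <- mutadyn:::random_rigid_motion()
  expect_equal(kabsch_superpose(mv(a), mv(b))$rmsd,
               kabsch_superpose(a, b)$rmsd, tolerance = 1e-9)
})

test_that("isolated-atom ASA matches the analytic sphere area", {
  s <- structure3d(data.frame(name = "CA", element = "C", resno = 1,
                              resid = "GLY", chain = "A"),
                   matrix(0, 1, 3))
  got <- shrake_rupley_asa(s, probe_radius = 1.4, n_points = 960L)
  expect_equal(got$atom, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-12)
})

test_that("a fully enclosed atom has (near) zero ASA", {
  # carbon at the origin surrounded by a dense shell of carbons
  pts <- mutadyn:::sphere_points(200) * 2.0
  atoms <- data.frame(name = "C", element = "C", resno = c(1, rep(2, 200)),
                      resid = "GLY", chain = "A")
  s <- structure3d(atoms, rbind(c(0, 0, 0), pts))
  got <- shrake_rupley_asa(s, n_points = 480L)
  expect_lt(got$atom[1], 1e-6)
})

test_that("two overlapping spheres match the spherical-cap formula", {
  # equal radii R = r_C + probe, centers distance d apart: each sphere
  # loses a cap of height h = R - d/2; exposed area 4 pi R^2 - 2 pi R h
  d <- 3.0
  R <- 1.7 + 1.4
  atoms <- data.frame(name = c("C1", "C2"), element = "C", resno = 1:2,
                      resid = "GLY", chain = "A")
  s <- structure3d(atoms, rbind(c(0, 0, 0), c(d, 0, 0)))
  got <- shrake_rupley_asa(s, n_points = 4000L)
  h <- R - d / 2
  analytic <- 4 * pi * R^2 - 2 * pi * R * h
  expect_equal(got$atom[1], analytic, tolerance = 0.01)
  expect_equal(got$atom[2], analytic, tolerance = 0.01)
})

test_that("total ASA discretization error decreases with point count", {
  hel <- make_helix(6)
  ref <- shrake_rupley_asa(hel, n_points = 8000L)$total
  errs <- vapply(c(120L, 480L, 1920L), function(np)
    abs(shrake_rupley_asa(hel, n_points = np)$total - ref), numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("unknown elements are rejected in ASA", {
  s <- structure3d(data.frame(name = "XX", element = "XX", resno = 1,
                              resid = "GLY", chain = "A"), matrix(0, 1, 3))
  expect_error(shrake_rupley_asa(s), "unknown element")
})

test_that("sequence_mass computes free glycine and is order-invariant and additive", {
  expect_equal(sequence_mass("G"), 0.07507, tolerance = 1e-4)
  sq <- "ACDEFGHIKLMNPQRSTVWY"
  rev_sq <- paste(rev(strsplit(sq, "")[[1]]), collapse = "")
  expect_identical(sequence_mass(sq), sequence_mass(rev_sq))
  water <- 18.01528 / 1000
  expect_equal(sequence_mass("ACD") + sequence_mass("EFG") - water,
               sequence_mass("ACDEFG"), tolerance = 1e-12)
  expect_error(sequence_mass("ABZ"), "invalid")
  expect_error(sequence_mass(""), "empty")
})

test_that("apply_substitutions respects author numbering and validates", {
  s <- "KQPD"
  expect_identical(apply_substitutions(s, "Q1514W", offset = 1513), "KWPD")
  expect_error(apply_substitutions(s, "A1514W", offset = 1513), "holds")
  expect_error(apply_substitutions(s, "K9999A", offset = 1513), "outside")
})

test_that("PDB writing and reading round-trips structures and trajectories", {
  hel <- make_helix(5, resno = 1532:1536)
  tmp <- tempfile(fileext = ".pdb")
  write_pdb(hel, tmp)
  back <- read_structure(tmp)
  expect_equal(back$xyz, hel$xyz, tolerance = 1e-3)
  expect_identical(back$atoms$resno, hel$atoms$resno)
  expect_identical(back$atoms$name, hel$atoms$name)

  spec <- two_state_spec(n_frames = 3, noise_sigma = 0.05)
  tr <- gen_two_state_trajectory(spec, seed = 2)$trajectory
  tmp2 <- tempfile(fileext = ".pdb")
  write_pdb(tr, tmp2)
  back2 <- read_trajectory(tmp2, dt = 0.4)
  expect_equal(n_frames(back2), 3L)
  expect_equal(back2$coords[, , 2], tr$coords[, , 2], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("elements are inferred from atom names when the column is blank", {
  expect_identical(mutadyn:::infer_element(c("CA", "N", "OD1", "NZ", "1HB")),
                   c("C", "N", "O", "N", "H"))
})
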