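# Geometry engine: SASA against closed forms, Kabsch superposition,
# radius of gyration, secondary-structure rule.

test_that("SASA matches the isolated-sphere closed form", {
  got <- sasa(matrix(0, 1, 3), radii = 1.7)
  expect_lt(abs(got - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.005)
  # two atoms beyond occlusion range keep the isolated value
  far <- sasa(rbind(c(0, 0, 0), c(6.3, 0, 0)), radii = c(1.7, 1.7))
  expect_equal(far, rep(4 * pi * 3.1^2, 2), tolerance = 1e-6)
})

test_that("SASA matches the two-sphere analytic overlap", {
  set.seed(42)
  for (k in 1:30) {
    r1 <- runif(1, 1.2, 2); r2 <- runif(1, 1.2, 2)
    d <- runif(1, 0.3, r1 + r2 + 2.5)
    got <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(r1, r2))[1]
    want <- two_sphere_area(r1, r2, d)
    expect_lt(abs(got - want) / (4 * pi * (r1 + 1.4)^2), 0.01)
  }
  # coincident equal atoms occlude each other completely
  expect_equal(sasa(rbind(c(0, 0, 0), c(0, 0, 0)), radii = c(1.7, 1.7)),
               c(0, 0))
})

test_that("removing an occluder never decreases any atom's SASA", {
  set.seed(7)
  for (k in 1:5) {
    n <- 12L
    xyz <- matrix(runif(3 * n, 0, 6), ncol = 3)
    radii <- runif(n, 1.4, 1.9)
    base <- sasa(xyz, sasa_options(n_points = 240), radii = radii)
    drop <- sample(n, 1)
    red <- sasa(xyz[-drop, , drop = FALSE], sasa_options(n_points = 240),
                radii = radii[-drop])
    expect_true(all(red >= base[-drop] - 1e-9))
  }
})

test_that("total SASA is invariant to rigid motion within lattice tolerance", {
  conf <- build_conformation(get_design("Pbeta"), motif = "hairpin")
  xyz <- coords(conf)
  radii <- conf$atoms$radius
  opts <- sasa_options(n_points = 480)
  a0 <- sum(sasa(xyz, opts, radii = radii))
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  a1 <- sum(sasa(sweep(xyz %*% R, 2, c(5, -3, 2), "+"), opts,
                 radii = radii))
  expect_lt(abs(a1 - a0) / a0, 0.01)
})

test_that("Kabsch superposition is exact on rigid copies and symmetric", {
  set.seed(1)
  x <- matrix(rnorm(45), ncol = 3)
  expect_equal(kabsch_superpose(x, x)$rmsd, 0, tolerance = 1e-10)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  y <- x %*% R + matrix(rep(c(1, 2, 3), each = nrow(x)), ncol = 3)
  s <- kabsch_superpose(y, x)
  expect_lt(s$rmsd, 1e-6)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-9)
  # metric symmetry
  y2 <- x + matrix(rnorm(45, 0, 0.5), ncol = 3)
  expect_equal(kabsch_superpose(y2, x)$rmsd,
               kabsch_superpose(x, y2)$rmsd, tolerance = 1e-6)
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "at least 3")
  col <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(col, col), "degenerate")
})

test_that("Kabsch matches a brute-force rotation-grid search on toy sets", {
  set.seed(5)
  x <- matrix(rnorm(12), ncol = 3)
  y <- matrix(rnorm(12), ncol = 3)
  got <- kabsch_superpose(x, y)$rmsd
  # exhaustive search over sampled rotations (independent oracle)
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  best <- Inf
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  half <- seq(0, pi, length.out = 13)
  for (a in ang) for (b in half) for (g in ang) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3)
    r <- sqrt(mean(rowSums((xc %*% (Rz1 %*% Ry %*% Rz2) - yc)^2)))
    if (r < best) best <- r
  }
  expect_lte(got, best + 1e-9)       # optimum cannot exceed any sample
  expect_lt(abs(got - best) / best, 0.05)
  # independent library check on the same pair
  expect_equal(got, bio3d::rmsd(as.vector(t(x)), as.vector(t(y)),
                                fit = TRUE),
               tolerance = 1e-3)
})

test_that("RMSD series recover planted displacements", {
  conf <- build_conformation(get_design("Pbeta"))
  ens0 <- perturb_ensemble(conf, 0, 4L)
  r0 <- rmsd_series(ens0)
  expect_equal(r0$rmsd, rep(0, 4), tolerance = 1e-9)
  expect_equal(rmsd_series(perturb_ensemble(conf, 0, 1L))$mean, 0,
               tolerance = 1e-9)
  # i.i.d. displacement of magnitude delta on every atom -> rmsd ~ delta
  set.seed(11)
  delta <- 1.5
  xyz <- coords(conf)
  u <- matrix(rnorm(length(xyz)), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * delta
  ens <- pepconj:::new_ensemble(conf$atoms,
                                rbind(as.vector(t(xyz)),
                                      as.vector(t(xyz + u))),
                                conf$topology)
  r <- rmsd_series(ens, selection = "all")
  expect_equal(r$rmsd[2], delta, tolerance = 0.1)
})

test_that("radius of gyration follows closed forms and scaling", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(3, 0, 0))), 1.5)
  s <- 2.4
  sq <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0))
  expect_equal(radius_of_gyration(sq), s / sqrt(2), tolerance = 1e-12)
  set.seed(2)
  x <- matrix(rnorm(60), ncol = 3)
  expect_equal(radius_of_gyration(3.7 * x),
               3.7 * radius_of_gyration(x), tolerance = 1e-12)
  # a folded hairpin is more compact than the extended chain
  top <- get_design("Pbeta")
  rg <- function(motif)
    radius_of_gyration(build_conformation(top, motif = motif),
                       selection = "CA")
  expect_lt(rg("hairpin"), rg("extended"))
})

test_that("secondary structure follows the Ramachandran-region rule", {
  helix <- build_conformation(get_design("Palpha"), motif = "helix")
  ss <- assign_secondary_structure(helix)
  n <- length(ss)
  expect_true(all(ss[2:(n - 1)] == "H"))
  expect_equal(unname(ss[c(1, n)]), c("C", "C"))
  ext <- assign_secondary_structure(
    build_conformation(get_design("Pbeta"), motif = "extended"))
  expect_true(all(ext[2:(length(ext) - 1)] == "E"))
  # mixed recipe: per-residue overrides are recovered away from termini
  mix <- build_conformation(get_design("Pbeta"), motif = "extended",
                            phi = c(rep(-60, 9), rep(-135, 9)),
                            psi = c(rep(-45, 9), rep(135, 9)))
  ssm <- assign_secondary_structure(mix)
  expect_true(all(ssm[2:8] == "H"))
  expect_true(all(ssm[11:17] == "E"))
})
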