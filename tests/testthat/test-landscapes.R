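# Free-energy surfaces and inertia-based shape statistics.

test_that("the PMF reproduces the normalisation and offset conventions", {
  # single conformation: W0 = -ln 2 and its bin carries W = -ln 2
  s1 <- pmf_surface(100, 20)
  expect_equal(s1$W0, -log(2))
  expect_equal(s1$W[!is.na(s1$W)], -log(2))
  # exp(W0 - W) over occupied bins reconstructs the probability
  set.seed(51)
  x1 <- rnorm(500, 300, 60); x2 <- rnorm(500, 40, 8)
  s <- pmf_surface(x1, x2)
  occ <- !is.na(s$W)
  expect_equal(sum(exp(s$W0 - s$W[occ])), 1, tolerance = 1e-10)
  # unoccupied bins are NA sentinels, not infinities
  expect_false(any(is.infinite(s$W)))
  expect_error(pmf_surface(1, 1, breaks1 = 0), "zero-width")
})

test_that("a uniform grid of coordinates yields a flat landscape", {
  # one conformation per bin centre: P uniform, W exactly constant
  g <- expand.grid(x1 = seq(25, 475, by = 50), x2 = seq(1, 39, by = 2))
  s <- pmf_surface(g$x1, g$x2, breaks1 = 50, breaks2 = 2)
  w <- s$W[!is.na(s$W)]
  expect_equal(max(w) - min(w), 0, tolerance = 1e-12)
  expect_equal(length(w), nrow(g))
})

test_that("a planted bimodal distribution is recovered within one bin", {
  set.seed(53)
  n <- 4000
  x1 <- c(rnorm(n / 2, 200, 15), rnorm(n / 2, 400, 15))
  x2 <- c(rnorm(n / 2, 20, 1.5), rnorm(n / 2, 60, 1.5))
  s <- pmf_surface(x1, x2, breaks1 = 50, breaks2 = 2)
  # the two deepest local minima sit at the planted means, within a bin
  w <- s$W
  ord <- order(w, na.last = NA)
  mins <- which(!is.na(w) & w <= sort(w, na.last = NA)[2], arr.ind = TRUE)
  centres1 <- (s$breaks1[mins[, 1]] + s$breaks1[mins[, 1] + 1]) / 2
  centres2 <- (s$breaks2[mins[, 2]] + s$breaks2[mins[, 2] + 1]) / 2
  expect_true(any(abs(centres1 - 200) <= 50 & abs(centres2 - 20) <= 2))
  expect_true(any(abs(centres1 - 400) <= 50 & abs(centres2 - 60) <= 2))
})

test_that("per-oligomer averaging pools peptides before binning", {
  # two dimers: peptide coordinates average within each oligomer
  x1 <- c(100, 200, 300, 400); x2 <- c(10, 20, 30, 40)
  olig <- c("a", "a", "b", "b")
  s <- pmf_surface(x1, x2, breaks1 = 50, breaks2 = 2,
                   mode = "per_oligomer_average", oligomer = olig)
  expect_equal(s$N, 2L)
  # occupied bins are those of the oligomer means (150, 15) and (350, 35)
  occ <- which(!is.na(s$W), arr.ind = TRUE)
  # means (150, 15) and (350, 35); 350 lies on an edge and the rightmost
  # bin is closed, so it lands in [300, 350]
  c1 <- (s$breaks1[occ[, 1]] + s$breaks1[occ[, 1] + 1]) / 2
  expect_setequal(round(c1), c(175, 325))
  expect_error(pmf_surface(x1, x2, mode = "per_oligomer_average"),
               "oligomer ids")
})

test_that("inertia spectra match symmetry and the elementwise oracle", {
  # eight unit masses at cube corners: threefold degenerate moments
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  I <- inertia_spectrum(cube, n = 1, M0 = 1)
  expect_equal(I$I, rep(16, 3))
  expect_false(I$degenerate)
  # collinear rod: I1 = I2 > 0, I3 = 0, flagged degenerate
  rod <- cbind(0, 0, seq(-5, 5))
  Ir <- inertia_spectrum(rod)
  expect_equal(Ir$I[1], Ir$I[2])
  expect_equal(Ir$I[3], 0)
  expect_true(Ir$degenerate)
  # random clouds against the elementwise tensor oracle
  set.seed(61)
  for (k in 1:10) {
    cloud <- matrix(rnorm(3 * 40, sd = 5), ncol = 3)
    got <- inertia_spectrum(cloud, M0 = 2)$I
    want <- oracle_inertia(cloud) / 2
    expect_equal(got, want, tolerance = 1e-10)
  }
  # rotation invariance at 1e-9 relative
  cloud <- matrix(rnorm(90, sd = 4), ncol = 3)
  I0 <- inertia_spectrum(cloud)$I
  for (k in 1:5) {
    expect_lt(max(abs(inertia_spectrum(rigid_motion(cloud))$I - I0)) /
                I0[1], 1e-9)
  }
})

test_that("scaling fits recover the closed-form rod and sphere exponents", {
  rods <- make_shape_ensemble("rod", orders = 1:10, seed = 71)
  fit_r <- fit_scaling_exponents(inertia_spectra(rods$conformations))
  # rods: length ~ n at fixed thickness gives alpha 1, beta 0, gamma 1
  expect_lt(abs(fit_r$alpha["value"] - 1), 2 * fit_r$alpha["se"] + 0.02)
  expect_lt(abs(fit_r$beta["value"] - 0), 2 * fit_r$beta["se"] + 0.02)
  expect_lt(abs(fit_r$gamma["value"] - 1), 2 * fit_r$gamma["se"] + 0.05)
  sph <- make_shape_ensemble("sphere", orders = 1:10, seed = 72)
  fit_s <- fit_scaling_exponents(inertia_spectra(sph$conformations))
  # compact spheres: I ~ n^(5/3) gives alpha = beta = 1/3, gamma = 1
  expect_lt(abs(fit_s$alpha["value"] - 1 / 3), 2 * fit_s$alpha["se"] + 0.02)
  expect_lt(abs(fit_s$beta["value"] - 1 / 3), 2 * fit_s$beta["se"] + 0.02)
  expect_lt(abs(fit_s$gamma["value"] - 1), 2 * fit_s$gamma["se"] + 0.05)
  # derived exponents recompute exactly from the fitted slopes
  a <- fit_s$exponents$exponent
  expect_equal(unname(fit_s$alpha["value"]), (a[1] + a[2]) / 4 - 0.5)
  expect_equal(unname(fit_s$beta["value"]), a[3] / 2 - 0.5)
  expect_equal(unname(fit_s$gamma["value"]), (a[1] + a[2]) / 4 + a[3] - 1.5)
  # multiplying every moment by a constant leaves the slopes unchanged
  sp2 <- inertia_spectra(sph$conformations)
  sp2[, c("I1", "I2", "I3")] <- sp2[, c("I1", "I2", "I3")] * 7
  fit2 <- fit_scaling_exponents(sp2)
  expect_equal(fit2$exponents$exponent, fit_s$exponents$exponent,
               tolerance = 1e-12)
  expect_error(fit_scaling_exponents(sp2[sp2$n <= 5, ]), "at least 3")
})

test_that("planted power-law ensembles recover slopes within 2 SE", {
  # moments with multiplicative noise around I ~ n^2.5
  set.seed(81)
  n <- rep(4:10, each = 12)
  mk <- function() 5 * n^2.5 * exp(rnorm(length(n), sd = 0.05))
  spectra <- data.frame(n = n, I1 = mk(), I2 = mk(), I3 = mk())
  fit <- fit_scaling_exponents(spectra, range12 = c(4, 10),
                               range3 = c(4, 10))
  for (k in 1:3) {
    expect_lt(abs(fit$exponents$exponent[k] - 2.5),
              2 * fit$exponents$se[k] + 0.02)
  }
})

test_that("shape ratios track elongation monotonically", {
  # enough sampled beads that the eigenvalue-ordering bias is small
  sph <- make_shape_ensemble("sphere", orders = 1:4, beads_per_unit = 1500L,
                             seed = 91)
  rs <- shape_ratios(inertia_spectra(sph$conformations))
  expect_true(all(abs(rs$r31 - 1) < 0.05))
  expect_true(all(abs(rs$r32 - 1) < 0.05))
  # increasingly elongated ellipsoids: ratios strictly decrease
  vals <- vapply(c(1, 2, 4, 8), function(a) {
    e <- make_shape_ensemble("ellipsoid", orders = 3, aspect = a,
                             replicates = 6, seed = 92)
    mean(shape_ratios(inertia_spectra(e$conformations))$r31)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  # aspect-5 ellipsoid against the uniform-ellipsoid closed form
  e5 <- make_shape_ensemble("ellipsoid", orders = 4, aspect = 5,
                            replicates = 10, seed = 93)
  r <- shape_ratios(inertia_spectra(e5$conformations))
  want <- 2 / (1 + 25)  # 2a^2 / (a^2 + c^2)
  expect_lt(abs(r$r31 - want) / want, 0.05)
})

test_that("landscape and scaling results export to CSV and JSON", {
  set.seed(95)
  s <- pmf_surface(rnorm(200, 300, 50), rnorm(200, 30, 5))
  f <- tempfile(fileext = ".csv")
  write_pmf_csv(s, f)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), sum(!is.na(s$W)))
  expect_true(all(is.finite(back$W)))
  sph <- make_shape_ensemble("sphere", orders = 1:10, seed = 96)
  fit <- fit_scaling_exponents(inertia_spectra(sph$conformations))
  fj <- tempfile(fileext = ".json")
  write_scaling_json(fit, fj)
  j <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(j$alpha$value, unname(fit$alpha["value"]))
})
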