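# Weighted Gower dissimilarity, square-root transform, and PCoA.

test_that("gowerDist matches a hand computation on a 3-species table", {
  df <- toySpecies(c("x", "y", "z"), mass = c(100, 200, 300))
  df$diet_inv <- c(100, 0, 50)
  df$diet_vert <- c(0, 100, 50)
  # remaining five diet variables are all-zero -> zero range, dropped
  warns <- capture_warnings(D <- gowerDist(df))
  expect_length(warns, 5)
  expect_true(all(grepl("zero-range", warns)))

  lm_ <- log10(c(100, 200, 300))
  r <- diff(range(lm_))
  massD <- abs(outer(lm_, lm_, "-")) / r
  dietD <- (abs(outer(df$diet_inv, df$diet_inv, "-")) / 100 +
            abs(outer(df$diet_vert, df$diet_vert, "-")) / 100) / 7
  # stratum, activity, habitat identical: contribute 0 to the numerator but
  # (1 + 1 + 1) to the total weight; diet keeps only 2/7 of its weight
  expected <- (massD + dietD) / (1 + 2 / 7 + 3)
  diag(expected) <- 0
  expect_equal(unname(D), expected, tolerance = 1e-12)
  expect_equal(diag(D), setNames(rep(0, 3), c("x", "y", "z")))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("gowerDist bounds: identical rows give 0, maximal contrast 1", {
  df <- toySpecies(c("p", "q"), mass = c(100, 100))
  warns <- capture_warnings(D <- gowerDist(df))  # constant mass + diets drop
  expect_true(all(grepl("zero-range", warns)))
  expect_equal(D["p", "q"], 0)

  df2 <- toySpecies(c("p", "q"), mass = c(1, 1e6))
  df2$diet_inv <- c(100, 0); df2$diet_plant <- c(0, 100)
  df2$foraging_stratum <- c("ground", "arboreal")
  df2$act_nocturnal <- c(TRUE, FALSE); df2$act_diurnal <- c(FALSE, TRUE)
  df2$act_crepuscular <- c(TRUE, FALSE)
  df2$habitat_flags <- c("forest", "desert")
  suppressWarnings(D2 <- gowerDist(df2))
  # every comparable variable differs maximally -> the upper bound
  expect_equal(D2["p", "q"], 1, tolerance = 1e-12)
})

test_that("gowerDist is permutation-equivariant and weight-scale invariant", {
  set.seed(201)
  sp <- simulateTraits(simulationConfig(seed = 11, n_species = 20))
  D <- gowerDist(sp)
  perm <- sample(nSpecies(sp))
  Dp <- gowerDist(speciesData(sp)[perm, ])
  expect_equal(Dp, D[perm, perm], tolerance = 1e-12)

  vars <- names(faunadiv:::gowerVariables(speciesData(sp)))
  groups <- vapply(faunadiv:::gowerVariables(speciesData(sp)),
                   `[[`, character(1), "group")
  w <- setNames(1 / as.numeric(table(groups)[groups]), vars)
  expect_equal(gowerDist(sp, weights = 2 * w), D, tolerance = 1e-12)
})

test_that("gowerDist agrees with cluster::daisy under matching setup", {
  skip_if_not_installed("cluster")
  # handcrafted so that every variable varies (daisy and gowerDist treat
  # zero-range variables differently, which is tested elsewhere)
  set.seed(202)
  n <- 8
  sp <- toySpecies(sprintf("d%02d", 1:n), mass = 10^runif(n, 1, 5))
  diet <- t(sapply(1:n, function(i) faunadiv:::roundToSum(rgamma(7, 1), 100)))
  for (j in 1:7) diet[j, j] <- diet[j, j] + 1L  # guarantee variation per column
  diet <- t(apply(diet, 1, faunadiv:::roundToSum, total = 100))
  sp[dietColumns()] <- diet
  sp$foraging_stratum <- rep(c("ground", "arboreal"), length.out = n)
  sp$act_nocturnal <- rep(c(TRUE, FALSE), length.out = n)
  sp$act_crepuscular <- rep(c(TRUE, TRUE, FALSE), length.out = n)
  sp$act_diurnal <- rep(c(FALSE, TRUE), length.out = n)
  sp$habitat_flags <- rep(c("forest", "forest;wetland", "wetland"),
                          length.out = n)
  vars <- faunadiv:::gowerVariables(sp)
  cols <- lapply(vars, function(v)
    if (v$type == "categorical") factor(v$x) else
    if (v$type == "binary") as.numeric(v$x) else v$x)
  daisyDf <- as.data.frame(cols, optional = TRUE)
  groups <- vapply(vars, `[[`, character(1), "group")
  w <- 1 / as.numeric(table(groups)[groups])
  # daisy treats 0/1 numeric flags as interval-scaled; with range 1 that is
  # the same 0/1 mismatch contribution used here
  ref <- as.matrix(cluster::daisy(daisyDf, metric = "gower", weights = w))
  D <- gowerDist(sp)
  expect_equal(unname(D), unname(ref), tolerance = 1e-10)
})

test_that("sqrtTransform is element-wise and preserves structure", {
  D <- matrix(c(0, 0.25, 0.25, 0), 2)
  expect_equal(sqrtTransform(D), matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(sqrtTransform(matrix(0, 3, 3)), matrix(0, 3, 3))
  one <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(sqrtTransform(one), one)
  expect_error(sqrtTransform(-one), "non-negative")
})

test_that("pcoaAxes recovers Euclidean configurations", {
  set.seed(203)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  ax <- pcoaAxes(D, k = 2)
  expect_equal(as.matrix(dist(ax$coordinates)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ax$varianceRepresented, 1, tolerance = 1e-8)
  expect_true(all(diff(ax$eigenvalues) <= 1e-12))

  # isometry up to rotation/reflection in up to 5 dims
  for (k in c(3, 5)) {
    pts <- matrix(rnorm(20 * k), 20, k)
    D <- as.matrix(dist(pts))
    ax <- pcoaAxes(D, k = k)
    expect_equal(as.matrix(dist(ax$coordinates)), D, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # two points at dissimilarity d embed at +/- d/2
  d <- 0.6
  ax2 <- pcoaAxes(matrix(c(0, d, d, 0), 2), k = 1)
  expect_equal(sort(ax2$coordinates[, 1]), c(-d / 2, d / 2))

  # collinear points have one positive eigenvalue: k = 2 must fail
  line <- cbind(c(0, 1, 2, 3), 0)
  expect_error(pcoaAxes(as.matrix(dist(line)), k = 2), "positive eigenvalues")
})

test_that("pcoaAxes flags strongly non-Euclidean input and sqrt cures it", {
  # one pair three times further apart than every other pair strongly
  # violates the triangle inequality: large negative eigenvalue
  D <- matrix(1, 4, 4); diag(D) <- 0; D[1, 2] <- D[2, 1] <- 3
  expect_error(pcoaAxes(D, k = 2), "sqrtTransform")
  expect_silent(pcoaAxes(sqrtTransform(D), k = 2))
})

test_that("pcoaAxes agrees with ape::pcoa on a seeded Gower matrix", {
  skip_if_not_installed("ape")
  sp <- simulateTraits(simulationConfig(seed = 13, n_species = 25))
  D <- sqrtTransform(gowerDist(sp))
  ax <- pcoaAxes(D, k = 4)
  ref <- ape::pcoa(as.dist(D))
  expect_equal(ax$eigenvalues, ref$values$Eigenvalues[1:4], tolerance = 1e-8)
  expect_equal(abs(ax$coordinates), abs(ref$vectors[, 1:4]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("trait space build keeps negative eigenvalue mass in tolerance", {
  sp <- simulateTraits(simulationConfig(seed = 14, n_species = 60))
  ts <- buildTraitSpace(sp, k = 5)
  expect_s4_class(ts, "TraitSpace")
  expect_length(speciesIds(ts), 60)
  expect_equal(dim(traitCoordinates(ts)), c(60, 5))
  expect_true(ts@varianceRepresented > 0 && ts@varianceRepresented <= 1)
  expect_true(ts@globalVolume > 0)
  # dissimilarity export/import round-trips
  path <- withr::local_tempfile(fileext = ".csv")
  D <- sqrtTransform(gowerDist(sp))
  writeDissimilarity(D, path)
  expect_equal(readDissimilarity(path), D, tolerance = 1e-12)
})
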