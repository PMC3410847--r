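test_that("torsion and planar angles reproduce constructed geometry", {
  ## four atoms placed at a known 90-degree torsion
  a <- c(1, 1, 0); b <- c(0, 0, 0); c_ <- c(0, 0, 1.5); d <- c(0.8, 0, 1.5 + 0.8)
  ## d lies in the xz plane; a in the xy plane: torsion is -90 under the
  ## standard convention (verified against bio3d below); build +90 instead
  d90 <- placeAtom(a, b, c_, 1.2, 110, 90)
  expect_equal(torsionAngle(a, b, c_, d90), 90, tolerance = 1e-9)
  expect_equal(vecAngle(b, c_, d90), 110, tolerance = 1e-9)
  ## straight angle and right angle
  expect_equal(vecAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vecAngle(c(1, 0, 0), c(0, 0, 0), c(-2, 0, 0)), 180)
})

test_that("torsion measurement matches the bio3d implementation on a real structure", {
  s <- readStructure(lysozymePath())
  pdb <- suppressWarnings(bio3d::read.pdb(lysozymePath(), verbose = FALSE))
  tor <- bio3d::torsion.pdb(pdb)
  for (r in c(10, 24, 40, 80)) {
    mine <- backboneDihedrals(s, "A", r)
    expect_equal(mine$phi, tor$phi[r], tolerance = 1e-4)
    expect_equal(mine$psi, tor$psi[r], tolerance = 1e-4)
  }
})

test_that("torsions and tau are invariant under rigid transforms", {
  set.seed(11)
  s <- serTemplate()
  ref <- backboneDihedrals(s, "A", 4)
  for (k in 1:5) {
    tr <- randomRigid()
    a <- atoms(s)
    m <- as.matrix(a[, c("x", "y", "z")]) %*% t(tr$R) +
      matrix(tr$t, nrow(a), 3, byrow = TRUE)
    a[, c("x", "y", "z")] <- m
    got <- backboneDihedrals(Structure(a), "A", 4)
    expect_equal(got$phi, ref$phi, tolerance = 1e-9)
    expect_equal(got$psi, ref$psi, tolerance = 1e-9)
    expect_equal(got$tau, ref$tau, tolerance = 1e-9)
  }
})

test_that("axis rotation matches an independent Rodrigues-matrix oracle", {
  set.seed(21)
  for (k in 1:10) {
    p <- rnorm(3, 0, 5); o <- rnorm(3); ax <- rnorm(3); ang <- runif(1, -180, 180)
    expect_equal(rotateAboutAxis(p, o, ax, ang),
                 oracleRotate(p, o, ax, ang), tolerance = 1e-9)
  }
  ## points on the axis never move
  o <- c(1, 2, 3); ax <- c(0.3, -1, 2)
  onAxis <- o + 2.7 * ax
  expect_equal(rotateAboutAxis(onAxis, o, ax, 73.2), onAxis, tolerance = 1e-12)
})

test_that("Kabsch superposition is optimal and matches bio3d::fit.xyz", {
  set.seed(31)
  target <- matrix(rnorm(18, 0, 4), 6, 3)
  tr <- randomRigid()
  mobile <- target %*% t(tr$R) + matrix(tr$t, 6, 3, byrow = TRUE)
  fit <- kabsch(mobile, target)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(applyTransform(mobile, fit), target, tolerance = 1e-9)

  ## noisy case: compare the attained RMSD to bio3d's least-squares fit
  noisy <- mobile + matrix(rnorm(18, 0, 0.3), 6, 3)
  fit2 <- kabsch(noisy, target)
  moved <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(target)),
                                           mobile = as.numeric(t(noisy))))
  refRmsd <- sqrt(mean(colSums(matrix((moved - as.numeric(t(target)))^2, 3))))
  expect_equal(fit2$rmsd, refRmsd, tolerance = 1e-6)

  ## no random rigid transform does better than the returned optimum
  set.seed(32)
  for (k in 1:20) {
    rr <- randomRigid()
    alt <- coordRmsd(noisy %*% t(rr$R) + matrix(rr$t, 6, 3, byrow = TRUE), target)
    expect_gte(alt, fit2$rmsd - 1e-9)
  }
})

test_that("internal-coordinate placement round-trips bond, angle and torsion", {
  set.seed(41)
  for (k in 1:10) {
    a <- rnorm(3); b <- a + rnorm(3); c_ <- b + rnorm(3)
    bond <- runif(1, 1, 2); ang <- runif(1, 60, 170); tor <- runif(1, -179, 179)
    d <- placeAtom(a, b, c_, bond, ang, tor)
    expect_equal(sqrt(sum((d - c_)^2)), bond, tolerance = 1e-9)
    expect_equal(vecAngle(b, c_, d), ang, tolerance = 1e-9)
    expect_equal(torsionAngle(a, b, c_, d), tor, tolerance = 1e-9)
  }
})
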