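test_that("the zero move is the identity and the pivots never move", {
  s <- serTemplate()
  m0 <- applyBackrub(s, "A", 2, BackrubMove(0, 0, 0))
  expect_identical(atoms(m0), atoms(s))
  for (th in c(-15, 7, 15)) {
    m <- applyBackrub(s, "A", 2, BackrubMove(th, 3, -2))
    expect_equal(atomXYZOf(m, "A", 1, "CA"), atomXYZOf(s, "A", 1, "CA"),
                 tolerance = 1e-12)
    expect_equal(atomXYZOf(m, "A", 3, "CA"), atomXYZOf(s, "A", 3, "CA"),
                 tolerance = 1e-12)
    ## atoms outside the window are untouched
    expect_equal(atomXYZOf(m, "A", 6, "CA"), atomXYZOf(s, "A", 6, "CA"))
    ## the central Calpha moves under the primary rotation
    expect_gt(sqrt(sum((atomXYZOf(m, "A", 2, "CA") -
                          atomXYZOf(s, "A", 2, "CA"))^2)), 0)
  }
})

test_that("rigid groups keep every internal distance", {
  s <- serTemplate()
  m <- applyBackrub(s, "A", 2, BackrubMove(12, 4, -3))
  a0 <- atoms(s); a1 <- atoms(m)
  ## the dipeptide minus the counter-rotated peptides stays rigid: compare
  ## pairwise distances among residue 2 atoms not moved by theta12/theta23
  core <- which(a0$resno == 2 & !(a0$elety %in% c("N", "H", "C", "O")))
  d0 <- dist(a0[core, c("x", "y", "z")])
  d1 <- dist(a1[core, c("x", "y", "z")])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("per-atom displacement equals the independent rotation oracle", {
  s <- serTemplate()
  th <- 9.5
  m <- applyBackrub(s, "A", 2, BackrubMove(th, 0, 0))
  o <- atomXYZOf(s, "A", 1, "CA")
  ax <- atomXYZOf(s, "A", 3, "CA") - o
  for (nm in c("CA", "CB", "OG")) {
    expect_equal(atomXYZOf(m, "A", 2, nm),
                 oracleRotate(atomXYZOf(s, "A", 2, nm), o, ax, th),
                 tolerance = 1e-9)
  }
})

test_that("the move set composes and inverts exactly", {
  s <- serTemplate()
  m <- applyBackrub(s, "A", 2, BackrubMove(11, 4, -2))
  back <- applyBackrub(m, "A", 2, BackrubMove(0, -4, 2))
  back <- applyBackrub(back, "A", 2, BackrubMove(-11, 0, 0))
  d <- abs(as.matrix(atoms(back)[, c("x", "y", "z")]) -
             as.matrix(atoms(s)[, c("x", "y", "z")]))
  expect_lte(max(d), 1e-6)
})

test_that("single-peptide rotation keeps both Calphas and inverts", {
  s <- serTemplate()
  m <- applyPeptideRotation(s, "A", 4, 15)
  expect_equal(atomXYZOf(m, "A", 4, "CA"), atomXYZOf(s, "A", 4, "CA"),
               tolerance = 1e-12)
  expect_equal(atomXYZOf(m, "A", 5, "CA"), atomXYZOf(s, "A", 5, "CA"),
               tolerance = 1e-12)
  back <- applyPeptideRotation(m, "A", 4, -15)
  d <- abs(as.matrix(atoms(back)[, c("x", "y", "z")]) -
             as.matrix(atoms(s)[, c("x", "y", "z")]))
  expect_lte(max(d), 1e-9)
  expect_identical(atoms(applyPeptideRotation(s, "A", 4, 0)), atoms(s))
})

test_that("counter-rotations restore the carbonyl oxygens", {
  s <- serTemplate()
  expect_equal(unname(restoringCounterRotations(s, "A", 2, 0)), c(0, 0))
  expect_equal(unname(restoringCounterRotations(s, "A", 2, 10, epsilon = 0)),
               c(0, 0))
  ## with epsilon = 1 the oxygens end strictly closer to their originals
  oDisp <- function(m) {
    sqrt(sum((atomXYZOf(m, "A", 1, "O") - atomXYZOf(s, "A", 1, "O"))^2)) +
      sqrt(sum((atomXYZOf(m, "A", 2, "O") - atomXYZOf(s, "A", 2, "O"))^2))
  }
  plain <- applyBackrub(s, "A", 2, BackrubMove(10, 0, 0))
  cr <- restoringCounterRotations(s, "A", 2, 10, epsilon = 1)
  restored <- applyBackrub(s, "A", 2, BackrubMove(10, cr[1], cr[2], 1))
  expect_lt(oDisp(restored), oDisp(plain))
})

test_that("fitting recovers applied moves across the analysis range", {
  s <- serTemplate()
  for (th in c(-15, -7, 7, 15)) {
    cr <- restoringCounterRotations(s, "A", 2, th, 0.7)
    m <- applyBackrub(s, "A", 2, BackrubMove(th, cr[1], cr[2]))
    fit <- fitBackrub(s, m, "A", 2)
    expect_equal(fit@move@theta13, th, tolerance = 0.1)
    expect_lte(fit@residualRmsd, 1e-3)
  }
  ident <- fitBackrub(s, s, "A", 2)
  expect_equal(ident@move@theta13, 0, tolerance = 0.05)
  expect_lte(ident@residualRmsd, 1e-6)
})

test_that("fitting works without a C-beta (Gly window)", {
  g <- buildChain(rep("GLY", 5), phi = -60, psi = -40)
  cr <- restoringCounterRotations(g, "A", 3, 8, 0.7)
  m <- applyBackrub(g, "A", 3, BackrubMove(8, cr[1], cr[2]))
  fit <- fitBackrub(g, m, "A", 3)
  expect_equal(fit@move@theta13, 8, tolerance = 0.1)
})

test_that("tau strain is definitional and appears at the flanking residues", {
  s <- serTemplate()
  expect_equal(unname(tauStrain(s, s, "A", 2)), c(0, 0, 0))
  m <- applyBackrub(s, "A", 2, BackrubMove(12, 0, 0))
  ts <- tauStrain(s, m, "A", 2)
  expect_gt(abs(ts[["dtau.im1"]]), 0.5)
  expect_gt(abs(ts[["dtau.ip1"]]), 0.5)
  ## equals direct re-measurement
  expect_equal(ts[["dtau.ip1"]],
               tauAngle(m, "A", 3) - tauAngle(s, "A", 3), tolerance = 1e-9)
})

test_that("degenerate windows raise errors", {
  s <- serTemplate()
  expect_error(applyBackrub(s, "A", 1, BackrubMove(5)), "window")
  expect_error(applyBackrub(s, "A", 10, BackrubMove(5)), "window")
})
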