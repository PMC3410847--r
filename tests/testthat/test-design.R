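test_that("the ideal N-cap template has the stated conformation", {
  t <- serTemplate()
  cap <- backboneDihedrals(t, "A", 2)
  expect_equal(cap$phi, -80, tolerance = 0.01)
  expect_equal(cap$psi, 170, tolerance = 0.01)
  n2 <- backboneDihedrals(t, "A", 4)   # cap + 2
  expect_equal(n2$phi, -60, tolerance = 0.01)
  expect_equal(n2$psi, -40, tolerance = 0.01)
  for (r in 2:9) expect_equal(tauAngle(t, "A", r), 111, tolerance = 0.1)
  expect_equal(atoms(t)$resid[atoms(t)$resno == 2][1], "SER")
})

test_that("beta-template mutations replace only the sidechain", {
  sh <- glySheet()
  ## Gly -> Ala: ideal C-beta, methyl hydrogens, backbone untouched
  ala <- prepareBetaTemplate(sh, "B", 4, "ALA")
  expect_equal(cbetaDeviation(ala, "B", 4), 0, tolerance = 1e-9)
  expect_true(all(c("CB", "HB1", "HA") %in%
                    atoms(ala)$elety[atoms(ala)$chain == "B" &
                                       atoms(ala)$resno == 4]))
  expect_equal(atomXYZOf(ala, "B", 4, "CA"), atomXYZOf(sh, "B", 4, "CA"))
  ## Ala -> Gly: nothing beyond the backbone plus HA2/HA3
  shA <- makeMotifFixtures("beta_other")$structure
  gly <- prepareBetaTemplate(shA, "B", 4, "GLY")
  nm <- atoms(gly)$elety[atoms(gly)$chain == "B" & atoms(gly)$resno == 4]
  expect_setequal(nm, c("N", "H", "CA", "C", "O", "HA2", "HA3"))
  ## keep is the identity
  expect_identical(atoms(prepareBetaTemplate(sh, "B", 4, "keep")), atoms(sh))
})

test_that("the tau filter brackets feasibility", {
  t <- serTemplate()
  expect_true(tauFilter(t, "A", 1:3))
  expect_true(tauFilter(t, "A", 1:3, limit = 180))
  big <- applyBackrub(t, "A", 2, BackrubMove(20, 0, 0))
  expect_false(tauFilter(big, "A", 1:3, limit = 2))
})

test_that("a singleton space returns itself as GMEC", {
  res <- enumerateGmec(serTemplate(), "A", 2, "SER",
                       backrubGrid = 0,
                       rotamers = rotamersFor("SER")[1, ])
  expect_equal(res@counts[["enumerated"]], 1)
  expect_equal(res@gmecInfo$theta13, 0)
  expect_equal(res@gmecInfo$rotamer, "p")
  ## total = elec + vdw + solv exactly
  gi <- res@gmecInfo
  expect_equal(gi$total, gi$elec + gi$vdw + gi$solv, tolerance = 1e-9)
})

test_that("the enumerated minimum is order-invariant and equals the ranking minimum", {
  grid <- seq(-6, 6, by = 2)
  fwd <- enumerateGmec(serTemplate(), "A", 2, "SER", backrubGrid = grid)
  rev <- enumerateGmec(serTemplate(), "A", 2, "SER", backrubGrid = base::rev(grid))
  expect_equal(fwd@gmecInfo$total, rev@gmecInfo$total, tolerance = 1e-9)
  expect_equal(fwd@gmecInfo$theta13, rev@gmecInfo$theta13)
  rk <- fwd@ranking
  expect_equal(fwd@gmecInfo$total, min(rk$total[rk$feasible]), tolerance = 1e-12)
})

test_that("halving the grid step never raises the GMEC energy", {
  coarse <- enumerateGmec(serTemplate(), "A", 2, "SER",
                          backrubGrid = seq(-14, 14, by = 4))
  fine <- enumerateGmec(serTemplate(), "A", 2, "SER",
                        backrubGrid = seq(-14, 14, by = 2))
  expect_lte(fine@gmecInfo$total, coarse@gmecInfo$total + 1e-9)
})

test_that("tau-infeasible points are skipped but counted", {
  res <- enumerateGmec(serTemplate(), "A", 2, "SER",
                       backrubGrid = seq(-15, 15, by = 5), tauLimit = 3)
  expect_gt(res@counts[["tauRejected"]], 0)
  expect_equal(res@counts[["enumerated"]],
               res@counts[["feasible"]] + res@counts[["tauRejected"]])
  ## an impossible limit yields an explicit empty result
  none <- enumerateGmec(serTemplate(), "A", 2, "SER",
                        backrubGrid = c(-15, 15), tauLimit = 0.01)
  expect_equal(none@counts[["feasible"]], 0)
  expect_equal(length(none@gmecInfo), 0L)
})

test_that("Ser and Asn ideal-cap models shift in opposite directions", {
  runs <- ncapDesignRuns()
  thS <- runs$ser@gmecInfo$theta13
  thN <- runs$asn@gmecInfo$theta13
  expect_true(thS != 0 && thN != 0)
  expect_lt(sign(thS) * sign(thN), 0)
  ## both keep the capping (plus-chi1) rotamer
  expect_match(runs$ser@gmecInfo$rotamer, "^p")
  expect_match(runs$asn@gmecInfo$rotamer, "^p")
})

test_that("a beta-sheet design with backrubs at both positions runs", {
  sh <- prepareBetaTemplate(glySheet(), "B", 4, "ALA")
  res <- enumerateGmec(sh, "A", 4, "PHE",
                       backrubGrid = seq(-6, 6, by = 3),
                       secondaryResno = NULL,
                       rotamers = rotamersFor("PHE")[1, , drop = FALSE])
  expect_gt(res@counts[["feasible"]], 0)
  res2 <- enumerateGmec(sh, "A", 4, "PHE",
                        backrubGrid = c(-3, 0, 3),
                        secondaryResno = 4, secondaryChain = "B",
                        rotamers = rotamersFor("PHE")[1, , drop = FALSE])
  expect_equal(res2@counts[["enumerated"]], 9)
  expect_gt(res2@counts[["feasible"]], 0)
})
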