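test_that("helix annotation finds spans, cap classes, and the 5.9 A rule", {
  ann <- annotateHelices(serTemplate())
  expect_equal(nrow(ann$helices), 1L)
  expect_equal(ann$helices$capClass, "alpha")
  expect_equal(ann$helices$ncapResno, 2L)
  ## the accepted cap satisfies the Calpha(i)..Calpha(i+3) extension rule
  s <- serTemplate()
  d <- sqrt(sum((atomXYZOf(s, "A", 2, "CA") - atomXYZOf(s, "A", 5, "CA"))^2))
  expect_lt(d, 5.9)
  ## 3-10 helix: i+3 bonds only
  h310 <- generateIdealHelix(10, phi = -71, psi = -18)
  ann310 <- annotateHelices(h310)
  expect_equal(ann310$helices$capClass[1], "three10")
  ## all-extended chain: no helices
  ext <- buildChain(rep("ALA", 10), phi = -120, psi = 130)
  expect_equal(nrow(annotateHelices(ext)$helices), 0L)
})

test_that("N-cap scanning assigns categories and clusters on fixtures", {
  for (k in c("ncap_ST", "ncap_ND", "ncap_other")) {
    fx <- makeMotifFixtures(k)
    hits <- findNcapMotifs(fx$structure)
    expect_equal(nrow(hits), fx$expected$nHits)
    expect_equal(hits$category, fx$expected$category)
    expect_equal(hits$cluster, fx$expected$cluster)
    expect_equal(hits$resno, fx$expected$resno)
  }
  ## ND/ST hits carry the i+3 bond geometry
  st <- findNcapMotifs(makeMotifFixtures("ncap_ST")$structure)
  expect_lt(st$hbEnergy, -0.5)
  expect_gt(st$hbLength, 0)
})

test_that("the B-factor filter drops caps at 40 or above", {
  fx <- makeMotifFixtures("ncap_ST")
  a <- atoms(fx$structure)
  a$b[a$resno == 2] <- 45
  expect_equal(nrow(findNcapMotifs(Structure(a))), 0L)
  a$b[a$resno == 2] <- 39
  expect_equal(nrow(findNcapMotifs(Structure(a))), 1L)
})

test_that("bifurcated caps are excluded", {
  ## two 3-10-like turns ahead of an alpha helix give the cap both an
  ## i+3 and an i+4 mainchain bond
  s <- buildChain(c("SER", rep("ALA", 9)),
                  phi = c(-60, -60, rep(-60, 8)),
                  psi = c(-30, -30, rep(-40, 8)),
                  chi = list(62))
  ann <- annotateHelices(s)
  expect_equal(ann$helices$capClass[1], "bifurcated")
  expect_equal(nrow(findNcapMotifs(s, annotation = ann)), 0L)
})

test_that("mid-helix controls require length, flanks, phi/psi and B", {
  mh <- findMidhelixControls(generateIdealHelix(15))
  expect_gte(nrow(mh), 1L)
  expect_true(8 %in% mh$resno)            # the central residue qualifies
  expect_true(all(mh$category == "midhelix"))
  expect_equal(nrow(findMidhelixControls(generateIdealHelix(11))), 0L)
  ## B-factor limit of 20
  h <- generateIdealHelix(15, bFactor = 21)
  expect_equal(nrow(findMidhelixControls(h)), 0L)
  ## a central residue outside the strict phi/psi box is dropped
  h2 <- buildChain(rep("ALA", 15), phi = c(rep(-60, 7), -70, rep(-60, 7)),
                   psi = c(rep(-40, 7), -40, rep(-40, 7)))
  expect_false(8 %in% findMidhelixControls(h2)$resno)
})

test_that("fray components match a direct recomputation oracle", {
  set.seed(17)
  sh <- glySheet()
  ## symmetric construction: fray 0
  fr <- computeFray(sh, list(chain = "A", resno = 4), list(chain = "B", resno = 4))
  expect_lte(abs(fr[["fray"]]), 1e-6)
  ## randomized geometry: recompute every component from raw coordinates
  a <- atoms(sh)
  a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + rnorm(3 * nrow(a), 0, 0.15)
  s2 <- Structure(a)
  fr2 <- computeFray(s2, list(chain = "A", resno = 4), list(chain = "B", resno = 4))
  ca <- function(ch, r) atomXYZOf(s2, ch, r, "CA")
  tN <- torsionAngle(ca("A", 3), ca("A", 4), ca("B", 4), ca("B", 5))
  tC <- torsionAngle(ca("A", 5), ca("A", 4), ca("B", 4), ca("B", 3))
  pA <- vecAngle(ca("A", 3), ca("A", 4), ca("A", 5))
  pO <- vecAngle(ca("B", 3), ca("B", 4), ca("B", 5))
  expect_equal(fr2[["tN"]], tN, tolerance = 1e-9)
  expect_equal(fr2[["tC"]], tC, tolerance = 1e-9)
  expect_equal(fr2[["fray"]], abs(tN - tC) - abs(pA - pO), tolerance = 1e-9)
  ## invariance under rigid transforms
  tr <- randomRigid()
  a3 <- atoms(s2)
  a3[, c("x", "y", "z")] <- as.matrix(a3[, c("x", "y", "z")]) %*% t(tr$R) +
    matrix(tr$t, nrow(a3), 3, byrow = TRUE)
  fr3 <- computeFray(Structure(a3), list(chain = "A", resno = 4),
                     list(chain = "B", resno = 4))
  expect_equal(fr3[["fray"]], fr2[["fray"]], tolerance = 1e-6)
})

test_that("beta-aromatic scanning applies the chi1, category and fray filters", {
  hits <- findBetaAromaticMotifs(glySheet())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$category, "gly")
  expect_equal(hits$oppositeAA, "GLY")
  expect_equal(classifyChi1(hits$chi1), "plus")
  ## minus-chi1 aromatic: no hit
  shm <- generateIdealSheet(aromaticAA = "PHE", aromaticChi = c(-65, -85),
                            oppositeAA = "GLY")
  expect_equal(nrow(findBetaAromaticMotifs(shm)), 0L)
  ## non-Gly opposite: category other
  shA <- makeMotifFixtures("beta_other")
  hA <- findBetaAromaticMotifs(shA$structure)
  expect_equal(hA$category, "other")
  ## frayed pair rejected
  sh11 <- generateIdealSheet(frayPerturb = 11, aromaticAA = "PHE",
                             oppositeAA = "GLY")
  expect_equal(nrow(findBetaAromaticMotifs(sh11)), 0L)
  ## the fray filter itself: an impossible limit rejects the intact pair
  cfg <- motifConfig(); cfg$frayLimit <- -1
  expect_equal(nrow(findBetaAromaticMotifs(glySheet(), cfg)), 0L)
})

test_that("relaxing any threshold never decreases the hit count", {
  fx <- makeMotifFixtures("ncap_ST")$structure
  a <- atoms(fx); a$b[a$resno == 2] <- 45
  tight <- Structure(a)
  cfg <- motifConfig()
  relaxedB <- cfg; relaxedB$bMaxCap <- 100
  expect_gte(nrow(findNcapMotifs(tight, relaxedB)),
             nrow(findNcapMotifs(tight, cfg)))
  sh <- glySheet()
  relaxedF <- cfg; relaxedF$frayLimit <- 50
  tightF <- cfg; tightF$frayLimit <- 1e-9
  expect_gte(nrow(findBetaAromaticMotifs(sh, relaxedF)),
             nrow(findBetaAromaticMotifs(sh, tightF)))
})

test_that("every accepted N-cap has exactly one category", {
  for (k in c("ncap_ST", "ncap_ND", "ncap_other")) {
    hits <- findNcapMotifs(makeMotifFixtures(k)$structure)
    expect_true(all(hits$category %in% c("ND", "ST", "other")))
    expect_equal(length(hits$category), length(unique(paste(hits$chain, hits$resno))))
  }
})

test_that("propensities are frequency ratios with NA off-background types", {
  expect_equal(aminoAcidPropensity(c("SER", "ALA"), c("SER", "ALA"))$propensity,
               c(1, 1))
  t2 <- aminoAcidPropensity(rep("SER", 10),
                            c(rep("SER", 10), rep("ALA", 90)))
  expect_equal(t2$propensity[t2$aa == "SER"], 10)
  expect_true(is.na(t2$propensity[t2$aa == "ALA"]) || t2$propensity[t2$aa == "ALA"] == 0)
  ## 3x enrichment constructed, recovered within sampling error
  set.seed(9)
  bg <- sample(c("ASN", "ALA", "GLY", "LEU"), 4000, replace = TRUE,
               prob = c(0.1, 0.3, 0.3, 0.3))
  mot <- sample(c("ASN", "ALA", "GLY", "LEU"), 1000, replace = TRUE,
                prob = c(0.3, 7 / 30, 7 / 30, 7 / 30))
  t3 <- aminoAcidPropensity(mot, bg)
  expect_equal(t3$propensity[t3$aa == "ASN"], 3, tolerance = 0.25)
  ## rank-sum convenience wrapper returns a one-sided htest
  vals <- c(2.5, 2.7, 3.0, 2.9, 0.9, 1.1, 1.0, 0.8, 1.2, 0.7)
  grp <- c(rep(TRUE, 4), rep(FALSE, 6))
  ht <- propensityRankSum(vals, grp)
  expect_s3_class(ht, "htest")
  expect_lt(ht$p.value, 0.05)
})
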