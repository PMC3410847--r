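windowOf <- function(s) backrubr:::.extractWindow(s, "A", 2L, -1L:3L)

test_that("superposition recovers rigid copies exactly", {
  set.seed(3)
  ref <- windowOf(serTemplate())
  frame <- frameAtoms("ncap4", 2)
  tr <- randomRigid()
  a <- atoms(ref)
  a[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) %*% t(tr$R) +
    matrix(tr$t, nrow(a), 3, byrow = TRUE)
  moved <- Structure(a)
  ens <- superposeOnFrame(list(moved, ref), ref, frame)
  expect_lte(ens@rmsd[1], 1e-9)
  expect_lte(ens@rmsd[2], 1e-12)   # self-superposition is the identity
  d <- abs(as.matrix(atoms(ens@members[[1]])[, c("x", "y", "z")]) -
             as.matrix(atoms(ref)[, c("x", "y", "z")]))
  expect_lte(max(d), 1e-9)
  expect_error(superposeOnFrame(list(ref), ref, frame[1:2, ]), "3 frame")
})

test_that("pruning removes exactly the displaced members", {
  ref <- windowOf(serTemplate())
  frame <- frameAtoms("ncap4", 2)
  near <- ref
  a <- atoms(ref); a$x <- a$x + 2   # uniform 2 A shift: rmsd 2 pre-fit, 0 post-fit
  ## instead displace only the frame atoms incoherently so the fit cannot absorb it
  a2 <- atoms(ref)
  sel <- a2$elety == "CA" & a2$resno %in% frame$resno
  a2[sel, "x"] <- a2[sel, "x"] + c(2, -2, 2, -2)
  far <- Structure(a2)
  ens <- superposeOnFrame(list(near, far), ref, frame)
  pruned <- pruneByRmsd(ens, 1.0)
  expect_equal(length(pruned@members), 1L)
  expect_equal(attr(pruned, "prunedFraction"), 0.5)
  ## a near-zero limit keeps only exact frame matches
  strict <- pruneByRmsd(ens, 1e-9)
  expect_equal(length(strict@members), 1L)
  expect_warning(pruneByRmsd(superposeOnFrame(list(far), ref, frame), 0.1),
                 "pruned")
})

test_that("reference selection minimises the pruned count with stable ties", {
  set.seed(23)
  base <- windowOf(serTemplate())
  frame <- frameAtoms("ncap4", 2)
  jitter <- function(s, sd) {
    a <- atoms(s)
    a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + rnorm(3 * nrow(a), 0, sd)
    Structure(a)
  }
  members <- lapply(1:20, function(i) jitter(base, 0.05))
  outlier <- jitter(base, 1.2)
  sel <- selectReference(list(outlier, members[[1]]), members, frame)
  expect_equal(sel$index, 2L)
  one <- selectReference(list(base), members, frame)
  expect_equal(one$index, 1L)
  ## identical candidates: first wins
  tie <- selectReference(list(base, base), members, frame)
  expect_equal(tie$index, 1L)
})

test_that("averaging is the arithmetic mean with per-atom counts", {
  base <- windowOf(serTemplate())
  frame <- frameAtoms("ncap4", 2)
  ens <- superposeOnFrame(list(base, base, base), base, frame)
  avg <- averageMotif(ens)
  expect_equal(avg@nMembers, 3)
  aAvg <- atoms(avg@structure); aBase <- atoms(base)
  key <- paste(aAvg$resno, aAvg$elety)
  keyB <- paste(aBase$resno, aBase$elety)
  m <- match(key, keyB)
  d <- abs(as.matrix(aAvg[, c("x", "y", "z")]) -
             as.matrix(aBase[m, c("x", "y", "z")]))
  expect_lte(max(d), 1e-12)
  ## two members with one atom at x and x+2 average to x+1
  a2 <- atoms(base)
  i <- which(a2$resno == 2 & a2$elety == "CA")
  a2$x[i] <- a2$x[i] + 2
  ens2 <- new("SuperposedEnsemble", members = list(base, Structure(a2)),
              reference = base, frameAtoms = frame, rmsd = c(0, 0))
  avg2 <- averageMotif(ens2)
  aA <- atoms(avg2@structure)
  expect_equal(aA$x[aA$resno == 2 & aA$elety == "CA"],
               atoms(base)$x[i] + 1, tolerance = 1e-12)
})

test_that("the attached rotamer uses member-median chi at the mean C-beta", {
  set.seed(29)
  frame <- frameAtoms("ncap4", 2)
  mk <- function(chi) {
    t <- buildIdealNcapTemplate("SER", capChi = chi)
    windowOf(t)
  }
  chis <- c(58, 62, 66, 70, 61)
  members <- lapply(chis, mk)
  ens <- superposeOnFrame(members, members[[1]], frame)
  avg <- averageMotif(ens, rotamerAA = "SER", rotamerResno = 2)
  expect_equal(unname(avg@chi["chi1"]), median(chis), tolerance = 0.5)
  ## the rebuilt OG sits at the median chi1 measured from the average
  got <- backboneDihedrals(avg@structure, "A", 2)$chi1
  expect_equal(got, median(chis), tolerance = 0.5)
  expect_true("OG" %in% atoms(avg@structure)$elety)
})

test_that("averaging commutes with a common rigid transform", {
  set.seed(37)
  base <- windowOf(serTemplate())
  frame <- frameAtoms("ncap4", 2)
  jitter <- function(s) {
    a <- atoms(s)
    a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + rnorm(3 * nrow(a), 0, 0.05)
    Structure(a)
  }
  members <- lapply(1:6, function(i) jitter(base))
  ensA <- new("SuperposedEnsemble", members = members, reference = base,
              frameAtoms = frame, rmsd = numeric(6))
  avgThenMove <- averageMotif(ensA)@structure
  tr <- randomRigid()
  move <- function(s) {
    a <- atoms(s)
    a[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) %*% t(tr$R) +
      matrix(tr$t, nrow(a), 3, byrow = TRUE)
    Structure(a)
  }
  ensB <- new("SuperposedEnsemble", members = lapply(members, move),
              reference = base, frameAtoms = frame, rmsd = numeric(6))
  moveThenAvg <- averageMotif(ensB)@structure
  d <- abs(as.matrix(atoms(move(avgThenMove))[, c("x", "y", "z")]) -
             as.matrix(atoms(moveThenAvg)[, c("x", "y", "z")]))
  expect_lte(max(d), 1e-9)
})

test_that("displacement reports recover applied moves between averages", {
  s <- windowOf(serTemplate())
  frame <- frameAtoms("ncap4", 2)
  same <- displacementReport(s, s, frame, 2)
  expect_true(all(same$displacements$delta < 1e-9))
  expect_equal(same$fit@move@theta13, 0, tolerance = 0.05)
  cr <- restoringCounterRotations(s, "A", 2, 11, 0.7)
  moved <- applyBackrub(s, "A", 2, BackrubMove(11, cr[1], cr[2]))
  rep <- displacementReport(s, moved, frame, 2)
  d <- rep$displacements
  expect_gt(d$delta[d$resno == 2 & d$elety == "CA"], 0.2)
  expect_lt(max(d$delta[d$elety == "CA" & d$resno != 2]), 0.05)
  expect_equal(rep$fit@move@theta13, 11, tolerance = 0.3)
})

test_that("van der Waals overlap is radii-sum minus distance", {
  expect_equal(vdwOverlap(c(0, 0, 0), c(2.4, 0, 0), "O", "H"), 0)
  expect_equal(vdwOverlap(c(0, 0, 0), c(3.4, 0, 0), "O", "H"), -1)
  expect_equal(vdwOverlap(c(0, 0, 0), c(1.9, 0, 0), "O", "H"), 0.5)
  expect_error(vdwOverlap(c(0, 0, 0), c(1, 0, 0), "X", "H"), "unknown")
})
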