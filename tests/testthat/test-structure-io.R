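test_that("a minimal PDB round-trips through read and write", {
  s <- buildChain(c("ALA", "ALA", "ALA"), phi = -120, psi = 130)
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  rt <- residueTable(s2)
  expect_equal(nrow(rt), 3L)
  expect_equal(unique(rt$chain), "A")
  expect_equal(atoms(s2)$elety, atoms(s)$elety)
  d <- abs(as.matrix(atoms(s2)[, c("x", "y", "z")]) -
             as.matrix(atoms(s)[, c("x", "y", "z")]))
  expect_lte(max(d), 0.001)
})

test_that("a long synthetic helix round-trips exactly at PDB precision", {
  s <- generateIdealHelix(1000)
  f <- tempfile(fileext = ".pdb")
  writeStructure(s, f)
  s2 <- readStructure(f)
  expect_equal(length(s2), length(s))
  d <- abs(as.matrix(atoms(s2)[, c("x", "y", "z")]) -
             as.matrix(atoms(s)[, c("x", "y", "z")]))
  expect_lte(max(d), 0.001)
})

test_that("alternate locations keep the highest-occupancy variant as primary", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  C   ALA A   1      12.745   7.100  -4.974  1.00 10.00           C",
    "ATOM      4  O   ALA A   1      13.425   7.437  -5.947  1.00 10.00           O",
    "ATOM      5  CB AALA A   1      10.526   6.298  -4.128  0.60 12.00           C",
    "ATOM      6  CB BALA A   1      10.626   6.398  -4.228  0.40 12.00           C",
    "END"), f)
  s <- readStructure(f)
  a <- atoms(s)
  cb <- a[a$elety == "CB", ]
  expect_equal(cb$alt[cb$primary], "A")
  expect_false(cb$primary[cb$alt == "B"])
  ## tie broken by alt-loc letter
  a2 <- a
  a2$occ[a2$elety == "CB"] <- 0.5
  a2$primary <- NULL
  s2 <- Structure(a2)
  cb2 <- atoms(s2)[atoms(s2)$elety == "CB", ]
  expect_equal(cb2$alt[cb2$primary], "A")
})

test_that("chain breaks are detected from the C-N distance", {
  s1 <- buildChain(rep("ALA", 5), phi = -60, psi = -40, chain = "A")
  s2 <- buildChain(rep("ALA", 5), phi = -60, psi = -40, chain = "A",
                   startResno = 6L)
  a2 <- atoms(s2)
  a2$x <- a2$x + 50
  both <- Structure(rbind(atoms(s1), a2))
  br <- chainBreaks(both)
  expect_equal(nrow(br), 1L)
  expect_equal(br$resnoBefore, 5L)
  expect_equal(br$resnoAfter, 6L)
  expect_gt(br$distance, 2.5)
  expect_equal(nrow(chainBreaks(s1)), 0L)
})

test_that("empty structures and bad inputs are handled explicitly", {
  f <- tempfile(fileext = ".pdb")
  writeStructure(Structure(data.frame()), f)
  expect_true(file.exists(f))
  expect_error(readStructure(tempfile()), "not found")
  bad <- atoms(buildChain("ALA", -60, -40))
  bad$elety[1] <- "ABCDE"
  expect_error(Structure(bad))
})

test_that("Calpha-only chains are flagged geometry-incomplete", {
  s <- buildChain(rep("GLY", 5), phi = -120, psi = 130, addHydrogens = FALSE)
  a <- atoms(s)
  a <- a[a$elety == "CA", ]
  f <- tempfile(fileext = ".pdb")
  writeStructure(Structure(a), f)
  s2 <- readStructure(f)
  expect_equal(s2@header$geometryIncomplete, "A")
})
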