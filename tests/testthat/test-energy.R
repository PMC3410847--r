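## a two-atom parameter table for the closed-form checks
pairPars <- function(q1, q2, rmin2a, rmin2b, epsa, epsb,
                     heavy = c(FALSE, FALSE), eef = NULL) {
  p <- data.frame(q = c(q1, q2), rmin2 = c(rmin2a, rmin2b),
                  eps = c(epsa, epsb), heavy = heavy)
  if (is.null(eef)) {
    p$dGref <- p$dGfree <- p$volume <- p$lambda <- p$Reef <- NA_real_
  } else {
    p$dGref <- eef$dGref; p$dGfree <- eef$dGfree; p$volume <- eef$volume
    p$lambda <- eef$lambda; p$Reef <- eef$R
  }
  p
}

test_that("two neutral particles at the LJ minimum score minus the well depth", {
  model <- energyModel(vdwRadiusScale = 1)
  rmin <- 1.9080 * 2
  xyz <- rbind(c(0, 0, 0), c(rmin, 0, 0))
  e <- backrubr:::.pairEnergy(xyz, pairPars(0, 0, 1.9080, 1.9080, 0.1094, 0.1094),
                              1L, 2L, FALSE, model)
  expect_equal(e[["vdw"]], -0.1094, tolerance = 1e-9)
  expect_equal(e[["elec"]], 0)
  expect_equal(e[["solv"]], 0)
})

test_that("two unit charges at 3.32 A with unit dielectric give ~100 kcal/mol", {
  model <- energyModel(dielectric = "constant", factor = 1)
  xyz <- rbind(c(0, 0, 0), c(3.32, 0, 0))
  e <- backrubr:::.pairEnergy(xyz, pairPars(1, 1, 1, 1, 0, 0), 1L, 2L, FALSE, model)
  expect_equal(e[["elec"]], 332.0636 / 3.32, tolerance = 1e-9)
  expect_equal(e[["elec"]], 100.0, tolerance = 0.05)
})

test_that("the EEF1 pair term matches its closed form", {
  model <- energyModel(solvScale = 1)
  eef <- list(dGref = c(1.089, 1.089), dGfree = c(1.50, 1.50),
              volume = c(30, 30), lambda = c(3.5, 3.5), R = c(2.165, 2.165))
  r <- 4.0
  xyz <- rbind(c(0, 0, 0), c(r, 0, 0))
  e <- backrubr:::.pairEnergy(xyz, pairPars(0, 0, 1, 1, 0, 0,
                                            heavy = c(TRUE, TRUE), eef = eef),
                              1L, 2L, FALSE, model)
  x <- (r - 2.165) / 3.5
  f <- 1.50 / (2 * pi^1.5 * 3.5 * r^2) * exp(-x^2)
  expect_equal(e[["solv"]], -2 * f * 30, tolerance = 1e-9)
})

test_that("conformation energies decompose exactly and respect exclusions", {
  s <- serTemplate()
  e <- conformationEnergy(s)
  expect_equal(e[["total"]], e[["elec"]] + e[["vdw"]] + e[["solv"]],
               tolerance = 1e-9)
  ## flexible = all residues reproduces the default full set
  eAll <- conformationEnergy(s, flexible = data.frame(chain = "A",
                                                      resno = 1:10))
  expect_equal(eAll, e, tolerance = 1e-12)
  ## a single flexible residue scores a strict subset of the pairs
  eFlex <- conformationEnergy(s, flexible = data.frame(chain = "A", resno = 2))
  expect_true(is.finite(eFlex[["total"]]))
  expect_false(isTRUE(all.equal(eFlex[["total"]], e[["total"]])))
  ## unknown residue types name the offending atom type
  a <- atoms(s); a$resid[a$resno == 4] <- "TRP"
  expect_error(conformationEnergy(Structure(a)), "TRP")
})

test_that("bonded topology classifies 1-2/1-3 as excluded and 1-4 as scaled", {
  s <- buildChain(c("ALA", "ALA"), phi = -60, psi = -40)
  a <- atoms(s)[!atoms(s)$het, ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  A <- backrubr:::.bondGraph(xyz, a$elem)
  sep <- backrubr:::.pairSeparation(A)
  i <- function(nm, r) which(a$elety == nm & a$resno == r)
  expect_equal(sep[i("N", 1), i("CA", 1)], 0L)          # 1-2
  expect_equal(sep[i("N", 1), i("C", 1)], 0L)           # 1-3
  expect_equal(sep[i("N", 1), i("O", 1)], 14L)          # 1-4
  expect_equal(sep[i("N", 1), i("CA", 2)], 99L)         # beyond
  expect_equal(sep[i("H", 2), i("CA", 2)], 0L)          # H bonded via N
})
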