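## Synthetic-data generators: ideal helices, two-strand antiparallel
## sheets with controlled twist/pleat/fray, motif fixtures with known
## expected hits, and two-population ensembles related by a known backrub
## plus isotropic Gaussian coordinate noise.
##
## Everything is grown by the same internal-coordinate builder used for
## the design templates, so generated parameters can be re-measured
## exactly by the geometry module.

#' Generate an ideal helix
#'
#' @param n residue count.
#' @param phi,psi backbone torsions (degrees); the (-60, -40) default is
#'   the idealized alpha-helix used throughout; (-71, -18) approximates a
#'   3-10 helix.
#' @param aa residue type (recycled).
#' @param bFactor B-factor on every atom.
#' @return a [Structure-class] with hydrogens.
#' @export
generateIdealHelix <- function(n = 12L, phi = -60, psi = -40, aa = "ALA",
                               bFactor = 10) {
  buildChain(rep_len(aa, n), phi = phi, psi = psi, bFactor = bFactor)
}

## solve strand (phi, psi) for a target Calpha virtual dihedral
## (180 - twist) and Calpha pleat angle
.strandTorsions <- function(twist, pleat) {
  measure <- function(p) {
    s <- buildChain(rep("GLY", 5L), phi = p[1], psi = p[2],
                    addHydrogens = FALSE)
    ca <- t(vapply(1:4, function(i) .atomXYZ(s, "A", i, "CA"), numeric(3)))
    v <- torsionAngle(ca[1, ], ca[2, ], ca[3, ], ca[4, ])
    c(v = v, p = vecAngle(ca[1, ], ca[2, ], ca[3, ]))
  }
  targetV <- 180 - twist
  obj <- function(p) {
    m <- measure(p)
    dv <- ((m["v"] - targetV + 180) %% 360) - 180
    dv^2 + (m["p"] - pleat)^2
  }
  fit <- optim(c(-125, 130), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  if (fit$value > 1e-4)
    stop("no strand geometry for twist = ", twist, ", pleat = ", pleat)
  fit$par
}

#' Generate an ideal two-strand antiparallel sheet
#'
#' Two antiparallel strands with narrow-pair H-bond registry between the
#' middle residues.  Strand geometry is solved from the requested `twist`
#' (the deviation of the Calpha virtual dihedral from planar, degrees;
#' 0 gives a flat pleated ribbon) and `pleat` (the Calpha i-1, i, i+1
#' angle, degrees).  The second strand is the two-fold rotation image of
#' the first about the sheet normal, placed by optimising the narrow-pair
#' H-bond geometry; `frayPerturb` then tilts the second strand to set the
#' measured fray statistic to the requested value (a small internal root
#' find).
#'
#' @param nRes residues per strand (>= 5).
#' @param twist,pleat strand geometry parameters (degrees).
#' @param frayPerturb target fray value (degrees; 0 keeps the symmetric
#'   construction).
#' @param aromaticAA residue type at the middle of strand A (e.g.
#'   `"PHE"`), or `NULL` for plain Ala.
#' @param aromaticChi chi angles for the aromatic (default plus rotamer
#'   c(65, 80)).
#' @param oppositeAA residue type at the middle of strand B.
#' @param bFactor B-factor on every atom.
#' @return a [Structure-class] with chains A and B; header field `motif`
#'   records the aromatic/opposite positions.
#' @export
generateIdealSheet <- function(nRes = 7L, twist = 0, pleat = 122,
                               frayPerturb = 0, aromaticAA = NULL,
                               aromaticChi = c(65, 80),
                               oppositeAA = "GLY", bFactor = 10) {
  if (nRes < 5L) stop("need at least 5 residues per strand")
  mid <- (nRes + 1L) %/% 2L
  tor <- .strandTorsions(twist, pleat)
  aaA <- rep("ALA", nRes)
  chiA <- vector("list", nRes)
  if (!is.null(aromaticAA)) {
    aaA[mid] <- toupper(aromaticAA)
    chiA[[mid]] <- aromaticChi
  }
  aaB <- rep("ALA", nRes)
  aaB[mid] <- toupper(oppositeAA)
  sA <- buildChain(aaA, phi = tor[1], psi = tor[2], chi = chiA,
                   chain = "A", bFactor = bFactor)
  sB <- buildChain(aaB, phi = tor[1], psi = tor[2],
                   chain = "B", bFactor = bFactor)

  ## canonical frame for strand A: axis -> z, sheet plane -> xz
  caA <- t(vapply(seq_len(nRes), function(i) .atomXYZ(sA, "A", i, "CA"),
                  numeric(3)))
  ctr <- colMeans(caA)
  sv <- svd(sweep(caA, 2L, ctr))
  R <- rbind(sv$v[, 2], sv$v[, 3], sv$v[, 1])   # rows -> x, y, z
  if (det(R) < 0) R[2, ] <- -R[2, ]
  toCanon <- list(R = R, t = -drop(R %*% ctr))
  sA <- .transformStructure(sA, toCanon)
  sB <- .transformStructure(sB, toCanon)
  ## amides of a pleated strand point along the Calpha-plane normal (y);
  ## make the middle amide point toward +y, where strand B will sit
  hMid <- .atomXYZ(sA, "A", mid, "H"); nMid <- .atomXYZ(sA, "A", mid, "N")
  if (!is.null(hMid) && (hMid - nMid)[2] < 0) {
    flip <- list(R = diag(c(-1, -1, 1)), t = c(0, 0, 0))
    sA <- .transformStructure(sA, flip)
    sB <- .transformStructure(sB, flip)
  }

  ## strand B: two-fold rotation about the pleat (x) axis through
  ## (0, cy, cz) -- antiparallel, same-side pleating -- optimised for
  ## narrow-pair H-bond geometry
  hbObj <- function(c2) {
    tr <- list(R = diag(c(1, -1, -1)), t = c(0, 2 * c2[1], 2 * c2[2]))
    err <- 0
    for (k in c(-2L, 0L, 2L)) {
      iA <- mid + k; iB <- mid - k
      nA <- .atomXYZ(sA, "A", iA, "N"); oA <- .atomXYZ(sA, "A", iA, "O")
      hA <- .atomXYZ(sA, "A", iA, "H")
      nB <- applyTransform(.atomXYZ(sB, "B", iB, "N"), tr)
      oB <- applyTransform(.atomXYZ(sB, "B", iB, "O"), tr)
      hB0 <- .atomXYZ(sB, "B", iB, "H")
      hB <- if (is.null(hB0)) NULL else applyTransform(hB0, tr)
      err <- err + (.vnorm(nA - oB) - 2.95)^2 + (.vnorm(nB - oA) - 2.95)^2
      if (!is.null(hA)) err <- err + (.vnorm(hA - oB) - 1.95)^2
      if (!is.null(hB)) err <- err + (.vnorm(hB - oA) - 1.95)^2
    }
    err
  }
  fit <- optim(c(2.4, 0), hbObj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  trB <- list(R = diag(c(1, -1, -1)), t = c(0, 2 * fit$par[1], 2 * fit$par[2]))
  sB <- .transformStructure(sB, trB)

  assemble <- function(sBx) {
    out <- Structure(rbind(sA@atoms, sBx@atoms))
    out@header$motif <- list(
      aromatic = list(chain = "A", resno = mid),
      opposite = list(chain = "B", resno = mid),
      twist = twist, pleat = pleat, frayTarget = frayPerturb)
    out
  }

  if (frayPerturb != 0) {
    ## fray: the strands "pull apart" locally.  The C-ward half of
    ## strand B is translated away from the pair (along +y) and twisted
    ## about the inter-strand Calpha(A mid) -> Calpha(B mid) axis; the
    ## fray statistic is invariant under either move alone (the pleat
    ## correction cancels a pure twist exactly), so a nested solve picks
    ## the twist that zeroes the pleat-difference correction and the
    ## separation that brings the residual twist difference -- the fray
    ## -- to the target
    caA0 <- .atomXYZ(sA, "A", mid, "CA")
    caB0 <- .atomXYZ(sB, "B", mid, "CA")
    perturb <- function(sBx, sep, tw) {
      hi <- which(sBx@atoms$resno > mid)
      m <- .xyz(sBx, hi)
      m[, 2] <- m[, 2] + sep
      m <- rotateAboutAxis(m, caB0, caB0 - caA0, tw)
      .setXYZ(sBx, hi, m)
    }
    frayOf <- function(sep, tw) {
      st <- assemble(perturb(sB, sep, tw))
      computeFray(st, list(chain = "A", resno = mid),
                  list(chain = "B", resno = mid))
    }
    twistFor <- function(sep) {
      uniroot(function(tw) {
        fr <- frayOf(sep, tw)
        fr[["pA"]] - fr[["pO"]]
      }, c(-45, 45), tol = 1e-8)$root
    }
    fAt <- function(sep) frayOf(sep, twistFor(sep))[["fray"]]
    root <- uniroot(function(sep) fAt(sep) - frayPerturb,
                    c(0.02, 5), tol = 1e-7, extendInt = "upX")
    sB <- perturb(sB, root$root, twistFor(root$root))
  }
  assemble(sB)
}

#' Generate two motif ensembles related by a known backrub
#'
#' Population A is `n` noisy copies of the base window; population B is
#' `n` noisy copies of the base after a backrub of `theta13` with
#' epsilon-scaled carbonyl-restoring counter-rotations.  Noise is i.i.d.
#' isotropic Gaussian per coordinate; B-factors are drawn uniformly from
#' `bRange`.  The manifest records the seed and ground truth for
#' parameter-recovery tests.
#'
#' @param base window [Structure-class]; default is the ideal Ser N-cap
#'   template window i-1..i+3.
#' @param chain,resno backrub position in `base`.
#' @param theta13 true primary rotation (degrees).
#' @param epsilon counter-rotation scale.
#' @param sigma coordinate noise standard deviation (angstrom).
#' @param n members per population.
#' @param bRange B-factor range (angstrom squared).
#' @param seed integer seed (recorded in the manifest).
#' @return list: `A`, `B` (lists of [Structure-class]), `manifest`.
#' @export
generateBackrubPairEnsembles <- function(base = NULL, chain = "A",
                                         resno = 2L, theta13 = 11,
                                         epsilon = 0.7, sigma = 0.1,
                                         n = 400L, bRange = c(5, 15),
                                         seed = 1L) {
  if (is.null(base)) {
    tmpl <- buildIdealNcapTemplate("SER")
    base <- .extractWindow(tmpl, "A", 2L, -1L:3L)
  }
  stopifnot(n >= 1L, sigma >= 0)
  set.seed(seed)
  cr <- restoringCounterRotations(base, chain, resno, theta13, epsilon)
  moved <- applyBackrub(base, chain, resno,
                        BackrubMove(theta13, cr[1], cr[2], epsilon))
  noisy <- function(s) {
    a <- s@atoms
    m <- nrow(a)
    a$x <- a$x + rnorm(m, 0, sigma)
    a$y <- a$y + rnorm(m, 0, sigma)
    a$z <- a$z + rnorm(m, 0, sigma)
    a$b <- runif(m, bRange[1], bRange[2])
    Structure(a, header = s@header)
  }
  list(A = lapply(seq_len(n), function(i) noisy(base)),
       B = lapply(seq_len(n), function(i) noisy(moved)),
       manifest = list(seed = seed, theta13 = theta13,
                       theta12 = unname(cr[1]), theta23 = unname(cr[2]),
                       epsilon = epsilon, sigma = sigma, n = n,
                       bRange = bRange, chain = chain, resno = resno))
}

#' Superpose-prune-average-fit recovery pipeline
#'
#' Runs the full ensemble analysis on two motif populations: superpose
#' every member of each population onto the common reference frame, prune
#' at the RMSD limit, average, and fit the backrub between the two
#' averages at `resno`.
#'
#' @param membersA,membersB lists of window [Structure-class]s.
#' @param reference common reference (e.g. the ideal template window).
#' @param frame frame atoms (see [frameAtoms()]).
#' @param resno motif residue for the fit.
#' @param limit RMSD pruning limit (angstrom).
#' @return list: `fit` ([BackrubFit-class]), `avgA`, `avgB`
#'   ([AverageMotif-class]), `keptA`, `keptB`.
#' @export
ensembleBackrubPipeline <- function(membersA, membersB, reference, frame,
                                    resno, limit = 1.0) {
  ensA <- pruneByRmsd(superposeOnFrame(membersA, reference, frame), limit)
  ensB <- pruneByRmsd(superposeOnFrame(membersB, reference, frame), limit)
  avgA <- averageMotif(ensA)
  avgB <- averageMotif(ensB)
  fit <- fitBackrub(avgA@structure, avgB@structure,
                    avgA@structure@atoms$chain[1L], resno)
  list(fit = fit, avgA = avgA, avgB = avgB,
       keptA = length(ensA@members), keptB = length(ensB@members))
}

#' Construct minimal motif fixtures with known expected hits
#'
#' Each fixture is built so the corresponding scanner finds exactly the
#' annotated hit set: `ncap_ST`/`ncap_ND`/`ncap_other` are ideal N-cap
#' templates (category from the cap type), `midhelix` is a 15-residue
#' ideal helix with one qualifying central residue (11 residues gives the
#' negative control), and `beta_gly`/`beta_other` are ideal antiparallel
#' sheets with a plus-chi1 Phe across from Gly or Ala.
#'
#' @param kind one of `"ncap_ST"`, `"ncap_ND"`, `"ncap_other"`,
#'   `"midhelix"`, `"beta_gly"`, `"beta_other"`.
#' @param helixLength helix length for `"midhelix"`.
#' @return list: `structure` ([Structure-class]) and `expected` (list of
#'   the expected category/cluster and hit position).
#' @export
makeMotifFixtures <- function(kind = c("ncap_ST", "ncap_ND", "ncap_other",
                                       "midhelix", "beta_gly", "beta_other"),
                              helixLength = 15L) {
  kind <- match.arg(kind)
  switch(kind,
    ncap_ST = list(structure = buildIdealNcapTemplate("SER"),
                   expected = list(chain = "A", resno = 2L, category = "ST",
                                   cluster = "primary", nHits = 1L)),
    ncap_ND = list(structure = buildIdealNcapTemplate("ASN"),
                   expected = list(chain = "A", resno = 2L, category = "ND",
                                   cluster = "primary", nHits = 1L)),
    ncap_other = list(structure = buildIdealNcapTemplate("ALA"),
                      expected = list(chain = "A", resno = 2L,
                                      category = "other",
                                      cluster = "primary", nHits = 1L)),
    midhelix = {
      s <- generateIdealHelix(helixLength)
      list(structure = s,
           expected = list(chain = "A",
                           nHits = if (helixLength >= 15L) NA_integer_ else 0L))
    },
    beta_gly = list(
      structure = generateIdealSheet(aromaticAA = "PHE", oppositeAA = "GLY"),
      expected = list(chain = "A", resno = 4L, category = "gly", nHits = 1L)),
    beta_other = list(
      structure = generateIdealSheet(aromaticAA = "PHE", oppositeAA = "ALA"),
      expected = list(chain = "A", resno = 4L, category = "other", nHits = 1L))
  )
}
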