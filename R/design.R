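## Exhaustive backrub-aware design search: template construction, the
## tau feasibility filter, and GMEC enumeration over the discrete space
## backrub grid x rotamers x single-peptide rotation.
##
## Enumeration (no pruning) makes the returned minimum the provable GMEC
## of the input model: every point of the space is scored or tau-rejected.

#' Build the idealized helix N-cap design template
#'
#' A polyalanine chain: the N-cap and its preceding residue in
#' polyproline-II conformation (phi, psi = -80, 170), followed by
#' `nHelix` ideal-helix residues (phi, psi = -60, -40); all tau at the
#' ideal 111.  The cap (residue 2) is mutated to `capAA` with an ideal
#' plus-chi1 sidechain; hydrogens are added.
#'
#' @param capAA `"SER"` or `"ASN"` (any type in [buildableResidues()]
#'   works).
#' @param nHelix helical residues after the cap (>= 8 recommended so the
#'   first turn is fully H-bonded).
#' @param capChi cap chi angles; default is the plus rotamer (chi1 62,
#'   and chi2 30 where defined).
#' @return a [Structure-class]; the cap is residue 2 of chain A.
#' @export
buildIdealNcapTemplate <- function(capAA = c("SER", "ASN"), nHelix = 8L,
                                   capChi = NULL) {
  capAA <- match.arg(capAA, choices = buildableResidues())
  n <- 2L + nHelix
  aa <- rep("ALA", n); aa[2L] <- capAA
  phi <- c(rep(-80, 2L), rep(-60, nHelix))
  psi <- c(rep(170, 2L), rep(-40, nHelix))
  if (is.null(capChi)) {
    nch <- .N_CHI[[capAA]]
    capChi <- if (nch >= 2) c(62, 30) else if (nch == 1) 62 else numeric(0)
  }
  chi <- vector("list", n); chi[[2L]] <- capChi
  buildChain(aa, phi, psi, chi = chi, chain = "A", startResno = 1L)
}

#' Prepare a beta-sheet design template by mutating the opposite residue
#'
#' Replaces the opposite residue's sidechain while leaving the backbone
#' untouched: `"GLY"` removes the sidechain and converts HA to HA2/HA3;
#' `"ALA"` rebuilds an ideal C-beta with methyl hydrogens; `"keep"`
#' returns the structure unchanged.
#'
#' @param s a [Structure-class].
#' @param chain,resno the opposite residue.
#' @param mutateTo `"GLY"`, `"ALA"`, or `"keep"`.
#' @return the mutated [Structure-class].
#' @export
prepareBetaTemplate <- function(s, chain, resno,
                                mutateTo = c("keep", "GLY", "ALA")) {
  mutateTo <- match.arg(mutateTo)
  if (mutateTo == "keep") return(s)
  rows <- .atomRows(s, chain, resno)
  aa0 <- s@atoms$resid[rows[1L]]
  if (identical(aa0, "PRO")) stop("mutating a Pro backbone is unsupported")
  N <- .atomXYZ(s, chain, resno, "N")
  CA <- .atomXYZ(s, chain, resno, "CA")
  C <- .atomXYZ(s, chain, resno, "C")
  keepNames <- c("N", "H", "C", "O", "CA")
  a <- s@atoms
  drop <- rows[!(a$elety[rows] %in% keepNames)]
  if (length(drop)) a <- a[-drop, , drop = FALSE]
  a$resid[a$chain == chain & a$resno == resno] <- mutateTo
  s2 <- Structure(a, header = s@header)
  template <- a[.atomRows(s2, chain, resno)[1L], , drop = FALSE]
  addRow <- function(acc, name, pos) {
    r <- template
    r$elety <- name; r$x <- pos[1]; r$y <- pos[2]; r$z <- pos[3]
    r$elem <- .guessElement(name)
    rbind(acc, r)
  }
  extra <- NULL
  if (mutateTo == "GLY") {
    dirs <- .tetrahedralPair(CA, N, C)
    extra <- addRow(extra, "HA2", CA + .BB$b_CAHA * dirs[[1]])
    extra <- addRow(extra, "HA3", CA + .BB$b_CAHA * dirs[[2]])
  } else {
    cb <- idealCbeta(N, CA, C)
    extra <- addRow(extra, "CB", cb)
    u <- .unit(.unit(N - CA) + .unit(C - CA) + .unit(cb - CA))
    extra <- addRow(extra, "HA", CA - .BB$b_CAHA * u)
    have <- list(N = N, CA = CA, C = C, CB = cb)
    for (nm in c("HB1", "HB2", "HB3")) {
      d <- .SIDECHAINS$ALA[.SIDECHAINS$ALA$name == nm, ]
      extra <- addRow(extra, nm, placeAtom(have[[d$a]], have[[d$b]],
                                           have[[d$c]], d$bond, d$angle,
                                           d$offset))
    }
  }
  Structure(rbind(a[seq_len(nrow(a)), ], extra), header = s@header)
}

#' tau feasibility filter
#'
#' A conformation is feasible when `|tau - 111| <= limit` at every listed
#' residue; tau is the only bond angle the move set allows to change, and
#' the filter prevents large strain accumulating there.
#'
#' @param s a [Structure-class].
#' @param chain chain identifier.
#' @param resnos residues to check.
#' @param limit allowed deviation (degrees), default 8.
#' @return logical scalar.
#' @export
tauFilter <- function(s, chain, resnos, limit = 8) {
  all(vapply(resnos, function(r) {
    t <- tauAngle(s, chain, r)
    !is.na(t) && abs(t - 111) <= limit
  }, logical(1)))
}

## sidechain block (CB + beyond, with H) for `aa` at chi, anchored on a
## backbone snapshot list(N, CA, C, O); returns matrix with rownames
.rotamerBlock <- function(anchor, aa, chi) {
  def <- .SIDECHAINS[[aa]]
  if (is.null(def)) return(NULL)
  have <- anchor
  out <- matrix(NA_real_, nrow(def), 3L,
                dimnames = list(def$name, NULL))
  for (k in seq_len(nrow(def))) {
    d <- def[k, ]
    tors <- if (d$h && !is.na(d$sibling)) {
      torsionAngle(have[[d$a]], have[[d$b]], have[[d$c]], have[[d$sibling]]) + d$offset
    } else if (d$chi > 0) chi[d$chi] + d$offset else d$offset
    pos <- placeAtom(have[[d$a]], have[[d$b]], have[[d$c]], d$bond, d$angle, tors)
    have[[d$name]] <- pos
    out[k, ] <- pos
  }
  out
}

## carbonyl-restoring counter-rotations computed directly on coordinates
.restoreAngles <- function(oPrev0, oSelf0, oPrev1, oSelf1,
                           caPrev, ca, caNext, epsilon) {
  if (epsilon == 0) return(c(0, 0))
  f12 <- function(th) .vnorm(rotateAboutAxis(oPrev1, caPrev, ca - caPrev, th) - oPrev0)
  f23 <- function(th) .vnorm(rotateAboutAxis(oSelf1, ca, caNext - ca, th) - oSelf0)
  c(epsilon * optimize(f12, c(-60, 60), tol = 1e-4)$minimum,
    epsilon * optimize(f23, c(-60, 60), tol = 1e-4)$minimum)
}

## precompute, for one backrub position, the moved coordinates of its
## window rows for every grid angle plus tau values
.backrubStage <- function(s, a, chain, resno, grid, epsilon) {
  rPrev <- .resAtOffset(s, chain, resno, -1L)
  rNext <- .resAtOffset(s, chain, resno, 1L)
  rws <- function(rn, nm = NULL) .atomRows(s, chain, rn, nm)
  dipRows <- c(rws(rPrev, c("C", "O")), rws(resno), rws(rNext, c("N", "H")))
  names12 <- c(rws(rPrev, c("C", "O")), rws(resno, c("N", "H")))
  names23 <- c(rws(resno, c("C", "O")), rws(rNext, c("N", "H")))
  i12 <- match(names12, dipRows); i23 <- match(names23, dipRows)
  caPrev <- .atomXYZ(s, chain, rPrev, "CA")
  ca <- .atomXYZ(s, chain, resno, "CA")
  caNext <- .atomXYZ(s, chain, rNext, "CA")
  X0 <- as.matrix(a[, c("x", "y", "z")])
  dip0 <- X0[dipRows, , drop = FALSE]
  oPrevIdx <- match(rws(rPrev, "O"), dipRows)
  oSelfIdx <- match(rws(resno, "O"), dipRows)
  nPrevRow <- rws(rPrev, "N"); caPrevRow <- rws(rPrev, "CA")
  nNextIdx <- match(rws(rNext, "N"), dipRows)
  caNextRow <- rws(rNext, "CA"); cNextRow <- rws(rNext, "C")
  nIdx <- match(rws(resno, "N"), dipRows)
  caIdx <- match(rws(resno, "CA"), dipRows)
  cIdx <- match(rws(resno, "C"), dipRows)
  oIdx <- oSelfIdx
  cPrevIdx <- match(rws(rPrev, "C"), dipRows)

  lapply(grid, function(th) {
    d <- rotateAboutAxis(dip0, caPrev, caNext - caPrev, th)
    anchor <- list(N = d[nIdx, ], CA = d[caIdx, ], C = d[cIdx, ],
                   O = d[oIdx, ])
    caMid <- d[caIdx, ]     # the central Calpha after the primary rotation
    cr <- if (th == 0) c(0, 0)
    else .restoreAngles(dip0[oPrevIdx, ], dip0[oSelfIdx, ],
                        d[oPrevIdx, ], d[oSelfIdx, ],
                        caPrev, caMid, caNext, epsilon)
    if (cr[1] != 0)
      d[i12, ] <- rotateAboutAxis(d[i12, , drop = FALSE], caPrev,
                                  caMid - caPrev, cr[1])
    if (cr[2] != 0)
      d[i23, ] <- rotateAboutAxis(d[i23, , drop = FALSE], caMid,
                                  caNext - caMid, cr[2])
    tau <- c(vecAngle(X0[nPrevRow, ], X0[caPrevRow, ], d[cPrevIdx, ]),
             vecAngle(d[nIdx, ], d[caIdx, ], d[cIdx, ]),
             vecAngle(d[nNextIdx, ], X0[caNextRow, ], X0[cNextRow, ]))
    list(theta13 = th, theta12 = cr[1], theta23 = cr[2],
         coords = d, tau = tau, anchor = anchor)
  })
}

#' Exhaustive GMEC search over backrub, rotamer, and peptide grids
#'
#' Enumerates every point of the discrete conformation space -- the
#' primary backrub grid at the design position (with epsilon-scaled
#' carbonyl-restoring counter-rotations), an optional second backrub
#' position, an optional single-peptide rotation grid, and the rotamers
#' of `designAA` -- scores each feasible point with
#' electrostatics + van der Waals + EEF1 solvation over all pairs
#' involving moved atoms, applies the tau filter, and returns the
#' minimum.  Because the space is enumerated exhaustively, the result is
#' the global minimum energy conformation of the input model by
#' construction.
#'
#' @param s template [Structure-class] (hydrogens present).
#' @param chain chain identifier.
#' @param resno design position (receives backrub + rotamer).
#' @param designAA residue type to build at the design position.
#' @param model an [energyModel()].
#' @param backrubGrid primary rotation grid (degrees).
#' @param epsilon counter-rotation scale factor.
#' @param peptideResno N-side residue of an additional single-peptide
#'   rotation (`NULL` for none; for an N-cap at `i` the `i+3` amide is
#'   steered by rotating the peptide at `i+2`).
#' @param peptideGrid peptide rotation grid (degrees).
#' @param secondaryResno optional second backrub position (same grid and
#'   epsilon; its sidechain rides the move).
#' @param secondaryChain chain of the second backrub position (defaults
#'   to `chain`; the opposite strand in the beta-sheet case).
#' @param rotamers data.frame from [rotamersFor()]; default the bundled
#'   library's entries for `designAA`.
#' @param tauLimit tau filter limit (degrees).
#' @return a [DesignResult-class].
#' @export
enumerateGmec <- function(s, chain, resno, designAA,
                          model = energyModel(),
                          backrubGrid = seq(-15, 15, by = 0.5),
                          epsilon = 0.7,
                          peptideResno = NULL,
                          peptideGrid = seq(-5, 15, by = 1),
                          secondaryResno = NULL,
                          secondaryChain = chain,
                          rotamers = NULL,
                          tauLimit = 8) {
  designAA <- toupper(designAA)
  if (length(backrubGrid) == 0L) stop("empty backrub grid")
  if (is.null(rotamers)) rotamers <- rotamersFor(designAA)

  ## strip the design sidechain, relabel, and attach the first rotamer so
  ## the atom table (and bonded topology) is complete
  bbNames <- c("N", "H", "CA", "HA", "HA2", "HA3", "C", "O")
  a <- s@atoms[!s@atoms$het & s@atoms$primary, , drop = FALSE]
  rows <- which(a$chain == chain & a$resno == resno)
  if (length(rows) == 0L) stop("design residue not found")
  a <- a[-rows[!(a$elety[rows] %in% bbNames)], , drop = FALSE]
  a$resid[a$chain == chain & a$resno == resno] <- designAA
  base <- Structure(a, header = s@header)
  chi1 <- as.numeric(rotamers[1L, c("chi1", "chi2")])
  anchor0 <- list(N = .atomXYZ(base, chain, resno, "N"),
                  CA = .atomXYZ(base, chain, resno, "CA"),
                  C = .atomXYZ(base, chain, resno, "C"),
                  O = .atomXYZ(base, chain, resno, "O"))
  block0 <- .rotamerBlock(anchor0, designAA, chi1)
  scRows <- integer(0)
  if (!is.null(block0)) {
    tmplRow <- base@atoms[.atomRows(base, chain, resno)[1L], , drop = FALSE]
    scA <- do.call(rbind, lapply(rownames(block0), function(nm) {
      r <- tmplRow
      r$elety <- nm
      r$x <- block0[nm, 1]; r$y <- block0[nm, 2]; r$z <- block0[nm, 3]
      r$elem <- .guessElement(nm)
      r
    }))
    a <- rbind(base@atoms, scA)
    base <- Structure(a, header = s@header)
    scRows <- seq(nrow(a) - nrow(block0) + 1L, nrow(a))
  }
  a <- base@atoms
  X0 <- as.matrix(a[, c("x", "y", "z")])
  pars <- .atomParams(base, model)

  ## stage precomputations
  st1 <- .backrubStage(base, a, chain, resno, backrubGrid, epsilon)
  rPrev <- .resAtOffset(base, chain, resno, -1L)
  rNext <- .resAtOffset(base, chain, resno, 1L)
  dipRows1 <- c(.atomRows(base, chain, rPrev, c("C", "O")),
                .atomRows(base, chain, resno),
                .atomRows(base, chain, rNext, c("N", "H")))
  ## the sidechain block rides the primary rotation rigidly
  caPrev <- .atomXYZ(base, chain, rPrev, "CA")
  caNext <- .atomXYZ(base, chain, rNext, "CA")
  scBlocks <- NULL
  if (length(scRows)) {
    scBlocks <- lapply(seq_len(nrow(rotamers)), function(ir) {
      blk <- .rotamerBlock(anchor0, designAA,
                           as.numeric(rotamers[ir, c("chi1", "chi2")]))
      lapply(seq_along(backrubGrid), function(i1)
        rotateAboutAxis(blk, caPrev, caNext - caPrev, backrubGrid[i1]))
    })
    ## remove sidechain rows from the dipeptide set (they are patched
    ## separately per rotamer)
    dipRows1 <- setdiff(dipRows1, scRows)
  }
  dipIdx1 <- match(dipRows1, .dipRowsOf(base, chain, resno))

  st2 <- NULL; dipRows2 <- integer(0)
  if (!is.null(secondaryResno)) {
    st2 <- .backrubStage(base, a, secondaryChain, secondaryResno,
                         backrubGrid, epsilon)
    r2p <- .resAtOffset(base, secondaryChain, secondaryResno, -1L)
    r2n <- .resAtOffset(base, secondaryChain, secondaryResno, 1L)
    dipRows2 <- c(.atomRows(base, secondaryChain, r2p, c("C", "O")),
                  .atomRows(base, secondaryChain, secondaryResno),
                  .atomRows(base, secondaryChain, r2n, c("N", "H")))
  }

  pepRows <- integer(0); pepPre <- NULL
  if (!is.null(peptideResno)) {
    pepNext <- .resAtOffset(base, chain, peptideResno, 1L)
    pepRows <- c(.atomRows(base, chain, peptideResno, c("C", "O")),
                 .atomRows(base, chain, pepNext, c("N", "H")))
    pCA1 <- .atomXYZ(base, chain, peptideResno, "CA")
    pCA2 <- .atomXYZ(base, chain, pepNext, "CA")
    pN <- .atomRows(base, chain, peptideResno, "N")
    pCAr <- .atomRows(base, chain, peptideResno, "CA")
    pCr <- .atomRows(base, chain, peptideResno, "C")
    nN2 <- .atomRows(base, chain, pepNext, "N")
    ca2r <- .atomRows(base, chain, pepNext, "CA")
    c2r <- .atomRows(base, chain, pepNext, "C")
    cIdxIn <- match(pCr, pepRows); nIdxIn <- match(nN2, pepRows)
    pepPre <- lapply(peptideGrid, function(ang) {
      m <- rotateAboutAxis(X0[pepRows, , drop = FALSE], pCA1, pCA2 - pCA1, ang)
      tau <- c(vecAngle(X0[pN, ], X0[pCAr, ], m[cIdxIn, ]),
               vecAngle(m[nIdxIn, ], X0[ca2r, ], X0[c2r, ]))
      list(angle = ang, coords = m, tau = tau)
    })
  } else peptideGrid <- 0

  ## pair list over all pairs touching a moved atom
  flex <- sort(unique(c(dipRows1, scRows, dipRows2, pepRows)))
  isFlex <- rep(FALSE, nrow(a)); isFlex[flex] <- TRUE
  sep <- .pairSeparation(.bondGraph(X0, a$elem))
  pm <- which(upper.tri(sep) & sep > 0L &
                (matrix(isFlex, nrow(a), nrow(a)) |
                   matrix(isFlex, nrow(a), nrow(a), byrow = TRUE)),
              arr.ind = TRUE)
  ii <- pm[, 1]; jj <- pm[, 2]; scale14 <- sep[pm] == 14L
  refSolv <- model$solvScale * sum(pars$dGref[isFlex & pars$heavy], na.rm = TRUE)

  n1 <- length(st1); n2 <- if (is.null(st2)) 1L else length(st2)
  np <- length(peptideGrid); nr <- nrow(rotamers)
  total <- n1 * n2 * np * nr
  res <- data.frame(theta13 = numeric(total), theta12 = numeric(total),
                    theta23 = numeric(total), theta13b = numeric(total),
                    peptide = numeric(total), rotamer = character(total),
                    elec = NA_real_, vdw = NA_real_, solv = NA_real_,
                    total = NA_real_, feasible = logical(total),
                    stringsAsFactors = FALSE)
  X <- X0
  row <- 0L
  bestE <- Inf; best <- NULL
  for (i1 in seq_len(n1)) {
    s1 <- st1[[i1]]
    ok1 <- all(abs(s1$tau - 111) <= tauLimit)
    X[dipRows1, ] <- s1$coords[dipIdx1, , drop = FALSE]
    for (i2 in seq_len(n2)) {
      if (!is.null(st2)) {
        s2 <- st2[[i2]]
        ok2 <- ok1 && all(abs(s2$tau - 111) <= tauLimit)
        X[dipRows2, ] <- s2$coords
      } else { s2 <- NULL; ok2 <- ok1 }
      for (ip in seq_len(np)) {
        if (!is.null(pepPre)) {
          pp <- pepPre[[ip]]
          ok3 <- ok2 && all(abs(pp$tau - 111) <= tauLimit)
          X[pepRows, ] <- pp$coords
        } else { pp <- NULL; ok3 <- ok2 }
        for (ir in seq_len(nr)) {
          row <- row + 1L
          res$theta13[row] <- s1$theta13
          res$theta12[row] <- s1$theta12
          res$theta23[row] <- s1$theta23
          res$theta13b[row] <- if (is.null(s2)) 0 else s2$theta13
          res$peptide[row] <- if (is.null(pp)) 0 else pp$angle
          res$rotamer[row] <- rotamers$name[ir]
          res$feasible[row] <- ok3
          if (!ok3) next
          if (length(scRows)) X[scRows, ] <- scBlocks[[ir]][[i1]]
          e <- .pairEnergy(X, pars, ii, jj, scale14, model)
          e["solv"] <- e["solv"] + refSolv
          tot <- sum(e)
          res$elec[row] <- e[["elec"]]; res$vdw[row] <- e[["vdw"]]
          res$solv[row] <- e[["solv"]]; res$total[row] <- tot
          if (tot < bestE) {
            bestE <- tot
            best <- list(X = X, i1 = i1, i2 = i2, ip = ip, ir = ir,
                         e = e, tau = s1$tau)
            best$X[] <- X            # force a copy
          }
        }
      }
    }
  }
  counts <- c(enumerated = total, feasible = sum(res$feasible),
              tauRejected = sum(!res$feasible))
  if (is.null(best)) {
    return(new("DesignResult", gmec = Structure(data.frame()),
               gmecInfo = list(), ranking = res, counts = counts))
  }
  aG <- a
  aG[, c("x", "y", "z")] <- best$X
  s1 <- st1[[best$i1]]
  info <- list(theta13 = s1$theta13, theta12 = s1$theta12,
               theta23 = s1$theta23,
               theta13b = if (is.null(st2)) 0 else st2[[best$i2]]$theta13,
               peptide = if (is.null(pepPre)) 0 else pepPre[[best$ip]]$angle,
               rotamer = rotamers$name[best$ir],
               chi = as.numeric(rotamers[best$ir, c("chi1", "chi2")]),
               elec = best$e[["elec"]], vdw = best$e[["vdw"]],
               solv = best$e[["solv"]], total = bestE, tau = best$tau)
  new("DesignResult", gmec = Structure(aG, header = s@header),
      gmecInfo = info, ranking = res, counts = counts)
}

## rows of the dipeptide window (helper shared with enumerateGmec)
.dipRowsOf <- function(s, chain, resno) {
  rPrev <- .resAtOffset(s, chain, resno, -1L)
  rNext <- .resAtOffset(s, chain, resno, 1L)
  c(.atomRows(s, chain, rPrev, c("C", "O")),
    .atomRows(s, chain, resno),
    .atomRows(s, chain, rNext, c("N", "H")))
}

#' Compare Ser and Asn ideal N-cap design models
#'
#' Reproduces the standard comparison between two lowest-energy N-cap
#' models: superposition on the four flanking Calphas (i-1, i+1..i+3),
#' per-atom displacements of the cap Calpha and Cbeta, the fitted backrub
#' between the two models, the signed tau change at i-1 and i+1 (A to B
#' direction), and each model's cap sidechain O to i+3 amide H distance.
#'
#' @param resA,resB [DesignResult-class] objects from [enumerateGmec()]
#'   run on the same template (e.g. cap = SER and cap = ASN).
#' @param chain chain identifier.
#' @param capResno cap residue number.
#' @return named list: `dCA`, `dCB` (angstrom), `backrub`
#'   ([BackrubFit-class]), `deltaTauIm1`, `deltaTauIp1` (degrees),
#'   `hbondA`, `hbondB` (angstrom).
#' @export
ncapDesignReport <- function(resA, resB, chain = "A", capResno = 2L) {
  sA <- resA@gmec; sB <- resB@gmec
  frame <- frameAtoms("ncap4", capResno)
  rep <- displacementReport(sA, sB, frame, capResno)
  d <- rep$displacements
  dCA <- d$delta[d$resno == capResno & d$elety == "CA"]
  dCB <- d$delta[d$resno == capResno & d$elety == "CB"]
  rm1 <- .resAtOffset(sA, chain, capResno, -1L)
  rp1 <- .resAtOffset(sA, chain, capResno, 1L)
  hbLen <- function(s, capAA) {
    oName <- switch(capAA, SER = "OG", THR = "OG1", ASN = "OD1",
                    ASP = "OD1", NA_character_)
    r3 <- .resAtOffset(s, chain, capResno, 3L)
    o <- .atomXYZ(s, chain, capResno, oName)
    h <- .atomXYZ(s, chain, r3, "H")
    if (is.null(o) || is.null(h)) NA_real_ else .vnorm(o - h)
  }
  aaA <- sA@atoms$resid[.atomRows(sA, chain, capResno)[1L]]
  aaB <- sB@atoms$resid[.atomRows(sB, chain, capResno)[1L]]
  list(dCA = dCA, dCB = dCB, backrub = rep$fit,
       deltaTauIm1 = tauAngle(sB, chain, rm1) - tauAngle(sA, chain, rm1),
       deltaTauIp1 = tauAngle(sB, chain, rp1) - tauAngle(sA, chain, rp1),
       hbondA = hbLen(sA, aaA), hbondB = hbLen(sB, aaB))
}
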