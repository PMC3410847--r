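## The backrub engine: the dipeptide rotation about the Calpha(i-1) to
## Calpha(i+1) axis, epsilon-scaled single-peptide counter-rotations,
## standalone peptide rotations, fitting, and tau-strain accounting.

## window atom row sets for the move at (chain, resno)
.backrubWindow <- function(s, chain, resno) {
  rPrev <- .resAtOffset(s, chain, resno, -1L)
  rNext <- .resAtOffset(s, chain, resno, 1L)
  if (is.na(rPrev) || is.na(rNext))
    stop("backrub window incomplete at ", chain, ":", resno)
  for (rn in c(rPrev, resno, rNext)) {
    have <- s@atoms$elety[.atomRows(s, chain, rn)]
    if (!all(c("N", "CA", "C") %in% have))
      stop("incomplete backbone in backrub window at ", chain, ":", rn)
  }
  caPrev <- .atomXYZ(s, chain, rPrev, "CA")
  caNext <- .atomXYZ(s, chain, rNext, "CA")
  ca <- .atomXYZ(s, chain, resno, "CA")
  if (.vnorm(caNext - caPrev) < 1e-6)
    stop("zero-length backrub axis")
  list(
    rPrev = rPrev, rNext = rNext,
    caPrev = caPrev, ca = ca, caNext = caNext,
    ## dipeptide: C,O of i-1; everything of i; N,H of i+1
    dipeptide = c(.atomRows(s, chain, rPrev, c("C", "O")),
                  .atomRows(s, chain, resno),
                  .atomRows(s, chain, rNext, c("N", "H"))),
    pep12 = c(.atomRows(s, chain, rPrev, c("C", "O")),
              .atomRows(s, chain, resno, c("N", "H"))),
    pep23 = c(.atomRows(s, chain, resno, c("C", "O")),
              .atomRows(s, chain, rNext, c("N", "H")))
  )
}

#' Apply a backrub move
#'
#' Rotates the dipeptide around residue `resno` (C,O of `i-1`; all atoms
#' of `i` including the sidechain, which rides the move; N,H of `i+1`) by
#' `theta13` about the Calpha(i-1)-Calpha(i+1) axis, then counter-rotates
#' the two individual peptides by `theta12` and `theta23` about their own
#' Calpha-Calpha axes.  Positive angles follow the right-hand rule about
#' the N-to-C axis direction.  The flanking Calphas and everything outside
#' the window are unmoved; intra-group distances are preserved exactly.
#'
#' @param s a [Structure-class].
#' @param chain chain identifier.
#' @param resno central residue of the move.
#' @param move a [BackrubMove-class].
#' @return the moved [Structure-class].
#' @export
applyBackrub <- function(s, chain, resno, move) {
  w <- .backrubWindow(s, chain, resno)
  ca <- w$ca
  if (move@theta13 != 0) {
    s <- .setXYZ(s, w$dipeptide,
                 rotateAboutAxis(.xyz(s, w$dipeptide), w$caPrev,
                                 w$caNext - w$caPrev, move@theta13))
    ## the central Calpha rides the primary rotation; the single-peptide
    ## axes are taken in the rotated conformation
    ca <- rotateAboutAxis(ca, w$caPrev, w$caNext - w$caPrev, move@theta13)
  }
  if (move@theta12 != 0)
    s <- .setXYZ(s, w$pep12,
                 rotateAboutAxis(.xyz(s, w$pep12), w$caPrev,
                                 ca - w$caPrev, move@theta12))
  if (move@theta23 != 0)
    s <- .setXYZ(s, w$pep23,
                 rotateAboutAxis(.xyz(s, w$pep23), ca,
                                 w$caNext - ca, move@theta23))
  s
}

#' Carbonyl-restoring counter-rotations for a primary backrub
#'
#' After a primary rotation `theta13`, each individual peptide is rotated
#' about its own Calpha-Calpha axis by the angle that minimises the
#' displacement of that peptide's carbonyl O from its pre-backrub position
#' (1-D minimisation to 1e-4 degree); the returned angles are scaled by
#' `epsilon`.  This restores the H-bonding geometry of the two peptides'
#' amides and carbonyls.
#'
#' @inheritParams applyBackrub
#' @param theta13 primary rotation (degrees).
#' @param epsilon scale factor in `[0, 1]`.
#' @param objective `"carbonyl"` (default) restores the carbonyl O;
#'   `"tau"` instead minimises strain `|tau - 111|` at the peptide's
#'   outer residue.
#' @return numeric `c(theta12, theta23)` in degrees.
#' @export
restoringCounterRotations <- function(s, chain, resno, theta13, epsilon = 0.7,
                                      objective = c("carbonyl", "tau")) {
  objective <- match.arg(objective)
  if (theta13 == 0 || epsilon == 0) return(c(theta12 = 0, theta23 = 0))
  w <- .backrubWindow(s, chain, resno)
  oPrev0 <- .atomXYZ(s, chain, w$rPrev, "O")
  oSelf0 <- .atomXYZ(s, chain, resno, "O")
  moved <- applyBackrub(s, chain, resno, BackrubMove(theta13, 0, 0))
  caMid <- rotateAboutAxis(w$ca, w$caPrev, w$caNext - w$caPrev, theta13)
  span <- c(-60, 60)

  obj12 <- if (objective == "carbonyl") {
    oPrev <- .atomXYZ(moved, chain, w$rPrev, "O")
    function(th) .vnorm(rotateAboutAxis(oPrev, w$caPrev, caMid - w$caPrev, th) - oPrev0)
  } else {
    function(th) {
      m2 <- applyBackrub(s, chain, resno, BackrubMove(theta13, th, 0))
      abs(tauAngle(m2, chain, w$rPrev) - 111)
    }
  }
  obj23 <- if (objective == "carbonyl") {
    oSelf <- .atomXYZ(moved, chain, resno, "O")
    function(th) .vnorm(rotateAboutAxis(oSelf, caMid, w$caNext - caMid, th) - oSelf0)
  } else {
    function(th) {
      m2 <- applyBackrub(s, chain, resno, BackrubMove(theta13, 0, th))
      abs(tauAngle(m2, chain, w$rNext) - 111)
    }
  }
  t12 <- optimize(obj12, span, tol = 1e-4)$minimum
  t23 <- optimize(obj23, span, tol = 1e-4)$minimum
  c(theta12 = epsilon * t12, theta23 = epsilon * t23)
}

#' Rotate a single peptide about its Calpha-Calpha axis
#'
#' Rotates the peptide group {C,O of `resno`; N,H of the next residue}
#' about the axis from Calpha(`resno`) to Calpha(next); both Calphas (on
#' the axis) are invariant.
#'
#' @inheritParams applyBackrub
#' @param resno N-side residue of the peptide.
#' @param angle rotation in degrees (right-hand rule, N-to-C axis).
#' @return the moved [Structure-class].
#' @export
applyPeptideRotation <- function(s, chain, resno, angle) {
  rNext <- .resAtOffset(s, chain, resno, 1L)
  if (is.na(rNext)) stop("no following residue for peptide at ", chain, ":", resno)
  ca1 <- .atomXYZ(s, chain, resno, "CA")
  ca2 <- .atomXYZ(s, chain, rNext, "CA")
  if (is.null(ca1) || is.null(ca2)) stop("missing Calpha for peptide rotation")
  rows <- c(.atomRows(s, chain, resno, c("C", "O")),
            .atomRows(s, chain, rNext, c("N", "H")))
  if (angle == 0) return(s)
  .setXYZ(s, rows, rotateAboutAxis(.xyz(s, rows), ca1, ca2 - ca1, angle))
}

## fitted atom set (names per window residue), intersected with both confs
.fitAtoms <- function(a, b, chain, resno) {
  w <- .backrubWindow(a, chain, resno)
  spec <- rbind(
    data.frame(resno = w$rPrev, elety = c("C", "O")),
    data.frame(resno = resno, elety = c("CA", "CB", "C", "O", "N", "H")),
    data.frame(resno = w$rNext, elety = c("N", "H")))
  keep <- vapply(seq_len(nrow(spec)), function(k) {
    !is.null(.atomXYZ(a, chain, spec$resno[k], spec$elety[k])) &&
      !is.null(.atomXYZ(b, chain, spec$resno[k], spec$elety[k]))
  }, logical(1))
  spec[keep, , drop = FALSE]
}

.coordsFor <- function(s, chain, spec)
  t(vapply(seq_len(nrow(spec)),
           function(k) .atomXYZ(s, chain, spec$resno[k], spec$elety[k]),
           numeric(3)))

#' Fit a backrub move between two conformations
#'
#' Finds the `(theta13, theta12, theta23)` minimising the RMSD between
#' `applyBackrub(confA, move)` and `confB` over the window atoms
#' {CA(i), CB(i), C,O(i-1), N,H(i), C,O(i), N,H(i+1)} (atoms missing from
#' either conformation, e.g. CB for Gly, are dropped).  Both conformations
#' must already sit in a common frame.  The search runs a 0.5-degree grid
#' on `theta13` over `range` with carbonyl-restoring secondary angles,
#' golden-section refinement to 0.01 degree, then a simplex polish of all
#' three angles.
#'
#' @param confA,confB [Structure-class] conformations in a common frame.
#' @param chain chain identifier.
#' @param resno central residue.
#' @param epsilon epsilon used for the secondary-angle initialisation.
#' @param range search interval for `theta13` (degrees).
#' @return a [BackrubFit-class].
#' @export
fitBackrub <- function(confA, confB, chain, resno, epsilon = 0.7,
                       range = c(-30, 30)) {
  spec <- .fitAtoms(confA, confB, chain, resno)
  target <- .coordsFor(confB, chain, spec)
  rmsdFor <- function(t13, t12, t23) {
    m <- applyBackrub(confA, chain, resno, BackrubMove(t13, t12, t23))
    coordRmsd(.coordsFor(m, chain, spec), target)
  }
  withRestore <- function(t13) {
    cr <- if (t13 == 0) c(0, 0)
          else restoringCounterRotations(confA, chain, resno, t13, epsilon)
    c(cr[1], cr[2], rmsdFor(t13, cr[1], cr[2]))
  }
  grid <- seq(range[1], range[2], by = 0.5)
  vals <- vapply(grid, function(t) withRestore(t)[3], numeric(1))
  best <- grid[which.min(vals)]
  lo <- max(range[1], best - 0.5); hi <- min(range[2], best + 0.5)
  opt <- optimize(function(t) withRestore(t)[3], c(lo, hi), tol = 0.01)
  t13 <- opt$minimum
  init <- withRestore(t13)
  ## simplex polish over all three angles
  pol <- optim(c(t13, init[1], init[2]),
               function(p) rmsdFor(p[1], p[2], p[3]),
               method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 500))
  par <- unname(pol$par)
  new("BackrubFit",
      move = BackrubMove(par[1], par[2], par[3], epsilon),
      residualRmsd = unname(pol$value))
}

#' tau strain across a backrub window
#'
#' Signed tau differences (after minus before) at the three window
#' residues.
#'
#' @param before,after [Structure-class] conformations.
#' @param chain chain identifier.
#' @param resno central residue.
#' @return named numeric: `dtau.im1`, `dtau.i`, `dtau.ip1` (degrees).
#' @export
tauStrain <- function(before, after, chain, resno) {
  rPrev <- .resAtOffset(before, chain, resno, -1L)
  rNext <- .resAtOffset(before, chain, resno, 1L)
  c(dtau.im1 = tauAngle(after, chain, rPrev) - tauAngle(before, chain, rPrev),
    dtau.i = tauAngle(after, chain, resno) - tauAngle(before, chain, resno),
    dtau.ip1 = tauAngle(after, chain, rNext) - tauAngle(before, chain, rNext))
}
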