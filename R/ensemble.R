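## Ensemble superposition, pruning, averaging, and displacement reporting
## for motif windows sharing a common residue numbering.

## coordinate matrix of the frame atoms (data.frame resno, elety) of s
.frameCoords <- function(s, frameAtoms, chain = NULL) {
  if (is.null(chain)) chain <- s@atoms$chain[1L]
  m <- t(vapply(seq_len(nrow(frameAtoms)), function(k) {
    p <- .atomXYZ(s, chain, frameAtoms$resno[k], frameAtoms$elety[k])
    if (is.null(p)) stop("frame atom missing: ", frameAtoms$resno[k], " ",
                         frameAtoms$elety[k])
    p
  }, numeric(3)))
  m
}

## rigid-transform a whole Structure
.transformStructure <- function(s, tr) {
  rows <- seq_len(nrow(s@atoms))
  .setXYZ(s, rows, applyTransform(.xyz(s, rows), tr))
}

#' Frame atom sets used in the motif analyses
#'
#' `"ncap4"`: the four Calphas flanking an N-cap at `resno` (`i-1`,
#' `i+1`, `i+2`, `i+3`; the cap Calpha itself is excluded to avoid biasing
#' its average position).  `"midhelix3"`: `i+1..i+3`.  `"beta5"`: aromatic
#' `i-2`, `i-1`, `i+1`, `i+2` plus the opposite Calpha as an anchor.
#'
#' @param kind one of `"ncap4"`, `"midhelix3"`, `"beta5"`.
#' @param resno motif residue number.
#' @param oppositeResno opposite residue number (beta case).
#' @return data.frame `resno`, `elety` naming the frame atoms.
#' @export
frameAtoms <- function(kind = c("ncap4", "midhelix3", "beta5"),
                       resno, oppositeResno = NULL) {
  kind <- match.arg(kind)
  offs <- switch(kind,
                 ncap4 = resno + c(-1L, 1L, 2L, 3L),
                 midhelix3 = resno + 1:3,
                 beta5 = resno + c(-2L, -1L, 1L, 2L))
  fa <- data.frame(resno = offs, elety = "CA", stringsAsFactors = FALSE)
  if (kind == "beta5") {
    if (is.null(oppositeResno)) stop("beta5 frame needs oppositeResno")
    fa <- rbind(fa, data.frame(resno = oppositeResno, elety = "CA"))
  }
  fa
}

#' Superpose ensemble members onto a reference frame
#'
#' Least-squares rigid superposition (optimal rotation + translation,
#' [kabsch()]) of each member's frame atoms onto the reference's; the RMSD
#' is computed over the frame atoms only.
#'
#' @param members list of [Structure-class] windows sharing residue
#'   numbering with the reference.
#' @param reference a [Structure-class] (a member or an external template).
#' @param frame data.frame `resno`, `elety` (see [frameAtoms()]); at least
#'   3 atoms.
#' @return a [SuperposedEnsemble-class].
#' @export
superposeOnFrame <- function(members, reference, frame) {
  if (nrow(frame) < 3L) stop("need at least 3 frame atoms")
  refC <- .frameCoords(reference, frame)
  rmsd <- numeric(length(members))
  out <- vector("list", length(members))
  for (k in seq_along(members)) {
    mc <- .frameCoords(members[[k]], frame)
    tr <- kabsch(mc, refC)
    out[[k]] <- .transformStructure(members[[k]], tr)
    rmsd[k] <- tr$rmsd
  }
  new("SuperposedEnsemble", members = out, reference = reference,
      frameAtoms = frame, rmsd = rmsd)
}

#' Prune a superposed ensemble by frame RMSD
#'
#' Members with frame-atom RMSD above `limit` (default 1 angstrom) are
#' removed; the pruned fraction is attached as attribute `prunedFraction`.
#'
#' @param ens a [SuperposedEnsemble-class].
#' @param limit RMSD threshold in angstrom.
#' @return the pruned [SuperposedEnsemble-class].
#' @export
pruneByRmsd <- function(ens, limit = 1.0) {
  keep <- ens@rmsd <= limit
  if (!any(keep)) warning("all ensemble members pruned at RMSD <= ", limit)
  out <- new("SuperposedEnsemble", members = ens@members[keep],
             reference = ens@reference, frameAtoms = ens@frameAtoms,
             rmsd = ens@rmsd[keep])
  attr(out, "prunedFraction") <- mean(!keep)
  out
}

#' Select a representative reference from candidates
#'
#' Each candidate is tried as superposition reference for the whole
#' ensemble; the candidate pruning the fewest members at the RMSD limit
#' wins (ties broken by lower mean RMSD, then input order).
#'
#' @param candidates list of candidate [Structure-class] references
#'   (typically 10 arbitrarily chosen members).
#' @param members the full member list.
#' @param frame frame atoms (see [frameAtoms()]).
#' @param limit RMSD pruning threshold (angstrom).
#' @return list: `reference` (the winning candidate), `index`,
#'   `prunedCount`, `meanRmsd`.
#' @export
selectReference <- function(candidates, members, frame, limit = 1.0) {
  if (length(candidates) == 0L) stop("no candidates")
  pruned <- meanR <- numeric(length(candidates))
  for (k in seq_along(candidates)) {
    ens <- superposeOnFrame(members, candidates[[k]], frame)
    pruned[k] <- sum(ens@rmsd > limit)
    meanR[k] <- mean(ens@rmsd)
  }
  ord <- order(pruned, meanR)
  list(reference = candidates[[ord[1L]]], index = ord[1L],
       prunedCount = pruned[ord[1L]], meanRmsd = meanR[ord[1L]])
}

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "H", "HA", "HA2", "HA3", "CB")

#' Average a superposed ensemble and attach a median rotamer
#'
#' Arithmetic mean of each named backbone atom (including hydrogens) and
#' C-beta over the members; a member missing an atom is excluded from that
#' atom's mean (counts reported).  If `rotamerAA` is given, the sidechain
#' beyond C-beta is rebuilt at the member-median chi angles from ideal
#' internal coordinates, keeping the mean C-beta position (the sidechain
#' is anchored on the mean N/CA/CB).
#'
#' @param ens a [SuperposedEnsemble-class] (already pruned).
#' @param rotamerAA 3-letter code of the sidechain to attach at
#'   `rotamerResno`, or `NULL` for backbone + C-beta only.
#' @param rotamerResno residue to receive the median rotamer.
#' @return an [AverageMotif-class].
#' @export
averageMotif <- function(ens, rotamerAA = NULL, rotamerResno = NULL) {
  if (length(ens@members) < 1L) stop("empty ensemble")
  m1 <- ens@members[[1L]]
  ch <- m1@atoms$chain[1L]
  rt <- residueTable(m1)
  ## accumulate means over named atoms
  keys <- list(); sums <- list(); cnt <- integer(0)
  for (mem in ens@members) {
    a <- mem@atoms
    sel <- which(!a$het & a$primary & a$elety %in% .BACKBONE_ATOMS)
    for (i in sel) {
      key <- paste(a$resno[i], a$elety[i], sep = "|")
      j <- match(key, names(sums))
      if (is.na(j)) {
        sums[[key]] <- c(a$x[i], a$y[i], a$z[i])
        cnt[key] <- 1L
        keys[[key]] <- list(resno = a$resno[i], elety = a$elety[i],
                            resid = a$resid[i])
      } else {
        sums[[key]] <- sums[[key]] + c(a$x[i], a$y[i], a$z[i])
        cnt[key] <- cnt[key] + 1L
      }
    }
  }
  rows <- lapply(names(sums), function(key) {
    p <- sums[[key]] / cnt[key]
    k <- keys[[key]]
    data.frame(chain = ch, resno = k$resno, inscode = "", resid = k$resid,
               elety = k$elety, alt = "", x = p[1], y = p[2], z = p[3],
               occ = 1, b = 0, elem = .guessElement(k$elety), het = FALSE,
               primary = TRUE, stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, rows)
  at <- at[order(match(at$resno, rt$resno)), ]
  avg <- Structure(at)
  chis <- numeric(0)
  if (!is.null(rotamerAA)) {
    if (is.null(rotamerResno)) stop("rotamerResno required with rotamerAA")
    nchi <- .N_CHI[[rotamerAA]]
    memberChi <- t(vapply(ens@members, function(mem) {
      dh <- backboneDihedrals(mem, ch, rotamerResno)
      c(dh$chi1, dh$chi2)
    }, numeric(2)))
    med <- apply(memberChi, 2L, median, na.rm = TRUE)
    chis <- med[seq_len(max(nchi, 1L))]
    avg <- .attachRotamer(avg, ch, rotamerResno, rotamerAA, chis)
    names(chis) <- paste0("chi", seq_along(chis))
  }
  new("AverageMotif", structure = avg, nMembers = length(ens@members),
      chi = chis, atomCounts = setNames(cnt, names(sums)))
}

## rebuild a sidechain beyond CB at given chi, anchored on existing N/CA/CB
.attachRotamer <- function(s, chain, resno, aa, chi) {
  def <- .SIDECHAINS[[aa]]
  if (is.null(def)) stop("no sidechain template for ", aa)
  N <- .atomXYZ(s, chain, resno, "N")
  CA <- .atomXYZ(s, chain, resno, "CA")
  C <- .atomXYZ(s, chain, resno, "C")
  CB <- .atomXYZ(s, chain, resno, "CB")
  if (is.null(CB)) CB <- idealCbeta(N, CA, C)
  have <- list(N = N, CA = CA, C = C, CB = CB)
  rows <- list()
  template <- s@atoms[.atomRows(s, chain, resno)[1L], , drop = FALSE]
  for (k in seq_len(nrow(def))) {
    d <- def[k, ]
    if (d$name == "CB") next
    tors <- if (d$h && !is.na(d$sibling)) {
      torsionAngle(have[[d$a]], have[[d$b]], have[[d$c]], have[[d$sibling]]) + d$offset
    } else if (d$chi > 0) chi[d$chi] + d$offset else d$offset
    pos <- placeAtom(have[[d$a]], have[[d$b]], have[[d$c]], d$bond, d$angle, tors)
    have[[d$name]] <- pos
    r <- template
    r$resid <- aa; r$elety <- d$name
    r$x <- pos[1]; r$y <- pos[2]; r$z <- pos[3]
    r$elem <- .guessElement(d$name)
    rows[[length(rows) + 1L]] <- r
  }
  a <- s@atoms
  ## drop any pre-existing atoms of the same names, relabel residue
  resRows <- .atomRows(s, chain, resno)
  drop <- resRows[a$elety[resRows] %in% def$name[def$name != "CB"]]
  if (length(drop)) a <- a[-drop, , drop = FALSE]
  a$resid[a$chain == chain & a$resno == resno] <- aa
  Structure(rbind(a, do.call(rbind, rows)), header = s@header)
}

#' Displacements, fitted backrub, and tau changes between two averages
#'
#' Superposes `avgB` onto `avgA` via the frame atoms, reports the per-atom
#' displacement of every shared named atom, fits the backrub between the
#' averages at `resno`, and takes signed tau differences (B minus A).
#' When ensemble-mean tau values are supplied (`tauA`, `tauB`, named by
#' resno) they are used instead of taus measured on the averaged
#' coordinates, which are less reliable.
#'
#' @param avgA,avgB [AverageMotif-class] (or [Structure-class]) objects.
#' @param frame frame atoms (see [frameAtoms()]).
#' @param resno motif residue for the backrub fit.
#' @param tauA,tauB optional named numeric vectors of ensemble-mean tau.
#' @param fitRange `theta13` search range passed to [fitBackrub()].
#' @return list: `displacements` (data.frame `resno`, `elety`, `delta`),
#'   `fit` ([BackrubFit-class]), `deltaTau` (named, degrees), `aligned`
#'   (the transformed `avgB` structure).
#' @export
displacementReport <- function(avgA, avgB, frame, resno,
                               tauA = NULL, tauB = NULL,
                               fitRange = c(-30, 30)) {
  sA <- if (is(avgA, "AverageMotif")) avgA@structure else avgA
  sB <- if (is(avgB, "AverageMotif")) avgB@structure else avgB
  ch <- sA@atoms$chain[1L]
  tr <- kabsch(.frameCoords(sB, frame), .frameCoords(sA, frame))
  sB2 <- .transformStructure(sB, tr)
  aA <- sA@atoms[!sA@atoms$het & sA@atoms$primary, ]
  keyA <- paste(aA$resno, aA$elety)
  aB <- sB2@atoms[!sB2@atoms$het & sB2@atoms$primary, ]
  keyB <- paste(aB$resno, aB$elety)
  shared <- intersect(keyA, keyB)
  disp <- data.frame(
    resno = aA$resno[match(shared, keyA)],
    elety = aA$elety[match(shared, keyA)],
    delta = vapply(shared, function(k) {
      i <- match(k, keyA); j <- match(k, keyB)
      .vnorm(c(aA$x[i], aA$y[i], aA$z[i]) - c(aB$x[j], aB$y[j], aB$z[j]))
    }, numeric(1)), stringsAsFactors = FALSE)
  rownames(disp) <- NULL
  fit <- fitBackrub(sA, sB2, ch, resno, range = fitRange)
  dtau <- if (!is.null(tauA) && !is.null(tauB)) {
    common <- intersect(names(tauA), names(tauB))
    setNames(tauB[common] - tauA[common], common)
  } else {
    rs <- c(.resAtOffset(sA, ch, resno, -1L), resno, .resAtOffset(sA, ch, resno, 1L))
    setNames(vapply(rs, function(r)
      tauAngle(sB2, ch, r) - tauAngle(sA, ch, r), numeric(1)), rs)
  }
  list(displacements = disp, fit = fit, deltaTau = dtau, aligned = sB2)
}

## Probe-style contact radii (angstrom)
.PROBE_RADII <- c(H = 1.0, C = 1.7, N = 1.55, O = 1.4, S = 1.8)

#' Van der Waals overlap between two atoms
#'
#' `overlap = r_a + r_b - distance`; positive values are clashes, negative
#' values gaps.  Default radii follow the all-atom contact tradition
#' (polar H 1.0, C 1.7, N 1.55, O 1.4, S 1.8 angstrom).
#'
#' @param posA,posB coordinate triples.
#' @param classA,classB atom classes (element letters for the default
#'   table).
#' @param radii named radii table (angstrom).
#' @return overlap in angstrom.
#' @export
vdwOverlap <- function(posA, posB, classA, classB, radii = .PROBE_RADII) {
  if (!(classA %in% names(radii))) stop("unknown atom class: ", classA)
  if (!(classB %in% names(radii))) stop("unknown atom class: ", classB)
  radii[[classA]] + radii[[classB]] - .vnorm(posA - posB)
}
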