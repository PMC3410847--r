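## Pairwise energy evaluation: Coulomb electrostatics with a (distance-
## dependent) dielectric, 12-6 Lennard-Jones, and EEF1 Gaussian-exclusion
## pairwise desolvation.  1-2 and 1-3 pairs are excluded, 1-4 pairs scaled.

## distance-based covalent bond detection (heavy-heavy < 1.85 A,
## H to nearest heavy < 1.3 A); returns adjacency matrix
.bondGraph <- function(xyz, elem) {
  n <- nrow(xyz)
  A <- matrix(FALSE, n, n)
  d2 <- as.matrix(dist(xyz))^2
  heavy <- elem != "H"
  hh <- outer(heavy, heavy, "&") & d2 < 1.85^2
  diag(hh) <- FALSE
  A[hh] <- TRUE
  for (i in which(!heavy)) {
    cand <- which(heavy & d2[i, ] < 1.3^2)
    if (length(cand)) {
      j <- cand[which.min(d2[i, cand])]
      A[i, j] <- A[j, i] <- TRUE
    }
  }
  A
}

## bonded separation class: 0 = excluded (1-2/1-3), 14 = 1-4, 99 = full
.pairSeparation <- function(A) {
  A1 <- A
  A2 <- (A1 %*% A1) > 0
  A3 <- (A2 %*% A1) > 0
  n <- nrow(A)
  sep <- matrix(99L, n, n)
  sep[A3] <- 14L
  sep[A2] <- 0L
  sep[A1] <- 0L
  diag(sep) <- 0L
  sep
}

## internal pairwise engine on prepared vectors
.pairEnergy <- function(xyz, pars, ii, jj, scale, model) {
  dx <- xyz[ii, 1] - xyz[jj, 1]
  dy <- xyz[ii, 2] - xyz[jj, 2]
  dz <- xyz[ii, 3] - xyz[jj, 3]
  r2 <- dx * dx + dy * dy + dz * dz
  keep <- r2 < model$cutoff^2
  if (!any(keep)) return(c(elec = 0, vdw = 0, solv = 0))
  ii <- ii[keep]; jj <- jj[keep]; r2 <- r2[keep]; scale14 <- scale[keep]
  r <- sqrt(r2)
  qq <- pars$q[ii] * pars$q[jj]
  elec <- if (model$dielectric == "distance")
    model$coulomb * qq / (model$factor * r2)
  else model$coulomb * qq / (model$factor * r)
  elec <- elec * ifelse(scale14, model$scale14elec, 1)
  rmin <- (pars$rmin2[ii] + pars$rmin2[jj]) * model$vdwRadiusScale
  eps <- sqrt(pars$eps[ii] * pars$eps[jj])
  s6 <- (rmin^2 / r2)^3
  vdw <- eps * (s6 * s6 - 2 * s6) * ifelse(scale14, model$scale14vdw, 1)
  hv <- pars$heavy[ii] & pars$heavy[jj]
  solv <- 0
  if (any(hv)) {
    i2 <- ii[hv]; j2 <- jj[hv]; rr <- r[hv]; rr2 <- r2[hv]
    xi <- (rr - pars$Reef[i2]) / pars$lambda[i2]
    xj <- (rr - pars$Reef[j2]) / pars$lambda[j2]
    fi <- pars$dGfree[i2] / (2 * pi^1.5 * pars$lambda[i2] * rr2) * exp(-xi^2)
    fj <- pars$dGfree[j2] / (2 * pi^1.5 * pars$lambda[j2] * rr2) * exp(-xj^2)
    solv <- -model$solvScale * sum(fi * pars$volume[j2] + fj * pars$volume[i2])
  }
  c(elec = sum(elec), vdw = sum(vdw), solv = solv)
}

#' Decomposed conformation energy over a flexible set
#'
#' Sums electrostatic, van der Waals, and EEF1 solvation terms over all
#' atom pairs with at least one member in the flexible set (1-2/1-3 pairs
#' excluded, 1-4 scaled, cutoff applied with no switching).  The solvation
#' term includes the conformation-independent EEF1 reference free energy
#' of the flexible atoms, so `total = elec + vdw + solv` exactly.
#'
#' @param s a [Structure-class] with hydrogens present.
#' @param model an [energyModel()].
#' @param flexible data.frame (`chain`, `resno`) of flexible residues, or
#'   an integer vector of atom row indices into the non-het primary atom
#'   table; `NULL` means all atoms.
#' @return named numeric: `elec`, `vdw`, `solv`, `total` (kcal/mol).
#' @export
conformationEnergy <- function(s, model = energyModel(), flexible = NULL) {
  a <- s@atoms[!s@atoms$het & s@atoms$primary, , drop = FALSE]
  sAll <- Structure(a, header = s@header)
  pars <- .atomParams(sAll, model)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(a)
  flexIdx <- if (is.null(flexible)) seq_len(n)
  else if (is.data.frame(flexible)) {
    which(paste(a$chain, a$resno) %in% paste(flexible$chain, flexible$resno))
  } else as.integer(flexible)
  isFlex <- rep(FALSE, n); isFlex[flexIdx] <- TRUE
  sep <- .pairSeparation(.bondGraph(xyz, a$elem))
  pair <- which(upper.tri(sep) & sep > 0L &
                  (outer(isFlex, rep(TRUE, n), "&") |
                     outer(rep(TRUE, n), isFlex, "&")), arr.ind = TRUE)
  if (nrow(pair) == 0L) return(c(elec = 0, vdw = 0, solv = 0, total = 0))
  ii <- pair[, 1]; jj <- pair[, 2]
  scale <- sep[pair] == 14L
  e <- .pairEnergy(xyz, pars, ii, jj, scale, model)
  e["solv"] <- e["solv"] + model$solvScale * sum(pars$dGref[isFlex & pars$heavy], na.rm = TRUE)
  c(e, total = sum(e))
}
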