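## chi-defining atoms (fourth atom of chi1, chi2) per residue type
.CHI1_G <- c(SER = "OG", THR = "OG1", CYS = "SG", VAL = "CG1", ILE = "CG1",
             ALA = NA, GLY = NA)
.CHI2_D <- c(ASN = "OD1", ASP = "OD1", PHE = "CD1", TYR = "CD1", TRP = "CD1",
             HIS = "ND1", LEU = "CD1", ILE = "CD1", MET = "SD")

.chi1Atom <- function(aa) {
  if (aa %in% names(.CHI1_G)) .CHI1_G[[aa]] else "CG"
}
.chi2Atom <- function(aa) {
  if (aa %in% names(.CHI2_D)) .CHI2_D[[aa]] else "CD"
}

#' Backbone dihedrals, tau, and chi angles for one residue
#'
#' phi, psi and omega follow the standard four-atom signed torsion
#' convention; tau is the planar N-CA-C bond angle.  Any angle whose atoms
#' are missing (chain termini, incomplete residues) is reported as `NA`,
#' never as 0.
#'
#' @param s a [Structure-class].
#' @param chain chain identifier.
#' @param resno residue number.
#' @return named list: `phi`, `psi`, `omega` (C(i-1)-N(i) peptide), `tau`,
#'   `chi1`, `chi2` in degrees.
#' @export
backboneDihedrals <- function(s, chain, resno) {
  rPrev <- .resAtOffset(s, chain, resno, -1L)
  rNext <- .resAtOffset(s, chain, resno, 1L)
  N <- .atomXYZ(s, chain, resno, "N")
  CA <- .atomXYZ(s, chain, resno, "CA")
  C <- .atomXYZ(s, chain, resno, "C")
  Cp <- if (!is.na(rPrev)) .atomXYZ(s, chain, rPrev, "C") else NULL
  CAp <- if (!is.na(rPrev)) .atomXYZ(s, chain, rPrev, "CA") else NULL
  Nn <- if (!is.na(rNext)) .atomXYZ(s, chain, rNext, "N") else NULL

  ang <- function(...) {
    pts <- list(...)
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    do.call(torsionAngle, pts)
  }
  phi <- ang(Cp, N, CA, C)
  psi <- ang(N, CA, C, Nn)
  omega <- ang(CAp, Cp, N, CA)
  tau <- if (is.null(N) || is.null(CA) || is.null(C)) NA_real_
         else vecAngle(N, CA, C)

  aa <- s@atoms$resid[.atomRows(s, chain, resno)][1L]
  CB <- .atomXYZ(s, chain, resno, "CB")
  g <- if (!is.na(.chi1Atom(aa))) .atomXYZ(s, chain, resno, .chi1Atom(aa)) else NULL
  d <- .atomXYZ(s, chain, resno, .chi2Atom(aa))
  chi1 <- ang(N, CA, CB, g)
  chi2 <- ang(CA, CB, g, d)
  list(phi = phi, psi = psi, omega = omega, tau = tau,
       chi1 = chi1, chi2 = chi2)
}

#' tau (N-CA-C) bond angle of a residue
#'
#' @inheritParams backboneDihedrals
#' @return angle in degrees, or `NA` if backbone atoms are missing.
#' @export
tauAngle <- function(s, chain, resno) backboneDihedrals(s, chain, resno)$tau

#' Classify a chi1 angle into a coarse rotamer bin
#'
#' `plus` covers (0, 120], `minus` (-120, 0], and `trans` the remaining
#' wrap-around interval (120, 180] + (-180, -120].
#'
#' @param chi1 chi1 angle(s) in degrees.
#' @return character vector in `{"plus", "trans", "minus"}` (`NA` passed
#'   through).
#' @export
classifyChi1 <- function(chi1) {
  out <- rep(NA_character_, length(chi1))
  w <- ((chi1 + 180) %% 360) - 180
  out[!is.na(w) & w > 0 & w <= 120] <- "plus"
  out[!is.na(w) & w <= 0 & w > -120] <- "minus"
  out[!is.na(w) & (w > 120 | w <= -120)] <- "trans"
  out
}

#' C-beta deviation from ideality
#'
#' Distance between the observed C-beta and the ideal C-beta constructed
#' from N, CA, C with ideal internal coordinates ([idealCbeta()]).  The
#' conventional outlier threshold is 0.25 angstrom.
#'
#' @inheritParams backboneDihedrals
#' @return deviation in angstrom; `NA` for Gly or incomplete backbones.
#' @export
cbetaDeviation <- function(s, chain, resno) {
  aa <- s@atoms$resid[.atomRows(s, chain, resno)][1L]
  if (identical(aa, "GLY")) return(NA_real_)
  N <- .atomXYZ(s, chain, resno, "N")
  CA <- .atomXYZ(s, chain, resno, "CA")
  C <- .atomXYZ(s, chain, resno, "C")
  CB <- .atomXYZ(s, chain, resno, "CB")
  if (is.null(N) || is.null(CA) || is.null(C) || is.null(CB))
    return(NA_real_)
  .vnorm(CB - idealCbeta(N, CA, C))
}
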