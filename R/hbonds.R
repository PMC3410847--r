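#' DSSP hydrogen-bond pseudo-energy
#'
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol for an
#' N-H...O=C candidate; a bond is called at `E < -0.5` kcal/mol.
#'
#' @param rON,rCH,rOH,rCN the four donor/acceptor atom distances
#'   (angstrom): acceptor O to donor N, acceptor C to donor H, acceptor O
#'   to donor H, acceptor C to donor N.
#' @return pseudo-energy in kcal/mol.
#' @export
dsspEnergy <- function(rON, rCH, rOH, rCN)
  0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)

## internal: all donor (N,H) and acceptor (C,O) pairs below the energy
## cutoff.  donors/acceptors: data.frames with chain, resno, and coordinate
## columns for the four atoms.
.hbondScan <- function(donors, acceptors, cutoff, kind,
                       excludeSame = TRUE, maxON = 5.2) {
  out <- list()
  if (nrow(donors) == 0L || nrow(acceptors) == 0L) return(NULL)
  for (i in seq_len(nrow(donors))) {
    dN <- as.numeric(donors[i, c("nx", "ny", "nz")])
    dH <- as.numeric(donors[i, c("hx", "hy", "hz")])
    for (j in seq_len(nrow(acceptors))) {
      if (excludeSame &&
          donors$chain[i] == acceptors$chain[j] &&
          (donors$pos[i] == acceptors$pos[j] ||
           donors$pos[i] - 1L == acceptors$pos[j] && kind == "mainchain-mainchain"))
        next
      aO <- as.numeric(acceptors[j, c("ox", "oy", "oz")])
      rON <- .vnorm(aO - dN)
      if (rON > maxON) next
      aC <- as.numeric(acceptors[j, c("cx", "cy", "cz")])
      e <- dsspEnergy(rON, .vnorm(aC - dH), .vnorm(aO - dH), .vnorm(aC - dN))
      if (e < cutoff)
        out[[length(out) + 1L]] <- data.frame(
          donorChain = donors$chain[i], donorResno = donors$resno[i],
          acceptorChain = acceptors$chain[j], acceptorResno = acceptors$resno[j],
          acceptorAtom = acceptors$atom[j],
          energy = e, lengthOH = .vnorm(aO - dH), kind = kind,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

## donor table: mainchain N-H (skips Pro and residues without H)
.mcDonors <- function(s) {
  rt <- residueTable(s)
  rows <- list()
  for (k in seq_len(nrow(rt))) {
    if (rt$resid[k] == "PRO") next
    N <- .atomXYZ(s, rt$chain[k], rt$resno[k], "N")
    H <- .atomXYZ(s, rt$chain[k], rt$resno[k], "H")
    if (is.null(N) || is.null(H)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chain = rt$chain[k], resno = rt$resno[k], pos = k,
      nx = N[1], ny = N[2], nz = N[3], hx = H[1], hy = H[2], hz = H[3],
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(0))
}

#' Mainchain-mainchain hydrogen bonds (DSSP criterion)
#'
#' Scans every N-H donor against every backbone C=O acceptor and reports
#' pairs with DSSP pseudo-energy below `cutoff`.  Amide hydrogens are
#' added first if absent.
#'
#' @param s a [Structure-class].
#' @param cutoff pseudo-energy threshold, default -0.5 kcal/mol.
#' @return data.frame with donor/acceptor residue references, `energy`
#'   (kcal/mol), `lengthOH` (angstrom), and `kind`.
#' @export
mainchainHBonds <- function(s, cutoff = -0.5) {
  if (!any(s@atoms$elety == "H")) s <- addPolarAndCbHydrogens(s)
  rt <- residueTable(s)
  donors <- .mcDonors(s)
  acc <- list()
  for (k in seq_len(nrow(rt))) {
    C <- .atomXYZ(s, rt$chain[k], rt$resno[k], "C")
    O <- .atomXYZ(s, rt$chain[k], rt$resno[k], "O")
    if (is.null(C) || is.null(O)) next
    acc[[length(acc) + 1L]] <- data.frame(
      chain = rt$chain[k], resno = rt$resno[k], pos = k, atom = "O",
      cx = C[1], cy = C[2], cz = C[3], ox = O[1], oy = O[2], oz = O[3],
      stringsAsFactors = FALSE)
  }
  acceptors <- if (length(acc)) do.call(rbind, acc) else data.frame(chain = character(0))
  hb <- .hbondScan(donors, acceptors, cutoff, "mainchain-mainchain")
  if (is.null(hb))
    data.frame(donorChain = character(0), donorResno = integer(0),
               acceptorChain = character(0), acceptorResno = integer(0),
               acceptorAtom = character(0), energy = numeric(0),
               lengthOH = numeric(0), kind = character(0))
  else hb
}

## sidechain acceptor groups: acceptor-side O with its covalently bonded C
.SC_ACCEPTORS <- list(
  SER = list(c(O = "OG",  C = "CB")),
  THR = list(c(O = "OG1", C = "CB")),
  ASN = list(c(O = "OD1", C = "CG")),
  ASP = list(c(O = "OD1", C = "CG"), c(O = "OD2", C = "CG")),
  TYR = list(c(O = "OH",  C = "CZ"))
)

#' Sidechain-mainchain hydrogen bonds
#'
#' Mainchain N-H donors against sidechain oxygen acceptors (Ser OG,
#' Thr OG1, Asn OD1, Asp OD1/OD2, Tyr OH), scored with the same DSSP
#' functional form using the oxygen's covalently bonded carbon as the
#' C of the formula, and the same cutoff.
#'
#' @inheritParams mainchainHBonds
#' @return data.frame as for [mainchainHBonds()] with
#'   `kind == "sidechain-mainchain"`; `acceptorAtom` names the sidechain O.
#' @export
sidechainMainchainHBonds <- function(s, cutoff = -0.5) {
  if (!any(s@atoms$elety == "H")) s <- addPolarAndCbHydrogens(s)
  rt <- residueTable(s)
  donors <- .mcDonors(s)
  acc <- list()
  for (k in seq_len(nrow(rt))) {
    groups <- .SC_ACCEPTORS[[rt$resid[k]]]
    if (is.null(groups)) next
    for (g in groups) {
      O <- .atomXYZ(s, rt$chain[k], rt$resno[k], g[["O"]])
      C <- .atomXYZ(s, rt$chain[k], rt$resno[k], g[["C"]])
      if (is.null(O) || is.null(C)) next
      acc[[length(acc) + 1L]] <- data.frame(
        chain = rt$chain[k], resno = rt$resno[k], pos = k, atom = g[["O"]],
        cx = C[1], cy = C[2], cz = C[3], ox = O[1], oy = O[2], oz = O[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(acc) == 0L)
    return(data.frame(donorChain = character(0), donorResno = integer(0),
                      acceptorChain = character(0), acceptorResno = integer(0),
                      acceptorAtom = character(0), energy = numeric(0),
                      lengthOH = numeric(0), kind = character(0)))
  acceptors <- do.call(rbind, acc)
  hb <- .hbondScan(donors, acceptors, cutoff, "sidechain-mainchain")
  if (is.null(hb))
    data.frame(donorChain = character(0), donorResno = integer(0),
               acceptorChain = character(0), acceptorResno = integer(0),
               acceptorAtom = character(0), energy = numeric(0),
               lengthOH = numeric(0), kind = character(0))
  else hb
}
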