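## Internal-coordinate construction of polypeptide geometry.
##
## One builder is shared by the synthetic-data generators, the motif
## fixtures and the design templates, so measured parameters can be checked
## against construction inputs exactly.

## ideal backbone internal coordinates (angstrom / degrees)
.BB <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
  a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.8, a_NCAC = 111.0,
  b_NH = 1.00, b_CAHA = 1.09
)

#' Place an atom from internal coordinates (NeRF)
#'
#' Returns the position `d` bonded to `c` with bond length `bond`,
#' planar angle `angle` = angle(b, c, d), and torsion
#' `tors` = torsion(a, b, c, d).
#'
#' @param a,b,c reference coordinates.
#' @param bond bond length c-d (angstrom).
#' @param angle planar angle at c (degrees).
#' @param tors torsion a-b-c-d (degrees).
#' @return coordinate triple for the new atom.
#' @export
placeAtom <- function(a, b, c, bond, angle, tors) {
  th <- angle / .DEG; ch <- tors / .DEG
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

## sidechain definition table ------------------------------------------------
## torsion for heavy atoms: chi[chi] + offset (absolute when chi == 0);
## torsion for hydrogens: measured torsion of `sibling` + offset, or the
## absolute `offset` when sibling is NA.
.scRow <- function(name, a, b, c, bond, angle, chi, offset,
                   h = FALSE, sibling = NA_character_)
  data.frame(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
             chi = chi, offset = offset, h = h, sibling = sibling,
             stringsAsFactors = FALSE)

.CB_ROW <- .scRow("CB", "C", "N", "CA", 1.530, 110.4, 0, -122.6)

.SIDECHAINS <- list(
  GLY = NULL,
  ALA = rbind(
    .CB_ROW,
    .scRow("HB1", "N", "CA", "CB", 1.09, 109.4, 0, 180, h = TRUE),
    .scRow("HB2", "N", "CA", "CB", 1.09, 109.4, 0,  60, h = TRUE),
    .scRow("HB3", "N", "CA", "CB", 1.09, 109.4, 0, -60, h = TRUE)),
  SER = rbind(
    .CB_ROW,
    .scRow("OG",  "N", "CA", "CB", 1.417, 110.8, 1, 0),
    .scRow("HB2", "N", "CA", "CB", 1.09, 109.4, 0, 120, h = TRUE, sibling = "OG"),
    .scRow("HB3", "N", "CA", "CB", 1.09, 109.4, 0, -120, h = TRUE, sibling = "OG"),
    .scRow("HG",  "CA", "CB", "OG", 0.96, 108.5, 0, 180, h = TRUE)),
  THR = rbind(
    .CB_ROW,
    .scRow("OG1", "N", "CA", "CB", 1.433, 109.6, 1, 0),
    .scRow("CG2", "N", "CA", "CB", 1.521, 110.5, 1, -120),
    .scRow("HB",  "N", "CA", "CB", 1.09, 109.4, 0, 120, h = TRUE, sibling = "OG1"),
    .scRow("HG1", "CA", "CB", "OG1", 0.96, 108.5, 0, 180, h = TRUE),
    .scRow("HG21", "CA", "CB", "CG2", 1.09, 109.4, 0, 180, h = TRUE),
    .scRow("HG22", "CA", "CB", "CG2", 1.09, 109.4, 0, 60, h = TRUE),
    .scRow("HG23", "CA", "CB", "CG2", 1.09, 109.4, 0, -60, h = TRUE)),
  ASN = rbind(
    .CB_ROW,
    .scRow("CG",  "N", "CA", "CB", 1.516, 112.6, 1, 0),
    .scRow("OD1", "CA", "CB", "CG", 1.231, 120.8, 2, 0),
    .scRow("ND2", "CA", "CB", "CG", 1.328, 116.4, 2, 180),
    .scRow("HB2", "N", "CA", "CB", 1.09, 109.4, 0, 120, h = TRUE, sibling = "CG"),
    .scRow("HB3", "N", "CA", "CB", 1.09, 109.4, 0, -120, h = TRUE, sibling = "CG"),
    .scRow("HD21", "CB", "CG", "ND2", 1.01, 120, 0, 180, h = TRUE),
    .scRow("HD22", "CB", "CG", "ND2", 1.01, 120, 0, 0, h = TRUE)),
  ASP = rbind(
    .CB_ROW,
    .scRow("CG",  "N", "CA", "CB", 1.516, 112.6, 1, 0),
    .scRow("OD1", "CA", "CB", "CG", 1.250, 118.4, 2, 0),
    .scRow("OD2", "CA", "CB", "CG", 1.250, 118.4, 2, 180),
    .scRow("HB2", "N", "CA", "CB", 1.09, 109.4, 0, 120, h = TRUE, sibling = "CG"),
    .scRow("HB3", "N", "CA", "CB", 1.09, 109.4, 0, -120, h = TRUE, sibling = "CG")),
  PHE = rbind(
    .CB_ROW,
    .scRow("CG",  "N", "CA", "CB", 1.50, 113.8, 1, 0),
    .scRow("CD1", "CA", "CB", "CG", 1.39, 120.8, 2, 0),
    .scRow("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
    .scRow("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0, 180),
    .scRow("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0, 180),
    .scRow("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, 0),
    .scRow("HB2", "N", "CA", "CB", 1.09, 109.4, 0, 120, h = TRUE, sibling = "CG"),
    .scRow("HB3", "N", "CA", "CB", 1.09, 109.4, 0, -120, h = TRUE, sibling = "CG"),
    .scRow("HD1", "CB", "CG", "CD1", 1.08, 120, 0, 0, h = TRUE),
    .scRow("HD2", "CB", "CG", "CD2", 1.08, 120, 0, 0, h = TRUE),
    .scRow("HE1", "CG", "CD1", "CE1", 1.08, 120, 0, 180, h = TRUE),
    .scRow("HE2", "CG", "CD2", "CE2", 1.08, 120, 0, 180, h = TRUE),
    .scRow("HZ",  "CD1", "CE1", "CZ", 1.08, 120, 0, 180, h = TRUE)),
  TYR = rbind(
    .CB_ROW,
    .scRow("CG",  "N", "CA", "CB", 1.51, 113.8, 1, 0),
    .scRow("CD1", "CA", "CB", "CG", 1.39, 120.8, 2, 0),
    .scRow("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
    .scRow("CE1", "CB", "CG", "CD1", 1.39, 120.0, 0, 180),
    .scRow("CE2", "CB", "CG", "CD2", 1.39, 120.0, 0, 180),
    .scRow("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, 0),
    .scRow("OH",  "CD1", "CE1", "CZ", 1.38, 120.0, 0, 180),
    .scRow("HB2", "N", "CA", "CB", 1.09, 109.4, 0, 120, h = TRUE, sibling = "CG"),
    .scRow("HB3", "N", "CA", "CB", 1.09, 109.4, 0, -120, h = TRUE, sibling = "CG"),
    .scRow("HD1", "CB", "CG", "CD1", 1.08, 120, 0, 0, h = TRUE),
    .scRow("HD2", "CB", "CG", "CD2", 1.08, 120, 0, 0, h = TRUE),
    .scRow("HE1", "CG", "CD1", "CE1", 1.08, 120, 0, 180, h = TRUE),
    .scRow("HE2", "CG", "CD2", "CE2", 1.08, 120, 0, 180, h = TRUE),
    .scRow("HH",  "CE1", "CZ", "OH", 0.96, 108, 0, 0, h = TRUE))
)

#' Amino acid types with sidechain construction templates
#' @return character vector of 3-letter codes
#' @export
buildableResidues <- function() names(.SIDECHAINS)

## number of chi angles per supported residue type
.N_CHI <- c(GLY = 0, ALA = 0, SER = 1, THR = 1, ASN = 2, ASP = 2,
            PHE = 2, TYR = 2)

#' Build a polypeptide chain from ideal internal coordinates
#'
#' Grows an all-atom chain with ideal bond lengths and angles from supplied
#' backbone torsions.  `phi[1]` is unused (no preceding carbonyl);
#' `psi[n]` orients the final carbonyl O.  Sidechains (and their
#' hydrogens) are built for residue types in [buildableResidues()] from
#' the chi angles in `chi`; amide hydrogens and HA are added when
#' `addHydrogens = TRUE`.
#'
#' @param aa character vector of 3-letter residue codes.
#' @param phi,psi backbone torsions (degrees), recycled to `length(aa)`.
#' @param omega peptide torsions (degrees), default 180 (trans).
#' @param tau N-CA-C bond angles (degrees), default 111.0.
#' @param chi list (per residue) of chi angle vectors; `NULL` entries get
#'   chi = 180 for each angle.
#' @param chain chain identifier.
#' @param startResno first residue number.
#' @param bFactor B-factor written on every atom.
#' @param addHydrogens add amide H and HA/HA2/HA3 hydrogens.
#' @return a [Structure-class].
#' @export
buildChain <- function(aa, phi = -120, psi = 130, omega = 180, tau = 111.0,
                       chi = NULL, chain = "A", startResno = 1L,
                       bFactor = 10, addHydrogens = TRUE) {
  n <- length(aa)
  aa <- toupper(aa)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  omega <- rep_len(omega, n); tau <- rep_len(tau, n)
  if (is.null(chi)) chi <- vector("list", n)
  length(chi) <- n

  rows <- vector("list", 0L)
  addAtom <- function(resno, resid, name, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, inscode = "", resid = resid,
      elety = name, alt = "", x = pos[1], y = pos[2], z = pos[3],
      occ = 1, b = bFactor, elem = .guessElement(name), het = FALSE,
      primary = TRUE, stringsAsFactors = FALSE)
  }

  ## backbone N, CA, C positions
  N <- CA <- C <- matrix(NA_real_, n, 3L)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$b_NCA, 0, 0)
  C[1, ] <- CA[1, ] + .BB$b_CAC *
    c(-cos(tau[1] / .DEG), sin(tau[1] / .DEG), 0)
  if (n > 1) for (i in 2:n) {
    N[i, ] <- placeAtom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                        .BB$b_CN, .BB$a_CACN, psi[i - 1])
    CA[i, ] <- placeAtom(CA[i - 1, ], C[i - 1, ], N[i, ],
                         .BB$b_NCA, .BB$a_CNCA, omega[i])
    C[i, ] <- placeAtom(C[i - 1, ], N[i, ], CA[i, ],
                        .BB$b_CAC, tau[i], phi[i])
  }

  for (i in seq_len(n)) {
    resno <- startResno + i - 1L
    addAtom(resno, aa[i], "N", N[i, ])
    addAtom(resno, aa[i], "CA", CA[i, ])
    addAtom(resno, aa[i], "C", C[i, ])
    ## carbonyl O anti to the next amide N (psi + 180)
    O <- placeAtom(N[i, ], CA[i, ], C[i, ], .BB$b_CO, .BB$a_CACO,
                   psi[i] + 180)
    addAtom(resno, aa[i], "O", O)

    ## sidechain from the shared template
    def <- .SIDECHAINS[[aa[i]]]
    if (!is.null(def)) {
      have <- list(N = N[i, ], CA = CA[i, ], C = C[i, ], O = O)
      chis <- chi[[i]]
      nchi <- .N_CHI[[aa[i]]]
      if (is.null(chis)) chis <- rep(180, max(nchi, 1L))
      for (k in seq_len(nrow(def))) {
        d <- def[k, ]
        tors <- if (d$h && !is.na(d$sibling)) {
          torsionAngle(have[[d$a]], have[[d$b]], have[[d$c]],
                       have[[d$sibling]]) + d$offset
        } else if (d$chi > 0) {
          chis[d$chi] + d$offset
        } else d$offset
        pos <- placeAtom(have[[d$a]], have[[d$b]], have[[d$c]],
                         d$bond, d$angle, tors)
        have[[d$name]] <- pos
        addAtom(resno, aa[i], d$name, pos)
      }
    }

    if (addHydrogens) {
      if (i > 1 && aa[i] != "PRO") {
        h <- N[i, ] + .BB$b_NH *
          .unit(.unit(N[i, ] - C[i - 1, ]) + .unit(N[i, ] - CA[i, ]))
        addAtom(resno, aa[i], "H", h)
      }
      if (aa[i] == "GLY") {
        dirs <- .tetrahedralPair(CA[i, ], N[i, ], C[i, ])
        addAtom(resno, aa[i], "HA2", CA[i, ] + .BB$b_CAHA * dirs[[1]])
        addAtom(resno, aa[i], "HA3", CA[i, ] + .BB$b_CAHA * dirs[[2]])
      } else {
        cb <- placeAtom(C[i, ], N[i, ], CA[i, ], 1.530, 110.4, -122.6)
        u <- .unit(.unit(N[i, ] - CA[i, ]) + .unit(C[i, ] - CA[i, ]) +
                     .unit(cb - CA[i, ]))
        addAtom(resno, aa[i], "HA", CA[i, ] - .BB$b_CAHA * u)
      }
    }
  }

  Structure(do.call(rbind, rows))
}

## the two tetrahedral directions completing neighbors n1, n2 at `center`
.tetrahedralPair <- function(center, n1, n2) {
  b1 <- .unit(n1 - center); b2 <- .unit(n2 - center)
  bis <- .unit(b1 + b2)
  perp <- .unit(.cross(b1, b2))
  half <- (109.47 / 2) / .DEG
  list(-bis * cos(half) + perp * sin(half),
       -bis * cos(half) - perp * sin(half))
}

#' Ideal C-beta position from backbone atoms
#'
#' Constructs the ideal C-beta from N, CA, C using the same internal
#' coordinates as the chain builder (bond 1.530, angle N-CA-CB 110.4,
#' torsion C-N-CA-CB -122.6 for L-amino acids).
#'
#' @param n,ca,c backbone coordinates.
#' @return coordinate triple of the ideal C-beta.
#' @export
idealCbeta <- function(n, ca, c) placeAtom(c, n, ca, 1.530, 110.4, -122.6)
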