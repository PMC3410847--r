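#' Add amide, C-alpha/C-beta, and polar sidechain hydrogens
#'
#' Places the hydrogens the analysis needs from ideal internal coordinates:
#' the backbone amide H (in the peptide plane, N-H 1.00 angstrom, opposite
#' the carbonyl O of the preceding peptide), HA (HA2/HA3 for Gly), and
#' sidechain hydrogens for residue types in [buildableResidues()] (C-beta
#' hydrogens, Ser/Thr/Tyr hydroxyl H, Asn amide hydrogens, aromatic ring
#' hydrogens).  Existing hydrogens are preserved; N-terminal residues and
#' Pro receive no amide H.
#'
#' Building, stripping, and rebuilding is idempotent: placement depends
#' only on heavy-atom positions.
#'
#' @param s a [Structure-class].
#' @return a [Structure-class] with hydrogens added.
#' @export
addPolarAndCbHydrogens <- function(s) {
  rt <- residueTable(s)
  newRows <- list()
  a <- s@atoms
  for (ch in unique(rt$chain)) {
    rr <- rt[rt$chain == ch, ]
    for (k in seq_len(nrow(rr))) {
      resno <- rr$resno[k]
      aa <- rr$resid[k]
      present <- a$elety[.atomRows(s, ch, resno)]
      N <- .atomXYZ(s, ch, resno, "N")
      CA <- .atomXYZ(s, ch, resno, "CA")
      C <- .atomXYZ(s, ch, resno, "C")
      if (is.null(N) || is.null(CA) || is.null(C)) next
      add <- function(name, pos) {
        newRows[[length(newRows) + 1L]] <<- data.frame(
          chain = ch, resno = resno, inscode = rr$inscode[k], resid = aa,
          elety = name, alt = "", x = pos[1], y = pos[2], z = pos[3],
          occ = 1, b = a$b[.atomRows(s, ch, resno)][1L], elem = "H",
          het = FALSE, primary = TRUE, stringsAsFactors = FALSE)
      }

      ## amide H: bisector of C(i-1)->N and CA->N, in the peptide plane
      if (k > 1L && aa != "PRO" && !("H" %in% present)) {
        Cp <- .atomXYZ(s, ch, rr$resno[k - 1L], "C")
        if (!is.null(Cp) && .vnorm(N - Cp) < 2.5)
          add("H", N + .BB$b_NH * .unit(.unit(N - Cp) + .unit(N - CA)))
      }

      ## alpha hydrogens
      if (aa == "GLY") {
        if (!("HA2" %in% present)) {
          dirs <- .tetrahedralPair(CA, N, C)
          add("HA2", CA + .BB$b_CAHA * dirs[[1]])
          add("HA3", CA + .BB$b_CAHA * dirs[[2]])
        }
      } else if (!("HA" %in% present)) {
        CB <- .atomXYZ(s, ch, resno, "CB")
        if (is.null(CB)) CB <- idealCbeta(N, CA, C)
        u <- .unit(.unit(N - CA) + .unit(C - CA) + .unit(CB - CA))
        add("HA", CA - .BB$b_CAHA * u)
      }

      ## sidechain hydrogens from the construction templates
      def <- .SIDECHAINS[[aa]]
      if (!is.null(def)) {
        hdef <- def[def$h, , drop = FALSE]
        for (j in seq_len(nrow(hdef))) {
          d <- hdef[j, ]
          if (d$name %in% present) next
          refs <- lapply(c(d$a, d$b, d$c), function(nm) .atomXYZ(s, ch, resno, nm))
          if (any(vapply(refs, is.null, logical(1)))) next
          tors <- if (!is.na(d$sibling)) {
            sib <- .atomXYZ(s, ch, resno, d$sibling)
            if (is.null(sib)) next
            torsionAngle(refs[[1]], refs[[2]], refs[[3]], sib) + d$offset
          } else d$offset
          add(d$name, placeAtom(refs[[1]], refs[[2]], refs[[3]],
                                d$bond, d$angle, tors))
        }
      }
    }
  }
  if (length(newRows) == 0L) return(s)
  out <- rbind(a, do.call(rbind, newRows))
  ## keep residue blocks contiguous and ordered as before
  rt2 <- residueTable(Structure(out), includeHet = TRUE)
  key <- paste(out$chain, out$resno, out$inscode, sep = "|")
  ord <- order(match(key, paste(rt2$chain, rt2$resno, rt2$inscode, sep = "|")))
  Structure(out[ord, , drop = FALSE], header = s@header)
}

#' Strip all hydrogens from a structure
#'
#' @param s a [Structure-class].
#' @return a [Structure-class] containing heavy atoms only.
#' @export
stripHydrogens <- function(s) {
  Structure(s@atoms[s@atoms$elem != "H", , drop = FALSE], header = s@header)
}
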