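#' @import methods
#' @importFrom stats median optimize optim rnorm runif setNames uniroot wilcox.test
#' @importFrom utils head read.table write.table
NULL

.ATOM_COLS <- c("chain", "resno", "inscode", "resid", "elety", "alt",
                "x", "y", "z", "occ", "b", "elem", "het", "primary")

#' Protein structure as an atom table
#'
#' A `Structure` holds one or more protein chains as a flat per-atom table
#' (one row per atom, PDB-style fields).  Residues within a chain are kept
#' in file order; all windowed operations (`i - 1`, `i + 3`, ...) are
#' positional within a chain, not arithmetic on author numbering.
#'
#' @slot atoms data.frame with columns `chain`, `resno`, `inscode`,
#'   `resid` (3-letter code), `elety` (atom name), `alt` (alternate
#'   location, `""` if none), `x`, `y`, `z` (angstrom), `occ`, `b`
#'   (B-factor, squared angstrom), `elem`, `het` (logical, HETATM),
#'   `primary` (logical; highest-occupancy alternate, ties broken by
#'   alt-loc letter).
#' @slot header list of optional metadata (`id`, `resolution`).
#'
#' @export
setClass("Structure",
         representation(atoms = "data.frame", header = "list"),
         prototype(atoms = data.frame(), header = list()))

setValidity("Structure", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return(TRUE)
  miss <- setdiff(.ATOM_COLS, names(a))
  if (length(miss)) return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(a$occ < 0 | a$occ > 1, na.rm = TRUE)) return("occupancy outside [0,1]")
  if (any(a$b < 0, na.rm = TRUE)) return("negative B-factor")
  if (any(nchar(a$elety) > 4L)) return("atom name longer than 4 characters")
  TRUE
})

#' @describeIn Structure number of atoms
#' @param x,object a `Structure`
#' @export
setMethod("length", "Structure", function(x) nrow(x@atoms))

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  rt <- residueTable(object)
  cat("Structure:", nrow(a), "atoms,", nrow(rt), "residues,",
      length(unique(rt$chain)), "chain(s)\n")
  if (!is.null(object@header$id)) cat("  id:", object@header$id, "\n")
  if (nrow(rt)) {
    for (ch in unique(rt$chain)) {
      r <- rt[rt$chain == ch, ]
      cat("  chain ", ch, ": residues ", r$resno[1], "..",
          r$resno[nrow(r)], "\n", sep = "")
    }
  }
  invisible(NULL)
})

#' Construct a Structure from an atom table
#'
#' @param atoms data.frame with at least `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z`; missing bookkeeping columns are filled with
#'   defaults (full occupancy, B-factor 0, blank alt-loc).
#' @param header optional list of metadata.
#' @return a [Structure-class] object.
#' @export
Structure <- function(atoms, header = list()) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L) {
    empty <- data.frame(chain = character(0), resno = integer(0),
                        inscode = character(0), resid = character(0),
                        elety = character(0), alt = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        occ = numeric(0), b = numeric(0),
                        elem = character(0), het = logical(0),
                        primary = logical(0))
    return(new("Structure", atoms = empty, header = header))
  }
  n <- nrow(atoms)
  if (is.null(atoms$inscode)) atoms$inscode <- rep("", n)
  if (is.null(atoms$alt))     atoms$alt     <- rep("", n)
  if (is.null(atoms$occ))     atoms$occ     <- rep(1, n)
  if (is.null(atoms$b))       atoms$b       <- rep(0, n)
  if (is.null(atoms$elem))    atoms$elem    <- .guessElement(atoms$elety)
  if (is.null(atoms$het))     atoms$het     <- rep(FALSE, n)
  if (is.null(atoms$primary)) atoms$primary <- .flagPrimaryAlt(atoms)
  atoms <- atoms[, .ATOM_COLS]
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, header = header)
}

## element from PDB atom name: first letter after stripping digits/primes
.guessElement <- function(elety) {
  e <- sub("^[0-9']*", "", elety)
  substr(e, 1L, 1L)
}

## highest occupancy wins; ties broken by alt-loc letter order
.flagPrimaryAlt <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$inscode, atoms$elety, sep = "|")
  prim <- rep(TRUE, nrow(atoms))
  dup <- key %in% key[duplicated(key)]
  if (any(dup)) {
    for (k in unique(key[dup])) {
      idx <- which(key == k)
      ord <- order(-atoms$occ[idx], atoms$alt[idx])
      prim[idx] <- FALSE
      prim[idx[ord[1L]]] <- TRUE
    }
  }
  prim
}

#' @describeIn Structure the per-atom table
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' @rdname Structure-class
#' @export
setMethod("atoms", "Structure", function(object) object@atoms)

#' A parameterized backrub move
#'
#' The primary rotation `theta13` turns the dipeptide around residue `i`
#' about the Calpha(i-1)-Calpha(i+1) axis; `theta12` and `theta23` are the
#' single-peptide counter-rotations about Calpha(i-1)-Calpha(i) and
#' Calpha(i)-Calpha(i+1).  `epsilon` records the scale factor used when the
#' counter-rotations were derived from the carbonyl-restoring optimum.
#' Positive angles follow the right-hand rule about the N-to-C axis vector.
#'
#' @slot theta13,theta12,theta23 rotation angles in degrees
#' @slot epsilon counter-rotation scale factor in `[0, 1]`
#' @export
setClass("BackrubMove",
         representation(theta13 = "numeric", theta12 = "numeric",
                        theta23 = "numeric", epsilon = "numeric"),
         prototype(theta13 = 0, theta12 = 0, theta23 = 0, epsilon = 0.7))

setValidity("BackrubMove", function(object) {
  if (abs(object@theta13) > 90) return("|theta13| > 90 degrees")
  if (object@epsilon < 0 || object@epsilon > 1) return("epsilon outside [0,1]")
  TRUE
})

#' @rdname BackrubMove-class
#' @param theta13,theta12,theta23 rotation angles (degrees)
#' @param epsilon counter-rotation scale factor
#' @export
BackrubMove <- function(theta13 = 0, theta12 = 0, theta23 = 0, epsilon = 0.7)
  new("BackrubMove", theta13 = theta13, theta12 = theta12,
      theta23 = theta23, epsilon = epsilon)

setMethod("show", "BackrubMove", function(object) {
  cat(sprintf("BackrubMove: theta13 = %+.2f, theta12 = %+.2f, theta23 = %+.2f (deg), epsilon = %.2f\n",
              object@theta13, object@theta12, object@theta23, object@epsilon))
  invisible(NULL)
})

#' A fitted backrub between two conformations
#'
#' @slot move the fitted [BackrubMove-class]
#' @slot residualRmsd RMSD (angstrom) over the fitted atom set after the move
#' @slot signConvention text note on the axis orientation
#' @export
setClass("BackrubFit",
         representation(move = "BackrubMove", residualRmsd = "numeric",
                        signConvention = "character"),
         prototype(residualRmsd = 0,
                   signConvention = "right-hand rule about Calpha(i-1) -> Calpha(i+1)"))

setValidity("BackrubFit", function(object) {
  if (object@residualRmsd < 0) return("negative residual RMSD")
  TRUE
})

setMethod("show", "BackrubFit", function(object) {
  cat(sprintf("BackrubFit: theta13 = %+.2f deg (theta12 %+.2f, theta23 %+.2f), residual %.4f A\n",
              object@move@theta13, object@move@theta12, object@move@theta23,
              object@residualRmsd))
  invisible(NULL)
})

#' A motif ensemble superposed on a common frame
#'
#' @slot members list of [Structure-class] windows in the reference frame
#' @slot reference the reference [Structure-class]
#' @slot frameAtoms data.frame (`resno`, `elety`) naming the frame atoms
#' @slot rmsd per-member frame-atom RMSD (angstrom) to the reference
#' @export
setClass("SuperposedEnsemble",
         representation(members = "list", reference = "Structure",
                        frameAtoms = "data.frame", rmsd = "numeric"))

setValidity("SuperposedEnsemble", function(object) {
  if (length(object@members) != length(object@rmsd))
    return("rmsd length != member count")
  if (any(object@rmsd < 0)) return("negative rmsd")
  TRUE
})

setMethod("show", "SuperposedEnsemble", function(object) {
  cat("SuperposedEnsemble:", length(object@members), "members,",
      nrow(object@frameAtoms), "frame atoms")
  if (length(object@rmsd))
    cat(sprintf("; rmsd %.3f-%.3f A", min(object@rmsd), max(object@rmsd)))
  cat("\n")
  invisible(NULL)
})

#' Mean-coordinate motif with an attached median rotamer
#'
#' @slot structure [Structure-class] of mean backbone/H/Cbeta positions
#'   (plus any rebuilt sidechain)
#' @slot nMembers number of ensemble members averaged
#' @slot chi named numeric vector of median sidechain chi angles (degrees)
#' @slot atomCounts named integer vector: members contributing to each atom
#' @export
setClass("AverageMotif",
         representation(structure = "Structure", nMembers = "numeric",
                        chi = "numeric", atomCounts = "integer"),
         prototype(nMembers = 0, chi = numeric(0), atomCounts = integer(0)))

setValidity("AverageMotif", function(object) {
  if (object@nMembers < 1) return("nMembers < 1")
  TRUE
})

setMethod("show", "AverageMotif", function(object) {
  cat("AverageMotif over", object@nMembers, "members;",
      length(object@structure), "atoms")
  if (length(object@chi))
    cat("; chi:", paste(sprintf("%s=%.1f", names(object@chi), object@chi),
                        collapse = ", "))
  cat("\n")
  invisible(NULL)
})

#' Result of an exhaustive backrub/rotamer design search
#'
#' @slot gmec [Structure-class] of the global minimum energy conformation
#' @slot gmecInfo list: backrub angles, peptide rotation, rotamer,
#'   energy terms (kcal/mol), tau values (degrees)
#' @slot ranking data.frame of every enumerated conformation with
#'   decomposed energies and feasibility flags
#' @slot counts named numeric vector: `enumerated`, `feasible`, `tauRejected`
#' @export
setClass("DesignResult",
         representation(gmec = "Structure", gmecInfo = "list",
                        ranking = "data.frame", counts = "numeric"))

setValidity("DesignResult", function(object) {
  rk <- object@ranking
  if (nrow(rk) && length(object@gmecInfo)) {
    feas <- rk$total[rk$feasible]
    if (length(feas) && object@gmecInfo$total > min(feas) + 1e-9)
      return("gmec energy above the ranked minimum")
  }
  TRUE
})

setMethod("show", "DesignResult", function(object) {
  cat("DesignResult:", object@counts["enumerated"], "conformations enumerated,",
      object@counts["tauRejected"], "tau-rejected\n")
  gi <- object@gmecInfo
  if (length(gi))
    cat(sprintf("  GMEC: theta13 %+.1f deg, peptide %+.1f deg, rotamer %s, total %.3f kcal/mol\n",
                gi$theta13, gi$peptide, gi$rotamer, gi$total))
  invisible(NULL)
})
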