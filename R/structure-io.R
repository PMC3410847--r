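#' Read a protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] producing a [Structure-class].
#' All protein chains are returned; waters and het groups are retained in
#' the atom table (flagged `het`) but excluded from geometry operations.
#' Alternate locations are kept, with the highest-occupancy variant of each
#' atom flagged `primary` (ties broken by alt-loc letter order).
#'
#' @param path path to a PDB-format file.
#' @return a [Structure-class]; chains consisting only of C-alpha atoms are
#'   flagged `geometryIncomplete` in the header.
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    inscode = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    alt = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    elem = ifelse(is.na(a$elesy) | a$elesy == "", .guessElement(a$elety), a$elesy),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE)
  s <- Structure(atoms, header = list(id = sub("\\.pdb$", "", basename(path))))
  ## flag chains with no usable backbone (C-alpha traces)
  rt <- residueTable(s)
  incomplete <- character(0)
  for (ch in unique(rt$chain)) {
    el <- atoms$elety[!atoms$het & atoms$chain == ch]
    if (length(el) && all(el %in% c("CA"))) incomplete <- c(incomplete, ch)
  }
  if (length(incomplete)) s@header$geometryIncomplete <- incomplete
  s
}

#' Write a structure to a PDB file
#'
#' Fixed-column PDB v3 output via [bio3d::write.pdb()]; coordinates keep
#' the format's 3-decimal precision, occupancy and B-factor columns are
#' honoured.
#'
#' @param s a [Structure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(s, path) {
  validObject(s)
  a <- s@atoms
  if (nrow(a) == 0L) {
    writeLines("END", path)
    return(invisible(path))
  }
  ## assemble a bio3d pdb object
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(a$inscode == "", NA, a$inscode),
                   alt = ifelse(a$alt == "", NA, a$alt),
                   o = a$occ, b = a$b, elesy = a$elem, xyz = xyz)
  invisible(path)
}

#' Residue-level summary of a structure
#'
#' @param s a [Structure-class].
#' @param includeHet keep het/water residues (default drops them).
#' @return data.frame with `chain`, `resno`, `inscode`, `resid` in file
#'   order, one row per residue.
#' @export
residueTable <- function(s, includeHet = FALSE) {
  a <- s@atoms
  if (!includeHet && nrow(a)) a <- a[!a$het, , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(chain = character(0), resno = integer(0),
                      inscode = character(0), resid = character(0)))
  key <- paste(a$chain, a$resno, a$inscode, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             inscode = a$inscode[first], resid = a$resid[first],
             stringsAsFactors = FALSE)
}

## positional index of (chain, resno) within the chain's residue order;
## NA when absent
.resPos <- function(rt, chain, resno) {
  idx <- which(rt$chain == chain)
  p <- match(resno, rt$resno[idx])
  if (is.na(p)) NA_integer_ else p
}

## resno of the residue at positional offset from (chain, resno)
.resAtOffset <- function(s, chain, resno, offset) {
  rt <- residueTable(s)
  idx <- which(rt$chain == chain)
  p <- match(resno, rt$resno[idx])
  if (is.na(p)) return(NA_integer_)
  q <- p + offset
  if (q < 1L || q > length(idx)) return(NA_integer_)
  rt$resno[idx[q]]
}

## atom table row indices for (chain, resno [, names]); primary alts only
.atomRows <- function(s, chain, resno, names = NULL) {
  a <- s@atoms
  sel <- a$chain == chain & a$resno %in% resno & !a$het & a$primary
  if (!is.null(names)) sel <- sel & a$elety %in% names
  which(sel)
}

## coordinates of one named atom; NULL if absent
.atomXYZ <- function(s, chain, resno, name) {
  i <- .atomRows(s, chain, resno, name)
  if (length(i) == 0L) return(NULL)
  as.numeric(s@atoms[i[1L], c("x", "y", "z")])
}

## coordinate matrix for given rows
.xyz <- function(s, rows) as.matrix(s@atoms[rows, c("x", "y", "z")])

## overwrite coordinates at rows
.setXYZ <- function(s, rows, m) {
  s@atoms[rows, c("x", "y", "z")] <- m
  s
}

#' Detect chain breaks
#'
#' A break is recorded between consecutive residues of a chain when the
#' C(i)-N(i+1) distance exceeds `limit` (default 2.5 angstrom, about 1.6x
#' the ideal peptide bond) or either atom is missing.
#'
#' @param s a [Structure-class].
#' @param limit distance threshold in angstrom.
#' @return data.frame with `chain`, `resnoBefore`, `resnoAfter`, `distance`.
#' @export
chainBreaks <- function(s, limit = 2.5) {
  rt <- residueTable(s)
  out <- list()
  for (ch in unique(rt$chain)) {
    rr <- rt$resno[rt$chain == ch]
    if (length(rr) < 2L) next
    for (k in seq_len(length(rr) - 1L)) {
      c1 <- .atomXYZ(s, ch, rr[k], "C")
      n2 <- .atomXYZ(s, ch, rr[k + 1L], "N")
      d <- if (is.null(c1) || is.null(n2)) Inf else .vnorm(n2 - c1)
      if (d > limit)
        out[[length(out) + 1L]] <- data.frame(
          chain = ch, resnoBefore = rr[k], resnoAfter = rr[k + 1L],
          distance = d, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chain = character(0), resnoBefore = integer(0),
                  resnoAfter = integer(0), distance = numeric(0))
}

## extract a window of residues (positional offsets) as a new Structure
.extractWindow <- function(s, chain, resno, offsets) {
  rns <- vapply(offsets, function(o) .resAtOffset(s, chain, resno, o), integer(1))
  rns <- rns[!is.na(rns)]
  rows <- .atomRows(s, chain, rns)
  Structure(s@atoms[rows, , drop = FALSE], header = s@header)
}
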