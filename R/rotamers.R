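#' Load a modal rotamer library
#'
#' Reads a plain-text tab-separated rotamer library with columns `aa`
#' (3-letter code), `name`, `chi1`, `chi2` (degrees, `NA` where a residue
#' has fewer chi angles), and `freq`.  The bundled default carries modal
#' (peak) chi values of the common rotamers for the residue types the
#' package can build; a Dunbrack-style library in the same column format
#' can be substituted.
#'
#' @param path library file; default is the bundled table.
#' @return data.frame with one row per rotamer.
#' @export
rotamerLibrary <- function(path = system.file("extdata", "rotamers.tsv",
                                              package = "backrubr")) {
  lib <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("aa", "name", "chi1", "chi2", "freq")
  if (!all(need %in% names(lib)))
    stop("rotamer library must have columns: ", paste(need, collapse = ", "))
  lib
}

#' Rotamers for one residue type
#'
#' @param aa 3-letter code.
#' @param library data.frame from [rotamerLibrary()].
#' @return data.frame of rotamers; for Gly/Ala a single chi-less row.
#' @export
rotamersFor <- function(aa, library = rotamerLibrary()) {
  aa <- toupper(aa)
  if (.N_CHI[[aa]] == 0)
    return(data.frame(aa = aa, name = "-", chi1 = NA_real_,
                      chi2 = NA_real_, freq = 1, stringsAsFactors = FALSE))
  out <- library[library$aa == aa, , drop = FALSE]
  if (nrow(out) == 0L) stop("no rotamers for ", aa)
  rownames(out) <- NULL
  out
}
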