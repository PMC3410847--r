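## Motif mining: DSSP-style helix and strand annotation, alpha-helix N-cap
## identification with category/cluster labels, mid-helix controls, and
## plus-chi1 aromatics opposite a partner strand residue in antiparallel
## beta-sheet with the fray statistic.

#' Default motif-search configuration
#'
#' Thresholds used by the motif scanners: DSSP H-bond cutoff (kcal/mol),
#' N-cap extension distance (angstrom), B-factor limits, phi/psi windows
#' (degrees), and the fray limit (degrees).
#'
#' @return a named list of thresholds.
#' @export
motifConfig <- function() {
  list(
    hbondCutoff = -0.5,
    capExtendDist = 5.9,
    minHelixLength = 5L,
    bMaxCap = 40,
    bMaxMidhelix = 20,
    bMaxBeta = 40,
    ## primary phi,psi window: between (-100,155) and (-60,180)
    primaryBox = c(phiMin = -100, phiMax = -60, psiMin = 155, psiMax = 180),
    ## secondary window: a box of the same dimensions centred at (-150,170)
    secondaryBox = c(phiMin = -170, phiMax = -130, psiMin = 150, psiMax = 180),
    midhelixBox = c(phiMin = -65, phiMax = -55, psiMin = -45, psiMax = -35),
    midhelixFlank = 4L,
    midhelixTotalH = 13L,
    frayLimit = 10,
    fraySigned = FALSE
  )
}

#' Annotate helices from mainchain H-bond turns
#'
#' Recognises helices from consecutive alpha-like (`i -> i+4`
#' mainchain-mainchain H-bond, acceptor notation: O(i) accepting from
#' N(i+4)) and/or 3-10-like (`i -> i+3`) turns, requiring at least five
#' residues including both caps.  The N-terminus is extended residue by
#' residue while the candidate cap's Calpha lies within `capExtendDist`
#' (5.9 angstrom) of the `i+3` Calpha.  The cap class comes from the
#' cap's own mainchain bonds: `i+4` only is `alpha`, `i+3` only is
#' `three10`, both is `bifurcated`, neither is `none`.
#'
#' @param s a [Structure-class].
#' @param config list from [motifConfig()].
#' @return list with `residues` (per-residue flags: `turn4`, `turn3`,
#'   `hLabel`) and `helices` (one row per helix: `chain`, `ncapResno`,
#'   `endResno`, `capClass`, `nH`).
#' @export
annotateHelices <- function(s, config = motifConfig()) {
  rt <- residueTable(s)
  n <- nrow(rt)
  hb <- mainchainHBonds(s, config$hbondCutoff)
  pos <- function(ch, rn) {
    i <- which(rt$chain == ch & rt$resno == rn)
    if (length(i)) i[1] else NA_integer_
  }
  turn4 <- turn3 <- logical(n)
  if (nrow(hb)) for (k in seq_len(nrow(hb))) {
    di <- pos(hb$donorChain[k], hb$donorResno[k])
    ai <- pos(hb$acceptorChain[k], hb$acceptorResno[k])
    if (is.na(di) || is.na(ai)) next
    if (rt$chain[di] != rt$chain[ai]) next
    if (di - ai == 4L) turn4[ai] <- TRUE
    if (di - ai == 3L) turn3[ai] <- TRUE
  }
  ## DSSP-style H label: two consecutive alpha turns cover q+1 .. q+4
  hLabel <- logical(n)
  for (q in seq_len(max(n - 1L, 0L)))
    if (turn4[q] && q + 1L <= n && turn4[q + 1L] &&
        rt$chain[q] == rt$chain[min(q + 5L, n)])
      hLabel[(q + 1L):min(q + 4L, n)] <- TRUE

  ## helix spans: union of turn intervals, merged
  helices <- list()
  for (ch in unique(rt$chain)) {
    idx <- which(rt$chain == ch)
    iv <- list()
    for (q in idx) {
      if (turn4[q]) iv[[length(iv) + 1L]] <- c(q, min(q + 4L, max(idx)))
      if (turn3[q]) iv[[length(iv) + 1L]] <- c(q, min(q + 3L, max(idx)))
    }
    if (length(iv) == 0L) next
    iv <- iv[order(vapply(iv, `[`, numeric(1), 1L))]
    merged <- list(iv[[1L]])
    for (v in iv[-1L]) {
      last <- merged[[length(merged)]]
      if (v[1] <= last[2] + 1L)
        merged[[length(merged)]] <- c(last[1], max(last[2], v[2]))
      else merged[[length(merged) + 1L]] <- v
    }
    for (m in merged) {
      start <- m[1]
      ## N-terminal extension by the Calpha(i) - Calpha(i+3) distance rule
      repeat {
        cand <- start - 1L
        if (cand < min(idx) || rt$chain[cand] != ch) break
        ca <- .atomXYZ(s, ch, rt$resno[cand], "CA")
        ca3 <- if (cand + 3L <= max(idx)) .atomXYZ(s, ch, rt$resno[cand + 3L], "CA") else NULL
        if (is.null(ca) || is.null(ca3)) break
        if (.vnorm(ca3 - ca) >= config$capExtendDist) break
        start <- cand
      }
      if (m[2] - start + 1L < config$minHelixLength) next
      cls <- if (turn4[start] && turn3[start]) "bifurcated"
             else if (turn4[start]) "alpha"
             else if (turn3[start]) "three10"
             else "none"
      helices[[length(helices) + 1L]] <- data.frame(
        chain = ch, ncapResno = rt$resno[start], endResno = rt$resno[m[2]],
        capClass = cls, nH = sum(hLabel[start:m[2]]),
        stringsAsFactors = FALSE)
    }
  }
  list(residues = cbind(rt, turn4 = turn4, turn3 = turn3, hLabel = hLabel),
       helices = if (length(helices)) do.call(rbind, helices)
                 else data.frame(chain = character(0), ncapResno = integer(0),
                                 endResno = integer(0), capClass = character(0),
                                 nH = integer(0)))
}

.inBox <- function(phi, psi, box)
  !is.na(phi) && !is.na(psi) &&
    phi >= box["phiMin"] && phi <= box["phiMax"] &&
    psi >= box["psiMin"] && psi <= box["psiMax"]

.maxB <- function(s, chain, resno) {
  rows <- .atomRows(s, chain, resno)
  rows <- rows[s@atoms$elem[rows] != "H"]
  if (length(rows)) max(s@atoms$b[rows]) else NA_real_
}

#' Find alpha-helix N-cap motifs
#'
#' Keeps alpha-class caps (an `i+4` but no `i+3` mainchain bond from the
#' cap; bifurcated caps are dropped), assigns the category from the cap
#' amino acid (Asn/Asp `ND`, Ser/Thr `ST`, anything else `other`), and for
#' ND/ST requires the `i+3` sidechain-mainchain H-bond present and the
#' `i+2` one absent (both by the DSSP pseudo-energy criterion).  The cap
#' phi/psi must fall in the primary or secondary cluster window, and the
#' cap residue's maximum non-hydrogen B-factor must stay below the limit.
#'
#' @param s a [Structure-class].
#' @param config list from [motifConfig()].
#' @param annotation optional precomputed [annotateHelices()] result.
#' @return data.frame, one row per accepted cap: `chain`, `resno`, `aa`,
#'   `category`, `cluster`, `phi`, `psi`, `hbEnergy`, `hbLength`, `maxB`.
#' @export
findNcapMotifs <- function(s, config = motifConfig(), annotation = NULL) {
  if (is.null(annotation)) annotation <- annotateHelices(s, config)
  hx <- annotation$helices
  empty <- data.frame(chain = character(0), resno = integer(0),
                      aa = character(0), category = character(0),
                      cluster = character(0), phi = numeric(0),
                      psi = numeric(0), hbEnergy = numeric(0),
                      hbLength = numeric(0), maxB = numeric(0))
  if (nrow(hx) == 0L) return(empty)
  scb <- sidechainMainchainHBonds(s, config$hbondCutoff)
  out <- list()
  for (k in seq_len(nrow(hx))) {
    if (hx$capClass[k] != "alpha") next
    ch <- hx$chain[k]; cap <- hx$ncapResno[k]
    aa <- residueTable(s)
    aa <- aa$resid[aa$chain == ch & aa$resno == cap][1]
    category <- if (aa %in% c("ASN", "ASP")) "ND"
                else if (aa %in% c("SER", "THR")) "ST"
                else "other"
    dh <- backboneDihedrals(s, ch, cap)
    cluster <- if (.inBox(dh$phi, dh$psi, config$primaryBox)) "primary"
               else if (.inBox(dh$phi, dh$psi, config$secondaryBox)) "secondary"
               else next
    b <- .maxB(s, ch, cap)
    if (is.na(b) || b >= config$bMaxCap) next
    hbE <- hbL <- NA_real_
    if (category %in% c("ND", "ST")) {
      r3 <- .resAtOffset(s, ch, cap, 3L)
      r2 <- .resAtOffset(s, ch, cap, 2L)
      i3 <- scb$donorChain == ch & scb$donorResno == r3 &
        scb$acceptorChain == ch & scb$acceptorResno == cap
      i2 <- scb$donorChain == ch & scb$donorResno == r2 &
        scb$acceptorChain == ch & scb$acceptorResno == cap
      if (!any(i3) || any(i2)) next
      hbE <- min(scb$energy[i3]); hbL <- scb$lengthOH[i3][which.min(scb$energy[i3])]
    }
    out[[length(out) + 1L]] <- data.frame(
      chain = ch, resno = cap, aa = aa, category = category,
      cluster = cluster, phi = dh$phi, psi = dh$psi,
      hbEnergy = hbE, hbLength = hbL, maxB = b, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Find mid-helix control residues
#'
#' Central residues of long helices used as a neutral-backbone reference
#' population: strictly alpha-helical phi/psi (between (-65,-45) and
#' (-55,-35)), at least `midhelixFlank` H-labelled residues on each side,
#' at least `midhelixTotalH` H-labelled residues in the helix, and a
#' maximum B-factor of `bMaxMidhelix`.
#'
#' @inheritParams findNcapMotifs
#' @return data.frame like [findNcapMotifs()] with `category "midhelix"`.
#' @export
findMidhelixControls <- function(s, config = motifConfig(), annotation = NULL) {
  if (is.null(annotation)) annotation <- annotateHelices(s, config)
  res <- annotation$residues
  hx <- annotation$helices
  out <- list()
  for (k in seq_len(nrow(hx))) {
    ch <- hx$chain[k]
    span <- which(res$chain == ch & res$resno >= hx$ncapResno[k] &
                    res$resno <= hx$endResno[k])
    hIdx <- span[res$hLabel[span]]
    if (length(hIdx) < config$midhelixTotalH) next
    for (p in hIdx) {
      before <- sum(res$hLabel[span][span < p])
      after <- sum(res$hLabel[span][span > p])
      if (before < config$midhelixFlank || after < config$midhelixFlank) next
      rn <- res$resno[p]
      dh <- backboneDihedrals(s, ch, rn)
      if (!.inBox(dh$phi, dh$psi, config$midhelixBox)) next
      b <- .maxB(s, ch, rn)
      if (is.na(b) || b > config$bMaxMidhelix) next
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, resno = rn, aa = res$resid[p], category = "midhelix",
        cluster = NA_character_, phi = dh$phi, psi = dh$psi,
        hbEnergy = NA_real_, hbLength = NA_real_, maxB = b,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chain = character(0), resno = integer(0), aa = character(0),
                  category = character(0), cluster = character(0),
                  phi = numeric(0), psi = numeric(0), hbEnergy = numeric(0),
                  hbLength = numeric(0), maxB = numeric(0))
}

#' Antiparallel beta-bridge annotation
#'
#' DSSP-style antiparallel bridges from the mainchain H-bond list: residues
#' i, j (|i-j| > 2) bridge when either both `i -> j` and `j -> i` donor
#' bonds exist, or both `i-1 -> j+1` and `j-1 -> i+1` exist.
#'
#' @inheritParams findNcapMotifs
#' @return list with `bridges` (data.frame `chainI`, `resnoI`, `chainJ`,
#'   `resnoJ`, `narrow` flag) and `isBeta` per-residue logical, aligned with
#'   [residueTable()].
#' @export
betaBridges <- function(s, config = motifConfig()) {
  rt <- residueTable(s)
  n <- nrow(rt)
  hb <- mainchainHBonds(s, config$hbondCutoff)
  pos <- function(ch, rn) {
    i <- which(rt$chain == ch & rt$resno == rn)
    if (length(i)) i[1] else NA_integer_
  }
  don <- vapply(seq_len(nrow(hb)), function(k) pos(hb$donorChain[k], hb$donorResno[k]), integer(1))
  acc <- vapply(seq_len(nrow(hb)), function(k) pos(hb$acceptorChain[k], hb$acceptorResno[k]), integer(1))
  bond <- matrix(FALSE, n, n)     # bond[i, j]: N-H(i) donates to O(j)
  ok <- !is.na(don) & !is.na(acc)
  bond[cbind(don[ok], acc[ok])] <- TRUE
  bridges <- list()
  isBeta <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i + 2L) next
    narrow <- bond[i, j] && bond[j, i]
    wide <- i > 1L && j < n && bond[i - 1L, j + 1L] && bond[j - 1L, i + 1L]
    if (narrow || wide) {
      isBeta[c(i, j)] <- TRUE
      bridges[[length(bridges) + 1L]] <- data.frame(
        chainI = rt$chain[i], resnoI = rt$resno[i],
        chainJ = rt$chain[j], resnoJ = rt$resno[j],
        narrow = narrow, stringsAsFactors = FALSE)
    }
  }
  list(bridges = if (length(bridges)) do.call(rbind, bridges)
       else data.frame(chainI = character(0), resnoI = integer(0),
                       chainJ = character(0), resnoJ = integer(0),
                       narrow = logical(0)),
       isBeta = isBeta)
}

#' Fray statistic for an aromatic/opposite strand pair
#'
#' Strand-pair irregularity near residue `i` (aromatic strand) and its
#' opposite residue `j`:
#' `t_N = torsion(CA_a(i-1), CA_a(i), CA_o(j), CA_o(j+1))` (N-ward twist),
#' `t_C = torsion(CA_a(i+1), CA_a(i), CA_o(j), CA_o(j-1))` (C-ward twist),
#' `p_a`, `p_o` the Calpha(i-1), i, i+1 planar angles on each strand, and
#' `f = |t_N - t_C| - |p_a - p_o|` (the pleat difference subtracted as a
#' correction term; set `config$fraySigned` for the signed alternate form
#' `(t_N - t_C) - (p_a - p_o)`).
#'
#' @param s a [Structure-class].
#' @param aromatic,opposite lists `list(chain =, resno =)` naming the two
#'   residues.
#' @param config list from [motifConfig()].
#' @return named numeric: `tN`, `tC`, `pA`, `pO`, `fray` (degrees), or
#'   `NA`s when a flanking Calpha is missing (strand end).
#' @export
computeFray <- function(s, aromatic, opposite, config = motifConfig()) {
  gca <- function(ref, off) {
    rn <- .resAtOffset(s, ref$chain, ref$resno, off)
    if (is.na(rn)) return(NULL)
    .atomXYZ(s, ref$chain, rn, "CA")
  }
  aM <- gca(aromatic, -1L); a0 <- gca(aromatic, 0L); aP <- gca(aromatic, 1L)
  oM <- gca(opposite, -1L); o0 <- gca(opposite, 0L); oP <- gca(opposite, 1L)
  if (any(vapply(list(aM, a0, aP, oM, o0, oP), is.null, logical(1))))
    return(c(tN = NA_real_, tC = NA_real_, pA = NA_real_, pO = NA_real_,
             fray = NA_real_))
  tN <- torsionAngle(aM, a0, o0, oP)
  tC <- torsionAngle(aP, a0, o0, oM)
  pA <- vecAngle(aM, a0, aP)
  pO <- vecAngle(oM, o0, oP)
  f <- if (isTRUE(config$fraySigned)) (tN - tC) - (pA - pO)
       else abs(tN - tC) - abs(pA - pO)
  c(tN = tN, tC = tC, pA = pA, pO = pO, fray = f)
}

#' Find plus-chi1 aromatics opposite a partner in antiparallel beta-sheet
#'
#' Phe/Tyr residues with a `plus` chi1 rotamer (0-120 degrees) in
#' antiparallel beta-sheet, whose opposite residue (the one between the
#' narrow pair of mainchain H-bonds, i.e. whose N and O both H-bond the
#' aromatic's O and N) is identified from the bond list.  Requires at
#' least one additional beta residue in each direction on both strands, a
#' maximum non-hydrogen B-factor below the limit on both residues, and
#' fray below the configured limit.  A Pro opposite cannot supply both
#' bonds and is rejected by construction.
#'
#' @inheritParams findNcapMotifs
#' @return data.frame, one row per hit: `chain`, `resno`, `aa`,
#'   `oppositeChain`, `oppositeResno`, `oppositeAA`, `category`
#'   (`"gly"`/`"other"`), `chi1`, `tN`, `tC`, `pA`, `pO`, `fray`, `maxB`.
#' @export
findBetaAromaticMotifs <- function(s, config = motifConfig()) {
  rt <- residueTable(s)
  bb <- betaBridges(s, config)
  empty <- data.frame(chain = character(0), resno = integer(0),
                      aa = character(0), oppositeChain = character(0),
                      oppositeResno = integer(0), oppositeAA = character(0),
                      category = character(0), chi1 = numeric(0),
                      tN = numeric(0), tC = numeric(0), pA = numeric(0),
                      pO = numeric(0), fray = numeric(0), maxB = numeric(0))
  br <- bb$bridges[bb$bridges$narrow, , drop = FALSE]
  if (nrow(br) == 0L) return(empty)
  isBetaAt <- function(ch, rn) {
    p <- which(rt$chain == ch & rt$resno == rn)
    length(p) == 1L && bb$isBeta[p]
  }
  out <- list()
  for (k in seq_len(nrow(rt))) {
    if (!(rt$resid[k] %in% c("PHE", "TYR"))) next
    if (!bb$isBeta[k]) next
    ch <- rt$chain[k]; rn <- rt$resno[k]
    chi1 <- backboneDihedrals(s, ch, rn)$chi1
    if (is.na(chi1) || classifyChi1(chi1) != "plus") next
    ## opposite: narrow-pair partner
    mk <- (br$chainI == ch & br$resnoI == rn)
    mk2 <- (br$chainJ == ch & br$resnoJ == rn)
    partners <- rbind(
      data.frame(chain = br$chainJ[mk], resno = br$resnoJ[mk]),
      data.frame(chain = br$chainI[mk2], resno = br$resnoI[mk2]))
    if (nrow(partners) == 0L) next
    if (nrow(partners) > 1L) {
      ## disambiguate toward the aromatic sidechain: nearest CB - CA(opp)
      cb <- .atomXYZ(s, ch, rn, "CB")
      d <- vapply(seq_len(nrow(partners)), function(q) {
        ca <- .atomXYZ(s, partners$chain[q], partners$resno[q], "CA")
        if (is.null(ca) || is.null(cb)) Inf else .vnorm(ca - cb)
      }, numeric(1))
      partners <- partners[which.min(d), , drop = FALSE]
    }
    och <- partners$chain[1]; orn <- partners$resno[1]
    oaa <- rt$resid[rt$chain == och & rt$resno == orn][1]
    ## flanking beta residues on both strands
    flanks <- c(.resAtOffset(s, ch, rn, -1L), .resAtOffset(s, ch, rn, 1L))
    oflanks <- c(.resAtOffset(s, och, orn, -1L), .resAtOffset(s, och, orn, 1L))
    if (any(is.na(c(flanks, oflanks)))) next
    if (!all(vapply(flanks, function(r) isBetaAt(ch, r), logical(1)))) next
    if (!all(vapply(oflanks, function(r) isBetaAt(och, r), logical(1)))) next
    bA <- .maxB(s, ch, rn); bO <- .maxB(s, och, orn)
    if (is.na(bA) || is.na(bO) || max(bA, bO) >= config$bMaxBeta) next
    fr <- computeFray(s, list(chain = ch, resno = rn),
                      list(chain = och, resno = orn), config)
    if (is.na(fr["fray"]) || fr["fray"] >= config$frayLimit) next
    out[[length(out) + 1L]] <- data.frame(
      chain = ch, resno = rn, aa = rt$resid[k], oppositeChain = och,
      oppositeResno = orn, oppositeAA = oaa,
      category = if (identical(oaa, "GLY")) "gly" else "other",
      chi1 = chi1, tN = fr["tN"], tC = fr["tC"], pA = fr["pA"],
      pO = fr["pO"], fray = fr["fray"], maxB = max(bA, bO),
      stringsAsFactors = FALSE)
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else empty
}

#' Amino-acid propensities at motif positions
#'
#' `propensity(aa) = fraction of motif residues of type aa / fraction of
#' background residues of type aa`; undefined (NA) when the type is absent
#' from the background.
#'
#' @param motifAA character vector of 3-letter codes at the motif position
#'   (or a list of [Structure-class]s whose residues are pooled).
#' @param backgroundAA character vector (or structure list) for the
#'   background.
#' @return data.frame: `aa`, `motifFreq`, `backgroundFreq`, `propensity`.
#' @export
aminoAcidPropensity <- function(motifAA, backgroundAA) {
  toAA <- function(x) {
    if (is.list(x)) x <- unlist(lapply(x, function(s) residueTable(s)$resid))
    if (is(x, "Structure")) x <- residueTable(x)$resid
    toupper(x)
  }
  m <- toAA(motifAA); b <- toAA(backgroundAA)
  if (length(m) == 0L || length(b) == 0L) stop("empty residue set")
  aa <- sort(unique(c(m, b)))
  mf <- as.numeric(table(factor(m, aa))) / length(m)
  bf <- as.numeric(table(factor(b, aa))) / length(b)
  data.frame(aa = aa, motifFreq = mf, backgroundFreq = bf,
             propensity = ifelse(bf > 0, mf / bf, NA_real_))
}

#' Rank-sum comparison of propensity groups
#'
#' Convenience wrapper for a one-tailed Mann-Whitney (Wilcoxon rank-sum)
#' test that the values of the residues in `inGroup` exceed the rest.
#'
#' @param values numeric vector (e.g. propensity differences).
#' @param inGroup logical vector marking the group of interest.
#' @return the `htest` object from [stats::wilcox.test()].
#' @export
propensityRankSum <- function(values, inGroup) {
  wilcox.test(values[inGroup], values[!inGroup], alternative = "greater",
              exact = TRUE)
}
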