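## Molecular-mechanics parameter tables for the design energy function:
## ff94-era partial charges and 12-6 Lennard-Jones types, plus
## Lazaridis-Karplus EEF1 per-atom solvation parameters for heavy atoms.
## Coverage is the residue set the builder can construct; unknown atoms
## raise an error naming the atom type.

## per-(residue, atom) charge (e) and LJ type
.chargeRow <- function(resid, elety, q, type, eef = NA_character_)
  data.frame(resid = resid, elety = elety, q = q, type = type, eef = eef,
             stringsAsFactors = FALSE)

.bbCharges <- function(resid, qCA, qHA, eefCA = "CH1E") rbind(
  .chargeRow(resid, "N", -0.4157, "N", "NH1"),
  .chargeRow(resid, "H", 0.2719, "H"),
  .chargeRow(resid, "CA", qCA, "CT", eefCA),
  .chargeRow(resid, "HA", qHA, "H1"),
  .chargeRow(resid, "C", 0.5973, "C", "C"),
  .chargeRow(resid, "O", -0.5679, "O", "O"))

.CHARGES <- rbind(
  rbind(.chargeRow("GLY", "N", -0.4157, "N", "NH1"),
        .chargeRow("GLY", "H", 0.2719, "H"),
        .chargeRow("GLY", "CA", -0.0252, "CT", "CH2E"),
        .chargeRow("GLY", "HA2", 0.0698, "H1"),
        .chargeRow("GLY", "HA3", 0.0698, "H1"),
        .chargeRow("GLY", "C", 0.5973, "C", "C"),
        .chargeRow("GLY", "O", -0.5679, "O", "O")),
  rbind(.bbCharges("ALA", 0.0337, 0.0823),
        .chargeRow("ALA", "CB", -0.1825, "CT", "CH3E"),
        .chargeRow("ALA", "HB1", 0.0603, "HC"),
        .chargeRow("ALA", "HB2", 0.0603, "HC"),
        .chargeRow("ALA", "HB3", 0.0603, "HC")),
  rbind(.bbCharges("SER", -0.0249, 0.0843),
        .chargeRow("SER", "CB", 0.2117, "CT", "CH2E"),
        .chargeRow("SER", "HB2", 0.0352, "H1"),
        .chargeRow("SER", "HB3", 0.0352, "H1"),
        .chargeRow("SER", "OG", -0.6546, "OH", "OH1"),
        .chargeRow("SER", "HG", 0.4275, "HO")),
  rbind(.bbCharges("THR", -0.0389, 0.1007),
        .chargeRow("THR", "CB", 0.3654, "CT", "CH1E"),
        .chargeRow("THR", "HB", 0.0043, "H1"),
        .chargeRow("THR", "OG1", -0.6761, "OH", "OH1"),
        .chargeRow("THR", "HG1", 0.4102, "HO"),
        .chargeRow("THR", "CG2", -0.2438, "CT", "CH3E"),
        .chargeRow("THR", "HG21", 0.0642, "HC"),
        .chargeRow("THR", "HG22", 0.0642, "HC"),
        .chargeRow("THR", "HG23", 0.0642, "HC")),
  rbind(.bbCharges("ASN", 0.0143, 0.1048),
        .chargeRow("ASN", "CB", -0.2041, "CT", "CH2E"),
        .chargeRow("ASN", "HB2", 0.0797, "HC"),
        .chargeRow("ASN", "HB3", 0.0797, "HC"),
        .chargeRow("ASN", "CG", 0.7130, "C", "C"),
        .chargeRow("ASN", "OD1", -0.5931, "O", "O"),
        .chargeRow("ASN", "ND2", -0.9191, "N", "NH2"),
        .chargeRow("ASN", "HD21", 0.4196, "H"),
        .chargeRow("ASN", "HD22", 0.4196, "H")),
  rbind(.bbCharges("ASP", 0.0381, 0.0880),
        .chargeRow("ASP", "CB", -0.0303, "CT", "CH2E"),
        .chargeRow("ASP", "HB2", -0.0122, "HC"),
        .chargeRow("ASP", "HB3", -0.0122, "HC"),
        .chargeRow("ASP", "CG", 0.7994, "C", "C"),
        .chargeRow("ASP", "OD1", -0.8014, "O2", "OC"),
        .chargeRow("ASP", "OD2", -0.8014, "O2", "OC")),
  rbind(.bbCharges("PHE", -0.0024, 0.0978),
        .chargeRow("PHE", "CB", -0.0343, "CT", "CH2E"),
        .chargeRow("PHE", "HB2", 0.0295, "HC"),
        .chargeRow("PHE", "HB3", 0.0295, "HC"),
        .chargeRow("PHE", "CG", 0.0118, "CA", "CR"),
        .chargeRow("PHE", "CD1", -0.1256, "CA", "CR1E"),
        .chargeRow("PHE", "CD2", -0.1256, "CA", "CR1E"),
        .chargeRow("PHE", "HD1", 0.1330, "HA"),
        .chargeRow("PHE", "HD2", 0.1330, "HA"),
        .chargeRow("PHE", "CE1", -0.1704, "CA", "CR1E"),
        .chargeRow("PHE", "CE2", -0.1704, "CA", "CR1E"),
        .chargeRow("PHE", "HE1", 0.1430, "HA"),
        .chargeRow("PHE", "HE2", 0.1430, "HA"),
        .chargeRow("PHE", "CZ", -0.1072, "CA", "CR1E"),
        .chargeRow("PHE", "HZ", 0.1297, "HA")),
  rbind(.bbCharges("TYR", -0.0014, 0.0876),
        .chargeRow("TYR", "CB", -0.0152, "CT", "CH2E"),
        .chargeRow("TYR", "HB2", 0.0295, "HC"),
        .chargeRow("TYR", "HB3", 0.0295, "HC"),
        .chargeRow("TYR", "CG", -0.0011, "CA", "CR"),
        .chargeRow("TYR", "CD1", -0.1906, "CA", "CR1E"),
        .chargeRow("TYR", "CD2", -0.1906, "CA", "CR1E"),
        .chargeRow("TYR", "HD1", 0.1699, "HA"),
        .chargeRow("TYR", "HD2", 0.1699, "HA"),
        .chargeRow("TYR", "CE1", -0.2341, "CA", "CR1E"),
        .chargeRow("TYR", "CE2", -0.2341, "CA", "CR1E"),
        .chargeRow("TYR", "HE1", 0.1656, "HA"),
        .chargeRow("TYR", "HE2", 0.1656, "HA"),
        .chargeRow("TYR", "CZ", 0.3226, "C", "CR"),
        .chargeRow("TYR", "OH", -0.5579, "OH", "OH1"),
        .chargeRow("TYR", "HH", 0.3992, "HO"))
)

## LJ well parameters: rmin/2 (angstrom), well depth (kcal/mol)
.LJ <- data.frame(
  type = c("N", "H", "CT", "C", "CA", "O", "O2", "OH", "HO", "H1", "HC", "HA"),
  rmin2 = c(1.8240, 0.6000, 1.9080, 1.9080, 1.9080, 1.6612, 1.6612, 1.7210,
            0.0001, 1.3870, 1.4870, 1.4590),
  eps = c(0.17, 0.0157, 0.1094, 0.086, 0.086, 0.21, 0.21, 0.2104,
          0.0, 0.0157, 0.0157, 0.015),
  stringsAsFactors = FALSE)

## EEF1 group parameters: dGref, dGfree (kcal/mol), volume (angstrom^3),
## correlation length lambda and vdW radius R (angstrom)
.EEF1 <- data.frame(
  eef = c("C", "CR", "CR1E", "CH1E", "CH2E", "CH3E",
          "NH1", "NH2", "O", "OC", "OH1"),
  dGref = c(0.000, -0.890, 0.057, -0.187, 0.372, 1.089,
            -5.950, -5.450, -5.330, -10.000, -5.920),
  dGfree = c(0.00, -1.40, 0.08, -0.25, 0.52, 1.50,
             -8.90, -7.80, -5.85, -10.00, -6.70),
  volume = c(14.7, 8.3, 18.4, 23.7, 22.4, 30.0, 4.4, 11.2, 10.8, 10.8, 10.8),
  lambda = c(3.5, 3.5, 3.5, 3.5, 3.5, 3.5, 3.5, 3.5, 3.5, 6.0, 3.5),
  R = c(2.100, 2.100, 2.100, 2.365, 2.235, 2.165, 1.600, 1.600, 1.600,
        1.600, 1.600),
  stringsAsFactors = FALSE)

#' Design energy model
#'
#' Parameter container for [conformationEnergy()] and [enumerateGmec()]:
#' molecular-mechanics partial charges and 12-6 Lennard-Jones terms plus
#' the EEF1 pairwise implicit-solvation term.  The default dielectric is
#' distance-dependent, `epsilon(r) = 6 r`; 1-4 pairs are scaled by 1/1.2
#' (electrostatics) and 1/2 (van der Waals).  By default no nonbonded
#' cutoff is applied: on the small templates this model targets, a hard
#' unswitched cutoff introduces energy discontinuities of the same order
#' as the differences that decide the minimum; a finite `cutoff`
#' (angstrom, no switching) is available for larger systems.
#'
#' @param dielectric `"distance"` for `epsilon(r) = factor * r`, or
#'   `"constant"` for a fixed dielectric equal to `factor`.
#' @param factor dielectric factor/constant (default 6).
#' @param cutoff nonbonded cutoff in angstrom.
#' @param scale14elec,scale14vdw 1-4 interaction scale factors.
#' @param solvScale scale factor on the EEF1 solvation term (the design
#'   lineage this model follows halves it).
#' @param vdwRadiusScale multiplier on Lennard-Jones radii (slightly
#'   softened contacts, 0.95, as in the same lineage).
#' @return a list of class `"energyModel"`.
#' @export
energyModel <- function(dielectric = c("distance", "constant"), factor = 6,
                        cutoff = Inf, scale14elec = 1 / 1.2, scale14vdw = 0.5,
                        solvScale = 0.5, vdwRadiusScale = 0.95) {
  dielectric <- match.arg(dielectric)
  stopifnot(factor > 0, cutoff > 0, solvScale >= 0, vdwRadiusScale > 0)
  structure(list(dielectric = dielectric, factor = factor, cutoff = cutoff,
                 scale14elec = scale14elec, scale14vdw = scale14vdw,
                 solvScale = solvScale, vdwRadiusScale = vdwRadiusScale,
                 charges = .CHARGES, lj = .LJ, eef1 = .EEF1,
                 coulomb = 332.0636),
            class = "energyModel")
}

## per-atom parameter lookup for the atoms of a Structure
.atomParams <- function(s, model) {
  a <- s@atoms[!s@atoms$het & s@atoms$primary, , drop = FALSE]
  key <- paste(a$resid, a$elety)
  tkey <- paste(model$charges$resid, model$charges$elety)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    missing <- unique(key[is.na(idx)])
    stop("no energy parameters for atom type(s): ",
         paste(missing, collapse = ", "))
  }
  p <- model$charges[idx, ]
  lj <- model$lj[match(p$type, model$lj$type), ]
  out <- data.frame(q = p$q, rmin2 = lj$rmin2, eps = lj$eps,
                    eef = p$eef, stringsAsFactors = FALSE)
  e1 <- model$eef1[match(p$eef, model$eef1$eef), ]
  out$dGref <- e1$dGref; out$dGfree <- e1$dGfree
  out$volume <- e1$volume; out$lambda <- e1$lambda; out$Reef <- e1$R
  out$heavy <- !is.na(p$eef)
  out
}
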