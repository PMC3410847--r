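## shared fixtures, built once per test run

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

idealHelix12 <- function() cached("helix12", generateIdealHelix(12))

serTemplate <- function() cached("serTemplate", buildIdealNcapTemplate("SER"))
asnTemplate <- function() cached("asnTemplate", buildIdealNcapTemplate("ASN"))

glySheet <- function()
  cached("glySheet", generateIdealSheet(aromaticAA = "PHE", oppositeAA = "GLY"))

lysozymePath <- function() system.file("examples", "1dpx.pdb", package = "bio3d")

## the full Ser/Asn ideal N-cap design runs (shared by the design and
## acceptance tests; ~15 s once)
ncapDesignRuns <- function() cached("ncapRuns", {
  list(ser = enumerateGmec(serTemplate(), "A", 2, "SER", peptideResno = 4),
       asn = enumerateGmec(asnTemplate(), "A", 2, "ASN", peptideResno = 4))
})

## independent axis-angle rotation oracle (Rodrigues via explicit matrix),
## written separately from rotateAboutAxis
oracleRotate <- function(p, origin, axis, angleDeg) {
  k <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  drop(R %*% (p - origin)) + origin
}

## random rigid transform
randomRigid <- function() {
  ax <- rnorm(3); ang <- runif(1, -180, 180)
  k <- ax / sqrt(sum(ax^2)); th <- ang * pi / 180
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = rnorm(3, 0, 10))
}

atomXYZOf <- function(s, chain, resno, name) {
  a <- atoms(s)
  as.numeric(a[a$chain == chain & a$resno == resno & a$elety == name &
                 a$primary, c("x", "y", "z")][1, ])
}
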