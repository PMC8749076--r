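# Small geometry + sequence helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

## Dihedral angle (degrees, in (-180, 180]) defined by four points (rows or
## length-3 vectors). Standard IUPAC sign convention.
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  -rad2deg(atan2(y, x))
}

## Planar angle at p2 (degrees).
bond_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

aa_1to3 <- function(x) {
  out <- AA3[match(toupper(x), AA1)]
  if (anyNA(out)) stop("unknown one-letter amino-acid code: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

aa_3to1 <- function(x) {
  out <- AA1[match(toupper(x), AA3)]
  out[is.na(out)] <- "X"
  out
}

## Default polar alphabet used throughout the polarity analyses.

#' Polar amino-acid alphabet
#'
#' The set of one-letter codes treated as "polar" in the core-position census
#' and the conservation analysis. Defaults to the strongly polar residues
#' Asp, Glu, His, Arg, Lys, Gln and Asn.
#'
#' @param polar_set character vector of one-letter codes.
#' @return A character vector of class \code{polar_alphabet}.
#' @export
polar_alphabet <- function(polar_set = c("D", "E", "H", "R", "K", "Q", "N")) {
  polar_set <- toupper(polar_set)
  if (!all(polar_set %in% AA1))
    stop("polar_set must be a subset of the 20 standard one-letter codes")
  structure(unique(polar_set), class = "polar_alphabet")
}
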