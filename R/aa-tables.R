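#' @keywords internal
"_PACKAGE"

## Amino-acid reference tables used across the package.
## Hydrophobicity: Kyte-Doolittle scale. Volumes: mean residue volumes (A^3),
## Zamyatnin-style consensus values. Both are scorer constants, versioned via
## the scorer spec, not fitted quantities.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
         G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
         M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
         S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA3_TO_1 <- stats::setNames(names(AA3), unname(AA3))

KYTE_DOOLITTLE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

RESIDUE_VOLUME <- c(
  A =  88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
  G =  60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
  M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
  S =  89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6)

is_aa1 <- function(x) x %in% AA1

aa1_to_aa3 <- function(x) {
  out <- AA3[x]
  if (anyNA(out)) stop("unknown one-letter amino-acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

aa3_to_aa1 <- function(x) {
  out <- AA3_TO_1[x]
  out[is.na(out)] <- NA_character_
  unname(out)
}
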