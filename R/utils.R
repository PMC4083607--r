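# Alphabet constants used across the package.  Feature vectors and the
# dipeptide composition use the alphabetical one-letter order; the PSSM
# block uses the blastpgp column order.
aa_standard <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

aa_nonstandard <- c("B", "Z", "X", "U", "O")

pssm_columns <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

aa_three <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR",
              B = "ASX", Z = "GLX", X = "UNK", U = "SEC", O = "PYL")

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "cbep_format_error")
}

stop_length <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "cbep_length_error")
}

# Run `code` under a fixed RNG state when `seed` is given, leaving the
# caller's RNG untouched; with seed = NULL the global stream is used.
with_seed_or_global <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Child seeds for independent stages, kept inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + offset) %% .Machine$integer.max)
}

euclidean <- function(a, b) sqrt(sum((a - b)^2))

# Max pairwise distance within a coordinate block (0 for a single point).
coord_diameter <- function(coords) {
  if (nrow(coords) < 2) return(0)
  max(dist(coords))
}
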