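#' Physicochemical residue scales
#'
#' Loads a table of per-amino-acid physicochemical scales and min-max
#' normalizes each scale to \[0, 1\]. The default table ships six standard
#' published scales commonly used in epitope prediction: Parker
#' hydrophilicity, Karplus-Schulz flexibility, Emini surface accessibility,
#' Grantham polarity, Janin accessible surface area, and Chou-Fasman
#' beta-turn propensity. The file is a plain TSV (column `aa` plus one
#' column per scale) so alternative scales can be dropped in.
#'
#' Non-standard residues (B, Z, X, U, O) are not listed; they receive the
#' value 0 on every scale during feature encoding.
#'
#' @param path Path to a scales TSV. Defaults to the table shipped with the
#'   package.
#' @return A tibble with column `aa` (the 20 standard one-letter codes) and
#'   one numeric column per scale, each spanning exactly \[0, 1\].
#' @export
#' @examples
#' sc <- default_scales()
#' range(sc$hydrophilicity)
default_scales <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "physicochemical_scales.tsv", package = "cbep")
  raw <- as_tibble(read.delim(path, check.names = FALSE))
  if (!"aa" %in% names(raw)) {
    stop_format("scales file '%s' lacks an 'aa' column", path)
  }
  missing <- setdiff(aa_standard, raw$aa)
  if (length(missing) > 0) {
    stop_format("scales file '%s' lacks residues: %s",
                path, paste(missing, collapse = ", "))
  }
  raw <- raw[match(aa_standard, raw$aa), , drop = FALSE]
  dplyr::mutate(raw, dplyr::across(
    dplyr::where(is.numeric),
    function(v) (v - min(v)) / (max(v) - min(v))
  ))
}

# Residue-by-scale matrix for a sequence; non-standard letters get 0.
scale_rows <- function(sequence, scales) {
  letters_ <- seq_chars(sequence)
  mat <- as.matrix(scales[, setdiff(names(scales), "aa"), drop = FALSE])
  rownames(mat) <- scales$aa
  idx <- match(letters_, rownames(mat))
  out <- matrix(0, nrow = length(letters_), ncol = ncol(mat),
                dimnames = list(NULL, colnames(mat)))
  ok <- !is.na(idx)
  out[ok, ] <- mat[idx[ok], , drop = FALSE]
  out
}
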