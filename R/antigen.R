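#' Antigen chain records
#'
#' An `antigen_record` bundles everything known about one antigen chain:
#' its sequence, optional per-residue epitope annotation, optional C-alpha
#' coordinates, and the per-residue profiles (PSSM, secondary structure,
#' disorder) used for feature encoding. All per-residue components must
#' match the sequence length, and the binary labels must agree with the
#' epitope membership vector when both are present.
#'
#' @param id Chain identifier string.
#' @param sequence Amino-acid string. Uppercased; the 20 standard letters
#'   plus B, Z, X, U, O are accepted (non-standard letters are retained so
#'   indexing stays aligned with external profile files, but are skipped in
#'   dipeptide counting and scored 0 on physicochemical scales).
#' @param labels Optional integer vector in \{0, 1\}; 1 marks an antigenic
#'   determinant residue.
#' @param epitope_ids Optional integer vector; 0 = not in an epitope,
#'   k > 0 = member of observed epitope k. When given without `labels`,
#'   labels are derived as `epitope_ids > 0`.
#' @param coords Optional numeric L x 3 matrix of C-alpha coordinates (.
#' @param pssm Optional L x 20 integer matrix of raw PSSM scores in
#'   blastpgp column order (see [read_pssm()]).
#' @param ss2 Optional L x 3 matrix of secondary-structure probabilities
#'   with columns helix, coil, strand (see [read_ss2()]).
#' @param disorder Optional length-L vector in \{0, 1\} (see
#'   [read_disorder()]).
#' @return An object of class `antigen_record`.
#' @export
#' @examples
#' rec <- antigen_record("demo", "ACDEFG",
#'                       epitope_ids = c(0L, 1L, 1L, 0L, 0L, 0L))
#' rec$labels
antigen_record <- function(id, sequence, labels = NULL, epitope_ids = NULL,
                           coords = NULL, pssm = NULL, ss2 = NULL,
                           disorder = NULL) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  if (len == 0) stop_format("record '%s': empty sequence", id)
  bad <- setdiff(unique(seq_chars(sequence)), c(aa_standard, aa_nonstandard))
  if (length(bad) > 0) {
    stop_format("record '%s': illegal sequence characters: %s",
                id, paste(bad, collapse = ", "))
  }

  check_len <- function(x, what, n = len) {
    rows <- if (is.matrix(x) || is.data.frame(x)) nrow(x) else length(x)
    if (rows != n) {
      stop_length("record '%s': %s has %d rows, sequence has %d residues",
                  id, what, rows, n)
    }
  }

  if (!is.null(epitope_ids)) {
    check_len(epitope_ids, "epitope_ids")
    epitope_ids <- as.integer(epitope_ids)
    if (any(epitope_ids < 0)) stop_format("record '%s': negative epitope id", id)
    if (is.null(labels)) labels <- as.integer(epitope_ids > 0)
  }
  if (!is.null(labels)) {
    check_len(labels, "labels")
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) {
      stop_format("record '%s': labels must be 0/1", id)
    }
    if (!is.null(epitope_ids) && !all((labels == 1L) == (epitope_ids > 0L))) {
      stop_format("record '%s': labels disagree with epitope_ids", id)
    }
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    check_len(coords, "coords")
    stopifnot(ncol(coords) == 3)
    colnames(coords) <- c("x", "y", "z")
  }
  if (!is.null(pssm)) {
    pssm <- as.matrix(pssm)
    check_len(pssm, "pssm")
    stopifnot(ncol(pssm) == 20)
    colnames(pssm) <- pssm_columns
  }
  if (!is.null(ss2)) {
    ss2 <- as.matrix(ss2)
    check_len(ss2, "ss2")
    stopifnot(ncol(ss2) == 3)
    colnames(ss2) <- c("helix", "coil", "strand")
    if (any(ss2 < 0 | ss2 > 1)) {
      stop_format("record '%s': ss2 probabilities outside [0, 1]", id)
    }
  }
  if (!is.null(disorder)) {
    check_len(disorder, "disorder")
    disorder <- as.integer(disorder)
    if (!all(disorder %in% c(0L, 1L))) {
      stop_format("record '%s': disorder values must be 0/1", id)
    }
  }

  structure(
    list(id = id, sequence = sequence, labels = labels,
         epitope_ids = epitope_ids, coords = coords,
         pssm = pssm, ss2 = ss2, disorder = disorder),
    class = "antigen_record"
  )
}

#' @export
print.antigen_record <- function(x, ...) {
  cat(sprintf("<antigen_record '%s': %d residues>\n", x$id, nchar(x$sequence)))
  have <- c(labels = !is.null(x$labels), coords = !is.null(x$coords),
            pssm = !is.null(x$pssm), ss2 = !is.null(x$ss2),
            disorder = !is.null(x$disorder))
  cat("  components:", paste(names(have)[have], collapse = ", "), "\n")
  if (!is.null(x$labels)) {
    cat(sprintf("  %d antigenic determinant residues (%.1f%%)\n",
                sum(x$labels), 100 * mean(x$labels)))
  }
  invisible(x)
}

#' Per-residue view of an antigen record
#'
#' @param record An [antigen_record()].
#' @return A tibble with one row per residue: `chain`, `residue` (1-based),
#'   `aa`, plus `label`, `epitope_id` and `x`, `y`, `z` when present.
#' @export
residues <- function(record) {
  stopifnot(inherits(record, "antigen_record"))
  out <- tibble(chain = record$id,
                residue = seq_len(nchar(record$sequence)),
                aa = seq_chars(record$sequence))
  if (!is.null(record$labels)) out$label <- record$labels
  if (!is.null(record$epitope_ids)) out$epitope_id <- record$epitope_ids
  if (!is.null(record$coords)) {
    out$x <- record$coords[, 1]
    out$y <- record$coords[, 2]
    out$z <- record$coords[, 3]
  }
  out
}
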