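#' Read antigen sequences from a FASTA file
#'
#' Parses a FASTA file into a list of [antigen_record()]s. Sequences are
#' uppercased; the 20 standard residues plus B, Z, X, U, O are accepted and
#' any other letter is a format error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A list of [antigen_record()]s, in file order. Record ids are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_format("cannot parse FASTA '%s': %s",
                                    path, conditionMessage(e))
  )
  if (length(set) == 0) stop_format("FASTA '%s' contains no records", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop_format("FASTA '%s': duplicate record ids: %s",
                path, paste(dup, collapse = ", "))
  }
  purrr::map2(ids, as.character(set),
              function(id, seq) antigen_record(id, seq))
}

# Shared line scanner: returns non-empty, non-comment lines with their
# original line numbers so format errors can point at the file.
numbered_lines <- function(path, comment = "#") {
  if (!file.exists(path)) stop_format("file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment)
  tibble(n = which(keep), text = trimws(lines[keep]))
}

#' Read a blastpgp ASCII PSSM
#'
#' Parses the ASCII matrix blastpgp writes with `-Q`: header lines followed
#' by one row per residue carrying the position, the residue letter, 20
#' log-odds integers (the raw scores used here), 20 weighted-percentage
#' columns and two information columns. Only the first 20 numeric columns
#' are retained.
#'
#' @param path Path to the PSSM file.
#' @param expected_length Sequence length the matrix must match.
#' @return An integer `expected_length` x 20 matrix with columns in the
#'   blastpgp order (A R N D C Q E G H I L K M F P S T W Y V) and a
#'   `residues` attribute holding the per-row letters.
#' @export
read_pssm <- function(path, expected_length) {
  lines <- numbered_lines(path)
  is_row <- grepl("^\\d+\\s+[A-Z]\\s+-?\\d", lines$text)
  rows <- lines[is_row, ]
  if (nrow(rows) == 0) stop_format("PSSM '%s': no matrix rows found", path)
  parsed <- purrr::map2(rows$text, rows$n, function(text, n) {
    toks <- strsplit(text, "\\s+")[[1]]
    if (length(toks) < 22 ||
        anyNA(suppressWarnings(as.integer(toks[3:22])))) {
      stop_format("PSSM '%s' line %d: expected 20 integer scores", path, n)
    }
    list(letter = toks[2], scores = as.integer(toks[3:22]))
  })
  if (length(parsed) != expected_length) {
    stop_length("PSSM '%s' has %d rows, expected %d",
                path, length(parsed), expected_length)
  }
  mat <- do.call(rbind, purrr::map(parsed, "scores"))
  colnames(mat) <- pssm_columns
  attr(mat, "residues") <- vapply(parsed, `[[`, character(1), "letter")
  mat
}

#' Read a PSIPRED .ss2 secondary-structure profile
#'
#' Parses PSIPRED VFORMAT output: comment/blank header lines, then one row
#' per residue with position, letter, predicted state and the coil, helix
#' and strand probabilities.
#'
#' @param path Path to the .ss2 file.
#' @param expected_length Sequence length the profile must match.
#' @return A numeric `expected_length` x 3 matrix with columns `helix`,
#'   `coil`, `strand`, each value in \[0, 1\].
#' @export
read_ss2 <- function(path, expected_length) {
  lines <- numbered_lines(path)
  parsed <- purrr::map2(lines$text, lines$n, function(text, n) {
    toks <- strsplit(text, "\\s+")[[1]]
    probs <- suppressWarnings(as.numeric(toks[4:6]))
    if (length(toks) < 6 || anyNA(probs)) {
      stop_format(".ss2 '%s' line %d: expected pos/letter/state + 3 probabilities",
                  path, n)
    }
    probs  # file order: coil, helix, strand
  })
  if (length(parsed) != expected_length) {
    stop_length(".ss2 '%s' has %d rows, expected %d",
                path, length(parsed), expected_length)
  }
  raw <- do.call(rbind, parsed)
  if (any(raw < 0 | raw > 1)) {
    stop_format(".ss2 '%s': probabilities outside [0, 1]", path)
  }
  mat <- cbind(helix = raw[, 2], coil = raw[, 1], strand = raw[, 3])
  mat
}

#' Read a DISOPRED disorder profile
#'
#' Parses DISOPRED plain output: one row per residue with position, letter,
#' a disorder mark (`*` disordered, `.` ordered) and a confidence value.
#'
#' @param path Path to the disorder file.
#' @param expected_length Sequence length the profile must match.
#' @return An integer vector of length `expected_length` in \{0, 1\}
#'   (1 = disordered).
#' @export
read_disorder <- function(path, expected_length) {
  lines <- numbered_lines(path)
  marks <- purrr::map2_chr(lines$text, lines$n, function(text, n) {
    toks <- strsplit(text, "\\s+")[[1]]
    if (length(toks) < 3 || !toks[3] %in% c("*", ".")) {
      stop_format("disorder file '%s' line %d: expected pos/letter/mark",
                  path, n)
    }
    toks[3]
  })
  if (length(marks) != expected_length) {
    stop_length("disorder file '%s' has %d rows, expected %d",
                path, length(marks), expected_length)
  }
  as.integer(marks == "*")
}

#' Read C-alpha coordinates for one chain of a PDB file
#'
#' Extracts ATOM/CA records for a chain via [bio3d::read.pdb()], keeping
#' the first altloc of each residue and ordering residues by author residue
#' number (insertion codes lexicographically). The mapping from sequence
#' position to author numbering is attached so callers can audit it.
#'
#' @param path Path to a PDB file.
#' @param chain_id Chain identifier to extract.
#' @return A numeric L x 3 coordinate matrix (columns x, y, z, in Angstrom)
#'   with a `mapping` attribute: a tibble of `residue` (1-based sequence
#'   position), `resno` and `insert`.
#' @export
read_ca_coords <- function(path, chain_id) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA" & at$chain == chain_id, ,
           drop = FALSE]
  if (nrow(at) == 0) {
    stop_format("PDB '%s': no CA atoms for chain '%s'", path, chain_id)
  }
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at <- at[order(at$resno, at$insert), , drop = FALSE]
  key <- paste(at$resno, at$insert)
  at <- at[!duplicated(key), , drop = FALSE]  # first altloc wins
  coords <- as.matrix(at[, c("x", "y", "z")])
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  attr(coords, "mapping") <- tibble(residue = seq_len(nrow(at)),
                                    resno = at$resno, insert = at$insert)
  coords
}

#' Read a residue-level epitope annotation table
#'
#' The annotation format is a TSV with columns `chain_id`,
#' `residue_index` (1-based) and `epitope_id` (> 0); residues not listed
#' are non-epitope.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `chain_id`, `residue_index`, `epitope_id`.
#' @export
read_epitope_annotations <- function(path) {
  tab <- as_tibble(read.delim(path))
  need <- c("chain_id", "residue_index", "epitope_id")
  if (!all(need %in% names(tab))) {
    stop_format("annotation file '%s' must have columns %s",
                path, paste(need, collapse = ", "))
  }
  if (any(tab$epitope_id <= 0) || any(tab$residue_index <= 0)) {
    stop_format("annotation file '%s': indices and epitope ids must be positive",
                path)
  }
  tab[need]
}

#' Attach epitope annotations to an antigen record
#'
#' @param record An [antigen_record()].
#' @param annotations A tibble as returned by [read_epitope_annotations()].
#' @return The record with `epitope_ids` and `labels` filled in.
#' @export
apply_annotations <- function(record, annotations) {
  stopifnot(inherits(record, "antigen_record"))
  len <- nchar(record$sequence)
  rows <- annotations[annotations$chain_id == record$id, , drop = FALSE]
  if (any(rows$residue_index > len)) {
    stop_length("annotations for chain '%s' reference residues beyond length %d",
                record$id, len)
  }
  epi <- integer(len)
  epi[rows$residue_index] <- as.integer(rows$epitope_id)
  antigen_record(record$id, record$sequence, epitope_ids = epi,
                 coords = record$coords, pssm = record$pssm,
                 ss2 = record$ss2, disorder = record$disorder)
}
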