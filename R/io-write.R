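#' Write antigen sequences to FASTA
#'
#' @param records A list of [antigen_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(
    setNames(vapply(records, `[[`, character(1), "sequence"),
             vapply(records, `[[`, character(1), "id"))
  )
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a raw PSSM matrix in the blastpgp ASCII dialect
#'
#' Emits the header, the duplicated column-letter line and one row per
#' residue with the 20 integer scores, zeroed percentage columns and
#' zeroed information columns, so that [read_pssm()] round-trips the
#' scores exactly.
#'
#' @param pssm Integer L x 20 matrix in blastpgp column order.
#' @param sequence The chain's amino-acid string (length L).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, sequence, path) {
  letters_ <- seq_chars(sequence)
  stopifnot(nrow(pssm) == length(letters_), ncol(pssm) == 20)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("          ",
           paste(sprintf("%3s", pssm_columns), collapse = ""),
           " ",
           paste(sprintf("%3s", pssm_columns), collapse = ""))
  ), con)
  for (i in seq_along(letters_)) {
    writeLines(sprintf(
      "%5d %s  %s %s  %4.2f %8.2f",
      i, letters_[i],
      paste(sprintf("%3d", pssm[i, ]), collapse = " "),
      paste(sprintf("%3d", integer(20)), collapse = " "),
      0, 0
    ), con)
  }
  invisible(path)
}

#' Write a secondary-structure profile in PSIPRED .ss2 VFORMAT
#'
#' @param ss2 Numeric L x 3 matrix with columns `helix`, `coil`, `strand`.
#' @param sequence The chain's amino-acid string.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss2 <- function(ss2, sequence, path) {
  letters_ <- seq_chars(sequence)
  stopifnot(nrow(ss2) == length(letters_), ncol(ss2) == 3)
  state <- c("H", "C", "E")[max.col(ss2, ties.method = "first")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# PSF format file generated by cbep", ""), con)
  for (i in seq_along(letters_)) {
    writeLines(sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                       i, letters_[i], state[i],
                       ss2[i, "coil"], ss2[i, "helix"], ss2[i, "strand"]),
               con)
  }
  invisible(path)
}

#' Write a disorder profile in the DISOPRED plain dialect
#'
#' @param disorder Integer vector in \{0, 1\} (1 = disordered).
#' @param sequence The chain's amino-acid string.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disorder <- function(disorder, sequence, path) {
  letters_ <- seq_chars(sequence)
  stopifnot(length(disorder) == length(letters_))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#         ----- DISOPRED version 3 -----", con)
  for (i in seq_along(letters_)) {
    writeLines(sprintf("%5d %s %s %5.2f",
                       i, letters_[i],
                       if (disorder[i] == 1) "*" else ".",
                       if (disorder[i] == 1) 0.9 else 0.1),
               con)
  }
  invisible(path)
}

#' Write C-alpha coordinates as a minimal PDB file
#'
#' Emits one ATOM/CA record per residue using the chain's sequence for
#' residue names and 1-based author numbering, terminated by TER/END.
#'
#' @param coords Numeric L x 3 coordinate matrix (Angstrom).
#' @param sequence The chain's amino-acid string.
#' @param chain_id One-character chain identifier for the PDB records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(coords, sequence, chain_id, path) {
  letters_ <- seq_chars(sequence)
  stopifnot(nrow(coords) == length(letters_), nchar(chain_id) == 1)
  res3 <- unname(aa_three[letters_])
  res3[is.na(res3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(letters_), res3, chain_id, seq_along(letters_),
    coords[, 1], coords[, 2], coords[, 3]
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Write a residue-level epitope annotation table
#'
#' @param records A list of annotated [antigen_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epitope_annotations <- function(records, path) {
  tab <- purrr::map_dfr(records, function(rec) {
    if (is.null(rec$epitope_ids)) return(NULL)
    idx <- which(rec$epitope_ids > 0)
    tibble(chain_id = rec$id, residue_index = idx,
           epitope_id = rec$epitope_ids[idx])
  })
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
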