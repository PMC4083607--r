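#' Logistic normalization of raw PSSM scores
#'
#' Maps each raw integer substitution score x to 1 / (1 + exp(-x)), so
#' every evolutionary-profile feature lies strictly inside (0, 1).
#'
#' @param pssm Numeric matrix of raw PSSM scores (residues x 20).
#' @return A numeric matrix of the same shape with values in (0, 1).
#' @export
#' @examples
#' normalize_pssm(matrix(c(0, 2), 1, 2))
normalize_pssm <- function(pssm) {
  out <- 1 / (1 + exp(-as.matrix(pssm)))
  dimnames(out) <- dimnames(pssm)
  out
}

#' Sliding-window encoding of a per-residue table
#'
#' Represents each residue by the concatenated rows of a window of `window`
#' residues centred on it. (window - 1)/2 pseudoterminal positions are
#' padded at each end of the chain and filled with `pad_value`, so terminal
#' residues get full-width windows (with window 9, 4 pad positions at the
#' head and the tail).
#'
#' @param mat Numeric matrix, one row per residue of the chain.
#' @param window Odd positive window size (default 11).
#' @param pad_value Fill value for out-of-chain positions (default 0).
#' @return A numeric matrix with `nrow(mat)` rows and
#'   `window * ncol(mat)` columns; column names are
#'   `"<offset>:<col>"` for offsets -(window-1)/2 ... +(window-1)/2, so a
#'   prefixed feature name reads `block:windowoffset:column`.
#' @export
window_encode <- function(mat, window = 11, pad_value = 0) {
  mat <- as.matrix(mat)
  if (length(window) != 1 || window < 1 || window %% 2 == 0) {
    abort("window size must be an odd positive integer",
          class = "cbep_config_error")
  }
  half <- (window - 1) / 2
  n <- nrow(mat)
  p <- ncol(mat)
  pad <- matrix(pad_value, nrow = half, ncol = p)
  padded <- rbind(pad, mat, pad)
  offsets <- seq(-half, half)
  cols <- colnames(mat) %||% paste0("c", seq_len(p))
  out <- do.call(cbind, lapply(offsets, function(o) {
    block <- padded[half + seq_len(n) + o, , drop = FALSE]
    colnames(block) <- paste0(o, ":", cols)
    block
  }))
  rownames(out) <- NULL
  out
}

#' Dipeptide composition of a chain
#'
#' A 420-component chain-level descriptor: the first 20 components are the
#' amino-acid composition (counts of each standard residue divided by the
#' chain length) and the remaining 400 are the frequencies of the ordered
#' residue pairs AA, AC, ..., YY among all overlapping adjacent pairs.
#' Pairs containing a non-standard letter are skipped, and the pair
#' denominator is the number of countable pairs; a chain with no countable
#' pair gets an all-zero dipeptide part.
#'
#' @param sequence Amino-acid string (length >= 1).
#' @return A named numeric vector of length 420 (`aac_A` ... `aac_Y`, then
#'   `dp_AA` ... `dp_YY`).
#' @export
#' @examples
#' v <- dipeptide_composition("ACA")
#' v[c("aac_A", "aac_C", "dp_AC", "dp_CA")]
dipeptide_composition <- function(sequence) {
  letters_ <- seq_chars(toupper(sequence))
  len <- length(letters_)
  if (len == 0) stop_format("empty sequence")

  aac <- vapply(aa_standard, function(a) sum(letters_ == a), numeric(1)) / len

  pair_names <- as.vector(t(outer(aa_standard, aa_standard, paste0)))
  pairs <- numeric(400)
  names(pairs) <- pair_names
  if (len >= 2) {
    first <- letters_[-len]
    second <- letters_[-1]
    ok <- first %in% aa_standard & second %in% aa_standard
    if (any(ok)) {
      counts <- table(factor(paste0(first[ok], second[ok]),
                             levels = pair_names))
      pairs <- as.numeric(counts) / sum(ok)
      names(pairs) <- pair_names
    }
  }
  setNames(c(aac, pairs),
           c(paste0("aac_", aa_standard), paste0("dp_", pair_names)))
}

# Ordered block layout for a window size; widths follow the five-class
# design (20N + 3N + N + 6N + 420).
feature_blocks <- function(window = 11, n_scales = 6) {
  w <- as.integer(window)
  tibble(
    block = c("pssm", "ss", "disorder", "phys", "dipep"),
    per_position = c(20L, 3L, 1L, as.integer(n_scales), NA_integer_),
    window = c(rep(w, 4), NA_integer_),
    width = c(20L * w, 3L * w, 1L * w, as.integer(n_scales) * w, 420L)
  )
}

#' Encode one antigen chain into per-residue feature vectors
#'
#' Builds the full feature table for a chain: the logistic-normalized PSSM,
#' secondary-structure probabilities, disorder status and six
#' physicochemical scales are each windowed with [window_encode()], and the
#' chain-level [dipeptide_composition()] is replicated on every residue
#' row. With the default window of 11 the blocks are 220 + 33 + 11 + 66 +
#' 420 = 750 features.
#'
#' @param record An [antigen_record()] carrying `pssm`, `ss2` and
#'   `disorder` profiles.
#' @param window Odd window size (default 11).
#' @param scales Physicochemical scale table from [default_scales()].
#' @return A tibble with columns `chain`, `residue`, `label` (if the record
#'   is annotated) followed by the feature columns, with a `feature_blocks`
#'   attribute describing the block layout.
#' @export
encode_residues <- function(record, window = 11, scales = default_scales()) {
  stopifnot(inherits(record, "antigen_record"))
  for (block in c("pssm", "ss2", "disorder")) {
    if (is.null(record[[block]])) {
      abort(sprintf("record '%s': missing %s profile required for encoding",
                    record$id, block),
            class = "cbep_missing_profile_error")
    }
  }
  len <- nchar(record$sequence)

  pssm_block <- window_encode(normalize_pssm(record$pssm), window)
  colnames(pssm_block) <- paste0("pssm:", colnames(pssm_block))
  ss_block <- window_encode(record$ss2, window)
  colnames(ss_block) <- paste0("ss:", colnames(ss_block))
  dis_block <- window_encode(matrix(record$disorder, ncol = 1,
                                    dimnames = list(NULL, "dis")), window)
  colnames(dis_block) <- paste0("dis:", colnames(dis_block))
  phys_block <- window_encode(scale_rows(record$sequence, scales), window)
  colnames(phys_block) <- paste0("phys:", colnames(phys_block))
  dipep <- dipeptide_composition(record$sequence)
  dipep_block <- matrix(dipep, nrow = len, ncol = 420, byrow = TRUE,
                        dimnames = list(NULL, paste0("dipep:", names(dipep))))

  feats <- cbind(pssm_block, ss_block, dis_block, phys_block, dipep_block)
  out <- tibble(chain = record$id, residue = seq_len(len))
  if (!is.null(record$labels)) out$label <- record$labels
  out <- dplyr::bind_cols(out, as_tibble(feats, .name_repair = "minimal"))
  attr(out, "feature_blocks") <- feature_blocks(window,
                                                n_scales = ncol(scales) - 1)
  out
}

#' Encode a set of antigen chains
#'
#' @param records A list of [antigen_record()]s with profiles attached.
#' @inheritParams encode_residues
#' @return Row-bound per-residue feature tibble over all chains (see
#'   [encode_residues()]).
#' @export
encode_dataset <- function(records, window = 11, scales = default_scales()) {
  encoded <- purrr::map(records, encode_residues, window = window,
                        scales = scales)
  out <- dplyr::bind_rows(encoded)
  attr(out, "feature_blocks") <- attr(encoded[[1]], "feature_blocks")
  out
}

#' Feature column names of an encoded tibble
#'
#' @param encoded A tibble from [encode_residues()] or [encode_dataset()].
#' @return Character vector of feature column names (everything except the
#'   `chain`, `residue`, `label` identifier columns).
#' @export
feature_cols <- function(encoded) {
  setdiff(names(encoded), c("chain", "residue", "label"))
}

#' Numeric feature matrix of an encoded tibble
#'
#' @inheritParams feature_cols
#' @param cols Optional subset of feature columns.
#' @return Numeric matrix of the feature columns.
#' @export
feature_matrix <- function(encoded, cols = feature_cols(encoded)) {
  as.matrix(encoded[, cols, drop = FALSE])
}
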