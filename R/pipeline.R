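#' Predict candidate epitopes for one antigen chain
#'
#' The end-to-end inference path for a single chain: encode its residues,
#' score them with a trained ensemble, call antigenic determinant residues
#' at the score threshold, and spatially cluster the called residues into
#' candidate epitopes (residues without coordinates are dropped from the
#' clustering with a warning).
#'
#' @param model A trained [csboost()] ensemble.
#' @param record An [antigen_record()] with profiles and coordinates.
#' @param window Window size used at training time (default 11).
#' @param scales Physicochemical scale table (default [default_scales()]).
#' @param threshold Score threshold for the residue call (default 0).
#' @param cluster_threshold Spatial threshold T in Angstrom (default
#'   [derive_threshold()]).
#' @param features Optional feature-column subset the model was trained on.
#' @param seed Seed for the clustering bisections.
#' @param ... Passed to [cluster_epitopes()].
#' @return A list with `scores` (per-residue tibble: chain, residue,
#'   score, call) and `clusters` (a `cbep_clusters` tibble with a `chain`
#'   column; empty when no residue is called positive).
#' @export
predict_epitopes <- function(model, record, window = 11,
                             scales = default_scales(), threshold = 0,
                             cluster_threshold = derive_threshold(),
                             features = NULL, seed = NULL, ...) {
  encoded <- encode_residues(record, window = window, scales = scales)
  cols <- features %||% model$feature_names
  score <- predict(model, feature_matrix(encoded, cols))
  scores <- tibble(chain = record$id,
                   residue = encoded$residue,
                   score = score,
                   call = as.integer(score > threshold))
  called <- which(scores$call == 1)
  if (length(called) == 0) {
    clusters <- tibble(cluster = integer(0), residue = integer(0),
                       x = numeric(0), y = numeric(0), z = numeric(0),
                       chain = character(0))
  } else {
    if (is.null(record$coords)) {
      abort(sprintf("record '%s' has no coordinates for clustering",
                    record$id),
            class = "cbep_config_error")
    }
    has_xyz <- !apply(is.na(record$coords[called, , drop = FALSE]), 1, any)
    if (!all(has_xyz)) {
      warn(sprintf("record '%s': %d called residues lack coordinates and are excluded from clustering",
                   record$id, sum(!has_xyz)))
      called <- called[has_xyz]
    }
    clusters <- cluster_epitopes(record$coords[called, , drop = FALSE],
                                 residues = called,
                                 threshold = cluster_threshold,
                                 seed = seed, ...)
    clusters$chain <- record$id
  }
  list(scores = scores, clusters = clusters)
}

#' Observed epitope membership of annotated records, in tidy form
#'
#' @param records A list of annotated [antigen_record()]s.
#' @return Tibble with columns `chain`, `epitope`, `residue` suitable for
#'   [epitope_metrics()].
#' @export
observed_epitopes <- function(records) {
  purrr::map_dfr(records, function(rec) {
    if (is.null(rec$epitope_ids)) return(NULL)
    idx <- which(rec$epitope_ids > 0)
    tibble(chain = rec$id, epitope = rec$epitope_ids[idx], residue = idx)
  })
}
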