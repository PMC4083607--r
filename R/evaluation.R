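#' Rank-statistic AUC with midrank tie handling
#'
#' Area under the ROC curve computed from the Wilcoxon rank-sum statistic;
#' tied scores receive midranks. Returns `NA` when only one class is
#' present.
#'
#' @param labels Binary labels (0/1).
#' @param scores Real-valued scores (higher = more positive).
#' @return AUC in \[0, 1\], or `NA`.
#' @export
auc_midrank <- function(labels, scores) {
  y <- as.integer(labels > 0)
  np <- sum(y == 1)
  nn <- sum(y == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Residue-level classification metrics
#'
#' Confusion counts at a score threshold plus the standard closed forms
#' ACC = (TP+TN)/(TP+TN+FP+FN), SN = TP/(TP+FN), SP = TN/(TN+FP),
#' F = 2TP/(2TP+FN+FP), and the midrank AUC over all scores. A metric
#' whose denominator is zero (or the AUC of a single-class chain) is
#' reported as `NA`.
#'
#' @param labels Binary labels (0/1), one per scored residue.
#' @param scores Real-valued predictor scores.
#' @param threshold Scores strictly above this are called positive
#'   (default 0, the sign rule on tanh-fused scores).
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `acc`, `sn`, `sp`,
#'   `f`, `auc`.
#' @export
#' @examples
#' residue_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
#'                 c(.9, .8, .7, -.2, .6, -.1, -.3, -.5, -.6, -.8))
residue_metrics <- function(labels, scores, threshold = 0) {
  stopifnot(length(labels) == length(scores))
  y <- as.integer(labels > 0)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    acc = safe_div(tp + tn, tp + tn + fp + fn),
    sn = safe_div(tp, tp + fn),
    sp = safe_div(tn, tn + fp),
    f = safe_div(2 * tp, 2 * tp + fn + fp),
    auc = auc_midrank(y, scores)
  )
}

#' Epitope-level metrics (V_site, V_p)
#'
#' Matches predicted clusters to observed epitopes one-to-one by greedy
#' descending overlap fraction |cluster intersect epitope| / |epitope|.
#' An observed epitope counts as correctly predicted when its matched
#' cluster covers strictly more than 30% of its residues; an antigen is
#' correctly predicted when every observed epitope is matched and the
#' number of predicted clusters equals the number of observed epitopes.
#' V_site is the number of correctly predicted epitopes over the number of
#' predicted clusters, and V_p the fraction of correctly predicted
#' antigens, both aggregated over the full evaluation set. Antigens with
#' observed epitopes but no predicted clusters contribute nothing to the
#' V_site denominator and count as incorrect.
#'
#' @param predicted Tibble with columns `chain`, `cluster`, `residue`
#'   (e.g. [cluster_epitopes()] output plus a `chain` column).
#' @param observed Tibble with columns `chain`, `epitope`, `residue`
#'   (observed epitope membership; see [residues()]).
#' @param min_coverage Strict lower bound on the coverage fraction
#'   (default 0.3).
#' @return A `cbep_epitope_metrics` object: list with `v_site`, `v_p`,
#'   `matches` (per matched pair) and `antigens` (per-antigen tallies).
#' @export
epitope_metrics <- function(predicted, observed, min_coverage = 0.3) {
  stopifnot(all(c("chain", "cluster", "residue") %in% names(predicted)),
            all(c("chain", "epitope", "residue") %in% names(observed)))
  chains <- unique(observed$chain)
  per_antigen <- purrr::map(chains, function(ch) {
    obs <- observed[observed$chain == ch, , drop = FALSE]
    prd <- predicted[predicted$chain == ch, , drop = FALSE]
    epi_sets <- split(obs$residue, obs$epitope)
    clu_sets <- split(prd$residue, prd$cluster)
    pairs <- tidyr::expand_grid(epitope = names(epi_sets),
                                cluster = names(clu_sets))
    if (nrow(pairs) > 0) {
      pairs$coverage <- purrr::map2_dbl(pairs$epitope, pairs$cluster,
        function(e, cl) {
          epi <- epi_sets[[e]]
          length(intersect(clu_sets[[cl]], epi)) / length(epi)
        })
      pairs <- pairs[pairs$coverage > min_coverage, , drop = FALSE]
      pairs <- pairs[order(-pairs$coverage,
                           as.integer(pairs$epitope),
                           as.integer(pairs$cluster)), , drop = FALSE]
    } else {
      pairs$coverage <- numeric(0)
    }
    matches <- list()
    used_e <- character(0)
    used_c <- character(0)
    for (i in seq_len(nrow(pairs))) {
      if (pairs$epitope[i] %in% used_e || pairs$cluster[i] %in% used_c) next
      matches[[length(matches) + 1]] <- pairs[i, ]
      used_e <- c(used_e, pairs$epitope[i])
      used_c <- c(used_c, pairs$cluster[i])
    }
    matches <- dplyr::bind_rows(matches)
    n_matched <- nrow(matches)
    list(
      matches = if (n_matched > 0) dplyr::mutate(matches, chain = ch) else NULL,
      summary = tibble(
        chain = ch,
        n_observed = length(epi_sets),
        n_predicted = length(clu_sets),
        n_matched = n_matched,
        correct = n_matched == length(epi_sets) &&
          length(clu_sets) == length(epi_sets)
      )
    )
  })
  antigens <- purrr::map_dfr(per_antigen, "summary")
  matches <- purrr::map_dfr(per_antigen, "matches")
  v_site <- if (sum(antigens$n_predicted) == 0) NA_real_ else
    sum(antigens$n_matched) / sum(antigens$n_predicted)
  structure(
    list(v_site = v_site,
         v_p = mean(antigens$correct),
         matches = matches,
         antigens = antigens),
    class = "cbep_epitope_metrics"
  )
}

#' @export
print.cbep_epitope_metrics <- function(x, ...) {
  cat(sprintf("<epitope-level metrics over %d antigens>\n", nrow(x$antigens)))
  cat(sprintf("  V_site = %.1f%%   V_p = %.1f%%\n",
              100 * x$v_site, 100 * x$v_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cbep_epitope_metrics <- function(x, ...) x$antigens

#' @exportS3Method generics::glance
glance.cbep_epitope_metrics <- function(x, ...) {
  tibble(v_site = x$v_site, v_p = x$v_p,
         n_antigens = nrow(x$antigens),
         n_predicted = sum(x$antigens$n_predicted),
         n_matched = sum(x$antigens$n_matched))
}

#' Leave-one-antigen-out cross-validation
#'
#' For each antigen chain, the ensemble is trained on all remaining chains
#' and scores the held-out chain; performance is summarized as the
#' unweighted mean of the per-chain AUCs (chains whose labels are
#' single-class are excluded from the mean with a note) plus pooled
#' residue-level metrics at the score threshold.
#'
#' @param encoded Encoded multi-chain feature tibble from
#'   [encode_dataset()] with `chain` and `label` columns.
#' @param features Optional subset of feature columns to train on (e.g. an
#'   IFS-selected prefix); default all.
#' @param threshold Score threshold for the pooled confusion counts.
#' @param seed Root seed; each fold trains with a seed derived from it.
#' @param ... Passed on to [csboost()] (cost, rounds, C, gamma, ...).
#' @return A `cbep_loocv` object: list with `per_chain` (tibble of chain,
#'   n, n_pos, auc), `mean_auc`, `pooled` (one-row [residue_metrics()]
#'   tibble over all held-out scores) and `scores` (per-residue tibble).
#' @export
loocv <- function(encoded, features = NULL, threshold = 0, seed = NULL, ...) {
  stopifnot(all(c("chain", "label") %in% names(encoded)))
  chains <- unique(encoded$chain)
  if (length(chains) < 2) {
    abort("leave-one-antigen-out needs at least 2 chains",
          class = "cbep_config_error")
  }
  cols <- features %||% feature_cols(encoded)
  folds <- purrr::imap(setNames(chains, chains), function(ch, i) {
    train <- encoded[encoded$chain != ch, , drop = FALSE]
    test <- encoded[encoded$chain == ch, , drop = FALSE]
    fold_seed <- derive_seed(seed, match(ch, chains))
    model <- csboost(feature_matrix(train, cols), y = train$label,
                     seed = fold_seed, ...)
    score <- predict(model, feature_matrix(test, cols))
    tibble(chain = ch, residue = test$residue, label = test$label,
           score = score)
  })
  scores <- dplyr::bind_rows(folds)
  per_chain <- dplyr::summarise(
    dplyr::group_by(scores, .data$chain),
    n = dplyr::n(),
    n_pos = sum(.data$label),
    auc = auc_midrank(.data$label, .data$score),
    .groups = "drop"
  )
  skipped <- per_chain$chain[is.na(per_chain$auc)]
  if (length(skipped) > 0) {
    warn(sprintf("chains excluded from the AUC mean (single-class labels): %s",
                 paste(skipped, collapse = ", ")))
  }
  structure(
    list(per_chain = per_chain,
         mean_auc = mean(per_chain$auc, na.rm = TRUE),
         pooled = residue_metrics(scores$label, scores$score, threshold),
         scores = scores),
    class = "cbep_loocv"
  )
}

#' @export
print.cbep_loocv <- function(x, ...) {
  cat(sprintf("<cbep_loocv: %d chains, mean AUC %.3f (pooled AUC %.3f)>\n",
              nrow(x$per_chain), x$mean_auc, x$pooled$auc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cbep_loocv <- function(x, ...) x$per_chain

#' @exportS3Method generics::glance
glance.cbep_loocv <- function(x, ...) {
  dplyr::bind_cols(tibble(mean_auc = x$mean_auc,
                          n_chains = nrow(x$per_chain)),
                   dplyr::rename_with(x$pooled,
                                      function(n) paste0("pooled_", n)))
}

#' @describeIn loocv ROC curves per held-out chain.
#' @param object A `cbep_loocv` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cbep_loocv <- function(object, ...) {
  roc <- dplyr::group_modify(
    dplyr::group_by(object$scores, .data$chain),
    function(df, key) {
      if (length(unique(df$label)) < 2) return(tibble())
      ord <- order(-df$score)
      y <- df$label[ord]
      tibble(fpr = c(0, cumsum(1 - y) / sum(1 - y)),
             tpr = c(0, cumsum(y) / sum(y)))
    }
  )
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$chain)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Leave-one-antigen-out ROC curves") +
    ggplot2::theme_minimal()
}
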