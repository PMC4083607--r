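#' Rank features by a per-feature Fisher discriminant score
#'
#' Scores each feature by the classical Fisher ratio
#' (mu_pos - mu_neg)^2 / (var_pos + var_neg) and returns the features in
#' non-increasing score order. Degenerate features with zero pooled
#' variance score +Inf when the class means differ and 0 when they do not;
#' score ties are broken by the lower original column index, so the ranking
#' is deterministic and invariant to sample order. The scorer is pluggable
#' for variants of the class-difference criterion.
#'
#' @param encoded An encoded feature tibble ([encode_dataset()]) or a
#'   numeric matrix / data frame of features.
#' @param y Binary labels (0/1 or -1/+1), one per row; taken from the
#'   `label` column when `encoded` carries one.
#' @param scorer Function `(feature_values, y01) -> scalar`; default is
#'   the Fisher ratio above.
#' @return A `cbep_ranking` tibble with columns `rank`, `feature`, `index`
#'   and `score`, best feature first.
#' @export
rank_features <- function(encoded, y = NULL, scorer = NULL) {
  if (is.data.frame(encoded) && "label" %in% names(encoded)) {
    y <- y %||% encoded$label
  }
  if (is.null(y)) abort("labels required for ranking", class = "cbep_config_error")
  x <- if (is.data.frame(encoded)) feature_matrix(encoded) else as.matrix(encoded)
  y01 <- as.integer(y > 0)
  if (length(unique(y01)) < 2) {
    abort("feature ranking needs both classes present",
          class = "cbep_config_error")
  }
  if (is.null(scorer)) scorer <- fisher_score
  scores <- vapply(seq_len(ncol(x)), function(j) scorer(x[, j], y01),
                   numeric(1))
  ord <- order(-scores, seq_along(scores))
  structure(
    tibble(rank = seq_along(ord),
           feature = colnames(x)[ord] %||% paste0("f", ord),
           index = ord,
           score = scores[ord]),
    class = c("cbep_ranking", "tbl_df", "tbl", "data.frame")
  )
}

fisher_score <- function(v, y01) {
  pos <- v[y01 == 1]
  neg <- v[y01 == 0]
  d2 <- (mean(pos) - mean(neg))^2
  denom <- var(pos) + var(neg)
  if (is.na(denom) || denom == 0) {
    if (d2 == 0) 0 else Inf
  } else {
    d2 / denom
  }
}

#' Incremental feature selection over a ranked list
#'
#' Walks the ranked feature list from the head, evaluating the predictor on
#' each growing prefix Set_i = \{feature_1, ..., feature_i\} and returning
#' the prefix that maximizes the evaluator's score (ties go to the smallest
#' prefix). A `stride` > 1 evaluates every stride-th prefix (plus the full
#' set) for desk-scale runs; stride 1 reproduces the full one-by-one
#' protocol.
#'
#' @param ranking A `cbep_ranking` from [rank_features()].
#' @param encoded Encoded feature tibble or matrix (same columns the
#'   ranking was computed on).
#' @param y Binary labels; taken from `encoded$label` when present.
#' @param evaluator Function `(x_matrix, y01) -> scalar score` (typically a
#'   cross-validated mean AUC); see [make_svm_cv_evaluator()].
#' @param stride Prefix stride (default 1 = every prefix).
#' @param max_size Largest prefix to consider (default all features).
#' @return A `cbep_ifs` object: list with `curve` (tibble of `size`,
#'   `score`), `optimal_size`, `optimal_features` and `ranking`.
#' @export
incremental_feature_selection <- function(ranking, encoded, y = NULL,
                                          evaluator = make_svm_cv_evaluator(),
                                          stride = 1,
                                          max_size = nrow(ranking)) {
  stopifnot(inherits(ranking, "cbep_ranking"))
  if (is.data.frame(encoded) && "label" %in% names(encoded)) {
    y <- y %||% encoded$label
  }
  x <- if (is.data.frame(encoded)) feature_matrix(encoded) else as.matrix(encoded)
  y01 <- as.integer(y > 0)
  sizes <- unique(c(seq(1, max_size, by = stride), max_size))
  scores <- vapply(sizes, function(k) {
    cols <- ranking$index[seq_len(k)]
    score <- tryCatch(
      evaluator(x[, cols, drop = FALSE], y01),
      error = function(e) abort(
        sprintf("IFS evaluator failed at prefix size %d: %s",
                k, conditionMessage(e)),
        class = "cbep_evaluator_error")
    )
    as.numeric(score)
  }, numeric(1))
  best <- sizes[which.max(scores)]  # which.max takes the first (smallest) tie
  structure(
    list(curve = tibble(size = sizes, score = scores),
         optimal_size = best,
         optimal_features = ranking$feature[seq_len(best)],
         ranking = ranking),
    class = "cbep_ifs"
  )
}

#' @export
print.cbep_ifs <- function(x, ...) {
  cat(sprintf("<cbep_ifs: %d prefixes evaluated, optimal size %d (score %.4f)>\n",
              nrow(x$curve), x$optimal_size,
              max(x$curve$score)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cbep_ifs <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.cbep_ifs <- function(x, ...) {
  tibble(optimal_size = x$optimal_size,
         optimal_score = max(x$curve$score),
         n_evaluated = nrow(x$curve))
}

#' @describeIn incremental_feature_selection Plot the IFS curve with the
#'   optimal prefix marked.
#' @param object A `cbep_ifs` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cbep_ifs <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$size, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$optimal_size,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Ranked-prefix size", y = "Evaluator score",
                  title = "Incremental feature selection") +
    ggplot2::theme_minimal()
}

#' Cross-validated single-SVM AUC evaluator for IFS
#'
#' A fast evaluator for [incremental_feature_selection()]: stratified
#' k-fold cross-validation of one RBF-kernel SVM, scored by mean fold AUC.
#' Using a single base SVM rather than the full boosted ensemble keeps a
#' 750-feature IFS sweep tractable; pass a custom evaluator wrapping
#' [csboost()] + [loocv()] to reproduce the full protocol.
#'
#' @param folds Number of CV folds (default 3).
#' @param seed Seed controlling fold assignment (default 1).
#' @param cost,gamma SVM hyperparameters (gamma defaults to 1/ncol).
#' @return A function `(x, y01) -> mean AUC`.
#' @export
make_svm_cv_evaluator <- function(folds = 3, seed = 1, cost = 1,
                                  gamma = NULL) {
  force(folds); force(seed); force(cost); force(gamma)
  function(x, y01) {
    x <- as.matrix(x)
    fold_of <- with_seed_or_global(seed, {
      f <- integer(length(y01))
      for (cl in unique(y01)) {
        idx <- which(y01 == cl)
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      f
    })
    aucs <- purrr::map_dbl(seq_len(folds), function(k) {
      tr <- fold_of != k
      if (length(unique(y01[tr])) < 2 || length(unique(y01[!tr])) < 2) {
        return(NA_real_)
      }
      g <- gamma %||% (1 / ncol(x))
      fit <- e1071::svm(x[tr, , drop = FALSE],
                        factor(y01[tr], levels = c(0, 1)),
                        kernel = "radial", cost = cost, gamma = g,
                        scale = FALSE)
      dv <- svm_decision_values(fit, x[!tr, , drop = FALSE])
      auc_midrank(y01[!tr], dv)
    })
    mean(aucs, na.rm = TRUE)
  }
}
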