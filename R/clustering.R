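#' Average residue-to-epitope-centre distance (R_avg)
#'
#' For every annotated antigenic determinant residue, the distance to the
#' centroid of its observed epitope is computed; R_avg is the mean over all
#' such residues across the supplied antigens. On the benchmark antigen
#' sets this quantity is about 19 Angstrom and anchors the clustering
#' threshold (see [derive_threshold()]).
#'
#' @param records A list of [antigen_record()]s with `epitope_ids` and
#'   `coords`.
#' @return R_avg in Angstrom (scalar).
#' @export
compute_r_avg <- function(records) {
  if (inherits(records, "antigen_record")) records <- list(records)
  dists <- purrr::map(records, function(rec) {
    if (is.null(rec$epitope_ids) || is.null(rec$coords)) return(numeric(0))
    ids <- setdiff(unique(rec$epitope_ids), 0L)
    purrr::map(ids, function(k) {
      members <- which(rec$epitope_ids == k)
      xyz <- rec$coords[members, , drop = FALSE]
      centroid <- colMeans(xyz)
      sqrt(rowSums((xyz - matrix(centroid, nrow(xyz), 3, byrow = TRUE))^2))
    })
  })
  dists <- unlist(dists)
  if (length(dists) == 0) {
    abort("no annotated epitopes with coordinates found",
          class = "cbep_config_error")
  }
  mean(dists)
}

#' Derive the spatial clustering threshold
#'
#' T = alpha * (2 * R_avg): twice the average residue-to-centre distance,
#' scaled by a coefficient that adjusts how far apart two epitopes must be.
#' The defaults (alpha = 1.1, R_avg = 19) give T = 41.8 Angstrom, the
#' setting found to cluster best on the benchmark antigen sets.
#'
#' @param alpha Dimensionless coefficient (> 0, default 1.1).
#' @param r_avg Average residue-to-epitope-centre distance in Angstrom
#'   (> 0, default 19).
#' @return Threshold T in Angstrom.
#' @export
#' @examples
#' derive_threshold()            # 41.8
#' derive_threshold(0.5, 10)     # 10
derive_threshold <- function(alpha = 1.1, r_avg = 19) {
  if (alpha <= 0 || r_avg <= 0) {
    abort("alpha and r_avg must be positive", class = "cbep_config_error")
  }
  alpha * (2 * r_avg)
}

#' Cluster predicted antigenic determinant residues into epitopes
#'
#' Groups predicted residues by divisive spatial clustering: all residues
#' start in one cluster; while any cluster's diameter (maximum pairwise
#' C-alpha distance) exceeds the threshold T, that cluster is bisected by
#' 2-means on the coordinates (best of `nstart` restarts). On termination
#' every cluster's diameter is at most T. An agglomerative
#' complete-linkage backend cut at height T is available for comparison;
#' it satisfies the same diameter bound.
#'
#' @param coords Numeric n x 3 C-alpha coordinate matrix of the predicted
#'   residues (rows without coordinates must be dropped by the caller).
#' @param residues Residue indices naming the rows (default 1..n).
#' @param threshold Clustering threshold T in Angstrom (default
#'   [derive_threshold()] = 41.8).
#' @param backend `"divisive"` (default) or `"complete"` linkage.
#' @param seed Seed for the 2-means bisections.
#' @param nstart k-means restarts per bisection (default 10).
#' @param min_size Drop clusters smaller than this (default 1 = keep all;
#'   singleton epitopes are legal).
#' @return A `cbep_clusters` tibble with columns `cluster`, `residue`,
#'   `x`, `y`, `z`; clusters are numbered in decreasing size (ties by
#'   smallest member residue). Attributes `centroids` (tibble of cluster
#'   centroids and sizes) and `threshold` are attached.
#' @export
cluster_epitopes <- function(coords, residues = NULL,
                             threshold = derive_threshold(),
                             backend = c("divisive", "complete"),
                             seed = NULL, nstart = 10, min_size = 1) {
  backend <- match.arg(backend)
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) {
    abort("no residues to cluster", class = "cbep_config_error")
  }
  if (anyNA(coords)) {
    abort(sprintf("residues without coordinates: %s",
                  paste(which(apply(is.na(coords), 1, any)), collapse = ", ")),
          class = "cbep_config_error")
  }
  residues <- residues %||% seq_len(nrow(coords))
  stopifnot(length(residues) == nrow(coords))

  membership <- if (backend == "divisive") {
    with_seed_or_global(seed, divisive_bisect(coords, threshold, nstart))
  } else {
    if (nrow(coords) == 1) {
      1L
    } else {
      cutree(hclust(dist(coords), method = "complete"), h = threshold)
    }
  }

  groups <- split(seq_len(nrow(coords)), membership)
  sizes <- lengths(groups)
  first_res <- vapply(groups, function(g) min(residues[g]), numeric(1))
  ord <- order(-sizes, first_res)
  groups <- unname(groups[ord])
  if (min_size > 1) groups <- groups[lengths(groups) >= min_size]

  out <- purrr::imap_dfr(groups, function(g, k) {
    tibble(cluster = as.integer(k), residue = residues[g],
           x = coords[g, 1], y = coords[g, 2], z = coords[g, 3])
  })
  centroids <- dplyr::summarise(
    dplyr::group_by(out, .data$cluster),
    size = dplyr::n(),
    diameter = coord_diameter(cbind(.data$x, .data$y, .data$z)),
    x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
    .groups = "drop"
  )
  structure(out,
            class = c("cbep_clusters", class(out)),
            centroids = centroids, threshold = threshold)
}

# Divisive bisection: queue of clusters, split any whose diameter > T with
# 2-means until all satisfy the bound.
divisive_bisect <- function(coords, threshold, nstart) {
  membership <- rep(1L, nrow(coords))
  next_id <- 2L
  queue <- 1L
  while (length(queue) > 0) {
    id <- queue[1]
    queue <- queue[-1]
    idx <- which(membership == id)
    sub <- coords[idx, , drop = FALSE]
    if (coord_diameter(sub) <= threshold) next
    if (nrow(unique(sub)) < 2) next  # duplicated points cannot be split
    split2 <- if (nrow(sub) == 2) {
      c(1L, 2L)  # kmeans needs centers < points; a pair splits trivially
    } else {
      kmeans(sub, centers = 2, nstart = nstart)$cluster
    }
    membership[idx[split2 == 2]] <- next_id
    queue <- c(queue, id, next_id)
    next_id <- next_id + 1L
  }
  membership
}

#' @export
print.cbep_clusters <- function(x, ...) {
  cen <- attr(x, "centroids")
  cat(sprintf("<cbep_clusters: %d residues in %d clusters (T = %.1f A)>\n",
              nrow(x), nrow(cen), attr(x, "threshold")))
  NextMethod()
}

#' Cluster centroid summary
#'
#' @param clusters A `cbep_clusters` tibble from [cluster_epitopes()].
#' @return Tibble of per-cluster size, centroid and diameter.
#' @export
cluster_centroids <- function(clusters) attr(clusters, "centroids")

#' @describeIn cluster_epitopes Scatter plot of clustered residues on two
#'   coordinate axes.
#' @param object A `cbep_clusters` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cbep_clusters <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = factor(.data$cluster))) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)", colour = "cluster",
                  title = "Predicted epitope clusters") +
    ggplot2::theme_minimal()
}
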