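# PCA and hierarchical clustering of treatment behaviour profiles.
#
# The object of study is a small matrix of group-averaged endpoints: rows are
# the six locomotor endpoints (variables), columns are treatment groups
# (samples). Endpoints live on wildly different scales (mm vs counts vs
# deg/um), so every row is unit-variance scaled before any multivariate step.
# Components come from a plain SVD of the scaled matrix; both axes of the
# heatmap are ordered by average-linkage (UPGMA) clustering on Pearson
# correlation distance, the configuration popularised by ClustVis.

#' Endpoints-by-groups behaviour matrix
#'
#' Averages each locomotor endpoint within each treatment group and arranges
#' the result with endpoints as rows (variables) and groups as columns
#' (samples).
#'
#' @param endpoints Endpoint tibble from [compute_endpoints()], several
#'   groups bound together.
#' @param na_rm Drop NA endpoint values (degenerate cells) before averaging.
#' @return A numeric matrix, 6 endpoints x n groups.
#' @export
behavior_matrix <- function(endpoints, na_rm = TRUE) {
  cols <- intersect(endpoint_names, names(endpoints))
  wide <- endpoints |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(cols), ~ mean(.x, na.rm = na_rm)),
      .groups = "drop"
    )
  m <- t(as.matrix(wide[cols]))
  colnames(m) <- wide$group
  m
}

#' Unit-variance scaling of matrix rows
#'
#' Centres each row (variable) to mean 0 and divides by its sample standard
#' deviation (n - 1), so all endpoints carry equal weight downstream.
#'
#' @param m Numeric matrix, variables in rows.
#' @return The scaled matrix.
#' @export
unit_variance_scale_rows <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (anyNA(m)) abort("Behaviour matrix must have no missing values.")
  sds <- apply(m, 1, sd)
  zero <- sds == 0
  if (any(zero)) {
    abort(sprintf(
      "Zero-variance row(s): %s — constant endpoints cannot be unit-variance scaled.",
      paste(rownames(m)[zero] %||% which(zero), collapse = ", ")
    ))
  }
  (m - rowMeans(m)) / sds
}

#' PCA by singular value decomposition
#'
#' SVD of the row-scaled matrix; treatment groups (columns) get scores,
#' endpoints (rows) get loadings, and explained variance comes from the
#' squared singular values. Row centering makes the rank at most
#' `min(n_rows, n_cols - 1)`; trailing null components are dropped.
#' Component signs are canonicalised so the largest-magnitude loading of
#' each component is positive, making score plots reproducible.
#'
#' @param scaled Row-scaled matrix from [unit_variance_scale_rows()].
#' @return A `pca_result`: `scores` (groups x components), `loadings`
#'   (endpoints x components), `explained_var_pct`. Methods: [tidy()],
#'   [autoplot()].
#' @export
pca_svd <- function(scaled) {
  stopifnot(is.matrix(scaled), all(is.finite(scaled)))
  sv <- svd(scaled)
  tol <- max(dim(scaled)) * max(sv$d) * .Machine$double.eps
  keep <- which(sv$d > tol)
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  # canonical signs: largest-magnitude loading positive
  for (j in seq_along(keep)) {
    if (u[which.max(abs(u[, j])), j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  scores <- sweep(v, 2, d, `*`)
  pcs <- paste0("PC", seq_along(keep))
  dimnames(scores) <- list(colnames(scaled), pcs)
  dimnames(u) <- list(rownames(scaled), pcs)
  structure(
    list(
      scores = scores,
      loadings = u,
      singular_values = d,
      explained_var_pct = 100 * d^2 / sum(sv$d^2)
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", ncol(x$scores), "components; explained variance (%):",
      paste(sprintf("%.1f", x$explained_var_pct), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  as_tibble(x$scores, rownames = "group") |>
    tidyr::pivot_longer(-"group", names_to = "component", values_to = "score") |>
    dplyr::left_join(
      tibble(
        component = paste0("PC", seq_along(x$explained_var_pct)),
        explained_var_pct = x$explained_var_pct
      ),
      by = "component"
    )
}

#' @export
autoplot.pca_result <- function(object, ...) {
  df <- as_tibble(object$scores, rownames = "group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2, label = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$explained_var_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$explained_var_pct[2])
    ) +
    ggplot2::theme_minimal()
}

#' Pearson correlation distance
#'
#' `d(u, v) = 1 - cor(u, v)`: 0 for identical profiles, 2 for exact
#' anti-correlation.
#'
#' @param m Numeric matrix.
#' @param axis `"rows"` or `"cols"`: which vectors to compare.
#' @return A [stats::dist] object.
#' @export
correlation_distance <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  vecs <- if (axis == "rows") t(m) else m
  if (ncol(vecs) < 2) abort("Need at least 2 vectors.")
  sds <- apply(vecs, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "Zero-variance vector(s): %s — correlation distance undefined.",
      paste(colnames(vecs)[sds == 0] %||% which(sds == 0), collapse = ", ")
    ))
  }
  as.dist(1 - cor(vecs))
}

#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Inter-cluster distance is the unweighted mean of all cross-pair
#' distances, which guarantees nondecreasing merge heights.
#'
#' @param d A [stats::dist] object.
#' @return An [stats::hclust] tree.
#' @export
average_linkage <- function(d) {
  stopifnot(inherits(d, "dist"))
  hclust(d, method = "average")
}

#' Cluster the behaviour matrix on both axes
#'
#' Rows are unit-variance scaled, then endpoints (rows) and treatment groups
#' (columns) are each clustered with correlation distance and average
#' linkage; the reordered scaled matrix and both trees are returned for
#' heatmap display and for cutting the column tree into behaviour clusters.
#'
#' @param m Raw behaviour matrix from [behavior_matrix()].
#' @return A `behavior_clustering`: `scaled`, `row_tree`, `col_tree`,
#'   `row_order`, `col_order`, `heatmap_values`. Methods: [autoplot()],
#'   [cut_cluster()].
#' @export
cluster_heatmap <- function(m) {
  scaled <- unit_variance_scale_rows(m)
  row_tree <- average_linkage(correlation_distance(scaled, "rows"))
  col_tree <- average_linkage(correlation_distance(scaled, "cols"))
  structure(
    list(
      scaled = scaled,
      row_tree = row_tree,
      col_tree = col_tree,
      row_order = row_tree$order,
      col_order = col_tree$order,
      heatmap_values = scaled[row_tree$order, col_tree$order, drop = FALSE]
    ),
    class = "behavior_clustering"
  )
}

#' @rdname cluster_heatmap
#' @param x A `behavior_clustering`.
#' @param k Number of clusters to cut the column (treatment) tree into.
#' @return Named integer vector of cluster memberships per group.
#' @export
cut_cluster <- function(x, k = 3) {
  stopifnot(inherits(x, "behavior_clustering"))
  cutree(x$col_tree, k = k)
}

#' @export
print.behavior_clustering <- function(x, ...) {
  cat(sprintf(
    "<behavior_clustering> %d endpoints x %d groups; column order: %s\n",
    nrow(x$scaled), ncol(x$scaled),
    paste(colnames(x$scaled)[x$col_order], collapse = ", ")
  ))
  invisible(x)
}

#' @export
autoplot.behavior_clustering <- function(object, ...) {
  df <- as_tibble(object$heatmap_values, rownames = "endpoint") |>
    tidyr::pivot_longer(-"endpoint", names_to = "group", values_to = "z")
  df$endpoint <- factor(df$endpoint, levels = rev(rownames(object$heatmap_values)))
  df$group <- factor(df$group, levels = colnames(object$heatmap_values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$endpoint, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# Newick-style serialisation of an hclust tree (leaf labels + merge heights),
# for the plain-text tree outputs of the pipeline.
hclust_to_newick <- function(tree) {
  labels <- tree$labels
  node_txt <- function(i) {
    if (i < 0) labels[-i] else {
      m <- tree$merge[i, ]
      sprintf("(%s:%g,%s:%g)", node_txt(m[1]), tree$height[i], node_txt(m[2]), tree$height[i])
    }
  }
  paste0(node_txt(nrow(tree$merge)), ";")
}
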