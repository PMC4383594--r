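#' Pairwise Spearman correlation matrix of the outcomes at one occasion
#'
#' Pairwise-complete Spearman correlations; a pair with fewer than 3
#' complete observations gets `NA` and is flagged.
#'
#' @param data A `longitudinal_df`, or a plain numeric matrix/data frame of
#'   outcome columns.
#' @param occasion Occasion level (required for a `longitudinal_df`).
#' @return A symmetric correlation matrix of class `spearman_mat` with unit
#'   diagonal; attribute `n_pairs` holds the pairwise complete counts.
#' @export
spearman_matrix <- function(data, occasion = NULL) {
  if (inherits(data, "longitudinal_df")) {
    roles <- roles_of(data)
    d <- if (is.null(occasion)) as_tibble(data) else
      as_tibble(at_occasion(data, occasion))
    m <- as.matrix(d[roles$outcomes])
  } else {
    m <- as.matrix(data)
  }
  if (ncol(m) < 2) {
    abort("Need at least 2 outcomes.", class = "longmed_validation_error")
  }
  rho <- suppressWarnings(cor(m, method = "spearman",
                              use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(m))
  few <- n_pairs < 3
  if (any(few[upper.tri(few)])) {
    warn("Some outcome pairs have fewer than 3 complete observations; their correlations are set to NA.")
    rho[few] <- NA_real_
  }
  diag(rho) <- 1
  structure(rho, n_pairs = n_pairs, class = c("spearman_mat", "matrix", "array"))
}

#' Hierarchical clustering ordering (Euclidean distance, complete linkage)
#'
#' Agglomerative clustering whose leaf order is used to rearrange the rows
#' of lasagna plots and heat maps so that similar items sit together.
#' Missing features are mean-imputed per column before computing distances
#' (the number of imputed cells is recorded), because the data being
#' ordered may legitimately contain missing values.
#'
#' @param x Numeric matrix or data frame, items in rows.
#' @param labels Optional item labels (default: rownames).
#' @return An object of class `cluster_ordering`: list with `leaf_order`
#'   (permutation of item indices), `labels`, `hclust` (the merge tree),
#'   `n_imputed`.
#' @export
hierarchical_order <- function(x, labels = NULL) {
  m <- as.matrix(x)
  labels <- labels %||% rownames(m) %||% as.character(seq_len(nrow(m)))
  if (nrow(m) < 2) {
    return(structure(list(leaf_order = seq_len(nrow(m)), labels = labels,
                          hclust = NULL, n_imputed = 0L),
                     class = "cluster_ordering"))
  }
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    mu <- colMeans(m, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mu[j]
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "complete")
  structure(list(leaf_order = hc$order, labels = labels, hclust = hc,
                 n_imputed = n_imputed),
            class = "cluster_ordering")
}

#' @export
print.cluster_ordering <- function(x, ...) {
  cat("Hierarchical ordering of", length(x$leaf_order),
      "items (Euclidean distance, complete linkage)\n")
  if (x$n_imputed > 0) cat("  mean-imputed cells:", x$n_imputed, "\n")
  cat("  leaf order:", paste(head(x$labels[x$leaf_order], 12), collapse = ", "),
      if (length(x$leaf_order) > 12) "..." else "", "\n")
  invisible(x)
}

# segment coordinates of an hclust tree, for ggplot dendrograms
dendro_segments <- function(hc) {
  n <- length(hc$order)
  xpos <- numeric(2 * n - 1)          # position of each node on the leaf axis
  xpos[seq_len(n)] <- order(hc$order) # leaf i sits at rank of i in the order
  height <- c(rep(0, n), hc$height)
  node_x <- function(idx) if (idx < 0) xpos[-idx] else xpos[n + idx]
  node_h <- function(idx) if (idx < 0) 0 else hc$height[idx]
  segs <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    xa <- node_x(a); xb <- node_x(b)
    ha <- node_h(a); hb <- node_h(b)
    h <- hc$height[k]
    xpos[n + k] <- (xa + xb) / 2
    segs[[k]] <- tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(ha, hb, h), yend = c(h, h, h))
  }
  bind_rows(segs)
}

#' Dendrogram plot of a hierarchical ordering
#'
#' @param object A `cluster_ordering` from [hierarchical_order()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_ordering <- function(object, ...) {
  if (is.null(object$hclust)) {
    abort("Single item: nothing to draw.", class = "longmed_validation_error")
  }
  hc <- object$hclust
  segs <- dendro_segments(hc)
  leaves <- tibble(x = seq_along(hc$order),
                   label = object$labels[hc$order])
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "Height (complete linkage)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' @rdname autoplot.cluster_ordering
#' @export
plot_dendrogram <- autoplot.cluster_ordering

#' Heat-map plot of a Spearman correlation matrix
#'
#' @param object A `spearman_mat` from [spearman_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spearman_mat <- function(object, ...) {
  m <- unclass(object)
  attr(m, "n_pairs") <- NULL
  df <- as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("row", "col", "rho")
  df$row <- factor(df$row, levels = rev(rownames(m)))
  df$col <- factor(df$col, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-1, 1), na.value = "grey90",
                                  name = "Spearman rho") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @rdname autoplot.spearman_mat
#' @export
plot_correlation <- autoplot.spearman_mat
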