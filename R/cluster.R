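# Average-linkage (UPGMA) clustering of expression rows, with the
# missing-data conventions used for the clustered image maps: Euclidean
# distance on pairwise-complete coordinates rescaled by
# sqrt(p_total / p_observed) (the convention of stats::dist), deterministic
# tie-breaking, and a deterministic leaf order.  The agglomeration itself is
# implemented here so merge order and leaf order are fully specified; the
# test-suite cross-checks it against stats::hclust on tie-free inputs.

#' Average-linkage cluster tree of expression rows
#'
#' UPGMA agglomeration on Euclidean row distances.  Pairs with missing
#' entries use pairwise-complete coordinates scaled up by
#' \code{sqrt(p_total / p_observed)}; rows comparable with no other row are
#' excluded with a warning and recorded in the result.  Ties in the minimum
#' inter-cluster distance are broken by the smallest (first cluster index,
#' then second); the leaf order puts the cluster with the smaller index on
#' the left.
#'
#' @param m numeric matrix (typically Z-scores), rows = genes.
#' @return Object of class \code{linkage_tree}: \code{merge} (m x 2, hclust
#'   convention: negative = leaf), \code{height}, \code{size} (cluster sizes
#'   after each merge), \code{order} (leaf permutation), \code{labels},
#'   \code{excluded} (labels of dropped rows).
#' @export
cluster_average_linkage <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2) stop("need a matrix with at least 2 rows")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))

  d <- as.matrix(stats::dist(m, method = "euclidean"))
  diag(d) <- NA
  comparable <- rowSums(!is.na(d)) > 0
  excluded <- labels[!comparable]
  if (length(excluded)) {
    warning("row(s) incomparable with all others excluded: ",
            paste(excluded, collapse = ", "))
    m <- m[comparable, , drop = FALSE]
    labels <- labels[comparable]
    d <- d[comparable, comparable, drop = FALSE]
  }
  n <- nrow(d)
  if (n < 2) stop("fewer than 2 comparable rows")
  if (any(is.na(d[upper.tri(d)]))) {
    stop("some comparable rows share no observed column pair; cannot cluster")
  }

  # active clusters: id (hclust convention), member leaf indices
  ids <- -seq_len(n)
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  size <- integer(n - 1)
  orders <- as.list(seq_len(n))   # leaf order within each active cluster
  D <- d

  for (k in seq_len(n - 1)) {
    na <- length(ids)
    # smallest distance; ties -> smallest (i, j) position pair
    best <- c(NA_integer_, NA_integer_)
    bd <- Inf
    for (i in seq_len(na - 1)) {
      for (j in seq((i + 1), na)) {
        if (D[i, j] < bd - 1e-15) {
          bd <- D[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[k, ] <- c(ids[i], ids[j])
    height[k] <- bd
    ni <- length(members[[i]]); nj <- length(members[[j]])
    size[k] <- ni + nj
    # UPGMA update: weighted mean of member distances
    newD <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    newD <- newD[-c(i, j)]
    neworder <- c(orders[[i]], orders[[j]])  # smaller cluster index left
    newmem <- c(members[[i]], members[[j]])
    keep <- setdiff(seq_len(na), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, newD), c(newD, NA))
    ids <- c(ids[keep], k)
    members <- c(members[keep], list(newmem))
    orders <- c(orders[keep], list(neworder))
  }
  structure(list(merge = merge, height = height, size = size,
                 order = orders[[1]], labels = labels, excluded = excluded),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("Average-linkage tree: %d leaves, heights %.3g-%.3g%s\n",
              length(x$labels), min(x$height), max(x$height),
              if (length(x$excluded)) paste0(" (", length(x$excluded),
                                             " rows excluded)") else ""))
  invisible(x)
}

#' Convert a linkage tree to an \code{hclust} object
#'
#' @param x a \code{linkage_tree}.
#' @param ... unused.
#' @return An object of class \code{hclust}.
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 dist.method = "euclidean",
                 call = match.call()), class = "hclust")
}

#' Export a clustered image map (CIM)
#'
#' Writes the matrix with rows in dendrogram leaf order as a TSV (missing
#' cells as \code{NA}) and, optionally, renders a heatmap image on a
#' symmetric diverging scale centred at 0 with missing cells left white.
#'
#' @param m matrix of Z-scores, rows = genes.
#' @param tree \code{linkage_tree} whose labels match \code{rownames(m)}
#'   (rows excluded from the tree are dropped from the export).
#' @param path output TSV path.
#' @param image_path optional PNG path for the rendered heatmap.
#' @return Invisible list with the reordered matrix and the written paths.
#' @export
export_cim <- function(m, tree, path, image_path = NULL) {
  keep <- tree$labels
  if (!all(keep %in% rownames(m))) {
    stop("tree labels do not match matrix row names")
  }
  mm <- m[keep, , drop = FALSE][tree$order, , drop = FALSE]
  write_expr_matrix(mm, path)
  if (!is.null(image_path)) {
    lim <- max(abs(mm), na.rm = TRUE)
    if (!is.finite(lim) || lim == 0) lim <- 1
    pal <- grDevices::colorRampPalette(c("green3", "black", "red"))(255)
    grDevices::png(image_path, width = 120 + 28 * ncol(mm),
                   height = 120 + 14 * nrow(mm))
    op <- graphics::par(mar = c(6, 1, 1, 8))
    graphics::image(t(mm[rev(seq_len(nrow(mm))), , drop = FALSE]),
                    col = pal, zlim = c(-lim, lim), axes = FALSE,
                    useRaster = FALSE)
    graphics::axis(1, at = seq(0, 1, length.out = ncol(mm)),
                   labels = colnames(mm), las = 2, cex.axis = 0.8)
    graphics::axis(4, at = seq(1, 0, length.out = nrow(mm)),
                   labels = rownames(mm), las = 2, cex.axis = 0.7, tick = FALSE)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(list(matrix = mm, path = path, image_path = image_path))
}
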