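#' Ward agglomerative hierarchical clustering
#'
#' Clusters the rows of a numeric matrix by Ward's minimum-variance method:
#' at each step the two clusters whose merger least increases the total
#' within-cluster sum of squares are joined. Implemented with the
#' Lance-Williams recurrence on squared Euclidean distances; merge heights
#' follow the Ward.D2 convention (the square root of the updated squared
#' distance), so two singletons merge at their Euclidean distance. Among
#' equal-cost merges the pair with the smallest (left, right) node indices is
#' taken (leaves are numbered 1..n in input order, internal nodes n+1, n+2,
#' ... in creation order), which makes the tree order-stable.
#'
#' @param x Numeric matrix (rows are the objects to cluster, columns the
#'   features); at least 2 rows, all entries finite.
#' @param standardize If `TRUE`, z-score each feature column first
#'   (default `FALSE`).
#' @param height `"D2"` (default, square-root heights) or `"D1"` (heights on
#'   the squared-distance scale).
#' @return A `ward_clust` object: list with `merge` (hclust-style (n-1) x 2
#'   matrix; negative entries are leaves, positive entries earlier merges),
#'   `height`, `size` (merged cluster sizes), `order` (depth-first leaf order,
#'   lower-index child first), `labels`, and `height_type`.
#' @export
ward_linkage <- function(x, standardize = FALSE, height = c("D2", "D1")) {
  height <- match.arg(height)
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("ward_linkage needs at least 2 rows")
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(paste0("non-finite matrix entry at row ", bad[1],
                 ", column ", bad[2]))
  }
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0
  }
  n <- nrow(x)
  labels <- rownames(x) %||% as.character(seq_len(n))

  # squared Euclidean distances
  d2 <- as.matrix(stats::dist(x))^2
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  node_id <- seq_len(n)            # creation index of the cluster in slot i
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  msize <- integer(n - 1L)
  hc_node <- -seq_len(n)           # hclust-style id of the cluster in slot i

  for (s in seq_len(n - 1L)) {
    best <- NULL
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      for (j in act[(ii + 1L):length(act)]) {
        pi <- sort(c(node_id[i], node_id[j]))
        cand <- list(d = d2[i, j], pair = pi, slots = c(i, j))
        if (is.null(best) ||
            cand$d < best$d - 0 ||
            (cand$d == best$d &&
             (cand$pair[1] < best$pair[1] ||
              (cand$pair[1] == best$pair[1] && cand$pair[2] < best$pair[2])))) {
          best <- cand
        }
      }
    }
    i <- best$slots[1]; j <- best$slots[2]
    # order the merge row by node index (lower first)
    if (node_id[i] > node_id[j]) { tmp <- i; i <- j; j <- tmp }
    merge[s, ] <- c(hc_node[i], hc_node[j])
    heights[s] <- if (height == "D2") sqrt(d2[i, j]) else d2[i, j]
    ni <- sizes[i]; nj <- sizes[j]
    msize[s] <- ni + nj

    # Lance-Williams update (Ward, on squared distances) into slot i
    for (k in act) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dnew <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                 nk * d2[i, j]) / (ni + nj + nk)
      d2[i, k] <- dnew
      d2[k, i] <- dnew
    }
    sizes[i] <- ni + nj
    active[j] <- FALSE
    node_id[i] <- n + s
    hc_node[i] <- s
  }

  ord <- dfs_leaf_order(merge, n)
  structure(
    list(merge = merge, height = heights, size = msize, order = ord,
         labels = labels, height_type = height, method = "ward",
         n_leaves = n),
    class = "ward_clust"
  )
}

# Depth-first leaf order; at each internal node the lower-index child is
# visited first (leaves are 1..n, the s-th internal node is n+s).
dfs_leaf_order <- function(merge, n) {
  node_index <- function(e) if (e < 0) -e else n + e
  visit <- function(e) {
    if (e < 0) return(-e)
    ch <- merge[e, ]
    ch <- ch[order(vapply(ch, node_index, numeric(1)))]
    c(visit(ch[1]), visit(ch[2]))
  }
  visit(nrow(merge))
}

#' @export
print.ward_clust <- function(x, ...) {
  cat("<ward_clust> ", x$n_leaves, " leaves, heights [",
      format(min(x$height), digits = 4), ", ",
      format(max(x$height), digits = 4), "] (", x$height_type, ")\n",
      sep = "")
  invisible(x)
}

#' @export
as.hclust.ward_clust <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = paste0("ward.", x$height_type),
         call = match.call(), dist.method = "euclidean"),
    class = "hclust"
  )
}

#' @export
tidy.ward_clust <- function(x, ...) {
  tibble(step = seq_len(nrow(x$merge)),
         left = x$merge[, 1], right = x$merge[, 2],
         height = x$height, size = x$size)
}

#' @export
glance.ward_clust <- function(x, ...) {
  tibble(n_leaves = x$n_leaves, max_height = max(x$height),
         height_type = x$height_type)
}

#' Cut a Ward tree into k clusters
#'
#' Cuts the merge sequence after `n_leaves - k` merges, yielding exactly `k`
#' clusters. Cluster ids are assigned by first appearance in leaf-label
#' order; `leaf_order` is the depth-first dendrogram ordering.
#'
#' @param tree A `ward_clust`.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A `cluster_assignment` object: list with `k`, `labels` (named
#'   integer vector leaf -> cluster id), `leaf_order` (character).
#' @export
cut_linkage <- function(tree, k) {
  stopifnot(inherits(tree, "ward_clust"))
  n <- tree$n_leaves
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != floor(k)) {
    abort(paste0("k must be an integer in [1, ", n, "]"))
  }
  labs <- cutree(as.hclust(tree), k = k)
  structure(
    list(k = as.integer(k), labels = labs,
         leaf_order = tree$labels[tree$order]),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k = ", x$k, "\n", sep = "")
  print(split(names(x$labels), x$labels))
  invisible(x)
}

#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble(label = names(x$labels), cluster = unname(x$labels))
}

#' Two-way Ward clustering of a signal matrix
#'
#' Clusters the drug axis (features: the event lnROR profiles) and the event
#' axis (features: the drug lnROR profiles) of a filtered lnROR matrix, cuts
#' each tree at the requested cluster counts, and reorders the matrix by both
#' dendrogram leaf orders for heatmap display.
#'
#' @param x A `signal_matrix` (or plain numeric matrix with dimnames).
#' @param k_drugs,k_events Cluster counts for rows/columns. The published
#'   opioid analysis used 5 drug clusters and 7 event clusters.
#' @param standardize Z-score feature columns before clustering (default
#'   `FALSE`; the lnROR scale is already shared across the matrix).
#' @param height Height convention, see [ward_linkage()].
#' @return A `two_way_cluster` object: list with `drug_tree`, `drug_clusters`,
#'   `event_tree`, `event_clusters`, and `matrix` (the lnROR matrix reordered
#'   by both leaf orders).
#' @export
two_way_cluster <- function(x, k_drugs = 5, k_events = 7,
                            standardize = FALSE, height = "D2") {
  m <- if (inherits(x, "signal_matrix")) x$lnror else as.matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("two-way clustering needs at least 2 drugs and 2 events")
  }
  drug_tree <- ward_linkage(m, standardize = standardize, height = height)
  event_tree <- ward_linkage(t(m), standardize = standardize, height = height)
  drug_cl <- cut_linkage(drug_tree, k_drugs)
  event_cl <- cut_linkage(event_tree, k_events)
  reordered <- m[drug_tree$order, event_tree$order, drop = FALSE]
  structure(
    list(drug_tree = drug_tree, drug_clusters = drug_cl,
         event_tree = event_tree, event_clusters = event_cl,
         matrix = reordered),
    class = "two_way_cluster"
  )
}

#' @export
print.two_way_cluster <- function(x, ...) {
  cat("<two_way_cluster> ", nrow(x$matrix), " drugs in ",
      x$drug_clusters$k, " clusters x ", ncol(x$matrix), " events in ",
      x$event_clusters$k, " clusters\n", sep = "")
  invisible(x)
}

#' @export
tidy.two_way_cluster <- function(x, ...) {
  bind_rows(
    mutate(tidy(x$drug_clusters), axis = "drug"),
    mutate(tidy(x$event_clusters), axis = "event")
  ) %>% select("axis", "label", "cluster")
}

#' @export
glance.two_way_cluster <- function(x, ...) {
  tibble(n_drugs = nrow(x$matrix), n_events = ncol(x$matrix),
         k_drugs = x$drug_clusters$k, k_events = x$event_clusters$k)
}

#' Export a Ward tree in Newick format
#'
#' Branch lengths are derived from the merge heights (each child branch spans
#' the height difference to its parent).
#'
#' @param tree A `ward_clust`.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ward_clust"))
  phy <- ape::as.phylo(as.hclust(tree))
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

#' Write linkage and membership tables as TSV
#'
#' `write_linkage()` emits one row per merge (`left`, `right`, `height`,
#' `size`; negative indices are leaves, positive indices earlier merges).
#' `write_clusters()` emits `label`, `cluster`.
#'
#' @param tree A `ward_clust`; `assignment` a `cluster_assignment`.
#' @param path Output path.
#' @export
write_linkage <- function(tree, path) {
  write_tsv_plain(tidy(tree), path)
}

#' @rdname write_linkage
#' @param assignment A `cluster_assignment`.
#' @export
write_clusters <- function(assignment, path) {
  write_tsv_plain(tidy(assignment), path)
}
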