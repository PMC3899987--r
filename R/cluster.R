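#' Construct a dendrogram object from merge data
#'
#' Internal-facing constructor following the `hclust` encoding: row `m` of
#' `merge` lists the two clusters united at step `m`, negative entries
#' being leaves (by index into `labels`) and positive entries earlier
#' merge steps.  `height[m]` is the inter-cluster distance recorded at
#' that merge; leaves sit at height zero.
#'
#' @param merge Integer matrix, `(n-1) x 2`.
#' @param height Numeric vector of length `n - 1`.
#' @param labels Character vector of the `n` leaf accessions.
#' @param method Clustering method label (free-form).
#' @return An object of class `rna_dendrogram`.
#' @export
new_dendrogram <- function(merge, height, labels, method = "manual") {
  merge <- matrix(as.integer(merge), ncol = 2L)
  n <- length(labels)
  stopifnot(nrow(merge) == n - 1L, length(height) == n - 1L,
            !anyDuplicated(labels))
  structure(list(merge = merge, height = as.numeric(height),
                 labels = as.character(labels), method = method),
            class = "rna_dendrogram")
}

#' @export
print.rna_dendrogram <- function(x, ...) {
  cat(sprintf("<rna_dendrogram> %d leaves, method '%s', root height %g\n",
              length(x$labels), x$method, max(x$height)))
  invisible(x)
}

#' Agglomerative clustering of a distance matrix
#'
#' Iteratively unites the two closest clusters, starting from singletons,
#' and records the merge at the inter-cluster distance current when the
#' pair is united.  Inter-cluster distances are maintained with the
#' Lance-Williams recursions: UPGMA uses the size-weighted (true
#' group-average) update
#' `D(X+Y, Z) = (|X| D(X,Z) + |Y| D(Y,Z)) / (|X| + |Y|)`, single linkage
#' the minimum and complete linkage the maximum.  Ties between equally
#' close pairs are broken deterministically in favour of the pair whose
#' member clusters contain the smallest original row indices, so the
#' dendrogram is reproducible regardless of storage order.
#'
#' @param m Symmetric distance matrix with accession dimnames (e.g. from
#'   [distance_matrix()] or [read_phylip_matrix()]).
#' @param method One of `"upgma"`, `"single"`, `"complete"`.
#' @return An [new_dendrogram()] object.
#' @examples
#' m <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' agglomerate(m, "upgma")$height   # 2 then (6 + 8) / 2 = 7
#' @export
agglomerate <- function(m, method = c("upgma", "single", "complete")) {
  method <- match.arg(method)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (anyNA(m)) stop("distance matrix contains NA/NaN", call. = FALSE)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))

  D <- m
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  tag <- seq_len(n)          # smallest original index in each cluster
  node <- -seq_len(n)        # hclust-style id of the cluster in each slot
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    # candidate pairs at the minimum, tie-broken on original-index tags
    hits <- which(sub == dmin, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    a <- idx[hits[, 1]]; b <- idx[hits[, 2]]
    lo <- pmin(tag[a], tag[b]); hi <- pmax(tag[a], tag[b])
    pick <- order(lo, hi)[1L]
    i <- a[pick]; j <- b[pick]

    height[step] <- dmin
    merge[step, ] <- .order_merge_pair(node[i], node[j])
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      di <- D[i, others]; dj <- D[j, others]
      D[i, others] <- switch(method,
        upgma = (size[i] * di + size[j] * dj) / (size[i] + size[j]),
        single = pmin(di, dj),
        complete = pmax(di, dj))
      D[others, i] <- D[i, others]
    }
    size[i] <- size[i] + size[j]
    tag[i] <- min(tag[i], tag[j])
    node[i] <- step
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  new_dendrogram(merge, height, labels, method)
}

# canonical child order of a merge row: leaves before earlier merges,
# each kind by increasing original index / step
.order_merge_pair <- function(a, b) {
  pair <- c(a, b)
  pair[order(pair >= 0L, abs(pair))]
}

#' Enumerate every cluster of a dendrogram
#'
#' Each of the `2n - 1` nodes of the dendrogram (the `n` leaves plus the
#' `n - 1` merges) identifies one cluster: the set of leaves of the
#' subtree rooted there, at that node's height (zero for leaves).
#'
#' @param t An `rna_dendrogram`.
#' @return A list of `2n - 1` entries, each `list(members, height)` with
#'   `members` a character vector of accessions.  Leaves come first in
#'   label order, then merges in merge order.
#' @export
all_clusters <- function(t) {
  stopifnot(inherits(t, "rna_dendrogram"))
  n <- length(t$labels)
  leaves <- lapply(seq_len(n), function(i)
    list(members = t$labels[i], height = 0))
  merged <- vector("list", n - 1L)
  members_of <- function(k)
    if (k < 0L) t$labels[-k] else merged[[k]]$members
  for (s in seq_len(n - 1L)) {
    merged[[s]] <- list(
      members = c(members_of(t$merge[s, 1]), members_of(t$merge[s, 2])),
      height = t$height[s])
  }
  c(leaves, merged)
}

#' Newick export of a dendrogram
#'
#' Branch lengths are height differences `h(parent) - h(child)`, so the
#' tree is ultrametric with all leaves at depth equal to the root height.
#' The root height is also recorded in a bracket comment before the final
#' semicolon, letting a reader recover absolute node heights by
#' subtracting root-to-node path lengths.  Labels containing Newick
#' metacharacters are single-quoted.
#'
#' @param t An `rna_dendrogram`.
#' @param digits Number of significant digits for branch lengths.
#' @return A single Newick string terminated by `;`.
#' @export
to_newick <- function(t, digits = 10) {
  stopifnot(inherits(t, "rna_dendrogram"))
  n <- length(t$labels)
  fmt <- function(x) format(x, digits = digits, trim = TRUE,
                            scientific = FALSE)
  quote_label <- function(lab) {
    if (grepl("[][(),:;'_[:space:]]", lab))
      paste0("'", gsub("'", "''", lab), "'")
    else lab
  }
  build <- function(k) {
    # returns c(subtree_string_without_length, height_of_node)
    if (k < 0L) return(list(str = quote_label(t$labels[-k]), h = 0))
    l <- build(t$merge[k, 1]); r <- build(t$merge[k, 2])
    h <- t$height[k]
    list(str = paste0("(", l$str, ":", fmt(h - l$h), ",",
                      r$str, ":", fmt(h - r$h), ")"),
         h = h)
  }
  root <- build(n - 1L)
  paste0(root$str, "[&height=", fmt(root$h), "];")
}

#' Read an ultrametric Newick dendrogram back
#'
#' Parses a Newick string or file (comments in square brackets are
#' stripped) and reconstructs node heights bottom-up from the branch
#' lengths, assuming leaves sit at height zero.
#'
#' @param x A Newick string, or a file path when `file = TRUE`.
#' @param file Treat `x` as a path.
#' @return An `rna_dendrogram`.
#' @export
read_newick <- function(x, file = FALSE) {
  txt <- if (file) paste(readLines(x, warn = FALSE), collapse = "") else x
  txt <- gsub("\\[[^]]*\\]", "", txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  # undo single-quoting of labels with metacharacters
  quoted <- grepl("^'.*'$", tr$tip.label)
  tr$tip.label[quoted] <- gsub("''", "'",
                               gsub("^'|'$", "", tr$tip.label[quoted]))
  if (!ape::is.binary(tr) || !ape::is.rooted(tr))
    stop("dendrogram Newick must be rooted and binary", call. = FALSE)
  n <- length(tr$tip.label)
  # height of every node from the leaves up
  nheight <- numeric(n + tr$Nnode)
  children <- split(tr$edge[, 2], tr$edge[, 1])
  elen <- split(tr$edge.length, tr$edge[, 1])
  merged_id <- integer(n + tr$Nnode)   # ape node id -> merge row / -leaf
  merged_id[seq_len(n)] <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  row <- 0L
  visit <- function(v) {
    kids <- children[[as.character(v)]]
    if (is.null(kids)) return(invisible(NULL))
    for (k in kids) visit(k)
    lens <- elen[[as.character(v)]]
    hs <- nheight[kids] + lens
    if (diff(range(hs)) > 1e-6 * max(1, max(hs)))
      warning("non-ultrametric branch lengths; using the maximum height",
              call. = FALSE)
    nheight[v] <<- max(hs)
    row <<- row + 1L
    merge[row, ] <<- .order_merge_pair(merged_id[kids][1], merged_id[kids][2])
    height[row] <<- nheight[v]
    merged_id[v] <<- row
  }
  visit(n + 1L)
  new_dendrogram(merge, height, tr$tip.label, "newick")
}

#' Convert to a base-R hclust object
#'
#' Useful for plotting with [stats::plot.hclust()] and for cophenetic
#' distances via [stats::cophenetic()].
#'
#' @param x An `rna_dendrogram`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.rna_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  # build a valid leaf ordering by traversing the root
  ord <- integer(0)
  walk <- function(k) {
    if (k < 0L) ord <<- c(ord, -k)
    else { walk(x$merge[k, 1]); walk(x$merge[k, 2]) }
  }
  walk(n - 1L)
  structure(list(merge = x$merge, height = x$height, order = ord,
                 labels = x$labels,
                 method = x$method, call = match.call(),
                 dist.method = "tree_edit"),
            class = "hclust")
}

#' Leaf accessions in dendrogram display order
#'
#' @param t An `rna_dendrogram`.
#' @return Character vector of the `n` leaf labels in the order induced by
#'   the merge tree's child order.
#' @export
leaf_order <- function(t) {
  stopifnot(inherits(t, "rna_dendrogram"))
  t$labels[as.hclust(t)$order]
}
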