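# Per-subtype normalisation and complete-linkage clustering under the
# Chebyshev (maximum) metric.
#
# Each subtype column is min-max scaled to [0,1] before clustering so
# that subtypes with very different literature volumes are comparable.
# Gene profiles are then agglomerated with complete (maximum) linkage,
# where the distance between profiles is the Chebyshev maximum
# coordinate difference. The agglomerator is written here rather than
# delegated because reproducibility demands a documented tie-break:
# among minimum-distance cluster pairs the pair with the
# lexicographically earliest (label, label) pair wins, a cluster being
# labelled by its lexicographically smallest leaf.

#' Min-max normalise each subtype column
#'
#' `v' = (v - min) / (max - min)` per column; a constant column (no
#' contrast) maps to all zeros. Every non-constant column spans exactly
#' \[0, 1\] afterwards.
#'
#' @param matrix Numeric gene-by-subtype matrix (non-empty).
#' @param method `"minmax"` (default) or `"zscore"` (per-column
#'   standardisation; constant columns again map to zeros).
#' @return Numeric matrix of the same shape.
#' @export
normalize_per_subtype <- function(matrix, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1L, ncol(matrix) >= 1L)
  out <- apply(matrix, 2L, function(v) {
    if (method == "minmax") {
      r <- range(v)
      if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
    } else {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
  })
  out <- matrix(out, nrow = nrow(matrix), dimnames = dimnames(matrix))
  out
}

#' Chebyshev (maximum) distance
#'
#' @param u,v Numeric vectors of equal positive length.
#' @return `max_i |u_i - v_i|`.
#' @export
chebyshev <- function(u, v) {
  if (length(u) != length(v) || length(u) < 1L)
    stop("vectors must have equal positive length", call. = FALSE)
  max(abs(u - v))
}

# Pairwise Chebyshev distance matrix for the rows of m.
.chebyshev_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    di <- apply(abs(sweep(m, 2L, m[i, ], "-")), 1L, max)
    d[i, ] <- di
  }
  d
}

#' Agglomerative complete-linkage clustering under Chebyshev distance
#'
#' Starts from singletons and repeatedly merges the pair of clusters
#' with the smallest inter-cluster distance, defined as the maximum
#' Chebyshev distance over cross-pairs (the Lance-Williams complete
#' update). Ties are broken deterministically: among minimal pairs, the
#' one whose (smallest-leaf, smallest-leaf) label pair sorts first.
#'
#' @param matrix Numeric matrix with at least 2 uniquely named rows
#'   (typically a [normalize_per_subtype()] output).
#' @return An object of class `"gene_dendro"`: list with `merge`
#'   (hclust-style merge matrix), `height`, `labels`, `members` (leaf
#'   sets per merge step) and `order` (the deterministic leaf order).
#'   It can be coerced with [as.hclust()].
#' @export
complete_linkage <- function(matrix) {
  stopifnot(is.matrix(matrix))
  n <- nrow(matrix)
  if (n < 2L) stop("need at least 2 rows to cluster", call. = FALSE)
  labels <- rownames(matrix)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (anyDuplicated(labels)) stop("row labels must be unique", call. = FALSE)

  d <- .chebyshev_dist(matrix)
  active <- seq_len(n)                # indices into bookkeeping vectors
  node_of <- -seq_len(n)              # hclust code: -leaf or +merge step
  min_leaf <- labels                  # tie-break label per cluster
  members <- lapply(seq_len(n), function(i) labels[i])

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  merge_members <- vector("list", n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (ii in seq_len(k - 1L)) for (jj in seq.int(ii + 1L, k)) {
      i <- active[ii]; j <- active[jj]
      dij <- d[i, j]
      lab <- sort(c(min_leaf[i], min_leaf[j]))
      cand <- list(d = dij, lab1 = lab[1], lab2 = lab[2], i = i, j = j)
      if (is.null(best) || dij < best$d ||
          (dij == best$d && (cand$lab1 < best$lab1 ||
                             (cand$lab1 == best$lab1 && cand$lab2 < best$lab2))))
        best <- cand
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(node_of[i], node_of[j]))
    height[step] <- best$d
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    merge_members[[step]] <- members[[i]]
    # complete-linkage Lance-Williams update into slot i
    for (o in setdiff(active, c(i, j)))
      d[i, o] <- d[o, i] <- max(d[i, o], d[j, o])
    node_of[i] <- step
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
    active <- setdiff(active, j)
  }
  dn <- structure(list(merge = merge, height = height, labels = labels,
                       members = merge_members),
                  class = "gene_dendro")
  dn$order <- match(leaf_order(dn), labels)
  dn
}

#' @export
print.gene_dendro <- function(x, ...) {
  cat("<gene_dendro> ", length(x$labels), " leaves, root height ",
      format(max(x$height)), "\n", sep = "")
  invisible(x)
}

#' Coerce a dendrogram to hclust
#'
#' @param x A `"gene_dendro"` object.
#' @param ... Unused.
#' @return A `stats::hclust` object (plottable, cuttable).
#' @export
as.hclust.gene_dendro <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "complete",
                 dist.method = "chebyshev", call = match.call()),
            class = "hclust")
}

#' Deterministic left-to-right leaf order
#'
#' Depth-first traversal placing, at every internal node, the child that
#' contains the lexicographically smallest leaf on the left.
#'
#' @param dendrogram A [complete_linkage()] result.
#' @return Character vector of row labels in display order.
#' @export
leaf_order <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "gene_dendro"))
  labels <- dendrogram$labels
  walk <- function(code) {
    if (code < 0L) return(labels[-code])
    l <- walk(dendrogram$merge[code, 1])
    r <- walk(dendrogram$merge[code, 2])
    if (min(l) <= min(r)) c(l, r) else c(r, l)
  }
  walk(nrow(dendrogram$merge))
}

#' Is a label set monophyletic in the dendrogram?
#'
#' True when some cluster formed during agglomeration contains exactly
#' the given labels (or the set is a single leaf).
#'
#' @param dendrogram A [complete_linkage()] result.
#' @param labels Character vector of leaf labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(dendrogram, labels) {
  labels <- sort(unique(labels))
  stopifnot(all(labels %in% dendrogram$labels))
  if (length(labels) <= 1L) return(TRUE)
  any(vapply(dendrogram$members, function(m) identical(m, labels), logical(1)))
}

#' Serialise a dendrogram as a Newick string
#'
#' Ultrametric tree: each branch length is the parent merge height minus
#' the child's height (leaves have height 0); children are ordered by the
#' [leaf_order()] rule.
#'
#' @param dendrogram A [complete_linkage()] result.
#' @param digits Significant digits for branch lengths.
#' @return Newick string terminated with `";"`.
#' @export
dendro_to_newick <- function(dendrogram, digits = 10) {
  labels <- dendrogram$labels
  h <- dendrogram$height
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  node <- function(code, parent_h) {
    if (code < 0L)
      return(list(s = paste0(labels[-code], ":", fmt(parent_h)),
                  min = labels[-code]))
    l <- node(dendrogram$merge[code, 1], h[code])
    r <- node(dendrogram$merge[code, 2], h[code])
    if (l$min > r$min) { tmp <- l; l <- r; r <- tmp }
    list(s = paste0("(", l$s, ",", r$s, "):", fmt(parent_h - h[code])),
         min = min(l$min, r$min))
  }
  root <- nrow(dendrogram$merge)
  top <- node(root, h[root])
  paste0(sub(":[^:)]*$", "", top$s), ";")
}

#' Dendrogram merge table
#'
#' @param dendrogram A [complete_linkage()] result.
#' @return A data.frame `step`, `cluster1`, `cluster2` (each cluster
#'   named by its smallest leaf), `height`, `new_size`.
#' @export
merge_table <- function(dendrogram) {
  labels <- dendrogram$labels
  name_of <- function(code)
    if (code < 0L) labels[-code] else dendrogram$members[[code]][1]
  size_of <- function(code)
    if (code < 0L) 1L else length(dendrogram$members[[code]])
  n1 <- vapply(dendrogram$merge[, 1], name_of, character(1))
  n2 <- vapply(dendrogram$merge[, 2], name_of, character(1))
  sw <- n1 > n2
  tmp <- n1[sw]; n1[sw] <- n2[sw]; n2[sw] <- tmp
  data.frame(
    step = seq_along(dendrogram$height),
    cluster1 = n1, cluster2 = n2,
    height = dendrogram$height,
    new_size = vapply(dendrogram$merge[, 1], size_of, integer(1)) +
      vapply(dendrogram$merge[, 2], size_of, integer(1)),
    stringsAsFactors = FALSE
  )
}
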