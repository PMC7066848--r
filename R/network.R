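# Protein-interaction subnetwork induced on mined genes.
#
# Interaction evidence arrives as undirected edge lists (plain 2-column
# TSV or PSI-MI-TAB-like). The network stage keeps genes mined at least
# `min_count` times, induces the subgraph just among those genes (never
# their neighbours), deletes self-loops and isolated nodes, and ranks the
# remaining nodes by degree.

#' Load interaction edge files
#'
#' Each file is 2-column TSV or PSI-MI-TAB-like; only the first two
#' columns are used and interactor database prefixes such as
#' `"entrez gene:"` or `"uniprotkb:"` are stripped. Edges are
#' canonicalised as unordered pairs; duplicates within and across files
#' are merged with the union of their source tags. `#` comment lines are
#' skipped.
#'
#' @param paths Character vector of file paths; names (or basenames) are
#'   used as source tags.
#' @return An `"interaction_set"` data.frame: `a`, `b` (with `a <= b`),
#'   `sources` (`";"`-joined tags).
#' @export
load_interactions <- function(paths) {
  tags <- if (!is.null(names(paths)) && all(nzchar(names(paths))))
    names(paths) else basename(paths)
  pieces <- lapply(seq_along(paths), function(i) {
    lines <- readLines(paths[[i]], warn = FALSE)
    keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
    idx <- which(keep)
    if (length(idx) == 0L)
      return(data.frame(a = character(0), b = character(0),
                        source = character(0), stringsAsFactors = FALSE))
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad))
      stop("file '", paths[[i]], "' line ", idx[bad[1]],
           ": fewer than 2 columns", call. = FALSE)
    a <- vapply(parts, `[[`, character(1), 1L)
    b <- vapply(parts, `[[`, character(1), 2L)
    # strip PSI-MI-TAB interactor prefixes ("entrez gene:1234" -> "1234")
    a <- sub("^[A-Za-z][A-Za-z _.-]*:", "", trimws(a))
    b <- sub("^[A-Za-z][A-Za-z _.-]*:", "", trimws(b))
    if (any(!nzchar(a) | !nzchar(b)))
      stop("file '", paths[[i]], "': empty interactor identifier",
           call. = FALSE)
    data.frame(a = a, b = b, source = tags[[i]], stringsAsFactors = FALSE)
  })
  e <- do.call(rbind, pieces)
  if (nrow(e) == 0L)
    return(structure(data.frame(a = character(0), b = character(0),
                                sources = character(0),
                                stringsAsFactors = FALSE),
                     class = c("interaction_set", "data.frame")))
  lo <- pmin(e$a, e$b); hi <- pmax(e$a, e$b)
  key <- paste(lo, hi, sep = "\r")
  src <- vapply(split(e$source, key),
                function(s) paste(sort(unique(s)), collapse = ";"),
                character(1))
  u <- !duplicated(key)
  out <- data.frame(a = lo[u], b = hi[u],
                    sources = unname(src[key[u]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interaction_set", "data.frame"))
}

#' Induce the interaction network on frequently mined genes
#'
#' Candidate nodes are the genes of `genes` with `count >= min_count`
#' (genes mined fewer than 3 times are excluded by default). Only edges
#' with both endpoints among the candidates are kept — the network is
#' built just among the input genes, never their neighbours. Self-loops
#' are dropped, then nodes left without any edge.
#'
#' @param genes A [count_genes()] table (columns `gene_id`, `count`).
#' @param interactions A [load_interactions()] set.
#' @param min_count Minimum mining count for a gene to enter the network.
#' @return An undirected simple [igraph::graph] whose vertex names are
#'   gene ids; possibly empty.
#' @export
induce_network <- function(genes, interactions, min_count = 3) {
  stopifnot(min_count >= 0)
  cand <- genes$gene_id[genes$count >= min_count]
  keep <- interactions$a %in% cand & interactions$b %in% cand &
    interactions$a != interactions$b
  e <- interactions[keep, c("a", "b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Degree table of a network
#'
#' @param network An undirected [igraph::graph].
#' @param lexicon Optional lexicon to attach canonical symbols.
#' @return A data.frame `node`, (`symbol`,) `degree`, sorted by degree
#'   descending then node ascending.
#' @export
degree_table <- function(network, lexicon = NULL) {
  d <- igraph::degree(network)
  out <- data.frame(node = names(d), degree = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  if (!is.null(lexicon))
    out <- cbind(out[, "node", drop = FALSE],
                 symbol = lexicon_symbols(out$node, lexicon),
                 out[, "degree", drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Top nodes by degree
#'
#' Keeps nodes with degree strictly greater than `min_degree` (the hub
#' table convention "degree > 20").
#'
#' @param table A [degree_table()].
#' @param min_degree Non-negative integer.
#' @return Filtered table, order preserved.
#' @export
top_nodes <- function(table, min_degree) {
  stopifnot(min_degree >= 0)
  out <- table[table$degree > min_degree, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map interaction identifiers through the lexicon
#'
#' Edge files keyed by gene symbol are mapped onto lexicon gene ids
#' before induction; endpoints that match no lexicon key are dropped
#' (with a message giving the count).
#'
#' @param interactions A [load_interactions()] set.
#' @param lexicon A [load_gene_lexicon()] object.
#' @return An `"interaction_set"` on gene ids.
#' @export
map_interactions <- function(interactions, lexicon) {
  key2id <- stats::setNames(lexicon$gene_id, tolower(lexicon$key))
  syms <- attr(lexicon, "symbols")
  a <- ifelse(interactions$a %in% names(syms), interactions$a,
              key2id[tolower(interactions$a)])
  b <- ifelse(interactions$b %in% names(syms), interactions$b,
              key2id[tolower(interactions$b)])
  drop <- is.na(a) | is.na(b)
  if (any(drop))
    message(sum(drop), " edge(s) with unmappable endpoints dropped")
  out <- data.frame(a = pmin(a[!drop], b[!drop]),
                    b = pmax(a[!drop], b[!drop]),
                    sources = interactions$sources[!drop],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$a, out$b, sep = "\r")), , drop = FALSE]
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interaction_set", "data.frame"))
}
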