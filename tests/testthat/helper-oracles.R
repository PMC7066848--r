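# Independent brute-force oracles. These deliberately avoid the package's
# matching machinery (PCRE lookarounds, greedy overlap resolution, igraph,
# Lance-Williams updates): fixed-string scans with manual boundary checks,
# exhaustive enumeration, incidence recounts and a recompute-from-raw
# agglomerator.

# all boundary-valid fixed occurrences of `needle` in each of `haystacks`
.oracle_has_key <- function(haystacks, needle, case_sensitive = FALSE) {
  hay <- if (case_sensitive) haystacks else tolower(haystacks)
  ndl <- if (case_sensitive) needle else tolower(needle)
  hits <- gregexpr(ndl, hay, fixed = TRUE)
  vapply(seq_along(hay), function(i) {
    m <- hits[[i]]
    if (m[1] == -1L) return(FALSE)
    any(vapply(as.integer(m), function(p) {
      before <- if (p > 1L) substr(hay[i], p - 1L, p - 1L) else ""
      after_pos <- p + nchar(ndl)
      after <- if (after_pos <= nchar(hay[i]))
        substr(hay[i], after_pos, after_pos) else ""
      !grepl("[[:alnum:]]", before) && !grepl("[[:alnum:]]", after)
    }, logical(1)))
  }, logical(1))
}

# gene count table + subtype matrix by brute-force recount: loop over
# abstracts and sentences, scan every lexicon key and term with the
# fixed-string matcher above
oracle_recount <- function(corpus, genes_df, include_title = TRUE) {
  sets <- default_term_sets()
  key_rows <- do.call(rbind, lapply(seq_len(nrow(genes_df)), function(i) {
    syn <- if (nzchar(genes_df$synonyms[i]))
      strsplit(genes_df$synonyms[i], "|", fixed = TRUE)[[1]] else character(0)
    data.frame(gene_id = genes_df$gene_id[i],
               key = c(genes_df$symbol[i], syn), stringsAsFactors = FALSE)
  }))
  key_rows$cs <- nchar(key_rows$key) <= 3 & key_rows$key == toupper(key_rows$key) &
    grepl("[A-Z]", key_rows$key)

  sents <- character(0)
  for (ab in corpus)
    sents <- c(sents, c(if (include_title) split_sentences(ab$title),
                        split_sentences(ab$body)))

  gene_hit <- matrix(FALSE, length(sents), nrow(genes_df),
                     dimnames = list(NULL, genes_df$gene_id))
  for (j in seq_len(nrow(key_rows))) {
    g <- key_rows$gene_id[j]
    gene_hit[, g] <- gene_hit[, g] |
      .oracle_has_key(sents, key_rows$key[j], key_rows$cs[j])
  }
  has_drug <- Reduce(`|`, lapply(sets$drug$terms, function(tm)
    .oracle_has_key(sents, tm)))
  has_res <- Reduce(`|`, lapply(sets$resistance$terms, function(tm)
    .oracle_has_key(sents, tm)))
  labels <- sort(unique(unname(sets$subtype$labels)))
  lab_hit <- matrix(FALSE, length(sents), length(labels),
                    dimnames = list(NULL, labels))
  for (tm in sets$subtype$terms) {
    l <- unname(sets$subtype$labels[[tm]])
    lab_hit[, l] <- lab_hit[, l] | .oracle_has_key(sents, tm)
  }

  ev <- gene_hit & (has_drug & has_res)
  counts <- stats::setNames(as.integer(colSums(ev)), genes_df$gene_id)
  subm <- matrix(0L, nrow(genes_df), length(labels),
                 dimnames = list(genes_df$gene_id, labels))
  for (l in labels)
    subm[, l] <- as.integer(colSums(gene_hit & lab_hit[, l]))
  list(counts = counts, subtype = subm)
}

# P(X >= k) by exhaustive enumeration of all C(N, n) draws
oracle_hyper_tail <- function(k, K, n, N) {
  if (n == 0L || N == 0L) return(if (k == 0L) 1 else 0)
  draws <- utils::combn(N, n)
  overl <- apply(draws <= K, 2L, sum)
  mean(overl >= k)
}

# per-node incident-edge count from a plain edge data.frame
oracle_degrees <- function(edges) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  stats::setNames(vapply(nodes, function(v)
    sum(edges$a == v) + sum(edges$b == v), integer(1)), nodes)
}

# naive complete-linkage/Chebyshev agglomerator: recompute every
# cluster-pair distance from the raw rows at every step; same
# lexicographic tie rule as the contract demands
oracle_agglomerate <- function(m) {
  labs <- rownames(m)
  clusters <- lapply(labs, identity)
  heights <- numeric(0)
  merged <- list()
  cheb <- function(a, b) max(abs(m[a, ] - m[b, ]))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq.int(i + 1L, length(clusters))) {
        d <- max(vapply(clusters[[i]], function(a)
          max(vapply(clusters[[j]], function(b) cheb(a, b), numeric(1))),
          numeric(1)))
        lab <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || d < best$d ||
            (d == best$d && (lab[1] < best$lab[1] ||
               (lab[1] == best$lab[1] && lab[2] < best$lab[2]))))
          best <- list(d = d, lab = lab, i = i, j = j)
      }
    heights <- c(heights, best$d)
    newc <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merged[[length(merged) + 1L]] <- newc
    clusters[[best$i]] <- newc
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, members = merged)
}

# small two-gene lexicon used across unit tests
tiny_lexicon <- function() {
  load_gene_lexicon(c("7157\tTP53\tp53",
                      "672\tBRCA1\t",
                      "596\tBCL2\tBcl-2"))
}
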