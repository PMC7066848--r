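# Sentence-level co-occurrence mining.
#
# The counting rule: a gene earns one count for every distinct sentence
# in which it co-appears with at least one drug term AND at least one
# resistance term. A gene mentioned several times in one sentence is
# counted once. The gene-by-subtype matrix applies the same
# one-per-sentence rule to gene/subtype-term co-occurrence.

#' Mine gene-drug-resistance co-occurrence events
#'
#' Scans every sentence of the corpus; a gene yields one event per
#' sentence that contains a mention of the gene, a drug term and a
#' resistance term. Duplicate mentions within a sentence are collapsed.
#'
#' @param corpus List of [abstract] objects.
#' @param lexicon A [load_gene_lexicon()] object.
#' @param drug,resistance [term_set()] objects (defaults from
#'   [default_term_sets()]).
#' @param include_title Mine titles as well as abstract bodies.
#' @return A data.frame with one row per event: `pmid`, `sentence_index`,
#'   `gene_id`, `drug_labels`, `resistance_labels` (matched labels joined
#'   with `";"`).
#' @export
mine_events <- function(corpus, lexicon,
                        drug = default_term_sets()$drug,
                        resistance = default_term_sets()$resistance,
                        include_title = TRUE) {
  sent <- corpus_sentences(corpus, include_title = include_title)
  empty <- data.frame(pmid = character(0), sentence_index = integer(0),
                      gene_id = character(0), drug_labels = character(0),
                      resistance_labels = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(sent) == 0L) return(empty)
  txt <- normalize_text(sent$text)
  dlab <- .sentence_term_labels(txt, drug)
  rlab <- .sentence_term_labels(txt, resistance)
  eligible <- which(lengths(dlab) > 0L & lengths(rlab) > 0L)
  if (length(eligible) == 0L) return(empty)
  genes <- .sentence_genes(txt[eligible], lexicon)
  if (nrow(genes) == 0L) return(empty)
  sidx <- eligible[genes$sent]
  out <- data.frame(
    pmid = sent$pmid[sidx],
    sentence_index = sent$index[sidx],
    gene_id = genes$gene_id,
    drug_labels = vapply(dlab[sidx], paste, character(1), collapse = ";"),
    resistance_labels = vapply(rlab[sidx], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$pmid, out$sentence_index, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene frequency table from mined events
#'
#' @param events Output of [mine_events()].
#' @param lexicon Optional lexicon used to attach canonical symbols.
#' @return A data.frame `gene_id`, (`symbol`,) `count`, sorted by count
#'   descending then gene_id ascending.
#' @export
count_genes <- function(events, lexicon = NULL) {
  if (nrow(events) == 0L) {
    out <- data.frame(gene_id = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    tab <- table(events$gene_id)
    out <- data.frame(gene_id = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$gene_id), , drop = FALSE]
  }
  if (!is.null(lexicon))
    out <- cbind(out[, "gene_id", drop = FALSE],
                 symbol = lexicon_symbols(out$gene_id, lexicon),
                 out[, "count", drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Filter a gene count table by minimum count
#'
#' Keeps rows with `count >= min_count` (the frequency-table convention:
#' "count at least 15"), preserving order.
#'
#' @param table Output of [count_genes()].
#' @param min_count Non-negative integer threshold.
#' @return Filtered table.
#' @export
filter_by_count <- function(table, min_count) {
  stopifnot(min_count >= 0)
  out <- table[table$count >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-by-subtype co-occurrence matrix
#'
#' Counts, for every gene and histological-subtype label, the number of
#' distinct sentences containing a mention of the gene and a term of the
#' subtype. Terms sharing one label ("clear cell", "OCCC") contribute one
#' count per sentence, not two. Genes with all-zero rows are excluded;
#' columns are exactly the subtype label set. The co-occurrence scope
#' (sentence vs whole abstract) is configurable; sentence scope mirrors
#' the gene-drug rule and is the default.
#'
#' @param corpus List of [abstract] objects.
#' @param lexicon A [load_gene_lexicon()] object.
#' @param subtype Subtype [term_set()].
#' @param include_title Mine titles too.
#' @param scope `"sentence"` (default) or `"abstract"`.
#' @return Integer matrix, rownames gene_ids (sorted), colnames subtype
#'   labels.
#' @export
build_subtype_matrix <- function(corpus, lexicon,
                                 subtype = default_term_sets()$subtype,
                                 include_title = TRUE,
                                 scope = c("sentence", "abstract")) {
  scope <- match.arg(scope)
  sent <- corpus_sentences(corpus, include_title = include_title)
  labels <- sort(unique(unname(subtype$labels)))
  if (scope == "abstract" && nrow(sent) > 0L) {
    # pool each record's sentences into one matching unit
    pooled <- vapply(split(sent$text, sent$pmid), paste, character(1),
                     collapse = " ")
    sent <- data.frame(pmid = names(pooled), index = 0L,
                       text = unname(pooled), stringsAsFactors = FALSE)
  }
  empty <- matrix(0L, nrow = 0, ncol = length(labels),
                  dimnames = list(character(0), labels))
  if (nrow(sent) == 0L) return(empty)
  txt <- normalize_text(sent$text)
  slab <- .sentence_term_labels(txt, subtype)
  eligible <- which(lengths(slab) > 0L)
  if (length(eligible) == 0L) return(empty)
  genes <- .sentence_genes(txt[eligible], lexicon)
  if (nrow(genes) == 0L) return(empty)
  pairs <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    labs <- slab[[eligible[genes$sent[i]]]]
    data.frame(gene_id = genes$gene_id[i], label = labs,
               stringsAsFactors = FALSE)
  }))
  gid <- sort(unique(pairs$gene_id))
  m <- matrix(0L, nrow = length(gid), ncol = length(labels),
              dimnames = list(gid, labels))
  tab <- table(pairs$gene_id, pairs$label)
  m[rownames(tab), colnames(tab)] <- as.integer(tab)
  m
}
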