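# Annotation-term over-representation.
#
# For a query gene set (the mined genes) and an annotation map
# (term -> annotated genes over a finite background), each term is tested
# with the one-sided hypergeometric upper tail P(X >= k) and corrected
# with the Bonferroni method.

#' Load an annotation map
#'
#' Accepts 2/3-column TSV (`term_id<TAB>gene_id[<TAB>term_name]`) or
#' GAF 2.x (column 2 = gene, column 5 = term; `!` header lines skipped).
#' Gene sets are deduplicated. The background defaults to the union of
#' all annotated genes unless `background` is supplied.
#'
#' @param con File path or character vector of lines.
#' @param background Optional character vector of background gene ids; it
#'   must cover every annotated gene.
#' @return An `"annotation_map"` object: list with `terms` (named list of
#'   gene-id vectors), `term_names` (named character), `background`.
#' @export
load_annotations <- function(con, background = NULL) {
  lines <- .as_lines(con)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "!")
  idx <- which(keep)
  if (length(idx) == 0L) stop("annotation input is empty", call. = FALSE)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(parts)
  rows <- lapply(seq_along(parts), function(j) {
    p <- parts[[j]]
    if (length(p) >= 15L) {              # GAF 2.x
      term <- p[5]; gene <- p[2]; nm <- NA_character_
    } else if (length(p) >= 2L) {        # TSV
      term <- p[1]; gene <- p[2]
      nm <- if (length(p) >= 3L && nzchar(p[3])) p[3] else NA_character_
    } else {
      stop("malformed annotation line ", idx[j], ": fewer than 2 columns",
           call. = FALSE)
    }
    if (!nzchar(term) || !nzchar(gene))
      stop("malformed annotation line ", idx[j], ": empty field", call. = FALSE)
    c(term, gene, nm)
  })
  term <- vapply(rows, `[[`, character(1), 1L)
  gene <- vapply(rows, `[[`, character(1), 2L)
  nm <- vapply(rows, `[[`, character(1), 3L)
  terms <- lapply(split(gene, term), function(g) sort(unique(g)))
  term_names <- vapply(split(nm, term), function(v) {
    v <- v[!is.na(v)]; if (length(v)) v[[1]] else NA_character_
  }, character(1))
  universe <- sort(unique(gene))
  if (is.null(background)) {
    background <- universe
  } else {
    background <- sort(unique(as.character(background)))
    miss <- setdiff(universe, background)
    if (length(miss))
      stop("annotated genes missing from supplied background: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(terms = terms, term_names = term_names,
                 background = background),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("<annotation_map> ", length(x$terms), " terms over ",
      length(x$background), " background genes\n", sep = "")
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without
#' replacement from a background of `N` genes of which `K` are annotated.
#' Evaluated with the log-space-stable distribution function in `stats`.
#'
#' @param k Observed overlap (vectorised).
#' @param K Annotated genes in the background.
#' @param n Query size.
#' @param N Background size.
#' @return Probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  p <- cbind(k = k, K = K, n = n, N = N)  # recycle to common length
  k <- p[, "k"]; K <- p[, "K"]; n <- p[, "n"]; N <- p[, "N"]
  if (any(K < 0 | K > N | n < 0 | n > N | k < 0 | k > pmin(K, n)))
    stop("require 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)",
         call. = FALSE)
  unname(stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' `p_corrected = min(1, m * p)`, preserving order. `m` must be at least
#' the number of p-values supplied (the number of tests performed).
#'
#' @param p_values Numeric vector in (0, 1].
#' @param m Number of tests.
#' @return Corrected p-values.
#' @export
bonferroni <- function(p_values, m) {
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (m < length(p_values)) stop("m must be >= number of p-values",
                                 call. = FALSE)
  pmin(1, m * p_values)
}

#' Term over-representation for a gene set
#'
#' Tests every annotation term with at least one query gene: with `N` the
#' background size, `K` the term's annotated genes, `n` the query genes
#' inside the background and `k` their overlap, the raw p-value is the
#' hypergeometric upper tail P(X >= k), Bonferroni-corrected over the `m`
#' tested terms (optionally over all terms in the map). Query genes
#' outside the background are dropped before `n` is computed.
#'
#' @param query Character vector of gene ids (non-empty).
#' @param ann An [load_annotations()] object.
#' @param m_all Correct over all terms in the map instead of only the
#'   tested (k >= 1) terms.
#' @return A data.frame `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_raw`, `p_corrected`, sorted by `p_corrected` then `term_id`, with
#'   attribute `n_dropped` (query genes outside the background).
#' @export
enrich <- function(query, ann, m_all = FALSE) {
  stopifnot(inherits(ann, "annotation_map"))
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("query is empty", call. = FALSE)
  inbg <- intersect(query, ann$background)
  n_dropped <- length(query) - length(inbg)
  if (n_dropped > 0L)
    message(n_dropped, " query gene(s) outside the background were dropped")
  if (length(inbg) == 0L)
    stop("no query gene lies in the annotation background", call. = FALSE)
  N <- length(ann$background)
  n <- length(inbg)
  k <- vapply(ann$terms, function(g) length(intersect(g, inbg)), integer(1))
  K <- lengths(ann$terms)
  tested <- k >= 1L
  m <- if (m_all) length(ann$terms) else sum(tested)
  out <- data.frame(
    term_id = names(ann$terms)[tested],
    term_name = unname(ann$term_names[names(ann$terms)[tested]]),
    k = unname(k[tested]), K = unname(K[tested]), n = n, N = N,
    stringsAsFactors = FALSE
  )
  out$p_raw <- hypergeom_upper_tail(out$k, out$K, out$n, out$N)
  out$p_corrected <- bonferroni(out$p_raw, m)
  out <- out[order(out$p_corrected, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "m") <- m
  out
}
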