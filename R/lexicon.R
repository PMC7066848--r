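# Gene lexicon and fixed keyword dictionaries.
#
# Gene recognition is deterministic dictionary matching against a
# user-supplied lexicon of identifiers, canonical symbols and synonyms
# (the stand-in for NER output verified against Entrez Gene). Drug,
# resistance and histological-subtype keywords are small fixed whole-word
# dictionaries.

# Short all-uppercase keys (<= this many characters) are matched
# case-sensitively: "CBP" must not fire inside ordinary words or on "cbp".
.CASE_SENSITIVE_MAX_NCHAR <- 3L

#' Load a gene lexicon from a TSV stream
#'
#' Each record is `gene_id<TAB>symbol<TAB>pipe-separated synonyms` (the
#' synonym column may be empty); `#` comment lines are skipped. The
#' canonical symbol is always a match key. Synonyms are deduplicated
#' case-insensitively, and a synonym claimed by two gene identifiers is a
#' load error: ambiguous keys would make counts irreproducible.
#'
#' @param con File path or character vector of lines.
#' @return A `"gene_lexicon"` object: a data.frame of match keys with
#'   columns `key`, `gene_id`, `case_sensitive`, plus attributes `entries`
#'   (the raw records) and `symbols` (named `gene_id -> symbol`).
#' @export
load_gene_lexicon <- function(con) {
  lines <- .as_lines(con)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("gene lexicon is empty", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  entries <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 2L || !nzchar(p[1]) || !nzchar(p[2]))
      stop("malformed lexicon record at line ", i, ": need gene_id<TAB>symbol",
           call. = FALSE)
    syn <- if (length(p) >= 3L && nzchar(p[3]))
      trimws(strsplit(p[3], "|", fixed = TRUE)[[1]]) else character(0)
    syn <- syn[nzchar(syn)]
    keys <- c(p[2], syn)
    keys <- keys[!duplicated(tolower(keys))]
    list(gene_id = p[1], symbol = p[2], keys = keys)
  })
  ids <- vapply(entries, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene_id in lexicon: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  key_tab <- data.frame(
    key = unlist(lapply(entries, `[[`, "keys"), use.names = FALSE),
    gene_id = rep(ids, vapply(entries, function(e) length(e$keys), integer(1))),
    stringsAsFactors = FALSE
  )
  low <- tolower(key_tab$key)
  for (k in unique(low[duplicated(low)])) {
    owners <- unique(key_tab$gene_id[low == k])
    if (length(owners) > 1L)
      stop("synonym '", k, "' claimed by gene_ids ",
           paste(owners, collapse = " and "), call. = FALSE)
  }
  key_tab <- key_tab[!duplicated(low), , drop = FALSE]
  key_tab$case_sensitive <- nchar(key_tab$key) <= .CASE_SENSITIVE_MAX_NCHAR &
    key_tab$key == toupper(key_tab$key) & grepl("[A-Z]", key_tab$key)
  # longest keys first so the greedy matcher prefers them
  key_tab <- key_tab[order(-nchar(key_tab$key), key_tab$key), , drop = FALSE]
  rownames(key_tab) <- NULL
  symbols <- vapply(entries, `[[`, character(1), "symbol")
  names(symbols) <- ids
  structure(key_tab, entries = entries, symbols = symbols,
            class = c("gene_lexicon", "data.frame"))
}

#' @export
print.gene_lexicon <- function(x, ...) {
  cat("<gene_lexicon> ", length(attr(x, "symbols")), " genes, ",
      nrow(x), " match keys\n", sep = "")
  invisible(x)
}

#' Map gene identifiers to canonical symbols
#'
#' @param gene_ids Character vector of identifiers.
#' @param lexicon A [load_gene_lexicon()] object.
#' @return Character vector of symbols (`NA` where unknown).
#' @export
lexicon_symbols <- function(gene_ids, lexicon) {
  unname(attr(lexicon, "symbols")[gene_ids])
}

#' Build a term set
#'
#' @param name One of `"drug"`, `"resistance"`, `"subtype"`.
#' @param terms Character vector of lowercase whole-word terms.
#' @param labels Optional named mapping `term -> label`; defaults to the
#'   terms themselves (several terms may share one label, as "clear cell"
#'   and "occc" both denote clear-cell carcinoma).
#' @return A `"term_set"` object.
#' @export
term_set <- function(name, terms, labels = NULL) {
  terms <- tolower(trimws(terms))
  stopifnot(length(terms) > 0L, all(nzchar(terms)))
  if (is.null(labels)) labels <- stats::setNames(terms, terms)
  stopifnot(all(terms %in% names(labels)))
  structure(list(name = name, terms = terms, labels = labels),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set '", x$name, "'> ", paste(x$terms, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' The default drug, resistance and subtype dictionaries
#'
#' Drug terms cover cisplatin/carboplatin and their shorthands
#' (platinum, platin, cisplatin, DDP, carboplatin, CBP); resistance terms
#' are "resistance" and "resistant"; subtype terms name the four
#' histological subtypes of ovarian cancer, with "clear cell" and "OCCC"
#' collapsed onto one clear-cell label.
#'
#' @return A named list with elements `drug`, `resistance`, `subtype`.
#' @export
default_term_sets <- function() {
  list(
    drug = term_set("drug", c("platinum", "platin", "cisplatin", "ddp",
                              "carboplatin", "cbp")),
    resistance = term_set("resistance", c("resistance", "resistant")),
    subtype = term_set(
      "subtype",
      c("serous", "mucinous", "endometrioid", "clear cell", "occc"),
      labels = c(serous = "serous", mucinous = "mucinous",
                 endometrioid = "endometrioid", "clear cell" = "clear_cell",
                 occc = "clear_cell"))
  )
}

#' Load term sets from a config file
#'
#' YAML mapping each set name to a list of terms; for `subtype`, entries
#' may be `term: label` pairs.
#'
#' @param path YAML file path.
#' @return Same shape as [default_term_sets()].
#' @export
load_term_sets <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- default_term_sets()
  for (nm in intersect(names(cfg), c("drug", "resistance", "subtype"))) {
    v <- cfg[[nm]]
    if (is.list(v) && !is.null(names(v)) && all(nzchar(names(v)))) {
      out[[nm]] <- term_set(nm, names(v), stats::setNames(unlist(v), tolower(names(v))))
    } else {
      out[[nm]] <- term_set(nm, unlist(v))
    }
  }
  out
}

.escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

.key_pattern <- function(key, case_sensitive) {
  # whole-token match: no letter/digit may flank the key; internal
  # punctuation (hyphens) is matched literally; whitespace in multiword
  # terms tolerates any run of whitespace
  body <- gsub("\\s+", "\\\\s+", .escape_regex(key))
  paste0(if (case_sensitive) "" else "(?i)",
         "(?<![\\p{L}\\p{N}])", body, "(?![\\p{L}\\p{N}])")
}

# Vectorised candidate scan: all whole-word key hits in each sentence.
# Returns data.frame(sent = index into `sentences`, gene_id, key, start, len).
.scan_candidates <- function(sentences, lexicon) {
  out <- vector("list", nrow(lexicon))
  for (i in seq_len(nrow(lexicon))) {
    pat <- .key_pattern(lexicon$key[i], lexicon$case_sensitive[i])
    m <- gregexpr(pat, sentences, perl = TRUE)
    hits <- lapply(m, function(mm) if (mm[1] == -1L) integer(0) else as.integer(mm))
    ns <- lengths(hits)
    if (sum(ns) == 0L) next
    out[[i]] <- data.frame(
      sent = rep(seq_along(sentences), ns),
      gene_id = lexicon$gene_id[i],
      key = lexicon$key[i],
      start = unlist(hits, use.names = FALSE),
      len = nchar(lexicon$key[i]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sent = integer(0), gene_id = character(0),
                      key = character(0), start = integer(0), len = integer(0),
                      stringsAsFactors = FALSE)
  out
}

# Resolve overlapping candidate spans: longer wins, then leftmost.
.resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  cand <- cand[order(-cand$len, cand$start), , drop = FALSE]
  taken_start <- integer(0)
  taken_end <- integer(0)
  keep <- logical(nrow(cand))
  for (j in seq_len(nrow(cand))) {
    s <- cand$start[j]; e <- cand$start[j] + cand$len[j] - 1L
    if (!any(s <= taken_end & e >= taken_start)) {
      keep[j] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand[order(cand$start), , drop = FALSE]
}

#' Find gene mentions in one sentence
#'
#' Whole-token dictionary matching against the lexicon's keys. Matching is
#' case-insensitive except for short all-uppercase keys (at most 3
#' characters, e.g. `"CBP"`), which match only case-sensitively to
#' suppress hits inside ordinary words. Overlapping candidates are
#' resolved in favour of the longer match, then the leftmost; returned
#' spans never overlap.
#'
#' @param sentence_text Character scalar.
#' @param lexicon A [load_gene_lexicon()] object.
#' @return A data.frame with columns `gene_id`, `matched_text`, `start`,
#'   `end` (0-based half-open character offsets), ordered by `start`.
#' @export
find_gene_mentions <- function(sentence_text, lexicon) {
  stopifnot(length(sentence_text) == 1L)
  cand <- .scan_candidates(sentence_text, lexicon)
  cand <- .resolve_overlaps(cand)
  if (nrow(cand) == 0L)
    return(data.frame(gene_id = character(0), matched_text = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  data.frame(
    gene_id = cand$gene_id,
    matched_text = substring(sentence_text, cand$start, cand$start + cand$len - 1L),
    start = cand$start - 1L,
    end = cand$start + cand$len - 1L,
    stringsAsFactors = FALSE
  )
}

# Vectorised per-sentence distinct gene sets (post overlap resolution).
# Returns data.frame(sent, gene_id), unique pairs.
.sentence_genes <- function(sentences, lexicon) {
  cand <- .scan_candidates(sentences, lexicon)
  if (nrow(cand) == 0L)
    return(data.frame(sent = integer(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  # overlap resolution only matters within a sentence; do it per sentence
  pieces <- split(cand, cand$sent)
  pieces <- lapply(pieces, .resolve_overlaps)
  res <- do.call(rbind, pieces)
  res <- unique(res[, c("sent", "gene_id")])
  res <- res[order(res$sent, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Match a term set in a sentence
#'
#' Case-insensitive whole-word (or whole-phrase) matching of every term in
#' the set; hyphens and other punctuation count as word boundaries, so
#' `"platinum-resistant"` matches both `"platinum"` and `"resistant"`.
#'
#' @param sentence_text Character scalar.
#' @param terms A [term_set()].
#' @return Character vector of the distinct matched term labels (possibly
#'   empty), sorted.
#' @export
contains_term <- function(sentence_text, terms) {
  stopifnot(length(sentence_text) == 1L, inherits(terms, "term_set"))
  hit <- vapply(terms$terms, function(tm)
    grepl(.key_pattern(tm, FALSE), sentence_text, perl = TRUE), logical(1))
  sort(unique(unname(terms$labels[terms$terms[hit]])))
}

# Vectorised term-label matrix: list over sentences of matched label sets.
.sentence_term_labels <- function(sentences, terms) {
  hit <- vapply(terms$terms, function(tm)
    grepl(.key_pattern(tm, FALSE), sentences, perl = TRUE),
    logical(length(sentences)))
  hit <- matrix(hit, nrow = length(sentences))
  labs <- unname(terms$labels[terms$terms])
  apply(hit, 1L, function(h) sort(unique(labs[h])), simplify = FALSE)
}
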