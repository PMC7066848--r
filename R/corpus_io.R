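# MEDLINE flat-file ingest and sentence segmentation.
#
# The unit of evidence in the whole pipeline is the sentence: a gene is
# linked to platinum resistance only when it co-appears with a drug term
# and a resistance term inside one sentence. Everything downstream
# therefore depends on a deterministic, testable segmentation of each
# titled abstract into sentences.

# Abbreviations that never terminate a sentence, matched case-insensitively
# as a suffix of the text preceding a candidate boundary.
.SENT_ABBREV <- c(
  "vs.", "et al.", "al.", "e.g.", "i.e.", "fig.", "figs.", "ref.",
  "no.", "approx.", "ca.", "cf.", "resp.", "etc.", "dr.", "st."
)

#' Construct an abstract record
#'
#' An abstract is one titled PubMed-style record: a PMID, a title and an
#' (optionally empty) abstract body. Title-only records are legal and
#' contribute their title's sentences to mining.
#'
#' @param pmid Non-empty character scalar, unique within a corpus.
#' @param title Character scalar (free text).
#' @param body Character scalar; `""` for title-only records.
#' @return An object of class `"abstract"` (a named list).
#' @export
abstract <- function(pmid, title = "", body = "") {
  stopifnot(is.character(pmid), length(pmid) == 1L, nzchar(pmid))
  structure(list(pmid = pmid, title = title, body = body),
            class = "abstract")
}

#' @export
print.abstract <- function(x, ...) {
  cat("<abstract ", x$pmid, "> ", x$title, "\n", sep = "")
  invisible(x)
}

#' Normalise text before segmentation and matching
#'
#' Applies Unicode NFKC normalisation and maps typographic quotes and
#' dashes to their ASCII equivalents, so that typography in a corpus
#' cannot defeat whole-word term matching.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  # NFKC leaves typographic quotes/dashes untouched; fold them explicitly.
  from <- c("‘", "’", "“", "”", "–", "—", " ")
  to <- c("'", "'", "\"", "\"", "-", "-", " ")
  stringi::stri_replace_all_fixed(x, from, to, vectorize_all = FALSE)
}

# accept a file path, a connection, a character vector of lines, or a
# single string with embedded newlines
.as_lines <- function(con) {
  if (is.character(con)) {
    if (length(con) != 1L) return(enc2utf8(con))
    if (grepl("\n", con, fixed = TRUE))
      return(enc2utf8(strsplit(con, "\n", fixed = TRUE)[[1]]))
    if (file.exists(con)) return(enc2utf8(readLines(con, warn = FALSE)))
    return(enc2utf8(con))
  }
  enc2utf8(readLines(con, warn = FALSE))
}

#' Parse a MEDLINE flat file into abstract records
#'
#' Reads the tagged flat-file format emitted by PubMed (`PMID-`, `TI  -`,
#' `AB  -` fields; continuation lines indented; records separated by blank
#' lines). Tags other than PMID/TI/AB are ignored. Multi-line fields are
#' joined with single spaces; records lacking an `AB` field get an empty
#' body.
#'
#' @param con Path to a MEDLINE file, or a character vector of lines
#'   (anything `readLines()`-compatible also works).
#' @return A list of [abstract] objects, in file order.
#' @examples
#' recs <- parse_medline(c("PMID- 1", "TI  - A title.", "AB  - Body text."))
#' recs[[1]]$title
#' @export
parse_medline <- function(con) {
  lines <- .as_lines(con)

  records <- list()
  seen <- character(0)
  cur <- NULL          # list(pmid=, fields=list(TAG=chr vector of parts))
  cur_tag <- NA_character_
  start_line <- NA_integer_

  flush_record <- function() {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$pmid)) {
      stop("MEDLINE record starting at line ", start_line,
           " has no PMID field", call. = FALSE)
    }
    if (cur$pmid %in% seen) {
      stop("duplicate PMID '", cur$pmid, "' in MEDLINE input", call. = FALSE)
    }
    seen[[length(seen) + 1L]] <<- cur$pmid
    ti <- paste(cur$fields[["TI"]] %||% character(0), collapse = " ")
    ab <- paste(cur$fields[["AB"]] %||% character(0), collapse = " ")
    records[[length(records) + 1L]] <<- abstract(cur$pmid, ti, ab)
    cur <<- NULL
    cur_tag <<- NA_character_
    invisible()
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush_record(); next }
    if (grepl("^[A-Z][A-Z0-9]{0,3}\\s*- ?", ln)) {
      m <- regexpr("^[A-Z][A-Z0-9]{0,3}", ln)
      tag <- regmatches(ln, m)
      val <- trimws(sub("^[A-Z][A-Z0-9]{0,3}\\s*- ?", "", ln))
      if (is.null(cur)) { cur <- list(pmid = NULL, fields = list()); start_line <- i }
      if (tag == "PMID") {
        if (!is.null(cur$pmid)) {
          # a second PMID without a blank separator starts a new record
          flush_record(); cur <- list(pmid = NULL, fields = list()); start_line <- i
        }
        cur$pmid <- val
        cur_tag <- NA_character_
      } else {
        cur$fields[[tag]] <- c(cur$fields[[tag]], val)
        cur_tag <- tag
      }
    } else if (grepl("^\\s+", ln)) {
      # continuation of the previous field
      if (!is.null(cur) && !is.na(cur_tag)) {
        parts <- cur$fields[[cur_tag]]
        parts[length(parts)] <- paste(parts[length(parts)], trimws(ln))
        cur$fields[[cur_tag]] <- parts
      }
    }
  }
  flush_record()
  records
}

#' Write abstracts as a MEDLINE flat file
#'
#' Inverse of [parse_medline()]: emits `PMID-`/`TI  -`/`AB  -` fields with
#' continuation lines wrapped at 80 columns, records separated by blank
#' lines. Round-trips pmid/title/body exactly for single-spaced text.
#'
#' @param abstracts List of [abstract] objects.
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_medline <- function(abstracts, path = NULL) {
  wrap_field <- function(tag, text) {
    if (!nzchar(text)) return(character(0))
    words <- strsplit(text, " ", fixed = TRUE)[[1]]
    out <- character(0)
    cur <- paste0(tag, "- ")
    width <- 0L
    first <- TRUE
    for (w in words) {
      cand <- if (first) paste0(cur, w) else paste(cur, w)
      if (!first && nchar(cand) > 80L) {
        out <- c(out, cur)
        cur <- paste0("      ", w)
      } else cur <- cand
      first <- FALSE
    }
    c(out, cur)
  }
  lines <- unlist(lapply(abstracts, function(a) {
    c(paste0("PMID- ", a$pmid),
      wrap_field("TI  ", a$title),
      wrap_field("AB  ", a$body),
      "")
  }), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Split text into sentences
#'
#' Deterministic rule-based segmentation: a sentence ends at `.`, `!` or
#' `?` followed by whitespace and an uppercase letter or digit, unless the
#' text before the boundary ends in a known abbreviation (`"vs."`,
#' `"et al."`, `"Fig."`, `"e.g."`, `"i.e."`, ...). Returned sentences are
#' trimmed and non-empty; input is NFKC-normalised first.
#'
#' @param text Character scalar.
#' @return Character vector of sentences (possibly empty).
#' @examples
#' split_sentences("A is true. B is false.")
#' split_sentences("Treated with cisplatin vs. carboplatin in Fig. 2.")
#' @export
split_sentences <- function(text) {
  if (length(text) != 1L) stop("`text` must be a single string")
  text <- normalize_text(text)
  if (!nzchar(trimws(text))) return(character(0))
  # candidate boundaries: sentence punctuation, whitespace, upper/digit
  m <- gregexpr("[.!?]+(?=\\s+[A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      prefix <- substr(text, 1L, e)
      abbrev <- any(vapply(.SENT_ABBREV, function(a) {
        n <- nchar(a)
        nchar(prefix) >= n &&
          tolower(substr(prefix, nchar(prefix) - n + 1L, nchar(prefix))) == a &&
          # the abbreviation must start at a word boundary
          (nchar(prefix) == n ||
             grepl("[^\\p{L}\\p{N}]", substr(prefix, nchar(prefix) - n, nchar(prefix) - n), perl = TRUE))
      }, logical(1)))
      if (!abbrev) cuts <- c(cuts, e)
    }
  }
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, nchar(text))
  out <- trimws(substring(text, starts, stops))
  out[nzchar(out)]
}

#' Sentences of an abstract
#'
#' Applies [split_sentences()] to the title and then the body, assigning
#' consecutive 0-based indices across both, so a sentence is addressable
#' as (pmid, index).
#'
#' @param x An [abstract].
#' @param include_title Mine the title's sentences too (default `TRUE`).
#' @return A data.frame with columns `pmid`, `index`, `text`.
#' @export
sentences_of <- function(x, include_title = TRUE) {
  stopifnot(inherits(x, "abstract"))
  txt <- c(if (include_title) split_sentences(x$title), split_sentences(x$body))
  data.frame(pmid = rep(x$pmid, length(txt)),
             index = seq_along(txt) - 1L,
             text = as.character(txt),
             stringsAsFactors = FALSE)
}

#' Sentence table for a whole corpus
#'
#' @param corpus List of [abstract] objects.
#' @param include_title Mine titles as well as bodies.
#' @return A data.frame with columns `pmid`, `index`, `text`, one row per
#'   sentence, in corpus order.
#' @export
corpus_sentences <- function(corpus, include_title = TRUE) {
  tabs <- lapply(corpus, sentences_of, include_title = include_title)
  out <- do.call(rbind, tabs)
  if (is.null(out)) {
    out <- data.frame(pmid = character(0), index = integer(0),
                      text = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
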