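# Synthetic corpus generator with planted signal.
#
# Stands in, at desk scale, for a PubMed snapshot of ovarian-cancer
# platinum-resistance abstracts. Every stage of the pipeline can be
# exercised against known ground truth: per-sentence Bernoulli rates
# plant gene-drug-resistance events and gene-subtype mentions, decoy
# sentences exercise the counting rule's negatives (gene without drug,
# drug without resistance, abbreviation traps), and companion generators
# emit an annotation map with one enriched term and an interaction file
# with a planted hub.

# evaluate `code` under `seed`, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default synthetic gene panel
#'
#' Twenty genes recurrently discussed in the ovarian-cancer
#' platinum-resistance literature, with Entrez-style identifiers and a
#' few synonyms each.
#'
#' @return A data.frame `gene_id`, `symbol`, `synonyms` (pipe-separated).
#' @export
default_synthetic_genes <- function() {
  d <- rbind(
    c("7157", "TP53", "p53"),
    c("5243", "ABCB1", "MDR1|P-glycoprotein"),
    c("207", "AKT1", ""),
    c("2067", "ERCC1", ""),
    c("596", "BCL2", "Bcl-2"),
    c("1956", "EGFR", "ERBB1"),
    c("672", "BRCA1", ""),
    c("5290", "PIK3CA", ""),
    c("5594", "MAPK1", "ERK2"),
    c("4363", "ABCC1", "MRP1"),
    c("3569", "IL6", ""),
    c("4790", "NFKB1", ""),
    c("6774", "STAT3", ""),
    c("2475", "MTOR", "FRAP1"),
    c("142", "PARP1", ""),
    c("675", "BRCA2", ""),
    c("3065", "HDAC1", ""),
    c("2064", "ERBB2", "HER2"),
    c("10551", "AGR3", ""),
    c("7124", "TNF", "")
  )
  data.frame(gene_id = d[, 1], symbol = d[, 2], synonyms = d[, 3],
             stringsAsFactors = FALSE)
}

.SUBTYPE_LABELS <- c("clear_cell", "endometrioid", "mucinous", "serous")

#' Build a synthetic-corpus configuration
#'
#' Defaults describe the study conditions the pipeline is tested under:
#' one strongly planted resistance gene (TP53 at per-sentence event
#' probability 0.3), a handful of intermediate genes, decoys at 0.01, and
#' two subtype-specific gene groups (BCL2/AKT1/STAT3 on endometrioid,
#' ERBB2/AGR3/TNF on mucinous) whose profiles should separate under
#' clustering. All probabilities are per sentence and per gene.
#'
#' @param n_abstracts Number of abstracts (>= 1).
#' @param sentences_range Integer range of body sentences per abstract.
#' @param genes Gene panel as in [default_synthetic_genes()].
#' @param p_event Named per-gene per-sentence probability that a sentence
#'   carries a gene + drug + resistance event.
#' @param p_subtype Gene-by-subtype matrix of per-sentence mention
#'   probabilities (rows = gene ids, columns = subtype labels).
#' @param decoy_gene_rate,decoy_drug_rate,decoy_resistance_rate Rates of
#'   the partial-evidence decoy sentence types among non-event sentences.
#' @param deterministic Plant exact counts instead of Bernoulli draws.
#' @param planted_events In deterministic mode, named gene -> exact event
#'   sentence count.
#' @param planted_subtype In deterministic mode, exact gene-by-subtype
#'   sentence counts (matrix with dimnames), or `NULL`.
#' @param seed Integer seed fixing the corpus byte-for-byte.
#' @param n_background_genes Extra annotated-but-never-mentioned genes in
#'   the annotation background.
#' @param enriched_term_genes Gene ids of the planted enriched term.
#' @param n_decoy_terms,decoy_term_size Decoy annotation terms.
#' @param hub_gene,hub_degree,n_background_edges Planted interaction hub
#'   and random background edges.
#' @return A validated `"synthetic_config"` list.
#' @export
synthetic_config <- function(n_abstracts = 300L,
                             sentences_range = c(3L, 8L),
                             genes = default_synthetic_genes(),
                             p_event = NULL,
                             p_subtype = NULL,
                             decoy_gene_rate = 0.30,
                             decoy_drug_rate = 0.15,
                             decoy_resistance_rate = 0.10,
                             deterministic = FALSE,
                             planted_events = NULL,
                             planted_subtype = NULL,
                             seed = 1L,
                             n_background_genes = 30L,
                             enriched_term_genes = NULL,
                             n_decoy_terms = 8L,
                             decoy_term_size = 8L,
                             hub_gene = "7157",
                             hub_degree = 10L,
                             n_background_edges = 12L) {
  gid <- genes$gene_id
  if (is.null(p_event)) {
    p_event <- stats::setNames(rep(0.01, length(gid)), gid)
    p_event[intersect(c("7157"), gid)] <- 0.30
    mids <- intersect(c("5243", "207", "2067", "596", "1956"), gid)
    p_event[mids] <- c(0.08, 0.06, 0.05, 0.04, 0.04)[seq_along(mids)]
  }
  if (is.null(p_subtype)) {
    p_subtype <- matrix(0.001, nrow = length(gid), ncol = 4,
                        dimnames = list(gid, .SUBTYPE_LABELS))
    grp_endo <- intersect(c("596", "207", "6774"), gid)
    grp_muc <- intersect(c("2064", "10551", "7124"), gid)
    # planted groups are strictly subtype-exclusive: min-max scaling of a
    # sparse column turns even 1-2 stray counts into large coordinates
    p_subtype[c(grp_endo, grp_muc), ] <- 0
    p_subtype[grp_endo, "endometrioid"] <- 0.12
    p_subtype[grp_muc, "mucinous"] <- 0.12
    others <- setdiff(gid, c(grp_endo, grp_muc))
    p_subtype[others, "serous"] <- 0.012
    p_subtype[others, "clear_cell"] <- 0.01
  }
  if (is.null(enriched_term_genes))
    enriched_term_genes <- intersect(c("7157", "5243", "207", "2067", "596",
                                       "1956"), gid)
  cfg <- list(
    n_abstracts = as.integer(n_abstracts),
    sentences_range = as.integer(sentences_range),
    genes = genes, p_event = p_event, p_subtype = p_subtype,
    decoy_gene_rate = decoy_gene_rate, decoy_drug_rate = decoy_drug_rate,
    decoy_resistance_rate = decoy_resistance_rate,
    deterministic = isTRUE(deterministic),
    planted_events = planted_events, planted_subtype = planted_subtype,
    seed = as.integer(seed),
    n_background_genes = as.integer(n_background_genes),
    enriched_term_genes = enriched_term_genes,
    n_decoy_terms = as.integer(n_decoy_terms),
    decoy_term_size = as.integer(decoy_term_size),
    hub_gene = hub_gene, hub_degree = as.integer(hub_degree),
    n_background_edges = as.integer(n_background_edges),
    subtype_groups = list(
      endometrioid = intersect(c("596", "207", "6774"), gid),
      mucinous = intersect(c("2064", "10551", "7124"), gid))
  )
  if (cfg$n_abstracts < 1L) stop("n_abstracts must be >= 1", call. = FALSE)
  if (length(cfg$sentences_range) != 2L ||
      cfg$sentences_range[1] < 1L ||
      cfg$sentences_range[2] < cfg$sentences_range[1])
    stop("sentences_range must be an increasing positive pair", call. = FALSE)
  probs <- c(cfg$p_event, cfg$p_subtype,
             cfg$decoy_gene_rate, cfg$decoy_drug_rate,
             cfg$decoy_resistance_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (!setequal(names(cfg$p_event), gid))
    stop("p_event must be named by the gene panel's gene_ids", call. = FALSE)
  if (!identical(sort(rownames(cfg$p_subtype)), sort(gid)) ||
      !setequal(colnames(cfg$p_subtype), .SUBTYPE_LABELS))
    stop("p_subtype must be a gene-by-subtype matrix over the panel",
         call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# ---- sentence realisation ---------------------------------------------------

# Every emitted sentence starts with an uppercase letter or digit so the
# rule-based splitter recognises each boundary; lexicon matching is
# case-insensitive for mixed-case keys ("p53" -> "P53"), so mention
# recovery is unaffected.
.cap1 <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

.DRUG_FORMS <- c("cisplatin", "carboplatin", "platinum", "DDP", "CBP")
.SUBTYPE_FORMS <- list(clear_cell = c("clear cell", "OCCC"),
                       endometrioid = "endometrioid",
                       mucinous = "mucinous",
                       serous = "serous")

.gene_form <- function(cfg, gene_id) {
  row <- cfg$genes[cfg$genes$gene_id == gene_id, ]
  keys <- c(row$symbol,
            if (nzchar(row$synonyms))
              strsplit(row$synonyms, "|", fixed = TRUE)[[1]])
  keys[sample.int(length(keys), 1L)]
}

.event_sentence <- function(cfg, gene_ids) {
  gs <- vapply(gene_ids, function(g) .gene_form(cfg, g), character(1))
  glist <- paste(gs, collapse = " and ")
  drug <- sample(.DRUG_FORMS, 1L)
  style <- sample.int(5L, 1L)
  switch(style,
    paste0(glist, " overexpression confers ", drug,
           " resistance in ovarian cancer cells."),
    paste0("Knockdown of ", glist, " restored sensitivity in ", drug,
           "-resistant cells."),
    paste0(glist, " expression correlated with resistance to ", drug,
           " in treated patients."),
    paste0("High ", glist, " levels were associated with ", drug,
           " resistance after chemotherapy."),
    paste0(gs[1], "-mediated signaling promoted ", drug,
           " resistance", if (length(gs) > 1L)
             paste0(" together with ", paste(gs[-1], collapse = " and "))
           else "", ".")
  )
}

.subtype_sentence <- function(cfg, gene_ids, labels) {
  gs <- vapply(gene_ids, function(g) .gene_form(cfg, g), character(1))
  forms <- vapply(labels, function(l) {
    f <- .SUBTYPE_FORMS[[l]]
    f[sample.int(length(f), 1L)]
  }, character(1))
  glist <- paste(gs, collapse = " and ")
  slist <- paste(forms, collapse = " and ")
  if (sample.int(2L, 1L) == 1L)
    paste0(glist, " expression was elevated in ", slist,
           " ovarian carcinoma samples.")
  else
    paste0("Alterations of ", glist, " are frequent in ", slist, " tumors.")
}

.DECOY_PLAIN <- c(
  "Patients were followed for five years after primary surgery.",
  "Overall survival was estimated with the Kaplan-Meier method, as shown in Fig. 3.",
  "Median age at diagnosis was 58 years vs. 61 years in the control group.",
  "Similar observations were published by Smith et al. in an earlier cohort.",
  "Tissue samples were collected under an approved institutional protocol.",
  "The study enrolled women treated at a single tertiary referral center."
)

.decoy_sentence <- function(cfg) {
  u <- stats::runif(1)
  if (u < cfg$decoy_gene_rate) {
    g <- cfg$genes$gene_id[sample.int(nrow(cfg$genes), 1L)]
    paste0(.gene_form(cfg, g),
           " expression was measured by quantitative PCR and western blot.")
  } else if (u < cfg$decoy_gene_rate + cfg$decoy_drug_rate) {
    paste0("Patients received ", sample(.DRUG_FORMS, 1L),
           "-based combination chemotherapy.")
  } else if (u < cfg$decoy_gene_rate + cfg$decoy_drug_rate +
             cfg$decoy_resistance_rate) {
    "Acquired drug resistance remains a major clinical obstacle."
  } else {
    sample(.DECOY_PLAIN, 1L)
  }
}

.TITLES <- c(
  "Molecular determinants of chemotherapy outcome in ovarian cancer.",
  "A retrospective cohort study of epithelial ovarian cancer.",
  "Mechanisms of treatment failure in advanced ovarian cancer.",
  "Predictive biomarkers for first-line chemotherapy in ovarian cancer.",
  "Signaling pathways and chemotherapy response in ovarian cancer."
)

#' Generate a synthetic abstract corpus with ground truth
#'
#' Stochastic mode draws, per sentence and per gene, a Bernoulli event
#' (gene + drug term + resistance term in one sentence) at the configured
#' probability, and likewise gene-subtype mentions; remaining sentences
#' are decoys carrying none or only part of the evidence. Deterministic
#' mode plants exactly the requested counts. The ground truth records
#' every realised event, so an oracle recount of the emitted corpus must
#' reproduce it.
#'
#' @param config A [synthetic_config()].
#' @return List with `corpus` (list of [abstract]), `truth` (list:
#'   `event_counts`, `subtype_counts`, `events` data.frame,
#'   `subtype_groups`), and `lexicon_lines` (TSV lines for the panel).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(cfg) {
  gid <- cfg$genes$gene_id
  labels <- colnames(cfg$p_subtype)
  n_sent <- sample(seq.int(cfg$sentences_range[1], cfg$sentences_range[2]),
                   cfg$n_abstracts, replace = TRUE)
  # plan per sentence: list(type, genes, labels)
  plans <- vector("list", sum(n_sent))
  if (cfg$deterministic) {
    want <- cfg$planted_events
    if (is.null(want)) want <- stats::setNames(integer(length(gid)), gid)
    plan_list <- list()
    for (g in names(want)) if (want[[g]] > 0L)
      plan_list <- c(plan_list, replicate(want[[g]],
        list(type = "event", genes = g, labels = NULL), simplify = FALSE))
    ps <- cfg$planted_subtype
    if (!is.null(ps)) {
      for (g in rownames(ps)) for (l in colnames(ps)) if (ps[g, l] > 0L)
        plan_list <- c(plan_list, replicate(ps[g, l],
          list(type = "subtype", genes = g, labels = l), simplify = FALSE))
    }
    if (length(plan_list) > length(plans))
      stop("corpus too small for the planted counts: need at least ",
           length(plan_list), " sentences", call. = FALSE)
    # spread planted sentences evenly across the corpus
    if (length(plan_list) > 0L) {
      pos <- floor(seq(1, length(plans), length.out = length(plan_list)))
      plans[pos] <- plan_list
    }
    for (i in which(vapply(plans, is.null, logical(1))))
      plans[[i]] <- list(type = "decoy", genes = NULL, labels = NULL)
  } else {
    S <- length(plans)
    G <- length(gid)
    ev <- matrix(stats::runif(S * G), S, G) <
      matrix(cfg$p_event[gid], S, G, byrow = TRUE)
    sub <- array(stats::runif(S * G * length(labels)),
                 dim = c(S, G, length(labels))) <
      aperm(array(cfg$p_subtype[gid, labels],
                  dim = c(G, length(labels), S)), c(3, 1, 2))
    for (s in seq_len(S)) {
      if (any(ev[s, ])) {
        plans[[s]] <- list(type = "event", genes = gid[ev[s, ]], labels = NULL)
      } else if (any(sub[s, , ])) {
        # exactly one (gene, subtype) pair per sentence: gene mentions and
        # subtype terms in one sentence co-occur combinatorially under the
        # counting rule, so multi-pair sentences would smear the planted
        # per-pair rates across subtypes
        hit <- which(sub[s, , , drop = TRUE], arr.ind = TRUE)
        if (is.null(dim(hit))) hit <- matrix(hit, ncol = 2)
        pick <- hit[sample.int(nrow(hit), 1L), ]
        plans[[s]] <- list(type = "subtype",
                           genes = gid[pick[1]],
                           labels = labels[pick[2]])
      } else {
        plans[[s]] <- list(type = "decoy", genes = NULL, labels = NULL)
      }
    }
  }

  # realise sentences and assemble abstracts
  corpus <- vector("list", cfg$n_abstracts)
  ev_rows <- list()
  sub_rows <- list()
  cursor <- 0L
  for (a in seq_len(cfg$n_abstracts)) {
    pmid <- as.character(100000L + a)
    title <- .TITLES[((a - 1L) %% length(.TITLES)) + 1L]
    body <- character(n_sent[a])
    for (s in seq_len(n_sent[a])) {
      pl <- plans[[cursor + s]]
      # sentence index within the record: title occupies index 0
      idx <- s
      if (pl$type == "event") {
        body[s] <- .cap1(.event_sentence(cfg, pl$genes))
        ev_rows[[length(ev_rows) + 1L]] <-
          data.frame(pmid = pmid, sentence_index = idx, gene_id = pl$genes,
                     stringsAsFactors = FALSE)
      } else if (pl$type == "subtype") {
        lbl <- if (is.null(pl$labels))
          labels[sample.int(length(labels), 1L)] else pl$labels
        body[s] <- .cap1(.subtype_sentence(cfg, pl$genes, lbl))
        sub_rows[[length(sub_rows) + 1L]] <-
          expand.grid(pmid = pmid, sentence_index = idx,
                      gene_id = pl$genes, label = lbl,
                      stringsAsFactors = FALSE)
      } else {
        body[s] <- .cap1(.decoy_sentence(cfg))
      }
    }
    corpus[[a]] <- abstract(pmid, title, paste(body, collapse = " "))
    cursor <- cursor + n_sent[a]
  }

  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(pmid = character(0), sentence_index = integer(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  event_counts <- stats::setNames(integer(length(gid)), gid)
  if (nrow(events)) {
    tab <- table(events$gene_id)
    event_counts[names(tab)] <- as.integer(tab)
  }
  subtype_counts <- matrix(0L, length(gid), length(labels),
                           dimnames = list(gid, labels))
  if (length(sub_rows)) {
    subs <- do.call(rbind, sub_rows)
    tab <- table(subs$gene_id, subs$label)
    subtype_counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  lex_lines <- paste(cfg$genes$gene_id, cfg$genes$symbol, cfg$genes$synonyms,
                     sep = "\t")
  list(corpus = corpus,
       truth = list(event_counts = event_counts,
                    subtype_counts = subtype_counts,
                    events = events,
                    subtype_groups = cfg$subtype_groups),
       lexicon_lines = lex_lines)
}

#' Generate a synthetic annotation map with one enriched term
#'
#' The designated enriched term annotates the planted high-count genes;
#' decoy terms annotate random draws from a background that also contains
#' genes never mentioned in the corpus, so the mined query is a proper
#' subset of the background.
#'
#' @param config A [synthetic_config()].
#' @return List with `lines` (TSV `term_id`, `gene_id`, `term_name`),
#'   `background` gene ids, and `enriched_term` id.
#' @export
generate_annotations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 1000L, {
    gid <- config$genes$gene_id
    extra <- sprintf("9%04d", seq_len(config$n_background_genes))
    background <- c(gid, extra)
    rows <- data.frame(term_id = "GO:0000001",
                       gene_id = config$enriched_term_genes,
                       term_name = "planted resistance process",
                       stringsAsFactors = FALSE)
    for (t in seq_len(config$n_decoy_terms)) {
      g <- sample(background, config$decoy_term_size)
      rows <- rbind(rows, data.frame(
        term_id = sprintf("GO:%07d", t + 1L), gene_id = g,
        term_name = sprintf("decoy process %d", t),
        stringsAsFactors = FALSE))
    }
    # genes annotated nowhere else are attached to a catch-all term so the
    # supplied background equals the annotation universe
    unannot <- setdiff(background, rows$gene_id)
    if (length(unannot))
      rows <- rbind(rows, data.frame(term_id = "GO:9999999",
                                     gene_id = unannot,
                                     term_name = "background catch-all",
                                     stringsAsFactors = FALSE))
    list(lines = paste(rows$term_id, rows$gene_id, rows$term_name, sep = "\t"),
         background = background,
         enriched_term = "GO:0000001")
  })
}

#' Generate a synthetic interaction edge file with a planted hub
#'
#' The hub gene is wired to `hub_degree` other panel genes; random
#' background edges, deliberate duplicates and self-loops exercise the
#' induction filters.
#'
#' @param config A [synthetic_config()].
#' @return List with `lines` (2-column TSV), `hub` gene id, and
#'   `hub_degree`.
#' @export
generate_interactions <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 2000L, {
    gid <- config$genes$gene_id
    others <- setdiff(gid, config$hub_gene)
    if (config$hub_degree > length(others))
      stop("hub_degree exceeds the number of available partner genes",
           call. = FALSE)
    partners <- sample(others, config$hub_degree)
    hub_edges <- data.frame(a = config$hub_gene, b = partners,
                            stringsAsFactors = FALSE)
    pool <- t(utils::combn(others, 2L))
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    bg <- data.frame(a = pool[seq_len(min(config$n_background_edges,
                                          nrow(pool))), 1],
                     b = pool[seq_len(min(config$n_background_edges,
                                          nrow(pool))), 2],
                     stringsAsFactors = FALSE)
    e <- rbind(hub_edges, bg)
    # deliberate noise: a self-loop and duplicated/reversed edges
    e <- rbind(e,
               data.frame(a = config$hub_gene, b = config$hub_gene),
               data.frame(a = e$b[1], b = e$a[1]),
               e[2, ])
    list(lines = paste(e$a, e$b, sep = "\t"),
         hub = config$hub_gene, hub_degree = config$hub_degree)
  })
}

#' Write a complete synthetic bundle to disk
#'
#' Emits `corpus.medline`, `lexicon.tsv`, `annotations.tsv`, `edges.tsv`
#' and `truth.json` under `dir`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the `truth`
#'   object (including annotation and interaction truth).
#' @export
generate_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corp <- generate_corpus(config)
  ann <- generate_annotations(config)
  net <- generate_interactions(config)
  paths <- list(
    corpus = file.path(dir, "corpus.medline"),
    lexicon = file.path(dir, "lexicon.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    edges = file.path(dir, "edges.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_medline(corp$corpus, paths$corpus)
  writeLines(corp$lexicon_lines, paths$lexicon, useBytes = TRUE)
  writeLines(ann$lines, paths$annotations, useBytes = TRUE)
  writeLines(net$lines, paths$edges, useBytes = TRUE)
  truth <- c(corp$truth,
             list(background = ann$background,
                  enriched_term = ann$enriched_term,
                  hub = net$hub, hub_degree = net$hub_degree))
  jsonlite::write_json(
    list(event_counts = as.list(truth$event_counts),
         subtype_counts = truth$subtype_counts,
         enriched_term = truth$enriched_term,
         hub = truth$hub, hub_degree = truth$hub_degree,
         subtype_groups = truth$subtype_groups),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}
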