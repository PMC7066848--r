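test_that("config validation rejects bad probabilities and shapes", {
  expect_error(synthetic_config(n_abstracts = 0), "n_abstracts")
  expect_error(synthetic_config(sentences_range = c(5, 2)), "sentences_range")
  genes <- default_synthetic_genes()
  bad <- stats::setNames(rep(1.5, nrow(genes)), genes$gene_id)
  expect_error(synthetic_config(p_event = bad), "probabilities")
  expect_error(synthetic_config(p_event = c(x = 0.1)), "gene panel")
})

test_that("the same seed reproduces the corpus byte-for-byte", {
  cfg <- synthetic_config(n_abstracts = 20L, seed = 42)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(write_medline(a$corpus), write_medline(b$corpus))
  expect_identical(a$truth, b$truth)
  # a different seed gives a different corpus
  c2 <- generate_corpus(synthetic_config(n_abstracts = 20L, seed = 43))
  expect_false(identical(write_medline(a$corpus), write_medline(c2$corpus)))
})

test_that("all-zero probabilities produce an event-free corpus", {
  genes <- default_synthetic_genes()
  p0 <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  s0 <- matrix(0, nrow(genes), 4,
               dimnames = list(genes$gene_id,
                               c("clear_cell", "endometrioid", "mucinous",
                                 "serous")))
  cfg <- synthetic_config(n_abstracts = 30L, p_event = p0, p_subtype = s0,
                          seed = 9)
  gen <- generate_corpus(cfg)
  expect_true(all(gen$truth$event_counts == 0L))
  expect_true(all(gen$truth$subtype_counts == 0L))
  lex <- load_gene_lexicon(gen$lexicon_lines)
  expect_equal(nrow(mine_events(gen$corpus, lex)), 0L)
})

test_that("deterministic mode plants exact event counts", {
  want <- c("7157" = 5L, "596" = 3L)
  cfg <- synthetic_config(n_abstracts = 10L, deterministic = TRUE,
                          planted_events = want, seed = 4)
  gen <- generate_corpus(cfg)
  lex <- load_gene_lexicon(gen$lexicon_lines)
  tab <- count_genes(mine_events(gen$corpus, lex))
  expect_equal(tab$count[tab$gene_id == "7157"], 5L)
  expect_equal(tab$count[tab$gene_id == "596"], 3L)
  expect_equal(sum(tab$count), 8L)

  ps <- matrix(0L, 2, 4, dimnames = list(c("7157", "2064"),
               c("clear_cell", "endometrioid", "mucinous", "serous")))
  ps["7157", "serous"] <- 4L
  ps["2064", "mucinous"] <- 2L
  cfg <- synthetic_config(n_abstracts = 10L, deterministic = TRUE,
                          planted_subtype = ps, seed = 4)
  gen <- generate_corpus(cfg)
  sm <- build_subtype_matrix(gen$corpus, load_gene_lexicon(gen$lexicon_lines))
  expect_equal(sm["7157", "serous"], 4L)
  expect_equal(sm["2064", "mucinous"], 2L)

  # demanding more sentences than the corpus holds is an error
  expect_error(generate_corpus(
    synthetic_config(n_abstracts = 1L, sentences_range = c(1L, 1L),
                     deterministic = TRUE,
                     planted_events = c("7157" = 50L), seed = 1)),
    "too small")
})

test_that("realized ground truth equals an oracle recount of the corpus", {
  cfg <- synthetic_config(n_abstracts = 50L, seed = 31)
  gen <- generate_corpus(cfg)
  ora <- oracle_recount(gen$corpus, cfg$genes)
  expect_identical(ora$counts, gen$truth$event_counts)
  expect_identical(ora$subtype, gen$truth$subtype_counts)
})

test_that("annotation generator plants a recoverable enriched term", {
  cfg <- synthetic_config(seed = 13)
  ann_gen <- generate_annotations(cfg)
  ann <- load_annotations(ann_gen$lines, background = ann_gen$background)
  # round trip: re-parsing the emitted lines yields the same map
  ann2 <- load_annotations(ann_gen$lines, background = ann_gen$background)
  expect_identical(ann$terms, ann2$terms)
  # querying with the full mined panel ranks the planted term first
  res <- enrich(cfg$genes$gene_id, ann)
  expect_equal(res$term_id[1], ann_gen$enriched_term)
  expect_equal(res$k[1], length(cfg$enriched_term_genes))
})

test_that("interaction generator plants hub, loops and duplicates", {
  cfg <- synthetic_config(seed = 19)
  net_gen <- generate_interactions(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(net_gen$lines, f)
  ints <- load_interactions(c(x = f))
  # a deliberate self-loop survives loading but not induction
  expect_true(any(ints$a == ints$b))
  counts <- data.frame(gene_id = cfg$genes$gene_id, count = 10L)
  net <- induce_network(counts, ints, min_count = 3)
  expect_false(igraph::any_loop(net))
  d <- degree_table(net)
  expect_equal(d$node[1], net_gen$hub)
  expect_equal(d$degree[1], net_gen$hub_degree)
})

test_that("generate_bundle writes a self-consistent file set", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_abstracts = 25L, seed = 77)
  b <- generate_bundle(cfg, dir)
  expect_true(all(file.exists(unlist(b$paths))))
  corpus <- parse_medline(b$paths$corpus)
  expect_length(corpus, 25L)
  lex <- load_gene_lexicon(b$paths$lexicon)
  tab <- count_genes(mine_events(corpus, lex))
  got <- stats::setNames(rep(0L, nrow(cfg$genes)), cfg$genes$gene_id)
  got[tab$gene_id] <- tab$count
  expect_identical(got, b$truth$event_counts)
  truth_json <- jsonlite::read_json(b$paths$truth)
  expect_equal(unlist(truth_json$event_counts["7157"]),
               c("7157" = b$truth$event_counts[["7157"]]))
})
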