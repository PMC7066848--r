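make_corpus <- function(...) {
  bodies <- c(...)
  lapply(seq_along(bodies), function(i)
    abstract(as.character(i), title = "Neutral title here.", body = bodies[i]))
}

test_that("a gene scores iff it shares a sentence with drug AND resistance", {
  lex <- tiny_lexicon()
  ev <- mine_events(make_corpus("TP53 loss confers cisplatin resistance."), lex)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene_id, "7157")
  expect_equal(ev$drug_labels, "cisplatin")
  expect_equal(ev$resistance_labels, "resistance")

  # no drug or no resistance term: no event
  ev <- mine_events(make_corpus("TP53 is mutated in ovarian cancer."), lex)
  expect_equal(nrow(ev), 0L)
  ev <- mine_events(make_corpus("TP53 responds to cisplatin treatment."), lex)
  expect_equal(nrow(ev), 0L)

  # evidence split across sentences does not count
  ev <- mine_events(
    make_corpus("TP53 is mutated. Cisplatin resistance is common."), lex)
  expect_equal(nrow(ev), 0L)

  # a single hyphenated token supplies both term groups
  ev <- mine_events(make_corpus("BCL2 drives cisplatin-resistant growth."), lex)
  expect_equal(ev$gene_id, "596")
})

test_that("a gene mentioned twice in one sentence counts once", {
  lex <- tiny_lexicon()
  ev <- mine_events(
    make_corpus("TP53 and p53 drive cisplatin resistance."), lex)
  expect_equal(nrow(ev), 1L)
  # but two sentences give two events
  ev <- mine_events(make_corpus(
    "TP53 drives cisplatin resistance. Here p53 confers DDP resistance."), lex)
  expect_equal(nrow(ev), 2L)
  expect_equal(unique(ev$gene_id), "7157")
})

test_that("count_genes orders by count then gene_id and filters at >=", {
  ev <- data.frame(
    pmid = c("1", "1", "2", "3"), sentence_index = c(0L, 1L, 0L, 0L),
    gene_id = c("A", "A", "A", "B"),
    drug_labels = "cisplatin", resistance_labels = "resistance",
    stringsAsFactors = FALSE)
  tab <- count_genes(ev)
  expect_equal(tab$gene_id, c("A", "B"))
  expect_equal(tab$count, c(3L, 1L))
  expect_equal(sum(tab$count), nrow(ev))

  expect_equal(nrow(count_genes(ev[0, ])), 0L)

  # equal counts break ties lexicographically by gene_id
  ev2 <- ev; ev2$gene_id <- c("Z", "B", "B", "Z")
  expect_equal(count_genes(ev2)$gene_id, c("B", "Z"))

  tab3 <- data.frame(gene_id = c("A", "B", "C"), count = c(20L, 15L, 14L))
  expect_equal(filter_by_count(tab3, 15)$gene_id, c("A", "B"))
  expect_equal(filter_by_count(tab3, 0), tab3)
  expect_equal(nrow(filter_by_count(tab3[0, ], 5)), 0L)
})

test_that("subtype matrix counts once per sentence-gene-label triple", {
  lex <- tiny_lexicon()
  m <- build_subtype_matrix(make_corpus("BCL2 in endometrioid carcinoma."), lex)
  expect_equal(rownames(m), "596")
  expect_equal(m["596", "endometrioid"], 1L)
  expect_equal(sum(m), 1L)

  # synonymous subtype terms collapse to one label
  m <- build_subtype_matrix(
    make_corpus("TP53 in clear cell carcinoma, also called OCCC."), lex)
  expect_equal(m["7157", "clear_cell"], 1L)

  # corpus without subtype words gives an empty matrix with fixed columns
  m <- build_subtype_matrix(make_corpus("TP53 is a gene."), lex)
  expect_equal(nrow(m), 0L)
  expect_setequal(colnames(m),
                  c("serous", "mucinous", "endometrioid", "clear_cell"))

  # abstract scope links gene and subtype across sentences
  corp <- make_corpus("TP53 is mutated. The serous subtype dominates.")
  expect_equal(nrow(build_subtype_matrix(corp, lex)), 0L)
  m <- build_subtype_matrix(corp, lex, scope = "abstract")
  expect_equal(m["7157", "serous"], 1L)
})

test_that("pipeline counts equal the brute-force oracle recount", {
  for (s in c(101, 202)) {
    cfg <- synthetic_config(n_abstracts = 60L, seed = s)
    gen <- generate_corpus(cfg)
    lex <- load_gene_lexicon(gen$lexicon_lines)
    ora <- oracle_recount(gen$corpus, cfg$genes)
    tab <- count_genes(mine_events(gen$corpus, lex))
    got <- stats::setNames(rep(0L, nrow(cfg$genes)), cfg$genes$gene_id)
    got[tab$gene_id] <- tab$count
    expect_identical(got, ora$counts)
    sm <- build_subtype_matrix(gen$corpus, lex)
    full <- ora$subtype[rowSums(ora$subtype) > 0L, , drop = FALSE]
    expect_identical(sm[order(rownames(sm)), ],
                     full[order(rownames(full)), ])
  }
})

test_that("mined counts equal the generator's planted ground truth", {
  cfg <- synthetic_config(n_abstracts = 80L, seed = 17)
  gen <- generate_corpus(cfg)
  lex <- load_gene_lexicon(gen$lexicon_lines)
  tab <- count_genes(mine_events(gen$corpus, lex))
  got <- stats::setNames(rep(0L, nrow(cfg$genes)), cfg$genes$gene_id)
  got[tab$gene_id] <- tab$count
  expect_identical(got, gen$truth$event_counts)
  sm <- build_subtype_matrix(gen$corpus, lex)
  truth <- gen$truth$subtype_counts
  expect_identical(sm, truth[rownames(sm), colnames(sm)])
  expect_true(all(truth[setdiff(rownames(truth), rownames(sm)), ] == 0L))
})

test_that("adding an abstract never decreases any gene's count", {
  cfg <- synthetic_config(n_abstracts = 30L, seed = 23)
  gen <- generate_corpus(cfg)
  lex <- load_gene_lexicon(gen$lexicon_lines)
  base <- count_genes(mine_events(gen$corpus[1:20], lex))
  for (k in 21:25) {
    bigger <- count_genes(mine_events(gen$corpus[1:k], lex))
    for (g in base$gene_id) {
      b <- base$count[base$gene_id == g]
      a <- bigger$count[bigger$gene_id == g]
      expect_true(length(a) == 1L && a >= b)
    }
    base <- bigger
  }
})
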