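# End-to-end orchestration: corpus -> counts -> enrichment -> network ->
# clustering, with a stable on-disk output layout and a run manifest.
# The pipeline itself is deterministic; any randomness lives in the
# synthetic generator's seed.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
}

#' Build a pipeline configuration
#'
#' Thresholds default to the frequency-table cut (count >= 15), the
#' network inclusion cut (count >= 3), the hub cut (degree > 20) and the
#' significance level 0.05.
#'
#' @param corpus Path to a MEDLINE file.
#' @param lexicon Path to a gene-lexicon TSV.
#' @param annotations Optional annotation TSV/GAF path (`NULL` skips the
#'   enrichment stage).
#' @param edges Optional character vector of interaction edge files
#'   (`NULL` skips the network stage).
#' @param out_dir Output directory.
#' @param min_count_table Frequency-table threshold.
#' @param network_min_count Minimum count for network inclusion.
#' @param min_degree Strict degree threshold for the hub table.
#' @param alpha Corrected-p significance level.
#' @param include_title Mine titles as well as bodies.
#' @param subtype_scope `"sentence"` or `"abstract"` co-occurrence scope
#'   for the gene-by-subtype matrix.
#' @param term_sets Optional YAML path overriding the default term sets.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(corpus, lexicon, annotations = NULL,
                            edges = NULL, out_dir = tempfile("platmine_"),
                            min_count_table = 15L, network_min_count = 3L,
                            min_degree = 20L, alpha = 0.05,
                            include_title = TRUE,
                            subtype_scope = c("sentence", "abstract"),
                            term_sets = NULL) {
  stopifnot(min_count_table >= 0, network_min_count >= 0, min_degree >= 0,
            alpha > 0, alpha < 1)
  structure(list(corpus = corpus, lexicon = lexicon,
                 annotations = annotations, edges = edges, out_dir = out_dir,
                 min_count_table = as.integer(min_count_table),
                 network_min_count = as.integer(network_min_count),
                 min_degree = as.integer(min_degree), alpha = alpha,
                 include_title = isTRUE(include_title),
                 subtype_scope = match.arg(subtype_scope),
                 term_sets = term_sets),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `"pipeline_config"` list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full mining pipeline
#'
#' Stages: parse the corpus; mine sentence-level gene-drug-resistance
#' events and write the audit log, gene count table and thresholded top
#' table; build, normalise and cluster the gene-by-subtype matrix (when
#' at least two genes co-occur with subtypes); test annotation-term
#' over-representation of all mined genes (when annotations are given);
#' induce the interaction network on genes mined at least
#' `network_min_count` times and rank nodes by degree (when edge files
#' are given). Identical config and inputs produce byte-identical
#' outputs; skipped stages are reported in the manifest.
#'
#' @param config A [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every in-memory stage result
#'   (`corpus`, `events`, `counts`, `top_genes`, `subtype_matrix`,
#'   `normalized`, `dendrogram`, `enrichment`, `network`, `degrees`,
#'   `hubs`, `manifest`) plus `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[platmine] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  res <- list(config = config)
  sets <- if (is.null(config$term_sets)) default_term_sets()
          else load_term_sets(config$term_sets)

  say("parsing corpus")
  corpus <- stage("corpus_io", parse_medline(config$corpus))
  lexicon <- stage("lexicon", load_gene_lexicon(config$lexicon))
  res$corpus <- corpus

  say("mining co-occurrence events")
  events <- stage("cooccurrence",
                  mine_events(corpus, lexicon, sets$drug, sets$resistance,
                              include_title = config$include_title))
  counts <- count_genes(events, lexicon)
  top <- filter_by_count(counts, config$min_count_table)
  res$events <- events; res$counts <- counts; res$top_genes <- top
  paths$events <- file.path(config$out_dir, "events.tsv")
  paths$counts <- file.path(config$out_dir, "gene_counts.tsv")
  paths$top_genes <- file.path(config$out_dir, "top_genes.tsv")
  .write_tsv(events, paths$events)
  .write_tsv(counts, paths$counts)
  .write_tsv(top, paths$top_genes)

  say("building gene-by-subtype matrix")
  sm <- stage("cooccurrence",
              build_subtype_matrix(corpus, lexicon, sets$subtype,
                                   include_title = config$include_title,
                                   scope = config$subtype_scope))
  res$subtype_matrix <- sm
  paths$subtype_matrix <- file.path(config$out_dir, "subtype_matrix.tsv")
  .write_tsv(data.frame(gene_id = rownames(sm), sm, check.names = FALSE),
             paths$subtype_matrix)
  if (nrow(sm) >= 2L) {
    say("clustering ", nrow(sm), " gene profiles")
    nm <- stage("clustering", normalize_per_subtype(sm))
    dn <- stage("clustering", complete_linkage(nm))
    res$normalized <- nm; res$dendrogram <- dn
    paths$normalized <- file.path(config$out_dir, "normalized_matrix.tsv")
    paths$merges <- file.path(config$out_dir, "merge_table.tsv")
    paths$newick <- file.path(config$out_dir, "dendrogram.nwk")
    .write_tsv(data.frame(gene_id = rownames(nm),
                          round(nm, 10), check.names = FALSE),
               paths$normalized)
    .write_tsv(merge_table(dn), paths$merges)
    writeLines(dendro_to_newick(dn), paths$newick, useBytes = TRUE)
  } else {
    say("fewer than 2 genes with subtype co-occurrence; clustering skipped")
  }

  if (!is.null(config$annotations) && nrow(counts) > 0L) {
    say("testing term over-representation")
    ann <- stage("enrichment", load_annotations(config$annotations))
    enr <- stage("enrichment", enrich(counts$gene_id, ann))
    enr$p_raw <- signif(enr$p_raw, 10)
    enr$p_corrected <- signif(enr$p_corrected, 10)
    res$enrichment <- enr
    res$significant <- enr[enr$p_corrected < config$alpha, , drop = FALSE]
    paths$enrichment <- file.path(config$out_dir, "enrichment.tsv")
    .write_tsv(enr, paths$enrichment)
  } else say("enrichment stage skipped (no annotation input)")

  if (!is.null(config$edges) && nrow(counts) > 0L) {
    say("inducing interaction network")
    ints <- stage("network", load_interactions(config$edges))
    ints <- stage("network", map_interactions(ints, lexicon))
    net <- stage("network",
                 induce_network(counts, ints, config$network_min_count))
    deg <- degree_table(net, lexicon)
    res$network <- net; res$degrees <- deg
    res$hubs <- top_nodes(deg, config$min_degree)
    paths$network_edges <- file.path(config$out_dir, "network_edges.tsv")
    paths$degrees <- file.path(config$out_dir, "node_degrees.tsv")
    paths$hubs <- file.path(config$out_dir, "hub_nodes.tsv")
    el <- igraph::as_data_frame(net, what = "edges")
    names(el) <- c("a", "b")
    .write_tsv(el, paths$network_edges)
    .write_tsv(deg, paths$degrees)
    .write_tsv(res$hubs, paths$hubs)
  } else say("network stage skipped (no edge input)")

  manifest <- list(
    package = "platmine",
    version = as.character(utils::packageVersion("platmine")),
    config = unclass(config),
    config_hash = .config_hash(config),
    n_abstracts = length(corpus),
    n_events = nrow(events),
    n_genes = nrow(counts),
    count_total = sum(counts$count),
    n_top_genes = nrow(top),
    n_subtype_genes = nrow(sm),
    n_terms_tested = if (!is.null(res$enrichment)) attr(res$enrichment, "m")
                     else NULL,
    n_network_nodes = if (!is.null(res$network))
      igraph::vcount(res$network) else NULL,
    n_network_edges = if (!is.null(res$network))
      igraph::ecount(res$network) else NULL
  )
  res$manifest <- manifest
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  res$paths <- paths
  say("done: ", config$out_dir)
  invisible(res)
}
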