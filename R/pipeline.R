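#' Pipeline configuration
#'
#' Collects every input path and stage parameter for [run_pipeline()].
#' Defaults mirror the motivating study's printed parameters: abstracts
#' from 1990-2023, enrichment cutoff p < 0.01 on the raw hypergeometric
#' p-value, expression statistics at p < 0.05, GAPDH reference gene and
#' healthy controls as calibrator, anchor protein BDNF.
#'
#' @param corpus path to the abstract corpus.
#' @param lexicon path to the gene lexicon TSV.
#' @param catalogue path to the reference interaction catalogue
#'   (SIF/TSV).
#' @param targets path to the drug -> receptor TSV.
#' @param gmt path to the GMT annotation collection.
#' @param ct optional path to the Ct CSV (skip the expression stage with
#'   `NULL`).
#' @param elisa optional path to the ELISA CSV.
#' @param corpus_format `"structured"` or `"medline"`.
#' @param anchor anchor protein symbol.
#' @param disease_terms terms defining disease documents for PMI.
#' @param keywords curation inclusion keywords (empty = keep all in
#'   range).
#' @param year_min,year_max curation year range.
#' @param exclusion_terms curation exclusion terms.
#' @param min_pmi,min_docs protein-ranking thresholds (the PMI cutoff has
#'   no literature default and is deliberately a configuration choice).
#' @param path_budget interactome hop budget (`NULL` = shortest + 2).
#' @param alpha_enrich enrichment significance cutoff.
#' @param alpha_stats ANOVA/Tukey significance cutoff.
#' @param reference_gene housekeeping gene.
#' @param calibrator_group calibrator group name.
#' @param seed integer seed recorded in the report.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus, lexicon, catalogue, targets, gmt,
                            ct = NULL, elisa = NULL,
                            corpus_format = c("structured", "medline"),
                            anchor = "BDNF",
                            disease_terms = c("T2DM", "type 2 diabetes",
                                              "diabetes"),
                            keywords = character(),
                            year_min = 1990L, year_max = 2023L,
                            exclusion_terms = character(),
                            min_pmi = -Inf, min_docs = 1L,
                            path_budget = NULL,
                            alpha_enrich = 0.01, alpha_stats = 0.05,
                            reference_gene = "GAPDH",
                            calibrator_group = "healthy_control",
                            seed = 1L) {
  stopifnot(alpha_enrich > 0, alpha_enrich < 1,
            alpha_stats > 0, alpha_stats < 1, nzchar(anchor))
  structure(list(
    corpus = corpus, lexicon = lexicon, catalogue = catalogue,
    targets = targets, gmt = gmt, ct = ct, elisa = elisa,
    corpus_format = match.arg(corpus_format), anchor = toupper(anchor),
    disease_terms = disease_terms, keywords = keywords,
    year_min = year_min, year_max = year_max,
    exclusion_terms = exclusion_terms, min_pmi = min_pmi,
    min_docs = min_docs, path_budget = path_budget,
    alpha_enrich = alpha_enrich, alpha_stats = alpha_stats,
    reference_gene = toupper(reference_gene),
    calibrator_group = calibrator_group, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys are the arguments of [pipeline_config()]; relative input paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (k in c("corpus", "lexicon", "catalogue", "targets", "gmt", "ct",
              "elisa")) {
    if (!is.null(raw[[k]]) && !file.exists(raw[[k]]))
      raw[[k]] <- file.path(base, raw[[k]])
  }
  do.call(pipeline_config, raw)
}

.stage <- function(name, manifest_path, code) {
  res <- tryCatch(code, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e),
         call. = FALSE))
  cat(paste0(name, "\tdone\n"), file = manifest_path, append = TRUE)
  res
}

#' Run the full literature-to-network-to-validation pipeline
#'
#' Executes the stages in order: curate -> mine (mentions, PMI ranking)
#' -> network induction -> per-drug interactome and shortest cascade ->
#' enrichment -> expression statistics -> ELISA quantification (the last
#' two only when their inputs are configured). Per-stage outputs are
#' written under `out_dir` together with a `MANIFEST` of completed
#' stages and a single machine-readable `report.json`. The run is a pure
#' function of the inputs and config, so repeated runs produce
#' byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(out_dir, "MANIFEST")
  cat("", file = manifest)
  report <- list(parameters = list(
    anchor = config$anchor, year_min = config$year_min,
    year_max = config$year_max, min_pmi = config$min_pmi,
    min_docs = config$min_docs,
    alpha_enrich = config$alpha_enrich,
    alpha_stats = config$alpha_stats,
    reference_gene = config$reference_gene,
    calibrator_group = config$calibrator_group, seed = config$seed))

  curated <- .stage("curate", manifest, {
    corpus <- if (config$corpus_format == "medline")
      read_medline(config$corpus) else read_corpus(config$corpus)
    cur <- curate_corpus(corpus, config$keywords, config$year_min,
                         config$year_max, config$exclusion_terms)
    if (!nrow(cur)) stop("no abstracts retained after curation")
    write_corpus(cur, file.path(out_dir, "curated_corpus.tsv"))
    cur
  })
  report$curation <- list(n_curated = nrow(curated))

  mined <- .stage("mine", manifest, {
    lex <- read_lexicon(config$lexicon)
    hits <- mine_corpus(curated, lex)
    disease <- find_disease_records(curated, config$disease_terms)
    counts <- count_cooccurrence(hits, disease, nrow(curated))
    scores <- pmi_scores(counts)
    write_pmi_scores(scores, file.path(out_dir, "pmi_scores.tsv"))
    proteins <- rank_proteins(scores, config$min_pmi, config$min_docs)
    if (!length(proteins)) stop("no proteins passed the PMI filter")
    list(proteins = proteins, scores = scores,
         n_disease_docs = counts$disease_doc_count)
  })
  report$mining <- list(
    n_proteins = length(mined$proteins),
    n_disease_docs = mined$n_disease_docs,
    top_proteins = utils::head(mined$proteins, 10))

  net <- .stage("network", manifest, {
    cat_edges <- load_edge_catalogue(config$catalogue)
    n <- induce_disease_network(mined$proteins, cat_edges)
    write_sif(n, file.path(out_dir, "disease_network.sif"))
    n
  })
  ns <- network_summary(net)
  jsonlite::write_json(ns, file.path(out_dir, "network_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  report$network <- ns

  drugs <- .stage("cascade", manifest, {
    targets <- read_drug_targets(config$targets)
    lapply(names(targets), function(drug) {
      it <- extract_interactome(net, targets[[drug]], config$anchor,
                                max_path_len = config$path_budget,
                                drug = drug)
      write_interactome(
        it, file.path(out_dir, paste0("interactome_", drug, ".json")),
        file.path(out_dir, paste0("interactome_", drug, ".sif")))
      it
    })
  })
  names(drugs) <- vapply(drugs, function(d) d$drug, character(1))
  report$drugs <- lapply(drugs, function(d) {
    canonical <- if (length(d$cascades)) d$cascades[[1]]$nodes
                 else character()
    list(receptors = d$receptors, anchor = d$anchor,
         interactome_nodes = length(d$nodes),
         interactome_edges = nrow(d$edges),
         path_budget = d$max_path_len,
         n_shortest_cascades = length(d$cascades),
         canonical_cascade = canonical,
         cascade_length = if (length(canonical))
           length(canonical) - 1L else NA_integer_,
         intermediaries = if (length(d$cascades))
           intermediaries(d$cascades[[1]]) else character())
  })

  enr <- .stage("enrich", manifest, {
    gmt <- read_gmt(config$gmt)
    lapply(drugs, function(d) {
      if (d$empty) return(NULL)
      res <- suppressWarnings(
        enrich(d$nodes, gmt, universe = net$nodes,
               alpha = config$alpha_enrich))
      write_enrichment(
        res, file.path(out_dir, paste0("enrichment_", d$drug, ".tsv")))
      res
    })
  })
  report$enrichment <- lapply(enr, function(res) {
    if (is.null(res)) return(list(n_terms = 0L, n_significant = 0L))
    list(n_terms = nrow(res), n_significant = sum(res$significant),
         significant_terms = res$term[res$significant])
  })

  if (!is.null(config$ct)) {
    expr <- .stage("expr", manifest, {
      ctab <- read_ct_table(config$ct)
      folds <- delta_delta_ct(ctab, config$reference_gene,
                              config$calibrator_group)
      utils::write.table(folds, file.path(out_dir, "fold_changes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(folds = folds,
           stats = expression_group_stats(
             folds, alpha = config$alpha_stats))
    })
    report$expression <- lapply(expr$stats, function(gc) {
      gs <- gc$group_stats
      list(F = gc$F, p_anova = gc$p_anova,
           group_means = stats::setNames(as.list(gs$mean), gs$group),
           group_sd = stats::setNames(as.list(gs$sd), gs$group),
           significant_pairs = paste(
             gc$tukey$group_i[gc$tukey$significant],
             gc$tukey$group_j[gc$tukey$significant], sep = " vs "))
    })
  }

  if (!is.null(config$elisa)) {
    eli <- .stage("elisa", manifest, {
      e <- read_elisa(config$elisa)
      curve <- fit_standard_curve(e$standards, model = "linear")
      conc <- elisa_sample_concentrations(e, curve)
      utils::write.table(conc,
                         file.path(out_dir, "elisa_concentrations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ok <- conc[!conc$out_of_range, ]
      vbg <- split(ok$concentration, ok$group)
      vbg <- vbg[unique(ok$group)]
      list(curve = curve,
           comparison = group_comparison(vbg, label = "serum BDNF",
                                         alpha = config$alpha_stats),
           n_out_of_range = sum(conc$out_of_range))
    })
    gc <- eli$comparison
    report$elisa <- list(
      curve = as.list(eli$curve$coef),
      n_out_of_range = eli$n_out_of_range,
      F = gc$F, p_anova = gc$p_anova,
      group_means = stats::setNames(as.list(gc$group_stats$mean),
                                    gc$group_stats$group),
      significant_pairs = paste(gc$tukey$group_i[gc$tukey$significant],
                                gc$tukey$group_j[gc$tukey$significant],
                                sep = " vs "))
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(report)
}

#' Materialize the bundled fixture inputs
#'
#' Copies the package's small plain-text fixtures (abstract corpus,
#' lexicon, interaction catalogue encoding the two published cascades
#' plus longer decoy routes, drug-target map, pathway GMT) into `dir`
#' and generates the four-group Ct and ELISA tables there with the
#' seeded synthetic generators. Returns a ready [pipeline_config()].
#'
#' @param dir destination directory.
#' @param seed integer seed for the generated Ct/ELISA tables.
#' @return a `pipeline_config` pointing at the materialized files.
#' @export
fixture_bundle <- function(dir, seed = 20230401L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  src <- system.file("extdata", package = "drugcascade")
  files <- c("corpus.tsv", "lexicon.tsv", "catalogue.sif",
             "drug_targets.tsv", "pathways.gmt")
  for (f in files) file.copy(file.path(src, f), file.path(dir, f),
                             overwrite = TRUE)
  sim <- simulate_expression(default_expression_spec(seed))
  utils::write.csv(sim$data, file.path(dir, "ct.csv"),
                   row.names = FALSE, quote = FALSE)
  eli <- simulate_elisa(seed + 1L)
  utils::write.csv(eli$data, file.path(dir, "elisa.csv"),
                   row.names = FALSE, quote = FALSE)
  pipeline_config(
    corpus = file.path(dir, "corpus.tsv"),
    lexicon = file.path(dir, "lexicon.tsv"),
    catalogue = file.path(dir, "catalogue.sif"),
    targets = file.path(dir, "drug_targets.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    ct = file.path(dir, "ct.csv"),
    elisa = file.path(dir, "elisa.csv"),
    keywords = c("T2DM", "type 2 diabetes", "diabetes", "cognitive"),
    exclusion_terms = c("meta-analysis", "mouse model"),
    seed = seed)
}
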