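# Run code under a fixed RNG seed, restoring the caller's RNG state so
# generators are pure functions of their spec.
.with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.check_prob <- function(p, what) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop(what, " must be probabilities in [0, 1]")
}

#' Specification for a synthetic abstract corpus
#'
#' Each simulated abstract independently is a "disease document" with
#' probability `p_disease`, and mentions each symbol with the symbol's
#' background probability (or its disease-conditional probability inside
#' disease documents). The generator embeds symbols with proper word
#' boundaries and records exact ground-truth per-document counts, so the
#' mining stage can be validated end to end.
#'
#' @param seed integer RNG seed.
#' @param n_abstracts number of abstracts.
#' @param association_table data.frame with columns `symbol`,
#'   `p_mention` (background) and `p_mention_disease` (conditional on a
#'   disease document).
#' @param disease_terms character vector; the first term is embedded in
#'   disease documents.
#' @param p_disease probability that a document is a disease document.
#' @param year_range inclusive range years are drawn from.
#' @param hard_mode embed boundary-violating confusable substrings (e.g.
#'   `xBDNFx`) of unmentioned symbols, which a correct matcher must skip.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(seed, n_abstracts, association_table,
                        disease_terms = c("T2DM", "type 2 diabetes"),
                        p_disease = 0.5, year_range = c(1990L, 2023L),
                        hard_mode = FALSE) {
  stopifnot(n_abstracts >= 1,
            all(c("symbol", "p_mention", "p_mention_disease") %in%
                  names(association_table)),
            length(disease_terms) >= 1)
  .check_prob(association_table$p_mention, "p_mention")
  .check_prob(association_table$p_mention_disease, "p_mention_disease")
  .check_prob(p_disease, "p_disease")
  association_table$symbol <- toupper(association_table$symbol)
  structure(list(seed = as.integer(seed),
                 n_abstracts = as.integer(n_abstracts),
                 association_table = association_table,
                 disease_terms = disease_terms, p_disease = p_disease,
                 year_range = as.integer(year_range),
                 hard_mode = isTRUE(hard_mode)),
            class = "corpus_spec")
}

#' Simulate an abstract corpus with known co-occurrence structure
#'
#' @param spec a [corpus_spec()].
#' @return list with `corpus` (an [abstract_corpus()]) and `truth`: exact
#'   `doc_count` (n_x), `joint_count` (n_xd), `disease_records`,
#'   `disease_doc_count` (n_d), `n_docs`, and `mentions_by_record`.
#' @export
simulate_corpus <- function(spec) .with_seed(spec$seed, {
  at <- spec$association_table
  syms <- at$symbol
  n <- spec$n_abstracts
  filler <- c("cohort", "glucose", "plasma", "signalling", "insulin",
              "secretion", "pathway", "expression", "serum", "patients")
  ids <- sprintf("SIM%05d", seq_len(n))
  years <- sample(seq(spec$year_range[1], spec$year_range[2]),
                  n, replace = TRUE)
  is_disease <- stats::runif(n) < spec$p_disease
  bodies <- character(n)
  mentions <- vector("list", n); names(mentions) <- ids
  for (i in seq_len(n)) {
    p <- if (is_disease[i]) at$p_mention_disease else at$p_mention
    mentioned <- syms[stats::runif(length(syms)) < p]
    words <- c("We studied",
               sample(filler, 3, replace = TRUE))
    if (is_disease[i])
      words <- c(words, "in", spec$disease_terms[1], "subjects")
    for (s in mentioned)
      words <- c(words, "and the", s, "gene")
    if (spec$hard_mode) {
      confus <- setdiff(syms, mentioned)
      confus <- confus[stats::runif(length(confus)) < 0.3]
      for (s in confus) words <- c(words, paste0("x", s, "x"))
    }
    bodies[i] <- paste0(paste(words, collapse = " "), ".")
    mentions[[i]] <- mentioned
  }
  corpus <- abstract_corpus(ids, paste("Simulated record", seq_len(n)),
                            bodies, years)
  doc_count <- vapply(syms, function(s)
    sum(vapply(mentions, function(v) s %in% v, logical(1))), integer(1))
  joint <- vapply(syms, function(s)
    sum(vapply(mentions[is_disease], function(v) s %in% v, logical(1))),
    integer(1))
  list(corpus = corpus,
       truth = list(n_docs = n, doc_count = doc_count,
                    joint_count = joint,
                    disease_records = ids[is_disease],
                    disease_doc_count = sum(is_disease),
                    mentions_by_record = mentions))
})

#' Specification for a synthetic interaction catalogue
#'
#' A sparse Erdos-Renyi background with one or more planted
#' receptor -> anchor paths. A pruning step guarantees that every
#' receptor -> anchor route other than its planted path is at least
#' `min_decoy_length` hops, so the planted path is the strict shortest
#' cascade.
#'
#' @param seed integer RNG seed.
#' @param n_nodes total node count (planted nodes included).
#' @param edge_probability background edge probability.
#' @param planted_paths list of lists with elements `receptor`,
#'   `intermediaries` (character vector, may be empty), `anchor`.
#' @param min_decoy_length minimum hop count of any non-planted
#'   receptor -> anchor route; must exceed every planted path length.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(seed, n_nodes, edge_probability, planted_paths,
                         min_decoy_length = NULL) {
  stopifnot(length(planted_paths) >= 1)
  paths <- lapply(planted_paths, function(p) {
    nodes <- toupper(c(p$receptor, p$intermediaries, p$anchor))
    if (anyDuplicated(nodes)) stop("planted path nodes must be distinct")
    nodes
  })
  plen <- vapply(paths, length, integer(1)) - 1L
  if (is.null(min_decoy_length)) min_decoy_length <- max(plen) + 1L
  if (min_decoy_length <= max(plen))
    stop("min_decoy_length must exceed every planted path length")
  if (length(unique(unlist(paths))) > n_nodes)
    stop("infeasible spec: planted paths need more nodes than n_nodes")
  .check_prob(edge_probability, "edge_probability")
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 edge_probability = edge_probability,
                 planted_paths = paths,
                 min_decoy_length = as.integer(min_decoy_length)),
            class = "network_spec")
}

#' Simulate an edge catalogue with planted shortest cascades
#'
#' Background edges are drawn independently; planted path edges are then
#' added; finally, any receptor -> anchor route that omits at least one
#' planted edge and is shorter than `min_decoy_length` is broken by
#' removing one of its non-planted edges (repeatedly, until none
#' remains). The result is returned as an [edge_catalogue()] plus a
#' ground-truth sidecar listing the planted cascades.
#'
#' @param spec a [network_spec()].
#' @return list with `catalogue` and `truth` (`planted_paths`, `nodes`).
#' @export
simulate_network <- function(spec) .with_seed(spec$seed, {
  planted_nodes <- unique(unlist(spec$planted_paths))
  n_extra <- spec$n_nodes - length(planted_nodes)
  nodes <- c(planted_nodes, sprintf("P%03d", seq_len(n_extra)))
  pairs <- utils::combn(sort(nodes), 2)
  take <- stats::runif(ncol(pairs)) < spec$edge_probability
  a <- pairs[1, take]; b <- pairs[2, take]
  planted_a <- character(); planted_b <- character()
  for (p in spec$planted_paths) {
    x <- p[-length(p)]; y <- p[-1]
    planted_a <- c(planted_a, pmin(x, y))
    planted_b <- c(planted_b, pmax(x, y))
  }
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\t")
  pkeys <- key(planted_a, planted_b)
  ek <- unique(c(key(a, b), pkeys))
  edges <- do.call(rbind, strsplit(ek, "\t", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(a = edges[, 1], b = edges[, 2]), directed = FALSE,
    vertices = data.frame(name = sort(nodes)))

  # prune alternative routes shorter than min_decoy_length
  for (p in spec$planted_paths) {
    r <- p[1]; anchor <- p[length(p)]
    px <- p[-length(p)]; py <- p[-1]
    pk <- key(px, py)
    repeat {
      offending <- NULL
      for (i in seq_along(pk)) {
        eid <- igraph::get_edge_ids(g, c(px[i], py[i]))
        if (eid == 0) next
        g2 <- igraph::delete_edges(g, eid)
        sp <- suppressWarnings(
          igraph::shortest_paths(g2, from = r, to = anchor)$vpath[[1]])
        if (length(sp) > 1L &&
            (length(sp) - 1L) < spec$min_decoy_length) {
          offending <- names(sp); break
        }
      }
      if (is.null(offending)) break
      ox <- offending[-length(offending)]; oy <- offending[-1]
      ok <- key(ox, oy)
      removable <- which(!ok %in% pkeys)
      if (!length(removable))
        stop("infeasible spec: alternative route uses only planted edges")
      ridx <- removable[length(removable)]
      g <- igraph::delete_edges(
        g, igraph::get_edge_ids(g, c(ox[ridx], oy[ridx])))
    }
  }
  el <- igraph::as_edgelist(g)
  catalogue <- edge_catalogue(el[, 1], el[, 2])
  list(catalogue = catalogue,
       truth = list(planted_paths = spec$planted_paths,
                    nodes = sort(nodes),
                    min_decoy_length = spec$min_decoy_length))
})

#' Specification for a synthetic four-group qPCR experiment
#'
#' Per sample, the reference-gene Ct is drawn around a sample-level
#' baseline (baseline shifts cancel in dCt, mimicking loading
#' differences); each target gene's Ct sits `delta_ct` cycles above the
#' baseline, where `delta_ct = base_delta_ct - log2(planted_fold)` for
#' the sample's group. Every Ct is measured `n_replicates` times with
#' technical noise `ct_sd`.
#'
#' @param seed integer RNG seed.
#' @param genes character vector of target genes.
#' @param groups named integer vector: group -> samples per group.
#' @param planted_fold numeric matrix (genes x groups) of fold changes
#'   relative to the calibrator group (whose column must be 1).
#' @param base_delta_ct named numeric: per-gene dCt in the calibrator.
#' @param ct_sd technical replicate SD in cycles.
#' @param sample_sd SD of the per-sample baseline shift.
#' @param reference list: `gene`, `mean` Ct of the reference gene.
#' @param n_replicates technical replicates per (sample, gene).
#' @param calibrator_group name of the calibrator group.
#' @return object of class `expression_spec`.
#' @export
expression_spec <- function(seed, genes, groups, planted_fold,
                            base_delta_ct, ct_sd = 0.3, sample_sd = 0.5,
                            reference = list(gene = "GAPDH", mean = 20),
                            n_replicates = 3L,
                            calibrator_group = "healthy_control") {
  genes <- toupper(genes)
  stopifnot(is.matrix(planted_fold),
            nrow(planted_fold) == length(genes),
            ncol(planted_fold) == length(groups),
            all(groups >= 2), ct_sd > 0, sample_sd >= 0,
            n_replicates >= 1,
            calibrator_group %in% names(groups),
            all(genes %in% names(base_delta_ct)))
  rownames(planted_fold) <- genes
  colnames(planted_fold) <- names(groups)
  if (any(abs(planted_fold[, calibrator_group] - 1) > 1e-12))
    stop("planted_fold must be 1 in the calibrator group")
  if (any(planted_fold <= 0)) stop("planted folds must be positive")
  structure(list(seed = as.integer(seed), genes = genes, groups = groups,
                 planted_fold = planted_fold,
                 base_delta_ct = base_delta_ct[genes], ct_sd = ct_sd,
                 sample_sd = sample_sd, reference = reference,
                 n_replicates = as.integer(n_replicates),
                 calibrator_group = calibrator_group),
            class = "expression_spec")
}

#' The study-shaped default expression experiment
#'
#' Four groups of 30 samples (untreated disease, two drug arms, healthy
#' controls), GAPDH reference, and the four cascade genes with planted
#' fold changes qualitatively matching the motivating study: all targets
#' reduced untreated, APP doubled under metformin, AP2M1/ESR1/BDNF raised
#' under glimepiride (BDNF doubled).
#'
#' @param seed integer RNG seed.
#' @return an [expression_spec()].
#' @export
default_expression_spec <- function(seed) {
  groups <- c(untreated_T2DM = 30L, metformin = 30L, glimepiride = 30L,
              healthy_control = 30L)
  genes <- c("APP", "AP2M1", "ESR1", "BDNF")
  fold <- rbind(
    APP   = c(0.6, 2.0, 1.2, 1),
    AP2M1 = c(0.6, 1.1, 1.8, 1),
    ESR1  = c(0.7, 1.0, 1.9, 1),
    BDNF  = c(0.5, 1.5, 2.0, 1)
  )
  colnames(fold) <- names(groups)
  expression_spec(seed, genes, groups, fold,
                  base_delta_ct = c(APP = 5, AP2M1 = 4, ESR1 = 6,
                                    BDNF = 7))
}

#' Simulate a Ct table from an expression spec
#'
#' @param spec an [expression_spec()].
#' @return list with `data` (Ct data.frame: `sample_id`, `group`, `gene`,
#'   `replicate`, `ct`) and `truth` (`planted_fold`, `delta_ct_mean`).
#' @export
simulate_expression <- function(spec) .with_seed(spec$seed, {
  dct_mean <- sweep(-log2(spec$planted_fold), 1,
                    spec$base_delta_ct, `+`)
  nr <- spec$n_replicates
  genes <- c(spec$reference$gene, spec$genes)
  blocks <- lapply(names(spec$groups), function(grp) {
    n_s <- spec$groups[[grp]]
    sids <- sprintf("%s_%02d", grp, seq_len(n_s))
    baseline <- spec$reference$mean + stats::rnorm(n_s, 0, spec$sample_sd)
    do.call(rbind, lapply(genes, function(g) {
      true_ct <- baseline + if (g == spec$reference$gene) 0
                            else dct_mean[g, grp]
      data.frame(
        sample_id = rep(sids, each = nr), group = grp, gene = g,
        replicate = rep(seq_len(nr), n_s),
        ct = rep(true_ct, each = nr) +
          stats::rnorm(n_s * nr, 0, spec$ct_sd),
        stringsAsFactors = FALSE)
    }))
  })
  data <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  if (any(data$ct <= 0 | data$ct >= 45))
    stop("simulated Ct outside (0, 45); adjust the spec")
  list(data = data,
       truth = list(planted_fold = spec$planted_fold,
                    delta_ct_mean = dct_mean))
})

#' Simulate an ELISA plate (standards plus samples)
#'
#' Standards follow the stated response curve with additive absorbance
#' noise; each sample has a true concentration drawn around its group
#' mean and `n_replicates` absorbance reads.
#'
#' @param seed integer RNG seed.
#' @param group_means named numeric: group -> mean concentration (ng/mL).
#' @param group_sd between-sample concentration SD (ng/mL).
#' @param n_per_group samples per group.
#' @param standards numeric vector of standard concentrations (ng/mL),
#'   strictly increasing, starting at the blank.
#' @param curve list describing the true response: `model` ("linear":
#'   `intercept`, `slope`; or "4pl": `a`, `d`, `c`, `b`).
#' @param noise_sd absorbance noise SD.
#' @param n_replicates reads per sample.
#' @return list with `data` (data.frame: `type`, `id`, `group`,
#'   `concentration`, `absorbance`) and `truth` (`group_means`,
#'   `sample_concentration`, `curve`).
#' @export
simulate_elisa <- function(seed,
                           group_means = c(untreated_T2DM = 14,
                                           metformin = 19,
                                           glimepiride = 25,
                                           healthy_control = 22),
                           group_sd = 3, n_per_group = 30L,
                           standards = c(0, 5, 10, 15, 20, 25, 30, 40),
                           curve = list(model = "linear",
                                        intercept = 0.01, slope = 0.05),
                           noise_sd = 0.01, n_replicates = 3L) {
  stopifnot(all(diff(standards) > 0), all(standards >= 0),
            noise_sd >= 0, group_sd >= 0)
  respond <- function(conc) {
    if (curve$model == "linear") curve$intercept + curve$slope * conc
    else curve$d + (curve$a - curve$d) / (1 + (conc / curve$c)^curve$b)
  }
  .with_seed(seed, {
    std <- data.frame(
      type = "standard",
      id = sprintf("STD%02d", seq_along(standards)),
      group = NA_character_, concentration = standards,
      absorbance = respond(standards) +
        stats::rnorm(length(standards), 0, noise_sd),
      stringsAsFactors = FALSE)
    rows <- list(); true_conc <- numeric(0)
    for (grp in names(group_means)) {
      conc <- pmax(stats::rnorm(n_per_group, group_means[[grp]],
                                group_sd), 0.1)
      names(conc) <- sprintf("%s_%02d", grp, seq_len(n_per_group))
      true_conc <- c(true_conc, conc)
      for (i in seq_len(n_per_group)) {
        rows[[length(rows) + 1L]] <- data.frame(
          type = "sample", id = names(conc)[i], group = grp,
          concentration = NA_real_,
          absorbance = respond(conc[i]) +
            stats::rnorm(n_replicates, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    data <- do.call(rbind, c(list(std), rows,
                             list(make.row.names = FALSE)))
    list(data = data,
         truth = list(group_means = group_means,
                      sample_concentration = true_conc, curve = curve))
  })
}
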