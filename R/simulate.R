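#' Configuration of the synthetic cohort
#'
#' The defaults define the study conditions the pipeline is built for:
#' 4100 genes at a 1:40 pain/non-pain imbalance (100 positives), positives
#' preferentially planted on hubs of a scale-free interaction graph, a
#' subset of ontology terms enriched in positives, and per-group expression
#' effects concentrated in the positive class.
#'
#' @param n_genes Number of genes (default 4100).
#' @param pos_fraction Positive-label fraction (default 1/41, i.e. P/NP = 1/40).
#' @param seed Master integer seed; per-component seeds are derived from it
#'   by fixed offsets.
#' @param graph_attachment Preferential-attachment edges per new node
#'   (default 3).
#' @param hub_bias Exponent of the degree-proportional positive-sampling
#'   weight (default 2; 0 = uniform labelling).
#' @param n_go_terms Number of background GO terms (default 300).
#' @param go_enrichment_odds Odds multiplier of informative terms in
#'   positives (default 4).
#' @param n_informative_terms Number of informative terms (default 30).
#' @param n_omics_groups Number of tissue-by-species omics groups
#'   (default 6); each group carries two LFC/FDR dataset pairs and one TPM
#'   column.
#' @param lfc_effect Log2 shift added to effect carriers among positives
#'   (default 1).
#' @param lfc_noise_sd Gaussian LFC noise SD (default 1).
#' @param frac_significant_background Fraction of non-carrier entries given
#'   a significant FDR (default 0.05).
#' @param validation_overlap Fraction of the synthetic external validation
#'   set drawn from planted positives (default 0.5).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 4100, pos_fraction = 1 / 41, seed = 20240101,
                       graph_attachment = 3, hub_bias = 2.0, n_go_terms = 300,
                       go_enrichment_odds = 4.0, n_informative_terms = 30,
                       n_omics_groups = 6, lfc_effect = 1.0, lfc_noise_sd = 1.0,
                       frac_significant_background = 0.05,
                       validation_overlap = 0.5) {
  cfg <- list(n_genes = n_genes, pos_fraction = pos_fraction, seed = seed,
              graph_attachment = graph_attachment, hub_bias = hub_bias,
              n_go_terms = n_go_terms,
              go_enrichment_odds = go_enrichment_odds,
              n_informative_terms = n_informative_terms,
              n_omics_groups = n_omics_groups, lfc_effect = lfc_effect,
              lfc_noise_sd = lfc_noise_sd,
              frac_significant_background = frac_significant_background,
              validation_overlap = validation_overlap)
  errs <- character(0)
  if (cfg$n_genes < 10) errs <- c(errs, "n_genes must be >= 10")
  if (cfg$pos_fraction <= 0 || cfg$pos_fraction >= 1) {
    errs <- c(errs, "pos_fraction must be in (0, 1)")
  }
  if (cfg$graph_attachment < 1 || cfg$graph_attachment >= cfg$n_genes) {
    errs <- c(errs, "graph_attachment must be in [1, n_genes)")
  }
  if (cfg$hub_bias < 0) errs <- c(errs, "hub_bias must be >= 0")
  if (cfg$validation_overlap < 0 || cfg$validation_overlap > 1) {
    errs <- c(errs, "validation_overlap must be in [0, 1]")
  }
  if (cfg$frac_significant_background < 0 || cfg$frac_significant_background >= 1) {
    errs <- c(errs, "frac_significant_background must be in [0, 1)")
  }
  if (length(errs)) stop(paste(errs, collapse = "; "))
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("G%06d", seq_len(n))

#' Simulate a scale-free interaction graph
#'
#' Connected preferential-attachment graph over all genes, giving the
#' heavy-tailed degree distribution typical of protein interaction networks.
#'
#' @param cfg A [sim_config()].
#' @return An undirected simple `igraph` with gene-identifier vertex names.
#' @export
simulate_graph <- function(cfg) {
  set.seed(cfg$seed + 1L)
  g <- igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$graph_attachment,
                         directed = FALSE)
  igraph::V(g)$name <- sim_gene_ids(cfg$n_genes)
  igraph::simplify(g)
}

#' Plant pain labels on network hubs
#'
#' Positives are sampled without replacement with probability proportional
#' to `degree^hub_bias`; the positive count is `round(n_genes *
#' pos_fraction)`.
#'
#' @param g Graph from [simulate_graph()].
#' @param cfg A [sim_config()].
#' @return List with `labels` (named 0/1 vector over all genes) and
#'   `positives` (character vector).
#' @export
plant_labels <- function(g, cfg) {
  genes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  n_pos <- round(cfg$n_genes * cfg$pos_fraction)
  set.seed(cfg$seed + 2L)
  pos <- sample(genes, n_pos, prob = deg^cfg$hub_bias)
  labels <- setNames(as.integer(genes %in% pos), genes)
  list(labels = labels, positives = pos)
}

#' Simulate GO annotations with informative terms
#'
#' Background terms are annotated at per-term base rates; a designated
#' informative subset is annotated to positives with multiplied odds. One
#' decoy term named "response to pain signal" is always included (enriched
#' in positives) to exercise the feature-space exclusion guard.
#'
#' @param labels Named 0/1 label vector.
#' @param cfg A [sim_config()].
#' @return List with `annotations` (data frame `gene_id`, `term_id`,
#'   `term_name`), `informative_terms` and `decoy_term`.
#' @export
simulate_go <- function(labels, cfg) {
  genes <- names(labels)
  set.seed(cfg$seed + 3L)
  term_ids <- sprintf("GO:SYN%04d", seq_len(cfg$n_go_terms))
  term_names <- sprintf("synthetic process %04d", seq_len(cfg$n_go_terms))
  base_rate <- runif(cfg$n_go_terms, 0.01, 0.15)
  n_inf <- min(cfg$n_informative_terms, cfg$n_go_terms)
  informative <- term_ids[seq_len(n_inf)]

  is_pos <- labels == 1
  rows <- vector("list", cfg$n_go_terms + 1L)
  for (t in seq_len(cfg$n_go_terms)) {
    p <- rep(base_rate[t], length(genes))
    if (term_ids[t] %in% informative) {
      odds <- base_rate[t] / (1 - base_rate[t]) * cfg$go_enrichment_odds
      p[is_pos] <- odds / (1 + odds)
    }
    hit <- runif(length(genes)) < p
    if (any(hit)) {
      rows[[t]] <- data.frame(gene_id = genes[hit], term_id = term_ids[t],
                              term_name = term_names[t],
                              stringsAsFactors = FALSE)
    }
  }
  # decoy: strongly enriched in positives, must never reach the feature space
  p_decoy <- ifelse(is_pos, 0.4, 0.03)
  hit <- runif(length(genes)) < p_decoy
  decoy_id <- "GO:SYNPAIN"
  rows[[cfg$n_go_terms + 1L]] <- data.frame(
    gene_id = genes[hit], term_id = decoy_id,
    term_name = "response to pain signal", stringsAsFactors = FALSE)
  list(annotations = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
       informative_terms = informative, decoy_term = decoy_id)
}

sim_group_table <- function(cfg) {
  tissues <- c("DRG", "skin", "spinal_cord", "sciatic_nerve", "iPSC", "brain")
  species <- c("mouse", "human", "rat")
  grid <- expand.grid(tissue = tissues, species = species,
                      stringsAsFactors = FALSE)
  grid[seq_len(min(cfg$n_omics_groups, nrow(grid))), , drop = FALSE]
}

#' Simulate omics LFC/FDR/TPM columns
#'
#' Per tissue-by-species group: two LFC/FDR dataset pairs and one TPM
#' column. Within each dataset, a random half of the positives are effect
#' carriers: their LFC is shifted by `lfc_effect` and their FDR is drawn
#' below 0.05; non-carriers get null LFC noise and mostly non-significant
#' FDR (a small background fraction is spuriously significant). TPM is
#' log-normal.
#'
#' @param labels Named 0/1 label vector.
#' @param cfg A [sim_config()].
#' @return List with `columns` (data frame of omics columns, rows in
#'   `names(labels)` order), `meta` (column metadata data frame) and
#'   `effect_carriers` (named list per dataset).
#' @export
simulate_omics <- function(labels, cfg) {
  genes <- names(labels)
  n <- length(genes)
  pos <- genes[labels == 1]
  groups <- sim_group_table(cfg)
  set.seed(cfg$seed + 4L)
  cols <- list()
  meta <- list()
  carriers <- list()
  for (gi in seq_len(nrow(groups))) {
    tis <- groups$tissue[gi]
    sp <- groups$species[gi]
    for (rep_i in 1:2) {
      ds <- sprintf("%s_%s_ds%d", tis, sp, rep_i)
      carrier <- sample(pos, max(1, round(length(pos) / 2)))
      lfc <- rnorm(n, 0, cfg$lfc_noise_sd)
      lfc[genes %in% carrier] <- lfc[genes %in% carrier] + cfg$lfc_effect
      fdr <- runif(n, 0.05, 1)
      bg_sig <- runif(n) < cfg$frac_significant_background
      fdr[bg_sig] <- runif(sum(bg_sig), 0.001, 0.049)
      fdr[genes %in% carrier] <- runif(length(carrier), 0.001, 0.049)
      lfc_col <- paste0("LFC_", ds)
      fdr_col <- paste0("FDR_", ds)
      cols[[lfc_col]] <- lfc
      cols[[fdr_col]] <- fdr
      meta[[lfc_col]] <- data.frame(column = lfc_col, dataset = ds,
                                    tissue = tis, species = sp,
                                    modality = "transcriptome",
                                    measure = "LFC", stringsAsFactors = FALSE)
      meta[[fdr_col]] <- data.frame(column = fdr_col, dataset = ds,
                                    tissue = tis, species = sp,
                                    modality = "transcriptome",
                                    measure = "FDR", stringsAsFactors = FALSE)
      carriers[[ds]] <- carrier
    }
    tpm_col <- sprintf("TPM_%s_%s", tis, sp)
    cols[[tpm_col]] <- rlnorm(n, meanlog = 2, sdlog = 1.5)
    meta[[tpm_col]] <- data.frame(column = tpm_col,
                                  dataset = sprintf("%s_%s_tpm", tis, sp),
                                  tissue = tis, species = sp,
                                  modality = "transcriptome",
                                  measure = "TPM", stringsAsFactors = FALSE)
  }
  list(columns = as.data.frame(cols), meta = do.call(rbind, meta),
       effect_carriers = carriers)
}

#' Simulate genomic annotation columns
#'
#' Cellular compartment, tissue of highest expression, chromosome, GC
#' content and conservation score; all label-neutral (the planted signal
#' lives in the network, ontology and omics features).
#'
#' @param labels Named 0/1 label vector.
#' @param cfg A [sim_config()].
#' @return Data frame of genomic columns, rows in `names(labels)` order.
#' @export
simulate_genomic <- function(labels, cfg) {
  n <- length(labels)
  set.seed(cfg$seed + 5L)
  data.frame(
    cellular_compartment = sample(c("membrane", "nucleus", "cytosol",
                                    "extracellular", "mitochondrion"),
                                  n, replace = TRUE),
    tissue = sample(c("DRG", "skin", "spinal_cord", "brain", "liver"),
                    n, replace = TRUE),
    chromosome_name = sample(c(as.character(1:22), "X", "Y"), n, replace = TRUE),
    gc_content = pmin(pmax(rnorm(n, 41, 5), 25), 75),
    conservation_score = rbeta(n, 2, 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate the external validation gene set
#'
#' A synthetic analogue of a pain-SNP gene list: about twice the positive
#' count, `validation_overlap` of it drawn from planted positives and the
#' remainder from hub-weighted non-positives (unlabelled-but-true
#' analogues).
#'
#' @param labels Named 0/1 label vector.
#' @param g The interaction graph (for hub weighting).
#' @param cfg A [sim_config()].
#' @return A [gene_set()] named `synthetic_HPGDB`.
#' @export
simulate_validation_set <- function(labels, g, cfg) {
  genes <- names(labels)
  pos <- genes[labels == 1]
  neg <- genes[labels == 0]
  size <- 2 * length(pos)
  n_from_pos <- round(cfg$validation_overlap * size)
  n_from_pos <- min(n_from_pos, length(pos))
  set.seed(cfg$seed + 6L)
  from_pos <- if (n_from_pos > 0) sample(pos, n_from_pos) else character(0)
  deg <- igraph::degree(g)[neg]
  from_neg <- sample(neg, size - n_from_pos, prob = deg^cfg$hub_bias)
  gene_set("synthetic_HPGDB", c(from_pos, from_neg),
           "synthetic pain-SNP gene list for external rank validation")
}

#' Generate the full synthetic cohort
#'
#' Composes graph, labels, ontology, omics, genomic columns and the external
#' validation set under a single master seed, optionally writing every
#' standard-format file.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory; when given, writes
#'   `gene_table.tsv`, `gene_table_meta.yaml`, `go_annotations.tsv`,
#'   `ppi_edges.tsv`, `labels.tsv`, `validation_sets.gmt` and `truth.json`.
#' @return An object of class `synthetic_cohort`: `tab` (raw gene table),
#'   `meta`, `annotations`, `graph`, `labels`, `validation_set`, and
#'   `truth` (planted positives, informative terms, decoy term, effect
#'   carriers).
#' @export
generate_cohort <- function(cfg = sim_config(), dir = NULL) {
  g <- simulate_graph(cfg)
  lab <- plant_labels(g, cfg)
  go <- simulate_go(lab$labels, cfg)
  om <- simulate_omics(lab$labels, cfg)
  gen <- simulate_genomic(lab$labels, cfg)
  vset <- simulate_validation_set(lab$labels, g, cfg)

  tab <- cbind(data.frame(gene_id = names(lab$labels),
                          stringsAsFactors = FALSE),
               gen, om$columns)
  cohort <- structure(list(
    tab = tab, meta = om$meta, annotations = go$annotations, graph = g,
    labels = lab$labels, validation_set = vset,
    truth = list(positives = lab$positives,
                 informative_terms = go$informative_terms,
                 decoy_term = go$decoy_term,
                 effect_carriers = om$effect_carriers),
    config = cfg
  ), class = "synthetic_cohort")

  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a synthetic cohort to standard-format files
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort$tab, file.path(dir, "gene_table.tsv"), sep = "\t")
  meta_list <- lapply(seq_len(nrow(cohort$meta)), function(i) {
    as.list(cohort$meta[i, c("dataset", "tissue", "species", "modality",
                             "measure")])
  })
  names(meta_list) <- cohort$meta$column
  yaml::write_yaml(meta_list, file.path(dir, "gene_table_meta.yaml"))
  ann <- data.frame(gene_id = cohort$annotations$gene_id,
                    term = paste(cohort$annotations$term_id,
                                 cohort$annotations$term_name, sep = "|"))
  data.table::fwrite(ann, file.path(dir, "go_annotations.tsv"), sep = "\t")
  el <- igraph::as_edgelist(cohort$graph)
  data.table::fwrite(data.frame(protein1 = el[, 1], protein2 = el[, 2]),
                     file.path(dir, "ppi_edges.tsv"), sep = "\t")
  data.table::fwrite(data.frame(gene_id = names(cohort$labels),
                                label = unname(cohort$labels)),
                     file.path(dir, "labels.tsv"), sep = "\t")
  write_gmt(list(cohort$validation_set), file.path(dir, "validation_sets.gmt"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A `synthetic_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  gt <- read_gene_table(file.path(dir, "gene_table.tsv"),
                        file.path(dir, "gene_table_meta.yaml"))
  ann <- read_go_annotations(file.path(dir, "go_annotations.tsv"))
  edges <- read_edge_list(file.path(dir, "ppi_edges.tsv"))
  labs <- data.table::fread(file.path(dir, "labels.tsv"), data.table = FALSE)
  labels <- setNames(labs$label, labs$gene_id)
  g <- ppi_graph(edges, nodes = labs$gene_id)
  vsets <- read_gmt(file.path(dir, "validation_sets.gmt"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(tab = gt$tab, meta = gt$meta, annotations = ann, graph = g,
                 labels = labels, validation_set = vsets[[1]], truth = truth,
                 config = NULL),
            class = "synthetic_cohort")
}
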