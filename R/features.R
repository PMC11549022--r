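#' Fit an ordinal encoder on a categorical column
#'
#' Levels are assigned consecutive integer codes by sorted label order, so the
#' encoding is deterministic. Labels unseen at fit time map to a reserved code
#' one past the last fitted level.
#'
#' @param values Character vector of category labels observed at fit time.
#' @return An object of class `ordinal_encoder` with elements `levels` and
#'   `unseen_code`.
#' @export
fit_ordinal_encoder <- function(values) {
  values <- as.character(values)
  if (any(is.na(values) | values == "")) stop("category labels must be non-empty")
  lev <- sort(unique(values))
  structure(list(levels = lev, unseen_code = length(lev)),
            class = "ordinal_encoder")
}

#' Apply a fitted ordinal encoder
#'
#' @param enc An `ordinal_encoder` from [fit_ordinal_encoder()].
#' @param values Character vector to encode.
#' @return Integer codes, 0-based; unseen labels get the reserved code.
#' @export
apply_ordinal_encoder <- function(enc, values) {
  i <- match(as.character(values), enc$levels)
  code <- i - 1L
  code[is.na(i)] <- enc$unseen_code
  code
}

#' Decode ordinal codes back to labels
#'
#' @param enc An `ordinal_encoder`.
#' @param codes Integer codes produced by [apply_ordinal_encoder()].
#' @return Character labels; the reserved unseen code decodes to `NA`.
#' @export
decode_ordinal <- function(enc, codes) {
  out <- enc$levels[codes + 1L]
  out[codes == enc$unseen_code] <- NA_character_
  out
}

#' Ordinal-encode the categorical gene features
#'
#' @param tab Data frame with the categorical columns.
#' @param cols Names of the columns to encode.
#' @param fit_rows Row indices used to fit the encoders (default all rows);
#'   encoders are applied to every row.
#' @return List with `codes` (data frame of integer codes) and `encoders`.
#' @export
encode_categoricals <- function(tab, cols, fit_rows = seq_len(nrow(tab))) {
  encoders <- lapply(cols, function(cl) fit_ordinal_encoder(tab[[cl]][fit_rows]))
  names(encoders) <- cols
  codes <- as.data.frame(lapply(cols, function(cl) {
    apply_ordinal_encoder(encoders[[cl]], tab[[cl]])
  }), col.names = cols)
  list(codes = codes, encoders = encoders)
}

#' TF-IDF + PCA features from Gene Ontology annotations
#'
#' Builds the low-dimensional ontology features (`GO1`, `GO2`, ...):
#' terms whose *name* contains the substring "pain" (case-insensitive) are
#' excluded outright as a label-leakage guard; terms annotated to at least
#' 20% of the fitting genes are dropped (only rarer, more specific terms are
#' informative); the remaining gene-term incidence is TF-IDF weighted
#' (smoothed IDF `ln((1+N)/(1+df)) + 1`, L2 row normalization) and projected
#' onto principal components fitted on the fitting genes only.
#'
#' @param annotations Data frame with columns `gene_id`, `term_id`,
#'   `term_name` (one gene-term pair per row).
#' @param genes Character vector: the gene universe, in output row order.
#' @param n_components Number of principal components to keep (default 2).
#' @param fit_genes Genes used to fit vocabulary, IDF and PCA (default all of
#'   `genes`); typically the training split, to avoid leakage.
#' @param max_prevalence Terms annotated to at least this fraction of the
#'   fitting genes are dropped (default 0.20).
#' @return List with `features` (matrix, `length(genes)` x `n_components`,
#'   columns `GO1..`), `vocabulary`, `idf`, `pca` and `dropped_pain_terms`.
#' @export
go_vectorize <- function(annotations, genes, n_components = 2,
                         fit_genes = genes, max_prevalence = 0.20) {
  stopifnot(all(c("gene_id", "term_id", "term_name") %in% names(annotations)))
  ann <- annotations[annotations$gene_id %in% genes, , drop = FALSE]
  if (length(unique(ann$gene_id)) < 2) stop("need >= 2 annotated genes")

  pain_mask <- grepl("pain", ann$term_name, ignore.case = TRUE)
  dropped_pain <- unique(ann$term_id[pain_mask])
  ann <- ann[!pain_mask, , drop = FALSE]

  fit_ann <- ann[ann$gene_id %in% fit_genes, , drop = FALSE]
  n_fit <- length(fit_genes)
  df <- tapply(fit_ann$gene_id, fit_ann$term_id,
               function(g) length(unique(g)))
  vocab <- names(df)[df / n_fit < max_prevalence & df > 0]
  if (length(vocab) == 0) {
    warning("no GO terms survive filtering; emitting zero features")
    z <- matrix(0, length(genes), n_components,
                dimnames = list(genes, paste0("GO", seq_len(n_components))))
    return(list(features = z, vocabulary = character(0), idf = numeric(0),
                pca = NULL, dropped_pain_terms = dropped_pain))
  }

  idf <- log((1 + n_fit) / (1 + as.numeric(df[vocab]))) + 1
  names(idf) <- vocab

  tfidf <- function(which_genes) {
    sub <- ann[ann$gene_id %in% which_genes & ann$term_id %in% vocab, ,
               drop = FALSE]
    i <- match(sub$gene_id, which_genes)
    j <- match(sub$term_id, vocab)
    m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(length(which_genes), length(vocab)))
    m <- m %*% Matrix::Diagonal(x = idf)
    nrm <- sqrt(Matrix::rowSums(m^2))
    nrm[nrm == 0] <- 1
    as.matrix(Matrix::Diagonal(x = 1 / nrm) %*% m)
  }

  x_fit <- tfidf(fit_genes)
  k <- min(n_components, ncol(x_fit), nrow(x_fit) - 1)
  pca <- prcomp(x_fit, center = TRUE, scale. = FALSE, rank. = k)
  x_all <- tfidf(genes)
  proj <- predict(pca, x_all)[, seq_len(k), drop = FALSE]
  if (k < n_components) {
    proj <- cbind(proj, matrix(0, nrow(proj), n_components - k))
  }
  colnames(proj) <- paste0("GO", seq_len(n_components))
  rownames(proj) <- genes
  list(features = proj, vocabulary = vocab, idf = idf, pca = pca,
       dropped_pain_terms = dropped_pain)
}

#' Composite log-fold-change features per tissue and species
#'
#' Omics LFC columns are grouped by (tissue, species); within each group an
#' entry is set to 0 when its paired FDR is >= 0.05 (i.e. not significant) or
#' missing, and the per-gene mean over the group's datasets is taken. One
#' composite column is emitted per group.
#'
#' @param tab Data frame holding the omics columns (plus anything else).
#' @param meta Data frame describing the omics columns, with columns
#'   `column`, `dataset`, `tissue`, `species`, `modality`, `measure`
#'   (`measure` one of "LFC", "FDR", "TPM"). Each LFC column must share a
#'   `dataset` with exactly one FDR column.
#' @param fdr_cutoff Significance threshold (default 0.05).
#' @return A data frame of composite columns named `cLFC_<tissue>_<species>`,
#'   rows aligned with `tab`.
#' @export
composite_lfc <- function(tab, meta, fdr_cutoff = 0.05) {
  need <- c("column", "dataset", "tissue", "species", "measure")
  stopifnot(all(need %in% names(meta)))
  lfc_meta <- meta[meta$measure == "LFC", , drop = FALSE]
  fdr_meta <- meta[meta$measure == "FDR", , drop = FALSE]
  if (nrow(lfc_meta) == 0) stop("no LFC columns declared in metadata")

  zeroed <- lapply(seq_len(nrow(lfc_meta)), function(i) {
    ds <- lfc_meta$dataset[i]
    fdr_col <- fdr_meta$column[fdr_meta$dataset == ds]
    if (length(fdr_col) != 1) {
      stop("LFC column '", lfc_meta$column[i],
           "' lacks a unique FDR partner column")
    }
    lfc <- tab[[lfc_meta$column[i]]]
    fdr <- tab[[fdr_col]]
    sig <- !is.na(fdr) & fdr < fdr_cutoff & !is.na(lfc)
    ifelse(sig, lfc, 0)
  })
  grp <- paste(lfc_meta$tissue, lfc_meta$species, sep = "_")
  out <- lapply(unique(grp), function(g) {
    cols <- zeroed[grp == g]
    Reduce(`+`, cols) / length(cols)
  })
  out <- as.data.frame(out, col.names = paste0("cLFC_", unique(grp)))
  rownames(out) <- NULL
  out
}

#' Drop one member of every highly correlated feature pair
#'
#' Repeatedly finds the feature pair with the largest absolute Pearson
#' correlation at or above `threshold` and removes the member with the
#' smaller variance (ties: the later column), until no pair remains.
#' Correlations and variances are computed on `fit_rows` only.
#'
#' @param x Numeric feature matrix with column names.
#' @param threshold Absolute correlation triggering removal (default 0.75).
#' @param fit_rows Rows used to measure correlation/variance (default all).
#' @return List with `x` (filtered matrix, all rows) and `dropped`
#'   (character vector of removed feature names, in removal order).
#' @export
correlation_filter <- function(x, threshold = 0.75, fit_rows = seq_len(nrow(x))) {
  if (ncol(x) < 2) return(list(x = x, dropped = character(0)))
  dropped <- character(0)
  keep <- colnames(x)
  repeat {
    xf <- x[fit_rows, keep, drop = FALSE]
    if (length(keep) < 2) break
    C <- suppressWarnings(abs(cor(xf)))
    C[!is.finite(C)] <- 0      # zero-variance columns correlate with nothing
    diag(C) <- 0
    mx <- max(C)
    if (mx < threshold) break
    pair <- which(C == mx, arr.ind = TRUE)[1, ]
    v <- apply(xf[, pair, drop = FALSE], 2, stats::var)
    drop_i <- if (v[1] < v[2]) pair[1] else if (v[2] < v[1]) pair[2] else max(pair)
    dropped <- c(dropped, keep[drop_i])
    keep <- keep[-drop_i]
  }
  list(x = x[, keep, drop = FALSE], dropped = dropped)
}

#' Min-max scale features to [-1, 1]
#'
#' The affine transform is fitted on `fit_rows` only (so those rows span
#' `[-1, 1]`) and applied to every row; validation rows outside the fitted
#' range land outside `[-1, 1]` by design, which the caller may flag.
#' Constant features map to 0.
#'
#' @param x Numeric matrix.
#' @param fit_rows Rows to fit the range on (default all).
#' @return List with `x` (scaled matrix), `min` and `max` (fitted per-column
#'   parameters).
#' @export
scale_minmax <- function(x, fit_rows = seq_len(nrow(x))) {
  if (length(fit_rows) == 0) stop("fit_rows must be non-empty")
  xf <- x[fit_rows, , drop = FALSE]
  mn <- apply(xf, 2, min)
  mx <- apply(xf, 2, max)
  rng <- mx - mn
  scaled <- sweep(x, 2, mn)
  scaled <- sweep(scaled, 2, ifelse(rng == 0, 1, rng), `/`) * 2 - 1
  scaled[, rng == 0] <- 0
  list(x = scaled, min = mn, max = mx)
}

#' Stratified train/validation split
#'
#' @param labels Named binary vector (1 = pain class).
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7); must be strictly between 0 and 1.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with `train` and `validation` (character vectors of gene
#'   identifiers, disjoint and exhaustive).
#' @export
split_stratified <- function(labels, train_fraction = 0.7, seed) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  genes <- names(labels)
  if (is.null(genes)) stop("labels must be a named vector")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("both classes must be present")
  set.seed(seed)
  train <- unlist(lapply(classes, function(cl) {
    g <- genes[labels == cl]
    if (length(g) < 2) stop("class ", cl, " has fewer than 2 members")
    sample(g, round(length(g) * train_fraction))
  }), use.names = FALSE)
  list(train = train, validation = setdiff(genes, train))
}

#' Assemble the gene-by-feature matrix
#'
#' Concatenates encoded categoricals, GC content, conservation score, the GO
#' principal components, composite LFC columns, TPM columns and the eleven
#' topology features (plus a `topo_missing` flag for genes absent from the
#' graph; their topology features are 0). Missing numeric values are imputed
#' as 0 and zero-variance features (measured on the fitting genes) are
#' dropped with provenance.
#'
#' All fitted transforms (encoders, GO vocabulary/IDF/PCA) use `fit_genes`
#' only, so the training/validation split leaks nothing.
#'
#' @param tab Raw gene table (one row per gene, `gene_id` column).
#' @param meta Omics column metadata, as in [composite_lfc()].
#' @param annotations GO annotations, as in [go_vectorize()].
#' @param topology Topology profiles from [compute_topology()].
#' @param labels Named binary label vector (1 = pain).
#' @param fit_genes Genes used to fit encoders/GO transform and to measure
#'   variance (default: all labelled genes).
#' @param categorical_cols Categorical columns to encode.
#' @param go_components Number of GO principal components (default 2).
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix, rownames = gene ids), `gene_id`, `labels`, and `provenance`
#'   (dropped features, fitted transform objects).
#' @export
assemble_features <- function(tab, meta, annotations, topology, labels,
                              fit_genes = NULL,
                              categorical_cols = c("cellular_compartment",
                                                   "tissue", "chromosome_name"),
                              go_components = 2) {
  genes <- intersect(names(labels), tab$gene_id)
  if (length(genes) == 0) stop("empty intersection of gene universes")
  if (is.null(fit_genes)) fit_genes <- genes
  fit_genes <- intersect(fit_genes, genes)
  tab <- tab[match(genes, tab$gene_id), , drop = FALSE]
  fit_rows <- match(fit_genes, genes)

  categorical_cols <- intersect(categorical_cols, names(tab))
  enc <- encode_categoricals(tab, categorical_cols, fit_rows)
  go <- go_vectorize(annotations, genes, n_components = go_components,
                     fit_genes = fit_genes)
  clfc <- composite_lfc(tab, meta)
  tpm_cols <- meta$column[meta$measure == "TPM"]
  tpm <- tab[, intersect(tpm_cols, names(tab)), drop = FALSE]

  topo_idx <- match(genes, topology$gene_id)
  topo_missing <- as.numeric(is.na(topo_idx))
  topo <- topology[topo_idx, topology_feature_names, drop = FALSE]
  topo[is.na(topo_idx), ] <- 0

  numeric_extra <- tab[, intersect(c("gc_content", "conservation_score"),
                                   names(tab)), drop = FALSE]

  x <- cbind(
    as.matrix(enc$codes),
    as.matrix(numeric_extra),
    go$features,
    as.matrix(clfc),
    as.matrix(tpm),
    as.matrix(topo),
    topo_missing = topo_missing
  )
  rownames(x) <- genes
  x[is.na(x)] <- 0
  if (anyDuplicated(colnames(x))) stop("duplicate feature names in assembly")

  v <- apply(x[fit_rows, , drop = FALSE], 2, stats::var)
  zero_var <- colnames(x)[v == 0]
  x <- x[, v > 0, drop = FALSE]

  structure(list(
    x = x,
    gene_id = genes,
    labels = labels[genes],
    provenance = list(zero_variance_dropped = zero_var,
                      pain_terms_dropped = go$dropped_pain_terms,
                      fit_genes = fit_genes,
                      encoders = enc$encoders,
                      go_vocabulary = go$vocabulary,
                      go_idf = go$idf,
                      go_pca = go$pca)
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d genes x %d features (%d positives)\n",
              nrow(x$x), ncol(x$x), sum(x$labels == 1)))
  invisible(x)
}

#' Read a raw gene table with its YAML column metadata
#'
#' @param path TSV/CSV gene table, one row per gene with a `gene_id` column.
#' @param meta_path YAML sidecar mapping omics column names to
#'   `{dataset, tissue, species, modality, measure}`.
#' @return List with `tab` (data frame) and `meta` (data frame).
#' @export
read_gene_table <- function(path, meta_path) {
  tab <- data.table::fread(path, data.table = FALSE)
  raw <- yaml::read_yaml(meta_path)
  meta <- do.call(rbind, lapply(names(raw), function(cl) {
    data.frame(column = cl,
               dataset = raw[[cl]]$dataset,
               tissue = raw[[cl]]$tissue,
               species = raw[[cl]]$species,
               modality = raw[[cl]]$modality,
               measure = raw[[cl]]$measure,
               stringsAsFactors = FALSE)
  }))
  list(tab = tab, meta = meta)
}

#' Read GO annotations
#'
#' Two-column TSV `gene_id<TAB>term_id|term_name`, one pair per line.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns `gene_id`, `term_id`, `term_name`.
#' @export
read_go_annotations <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  parts <- strsplit(dt[[2]], "|", fixed = TRUE)
  data.frame(gene_id = dt[[1]],
             term_id = vapply(parts, `[`, "", 1),
             term_name = vapply(parts, function(p) paste(p[-1], collapse = "|"), ""),
             stringsAsFactors = FALSE)
}

#' Write a feature matrix and its provenance log
#'
#' @param fm A `feature_matrix`.
#' @param path TSV output path (genes as rows, header included).
#' @param provenance_path Optional JSON output for the provenance log.
#' @export
write_feature_matrix <- function(fm, path, provenance_path = NULL) {
  out <- data.frame(gene_id = fm$gene_id, label = fm$labels,
                    fm$x, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  if (!is.null(provenance_path)) {
    prov <- fm$provenance[c("zero_variance_dropped", "pain_terms_dropped",
                            "go_vocabulary")]
    jsonlite::write_json(prov, provenance_path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return A `feature_matrix` (without fitted transform provenance).
#' @export
read_feature_matrix <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  x <- as.matrix(dt[, setdiff(names(dt), c("gene_id", "label")), drop = FALSE])
  rownames(x) <- dt$gene_id
  structure(list(x = x, gene_id = dt$gene_id,
                 labels = setNames(dt$label, dt$gene_id),
                 provenance = list()),
            class = "feature_matrix")
}
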