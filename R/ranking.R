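#' Rank genes by pain score
#'
#' Descending probability order; ties break deterministically by gene
#' identifier, so the ranking is stable under permutations of the input.
#'
#' @param scores Named numeric vector of class-1 probabilities in `[0, 1]`.
#' @return A data frame (`pain_score_table`) with columns `gene_id`,
#'   `pain_score` and `rank` (1 = highest score).
#' @export
rank_genes <- function(scores) {
  if (length(scores) == 0) stop("scores must be non-empty")
  if (is.null(names(scores))) stop("scores must be named by gene")
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]")
  }
  o <- order(-scores, names(scores))
  out <- data.frame(gene_id = names(scores)[o],
                    pain_score = unname(scores[o]),
                    rank = seq_along(scores),
                    stringsAsFactors = FALSE)
  class(out) <- c("pain_score_table", "data.frame")
  out
}

#' A named gene set
#'
#' @param name Set name.
#' @param members Character vector of member gene identifiers (deduplicated;
#'   must be non-empty).
#' @param description Free-text description (default empty).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, members, description = "") {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = name, description = description, members = members),
            class = "gene_set")
}

#' Remove training-label leakage from a validation gene set
#'
#' @param s A [gene_set()].
#' @param training_positives Character vector of genes labelled positive in
#'   training; these are removed from `s`.
#' @return The reduced `gene_set`, with attribute `removed` giving the
#'   number of members removed. Errors if nothing remains.
#' @export
remove_leakage <- function(s, training_positives) {
  kept <- setdiff(s$members, training_positives)
  if (length(kept) == 0) {
    stop("gene set '", s$name, "' is empty after leakage removal; cannot validate")
  }
  out <- gene_set(s$name, kept, s$description)
  attr(out, "removed") <- length(s$members) - length(kept)
  out
}

# enrichment score of the classic running sum from sorted 1-based hit ranks;
# increments at hits, -1/(N-K) at misses. For exponent 0 every hit adds 1/K;
# otherwise hits are weighted by |score|^p. Returns the signed extremum
# (positive branch wins exact ties).
running_sum_es <- function(hit_ranks, n, weights = NULL) {
  k <- length(hit_ranks)
  r <- sort(hit_ranks)
  if (is.null(weights)) {
    inc <- rep(1 / k, k)
  } else {
    w <- weights[order(hit_ranks)]
    inc <- w / sum(w)
  }
  miss <- 1 / (n - k)
  cum_inc <- cumsum(inc)
  at_hit <- cum_inc - (r - seq_len(k)) * miss
  before_hit <- c(0, cum_inc[-k]) - (r - 1 - (seq_len(k) - 1)) * miss
  mx <- max(at_hit)
  mn <- min(before_hit)
  # exact ties between the two extrema resolve to the positive branch;
  # compare with a tolerance so float noise cannot flip the sign
  if (mx >= -mn - 1e-12) mx else mn
}

#' Running-sum (GSEA-style) enrichment of a gene set in a ranking
#'
#' Walks the ranking from the top; hits increment the running sum, misses
#' decrement it by `1/(N - K)`. With `weighting_exponent = 0` (the default)
#' every hit adds `1/K` — the classic unweighted Kolmogorov-Smirnov
#' statistic, which depends only on rank order; with exponent `p > 0` hits
#' add `|score|^p` weights. The enrichment score (ES) is the signed extremum
#' of the running sum. Significance is assessed by gene-label permutation:
#' set membership is re-drawn uniformly over the ranked universe, and the
#' add-one estimator `p = (1 + #{|ES*| >= |ES|}) / (n_perm + 1)` is
#' reported.
#'
#' @param ranking A `pain_score_table` from [rank_genes()].
#' @param s A [gene_set()]; members absent from the ranking are dropped
#'   (count recorded in the result). At least 2 members must remain, and
#'   the set must not cover the whole universe.
#' @param n_perm Number of membership permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param weighting_exponent Hit weighting exponent (default 0).
#' @return An object of class `enrichment_result`: `es`, `p_perm`, `n_perm`,
#'   `leading_edge` (genes up to the running-sum extremum), `n_hits`,
#'   `n_dropped`.
#' @export
gsea_enrichment <- function(ranking, s, n_perm = 1000, seed = 20240101,
                            weighting_exponent = 0) {
  stopifnot(inherits(ranking, "pain_score_table"))
  n <- nrow(ranking)
  members <- intersect(s$members, ranking$gene_id)
  n_dropped <- length(s$members) - length(members)
  if (length(members) < 2) stop("fewer than 2 set members in the ranking universe")
  if (length(members) == n) stop("set covers the entire universe; no misses to walk")

  hit_ranks <- sort(ranking$rank[match(members, ranking$gene_id)])
  k <- length(hit_ranks)
  weights <- NULL
  if (weighting_exponent > 0) {
    weights <- abs(ranking$pain_score[hit_ranks])^weighting_exponent
    if (sum(weights) == 0) weights <- NULL
  }
  es <- running_sum_es(hit_ranks, n, weights)

  set.seed(seed)
  perm_abs <- vapply(seq_len(n_perm), function(i) {
    pr <- sample.int(n, k)
    pw <- if (is.null(weights)) NULL else
      abs(ranking$pain_score[sort(pr)])^weighting_exponent
    abs(running_sum_es(pr, n, pw))
  }, numeric(1))
  # ties count as at-least-as-extreme (conservative); tolerance keeps exact
  # rational ties from being dropped by float rounding
  p_perm <- (1 + sum(perm_abs >= abs(es) - 1e-12)) / (n_perm + 1)

  leading <- if (es >= 0) {
    ext <- extremum_rank(hit_ranks, n, weights, positive = TRUE)
    ranking$gene_id[ranking$rank %in% hit_ranks[hit_ranks <= ext]]
  } else {
    ext <- extremum_rank(hit_ranks, n, weights, positive = FALSE)
    ranking$gene_id[ranking$rank %in% hit_ranks[hit_ranks >= ext]]
  }

  structure(list(es = es, p_perm = p_perm, n_perm = n_perm,
                 leading_edge = leading, n_hits = k, n_dropped = n_dropped),
            class = "enrichment_result")
}

# rank position at which the running sum attains its extremum
extremum_rank <- function(hit_ranks, n, weights = NULL, positive = TRUE) {
  k <- length(hit_ranks)
  r <- sort(hit_ranks)
  inc <- if (is.null(weights)) rep(1 / k, k) else {
    w <- weights[order(hit_ranks)]
    w / sum(w)
  }
  miss <- 1 / (n - k)
  cum_inc <- cumsum(inc)
  at_hit <- cum_inc - (r - seq_len(k)) * miss
  before_hit <- c(0, cum_inc[-k]) - (r - 1 - (seq_len(k) - 1)) * miss
  if (positive) r[which.max(at_hit)] else r[which.min(before_hit)]
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("ES=%.4f  p_perm=%.4g (n_perm=%d, hits=%d)\n",
              x$es, x$p_perm, x$n_perm, x$n_hits))
  invisible(x)
}

#' Over-representation of annotation terms in a ranking decile
#'
#' Takes the top (or bottom) `fraction` of the ranking and tests each
#' annotation term for over-representation with the hypergeometric upper
#' tail, Benjamini-Hochberg corrected across terms. Significance is flagged
#' at adjusted p < 0.05.
#'
#' @param ranking A `pain_score_table`.
#' @param annotations Data frame with columns `gene_id` and `term_id`
#'   (optionally `term_name`).
#' @param which `"top"` or `"bottom"`.
#' @param fraction Selection fraction in `(0, 0.5]` (default 0.10).
#' @return Data frame, one row per tested term: `term_id`, `term_name`, `k`
#'   (hits in selection), `K` (term size in universe), `n` (selection size),
#'   `N` (universe size), `p`, `p_adj`, `significant`.
#' @export
ora_decile <- function(ranking, annotations, which = c("top", "bottom"),
                       fraction = 0.10) {
  which <- match.arg(which)
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  stopifnot(inherits(ranking, "pain_score_table"))
  N <- nrow(ranking)
  n_sel <- ceiling(fraction * N)
  sel <- if (which == "top") {
    ranking$gene_id[ranking$rank <= n_sel]
  } else {
    ranking$gene_id[ranking$rank > N - n_sel]
  }
  ann <- annotations[annotations$gene_id %in% ranking$gene_id, , drop = FALSE]
  if (nrow(ann) == 0) stop("annotations cover no ranked gene")
  if (!"term_name" %in% names(ann)) ann$term_name <- ann$term_id
  ann <- unique(ann[, c("gene_id", "term_id", "term_name")])

  terms <- unique(ann[, c("term_id", "term_name")])
  res <- lapply(seq_len(nrow(terms)), function(i) {
    members <- ann$gene_id[ann$term_id == terms$term_id[i]]
    K <- length(members)
    k <- length(intersect(members, sel))
    p <- phyper(k - 1, K, N - K, n_sel, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               k = k, K = K, n = n_sel, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < 0.05
  out[order(out$p), ]
}

#' Enrichment of validation sets with and without leakage removal
#'
#' For each gene set, runs [gsea_enrichment()] on the full set and on the
#' set minus the training positives, reporting both side by side. A set
#' that empties under leakage removal keeps its with-labels result and
#' marks the without-labels result unavailable.
#'
#' @param ranking A `pain_score_table`.
#' @param sets List of [gene_set()] objects.
#' @param training_positives Genes labelled positive in training.
#' @param n_perm,seed,weighting_exponent Passed to [gsea_enrichment()].
#' @return Named list (one element per set) of lists with `with_labels` and
#'   `without_labels` enrichment results (`without_labels` may be `NULL`).
#' @export
validate_against_sets <- function(ranking, sets, training_positives,
                                  n_perm = 1000, seed = 20240101,
                                  weighting_exponent = 0) {
  out <- lapply(sets, function(s) {
    full <- gsea_enrichment(ranking, s, n_perm, seed, weighting_exponent)
    reduced <- tryCatch(remove_leakage(s, training_positives),
                        error = function(e) NULL)
    noleak <- if (is.null(reduced)) NULL else
      tryCatch(gsea_enrichment(ranking, reduced, n_perm, seed,
                               weighting_exponent),
               error = function(e) NULL)
    list(with_labels = full, without_labels = noleak)
  })
  names(out) <- vapply(sets, function(s) s$name, "")
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (`name<TAB>description<TAB>member...` per line).
#' @return List of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    gene_set(f[1], f[-(1:2)], f[2])
  })
}

#' Write gene sets to a GMT file
#'
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a pain-score table as TSV
#'
#' Deterministic rank order, columns `gene_id`, `pain_score`, `rank`.
#'
#' @param ranking A `pain_score_table`.
#' @param path Output path.
#' @export
write_pain_scores <- function(ranking, path) {
  data.table::fwrite(as.data.frame(ranking), path, sep = "\t")
  invisible(path)
}

#' Write an enrichment report as TSV
#'
#' One row per set and condition, with ES, permutation p-value and
#' leading-edge size.
#'
#' @param results Output of [validate_against_sets()].
#' @param path Output path.
#' @export
write_enrichment_report <- function(results, path) {
  rows <- list()
  for (nm in names(results)) {
    for (cond in c("with_labels", "without_labels")) {
      r <- results[[nm]][[cond]]
      rows[[length(rows) + 1]] <- data.frame(
        set = nm, condition = cond,
        es = if (is.null(r)) NA_real_ else r$es,
        p_perm = if (is.null(r)) NA_real_ else r$p_perm,
        n_hits = if (is.null(r)) NA_integer_ else r$n_hits,
        leading_edge_size = if (is.null(r)) NA_integer_ else length(r$leading_edge),
        available = !is.null(r),
        stringsAsFactors = FALSE)
    }
  }
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}
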