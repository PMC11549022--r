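#' Construct a protein-protein interaction graph
#'
#' Builds a simple undirected [igraph::igraph] from an edge table, dropping
#' self-loops and duplicate edges. Identifiers are treated as opaque strings.
#'
#' @param edges A data frame whose first two columns are the interacting
#'   gene/protein identifiers; an optional `combined_score` column carries
#'   STRING-style confidence scores.
#' @param min_score Optional minimum `combined_score`; edges below it are
#'   dropped. Default keeps all edges (the confidence cutoff is a caller
#'   decision made upstream).
#' @param nodes Optional character vector of node identifiers to declare even
#'   if they have no edges (isolated nodes).
#' @return An undirected simple `igraph` with vertex attribute `name`.
#' @export
ppi_graph <- function(edges, min_score = NULL, nodes = NULL) {
  if (ncol(edges) < 2) stop("edge table needs at least two columns")
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (!is.null(min_score)) {
    if (!"combined_score" %in% names(edges)) {
      stop("min_score given but edge table has no combined_score column")
    }
    keep <- as.numeric(edges$combined_score) >= min_score
    a <- a[keep]
    b <- b[keep]
  }
  loops <- a == b
  a <- a[!loops]
  b <- b[!loops]
  verts <- unique(c(a, b, as.character(nodes)))
  g <- igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                     directed = FALSE,
                                     vertices = verts)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a STRING-style edge list
#'
#' Tab-separated file with columns `protein1`, `protein2` and optionally
#' `combined_score`; a header line is detected automatically.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `protein1`, `protein2` and, when
#'   present, `combined_score`.
#' @export
read_edge_list <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  has_header <- any(tolower(first[1:2]) %in% c("protein1", "protein2", "gene1",
                                               "gene2", "from", "to"))
  dt <- data.table::fread(path, header = has_header, sep = "\t",
                          data.table = FALSE)
  if (!has_header) {
    names(dt) <- c("protein1", "protein2", "combined_score")[seq_len(ncol(dt))]
  }
  dt
}

topology_feature_names <- c(
  "degree", "undirected_edges", "avg_shortest_path", "betweenness",
  "closeness", "clustering_coefficient", "eccentricity",
  "neighborhood_connectivity", "radiality", "stress", "topological_coefficient"
)

#' Per-node topological feature profiles
#'
#' Computes the eleven centrality and neighbourhood features used as network
#' predictors: degree, undirected edge count, average shortest path length,
#' betweenness (normalized), closeness, local clustering coefficient,
#' eccentricity, neighborhood connectivity, radiality, stress centrality and
#' the topological coefficient. Path-based features are computed within
#' connected components (unreachable pairs are excluded, the "noninfinite"
#' convention); isolated nodes get 0 for path-based features.
#'
#' @param g An undirected simple graph from [ppi_graph()] (or any `igraph`).
#' @return A data frame with one row per node: a `gene_id` column followed by
#'   the eleven features in fixed order.
#' @export
compute_topology <- function(g) {
  if (!igraph::is_igraph(g)) stop("g must be an igraph object")
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))

  deg <- as.numeric(igraph::degree(g))
  d <- igraph::distances(g)          # hop distances, Inf across components
  fin <- is.finite(d)
  diag(fin) <- FALSE                 # exclude self-distances

  n_reach <- rowSums(fin)            # reachable others = component size - 1
  sum_d <- rowSums(ifelse(fin, d, 0))
  asp <- ifelse(n_reach > 0, sum_d / n_reach, 0)
  closeness <- ifelse(asp > 0, 1 / asp, 0)
  ecc <- apply(ifelse(fin, d, -Inf), 1, max)
  ecc[n_reach == 0] <- 0

  # radiality within the node's component: sum over reachable w of
  # (diameter + 1 - d(v, w)) / (component size - 1)
  comp <- igraph::components(g)$membership
  radial <- numeric(n)
  for (cid in unique(comp)) {
    mem <- which(comp == cid)
    if (length(mem) < 2) next
    dc <- d[mem, mem, drop = FALSE]
    diam <- max(dc)
    radial[mem] <- rowSums(diam + 1 - dc) / (length(mem) - 1)
    # rowSums includes the self term (diam + 1 - 0); remove it
    radial[mem] <- radial[mem] - (diam + 1) / (length(mem) - 1)
  }

  betw <- as.numeric(igraph::betweenness(g, normalized = TRUE))
  clust <- igraph::transitivity(g, type = "local", isolates = "zero")

  adj <- igraph::as_adj_list(g)
  neigh_conn <- vapply(adj, function(nb) {
    if (length(nb) == 0) 0 else mean(deg[as.integer(nb)])
  }, numeric(1))

  stress <- stress_centrality_cpp(lapply(adj, function(nb) as.integer(nb) - 1L))

  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  tc <- topological_coefficient_all(A, deg)

  out <- data.frame(
    gene_id = ids,
    degree = deg,
    undirected_edges = deg,
    avg_shortest_path = asp,
    betweenness = betw,
    closeness = closeness,
    clustering_coefficient = as.numeric(clust),
    eccentricity = as.numeric(ecc),
    neighborhood_connectivity = neigh_conn,
    radiality = radial,
    stress = as.numeric(stress),
    topological_coefficient = tc,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Topological coefficient for every node from the sparse adjacency matrix.
# S = A^2 counts shared neighbours; J(v, w) adds 1 when v and w are adjacent.
topological_coefficient_all <- function(A, deg) {
  S <- A %*% A
  n <- nrow(A)
  tc <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < 2) next   # tool convention: 0 for degree 0/1 nodes
    sv <- S[v, ]
    sv[v] <- 0
    w <- which(sv > 0)
    if (length(w) == 0) next
    J <- sv[w] + as.numeric(A[v, w] > 0)
    tc[v] <- mean(J) / deg[v]
  }
  tc
}

#' Stress centrality of one node
#'
#' Number of shortest paths between distinct node pairs that pass through
#' `v` (endpoints excluded), each unordered pair counted once.
#'
#' @param g An undirected `igraph`.
#' @param v A node identifier present in `g`.
#' @return An integer-valued count.
#' @export
stress_centrality <- function(g, v) {
  profile_one(g, v, "stress")
}

#' Radiality of one node
#'
#' `sum_w (diameter + 1 - d(v, w)) / (n_component - 1)` over nodes `w`
#' reachable from `v`, with the diameter taken within the node's component.
#' Isolated nodes score 0.
#'
#' @inheritParams stress_centrality
#' @return Radiality as a single number.
#' @export
radiality <- function(g, v) {
  profile_one(g, v, "radiality")
}

#' Topological coefficient of one node
#'
#' Average, over nodes `w` sharing at least one neighbour with `v`, of
#' `J(v, w) / degree(v)`, where `J(v, w)` is the number of shared neighbours
#' plus 1 when `v` and `w` are adjacent. Nodes of degree 0 or 1 score 0.
#'
#' @inheritParams stress_centrality
#' @return The topological coefficient in `[0, 1]`.
#' @export
topological_coefficient <- function(g, v) {
  profile_one(g, v, "topological_coefficient")
}

profile_one <- function(g, v, feature) {
  prof <- compute_topology(g)
  i <- match(as.character(v), prof$gene_id)
  if (is.na(i)) stop("unknown node: ", v)
  prof[[feature]][i]
}

#' Compare topology features between pain and non-pain genes
#'
#' Per feature: group means and medians for the two label classes and a
#' two-sided Wilcoxon rank-sum p-value. Used to verify that the positive
#' class occupies network hubs.
#'
#' @param profiles Data frame from [compute_topology()].
#' @param labels Named binary vector (1 = pain) covering a subset of
#'   `profiles$gene_id`.
#' @return A data frame with one row per topology feature.
#' @export
compare_topology_by_label <- function(profiles, labels) {
  genes <- names(labels)
  if (is.null(genes) || !all(genes %in% profiles$gene_id)) {
    stop("every labelled gene must be present in the topology profiles")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary (0/1)")
  if (length(unique(labels)) < 2) stop("both label classes must be present")
  idx <- match(genes, profiles$gene_id)
  pos <- idx[labels == 1]
  neg <- idx[labels == 0]
  rows <- lapply(topology_feature_names, function(f) {
    xp <- profiles[[f]][pos]
    xn <- profiles[[f]][neg]
    p <- tryCatch(wilcox.test(xp, xn, exact = FALSE)$p.value,
                  error = function(e) NA_real_)
    data.frame(feature = f,
               mean_P = mean(xp), mean_NP = mean(xn),
               median_P = median(xp), median_NP = median(xn),
               p_ranksum = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write topology profiles as TSV
#'
#' One row per gene, eleven feature columns in fixed order.
#'
#' @param profiles Data frame from [compute_topology()].
#' @param path Output file path.
#' @export
write_topology <- function(profiles, path) {
  data.table::fwrite(profiles[, c("gene_id", topology_feature_names)],
                     path, sep = "\t")
  invisible(path)
}
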