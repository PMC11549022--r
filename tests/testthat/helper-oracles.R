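# Independent oracles, coded directly from the definitions and sharing no
# code with the package implementation.

# --- confusion-metric formulas, evaluated verbatim ---------------------------

oracle_metrics <- function(tp, tn, fp, fn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den),
    gm = sqrt(sens * spec),
    f1 = if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens),
    ba = (sens + spec) / 2
  )
}

# --- graph features by explicit all-pairs shortest-path enumeration ----------

# adjacency list from a 2-column edge matrix over nodes 1..n
oracle_adj <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

oracle_distances <- function(adj, n) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {      # plain BFS
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          nxt <- c(nxt, w)
        }
      }
      frontier <- nxt
    }
  }
  d
}

# every shortest path from s to t, as a list of vertex vectors
oracle_all_shortest_paths <- function(adj, d, s, t) {
  if (is.infinite(d[s, t])) return(list())
  if (s == t) return(list(s))
  out <- list()
  for (w in adj[[s]]) {
    if (d[w, t] == d[s, t] - 1) {
      for (p in oracle_all_shortest_paths(adj, d, w, t)) {
        out[[length(out) + 1]] <- c(s, p)
      }
    }
  }
  out
}

# all 11 features for every node, by direct enumeration
oracle_topology <- function(edges, n) {
  adj <- oracle_adj(edges, n)
  d <- oracle_distances(adj, n)
  deg <- vapply(seq_len(n), function(v) length(adj[[v]]), 0L)

  stress <- numeric(n)
  betw_raw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_all_shortest_paths(adj, d, s, t)
    if (length(paths) == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(paths, function(p) v %in% p, TRUE))
      stress[v] <- stress[v] + through
      betw_raw[v] <- betw_raw[v] + through / length(paths)
    }
  }
  betw <- if (n > 2) betw_raw / ((n - 1) * (n - 2) / 2) else betw_raw

  asp <- ecc <- radial <- clo <- numeric(n)
  comp_of <- rep(NA_integer_, n); cid <- 0
  for (v in seq_len(n)) if (is.na(comp_of[v])) {
    cid <- cid + 1
    comp_of[is.finite(d[v, ])] <- cid
  }
  for (v in seq_len(n)) {
    reach <- setdiff(which(is.finite(d[v, ])), v)
    if (length(reach) == 0) next
    asp[v] <- mean(d[v, reach])
    ecc[v] <- max(d[v, reach])
    clo[v] <- 1 / asp[v]
    mem <- which(comp_of == comp_of[v])
    diam <- max(d[mem, mem])
    radial[v] <- sum(diam + 1 - d[v, reach]) / (length(mem) - 1)
  }

  cc <- numeric(n)
  for (v in seq_len(n)) {
    k <- deg[v]
    if (k < 2) next
    nb <- adj[[v]]
    tri <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (nb[j] %in% adj[[nb[i]]]) tri <- tri + 1
    }
    cc[v] <- 2 * tri / (k * (k - 1))
  }

  nconn <- vapply(seq_len(n), function(v) {
    if (deg[v] == 0) 0 else mean(deg[adj[[v]]])
  }, 0)

  tc <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < 2) next
    Js <- c()
    for (w in seq_len(n)) {
      if (w == v) next
      shared <- length(intersect(adj[[v]], adj[[w]]))
      if (shared > 0) Js <- c(Js, shared + (w %in% adj[[v]]))
    }
    if (length(Js) > 0) tc[v] <- mean(Js) / deg[v]
  }

  data.frame(degree = as.numeric(deg), undirected_edges = as.numeric(deg),
             avg_shortest_path = asp, betweenness = betw, closeness = clo,
             clustering_coefficient = cc, eccentricity = ecc,
             neighborhood_connectivity = nconn, radiality = radial,
             stress = stress, topological_coefficient = tc)
}

# random connected simple graph on n nodes as an edge matrix
random_connected_edges <- function(n, p = 0.4) {
  repeat {
    m <- matrix(runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    edges <- which(m, arr.ind = TRUE)
    if (nrow(edges) == 0) next
    adj <- oracle_adj(edges, n)
    if (all(is.finite(oracle_distances(adj, n)))) return(unname(edges))
  }
}

# --- running-sum enrichment score by a literal walk --------------------------

oracle_es <- function(hit_ranks, n) {
  k <- length(hit_ranks)
  s <- 0; best <- 0
  for (i in seq_len(n)) {
    s <- s + if (i %in% hit_ranks) 1 / k else -1 / (n - k)
    if (abs(s) > abs(best) + 1e-12) best <- s
    else if (abs(abs(s) - abs(best)) <= 1e-12 && s > best) best <- s
  }
  best
}

# --- brute-force weight-permutation search -----------------------------------

all_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

oracle_weight_search <- function(probas, truth, multiset) {
  perms <- unique(all_permutations(sort(multiset)))
  best_gm <- -1; best_w <- NULL
  for (w in perms) {
    comb <- as.vector(probas %*% w) / sum(w)
    pred <- as.integer(comb >= 0.5)
    m <- oracle_metrics(sum(truth == 1 & pred == 1), sum(truth == 0 & pred == 0),
                        sum(truth == 0 & pred == 1), sum(truth == 1 & pred == 0))
    if (m$gm > best_gm) { best_gm <- m$gm; best_w <- w }
  }
  list(weights = best_w, gm = best_gm)
}

# --- Benjamini-Hochberg step-up, hand-coded ----------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- smoothed TF-IDF, hand-coded ---------------------------------------------

oracle_tfidf <- function(incidence) {
  # incidence: binary gene x term matrix
  n <- nrow(incidence)
  df <- colSums(incidence > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  m <- sweep(incidence, 2, idf, `*`)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# small default cohort settings for fast tests
tiny_sim <- function(seed = 1, ...) {
  sim_config(n_genes = 250, pos_fraction = 0.1, n_go_terms = 50,
             n_informative_terms = 8, n_omics_groups = 3, seed = seed, ...)
}
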