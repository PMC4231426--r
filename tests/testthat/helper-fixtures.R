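# The cyclic worked-example graph: A regulates B, C, D; B and C form a
# 2-cycle (B -> C, C -| B); D activates B, inhibits E; E activates C.
# Weights order the three indirect candidates A->C > A->B > D->B above all
# direct edges, and each of the cited explaining paths satisfies the
# bottleneck rule at alpha = 0.95.
make_figure_graph <- function() {
  pg_from_edges(tibble::tibble(
    from   = c("A", "A", "A", "B", "C", "D", "D", "E"),
    to     = c("B", "C", "D", "C", "B", "B", "E", "C"),
    sign   = c("+", "+", "+", "+", "-", "+", "-", "+"),
    weight = c(0.8, 0.9, 0.5, 0.5, 0.5, 0.7, 0.5, 0.5)
  ))
}

# random signed weighted digraph for property tests
random_pg <- function(seed, n = 8, p = 0.25, signed = TRUE) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, ]
  sel <- runif(nrow(pairs)) < p
  if (!any(sel)) sel[1] <- TRUE
  e <- pairs[sel, ]
  edges <- tibble::tibble(
    from = ids[e$i], to = ids[e$j],
    sign = if (signed) sample(c(1L, -1L), nrow(e), replace = TRUE) else NA_integer_,
    weight = round(runif(nrow(e), 0.05, 0.95), 2)
  )
  pg_from_edges(edges, gene_ids = ids)
}

# --- independent oracles ----------------------------------------------------

# exhaustive enumeration of simple paths from -> to avoiding `exclude`;
# returns a data frame with one row per path (overall sign, bottleneck
# weight, number of edges)
oracle_paths <- function(pg, from, to, exclude = c(from, to)) {
  edges <- pg$edges
  res <- list()
  walk <- function(node, visited, sgn, wmax, len) {
    out <- edges[edges$from == node, ]
    for (r in seq_len(nrow(out))) {
      nxt <- out$to[r]
      if (node == exclude[1] && nxt == exclude[2]) next
      s2 <- sgn * (if (is.na(out$sign[r])) 1L else out$sign[r])
      w2 <- max(wmax, out$weight[r])
      if (nxt == to) {
        res[[length(res) + 1]] <<- c(sign = s2, wmax = w2, len = len + 1)
      } else if (!(nxt %in% visited)) {
        walk(nxt, c(visited, nxt), s2, w2, len + 1)
      }
    }
  }
  walk(from, c(from), 1L, 0, 0)
  if (length(res) == 0) {
    return(data.frame(sign = integer(0), wmax = numeric(0), len = numeric(0)))
  }
  as.data.frame(do.call(rbind, res))
}

oracle_path_exists <- function(pg, from, to, sign = "any", L = Inf, bound = Inf,
                               exclude = c(from, to)) {
  ps <- oracle_paths(pg, from, to, exclude)
  if (nrow(ps) == 0) {
    return(FALSE)
  }
  want <- switch(sign, any = c(1, -1), "+" = 1, "-" = -1)
  any(ps$sign %in% want & ps$len <= L & ps$wmax < bound)
}

# reachability closure by Warshall's algorithm (SCC oracle)
oracle_reachability <- function(pg) {
  n <- pg$n
  A <- matrix(FALSE, n, n, dimnames = list(pg$gene_ids, pg$gene_ids))
  A[cbind(pg$edges$from, pg$edges$to)] <- TRUE
  for (k in seq_len(n)) {
    A <- A | (outer(A[, k], A[k, ]))
  }
  A
}

oracle_scc <- function(pg) {
  R <- oracle_reachability(pg)
  mutual <- (R & t(R)) | diag(TRUE, pg$n)
  labels <- integer(pg$n)
  lab <- 0L
  for (v in seq_len(pg$n)) {
    if (labels[v] == 0L) {
      lab <- lab + 1L
      labels[mutual[v, ]] <- lab
    }
  }
  stats::setNames(labels, pg$gene_ids)
}

# point-by-point curve integration over a 0/1 relevance vector in list order
oracle_aupr <- function(hits) {
  g <- sum(hits)
  tp <- 0
  prev_r <- 0
  prev_p <- 1
  area <- 0
  for (k in seq_along(hits)) {
    tp <- tp + hits[k]
    r <- tp / g
    p <- tp / k
    area <- area + (r - prev_r) * (p + prev_p) / 2
    prev_r <- r
    prev_p <- p
  }
  area
}

oracle_auroc <- function(hits) {
  g <- sum(hits)
  m <- length(hits)
  wins <- 0
  for (k in which(hits == 1)) {
    wins <- wins + sum(hits[seq_len(m) > k] == 0)
  }
  wins / (g * (m - g))
}

# --- closure-recovery study material ---------------------------------------

# random DAG with balanced signs (edge sign = product of node potentials, so
# every path between a pair carries one unique sign), transitively reduced so
# that the ground truth is identifiable from its closure
random_reduced_dag <- function(seed, n = 30, mean_deg = 2) {
  set.seed(seed)
  ord <- sample(n)
  ids <- sprintf("N%02d", seq_len(n))
  p <- mean_deg * n / choose(n, 2)
  A <- matrix(runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  idx <- which(A, arr.ind = TRUE)
  phi <- sample(c(-1L, 1L), n, replace = TRUE)
  names(phi) <- ids
  dag <- tibble::tibble(
    from = ids[ord[idx[, 1]]],
    to = ids[ord[idx[, 2]]],
    sign = as.integer(phi[ids[ord[idx[, 1]]]] * phi[ids[ord[idx[, 2]]]])
  )
  g <- igraph::graph_from_data_frame(dag[c("from", "to")],
    vertices = data.frame(name = ids)
  )
  keep <- vapply(seq_len(nrow(dag)), function(e) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(dag$from[e], dag$to[e])))
    !is.finite(igraph::distances(g2, v = dag$from[e], to = dag$to[e], mode = "out"))
  }, logical(1))
  list(truth = dag[keep, ], gene_ids = ids)
}

# the idealized perturbation graph of a true network: its signed transitive
# closure, with true edges strictly more confident (smaller weight) than the
# induced indirect edges
closure_pg <- function(truth, gene_ids, w_true = 0.1, w_induced = 0.5) {
  clo <- transitive_closure(truth, nodes = gene_ids)
  tk <- paste(clo$from, clo$to) %in% paste(truth$from, truth$to)
  clo$weight <- ifelse(tk, w_true, w_induced)
  pg_from_edges(clo, gene_ids = gene_ids)
}

edge_set <- function(edges) paste(edges$from, edges$to)

# small complete-screen dataset with prescribed values in selected columns
toy_dataset <- function(ko, wt) {
  ids <- LETTERS[seq_len(ncol(ko))]
  expression_dataset(wt, ko, gene_ids = ids)
}
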