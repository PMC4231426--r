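#' The benchmark noise grid
#'
#' The nine combinations of biological variance (`sigma_theta`, the standard
#' deviation of the per-gene synthesis/degradation multipliers) and
#' multiplicative measurement noise (`sigma_nu`), each taking the values
#' 0.025 (L), 0.05 (M) and 0.1 (H). Labels concatenate the biological and
#' measurement level, e.g. `"LM"` = low biological, medium measurement noise.
#'
#' @return A 9-row tibble with `configuration`, `label`, `sigma_theta`,
#'   `sigma_nu`.
#' @export
noise_grid <- function() {
  lv <- c(L = 0.025, M = 0.05, H = 0.1)
  grid <- expand.grid(nu = names(lv), theta = names(lv), stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$theta, names(lv)), match(grid$nu, names(lv))), ]
  tibble(
    configuration = 1:9,
    label = paste0(grid$theta, grid$nu),
    sigma_theta = unname(lv[grid$theta]),
    sigma_nu = unname(lv[grid$nu])
  )
}

# derive independent sub-seeds from one master seed (kept below 2^31)
split_seed <- function(seed, k) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Generate a synthetic regulatory network topology
#'
#' Draws a directed, signed gene network with the degree structure observed
#' in transcriptional networks: heavy-tailed out-degrees (a few master
#' regulators with many targets) from a discrete power law with exponent
#' `exponent` capped at `n/10`, and light-tailed in-degrees from a geometric
#' distribution. Both sequences are adjusted to the target edge count
#' `round(n * K)` and matched by stub pairing, rejecting self-loops and
#' duplicate edges. Nodes are pre-assigned to `ceiling(sqrt(n)/2)` modules and
#' each edge targets its source's module with probability
#' `intra_module_prob`, giving a modular structure. Edge signs are activating
#' with probability `activation_fraction`.
#'
#' @param n Number of genes (>= 2).
#' @param K Target mean degree (edges per gene); `K = 0` gives an empty graph.
#' @param activation_fraction Probability that an edge is activating.
#' @param intra_module_prob Probability of targeting the source's module.
#' @param exponent Power-law exponent of the out-degree distribution.
#' @param seed Optional integer seed (topology is deterministic given it).
#' @param max_rounds Rejection rounds before the degree sequence is declared
#'   infeasible.
#' @return A `true_network`: list with `n`, `gene_ids`, `edges` (tibble
#'   `from`, `to`, `sign`, `a`, `m` -- regulation strength and Hill exponent,
#'   both defaulting to 1), and `module` assignment.
#' @export
generate_topology <- function(n, K = 1.5, activation_fraction = 0.5,
                              intra_module_prob = 0.7, exponent = 2.5,
                              seed = NULL, max_rounds = 1000) {
  if (n < 2) abort("a network needs at least 2 genes")
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- sprintf("G%0*d", nchar(n), seq_len(n))
  n_mod <- max(1L, ceiling(sqrt(n) / 2))
  module <- sample(rep_len(seq_len(n_mod), n))
  e_target <- round(n * K)
  if (e_target == 0) {
    return(structure(
      list(
        n = n, gene_ids = gene_ids,
        edges = tibble(
          from = character(0), to = character(0), sign = integer(0),
          a = numeric(0), m = numeric(0)
        ),
        module = setNames(module, gene_ids)
      ),
      class = "true_network"
    ))
  }
  cap <- max(2L, floor(n / 10))
  # out-degrees: discrete power law on 1..cap, then adjusted to the target sum
  support <- seq_len(cap)
  pw <- support^(-exponent)
  out_deg <- sample(support, n, replace = TRUE, prob = pw)
  out_deg <- adjust_degrees(out_deg, e_target, cap)
  # in-degrees: geometric with matching mean
  in_deg <- rgeom(n, 1 / (1 + e_target / n))
  in_deg <- adjust_degrees(in_deg, e_target, n - 1L)
  # stub pairing with module preference
  src <- sample(rep(seq_len(n), out_deg))
  pools <- split(rep(seq_len(n), in_deg), module[rep(seq_len(n), in_deg)])
  seen <- matrix(FALSE, n, n)
  from <- integer(e_target)
  to <- integer(e_target)
  n_edges <- 0L
  rounds <- 0L
  for (s in src) {
    placed <- FALSE
    for (try in 1:20) {
      use_mod <- runif(1) < intra_module_prob
      pool_name <- as.character(module[s])
      pool <- if (use_mod) pools[[pool_name]] else unlist(pools, use.names = FALSE)
      if (length(pool) == 0) pool <- unlist(pools, use.names = FALSE)
      if (length(pool) == 0) break
      t <- pool[sample.int(length(pool), 1)]
      if (t == s || seen[s, t]) next
      n_edges <- n_edges + 1L
      from[n_edges] <- s
      to[n_edges] <- t
      seen[s, t] <- TRUE
      pn <- as.character(module[t])
      hit <- match(t, pools[[pn]])
      pools[[pn]] <- pools[[pn]][-hit]
      placed <- TRUE
      break
    }
    if (!placed) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) abort("infeasible degree sequence: too many rejection rounds")
    }
  }
  from <- from[seq_len(n_edges)]
  to <- to[seq_len(n_edges)]
  if (n_edges < 0.9 * e_target) {
    abort("infeasible degree sequence: realized edge count fell short of the target")
  }
  edges <- tibble(
    from = gene_ids[from],
    to = gene_ids[to],
    sign = ifelse(runif(n_edges) < activation_fraction, 1L, -1L),
    a = 1,
    m = 1
  )
  edges <- edges[order(edges$from, edges$to), ]
  structure(
    list(
      n = n, gene_ids = gene_ids, edges = edges,
      module = setNames(module, gene_ids)
    ),
    class = "true_network"
  )
}

adjust_degrees <- function(deg, target, cap) {
  n <- length(deg)
  excess <- sum(deg) - target
  while (excess > 0) {
    pos <- which(deg > 0)
    take <- pos[sample.int(length(pos), min(length(pos), excess))]
    deg[take] <- deg[take] - 1L
    excess <- sum(deg) - target
  }
  while (excess < 0) {
    room <- which(deg < cap)
    give <- room[sample.int(length(room), min(length(room), -excess))]
    deg[give] <- deg[give] + 1L
    excess <- sum(deg) - target
  }
  deg
}

#' @export
print.true_network <- function(x, ...) {
  cat(
    "<true_network> ", x$n, " genes, ", nrow(x$edges), " edges (",
    sum(x$edges$sign > 0), " activating)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.true_network <- function(x, ...) {
  out <- x$edges
  out$sign <- ifelse(out$sign > 0, "+", "-")
  out
}

#' Gold standard carried by a synthetic network
#'
#' @param net A `true_network`.
#' @return A [gold_standard()] over the network's genes.
#' @export
network_gold_standard <- function(net) {
  gold_standard(net$edges[c("from", "to")], nodes = net$gene_ids)
}

# multiplicative regulation factor of one edge given the regulator level x:
# saturating Hill response, normalized so an unregulated or half-activated
# regulator (x = 1 with a = 1, m = 1) leaves the target at its basal level
regulation_factor <- function(x, sign, a, m) {
  h <- x^m / (x^m + 1)
  act <- (1 + a * h) / (1 + a / 2)
  ifelse(sign > 0, act, 1 / act)
}

#' Simulate steady-state knockout expression on a known network
#'
#' Steady-state expression solves `x_j = b_j * prod_i r(x_i)` over the
#' regulators i of gene j, where the basal level `b_j = theta_syn_j /
#' theta_deg_j` is the ratio of per-gene synthesis and (first-order)
#' degradation multipliers, and `r` is a saturating Hill response: for an
#' activator `r(x) = (1 + a*H) / (1 + a/2)` and for an inhibitor its
#' reciprocal, with `H = x^m / (x^m + 1)`. The system is solved by damped
#' fixed-point iteration (damping 0.5, absolute tolerance 1e-9, at most 500
#' sweeps). Each knockout experiment clamps the deleted gene to exactly 0
#' throughout; the wild type is solved unclamped.
#'
#' Biological variability enters once per dataset through
#' `theta ~ Normal(1, sigma_theta)` truncated below at 0.1; measurement noise
#' multiplies every reported value by `exp(nu)`, `nu ~ Normal(0, sigma_nu)`,
#' independently per measurement.
#'
#' @param net A `true_network` from [generate_topology()].
#' @param sigma_theta,sigma_nu Noise standard deviations (see [noise_grid()]).
#' @param seed Optional integer seed.
#' @param tol,max_iter,damping Fixed-point controls.
#' @return An [expression_dataset()] with one knockout row per gene.
#' @export
simulate_knockouts <- function(net, sigma_theta = 0.025, sigma_nu = 0.025,
                               seed = NULL, tol = 1e-9, max_iter = 500,
                               damping = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  n <- net$n
  theta_syn <- pmax(rnorm(n, 1, sigma_theta), 0.1)
  theta_deg <- pmax(rnorm(n, 1, sigma_theta), 0.1)
  b <- theta_syn / theta_deg
  src <- match(net$edges$from, net$gene_ids)
  tgt <- match(net$edges$to, net$gene_ids)
  solve_state <- function(clamp = NULL, label = "wild type") {
    x <- b
    if (!is.null(clamp)) x[clamp] <- 0
    for (it in seq_len(max_iter)) {
      reg <- rep(1, n)
      if (length(src) > 0) {
        r <- regulation_factor(x[src], net$edges$sign, net$edges$a, net$edges$m)
        prod_by_target <- rowsum(log(r), tgt)
        reg[as.integer(rownames(prod_by_target))] <- exp(prod_by_target[, 1])
      }
      x_new <- damping * x + (1 - damping) * (b * reg)
      if (!is.null(clamp)) x_new[clamp] <- 0
      delta <- max(abs(x_new - x))
      x <- x_new
      if (delta < tol) {
        return(x)
      }
    }
    abort(paste0("steady state did not converge for experiment: ", label))
  }
  wt <- solve_state()
  ko <- matrix(0, n, n, dimnames = list(net$gene_ids, net$gene_ids))
  for (i in seq_len(n)) {
    ko[i, ] <- solve_state(clamp = i, label = net$gene_ids[i])
  }
  if (sigma_nu > 0) {
    wt <- wt * exp(rnorm(n, 0, sigma_nu))
    ko <- ko * exp(matrix(rnorm(n * n, 0, sigma_nu), n, n))
  }
  expression_dataset(wt, ko, gene_ids = net$gene_ids)
}

#' Signed transitive closure of an acyclic signed digraph
#'
#' Adds an edge i => j with sign s for every ordered pair connected by a
#' simple path of overall sign s. A pair connected by both a positive and a
#' negative path yields two rows. The closure is the idealized noise-free
#' perturbation graph of a true network: knocking out i visibly perturbs
#' every downstream j. Cyclic inputs are refused (path signs are then not
#' well defined as a finite closure).
#'
#' @param edges Data frame with `from`, `to`, `sign` (+1/-1 or `"+"`/`"-"`),
#'   or a `true_network`.
#' @param nodes Optional node universe.
#' @return A tibble `from`, `to`, `sign` (integer) containing the closure.
#' @export
transitive_closure <- function(edges, nodes = NULL) {
  if (inherits(edges, "true_network")) {
    nodes <- edges$gene_ids
    edges <- edges$edges
  }
  edges <- as_tibble(edges)
  if (is.character(edges$sign)) edges$sign <- c("+" = 1L, "-" = -1L)[edges$sign]
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to")],
    directed = TRUE, vertices = data.frame(name = nodes)
  )
  if (!igraph::is_dag(g)) abort("transitive closure of signed graphs requires an acyclic input")
  topo <- as.integer(igraph::topo_sort(g, mode = "out"))
  src <- match(edges$from, nodes)
  tgt <- match(edges$to, nodes)
  pos <- matrix(FALSE, n, n) # pos[i, j]: positive path i => j
  neg <- matrix(FALSE, n, n)
  for (v in rev(topo)) {
    out <- which(src == v)
    for (e in out) {
      u <- tgt[e]
      if (edges$sign[e] > 0) {
        pos[v, u] <- TRUE
        pos[v, ] <- pos[v, ] | pos[u, ]
        neg[v, ] <- neg[v, ] | neg[u, ]
      } else {
        # a negative first edge flips the sign of everything downstream
        neg[v, u] <- TRUE
        neg[v, ] <- neg[v, ] | pos[u, ]
        pos[v, ] <- pos[v, ] | neg[u, ]
      }
    }
  }
  pi <- which(pos, arr.ind = TRUE)
  ni <- which(neg, arr.ind = TRUE)
  out <- tibble(
    from = nodes[c(pi[, 1], ni[, 1])],
    to = nodes[c(pi[, 2], ni[, 2])],
    sign = c(rep(1L, nrow(pi)), rep(-1L, nrow(ni)))
  )
  out[order(out$from, out$to, -out$sign), ]
}

#' Enumerate (and optionally simulate) a knockout benchmark suite
#'
#' Builds the full factorial design of topology replicates and noise
#' configurations. The published design is 10 replicate topologies at each of
#' three mean degrees (1.5, 2, 2.5) crossed with the 9-point noise grid: 270
#' datasets. The manifest is always returned; with `simulate = TRUE` each row
#' additionally carries the generated network and simulated dataset
#' (practical for desk-scale `n`, not for 5000 genes).
#'
#' @param n Genes per network.
#' @param K_list Mean degrees.
#' @param noise_labels Subset of [noise_grid()] labels.
#' @param replicates Topology replicates per mean degree.
#' @param seed Master seed; topology and noise sub-seeds derive from it.
#' @param simulate Also generate the networks and datasets?
#' @return A `benchmark_suite` tibble: one row per dataset with `network_id`,
#'   `K`, `replicate`, `label`, `sigma_theta`, `sigma_nu`, `topology_seed`,
#'   `noise_seed`, and (if simulated) list-columns `network` and `dataset`.
#' @export
make_benchmark_suite <- function(n = 5000, K_list = c(1.5, 2, 2.5),
                                 noise_labels = noise_grid()$label,
                                 replicates = 10, seed = 1, simulate = FALSE) {
  grid <- noise_grid()
  bad <- setdiff(noise_labels, grid$label)
  if (length(bad) > 0) abort(paste0("unknown noise label(s): ", paste(bad, collapse = ", ")))
  topo <- expand.grid(
    replicate = seq_len(replicates), K = K_list,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  if (nrow(topo) == 0 || length(noise_labels) == 0) {
    manifest <- tibble(
      network_id = integer(0), K = numeric(0), replicate = integer(0),
      label = character(0), sigma_theta = numeric(0), sigma_nu = numeric(0),
      topology_seed = integer(0), noise_seed = integer(0)
    )
    return(structure(manifest, n_genes = n, class = c("benchmark_suite", class(manifest))))
  }
  topo$network_id <- seq_len(nrow(topo))
  topo$topology_seed <- split_seed(seed, nrow(topo))
  rows <- merge(topo, grid[grid$label %in% noise_labels, ], by = NULL)
  rows <- rows[order(rows$network_id, rows$configuration), ]
  rows$noise_seed <- split_seed(seed + 1L, nrow(rows))
  manifest <- as_tibble(rows[c(
    "network_id", "K", "replicate", "label",
    "sigma_theta", "sigma_nu", "topology_seed", "noise_seed"
  )])
  if (simulate) {
    nets <- lapply(
      seq_len(nrow(topo)),
      function(i) generate_topology(n, topo$K[i], seed = topo$topology_seed[i])
    )
    manifest$network <- nets[manifest$network_id]
    manifest$dataset <- purrr::pmap(
      list(manifest$network, manifest$sigma_theta, manifest$sigma_nu, manifest$noise_seed),
      function(net, st, sn, sd) simulate_knockouts(net, st, sn, seed = sd)
    )
  }
  structure(manifest, n_genes = n, class = c("benchmark_suite", class(manifest)))
}

#' Out- versus in-degree structure of a generated topology
#'
#' @param object A `true_network`.
#' @param ... Unused.
#' @return A ggplot of the two degree distributions on log-log axes.
#' @export
autoplot.true_network <- function(object, ...) {
  deg <- dplyr::bind_rows(
    tibble(direction = "out-degree", degree = as.integer(table(
      factor(object$edges$from, levels = object$gene_ids)
    ))),
    tibble(direction = "in-degree", degree = as.integer(table(
      factor(object$edges$to, levels = object$gene_ids)
    )))
  )
  counts <- dplyr::count(deg[deg$degree > 0, ], .data$direction, .data$degree)
  ggplot2::ggplot(counts, ggplot2::aes(.data$degree, .data$n, colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Degree", y = "Genes", colour = NULL) +
    ggplot2::theme_minimal()
}
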