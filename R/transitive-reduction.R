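#' Configure a transitive reduction run
#'
#' Bundles the knobs shared by the reduction variants. `transwesd` explains an
#' edge by a sign-consistent simple path whose bottleneck (maximum) edge
#' weight stays strictly below `alpha` times the edge's own weight; `ltr`
#' (local transitive reduction) only accepts feed-forward-loop 2-paths and
#' replaces the bottleneck rule by the multiplicative confidence rule
#' `alpha * Zc_ij <= Zc_ik * Zc_kj` (non-strict) on the correlation z-scores
#' `Zc = 1 - weight`; `drffl` removes edges between different strongly
#' connected components that have any unsigned alternative path.
#'
#' @param method `"transwesd"`, `"ltr"` or `"drffl"`.
#' @param signed Respect edge signs when matching explaining paths? Ignored
#'   for unsigned graphs.
#' @param weighted Apply the weight rule? Unweighted `transwesd` is the
#'   `alpha = Inf` limit; unweighted `ltr` the `alpha = 0` limit.
#' @param L Maximum explaining-path length in edges (`Inf` = unbounded;
#'   forced to 2 for `ltr`).
#' @param alpha Confidence factor, `> 0`. Defaults to the benchmark settings:
#'   0.95 for `transwesd` with unbounded paths, 1.5 for `transwesd` with
#'   `L = 2`, 0.15 for `ltr`.
#' @param path_exact Use exact simple-path search (`TRUE`) or the polynomial
#'   approximate walk search. `ltr` checks triangles directly and is always
#'   exact.
#' @param full_check Re-check after each deletion that every original
#'   candidate edge is still explainable by the remaining graph (`TRUE`), or
#'   freeze all removal decisions on the original graph (`FALSE`).
#' @return A `tr_config` list.
#' @export
tr_config <- function(method = c("transwesd", "ltr", "drffl"),
                      signed = TRUE, weighted = TRUE, L = Inf, alpha = NULL,
                      path_exact = TRUE, full_check = TRUE) {
  method <- match.arg(method)
  if (method == "ltr") {
    L <- 2
    path_exact <- TRUE
    full_check <- TRUE
  }
  if (is.null(alpha)) {
    alpha <- switch(method,
      transwesd = if (is.infinite(L)) 0.95 else 1.5,
      ltr = 0.15,
      drffl = NA_real_
    )
  }
  if (method != "drffl" && !is.na(alpha) && alpha < 0) abort("`alpha` must be positive")
  structure(
    list(
      method = method, signed = signed, weighted = weighted,
      L = L, alpha = alpha, path_exact = path_exact, full_check = full_check
    ),
    class = "tr_config"
  )
}

edge_key <- function(from, to) paste(from, to, sep = "\r")

# deterministic processing order: weight key first, then lexicographic
# (source, target) gene identifiers
order_candidates <- function(edges, weight_key) {
  order(weight_key, edges$from, edges$to, method = "radix")
}

#' Potentially removable edges under the TRANSWESD rule
#'
#' An edge i -> j is potentially removable when an alternative simple path
#' i => j exists that (i) avoids the edge itself, (ii) has the same overall
#' sign (if `signed`), (iii) uses at most `L` edges, and (iv) has bottleneck
#' weight strictly below `alpha * w_ij` (if `weighted`).
#'
#' @param pg A `perturbation_graph`.
#' @param config A [tr_config()] with `method = "transwesd"`.
#' @return The subset of `pg$edges` that is potentially removable (the set R),
#'   in the order edges would be processed: highest weight (lowest confidence)
#'   first, ties broken lexicographically.
#' @export
identify_removable_transwesd <- function(pg, config = tr_config("transwesd")) {
  edges <- pg$edges
  removable <- vapply(seq_len(nrow(edges)), function(k) {
    e <- edges[k, ]
    path_exists(
      edges, pg$gene_ids, e$from, e$to,
      required_sign = if (config$signed && !is.na(e$sign)) e$sign else 0L,
      max_len = config$L,
      weight_bound = if (config$weighted) config$alpha * e$weight else Inf,
      exclude = c(e$from, e$to),
      exact = config$path_exact
    )
  }, logical(1))
  R <- edges[removable, ]
  R[order_candidates(R, -R$weight), ]
}

# does a cached witness (node sequence) survive in the current edge set?
witness_alive <- function(witness, live_keys) {
  if (is.null(witness) || length(witness) < 2) {
    return(FALSE)
  }
  all(edge_key(witness[-length(witness)], witness[-1]) %in% live_keys)
}

# shared iterative removal loop with explainability re-checking.
# `explain_query(edges_tbl, f_row)` must return NULL or a witness node vector
# certifying that edge f is explainable by the remaining graph.
iterative_reduce <- function(pg, R, config, explain_query) {
  edges <- pg$edges
  keys <- edge_key(edges$from, edges$to)
  live <- rep(TRUE, nrow(edges))
  names(live) <- keys
  removed_rows <- integer(0)
  removed_iter <- integer(0)
  kept_rows <- integer(0)
  witnesses <- list()
  iter <- 0L
  for (k in match(edge_key(R$from, R$to), keys)) {
    live[k] <- FALSE # tentative removal
    check_rows <- c(removed_rows, k)
    ok <- TRUE
    new_wit <- list()
    live_keys <- keys[live]
    for (f in check_rows) {
      fk <- keys[f]
      if (witness_alive(witnesses[[fk]], live_keys)) next
      wit <- explain_query(edges[live, , drop = FALSE], edges[f, ])
      if (is.null(wit)) {
        ok <- FALSE
        break
      }
      new_wit[[fk]] <- wit
    }
    if (ok) {
      iter <- iter + 1L
      removed_rows <- c(removed_rows, k)
      removed_iter <- c(removed_iter, iter)
      for (fk in names(new_wit)) witnesses[[fk]] <- new_wit[[fk]]
    } else {
      live[k] <- TRUE
      kept_rows <- c(kept_rows, k)
    }
  }
  removed <- edges[removed_rows, ]
  removed$iteration <- removed_iter
  list(
    kept = edges[live, ],
    removed = removed,
    kept_explainable = edges[kept_rows, ]
  )
}

new_reduction_result <- function(pg, config, kept, removed, candidates,
                                 kept_explainable) {
  if (!"iteration" %in% names(removed)) {
    removed$iteration <- seq_len(nrow(removed))
  }
  structure(
    list(
      pg = pg, config = config, kept = kept, removed = removed,
      candidates = candidates, kept_explainable = kept_explainable
    ),
    class = "reduction_result"
  )
}

#' Transitive reduction for weighted signed digraphs (TRANSWESD)
#'
#' Identifies the potentially removable edge set R with
#' [identify_removable_transwesd()] and deletes its edges iteratively,
#' highest weight (lowest confidence) first. With `full_check` on, an edge is
#' only deleted if afterwards every edge originally in the perturbation graph
#' is still either present or explainable by a qualifying path in the
#' remaining graph; edges failing this test are kept (`kept_explainable`).
#' With `full_check` off all decisions are frozen on the original graph and
#' the whole set R is removed.
#'
#' @param pg A `perturbation_graph` with finite weights on all edges.
#' @param config A [tr_config()].
#' @return A `reduction_result`: list with the reduced graph's `kept` edges,
#'   the `removed` log (edge, iteration), the candidate set `candidates` and
#'   `kept_explainable`.
#' @export
reduce_transwesd <- function(pg, config = tr_config("transwesd")) {
  if (!all(is.finite(pg$edges$weight))) abort("all edge weights must be finite")
  R <- identify_removable_transwesd(pg, config)
  if (!config$full_check) {
    kept <- dplyr::anti_join(pg$edges, R[c("from", "to")], by = c("from", "to"))
    return(new_reduction_result(pg, config, kept, R, R, pg$edges[0, ]))
  }
  explain_query <- function(current, f) {
    res <- query_path(
      current, pg$gene_ids, f$from, f$to,
      required_sign = if (config$signed && !is.na(f$sign)) f$sign else 0L,
      max_len = config$L,
      weight_bound = if (config$weighted) config$alpha * f$weight else Inf,
      exclude = c(f$from, f$to),
      exact = config$path_exact, want_witness = TRUE
    )
    if (is.null(res)) NULL else res$nodes %||% character(0)
  }
  parts <- iterative_reduce(pg, R, config, explain_query)
  new_reduction_result(pg, config, parts$kept, parts$removed, R, parts$kept_explainable)
}

#' Local transitive reduction over feed-forward loops (LTR)
#'
#' An edge i -> j is potentially removable if a feed-forward loop
#' `i -> k, k -> j` exists whose sign product matches the edge sign (if
#' `signed`) and whose correlation z-scores satisfy
#' `alpha * Zc_ij <= Zc_ik * Zc_kj` (if `weighted`; `Zc = 1 - weight`, so a
#' large `Zc` means high confidence). Candidates are deleted lowest confidence
#' (smallest `Zc`) first. Before each deletion the remaining graph must keep
#' every original edge represented: present, or connected by a
#' sign-consistent directed path of any length (this re-check deliberately
#' allows longer paths than the 2-path candidacy rule -- after pruning, the
#' remaining explanation of a long-range indirect edge is the multi-step
#' chain it arose from).
#'
#' @param pg A `perturbation_graph`.
#' @param config A [tr_config()] with `method = "ltr"`.
#' @return A `reduction_result`, see [reduce_transwesd()].
#' @export
reduce_ltr <- function(pg, config = tr_config("ltr")) {
  edges <- pg$edges
  zc <- 1 - edges$weight
  keys <- edge_key(edges$from, edges$to)
  zc_of <- setNames(zc, keys)
  sign_of <- setNames(ifelse(is.na(edges$sign), 1L, edges$sign), keys)
  use_sign <- config$signed && !all(is.na(edges$sign))
  use_weight <- config$weighted && !is.na(config$alpha) && config$alpha > 0
  candidate_in <- function(current, f) {
    ks <- setdiff(
      intersect(current$to[current$from == f$from], current$from[current$to == f$to]),
      c(f$from, f$to)
    )
    if (length(ks) == 0) {
      return(FALSE)
    }
    k1 <- edge_key(f$from, ks)
    k2 <- edge_key(ks, f$to)
    ok <- rep(TRUE, length(ks))
    if (use_sign) {
      s <- if (is.na(f$sign)) 1L else f$sign
      ok <- ok & (sign_of[k1] * sign_of[k2] == s)
    }
    if (use_weight) {
      ok <- ok & (config$alpha * (1 - f$weight) <= zc_of[k1] * zc_of[k2])
    }
    any(ok)
  }
  removable <- vapply(
    seq_len(nrow(edges)),
    function(i) candidate_in(edges, edges[i, ]),
    logical(1)
  )
  R <- edges[removable, ]
  R <- R[order_candidates(R, 1 - R$weight), ] # ascending Zc = lowest confidence
  parts <- iterative_reduce_ltr(pg, R, config, use_sign)
  new_reduction_result(pg, config, parts$kept, parts$removed, R, parts$kept_explainable)
}

# LTR removal loop: the candidate set is fixed on the original graph (the
# feed-forward-loop criteria are not re-evaluated); each deletion must leave
# every edge removed so far, and the candidate itself, represented by a
# sign-consistent path of any length in the remaining graph.
iterative_reduce_ltr <- function(pg, R, config, use_sign) {
  edges <- pg$edges
  keys <- edge_key(edges$from, edges$to)
  live <- rep(TRUE, nrow(edges))
  removed_rows <- integer(0)
  removed_iter <- integer(0)
  kept_rows <- integer(0)
  witnesses <- list()
  iter <- 0L
  for (k in match(edge_key(R$from, R$to), keys)) {
    live[k] <- FALSE
    check_rows <- c(removed_rows, k)
    ok <- TRUE
    new_wit <- list()
    live_keys <- keys[live]
    current <- edges[live, , drop = FALSE]
    for (f in check_rows) {
      fk <- keys[f]
      if (witness_alive(witnesses[[fk]], live_keys)) next
      ff <- edges[f, ]
      res <- query_path(
        current, pg$gene_ids, ff$from, ff$to,
        required_sign = if (use_sign && !is.na(ff$sign)) ff$sign else 0L,
        max_len = Inf, weight_bound = Inf,
        exclude = c(ff$from, ff$to),
        exact = FALSE, want_witness = TRUE
      )
      if (is.null(res)) {
        ok <- FALSE
        break
      }
      new_wit[[fk]] <- res$nodes %||% character(0)
    }
    if (ok) {
      iter <- iter + 1L
      removed_rows <- c(removed_rows, k)
      removed_iter <- c(removed_iter, iter)
      for (fk in names(new_wit)) witnesses[[fk]] <- new_wit[[fk]]
    } else {
      live[k] <- TRUE
      kept_rows <- c(kept_rows, k)
    }
  }
  removed <- edges[removed_rows, ]
  removed$iteration <- removed_iter
  list(
    kept = edges[live, ],
    removed = removed,
    kept_explainable = edges[kept_rows, ]
  )
}

#' Reduction across strongly connected components (DR-FFL style)
#'
#' The legacy strategy: an edge i -> j is removed iff i and j lie in different
#' strongly connected components and an alternative directed path i => j
#' (unsigned, unweighted, any length) exists in the original graph avoiding
#' the edge. All qualifying edges are removed simultaneously; edges within a
#' component are never touched.
#'
#' @param pg A `perturbation_graph`.
#' @return A `reduction_result`, see [reduce_transwesd()].
#' @export
reduce_drffl <- function(pg) {
  labels <- scc_labels(pg)
  edges <- pg$edges
  cross <- labels[edges$from] != labels[edges$to]
  removable <- cross & vapply(seq_len(nrow(edges)), function(i) {
    cross[i] && path_exists(
      edges, pg$gene_ids, edges$from[i], edges$to[i],
      required_sign = 0L, max_len = Inf, weight_bound = Inf,
      exclude = c(edges$from[i], edges$to[i]), exact = FALSE
    )
  }, logical(1))
  R <- edges[removable, ]
  R <- R[order_candidates(R, -R$weight), ]
  removed <- R
  removed$iteration <- rep(1L, nrow(removed))
  kept <- edges[!removable, ]
  cfg <- structure(
    list(
      method = "drffl", signed = FALSE, weighted = FALSE, L = Inf,
      alpha = NA_real_, path_exact = FALSE, full_check = FALSE
    ),
    class = "tr_config"
  )
  new_reduction_result(pg, cfg, kept, removed, R, edges[0, ])
}

#' Run a configured transitive reduction
#'
#' Dispatches to [reduce_transwesd()], [reduce_ltr()] or [reduce_drffl()].
#'
#' @param pg A `perturbation_graph`.
#' @param method,... Passed to [tr_config()].
#' @return A `reduction_result`.
#' @export
reduce_graph <- function(pg, method = c("transwesd", "ltr", "drffl"), ...) {
  method <- match.arg(method)
  switch(method,
    transwesd = reduce_transwesd(pg, tr_config("transwesd", ...)),
    ltr = reduce_ltr(pg, tr_config("ltr", ...)),
    drffl = reduce_drffl(pg)
  )
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(
    "<reduction_result> [", x$config$method, "] ",
    nrow(x$pg$edges), " edges -> ", nrow(x$kept), " kept, ",
    nrow(x$removed), " removed (", nrow(x$candidates), " candidates, ",
    nrow(x$kept_explainable), " kept despite explanation)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a reduction result into a per-edge status table
#'
#' @param x A `reduction_result`.
#' @param ... Unused.
#' @return A tibble with one row per original edge: `from`, `to`, `sign`,
#'   `weight`, `status` (`"kept"`, `"removed"` or `"kept_explainable"`) and
#'   `iteration` (removal step, `NA` for kept edges).
#' @export
tidy.reduction_result <- function(x, ...) {
  out <- x$pg$edges
  k <- edge_key(out$from, out$to)
  out$status <- "kept"
  out$status[k %in% edge_key(x$removed$from, x$removed$to)] <- "removed"
  out$status[k %in% edge_key(x$kept_explainable$from, x$kept_explainable$to)] <-
    "kept_explainable"
  out$iteration <- x$removed$iteration[match(k, edge_key(x$removed$from, x$removed$to))]
  out$sign <- ifelse(is.na(out$sign), NA_character_, ifelse(out$sign > 0, "+", "-"))
  out
}

#' @export
glance.reduction_result <- function(x, ...) {
  tibble(
    method = x$config$method,
    signed = x$config$signed,
    weighted = x$config$weighted,
    L = x$config$L,
    alpha = x$config$alpha,
    n_edges = nrow(x$pg$edges),
    n_candidates = nrow(x$candidates),
    n_removed = nrow(x$removed),
    n_kept = nrow(x$kept)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
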