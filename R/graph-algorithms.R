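# integer (i, j, sign, weight) view of an edge tibble, indexed into gene_ids;
# unsigned edges get sign +1 (callers pass required_sign = "any" to ignore)
edge_index_view <- function(edges, gene_ids) {
  list(
    from = match(edges$from, gene_ids),
    to = match(edges$to, gene_ids),
    sign = ifelse(is.na(edges$sign), 1L, edges$sign),
    weight = edges$weight
  )
}

sign_to_int <- function(required_sign) {
  switch(required_sign, "any" = 0L, "+" = 1L, "-" = -1L,
    abort('`required_sign` must be "any", "+" or "-"')
  )
}

#' Strongly connected components of a perturbation graph
#'
#' Two genes share a component label iff each can reach the other along
#' directed candidate edges. DR-FFL-style reduction only removes edges that
#' cross component boundaries.
#'
#' @param pg A `perturbation_graph`.
#' @return A named integer vector of component labels, one per gene.
#' @export
scc_labels <- function(pg) {
  g <- igraph::graph_from_data_frame(
    pg$edges[c("from", "to")],
    directed = TRUE,
    vertices = data.frame(name = pg$gene_ids)
  )
  comp <- igraph::components(g, mode = "strong")
  setNames(as.integer(comp$membership), pg$gene_ids)
}

#' Search for an explaining path between two genes
#'
#' Looks for a directed path `from => to` that could transmit the observed
#' perturbation effect: its overall sign (product of edge signs) matches
#' `required_sign`, it uses at most `max_len` edges, every edge weight is
#' strictly below `weight_bound`, and it avoids `exclude` (by default the
#' direct edge `from -> to`, the edge the path is meant to explain).
#'
#' Exact mode enumerates simple paths depth-first with weight/length pruning
#' and is guaranteed correct; sign-constrained search in cyclic signed
#' digraphs is NP-complete, so for large graphs the approximate mode runs a
#' label-correcting dynamic program over (node, sign-parity) states that
#' minimizes the bottleneck edge weight over walks. The approximation is
#' complete: it never misses a qualifying simple path, but its witness may be
#' a non-simple walk. Ties are broken deterministically by node order.
#'
#' @param pg A `perturbation_graph`.
#' @param from,to Gene identifiers, distinct.
#' @param required_sign `"any"`, `"+"` or `"-"`.
#' @param max_len Maximum number of edges on the path (`Inf` = unbounded).
#' @param weight_bound Edges must have weight strictly below this bound.
#' @param exclude Length-2 character vector: the ordered pair the path must
#'   avoid. Defaults to `c(from, to)`.
#' @param exact Use the exact simple-path search (default) or the approximate
#'   walk-based search.
#' @return `NULL` if no qualifying path exists, else a list with `nodes`
#'   (gene sequence), `sign` (`"+"`/`"-"`) and `wmax` (bottleneck weight).
#' @export
find_explaining_path <- function(pg, from, to, required_sign = "any",
                                 max_len = Inf, weight_bound = Inf,
                                 exclude = c(from, to), exact = TRUE) {
  if (from == to) abort("`from` and `to` must differ")
  query_path(
    pg$edges, pg$gene_ids, from, to,
    required_sign = sign_to_int(required_sign),
    max_len = max_len, weight_bound = weight_bound,
    exclude = exclude, exact = exact, want_witness = TRUE
  )
}

# shared worker; edges is an edge tibble, exclude a length-2 id vector or NULL
query_path <- function(edges, gene_ids, from, to, required_sign = 0L,
                       max_len = Inf, weight_bound = Inf, exclude = NULL,
                       exact = TRUE, want_witness = FALSE) {
  ev <- edge_index_view(edges, gene_ids)
  src <- match(from, gene_ids)
  dst <- match(to, gene_ids)
  ex <- if (is.null(exclude)) c(0L, 0L) else match(exclude, gene_ids)
  if (exact) {
    res <- path_search_exact_cpp(
      length(gene_ids), ev$from, ev$to, ev$sign, ev$weight,
      src, dst, required_sign, max_len, weight_bound, ex[1], ex[2]
    )
  } else {
    res <- path_search_approx_cpp(
      length(gene_ids), ev$from, ev$to, ev$sign, ev$weight,
      src, dst, required_sign, max_len, weight_bound, ex[1], ex[2],
      want_witness
    )
  }
  if (!res$found) {
    return(NULL)
  }
  list(
    nodes = if (!is.null(res$nodes)) gene_ids[res$nodes] else NULL,
    sign = if (res$sign > 0) "+" else "-",
    wmax = res$wmax
  )
}

# fast existence check used by the reduction loops
path_exists <- function(edges, gene_ids, from, to, required_sign = 0L,
                        max_len = Inf, weight_bound = Inf, exclude = NULL,
                        exact = TRUE) {
  !is.null(query_path(edges, gene_ids, from, to, required_sign,
    max_len, weight_bound, exclude,
    exact = exact, want_witness = FALSE
  ))
}

#' Middle nodes of feed-forward loops over a given edge
#'
#' Returns every gene k that closes a feed-forward loop with the edge
#' `from -> to`, i.e. both `from -> k` and `k -> to` are candidate edges.
#' These 2-paths are the only explanations local transitive reduction
#' considers.
#'
#' @param pg A `perturbation_graph`.
#' @param from,to Gene identifiers of an edge of `pg`.
#' @return Character vector of middle genes (possibly empty), sorted.
#' @export
explaining_triangles <- function(pg, from, to) {
  out_of_i <- pg$edges$to[pg$edges$from == from]
  into_j <- pg$edges$from[pg$edges$to == to]
  sort(setdiff(intersect(out_of_i, into_j), c(from, to)))
}
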