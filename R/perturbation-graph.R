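new_perturbation_graph <- function(gene_ids, perturbed, edges, Wt, Wr, method) {
  structure(
    list(
      gene_ids = gene_ids,
      perturbed = perturbed,
      n = length(gene_ids),
      edges = edges,
      Wt = Wt,
      Wr = Wr,
      method = method
    ),
    class = "perturbation_graph"
  )
}

edge_tibble <- function(idx, gene_ids, perturbed, sign, weight) {
  tibble(
    from = perturbed[idx[, 1]],
    to = gene_ids[idx[, 2]],
    sign = sign,
    weight = weight
  )
}

# off-diagonal mask for an m x n source-by-target matrix
offdiag_mask <- function(perturbed, gene_ids) {
  outer(match(perturbed, gene_ids), seq_along(gene_ids), "!=")
}

#' Build the z-score perturbation graph (PG1)
#'
#' The simplest candidate-edge selection: an unsigned edge i -> j is included
#' whenever the absolute z-score of the knockout-induced deviation exceeds the
#' threshold `beta` (strictly). The weight used by transitive reduction is
#' `1 - minmax(|Z|)` (low weight = high confidence) and the ranking weight is
#' `minmax(|Z|)`, min-max normalized globally over all off-diagonal pairs.
#'
#' @param zb A `zscore_bundle` from [compute_zscores()].
#' @param beta Z-score threshold (strict `>`).
#' @return A `perturbation_graph` with unsigned edges (`sign` is `NA`).
#' @export
build_pg1 <- function(zb, beta = 2) {
  gene_ids <- colnames(zb$Z)
  perturbed <- rownames(zb$Z)
  absZ <- abs(zb$Z)
  off <- offdiag_mask(perturbed, gene_ids)
  scaled <- minmax_scale(ifelse(off, absZ, NA))
  sel <- off & absZ > beta
  idx <- which(sel, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  Wt <- matrix(Inf, nrow(absZ), ncol(absZ), dimnames = dimnames(absZ))
  Wt[idx] <- 1 - scaled[idx]
  edges <- edge_tibble(idx, gene_ids, perturbed, NA_integer_, Wt[idx])
  new_perturbation_graph(gene_ids, perturbed, edges, Wt, scaled, "pg1")
}

#' Build the two-threshold signed perturbation graph (PG2)
#'
#' An edge i -> j is included when the absolute z-score exceeds `beta` and the
#' absolute change of gene j's expression relative to wild type exceeds the
#' minimal deviation `gamma` (both strict). The edge sign is
#' `sign(wt[j] - ko[i, j])`: positive when the knockout (a decrease of i)
#' decreases j, i.e. when i and j move in the same direction. The transitive
#' reduction weight is `1 - |c_ij|` with `c_ij` the conditional correlation;
#' the ranking weight is `minmax(|Z|)`.
#'
#' @param dataset The [expression_dataset()] the bundles were computed from.
#' @param zb A `zscore_bundle`.
#' @param cb A `correlation_bundle`.
#' @param beta Z-score threshold (strict `>`).
#' @param gamma Minimal absolute deviation from wild type (strict `>`).
#' @return A signed `perturbation_graph`.
#' @export
build_pg2 <- function(dataset, zb, cb, beta = 2, gamma = 0.05) {
  gene_ids <- colnames(zb$Z)
  perturbed <- rownames(zb$Z)
  delta <- matrix(
    rep(dataset$wt, each = nrow(zb$Z)),
    nrow(zb$Z), ncol(zb$Z)
  ) - dataset$ko
  off <- offdiag_mask(perturbed, gene_ids)
  absZ <- abs(zb$Z)
  sel <- off & absZ > beta & abs(delta) > gamma
  idx <- which(sel, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  Wt <- matrix(Inf, nrow(absZ), ncol(absZ), dimnames = dimnames(absZ))
  Wt[idx] <- 1 - abs(cb$C[idx])
  edges <- edge_tibble(
    idx, gene_ids, perturbed,
    as.integer(sign(delta[idx])), Wt[idx]
  )
  Wr <- minmax_scale(ifelse(off, absZ, NA))
  new_perturbation_graph(gene_ids, perturbed, edges, Wt, Wr, "pg2")
}

#' Build the combined z-score/correlation perturbation graph (PGnew)
#'
#' Candidate edges must pass three filters: `|Z| > beta` (strong deviation),
#' `|C| > gamma` (non-trivial conditional correlation) and `C * Z < 0`
#' (sign consistency: deleting an activator lowers its targets, giving a
#' negative z-score together with a positive correlation, and vice versa).
#' Edges with a negative z-score are therefore positive (activating) and edges
#' with a positive z-score negative (repressing).
#'
#' The transitive reduction weight is `1 - Zc` (so a high correlation z-score
#' means high confidence) and the ranking weight mixes both measures:
#' `minmax(|Z| + Zc)` over all off-diagonal pairs.
#'
#' @param zb A `zscore_bundle`.
#' @param cb A `correlation_bundle` with `Zc` filled by [compute_zc()].
#' @param beta Z-score threshold (strict `>`).
#' @param gamma Conditional-correlation threshold (strict `>`).
#' @return A signed `perturbation_graph`.
#' @export
build_pg_new <- function(zb, cb, beta = 2, gamma = 0.05) {
  if (is.null(cb$Zc)) abort("run compute_zc() on the correlation bundle first")
  gene_ids <- colnames(zb$Z)
  perturbed <- rownames(zb$Z)
  off <- offdiag_mask(perturbed, gene_ids)
  absZ <- abs(zb$Z)
  sel <- off & absZ > beta & abs(cb$C) > gamma & cb$C * zb$Z < 0
  sel[is.na(sel)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  Wt <- matrix(Inf, nrow(absZ), ncol(absZ), dimnames = dimnames(absZ))
  Wt[idx] <- 1 - cb$Zc[idx]
  edges <- edge_tibble(
    idx, gene_ids, perturbed,
    ifelse(zb$Z[idx] < 0, 1L, -1L), Wt[idx]
  )
  Wr <- minmax_scale(ifelse(off, absZ + cb$Zc, NA))
  new_perturbation_graph(gene_ids, perturbed, edges, Wt, Wr, "pgnew")
}

#' Assemble a perturbation graph from an explicit edge list
#'
#' Mainly useful for worked examples, oracle constructions and tests; pipeline
#' graphs come from [build_pg1()], [build_pg2()] or [build_pg_new()].
#'
#' @param edges Data frame with columns `from`, `to`, `weight` and optionally
#'   `sign` (`"+"`/`"-"`, or `+1`/`-1`; `NA` = unsigned).
#' @param gene_ids Node universe; defaults to the genes mentioned in `edges`.
#' @param wr Optional ranking-weight matrix; defaults to `1 - weight` on edges
#'   and 0 elsewhere.
#' @return A `perturbation_graph`.
#' @export
pg_from_edges <- function(edges, gene_ids = NULL, wr = NULL) {
  edges <- as_tibble(edges)
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(edges$from, edges$to)))
  if (!"sign" %in% names(edges)) edges$sign <- NA_integer_
  if (is.character(edges$sign)) {
    edges$sign <- c("+" = 1L, "-" = -1L)[edges$sign]
  }
  edges$sign <- as.integer(edges$sign)
  if (!"weight" %in% names(edges)) edges$weight <- 0.5
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  n <- length(gene_ids)
  Wt <- matrix(Inf, n, n, dimnames = list(gene_ids, gene_ids))
  Wt[cbind(match(edges$from, gene_ids), match(edges$to, gene_ids))] <- edges$weight
  if (is.null(wr)) {
    wr <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
    wr[is.finite(Wt)] <- pmin(pmax(1 - Wt[is.finite(Wt)], 0), 1)
    diag(wr) <- NA_real_
  }
  edges <- edges[order(match(edges$from, gene_ids), match(edges$to, gene_ids)), ]
  new_perturbation_graph(
    gene_ids, gene_ids,
    edges[c("from", "to", "sign", "weight")], Wt, wr, "manual"
  )
}

#' @export
print.perturbation_graph <- function(x, ...) {
  cat(
    "<perturbation_graph> [", x$method, "] ", x$n, " genes, ",
    nrow(x$edges), " candidate edges",
    if (all(is.na(x$edges$sign))) " (unsigned)" else " (signed)", "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a perturbation graph into its edge list
#'
#' @param x A `perturbation_graph`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `sign` (`"+"`, `"-"` or `NA`)
#'   and `weight` (the transitive-reduction weight; low = confident).
#' @export
tidy.perturbation_graph <- function(x, ...) {
  out <- x$edges
  out$sign <- ifelse(is.na(out$sign), NA_character_, ifelse(out$sign > 0, "+", "-"))
  out
}

#' @export
glance.perturbation_graph <- function(x, ...) {
  tibble(
    method = x$method,
    n_genes = x$n,
    n_perturbed = length(x$perturbed),
    n_edges = nrow(x$edges),
    n_positive = sum(x$edges$sign == 1L, na.rm = TRUE),
    n_negative = sum(x$edges$sign == -1L, na.rm = TRUE)
  )
}
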