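#' Rank all ordered gene pairs by confidence
#'
#' Produces the confidence-sorted list of every ordered pair (source must be a
#' perturbed gene; self-pairs excluded). Pairs are scored by the ranking
#' weight `Wr` plus a tier offset that guarantees tier dominance: with
#' `two_tier`, edges of the reduced graph GT outrank everything else; with
#' `three_tier`, edges removed from the perturbation graph during reduction
#' form a middle tier above never-candidate pairs. Within a tier pairs sort by
#' `Wr` descending with lexicographic tie-breaking, so the output is a
#' deterministic permutation of all pairs.
#'
#' @param pg A `perturbation_graph` (supplies `Wr`).
#' @param reduction Optional `reduction_result`; without it the whole
#'   perturbation graph is the top tier.
#' @param scheme `"two_tier"` or `"three_tier"`.
#' @param tier_offset Score offset per tier (+2 per tier on the
#'   \[0, 1\]-normalized weights by default; only the ordering matters).
#' @return A `ranked_edges` tibble: `rank`, `from`, `to`, `score`, `tier`
#'   (`"GT"`, `"removed_from_PG"` or `"other"`).
#' @export
rank_edges <- function(pg, reduction = NULL,
                       scheme = c("two_tier", "three_tier"),
                       tier_offset = 2) {
  scheme <- match.arg(scheme)
  idx <- which(offdiag_mask(pg$perturbed, pg$gene_ids), arr.ind = TRUE)
  pairs <- tibble(
    from = pg$perturbed[idx[, 1]],
    to = pg$gene_ids[idx[, 2]],
    score = pg$Wr[idx]
  )
  gt <- if (is.null(reduction)) pg$edges else reduction$kept
  removed <- if (is.null(reduction)) pg$edges[0, ] else reduction$removed
  key <- edge_key(pairs$from, pairs$to)
  pairs$tier <- "other"
  pairs$tier[key %in% edge_key(removed$from, removed$to)] <- "removed_from_PG"
  pairs$tier[key %in% edge_key(gt$from, gt$to)] <- "GT"
  lift <- c(GT = 2, removed_from_PG = 1, other = 0)
  if (scheme == "two_tier") lift["removed_from_PG"] <- 0
  pairs$score <- pairs$score + tier_offset * lift[pairs$tier]
  pairs <- pairs[order(-pairs$score, pairs$from, pairs$to, method = "radix"), ]
  pairs$rank <- seq_len(nrow(pairs))
  structure(
    pairs[c("rank", "from", "to", "score", "tier")],
    class = c("ranked_edges", class(pairs))
  )
}

#' Confusion counts of a predicted edge set against a gold standard
#'
#' With `restrict_to_common_nodes` (the silver-standard convention), predicted
#' edges touching nodes outside the gold universe are not scored, and gold
#' edges touching nodes outside the prediction universe are dropped before
#' counting.
#'
#' @param predicted Data frame of predicted edges (`from`, `to`).
#' @param gold A [gold_standard()].
#' @param restrict_to_common_nodes Apply the node restriction?
#' @param predicted_nodes Node universe of the predictions; defaults to the
#'   nodes mentioned in `predicted`.
#' @return A one-row tibble with `TP`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, gold, restrict_to_common_nodes = TRUE,
                             predicted_nodes = NULL) {
  pred <- as_tibble(predicted)[c("from", "to")]
  gold_edges <- as_tibble(gold)[c("from", "to")]
  if (restrict_to_common_nodes) {
    gold_nodes <- attr(gold, "nodes") %||% unique(c(gold_edges$from, gold_edges$to))
    if (is.null(predicted_nodes)) {
      predicted_nodes <- unique(c(pred$from, pred$to))
    }
    pred <- pred[pred$from %in% gold_nodes & pred$to %in% gold_nodes, ]
    gold_edges <- gold_edges[
      gold_edges$from %in% predicted_nodes & gold_edges$to %in% predicted_nodes,
    ]
  }
  pk <- edge_key(pred$from, pred$to)
  gk <- edge_key(gold_edges$from, gold_edges$to)
  tibble(
    TP = sum(pk %in% gk),
    FP = sum(!pk %in% gk),
    FN = sum(!gk %in% pk)
  )
}

# shared sweep over a ranked list: cumulative precision/recall/fpr
pr_roc_points <- function(ranked, gold) {
  gk <- edge_key(gold$from, gold$to)
  if (length(gk) == 0) abort("gold standard is empty on the scored universe")
  hit <- edge_key(ranked$from, ranked$to) %in% gk
  tp <- cumsum(hit)
  k <- seq_along(hit)
  g <- length(gk)
  tibble(
    rank = k,
    precision = tp / k,
    recall = tp / g,
    fpr = (k - tp) / max(length(hit) - g, 1)
  )
}

restrict_ranked <- function(ranked, gold, restrict_to_common_nodes = TRUE) {
  gold_edges <- as_tibble(gold)[c("from", "to")]
  if (!restrict_to_common_nodes) {
    return(list(ranked = ranked, gold = gold_edges))
  }
  gold_nodes <- attr(gold, "nodes") %||% unique(c(gold_edges$from, gold_edges$to))
  pred_nodes <- unique(c(ranked$from, ranked$to))
  list(
    ranked = ranked[ranked$from %in% gold_nodes & ranked$to %in% gold_nodes, ],
    gold = gold_edges[gold_edges$from %in% pred_nodes & gold_edges$to %in% pred_nodes, ]
  )
}

#' Area under the precision-recall curve of a ranked edge list
#'
#' The PR curve is swept one edge at a time down the full ranking; the area is
#' the trapezoidal integral over the (recall, precision) points, anchored at
#' (0, 1). A perfect ranking (all gold edges first) gives 1.
#'
#' @param ranked A `ranked_edges` tibble from [rank_edges()].
#' @param gold A [gold_standard()].
#' @param restrict_to_common_nodes Apply the silver-standard node restriction?
#' @return A scalar in \[0, 1\].
#' @export
aupr <- function(ranked, gold, restrict_to_common_nodes = TRUE) {
  parts <- restrict_ranked(ranked, gold, restrict_to_common_nodes)
  pts <- pr_roc_points(parts$ranked, parts$gold)
  r <- c(0, pts$recall)
  p <- c(1, pts$precision)
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

#' Area under the ROC curve of a ranked edge list
#'
#' Equals the Mann-Whitney statistic: the proportion of (gold, non-gold) pairs
#' in which the gold edge is ranked better. 1 for a perfect ranking, 0 when
#' every gold edge is ranked last.
#'
#' @inheritParams aupr
#' @return A scalar in \[0, 1\].
#' @export
auroc <- function(ranked, gold, restrict_to_common_nodes = TRUE) {
  parts <- restrict_ranked(ranked, gold, restrict_to_common_nodes)
  gk <- edge_key(parts$gold$from, parts$gold$to)
  if (length(gk) == 0) abort("gold standard is empty on the scored universe")
  hit <- edge_key(parts$ranked$from, parts$ranked$to) %in% gk
  g <- sum(hit)
  m <- length(hit)
  if (g == 0 || g == m) abort("AUROC needs both gold and non-gold pairs in the ranking")
  # for each gold edge, count non-gold edges ranked below it
  below <- cumsum(!hit)
  sum((m - g) - below[hit]) / (g * (m - g))
}

#' True positives among the k most confident predictions
#'
#' @inheritParams aupr
#' @param k Number of top-ranked pairs to inspect (default 100).
#' @return Integer count of gold edges among the top k.
#' @export
tp_at_k <- function(ranked, gold, k = 100, restrict_to_common_nodes = TRUE) {
  parts <- restrict_ranked(ranked, gold, restrict_to_common_nodes)
  if (k > nrow(parts$ranked)) abort("`k` exceeds the ranking length")
  top <- parts$ranked[seq_len(k), ]
  sum(edge_key(top$from, top$to) %in% edge_key(parts$gold$from, parts$gold$to))
}

#' Hypergeometric enrichment of gold edges among the top k
#'
#' Probability of observing at least the given top-k overlap when drawing k
#' pairs at random from the scored universe.
#'
#' @inheritParams tp_at_k
#' @return A one-row tibble with `k`, `TP_at_k` and `p_value`.
#' @export
topk_enrichment <- function(ranked, gold, k = 100, restrict_to_common_nodes = TRUE) {
  parts <- restrict_ranked(ranked, gold, restrict_to_common_nodes)
  g <- sum(edge_key(parts$ranked$from, parts$ranked$to) %in%
    edge_key(parts$gold$from, parts$gold$to))
  m <- nrow(parts$ranked)
  tp <- tp_at_k(ranked, gold, k, restrict_to_common_nodes)
  tibble(
    k = k,
    TP_at_k = tp,
    p_value = stats::phyper(tp - 1, g, m - g, k, lower.tail = FALSE)
  )
}

#' Score a ranked edge list against a gold standard
#'
#' Computes AUPR, AUROC, the confusion counts at the reduced-graph cut (the
#' `"GT"` tier of the ranking is taken as the predicted edge set) and the
#' true-positive count among the top k, in one report.
#'
#' @inheritParams aupr
#' @param k Top-list size for `TP_at_k` (default 100, capped at the ranking
#'   length).
#' @return An `eval_report` list with fields `AUPR`, `AUROC`, `edges`, `TP`,
#'   `FP`, `FN`, `TP_at_k`, `k`, and the swept `curve` points.
#' @export
evaluate_ranking <- function(ranked, gold, k = 100,
                             restrict_to_common_nodes = TRUE) {
  parts <- restrict_ranked(ranked, gold, restrict_to_common_nodes)
  k <- min(k, nrow(parts$ranked))
  predicted <- ranked[ranked$tier == "GT", ]
  cc <- confusion_counts(
    predicted, gold, restrict_to_common_nodes,
    predicted_nodes = unique(c(ranked$from, ranked$to))
  )
  structure(
    list(
      AUPR = aupr(ranked, gold, restrict_to_common_nodes),
      AUROC = auroc(ranked, gold, restrict_to_common_nodes),
      edges = nrow(predicted),
      TP = cc$TP, FP = cc$FP, FN = cc$FN,
      TP_at_k = tp_at_k(ranked, gold, k, restrict_to_common_nodes),
      k = k,
      curve = pr_roc_points(parts$ranked, parts$gold)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(
    "<eval_report> AUPR ", signif(x$AUPR, 4), ", AUROC ", signif(x$AUROC, 4),
    " | ", x$edges, " predicted edges: TP ", x$TP, ", FP ", x$FP, ", FN ", x$FN,
    " | TP@", x$k, " = ", x$TP_at_k, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    AUPR = x$AUPR, AUROC = x$AUROC, edges = x$edges,
    TP = x$TP, FP = x$FP, FN = x$FN, TP_at_k = x$TP_at_k, k = x$k
  )
}

#' Plot the precision-recall curve of an evaluation report
#'
#' @param object An `eval_report` from [evaluate_ranking()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Recall", y = "Precision",
      title = sprintf("AUPR = %.4f", object$AUPR)
    ) +
    ggplot2::theme_minimal()
}
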