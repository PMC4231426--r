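default_alpha <- function(tr, L) {
  switch(tr,
    transwesd = if (is.infinite(L)) 0.95 else 1.5,
    ltr = 0.15,
    NA_real_
  )
}

#' Run the full inference pipeline on a knockout screen
#'
#' Perturbation-graph generation, transitive reduction and edge ranking in one
#' call, with optional evaluation against a gold standard. The defaults are
#' the benchmark settings: `beta = 2`, `gamma = 0.05`, `alpha = 0.95` for
#' TRANSWESD with unbounded paths, 1.5 for local TRANSWESD (`L = 2`) and 0.15
#' for LTR.
#'
#' @param dataset An [expression_dataset()] (complete screen).
#' @param pg_method `"pgnew"` (default), `"pg1"` or `"pg2"`.
#' @param beta Z-score threshold.
#' @param gamma Deviation (`pg2`) or correlation (`pgnew`) threshold.
#' @param tr Reduction method: `"ltr"` (default), `"transwesd"`, `"drffl"` or
#'   `"none"`.
#' @param signed,weighted,L,alpha,path_exact,full_check Passed to
#'   [tr_config()].
#' @param scheme Ranking tier scheme, see [rank_edges()].
#' @param gold Optional [gold_standard()] for evaluation.
#' @param k Top-list size for the evaluation report.
#' @param exclusion Conditional-correlation exclusion rule, see
#'   [compute_conditional_correlation()].
#' @param sd_type Standard-deviation convention for z-scores.
#' @return A `network_inference` object: list with `pg`, `reduction` (or
#'   `NULL`), `ranking`, `report` (or `NULL`) and a `summary` tibble of edge
#'   counts at each stage (plus TP/FP/FN and TP@k when a gold standard is
#'   supplied).
#' @export
infer_network <- function(dataset,
                          pg_method = c("pgnew", "pg1", "pg2"),
                          beta = 2, gamma = 0.05,
                          tr = c("ltr", "transwesd", "drffl", "none"),
                          signed = TRUE, weighted = TRUE, L = Inf,
                          alpha = NULL, path_exact = TRUE, full_check = TRUE,
                          scheme = c("two_tier", "three_tier"),
                          gold = NULL, k = 100,
                          exclusion = "drop_j",
                          sd_type = "sample") {
  pg_method <- match.arg(pg_method)
  tr <- match.arg(tr)
  scheme <- match.arg(scheme)
  zb <- compute_zscores(dataset, sd_type = sd_type)
  pg <- switch(pg_method,
    pg1 = build_pg1(zb, beta = beta),
    pg2 = {
      cb <- compute_conditional_correlation(dataset, exclusion = exclusion)
      build_pg2(dataset, zb, cb, beta = beta, gamma = gamma)
    },
    pgnew = {
      cb <- compute_conditional_correlation(dataset, exclusion = exclusion)
      cb <- compute_zc(cb)
      build_pg_new(zb, cb, beta = beta, gamma = gamma)
    }
  )
  reduction <- if (tr == "none") {
    NULL
  } else if (tr == "drffl") {
    reduce_drffl(pg)
  } else {
    cfg <- tr_config(tr,
      signed = signed, weighted = weighted, L = L,
      alpha = alpha %||% default_alpha(tr, L),
      path_exact = path_exact, full_check = full_check
    )
    if (tr == "transwesd") reduce_transwesd(pg, cfg) else reduce_ltr(pg, cfg)
  }
  ranking <- rank_edges(pg, reduction, scheme = scheme)
  report <- if (!is.null(gold)) evaluate_ranking(ranking, gold, k = k)
  summary <- tibble(
    pg_method = pg_method,
    tr = tr,
    pg_edges = nrow(pg$edges),
    removed = if (is.null(reduction)) 0L else nrow(reduction$removed),
    edges = if (is.null(reduction)) nrow(pg$edges) else nrow(reduction$kept)
  )
  if (!is.null(report)) {
    summary <- dplyr::bind_cols(summary, glance(report)[c("TP", "FP", "FN", "TP_at_k", "AUPR", "AUROC")])
  }
  structure(
    list(
      pg = pg, reduction = reduction, ranking = ranking,
      report = report, summary = summary
    ),
    class = "network_inference"
  )
}

#' @export
print.network_inference <- function(x, ...) {
  cat("<network_inference>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.network_inference <- function(x, ...) x$ranking

#' @export
glance.network_inference <- function(x, ...) x$summary

#' @export
autoplot.network_inference <- function(object, ...) {
  if (is.null(object$report)) {
    abort("nothing to plot: run the pipeline with a gold standard")
  }
  autoplot(object$report, ...)
}

#' Infer from a partial perturbation screen
#'
#' When only `m < n` genes were knocked out (e.g. a transcription-factor
#' deletion library), two complementary reconstructions are possible: (i) the
#' complete sub-network among the m perturbed genes, inferred with the full
#' perturbation-graph/transitive-reduction pipeline on the m x m block, and
#' (ii) candidate edges from perturbed to unperturbed genes, for which
#' transitive reduction cannot help (no paths exist among never-perturbed
#' targets) and the perturbation graph itself is reported.
#'
#' @param dataset A partial [expression_dataset()] (`m < n` knockout rows,
#'   `m >= 3` so conditional correlations are defined).
#' @param ... Passed on to [infer_network()] for the sub-network part.
#' @return A list with `sub` (a `network_inference` over the perturbed genes)
#'   and `cross` (a `ranked_edges` tibble of perturbed -> unperturbed pairs,
#'   tier `"GT"` for perturbation-graph edges).
#' @export
infer_partial_network <- function(dataset, ...) {
  m <- length(dataset$perturbed)
  if (m < 3) abort("at least 3 perturbed genes are required (correlations undefined)")
  args <- list(...)
  sub_data <- expression_dataset(
    wt = dataset$wt[dataset$perturbed],
    ko = dataset$ko[, dataset$perturbed, drop = FALSE],
    gene_ids = dataset$perturbed
  )
  sub <- infer_network(sub_data, ...)
  # cross edges: full-width PG restricted to unperturbed targets
  pg_method <- args$pg_method %||% "pgnew"
  zb <- compute_zscores(dataset, sd_type = args$sd_type %||% "sample")
  pg <- switch(pg_method,
    pg1 = build_pg1(zb, beta = args$beta %||% 2),
    pg2 = {
      cb <- compute_conditional_correlation(dataset, exclusion = args$exclusion %||% "drop_j")
      build_pg2(dataset, zb, cb, beta = args$beta %||% 2, gamma = args$gamma %||% 0.05)
    },
    pgnew = {
      cb <- compute_zc(compute_conditional_correlation(dataset, exclusion = args$exclusion %||% "drop_j"))
      build_pg_new(zb, cb, beta = args$beta %||% 2, gamma = args$gamma %||% 0.05)
    }
  )
  ranking <- rank_edges(pg, NULL, scheme = args$scheme %||% "two_tier")
  cross <- ranking[!(ranking$to %in% dataset$perturbed), ]
  cross$rank <- seq_len(nrow(cross))
  list(sub = sub, cross = cross)
}

#' Run the pipeline from files
#'
#' File-level wrapper around [infer_network()]: reads the wild-type and
#' knockout matrices (DREAM4 dialect), optionally a gold standard, runs the
#' pipeline, and optionally writes the prediction list.
#'
#' @param wildtype_path,knockout_path Input expression files.
#' @param gold_path Optional gold-standard edge list.
#' @param output_path Optional predictions output
#'   (`source TAB target TAB confidence`).
#' @param top_n Truncate the written predictions.
#' @param verbose Print the stage summary?
#' @param ... Passed to [infer_network()].
#' @return The `network_inference` object, invisibly.
#' @export
run_pipeline <- function(wildtype_path, knockout_path, gold_path = NULL,
                         output_path = NULL, top_n = NULL, verbose = TRUE, ...) {
  dataset <- read_expression(wildtype_path, knockout_path)
  gold <- if (!is.null(gold_path)) read_gold_standard(gold_path)
  res <- infer_network(dataset, gold = gold, ...)
  if (!is.null(output_path)) write_predictions(res$ranking, output_path, top_n = top_n)
  if (verbose) print(res)
  invisible(res)
}
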