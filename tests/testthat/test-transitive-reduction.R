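test_that("the worked example identifies exactly three removable edges", {
  fig <- make_figure_graph()
  cfg <- tr_config("transwesd", alpha = 0.95)
  R <- identify_removable_transwesd(fig, cfg)
  # ordered highest weight first: the A -> C shortcut, then A -> B, then D -> B
  expect_equal(edge_set(R), c("A C", "A B", "D B"))
  # a vanishing confidence factor admits no explaining path at all
  expect_equal(nrow(identify_removable_transwesd(
    fig, tr_config("transwesd", alpha = 1e-9)
  )), 0)
})

test_that("full checking stops the removal cascade at the last explainable edge", {
  fig <- make_figure_graph()
  res <- reduce_transwesd(fig, tr_config("transwesd", alpha = 0.95))
  expect_equal(edge_set(res$removed), c("A C", "A B"))
  expect_equal(res$removed$iteration, c(1L, 2L))
  # D -> B stays although an explaining path exists: removing it would leave
  # the observed positive influence of A on C unrepresented
  expect_equal(edge_set(res$kept_explainable), "D B")
  expect_true("D B" %in% edge_set(res$kept))
  # without the re-check the frozen decisions also remove D -> B
  res0 <- reduce_transwesd(fig, tr_config("transwesd", alpha = 0.95, full_check = FALSE))
  expect_equal(sort(edge_set(res0$removed)), c("A B", "A C", "D B"))
})

test_that("reduction partitions the edge set and never invents edges", {
  for (seed in c(1, 2, 3)) {
    pg <- random_pg(seed, n = 9, p = 0.3)
    for (res in list(
      reduce_transwesd(pg, tr_config("transwesd", alpha = 0.95)),
      reduce_ltr(pg, tr_config("ltr", alpha = 0.15)),
      reduce_drffl(pg)
    )) {
      all_edges <- sort(edge_set(pg$edges))
      expect_equal(sort(c(edge_set(res$kept), edge_set(res$removed))), all_edges)
      expect_true(all(edge_set(res$removed) %in% edge_set(res$candidates)))
      # kept edges keep their signs and weights
      m <- match(edge_set(res$kept), edge_set(pg$edges))
      expect_equal(res$kept$sign, pg$edges$sign[m])
      expect_equal(res$kept$weight, pg$edges$weight[m])
    }
  }
})

test_that("unsigned unweighted unbounded reduction of a DAG is the classic one", {
  for (seed in 1:10) {
    d <- random_reduced_dag(seed, n = 10, mean_deg = 1.8)
    clo <- transitive_closure(d$truth, nodes = d$gene_ids)
    clo$weight <- 0.5
    pg <- pg_from_edges(clo, gene_ids = d$gene_ids)
    res <- reduce_transwesd(pg, tr_config("transwesd", signed = FALSE, weighted = FALSE))
    # oracle: on a DAG the unique minimal reachability-preserving graph keeps
    # exactly the edges with no alternative path
    keep <- vapply(seq_len(nrow(clo)), function(e) {
      !oracle_path_exists(pg, clo$from[e], clo$to[e], sign = "any")
    }, logical(1))
    expect_equal(sort(edge_set(res$kept)), sort(edge_set(clo[keep, ])))
    expect_equal(sort(edge_set(res$kept)), sort(edge_set(d$truth)))
  }
})

test_that("the LTR weight rule follows the multiplicative inequality", {
  # alpha * Zc_ij <= Zc_ik * Zc_kj with Zc = 1 - weight: 0.15 * 0.2 = 0.03
  # against 0.6 * 0.5 = 0.30 -> removable
  pg <- pg_from_edges(tibble::tibble(
    from = c("I", "K", "I"), to = c("K", "J", "J"),
    sign = "+", weight = c(1 - 0.6, 1 - 0.5, 1 - 0.2)
  ))
  res <- reduce_ltr(pg, tr_config("ltr", alpha = 0.15))
  expect_equal(edge_set(res$removed), "I J")
  # the same triangle fails once alpha exceeds the weight ratio
  res2 <- reduce_ltr(pg, tr_config("ltr", alpha = 2))
  expect_equal(nrow(res2$removed), 0)
  # non-strict comparison: equality still removes
  pg_eq <- pg_from_edges(tibble::tibble(
    from = c("I", "K", "I"), to = c("K", "J", "J"),
    sign = "+", weight = c(0.5, 0.5, 1 - (0.5 * 0.5))
  ))
  res3 <- reduce_ltr(pg_eq, tr_config("ltr", alpha = 1))
  expect_equal(edge_set(res3$removed), "I J")
})

test_that("sign-inconsistent feed-forward loops are kept in signed mode", {
  pg <- pg_from_edges(tibble::tibble(
    from = c("I", "K", "I"), to = c("K", "J", "J"),
    sign = c("+", "-", "+"), weight = c(0.2, 0.2, 0.8)
  ))
  expect_equal(nrow(reduce_ltr(pg, tr_config("ltr", alpha = 0.15))$removed), 0)
  # the unsigned variant removes it
  res <- reduce_ltr(pg, tr_config("ltr", signed = FALSE, alpha = 0.15))
  expect_equal(edge_set(res$removed), "I J")
})

test_that("unweighted LTR removes any sign-consistent feed-forward loop", {
  pg <- pg_from_edges(tibble::tibble(
    from = c("I", "K", "I"), to = c("K", "J", "J"),
    sign = c("+", "-", "-"), weight = c(0.99, 0.99, 0.01)
  ))
  # weighted: 0.15 * 0.99 > 0.01 * 0.01 -> kept
  expect_equal(nrow(reduce_ltr(pg, tr_config("ltr", alpha = 0.15))$removed), 0)
  # unweighted (alpha = 0 limit): removed
  res <- reduce_ltr(pg, tr_config("ltr", weighted = FALSE))
  expect_equal(edge_set(res$removed), "I J")
})

test_that("DR-FFL reduction only crosses component boundaries", {
  fig <- make_figure_graph()
  res <- reduce_drffl(fig)
  expect_equal(sort(edge_set(res$removed)), c("A B", "A C", "D B"))
  lab <- scc_labels(fig)
  expect_true(all(lab[res$removed$from] != lab[res$removed$to]))
  # a triangle inside one cycle is untouched
  cyc <- pg_from_edges(tibble::tibble(
    from = c("A", "B", "C", "A"), to = c("B", "C", "A", "C"),
    sign = "+", weight = 0.5
  ))
  expect_equal(nrow(reduce_drffl(cyc)$removed), 0)
  # the classic DAG shortcut goes
  dag <- pg_from_edges(tibble::tibble(
    from = c("A", "B", "A"), to = c("B", "C", "C"), sign = "+", weight = 0.5
  ))
  expect_equal(edge_set(reduce_drffl(dag)$removed), "A C")
})

test_that("identical input and configuration give identical removal logs", {
  pg <- random_pg(17, n = 10, p = 0.35)
  for (maker in list(
    function() reduce_transwesd(pg, tr_config("transwesd", alpha = 0.95)),
    function() reduce_ltr(pg, tr_config("ltr", alpha = 0.15)),
    function() reduce_drffl(pg)
  )) {
    a <- maker()
    b <- maker()
    expect_identical(a$removed, b$removed)
    expect_identical(a$kept, b$kept)
  }
})

test_that("after reduction every original edge stays present or explainable", {
  for (seed in c(4, 8, 15)) {
    pg <- random_pg(seed, n = 9, p = 0.35)
    cfg <- tr_config("transwesd", alpha = 0.95)
    res <- reduce_transwesd(pg, cfg)
    kept_pg <- pg_from_edges(res$kept, gene_ids = pg$gene_ids)
    for (r in seq_len(nrow(res$removed))) {
      e <- res$removed[r, ]
      expect_true(oracle_path_exists(
        kept_pg, e$from, e$to,
        sign = if (e$sign > 0) "+" else "-",
        L = cfg$L, bound = cfg$alpha * e$weight
      ), info = paste(seed, e$from, e$to))
    }
  }
})

test_that("signed and unsigned weighted reduction agree without negative loops", {
  # balanced edge signs exclude negative feed-forward loops by construction
  for (seed in 1:8) {
    d <- random_reduced_dag(seed, n = 12, mean_deg = 1.6)
    pg <- closure_pg(d$truth, d$gene_ids)
    s <- reduce_transwesd(pg, tr_config("transwesd", signed = TRUE, alpha = 0.95))
    u <- reduce_transwesd(pg, tr_config("transwesd", signed = FALSE, alpha = 0.95))
    expect_equal(sort(edge_set(s$kept)), sort(edge_set(u$kept)))
  }
})
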