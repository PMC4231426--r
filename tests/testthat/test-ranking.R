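ranked_fixture <- function(seed = 1, n = 5, tr = TRUE) {
  pg <- random_pg(seed, n = n, p = 0.4)
  red <- if (tr) reduce_transwesd(pg, tr_config("transwesd", alpha = 0.95))
  list(pg = pg, red = red, ranking = rank_edges(pg, red))
}

test_that("the ranking is a permutation of all ordered pairs", {
  f <- ranked_fixture(n = 3)
  expect_equal(nrow(f$ranking), 3 * 2)
  f <- ranked_fixture(seed = 2, n = 7)
  expect_equal(nrow(f$ranking), 7 * 6)
  expect_false(any(duplicated(paste(f$ranking$from, f$ranking$to))))
  expect_false(any(f$ranking$from == f$ranking$to))
  expect_equal(f$ranking$rank, seq_len(nrow(f$ranking)))
  expect_true(all(diff(f$ranking$score) <= 0))
})

test_that("tier dominance overrides the raw ranking weight", {
  f <- ranked_fixture(seed = 3, n = 6)
  tiers <- f$ranking$tier
  # every reduced-graph edge precedes every non-GT pair
  expect_true(max(which(tiers == "GT")) < min(which(tiers != "GT")))
  # three-tier: removed PG edges above never-candidates even at lower Wr
  r3 <- rank_edges(f$pg, f$red, scheme = "three_tier")
  t3 <- r3$tier
  if (any(t3 == "removed_from_PG") && any(t3 == "other")) {
    expect_true(max(which(t3 == "removed_from_PG")) < min(which(t3 == "other")))
  }
  # within a tier the ordering follows Wr descending
  gt <- r3[t3 == "GT", ]
  wr <- f$pg$Wr[cbind(gt$from, gt$to)]
  expect_true(all(diff(wr) <= 0))
})

test_that("three-tier ranking lifts a removed low-weight edge over a better never-candidate", {
  pg <- pg_from_edges(
    tibble::tibble(
      from = c("A", "B", "A"), to = c("B", "C", "C"),
      sign = "+", weight = c(0.05, 0.05, 0.5)
    ),
    gene_ids = c("A", "B", "C", "D")
  )
  pg$Wr["A", "C"] <- 0.9 # removed edge, modest weight
  pg$Wr["D", "A"] <- 0.95 # never a candidate, higher weight
  red <- reduce_transwesd(pg, tr_config("transwesd", alpha = 0.95))
  expect_equal(edge_set(red$removed), "A C")
  r3 <- rank_edges(pg, red, scheme = "three_tier")
  expect_lt(which(edge_set(r3) == "A C"), which(edge_set(r3) == "D A"))
  # under two tiers the raw weight decides between them
  r2 <- rank_edges(pg, red, scheme = "two_tier")
  expect_gt(which(edge_set(r2) == "A C"), which(edge_set(r2) == "D A"))
})

test_that("confusion counts respect the common-node restriction", {
  gold <- gold_standard(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  pred <- tibble::tibble(from = c("A", "C"), to = c("B", "A"))
  cc <- confusion_counts(pred, gold, restrict_to_common_nodes = FALSE)
  expect_equal(c(cc$TP, cc$FP, cc$FN), c(1, 1, 1))
  # identical sets: perfect
  cc2 <- confusion_counts(gold, gold)
  expect_equal(c(cc2$TP, cc2$FP, cc2$FN), c(2, 0, 0))
  # disjoint on the same universe
  cc3 <- confusion_counts(tibble::tibble(from = "C", to = "A"), gold,
    restrict_to_common_nodes = FALSE
  )
  expect_equal(cc3$TP, 0)
  # predictions touching nodes unknown to the gold standard are unscored,
  # and gold edges over nodes absent from the prediction universe drop out
  # (B -> C leaves the count because C was never measured)
  pred4 <- tibble::tibble(from = c("A", "X"), to = c("B", "B"))
  cc4 <- confusion_counts(pred4, gold,
    restrict_to_common_nodes = TRUE,
    predicted_nodes = c("A", "B", "X")
  )
  expect_equal(c(cc4$TP, cc4$FP, cc4$FN), c(1, 0, 0))
})

test_that("AUPR and AUROC have the right extremes", {
  pg <- random_pg(5, n = 5, p = 0.9)
  ranking <- rank_edges(pg, NULL)
  top <- ranking[1:4, ]
  gold_top <- gold_standard(top[c("from", "to")], nodes = pg$gene_ids)
  expect_equal(aupr(ranking, gold_top), 1)
  expect_equal(auroc(ranking, gold_top), 1)
  bottom <- ranking[(nrow(ranking) - 2):nrow(ranking), ]
  gold_bottom <- gold_standard(bottom[c("from", "to")], nodes = pg$gene_ids)
  expect_equal(auroc(ranking, gold_bottom), 0)
  empty <- gold_standard(tibble::tibble(from = character(0), to = character(0)),
    nodes = pg$gene_ids
  )
  expect_error(aupr(ranking, empty), "empty")
})

test_that("curve areas match the brute-force integration oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    pg <- random_pg(seed, n = 5, p = 0.6)
    ranking <- rank_edges(pg, NULL)
    m <- nrow(ranking)
    gold_rows <- sample(m, sample(2:(m - 2), 1))
    gold <- gold_standard(ranking[gold_rows, c("from", "to")], nodes = pg$gene_ids)
    hits <- as.integer(seq_len(m) %in% gold_rows)
    expect_equal(aupr(ranking, gold), oracle_aupr(hits), tolerance = 1e-12)
    expect_equal(auroc(ranking, gold), oracle_auroc(hits), tolerance = 1e-12)
  }
  # miniature hand-checked case, ranking gold/non/gold/non: trapezoids give
  # 1/2 * 1 (first gold) plus 1/2 * mean(1/2, 2/3) (second gold) = 19/24
  expect_equal(oracle_aupr(c(1, 0, 1, 0)), 19 / 24, tolerance = 1e-12)
  expect_equal(oracle_auroc(c(1, 0, 1, 0)), 3 / 4, tolerance = 1e-12)
})

test_that("top-k counts and enrichment come from plain set intersection", {
  f <- ranked_fixture(seed = 6, n = 6)
  m <- nrow(f$ranking)
  set.seed(1)
  gold_rows <- sample(m, 8)
  gold <- gold_standard(f$ranking[gold_rows, c("from", "to")], nodes = f$pg$gene_ids)
  k <- 10
  expect_equal(
    tp_at_k(f$ranking, gold, k),
    sum(gold_rows <= k)
  )
  expect_error(tp_at_k(f$ranking, gold, m + 1), "exceeds")
  enr <- topk_enrichment(f$ranking, gold, k)
  expect_equal(enr$TP_at_k, tp_at_k(f$ranking, gold, k))
  expect_equal(
    enr$p_value,
    phyper(enr$TP_at_k - 1, 8, m - 8, k, lower.tail = FALSE)
  )
})

test_that("the evaluation report assembles consistent counts", {
  f <- ranked_fixture(seed = 7, n = 6)
  gt_pairs <- f$ranking[f$ranking$tier == "GT", ]
  set.seed(2)
  gold <- gold_standard(
    rbind(gt_pairs[1, c("from", "to")], f$ranking[25:28, c("from", "to")]),
    nodes = f$pg$gene_ids
  )
  rep <- evaluate_ranking(f$ranking, gold, k = 10)
  expect_s3_class(glance(rep), "tbl_df")
  expect_equal(rep$TP + rep$FP, rep$edges)
  expect_equal(rep$TP + rep$FN, nrow(gold))
  expect_equal(rep$AUPR, aupr(f$ranking, gold))
  expect_equal(rep$TP_at_k, tp_at_k(f$ranking, gold, 10))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})

test_that("row order of the input edges never changes the ranking", {
  pg <- random_pg(8, n = 6, p = 0.4)
  red <- reduce_ltr(pg, tr_config("ltr", alpha = 0.15))
  r1 <- rank_edges(pg, red)
  pg2 <- pg
  set.seed(4)
  perm <- sample(nrow(pg2$edges))
  pg2$edges <- pg2$edges[perm, ]
  red2 <- reduce_ltr(pg2, tr_config("ltr", alpha = 0.15))
  r2 <- rank_edges(pg2, red2)
  expect_equal(r1, r2)
})
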