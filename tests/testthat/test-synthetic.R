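test_that("the noise grid is the published 3x3 design", {
  g <- noise_grid()
  expect_equal(nrow(g), 9)
  expect_equal(g$label, c("LL", "LM", "LH", "ML", "MM", "MH", "HL", "HM", "HH"))
  expect_equal(sort(unique(g$sigma_theta)), c(0.025, 0.05, 0.1))
  expect_equal(sort(unique(g$sigma_nu)), c(0.025, 0.05, 0.1))
  expect_equal(g$sigma_theta[g$label == "MH"], 0.05)
  expect_equal(g$sigma_nu[g$label == "MH"], 0.1)
})

test_that("topology generation is deterministic and hits the target density", {
  a <- generate_topology(200, K = 1.5, seed = 5)
  b <- generate_topology(200, K = 1.5, seed = 5)
  expect_identical(a$edges, b$edges)
  expect_lt(abs(nrow(a$edges) - 300) / 300, 0.1)
  expect_false(any(a$edges$from == a$edges$to))
  expect_false(any(duplicated(paste(a$edges$from, a$edges$to))))
  expect_true(all(a$edges$sign %in% c(-1L, 1L)))
  # K = 0 gives the empty graph
  expect_equal(nrow(generate_topology(50, K = 0, seed = 1)$edges), 0)
})

test_that("out-degrees are heavier tailed than in-degrees", {
  net <- generate_topology(1000, K = 2, seed = 11)
  out_deg <- table(factor(net$edges$from, levels = net$gene_ids))
  in_deg <- table(factor(net$edges$to, levels = net$gene_ids))
  expect_gt(max(out_deg), max(in_deg))
  expect_gt(stats::var(as.numeric(out_deg)), stats::var(as.numeric(in_deg)))
  # log-log regression of the tail frequencies: the out-degree slope must be
  # shallower (heavier tail)
  slope <- function(d) {
    tab <- table(d[d > 0])
    x <- log(as.numeric(names(tab)))
    y <- log(as.numeric(tab))
    unname(stats::coef(stats::lm(y ~ x))[2])
  }
  expect_gt(slope(as.numeric(out_deg)), slope(as.numeric(in_deg)))
})

test_that("noise-free simulation follows the closed-form expectations", {
  # no regulation: every level is the basal ratio 1
  empty <- generate_topology(4, K = 0, seed = 1)
  ds <- simulate_knockouts(empty, sigma_theta = 0, sigma_nu = 0)
  expect_equal(unname(ds$wt), rep(1, 4))
  expect_equal(unname(diag(ds$ko)), rep(0, 4)) # clamp contract
  expect_equal(unname(ds$ko[1, -1]), rep(1, 3))
  # a single activator edge: knocking out the source lowers the target to
  # r(0) = 1 / (1 + a/2) of its basal level, other knockouts leave it alone
  net <- generate_topology(3, K = 0, seed = 1)
  net$edges <- tibble::tibble(from = "G1", to = "G2", sign = 1L, a = 1, m = 1)
  ds <- simulate_knockouts(net, 0, 0)
  expect_equal(ds$wt[["G2"]], 1, tolerance = 1e-7)
  expect_equal(ds$ko["G1", "G2"], 1 / 1.5, tolerance = 1e-6)
  expect_equal(ds$ko["G3", "G2"], 1, tolerance = 1e-7)
  expect_lt(ds$ko["G1", "G2"], ds$wt[["G2"]])
  # an inhibitor edge raises the target after the knockout
  net$edges$sign <- -1L
  ds2 <- simulate_knockouts(net, 0, 0)
  expect_gt(ds2$ko["G1", "G2"], ds2$wt[["G2"]])
})

test_that("noise-free deviations on a reduced DAG carry the path sign", {
  for (seed in c(3, 9)) {
    d <- random_reduced_dag(seed, n = 15, mean_deg = 1.5)
    net <- generate_topology(15, K = 0, seed = seed)
    net$gene_ids <- d$gene_ids
    net$edges <- dplyr::mutate(d$truth, a = 1, m = 1)
    dimnames_fix <- d$gene_ids
    ds <- simulate_knockouts(net, 0, 0)
    clo <- transitive_closure(d$truth, nodes = d$gene_ids)
    for (r in seq_len(nrow(clo))) {
      dev <- ds$wt[[clo$to[r]]] - ds$ko[clo$from[r], clo$to[r]]
      expect_gt(dev * clo$sign[r], 0)
    }
  }
})

test_that("the signed closure matches exhaustive path enumeration", {
  # chains accumulate sign products
  chain <- tibble::tibble(from = c("A", "B"), to = c("B", "C"), sign = c(1L, 1L))
  clo <- transitive_closure(chain)
  expect_true("A C" %in% edge_set(clo))
  expect_equal(clo$sign[edge_set(clo) == "A C"], 1L)
  mixed <- tibble::tibble(from = c("A", "B"), to = c("B", "C"), sign = c(1L, -1L))
  clo2 <- transitive_closure(mixed)
  expect_equal(clo2$sign[edge_set(clo2) == "A C"], -1L)
  # cyclic input is refused
  cyc <- tibble::tibble(from = c("A", "B"), to = c("B", "A"), sign = 1L)
  expect_error(transitive_closure(cyc), "acyclic")
  # random DAGs against the simple-path oracle
  for (seed in 1:8) {
    d <- random_reduced_dag(seed, n = 8, mean_deg = 1.5)
    w <- d$truth
    w$weight <- 0.5
    pg <- pg_from_edges(w, gene_ids = d$gene_ids)
    clo <- transitive_closure(d$truth, nodes = d$gene_ids)
    for (i in d$gene_ids) {
      for (j in setdiff(d$gene_ids, i)) {
        ps <- oracle_paths(pg, i, j, exclude = c("", ""))
        expect_equal(
          sort(unique(clo$sign[clo$from == i & clo$to == j])),
          sort(unique(ps$sign))
        )
      }
    }
  }
})

test_that("the benchmark suite enumerates the factorial design", {
  suite <- make_benchmark_suite(
    n = 5000, K_list = c(1.5, 2, 2.5),
    replicates = 10, seed = 1
  )
  expect_equal(nrow(suite), 270)
  expect_equal(length(unique(suite$network_id)), 30)
  expect_equal(as.integer(table(suite$K)), c(90L, 90L, 90L))
  expect_false(any(duplicated(suite[c("network_id", "label")])))
  # reproducible from the master seed
  suite2 <- make_benchmark_suite(n = 5000, replicates = 10, seed = 1)
  expect_identical(as.data.frame(suite), as.data.frame(suite2))
  # no replicates, no rows
  expect_equal(nrow(make_benchmark_suite(replicates = 0, seed = 1)), 0)
  # a subset of noise labels scales the row count
  expect_equal(nrow(make_benchmark_suite(
    K_list = 1.5, noise_labels = c("LL", "HH"),
    replicates = 2, seed = 3
  )), 4)
})

test_that("simulated suites carry datasets matching their manifest", {
  suite <- make_benchmark_suite(
    n = 20, K_list = 1.5, noise_labels = "LL",
    replicates = 2, seed = 7, simulate = TRUE
  )
  expect_equal(nrow(suite), 2)
  for (r in seq_len(nrow(suite))) {
    expect_s3_class(suite$network[[r]], "true_network")
    expect_s3_class(suite$dataset[[r]], "expression_dataset")
    expect_equal(length(suite$dataset[[r]]$gene_ids), 20)
  }
  # same seed, same data
  suite2 <- make_benchmark_suite(
    n = 20, K_list = 1.5, noise_labels = "LL",
    replicates = 2, seed = 7, simulate = TRUE
  )
  expect_identical(suite$dataset[[1]]$ko, suite2$dataset[[1]]$ko)
})
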