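#' Z-scores of knockout-induced expression deviations
#'
#' For every ordered pair (i, j) the z-score
#' `z_ij = (ko[i, j] - mu_j) / sigma_j` quantifies how far the expression of
#' gene `j` after knockout of gene `i` deviates from the typical expression of
#' gene `j`. `mu_j` and `sigma_j` are computed over all available measurements
#' of gene `j`: its value in every knockout experiment (including the
#' self-knockout row) plus the wild-type value. The sample standard deviation
#' (denominator `n`) is the default.
#'
#' A gene whose measurements are constant carries no information; its column
#' of z-scores is set to 0 and the gene is recorded in the `degenerate`
#' field (with a warning).
#'
#' @param dataset An [expression_dataset()].
#' @param sd_type `"sample"` (default) or `"population"` standard deviation.
#' @return A `zscore_bundle`: list with `Z` (m x n matrix, rows = knocked-out
#'   genes), `mu`, `sigma` (length-n vectors) and `degenerate` (character
#'   vector of zero-variance genes). The diagonal entries `Z[j, j]` are the
#'   self-knockout effects; perturbation-graph builders ignore them.
#' @export
compute_zscores <- function(dataset, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ko <- dataset$ko
  wt <- dataset$wt
  vals <- rbind(ko, wt) # (m + 1) x n, all measurements of each gene
  n_obs <- nrow(vals)
  mu <- colMeans(vals)
  if (sd_type == "sample") {
    sigma <- apply(vals, 2, stats::sd)
  } else {
    sigma <- sqrt(colMeans(sweep(vals, 2, mu)^2))
  }
  degenerate <- dataset$gene_ids[sigma == 0]
  if (length(degenerate) > 0) {
    warn(paste0(
      "zero-variance expression for gene(s) ",
      paste(degenerate, collapse = ", "),
      "; their z-scores are set to 0"
    ))
  }
  denom <- ifelse(sigma > 0, sigma, Inf)
  Z <- sweep(sweep(ko, 2, mu), 2, denom, "/")
  dimnames(Z) <- dimnames(ko)
  structure(
    list(
      Z = Z,
      mu = setNames(mu, dataset$gene_ids),
      sigma = setNames(sigma, dataset$gene_ids),
      degenerate = degenerate
    ),
    class = "zscore_bundle"
  )
}

#' Conditional correlation of gene pairs across perturbation experiments
#'
#' `c_ij` is the Pearson correlation between the measurement columns of genes
#' i (a knocked-out gene, the candidate source) and j over the wild-type row
#' and all knockout rows, excluding the experiment that directly perturbs the
#' conditioning gene. The default `"drop_j"` removes only the row in which j
#' itself was knocked out (its value there reflects the perturbation, not the
#' regulatory response); `"drop_i_and_j"` additionally removes the row where i
#' was knocked out.
#'
#' Pairs in which either gene has zero variance over the retained rows are
#' uninformative; their correlation is set to 0 and recorded.
#'
#' @param dataset An [expression_dataset()].
#' @param exclusion Row-exclusion rule, see above.
#' @return A `correlation_bundle`: list with `C` (m x n matrix of conditional
#'   correlations, rows = knocked-out genes, diagonal `NA`), `exclusion`, and
#'   `degenerate_pairs` (tibble of zeroed pairs). `Zc` and `offset` are filled
#'   by [compute_zc()].
#' @export
compute_conditional_correlation <- function(dataset,
                                            exclusion = c("drop_j", "drop_i_and_j")) {
  exclusion <- match.arg(exclusion)
  vals <- rbind(wt = dataset$wt, dataset$ko) # (m + 1) x n
  m <- length(dataset$perturbed)
  n <- length(dataset$gene_ids)
  min_rows <- if (exclusion == "drop_j") m else m - 1
  if (min_rows < 3) abort("at least 3 experiments must remain after exclusion")
  src_cols <- match(dataset$perturbed, dataset$gene_ids)
  C <- matrix(NA_real_, m, n, dimnames = list(dataset$perturbed, dataset$gene_ids))
  row_of <- match(dataset$gene_ids, dataset$perturbed) + 1L # row in vals, NA if unperturbed
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(m + 1L), row_of[j])
    if (exclusion == "drop_j") {
      x <- vals[keep, , drop = FALSE]
      cj <- suppressWarnings(cor(x[, src_cols, drop = FALSE], x[, j]))
      C[, j] <- as.numeric(cj)
    } else {
      for (i in seq_len(m)) {
        keep_ij <- setdiff(keep, row_of[match(dataset$perturbed[i], dataset$gene_ids)])
        C[i, j] <- suppressWarnings(cor(vals[keep_ij, src_cols[i]], vals[keep_ij, j]))
      }
    }
  }
  degenerate <- which(is.na(C), arr.ind = TRUE)
  self <- src_cols[degenerate[, 1]] == degenerate[, 2]
  degenerate <- degenerate[!self, , drop = FALSE]
  if (nrow(degenerate) > 0) {
    warn(paste0(
      nrow(degenerate),
      " gene pair(s) with zero variance over retained experiments;",
      " their conditional correlations are set to 0"
    ))
    C[degenerate] <- 0
  }
  for (i in seq_len(m)) C[i, src_cols[i]] <- NA_real_ # diagonal unset
  structure(
    list(
      C = C,
      Zc = NULL,
      offset = NULL,
      exclusion = exclusion,
      degenerate_pairs = tibble(
        from = rownames(C)[degenerate[, 1]],
        to = colnames(C)[degenerate[, 2]]
      )
    ),
    class = "correlation_bundle"
  )
}

#' Z-scores of conditional correlations, shifted positive
#'
#' Standardizes the absolute conditional correlations within each target
#' column j (excluding the diagonal): a large `Zc[i, j]` means that i's
#' knockout response correlates with gene j unusually strongly relative to the
#' average conditional correlation related to gene j. A single global shift
#' then makes the smallest off-diagonal entry equal to `epsilon`, so that all
#' entries are strictly positive (the multiplicative weight rule of local
#' transitive reduction requires positive weights).
#'
#' Columns whose absolute correlations are constant are standardized to 0
#' before the shift, with a warning.
#'
#' @param cb A `correlation_bundle` from [compute_conditional_correlation()].
#' @param epsilon Value of the smallest off-diagonal entry after the shift.
#' @return The bundle with `Zc` (same shape as `C`) and `offset` filled.
#' @export
compute_zc <- function(cb, epsilon = 1e-6) {
  absC <- abs(cb$C)
  Zc <- absC
  degenerate <- character(0)
  for (j in seq_len(ncol(absC))) {
    col <- absC[, j]
    ok <- !is.na(col)
    s <- stats::sd(col[ok])
    if (!isTRUE(s > 0)) {
      Zc[ok, j] <- 0
      degenerate <- c(degenerate, colnames(absC)[j])
    } else {
      Zc[ok, j] <- (col[ok] - mean(col[ok])) / s
    }
  }
  if (length(degenerate) > 0) {
    warn(paste0(
      "constant |correlation| column(s) for gene(s) ",
      paste(degenerate, collapse = ", "),
      "; standardized to 0 before the positivity shift"
    ))
  }
  offset <- epsilon - min(Zc, na.rm = TRUE)
  cb$Zc <- Zc + offset
  cb$offset <- offset
  cb
}

# min-max scale the finite off-diagonal entries of a weight matrix into [0, 1];
# constant matrices map to 0
minmax_scale <- function(M) {
  rng <- range(M, na.rm = TRUE, finite = TRUE)
  if (rng[2] > rng[1]) {
    (M - rng[1]) / (rng[2] - rng[1])
  } else {
    M * 0
  }
}
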