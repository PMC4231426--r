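#' Assemble a knockout expression dataset
#'
#' Bundles the wild-type expression vector and the knockout expression matrix
#' of a systematic single-gene perturbation screen. Row `i` of `ko` holds the
#' steady-state expression of every gene measured after knocking out gene `i`
#' (the row order of `ko` must follow `gene_ids`). In a complete screen every
#' gene is knocked out once and `ko` is square; a partial screen (only the
#' first `m` genes perturbed, as in transcription-factor deletion libraries)
#' is allowed and flagged, in which case only the perturbed rows are present.
#'
#' @param wt Numeric vector of length `n`: wild-type expression, one entry per
#'   gene, arbitrary non-negative units.
#' @param ko Numeric `m x n` matrix of post-knockout expression, `m <= n`.
#' @param gene_ids Character vector of `n` unique gene identifiers. Defaults
#'   to the column names of `ko`, or `G1..Gn`.
#' @param perturbed Character vector of the `m` knocked-out genes, in row
#'   order of `ko`. Defaults to `gene_ids[seq_len(nrow(ko))]`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `gene_ids`, `wt` (named vector), `ko` (matrix with dimnames), and
#'   `perturbed`.
#' @export
#'
#' @examples
#' wt <- c(A = 1, B = 1, C = 1)
#' ko <- matrix(runif(9), 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' expression_dataset(wt, ko)
expression_dataset <- function(wt, ko, gene_ids = NULL, perturbed = NULL) {
  ko <- as.matrix(ko)
  if (is.null(gene_ids)) {
    gene_ids <- colnames(ko)
    if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(ko)))
  }
  n <- length(gene_ids)
  if (n < 2) abort("an expression dataset needs at least 2 genes")
  if (anyDuplicated(gene_ids)) abort("gene identifiers must be unique")
  if (length(wt) != n) abort("`wt` length must equal the number of genes")
  if (ncol(ko) != n) abort("`ko` must have one column per gene")
  if (nrow(ko) > n) abort("`ko` cannot have more rows than genes")
  if (is.null(perturbed)) {
    perturbed <- rownames(ko)
    if (is.null(perturbed)) perturbed <- gene_ids[seq_len(nrow(ko))]
  }
  if (length(perturbed) != nrow(ko)) {
    abort("`perturbed` must name one gene per row of `ko`")
  }
  if (!all(perturbed %in% gene_ids)) abort("`perturbed` genes must appear in `gene_ids`")
  if (anyDuplicated(perturbed)) abort("each gene can be knocked out once only")
  wt <- as.numeric(wt)
  if (!all(is.finite(wt)) || !all(is.finite(ko))) abort("expression values must be finite")
  dimnames(ko) <- list(perturbed, gene_ids)
  structure(
    list(
      gene_ids = gene_ids,
      wt = setNames(wt, gene_ids),
      ko = ko,
      perturbed = perturbed
    ),
    class = "expression_dataset"
  )
}

is_complete_screen <- function(dataset) {
  length(dataset$perturbed) == length(dataset$gene_ids)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(
    "<expression_dataset> ", length(x$gene_ids), " genes, ",
    length(x$perturbed), " single-gene knockouts\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.expression_dataset <- function(x, ...) {
  tibble(
    knockout = rep(x$perturbed, times = length(x$gene_ids)),
    gene = rep(x$gene_ids, each = length(x$perturbed)),
    expression = as.vector(x$ko),
    wildtype = rep(unname(x$wt), each = length(x$perturbed))
  )
}

#' Read a knockout screen from wild-type and knockout matrix files
#'
#' Both files are tab-separated with a header row of gene identifiers
#' (DREAM4 dialect). The wild-type file carries a single data row; the
#' knockout file carries one data row per knocked-out gene, in the same order
#' as the header columns (row `i` = knockout of gene `i`). A knockout file
#' with fewer rows than columns is read as a partial screen of the first
#' genes.
#'
#' @param wildtype_path,knockout_path Paths to the two files.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(wildtype_path, knockout_path) {
  raw_header <- strsplit(readLines(knockout_path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(raw_header)) abort("duplicate gene identifier in header")
  wt_tab <- readr::read_tsv(
    wildtype_path,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  )
  ko_tab <- readr::read_tsv(
    knockout_path,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  )
  if (!identical(names(wt_tab), names(ko_tab))) {
    abort("wild-type and knockout headers disagree")
  }
  if (anyDuplicated(names(ko_tab))) abort("duplicate gene identifier in header")
  if (nrow(wt_tab) != 1) abort("wild-type file must contain exactly one data row")
  gene_ids <- names(ko_tab)
  if (nrow(ko_tab) > length(gene_ids)) {
    abort("knockout file has more rows than genes in the header")
  }
  ko <- as.matrix(ko_tab)
  if (any(!is.finite(ko)) || any(!is.finite(as.numeric(wt_tab[1, ])))) {
    abort("non-numeric or missing expression value")
  }
  expression_dataset(
    wt = as.numeric(wt_tab[1, ]),
    ko = ko,
    gene_ids = gene_ids,
    perturbed = gene_ids[seq_len(nrow(ko))]
  )
}

#' Write a knockout screen to wild-type and knockout matrix files
#'
#' Inverse of [read_expression()]; emits the tab-separated DREAM4 dialect.
#'
#' @param dataset An [expression_dataset()].
#' @param wildtype_path,knockout_path Output paths.
#' @return `dataset`, invisibly.
#' @export
write_expression <- function(dataset, wildtype_path, knockout_path) {
  write_tsv_matrix(matrix(dataset$wt, nrow = 1), dataset$gene_ids, wildtype_path)
  write_tsv_matrix(dataset$ko, dataset$gene_ids, knockout_path)
  invisible(dataset)
}

write_tsv_matrix <- function(m, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  utils::write.table(
    m, con,
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
}

#' Convert log2 fold changes to the expression scale
#'
#' Knockout screens are often distributed as log2 fold changes `L[i, j]` of
#' gene `j` after deletion of gene `i`. The pipeline expects expression-like
#' ratios, obtained elementwise as `2^L`. On this scale a value above 1 means
#' the deleted gene represses the target and a value below 1 means it
#' activates it; the wild-type reference is 1 for every gene.
#'
#' @param lfc Numeric matrix (or data frame) of log2 fold changes.
#' @return A numeric matrix `2^lfc` with the same dimnames.
#' @export
lfc_to_expression <- function(lfc) {
  lfc <- as.matrix(lfc)
  if (!all(is.finite(lfc))) abort("log-fold-change matrix must be finite")
  2^lfc
}

#' Read and write directed gold-standard edge lists
#'
#' The file dialect is tab-separated `source TAB target TAB {0|1}` without a
#' header (DREAM dialect); pairs absent from the file count as 0. Rows with a
#' final 0 are dropped on reading. The node universe of the standard is the
#' set of genes mentioned in the file unless `nodes` widens it.
#'
#' @param path File path.
#' @param nodes Optional character vector fixing the node universe.
#' @return `read_gold_standard()` returns a `gold_standard`: a tibble with
#'   columns `from`, `to` and a `nodes` attribute.
#' @export
read_gold_standard <- function(path, nodes = NULL) {
  tab <- readr::read_tsv(
    path,
    col_names = c("from", "to", "present"),
    col_types = "cci", progress = FALSE, show_col_types = FALSE
  )
  gold_standard(tab[tab$present == 1, c("from", "to")], nodes = nodes)
}

#' @rdname read_gold_standard
#' @param edges Data frame with columns `from` and `to` (one row per true
#'   directed edge).
#' @export
gold_standard <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)[c("from", "to")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) abort("gold standards cannot contain self-loops")
  edges <- dplyr::distinct(edges)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  structure(edges, nodes = nodes, class = c("gold_standard", class(edges)))
}

#' @rdname read_gold_standard
#' @param gold A `gold_standard`.
#' @export
write_gold_standard <- function(gold, path) {
  tab <- data.frame(gold$from, gold$to, 1L)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(gold)
}

#' Write a ranked prediction list
#'
#' Emits `source TAB target TAB confidence`, one row per ordered pair in
#' ranking order (DREAM submission dialect), optionally truncated.
#'
#' @param ranking A ranked edge list from [rank_edges()].
#' @param path Output path.
#' @param top_n Keep only the first `top_n` rows if given.
#' @return `ranking`, invisibly.
#' @export
write_predictions <- function(ranking, path, top_n = NULL) {
  tab <- as.data.frame(ranking[c("from", "to", "score")])
  if (!is.null(top_n)) tab <- utils::head(tab, top_n)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(ranking)
}
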