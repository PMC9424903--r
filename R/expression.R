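expr_to_matrix <- function(matrix_tbl) {
  if (is.matrix(matrix_tbl)) return(matrix_tbl)
  if (!"gene" %in% names(matrix_tbl)) {
    abort("expression table needs a `gene` column plus one column per sample.")
  }
  m <- as.matrix(matrix_tbl[setdiff(names(matrix_tbl), "gene")])
  rownames(m) <- matrix_tbl$gene
  m
}

matrix_to_expr <- function(m) {
  bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

#' Filter low-expressed genes and shift the expression matrix
#'
#' Removes genes whose raw normalized value is below 1.5 in more than 50% of
#' samples (strictly more, so a gene at exactly 50% is retained), then shifts
#' every value by +1 for downstream fold-change computation on a positive
#' scale. The filter is applied to the raw values; the threshold and the
#' sample-fraction cut are configurable.
#'
#' @param matrix_tbl Tibble with a `gene` column plus one numeric column per
#'   sample (raw normalized expression), or an equivalent matrix with gene
#'   rownames.
#' @param min_value Low-expression threshold on the raw scale (default 1.5).
#' @param max_low_fraction Genes with a raw value below `min_value` in more
#'   than this fraction of samples are removed (default 0.5).
#' @param shift Value added after filtering (default 1).
#' @return Filtered, shifted tibble; removed gene names in attribute
#'   `"removed_genes"`, `"transform"` set to `"shifted"`.
#' @export
preprocess_expression <- function(matrix_tbl, min_value = 1.5,
                                  max_low_fraction = 0.5, shift = 1) {
  m <- expr_to_matrix(matrix_tbl)
  if (nrow(m) == 0 || ncol(m) == 0) abort("expression matrix is empty.")
  if (identical(attr(matrix_tbl, "transform"), "shifted")) {
    out <- matrix_to_expr(m)
    attr(out, "removed_genes") <- attr(matrix_tbl, "removed_genes")
    attr(out, "transform") <- "shifted"
    return(out)
  }
  low_frac <- rowMeans(m < min_value)
  keep <- low_frac <= max_low_fraction
  out <- matrix_to_expr(m[keep, , drop = FALSE] + shift)
  attr(out, "removed_genes") <- rownames(m)[!keep]
  attr(out, "transform") <- "shifted"
  out
}

#' Rank genes by Spearman correlation with a target gene
#'
#' @param matrix_tbl Preprocessed expression table ([preprocess_expression()]).
#' @param target_gene Gene whose co-expression partners are sought.
#' @return Tibble `gene`, `rho`, `rho_rank`, sorted by decreasing Spearman
#'   rho; the target itself is excluded.
#' @examples
#' sim <- simulate_expression(expression_sim_params(n_genes = 60, n_samples = 40), seed = 1)
#' mat <- preprocess_expression(sim$matrix)
#' head(rank_correlates(mat, "MMP14"))
#' @export
rank_correlates <- function(matrix_tbl, target_gene) {
  m <- expr_to_matrix(matrix_tbl)
  if (!target_gene %in% rownames(m)) {
    abort(paste0("target gene `", target_gene,
                 "` absent from the (filtered) matrix."))
  }
  target <- m[target_gene, ]
  rho <- apply(m, 1L, function(g) suppressWarnings(
    cor(g, target, method = "spearman")))
  tibble(gene = rownames(m), rho = unname(rho)) |>
    filter(.data$gene != target_gene) |>
    arrange(desc(.data$rho)) |>
    mutate(rho_rank = row_number())
}

#' Median-split differential expression against a target gene
#'
#' Splits samples at the median expression of the target gene (ties at the
#' median go to the low group), then for every other gene computes the log2
#' fold change of shifted group means (high vs low), a two-sided Wilcoxon
#' rank-sum p-value, and Benjamini-Hochberg FDR q-values over all tested
#' genes; genes are ranked by decreasing log2 fold change.
#'
#' @inheritParams rank_correlates
#' @param test `"wilcoxon"` (default) rank-sum test for the per-gene p-value.
#' @return Tibble `gene`, `log2fc`, `p`, `q`, `fc_rank` (target excluded).
#' @export
differential_expression <- function(matrix_tbl, target_gene,
                                    test = c("wilcoxon")) {
  test <- match.arg(test)
  m <- expr_to_matrix(matrix_tbl)
  if (!target_gene %in% rownames(m)) {
    abort(paste0("target gene `", target_gene,
                 "` absent from the (filtered) matrix."))
  }
  tgt <- m[target_gene, ]
  low <- tgt <= median(tgt)
  if (sum(low) < 2 || sum(!low) < 2) {
    abort("degenerate median split: need at least two samples per group.")
  }
  others <- setdiff(rownames(m), target_gene)
  hi <- m[others, !low, drop = FALSE]
  lo <- m[others, low, drop = FALSE]
  log2fc <- log2(rowMeans(hi) / rowMeans(lo))
  p <- vapply(seq_along(others), function(i) {
    suppressWarnings(wilcox.test(hi[i, ], lo[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  tibble(gene = others, log2fc = unname(log2fc), p = p,
         q = p.adjust(p, method = "BH")) |>
    arrange(desc(.data$log2fc)) |>
    mutate(fc_rank = row_number())
}

#' Full target-gene co-expression screen
#'
#' Combines [rank_correlates()] and [differential_expression()] into one
#' per-gene result table.
#'
#' @inheritParams rank_correlates
#' @return Tibble `gene`, `rho`, `rho_rank`, `log2fc`, `p`, `q`, `fc_rank`,
#'   sorted by `rho_rank`.
#' @export
screen_target <- function(matrix_tbl, target_gene) {
  left_join(rank_correlates(matrix_tbl, target_gene),
            differential_expression(matrix_tbl, target_gene),
            by = "gene")
}
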