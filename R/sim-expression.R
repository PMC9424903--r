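#' Parameters for simulating a bulk expression matrix with planted structure
#'
#' The generator emulates a normalized RNA-seq matrix (genes x samples, RSEM-
#' style non-negative values) in which a configurable number of genes share a
#' latent factor with a named target gene, a further fraction of genes is
#' expressed below the low-expression filter threshold, and the remainder are
#' independent noise.
#'
#' @param n_genes Total genes simulated.
#' @param n_samples Samples (default 592, a colorectal-adenocarcinoma-cohort
#'   scale).
#' @param target_gene Name of the target gene (default "MMP14").
#' @param n_correlated Genes planted as co-expressed with the target.
#' @param rho_target Latent-scale correlation between each planted gene and
#'   the target, in [0, 1].
#' @param low_expression_fraction Fraction of genes simulated below the
#'   1.5-expression threshold in essentially all samples.
#' @return List of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_genes = 2000L, n_samples = 592L,
                                  target_gene = "MMP14",
                                  n_correlated = 20L, rho_target = 0.7,
                                  low_expression_fraction = 0.3) {
  if (n_correlated < 0 || n_correlated > n_genes - 1) {
    abort("`n_correlated` must lie in [0, n_genes - 1].")
  }
  if (rho_target < 0 || rho_target > 1) abort("`rho_target` must lie in [0, 1].")
  if (low_expression_fraction < 0 || low_expression_fraction > 1) {
    abort("`low_expression_fraction` must lie in [0, 1].")
  }
  if (!nzchar(target_gene)) abort("`target_gene` must be a non-empty name.")
  structure(as.list(environment()), class = "expression_sim_params")
}

#' Simulate an expression cohort with planted target-gene correlates
#'
#' Samples draw a latent factor z; the target gene is a log-normal transform
#' of z, each planted correlate is `rho_target * z` plus independent noise on
#' the log scale (so the latent correlation with the target is exactly
#' `rho_target`, and rank correlations survive the monotone transform), low
#' genes are log-normal with a small mean so they fail the 1.5 filter, and
#' all other genes are independent log-normal noise.
#'
#' @param params An [expression_sim_params()] object.
#' @param seed Integer seed.
#' @return List of class `expression_sim` with `matrix` (tibble: `gene`
#'   column plus one column per sample, raw non-negative values),
#'   `correlated_genes` and `low_genes` (character ground truth).
#' @examples
#' sim <- simulate_expression(expression_sim_params(n_genes = 100, n_samples = 50), seed = 3)
#' dim(sim$matrix)
#' @export
simulate_expression <- function(params = expression_sim_params(), seed = 1L) {
  stopifnot(inherits(params, "expression_sim_params"))
  set.seed(seed)
  ng <- params$n_genes; ns <- params$n_samples
  n_low <- round(params$low_expression_fraction * ng)
  n_cor <- params$n_correlated
  n_noise <- ng - 1L - n_cor - n_low
  if (n_noise < 0) abort("n_genes too small for the requested correlated + low genes.")

  genes <- c(params$target_gene,
             sprintf("CORG%04d", seq_len(n_cor)),
             sprintf("GENE%04d", seq_len(n_noise)),
             sprintf("LOWG%04d", seq_len(n_low)))

  z <- rnorm(ns)
  rho <- params$rho_target
  rows <- matrix(0, nrow = ng, ncol = ns, dimnames = list(genes, NULL))
  rows[1, ] <- exp(1.5 + 1.0 * z)
  if (n_cor > 0) {
    mu <- runif(n_cor, 1, 3)
    lat <- rho * matrix(z, n_cor, ns, byrow = TRUE) +
      sqrt(1 - rho^2) * matrix(rnorm(n_cor * ns), n_cor, ns)
    rows[1L + seq_len(n_cor), ] <- exp(mu + 0.8 * lat)
  }
  if (n_noise > 0) {
    mu <- runif(n_noise, 0.8, 3.5)
    rows[1L + n_cor + seq_len(n_noise), ] <-
      exp(mu + 0.8 * matrix(rnorm(n_noise * ns), n_noise, ns))
  }
  if (n_low > 0) {
    rows[1L + n_cor + n_noise + seq_len(n_low), ] <-
      exp(matrix(rnorm(n_low * ns, -2.2, 0.5), n_low, ns))
  }
  colnames(rows) <- sprintf("S%04d", seq_len(ns))
  mat <- bind_cols(tibble(gene = genes), as_tibble(rows))
  structure(list(matrix = mat,
                 correlated_genes = genes[1L + seq_len(n_cor)],
                 low_genes = if (n_low > 0) genes[1L + n_cor + n_noise + seq_len(n_low)] else character()),
            class = "expression_sim")
}
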