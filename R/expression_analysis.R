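#' Spearman correlation of every gene with a miRNA expression vector
#'
#' Missing samples are dropped pairwise per gene; a gene with fewer than 3
#' overlapping samples gets `NA`. Ties are handled by average ranks (the
#' behaviour of `stats::cor(method = "spearman")`).
#'
#' @param mirna_vector named numeric vector (names = sample ids).
#' @param gene_matrix numeric matrix, rows = genes, columns = samples;
#'   column names must cover the miRNA vector's samples.
#' @return named numeric vector of per-gene Spearman rho.
#' @export
spearman_profile <- function(mirna_vector, gene_matrix) {
  if (is.null(colnames(gene_matrix)) || is.null(names(mirna_vector))) {
    if (ncol(gene_matrix) != length(mirna_vector)) {
      stop("unnamed inputs must have matching sample order/length")
    }
    samples <- seq_along(mirna_vector)
    gm <- gene_matrix
    mv <- mirna_vector
  } else {
    samples <- intersect(colnames(gene_matrix), names(mirna_vector))
    if (length(samples) < 3L) stop("fewer than 3 shared samples")
    gm <- gene_matrix[, samples, drop = FALSE]
    mv <- mirna_vector[samples]
  }
  apply(gm, 1L, function(g) {
    ok <- !is.na(g) & !is.na(mv)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(g[ok], mv[ok], method = "spearman")
  })
}

#' Random-gene null distribution of correlations
#'
#' Draws `n_draws` random gene sets of size `n_genes_per_draw` (without
#' replacement within a draw) and records their Spearman correlations with
#' the miRNA vector. Genes listed in `exclude` (e.g. the miRNA's own
#' predicted targets) are removed from the pool first.
#'
#' @param n_genes_per_draw genes per draw (the size of the target set being
#'   mimicked).
#' @param gene_matrix numeric matrix, rows = genes.
#' @param mirna_vector named numeric vector.
#' @param n_draws number of resamples (default 1000).
#' @param rng_seed integer seed; identical seeds give identical nulls.
#' @param exclude character vector of gene ids to drop from the pool.
#' @return list with `rhos` (numeric vector, `n_draws * n_genes_per_draw`
#'   values), `draw` (draw index per value).
#' @export
random_gene_null <- function(n_genes_per_draw, gene_matrix, mirna_vector,
                             n_draws = 1000L, rng_seed = 1L,
                             exclude = character()) {
  if (n_draws < 1L) stop("n_draws must be >= 1")
  pool <- setdiff(rownames(gene_matrix), exclude)
  if (n_genes_per_draw > length(pool)) {
    stop("draw size exceeds the gene pool (", length(pool), ")")
  }
  # rho per gene does not depend on the draw, so compute once and resample
  all_rho <- spearman_profile(mirna_vector,
                              gene_matrix[pool, , drop = FALSE])
  set.seed(rng_seed)
  idx <- replicate(n_draws, sample.int(length(pool), n_genes_per_draw))
  rhos <- all_rho[as.vector(idx)]
  list(rhos = unname(rhos),
       draw = rep(seq_len(n_draws), each = n_genes_per_draw))
}

#' Compare target correlations with a null
#'
#' Two-sided Wilcoxon rank-sum test of the target-group rho values against
#' the resampled null, with medians and direction.
#'
#' @param target_rhos numeric vector of target-gene correlations.
#' @param null_rhos numeric vector of null correlations.
#' @return list with `p_value`, `median_target`, `median_null`,
#'   `direction` (`"more_negative"` / `"more_positive"` / `"tie"`),
#'   `low_power` flag when either group has < 3 values.
#' @export
compare_rho_groups <- function(target_rhos, null_rhos) {
  target_rhos <- target_rhos[!is.na(target_rhos)]
  null_rhos <- null_rhos[!is.na(null_rhos)]
  if (length(target_rhos) == 0L || length(null_rhos) == 0L) {
    stop("empty group")
  }
  p <- suppressWarnings(
    stats::wilcox.test(target_rhos, null_rhos, exact = FALSE)$p.value)
  mt <- stats::median(target_rhos); mn <- stats::median(null_rhos)
  list(p_value = p, median_target = mt, median_null = mn,
       direction = if (mt < mn) "more_negative"
                   else if (mt > mn) "more_positive" else "tie",
       low_power = length(target_rhos) < 3L || length(null_rhos) < 3L)
}

#' Transfection shift test
#'
#' One-sided Mann-Whitney-Wilcoxon test of the target genes' fold changes
#' against control genes. `direction = "down"` is the over-expression
#' hypothesis (targets repressed, shifted to lower logFC);
#' `direction = "up"` the knock-down hypothesis. Genes present in both sets
#' are removed from the control with a warning.
#'
#' @param fold_changes named numeric vector of per-gene log fold changes.
#' @param target_set,control_set character vectors of gene ids.
#' @param direction `"down"` or `"up"`.
#' @return list with `p_value`, `direction`, `median_shift` (target median
#'   minus control median), `n_target`, `n_control`.
#' @export
transfection_shift_test <- function(fold_changes, target_set, control_set,
                                    direction = c("down", "up")) {
  direction <- match.arg(direction)
  overlap <- intersect(target_set, control_set)
  if (length(overlap) > 0L) {
    warning(length(overlap), " gene(s) in both sets removed from control")
    control_set <- setdiff(control_set, overlap)
  }
  ft <- fold_changes[intersect(target_set, names(fold_changes))]
  fc <- fold_changes[intersect(control_set, names(fold_changes))]
  if (length(ft) == 0L || length(fc) == 0L) stop("empty group after matching")
  alt <- if (direction == "down") "less" else "greater"
  p <- suppressWarnings(
    stats::wilcox.test(ft, fc, alternative = alt, exact = FALSE)$p.value)
  list(p_value = p, direction = direction,
       median_shift = stats::median(ft) - stats::median(fc),
       n_target = length(ft), n_control = length(fc))
}
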