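#' Read a gene expression table
#'
#' TSV with a header and columns `gene_id` and `rpkm`. Values must be
#' finite and non-negative; gene ids must be unique.
#'
#' @param path TSV file path.
#' @return A named numeric vector of RPKM values keyed by gene id.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "numeric"))
  if (!all(c("gene_id", "rpkm") %in% names(tab)))
    stop("expression table must have columns gene_id and rpkm")
  expression_table(stats::setNames(tab$rpkm, tab$gene_id))
}

#' Validate a named expression vector
#' @param values named numeric vector (RPKM, non-negative, finite).
#' @return The validated vector.
#' @export
expression_table <- function(values) {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("expression values must be uniquely named by gene id")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  values
}

#' Write an expression table as TSV
#' @param values named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path) {
  utils::write.table(
    data.frame(gene_id = names(values),
               rpkm = format(values, digits = 17, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-component correlation between FPC scores and gene expression
#'
#' For each retained component, Pearson correlation between the score
#' column and expression over the region ids shared between the fit and the
#' expression table, with a two-sided t-test p-value. Significance is
#' assessed per component at `alpha` (no multiplicity correction across
#' components).
#'
#' @param result a fitted [fpca()] object.
#' @param expr named expression vector (see [expression_table()]).
#' @param alpha per-component significance threshold, default `1e-6`.
#' @param log2_transform if `TRUE`, correlate against `log2(rpkm + 1)`
#'   instead of raw RPKM. Off by default.
#' @return data.frame with columns `component`, `r`, `p`, `significant`,
#'   plus attribute `n_shared`.
#' @export
score_expression_correlation <- function(result, expr, alpha = 1e-6,
                                         log2_transform = FALSE) {
  shared <- intersect(result$region_ids, names(expr))
  n <- length(shared)
  if (n < 3) stop("need at least 3 region ids shared with expression table")
  S <- result$scores[match(shared, result$region_ids), , drop = FALSE]
  y <- unname(expr[shared])
  if (log2_transform) y <- log2(y + 1)
  r <- drop(stats::cor(S, y))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(component = seq_len(result$J), r = r, p = p,
                    significant = p <= alpha)
  attr(out, "n_shared") <- n
  out
}

# equal-count quantile assignment: ties broken by position (stable order),
# remainder spread over the lowest bins
quantile_bins <- function(score, n_quantiles) {
  n <- length(score)
  sizes <- rep(n %/% n_quantiles, n_quantiles)
  rem <- n %% n_quantiles
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  if (any(sizes < 2)) stop("quantile with fewer than 2 members")
  bin <- rep(seq_len(n_quantiles), times = sizes)
  ord <- order(score) # stable: ties keep region order
  out <- integer(n)
  out[ord] <- bin
  out
}

#' Expression contrast between extreme score quantiles
#'
#' Ranks the shared regions by the score of one component, cuts them into
#' `n_quantiles` equal-count bins (Q1 = lowest scores), and contrasts gene
#' expression between the lowest and highest bins. The primary statistic is
#' a Welch two-sample t-test; a rank-paired variant (pairing the i-th order
#' statistic of Q1 with the i-th of Q10 after truncation to equal length)
#' is also reported.
#'
#' @param result a fitted [fpca()] object.
#' @param expr named expression vector.
#' @param component component whose scores define the ranking.
#' @param n_quantiles number of equal-count bins; default 10.
#' @return A list with `component`, `n_quantiles`, `n_per_quantile`,
#'   `mean_q1`, `mean_qn`, `median_q1`, `median_qn`, `p_welch`,
#'   `p_paired_rank` and the two expression vectors `expr_q1`, `expr_qn`.
#' @export
quantile_expression_test <- function(result, expr, component,
                                     n_quantiles = 10) {
  if (component > result$J) stop("component exceeds J")
  shared <- intersect(result$region_ids, names(expr))
  score <- result$scores[match(shared, result$region_ids), component]
  y <- unname(expr[shared])
  bin <- quantile_bins(score, n_quantiles)
  y1 <- y[bin == 1]
  yn <- y[bin == n_quantiles]
  p_welch <- if (stats::sd(y1) == 0 && stats::sd(yn) == 0 &&
                 mean(y1) == mean(yn)) 1 else
    stats::t.test(y1, yn)$p.value
  m <- min(length(y1), length(yn))
  d <- sort(yn)[seq_len(m)] - sort(y1)[seq_len(m)]
  p_paired <- if (stats::sd(d) == 0) {
    if (mean(d) == 0) 1 else 0
  } else stats::t.test(d)$p.value
  list(component = component, n_quantiles = n_quantiles,
       n_per_quantile = as.vector(table(bin)),
       mean_q1 = mean(y1), mean_qn = mean(yn),
       median_q1 = stats::median(y1), median_qn = stats::median(yn),
       p_welch = p_welch, p_paired_rank = p_paired,
       expr_q1 = y1, expr_qn = yn)
}

#' Compare one score quantile's expression between two datasets
#'
#' Selects the gene set falling in quantile `quantile_index` of the given
#' component for each of two fits, then contrasts the two sets' expression
#' values (Welch two-sample t-test; `p = 1` by convention when the sets are
#' identical) and reports the Jaccard overlap of the sets as a diagnostic.
#'
#' @param resA,resB fitted [fpca()] objects.
#' @param expr named expression vector.
#' @param component component whose scores define the ranking.
#' @param quantile_index which quantile to compare (1 = lowest).
#' @param n_quantiles number of equal-count bins; default 10.
#' @return A list with `p_welch`, `jaccard`, `n_A`, `n_B`, `mean_A`,
#'   `mean_B` and the two id sets.
#' @export
cross_mark_quantile_comparison <- function(resA, resB, expr, component,
                                           quantile_index,
                                           n_quantiles = 10) {
  pick <- function(res) {
    shared <- intersect(res$region_ids, names(expr))
    score <- res$scores[match(shared, res$region_ids), component]
    bin <- quantile_bins(score, n_quantiles)
    shared[bin == quantile_index]
  }
  ids_A <- pick(resA)
  ids_B <- pick(resB)
  yA <- unname(expr[ids_A])
  yB <- unname(expr[ids_B])
  p <- if (setequal(ids_A, ids_B)) 1 else stats::t.test(yA, yB)$p.value
  list(p_welch = p,
       jaccard = length(intersect(ids_A, ids_B)) /
         length(union(ids_A, ids_B)),
       n_A = length(ids_A), n_B = length(ids_B),
       mean_A = mean(yA), mean_B = mean(yB),
       ids_A = ids_A, ids_B = ids_B)
}
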