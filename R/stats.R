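#' @include utils.R
NULL

#' One-sided hypergeometric enrichment test
#'
#' Upper-tail probability P[X >= k] of drawing k or more members of a
#' category of size K in a sample of size n from a population of size N.
#' Computed in log space; no underflow for p >= 1e-300.
#'
#' @param k successes in the sample.
#' @param n sample size.
#' @param K successes in the population.
#' @param N population size.
#' @param log10p also return log10 of the p value.
#' @return list: \code{p}, \code{log10p}.
#' @export
hypergeomEnrichment <- function(k, n, K, N, log10p = TRUE) {
  if (k < 0 || n > N || K > N || k > min(n, K))
    stop("invalid contingency: need 0 <= k <= min(n, K), n <= N, K <= N")
  lp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  list(p = exp(lp), log10p = lp / log(10))
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @return list: \code{t}, \code{df}, \code{p}.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 observations")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up adjustment with monotone enforcement; order-preserving.
#'
#' @param pvals numeric vector of p values.
#' @return adjusted p values, same order as input.
#' @export
benjaminiHochberg <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Differential binding between two library groups (stand-in model)
#'
#' A self-contained stand-in for gene-level differential binding (not a
#' negative-binomial GLM; raw count matrices can be exported with
#' \code{\link{writeCountMatrix}} for external tools): per gene, counts are
#' normalized to counts per million of library unique events, log2 fold
#' change of group means uses a pseudo-count of 0.5, and the p value is an
#' exact binomial test of the pooled group-A count against the pooled total
#' at the library-size-implied proportion. P values are BH-adjusted. A gene
#' is "enriched" at adjusted p < \code{adj_p_threshold} with positive
#' log2FC, and "strongly bound" above \code{strong_binding_log2fc}.
#'
#' @param counts gene x library numeric matrix of raw counts.
#' @param groupA,groupB column names or indices of the two groups.
#' @param params \code{\link{pipelineParams}}.
#' @param lib_sizes optional named library sizes; default column sums.
#' @return data.frame per gene: \code{log2fc}, \code{p}, \code{adj_p},
#'   \code{enriched}, \code{strongly_bound}.
#' @export
differentialBindingStandin <- function(counts, groupA, groupB,
                                       params = pipelineParams(),
                                       lib_sizes = NULL) {
  A <- counts[, groupA, drop = FALSE]
  B <- counts[, groupB, drop = FALSE]
  if (!ncol(A) || !ncol(B)) stop("both groups must contain >= 1 library")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  szA <- lib_sizes[groupA]; szB <- lib_sizes[groupB]
  cpmA <- rowMeans(sweep(A, 2L, szA, "/")) * 1e6
  cpmB <- rowMeans(sweep(B, 2L, szB, "/")) * 1e6
  log2fc <- log2((cpmA + 0.5) / (cpmB + 0.5))
  pA <- sum(szA) / (sum(szA) + sum(szB))
  totA <- rowSums(A); tot <- totA + rowSums(B)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    if (tot[i] == 0) return(1)
    stats::binom.test(round(totA[i]), round(tot[i]), p = pA)$p.value
  }, numeric(1))
  adj <- benjaminiHochberg(p)
  data.frame(log2fc = log2fc, p = p, adj_p = adj,
             enriched = adj < params$adj_p_threshold & log2fc > 0,
             strongly_bound = log2fc > params$strong_binding_log2fc,
             row.names = rownames(counts))
}
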