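#' Boundary likelihood-ratio test p-value
#'
#' For nested count models whose extra parameter sits on the boundary of its
#' space under the null (dispersion 0 for Poisson-vs-NB, zero mass 0 for
#' NB-vs-ZINB), the LRT statistic is asymptotically distributed as an equal
#' mixture of a point mass at 0 and a chi-square with 1 degree of freedom.
#' The statistic is clamped at 0 (small negative differences can arise from
#' numerical likelihood maximization), where the p-value is 0.5.
#'
#' @param loglik_null log-likelihood of the simpler model.
#' @param loglik_alt log-likelihood of the richer model.
#' @return p-value(s); `NA` where either log-likelihood is missing.
#' @export
boundary_lrt_pvalue <- function(loglik_null, loglik_alt) {
  d <- pmax(0, 2 * (loglik_alt - loglik_null))
  p <- ifelse(d > 0, 0.5 * stats::pchisq(d, df = 1, lower.tail = FALSE), 0.5)
  p[is.na(loglik_null) | is.na(loglik_alt)] <- NA_real_
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; missing p-values are passed through as missing.
#'
#' @param pvalues vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Backward model selection per gene: ZINB vs NB, then NB vs Poisson
#'
#' Fits Poisson, NB, and ZINB models to every gene detected in at least
#' `min_nonzero_cells` cells, then selects the simplest adequate model in two
#' stages. Stage 1 tests ZINB against NB with the boundary LRT; BH-adjusted
#' q-values below `alpha` select ZINB. Stage 2, run only on the genes that did
#' not reject NB, tests NB against Poisson the same way; q-values below
#' `alpha` select NB, the rest select Poisson. Genes whose fitted likelihoods
#' violate the nesting order by more than `delta` (L(Poisson) > L(NB) + delta
#' or L(NB) > L(ZINB) + delta) are labeled unconverged and excluded from both
#' BH pools.
#'
#' @param matrix a [count_matrix()].
#' @param alpha FDR level for both stages (default 0.05).
#' @param delta numerical slack allowed in the likelihood ordering
#'   (default 0.5).
#' @param min_nonzero_cells detection filter applied before fitting
#'   (default 5).
#' @return a data.frame with one row per tested gene: the three
#'   log-likelihoods, convergence flag, stage p- and q-values, and the
#'   selected family. A named-count `summary` attribute mirrors the usual
#'   reporting (genes tested/converged, counts per family, percent Poisson).
#' @export
select_models <- function(matrix, alpha = 0.05, delta = 0.5,
                          min_nonzero_cells = 5L) {
  matrix <- filter_genes(count_matrix(matrix), min_nonzero_cells)
  n_genes <- nrow(matrix)
  if (n_genes == 0L) {
    out <- data.frame(gene_id = character(), loglik_poisson = numeric(),
                      loglik_nb = numeric(), loglik_zinb = numeric(),
                      converged = logical(), p_zinb_vs_nb = numeric(),
                      q_zinb_vs_nb = numeric(), p_nb_vs_poisson = numeric(),
                      q_nb_vs_poisson = numeric(), selected = character(),
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- c(n_tested = 0, n_converged = 0, zinb = 0, nb = 0,
                              poisson = 0, pct_poisson = NaN)
    return(out)
  }
  ll_p <- ll_n <- ll_z <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    y <- unclass(matrix)[g, ]
    ll_p[g] <- fit_poisson(y)$loglik
    ll_n[g] <- fit_nb(y)$loglik
    ll_z[g] <- fit_zinb(y)$loglik
  }
  # convergence by the likelihood-ordering criterion with slack delta
  converged <- (ll_p <= ll_n + delta) & (ll_n <= ll_z + delta)

  p1 <- rep(NA_real_, n_genes)
  p1[converged] <- boundary_lrt_pvalue(ll_n[converged], ll_z[converged])
  q1 <- rep(NA_real_, n_genes)
  q1[converged] <- bh_fdr(p1[converged])

  selected <- rep("unconverged", n_genes)
  sel_zinb <- converged & !is.na(q1) & q1 < alpha
  selected[sel_zinb] <- "zinb"

  stage2 <- converged & !sel_zinb  # genes that did not reject the NB model
  p2 <- rep(NA_real_, n_genes)
  p2[stage2] <- boundary_lrt_pvalue(ll_p[stage2], ll_n[stage2])
  q2 <- rep(NA_real_, n_genes)
  q2[stage2] <- bh_fdr(p2[stage2])
  selected[stage2] <- ifelse(q2[stage2] < alpha, "nb", "poisson")

  out <- data.frame(gene_id = rownames(matrix), loglik_poisson = ll_p,
                    loglik_nb = ll_n, loglik_zinb = ll_z,
                    converged = converged, p_zinb_vs_nb = p1,
                    q_zinb_vs_nb = q1, p_nb_vs_poisson = p2,
                    q_nb_vs_poisson = q2, selected = selected,
                    stringsAsFactors = FALSE)
  n_pois <- sum(selected == "poisson")
  attr(out, "summary") <- c(n_tested = n_genes, n_converged = sum(converged),
                            zinb = sum(selected == "zinb"),
                            nb = sum(selected == "nb"), poisson = n_pois,
                            pct_poisson = 100 * n_pois / n_genes)
  out
}
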