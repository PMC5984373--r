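#' Build count-value bins for the chi-square goodness-of-fit test
#'
#' Each unique observed count value starts as its own bin. Scanning from the
#' bin with the largest value downward, any bin holding no more than
#' `min_cells` cells is merged into the next smaller-valued bin; merging
#' continues until the scan completes. After merging, every bin except
#' possibly the smallest-valued one holds more than `min_cells` cells (a
#' sparse remainder at the bottom of the scan is left as-is).
#'
#' @param y non-negative integer count vector.
#' @param min_cells occupancy threshold below which bins are merged
#'   (default 5).
#' @return a data.frame of class `binning` with columns `lo`, `hi` (inclusive
#'   count-value range) and `observed` (cells in the bin), ordered by
#'   increasing value; attribute `k` holds the number of bins.
#' @export
build_bins <- function(y, min_cells = 5L) {
  y <- check_counts(y)
  tab <- table(y)
  vals <- rev(as.numeric(names(tab)))   # largest value first
  cnts <- rev(as.numeric(tab))
  lo <- hi <- obs <- numeric(0)
  acc <- 0; acc_hi <- NA_real_
  for (i in seq_along(vals)) {
    if (acc == 0) acc_hi <- vals[i]
    acc <- acc + cnts[i]
    if (acc > min_cells) {
      lo <- c(lo, vals[i]); hi <- c(hi, acc_hi); obs <- c(obs, acc)
      acc <- 0
    }
  }
  if (acc > 0) {  # sparse remainder at the smallest values
    lo <- c(lo, vals[length(vals)]); hi <- c(hi, acc_hi); obs <- c(obs, acc)
  }
  out <- data.frame(lo = rev(lo), hi = rev(hi), observed = rev(obs))
  class(out) <- c("binning", "data.frame")
  attr(out, "k") <- nrow(out)
  out
}

# cdf of a fitted count model at integer points
model_cdf <- function(fit) {
  if (fit$family == "poisson" || fit$dispersion == 0) {
    base <- function(q) stats::ppois(q, fit$mean)
  } else {
    base <- function(q) stats::pnbinom(q, size = 1 / fit$dispersion,
                                       mu = fit$mean)
  }
  if (fit$family == "zinb" && fit$zero_mass > 0) {
    pi0 <- fit$zero_mass
    function(q) ifelse(q < 0, 0, pi0 + (1 - pi0) * base(q))
  } else base
}

# pmf of a fitted count model at integer points
model_pmf <- function(fit) {
  if (fit$family == "poisson" || fit$dispersion == 0) {
    base <- function(x) stats::dpois(x, fit$mean)
  } else {
    base <- function(x) stats::dnbinom(x, size = 1 / fit$dispersion,
                                       mu = fit$mean)
  }
  if (fit$family == "zinb" && fit$zero_mass > 0) {
    pi0 <- fit$zero_mass
    function(x) (1 - pi0) * base(x) + pi0 * (x == 0)
  } else base
}

#' Expected bin probabilities under a fitted count model
#'
#' The lowest bin absorbs any model mass below the smallest observed value
#' and the highest bin absorbs the upper tail, so the probabilities form a
#' proper distribution (sum exactly 1).
#'
#' @param fit a `model_fit` (Poisson or NB; a ZINB mixture is also accepted).
#' @param binning a [build_bins()] result.
#' @return numeric vector of bin probabilities.
#' @export
expected_bin_probs <- function(fit, binning) {
  k <- nrow(binning)
  cdf <- model_cdf(fit)
  if (k == 1L) return(1)
  upper <- cdf(binning$hi[-k])
  probs <- c(upper[1L], diff(upper), 1 - upper[k - 1L])
  probs
}

#' Chi-square goodness-of-fit test for one gene
#'
#' Pearson's statistic on merged count-value bins, with degrees of freedom
#' `k - p - 1` where `k` is the number of bins and `p` the number of fitted
#' model parameters (1 for Poisson, 2 for NB, so df is `k - 2` and `k - 3`
#' respectively). Genes whose binning leaves fewer than 1 degree of freedom
#' (e.g. counts taking only the values 0 and 1) are skipped rather than
#' tested.
#'
#' @param y non-negative integer count vector the model was fitted to.
#' @param fit the fitted `model_fit`.
#' @param min_cells bin-merging threshold passed to [build_bins()].
#' @return one-row data.frame: `family`, `k`, `p_model`, `df`, `statistic`,
#'   `p`, `decision` (`"tested"` or `"skipped"`).
#' @export
chisq_gof <- function(y, fit, min_cells = 5L) {
  y <- check_counts(y)
  binning <- build_bins(y, min_cells)
  k <- nrow(binning)
  p_model <- fit$n_params
  df <- k - p_model - 1L
  rec <- data.frame(family = fit$family, k = k, p_model = p_model, df = df,
                    statistic = NA_real_, p = NA_real_, decision = "skipped",
                    stringsAsFactors = FALSE)
  if (df < 1L || !fit$converged) return(rec)
  probs <- expected_bin_probs(fit, binning)
  if (any(probs <= 0)) return(rec)  # statistic undefined on empty-mass bins
  expected <- length(y) * probs
  rec$statistic <- sum((binning$observed - expected)^2 / expected)
  rec$p <- stats::pchisq(rec$statistic, df = df, lower.tail = FALSE)
  rec$decision <- "tested"
  rec
}

#' Goodness-of-fit pipeline over a count matrix
#'
#' Down-samples all cells to a common depth (the `depth_quantile` quantile of
#' the per-cell totals, dropping cells below it), keeps genes detected in at
#' least `min_nonzero_cells` cells, fits Poisson and NB models to each gene,
#' runs the binned chi-square test for both families, and adjusts p-values by
#' Benjamini-Hochberg within each family. A model is rejected for a gene when
#' its q-value falls below `alpha`.
#'
#' @param matrix a [count_matrix()].
#' @param alpha FDR level (default 0.05).
#' @param seed integer seed for the down-sampling draw.
#' @param depth_quantile target-depth quantile (default 0.10).
#' @param min_nonzero_cells post-down-sampling detection filter (default 6,
#'   i.e. non-zero in more than five cells).
#' @param min_cells bin-merging threshold (default 5).
#' @return a data.frame with one row per gene and family, including q-values
#'   and accept/reject/skipped decisions; a `summary` attribute reports the
#'   counts usually quoted (genes tested, rejections per family, percent
#'   accepting Poisson, percent rejecting NB).
#' @export
run_gof <- function(matrix, alpha = 0.05, seed, depth_quantile = 0.10,
                    min_nonzero_cells = 6L, min_cells = 5L) {
  matrix <- count_matrix(matrix)
  down <- downsample_cells(matrix, depth_quantile, seed = seed)
  down <- filter_genes(down, min_nonzero_cells)
  recs <- vector("list", nrow(down))
  for (g in seq_len(nrow(down))) {
    y <- unclass(down)[g, ]
    fp <- fit_poisson(y)
    fn <- fit_nb(y)
    rp <- chisq_gof(y, fp, min_cells)
    rn <- chisq_gof(y, fn, min_cells)
    recs[[g]] <- cbind(gene_id = rownames(down)[g], rbind(rp, rn))
  }
  out <- do.call(rbind, recs)
  out$q <- NA_real_
  for (fam in c("poisson", "nb")) {
    idx <- out$family == fam & out$decision == "tested"
    out$q[idx] <- bh_fdr(out$p[idx])
  }
  out$decision[out$decision == "tested"] <-
    ifelse(out$q[out$decision == "tested"] < alpha, "reject", "accept")
  n_tested <- sum(out$family == "poisson" & out$decision != "skipped")
  rej_p <- sum(out$family == "poisson" & out$decision == "reject")
  rej_n <- sum(out$family == "nb" & out$decision == "reject")
  attr(out, "summary") <- c(
    genes_tested = n_tested, reject_poisson = rej_p, reject_nb = rej_n,
    pct_accept_poisson = 100 * (n_tested - rej_p) / n_tested,
    pct_reject_nb = 100 * rej_n / n_tested)
  rownames(out) <- NULL
  out
}

#' Empirical versus theoretical pmf and cdf for one gene
#'
#' Tabulates, for every count value from 0 to the observed maximum, the
#' empirical frequency and the fitted model's probability, together with
#' their cumulative versions; the usual input for overlay plots of fit
#' quality.
#'
#' @param y non-negative integer count vector.
#' @param fit the fitted `model_fit`.
#' @return data.frame with columns `value`, `empirical_pmf`,
#'   `theoretical_pmf`, `empirical_cdf`, `theoretical_cdf`.
#' @export
empirical_vs_theoretical <- function(y, fit) {
  y <- check_counts(y)
  v <- 0:max(y)
  emp <- as.numeric(tabulate(y + 1L, nbins = length(v))) / length(y)
  pmf <- model_pmf(fit)(v)
  data.frame(value = v, empirical_pmf = emp, theoretical_pmf = pmf,
             empirical_cdf = cumsum(emp), theoretical_cdf = model_cdf(fit)(v))
}
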