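#' Realized false discovery rate against simulation truth
#'
#' Genes with `q < alpha` are called differentially expressed; the realized
#' FDR is the fraction of calls absent from the truth set (0 when nothing is
#' called).
#'
#' @param qvalues named vector of q-values (names are gene identifiers;
#'   missing values are never called).
#' @param truth a `sim_truth` (or any list with a `de_genes` character
#'   vector).
#' @param alpha call threshold (default 0.05).
#' @return list with `fdr`, `n_false`, `n_called`.
#' @export
realized_fdr <- function(qvalues, truth, alpha = 0.05) {
  if (is.null(names(qvalues))) stop("qvalues must be named by gene")
  called <- names(qvalues)[!is.na(qvalues) & qvalues < alpha]
  n_called <- length(called)
  n_false <- sum(!(called %in% truth$de_genes))
  list(fdr = if (n_called == 0) 0 else n_false / n_called,
       n_false = n_false, n_called = n_called)
}

#' Precision-recall curve against simulation truth
#'
#' Sweeps the call threshold over the sorted p-values; tied p-values enter
#' and leave the call set together, so the curve is a step function over
#' distinct p-values. Genes with missing p-values are never called but still
#' count in the recall denominator.
#'
#' @param pvalues named vector of p-values.
#' @param truth a `sim_truth` (or any list with a `de_genes` character
#'   vector).
#' @return object of class `pr_curve`: `precision`, `recall`, `thresholds`,
#'   `n_true`.
#' @export
pr_curve <- function(pvalues, truth) {
  if (is.null(names(pvalues))) stop("pvalues must be named by gene")
  n_true <- length(truth$de_genes)
  if (n_true == 0L) stop("truth contains no DE genes")
  p <- pvalues[!is.na(pvalues)]
  ord <- order(p)
  p <- p[ord]
  is_true <- names(p) %in% truth$de_genes
  cum_tp <- cumsum(is_true)
  n_called <- seq_along(p)
  last <- !duplicated(p, fromLast = TRUE)   # one point per distinct p-value
  structure(list(precision = cum_tp[last] / n_called[last],
                 recall = cum_tp[last] / n_true,
                 thresholds = p[last], n_true = n_true),
            class = "pr_curve")
}

#' Area under the precision-recall curve above a precision floor
#'
#' Trapezoidal area over recall, counting only the parts of the curve with
#' precision above `precision_floor` (precision 0.8 corresponds to FDR 0.2);
#' segments crossing the floor are clipped at the crossing point. A perfect
#' method (precision 1 up to recall 1) scores 1; a curve never exceeding the
#' floor scores 0. The curve is anchored at recall 0 with its first
#' precision value.
#'
#' @param curve a [pr_curve()].
#' @param precision_floor precision cutoff (default 0.8).
#' @return the restricted area, a number in `[0, 1]`.
#' @export
auc_restricted <- function(curve, precision_floor = 0.8) {
  r <- c(0, curve$recall)
  p <- c(curve$precision[1L], curve$precision)
  area <- 0
  for (i in seq_len(length(r) - 1L)) {
    r1 <- r[i]; r2 <- r[i + 1L]; p1 <- p[i]; p2 <- p[i + 1L]
    if (r2 <= r1) next
    above1 <- p1 > precision_floor; above2 <- p2 > precision_floor
    if (above1 && above2) {
      area <- area + (r2 - r1) * (p1 + p2) / 2
    } else if (above1 || above2) {
      rc <- r1 + (r2 - r1) * (p1 - precision_floor) / (p1 - p2)
      if (above1) area <- area + (rc - r1) * (p1 + precision_floor) / 2
      else area <- area + (r2 - rc) * (precision_floor + p2) / 2
    }
  }
  area
}

#' Score one replicate of a DE simulation
#'
#' Convenience wrapper combining [realized_fdr()], [pr_curve()], and
#' [auc_restricted()] into the per-replicate summary consumed by
#' [summarize_replicates()].
#'
#' @param pvalues,qvalues named vectors from a DE result table.
#' @param truth a `sim_truth`.
#' @param alpha call threshold for the realized FDR.
#' @param precision_floor precision cutoff for the restricted AUC.
#' @return list of class `pr_summary` with `precision`, `recall`,
#'   `auc_restricted`, `realized_fdr`, `n_called`, `n_false`.
#' @export
evaluate_de <- function(pvalues, qvalues, truth, alpha = 0.05,
                        precision_floor = 0.8) {
  fdr <- realized_fdr(qvalues, truth, alpha)
  curve <- pr_curve(pvalues, truth)
  structure(list(precision = curve$precision, recall = curve$recall,
                 auc_restricted = auc_restricted(curve, precision_floor),
                 realized_fdr = fdr$fdr, n_called = fdr$n_called,
                 n_false = fdr$n_false),
            class = "pr_summary")
}

#' Aggregate per-replicate DE evaluation summaries
#'
#' Averages realized FDR, false and total call counts, and restricted AUC
#' over replicates; replicates recorded as failed (`NULL` entries) are
#' dropped and counted.
#'
#' @param per_replicate list of `pr_summary` objects (or `NULL` for failed
#'   replicates).
#' @return one-row data.frame: `n_replicates`, `n_dropped`, `mean_fdr`,
#'   `mean_false`, `mean_called`, `mean_auc_restricted`.
#' @export
summarize_replicates <- function(per_replicate) {
  if (length(per_replicate) == 0L) stop("need at least one replicate")
  ok <- !vapply(per_replicate, is.null, logical(1))
  reps <- per_replicate[ok]
  if (length(reps) == 0L) stop("all replicates failed")
  get <- function(field) vapply(reps, function(x) as.numeric(x[[field]]),
                                numeric(1))
  data.frame(n_replicates = length(reps), n_dropped = sum(!ok),
             mean_fdr = mean(get("realized_fdr")),
             mean_false = mean(get("n_false")),
             mean_called = mean(get("n_called")),
             mean_auc_restricted = mean(get("auc_restricted")))
}
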