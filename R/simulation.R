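#' Generate a synthetic droplet-like NB count matrix
#'
#' Emulates UMI counts from droplet scRNA-seq: gene mean-proportions are
#' drawn log-normally and normalized to sum to one, gene dispersions are
#' drawn from a gamma distribution, per-cell depths are drawn log-normally
#' around a median depth, and counts are NB with mean `depth_i * prop_g` and
#' gene dispersion `phi_g`.
#'
#' @param n_genes,n_cells matrix dimensions.
#' @param meanlog,sdlog log-normal parameters for the (unnormalized) gene
#'   mean-proportions; only `sdlog` matters after normalization.
#' @param dispersion_shape,dispersion_rate gamma parameters for the gene
#'   dispersions (default mean 1/3).
#' @param median_depth median per-cell total UMI count (default 1000,
#'   droplet-like).
#' @param depth_variation log-scale standard deviation of the per-cell
#'   depths; 0 gives (near-)constant totals.
#' @param seed integer seed.
#' @return list with `matrix` (a [count_matrix()]) and the generating truth:
#'   `props`, `dispersions`, `depths`.
#' @export
generate_nb_matrix <- function(n_genes, n_cells, meanlog = 0, sdlog = 1.5,
                               dispersion_shape = 2, dispersion_rate = 6,
                               median_depth = 1000, depth_variation = 0.3,
                               seed) {
  stopifnot(n_genes > 0, n_cells > 0, median_depth > 0, depth_variation >= 0)
  set.seed(seed)
  props <- stats::rlnorm(n_genes, meanlog, sdlog)
  props <- props / sum(props)
  phi <- stats::rgamma(n_genes, shape = dispersion_shape,
                       rate = dispersion_rate)
  depths <- pmax(1, round(median_depth *
                            exp(stats::rnorm(n_cells, 0, depth_variation))))
  mu <- props %o% depths                    # genes x cells expected counts
  counts <- stats::rnbinom(n_genes * n_cells,
                           size = rep(1 / phi, times = n_cells),
                           mu = as.vector(mu))
  dim(counts) <- c(n_genes, n_cells)
  list(matrix = count_matrix(counts), props = props, dispersions = phi,
       depths = depths)
}

# first `n_pairs` genes (ascending average order, ties by index) whose
# group-2 average strictly exceeds `anchor`, restricted to `candidates`
pick_anchor_genes <- function(avg, anchor, n_pairs, candidates, what) {
  pool <- candidates[avg[candidates] > anchor]
  pool <- pool[order(avg[pool], pool)]
  if (length(pool) < n_pairs)
    stop(sprintf("need %d genes with group-2 average above %.4g, found %d (%s)",
                 n_pairs, anchor, length(pool), what))
  pool[seq_len(n_pairs)]
}

#' Create differential expression by swapping gene rows in one group
#'
#' Samples `n_group1 + n_group2` cells, splits them randomly into two groups,
#' and creates true DE genes by exchanging the count rows of two
#' expression-matched gene sets in group-2 cells only: set A holds `n_pairs`
#' genes whose group-2 average count sits just above `t`, set B holds
#' `n_pairs` genes just above `fc * t`. Swapping rows preserves every cell's
#' total UMI count and the marginal count structure, so the only signal is
#' the intended fold change of about `fc` (up for set A, down for set B).
#'
#' @param matrix a [count_matrix()] to draw cells from.
#' @param n_group1,n_group2 cells per group.
#' @param t average-count anchor of the lower gene set (must be > 0).
#' @param fc simulated fold change (> 1).
#' @param n_pairs genes per set (default 50, i.e. 100 true DE genes).
#' @param seed integer seed.
#' @return list with `matrix` (the simulated two-group [count_matrix()]),
#'   `groups` (per-cell labels `"group1"`/`"group2"`), and `truth`
#'   (a `sim_truth`: `de_genes`, `swap_pairs`, `t`, `fc`,
#'   `thinning_ratio_range`, `group_assignment`, `seed`).
#' @export
simulate_swap_de <- function(matrix, n_group1, n_group2, t, fc, n_pairs = 50L,
                             seed) {
  matrix <- count_matrix(matrix)
  if (fc <= 1) stop("fc must be greater than 1")
  if (t <= 0) stop("t must be positive")
  if (n_group1 + n_group2 > ncol(matrix))
    stop("matrix has fewer cells than n_group1 + n_group2")
  set.seed(seed)
  cells <- sample.int(ncol(matrix), n_group1 + n_group2)
  sub <- unclass(matrix)[, cells, drop = FALSE]
  groups <- rep(c("group1", "group2"), c(n_group1, n_group2))
  g2 <- which(groups == "group2")
  avg2 <- rowMeans(sub[, g2, drop = FALSE])
  all_genes <- seq_len(nrow(sub))
  set_a <- pick_anchor_genes(avg2, t, n_pairs, all_genes, "set A")
  set_b <- pick_anchor_genes(avg2, fc * t, n_pairs,
                             setdiff(all_genes, set_a), "set B")
  if (length(intersect(set_a, set_b)) > 0)
    stop("anchor gene sets overlap; increase fc or t")
  tmp <- sub[set_a, g2, drop = FALSE]
  sub[set_a, g2] <- sub[set_b, g2, drop = FALSE]
  sub[set_b, g2] <- tmp
  ids <- rownames(matrix)
  truth <- structure(list(
    de_genes = ids[c(set_a, set_b)],
    swap_pairs = data.frame(low_gene = ids[set_a], high_gene = ids[set_b],
                            stringsAsFactors = FALSE),
    t = t, fc = fc, thinning_ratio_range = c(1, 1),
    group_assignment = stats::setNames(groups, colnames(sub)),
    batch_assignment = NULL, seed = seed), class = "sim_truth")
  list(matrix = count_matrix(sub), groups = groups, truth = truth)
}

#' Thin (sub-sample) the molecules of selected cells
#'
#' For each selected cell a retention ratio is drawn uniformly from
#' `ratio_range` and the cell's molecules are sub-sampled without replacement
#' (multivariate hypergeometric) to `round(ratio * total)`. Emulates
#' systematic depth differences between groups, e.g. 80-90% or 50-60% of
#' UMIs retained.
#'
#' @param matrix a [count_matrix()].
#' @param cells column indices or cell identifiers to thin.
#' @param ratio_range length-2 interval within (0, 1].
#' @param seed integer seed.
#' @return the thinned [count_matrix()].
#' @export
thin_counts <- function(matrix, cells, ratio_range, seed) {
  matrix <- count_matrix(matrix)
  if (is.character(cells)) cells <- match(cells, colnames(matrix))
  if (anyNA(cells)) stop("unknown cell identifiers")
  stopifnot(length(ratio_range) == 2L, ratio_range[1] <= ratio_range[2],
            ratio_range[1] > 0, ratio_range[2] <= 1)
  set.seed(seed)
  out <- unclass(matrix)
  ratios <- stats::runif(length(cells), ratio_range[1], ratio_range[2])
  for (k in seq_along(cells)) {
    j <- cells[k]
    target <- round(ratios[k] * sum(out[, j]))
    out[, j] <- sample_molecules(out[, j], target)
  }
  count_matrix(out)
}

#' Batch-confounded two-group design with batch-neutral true DE genes
#'
#' Builds a two-group dataset in which group and batch (replicate) are
#' deliberately confounded: each group draws a different number of cells from
#' replicates A and B. True DE genes are then created by the gene-swap
#' construction, restricted to batch-neutral candidates -- genes whose
#' replicate-A-versus-replicate-B NBID p-value exceeds `neutrality_p` -- so
#' that detecting a true DE gene cannot be explained by the batch difference.
#' Batch labels are returned for covariate adjustment.
#'
#' @param rep_a,rep_b [count_matrix()] objects sharing a gene universe.
#' @param composition list with numeric vectors `group1` and `group2`, each
#'   `c(a = ..., b = ...)` cells drawn from the two replicates. Two presets
#'   from the plate-based design are exported as
#'   [batch_composition_presets()].
#' @param t,fc,n_pairs,seed as in [simulate_swap_de()].
#' @param neutrality_p minimum between-replicate DE p-value for a gene to be
#'   eligible as a true DE gene (default 0.5).
#' @return list with `matrix`, `groups`, `batch` (per-cell replicate label),
#'   and `truth` (a `sim_truth` with `batch_assignment` filled in).
#' @export
simulate_batch_confounded <- function(rep_a, rep_b, composition, t, fc,
                                      n_pairs = 50L, seed,
                                      neutrality_p = 0.5) {
  rep_a <- count_matrix(rep_a); rep_b <- count_matrix(rep_b)
  if (!identical(rownames(rep_a), rownames(rep_b)))
    stop("replicates must share an identical gene universe")
  if (fc <= 1) stop("fc must be greater than 1")
  stopifnot(all(c("group1", "group2") %in% names(composition)))
  n_a <- vapply(composition, function(x) x[["a"]], numeric(1))
  n_b <- vapply(composition, function(x) x[["b"]], numeric(1))
  if (sum(n_a) > ncol(rep_a) || sum(n_b) > ncol(rep_b))
    stop("composition asks for more cells than a replicate contains")

  # batch-neutrality screen: DE between the full replicates
  combined <- cbind(unclass(rep_a), unclass(rep_b))
  colnames(combined) <- c(paste0("a_", colnames(rep_a)),
                          paste0("b_", colnames(rep_b)))
  batch_de <- run_nbid(count_matrix(combined),
                       rep(c("a", "b"), c(ncol(rep_a), ncol(rep_b))))
  neutral_ids <- batch_de$gene_id[!is.na(batch_de$p) &
                                    batch_de$p > neutrality_p]
  if (length(neutral_ids) < 2L * n_pairs)
    stop(sprintf("only %d batch-neutral genes (p > %.2g); need at least %d",
                 length(neutral_ids), neutrality_p, 2L * n_pairs))

  set.seed(seed)
  pick_a <- sample.int(ncol(rep_a), sum(n_a))
  pick_b <- sample.int(ncol(rep_b), sum(n_b))
  a1 <- pick_a[seq_len(n_a[["group1"]])]
  a2 <- pick_a[-seq_len(n_a[["group1"]])]
  b1 <- pick_b[seq_len(n_b[["group1"]])]
  b2 <- pick_b[-seq_len(n_b[["group1"]])]
  sub <- cbind(unclass(rep_a)[, a1, drop = FALSE],
               unclass(rep_b)[, b1, drop = FALSE],
               unclass(rep_a)[, a2, drop = FALSE],
               unclass(rep_b)[, b2, drop = FALSE])
  colnames(sub) <- make.unique(c(paste0("a_", colnames(rep_a)[a1]),
                                 paste0("b_", colnames(rep_b)[b1]),
                                 paste0("a_", colnames(rep_a)[a2]),
                                 paste0("b_", colnames(rep_b)[b2])))
  n1 <- length(a1) + length(b1)
  n2 <- length(a2) + length(b2)
  groups <- rep(c("group1", "group2"), c(n1, n2))
  batch <- c(rep("a", length(a1)), rep("b", length(b1)),
             rep("a", length(a2)), rep("b", length(b2)))
  g2 <- which(groups == "group2")
  avg2 <- rowMeans(sub[, g2, drop = FALSE])
  candidates <- match(neutral_ids, rownames(sub))
  set_a <- pick_anchor_genes(avg2, t, n_pairs, candidates, "set A")
  set_b <- pick_anchor_genes(avg2, fc * t, n_pairs,
                             setdiff(candidates, set_a), "set B")
  if (length(intersect(set_a, set_b)) > 0)
    stop("anchor gene sets overlap; increase fc or t")
  tmp <- sub[set_a, g2, drop = FALSE]
  sub[set_a, g2] <- sub[set_b, g2, drop = FALSE]
  sub[set_b, g2] <- tmp
  ids <- rownames(sub)
  truth <- structure(list(
    de_genes = ids[c(set_a, set_b)],
    swap_pairs = data.frame(low_gene = ids[set_a], high_gene = ids[set_b],
                            stringsAsFactors = FALSE),
    t = t, fc = fc, thinning_ratio_range = c(1, 1),
    group_assignment = stats::setNames(groups, colnames(sub)),
    batch_assignment = stats::setNames(batch, colnames(sub)),
    seed = seed), class = "sim_truth")
  list(matrix = count_matrix(sub), groups = groups, batch = batch,
       truth = truth)
}

#' Preset group/replicate compositions for the batch-confounded design
#'
#' Two published variants of the plate-based confounded design: both draw
#' 9 A + 21 B cells for the reference group; the second group draws either
#' 18 A + 22 B (`"methods"`) or 18 A + 12 B (`"table"`).
#'
#' @return named list of composition lists for
#'   [simulate_batch_confounded()].
#' @export
batch_composition_presets <- function() {
  list(
    methods = list(group1 = c(a = 9, b = 21), group2 = c(a = 18, b = 22)),
    table   = list(group1 = c(a = 9, b = 21), group2 = c(a = 18, b = 12)))
}
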