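# Simulation helpers shared across test files. All fixtures are built in
# code under fixed seeds.

# genes x cells matrix of independent NB genes with given mean/dispersion
# ranges (no depth structure; intercept-only gene models)
nb_gene_matrix <- function(n_genes, n_cells, mu_range, phi_range, seed) {
  set.seed(seed)
  mu <- runif(n_genes, mu_range[1], mu_range[2])
  phi <- runif(n_genes, phi_range[1], phi_range[2])
  counts <- t(vapply(seq_len(n_genes),
                     function(g) rnbinom(n_cells, mu = mu[g], size = 1 / phi[g]),
                     numeric(n_cells)))
  list(matrix = count_matrix(counts), mu = mu, phi = phi)
}

pois_gene_matrix <- function(n_genes, n_cells, mu_range, seed) {
  set.seed(seed)
  mu <- runif(n_genes, mu_range[1], mu_range[2])
  counts <- t(vapply(seq_len(n_genes),
                     function(g) rpois(n_cells, mu[g]), numeric(n_cells)))
  list(matrix = count_matrix(counts), mu = mu)
}

# two-group NB counts with per-cell depths and log-link group effect;
# returns everything needed for an NBID fit
two_group_gene <- function(n_per_group, prop0, log_fc, phi0, phi1,
                           median_depth = 2000, depth_sd = 0.3, seed) {
  set.seed(seed)
  n <- 2L * n_per_group
  gi <- rep(0:1, each = n_per_group)
  depths <- pmax(1, round(median_depth * exp(rnorm(n, 0, depth_sd))))
  mu <- depths * prop0 * exp(log_fc * gi)
  phi <- ifelse(gi == 0, phi0, phi1)
  y <- rnbinom(n, mu = mu, size = 1 / phi)
  list(y = y, group = gi, offsets = log(depths), depths = depths)
}

# two synthetic plate-like replicates with a mass-balanced batch shift:
# `up` genes scaled up, a disjoint `down` set scaled so the total proportion
# mass (hence every unshifted gene's proportion) is unchanged between
# replicates
batch_replicates <- function(seed, n_genes = 800, n_a = 30, n_b = 35,
                             up_frac = 0.08, down_frac = 0.3, shift = 3,
                             median_depth = 20000) {
  set.seed(seed)
  props <- rlnorm(n_genes, 0, 1.5)
  props <- props / sum(props)
  phi <- rgamma(n_genes, 2, 6)
  # redraw the shifted sets until the down-scaling stays moderate (the up
  # set may randomly capture too much proportion mass)
  for (attempt in 1:50) {
    idx <- sample.int(n_genes)
    up <- idx[seq_len(round(up_frac * n_genes))]
    down <- idx[round(up_frac * n_genes) + seq_len(round(down_frac * n_genes))]
    added <- sum(props[up]) * (shift - 1)
    f <- (sum(props[down]) - added) / sum(props[down])
    if (f > 0.2) break
  }
  stopifnot(f > 0.2)
  props_b <- props
  props_b[up] <- props_b[up] * shift
  props_b[down] <- props_b[down] * f
  gen <- function(pp, n_cells, prefix) {
    depths <- pmax(1, round(median_depth * exp(rnorm(n_cells, 0, 0.2))))
    mu <- pp %o% depths
    counts <- rnbinom(length(mu), size = rep(1 / phi, n_cells),
                      mu = as.vector(mu))
    dim(counts) <- dim(mu)
    count_matrix(counts, gene_ids = paste0("gene", seq_len(n_genes)),
                 cell_ids = paste0(prefix, seq_len(n_cells)))
  }
  list(a = gen(props, n_a, "a"), b = gen(props_b, n_b, "b"),
       shifted = paste0("gene", c(up, down)),
       up = paste0("gene", up))
}

# one replicate of the swap-DE benchmark: droplet-like base matrix, 100
# swapped DE genes, optional thinning of group-2 cells, NBID, realized FDR
swap_fdr_replicate <- function(seed, thin_range = NULL, n_genes = 2000,
                               n_cells = 1000, n_per_group = 500,
                               t_anchor = 0.5, fc = 4) {
  base <- generate_nb_matrix(n_genes, n_cells, seed = seed)
  sim <- simulate_swap_de(base$matrix, n_per_group, n_per_group,
                          t = t_anchor, fc = fc, seed = seed + 1L)
  m <- sim$matrix
  if (!is.null(thin_range))
    m <- thin_counts(m, which(sim$groups == "group2"), thin_range,
                     seed = seed + 2L)
  de <- run_nbid(m, sim$groups)
  fdr <- realized_fdr(stats::setNames(de$q, de$gene_id), sim$truth)
  list(de = de, truth = sim$truth, fdr = fdr)
}

binom_band <- function(p0, n, k = 3) p0 + c(-k, k) * sqrt(p0 * (1 - p0) / n)
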