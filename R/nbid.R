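# ---- internal helpers ------------------------------------------------------

# crude per-group intercepts and moment dispersion estimates used as
# optimizer starting values
nbid_starts <- function(y, gi, off) {
  e_off <- exp(off)
  b <- numeric(2)
  for (g in 0:1) {
    idx <- gi == g
    b[g + 1] <- log((sum(y[idx]) + 0.5) / sum(e_off[idx]))
  }
  mu <- exp(off + b[gi + 1])
  lth <- numeric(2)
  for (g in 0:1) {
    idx <- gi == g
    phi_mm <- sum((y[idx] - mu[idx])^2 - mu[idx]) / sum(mu[idx]^2)
    lth[g + 1] <- log(min(max(1 / max(phi_mm, 1e-4), .THETA_MIN), .THETA_MAX))
  }
  phi_pool <- sum((y - mu)^2 - mu) / sum(mu^2)
  lth_pool <- log(min(max(1 / max(phi_pool, 1e-4), .THETA_MIN), .THETA_MAX))
  list(beta0 = b[1], beta1 = b[2] - b[1], lth = lth, lth_pool = lth_pool)
}

# nlminb stops with "false/singular convergence" messages at solutions whose
# projected gradient is numerically zero; accept those after a KKT check
nlminb_converged <- function(fit, gr, lower, upper, tol = 1e-4) {
  if (fit$convergence == 0) return(TRUE)
  g <- gr(fit$par)
  at_lo <- fit$par <= lower + 1e-8
  at_hi <- fit$par >= upper - 1e-8
  g[at_lo & g > 0] <- 0   # pushing outward at a bound is fine
  g[at_hi & g < 0] <- 0
  max(abs(g)) < tol * (1 + abs(fit$objective))
}

# full-model fit given precomputed design pieces; returns an "nbid_fit"
nbid_fit_full_core <- function(y, X, gi, off, common_dispersion = FALSE) {
  p <- ncol(X)
  if (p == 2L && !common_dispersion) {
    # no covariates: the model factorizes into two independent group fits
    f <- nbid_fit_two_groups(y, exp(off), as.integer(gi), .THETA_MIN,
                             .THETA_MAX)
    flag <- "ok"
    if (sum(y[gi == 0]) == 0 || sum(y[gi == 1]) == 0) flag <- "separation"
    return(structure(list(beta0 = f$b0, beta1 = f$b1 - f$b0,
                          gamma = numeric(0),
                          phi0 = 1 / f$theta0, phi1 = 1 / f$theta1,
                          theta0 = f$theta0, theta1 = f$theta1,
                          loglik = f$loglik, converged = f$converged,
                          flag = flag),
                     class = "nbid_fit"))
  }
  st <- nbid_starts(y, gi, off)
  coef_start <- c(st$beta0, st$beta1, rep(0, p - 2L))
  lo_coef <- rep(-40, p); hi_coef <- rep(40, p)
  lt_lo <- log(.THETA_MIN); lt_hi <- log(.THETA_MAX)

  if (common_dispersion) {
    obj <- function(par) nbid_full_nll(c(par[1:p], par[p + 1], par[p + 1]),
                                       y, X, off, gi)
    gr <- function(par) {
      g <- nbid_full_grad(c(par[1:p], par[p + 1], par[p + 1]), y, X, off, gi)
      c(g[1:p], g[p + 1] + g[p + 2])
    }
    starts <- list(c(coef_start, st$lth_pool))
    lower <- c(lo_coef, lt_lo); upper <- c(hi_coef, lt_hi)
  } else {
    obj <- function(par) nbid_full_nll(par, y, X, off, gi)
    gr <- function(par) nbid_full_grad(par, y, X, off, gi)
    starts <- list(c(coef_start, st$lth),
                   c(coef_start, st$lth_pool, st$lth_pool))
    lower <- c(lo_coef, lt_lo, lt_lo); upper <- c(hi_coef, lt_hi, lt_hi)
  }
  best <- NULL
  for (s in starts) {
    fit <- try(stats::nlminb(s, obj, gradient = gr, lower = lower,
                             upper = upper,
                             control = list(rel.tol = 1e-10, iter.max = 300L)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, loglik = NA_real_),
                     class = "nbid_fit"))
  par <- best$par
  if (common_dispersion) par <- c(par[1:p], par[p + 1], par[p + 1])
  theta <- exp(par[c(p + 1, p + 2)])
  flag <- "ok"
  if (sum(y[gi == 0]) == 0 || sum(y[gi == 1]) == 0) flag <- "separation"
  structure(list(beta0 = par[1], beta1 = par[2],
                 gamma = if (p > 2L) par[3:p] else numeric(0),
                 phi0 = 1 / theta[1], phi1 = 1 / theta[2],
                 theta0 = theta[1], theta1 = theta[2],
                 loglik = -best$objective,
                 converged = nlminb_converged(best, gr, lower, upper),
                 flag = flag),
            class = "nbid_fit")
}

# null-model fit (beta1 = 0) with per-group dispersions fixed from the full
# model; theta is the length-2 vector c(theta0, theta1)
nbid_fit_null_core <- function(y, X0, gi, off, theta, init = NULL) {
  p <- ncol(X0)
  theta_i <- theta[gi + 1]
  if (p == 1L) {  # intercept-only null: damped Newton on the 1-d score
    f <- nbid_fit_null_1d(y, exp(off), theta_i)
    return(structure(list(beta0 = f$b0, gamma = numeric(0),
                          loglik = f$loglik, converged = f$converged,
                          flag = "ok"),
                     class = "nbid_fit"))
  }
  obj <- function(par) nbid_null_nll(par, y, X0, off, theta_i)
  gr <- function(par) nbid_null_grad(par, y, X0, off, theta_i)
  starts <- list(c(log((sum(y) + 0.5) / sum(exp(off))), rep(0, p - 1L)))
  if (!is.null(init)) starts <- c(list(init), starts)
  best <- NULL
  for (s in starts) {
    fit <- try(stats::nlminb(s, obj, gradient = gr, lower = rep(-40, p),
                             upper = rep(40, p),
                             control = list(rel.tol = 1e-10, iter.max = 300L)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, loglik = NA_real_),
                     class = "nbid_fit"))
  structure(list(beta0 = best$par[1],
                 gamma = if (p > 1L) best$par[2:p] else numeric(0),
                 loglik = -best$objective,
                 converged = nlminb_converged(best, gr, rep(-40, p),
                                              rep(40, p)),
                 flag = "ok"),
            class = "nbid_fit")
}

# validate and normalize the (group, covariates, offsets) design
nbid_design <- function(group, covariates, offsets, n) {
  if (length(group) != n) stop("group labels must match the number of cells")
  gf <- factor(group)
  if (nlevels(gf) != 2L) stop("exactly two distinct group labels are required")
  gi <- as.integer(gf) - 1L
  Z <- NULL
  if (!is.null(covariates)) {
    if (is.data.frame(covariates)) {
      Z <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
    } else {
      Z <- as.matrix(covariates)
    }
    if (nrow(Z) != n) stop("covariates must have one row per cell")
    storage.mode(Z) <- "double"
  }
  if (length(offsets) != n) stop("offsets must match the number of cells")
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  X <- cbind(intercept = 1, group = gi, Z)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (collinear covariates)")
  list(gi = gi, X = X, X0 = X[, -2L, drop = FALSE],
       offsets = as.numeric(offsets), levels = levels(gf))
}

# ---- exported API ----------------------------------------------------------

#' Fit the full NBID model for one gene
#'
#' Maximizes the NB likelihood with mean model
#' `log(mu_i) = offset_i + beta0 + beta1 * g_i + gamma' x_i` and an
#' independent dispersion parameter in each group (`phi0`, `phi1`).
#' Optimization is gradient-based (box-bounded quasi-Newton on the
#' coefficients and log-scale dispersions) with multiple starts: per-group
#' moment dispersions and the pooled-dispersion estimate.
#'
#' @param y non-negative integer counts, one per cell.
#' @param group two-level group labels, one per cell.
#' @param covariates optional numeric matrix or data.frame of per-cell
#'   covariates (e.g. batch).
#' @param offsets per-cell log size factors (e.g. `log(cell_totals(m))`).
#' @param common_dispersion if `TRUE`, constrain `phi0 = phi1` (the standard
#'   equal-dispersion NB GLM).
#' @return an `nbid_fit`: `beta0`, `beta1` (group effect, natural-log scale),
#'   `gamma`, `phi0`, `phi1`, `loglik`, `converged`, `flag`.
#' @export
fit_nbid_full <- function(y, group, covariates = NULL, offsets,
                          common_dispersion = FALSE) {
  y <- check_counts(y)
  d <- nbid_design(group, covariates, offsets, length(y))
  nbid_fit_full_core(y, d$X, d$gi, d$offsets, common_dispersion)
}

#' Fit the NBID null model for one gene
#'
#' Maximizes over the intercept (and covariate coefficients) only, with
#' `beta1` fixed at 0 and each cell's dispersion fixed at its group's value
#' from the full-model fit.
#'
#' @inheritParams fit_nbid_full
#' @param phi_from_full length-2 vector of group dispersions (phi0, phi1)
#'   taken from the full fit.
#' @return an `nbid_fit` with `beta0`, `gamma`, `loglik`, `converged`.
#' @export
fit_nbid_null <- function(y, group, covariates = NULL, offsets,
                          phi_from_full) {
  y <- check_counts(y)
  d <- nbid_design(group, covariates, offsets, length(y))
  stopifnot(length(phi_from_full) == 2L, all(phi_from_full >= 0))
  theta <- ifelse(phi_from_full > 0, 1 / phi_from_full, .THETA_MAX)
  nbid_fit_null_core(y, d$X0, d$gi, d$offsets, theta)
}

# shared per-gene test path (precomputed design)
nbid_test_core <- function(y, X, X0, gi, off) {
  out <- data.frame(log2_fold_change = NA_real_, phi0 = NA_real_,
                    phi1 = NA_real_, lrt_stat = NA_real_, p = NA_real_,
                    flag = "ok", stringsAsFactors = FALSE)
  if (all(y == 0)) { out$flag <- "all_zero"; return(out) }
  full <- nbid_fit_full_core(y, X, gi, off)
  if (!isTRUE(full$converged)) {
    out$flag <- if (is.null(full$flag) || full$flag == "ok") "unconverged"
                else full$flag
    if (is.na(full$loglik)) return(out)
  }
  null <- nbid_fit_null_core(y, X0, gi, off,
                             theta = c(full$theta0, full$theta1),
                             init = c(full$beta0 + log(mean(exp(full$beta1 * gi))),
                                      full$gamma))
  d <- max(0, 2 * (full$loglik - null$loglik))
  out$log2_fold_change <- full$beta1 / log(2)
  out$phi0 <- full$phi0; out$phi1 <- full$phi1
  out$lrt_stat <- d
  out$p <- stats::pchisq(d, df = 1, lower.tail = FALSE)
  if (full$flag != "ok") out$flag <- full$flag
  if (!isTRUE(full$converged)) out$p <- NA_real_
  out
}

#' NBID differential-expression test for one gene
#'
#' Fits the full model (independent group dispersions), then the null model
#' with the group effect removed and dispersions held at their full-model
#' values, and compares them with a likelihood-ratio test on 1 degree of
#' freedom. Negative likelihood differences (possible because the null
#' dispersions are fixed) are clamped to 0.
#'
#' @inheritParams fit_nbid_full
#' @param gene_id optional identifier copied into the result.
#' @return one-row data.frame: `gene_id`, `log2_fold_change`
#'   (`beta1 / ln 2`), `phi0`, `phi1`, `lrt_stat`, `p`, `flag`.
#' @export
nbid_gene_test <- function(y, group, covariates = NULL, offsets,
                           gene_id = NA_character_) {
  y <- check_counts(y)
  d <- nbid_design(group, covariates, offsets, length(y))
  cbind(gene_id = gene_id,
        nbid_test_core(y, d$X, d$X0, d$gi, d$offsets))
}

#' NBID differential expression over a count matrix
#'
#' Runs the per-gene NBID likelihood-ratio test for every gene passing the
#' detection filter, using `log(size_factors)` as the per-cell offset when
#' size factors are supplied (e.g. from scran) and `log(total UMIs)`
#' otherwise. P-values are BH-adjusted across tested genes.
#'
#' @param matrix a [count_matrix()].
#' @param groups two-level group labels, one per cell.
#' @param covariates optional per-cell covariates (matrix or data.frame).
#' @param size_factors optional positive per-cell size factors; defaults to
#'   the per-cell total UMI counts.
#' @param alpha FDR level used in the call summary (default 0.05).
#' @param min_nonzero_cells detection filter (default 5 non-zero cells).
#' @return data.frame with one row per tested gene: `gene_id`,
#'   `log2_fold_change`, `mean_tpm_group0`, `mean_tpm_group1`, `phi0`,
#'   `phi1`, `lrt_stat`, `p`, `q`, `flag`. Attribute `summary` reports the
#'   number of tested genes and of calls at `q < alpha`; attribute `groups`
#'   records which label was coded 0 and 1.
#' @export
run_nbid <- function(matrix, groups, covariates = NULL, size_factors = NULL,
                     alpha = 0.05, min_nonzero_cells = 5L) {
  matrix <- count_matrix(matrix)
  n <- ncol(matrix)
  if (length(groups) != n) stop("groups must assign one label per cell")
  totals <- colSums(unclass(matrix))
  if (is.null(size_factors)) {
    drop <- totals == 0
    if (any(drop)) {
      warning(sum(drop), " cell(s) with zero total UMIs dropped")
      matrix <- matrix[, !drop, drop = FALSE]
      groups <- groups[!drop]
      if (!is.null(covariates))
        covariates <- if (is.null(dim(covariates))) covariates[!drop]
                      else covariates[!drop, , drop = FALSE]
      totals <- totals[!drop]
    }
    offsets <- log(totals)
  } else {
    if (length(size_factors) != n) stop("size_factors must match cells")
    if (any(!is.finite(size_factors)) || any(size_factors <= 0))
      stop("size factors must be positive and finite")
    offsets <- log(size_factors)
  }
  if (!is.null(covariates) && is.null(dim(covariates)) &&
      !is.data.frame(covariates))
    covariates <- cbind(covariate = as.numeric(factor(covariates)) - 1)
  d <- nbid_design(groups, covariates, offsets, ncol(matrix))
  tpm <- tpm_per_group(matrix, groups)
  tested <- filter_genes(matrix, min_nonzero_cells)
  rows <- vector("list", nrow(tested))
  for (g in seq_len(nrow(tested))) {
    y <- as.numeric(unclass(tested)[g, ])
    rows[[g]] <- nbid_test_core(y, d$X, d$X0, d$gi, d$offsets)
  }
  out <- do.call(rbind, rows)
  gene_id <- rownames(tested)
  out <- cbind(gene_id = gene_id,
               out[, "log2_fold_change", drop = FALSE],
               mean_tpm_group0 = tpm[gene_id, 1L],
               mean_tpm_group1 = tpm[gene_id, 2L],
               out[, c("phi0", "phi1", "lrt_stat", "p", "flag")])
  out$q <- bh_fdr(out$p)
  out <- out[, c("gene_id", "log2_fold_change", "mean_tpm_group0",
                 "mean_tpm_group1", "phi0", "phi1", "lrt_stat", "p", "q",
                 "flag")]
  rownames(out) <- NULL
  attr(out, "summary") <- c(n_tested = nrow(out),
                            n_called = sum(out$q < alpha, na.rm = TRUE))
  attr(out, "groups") <- stats::setNames(d$levels, c("group0", "group1"))
  out
}
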