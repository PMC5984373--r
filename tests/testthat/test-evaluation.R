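toy_truth <- function(true_ids) structure(list(de_genes = true_ids),
                                          class = "sim_truth")

test_that("realized_fdr counts false calls at the q threshold", {
  truth <- toy_truth(paste0("t", 1:5))
  q_none <- setNames(rep(0.9, 8), paste0("g", 1:8))
  r0 <- realized_fdr(q_none, truth)
  expect_equal(r0$fdr, 0)
  expect_equal(r0$n_called, 0)

  q_true <- setNames(rep(0.01, 3), paste0("t", 1:3))
  expect_equal(realized_fdr(q_true, truth)$fdr, 0)

  q_mixed <- setNames(c(rep(0.01, 10), rep(0.5, 5)),
                      c(paste0("t", 1:5), paste0("f", 1:5), paste0("n", 1:5)))
  truth2 <- toy_truth(paste0("t", 1:7))
  r <- realized_fdr(q_mixed, truth2)
  expect_equal(r$n_called, 10)
  expect_equal(r$n_false, 5)
  expect_equal(r$fdr, 0.5)
  # nested call sets: fdr of the stricter threshold cannot use more calls
  expect_lte(realized_fdr(q_mixed, truth2, alpha = 0.02)$n_called,
             realized_fdr(q_mixed, truth2, alpha = 0.6)$n_called)
})

test_that("pr_curve handles perfect separation, ties, and missing values", {
  truth <- toy_truth(paste0("t", 1:4))
  p <- setNames(c(1e-6, 1e-5, 1e-4, 1e-3, 0.2, 0.4, 0.6, 0.9),
                c(paste0("t", 1:4), paste0("n", 1:4)))
  curve <- pr_curve(p, truth)
  at_full <- curve$precision[curve$recall == 1]
  expect_equal(at_full[1], 1)   # precision still 1 when recall first hits 1
  expect_true(all(curve$precision[seq_len(4)] == 1))

  # ties enter together: both tied genes form a single step
  p_tie <- setNames(c(0.01, 0.01, 0.5), c("t1", "n1", "t2"))
  c_tie <- pr_curve(p_tie, toy_truth(c("t1", "t2")))
  expect_equal(c_tie$precision[1], 0.5)
  expect_equal(c_tie$recall[1], 0.5)

  # missing p-values lower attainable recall
  p_na <- setNames(c(0.01, NA), c("t1", "t2"))
  c_na <- pr_curve(p_na, toy_truth(c("t1", "t2")))
  expect_equal(max(c_na$recall), 0.5)

  # random scores give precision about the prevalence
  set.seed(1201)
  ids <- paste0("g", 1:2000)
  truth_r <- toy_truth(ids[1:400])
  c_r <- pr_curve(setNames(runif(2000), ids), truth_r)
  expect_lt(abs(c_r$precision[length(c_r$precision)] - 0.2), 0.01)
  tail_region <- c_r$recall > 0.5
  expect_lt(abs(mean(c_r$precision[tail_region]) - 0.2), 0.05)
})

test_that("restricted AUC clips at the precision floor", {
  perfect <- structure(list(precision = c(1, 1), recall = c(0.5, 1),
                            thresholds = c(0.01, 0.02), n_true = 10),
                       class = "pr_curve")
  expect_equal(auc_restricted(perfect), 1)
  expect_equal(auc_restricted(perfect, 0), auc_restricted(perfect, 0.8))

  low <- structure(list(precision = c(0.5, 0.4), recall = c(0.5, 1),
                        thresholds = c(0.01, 0.02), n_true = 10),
                   class = "pr_curve")
  expect_equal(auc_restricted(low), 0)

  # piecewise hand calculation: points (r, p) = (0.2, 1), (0.5, 0.9),
  # (1, 0.6); anchored at (0, 1); the last segment crosses 0.8 at r = 2/3
  toy <- structure(list(precision = c(1, 0.9, 0.6), recall = c(0.2, 0.5, 1),
                        thresholds = 1:3, n_true = 10), class = "pr_curve")
  hand <- 0.2 * 1 + 0.3 * (1 + 0.9) / 2 +
    (2 / 3 - 0.5) * (0.9 + 0.8) / 2
  expect_equal(auc_restricted(toy), hand, tolerance = 1e-12)
  expect_lte(auc_restricted(toy), auc_restricted(toy, 0))
})

test_that("replicate summaries average the per-replicate metrics", {
  mk <- function(fdr, false, called, auc)
    structure(list(precision = 1, recall = 1, auc_restricted = auc,
                   realized_fdr = fdr, n_called = called, n_false = false),
              class = "pr_summary")
  one <- summarize_replicates(list(mk(0.1, 2, 20, 0.7)))
  expect_equal(one$mean_fdr, 0.1)
  expect_equal(one$n_replicates, 1)

  two <- summarize_replicates(list(mk(0, 0, 10, 0.8), mk(0.1, 1, 10, 0.6)))
  expect_equal(two$mean_fdr, 0.05)
  expect_equal(two$mean_auc_restricted, 0.7)

  with_fail <- summarize_replicates(list(mk(0, 0, 10, 0.8), NULL,
                                         mk(0.2, 2, 10, 0.4)))
  expect_equal(with_fail$n_dropped, 1)
  expect_equal(with_fail$mean_fdr, 0.1)

  # aggregate equals an independent recomputation on a synthetic run
  set.seed(1202)
  reps <- lapply(1:20, function(i) mk(runif(1, 0, 0.1), rpois(1, 2),
                                      rpois(1, 50), runif(1)))
  agg <- summarize_replicates(reps)
  expect_equal(agg$mean_fdr,
               mean(vapply(reps, `[[`, numeric(1), "realized_fdr")))
  expect_equal(agg$mean_called,
               mean(vapply(reps, `[[`, numeric(1), "n_called")))
})

test_that("evaluate_de combines the FDR and curve summaries", {
  truth <- toy_truth(paste0("t", 1:3))
  p <- setNames(c(1e-5, 1e-4, 1e-3, 0.3, 0.7), c(paste0("t", 1:3), "n1", "n2"))
  q <- bh_fdr(p)
  names(q) <- names(p)
  s <- evaluate_de(p, q, truth)
  expect_s3_class(s, "pr_summary")
  expect_equal(s$realized_fdr, 0)
  expect_equal(s$n_called, 3)
  expect_equal(s$auc_restricted, 1)
})
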