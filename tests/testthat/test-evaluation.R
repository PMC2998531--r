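test_that("fold assignment partitions evenly and reproducibly", {
  f10 <- make_folds(10, k = 5, seed = 1)
  expect_equal(as.vector(table(f10)), rep(2L, 5))
  f11 <- make_folds(11, k = 5, seed = 1)
  expect_equal(sort(as.vector(table(f11)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L))
  expect_identical(make_folds(50, 5, seed = 7), make_folds(50, 5, seed = 7))
  expect_false(identical(make_folds(50, 5, 7), make_folds(50, 5, 8)))
  expect_error(make_folds(10, k = 1), "between 2")
  expect_error(make_folds(4, k = 5), "between 2")
})

test_that("cross-validation predicts each peptide exactly once, blinded", {
  w <- synthetic_world(seed = 31)
  d <- simulate_dataset(w, 60, mix = c(random = 1, tiles = 0, scan = 0,
                                       variants = 0))
  folds <- make_folds(nrow(d), 5, seed = 2)
  cv <- cross_validate(d, baseline_trainer(trainer_config(max_iterations = 2)),
                       folds = folds)
  expect_equal(nrow(cv), nrow(d))
  expect_setequal(cv$sequence, d$sequence)
  expect_equal(anyDuplicated(cv$sequence), 0L)
  expect_setequal(cv$fold, 1:5)
  # blinding: each peptide's fold matches the assignment it was held out in
  expect_identical(cv$fold[match(d$sequence, cv$sequence)], folds)

  # a constant predictor scores everything 1 -> AUC exactly 0.5 by tie credit
  const_trainer <- function(train) all_ones_matrix()
  cv0 <- cross_validate(d, const_trainer, folds = folds)
  expect_equal(roc_auc(cv0$score, cv0$binder)$auc, 0.5)
})

test_that("ROC/AUC matches hand counts and the pairwise oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  # binders at (1, 3), non-binders at (2, 4): 3 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)

  set.seed(19)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    scores <- sample(round(runif(n, 0, 10), 1))  # coarse grid -> ties
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "non-binder")
})

test_that("ROC curve geometry and AUC invariances hold", {
  set.seed(23)
  scores <- runif(200)
  labels <- runif(200) < 0.5
  r <- roc_auc(scores, labels)
  pts <- tidy(r)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  # monotone transform invariance
  expect_equal(roc_auc(log(scores + 1), labels)$auc, r$auc)
  # orientation flip complements the AUC
  expect_equal(roc_auc(scores, labels, "higher")$auc, 1 - r$auc)
  expect_equal(glance(r)$auc, r$auc)
})

test_that("Spearman rho matches the rank formula and handles orientation", {
  ic50 <- c(10, 50, 200, 900, 4000)
  expect_equal(spearman_rho(ic50, ic50), 1.0)
  expect_equal(spearman_rho(rev(ic50), ic50), -1.0)
  set.seed(5)
  pred <- runif(5)
  expect_equal(spearman_rho(pred, ic50), oracle_spearman(pred, ic50))
  expect_equal(spearman_rho(-pred, ic50, orientation = "higher"),
               oracle_spearman(pred, ic50))
  expect_error(spearman_rho(rep(1, 5), ic50), "constant")
  expect_error(spearman_rho(c(1, 2), c(3, 4)), "at least 3")
})

test_that("fixed-method evaluation is self-consistent on noiseless data", {
  w <- synthetic_world(seed = 41, sigma = 0)
  d <- simulate_dataset(w, 100, mix = c(random = 1, tiles = 0, scan = 0,
                                        variants = 0))
  ev <- evaluate_fixed_method(w$truth, d, method = "truth")
  expect_equal(ev$auc, 1.0)  # labels are a deterministic function of scores
  expect_gt(ev$rho, 0.999)
  expect_equal(ev$n, 100L)

  # an uninformative matrix is near-chance on noisy data
  w2 <- synthetic_world(seed = 43)
  d2 <- simulate_dataset(w2, 400, mix = c(random = 1, tiles = 0, scan = 0,
                                          variants = 0))
  ev2 <- evaluate_fixed_method(all_ones_matrix(), d2, method = "flat")
  expect_equal(ev2$auc, 0.5, tolerance = 0.02)
})

test_that("report summary rows are means/extremes at 3 decimals", {
  rep <- tibble::tibble(allele = c("A", "B", "C"), method = "m",
                        variant = "ALL", n = 10, n_binder = 5,
                        auc = c(0.7012, 0.8006, 0.9001), rho = 0.5)
  s <- report_summary(rep)
  expect_equal(s$auc[s$allele == "Average"], round(mean(rep$auc), 3))
  expect_equal(s$auc[s$allele == "Min"], 0.701)
  expect_equal(s$auc[s$allele == "Max"], 0.9)
})

test_that("homolog-impact analysis: no homologs means identical predictions", {
  w <- synthetic_world(seed = 7)
  d <- simulate_dataset(w, 120, mix = c(random = 1, tiles = 0, scan = 0,
                                        variants = 0))
  ann <- similarity_reduce(d)
  skip_if(any(!ann$in_sp), "random draw produced an accidental homolog pair")
  sp <- sp_impact_analysis(d, baseline_trainer(trainer_config(max_iterations = 3)),
                           k = 5, seed = 11)
  tab <- tidy(sp)
  expect_identical(tab$n_all, tab$n_sr)
  expect_equal(tab$auc_reduction, 0)
  expect_equal(tab$n_reduced, 0L)
  expect_equal(tab$frac_reduced, 0)
})

test_that("homolog-impact table carries the paired design columns", {
  w <- synthetic_world(seed = 3)
  d <- simulate_dataset(w, 250)
  sp <- sp_impact_analysis(d, baseline_trainer(trainer_config(max_iterations = 3)),
                           k = 5, seed = 4)
  tab <- tidy(sp)
  expect_true(all(c("allele", "n_all", "n_sr", "n_sp", "auc_sr", "auc_all",
                    "auc_reduction", "n_reduced", "frac_reduced") %in%
                    names(tab)))
  expect_equal(tab$auc_reduction, tab$auc_all - tab$auc_sr)
  expect_equal(tab$n_reduced, tab$n_all - tab$n_sr)
  expect_equal(tab$frac_reduced, 1 - tab$n_sr / tab$n_all)
  expect_true(tab$n_sp <= tab$n_sr && tab$n_sr <= tab$n_all)
  g <- glance(sp)
  expect_equal(g$mean_auc_reduction, mean(tab$auc_reduction))
})
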