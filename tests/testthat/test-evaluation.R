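test_that("stratified folds balance both classes to within one protein", {
  labs <- tibble::tibble(protein = sprintf("P%03d", 1:100),
                         essential = rep(c(TRUE, FALSE), c(20, 80)))
  folds <- stratified_kfold(labs, k = 10, seed = 1)
  per <- dplyr::count(folds, fold, essential)
  expect_true(all(per$n[per$essential] == 2))
  expect_true(all(per$n[!per$essential] == 8))

  labs10 <- tibble::tibble(protein = letters[1:10],
                           essential = rep(c(TRUE, FALSE), c(2, 8)))
  f5 <- suppressWarnings(stratified_kfold(labs10, k = 5, seed = 2))
  pos_per_fold <- vapply(1:5, function(k) sum(f5$essential[f5$fold == k]),
                         numeric(1))
  expect_equal(sort(pos_per_fold, decreasing = TRUE), c(1, 1, 0, 0, 0))
  neg_per_fold <- vapply(1:5, function(k) sum(!f5$essential[f5$fold == k]),
                         numeric(1))
  expect_true(max(neg_per_fold) - min(neg_per_fold) <= 1)

  expect_identical(stratified_kfold(labs, 10, seed = 7),
                   stratified_kfold(labs, 10, seed = 7))
  expect_warning(stratified_kfold(labs10, k = 3), "fewer than k")
  expect_error(stratified_kfold(dplyr::mutate(labs10, essential = FALSE),
                                k = 3), "both classes")
})

test_that("ROC/AUC agrees with the rank-sum oracle and behaves at the extremes", {
  labs <- tibble::tibble(protein = letters[1:6],
                         essential = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  perfect <- tibble::tibble(protein = letters[1:6], score = 6:1)
  expect_equal(roc_auc(perfect, labs)$auc, 1)
  inverted <- tibble::tibble(protein = letters[1:6], score = 1:6)
  expect_equal(roc_auc(inverted, labs)$auc, 0)
  tied <- tibble::tibble(protein = letters[1:6],
                         score = c(3, 2, 2, 2, 1, 1))
  expect_equal(roc_auc(tied, labs)$auc,
               oracle_auc_ranksum(tied$score, labs$essential))
  expect_error(roc_auc(perfect, dplyr::mutate(labs, essential = FALSE)),
               "both classes")

  set.seed(19)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    ess <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    sc <- sample(seq_len(max(2, n %/% 2)), n, replace = TRUE) # plenty of ties
    r <- roc_auc(setNames(as.numeric(sc), sprintf("P%02d", 1:n)),
                 tibble::tibble(protein = sprintf("P%02d", 1:n),
                                essential = ess))
    expect_equal(r$auc, oracle_auc_ranksum(sc, ess), tolerance = 1e-12)
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
    expect_equal(r$roc$fpr[nrow(r$roc)], 1)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
    expect_false(is.unsorted(r$roc$fpr)); expect_false(is.unsorted(r$roc$tpr))
  }
})

test_that("top-k metrics reproduce the confusion identities", {
  labs <- tibble::tibble(protein = sprintf("P%02d", 1:10),
                         essential = rep(c(TRUE, FALSE), c(4, 6)))
  perfect <- tibble::tibble(protein = labs$protein, score = 10:1)
  m <- topk_metrics(perfect, labs, k = 4)
  expect_equal(unlist(m[c("SN", "SP", "PPV", "NPV", "F_measure", "ACC", "MCC")]),
               c(SN = 1, SP = 1, PPV = 1, NPV = 1, F_measure = 1, ACC = 1,
                 MCC = 1))
  expect_equal(m$FPR, 0)

  # TP=3 FP=2 FN=1 TN=4 arithmetic check
  mcc <- (3 * 4 - 2 * 1) / sqrt(5 * 4 * 6 * 5)
  labs2 <- tibble::tibble(protein = sprintf("P%02d", 1:10),
                          essential = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                        TRUE, FALSE, FALSE, FALSE, FALSE))
  sc2 <- tibble::tibble(protein = labs2$protein, score = 10:1)
  m2 <- topk_metrics(sc2, labs2, k = 5)
  expect_equal(m2$MCC, mcc, tolerance = 1e-12)

  # k = number of positives forces SN = PPV, SP = NPV, FPR = 1 - SP
  set.seed(27)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    ess <- rep(FALSE, n); ess[sample(n, sample(2:(n - 2), 1))] <- TRUE
    sc <- runif(n)
    mt <- topk_metrics(setNames(sc, sprintf("P%02d", 1:n)),
                       tibble::tibble(protein = sprintf("P%02d", 1:n),
                                      essential = ess), k = sum(ess))
    expect_equal(mt$SN, mt$PPV, tolerance = 1e-12)
    expect_equal(mt$SP, mt$NPV, tolerance = 1e-12)
    expect_equal(mt$FPR, 1 - mt$SP, tolerance = 1e-12)
  }
})

test_that("cross-validation tests each protein exactly once and reproduces", {
  fix <- planted_tabular_fixture(90, seed = 33)
  cfg <- tiny_gep_config(rng_seed = 77)
  cv <- cross_validate(fix$features, fix$labels, cfg, k = 3)
  expect_equal(nrow(cv$summary), 3)
  expect_equal(sum(cv$summary$n_test), 90)
  expect_equal(cv$summary$n_train + cv$summary$n_test, rep(90, 3))
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(glance(cv)$mean_auc, cv$mean_auc)
  expect_true(cv$selected_fold %in% 1:3)
  expect_equal(cv$selected_fold,
               order(abs(cv$summary$auc - cv$mean_auc))[1])

  cv2 <- cross_validate(fix$features, fix$labels, cfg, k = 3)
  expect_identical(cv$summary, cv2$summary)
  # evolved classifiers beat a random-score baseline on held-out data
  expect_gt(cv$mean_auc, 0.7)
})
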