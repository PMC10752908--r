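# Fold plans, out-of-fold PF generation, APF assembly, meta fit, end-to-end.

test_that("fold plans are stratified, exact partitions, deterministic", {
  y <- rep(c(1, 0), c(60, 40))
  plan <- make_fold_plan(y, k = 10, seed = 5)
  expect_equal(sort(unique(plan$assignment)), 1:10)
  expect_length(plan$assignment, 100)
  sizes <- table(plan$assignment)
  expect_true(all(sizes == 10))                       # exact division
  # stratification: each fold holds 6 actives, 4 inactives
  for (f in 1:10) {
    expect_equal(sum(y[plan$assignment == f] == 1), 6)
  }
  y2 <- rep(c(1, 0), c(12, 11))
  p2 <- make_fold_plan(y2, k = 10, seed = 1)
  expect_true(all(table(p2$assignment) %in% c(2, 3)))  # remainder spread
  expect_identical(make_fold_plan(y, 10, 7)$assignment,
                   make_fold_plan(y, 10, 7)$assignment)
  expect_error(make_fold_plan(y[1:5], k = 10), "exceeds")
})

test_that("a constant learner yields a constant PF column in [0,1]", {
  cur <- tiny_curated()[1:30, ]
  y <- qsarstack:::as_binary01(as.character(cur$label))
  flat <- qsarstack:::new_fp_block("FP4", matrix(0L, 30, 307), cur$id)
  plan <- make_fold_plan(y, k = 5, seed = 2)
  pf <- suppressWarnings(out_of_fold_pf("RF", flat, y, plan,
                                        grid = list(mtry_mult = 1), seed = 3))
  expect_true(all(pf >= 0 & pf <= 1))
  # prevalence-only fold models emit one value per fold, all near the base rate
  expect_true(all(abs(pf - mean(y)) < 0.15))
})

test_that("out-of-fold predictions never see their own row (no leakage)", {
  cur <- tiny_curated()
  blk <- gen_fp_block(cur, "FP4", signal_frac = 0.03, flip_prob = 0.1,
                      seed = 23)
  y <- qsarstack:::as_binary01(as.character(cur$label))
  plan <- make_fold_plan(y, k = 5, seed = 11)
  pf1 <- out_of_fold_pf("GLM", blk, y, plan, grid = list(lambda = 0.01),
                        seed = 7)
  # perturb one row's features; the model serving its fold was trained
  # without it, so its fold-mates' PF entries must not move
  i <- 5L
  f <- plan$assignment[i]
  mates <- setdiff(which(plan$assignment == f), i)
  blk2 <- blk
  blk2$matrix[i, ] <- withr::with_seed(1, sample(c(0L, 1L), 307, TRUE))
  pf2 <- out_of_fold_pf("GLM", blk2, y, plan, grid = list(lambda = 0.01),
                        seed = 7)
  expect_equal(pf2[mates], pf1[mates], tolerance = 1e-10)
  expect_true(all(pf1 >= 0 & pf1 <= 1))
})

test_that("permuting rows and the fold plan together leaves PFs unchanged", {
  cur <- tiny_curated()[1:40, ]
  blk <- gen_fp_block(cur, "FP4", signal_frac = 0.03, flip_prob = 0.1,
                      seed = 29)
  y <- qsarstack:::as_binary01(as.character(cur$label))
  plan <- make_fold_plan(y, k = 5, seed = 13)
  pf <- out_of_fold_pf("GLM", blk, y, plan, grid = list(lambda = 0.01),
                       seed = 19)
  perm <- withr::with_seed(2, sample(40))
  blk_p <- qsarstack:::new_fp_block("FP4", blk$matrix[perm, , drop = FALSE],
                                    blk$row_ids[perm])
  plan_p <- plan
  plan_p$assignment <- plan$assignment[perm]
  pf_p <- out_of_fold_pf("GLM", blk_p, y[perm], plan_p,
                         grid = list(lambda = 0.01), seed = 19)
  expect_equal(as.numeric(pf_p), as.numeric(pf[perm]), tolerance = 1e-6)
})

test_that("APF assembly fixes width and rejects misaligned columns", {
  plan_a <- structure(list(k = 2L, assignment = rep(1:2, 5), seed = 1L),
                      class = "fold_plan")
  plan_b <- structure(list(k = 2L, assignment = rep(2:1, 5), seed = 2L),
                      class = "fold_plan")
  col <- function(plan) {
    x <- runif(10)
    attr(x, "fold_plan") <- plan
    x
  }
  withr::with_seed(3, {
    cols6 <- setNames(replicate(6, col(plan_a), simplify = FALSE),
                      paste0("A", 1:6, "__D"))
    apf <- assemble_apf(cols6)
    expect_equal(ncol(apf$matrix), 6)                   # 2 algos x 3 descriptors
    bad <- cols6
    attr(bad[[2]], "fold_plan") <- plan_b
    expect_error(assemble_apf(bad), "alignment")
    short <- cols6
    short[[3]] <- short[[3]][1:5]
    expect_error(assemble_apf(short), "alignment")
  })
})

test_that("the meta SVM separates a perfect PF column and is deterministic", {
  withr::with_seed(8, {
    y <- rep(c(1, 0), each = 25)
    pf <- cbind(perfect__PF = y * 0.9 + 0.05,
                noise__PF = runif(50))
    m <- fit_meta(pf, y, selected = "perfect__PF", k = 5, seed = 3)
    p <- qsarstack:::predict_learner(m$fit, pf[, "perfect__PF", drop = FALSE])
    expect_equal(qsarstack:::mcc_from_counts(
      confusion_counts(y, as.integer(p >= 0.5))), 1)
    expect_error(fit_meta(pf, y, selected = character(0)), "at least one")
    m2 <- fit_meta(pf, y, selected = "perfect__PF", k = 5, seed = 3)
    expect_identical(m$tuned_params, m2$tuned_params)
  })
})

test_that("the full stacker runs end to end on a small configuration", {
  cur <- tiny_curated(60, 60, label_noise = 0.05, seed = 41)
  blocks <- list(
    FP4 = gen_fp_block(cur, "FP4", signal_frac = 0.03, flip_prob = 0.15,
                       seed = 5),
    Pubchem = gen_fp_block(cur, "Pubchem", signal_frac = 0.02,
                           flip_prob = 0.2, seed = 6))
  grids <- qsarstack:::experiment_grids()
  model <- fit_stacker(cur, blocks, algorithms = c("GLM", "CART"),
                       grids = grids, sel_grid = selection_grid(2, 4, 2),
                       k = 5, seed = 17)
  expect_s3_class(model, "stacked_model")
  expect_length(model$base_models, 4)                    # 2 algos x 2 blocks
  expect_equal(ncol(model$apf$matrix), 4)
  expect_lte(length(model$selection$chosen_columns), 4)
  expect_true(all(model$selection$chosen_columns %in%
                    colnames(model$apf$matrix)))
  # deployment predictions on the training compounds are stable and bounded
  pred <- predict(model, blocks = blocks)
  expect_equal(pred$id, cur$id)
  expect_true(all(pred$p_active >= 0 & pred$p_active <= 1))
  pred2 <- predict(model, blocks = blocks)
  expect_identical(pred$p_active, pred2$p_active)
  # planted-motif compounds score as active under a separable fixture
  sep <- tiny_curated(30, 30, seed = 51)
  sep_blocks <- list(FP4 = separable_block(sep, seed = 7))
  sep_model <- fit_stacker(sep, sep_blocks, algorithms = c("GLM", "CART"),
                           grids = grids, sel_grid = selection_grid(1, 2, 1),
                           k = 5, seed = 19)
  sep_pred <- predict(sep_model, blocks = sep_blocks)
  agree <- mean((sep_pred$p_active > 0.5) == (sep$label == "active"))
  expect_gte(agree, 0.95)
  expect_error(predict(sep_model, blocks = list()), "missing fingerprint")
  expect_error(fit_stacker(cur[0, ], blocks), "empty training split")
})

test_that("independent evaluation guards against train/test leakage", {
  cur <- stratified_split(tiny_curated(60, 60, seed = 41), 0.8, seed = 3)
  tr <- cur[cur$split == "train", ]
  te <- cur[cur$split == "test", ]
  blk_all <- gen_fp_block(cur, "FP4", signal_frac = 0.03, flip_prob = 0.1,
                          seed = 33)
  sub_block <- function(rows) qsarstack:::new_fp_block(
    "FP4", blk_all$matrix[match(rows$id, cur$id), , drop = FALSE], rows$id)
  model <- fit_stacker(tr, list(FP4 = sub_block(tr)),
                       algorithms = c("GLM", "CART"),
                       grids = qsarstack:::experiment_grids(),
                       sel_grid = selection_grid(1, 2, 1), k = 5, seed = 23)
  rep <- evaluate_independent(model, te, list(FP4 = sub_block(te)))
  expect_equal(rep$context, "independent_test")
  expect_equal(rep$TP + rep$TN + rep$FP + rep$FN, nrow(te))
  expect_error(evaluate_independent(model, tr, list(FP4 = sub_block(tr))),
               "leakage")
  expect_error(evaluate_independent(model, te[0, ], list()), "empty")
})

test_that("independent performance tracks cross-validation on shared fixtures", {
  deltas <- vapply(1:6, function(s) {
    cur <- stratified_split(
      tiny_curated(100, 100, label_noise = 0.05, seed = 60 + s), 0.75,
      seed = s)
    tr <- cur[cur$split == "train", ]; te <- cur[cur$split == "test", ]
    blk <- gen_fp_block(cur, "FP4", signal_frac = 0.05, flip_prob = 0.1,
                        seed = 70 + s)
    pick <- function(rows) qsarstack:::new_fp_block(
      "FP4", blk$matrix[match(rows$id, cur$id), , drop = FALSE], rows$id)
    fit_fun <- function(Xtr, ytr, sd) {
      lf <- qsarstack:::fit_learner("GLM", Xtr, ytr, list(lambda = 0.01), sd)
      function(Xte) qsarstack:::predict_learner(lf, Xte)
    }
    cv <- cross_validate(pick(tr)$matrix, tr$label, fit_fun, k = 5, seed = s)
    lf <- qsarstack:::fit_learner(
      "GLM", pick(tr)$matrix,
      qsarstack:::as_binary01(as.character(tr$label)), list(lambda = 0.01), s)
    ind <- compute_metrics(
      te$label, scores = qsarstack:::predict_learner(lf, pick(te)$matrix),
      context = "independent_test")
    abs(cv$MCC - ind$MCC)
  }, numeric(1))
  expect_lte(stats::median(deltas), 0.15)
  expect_lte(max(deltas), 0.3)
})
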