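two_tissue_fixture <- function(n_per = 100, seed = 1) {
  specs <- lapply(1:2, function(i)
    cohort_spec(paste0("TT", i), n_tumor = n_per, seed = seed + i,
                base_alpha = base_alpha(80, seed = i)))
  cohorts <- lapply(specs, generate_cohort)
  fr <- do.call(rbind, lapply(cohorts, function(co)
    relative_expression(co$expression)$fractions))
  meta <- data.frame(sample = rownames(fr),
                     cohort = rep(paste0("TT", 1:2), each = n_per))
  list(features = fr, meta = meta,
       labels = setNames(meta$cohort, meta$sample))
}

test_that("balanced splits follow the 60/10/30 per-cohort rule", {
  meta <- data.frame(sample = paste0("s", 1:100),
                     cohort = rep(c("A", "B"), each = 50))
  sp <- balanced_split(meta, seed = 3)
  expect_equal(unname(sp$per_cohort), c(30, 5, 15))
  expect_equal(length(sp$train), 60)
  expect_equal(length(sp$validation), 10)
  expect_equal(length(sp$test), 30)
  all_ids <- c(sp$train, sp$validation, sp$test)
  expect_equal(anyDuplicated(all_ids), 0L)       # disjoint
  expect_true(all(table(meta$cohort[match(sp$test, meta$sample)]) == 15))

  # unequal cohorts: both capped at the smallest cohort's size
  meta2 <- data.frame(sample = paste0("s", 1:150),
                      cohort = rep(c("A", "B"), c(50, 100)))
  sp2 <- balanced_split(meta2, seed = 3)
  expect_equal(length(c(sp2$train, sp2$validation, sp2$test)), 100)

  expect_identical(balanced_split(meta, seed = 9)$train,
                   balanced_split(meta, seed = 9)$train)
  meta3 <- data.frame(sample = paste0("s", 1:15),
                      cohort = rep(c("A", "B"), c(9, 6)))
  expect_error(balanced_split(meta3), "A.*B|B.*A|minimum size")
})

test_that("the c-statistic agrees with brute-force pair counting", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.3), c(1, 1, 0)), 1.0)
  set.seed(60)
  for (rep in 1:20) {
    scores <- round(runif(30), 2)    # rounded: exercises tie handling
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    brute <- mean(ifelse(scores[pairs$i] > scores[pairs$j], 1,
                         ifelse(scores[pairs$i] == scores[pairs$j], 0.5, 0)))
    expect_equal(c_statistic(scores, y), brute, tolerance = 1e-12)
  }
})

test_that("logistic classifier separates well-separated tissue compositions", {
  fx <- two_tissue_fixture(seed = 5)
  sp <- balanced_split(fx$meta, seed = 2)
  model <- fit_logistic_classifier(fx$features, fx$labels, sp)
  expect_gte(model$report$accuracy, 0.95)
  expect_gte(model$report$c_statistic, 0.95)
})

test_that("permuted labels give a chance-level c-statistic", {
  fx <- two_tissue_fixture(seed = 7)
  sp <- balanced_split(fx$meta, seed = 4)
  cs <- vapply(1:6, function(s) {
    set.seed(100 + s)
    perm <- setNames(sample(unname(fx$labels)), names(fx$labels))
    fit_logistic_classifier(fx$features, perm, sp)$report$c_statistic
  }, 0)
  expect_lt(abs(mean(cs) - 0.5), 0.1)
})

test_that("complete separation is reported as a status, not an exception", {
  x <- matrix(c(1:10, 21:30), ncol = 1,
              dimnames = list(paste0("s", 1:20), "f"))
  labels <- setNames(rep(c("lo", "hi"), each = 10), rownames(x))
  meta <- data.frame(sample = rownames(x), cohort = "C")
  sp <- balanced_split(meta, seed = 1)
  model <- fit_logistic_classifier(x, labels, sp)
  expect_true(model$status %in% c("complete_separation", "non_converged"))
})

test_that("classifier evaluation computes exact-match metrics and guards labels", {
  fx <- two_tissue_fixture(seed = 9)
  sp <- balanced_split(fx$meta, seed = 6)
  model <- fit_logistic_classifier(fx$features, fx$labels, sp)
  # predictions identical to labels on training-like data: accuracy 1
  rep_tr <- evaluate_classifier(model, fx$features[sp$train, ],
                                fx$labels[sp$train])
  expect_gte(rep_tr$accuracy, 0.99)
  expect_error(evaluate_classifier(model, fx$features[sp$test, ],
                                   setNames(rep("XX", length(sp$test)),
                                            sp$test)),
               "unseen")
})

test_that("a constant predictor on a balanced set scores accuracy one half", {
  # degenerate model: intercept-only logistic always predicts one class
  x <- matrix(rnorm(40), ncol = 2,
              dimnames = list(paste0("s", 1:20), c("a", "b")))
  labels <- setNames(rep(c("n", "p"), each = 10), rownames(x))
  fake <- structure(list(fit = glm(y ~ 1,
                                   data = data.frame(y = c(0, 1, 0, 1)),
                                   family = binomial()),
                         classes = c("n", "p"), status = "converged"),
                    class = "rpt_logistic")
  rep0 <- evaluate_classifier(fake, x, labels)
  expect_equal(rep0$accuracy, 0.5)
  expect_true(rep0$sensitivity == 0 || rep0$specificity == 0)
})

test_that("the hyperparameter sweep trains the full grid reproducibly", {
  fx <- two_tissue_fixture(seed = 11)
  sp <- balanced_split(fx$meta, seed = 8)
  grid <- ann_grid(learning_rate = c(0.005, 0.01), batch_size = NA,
                   dropout_keep = 1, hidden = list(10, 25), l2 = 1e-4)
  expect_equal(nrow(grid), 4L)                  # Cartesian product
  sw1 <- ann_hyperparameter_sweep(fx$features, fx$labels, sp, grid,
                                  seed = 3, max_epochs = 60)
  sw2 <- ann_hyperparameter_sweep(fx$features, fx$labels, sp, grid,
                                  seed = 3, max_epochs = 60)
  expect_equal(nrow(sw1$grid_results), 4L)
  expect_true(all(is.finite(sw1$grid_results$validation_accuracy)))
  expect_identical(sw1$best_index, sw2$best_index)
  expect_identical(sw1$model$W, sw2$model$W)
  expect_equal(sw1$report$accuracy, sw2$report$accuracy)
})

test_that("a zero-size hidden layer reduces the network to logistic regression", {
  # low-dimensional overlapping classes: the logistic MLE is finite
  # (no separation), so the two linear fits must land on near-identical
  # decision rules
  set.seed(77)
  n <- 150
  x <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = 1.2), n, 2))
  rownames(x) <- paste0("s", seq_len(2 * n))
  colnames(x) <- c("f1", "f2")
  meta <- data.frame(sample = rownames(x), cohort = "C")
  labels <- setNames(rep(c("a", "b"), each = n), rownames(x))
  sp <- balanced_split(meta, seed = 10)
  lin <- ann_hyperparameter_sweep(x, labels, sp,
                                  ann_grid(learning_rate = 0.05,
                                           batch_size = NA, dropout_keep = 1,
                                           hidden = list(0), l2 = 1e-5),
                                  seed = 2)
  lr <- fit_logistic_classifier(x, labels, sp)
  expect_identical(lr$status, "converged")
  expect_lte(abs(lin$report$accuracy - lr$report$accuracy), 0.05)
})

test_that("the default sweep grid spans the documented axes", {
  g <- ann_grid()
  expect_setequal(unique(g$learning_rate), c(0.001, 0.002, 0.005, 0.01))
  expect_setequal(unique(g$dropout_keep), c(0.9, 0.95, 1))
  expect_true(any(is.na(unique(g$batch_size))))
  lens <- lengths(unique(g$hidden))
  expect_true(all(lens <= 2))
  sizes <- unlist(unique(g$hidden))
  expect_true(all(sizes %in% seq(0, 200, by = 25)))
})
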