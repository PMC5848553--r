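#' Cohort-balanced train/validation/test split
#'
#' Balances by cancer cohort: every cohort contributes the same number of
#' samples (the smallest cohort's size caps the per-cohort draw), and the
#' 60/10/30 fractions are applied within each cohort with floor rounding,
#' the remainder going to the training set. Draws are seed-deterministic.
#'
#' @param sample_meta Data frame with \code{sample} and \code{cohort}
#'   columns.
#' @param fractions Train/validation/test fractions summing to 1
#'   (default \code{c(0.6, 0.1, 0.3)}).
#' @param seed Integer seed.
#' @param min_cohort Minimum cohort size (default 10); smaller cohorts are
#'   an error.
#' @return Object of class \code{rpt_split}: list with \code{train},
#'   \code{validation}, \code{test} (sample-id vectors), \code{per_cohort}
#'   counts and \code{seed}.
#' @export
balanced_split <- function(sample_meta, fractions = c(0.6, 0.1, 0.3),
                           seed = 1, min_cohort = 10) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9,
            all(fractions > 0))
  counts <- table(sample_meta$cohort)
  small <- counts < min_cohort
  if (any(small))
    stop_ribotype("cohort(s) below the minimum size of ", min_cohort, ": ",
                  paste(names(counts)[small], collapse = ", "))
  cap <- min(counts)
  n_va <- floor(fractions[2L] * cap)
  n_te <- floor(fractions[3L] * cap)
  n_tr <- cap - n_va - n_te
  sets <- with_seed(seed, {
    lapply(split(sample_meta$sample, sample_meta$cohort), function(ids) {
      drawn <- sample(ids, cap)
      list(train = drawn[seq_len(n_tr)],
           validation = drawn[n_tr + seq_len(n_va)],
           test = drawn[n_tr + n_va + seq_len(n_te)])
    })
  })
  structure(list(train = unlist(lapply(sets, `[[`, "train"), use.names = FALSE),
                 validation = unlist(lapply(sets, `[[`, "validation"), use.names = FALSE),
                 test = unlist(lapply(sets, `[[`, "test"), use.names = FALSE),
                 per_cohort = c(train = n_tr, validation = n_va, test = n_te),
                 seed = seed),
            class = "rpt_split")
}

#' @export
print.rpt_split <- function(x, ...) {
  cat("Balanced split:", length(x$train), "train /", length(x$validation),
      "validation /", length(x$test), "test (",
      paste(x$per_cohort, collapse = "/"), "per cohort )\n")
  invisible(x)
}

feature_matrix <- function(features) {
  if (inherits(features, "rpt_relexpr")) features$fractions else as.matrix(features)
}

#' Area under the ROC curve (c-statistic)
#'
#' Probability that a randomly chosen positive scores above a randomly
#' chosen negative, ties counted half; computed from ranks.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, or coercible to 0/1).
#' @return AUC in [0, 1].
#' @export
c_statistic <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_ribotype("need both classes for a c-statistic")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and evaluate a binary logistic classifier
#'
#' Maximum-likelihood logistic regression on the training set of a balanced
#' split; the c-statistic, sensitivity and specificity (at a 0.5 threshold)
#' and accuracy are reported on the held-out test set. Complete separation
#' or non-convergence is detected and reported in the \code{status} field
#' rather than raised.
#'
#' @param features An \code{rpt_relexpr} or samples-by-features matrix with
#'   row names.
#' @param labels Binary labels named by sample (or aligned with the feature
#'   rows); coerced to factor, second level = positive.
#' @param split An \code{rpt_split}.
#' @return Object of class \code{rpt_logistic}: list with \code{fit},
#'   \code{classes}, \code{status} and \code{report}
#'   (accuracy, c_statistic, sensitivity, specificity on the test set).
#' @export
fit_logistic_classifier <- function(features, labels, split) {
  m <- feature_matrix(features)
  labels <- align_labels(labels, m)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop_ribotype("logistic classifier needs exactly 2 classes")
  tr <- match(split$train, rownames(m))
  if (anyNA(tr)) stop_ribotype("split references unknown samples")
  ytr <- y[tr]
  if (length(unique(ytr)) < 2L) stop_ribotype("training labels are single-class")
  df_tr <- data.frame(.y = as.integer(ytr) - 1L, m[tr, , drop = FALSE],
                      check.names = FALSE)
  status <- "converged"
  withCallingHandlers(
    fit <- stats::glm(.y ~ ., data = df_tr, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        status <<- "complete_separation"
      else if (grepl("did not converge", conditionMessage(w)))
        status <<- "non_converged"
      invokeRestart("muffleWarning")
    })
  if (status == "converged" && !fit$converged) status <- "non_converged"
  model <- structure(list(fit = fit, classes = levels(y), status = status),
                     class = "rpt_logistic")
  model$report <- evaluate_classifier(model, m[split$test, , drop = FALSE],
                                      y[match(split$test, rownames(m))])
  model
}

#' @export
predict.rpt_logistic <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  nd <- as.data.frame(feature_matrix(newdata))
  # compositional features are rank-deficient by construction (fractions sum
  # to 1); the aliased-coefficient warning from predict.lm is expected
  pr <- suppressWarnings(stats::predict(object$fit, newdata = nd,
                                        type = "response"))
  if (type == "prob") return(pr)
  factor(object$classes[1L + (pr >= 0.5)], levels = object$classes)
}

align_labels <- function(labels, m) {
  if (!is.null(names(labels))) {
    out <- labels[rownames(m)]
    if (anyNA(out) && !anyNA(labels))
      stop_ribotype("labels do not cover all feature rows")
    return(out)
  }
  if (length(labels) != nrow(m))
    stop_ribotype("labels length does not match feature rows")
  stats::setNames(labels, rownames(m))
}

#' Evaluate a trained classifier on labelled data
#'
#' Exact-match accuracy; binary models additionally report the c-statistic
#' and the sensitivity/specificity of the 0.5-threshold rule. Metrics are
#' computed on the provided samples only.
#'
#' @param model An \code{rpt_logistic} or \code{rpt_mlp}.
#' @param features Feature matrix (or \code{rpt_relexpr}) for the evaluation
#'   samples.
#' @param labels True labels; every label must have been seen in training.
#' @return List with \code{accuracy}, \code{n}, and for binary models
#'   \code{c_statistic}, \code{sensitivity}, \code{specificity}.
#' @export
evaluate_classifier <- function(model, features, labels) {
  m <- feature_matrix(features)
  y <- as.character(align_labels(labels, m))
  unknown <- setdiff(unique(y), model$classes)
  if (length(unknown))
    stop_ribotype("labels unseen in training: ", paste(unknown, collapse = ", "))
  pred <- as.character(predict(model, m))
  out <- list(accuracy = mean(pred == y), n = length(y))
  if (length(model$classes) == 2L) {
    pos <- model$classes[2L]
    scores <- if (inherits(model, "rpt_logistic")) {
      predict(model, m, type = "prob")
    } else {
      predict(model, m, type = "prob")[, pos]
    }
    is_pos <- y == pos
    out$c_statistic <- c_statistic(scores, is_pos)
    out$sensitivity <- if (any(is_pos)) mean(pred[is_pos] == pos) else NA_real_
    out$specificity <- if (any(!is_pos)) mean(pred[!is_pos] != pos) else NA_real_
  }
  out
}
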