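#' Train a feed-forward ReLU network
#'
#' Fully-connected multilayer perceptron with ReLU hidden activations and a
#' softmax output, trained by mini-batch gradient descent on the
#' cross-entropy loss with optional inverted dropout and L2 weight decay.
#' Validation accuracy is evaluated once per epoch; training stops when it
#' has not improved by more than \code{min_gain} over \code{patience}
#' consecutive evaluations (a plateau), or at \code{max_epochs}. The weights
#' achieving the best validation accuracy are kept. A hidden layer of size 0
#' is treated as absent, so \code{hidden = 0} reduces the model to
#' multinomial logistic regression.
#'
#' @param x Training features (samples x features).
#' @param y Training labels (factor or character).
#' @param x_val,y_val Validation set (required; drives the stopping rule).
#' @param hidden Integer vector of hidden-layer sizes (at most two layers in
#'   the standard sweep).
#' @param learning_rate Gradient-descent step size.
#' @param batch_size Mini-batch size; \code{NULL} means full batch.
#' @param dropout_keep Keep-probability for hidden units during training
#'   (1 disables dropout).
#' @param l2 L2 regularization rate.
#' @param max_epochs Maximum passes over the training data.
#' @param patience,min_gain Plateau rule for early stopping.
#' @param eval_every Epochs between validation evaluations; the plateau rule
#'   counts evaluations, so the default (25) tolerates up to
#'   \code{patience * eval_every} epochs without measurable gain before
#'   stopping.
#' @param seed Seed for initialization, shuffling and dropout.
#' @param standardize Center and scale features by their training-set mean
#'   and standard deviation (stored in the model and reapplied at
#'   prediction). Off by default: the classifiers consume relative
#'   expression fractions as-is.
#' @return Object of class \code{rpt_mlp} with weights, \code{classes},
#'   \code{config} and \code{validation_accuracy}.
#' @export
train_mlp <- function(x, y, x_val, y_val, hidden = 50, learning_rate = 0.005,
                      batch_size = NULL, dropout_keep = 1, l2 = 1e-4,
                      max_epochs = 4000, patience = 20, min_gain = 1e-3,
                      eval_every = 25, seed = 1, standardize = FALSE) {
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  if (nrow(x_val) == 0L) stop_ribotype("empty validation set")
  scaling <- NULL
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    scaling <- list(center = ctr, scale = scl)
    x <- scale(x, ctr, scl)
    x_val <- scale(x_val, ctr, scl)
  }
  y <- factor(y)
  classes <- levels(y)
  y_val <- factor(y_val, levels = classes)
  hidden <- hidden[hidden > 0]
  sizes <- c(ncol(x), hidden, length(classes))
  n <- nrow(x)
  t_onehot <- diag(length(classes))[as.integer(y), , drop = FALSE]

  with_seed(seed, {
    nl <- length(sizes) - 1L
    W <- vector("list", nl); b <- vector("list", nl)
    for (l in seq_len(nl)) {   # He initialization for ReLU stacks
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    best <- list(W = W, b = b, acc = -Inf)
    acc_hist <- numeric(0)        # best-so-far at each evaluation
    bs <- if (is.null(batch_size)) n else min(batch_size, n)

    for (epoch in seq_len(max_epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        tb <- t_onehot[idx, , drop = FALSE]
        nb <- nrow(xb)
        # forward with dropout masks on hidden activations
        A <- vector("list", nl + 1L); A[[1L]] <- xb
        masks <- vector("list", nl)
        for (l in seq_len(nl)) {
          Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
          if (l < nl) {
            H <- pmax(Z, 0)
            if (dropout_keep < 1) {
              masks[[l]] <- matrix(stats::runif(length(H)) < dropout_keep,
                                   nrow(H), ncol(H)) / dropout_keep
              H <- H * masks[[l]]
            }
            A[[l + 1L]] <- H
          } else {
            A[[l + 1L]] <- softmax_rows(Z)
          }
        }
        # backward
        delta <- (A[[nl + 1L]] - tb) / nb
        for (l in rev(seq_len(nl))) {
          gW <- crossprod(A[[l]], delta) + l2 * W[[l]]
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- delta %*% t(W[[l]])
            gate <- A[[l]] > 0              # ReLU gate; zero where dropped
            if (dropout_keep < 1) gate <- gate / dropout_keep
            delta <- delta * gate
          }
          W[[l]] <- W[[l]] - learning_rate * gW
          b[[l]] <- b[[l]] - learning_rate * gb
        }
      }
      if (epoch %% eval_every == 0L || epoch == max_epochs) {
        acc <- mean(mlp_predict_classes(W, b, x_val, classes) ==
                      as.character(y_val))
        # ties keep the most recent weights: the margin keeps growing
        # after the validation accuracy saturates
        if (acc >= best$acc) best <- list(W = W, b = b, acc = acc)
        acc_hist <- c(acc_hist, best$acc)
        ne <- length(acc_hist)
        # plateau: best accuracy gained no more than min_gain over the
        # last `patience` evaluations
        if (ne > patience &&
            acc_hist[ne] - acc_hist[ne - patience] <= min_gain) break
      }
    }
    structure(list(W = best$W, b = best$b, classes = classes,
                   scaling = scaling,
                   validation_accuracy = best$acc,
                   config = list(hidden = hidden,
                                 learning_rate = learning_rate,
                                 batch_size = batch_size,
                                 dropout_keep = dropout_keep, l2 = l2,
                                 max_epochs = max_epochs,
                                 patience = patience, min_gain = min_gain,
                                 eval_every = eval_every, seed = seed)),
              class = "rpt_mlp")
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward_probs <- function(W, b, x) {
  nl <- length(W)
  A <- as.matrix(x)
  for (l in seq_len(nl)) {
    Z <- sweep(A %*% W[[l]], 2, b[[l]], "+")
    A <- if (l < nl) pmax(Z, 0) else softmax_rows(Z)
  }
  A
}

mlp_predict_classes <- function(W, b, x, classes) {
  classes[max.col(mlp_forward_probs(W, b, x), ties.method = "first")]
}

#' @export
predict.rpt_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- feature_matrix(newdata)
  if (!is.null(object$scaling))
    x <- scale(x, object$scaling$center, object$scaling$scale)
  pr <- mlp_forward_probs(object$W, object$b, x)
  colnames(pr) <- object$classes
  if (type == "prob") return(pr)
  factor(mlp_predict_classes(object$W, object$b, x, object$classes),
         levels = object$classes)
}

#' @export
print.rpt_mlp <- function(x, ...) {
  cat("ReLU MLP:", paste(x$config$hidden, collapse = "-"),
      "hidden;", length(x$classes), "classes; validation accuracy",
      format(x$validation_accuracy, digits = 3), "\n")
  invisible(x)
}

#' Hyperparameter grid for the network sweep
#'
#' Default grids mirror the sweep protocol: learning rate
#' \{0.001, 0.002, 0.005, 0.01\}, batch size \{100, 500, none\}, dropout
#' keep-probability \{0.9, 0.95, 1\}, one or two hidden layers with sizes
#' 0-200 in steps of 25, and L2 rate \{1e-5, 1e-4, 1e-3\}. Any axis can be
#' reduced; the sweep trains the full Cartesian product.
#'
#' @param learning_rate,batch_size,dropout_keep,l2 Numeric grids
#'   (\code{batch_size} may contain \code{NA} meaning full batch).
#' @param hidden List of integer vectors of hidden sizes.
#' @return Data frame (one row per configuration) with a list column
#'   \code{hidden}.
#' @export
ann_grid <- function(learning_rate = c(0.001, 0.002, 0.005, 0.01),
                     batch_size = c(100, 500, NA),
                     dropout_keep = c(0.9, 0.95, 1),
                     hidden = c(lapply(seq(0, 200, by = 25), function(h) h),
                                unlist(lapply(seq(0, 200, by = 25), function(h1)
                                  lapply(seq(0, 200, by = 25), function(h2)
                                    c(h1, h2))), recursive = FALSE)),
                     l2 = c(1e-5, 1e-4, 1e-3)) {
  grid <- expand.grid(learning_rate = learning_rate,
                      batch_size = batch_size,
                      dropout_keep = dropout_keep,
                      hidden_idx = seq_along(hidden),
                      l2 = l2)
  grid$hidden <- hidden[grid$hidden_idx]
  grid$hidden_idx <- NULL
  grid
}

#' Hyperparameter sweep for the feed-forward network
#'
#' Trains one network per grid row on the training set, selects the
#' configuration with the highest validation accuracy (ties: first row),
#' and reports the test metrics of the selected model only.
#'
#' @param features An \code{rpt_relexpr} or samples-by-features matrix.
#' @param labels Labels named by sample (or aligned with feature rows).
#' @param split An \code{rpt_split}.
#' @param grid Data frame from \code{\link{ann_grid}} (use a reduced grid
#'   for interactive work).
#' @param seed Training seed shared by all configurations.
#' @param max_epochs,patience,min_gain,eval_every,standardize Passed to
#'   \code{\link{train_mlp}}.
#' @return List with \code{model} (the selected \code{rpt_mlp}),
#'   \code{report} (test metrics), \code{grid_results} (validation accuracy
#'   per configuration) and \code{best_index}.
#' @export
ann_hyperparameter_sweep <- function(features, labels, split,
                                     grid = ann_grid(), seed = 1,
                                     max_epochs = 4000, patience = 20,
                                     min_gain = 1e-3, eval_every = 25,
                                     standardize = FALSE) {
  if (nrow(grid) == 0L) stop_ribotype("empty hyperparameter grid")
  m <- feature_matrix(features)
  labels <- align_labels(labels, m)
  if (length(unique(labels)) < 2L) stop_ribotype("need >= 2 classes")
  if (length(split$validation) == 0L) stop_ribotype("empty validation set")
  tr <- match(split$train, rownames(m))
  va <- match(split$validation, rownames(m))
  te <- match(split$test, rownames(m))
  if (anyNA(c(tr, va, te))) stop_ribotype("split references unknown samples")
  y <- factor(labels)
  models <- vector("list", nrow(grid))
  val_acc <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    bs <- grid$batch_size[i]
    models[[i]] <- train_mlp(m[tr, , drop = FALSE], y[tr],
                             m[va, , drop = FALSE], y[va],
                             hidden = grid$hidden[[i]],
                             learning_rate = grid$learning_rate[i],
                             batch_size = if (is.na(bs)) NULL else bs,
                             dropout_keep = grid$dropout_keep[i],
                             l2 = grid$l2[i], max_epochs = max_epochs,
                             patience = patience, min_gain = min_gain,
                             eval_every = eval_every, seed = seed,
                             standardize = standardize)
    val_acc[i] <- models[[i]]$validation_accuracy
  }
  best <- which.max(val_acc)
  model <- models[[best]]
  report <- evaluate_classifier(model, m[te, , drop = FALSE], y[te])
  grid_results <- grid
  grid_results$validation_accuracy <- val_acc
  list(model = model, report = report, grid_results = grid_results,
       best_index = best)
}
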