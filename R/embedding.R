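#' PCA embedding of relative RPT expression
#'
#' Column-centered projection onto the top principal axes, with the fraction
#' of total variance explained by each retained component.
#'
#' @param x An \code{rpt_relexpr} or a plain numeric samples-by-features
#'   matrix.
#' @param k Number of components to retain.
#' @return List with \code{coords} (samples x k scores) and
#'   \code{explained_variance} (length-k non-increasing fractions of the
#'   total variance; they sum to 1 when \code{k} spans the full rank).
#' @export
pca_embed <- function(x, k = 2) {
  m <- if (inherits(x, "rpt_relexpr")) x$fractions else as.matrix(x)
  if (k <= 0) stop_ribotype("k must be positive")
  if (k > min(dim(m))) stop_ribotype("k exceeds min(n_samples, n_features)")
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  list(coords = fit$x[, seq_len(k), drop = FALSE],
       explained_variance = (ev / sum(ev))[seq_len(k)])
}

#' t-SNE embedding configuration
#'
#' Records every knob of the t-SNE optimization protocol: a learning rate
#' (epsilon) of 10 and up to 5000 iterations, stopping early once the
#' embedding has stabilized (maximum per-coordinate update below
#' \code{stall_tol}); early exaggeration of the affinities by a factor of 12
#' for the first 250 iterations; momentum 0.5 switching to 0.8 at iteration
#' 250. Perplexity is conventionally swept in 6-15 for single-cohort runs and
#' 10-30 for grouped runs.
#'
#' @param dims Output dimensionality, 2 or 3.
#' @param perplexity Target perplexity (effective neighbor count); must be
#'   below \code{n_samples - 1}.
#' @param epsilon Gradient-descent learning rate.
#' @param iterations Maximum iterations.
#' @param early_exaggeration,exaggeration_duration Exaggeration factor and the
#'   number of initial iterations it applies to.
#' @param momentum_initial,momentum_final,momentum_switch Momentum schedule.
#' @param seed Seed for the Gaussian initialization.
#' @param init \code{"gaussian"} (sd 1e-4) or \code{"pca"} (first
#'   \code{dims} principal components, rescaled to sd 1e-4).
#' @param stall_tol Stabilization threshold on the max coordinate update.
#' @param record_every Iteration stride for the KL divergence trace.
#' @return List of class \code{embedding_config}.
#' @export
embedding_config <- function(dims = 2, perplexity = 10, epsilon = 10,
                             iterations = 5000, early_exaggeration = 12,
                             exaggeration_duration = 250,
                             momentum_initial = 0.5, momentum_final = 0.8,
                             momentum_switch = 250, seed = 1,
                             init = c("gaussian", "pca"),
                             stall_tol = 1e-7, record_every = 50) {
  stopifnot(dims %in% c(2, 3), perplexity > 0, iterations >= 1, epsilon > 0)
  structure(list(dims = dims, perplexity = perplexity, epsilon = epsilon,
                 iterations = iterations,
                 early_exaggeration = early_exaggeration,
                 exaggeration_duration = exaggeration_duration,
                 momentum_initial = momentum_initial,
                 momentum_final = momentum_final,
                 momentum_switch = momentum_switch, seed = seed,
                 init = match.arg(init), stall_tol = stall_tol,
                 record_every = record_every),
            class = "embedding_config")
}

#' Calibrate one conditional affinity row to a target perplexity
#'
#' Finds the Gaussian bandwidth (precision beta) whose Gibbs distribution
#' over a point's neighbors has Shannon entropy H with \code{2^H} equal to
#' the requested perplexity, by bisection on beta.
#'
#' @param d2 Squared distances to the neighbors (self excluded), finite.
#' @param perplexity Target perplexity; must be below \code{length(d2)}.
#' @param tol Convergence tolerance on \code{|2^H - perplexity|}.
#' @param max_iter Maximum bisection steps.
#' @return List with \code{p} (probability row summing to 1) and \code{beta}
#'   (precision of the Gaussian kernel).
#' @export
calibrate_conditional_probabilities <- function(d2, perplexity, tol = 1e-5,
                                                max_iter = 100) {
  n <- length(d2)
  if (any(!is.finite(d2))) stop_ribotype("non-finite distances")
  if (perplexity >= n)
    stop_ribotype("perplexity ", perplexity, " unreachable with ", n,
                  " neighbors (2^H <= ", n, ")")
  d2s <- d2 - min(d2)
  beta <- 1; betamin <- -Inf; betamax <- Inf
  achieved <- NA_real_; p <- NULL
  for (iter in seq_len(max_iter)) {
    w <- exp(-beta * d2s)
    sw <- sum(w)
    p <- w / sw
    # entropy in nats; shift-invariant because p is normalized
    h <- log(sw) + beta * sum(d2s * w) / sw
    achieved <- exp(h)
    if (abs(achieved - perplexity) <= tol) {
      return(list(p = p, beta = beta))
    }
    if (achieved > perplexity) {       # too entropic: sharpen
      betamin <- beta
      beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
    } else {
      betamax <- beta
      beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
    }
  }
  stop_ribotype("perplexity calibration did not converge after ", max_iter,
                " iterations (achieved ", format(achieved), ", target ",
                perplexity, ")")
}

# Symmetrized joint affinity matrix P over all samples.
joint_affinities <- function(x, perplexity, tol = 1e-5) {
  d2 <- squared_distances(x)
  n <- nrow(d2)
  pc <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cal <- calibrate_conditional_probabilities(d2[i, -i], perplexity, tol = tol)
    pc[i, -i] <- cal$p
  }
  (pc + t(pc)) / (2 * n)
}

#' Kullback-Leibler divergence of an embedding
#'
#' Computes \code{KL(P || Q)} where Q is the normalized Student-t (one degree
#' of freedom) kernel over the embedding coordinates -- the t-SNE objective.
#'
#' @param P Joint affinity matrix (symmetric, zero diagonal, sums to 1).
#' @param coords Embedding coordinates, samples in rows.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(P, coords) {
  num <- 1 / (1 + squared_distances(coords))
  diag(num) <- 0
  Q <- num / sum(num)
  pos <- P > 0
  sum(P[pos] * log(P[pos] / pmax(Q[pos], 1e-300)))
}

#' Exact t-SNE embedding of relative RPT expression
#'
#' Full (O(n^2)) t-SNE: Gaussian conditional affinities calibrated per sample
#' to the target perplexity, symmetrized to a joint distribution P, then
#' gradient descent with momentum, adaptive gains and early exaggeration on
#' the KL divergence between P and the Student-t low-dimensional kernel.
#' Distances are Euclidean on the relative-expression fractions. The run is
#' bitwise reproducible from the config seed, and stops early once the
#' maximum per-coordinate update falls below the stall tolerance.
#'
#' @param x An \code{rpt_relexpr} or a plain samples-by-features matrix.
#' @param config An \code{\link{embedding_config}}.
#' @return Object of class \code{rpt_tsne}: list with \code{coords}
#'   (samples x dims), \code{config}, \code{kl_trace} (data frame
#'   \code{iter}, \code{kl}), \code{P} and \code{iterations_run}.
#' @export
tsne_embed <- function(x, config = embedding_config()) {
  m <- if (inherits(x, "rpt_relexpr")) x$fractions else as.matrix(x)
  n <- nrow(m)
  if (n < 4) stop_ribotype("t-SNE needs at least 4 samples")
  if (config$perplexity >= n - 1)
    stop_ribotype("perplexity must be below n_samples - 1")
  if (all(apply(m, 2, function(col) diff(range(col))) == 0))
    stop_ribotype("degenerate input: all samples identical (zero variance)")

  P <- joint_affinities(m, config$perplexity)
  dims <- config$dims
  # exaggeration never occupies more than the first half of a short run, so
  # the reported KL (always on the true P) can settle below its start
  exag_end <- min(config$exaggeration_duration, floor(config$iterations / 2))
  Y <- with_seed(config$seed, {
    if (config$init == "pca") {
      y0 <- pca_embed(m, dims)$coords
      y0 <- scale(y0, center = TRUE, scale = FALSE)
      y0 * (1e-4 / max(stats::sd(y0), .Machine$double.eps))
    } else {
      matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
    }
  })
  upd <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  trace_iter <- 0L
  trace_kl <- kl_divergence(P, Y)
  it_run <- 0L

  for (it in seq_len(config$iterations)) {
    exag <- if (it <= exag_end) config$early_exaggeration else 1
    mom <- if (it <= config$momentum_switch) config$momentum_initial else config$momentum_final
    num <- 1 / (1 + squared_distances(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    L <- (exag * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    same <- sign(grad) == sign(upd)
    gains <- ifelse(same, gains * 0.8, gains + 0.2)
    gains[gains < 0.01] <- 0.01
    upd <- mom * upd - config$epsilon * gains * grad
    Y <- Y + upd
    Y <- sweep(Y, 2, colMeans(Y))
    it_run <- it
    if (it %% config$record_every == 0L || it == config$iterations) {
      trace_iter <- c(trace_iter, it)
      trace_kl <- c(trace_kl, kl_divergence(P, Y))
    }
    if (it > exag_end && max(abs(upd)) < config$stall_tol)
      break
  }
  if (trace_iter[length(trace_iter)] != it_run) {
    trace_iter <- c(trace_iter, it_run)
    trace_kl <- c(trace_kl, kl_divergence(P, Y))
  }
  rownames(Y) <- rownames(m)
  colnames(Y) <- c("x", "y", "z")[seq_len(dims)]
  structure(list(coords = Y, config = config,
                 kl_trace = data.frame(iter = trace_iter, kl = trace_kl),
                 P = P, iterations_run = it_run),
            class = "rpt_tsne")
}

#' @export
print.rpt_tsne <- function(x, ...) {
  kl <- x$kl_trace$kl
  cat("t-SNE embedding:", nrow(x$coords), "samples in", ncol(x$coords),
      "dims; perplexity", x$config$perplexity, ";",
      x$iterations_run, "iterations; KL",
      format(kl[1], digits = 4), "->", format(kl[length(kl)], digits = 4), "\n")
  invisible(x)
}

#' @export
plot.rpt_tsne <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) 1 else as.integer(factor(labels))
  graphics::plot(x$coords[, 1], x$coords[, 2], col = col, pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  invisible(x)
}

#' Write an embedding and its configuration to disk
#'
#' @param embedding An \code{rpt_tsne}.
#' @param prefix Output path prefix; writes \code{<prefix>.tsv} (sample,
#'   coordinates), \code{<prefix>_config.yaml} and \code{<prefix>_kl.csv}.
#' @return \code{prefix}, invisibly.
#' @export
write_embedding <- function(embedding, prefix) {
  out <- data.frame(sample = rownames(embedding$coords), embedding$coords,
                    check.names = FALSE)
  utils::write.table(out, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- embedding$config
  yaml::write_yaml(unclass(cfg), paste0(prefix, "_config.yaml"))
  utils::write.csv(embedding$kl_trace, paste0(prefix, "_kl.csv"),
                   row.names = FALSE)
  invisible(prefix)
}
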