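test_that("PCA recovers rank structure and matches an eigen oracle", {
  # collinear data: one axis carries all variance
  line <- cbind(1:10, 2 * (1:10))
  fit <- pca_embed(line, k = 2)
  expect_equal(fit$explained_variance[1], 1, tolerance = 1e-12)

  set.seed(4)
  m <- matrix(rnorm(20 * 6), 20, 6)
  full <- pca_embed(m, k = 6)
  expect_lt(abs(sum(full$explained_variance) - 1), 1e-9)
  expect_true(all(diff(full$explained_variance) <= 1e-12))

  # brute-force covariance eigen-decomposition oracle, up to sign
  m4 <- matrix(c(1, 2, 0, 4, 3, 1, 0, 1, 2, 5, 1, 0), 4, 3)
  fit4 <- pca_embed(m4, k = 3)
  cm <- scale(m4, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(cm) / (nrow(m4) - 1))
  oracle <- cm %*% eig$vectors
  for (j in 1:3)
    expect_lt(min(max(abs(fit4$coords[, j] - oracle[, j])),
                  max(abs(fit4$coords[, j] + oracle[, j]))), 1e-8)

  expect_error(pca_embed(m, k = 0), "positive")
  expect_error(pca_embed(m, k = 7), "exceeds")
})

test_that("perplexity calibration hits its entropy target", {
  # equidistant neighbors force a uniform row whose perplexity is exactly n,
  # so any target below n is unreachable and must be reported
  expect_error(calibrate_conditional_probabilities(rep(2, 5), 4),
               "did not converge")
  # ... and targets at or above the neighbor count are rejected up front
  expect_error(calibrate_conditional_probabilities(runif(6), 10),
               "unreachable")

  set.seed(8)
  for (target in c(5, 8, 20)) {
    d2 <- runif(50, 0.1, 4)^2
    cal <- calibrate_conditional_probabilities(d2, target)
    expect_equal(sum(cal$p), 1, tolerance = 1e-12)
    h_bits <- -sum(cal$p * log2(cal$p))      # independent entropy recompute
    expect_lt(abs(2^h_bits - target), 1e-4)
  }
})

test_that("KL divergence matches a brute-force double loop and is non-negative", {
  set.seed(5)
  y <- matrix(rnorm(8), 4, 2)
  # construct P equal to the Student-t Q of the coordinates: KL must be 0
  d2 <- as.matrix(dist(y))^2
  num <- 1 / (1 + d2); diag(num) <- 0
  Q <- num / sum(num)
  expect_lt(kl_divergence(Q, y), 1e-12)

  P <- matrix(runif(16), 4, 4); diag(P) <- 0
  P <- (P + t(P)); P <- P / sum(P)
  kl <- kl_divergence(P, y)
  expect_gte(kl, 0)
  brute <- 0
  for (i in 1:4) for (j in 1:4) {
    if (i == j || P[i, j] == 0) next
    qij <- (1 / (1 + sum((y[i, ] - y[j, ])^2))) / sum(num)
    brute <- brute + P[i, j] * log(P[i, j] / qij)
  }
  expect_equal(kl, brute, tolerance = 1e-12)
})

test_that("t-SNE is seed-reproducible and decreases the KL objective", {
  rel <- relative_expression(generate_cohort(
    cohort_spec("TS", n_tumor = 40, seed = 3))$expression)
  cfg <- embedding_config(perplexity = 8, iterations = 150, seed = 11)
  e1 <- tsne_embed(rel, cfg)
  e2 <- tsne_embed(rel, cfg)
  expect_identical(e1$coords, e2$coords)   # bitwise

  expect_lt(max(abs(e1$P - t(e1$P))), 1e-15)
  expect_lt(abs(sum(e1$P) - 1), 1e-9)
  kl <- e1$kl_trace$kl
  expect_lt(kl[length(kl)], kl[1])
  # final KL agrees with an independent recompute from stored P and coords
  expect_equal(kl[length(kl)], kl_divergence(e1$P, e1$coords),
               tolerance = 1e-8)

  flat <- matrix(1, 10, 4, dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  expect_error(tsne_embed(flat, cfg), "identical")
})

test_that("small runs keep a non-increasing KL tail", {
  set.seed(2)
  m <- matrix(runif(5 * 3) + 0.2, 5, 3,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:3)))
  e <- tsne_embed(make_relexpr(m),
                  embedding_config(perplexity = 2, iterations = 400,
                                   record_every = 5, seed = 1))
  tail_kl <- utils::tail(e$kl_trace$kl, 10)
  expect_true(all(diff(tail_kl) <= 1e-8))
})

test_that("well-separated compositions stay separable in the embedding", {
  co <- patterned_cohort(K = 2, n_per_cluster = 50, seed = 6)
  rel <- relative_expression(co$expression)
  emb <- tsne_embed(rel, embedding_config(perplexity = 10, iterations = 500,
                                          seed = 4))
  labs <- co$truth[rownames(emb$coords)]
  centroids <- t(vapply(unique(labs), function(l)
    colMeans(emb$coords[labs == l, , drop = FALSE]), numeric(2)))
  pred <- unique(labs)[apply(emb$coords, 1, function(pt)
    which.min(colSums((t(centroids) - pt)^2)))]
  expect_gte(mean(pred == labs), 0.99)
})

test_that("tissue identity is recoverable from a grouped embedding", {
  specs <- lapply(1:5, function(i)
    cohort_spec(paste0("T", i), n_tumor = 40, seed = 100 + i,
                base_alpha = base_alpha(80, seed = i)))
  cohorts <- lapply(specs, generate_cohort)
  fr <- do.call(rbind, lapply(cohorts, function(co)
    relative_expression(co$expression)$fractions))
  tissue <- rep(paste0("T", 1:5), each = 40)
  emb <- tsne_embed(fr, embedding_config(perplexity = 12, iterations = 500,
                                         seed = 2))
  centroids <- t(vapply(unique(tissue), function(l)
    colMeans(emb$coords[tissue == l, , drop = FALSE]), numeric(2)))
  pred <- unique(tissue)[apply(emb$coords, 1, function(pt)
    which.min(colSums((t(centroids) - pt)^2)))]
  expect_gte(mean(pred == tissue), 0.95)
})
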