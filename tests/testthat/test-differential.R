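toy_relexpr_groups <- function(values_by_gene, labels) {
  # build an rpt_relexpr where listed genes carry given per-sample values and
  # a filler gene absorbs the remainder so rows sum to 1
  n <- length(labels)
  m <- do.call(cbind, values_by_gene)
  filler <- pmax(1 - rowSums(m), 0)
  m <- cbind(m, filler = filler)
  rownames(m) <- names(labels) <- paste0("s", seq_len(n))
  list(rel = make_relexpr(m), assign = make_assignment(labels))
}

test_that("one-way ANOVA matches hand computation on the classic toy case", {
  # groups {1,2,3} and {4,5,6} scaled to fractions: F is scale-free
  vals <- c(1, 2, 3, 4, 5, 6) / 100
  fx <- toy_relexpr_groups(list(g = vals),
                           c("1", "1", "1", "2", "2", "2"))
  vol <- anova_across_clusters(fx$rel, fx$assign)
  row <- vol[vol$gene == "g", ]
  expect_equal(row$F, 13.5, tolerance = 1e-10)
  expect_equal(attr(vol, "df"), c(1, 4))
  expect_equal(row$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(row$neg_log10_p, -log10(row$p), tolerance = 1e-10)
  # K = 2: delta is the signed difference of cluster means
  expect_equal(row$delta, mean(vals[1:3]) - mean(vals[4:6]), tolerance = 1e-12)
})

test_that("identical groups and constant genes are degenerate, not errors", {
  vals <- rep(c(0.1, 0.2, 0.3), 2)
  fx <- toy_relexpr_groups(list(g = vals, h = rep(0.05, 6)),
                           c("1", "1", "1", "2", "2", "2"))
  vol <- anova_across_clusters(fx$rel, fx$assign)
  expect_equal(vol[vol$gene == "g", "F"], 0)
  expect_equal(vol[vol$gene == "g", "p"], 1)
  expect_true(vol[vol$gene == "h", "degenerate"])
  expect_equal(vol[vol$gene == "h", "p"], 1)
})

test_that("two-cluster ANOVA equals the squared pooled t statistic", {
  set.seed(30)
  for (rep in 1:10) {
    a <- runif(6, 0.05, 0.2); b <- runif(8, 0.05, 0.2)
    fx <- toy_relexpr_groups(list(g = c(a, b)),
                             c(rep("1", 6), rep("2", 8)))
    vol <- anova_across_clusters(fx$rel, fx$assign)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(vol[vol$gene == "g", "F"], unname(tt$statistic)^2,
                 tolerance = 1e-10)
  }
})

test_that("volcano delta for K > 2 is the range of cluster means", {
  set.seed(31)
  g <- c(runif(5, 0.10, 0.12), runif(5, 0.20, 0.22), runif(5, 0.14, 0.16))
  labels <- rep(c("1", "2", "3"), each = 5)
  fx <- toy_relexpr_groups(list(g = g), labels)
  vol <- anova_across_clusters(fx$rel, fx$assign)
  means <- tapply(g, labels, mean)
  expect_equal(vol[vol$gene == "g", "delta"], max(means) - min(means),
               tolerance = 1e-12)
})

test_that("cluster-vs-rest contrast detects a planted anchor", {
  sub <- subcluster_spec("up", 0.25, anchor_shifts = c(RPL8 = 1))
  co <- generate_cohort(cohort_spec("CT", n_tumor = 200,
                                    subclusters = list(sub), seed = 17))
  rel <- relative_expression(co$expression)
  ct <- cluster_vs_rest_contrast(rel, truth_assignment(co), "up")
  row <- ct[ct$gene == "RPL8", ]
  expect_equal(row$direction, 1)
  expect_lt(row$p, 1e-6)
  expect_equal(attr(ct, "n")[["cluster"]], 50L)
})

test_that("a gene identical in both groups gets p = 1 and direction 0", {
  vals <- c(0.1, 0.11, 0.12, 0.1, 0.11, 0.12)
  fx <- toy_relexpr_groups(list(g = vals, const = rep(0.2, 6)),
                           c("1", "1", "1", "2", "2", "2"))
  ct <- cluster_vs_rest_contrast(fx$rel, fx$assign, "1")
  expect_equal(ct[ct$gene == "const", "direction"], 0)
  expect_equal(ct[ct$gene == "const", "p"], 1)
})

fake_contrast <- function(cohort, cluster, genes, direction, p) {
  out <- data.frame(gene = genes, direction = direction, p = p,
                    mean_diff = direction * 0.01, stringsAsFactors = FALSE)
  attr(out, "cluster") <- cluster
  class(out) <- c("rpt_contrast", "data.frame")
  out
}

test_that("co-regulated sets require recurrence, consistency and significance", {
  genes <- c("RPL8", "RPL7", "RPL10", "RPS6")
  ct1 <- fake_contrast("A", "2", genes, c(1, 1, -1, 1), c(1e-9, 1e-5, 1e-5, 0.5))
  ct2 <- fake_contrast("B", "1", genes, c(1, 1, -1, -1), c(1e-8, 1e-4, 1e-6, 1e-6))
  pat <- find_coregulated_sets(list(A = ct1, B = ct2), anchor = "RPL8",
                               direction = 1, alpha = 0.01)
  expect_equal(pat$higher_set, "RPL7")
  expect_equal(pat$lower_set, "RPL10")       # RPS6 flips sign: excluded
  expect_false("RPL8" %in% c(pat$higher_set, pat$lower_set))

  expect_error(find_coregulated_sets(list(A = ct1), "RPL8", 1),
               "recurrence|>= 2")
  ct3 <- fake_contrast("C", "1", genes, c(1, 1, -1, 1), c(0.5, 1e-4, 1e-6, 0.5))
  expect_error(find_coregulated_sets(list(A = ct1, C = ct3), "RPL8", 1),
               "not significant")

  # sign-only mode admits members without per-cluster significance
  pat2 <- find_coregulated_sets(list(A = ct1, B = ct2), "RPL8", 1,
                                sign_only = TRUE)
  expect_true(all(c("RPL7") %in% pat2$higher_set))
})

test_that("planted co-regulation is recovered across five cohorts", {
  shared <- recurring_patterns(0.4)
  specs <- lapply(1:5, function(i)
    cohort_spec(paste0("P", i), n_tumor = 100, seed = 40 + i,
                base_alpha = base_alpha(80, seed = i)))
  cohorts <- generate_pan_cancer_set(specs, shared)
  contrasts <- lapply(cohorts, function(co) {
    rel <- relative_expression(co$expression)
    cluster_vs_rest_contrast(rel, truth_assignment(co), "high_rpl8_rpl30")
  })
  names(contrasts) <- paste0("P", 1:5)
  pat <- find_coregulated_sets(contrasts, anchor = "RPL8", direction = 1,
                               alpha = 0.01)
  expect_true(all(c("RPL7") %in% pat$higher_set))
  expect_true(all(c("RPL10") %in% pat$lower_set))
})
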