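test_that("GISTIC calls partition into amplification/deletion/neutral", {
  calls <- matrix(c(2L, -1L, 0L, 1L, -2L, 0L), 2, 3,
                  dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  ind <- classify_cnv_calls(calls)
  expect_true(ind$amplification["s1", "g1"])
  expect_true(ind$deletion["s2", "g1"])
  expect_true(ind$neutral["s1", "g2"])
  expect_true(all(ind$amplification + ind$deletion + ind$neutral == 1))
  expect_error(classify_cnv_calls(matrix(0.5, 1, 1)), "integer")
})

test_that("chi-squared independence matches closed forms and brute force", {
  flat <- chi_squared_independence(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  diag40 <- chi_squared_independence(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(diag40$statistic, 40, tolerance = 1e-12)

  tab <- matrix(c(8, 3, 5, 9, 2, 6), 2, 3)
  got <- chi_squared_independence(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  brute <- sum((tab - expected)^2 / expected)
  expect_equal(got$statistic, brute, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p, pchisq(brute, 2, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(chi_squared_independence(matrix(c(1, 0, 2, 0), 2, 2,
                                               byrow = TRUE)), "margin")
})

test_that("Benjamini-Hochberg follows the step-up rule", {
  one <- benjamini_hochberg(0.03, q = 0.05)
  expect_equal(one$adjusted, 0.03)
  expect_true(one$rejected)

  bh <- benjamini_hochberg(c(0.01, 0.02, 0.04), q = 0.05)
  expect_equal(bh$adjusted, c(0.03, 0.03, 0.04))
  expect_true(all(bh$rejected))

  none <- benjamini_hochberg(rep(1, 5), q = 0.05)
  expect_false(any(none$rejected))
  expect_error(benjamini_hochberg(numeric(0)), "empty")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "outside")
})

test_that("continuous comparisons gate on normality as specified", {
  set.seed(50)
  v <- rnorm(15)
  same <- compare_continuous(v, v)
  expect_equal(same$test, "welch_t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # heavily skewed, completely separated groups: rank-sum branch with the
  # exact enumeration p-value 2 / choose(20, 10)
  a <- exp(1:10); b <- exp(11:20)
  rs <- compare_continuous(a, b)
  expect_equal(rs$test, "wilcoxon_rank_sum")
  expect_equal(rs$statistic, 0)      # minimum possible rank-sum statistic
  expect_equal(rs$p, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("the Welch branch holds its type-I error under heteroskedasticity", {
  set.seed(51)
  reject <- replicate(2000, {
    a <- rnorm(12, sd = 1); b <- rnorm(20, sd = 3)
    compare_continuous(a, b)$p < 0.05
  })
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("Kaplan-Meier follows the product-limit construction", {
  no_events <- km_curve(data.frame(time = c(3, 5, 8), event = c(0, 0, 0)))
  expect_true(all(no_events$survival == 1))

  km <- km_curve(data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0)))
  expect_equal(km$survival[km$time == 1], 0.75)       # 3/4
  expect_equal(km$survival[km$time == 2], 0.5)        # (3/4)(2/3)

  all_die <- km_curve(data.frame(time = rep(5, 4), event = rep(1, 4)))
  expect_equal(all_die$survival[all_die$time == 5], 0)
  expect_error(km_curve(data.frame(time = -1, event = 1)), "negative")
})

test_that("survival tests match hand tabulation and the survdiff oracle", {
  # identical groups: both statistics are exactly zero
  base <- data.frame(time = c(2, 4, 6, 8), event = c(1, 0, 1, 1))
  same <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  st <- survival_tests(same)
  expect_equal(st$logrank$statistic, 0, tolerance = 1e-12)
  expect_equal(st$logrank$p, 1)
  expect_equal(st$gehan_breslow_wilcoxon$statistic, 0, tolerance = 1e-12)

  # A dies at 1,2; B dies at 3,4: hand-tabulated log-rank is 49/17
  dat <- data.frame(time = 1:4, event = 1,
                    group = c("A", "A", "B", "B"))
  st2 <- survival_tests(dat)
  expect_equal(st2$logrank$statistic, 49 / 17, tolerance = 1e-10)
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  expect_equal(st2$logrank$statistic, unname(sd2$chisq), tolerance = 1e-8)

  # single event time: the Gehan weight is constant, the tests coincide
  one_t <- data.frame(time = c(5, 5, 7, 8), event = c(1, 1, 0, 0),
                      group = c("A", "B", "A", "B"))
  st3 <- survival_tests(one_t)
  expect_equal(st3$logrank$p, st3$gehan_breslow_wilcoxon$p, tolerance = 1e-12)

  expect_error(survival_tests(data.frame(time = 1:4, event = 0,
                                         group = c("A", "A", "B", "B"))),
               "no events")
})

test_that("CNV enrichment applies the FDR and >90% incidence filters", {
  set.seed(52)
  n_in <- 80; n_out <- 120
  genes <- paste0("g", 1:20)
  calls <- matrix(0L, n_in + n_out, 20,
                  dimnames = list(paste0("s", 1:200), genes))
  # background 2% everywhere
  bg <- matrix(runif(200 * 20) < 0.02, 200, 20)
  calls[bg] <- 1L
  # g1: exactly 95% incidence inside the cluster; g2: exactly 50%
  calls[1:n_in, "g1"] <- rep(c(1L, 0L), c(76, 4))
  calls[1:n_in, "g2"] <- rep(c(1L, 0L), c(40, 40))
  labels <- setNames(c(rep("1", n_in), rep("2", n_out)), rownames(calls))
  res <- cnv_cluster_enrichment(calls, make_assignment(labels))

  g1 <- res[res$gene == "g1" & res$cluster == "1" & res$type == "amplification", ]
  expect_true(g1$significant && g1$flagged)
  g2 <- res[res$gene == "g2" & res$cluster == "1" & res$type == "amplification", ]
  expect_true(g2$significant)
  expect_false(g2$flagged)                       # fails the >90% rule
  # equal incidence in and out: neither significant nor flagged
  g3 <- res[res$gene == "g3" & res$cluster == "1" & res$type == "amplification", ]
  expect_false(isTRUE(g3$significant) || isTRUE(g3$flagged))
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("categorical clinical association uses raw-alpha chi-squared", {
  set.seed(53)
  n <- 120
  labels <- setNames(rep(c("1", "2"), each = n / 2), paste0("s", 1:n))
  pheno <- data.frame(sample = names(labels),
                      sex = ifelse(runif(n) < ifelse(labels == "1", 0.8, 0.3),
                                   "female", "male"))
  res <- clinical_association(pheno, make_assignment(labels), "sex")
  expect_true(res$significant)
  expect_equal(res$df, 1)
})
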