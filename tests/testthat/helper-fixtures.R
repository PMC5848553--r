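# Shared fixture builders. Everything is generated in code; no stored data.

# Wrap a positive matrix as an rpt_relexpr (rows renormalized to sum to 1).
make_relexpr <- function(m, meta = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  relative_expression(expression_matrix(m, sample_meta = meta))
}

# Build an rpt_clusters object directly from a named label vector
# ("NOISE" allowed), bypassing discovery — used to test downstream stages
# against ground truth.
make_assignment <- function(labels) {
  ids <- setdiff(sort(unique(labels)), "NOISE")
  sizes <- vapply(ids, function(cl) sum(labels == cl), 0L)
  structure(list(labels = labels, min_size = 10, radius = NA_real_,
                 sizes = stats::setNames(sizes, ids)),
            class = "rpt_clusters")
}

# 2D Gaussian blob.
blob2d <- function(n, center, sd = 0.5, seed = 1) {
  set.seed(seed)
  cbind(rnorm(n, center[1], sd), rnorm(n, center[2], sd))
}

# Cluster assignment from a cohort's planted truth (tumors only).
truth_assignment <- function(cohort) {
  make_assignment(cohort$truth)
}

# A cohort whose K subclusters carry the recurring RPT patterns, with the
# proportions splitting the tumors evenly (no bulk remainder).
patterned_cohort <- function(K, n_per_cluster = 50, seed = 1, code = "SYN", ...) {
  subs <- recurring_patterns(rep(1 / K, K) - 1e-9, ...)
  generate_cohort(cohort_spec(code, n_tumor = K * n_per_cluster,
                              subclusters = subs, seed = seed))
}
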