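#' ANOVA volcano table across clusters
#'
#' One-way fixed-effects ANOVA of relative expression per gene across the
#' non-noise clusters, yielding the volcano coordinates: \code{-log10(p)}
#' against the spread in mean relative expression across clusters. For two
#' clusters the effect size \code{delta} is the signed difference
#' mean(cluster 1) - mean(cluster 2); for more clusters it is the range
#' (max - min) of the cluster means. \code{neg_log10_p} is computed on the
#' log scale, so extremely small p-values (down to the 1e-220 region and
#' beyond) are represented without underflow.
#'
#' @param relexpr An \code{rpt_relexpr}.
#' @param assignment An \code{rpt_clusters} with at least two non-noise
#'   clusters of at least two samples each.
#' @return Object of class \code{rpt_volcano}: a data frame with one row per
#'   gene (\code{gene}, \code{F}, \code{p}, \code{neg_log10_p}, \code{delta},
#'   \code{degenerate}) plus a \code{cluster_means} attribute
#'   (clusters x genes).
#' @export
anova_across_clusters <- function(relexpr, assignment) {
  stopifnot(inherits(relexpr, "rpt_relexpr"))
  labs <- assignment$labels[relexpr$sample_ids]
  keep <- !is.na(labs) & labs != "NOISE"
  labs <- labs[keep]
  m <- relexpr$fractions[keep, , drop = FALSE]
  ids <- sort(unique(labs))
  if (length(ids) < 2L) stop_ribotype("need >= 2 non-noise clusters")
  sizes <- vapply(ids, function(cl) sum(labs == cl), 0L)
  if (any(sizes < 2L)) stop_ribotype("every cluster needs >= 2 samples")
  n <- nrow(m); k <- length(ids)

  means <- t(vapply(ids, function(cl) colMeans(m[labs == cl, , drop = FALSE]),
                    numeric(ncol(m))))
  rownames(means) <- ids
  grand <- colMeans(m)
  ssb <- colSums(sizes * (sweep(means, 2, grand))^2)
  sst <- colSums(sweep(m, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1L; df2 <- n - k
  msb <- ssb / df1; msw <- ssw / df2
  degenerate <- sst <= .Machine$double.eps * n
  f <- ifelse(msw > 0, msb / msw, ifelse(ssb > 0, Inf, 0))
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  nlp <- -stats::pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE) / log(10)
  p[degenerate] <- 1
  nlp[degenerate] <- 0
  delta <- if (k == 2L) means[1L, ] - means[2L, ] else
    apply(means, 2, max) - apply(means, 2, min)
  out <- data.frame(gene = colnames(m), F = f, p = p, neg_log10_p = nlp,
                    delta = delta, degenerate = degenerate,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "cluster_means") <- means
  attr(out, "df") <- c(df1, df2)
  class(out) <- c("rpt_volcano", "data.frame")
  out
}

#' @export
plot.rpt_volcano <- function(x, alpha = 0.01, ...) {
  graphics::plot(x$delta, x$neg_log10_p,
                 xlab = "difference in relative expression",
                 ylab = "-log10 ANOVA p", pch = 19,
                 col = ifelse(x$p < alpha, 2, 1), ...)
  invisible(x)
}

#' Cluster-versus-rest contrast of relative expression
#'
#' Welch (unequal-variance) two-sample t-test per gene comparing one cluster
#' against all other non-noise tumors of the same cohort, with the direction
#' of each gene's change (+1 higher in the cluster, -1 lower, 0 undefined
#' when the two groups are identical).
#'
#' @param relexpr An \code{rpt_relexpr}.
#' @param assignment An \code{rpt_clusters}.
#' @param cluster Cluster id to contrast against the rest.
#' @return Object of class \code{rpt_contrast}: data frame with
#'   \code{gene}, \code{direction}, \code{p}, \code{mean_diff}, plus
#'   \code{cluster} and \code{n} attributes.
#' @export
cluster_vs_rest_contrast <- function(relexpr, assignment, cluster) {
  stopifnot(inherits(relexpr, "rpt_relexpr"))
  labs <- assignment$labels[relexpr$sample_ids]
  keep <- !is.na(labs) & labs != "NOISE"
  labs <- labs[keep]
  m <- relexpr$fractions[keep, , drop = FALSE]
  cluster <- as.character(cluster)
  in_cl <- labs == cluster
  if (sum(in_cl) < 2L) stop_ribotype("cluster '", cluster, "' has < 2 samples")
  if (sum(!in_cl) < 2L) stop_ribotype("complement of cluster '", cluster,
                                      "' has < 2 samples")
  res <- apply(m, 2, function(v) {
    a <- v[in_cl]; b <- v[!in_cl]
    dm <- mean(a) - mean(b)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (dm == 0) return(c(0, 1, 0))
      return(c(sign(dm), .Machine$double.xmin, dm))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    c(if (dm == 0) 0 else sign(dm), tt$p.value, dm)
  })
  out <- data.frame(gene = colnames(m), direction = res[1L, ], p = res[2L, ],
                    mean_diff = res[3L, ], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "cluster") <- cluster
  attr(out, "n") <- c(cluster = sum(in_cl), rest = sum(!in_cl))
  class(out) <- c("rpt_contrast", "data.frame")
  out
}

#' Cross-cohort co-regulated transcript discovery
#'
#' Given cluster-versus-rest contrasts from clusters (in different cohorts)
#' that all share a significant anchor transcript change in the same
#' direction, extracts the transcripts that are consistently co-regulated:
#' \code{higher_set} holds genes significantly higher in every member
#' cluster, \code{lower_set} those significantly lower in every member
#' cluster; the anchor itself is excluded. With \code{sign_only = TRUE},
#' membership requires only a consistent direction ("on average"), not
#' per-cluster significance.
#'
#' @param contrasts Named list of \code{rpt_contrast} objects (names are
#'   cohort codes); at least two (a recurring pattern needs recurrence).
#' @param anchor Anchor gene symbol.
#' @param direction +1 (anchor higher in the member clusters) or -1.
#' @param alpha Per-gene significance threshold (default 0.01).
#' @param sign_only Drop the per-cluster significance requirement for
#'   co-regulated members.
#' @return Object of class \code{coregulation_pattern}: list with
#'   \code{anchor}, \code{direction}, \code{members} (cohort/cluster data
#'   frame), \code{higher_set}, \code{lower_set} and \code{alpha}.
#' @export
find_coregulated_sets <- function(contrasts, anchor, direction, alpha = 0.01,
                                  sign_only = FALSE) {
  if (length(contrasts) < 2L)
    stop_ribotype("a recurring pattern needs >= 2 member contrasts")
  stopifnot(direction %in% c(-1, 1))
  if (is.null(names(contrasts)))
    names(contrasts) <- paste0("cohort", seq_along(contrasts))
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    row <- ct[ct$gene == anchor, ]
    if (nrow(row) != 1L)
      stop_ribotype("anchor ", anchor, " absent from contrast '", nm, "'")
    if (row$p >= alpha || row$direction != direction)
      stop_ribotype("anchor ", anchor, " not significant in direction ",
                    direction, " in contrast '", nm, "'")
  }
  genes <- contrasts[[1L]]$gene
  consistent <- function(dir) {
    hits <- Reduce(`&`, lapply(contrasts, function(ct) {
      ct <- ct[match(genes, ct$gene), ]
      ok <- ct$direction == dir
      if (!sign_only) ok <- ok & ct$p < alpha
      ok
    }))
    setdiff(genes[hits], anchor)
  }
  members <- data.frame(cohort = names(contrasts),
                        cluster = vapply(contrasts, attr, "", "cluster"),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(anchor = anchor, direction = direction, members = members,
                 higher_set = consistent(1), lower_set = consistent(-1),
                 alpha = alpha, sign_only = sign_only),
            class = "coregulation_pattern")
}

#' @export
print.coregulation_pattern <- function(x, ...) {
  cat("Co-regulation pattern: anchor", x$anchor,
      if (x$direction > 0) "(high)" else "(low)", "in",
      nrow(x$members), "clusters\n")
  cat("  higher:", if (length(x$higher_set)) paste(x$higher_set, collapse = ", ") else "-", "\n")
  cat("  lower: ", if (length(x$lower_set)) paste(x$lower_set, collapse = ", ") else "-", "\n")
  invisible(x)
}

#' Write a volcano table as TSV
#'
#' @param volcano An \code{rpt_volcano}.
#' @param path Output path; cluster means are appended as extra columns.
#' @return \code{path}, invisibly.
#' @export
write_volcano <- function(volcano, path) {
  means <- t(attr(volcano, "cluster_means"))
  colnames(means) <- paste0("mean_cluster_", colnames(means))
  out <- cbind(as.data.frame(volcano), means)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-regulation pattern report as YAML
#'
#' @param pattern A \code{coregulation_pattern}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_coregulation <- function(pattern, path) {
  yaml::write_yaml(list(anchor = pattern$anchor,
                        direction = pattern$direction,
                        alpha = pattern$alpha,
                        members = pattern$members,
                        higher_set = pattern$higher_set,
                        lower_set = pattern$lower_set),
                   path)
  invisible(path)
}
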