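#' Classify GISTIC-thresholded copy-number calls
#'
#' Positive calls are amplifications, negative calls deletions, zero neutral;
#' the three indicator matrices partition the call matrix exhaustively.
#'
#' @param calls Integer samples-by-genes matrix of GISTIC calls (-2..2).
#' @return List of logical matrices \code{amplification}, \code{deletion},
#'   \code{neutral}.
#' @export
classify_cnv_calls <- function(calls) {
  calls <- as.matrix(calls)
  if (any(calls != round(calls)))
    stop_ribotype("CNV calls must be integers")
  list(amplification = calls > 0, deletion = calls < 0, neutral = calls == 0)
}

#' Pearson chi-squared test of independence
#'
#' Pearson chi-squared on an r x c contingency table, without continuity
#' correction, with \code{(r-1)(c-1)} degrees of freedom.
#'
#' @param table Matrix of non-negative counts.
#' @return List with \code{statistic}, \code{df} and \code{p}.
#' @export
chi_squared_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop_ribotype("negative counts")
  rz <- rowSums(table) == 0
  cz <- colSums(table) == 0
  if (any(rz))
    stop_ribotype("degenerate contingency table: zero row margin at row ",
                  paste(which(rz), collapse = ", "))
  if (any(cz))
    stop_ribotype("degenerate contingency table: zero column margin at column ",
                  paste(which(cz), collapse = ", "))
  fit <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' CNV-cluster enrichment with FDR and incidence filters
#'
#' For every gene, alteration type (amplification/deletion) and non-noise
#' cluster, tests by chi-squared whether the alteration's incidence in the
#' cluster differs from the rest of the cohort; Benjamini-Hochberg adjusts
#' all tests of the cohort jointly at \code{fdr_q}. An association is
#' \emph{flagged} only when it is BH-significant \emph{and} the in-cluster
#' incidence exceeds \code{incidence_min} -- the reporting rule used for
#' cluster-defining amplicons.
#'
#' @param calls Integer samples-by-genes GISTIC call matrix.
#' @param assignment An \code{rpt_clusters} over the same samples.
#' @param fdr_q BH false-discovery level (default 0.05).
#' @param incidence_min In-cluster incidence threshold (default 0.90).
#' @return Data frame with one row per gene x type x cluster:
#'   \code{gene}, \code{type}, \code{cluster}, \code{incidence_in},
#'   \code{incidence_out}, \code{statistic}, \code{p}, \code{q},
#'   \code{significant}, \code{flagged}.
#' @export
cnv_cluster_enrichment <- function(calls, assignment, fdr_q = 0.05,
                                   incidence_min = 0.90) {
  labs <- assignment$labels[rownames(calls)]
  keep <- !is.na(labs) & labs != "NOISE"
  labs <- labs[keep]
  calls <- calls[keep, , drop = FALSE]
  ids <- sort(unique(labs))
  if (length(ids) < 2L) stop_ribotype("need >= 2 clusters")
  if (any(vapply(ids, function(cl) sum(labs == cl), 0L) < 2L))
    stop_ribotype("cluster smaller than 2")
  ind <- classify_cnv_calls(calls)
  rows <- list()
  for (type in c("amplification", "deletion")) {
    alt <- ind[[type]]
    for (cl in ids) {
      in_cl <- labs == cl
      a_in <- colSums(alt[in_cl, , drop = FALSE])
      a_out <- colSums(alt[!in_cl, , drop = FALSE])
      n_in <- sum(in_cl); n_out <- sum(!in_cl)
      for (j in seq_len(ncol(alt))) {
        tab <- matrix(c(a_in[j], n_in - a_in[j], a_out[j], n_out - a_out[j]),
                      2, 2, byrow = TRUE)
        if (sum(tab[, 1L]) == 0 || sum(tab[, 2L]) == 0) {
          st <- list(statistic = 0, p = 1)  # alteration absent or universal
        } else {
          st <- chi_squared_independence(tab)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene = colnames(alt)[j], type = type, cluster = cl,
          incidence_in = a_in[j] / n_in, incidence_out = a_out[j] / n_out,
          statistic = st$statistic, p = st$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  bh <- benjamini_hochberg(out$p, q = fdr_q)
  out$q <- bh$adjusted
  out$significant <- bh$rejected
  out$flagged <- out$significant & out$incidence_in > incidence_min
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up false-discovery control
#'
#' Standard BH adjusted p-values with the rejection set at level \code{q}.
#'
#' @param pvalues Numeric vector of raw p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with \code{adjusted} (same order as input) and
#'   \code{rejected} (logical).
#' @export
benjamini_hochberg <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) stop_ribotype("empty p-value vector")
  if (any(pvalues < 0 | pvalues > 1)) stop_ribotype("p-values outside [0, 1]")
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, rejected = adjusted <= q)
}

#' Compare a continuous clinical variable between two groups
#'
#' Implements the normality-gated dichotomy used for continuous clinical
#' covariates: Shapiro-Wilk in each group at \code{normality_alpha}; when
#' both groups look normal, a Welch (heteroskedastic) t-test; otherwise a
#' two-sample Wilcoxon rank-sum test with mid-rank tie handling. All tests
#' two-tailed.
#'
#' @param a,b Numeric vectors, each of length >= 3.
#' @param normality_alpha Shapiro-Wilk level (default 0.05).
#' @return List with \code{test} ("welch_t" or "wilcoxon_rank_sum"),
#'   \code{statistic} and \code{p}.
#' @export
compare_continuous <- function(a, b, normality_alpha = 0.05) {
  stopifnot(length(a) >= 3L, length(b) >= 3L)
  sw <- function(v) {
    if (stats::sd(v) == 0) return(0)  # constant: certainly not normal
    stats::shapiro.test(v)$p.value
  }
  normal <- sw(a) > normality_alpha && sw(b) > normality_alpha
  if (normal) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
      return(list(test = "welch_t", statistic = 0, p = 1))
    fit <- stats::t.test(a, b, var.equal = FALSE)
    list(test = "welch_t", statistic = unname(fit$statistic),
         p = fit$p.value)
  } else {
    fit <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
    list(test = "wilcoxon_rank_sum", statistic = unname(fit$statistic),
         p = fit$p.value)
  }
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function for one group (or the
#' pooled sample): a right-continuous step function starting at 1 that drops
#' only at observed event times.
#'
#' @param survival Data frame with columns \code{time} (days, >= 0) and
#'   \code{event} (1 death, 0 censored), and optionally \code{group}.
#' @param group If given, restrict to this value of \code{survival$group}.
#' @return Object of class \code{rpt_km}: data frame with \code{time},
#'   \code{n_risk}, \code{n_event}, \code{survival}.
#' @export
km_curve <- function(survival, group = NULL) {
  if (!is.null(group)) survival <- survival[survival$group == group, ]
  if (nrow(survival) < 1L) stop_ribotype("no subjects")
  if (any(survival$time < 0)) stop_ribotype("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("rpt_km", "data.frame")
  out
}

#' @export
plot.rpt_km <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$survival)), do.points = FALSE,
                 xlab = "time (days)", ylab = "S(t)", ylim = c(0, 1),
                 main = "", ...)
  invisible(x)
}

#' Log-rank and Gehan-Breslow-Wilcoxon survival comparisons
#'
#' K-group weighted log-rank machinery over the pooled distinct event times:
#' the Mantel-Haenszel (log-rank) test uses unit weights; the
#' Gehan-Breslow-Wilcoxon variant weights each event time by the total
#' number at risk, emphasizing early events. Tied events are handled within
#' a single risk-set evaluation. Both statistics are chi-squared with
#' \code{groups - 1} degrees of freedom.
#'
#' @param survival Data frame with \code{time}, \code{event} and
#'   \code{group} columns (or pass \code{groups} separately).
#' @param groups Optional group labels overriding \code{survival$group}.
#' @return List with elements \code{logrank} and
#'   \code{gehan_breslow_wilcoxon}, each a list \code{(statistic, df, p)}.
#' @export
survival_tests <- function(survival, groups = NULL) {
  time <- survival$time
  event <- survival$event
  g <- factor(groups %||% survival$group)
  if (nlevels(g) < 2L) stop_ribotype("need >= 2 groups")
  if (sum(event) == 0) stop_ribotype("no events observed")
  if (any(time < 0)) stop_ribotype("negative survival times")
  list(logrank = weighted_logrank(time, event, g, weight = "logrank"),
       gehan_breslow_wilcoxon = weighted_logrank(time, event, g,
                                                 weight = "gehan"))
}

# K-group weighted log-rank: U' V^- U over the first K-1 groups.
weighted_logrank <- function(time, event, g, weight = c("logrank", "gehan")) {
  weight <- match.arg(weight)
  k <- nlevels(g)
  ev_times <- sort(unique(time[event == 1]))
  U <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(event == 1 & time == t)
    if (n_j == 0 || d_j == 0) next
    n_ij <- vapply(levels(g), function(l) sum(at_risk & g == l), 0)
    d_ij <- vapply(levels(g), function(l) sum(event == 1 & time == t & g == l), 0)
    w <- if (weight == "gehan") n_j else 1
    U <- U + w * (d_ij - d_j * n_ij / n_j)
    if (n_j > 1) {
      frac <- n_ij / n_j
      vmat <- (diag(frac) - tcrossprod(frac)) *
        d_j * (n_j - d_j) / (n_j - 1)
      V <- V + w^2 * vmat
    }
  }
  idx <- seq_len(k - 1L)
  Vsub <- V[idx, idx, drop = FALSE]
  Usub <- U[idx]
  Vinv <- tryCatch(solve(Vsub), error = function(e) MASS_ginv(Vsub))
  stat <- drop(t(Usub) %*% Vinv %*% Usub)
  stat <- max(stat, 0)
  list(statistic = stat, df = k - 1L,
       p = stats::pchisq(stat, k - 1L, lower.tail = FALSE))
}

# Moore-Penrose pseudo-inverse via SVD (degenerate variance matrices).
MASS_ginv <- function(x, tol = sqrt(.Machine$double.eps)) {
  s <- svd(x)
  pos <- s$d > tol * max(s$d, 0)
  if (!any(pos)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Test a categorical clinical covariate across clusters
#'
#' Chi-squared independence test of a categorical phenotype field against
#' the cluster assignment (noise excluded), reported at raw alpha.
#'
#' @param phenotype Data frame with \code{sample} and the field.
#' @param assignment An \code{rpt_clusters}.
#' @param field Column name of the categorical variable.
#' @param alpha Significance level for the \code{significant} flag
#'   (default 0.01).
#' @return List with \code{table}, \code{statistic}, \code{df}, \code{p},
#'   \code{significant}.
#' @export
clinical_association <- function(phenotype, assignment, field, alpha = 0.01) {
  labs <- assignment$labels[phenotype$sample]
  keep <- !is.na(labs) & labs != "NOISE" & !is.na(phenotype[[field]])
  tab <- table(cluster = labs[keep], value = phenotype[[field]][keep])
  st <- chi_squared_independence(tab)
  c(list(table = tab), st, list(significant = st$p < alpha))
}
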