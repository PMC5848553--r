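#' Specify a planted tumor subcluster
#'
#' Describes one planted subpopulation of tumors: the composition shifts that
#' define its RPT expression pattern (an anchor transcript plus co-regulated
#' transcripts), an optional copy-number amplicon, an optional clinical
#' covariate enrichment, and an optional survival hazard.
#'
#' @param name Subcluster label.
#' @param proportion Fraction of the cohort's tumors belonging to the
#'   subcluster, in (0, 1).
#' @param anchor_shifts Named numeric vector of log2 fold changes applied to
#'   the Dirichlet concentration of the anchor gene(s).
#' @param coreg_shifts Named numeric vector of log2 fold changes for the
#'   co-regulated gene set.
#' @param cnv_amplicon Optional list \code{(genes, call, incidence,
#'   log2_effect)}: members of the subcluster carry integer GISTIC call
#'   \code{call} at all \code{genes} with probability \code{incidence}, and
#'   carriers get \code{log2_effect} added to those genes' expression shifts.
#' @param clinical_effect Optional list \code{(field, level, p_in, p_out)}:
#'   probability of the categorical \code{level} inside vs outside the
#'   subcluster.
#' @param hazard Optional exponential event rate (per day) replacing the
#'   cohort baseline for members.
#' @param censor_rate Optional exponential censoring rate for members.
#' @return A list of class \code{subcluster_spec}.
#' @export
subcluster_spec <- function(name, proportion,
                            anchor_shifts = numeric(),
                            coreg_shifts = numeric(),
                            cnv_amplicon = NULL,
                            clinical_effect = NULL,
                            hazard = NULL,
                            censor_rate = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            proportion > 0, proportion < 1)
  if (!is.null(cnv_amplicon)) {
    stopifnot(is.list(cnv_amplicon),
              all(c("genes", "call", "incidence") %in% names(cnv_amplicon)))
    if (cnv_amplicon$incidence < 0 || cnv_amplicon$incidence > 1)
      stop_ribotype("amplicon incidence must lie in [0, 1]")
    cnv_amplicon$log2_effect <- cnv_amplicon$log2_effect %||% 0
  }
  if (!is.null(hazard) && hazard <= 0) stop_ribotype("hazard must be positive")
  structure(list(name = name, proportion = proportion,
                 anchor_shifts = anchor_shifts, coreg_shifts = coreg_shifts,
                 cnv_amplicon = cnv_amplicon,
                 clinical_effect = clinical_effect,
                 hazard = hazard, censor_rate = censor_rate),
            class = "subcluster_spec")
}

#' Baseline composition concentrations for a synthetic tissue
#'
#' Draws a strictly positive Dirichlet concentration vector representing a
#' tissue's baseline RPT composition: per-gene weights are log-normal
#' (sdlog 0.5, a few-fold spread between the least and most expressed RP
#' transcript) scaled to a total concentration that controls within-tissue
#' noise. The default total of 2000 gives a typical per-gene coefficient of
#' variation near 20%, in line with the tight regulation of RP transcripts.
#'
#' @param n_genes Number of registry genes.
#' @param concentration Total concentration (sum of the vector).
#' @param seed Seed making the tissue's composition reproducible.
#' @return Positive numeric vector of length \code{n_genes}.
#' @export
base_alpha <- function(n_genes = 80, concentration = 2000, seed = 1) {
  w <- with_seed(seed, exp(stats::rnorm(n_genes, 0, 0.5)))
  concentration * w / sum(w)
}

#' Specify a synthetic cancer cohort
#'
#' @param cohort_code Short cohort label (e.g. \code{"PRAD"}).
#' @param n_tumor,n_normal Sample counts.
#' @param base_alpha Positive concentration vector, one entry per registry
#'   gene (see \code{\link{base_alpha}}).
#' @param subclusters List of \code{\link{subcluster_spec}} objects; their
#'   proportions must sum to at most 1 (the remainder forms the unplanted
#'   \code{"bulk"} tumor background).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param registry \code{\link{rp_registry}} giving gene names and order.
#' @param tumor_shifts Named log2 fold changes applied to every tumor (a
#'   global tumor-vs-normal composition shift).
#' @param baseline_hazard,baseline_censor Exponential event/censoring rates
#'   (per day) for tumors outside any hazard-bearing subcluster.
#' @param library_size_meanlog,library_size_sdlog Log-normal model of total
#'   RP RPKM per sample.
#' @param cnv_background Probability that a gene carries a spurious
#'   (+1 or -1) GISTIC call in a sample outside the planted amplicon.
#' @return A list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(cohort_code, n_tumor, n_normal = 0,
                        base_alpha = ribotype::base_alpha(nrow(registry)),
                        subclusters = list(), seed = 1,
                        registry = rp_registry(),
                        tumor_shifts = numeric(),
                        baseline_hazard = 5e-4, baseline_censor = 4e-4,
                        library_size_meanlog = log(2000),
                        library_size_sdlog = 0.4,
                        cnv_background = 0.02) {
  stopifnot(n_tumor >= 0, n_normal >= 0, length(base_alpha) == nrow(registry),
            all(base_alpha > 0))
  props <- vapply(subclusters, function(s) s$proportion, 0)
  if (length(props) && sum(props) > 1)
    stop_ribotype("subcluster proportions sum to ", sum(props), " > 1")
  all_shift_genes <- unique(c(names(tumor_shifts),
                              unlist(lapply(subclusters, function(s)
                                c(names(s$anchor_shifts), names(s$coreg_shifts),
                                  s$cnv_amplicon$genes)))))
  unknown <- setdiff(all_shift_genes, registry$gene)
  if (length(unknown))
    stop_ribotype("shifts reference genes outside the registry: ",
                  paste(unknown, collapse = ", "))
  structure(list(cohort_code = cohort_code, n_tumor = n_tumor,
                 n_normal = n_normal, base_alpha = base_alpha,
                 subclusters = subclusters, seed = seed, registry = registry,
                 tumor_shifts = tumor_shifts,
                 baseline_hazard = baseline_hazard,
                 baseline_censor = baseline_censor,
                 library_size_meanlog = library_size_meanlog,
                 library_size_sdlog = library_size_sdlog,
                 cnv_background = cnv_background),
            class = "cohort_spec")
}

#' Planted analogs of the recurring RPT expression patterns
#'
#' Subcluster templates mirroring the four recurring tumor-cluster patterns
#' (anchor transcript plus direction-consistent co-regulated sets): high
#' RPL8/RPL30, low RPL3, high RPS4X and high RPL13. Anchor genes get a log2
#' shift of magnitude 1 and co-regulated genes 0.75, in the directions the
#' patterns show; each template shifts 7-11 transcripts, reflecting the
#' breadth of the observed co-regulated sets.
#'
#' @param proportions Numeric vector (length up to 4) of tumor proportions,
#'   one per returned pattern, summing to at most 1.
#' @param ... Extra fields (e.g. \code{cnv_amplicon}, \code{hazard}) applied
#'   to the \emph{first} pattern via \code{\link{subcluster_spec}}.
#' @return List of \code{\link{subcluster_spec}} objects.
#' @export
recurring_patterns <- function(proportions = c(0.3, 0.25, 0.2), ...) {
  templates <- list(
    list(name = "high_rpl8_rpl30",
         anchor = c(RPL8 = 1, RPL30 = 1),
         coreg = c(RPL7 = 0.75, RPS20 = 0.75, RPL36A = 0.75,
                   RPL10 = -0.75, RPL5 = -0.75, RPS9 = -0.75)),
    list(name = "low_rpl3",
         anchor = c(RPL3 = -1),
         coreg = c(RPL5 = -0.75, RPL10 = -0.75, RPL17 = -0.75, RPS23 = -0.75,
                   RPL28 = 0.75, RPL35 = 0.75, RPL36 = 0.75, RPL38 = 0.75,
                   RPLP2 = 0.75)),
    list(name = "high_rps4x",
         anchor = c(RPS4X = 1),
         coreg = c(RPS3A = 0.75, RPL17 = 0.75, RPL13 = -0.75, RPL23 = -0.75,
                   RPL37 = -0.75, RPL8 = -0.75, RPLP1 = -0.75, RPS16 = -0.75,
                   RPS2 = -0.75)),
    list(name = "high_rpl13",
         anchor = c(RPL13 = 1),
         coreg = c(RPL10 = -0.75, RPL26 = -0.75, RPL3 = -0.75, RPL5 = -0.75,
                   RPL7 = -0.75, RPL12 = 0.75, RPL18 = 0.75, RPL24 = 0.75,
                   RPS19 = 0.75, FAU = 0.75)))
  stopifnot(length(proportions) >= 1L, length(proportions) <= length(templates))
  extras <- list(...)
  lapply(seq_along(proportions), function(k) {
    tm <- templates[[k]]
    args <- c(list(name = tm$name, proportion = proportions[k],
                   anchor_shifts = tm$anchor, coreg_shifts = tm$coreg),
              if (k == 1L) extras)
    do.call(subcluster_spec, args)
  })
}

rdirichlet_rows <- function(alpha_matrix) {
  g <- matrix(stats::rgamma(length(alpha_matrix), shape = alpha_matrix),
              nrow = nrow(alpha_matrix))
  g / rowSums(g)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Samples a cohort under a Dirichlet-composition noise model: each sample's
#' RPT composition is Dirichlet with the cohort baseline concentration,
#' element-wise scaled by \code{2^shift} for its subcluster's anchor and
#' co-regulated genes (and the global tumor shift); RPKM rows are the
#' composition times a log-normal library size. Planted amplicons set GISTIC
#' calls at the stated incidence inside the subcluster and at the background
#' rate outside, and add their expression effect for carriers. Survival times
#' are exponential with independent exponential censoring.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A list of class \code{rpt_cohort} with elements
#'   \code{expression} (\code{\link{expression_matrix}}), \code{cnv}
#'   (integer samples x genes matrix), \code{truth} (named subcluster label
#'   per tumor sample), \code{survival} (data frame sample/time/event) and
#'   \code{clinical} (phenotype data frame).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  genes <- spec$registry$gene
  p <- length(genes)
  n_t <- spec$n_tumor
  n_n <- spec$n_normal
  tumor_ids <- if (n_t) sprintf("%s-T%03d", spec$cohort_code, seq_len(n_t)) else character()
  normal_ids <- if (n_n) sprintf("%s-N%03d", spec$cohort_code, seq_len(n_n)) else character()
  ids <- c(tumor_ids, normal_ids)
  n <- n_t + n_n

  # deterministic subcluster sizes, randomly permuted membership
  truth <- rep("bulk", n_t)
  if (length(spec$subclusters) && n_t > 0) {
    sizes <- vapply(spec$subclusters, function(s) round(s$proportion * n_t), 0)
    if (sum(sizes) > n_t) stop_ribotype("subcluster sizes exceed cohort size")
    perm <- sample.int(n_t)
    at <- 0L
    for (k in seq_along(spec$subclusters)) {
      if (sizes[k] > 0) truth[perm[at + seq_len(sizes[k])]] <- spec$subclusters[[k]]$name
      at <- at + sizes[k]
    }
  }
  names(truth) <- tumor_ids
  sub_by_name <- stats::setNames(spec$subclusters,
                                 vapply(spec$subclusters, `[[`, "", "name"))

  # CNV calls first (carriers feed back into expression shifts)
  cnv <- matrix(0L, n, p, dimnames = list(ids, genes))
  bg <- spec$cnv_background
  if (bg > 0 && n_t > 0) {
    noise <- matrix(stats::runif(n_t * p) < bg, n_t, p)
    signs <- matrix(sample(c(-1L, 1L), n_t * p, replace = TRUE), n_t, p)
    cnv[seq_len(n_t), ][noise] <- signs[noise]
  }
  carrier <- matrix(FALSE, n, p, dimnames = list(ids, genes))
  for (s in spec$subclusters) {
    if (is.null(s$cnv_amplicon)) next
    members <- which(truth == s$name)
    amp <- s$cnv_amplicon
    carries <- stats::runif(length(members)) < amp$incidence
    cnv[tumor_ids[members], amp$genes] <- 0L  # planted region overrides noise
    cnv[tumor_ids[members[carries]], amp$genes] <- as.integer(amp$call)
    carrier[tumor_ids[members[carries]], amp$genes] <- TRUE
  }

  # per-sample concentration vectors
  alpha <- matrix(rep(spec$base_alpha, each = n), n, p,
                  dimnames = list(ids, genes))
  shift <- matrix(0, n, p, dimnames = list(ids, genes))
  if (n_t > 0 && length(spec$tumor_shifts))
    shift[seq_len(n_t), names(spec$tumor_shifts)] <-
      shift[seq_len(n_t), names(spec$tumor_shifts), drop = FALSE] +
      rep(spec$tumor_shifts, each = n_t)
  for (s in spec$subclusters) {
    members <- tumor_ids[truth == s$name]
    for (set in list(s$anchor_shifts, s$coreg_shifts)) {
      if (length(set))
        shift[members, names(set)] <- shift[members, names(set), drop = FALSE] +
          rep(set, each = length(members))
    }
    if (!is.null(s$cnv_amplicon) && s$cnv_amplicon$log2_effect != 0) {
      eff <- s$cnv_amplicon$log2_effect
      shift[, s$cnv_amplicon$genes] <- shift[, s$cnv_amplicon$genes, drop = FALSE] +
        eff * carrier[, s$cnv_amplicon$genes, drop = FALSE]
    }
  }
  alpha <- alpha * 2^shift

  comp <- rdirichlet_rows(alpha)
  libsize <- stats::rlnorm(n, spec$library_size_meanlog, spec$library_size_sdlog)
  rpkm <- comp * libsize
  dimnames(rpkm) <- list(ids, genes)

  # clinical covariates
  clinical <- data.frame(sample = ids,
                         cohort = spec$cohort_code,
                         tumor = c(rep(TRUE, n_t), rep(FALSE, n_n)),
                         subcluster = c(truth, rep(NA_character_, n_n)),
                         stringsAsFactors = FALSE)
  for (s in spec$subclusters) {
    if (is.null(s$clinical_effect)) next
    ce <- s$clinical_effect
    if (!ce$field %in% names(clinical)) clinical[[ce$field]] <- "other"
    in_cl <- c(truth == s$name, rep(FALSE, n_n))
    pr <- ifelse(in_cl, ce$p_in, ce$p_out)
    hit <- stats::runif(n) < pr
    clinical[[ce$field]][hit & clinical$tumor] <- ce$level
  }

  # survival (tumors only)
  surv <- NULL
  if (n_t > 0) {
    haz <- rep(spec$baseline_hazard, n_t)
    cens <- rep(spec$baseline_censor, n_t)
    for (s in spec$subclusters) {
      m <- truth == s$name
      if (!is.null(s$hazard)) haz[m] <- s$hazard
      if (!is.null(s$censor_rate)) cens[m] <- s$censor_rate
    }
    t_event <- stats::rexp(n_t, haz)
    t_cens <- stats::rexp(n_t, cens)
    surv <- data.frame(sample = tumor_ids,
                       time = pmin(t_event, t_cens),
                       event = as.integer(t_event <= t_cens),
                       stringsAsFactors = FALSE)
  }

  expr <- expression_matrix(rpkm, sample_meta = clinical)
  structure(list(expression = expr, cnv = cnv, truth = truth,
                 survival = surv, clinical = clinical, spec = spec),
            class = "rpt_cohort")
}

#' @export
print.rpt_cohort <- function(x, ...) {
  cat("Synthetic cohort", x$spec$cohort_code, ":", x$spec$n_tumor, "tumors,",
      x$spec$n_normal, "normals;",
      length(unique(x$truth[x$truth != "bulk"])), "planted subcluster(s)\n")
  invisible(x)
}

#' Generate a pan-cancer set of cohorts sharing planted patterns
#'
#' Injects each shared subcluster pattern (identical anchor and co-regulated
#' shifts) into every cohort spec, so that the cross-cohort co-regulation
#' stage has a recoverable ground truth, then generates all cohorts.
#'
#' @param specs List of at least two \code{\link{cohort_spec}} objects.
#' @param shared_patterns List of \code{\link{subcluster_spec}} objects to
#'   plant in every cohort.
#' @return List of \code{rpt_cohort} objects, one per spec.
#' @export
generate_pan_cancer_set <- function(specs, shared_patterns = list()) {
  if (length(specs) < 2L) stop_ribotype("a pan-cancer set needs >= 2 cohorts")
  lapply(specs, function(sp) {
    local_names <- vapply(sp$subclusters, `[[`, "", "name")
    shared_names <- vapply(shared_patterns, `[[`, "", "name")
    clash <- intersect(local_names, shared_names)
    if (length(clash))
      stop_ribotype("shared pattern name(s) collide with cohort-local subclusters in ",
                    sp$cohort_code, ": ", paste(clash, collapse = ", "))
    sp$subclusters <- c(sp$subclusters, shared_patterns)
    props <- vapply(sp$subclusters, function(s) s$proportion, 0)
    if (sum(props) > 1)
      stop_ribotype("subcluster proportions exceed 1 in ", sp$cohort_code)
    generate_cohort(sp)
  })
}

#' Write a synthetic cohort to disk in the package's TSV dialects
#'
#' Emits \code{expression.tsv} (Xena orientation, log2(RPKM+1)),
#' \code{cnv.tsv} (gene rows, integer GISTIC calls), \code{phenotype.tsv} and
#' \code{survival.tsv}, all readable by the package's loaders, so fixtures can
#' be exercised through the public readers.
#'
#' @param cohort An \code{rpt_cohort}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_table(cohort$expression, file.path(dir, "expression.tsv"),
                         dialect = "log2_plus1")
  cnv_out <- data.frame(gene = colnames(cohort$cnv), t(cohort$cnv),
                        check.names = FALSE)
  utils::write.table(cnv_out, file.path(dir, "cnv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$survival))
    utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a GISTIC-thresholded copy-number table
#'
#' @param path TSV with gene rows (first column gene symbol) and sample
#'   columns; integer calls in -2..2.
#' @return Integer matrix, samples in rows.
#' @export
load_cnv_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- trimws(as.character(tab[[1L]]))
  m <- t(m)
  if (anyNA(m) || any(m != round(m)))
    stop_ribotype("CNV table must hold integer GISTIC calls")
  storage.mode(m) <- "integer"
  m
}

#' Read a phenotype (clinical) table keyed by sample id
#'
#' @param path TSV with a \code{sample} column.
#' @return Data frame.
#' @export
load_phenotype_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample" %in% names(tab))
    stop_ribotype("phenotype table needs a 'sample' column")
  tab
}

#' Read a survival table (sample, time, event)
#'
#' @param path TSV with columns \code{sample}, \code{time} (days, >= 0) and
#'   \code{event} (1 = death observed, 0 = censored).
#' @return Data frame.
#' @export
load_survival_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(tab)))
    stop_ribotype("survival table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$time < 0)) stop_ribotype("negative survival times")
  if (!all(tab$event %in% c(0, 1))) stop_ribotype("event must be 0 or 1")
  tab
}
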