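#' Pipeline configuration
#'
#' Collects the thresholds and sweep settings shared by the per-cohort and
#' pan-cohort analyses. Perplexities default to the single-cohort range
#' (6-15) for individual runs and 10-30 for grouped runs; the displayed
#' volcano, co-regulation and clinical alpha levels default to 0.01; CNV
#' enrichment uses a 5% FDR with the >90% in-cluster incidence reporting
#' filter.
#'
#' @param registry An \code{\link{rp_registry}}.
#' @param dialect Expression storage dialect for any file loading.
#' @param perplexities Perplexity sweep for single-cohort embeddings.
#' @param grouped_perplexities Sweep for grouped (pan-cancer) embeddings.
#' @param iterations t-SNE iteration cap.
#' @param min_size Minimum cluster size.
#' @param alpha_volcano,alpha_coreg,alpha_clinical Raw significance levels.
#' @param fdr_q,incidence_min CNV enrichment thresholds.
#' @param classifier_grid Hyperparameter grid for the pan-cancer network
#'   (default: a small desk-scale grid; use \code{\link{ann_grid}()} for the
#'   full sweep).
#' @param seed Master seed.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(registry = rp_registry(),
                            dialect = "log2_plus1",
                            perplexities = c(6, 10, 15),
                            grouped_perplexities = c(10, 20, 30),
                            iterations = 5000,
                            min_size = 10,
                            alpha_volcano = 0.01,
                            alpha_coreg = 0.01,
                            alpha_clinical = 0.01,
                            fdr_q = 0.05,
                            incidence_min = 0.90,
                            classifier_grid = ann_grid(
                              learning_rate = c(0.005, 0.01),
                              batch_size = c(100, NA), dropout_keep = 1,
                              hidden = list(50, 100), l2 = 1e-4),
                            seed = 1) {
  stopifnot(all(perplexities >= 6 & perplexities <= 15),
            all(grouped_perplexities >= 10 & grouped_perplexities <= 30),
            alpha_volcano > 0 && alpha_volcano < 1,
            fdr_q > 0 && fdr_q < 1, incidence_min > 0 && incidence_min < 1)
  structure(list(registry = registry, dialect = dialect,
                 perplexities = perplexities,
                 grouped_perplexities = grouped_perplexities,
                 iterations = iterations, min_size = min_size,
                 alpha_volcano = alpha_volcano, alpha_coreg = alpha_coreg,
                 alpha_clinical = alpha_clinical, fdr_q = fdr_q,
                 incidence_min = incidence_min,
                 classifier_grid = classifier_grid, seed = seed),
            class = "pipeline_config")
}

# Mean silhouette width of a non-noise assignment on embedding coordinates;
# -1 when fewer than two clusters (no separation to score).
assignment_silhouette <- function(coords, labels) {
  keep <- labels != "NOISE"
  cl <- factor(labels[keep])
  if (nlevels(cl) < 2L) return(-1)
  sil <- cluster::silhouette(as.integer(cl), stats::dist(coords[keep, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Run the full per-cohort analysis
#'
#' Executes the per-cohort pipeline: registry extraction, relative
#' expression, a t-SNE perplexity sweep with density cluster discovery
#' (the run with the best mean silhouette is reported; all runs are kept),
#' the ANOVA volcano, per-cluster contrasts, CNV enrichment, categorical
#' clinical associations, and Kaplan-Meier curves with log-rank and
#' Gehan-Breslow-Wilcoxon tests.
#'
#' @param expression An \code{rpt_expression} (linear scale).
#' @param cnv Optional integer samples-by-genes GISTIC call matrix.
#' @param phenotype Optional phenotype data frame (\code{sample} column).
#' @param survival Optional survival data frame (\code{sample},
#'   \code{time}, \code{event}).
#' @param config A \code{\link{pipeline_config}}.
#' @param clinical_fields Phenotype columns to test; defaults to all
#'   character/factor columns except identifiers.
#' @param out_dir If given, every artifact is written there as TSV/YAML
#'   with a JSON-like manifest.
#' @return List of class \code{rpt_cohort_analysis} with elements
#'   \code{relexpr}, \code{sweep} (per-perplexity embeddings and
#'   assignments), \code{best} (index of the selected run),
#'   \code{embedding}, \code{clusters}, \code{profiles}, \code{volcano},
#'   \code{contrasts}, \code{cnv_enrichment}, \code{clinical},
#'   \code{survival} and \code{manifest}.
#' @export
run_cohort_analysis <- function(expression, cnv = NULL, phenotype = NULL,
                                survival = NULL, config = pipeline_config(),
                                clinical_fields = NULL, out_dir = NULL) {
  check_alignment <- function(ids, what) {
    if (!setequal(ids, expression$sample_ids) &&
        !all(expression$sample_ids %in% ids))
      stop_ribotype("sample ids of ", what,
                    " are not aligned with the expression matrix")
  }
  if (!is.null(cnv)) check_alignment(rownames(cnv), "cnv")
  if (!is.null(phenotype)) check_alignment(phenotype$sample, "phenotype")

  rp <- extract_rp_expression(expression, config$registry)
  relexpr <- relative_expression(rp)

  sweep_runs <- lapply(config$perplexities, function(px) {
    emb <- tsne_embed(relexpr, embedding_config(
      perplexity = px, iterations = config$iterations, seed = config$seed))
    cl <- tryCatch(discover_clusters(emb, min_size = config$min_size),
                   error = function(e) NULL)
    sil <- if (is.null(cl)) -Inf else assignment_silhouette(emb$coords, cl$labels)
    list(perplexity = px, embedding = emb, clusters = cl, silhouette = sil)
  })
  sils <- vapply(sweep_runs, `[[`, 0, "silhouette")
  best <- which.max(sils)
  embedding <- sweep_runs[[best]]$embedding
  clusters <- sweep_runs[[best]]$clusters
  if (is.null(clusters))
    stop_ribotype("no sweep run produced a cluster assignment")

  n_clusters <- length(clusters$sizes)
  profiles <- cluster_mean_profiles(relexpr, clusters)
  volcano <- NULL; contrasts <- NULL
  if (n_clusters >= 2L) {
    volcano <- anova_across_clusters(relexpr, clusters)
    contrasts <- lapply(names(clusters$sizes), function(cl)
      cluster_vs_rest_contrast(relexpr, clusters, cl))
    names(contrasts) <- names(clusters$sizes)
  }

  cnv_enrichment <- NULL
  if (!is.null(cnv) && n_clusters >= 2L) {
    cnv_enrichment <- cnv_cluster_enrichment(
      cnv, clusters, fdr_q = config$fdr_q,
      incidence_min = config$incidence_min)
  }

  clinical <- NULL
  if (!is.null(phenotype) && n_clusters >= 2L) {
    if (is.null(clinical_fields)) {
      skip <- c("sample", "cohort", "tumor", "subcluster")
      clinical_fields <- setdiff(
        names(phenotype)[vapply(phenotype, function(v)
          is.character(v) || is.factor(v), TRUE)], skip)
    }
    clinical <- lapply(clinical_fields, function(f)
      tryCatch(clinical_association(phenotype, clusters, f,
                                    alpha = config$alpha_clinical),
               error = function(e) list(error = conditionMessage(e))))
    names(clinical) <- clinical_fields
  }

  surv_out <- NULL
  if (!is.null(survival) && n_clusters >= 2L) {
    labs <- clusters$labels[survival$sample]
    keep <- !is.na(labs) & labs != "NOISE"
    sdat <- survival[keep, ]
    sdat$group <- labs[keep]
    if (sum(sdat$event) > 0) {
      surv_out <- list(
        curves = lapply(split(sdat, sdat$group), km_curve),
        tests = survival_tests(sdat))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ribotype")),
    seed = config$seed,
    perplexities = config$perplexities,
    best_perplexity = config$perplexities[best],
    iterations = config$iterations,
    min_size = config$min_size,
    n_samples = length(relexpr$sample_ids),
    n_genes = length(relexpr$gene_ids),
    n_clusters = n_clusters,
    noise = sum(clusters$labels == "NOISE"))

  out <- structure(list(relexpr = relexpr, sweep = sweep_runs, best = best,
                        embedding = embedding, clusters = clusters,
                        profiles = profiles, volcano = volcano,
                        contrasts = contrasts,
                        cnv_enrichment = cnv_enrichment,
                        clinical = clinical, survival = surv_out,
                        manifest = manifest, config = config),
                   class = "rpt_cohort_analysis")
  if (!is.null(out_dir)) write_cohort_analysis(out, out_dir)
  out
}

#' @export
print.rpt_cohort_analysis <- function(x, ...) {
  m <- x$manifest
  cat("Cohort analysis:", m$n_samples, "samples;", m$n_clusters,
      "cluster(s) (perplexity", m$best_perplexity, ", noise", m$noise, ")\n")
  if (!is.null(x$cnv_enrichment))
    cat("  CNV associations flagged:", sum(x$cnv_enrichment$flagged), "\n")
  if (!is.null(x$survival))
    cat("  log-rank p:", format(x$survival$tests$logrank$p, digits = 3), "\n")
  invisible(x)
}

write_cohort_analysis <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_embedding(x$embedding, file.path(out_dir, "embedding"))
  write_clusters(x$clusters, file.path(out_dir, "clusters"))
  if (!is.null(x$volcano)) write_volcano(x$volcano, file.path(out_dir, "volcano.tsv"))
  if (!is.null(x$cnv_enrichment))
    utils::write.table(x$cnv_enrichment, file.path(out_dir, "cnv_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(x$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Run the pan-cancer stage over several analyzed cohorts
#'
#' Concatenates the cohorts' relative expression for a grouped t-SNE
#' embedding (grouped perplexity range), extracts co-regulated transcript
#' sets for each requested anchor from the qualifying cluster contrasts of
#' every cohort, and fits the pan-cancer classifiers: a tissue-of-origin
#' network over cohort labels and, when normals are present, a
#' tumor-versus-normal logistic model.
#'
#' @param bundles Named list of \code{rpt_cohort_analysis} objects (names =
#'   cohort codes).
#' @param anchors List of lists \code{(gene, direction)} naming anchor
#'   transcripts to trace across cohorts.
#' @param config A \code{\link{pipeline_config}}.
#' @return List of class \code{rpt_pan_cancer} with \code{embedding},
#'   \code{coregulation}, \code{tissue_classifier},
#'   \code{tumor_normal_classifier}.
#' @export
run_pan_cancer <- function(bundles, anchors = list(),
                           config = pipeline_config()) {
  if (length(bundles) < 2L) stop_ribotype("need >= 2 cohort bundles")
  if (is.null(names(bundles)))
    names(bundles) <- vapply(bundles, function(b)
      b$relexpr$sample_meta$cohort[1L], "")
  gene_sets <- lapply(bundles, function(b) b$relexpr$gene_ids)
  if (!all(vapply(gene_sets, identical, TRUE, gene_sets[[1L]])))
    stop_ribotype("cohorts use mismatched gene registries")

  fractions <- do.call(rbind, lapply(bundles, function(b) b$relexpr$fractions))
  meta <- do.call(rbind, lapply(bundles, function(b) {
    sm <- b$relexpr$sample_meta
    sm[, intersect(c("sample", "cohort", "tumor"), names(sm)), drop = FALSE]
  }))
  rownames(meta) <- NULL
  combined <- structure(list(fractions = fractions,
                             sample_ids = rownames(fractions),
                             gene_ids = gene_sets[[1L]],
                             sample_meta = meta),
                        class = "rpt_relexpr")

  embedding <- tsne_embed(combined, embedding_config(
    perplexity = config$grouped_perplexities[1L],
    iterations = config$iterations, seed = config$seed))

  coregulation <- lapply(anchors, function(an) {
    members <- list()
    for (code in names(bundles)) {
      b <- bundles[[code]]
      if (is.null(b$contrasts)) next
      for (ct in b$contrasts) {
        row <- ct[ct$gene == an$gene, ]
        if (nrow(row) == 1L && row$p < config$alpha_coreg &&
            row$direction == an$direction)
          members[[paste0(code, ":", attr(ct, "cluster"))]] <- ct
      }
    }
    if (length(members) < 2L)
      return(list(anchor = an$gene, direction = an$direction,
                  skipped = "fewer than 2 qualifying clusters"))
    names(members) <- sub(":.*$", "", names(members))
    find_coregulated_sets(members, anchor = an$gene,
                          direction = an$direction,
                          alpha = config$alpha_coreg)
  })
  if (length(anchors))
    names(coregulation) <- vapply(anchors, `[[`, "", "gene")

  split <- balanced_split(meta, seed = config$seed)
  tissue_labels <- stats::setNames(meta$cohort, meta$sample)
  tissue <- ann_hyperparameter_sweep(combined, tissue_labels, split,
                                     grid = config$classifier_grid,
                                     seed = config$seed)

  tumor_normal <- NULL
  if ("tumor" %in% names(meta) && length(unique(meta$tumor)) == 2L) {
    tn_labels <- stats::setNames(ifelse(meta$tumor, "tumor", "normal"),
                                 meta$sample)
    tumor_normal <- fit_logistic_classifier(combined, tn_labels, split)
  }

  structure(list(embedding = embedding, coregulation = coregulation,
                 tissue_classifier = tissue,
                 tumor_normal_classifier = tumor_normal, split = split,
                 config = config),
            class = "rpt_pan_cancer")
}

#' @export
print.rpt_pan_cancer <- function(x, ...) {
  cat("Pan-cancer analysis:", nrow(x$embedding$coords), "samples\n")
  cat("  tissue-of-origin test accuracy:",
      format(x$tissue_classifier$report$accuracy, digits = 3), "\n")
  if (!is.null(x$tumor_normal_classifier))
    cat("  tumor-vs-normal test accuracy:",
        format(x$tumor_normal_classifier$report$accuracy, digits = 3), "\n")
  invisible(x)
}
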