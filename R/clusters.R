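#' Discover clusters in an embedding by density connectivity
#'
#' Operationalizes "clusters that separate visually": samples are linked when
#' their embedding distance is at most \code{radius}, connected components
#' with at least \code{min_size} members become clusters (numbered in
#' decreasing size order, 1 = largest), and everything else is labelled
#' \code{"NOISE"}. The default radius is chosen automatically at the elbow
#' (maximum-curvature point) of the sorted k-nearest-neighbor distance curve
#' with \code{k = min_size}.
#'
#' @param embedding An \code{rpt_tsne} or a coordinate matrix (samples in
#'   rows).
#' @param min_size Minimum cluster size (default 10).
#' @param radius Linking radius, or \code{"auto"}.
#' @return Object of class \code{rpt_clusters}: list with \code{labels}
#'   (named character vector, cluster id or \code{"NOISE"}), \code{min_size},
#'   \code{radius} and \code{sizes}.
#' @export
discover_clusters <- function(embedding, min_size = 10, radius = "auto") {
  coords <- if (inherits(embedding, "rpt_tsne")) embedding$coords else as.matrix(embedding)
  n <- nrow(coords)
  if (n < 1L) stop_ribotype("empty embedding")
  d <- sqrt(squared_distances(coords))
  if (identical(radius, "auto")) {
    radius <- knn_elbow_radius(d, k = min(min_size, n - 1L))
  }
  stopifnot(is.numeric(radius), radius > 0)

  # connected components of the radius graph (BFS)
  comp <- integer(n)
  ncomp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(d[v, ] <= radius & comp == 0L)
      comp[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(comp, ncomp)
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L)
    stop_ribotype("all points are noise at radius ", format(radius),
                  "; increase the radius")
  # decreasing size, ties broken by first-appearing component for determinism
  keep <- keep[order(-sizes[keep], keep)]
  labels <- rep("NOISE", n)
  for (i in seq_along(keep)) labels[comp == keep[i]] <- as.character(i)
  names(labels) <- rownames(coords)
  structure(list(labels = labels, min_size = min_size, radius = radius,
                 sizes = stats::setNames(sizes[keep], seq_along(keep))),
            class = "rpt_clusters")
}

# Elbow of the sorted kNN-distance curve: the point furthest from the chord
# joining the curve's endpoints (maximum-curvature proxy).
knn_elbow_radius <- function(d, k) {
  n <- nrow(d)
  kd <- vapply(seq_len(n), function(i) sort(d[i, -i], partial = k)[k], 0)
  s <- sort(kd)
  m <- length(s)
  if (m < 3L || s[m] == s[1L]) return(max(s[m], .Machine$double.eps))
  xs <- (seq_len(m) - 1) / (m - 1)
  ys <- (s - s[1L]) / (s[m] - s[1L])
  # distance from each point to the unit chord y = x
  elbow <- which.max(abs(ys - xs))
  max(s[elbow], .Machine$double.eps)
}

#' @export
print.rpt_clusters <- function(x, ...) {
  nn <- sum(x$labels == "NOISE")
  cat("Cluster assignment:", length(x$sizes), "cluster(s) of sizes",
      paste(x$sizes, collapse = ", "), ";", nn, "noise sample(s); radius",
      format(x$radius, digits = 4), "\n")
  invisible(x)
}

#' Per-cluster deviation profiles of relative RPT expression
#'
#' For each cluster and gene, the cluster's mean relative expression minus
#' the cohort-wide mean -- the data behind per-cluster "3D area map" displays
#' of expression deviation.
#'
#' @param relexpr An \code{rpt_relexpr}.
#' @param assignment An \code{rpt_clusters} covering its samples.
#' @return List with \code{deviation} (clusters x genes matrix),
#'   \code{cluster_sizes} and \code{overall_mean}.
#' @export
cluster_mean_profiles <- function(relexpr, assignment) {
  stopifnot(inherits(relexpr, "rpt_relexpr"), inherits(assignment, "rpt_clusters"))
  labs <- assignment$labels[relexpr$sample_ids]
  if (anyNA(labs))
    stop_ribotype("assignment does not cover all samples")
  overall <- colMeans(relexpr$fractions)
  ids <- setdiff(sort(unique(labs)), "NOISE")
  dev <- t(vapply(ids, function(cl) {
    members <- labs == cl
    if (!any(members)) stop_ribotype("empty cluster ", cl)
    colMeans(relexpr$fractions[members, , drop = FALSE]) - overall
  }, overall))
  rownames(dev) <- ids
  list(deviation = dev,
       cluster_sizes = stats::setNames(
         vapply(ids, function(cl) sum(labs == cl), 0L), ids),
       overall_mean = overall)
}

#' Write a cluster assignment with its parameter sidecar
#'
#' @param assignment An \code{rpt_clusters}.
#' @param prefix Path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>_params.yaml}.
#' @return \code{prefix}, invisibly.
#' @export
write_clusters <- function(assignment, prefix) {
  out <- data.frame(sample = names(assignment$labels),
                    cluster = unname(assignment$labels))
  utils::write.table(out, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(min_size = assignment$min_size,
                        radius = assignment$radius),
                   paste0(prefix, "_params.yaml"))
  invisible(prefix)
}
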