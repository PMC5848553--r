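#' Cytoplasmic ribosomal protein gene registry
#'
#' Loads the registry of cytoplasmic ribosomal protein (RP) gene symbols used
#' throughout the package. The packaged default lists the 80 canonical human
#' cytoplasmic RP genes (the \code{RPL*}/\code{RPS*} families plus
#' \code{RPLP0-2}, \code{RPSA}, \code{FAU}, \code{UBA52} and \code{RPS4Y1}),
#' each with its ribosomal subunit and, where well established, a cytoband.
#' Users may supply their own registry file: one gene per line, tab-separated
#' optional subunit (\code{large}/\code{small}) and cytoband columns, \code{#}
#' comments allowed.
#'
#' @param path Path to a registry file, or \code{NULL} for the packaged
#'   80-gene default.
#' @return A data frame of class \code{rp_registry} with columns \code{gene},
#'   \code{subunit} and \code{locus} (cytoband, possibly \code{NA}).
#' @examples
#' reg <- rp_registry()
#' nrow(reg)           # 80
#' table(reg$subunit)
#' @export
rp_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rp_genes.tsv", package = "ribotype",
                        mustWork = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_ribotype("registry file '", path, "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  gene <- trimws(vapply(parts, `[`, "", 1L))
  subunit <- trimws(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, ""))
  locus <- trimws(vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, ""))
  locus[!nzchar(locus) | is.na(locus)] <- NA_character_
  if (anyDuplicated(gene)) {
    stop_ribotype("duplicate registry symbols: ",
                  paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  ok <- grepl("^(RPL|RPS|RPLP|FAU$|UBA52$)", gene)
  if (!all(ok)) {
    stop_ribotype("symbols outside the cytoplasmic RP naming families: ",
                  paste(gene[!ok], collapse = ", "))
  }
  subunit[is.na(subunit) | !nzchar(subunit)] <- NA_character_
  bad <- !is.na(subunit) & !subunit %in% c("large", "small")
  if (any(bad)) {
    stop_ribotype("subunit must be 'large' or 'small': ",
                  paste(unique(subunit[bad]), collapse = ", "))
  }
  out <- data.frame(gene = gene, subunit = subunit, locus = locus,
                    stringsAsFactors = FALSE)
  class(out) <- c("rp_registry", "data.frame")
  out
}

#' @export
print.rp_registry <- function(x, ...) {
  cat("RP gene registry:", nrow(x), "genes (",
      sum(x$subunit == "large", na.rm = TRUE), "large /",
      sum(x$subunit == "small", na.rm = TRUE), "small )\n")
  invisible(x)
}
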