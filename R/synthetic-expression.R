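## Synthetic TPM tables: log-normal noise around planted pattern means, so
## that the filter / specificity / comparison logic can be validated against
## ground truth.

#' Design for the synthetic expression generator
#'
#' Patterns: `ubiquitous` genes are expressed in every group (mean TPM well
#' above the filter threshold), `silent` genes nowhere (mean TPM <= 1),
#' `tissue_specific:<tissue>` genes only in the named tissue, and
#' `condition_up:<group>` genes everywhere with a planted log-scale mean
#' shift in the named group.
#'
#' @param tissues Character vector of sample-group labels.
#' @param genes_per_pattern Named integer vector, pattern -> count.
#' @param n_replicates Replicates per group (default 3; condition patterns
#'   require at least 2).
#' @param baseline_log_mean Log-scale mean of expressed genes
#'   (default `log(50)`).
#' @param log_sd Log-scale standard deviation (default 0.25).
#' @param condition_shift Planted log-scale shift for `condition_up` genes,
#'   in units of `log_sd` (default 4).
#' @param seed Integer seed.
#' @return A validated list of class `"ExpressionDesign"`.
#' @export
expressionDesign <- function(tissues, genes_per_pattern,
                             n_replicates = 3L,
                             baseline_log_mean = log(50), log_sd = 0.25,
                             condition_shift = 4, seed = 1L) {
  stopifnot(length(tissues) >= 1, !anyDuplicated(tissues))
  pats <- names(genes_per_pattern)
  if (is.null(pats)) stop("genes_per_pattern must be named by pattern")
  for (p in pats) {
    if (p %in% c("ubiquitous", "silent")) next
    if (grepl("^tissue_specific:", p)) {
      t <- sub("^tissue_specific:", "", p)
      if (!t %in% tissues) stop("tissue_specific target not in tissues: ", t)
    } else if (grepl("^condition_up:", p)) {
      if (n_replicates < 2)
        stop("condition_up patterns require at least 2 replicates per group")
      t <- sub("^condition_up:", "", p)
      if (!t %in% tissues) stop("condition_up target not in tissues: ", t)
    } else stop("unknown pattern: ", p)
  }
  structure(list(tissues = tissues, genes_per_pattern = genes_per_pattern,
                 n_replicates = as.integer(n_replicates),
                 baseline_log_mean = baseline_log_mean, log_sd = log_sd,
                 condition_shift = condition_shift, seed = as.integer(seed)),
            class = "ExpressionDesign")
}

#' Generate a synthetic TPM matrix with planted patterns
#'
#' TPM values are drawn log-normally around per-pattern means: expressed
#' cells around `exp(baseline_log_mean)` (default 50), silent cells around
#' 0.3 (mean TPM at most 1, safely under the filter threshold of 2), and
#' `condition_up` cells with the planted shift added on the log scale in the
#' target group.
#'
#' @param design An [expressionDesign()].
#' @return A list with `matrix` (genes x samples), `meta` (sample_id, group,
#'   replicate) and `truth` (gene_id, pattern).
#' @export
#' @examples
#' d <- expressionDesign(c("sperm", "thallus"),
#'                       c(ubiquitous = 2, "tissue_specific:sperm" = 2))
#' makeExpressionMatrix(d)$truth
makeExpressionMatrix <- function(design) {
  stopifnot(inherits(design, "ExpressionDesign"))
  meta <- do.call(rbind, lapply(design$tissues, function(t)
    data.frame(sample_id = paste0(t, "_r", seq_len(design$n_replicates)),
               group = t, replicate = seq_len(design$n_replicates),
               stringsAsFactors = FALSE)))
  silent_log_mean <- log(0.3)
  withStreamSeed(design$seed, "expression", {
    rows <- list(); truth <- list()
    for (p in names(design$genes_per_pattern)) {
      n <- design$genes_per_pattern[[p]]
      if (n == 0) next
      for (k in seq_len(n)) {
        gid <- sprintf("%s_gene%03d", gsub("[^A-Za-z0-9]", "_", p), k)
        mu <- vapply(meta$group, function(g) {
          if (p == "ubiquitous") design$baseline_log_mean
          else if (p == "silent") silent_log_mean
          else if (grepl("^tissue_specific:", p)) {
            if (g == sub("^tissue_specific:", "", p))
              design$baseline_log_mean else silent_log_mean
          } else {  # condition_up
            design$baseline_log_mean +
              if (g == sub("^condition_up:", "", p))
                design$condition_shift * design$log_sd else 0
          }
        }, numeric(1))
        rows[[gid]] <- stats::rlnorm(nrow(meta), meanlog = mu,
                                     sdlog = design$log_sd)
        truth[[length(truth) + 1L]] <-
          data.frame(gene_id = gid, pattern = p, stringsAsFactors = FALSE)
      }
    }
    m <- do.call(rbind, rows)
    colnames(m) <- meta$sample_id
    list(matrix = m, meta = meta, truth = do.call(rbind, truth))
  })
}

#' Write a synthetic expression bundle as TSV
#'
#' @param bundle Result of [makeExpressionMatrix()].
#' @param dir Output directory.
#' @param prefix File prefix.
#' @return Invisibly, the paths written.
#' @export
writeExpression <- function(bundle, dir, prefix = "expression") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpm <- file.path(dir, paste0(prefix, "_tpm.tsv"))
  .writeTsv(data.frame(gene_id = rownames(bundle$matrix), bundle$matrix,
                       check.names = FALSE), tpm)
  meta <- file.path(dir, paste0(prefix, "_meta.tsv"))
  .writeTsv(bundle$meta, meta)
  truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  .writeTsv(bundle$truth, truth)
  invisible(c(tpm = tpm, meta = meta, truth = truth))
}
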