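## TPM-level expression filtering, tissue-specificity calling, and
## two-condition comparison (Student's t, P < 0.05 starring).

.checkExpr <- function(m, meta) {
  stopifnot(is.matrix(m), nrow(m) >= 1)
  if (any(m < 0)) stop("TPM values must be non-negative")
  stopifnot(all(c("sample_id", "group") %in% names(meta)))
  if (!setequal(colnames(m), meta$sample_id))
    stop("sample metadata must cover exactly the matrix columns")
  invisible(TRUE)
}

.groupMeans <- function(m, meta) {
  groups <- unique(meta$group)
  gm <- sapply(groups, function(g)
    rowMeans(m[, meta$sample_id[meta$group == g], drop = FALSE]))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1,
                                     dimnames = list(rownames(m), groups))
  gm
}

#' Filter genes by the TPM > threshold rule
#'
#' Keeps a gene when its group-mean TPM strictly exceeds `tpm_min` in at
#' least `min_groups` groups; a gene sitting exactly at the threshold is
#' removed.
#'
#' @param m Genes x samples TPM matrix (row/col names required).
#' @param meta Sample metadata `data.frame` with `sample_id`, `group`.
#' @param tpm_min Threshold (default 2).
#' @param min_groups Minimum number of groups above threshold (default 1).
#' @return Character vector of surviving gene ids.
#' @export
filterExpressed <- function(m, meta, tpm_min = 2, min_groups = 1L) {
  .checkExpr(m, meta)
  gm <- .groupMeans(m, meta)
  keep <- rowSums(gm > tpm_min) >= min_groups
  rownames(m)[keep]
}

#' Tissue-specificity calls
#'
#' A gene is expressed in a group when its group-mean TPM strictly exceeds
#' `tpm_min`; genes expressed nowhere are `not_expressed`, everywhere
#' `ubiquitous`, otherwise `specific:<group-set>`.
#'
#' @inheritParams filterExpressed
#' @return A `data.frame` with gene_id, expressed_in (comma-joined), label.
#' @export
specificityCall <- function(m, meta, tpm_min = 2) {
  .checkExpr(m, meta)
  if (length(unique(meta$group)) < 2) stop("need at least two groups")
  gm <- .groupMeans(m, meta)
  groups <- colnames(gm)
  rows <- lapply(rownames(m), function(g) {
    on <- groups[gm[g, ] > tpm_min]
    label <- if (length(on) == 0) "not_expressed"
             else if (length(on) == length(groups)) "ubiquitous"
             else paste0("specific:", paste(sort(on), collapse = ","))
    data.frame(gene_id = g, expressed_in = paste(sort(on), collapse = ","),
               label = label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-condition comparison (Student's t test)
#'
#' Two-sided equal-variance t test on TPM replicate values per gene, with a
#' `significant` flag at `p < alpha`. Genes failing [filterExpressed()] in
#' both groups are omitted. A Benjamini-Hochberg column is supplied as
#' supplementary output; the flag itself uses the raw p value. Genes with
#' zero variance in both groups and equal means get t = 0, p = 1.
#'
#' @param m Genes x samples TPM matrix.
#' @param meta Sample metadata.
#' @param groupA,groupB Group labels to compare.
#' @param alpha Significance level (default 0.05).
#' @param tpm_min Expression filter threshold (default 2).
#' @return A `data.frame` with gene_id, mean_A, mean_B, t, p, p_bh,
#'   significant.
#' @export
conditionCompare <- function(m, meta, groupA, groupB, alpha = 0.05,
                             tpm_min = 2) {
  .checkExpr(m, meta)
  sa <- meta$sample_id[meta$group == groupA]
  sb <- meta$sample_id[meta$group == groupB]
  if (length(sa) < 2 || length(sb) < 2)
    stop("need at least two replicates per group")
  sub_meta <- meta[meta$group %in% c(groupA, groupB), , drop = FALSE]
  keep <- filterExpressed(m[, sub_meta$sample_id, drop = FALSE], sub_meta,
                          tpm_min = tpm_min, min_groups = 1L)
  rows <- lapply(keep, function(g) {
    xa <- m[g, sa]; xb <- m[g, sb]
    if (stats::var(xa) == 0 && stats::var(xb) == 0) {
      tt <- if (mean(xa) == mean(xb)) list(statistic = 0, p.value = 1)
            else list(statistic = sign(mean(xa) - mean(xb)) * Inf,
                      p.value = 0)
    } else {
      ht <- stats::t.test(xa, xb, var.equal = TRUE)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(gene_id = g, mean_A = mean(xa), mean_B = mean(xb),
               t = tt$statistic, p = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(), mean_A = numeric(),
                      mean_B = numeric(), t = numeric(), p = numeric(),
                      p_bh = numeric(), significant = logical()))
  }
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out
}

#' Read a TPM matrix and sample metadata from TSV
#'
#' @param tpm_path TSV with gene rows (first column `gene_id`) and sample
#'   columns.
#' @param meta_path TSV with columns sample_id, group, replicate.
#' @return A list with `matrix` and `meta`.
#' @export
readExpression <- function(tpm_path, meta_path) {
  tab <- utils::read.delim(tpm_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  list(matrix = m, meta = meta)
}
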