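## Jalview-style consensus sequences, conservation classes, and
## position-frequency (logo) matrices from aligned sets, plus a small
## self-contained multiple aligner so tests need no external MSA engine.

#' @importFrom Biostrings pairwiseAlignment pattern subject aligned
NULL

PROPERTY_GROUPS <- list(
  basic = c("K", "R", "H"), acidic = c("D", "E"), hydroxyl = c("S", "T"),
  aromatic = c("F", "Y", "W"), aliphatic = c("I", "L", "V", "M"),
  small = c("A", "G"), amide = c("N", "Q"), cys = "C", pro = "P")

#' Construct an aligned set
#'
#' @param rows Named character vector of equal-length gapped sequences
#'   (residues plus `-`).
#' @return A validated list of class `"AlignedSet"` with `ids` and `rows`.
#' @export
alignedSet <- function(rows) {
  if (is.null(names(rows))) names(rows) <- paste0("seq", seq_along(rows))
  lens <- nchar(rows)
  if (length(unique(lens)) > 1) stop("all rows must have equal length")
  structure(list(ids = names(rows), rows = unname(rows)),
            class = "AlignedSet")
}

.alnMatrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, ""))
}

#' Per-column residue frequencies (logo matrix)
#'
#' Frequencies are computed over observed residues (gaps excluded from the
#' denominator); all-gap columns are emitted as zero columns and flagged.
#' Per-column occupancy (non-gap fraction) is reported separately.
#'
#' @param aln An [alignedSet()].
#' @return A list with `pfm` (20 x L matrix, columns sum to 1 unless
#'   all-gap), `occupancy`, and `all_gap` (logical).
#' @export
columnFrequencies <- function(aln) {
  if (length(aln$rows) < 1) stop("need at least one row")
  M <- .alnMatrix(aln)
  L <- ncol(M)
  pfm <- matrix(0, nrow = 20L, ncol = L, dimnames = list(AA20, NULL))
  occ <- numeric(L); allgap <- logical(L)
  for (j in seq_len(L)) {
    col <- M[, j]
    res <- col[col != "-"]
    occ[j] <- length(res) / nrow(M)
    if (length(res) == 0) { allgap[j] <- TRUE; next }
    tab <- table(factor(res, levels = AA20))
    pfm[, j] <- as.numeric(tab) / length(res)
  }
  list(pfm = pfm, occupancy = occ, all_gap = allgap)
}

#' Build a consensus profile from an aligned set
#'
#' Per column, the modal residue over non-gap symbols; a column is
#' `conserved` when the modal frequency reaches `c_high`, `semi_conserved`
#' when one residue property group (KRH, DE, ST, FYW, ILVM, AG, NQ, C, P)
#' reaches `c_group`, and `variable` otherwise.
#'
#' @param aln An [alignedSet()] with at least two rows.
#' @param c_high Modal-frequency threshold for `conserved` (default 0.9).
#' @param c_group Group-frequency threshold for `semi_conserved`
#'   (default 0.9).
#' @return A list with `consensus` (string), `columns` (data.frame of modal
#'   residue/frequency, group frequency, conservation class) and `pfm`.
#' @export
#' @examples
#' aln <- alignedSet(c(a = "KKA", b = "KRA"))
#' buildConsensus(aln)$columns$conservation
buildConsensus <- function(aln, c_high = 0.9, c_group = 0.9) {
  if (length(aln$rows) < 2) stop("consensus requires at least two rows")
  cf <- columnFrequencies(aln)
  L <- ncol(cf$pfm)
  modal <- character(L); modal_freq <- numeric(L)
  group_freq <- numeric(L); conservation <- character(L)
  for (j in seq_len(L)) {
    if (cf$all_gap[j]) {
      modal[j] <- "-"; modal_freq[j] <- 0; group_freq[j] <- 0
      conservation[j] <- "variable"; next
    }
    f <- cf$pfm[, j]
    modal[j] <- AA20[which.max(f)]
    modal_freq[j] <- max(f)
    group_freq[j] <- max(vapply(PROPERTY_GROUPS,
                                function(g) sum(f[g]), numeric(1)))
    conservation[j] <-
      if (modal_freq[j] >= c_high) "conserved"
      else if (group_freq[j] >= c_group) "semi_conserved"
      else "variable"
  }
  list(consensus = paste0(modal, collapse = ""),
       columns = data.frame(position = seq_len(L), modal = modal,
                            modal_freq = modal_freq, group_freq = group_freq,
                            conservation = conservation,
                            occupancy = cf$occupancy,
                            stringsAsFactors = FALSE),
       pfm = cf$pfm)
}

#' Align protein sequences (bundled center-star aligner)
#'
#' Small self-contained multiple aligner: the center sequence (minimum total
#' pairwise distance) is aligned pairwise to every other sequence with a
#' global Needleman-Wunsch (BLOSUM62, affine gaps), and the pairwise
#' alignments are merged on the center by the once-a-gap-always-a-gap rule.
#' Intended for test-scale sets; users with a preferred MSA engine can
#' supply an [alignedSet()] directly.
#'
#' @param seqs Named character vector of ungapped protein sequences.
#' @return An [alignedSet()].
#' @export
alignProteins <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (n == 1) return(alignedSet(seqs))
  ss <- Biostrings::AAStringSet(seqs)
  pw <- function(i, j) Biostrings::pairwiseAlignment(
    ss[i], ss[j], substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global")
  score_sum <- numeric(n)
  cache <- vector("list", n)
  for (i in seq_len(n)) cache[[i]] <- vector("list", n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- pw(i, j)
    cache[[i]][[j]] <- a
    s <- Biostrings::score(a)
    score_sum[i] <- score_sum[i] + s
    score_sum[j] <- score_sum[j] + s
  }
  ctr <- which.max(score_sum)
  ## master gap model on the center: gaps inserted before center position p
  center_len <- nchar(seqs[ctr])
  ins_before <- integer(center_len + 1L)   # index p+1: gaps before pos p+1
  pair_alns <- vector("list", n)
  for (k in seq_len(n)) {
    if (k == ctr) next
    if (ctr < k) {
      a <- cache[[ctr]][[k]]
      cp <- as.character(Biostrings::alignedPattern(a))
      co <- as.character(Biostrings::alignedSubject(a))
    } else {
      a <- cache[[k]][[ctr]]
      cp <- as.character(Biostrings::alignedSubject(a))
      co <- as.character(Biostrings::alignedPattern(a))
    }
    pair_alns[[k]] <- list(center = cp, other = co)
    ## count runs of '-' in the center row by preceding center position
    cc <- strsplit(cp, "")[[1]]
    pos <- 0L; run <- 0L
    for (ch in cc) {
      if (ch == "-") run <- run + 1L
      else {
        if (run > 0) ins_before[pos + 1L] <- max(ins_before[pos + 1L], run)
        run <- 0L; pos <- pos + 1L
      }
    }
    if (run > 0) ins_before[pos + 1L] <- max(ins_before[pos + 1L], run)
  }
  ## project every row onto the master coordinate system
  project <- function(center_row, other_row) {
    cc <- strsplit(center_row, "")[[1]]
    oo <- strsplit(other_row, "")[[1]]
    out <- character()
    pos <- 0L; i <- 1L
    pending <- character()
    flush <- function(slot_gaps) {
      pad <- slot_gaps - length(pending)
      out <<- c(out, pending, rep("-", pad))
      pending <<- character()
    }
    while (i <= length(cc)) {
      if (cc[i] == "-") {
        pending <- c(pending, oo[i])
      } else {
        flush(ins_before[pos + 1L])
        out <- c(out, oo[i])
        pos <- pos + 1L
      }
      i <- i + 1L
    }
    flush(ins_before[pos + 1L])
    paste0(out, collapse = "")
  }
  center_chars <- strsplit(seqs[ctr], "")[[1]]
  rows <- character(n)
  for (k in seq_len(n)) {
    if (k == ctr) {
      out <- character()
      for (p in 0:center_len) {
        out <- c(out, rep("-", ins_before[p + 1L]),
                 if (p < center_len) center_chars[p + 1L])
      }
      rows[k] <- paste0(out, collapse = "")
    } else {
      rows[k] <- project(pair_alns[[k]]$center, pair_alns[[k]]$other)
    }
  }
  names(rows) <- names(seqs)
  alignedSet(rows)
}

#' Read an aligned FASTA file as an AlignedSet
#'
#' @param path Aligned FASTA path.
#' @return An [alignedSet()].
#' @export
readAlignedFasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  alignedSet(stats::setNames(as.character(ss), names(ss)))
}

#' Write consensus outputs
#'
#' @param cons Result of [buildConsensus()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
writeConsensus <- function(cons, dir, prefix = "consensus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".faa"))
  writeLines(c(paste0(">", prefix), cons$consensus), fa)
  cols <- file.path(dir, paste0(prefix, "_columns.tsv"))
  .writeTsv(cons$columns, cols)
  pfm <- file.path(dir, paste0(prefix, "_pfm.tsv"))
  .writeTsv(data.frame(residue = rownames(cons$pfm), cons$pfm,
                       check.names = FALSE), pfm)
  invisible(c(consensus = fa, columns = cols, pfm = pfm))
}
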