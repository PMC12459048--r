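## Histone-fold anatomy: locate the fold in a protein by anchoring it to a
## reference position-frequency profile and delimit the nine regions on which
## all downstream features are defined.
##
## The alignment is global over the profile columns and local over the
## sequence (free unaligned prefix/suffix, which become the N- and C-tails),
## with affine gap costs. Residue r at column c scores
## log2(freq(r,c) + eps) - log2(background(r)), eps = 1e-3; X scores 0.

#' Strip the initial methionine from a protein record
#'
#' Mature histone sequences are conventionally displayed without the initial
#' methionine; this drops a leading M (if present) and marks the record
#' mature. Idempotent.
#'
#' @param sequence Amino-acid string (one-letter codes, 20 standard + X), or
#'   a record returned by a previous call (already-mature records pass
#'   through unchanged, making the operation idempotent).
#' @return A list with `sequence` and `mature = TRUE`.
#' @export
#' @examples
#' stripInitialMet("MSGRGKQ")$sequence
stripInitialMet <- function(sequence) {
  if (is.list(sequence)) {
    if (isTRUE(sequence$mature)) return(sequence)
    sequence <- sequence$sequence
  }
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  .checkResidues(sequence)
  if (substr(sequence, 1, 1) == "M")
    sequence <- substr(sequence, 2, nchar(sequence))
  list(sequence = sequence, mature = TRUE)
}

#' Default histone-fold reference profile
#'
#' Builds the shipped [ReferenceProfile-class]: fold regions (alphaN through
#' docking) of the nine class templates are stacked region-by-region (shorter
#' regions right-padded), residue counts per column are converted to
#' frequencies with a small pseudocount, and the acidic-patch columns are the
#' six columns opening the docking domain. The profile is RC-H2A-anchored in
#' the sense that its region grid follows the canonical fold; divergent
#' columns carry flat frequencies and therefore penalize no class unduly.
#'
#' @param pseudocount Pseudocount added per residue before normalization.
#' @return A [ReferenceProfile-class].
#' @export
#' @examples
#' defaultProfile()
defaultProfile <- function(pseudocount = 0.02) {
  tpls <- lapply(H2A_CLASSES, classTemplate)
  maxlen <- sapply(FOLD_REGIONS, function(r)
    max(vapply(tpls, function(t) nchar(t$regions[[r]]), integer(1))))
  cols <- list(); region_map <- list(); at <- 0L
  for (r in FOLD_REGIONS) {
    m <- matrix(0, nrow = 20L, ncol = maxlen[[r]], dimnames = list(AA20, NULL))
    for (t in tpls) {
      ch <- strsplit(t$regions[[r]], "")[[1]]
      for (j in seq_along(ch)) m[ch[j], j] <- m[ch[j], j] + 1
    }
    cols[[r]] <- m
    region_map[[r]] <- c(at + 1L, at + maxlen[[r]])
    at <- at + maxlen[[r]]
  }
  freqs <- do.call(cbind, cols)
  freqs <- freqs + pseudocount
  freqs <- sweep(freqs, 2, colSums(freqs), "/")
  patch <- region_map[["docking"]][1] + 0:5
  new("ReferenceProfile", freqs = freqs, regionMap = region_map,
      patchCols = as.integer(patch), name = "h2a_fold_default")
}

## Per-column match scores for a sequence: n x m matrix.
.matchScores <- function(chars, freqs, eps = 1e-3, background = 0.05) {
  m <- ncol(freqs)
  s <- matrix(0, nrow = length(chars), ncol = m)
  known <- chars %in% AA20
  if (any(known))
    s[known, ] <- log2(freqs[chars[known], , drop = FALSE] + eps) -
      log2(background)
  s   # X and unknown residues score 0 at every column
}

## Affine-gap DP, global on profile / local on sequence. Vectorized over the
## sequence index; the insert-in-sequence state is closed with a cumulative
## max. Returns score and the three state matrices for traceback.
.profileDP <- function(S, open = 11, extend = 1) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -1e18
  M <- matrix(NEG, n, m); X <- matrix(NEG, n, m); Y <- matrix(NEG, n, m)
  ## boundary rows for i = 0 (no sequence consumed yet)
  X0 <- -open - (seq_len(m) - 1L) * extend   # delete leading columns
  iext <- seq_len(n) * extend
  for (j in seq_len(m)) {
    if (j == 1L) {
      M[, 1L] <- S[, 1L]                     # free sequence prefix
      X[, 1L] <- -open                       # delete col 1 after free prefix
    } else {
      prevM <- M[, j - 1L]; prevX <- X[, j - 1L]; prevY <- Y[, j - 1L]
      best_prev <- pmax(prevM, prevX, prevY)
      diag_in <- c(X0[j - 1L], best_prev[-n])  # state at (i-1, j-1)
      M[, j] <- S[, j] + diag_in
      X[, j] <- pmax(pmax(prevM, prevY) - open, prevX - extend)
    }
    ## Y[i,j] = max over k < i of (max(M,X)[k,j] - open - (i-1-k) * extend)
    base <- pmax(M[, j], X[, j])
    run <- cummax(c(NEG, (base + iext)[-n]))
    Y[, j] <- run - open - iext + extend   # = run - open - (i-1)*extend
  }
  end_scores <- pmax(M[, m], X[, m], Y[, m])
  list(score = max(end_scores, X0[m]), M = M, X = X, Y = Y)
}

## Traceback from the best end cell; returns integer vector col2seq of length
## m: 1-based sequence index aligned to each profile column, NA if deleted.
.profileTraceback <- function(S, dp, open = 11, extend = 1) {
  n <- nrow(S); m <- ncol(S)
  tol <- 1e-7
  col2seq <- rep(NA_integer_, m)
  ends <- pmax(dp$M[, m], dp$X[, m], dp$Y[, m])
  i <- which.max(ends); j <- m
  state <- c("M", "X", "Y")[which.max(c(dp$M[i, m], dp$X[i, m], dp$Y[i, m]))]
  val <- function(st, i, j) {
    if (j == 0L) return(if (st == "X") 0 else -Inf)  # pre-profile boundary
    if (i == 0L) {
      if (st == "X") return(-open - (j - 1L) * extend)
      return(-Inf)
    }
    switch(st, M = dp$M[i, j], X = dp$X[i, j], Y = dp$Y[i, j])
  }
  while (j >= 1L) {
    if (state == "M") {
      col2seq[j] <- i
      if (j == 1L) break                      # free prefix start
      target <- dp$M[i, j] - S[i, j]
      cand <- c(M = val("M", i - 1L, j - 1L), X = val("X", i - 1L, j - 1L),
                Y = val("Y", i - 1L, j - 1L))
      hit <- names(cand)[abs(cand - target) < tol]
      state <- hit[1]; i <- i - 1L; j <- j - 1L
      if (i == 0L && state != "X") break      # reached boundary
    } else if (state == "X") {
      target <- if (i == 0L) -open - (j - 1L) * extend else dp$X[i, j]
      if (j == 1L) break
      cand <- c(M = val("M", i, j - 1L) - open,
                Y = val("Y", i, j - 1L) - open,
                X = val("X", i, j - 1L) - extend)
      hit <- names(cand)[abs(cand - target) < tol]
      state <- hit[1]; j <- j - 1L
    } else {  # Y: consumed sequence residue(s) between columns
      target <- dp$Y[i, j]
      cand <- c(M = val("M", i - 1L, j) - open,
                X = val("X", i - 1L, j) - open,
                Y = val("Y", i - 1L, j) - extend)
      hit <- names(cand)[abs(cand - target) < tol]
      state <- hit[1]; i <- i - 1L
    }
  }
  col2seq
}

#' Anchor a protein to the fold profile and delimit its regions
#'
#' Aligns the sequence to the profile (global on profile, local on sequence,
#' affine gaps with open 11 / extend 1) and maps the profile's region
#' boundaries onto sequence coordinates. The unaligned prefix becomes the
#' N-tail and the unaligned suffix the C-tail. The fold is considered
#' detected when the alignment score reaches `min_fold_score_frac` times the
#' self-score of the profile consensus.
#'
#' @param sequence Mature amino-acid string (see [stripInitialMet()]).
#' @param profile A [ReferenceProfile-class]; default [defaultProfile()].
#' @param record_id Id stored in the annotation.
#' @param min_fold_score_frac Fraction of the profile-consensus self-score
#'   required to call the fold detected (default 0.6).
#' @param min_fold_len Sequences shorter than this return an undetected-fold
#'   annotation (default 60).
#' @param gap_open,gap_extend Affine gap costs.
#' @return A [FoldAnnotation-class].
#' @export
#' @examples
#' tpl <- classTemplate("RC_H2A")
#' fa <- anchorToProfile(tpl$sequence, record_id = "rc")
#' foldDetected(fa)
anchorToProfile <- function(sequence, profile = defaultProfile(),
                            record_id = "query",
                            min_fold_score_frac = 0.6,
                            min_fold_len = 60L,
                            gap_open = 11, gap_extend = 1) {
  .checkResidues(sequence)
  n <- nchar(sequence)
  if (n < min_fold_len) {
    return(new("FoldAnnotation", recordId = record_id, regions = list(),
               alignmentScore = -Inf, foldDetected = FALSE,
               patchSites = integer()))
  }
  chars <- strsplit(sequence, "")[[1]]
  S <- .matchScores(chars, profile@freqs)
  dp <- .profileDP(S, open = gap_open, extend = gap_extend)
  threshold <- min_fold_score_frac * profileSelfScore(profile)
  if (dp$score < threshold) {
    return(new("FoldAnnotation", recordId = record_id, regions = list(),
               alignmentScore = dp$score, foldDetected = FALSE,
               patchSites = integer()))
  }
  col2seq <- .profileTraceback(S, dp, open = gap_open, extend = gap_extend)
  aligned <- which(!is.na(col2seq))
  aln_start <- col2seq[aligned[1]]           # 1-based first aligned residue
  aln_end <- col2seq[aligned[length(aligned)]]
  ## region start (0-based) = first aligned residue at column >= region start
  nextAligned <- function(col) {
    k <- aligned[aligned >= col]
    if (length(k) == 0) aln_end else col2seq[k[1]] - 1L
  }
  m <- ncol(profile@freqs)
  starts <- vapply(profile@regionMap, function(iv) nextAligned(iv[1]),
                   numeric(1))
  regions <- list(n_tail = c(0, aln_start - 1L))
  for (r in seq_along(FOLD_REGIONS)) {
    s <- starts[[r]]
    e <- if (r < length(FOLD_REGIONS)) starts[[r + 1L]] else aln_end
    regions[[FOLD_REGIONS[r]]] <- c(s, e)
  }
  regions[["c_tail"]] <- c(aln_end, n)
  patch <- col2seq[profile@patchCols] - 1L   # 0-based, NA if column deleted
  new("FoldAnnotation", recordId = record_id, regions = regions,
      alignmentScore = dp$score, foldDetected = TRUE,
      patchSites = as.integer(patch))
}

#' Self-score of a profile's consensus sequence
#'
#' Score obtained when the per-column modal residue is aligned to every
#' column without gaps; the scale-free reference against which the
#' fold-detection threshold is set.
#'
#' @param profile A [ReferenceProfile-class].
#' @param eps,background Scoring constants matching [anchorToProfile()].
#' @return Numeric scalar.
#' @export
profileSelfScore <- function(profile, eps = 1e-3, background = 0.05) {
  sum(log2(apply(profile@freqs, 2, max) + eps) - log2(background))
}

#' Consensus sequence realized from a profile
#'
#' @param profile A [ReferenceProfile-class].
#' @return The per-column modal-residue string.
#' @export
profileConsensus <- function(profile) {
  paste0(AA20[apply(profile@freqs, 2, which.max)], collapse = "")
}

#' Annotate a set of proteins
#'
#' Applies [anchorToProfile()] to every sequence of an [H2ASet-class].
#'
#' @param set An [H2ASet-class].
#' @param profile A [ReferenceProfile-class].
#' @param ... Passed to [anchorToProfile()].
#' @return Named list of [FoldAnnotation-class] objects.
#' @export
annotateSet <- function(set, profile = defaultProfile(), ...) {
  seqs <- sequences(set)
  out <- lapply(seq_along(seqs), function(i)
    anchorToProfile(as.character(seqs[[i]]), profile,
                    record_id = names(seqs)[i], ...))
  names(out) <- names(seqs)
  out
}

#' Write fold annotations as a region table
#'
#' @param annotations List of [FoldAnnotation-class].
#' @param path Output TSV path (1-based inclusive coordinates).
#' @return The data frame written, invisibly.
#' @export
writeRegionTable <- function(annotations, path = NULL) {
  rows <- list()
  for (fa in annotations) {
    if (!foldDetected(fa)) next
    for (r in names(foldRegions(fa))) {
      co <- foldRegions(fa)[[r]]
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = fa@recordId, region = r,
        start = co[1] + 1L, end = co[2], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), region = character(),
               start = integer(), end = integer())
  if (!is.null(path)) .writeTsv(df, path)
  invisible(df)
}
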