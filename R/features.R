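## The seven classification features: motif analysis of the alphaN helix,
## L1 loop, alpha2 helix, acidic patch and C-terminal ending, plus the
## lengths of the L1 loop and docking domain; auxiliary composition
## statistics (tail lengths, K/G and K/D/E enrichment) complete the vector.

SIGNATURES <- list(
  alpha2_z   = "LEYLTAEVLELAGNA",
  cterm_x    = "SQ[DE][FY]$",
  cterm_o    = "SQDY$",
  cterm_w    = "KSPKK$",
  cterm_z    = "KKRI$",
  l1_w       = "RY[AS][QK]",
  l1_m       = "RYA[QK]",
  alphaN_n   = "QSLRA",
  ntail_n    = "PLRP",
  docking_end = "VLLPKK"
)

.reg <- function(fold, name) foldRegions(fold)[[name]]
.regionSub <- function(seq, fold, name) {
  co <- .reg(fold, name)
  if (co[2] <= co[1]) "" else substr(seq, co[1] + 1L, co[2])
}
.stopIfNoFold <- function(fold) {
  if (!foldDetected(fold))
    stop("feature unavailable: fold not detected for ", fold@recordId)
}

#' Mismatch count of the H2A.Z alpha2 signature
#'
#' Minimum Hamming distance between the LEYLTAEVLELAGNA signature and any
#' 15-residue window of the alpha2 region extended by 3 residues on each
#' side; 15 when no full window exists.
#'
#' @param sequence Mature protein string.
#' @param fold A detected [FoldAnnotation-class].
#' @return Integer mismatch count in `[0, 15]`.
#' @export
scoreAlpha2Signature <- function(sequence, fold) {
  .stopIfNoFold(fold)
  co <- .reg(fold, "alpha2")
  minHammingWindow(sequence, co[1] + 1L, co[2], SIGNATURES$alpha2_z, ext = 3L)
}

#' Classify the L1 loop motif
#'
#' M_like when RYA\[Q/K\] matches within the L1 region, W_like when
#' RY\[A/S\]\[Q/K\] matches but RYA\[Q/K\] does not (i.e. RYS\[Q/K\]),
#' otherwise other.
#'
#' @inheritParams scoreAlpha2Signature
#' @return List with `l1_motif_class` and `l1_length`.
#' @export
classifyL1 <- function(sequence, fold) {
  .stopIfNoFold(fold)
  l1 <- .regionSub(sequence, fold, "L1")
  cls <- if (grepl(SIGNATURES$l1_m, l1)) "M_like"
         else if (grepl(SIGNATURES$l1_w, l1)) "W_like"
         else "other"
  list(l1_motif_class = cls, l1_length = nchar(l1))
}

#' C-terminal ending class and C-tail composition
#'
#' Examines the very end of the full sequence: terminal SQDY claims O_end
#' before the general SQ\[D/E\]\[F/Y\] (X_end); otherwise a terminal KSPKK
#' gives W_end and a terminal KKRI gives Z_end. Lysine and acidic fractions
#' are computed over the C-tail region only.
#'
#' @inheritParams scoreAlpha2Signature
#' @return List with `cterm_class`, `ctail_k_frac`, `ctail_de_frac`,
#'   `ctail_length`.
#' @export
ctermSignature <- function(sequence, fold) {
  .stopIfNoFold(fold)
  ct <- .regionSub(sequence, fold, "c_tail")
  if (!nzchar(ct))
    return(list(cterm_class = "none", ctail_k_frac = 0,
                ctail_de_frac = 0, ctail_length = 0L))
  cls <- if (grepl(SIGNATURES$cterm_o, sequence)) "O_end"
         else if (grepl(SIGNATURES$cterm_x, sequence)) "X_end"
         else if (grepl(SIGNATURES$cterm_w, sequence)) "W_end"
         else if (grepl(SIGNATURES$cterm_z, sequence)) "Z_end"
         else "none"
  ch <- strsplit(ct, "")[[1]]
  list(cterm_class = cls,
       ctail_k_frac = mean(ch == "K"),
       ctail_de_frac = mean(ch %in% c("D", "E")),
       ctail_length = length(ch))
}

#' N-tail composition statistics
#'
#' Length, lysine+glycine fraction, longest contiguous K/G run, and whether
#' the PLRP motif occurs in the N-tail.
#'
#' @inheritParams scoreAlpha2Signature
#' @return List with `ntail_length`, `ntail_kg_frac`, `ntail_kg_maxrun`,
#'   `ntail_plrp`.
#' @export
ntailStats <- function(sequence, fold) {
  .stopIfNoFold(fold)
  nt <- .regionSub(sequence, fold, "n_tail")
  if (!nzchar(nt))
    return(list(ntail_length = 0L, ntail_kg_frac = 0,
                ntail_kg_maxrun = 0L, ntail_plrp = FALSE))
  ch <- strsplit(nt, "")[[1]]
  kg <- ch %in% c("K", "G")
  runs <- rle(kg)
  maxrun <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(ntail_length = length(ch),
       ntail_kg_frac = mean(kg),
       ntail_kg_maxrun = as.integer(maxrun),
       ntail_plrp = grepl(SIGNATURES$ntail_n, nt))
}

#' Acidic-patch composition through the profile alignment
#'
#' Maps the profile's acidic-patch columns onto the sequence and reports the
#' number of mapped positions holding D or E and the residue at the first
#' mapped patch position.
#'
#' @inheritParams scoreAlpha2Signature
#' @return List with `acidic_patch_count` and `acidic_patch_first`.
#' @export
acidicPatchProfile <- function(sequence, fold) {
  .stopIfNoFold(fold)
  sites <- fold@patchSites
  sites <- sites[!is.na(sites)]
  if (length(sites) == 0)
    stop("feature unavailable: acidic-patch columns unalignable for ",
         fold@recordId)
  res <- strsplit(sequence, "")[[1]][sites + 1L]
  list(acidic_patch_count = sum(res %in% c("D", "E")),
       acidic_patch_first = res[1])
}

#' Docking-domain statistics
#'
#' Length of the docking region, histidine count within it, and whether the
#' region (extended by 3 residues downstream) contains the VLLPKK ending.
#'
#' @inheritParams scoreAlpha2Signature
#' @return List with `docking_length`, `docking_his_count`,
#'   `docking_end_match`.
#' @export
dockingStats <- function(sequence, fold) {
  .stopIfNoFold(fold)
  co <- .reg(fold, "docking")
  dk <- .regionSub(sequence, fold, "docking")
  ext <- substr(sequence, co[1] + 1L, min(nchar(sequence), co[2] + 3L))
  list(docking_length = nchar(dk),
       docking_his_count = sum(strsplit(dk, "")[[1]] == "H"),
       docking_end_match = grepl(SIGNATURES$docking_end, ext))
}

#' Mismatch count of the H2A.N alphaN motif
#'
#' Minimum Hamming distance between QSLRA and any 5-residue window of the
#' alphaN region extended by 2 residues on each side; 5 when no window
#' exists.
#'
#' @inheritParams scoreAlpha2Signature
#' @return Integer in `[0, 5]`.
#' @export
matchAlphaN <- function(sequence, fold) {
  .stopIfNoFold(fold)
  co <- .reg(fold, "alphaN")
  minHammingWindow(sequence, co[1] + 1L, co[2], SIGNATURES$alphaN_n, ext = 2L)
}

#' Extract the full feature vector for one protein
#'
#' Composes all signature and composition features on top of a fold
#' annotation. When the fold was not detected, a vector with
#' `fold_missing = TRUE` and NA feature fields is returned.
#'
#' @param sequence Mature protein string.
#' @param fold A [FoldAnnotation-class].
#' @param record_id Record id for the output row.
#' @return A one-row `data.frame` (the FeatureVector).
#' @export
#' @examples
#' tpl <- classTemplate("H2A.Z")
#' fa <- anchorToProfile(tpl$sequence, record_id = "z")
#' extractFeatures(tpl$sequence, fa, "z")$alpha2_mismatches
extractFeatures <- function(sequence, fold, record_id = fold@recordId) {
  if (!foldDetected(fold)) {
    return(data.frame(
      record_id = record_id, fold_missing = TRUE,
      alpha2_mismatches = NA_integer_, l1_motif_class = NA_character_,
      l1_length = NA_integer_, alphaN_mismatches = NA_integer_,
      acidic_patch_count = NA_integer_, acidic_patch_first = NA_character_,
      docking_length = NA_integer_, docking_his_count = NA_integer_,
      docking_end_match = NA, cterm_class = NA_character_,
      ctail_k_frac = NA_real_, ctail_de_frac = NA_real_,
      ctail_length = NA_integer_, ntail_length = NA_integer_,
      ntail_kg_frac = NA_real_, ntail_kg_maxrun = NA_integer_,
      ntail_plrp = NA, stringsAsFactors = FALSE))
  }
  l1 <- classifyL1(sequence, fold)
  ct <- ctermSignature(sequence, fold)
  nt <- ntailStats(sequence, fold)
  ap <- tryCatch(acidicPatchProfile(sequence, fold),
                 error = function(e) list(acidic_patch_count = NA_integer_,
                                          acidic_patch_first = NA_character_))
  dk <- dockingStats(sequence, fold)
  data.frame(
    record_id = record_id, fold_missing = FALSE,
    alpha2_mismatches = scoreAlpha2Signature(sequence, fold),
    l1_motif_class = l1$l1_motif_class, l1_length = l1$l1_length,
    alphaN_mismatches = matchAlphaN(sequence, fold),
    acidic_patch_count = ap$acidic_patch_count,
    acidic_patch_first = ap$acidic_patch_first,
    docking_length = dk$docking_length,
    docking_his_count = dk$docking_his_count,
    docking_end_match = dk$docking_end_match,
    cterm_class = ct$cterm_class,
    ctail_k_frac = ct$ctail_k_frac, ctail_de_frac = ct$ctail_de_frac,
    ctail_length = ct$ctail_length,
    ntail_length = nt$ntail_length, ntail_kg_frac = nt$ntail_kg_frac,
    ntail_kg_maxrun = nt$ntail_kg_maxrun, ntail_plrp = nt$ntail_plrp,
    stringsAsFactors = FALSE)
}

#' Extract feature vectors for a whole set
#'
#' @param set An [H2ASet-class].
#' @param profile A [ReferenceProfile-class].
#' @param ... Passed to [anchorToProfile()].
#' @return A `data.frame` with one FeatureVector row per sequence.
#' @export
extractFeatureTable <- function(set, profile = defaultProfile(), ...) {
  anns <- annotateSet(set, profile, ...)
  seqs <- sequences(set)
  do.call(rbind, lapply(names(seqs), function(id)
    extractFeatures(as.character(seqs[[id]]), anns[[id]], id)))
}

#' Assign modified peptides to proteins
#'
#' Matches each peptide as an exact substring against every record and maps
#' each modification offset to a 1-based protein coordinate. Peptides
#' matching several records yield one assignment per record; unmatched
#' peptides are reported separately.
#'
#' @param peptides A `data.frame` with columns `peptide`, `offset` (0-based
#'   within the peptide) and `mod` (one of ac, me1, me2, me3, ph); several
#'   rows may share a peptide.
#' @param set An [H2ASet-class] of mature records.
#' @return A list with `assignments` (record_id, peptide, site, mod) and
#'   `unmatched` (character vector of peptides).
#' @export
#' @examples
#' set <- makeBenchmarkSet(syntheticSpec(c(H2A.Z = 1)))
#' pep <- substr(as.character(sequences(set)[[1]]), 1, 10)
#' mapPtmPeptides(data.frame(peptide = pep, offset = 2, mod = "ac"), set)
mapPtmPeptides <- function(peptides, set) {
  stopifnot(all(c("peptide", "offset", "mod") %in% names(peptides)))
  for (p in unique(peptides$peptide)) {
    .checkResidues(p, what = paste0("peptide ", p))
    if (nchar(p) < 5) stop("peptide shorter than 5 residues: ", p)
  }
  bad_off <- peptides$offset < 0 | peptides$offset >= nchar(peptides$peptide)
  if (any(bad_off)) stop("modification offset outside peptide bounds")
  seqs <- vapply(seq_along(sequences(set)),
                 function(i) as.character(sequences(set)[[i]]), character(1))
  names(seqs) <- names(sequences(set))
  rows <- list(); matched <- character()
  for (k in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[k]
    for (id in names(seqs)) {
      hits <- gregexpr(pep, seqs[[id]], fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      matched <- union(matched, pep)
      for (h in hits) {
        rows[[length(rows) + 1L]] <- data.frame(
          record_id = id, peptide = pep,
          site = h + peptides$offset[k],      # 1-based protein coordinate
          mod = peptides$mod[k], stringsAsFactors = FALSE)
      }
    }
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record_id = character(), peptide = character(),
               site = integer(), mod = character())
  list(assignments = assignments,
       unmatched = setdiff(unique(peptides$peptide), matched))
}
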