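## Shared fixture: fold annotations of the zero-noise templates.
templateFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- defaultProfile()
      cache <<- lapply(stats::setNames(nm = h2aClasses()), function(cl) {
        s <- classTemplate(cl)$sequence
        list(seq = s, fold = anchorToProfile(s, p, record_id = cl))
      })
    }
    cache
  }
})

test_that("alpha2 signature scoring matches the Hamming-window oracle", {
  fx <- templateFixture()
  expect_identical(scoreAlpha2Signature(fx$H2A.Z$seq, fx$H2A.Z$fold), 0L)
  expect_gte(scoreAlpha2Signature(fx$RC_H2A$seq, fx$RC_H2A$fold), 3L)
  ## direct comparison against the oracle on every template
  for (cl in h2aClasses()) {
    co <- foldRegions(fx[[cl]]$fold)$alpha2
    expect_identical(
      as.integer(scoreAlpha2Signature(fx[[cl]]$seq, fx[[cl]]$fold)),
      as.integer(oracleMinHamming(fx[[cl]]$seq, co[1] + 1, co[2],
                                  "LEYLTAEVLELAGNA", ext = 3)),
      label = paste("alpha2 oracle", cl))
  }
  ## region of all A keeps only the signature's two A matches
  allA <- paste0(strrep("P", 20), strrep("A", 19), strrep("P", 20))
  fakeFold <- methods::new("FoldAnnotation", recordId = "fake",
    regions = list(n_tail = c(0, 10), alphaN = c(10, 14), alpha1 = c(14, 18),
                   L1 = c(18, 20), alpha2 = c(20, 39), L2 = c(39, 41),
                   alpha3 = c(41, 45), docking = c(45, 50),
                   c_tail = c(50, 59)),
    alignmentScore = 1, foldDetected = TRUE, patchSites = integer())
  ## the signature carries three A positions (6, 12, 15), so an all-A
  ## window keeps exactly those matches
  expect_identical(scoreAlpha2Signature(allA, fakeFold), 12L)
})

test_that("L1 motif classification distinguishes W-like and M-like loops", {
  mk <- function(l1) {
    s <- paste0(strrep("G", 10), l1, strrep("G", 50))
    fold <- methods::new("FoldAnnotation", recordId = "t",
      regions = list(n_tail = c(0, 5), alphaN = c(5, 8), alpha1 = c(8, 10),
                     L1 = c(10, 10 + nchar(l1)),
                     alpha2 = c(10 + nchar(l1), 20 + nchar(l1)),
                     L2 = c(20 + nchar(l1), 22 + nchar(l1)),
                     alpha3 = c(22 + nchar(l1), 30 + nchar(l1)),
                     docking = c(30 + nchar(l1), 40 + nchar(l1)),
                     c_tail = c(40 + nchar(l1), nchar(s))),
      alignmentScore = 1, foldDetected = TRUE, patchSites = integer())
    classifyL1(s, fold)
  }
  expect_identical(mk("RYSQK")$l1_motif_class, "W_like")
  expect_identical(mk("RYSKA")$l1_motif_class, "W_like")
  expect_identical(mk("RYAQT")$l1_motif_class, "M_like")
  expect_identical(mk("RYAKT")$l1_motif_class, "M_like")
  expect_identical(mk("NDEEL")$l1_motif_class, "other")
  expect_identical(mk("NDEEL")$l1_length, 5L)
})

test_that("C-terminal ending precedence puts SQDY before the general motif", {
  fx <- templateFixture()
  expect_identical(ctermSignature(fx$H2A.O$seq, fx$H2A.O$fold)$cterm_class,
                   "O_end")
  expect_identical(ctermSignature(fx$H2A.X$seq, fx$H2A.X$fold)$cterm_class,
                   "X_end")
  expect_identical(ctermSignature(fx$H2A.W$seq, fx$H2A.W$fold)$cterm_class,
                   "W_end")
  expect_identical(ctermSignature(fx$H2A.Z$seq, fx$H2A.Z$fold)$cterm_class,
                   "Z_end")
  rc <- ctermSignature(fx$RC_H2A$seq, fx$RC_H2A$fold)
  expect_identical(rc$cterm_class, "none")
  expect_gte(rc$ctail_k_frac, 0.4)   # RC C-tails are lysine-enriched
})

test_that("N-tail statistics match direct counting and are monotone", {
  fx <- templateFixture()
  nt <- ntailStats(fx$H2A.O$seq, fx$H2A.O$fold)
  tail_str <- substr(fx$H2A.O$seq, 1, foldRegions(fx$H2A.O$fold)$n_tail[2])
  ch <- strsplit(tail_str, "")[[1]]
  expect_equal(nt$ntail_kg_frac, mean(ch %in% c("K", "G")))
  expect_gte(nt$ntail_kg_maxrun, 6L)
  expect_true(ntailStats(fx$H2A.N$seq, fx$H2A.N$fold)$ntail_plrp)
  expect_false(nt$ntail_plrp)
  ## monotonicity: extending the tail with K/G never lowers the statistics
  base <- fx$RC_H2A
  for (add in c(1, 3, 8)) {
    ext_seq <- paste0(strrep("K", add), base$seq)
    fold <- anchorToProfile(ext_seq, defaultProfile())
    a <- ntailStats(base$seq, base$fold)
    b <- ntailStats(ext_seq, fold)
    expect_gte(b$ntail_kg_frac, a$ntail_kg_frac - 1e-12)
    expect_gte(b$ntail_kg_maxrun, a$ntail_kg_maxrun)
  }
})

test_that("acidic patch and docking statistics separate H2A.Z", {
  fx <- templateFixture()
  pz <- acidicPatchProfile(fx$H2A.Z$seq, fx$H2A.Z$fold)
  expect_identical(pz$acidic_patch_first, "G")
  expect_identical(pz$acidic_patch_count, 5L)
  pe <- acidicPatchProfile(fx$H2A.E$seq, fx$H2A.E$fold)
  expect_identical(pe$acidic_patch_first, "N")
  dz <- dockingStats(fx$H2A.Z$seq, fx$H2A.Z$fold)
  expect_identical(dz$docking_his_count, 2L)
  expect_false(dz$docking_end_match)
  drc <- dockingStats(fx$RC_H2A$seq, fx$RC_H2A$fold)
  expect_identical(drc$docking_his_count, 0L)
  expect_true(drc$docking_end_match)
  expect_identical(dockingStats(fx$H2A.E$seq, fx$H2A.E$fold)$docking_his_count,
                   1L)
})

test_that("alphaN motif scoring finds QSLRA only in H2A.N", {
  fx <- templateFixture()
  expect_identical(matchAlphaN(fx$H2A.N$seq, fx$H2A.N$fold), 0L)
  expect_gte(matchAlphaN(fx$RC_H2A$seq, fx$RC_H2A$fold), 3L)
  for (cl in h2aClasses()) {
    co <- foldRegions(fx[[cl]]$fold)$alphaN
    expect_identical(
      as.integer(matchAlphaN(fx[[cl]]$seq, fx[[cl]]$fold)),
      as.integer(oracleMinHamming(fx[[cl]]$seq, co[1] + 1, co[2],
                                  "QSLRA", ext = 2)),
      label = paste("alphaN oracle", cl))
  }
})

test_that("feature vectors of distinct classes differ and fold-missing propagates", {
  fx <- templateFixture()
  fvs <- do.call(rbind, lapply(h2aClasses(), function(cl)
    extractFeatures(fx[[cl]]$seq, fx[[cl]]$fold, cl)))
  key <- c("alpha2_mismatches", "l1_motif_class", "alphaN_mismatches",
           "acidic_patch_first", "docking_his_count", "docking_end_match",
           "cterm_class", "ntail_length", "ctail_length", "ntail_kg_maxrun")
  sig <- apply(fvs[, key], 1, paste, collapse = "|")
  expect_identical(anyDuplicated(sig), 0L)
  ## determinism
  again <- extractFeatures(fx$H2A.Z$seq, fx$H2A.Z$fold, "H2A.Z")
  expect_identical(again, fvs[fvs$record_id == "H2A.Z", ],
                   ignore_attr = TRUE)
  ## fold-missing record
  nofold <- methods::new("FoldAnnotation", recordId = "x", regions = list(),
                         alignmentScore = -Inf, foldDetected = FALSE,
                         patchSites = integer())
  fv <- extractFeatures("AAAA", nofold, "x")
  expect_true(fv$fold_missing)
  expect_true(is.na(fv$alpha2_mismatches))
  expect_error(scoreAlpha2Signature("AAAA", nofold), "fold not detected")
})

test_that("PTM peptides map to 1-based protein sites across all matches", {
  set <- makeBenchmarkSet(syntheticSpec(c(H2A.E = 2L, H2A.O = 1L), 0, 0, 1))
  seqs <- as.character(sequences(set))
  ## the E/O templates share their alpha2 block: a peptide from it hits all
  shared <- substr(classTemplate("H2A.E")$sequence,
                   classTemplate("H2A.E")$coords$alpha2[1] + 1,
                   classTemplate("H2A.E")$coords$alpha2[1] + 10)
  res <- mapPtmPeptides(
    data.frame(peptide = c(substr(seqs[[1]], 1, 10), shared, "WWWWWW"),
               offset = c(2L, 0L, 1L),
               mod = c("ac", "me1", "ph")),
    set)
  first <- res$assignments[res$assignments$peptide == substr(seqs[[1]], 1, 10), ]
  expect_equal(first$site[first$record_id == names(seqs)[1]], 3)
  shared_hits <- res$assignments[res$assignments$peptide == shared, ]
  expect_identical(sort(unique(shared_hits$record_id)), sort(names(seqs)))
  expect_identical(res$unmatched, "WWWWWW")
  expect_error(mapPtmPeptides(
    data.frame(peptide = "KKB", offset = 0L, mod = "ac"), set))
  expect_error(mapPtmPeptides(
    data.frame(peptide = "KKKKKK", offset = 9L, mod = "ac"), set),
    "offset")
})
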