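test_that("initial methionine stripping is correct and idempotent", {
  expect_identical(stripInitialMet("MSGRGK")$sequence, "SGRGK")
  expect_identical(stripInitialMet("SGRGK")$sequence, "SGRGK")
  once <- stripInitialMet("MMSGRGK")
  expect_identical(stripInitialMet(once), once)  # mature records pass through
  expect_error(stripInitialMet(""), "non-empty")
  expect_error(stripInitialMet("SGRB"), "non-residue")
})

test_that("profile consensus self-aligns onto the full region map", {
  p <- defaultProfile()
  cons <- profileConsensus(p)
  fa <- anchorToProfile(cons, p, record_id = "consensus")
  expect_true(foldDetected(fa))
  expect_equal(fa@alignmentScore, profileSelfScore(p), tolerance = 1e-9)
  ## regions map 1:1 (consensus has no tails)
  rg <- foldRegions(fa)
  expect_equal(unname(rg$n_tail), c(0, 0))
  expect_equal(unname(rg$c_tail), c(nchar(cons), nchar(cons)))
  for (r in names(p@regionMap)) {
    iv <- p@regionMap[[r]]
    expect_equal(unname(rg[[r]]), c(iv[1] - 1, iv[2]))
  }
})

test_that("region tiling invariant holds on noisy benchmark sequences", {
  set <- makeBenchmarkSet(benchSpec(per_class = 3L, seed = 77L))
  p <- defaultProfile()
  anns <- annotateSet(set, p)
  for (id in names(anns)) {
    fa <- anns[[id]]
    expect_true(foldDetected(fa))
    rg <- foldRegions(fa)
    len <- nchar(as.character(sequences(set)[[id]]))
    bounds <- unlist(rg, use.names = FALSE)
    expect_equal(bounds[1], 0)
    expect_equal(bounds[length(bounds)], len)
    starts <- vapply(rg, `[`, numeric(1), 1)
    ends <- vapply(rg, `[`, numeric(1), 2)
    expect_equal(unname(starts[-1]), unname(ends[-length(ends)]))
    expect_true(all(ends >= starts))
    expect_true(validObject(fa))
  }
})

test_that("prepending tail residues shifts fold regions exactly", {
  p <- defaultProfile()
  base <- classTemplate("RC_H2A")$sequence
  fa0 <- anchorToProfile(base, p)
  set.seed(4)
  for (k in c(1L, 7L, 23L, 50L)) {
    prefix <- paste0(sample(c("P", "W", "C", "F"), k, replace = TRUE),
                     collapse = "")
    fa <- anchorToProfile(paste0(prefix, base), p)
    expect_true(foldDetected(fa))
    for (r in setdiff(names(foldRegions(fa)), c("n_tail", "c_tail"))) {
      expect_equal(unname(foldRegions(fa)[[r]]),
                   unname(foldRegions(fa0)[[r]]) + k,
                   label = paste("shift", r, "k =", k))
    }
    expect_equal(unname(foldRegions(fa)$n_tail),
                 c(0, unname(foldRegions(fa0)$n_tail)[2] + k))
  }
})

test_that("alignment score matches the exhaustive DP oracle", {
  p <- defaultProfile()
  set.seed(11)
  for (rep in 1:30) {
    m <- sample(10:40, 1)
    cols <- sample(ncol(p@freqs), m)
    freqs <- p@freqs[, sort(cols), drop = FALSE]
    len <- sample(15:60, 1)
    seqstr <- if (rep %% 3 == 0) {
      ## fold-like: sample residues from the profile columns themselves
      paste0(vapply(sample(ncol(freqs), min(len, ncol(freqs))),
                    function(j) sample(AA, 1, prob = freqs[, j]),
                    character(1)), collapse = "")
    } else randomProtein(len)
    chars <- strsplit(seqstr, "")[[1]]
    got <- h2avariants:::.profileDP(
      h2avariants:::.matchScores(chars, freqs))$score
    want <- oracleProfileScore(chars, freqs)
    expect_equal(got, want, tolerance = 1e-8,
                 label = paste("DP oracle rep", rep))
  }
})

test_that("short or fold-free sequences yield no fold", {
  p <- defaultProfile()
  short <- anchorToProfile("SGRGKQGGKA", p)
  expect_false(foldDetected(short))
  expect_length(foldRegions(short), 0)
  set.seed(9)
  junk <- randomProtein(120)
  fa <- anchorToProfile(junk, p)
  expect_false(foldDetected(fa))
})
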