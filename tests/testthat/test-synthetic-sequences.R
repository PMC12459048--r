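test_that("zero-noise generation reproduces the class templates exactly", {
  spec <- syntheticSpec(stats::setNames(rep(1L, 9), h2aClasses()), 0, 0, 1)
  for (cl in h2aClasses()) {
    rec <- makeVariantSequence(cl, spec)
    tpl <- classTemplate(cl)
    expect_identical(rec$sequence, tpl$sequence)
    expect_identical(rec$coords, tpl$coords)
  }
})

test_that("planted class signatures are present in the templates", {
  z <- classTemplate("H2A.Z")
  a2 <- z$coords$alpha2
  expect_true(grepl("LEYLTAEVLELAGNA",
                    substr(z$sequence, a2[1] + 1, a2[2]), fixed = TRUE))
  x <- classTemplate("H2A.X")$sequence
  expect_true(oracleEndsWith(x, list("S", "Q", c("D", "E"), c("F", "Y"))))
  o <- classTemplate("H2A.O")$sequence
  expect_true(endsWith(o, "SQDY"))
  n <- classTemplate("H2A.N")
  expect_true(grepl("QSLRA", n$regions$alphaN, fixed = TRUE))
  expect_true(grepl("PLRP", n$regions$n_tail, fixed = TRUE))
  expect_gte(nchar(n$regions$n_tail),
             nchar(classTemplate("RC_H2A")$regions$n_tail) + 30)
  ## H2A.Z structural traits relative to RC: longer L1, shorter docking
  rc <- classTemplate("RC_H2A")
  expect_identical(nchar(z$regions$L1), nchar(rc$regions$L1) + 1L)
  expect_identical(nchar(z$regions$docking), nchar(rc$regions$docking) - 1L)
  expect_identical(substr(z$regions$docking, 1, 1), "G")
  expect_identical(sum(strsplit(z$regions$docking, "")[[1]] == "H"), 2L)
})

test_that("benchmark sets honor counts, labels and determinism", {
  spec <- syntheticSpec(c(H2A.Z = 10L, H2A.O = 10L, RC_H2A = 7L),
                        0.05, 0.05, seed = 1)
  a <- makeBenchmarkSet(spec)
  b <- makeBenchmarkSet(spec)
  expect_identical(as.character(sequences(a)), as.character(sequences(b)))
  expect_identical(truthLabels(a), truthLabels(b))
  tab <- table(truthLabels(a))
  expect_identical(as.integer(tab[c("H2A.Z", "H2A.O", "RC_H2A")]),
                   c(10L, 10L, 7L))
  ## empty case
  empty <- makeBenchmarkSet(syntheticSpec(c(H2A.Z = 0L)))
  expect_length(sequences(empty), 0)
  ## region truth stays within bounds (validity catches violations)
  expect_true(validObject(a))
})

test_that("signature positions survive mutation up to rate 0.1", {
  pats <- list(
    H2A.Z = function(s) grepl("LEYLTAEVLELAGNA", s, fixed = TRUE),
    H2A.X = function(s) grepl("SQ[DE][FY]$", s),
    H2A.O = function(s) grepl("SQDY$", s) &
      grepl("[KG]{6}", substr(s, 1, 20)),
    H2A.N = function(s) grepl("PLRP", s, fixed = TRUE) &
      grepl("QSLRA", s, fixed = TRUE),
    H2A.W = function(s) grepl("KSPKK$", s),
    H2A.M = function(s) grepl("RYA[QK]", s),
    RC_H2A = function(s) grepl("VLLPKK", s, fixed = TRUE))
  for (seed in 1:5) {
    spec <- syntheticSpec(
      stats::setNames(rep(3L, length(pats)), names(pats)),
      substitution_rate = 0.1, indel_rate = 0.1, seed = seed)
    set <- makeBenchmarkSet(spec)
    truth <- truthLabels(set)
    for (id in names(truth)) {
      s <- as.character(sequences(set)[[id]])
      expect_true(pats[[truth[[id]]]](s),
                  label = paste("signature integrity", truth[[id]], seed))
    }
  }
})

test_that("invalid generator specs are rejected", {
  expect_error(syntheticSpec(c(H2A.Q = 1L)), "unsupported")
  expect_error(syntheticSpec(c(H2A.Z = -1L)), ">= 0")
  expect_error(syntheticSpec(c(H2A.Z = 1L), substitution_rate = 1.5), "0, 1")
  expect_error(makeVariantSequence("H2A.Q", syntheticSpec(c(H2A.Z = 1L))),
               "unsupported")
})
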