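exprFixture <- function(seed = 40L) {
  d <- expressionDesign(
    c("sperm", "eggs", "female", "male"),
    c(ubiquitous = 6, silent = 6, "tissue_specific:sperm" = 6,
      "condition_up:sperm" = 6),
    seed = seed)
  makeExpressionMatrix(d)
}

test_that("the TPM > 2 filter is strict and recovers planted truth", {
  b <- exprFixture()
  keep <- filterExpressed(b$matrix, b$meta)
  planted_expressed <- b$truth$gene_id[b$truth$pattern != "silent"]
  expect_setequal(keep, planted_expressed)
  ## boundary: a gene sitting exactly at 2.0 everywhere is removed
  m2 <- rbind(b$matrix, boundary = rep(2, ncol(b$matrix)),
              above = rep(2.01, ncol(b$matrix)))
  keep2 <- filterExpressed(m2, b$meta)
  expect_false("boundary" %in% keep2)
  expect_true("above" %in% keep2)
  ## all TPM at 1.5 is removed
  m3 <- rbind(b$matrix, low = rep(1.5, ncol(b$matrix)))
  expect_false("low" %in% filterExpressed(m3, b$meta))
  expect_error(filterExpressed(-b$matrix, b$meta), "non-negative")
})

test_that("specificity calls recover the planted patterns", {
  b <- exprFixture()
  sc <- specificityCall(b$matrix, b$meta)
  lab <- stats::setNames(sc$label, sc$gene_id)
  for (i in seq_len(nrow(b$truth))) {
    g <- b$truth$gene_id[i]; p <- b$truth$pattern[i]
    want <- switch(p, silent = "not_expressed",
                   ubiquitous = "ubiquitous",
                   "tissue_specific:sperm" = "specific:sperm",
                   "condition_up:sperm" = "ubiquitous")
    expect_identical(unname(lab[g]), want, label = paste(g, p))
  }
})

test_that("condition comparison flags planted shifts and is antisymmetric", {
  b <- exprFixture()
  cc <- conditionCompare(b$matrix, b$meta, "sperm", "eggs")
  up <- cc[grepl("^condition_up", cc$gene_id), ]
  expect_true(all(up$significant))
  expect_true(all(up$mean_A > up$mean_B))
  ## silent genes are omitted by the expression filter
  expect_false(any(grepl("^silent", cc$gene_id)))
  ## antisymmetry
  cc_rev <- conditionCompare(b$matrix, b$meta, "eggs", "sperm")
  ord <- match(cc$gene_id, cc_rev$gene_id)
  expect_equal(cc_rev$t[ord], -cc$t)
  expect_equal(cc_rev$p[ord], cc$p)
  ## identical replicate vectors: t = 0, p = 1
  m <- rbind(flat = c(10, 11, 12, 10, 11, 12))
  colnames(m) <- b$meta$sample_id[b$meta$group %in% c("sperm", "eggs")]
  meta <- b$meta[b$meta$group %in% c("sperm", "eggs"), ]
  cc0 <- conditionCompare(m, meta, "sperm", "eggs")
  expect_equal(cc0$t, 0, tolerance = 1e-12)
  expect_equal(cc0$p, 1, tolerance = 1e-12)
  ## degenerate zero-variance case
  m1 <- rbind(const = rep(10, 6))
  colnames(m1) <- colnames(m)
  cc1 <- conditionCompare(m1, meta, "sperm", "eggs")
  expect_equal(cc1$t, 0)
  expect_equal(cc1$p, 1)
  expect_error(conditionCompare(b$matrix[, 1:4, drop = FALSE],
                                b$meta[1:4, ], "sperm", "eggs"),
               "replicates")
})

test_that("the generator validates designs", {
  expect_error(expressionDesign("a", c(weird = 1)), "unknown pattern")
  expect_error(expressionDesign(c("a", "b"),
                                c("tissue_specific:zz" = 1)), "not in tissues")
  expect_error(expressionDesign(c("a", "b"), c("condition_up:a" = 1),
                                n_replicates = 1), "2 replicates")
})
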