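test_that("intron counts equal exon_count - 1 and match a GFF3 parse oracle", {
  expect_identical(countIntrons(list(exon_count = 1L)), 0L)
  expect_identical(countIntrons(list(exon_count = 2L)), 1L)
  expect_error(countIntrons(list(exon_count = 0L)), ">= 1")
  lay <- makeHistoneLayout(n_clusters = 1, n_isolated = 2, seed = 12)
  gff <- tempfile(fileext = ".gff3")
  writeGeneModels(lay$genes, gff)
  gm <- readGeneModels(gff, "synthetic")
  ## oracle: count exon lines per parent straight from the GFF3 text
  txt <- readLines(gff)
  exon_lines <- txt[grepl("\texon\t", txt)]
  parents <- sub(".*Parent=([^;]+).*", "\\1", exon_lines)
  for (i in seq_len(nrow(gm))) {
    expect_identical(countIntrons(gm[i, ]),
                     sum(parents == gm$gene_id[i]) - 1L,
                     label = paste("introns", gm$gene_id[i]))
  }
  ## round trip preserves coordinates exactly
  ord <- match(lay$genes$gene_id, gm$gene_id)
  expect_identical(gm$start[ord], lay$genes$start)
  expect_identical(gm$end[ord], lay$genes$end)
  expect_identical(gm$strand[ord], lay$genes$strand)
})

test_that("cluster detection equals the union-find oracle on random layouts", {
  set.seed(5)
  for (rep in 1:40) {
    n <- sample(4:14, 1)
    genes <- data.frame(
      gene_id = sprintf("g%02d", seq_len(n)),
      genome_id = "g",
      contig = sample(paste0("ctg", 1:3), n, replace = TRUE),
      start = 0L, end = 0L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      exon_count = 1L,
      product_class = sample(c("H1", "H2A", "H2B", "H3", "H4", "other"),
                             n, replace = TRUE),
      variant = NA_character_, stringsAsFactors = FALSE)
    at <- stats::setNames(rep(0L, 3), paste0("ctg", 1:3))
    for (i in order(genes$contig)) {
      gap <- sample(c(500L, 5000L, 50000L), 1)
      genes$start[i] <- at[[genes$contig[i]]] + gap
      genes$end[i] <- genes$start[i] + 800L
      at[[genes$contig[i]]] <- genes$end[i]
    }
    got <- detectHistoneClusters(genes)
    got_sets <- sort(vapply(strsplit(got$gene_ids, ","), function(x)
      paste(sort(x), collapse = ","), character(1)))
    expect_identical(got_sets, oracleClusters(genes),
                     label = paste("cluster oracle rep", rep))
  }
})

test_that("planted histone clusters are found with tandem H2A-H2B flags", {
  lay <- makeHistoneLayout(n_clusters = 3, n_isolated = 2, seed = 9)
  cl <- detectHistoneClusters(lay$genes)
  expect_identical(nrow(cl), 3L)
  expect_identical(sort(cl$contig), sort(lay$planted_clusters$contig))
  expect_identical(cl$start[order(cl$contig)],
                   lay$planted_clusters$start[order(lay$planted_clusters$contig)])
  expect_true(all(cl$tandem_h2a_h2b))
  ## isolated H2A genes never form clusters
  expect_false(any(grepl("isolated", cl$contig)))
})

test_that("identity neighborhoods share all flankers with no breaks", {
  nb <- makeGeneNeighborhood(3, 4, 4, seed = 2)
  cmp <- compareNeighborhoods(nb$anchor_og, nb$genes, nb$orthogroups,
                              "genome01")
  expect_identical(length(cmp$reference), 8L)
  for (g in names(cmp$per_genome)) {
    pg <- cmp$per_genome[[g]]
    expect_true(all(pg$flanker_status == "shared"))
    expect_identical(nrow(pg$breaks), 0L)
    expect_equal(pg$order_score, 1)
  }
})

test_that("planted breaks are recovered exactly and order_score matches LCS", {
  set.seed(17)
  for (rep in 1:30) {
    kind <- sample(c("intercalated", "contig", "both", "none"), 1)
    nb <- makeGeneNeighborhood(
      2, 4, 4,
      intercalations = if (kind %in% c("intercalated", "both"))
        list(genome02 = sample(1:2, 1)) else list(),
      contig_breaks = if (kind %in% c("contig", "both")) "genome02"
        else character(),
      seed = 1000L + rep)
    cmp <- compareNeighborhoods(nb$anchor_og, nb$genes, nb$orthogroups,
                                "genome01")
    pg <- cmp$per_genome$genome02
    planted <- sort(nb$planted_breaks$kind)
    got <- sort(pg$breaks$kind)
    expect_identical(got, planted, label = paste("breaks rep", rep, kind))
    ## order_score against the independent recursive LCS
    tg <- nb$genes[nb$genes$genome_id == "genome02", ]
    tg$og <- nb$orthogroups$orthogroup_id[match(tg$gene_id,
                                                nb$orthogroups$gene_id)]
    tg <- tg[tg$contig == "ctg1", ]
    tg <- tg[order(tg$start), ]
    tgt_main <- tg$og[tg$og != "OG_anchor"]
    expect_equal(pg$order_score,
                 oracleLCS(cmp$reference, tgt_main) / length(cmp$reference),
                 label = paste("LCS rep", rep))
  }
})

test_that("strand flips and shuffles degrade order_score but not sharing", {
  nb <- makeGeneNeighborhood(2, 3, 3, anchor_strand_flips = "genome02",
                             seed = 4)
  cmp <- compareNeighborhoods(nb$anchor_og, nb$genes, nb$orthogroups,
                              "genome01")
  pg <- cmp$per_genome$genome02
  expect_true(all(pg$flanker_status == "shared"))
  expect_equal(pg$order_score, 1)   # orientation normalized by anchor strand
  ## scrambling target gene order can only lower the score
  genes2 <- nb$genes
  g2 <- genes2$genome_id == "genome02"
  set.seed(8)
  genes2$start[g2] <- sample(genes2$start[g2])
  genes2$end[g2] <- genes2$start[g2] + 900L
  cmp2 <- compareNeighborhoods(nb$anchor_og, genes2, nb$orthogroups,
                               "genome01")
  expect_lte(cmp2$per_genome$genome02$order_score, pg$order_score)
})

test_that("anchor absence and multi-copy anchors are handled", {
  nb <- makeGeneNeighborhood(2, 2, 2, seed = 6)
  ## remove the anchor from genome02
  og <- nb$orthogroups
  drop <- nb$genes$gene_id[nb$genes$genome_id == "genome02" &
    og$orthogroup_id[match(nb$genes$gene_id, og$gene_id)] == "OG_anchor"]
  genes <- nb$genes[nb$genes$gene_id != drop, ]
  cmp <- compareNeighborhoods(nb$anchor_og, genes, og, "genome01")
  expect_identical(cmp$per_genome$genome02$status, "absent")
  ## duplicate the anchor on a junk contig: best copy wins, flag set
  extra <- nb$genes[nb$genes$gene_id == drop, ]
  extra$gene_id <- "dup1"; extra$contig <- "ctg9"
  genes2 <- rbind(nb$genes, extra)
  og2 <- rbind(og, data.frame(gene_id = "dup1", orthogroup_id = "OG_anchor"))
  cmp2 <- compareNeighborhoods(nb$anchor_og, genes2, og2, "genome01")
  expect_true(cmp2$per_genome$genome02$multi_copy)
  expect_equal(cmp2$per_genome$genome02$order_score, 1)
})
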