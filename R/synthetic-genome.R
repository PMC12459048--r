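## Synthetic genome layouts: anchored flanking-gene neighborhoods with
## planted intercalations and contig breaks, and contig layouts with histone
## gene clusters, tandem H2A-H2B pairs and planted intron structures.

#' Generate anchored gene neighborhoods across genomes
#'
#' Each genome receives an anchor gene with `k_up` upstream and `k_down`
#' downstream flanking genes in conserved orthogroup order. Requested
#' perturbations plant, per genome, intercalated novel genes between
#' conserved flankers and/or move a suffix of the downstream flankers to a
#' new contig.
#'
#' @param n_genomes Number of genomes.
#' @param k_up,k_down Flank sizes (must be >= 0).
#' @param intercalations Named list genome_id -> number of intercalated
#'   genes to plant (or integer applied to those genomes).
#' @param contig_breaks Character vector of genome ids receiving a contig
#'   break (a random suffix of downstream flankers moves to a new contig).
#' @param anchor_strand_flips Character vector of genome ids whose anchor
#'   (and neighborhood) is placed on the minus strand.
#' @param seed Integer seed.
#' @return A list with `genes` (gene-model data.frame), `orthogroups`
#'   (gene_id / orthogroup_id data.frame), `anchor_og`, and
#'   `planted_breaks` (data.frame genome_id, kind).
#' @export
#' @examples
#' nb <- makeGeneNeighborhood(2, 2, 2, seed = 1)
#' table(nb$genes$genome_id)
makeGeneNeighborhood <- function(n_genomes, k_up = 4L, k_down = 4L,
                                 intercalations = list(),
                                 contig_breaks = character(),
                                 anchor_strand_flips = character(),
                                 seed = 1L) {
  if (k_up < 0 || k_down < 0) stop("flank sizes must be >= 0")
  genome_ids <- sprintf("genome%02d", seq_len(n_genomes))
  flank_ogs <- c(if (k_up > 0) sprintf("OG_up%d", seq_len(k_up)),
                 if (k_down > 0) sprintf("OG_down%d", seq_len(k_down)))
  withStreamSeed(seed, "neighborhood", {
    genes <- list(); ortho <- list(); planted <- list()
    for (g in genome_ids) {
      strand <- if (g %in% anchor_strand_flips) "-" else "+"
      ## biological chain: far-upstream ... anchor ... downstream
      chain <- c(rev(sprintf("OG_up%d", seq_len(k_up))), "OG_anchor",
                 sprintf("OG_down%d", seq_len(k_down)))
      anchor_at <- k_up + 1L
      n_elem <- length(chain)
      ## perturbations address gaps between consecutive original elements;
      ## the contig cut and the intercalations use disjoint gaps so every
      ## planted break stays individually recoverable
      cut_gap <- NA_integer_
      if (g %in% contig_breaks && anchor_at <= n_elem - 1L) {
        cut_gap <- if (anchor_at == n_elem - 1L) anchor_at
                   else sample(anchor_at:(n_elem - 1L), 1L)
        planted[[length(planted) + 1L]] <-
          data.frame(genome_id = g, kind = "contig",
                     stringsAsFactors = FALSE)
      }
      n_int <- if (is.list(intercalations)) intercalations[[g]] %||% 0L
               else as.integer(intercalations)
      int_gaps <- integer()
      if (n_int > 0) {
        free_gaps <- setdiff(seq_len(n_elem - 1L), cut_gap)
        n_int <- min(n_int, length(free_gaps))
        int_gaps <- sort(sample(free_gaps, n_int))
        for (q in seq_len(n_int))
          planted[[length(planted) + 1L]] <-
            data.frame(genome_id = g, kind = "intercalated",
                       stringsAsFactors = FALSE)
      }
      ## assemble the final chain with per-element contig assignment
      contig_of_gap <- function(gap)
        if (!is.na(cut_gap) && gap > cut_gap) "ctg2" else "ctg1"
      final <- character(); contig <- character()
      for (i in seq_len(n_elem)) {
        final <- c(final, chain[i])
        contig <- c(contig,
                    if (!is.na(cut_gap) && i > cut_gap) "ctg2" else "ctg1")
        ins_here <- which(int_gaps == i)
        for (q in ins_here) {
          final <- c(final, paste0("OG_novel_", g, "_", q))
          contig <- c(contig, contig_of_gap(i))
        }
      }
      chain <- final
      if (strand == "-") { chain <- rev(chain); contig <- rev(contig) }
      at <- stats::setNames(c(0L, 0L), c("ctg1", "ctg2"))
      for (i in seq_along(chain)) {
        start <- at[[contig[i]]] + 1000L
        end <- start + 900L
        at[[contig[i]]] <- end
        gid <- paste0(g, "_g", i)
        genes[[length(genes) + 1L]] <- data.frame(
          gene_id = gid, genome_id = g, contig = contig[i],
          start = start, end = end, strand = strand,
          exon_count = 1L,
          product_class = if (chain[i] == "OG_anchor") "H2A" else "other",
          variant = NA_character_, stringsAsFactors = FALSE)
        ortho[[length(ortho) + 1L]] <- data.frame(
          gene_id = gid, orthogroup_id = chain[i], stringsAsFactors = FALSE)
      }
    }
    planted <- if (length(planted)) do.call(rbind, planted) else
      data.frame(genome_id = character(), kind = character())
    list(genes = do.call(rbind, genes),
         orthogroups = do.call(rbind, ortho),
         anchor_og = "OG_anchor", planted_breaks = planted)
  })
}

#' Generate a contig layout with planted histone clusters
#'
#' Plants `n_clusters` histone gene clusters (each drawing genes from at
#' least two histone families, with a tandem H2A-H2B pair) separated and
#' flanked by non-histone genes and isolated single histone genes, with
#' planted intron structures (clustered replication-coupled-style genes are
#' intronless; dispersed variant-style genes carry introns).
#'
#' @param n_clusters Number of clusters to plant.
#' @param n_isolated Number of isolated single histone genes (own contigs).
#' @param genes_per_cluster Histone genes per cluster (>= 2).
#' @param intergenic_bp Gap between clustered genes (default 2000, well
#'   under the 20 kb chaining threshold).
#' @param seed Integer seed.
#' @return A list with `genes` (gene-model data.frame) and
#'   `planted_clusters` (data.frame contig, start, end).
#' @export
makeHistoneLayout <- function(n_clusters = 2L, n_isolated = 2L,
                              genes_per_cluster = 5L, intergenic_bp = 2000L,
                              seed = 1L) {
  stopifnot(genes_per_cluster >= 2)
  withStreamSeed(seed, "histone_layout", {
    genes <- list(); clusters <- list()
    addGene <- function(contig, start, end, fam, exons, variant = NA) {
      genes[[length(genes) + 1L]] <<- data.frame(
        gene_id = sprintf("gene%03d", length(genes) + 1L),
        genome_id = "synthetic", contig = contig, start = start, end = end,
        strand = sample(c("+", "-"), 1L), exon_count = exons,
        product_class = fam, variant = as.character(variant),
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_clusters)) {
      contig <- sprintf("cluster_ctg%02d", k)
      at <- 5000L
      ## leading non-histone gene
      addGene(contig, at, at + 800L, "other", 3L); at <- at + 800L + 30000L
      cstart <- at
      fams <- c("H2A", "H2B",
                sample(c("H1", "H3", "H4"), genes_per_cluster - 2L,
                       replace = genes_per_cluster - 2L > 3L))
      for (f in fams) {
        addGene(contig, at, at + 700L, f, 1L,
                variant = if (f == "H2A") "H2A.E" else NA)
        at <- at + 700L + intergenic_bp
      }
      cend <- at - intergenic_bp
      clusters[[length(clusters) + 1L]] <- data.frame(
        contig = contig, start = cstart, end = cend,
        stringsAsFactors = FALSE)
      ## trailing non-histone gene beyond the chaining gap
      at <- at + 30000L
      addGene(contig, at, at + 800L, "other", 2L)
    }
    for (k in seq_len(n_isolated)) {
      contig <- sprintf("isolated_ctg%02d", k)
      addGene(contig, 4000L, 4900L, "H2A", sample(2:4, 1L),
              variant = sample(c("H2A.N", "H2A.O"), 1L))
      addGene(contig, 40000L, 40900L, "other", 2L)
    }
    list(genes = do.call(rbind, genes),
         planted_clusters = do.call(rbind, clusters))
  })
}

#' Write gene models as GFF3 plus an orthogroup table
#'
#' Emits one `gene` row per gene model with `product_class` and `variant`
#' attributes, followed by its `exon` rows, and the orthogroup map as TSV.
#'
#' @param genes Gene-model `data.frame`.
#' @param gff_path Output GFF3 path.
#' @param orthogroups Optional orthogroup `data.frame`.
#' @param ortho_path Output TSV path for the orthogroups.
#' @return Invisibly, the paths written.
#' @export
writeGeneModels <- function(genes, gff_path, orthogroups = NULL,
                            ortho_path = NULL) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gr <- GenomicRanges::GRanges(
      seqnames = g$contig,
      ranges = IRanges::IRanges(start = g$start, end = g$end),
      strand = g$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = "gene", ID = g$gene_id, Parent = NA_character_,
      product_class = g$product_class, variant = g$variant)
    rows[[length(rows) + 1L]] <- gr
    ## exons: equal split with 100 bp introns
    ne <- g$exon_count
    width <- g$end - g$start + 1L
    exon_w <- max(1L, (width - (ne - 1L) * 100L) %/% ne)
    s <- g$start
    for (e in seq_len(ne)) {
      ee <- if (e == ne) g$end else s + exon_w - 1L
      er <- GenomicRanges::GRanges(
        seqnames = g$contig, ranges = IRanges::IRanges(start = s, end = ee),
        strand = g$strand)
      S4Vectors::mcols(er) <- S4Vectors::DataFrame(
        type = "exon", ID = paste0(g$gene_id, ".exon", e),
        Parent = g$gene_id, product_class = NA_character_,
        variant = NA_character_)
      rows[[length(rows) + 1L]] <- er
      s <- ee + 101L
    }
  }
  all <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(all, gff_path, format = "gff3")
  paths <- c(gff = gff_path)
  if (!is.null(orthogroups) && !is.null(ortho_path)) {
    .writeTsv(orthogroups, ortho_path)
    paths <- c(paths, orthogroups = ortho_path)
  }
  invisible(paths)
}
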