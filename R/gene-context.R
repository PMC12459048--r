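## Genomic-evidence layer: intron counts, histone gene-cluster detection,
## and anchored shared-synteny comparison with break annotation.

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

HISTONE_FAMILIES <- c("H1", "H2A", "H2B", "H3", "H4")

#' Read gene models from GFF3
#'
#' Imports `gene` and `exon` features and returns one row per gene with its
#' exon count and (when annotated) histone product class and variant label.
#' Coordinates stay 1-based inclusive as in GFF3.
#'
#' @param path GFF3 file.
#' @param genome_id Genome identifier attached to every row.
#' @return A `data.frame` with columns gene_id, genome_id, contig, start,
#'   end, strand, exon_count, product_class, variant.
#' @export
readGeneModels <- function(path, genome_id = basename(path)) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  genes <- gr[is_gene]
  gmd <- S4Vectors::mcols(genes)
  ids <- gmd$ID
  exons <- gr[md$type == "exon"]
  parents <- as.character(S4Vectors::mcols(exons)$Parent)
  exon_count <- vapply(ids, function(id) sum(parents == id), integer(1))
  exon_count[exon_count == 0L] <- 1L   # genes without exon rows: single exon
  pc <- if (!is.null(gmd$product_class)) as.character(gmd$product_class)
        else rep("other", length(genes))
  pc[is.na(pc)] <- "other"
  vr <- if (!is.null(gmd$variant)) as.character(gmd$variant)
        else rep(NA_character_, length(genes))
  data.frame(gene_id = ids, genome_id = genome_id,
             contig = as.character(GenomicRanges::seqnames(genes)),
             start = GenomicRanges::start(genes),
             end = GenomicRanges::end(genes),
             strand = as.character(GenomicRanges::strand(genes)),
             exon_count = exon_count, product_class = pc, variant = vr,
             stringsAsFactors = FALSE)
}

#' Count introns of a gene model
#'
#' @param gene One row of a gene-model table (or any list with
#'   `exon_count`).
#' @return `exon_count - 1`.
#' @export
#' @examples
#' countIntrons(list(exon_count = 2))
countIntrons <- function(gene) {
  if (is.null(gene$exon_count) || any(gene$exon_count < 1))
    stop("exon_count must be >= 1")
  gene$exon_count - 1L
}

#' Detect histone gene clusters on contigs
#'
#' Greedy chaining of histone-family genes along each contig: consecutive
#' histone genes with an inter-gene gap of at most `max_gap_bp` join one
#' chain; a chain is reported as a cluster when it spans at least
#' `min_families` distinct histone families. Tandem H2A-H2B adjacency within
#' a cluster is flagged.
#'
#' @param genes Gene-model `data.frame` (see [readGeneModels()]).
#' @param max_gap_bp Maximum gap between consecutive histone genes
#'   (default 20000).
#' @param min_families Minimum number of distinct histone families
#'   (default 2).
#' @return A `data.frame` with one row per cluster: genome_id, contig,
#'   start, end, n_genes, families, tandem_h2a_h2b, gene_ids.
#' @export
detectHistoneClusters <- function(genes, max_gap_bp = 20000L,
                                  min_families = 2L) {
  hist <- genes[genes$product_class %in% HISTONE_FAMILIES, , drop = FALSE]
  out <- list()
  for (key in unique(paste(hist$genome_id, hist$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- hist[hist$genome_id == parts[1] & hist$contig == parts[2], ,
                drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    chain_start <- 1L
    flushChain <- function(from, to) {
      ch <- sub[from:to, , drop = FALSE]
      fams <- unique(ch$product_class)
      if (length(fams) < min_families) return(NULL)
      tandem <- FALSE
      if (nrow(ch) > 1) {
        pc <- ch$product_class
        tandem <- any((pc[-nrow(ch)] == "H2A" & pc[-1] == "H2B") |
                        (pc[-nrow(ch)] == "H2B" & pc[-1] == "H2A"))
      }
      data.frame(genome_id = parts[1], contig = parts[2],
                 start = min(ch$start), end = max(ch$end),
                 n_genes = nrow(ch),
                 families = paste(sort(fams), collapse = ","),
                 tandem_h2a_h2b = tandem,
                 gene_ids = paste(ch$gene_id, collapse = ","),
                 stringsAsFactors = FALSE)
    }
    if (nrow(sub) == 0) next
    for (i in seq_len(nrow(sub))) {
      if (i == 1L) next
      gap <- sub$start[i] - sub$end[i - 1L]
      if (gap > max_gap_bp) {
        r <- flushChain(chain_start, i - 1L)
        if (!is.null(r)) out[[length(out) + 1L]] <- r
        chain_start <- i
      }
    }
    r <- flushChain(chain_start, nrow(sub))
    if (!is.null(r)) out[[length(out) + 1L]] <- r
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(genome_id = character(), contig = character(),
               start = integer(), end = integer(), n_genes = integer(),
               families = character(), tandem_h2a_h2b = logical(),
               gene_ids = character())
}

## Orthogroup of a gene; unmapped genes become singleton orthogroups.
.ogOf <- function(gene_ids, orthogroups) {
  og <- orthogroups$orthogroup_id[match(gene_ids, orthogroups$gene_id)]
  miss <- is.na(og)
  og[miss] <- paste0("OG_singleton:", gene_ids[miss])
  og
}

#' Compare anchored gene neighborhoods across genomes
#'
#' For each target genome, locates the anchor orthogroup, reads `k_up`
#' upstream and `k_down` downstream flanking genes in coordinate order
#' (orientation flipped when the anchor strand differs from the reference),
#' marks each reference flanker shared or absent, and annotates breaks:
#' `intercalated` when one or more non-matching genes sit between
#' consecutive shared flankers, `contig` when consecutive shared flankers
#' lie on different contigs. `order_score` is the length of the longest
#' common subsequence of the reference and target flanker orthogroup orders
#' divided by the number of reference flankers.
#'
#' @param anchor_og Anchor orthogroup id.
#' @param genes Gene-model `data.frame` covering all genomes.
#' @param orthogroups `data.frame` with columns gene_id, orthogroup_id.
#' @param reference_genome Genome id supplying the reference neighborhood.
#' @param k_up,k_down Number of flanking genes on each side.
#' @return A list with `reference` (flanker orthogroups) and `per_genome`
#'   (one entry per non-reference genome: status, flanker status, breaks,
#'   order_score, multi_copy flag).
#' @export
compareNeighborhoods <- function(anchor_og, genes, orthogroups,
                                 reference_genome, k_up = 4L, k_down = 4L) {
  if (k_up < 0 || k_down < 0) stop("flank sizes must be >= 0")
  genes$og <- .ogOf(genes$gene_id, orthogroups)

  ## ordered gene table of one contig
  contigGenes <- function(genome, contig) {
    sub <- genes[genes$genome_id == genome & genes$contig == contig, ,
                 drop = FALSE]
    sub[order(sub$start), , drop = FALSE]
  }
  ref_anchor <- genes[genes$genome_id == reference_genome &
                        genes$og == anchor_og, , drop = FALSE]
  if (nrow(ref_anchor) == 0) stop("anchor absent from reference genome")
  ref_anchor <- ref_anchor[1, ]
  ref_contig <- contigGenes(reference_genome, ref_anchor$contig)
  a <- which(ref_contig$gene_id == ref_anchor$gene_id)
  up <- ref_contig$og[rev(seq_len(a - 1L))]          # nearest first
  down <- ref_contig$og[seq_len(nrow(ref_contig)) > a]
  if (ref_anchor$strand == "-") { tmp <- up; up <- down; down <- tmp }
  up <- utils::head(up, k_up); down <- utils::head(down, k_down)
  ## reference chain in chromosomal order (oriented): far-up ... anchor ... down
  ref_ogs <- c(rev(up), "ANCHOR", down)
  ref_flankers <- setdiff(ref_ogs, "ANCHOR")

  compareOne <- function(genome, anchor_row) {
    tgt <- genes[genes$genome_id == genome, , drop = FALSE]
    tgt$og[tgt$gene_id == anchor_row$gene_id] <- "ANCHOR"
    flip <- anchor_row$strand != ref_anchor$strand
    ## target anchor-contig orthogroup order, oriented like the reference
    actg <- tgt[tgt$contig == anchor_row$contig, , drop = FALSE]
    actg <- actg[order(actg$start), , drop = FALSE]
    tgt_order <- if (flip) rev(actg$og) else actg$og
    ## map each chain element to its nearest target copy (genome-wide)
    anchor_idx <- which(tgt_order == "ANCHOR")[1]
    locate <- function(og) {
      if (og == "ANCHOR") {
        w <- which(tgt$og == "ANCHOR")
        return(tgt[w[1], , drop = FALSE])
      }
      w <- which(tgt$og == og)
      if (length(w) == 0) return(NULL)
      same <- w[tgt$contig[w] == anchor_row$contig]
      pick <- if (length(same)) {
        same[which.min(abs(tgt$start[same] - anchor_row$start))]
      } else w[1]
      tgt[pick, , drop = FALSE]
    }
    mapped <- lapply(ref_ogs, locate)
    names(mapped) <- ref_ogs
    status <- stats::setNames(
      ifelse(vapply(mapped[ref_flankers], is.null, logical(1)),
             "absent", "shared"), ref_flankers)
    ## breaks between consecutive mapped chain elements
    shared_chain <- which(!vapply(mapped, is.null, logical(1)))
    breaks <- list()
    posOnContig <- function(row) {
      ctg <- contigGenes(genome, row$contig)
      which(ctg$gene_id == row$gene_id)
    }
    for (s in seq_along(shared_chain)[-1]) {
      g1 <- mapped[[shared_chain[s - 1L]]]
      g2 <- mapped[[shared_chain[s]]]
      gap_label <- paste0(ref_ogs[shared_chain[s - 1L]], "|",
                          ref_ogs[shared_chain[s]])
      if (g1$contig != g2$contig) {
        breaks[[length(breaks) + 1L]] <-
          data.frame(kind = "contig", position = gap_label,
                     stringsAsFactors = FALSE)
      } else {
        p1 <- posOnContig(g1); p2 <- posOnContig(g2)
        if (abs(p2 - p1) > 1L) {
          ctg <- contigGenes(genome, g1$contig)
          between <- ctg$og[(min(p1, p2) + 1L):(max(p1, p2) - 1L)]
          between[ctg$gene_id[(min(p1, p2) + 1L):(max(p1, p2) - 1L)] ==
                    anchor_row$gene_id] <- "ANCHOR"
          if (any(!between %in% ref_ogs))
            breaks[[length(breaks) + 1L]] <-
              data.frame(kind = "intercalated", position = gap_label,
                         stringsAsFactors = FALSE)
        }
      }
    }
    breaks <- if (length(breaks)) do.call(rbind, breaks) else
      data.frame(kind = character(), position = character())
    order_score <- if (length(ref_flankers) == 0) 1 else
      lcsLength(ref_flankers, tgt_order[tgt_order != "ANCHOR"]) /
        length(ref_flankers)
    list(status = "present",
         flanker_status = status,
         breaks = breaks, order_score = order_score)
  }

  per_genome <- list()
  for (genome in setdiff(unique(genes$genome_id), reference_genome)) {
    anchors <- genes[genes$genome_id == genome & genes$og == anchor_og, ,
                     drop = FALSE]
    if (nrow(anchors) == 0) {
      per_genome[[genome]] <- list(status = "absent",
                                   flanker_status = NULL,
                                   breaks = NULL, order_score = 0,
                                   multi_copy = FALSE)
      next
    }
    cands <- lapply(seq_len(nrow(anchors)), function(i)
      compareOne(genome, anchors[i, ]))
    best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "order_score"))]]
    best$multi_copy <- nrow(anchors) > 1
    per_genome[[genome]] <- best
  }
  list(anchor = anchor_og, reference = ref_flankers,
       reference_genome = reference_genome, per_genome = per_genome)
}

#' Render a synteny comparison as text rows
#'
#' Gene arrows with `//` marking intercalation breaks and `XX` marking
#' contig breaks, one row per genome.
#'
#' @param cmp Result of [compareNeighborhoods()].
#' @return Character vector (one line per genome), invisibly printed.
#' @export
renderSynteny <- function(cmp) {
  lines <- paste0(cmp$reference_genome, " (ref): ",
                  paste0(">", c(cmp$reference[seq_len(length(cmp$reference))]),
                         collapse = " "))
  for (g in names(cmp$per_genome)) {
    pg <- cmp$per_genome[[g]]
    if (identical(pg$status, "absent")) {
      lines <- c(lines, paste0(g, ": anchor absent")); next
    }
    marks <- vapply(cmp$reference, function(og) {
      st <- pg$flanker_status[[og]]
      if (identical(st, "shared")) paste0(">", og) else paste0(".", og)
    }, character(1))
    brk <- if (nrow(pg$breaks) > 0)
      paste0(" [breaks: ", paste(paste0(pg$breaks$kind, "@",
                                        pg$breaks$position), collapse = "; "),
             "]") else ""
    lines <- c(lines, paste0(g, ": ", paste(marks, collapse = " "),
                             sprintf(" (order %.2f)%s", pg$order_score, brk)))
  }
  lines
}
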