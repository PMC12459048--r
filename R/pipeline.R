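## End-to-end orchestration: strip -> anatomy -> features -> classify, plus
## the optional gene-context / expression / clade evidence layers, producing
## a per-species variant inventory and a checksummed output manifest.

#' Pipeline run configuration
#'
#' @param fasta Protein FASTA path (required).
#' @param out_dir Output directory (required).
#' @param gff,orthogroups Optional gene annotation (GFF3) and orthogroup
#'   map (TSV) enabling the gene-context stage.
#' @param tpm,meta Optional TPM matrix and sample metadata (TSV) enabling
#'   the expression stage.
#' @param ptm_peptides Optional modified-peptide TSV (peptide, offset, mod)
#'   enabling PTM assignment.
#' @param classifier A [classifierConfig()].
#' @param run_consensus Build a per-class consensus when a class has >= 2
#'   members (default TRUE).
#' @param run_clades Run the clade sanity layer on the classified set when
#'   H2A.Z calls are present (default FALSE).
#' @param species_split Character used to split a FASTA id into
#'   species|record (default none: one species bucket "all").
#' @param seed Integer seed for any randomized stage.
#' @return A validated list of class `"RunConfig"`.
#' @export
runConfig <- function(fasta, out_dir, gff = NULL, orthogroups = NULL,
                      tpm = NULL, meta = NULL, ptm_peptides = NULL,
                      classifier = classifierConfig(),
                      run_consensus = TRUE, run_clades = FALSE,
                      species_split = NULL, seed = 1L) {
  for (p in c(fasta, gff, orthogroups, tpm, meta, ptm_peptides)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  if (!is.null(tpm) && is.null(meta))
    stop("expression stage needs both tpm and meta")
  structure(list(fasta = fasta, out_dir = out_dir, gff = gff,
                 orthogroups = orthogroups, tpm = tpm, meta = meta,
                 ptm_peptides = ptm_peptides, classifier = classifier,
                 run_consensus = run_consensus, run_clades = run_clades,
                 species_split = species_split, seed = as.integer(seed)),
            class = "RunConfig")
}

.speciesOf <- function(ids, split) {
  if (is.null(split)) return(stats::setNames(rep("all", length(ids)), ids))
  sp <- vapply(strsplit(ids, split, fixed = TRUE),
               function(x) x[1], character(1))
  stats::setNames(sp, ids)
}

#' Run the full pipeline
#'
#' Executes strip -> anatomy -> features -> classify on the input FASTA and
#' any optional evidence stages the configuration enables, writes all
#' artifacts under `out_dir`, and returns the per-species variant inventory
#' plus a manifest of outputs with MD5 checksums. Reruns with the same
#' configuration and seed produce byte-identical manifests.
#'
#' @param cfg A [runConfig()].
#' @return A list with `inventory` (species x class count matrix), `calls`,
#'   `features`, per-stage results, and `manifest` (file, md5 data.frame).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("h2a pipeline run",
                 paste0("seed: ", cfg$seed),
                 paste0("classifier: ",
                        paste(names(cfg$classifier), unlist(cfg$classifier),
                              sep = "=", collapse = " ")))
  raw <- Biostrings::readAAStringSet(cfg$fasta)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  mature <- stats::setNames(
    vapply(seq_along(raw), function(i)
      stripInitialMet(as.character(raw[[i]]))$sequence, character(1)), ids)
  set <- new("H2ASet", sequences = Biostrings::AAStringSet(mature),
    truth = character(), regionTruth = list(),
    species = .speciesOf(ids, cfg$species_split))

  profile <- defaultProfile()
  anns <- annotateSet(set, profile)
  regions_df <- writeRegionTable(anns, file.path(cfg$out_dir, "regions.tsv"))
  fvs <- do.call(rbind, lapply(ids, function(id)
    extractFeatures(mature[[id]], anns[[id]], id)))
  .writeTsv(fvs, file.path(cfg$out_dir, "features.tsv"))
  res <- classifyBatch(fvs, cfg$classifier)
  .writeTsv(res$calls, file.path(cfg$out_dir, "calls.tsv"))
  jsonlite::write_json(res$evidence,
                       file.path(cfg$out_dir, "evidence.json"),
                       auto_unbox = TRUE, digits = NA)

  species <- set@species[res$calls$record_id]
  inventory <- table(species = species,
                     class = factor(res$calls$label,
                                    levels = c(H2A_CLASSES, "unclassified")))
  .writeTsv(as.data.frame.matrix(inventory) |>
              (\(d) data.frame(species = rownames(d), d,
                               check.names = FALSE))(),
            file.path(cfg$out_dir, "inventory.tsv"))

  out <- list(inventory = inventory, calls = res$calls, counts = res$counts,
              features = fvs, regions = regions_df)

  if (isTRUE(cfg$run_consensus)) {
    for (cl in names(which(table(res$calls$label) >= 2))) {
      if (cl == "unclassified") next
      members <- res$calls$record_id[res$calls$label == cl]
      aln <- alignProteins(mature[members])
      cons <- buildConsensus(aln)
      writeConsensus(cons, cfg$out_dir,
                     prefix = paste0("consensus_", gsub("\\.", "", cl)))
      out$consensus[[cl]] <- cons
    }
  }
  if (!is.null(cfg$gff)) {
    genes <- readGeneModels(cfg$gff)
    clusters <- detectHistoneClusters(genes)
    .writeTsv(clusters, file.path(cfg$out_dir, "clusters.tsv"))
    introns <- data.frame(gene_id = genes$gene_id,
                          introns = countIntrons(genes))
    .writeTsv(introns, file.path(cfg$out_dir, "introns.tsv"))
    out$clusters <- clusters; out$introns <- introns
    if (!is.null(cfg$orthogroups))
      out$orthogroups <- utils::read.delim(cfg$orthogroups,
                                           stringsAsFactors = FALSE)
  }
  if (!is.null(cfg$tpm)) {
    expr <- readExpression(cfg$tpm, cfg$meta)
    keep <- filterExpressed(expr$matrix, expr$meta)
    spc <- specificityCall(expr$matrix, expr$meta)
    .writeTsv(spc, file.path(cfg$out_dir, "specificity.tsv"))
    out$expressed <- keep; out$specificity <- spc
  }
  if (!is.null(cfg$ptm_peptides)) {
    pep <- utils::read.delim(cfg$ptm_peptides, stringsAsFactors = FALSE)
    ptm <- mapPtmPeptides(pep, set)
    .writeTsv(ptm$assignments, file.path(cfg$out_dir, "ptm_assignments.tsv"))
    out$ptm <- ptm
  }
  if (isTRUE(cfg$run_clades) && "H2A.Z" %in% res$calls$label &&
      nrow(res$calls) >= 4) {
    labelled <- set
    labelled@truth <- stats::setNames(res$calls$label, res$calls$record_id)
    mono <- classMonophyly(labelled)
    writeNewick(mono$tree, file.path(cfg$out_dir, "tree.nwk"))
    out$monophyly <- mono$monophyly
  }

  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  files <- sort(setdiff(list.files(cfg$out_dir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))),
    stringsAsFactors = FALSE)
  .writeTsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  out$manifest <- manifest
  out
}
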