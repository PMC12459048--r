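## Synthetic protein generator: per-class templates with planted signatures,
## i.i.d. substitutions outside signature positions and single-residue indels
## at region junctions.

#' Specification for the synthetic sequence generator
#'
#' @param class_counts Named integer vector, variant class -> number of
#'   sequences to generate. Names must be a subset of [h2aClasses()].
#' @param substitution_rate Per-residue substitution probability applied to
#'   non-signature positions, in `[0, 1]`.
#' @param indel_rate Per-junction probability of a length-1 insertion or
#'   deletion at an inter-region junction, in `[0, 1]`.
#' @param seed Integer master seed; the same spec and seed always produce
#'   byte-identical output.
#' @return A validated list of class `"SyntheticSpec"`.
#' @export
#' @examples
#' syntheticSpec(c(H2A.Z = 5, H2A.O = 5), 0.05, 0.05, seed = 1)
syntheticSpec <- function(class_counts, substitution_rate = 0,
                          indel_rate = 0, seed = 1L) {
  if (length(class_counts) > 0) {
    if (is.null(names(class_counts)) || any(!nzchar(names(class_counts))))
      stop("class_counts must be named by variant class")
    bad <- setdiff(names(class_counts), H2A_CLASSES)
    if (length(bad)) stop("unsupported H2A class: ", paste(bad, collapse = ", "))
    if (any(class_counts < 0)) stop("class counts must be >= 0")
  }
  if (substitution_rate < 0 || substitution_rate > 1)
    stop("substitution_rate must be in [0, 1]")
  if (indel_rate < 0 || indel_rate > 1)
    stop("indel_rate must be in [0, 1]")
  structure(list(class_counts = class_counts,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

## Apply the mutation model to a template; assumes RNG state is set.
## Returns list(sequence, coords) with updated 0-based half-open coords.
.mutateTemplate <- function(tpl, substitution_rate, indel_rate) {
  chars <- strsplit(tpl$sequence, "")[[1]]
  mask <- tpl$mask
  if (substitution_rate > 0) {
    hit <- which(!mask & stats::runif(length(chars)) < substitution_rate)
    for (i in hit) {
      alt <- AA20[AA20 != chars[i]]
      chars[i] <- alt[sample.int(19L, 1L)]
    }
  }
  lens <- vapply(tpl$regions, nchar, integer(1))
  region_chars <- split(chars, rep(seq_along(lens), lens))
  region_mask <- split(mask, rep(seq_along(lens), lens))
  if (indel_rate > 0) {
    ## junctions sit between consecutive regions (8 of them)
    for (j in seq_len(length(lens) - 1L)) {
      if (stats::runif(1) >= indel_rate) next
      if (stats::runif(1) < 0.5) {          # insertion, assigned upstream
        ins <- AA20[sample.int(20L, 1L)]
        region_chars[[j]] <- c(region_chars[[j]], ins)
        region_mask[[j]] <- c(region_mask[[j]], FALSE)
      } else {                              # deletion of an unmasked flank residue
        up <- region_mask[[j]]; dn <- region_mask[[j + 1L]]
        if (length(up) > 0 && !up[length(up)]) {
          region_chars[[j]] <- region_chars[[j]][-length(up)]
          region_mask[[j]] <- up[-length(up)]
        } else if (length(dn) > 0 && !dn[1L]) {
          region_chars[[j + 1L]] <- region_chars[[j + 1L]][-1L]
          region_mask[[j + 1L]] <- dn[-1L]
        }                                   # both flanks protected: skip
      }
    }
  }
  new_lens <- vapply(region_chars, length, integer(1))
  ends <- cumsum(new_lens); starts <- ends - new_lens
  coords <- Map(function(s, e) c(s, e), starts, ends)
  names(coords) <- names(tpl$regions)
  list(sequence = paste0(unlist(region_chars), collapse = ""), coords = coords)
}

#' Generate one synthetic H2A protein of a given class
#'
#' Applies the spec's mutation model to the class template. Signature
#' positions are masked from substitution, so the class-defining motifs stay
#' intact at any substitution rate; indels (length 1) occur only at region
#' junctions.
#'
#' @param class_label One of [h2aClasses()].
#' @param spec A [syntheticSpec()].
#' @param id Record id to assign (default derived from the class).
#' @return A list with `id`, `sequence`, `class`, and `coords` (region truth,
#'   0-based half-open).
#' @export
#' @examples
#' rec <- makeVariantSequence("H2A.Z", syntheticSpec(c(H2A.Z = 1)))
#' grepl("LEYLTAEVLELAGNA", rec$sequence)
makeVariantSequence <- function(class_label, spec, id = NULL) {
  if (!inherits(spec, "SyntheticSpec")) stop("spec must be a syntheticSpec()")
  tpl <- classTemplate(class_label)
  mut <- withStreamSeed(spec$seed, paste0("seq:", class_label, ":", id %||% ""),
                        .mutateTemplate(tpl, spec$substitution_rate,
                                        spec$indel_rate))
  list(id = id %||% class_label, sequence = mut$sequence,
       class = class_label, coords = mut$coords)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a labelled benchmark set of synthetic H2A proteins
#'
#' @param spec A [syntheticSpec()] giving per-class counts, noise rates and
#'   the master seed.
#' @return An [H2ASet-class] whose `truth` and `regionTruth` record the
#'   planted class labels and region coordinates.
#' @export
#' @examples
#' bench <- makeBenchmarkSet(syntheticSpec(c(H2A.Z = 3, H2A.X = 3), 0.02))
#' table(truthLabels(bench))
makeBenchmarkSet <- function(spec) {
  if (!inherits(spec, "SyntheticSpec")) stop("spec must be a syntheticSpec()")
  seqs <- character(); truth <- character(); rtruth <- list()
  for (cls in names(spec$class_counts)) {
    n <- spec$class_counts[[cls]]
    if (n == 0) next
    for (i in seq_len(n)) {
      id <- sprintf("%s_%03d", gsub("\\.", "", cls), i)
      rec <- makeVariantSequence(cls, spec, id = id)
      seqs[[id]] <- rec$sequence
      truth[[id]] <- cls
      rtruth[[id]] <- rec$coords
    }
  }
  new("H2ASet",
      sequences = Biostrings::AAStringSet(seqs),
      truth = truth, regionTruth = rtruth,
      species = character())
}

#' Write a benchmark set to disk
#'
#' Writes the sequences as FASTA and the truth labels (plus region truth) as
#' JSON alongside.
#'
#' @param set An [H2ASet-class].
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
writeBenchmarkSet <- function(set, dir, prefix = "benchmark") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".faa"))
  Biostrings::writeXStringSet(sequences(set), fasta)
  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(list(truth = as.list(truthLabels(set)),
                            regions = regionTruth(set)),
                       truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, truth = truth_path))
}
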