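## Signature-combination classifier. The decision order encodes: macro-domain
## length first, then the alpha2-helix family split (H2A.Z-like signature ->
## Z family, refined into H2A.O / H2A.Z / H2A.E), then the C-terminal / L1 /
## alphaN specializations (H2A.X, H2A.W, H2A.M, H2A.N), with RC H2A as the
## residual for fold-bearing proteins with canonical docking or K-rich
## C-tails. Every rule evaluated is recorded in the evidence trace.

#' Classifier configuration
#'
#' @param alpha2_tol Maximum alpha2 signature mismatches for the Z family
#'   (default 2).
#' @param alphaN_tol Maximum QSLRA mismatches for H2A.N (default 1).
#' @param kg_run_min,kg_frac_min,kg_len_min K/G-rich N-tail thresholds: rich
#'   when the longest K/G run is at least `kg_run_min` (default 6) or the
#'   K+G fraction is at least `kg_frac_min` (default 0.5) over an N-tail of
#'   at least `kg_len_min` (default 10) residues.
#' @param ntail_long_min Minimum N-tail length for H2A.N (default 45).
#' @param macro_ctail_min Minimum C-tail length for macroH2A (default 100).
#' @param kde_frac_min Minimum C-tail lysine fraction for the RC residual
#'   rule (default 0.3).
#' @return A validated list of class `"ClassifierConfig"`.
#' @export
classifierConfig <- function(alpha2_tol = 2L, alphaN_tol = 1L,
                             kg_run_min = 6L, kg_frac_min = 0.5,
                             kg_len_min = 10L, ntail_long_min = 45L,
                             macro_ctail_min = 100L, kde_frac_min = 0.3) {
  stopifnot(alpha2_tol >= 0, alphaN_tol >= 0, kg_run_min >= 1,
            kg_frac_min >= 0, kg_frac_min <= 1, ntail_long_min >= 0,
            macro_ctail_min >= 0, kde_frac_min >= 0, kde_frac_min <= 1)
  structure(list(alpha2_tol = alpha2_tol, alphaN_tol = alphaN_tol,
                 kg_run_min = kg_run_min, kg_frac_min = kg_frac_min,
                 kg_len_min = kg_len_min, ntail_long_min = ntail_long_min,
                 macro_ctail_min = macro_ctail_min,
                 kde_frac_min = kde_frac_min),
            class = "ClassifierConfig")
}

.kgRich <- function(fv, config) {
  isTRUE(fv$ntail_length >= config$kg_len_min) &&
    (isTRUE(fv$ntail_kg_maxrun >= config$kg_run_min) ||
       isTRUE(fv$ntail_kg_frac >= config$kg_frac_min))
}

#' Classify one feature vector
#'
#' Applies the decision procedure and returns the label, a tier
#' (strong when every defining rule for the label fired, weak when the call
#' rested on a single rule) and the full ordered evidence trace.
#'
#' @param fv One FeatureVector row from [extractFeatures()].
#' @param config A [classifierConfig()].
#' @return A list with `record_id`, `label`, `tier` and `evidence`
#'   (data.frame of rule, fired, observed).
#' @export
#' @examples
#' tpl <- classTemplate("H2A.O")
#' fa <- anchorToProfile(tpl$sequence, record_id = "o")
#' classifyVariant(extractFeatures(tpl$sequence, fa, "o"))$label
classifyVariant <- function(fv, config = classifierConfig()) {
  ev <- list()
  note <- function(rule, fired, observed) {
    ev[[length(ev) + 1L]] <<- data.frame(
      rule = rule, fired = fired, observed = as.character(observed),
      stringsAsFactors = FALSE)
    fired
  }
  finish <- function(label, tier) {
    list(record_id = fv$record_id, label = label, tier = tier,
         evidence = do.call(rbind, ev))
  }
  if (note("fold_detected", !isTRUE(fv$fold_missing), fv$fold_missing) == FALSE)
    return(finish("unclassified", "weak"))
  if (note("macro_ctail", fv$ctail_length >= config$macro_ctail_min,
           fv$ctail_length))
    return(finish("macroH2A", "strong"))
  z_family <- note("alpha2_signature", fv$alpha2_mismatches <= config$alpha2_tol,
                   fv$alpha2_mismatches)
  if (z_family) {
    kg <- note("kg_rich_ntail", .kgRich(fv, config),
               paste0("run=", fv$ntail_kg_maxrun, ",frac=",
                      round(fv$ntail_kg_frac, 3)))
    o_end <- note("cterm_O_end", identical(fv$cterm_class, "O_end"),
                  fv$cterm_class)
    if (kg && o_end) return(finish("H2A.O", "strong"))
    votes <- c(
      note("docking_two_his", isTRUE(fv$docking_his_count == 2L),
           fv$docking_his_count),
      note("patch_first_gly", identical(fv$acidic_patch_first, "G"),
           fv$acidic_patch_first),
      note("cterm_Z_end", identical(fv$cterm_class, "Z_end"), fv$cterm_class))
    if (note("z_vote", sum(votes) >= 2L, sum(votes)))
      return(finish("H2A.Z", if (all(votes)) "strong" else "weak"))
    return(finish("H2A.E", "weak"))
  }
  if (note("cterm_X_like", fv$cterm_class %in% c("X_end", "O_end"),
           fv$cterm_class))
    return(finish("H2A.X", "strong"))
  w <- note("cterm_W_end", identical(fv$cterm_class, "W_end"), fv$cterm_class) &
    note("l1_WM_motif", fv$l1_motif_class %in% c("W_like", "M_like"),
         fv$l1_motif_class)
  if (w) return(finish("H2A.W", "strong"))
  if (note("l1_M_motif", identical(fv$l1_motif_class, "M_like"),
           fv$l1_motif_class))
    return(finish("H2A.M", "weak"))
  n <- note("alphaN_QSLRA", fv$alphaN_mismatches <= config$alphaN_tol,
            fv$alphaN_mismatches) &
    note("long_ntail", fv$ntail_length >= config$ntail_long_min,
         fv$ntail_length)
  if (n) return(finish("H2A.N", "strong"))
  dock <- note("docking_VLLPKK", isTRUE(fv$docking_end_match),
               fv$docking_end_match)
  krich <- note("ctail_k_rich", isTRUE(fv$ctail_k_frac >= config$kde_frac_min),
                round(fv$ctail_k_frac, 3))
  if (dock || krich)
    return(finish("RC_H2A", if (dock && krich) "strong" else "weak"))
  finish("unclassified", "weak")
}

#' Classify a table of feature vectors
#'
#' @param fvs FeatureVector `data.frame` from [extractFeatureTable()].
#' @param config A [classifierConfig()].
#' @return A list with `calls` (record_id, label, tier data.frame),
#'   `counts` (per-class table summing to `nrow(fvs)`) and `evidence`
#'   (named list of evidence traces).
#' @export
classifyBatch <- function(fvs, config = classifierConfig()) {
  labels_all <- c(H2A_CLASSES, "unclassified")
  if (is.null(fvs) || nrow(fvs) == 0) {
    return(list(calls = data.frame(record_id = character(),
                                   label = character(), tier = character()),
                counts = table(factor(character(), levels = labels_all)),
                evidence = list()))
  }
  res <- lapply(seq_len(nrow(fvs)), function(i)
    classifyVariant(fvs[i, , drop = FALSE], config))
  calls <- data.frame(
    record_id = vapply(res, `[[`, character(1), "record_id"),
    label = vapply(res, `[[`, character(1), "label"),
    tier = vapply(res, `[[`, character(1), "tier"),
    stringsAsFactors = FALSE)
  evidence <- lapply(res, `[[`, "evidence")
  names(evidence) <- calls$record_id
  list(calls = calls,
       counts = table(factor(calls$label, levels = labels_all)),
       evidence = evidence)
}

#' Confusion matrix of calls against truth labels
#'
#' @param calls The `calls` data.frame from [classifyBatch()].
#' @param truth Named character vector of truth labels.
#' @return A contingency table truth x called.
#' @export
confusionMatrix <- function(calls, truth) {
  lv <- c(H2A_CLASSES, "unclassified")
  table(truth = factor(truth[calls$record_id], levels = lv),
        called = factor(calls$label, levels = lv))
}
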