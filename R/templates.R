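## Per-class H2A templates.
##
## Each H2A variant class is represented by one hand-built template assembled
## region by region (N-tail, alphaN, alpha1, L1, alpha2, L2, alpha3, docking
## domain, C-tail). The diagnostic signatures of each class are planted
## verbatim:
##   H2A.Z/E/O  - LEYLTAEVLELAGNA in the alpha2 helix; L1 one residue longer
##                and docking one residue shorter (H2A.Z) with two histidines;
##                acidic patch opening with G (H2A.Z) or N (H2A.E/O).
##   H2A.X      - SQ[D/E][F/Y] at the very end of the C-tail.
##   H2A.O      - K/G-rich N-tail stretch plus terminal SQDY.
##   H2A.N      - N-tail extended by ~30 residues with a PLRP motif and a
##                QSLRA alphaN motif; K/D/E-enriched C-tail.
##   H2A.W      - RYS[Q/K]-type L1 plus terminal KSPKK.
##   H2A.M      - RYA[Q/K] L1.
##   macroH2A   - long (~110 aa) macro-domain-bearing C-tail.
##   RC H2A     - lysine-enriched C-tail and a VLLPKK docking ending.
## Non-Z-family alpha2 blocks sit at Hamming distance 4 from the H2A.Z
## signature so that the family split at the default tolerance of 2
## mismatches is unambiguous.
##
## `mask` marks signature positions that the mutation model never touches.

H2A_CLASSES <- c("RC_H2A", "H2A.X", "H2A.Z", "H2A.E", "H2A.O",
                 "H2A.N", "H2A.W", "H2A.M", "macroH2A")

ALPHA2_Z  <- "LEYLTAEVLELAGNA"
ALPHA2_RC <- "LEYLIAENLELVGNS"   # distance 4 from the H2A.Z signature

.MACRO_CTAIL <- paste0(
  "KTESHKELVSKGSKLEAVSNAAGLEVIRTASPDFEVTSLKAGDNLEATVGNKLDLIKSEVP",
  "NATLGDVTKLSVGEALSAHKDLFAVTEGKAPVSELAGTAARDNSKTRA")  # 109 aa + "GKA" below

.templateDefs <- function() {
  rc_dock <- "NDEEDELNKLLGGVTIAQGSPNIQAVLLPKK"
  list(
    RC_H2A = list(
      n_tail = "SGRGKQGGKARAKAKS", alphaN = "AGNYAERVGA",
      alpha1 = "GAPVYLAAVLE", L1 = "NDEEL",
      alpha2 = paste0("AG", ALPHA2_RC, "AR"), L2 = "DNKKTR",
      alpha3 = "IIPRNLQLA", docking = rc_dock,
      c_tail = "KTESKSKAKGKKGSKA"),
    H2A.X = list(
      n_tail = "ATSGRGKTGGKAKSRS", alphaN = "AGNYAERVGA",
      alpha1 = "GAPVYLAAVME", L1 = "NDEEL",
      alpha2 = paste0("AG", ALPHA2_RC, "AR"), L2 = "DNKKTR",
      alpha3 = "IIPRNLQLA", docking = rc_dock,
      c_tail = "GKKASGGKAGSQASQEY"),
    H2A.Z = list(
      n_tail = "AGGKAGKDSGKAKAKAVSRS", alphaN = "SRSQRAGLQF",
      alpha1 = "PAGRIHRHLK", L1 = "TSHGRV",
      alpha2 = paste0("AG", ALPHA2_Z, "SK"), L2 = "DSLIKA",
      alpha3 = "TIPRHLQLA", docking = "GDEEDEHLNKLIGHVTIASGGVKTIAGSPK",
      c_tail = "KATQKSGGKKRI"),
    H2A.E = list(
      n_tail = "AGTRSTSAKSGLTESA", alphaN = "SRAQRAGLQF",
      alpha1 = "PAGRVHRLLK", L1 = "TSNGKV",
      alpha2 = paste0("AG", ALPHA2_Z, "SK"), L2 = "DSLIKA",
      alpha3 = "TIPRNLQLA", docking = "NDEEDENLNKLIGHVTIASGGVKTIAGSPKA",
      c_tail = "SKSAAGTKAVSA"),
    H2A.O = list(
      n_tail = "AGGKGGKGGKGGKGAKSRSS", alphaN = "SRAQRAGLQF",
      alpha1 = "PAGRVHRLLK", L1 = "TSNGRV",
      alpha2 = paste0("AG", ALPHA2_Z, "SK"), L2 = "DSLIKA",
      alpha3 = "TIPRNLQLA", docking = "NDEEDENLNKLIGHVTIASGGVKTIAGSPKA",
      c_tail = "GKKGSATSQDY"),
    H2A.N = list(
      n_tail = "ATPLRPSGKGDAAKSGSKSAAKGTRSSKAGLTFPVGTESGKSKSAKSA",
      alphaN = "AQSLRAVGAG",
      alpha1 = "GAPVYLAAVLE", L1 = "NDEEL",
      alpha2 = paste0("AG", ALPHA2_RC, "AR"), L2 = "DNKKTR",
      alpha3 = "IIPRNLQLA", docking = rc_dock,
      c_tail = "KDESKDKAKEDKSKGA"),
    H2A.W = list(
      n_tail = "ATSKGGKSGSAKARAK", alphaN = "AGNYSERVGA",
      alpha1 = "GAPVYLAAVLE", L1 = "RYSQK",
      alpha2 = paste0("AG", ALPHA2_RC, "AR"), L2 = "DNKKTR",
      alpha3 = "IVPRNLQLA", docking = "NDEEDELNKLLGGVTIAQGSPNIQASVLPKK",
      c_tail = "SATGGKKSPKK"),
    H2A.M = list(
      n_tail = "ASTKGAKSGSAKSRAK", alphaN = "AGNYTERVGA",
      alpha1 = "GAPVYLAAVLE", L1 = "RYAQT",
      alpha2 = paste0("AG", ALPHA2_RC, "AR"), L2 = "DNKKTR",
      alpha3 = "IVPRNLQLA", docking = "NDEEDELNKLLGGVTIAQGSPNIQASVLPKA",
      c_tail = "AVSKTESGKAAK"),
    macroH2A = list(
      n_tail = "SGRGKTGGKARAKAKS", alphaN = "AGNYAERVGA",
      alpha1 = "GAPVYLAAVLE", L1 = "NDEEL",
      alpha2 = paste0("AG", ALPHA2_RC, "AR"), L2 = "DNKKTR",
      alpha3 = "IIPRNLQLA", docking = rc_dock,
      c_tail = paste0(.MACRO_CTAIL, "GKA"))
  )
}

## Mask of protected (signature) positions, per region, for one class.
.templateMask <- function(class_label, regions) {
  m <- lapply(regions, function(s) rep(FALSE, nchar(s)))
  maskAll <- function(r) m[[r]][] <<- TRUE
  maskPos <- function(r, idx) m[[r]][idx] <<- TRUE
  maskLastN <- function(r, k) {
    len <- nchar(regions[[r]])
    maskPos(r, max(1L, len - k + 1L):len)
  }
  maskAll("alpha2")                       # family-defining helix block
  maskPos("docking", 1:6)                 # acidic patch block
  maskLastN("docking", 6L)                # VLLPKK-type docking ending
  maskLastN("c_tail", 5L)                 # terminal motifs
  if (class_label %in% c("H2A.Z", "H2A.E", "H2A.O"))
    maskPos("docking", c(7L, 14L))        # histidine / asparagine sites
  if (class_label %in% c("H2A.W", "H2A.M")) maskAll("L1")
  if (class_label == "H2A.N") {
    maskAll("alphaN")                     # QSLRA motif
    maskPos("n_tail", 3:6)                # PLRP motif
    maskAll("c_tail")                     # K/D/E enrichment
  }
  if (class_label == "H2A.O") maskPos("n_tail", 2:14)  # K/G-rich stretch
  m
}

#' Variant classes supported by the package
#'
#' @return Character vector of the nine supported H2A variant class labels.
#' @export
#' @examples
#' h2aClasses()
h2aClasses <- function() H2A_CLASSES

#' Per-class H2A sequence templates
#'
#' Returns the hand-built template for one variant class: its region sequences
#' (in fold order N-tail through C-tail), the assembled full-length sequence,
#' the 0-based half-open region coordinates, and the logical mask of protected
#' signature positions used by the mutation model.
#'
#' @param class_label One of [h2aClasses()].
#' @return A list with elements `class`, `sequence`, `regions` (named list of
#'   region strings), `coords` (named list of `c(start, end)` 0-based
#'   half-open), and `mask` (logical vector over the full sequence).
#' @export
#' @examples
#' tpl <- classTemplate("H2A.Z")
#' substr(tpl$sequence, tpl$coords$alpha2[1] + 1, tpl$coords$alpha2[2])
classTemplate <- function(class_label) {
  defs <- .templateDefs()
  if (!class_label %in% names(defs))
    stop("unsupported H2A class: ", class_label)
  regions <- defs[[class_label]]
  mask_by_region <- .templateMask(class_label, regions)
  lens <- vapply(regions, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  coords <- Map(function(s, e) c(s, e), starts, ends)
  list(class = class_label,
       sequence = paste0(unlist(regions), collapse = ""),
       regions = regions,
       coords = coords,
       mask = unlist(mask_by_region, use.names = FALSE))
}
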