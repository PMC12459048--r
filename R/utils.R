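## Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

REGION_ORDER <- c("n_tail", "alphaN", "alpha1", "L1", "alpha2",
                  "L2", "alpha3", "docking", "c_tail")
FOLD_REGIONS <- c("alphaN", "alpha1", "L1", "alpha2", "L2", "alpha3", "docking")

## Deterministic per-generator stream seed derived from a master seed and a
## stream name; keeps independent generators decoupled while staying fully
## reproducible from one integer. Result always fits a 32-bit signed int.
streamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647)
}

withStreamSeed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(streamSeed(seed, stream))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

.checkResidues <- function(x, what = "sequence", allow_x = TRUE) {
  ok <- c(AA20, if (allow_x) "X")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), ok)
  if (length(bad) > 0)
    stop(what, " contains non-residue characters: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

## Minimum Hamming distance between `motif` and any window of `region`
## (region optionally extended by `ext` residues on each side within `seq`).
## Returns nchar(motif) when no full-length window exists.
minHammingWindow <- function(seq, start, end, motif, ext = 0L) {
  n <- nchar(seq)
  a <- max(1L, start - ext)
  b <- min(n, end + ext)
  k <- nchar(motif)
  if (b - a + 1L < k) return(k)
  sub <- strsplit(substr(seq, a, b), "")[[1]]
  mot <- strsplit(motif, "")[[1]]
  best <- k
  for (off in 0:(length(sub) - k)) {
    d <- sum(sub[off + seq_len(k)] != mot)
    if (d < best) best <- d
  }
  best
}

## Longest common subsequence length of two character vectors.
lcsLength <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
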