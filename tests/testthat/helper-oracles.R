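## Independent oracles used to cross-check the package implementations.
## These are deliberately written as plain, exhaustive procedures that share
## no code with the functions they validate.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

randomProtein <- function(len) paste0(sample(AA, len, replace = TRUE),
                                      collapse = "")

## exhaustive window scan: does any window of `seq` match the motif given as
## a list of allowed residue sets per position?
oracleWindowMatch <- function(seq, allowed) {
  ch <- strsplit(seq, "")[[1]]
  k <- length(allowed)
  if (length(ch) < k) return(FALSE)
  for (off in 0:(length(ch) - k)) {
    ok <- TRUE
    for (p in seq_len(k)) {
      if (!ch[off + p] %in% allowed[[p]]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

## does the sequence END with the motif (allowed residue sets, rightmost
## position last)?
oracleEndsWith <- function(seq, allowed) {
  ch <- strsplit(seq, "")[[1]]
  k <- length(allowed)
  if (length(ch) < k) return(FALSE)
  tail_ch <- ch[(length(ch) - k + 1):length(ch)]
  all(vapply(seq_len(k), function(p) tail_ch[p] %in% allowed[[p]],
             logical(1)))
}

## exhaustive minimum Hamming distance over all full-length windows of a
## substring of seq (1-based inclusive bounds, extended by ext within seq)
oracleMinHamming <- function(seq, start, end, motif, ext = 0) {
  ch <- strsplit(seq, "")[[1]]
  a <- max(1, start - ext); b <- min(length(ch), end + ext)
  mot <- strsplit(motif, "")[[1]]
  k <- length(mot)
  if (b - a + 1 < k) return(k)
  best <- k
  for (s in a:(b - k + 1)) {
    d <- 0
    for (p in seq_len(k)) if (ch[s + p - 1] != mot[p]) d <- d + 1
    if (d < best) best <- d
  }
  best
}

## naive affine-gap DP oracle: global on the profile columns, local on the
## sequence; plain three-matrix loops, no vectorization
oracleProfileScore <- function(chars, freqs, open = 11, extend = 1,
                               eps = 1e-3, background = 0.05) {
  n <- length(chars); m <- ncol(freqs)
  s <- function(i, j) {
    if (!chars[i] %in% rownames(freqs)) return(0)
    log2(freqs[chars[i], j] + eps) - log2(background)
  }
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m); X <- matrix(NEG, n + 1, m)
  Y <- matrix(NEG, n + 1, m)
  ## row index i+1 holds "i residues consumed"; the free-prefix boundary
  ## state (any i, zero columns) has score 0
  for (j in 1:m) {
    for (i in 0:n) {
      if (i > 0) {
        prev <- if (j == 1) 0 else max(M[i, j - 1], X[i, j - 1], Y[i, j - 1])
        M[i + 1, j] <- s(i, j) + prev
      }
      X[i + 1, j] <- if (j == 1) -open else
        max(max(M[i + 1, j - 1], Y[i + 1, j - 1]) - open,
            X[i + 1, j - 1] - extend)
      if (i > 0)
        Y[i + 1, j] <- max(max(M[i, j], X[i, j]) - open, Y[i, j] - extend)
    }
  }
  max(M[, m], X[, m], Y[, m])
}

## recursive memoized LCS (independent of the package's rolling-array DP)
oracleLCS <- function(a, b) {
  memo <- new.env()
  go <- function(i, j) {
    if (i == 0 || j == 0) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (a[i] == b[j]) go(i - 1L, j - 1L) + 1L
         else max(go(i - 1L, j), go(i, j - 1L))
    memo[[key]] <- v
    v
  }
  go(length(a), length(b))
}

## union-find cluster oracle: histone genes on a contig are linked when the
## inter-gene gap is at most max_gap; components spanning >= min_families
## distinct families are clusters (returned as sorted gene-id strings)
oracleClusters <- function(genes, max_gap = 20000, min_families = 2) {
  hist <- genes[genes$product_class %in% c("H1", "H2A", "H2B", "H3", "H4"), ]
  out <- character()
  for (ctg in unique(paste(hist$genome_id, hist$contig, sep = "\r"))) {
    parts <- strsplit(ctg, "\r")[[1]]
    sub <- hist[hist$genome_id == parts[1] & hist$contig == parts[2], ]
    n <- nrow(sub)
    if (n == 0) next
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      gap <- max(sub$start[i], sub$start[j]) - min(sub$end[i], sub$end[j])
      if (gap <= max_gap) parent[find(i)] <- find(j)
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cp in unique(comp)) {
      members <- which(comp == cp)
      if (length(unique(sub$product_class[members])) >= min_families)
        out <- c(out, paste(sort(sub$gene_id[members]), collapse = ","))
    }
  }
  sort(out)
}

## brute-force monophyly oracle: walk the rooted tree's edge table and
## collect every subtree leaf set
oracleCladeSets <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  leaves <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], leaves))
  }
  nodes <- unique(tree$edge[, 1])
  sets <- lapply(c(seq_len(n_tip), nodes), leaves)
  lapply(sets, sort)
}

oracleIsClade <- function(tree, leaf_set) {
  target <- sort(leaf_set)
  any(vapply(oracleCladeSets(tree), identical, logical(1), target))
}

## fixed-seed benchmark spec used by several test files
benchSpec <- function(per_class = 5L, sub = 0.05, indel = 0.05, seed = 101L) {
  syntheticSpec(stats::setNames(rep(per_class, length(h2aClasses())),
                                h2aClasses()),
                substitution_rate = sub, indel_rate = indel, seed = seed)
}
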