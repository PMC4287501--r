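# Independent brute-force oracles. These deliberately avoid the code
# paths of the package: regex scanning instead of integer k-mer codes,
# choose() enumeration instead of fisher.test, explicit rank formulas
# instead of kruskal.test.

# random A/C/G/T sequences as a named character vector
randomSeqs <- function(n, len, seed, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  setNames(
    vapply(seq_len(n), function(i)
      paste(sample(alphabet, len, replace = TRUE), collapse = ""), ""),
    sprintf("s%03d", seq_len(n)))
}

# overlapping dimer instances via a lookahead regex on a concatenated
# subject; "X" separators make cross-boundary matches impossible
oracleCountDimer <- function(seqs, w1, spacer) {
  subject <- paste(as.character(seqs), collapse = "X")
  w2 <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(w1)))
  pat <- paste0("(?=", w1,
                if (spacer > 0) paste0("[ACGT]{", spacer, "}") else "",
                w2, ")")
  m <- gregexpr(pat, subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

# overlapping word occurrences by sliding substring comparison
oracleCountWord <- function(seqs, word) {
  w <- nchar(word)
  sum(vapply(as.character(seqs), function(s) {
    L <- nchar(s)
    if (L < w) return(0L)
    sum(vapply(seq_len(L - w + 1L),
               function(i) substr(s, i, i + w - 1L) == word, NA))
  }, 0L))
}

# hypergeometric point probability of a 2x2 table from choose()
oracleTableProb <- function(a, b, c, d) {
  choose(a + b, a) * choose(c + d, c) / choose(a + b + c + d, a + c)
}

# one-sided (enrichment) exact p: sum over tables at least as extreme
oracleFisherGreater <- function(a, b, c, d) {
  hi <- min(a + b, a + c)
  sum(vapply(a:hi, function(k)
    oracleTableProb(k, a + b - k, a + c - k, d - a + k), 0))
}

# two-sided exact p: sum of probabilities <= observed (with the same
# relative slack fisher.test documents)
oracleFisherTwoSided <- function(a, b, c, d) {
  lo <- max(0L, a - d)
  hi <- min(a + b, a + c)
  probs <- vapply(lo:hi, function(k)
    oracleTableProb(k, a + b - k, a + c - k, d - a + k), 0)
  obs <- probs[a - lo + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Kruskal-Wallis H for tie-free data from the rank-sum formula
oracleKWStatistic <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)
  rs <- tapply(r, idx, sum)
  12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
}

# expand an IUPAC consensus into all concrete A/C/G/T words
oracleExpandIUPAC <- function(consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  sets <- strsplit(map[strsplit(consensus, "")[[1L]]], "")
  apply(do.call(expand.grid, c(sets, stringsAsFactors = FALSE)), 1L,
        paste, collapse = "")
}

# Poisson upper tail from the explicit partial sum
oraclePoissonTail <- function(k, lambda) {
  if (k == 0) return(1)
  1 - sum(exp(-lambda) * lambda^(0:(k - 1)) / factorial(0:(k - 1)))
}
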