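## Randomization controls and known-motif comparison.

#' Shuffle a sequence within fixed-size windows
#'
#' Splits each sequence into consecutive non-overlapping windows (the
#' last may be short) and permutes the bases uniformly at random within
#' each window independently, preserving local nucleotide composition.
#' Deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param x character vector or `DNAStringSet`/`PromoterSet`.
#' @param windowSize window width in nt (default 20).
#' @param seed required integer seed.
#' @return object of the same class as `x`, same names, widths and
#'   per-window base multisets.
#' @export
windowShuffle <- function(x, windowSize = 20L, seed) {
  stopifnot(windowSize >= 1L)
  isSet <- is(x, "XStringSet")
  chr <- as.character(x)
  shuffled <- .withSeed(seed, {
    vapply(chr, function(s) {
      b <- strsplit(s, "", fixed = TRUE)[[1L]]
      L <- length(b)
      if (L > 1L) {
        win <- (seq_len(L) - 1L) %/% windowSize
        for (wi in unique(win)) {
          i <- which(win == wi)
          if (length(i) > 1L) b[i] <- b[sample(i)]
        }
      }
      paste(b, collapse = "")
    }, "", USE.NAMES = FALSE)
  })
  if (isSet) {
    out <- DNAStringSet(shuffled)
    names(out) <- names(x)
    if (is(x, "PromoterSet")) {
      ps <- new("PromoterSet", out)
      mcols(ps) <- mcols(x)
      return(ps)
    }
    return(out)
  }
  stats::setNames(shuffled, names(x))
}

#' Real-versus-shuffled re-discovery control
#'
#' Runs the full dimer discovery on the promoters and on a
#' window-shuffled copy (by default re-estimating `N_motif` and alpha
#' on the shuffled data), computes per-promoter TFBS counts for both,
#' and compares the two distributions with a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test. On biological (or planted) signal the
#' shuffled counts are stochastically smaller; on signal-free input
#' the two distributions should not differ.
#'
#' @param promoters a `PromoterSet`.
#' @param seed integer seed for the shuffle.
#' @param windowSize shuffle window (default 20 nt).
#' @param mode counting mode, see [promoterTFBSCounts()].
#' @param reuseAlpha reuse the real-data significance threshold on the
#'   shuffled scan instead of recomputing it (default `FALSE`).
#' @param ... passed to [scanDimers()] (candidate space, expected-count
#'   form).
#' @return `list(realScan, shuffledScan, counts, test)` where `counts`
#'   is a `data.frame(promoter_id, real, shuffled)` and `test` holds
#'   the Mann-Whitney statistic and p-value.
#' @export
shuffledRediscovery <- function(promoters, seed, windowSize = 20L,
                                mode = c("distinct", "occurrences"),
                                reuseAlpha = FALSE, ...) {
  mode <- match.arg(mode)
  if (!length(promoters)) stop("empty promoter set")
  realScan <- scanDimers(promoters, ...)
  shuf <- windowShuffle(promoters, windowSize, seed)
  shufScan <- scanDimers(shuf, ...)
  if (reuseAlpha) {
    m <- shufScan@motifs
    m$significant <- m$log_p < log(realScan@alpha)
    shufScan@motifs <- m
    shufScan@alpha <- realScan@alpha
  }
  realCounts <- promoterTFBSCounts(realScan, mode)
  shufCounts <- promoterTFBSCounts(shufScan, mode)
  wt <- suppressWarnings(stats::wilcox.test(realCounts, shufCounts))
  # fully tied samples (e.g. no motif called on either side) carry no
  # evidence of a difference
  if (is.na(wt$p.value)) wt$p.value <- 1
  list(realScan = realScan, shuffledScan = shufScan,
       counts = data.frame(promoter_id = names(realCounts),
                           real = as.integer(realCounts),
                           shuffled = as.integer(shufCounts),
                           stringsAsFactors = FALSE),
       test = list(statistic = unname(wt$statistic), p = wt$p.value))
}

.IUPAC_RE <- "^[ACGTRYSWKMBDHVN]+$"

#' Read a known-motif consensus library
#'
#' Two-column TSV with header `name`, `consensus` (IUPAC nucleotide
#' strings).
#'
#' @param path path to the TSV.
#' @return `data.frame(name, consensus)`.
#' @export
readKnownMotifs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "consensus") %in% names(tab)))
    stop("known-motif table must have columns 'name' and 'consensus'")
  tab$consensus <- toupper(tab$consensus)
  bad <- !grepl(.IUPAC_RE, tab$consensus)
  if (any(bad))
    stop("malformed IUPAC consensus: ",
         paste(tab$name[bad], collapse = ", "))
  tab[, c("name", "consensus")]
}

#' Match predicted sites (or promoters) against known consensus motifs
#'
#' Scans both strands of each subject for exact IUPAC-consensus matches
#' (ambiguity codes in the consensus expand; a consensus N matches any
#' base). In site mode the subjects are the matched site texts and the
#' headline number is the fraction of predicted sites containing at
#' least one known-motif match.
#'
#' @param subjects site-call `data.frame` (from [siteCalls()]) or a
#'   `DNAStringSet`/`PromoterSet` of full promoters.
#' @param knownMotifs `data.frame(name, consensus)`, see
#'   [readKnownMotifs()].
#' @param environments optional per-subject environment labels for the
#'   per-environment count summary (defaults to `PromoterSet`
#'   metadata in promoter mode).
#' @return `list(matches, fraction, perMotif)`: `matches` a logical
#'   subject x motif matrix; `fraction` the share of subjects with at
#'   least one match; `perMotif` a `data.frame` of per-environment
#'   per-motif total match counts (both strands), usable for
#'   [metagenomeDensity()].
#' @export
scanKnownMotifs <- function(subjects, knownMotifs, environments = NULL) {
  bad <- !grepl(.IUPAC_RE, toupper(knownMotifs$consensus))
  if (any(bad))
    stop("malformed IUPAC consensus: ",
         paste(knownMotifs$name[bad], collapse = ", "))
  if (is.data.frame(subjects)) {
    seqs <- DNAStringSet(subjects$matched_seq)
    labels <- subjects$promoter_id
  } else {
    seqs <- as(subjects, "DNAStringSet")
    labels <- names(seqs)
    if (is.null(environments) && is(subjects, "PromoterSet"))
      environments <- environmentLabel(subjects)
  }
  if (is.null(environments)) environments <- rep(NA_character_,
                                                 length(seqs))
  nMot <- nrow(knownMotifs)
  hits <- matrix(0L, nrow = length(seqs), ncol = nMot,
                 dimnames = list(NULL, knownMotifs$name))
  for (j in seq_len(nMot)) {
    pat <- DNAString(toupper(knownMotifs$consensus[j]))
    fwd <- vcountPattern(pat, seqs, fixed = FALSE)
    rev <- vcountPattern(reverseComplement(pat), seqs, fixed = FALSE)
    hits[, j] <- fwd + rev
  }
  matches <- hits > 0L
  perMotif <- do.call(rbind, lapply(unique(environments), function(e) {
    sel <- environments %in% e | (is.na(e) & is.na(environments))
    data.frame(environment = e, motif = knownMotifs$name,
               n_sites = colSums(hits[sel, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(perMotif) <- NULL
  list(matches = matches,
       fraction = if (length(seqs)) mean(rowSums(matches) > 0) else NA_real_,
       perMotif = perMotif, subject_id = labels)
}
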