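## Palindromic dimer discovery.
##
## The scan engine encodes every promoter as integer base codes
## (A=0, C=1, G=2, T=3, N=NA), derives positional k-mer codes per word
## width, and counts all dimers of a given (width, spacer) geometry in
## one vectorized pass: a dimer instance is a position i whose w-mer
## code c satisfies code[i + w + spacer] == rc(c). Promoters are
## concatenated with NA gaps wider than the largest motif so no match
## can cross a boundary.

.BASES <- c("A", "C", "G", "T")

.seqToInts <- function(seqs) {
  ## list of integer vectors, NA at N
  lapply(strsplit(as.character(seqs), "", fixed = TRUE), function(ch) {
    unname(c(A = 0L, C = 1L, G = 2L, T = 3L)[ch])
  })
}

.kmerCodes <- function(ints, w) {
  n <- length(ints)
  if (n < w) return(integer(0))
  m <- stats::embed(ints, w)  # column j holds x[i + w - j]
  codes <- m %*% 4^(0:(w - 1L))
  as.integer(codes)
}

## reverse-complement code map for width w: rcMap[code + 1]
.rcCodeMap <- function(w) {
  x <- 0:(4^w - 1L)
  rc <- integer(length(x))
  for (j in seq_len(w)) {
    d <- x %% 4L
    x <- x %/% 4L
    rc <- rc * 4L + (3L - d)
  }
  rc
}

.codeToWord <- function(code, w) {
  out <- character(length(code))
  x <- code
  for (j in w:1) {
    d <- x %% 4L
    x <- x %/% 4L
    out <- paste0(.BASES[d + 1L], out)
  }
  out
}

.wordToCode <- function(word) {
  ints <- unname(c(A = 0L, C = 1L, G = 2L, T = 3L)[
    strsplit(word, "", fixed = TRUE)[[1L]]])
  sum(ints * 4^(rev(seq_along(ints)) - 1L))
}

## shared positional index over a promoter set
.buildCodeIndex <- function(promoters, widths = 3:5, gap = 41L) {
  ids <- names(promoters)
  if (is.null(ids)) ids <- paste0("seq_", seq_along(promoters))
  lens <- width(promoters)
  intsList <- .seqToInts(promoters)
  n <- length(intsList)
  sep <- rep(NA_integer_, gap)
  pieces <- vector("list", 2L * n)
  starts <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    pieces[[2L * i - 1L]] <- intsList[[i]]
    pieces[[2L * i]] <- sep
    pos <- pos + lens[i] + gap
  }
  ints <- unlist(pieces, use.names = FALSE)
  codes <- lapply(stats::setNames(widths, widths),
                  function(w) .kmerCodes(ints, w))
  list(ids = ids, lens = lens, starts = starts, ints = ints,
       codes = codes, widths = widths)
}

#' Enumerate the candidate palindromic dimer space
#'
#' All dimers with word width `wMin..wMax` and spacer
#' `spacerMin..spacerMax`; exactly `sum(4^w) * nSpacers` candidates, in
#' deterministic order (width, then `w1` lexicographic, then spacer).
#'
#' @param wMin,wMax word width bounds (defaults 3, 5).
#' @param spacerMin,spacerMax spacer bounds (defaults 0, 30).
#' @return `data.frame` with columns `name`, `w`, `spacer`, `w1`, `w2`.
#'   Defaults give 41,664 candidates.
#' @export
enumerateDimers <- function(wMin = 3L, wMax = 5L, spacerMin = 0L,
                            spacerMax = 30L) {
  if (wMin > wMax || spacerMin > spacerMax)
    stop("empty candidate range")
  stopifnot(wMin >= 1L, spacerMin >= 0L)
  out <- vector("list", wMax - wMin + 1L)
  for (w in wMin:wMax) {
    words <- .codeToWord(0:(4^w - 1L), w)
    ## lexicographic == code order since A<C<G<T
    grid <- expand.grid(spacer = spacerMin:spacerMax, w1 = words,
                        stringsAsFactors = FALSE)
    grid <- grid[order(match(grid$w1, words), grid$spacer), ]
    out[[w - wMin + 1L]] <- data.frame(
      w = w, spacer = grid$spacer, w1 = grid$w1,
      w2 = revComp(grid$w1), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- data.frame(name = paste(res$spacer, res$w, res$w1), res,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Encode / decode the compact motif name
#'
#' The compact form is `"<spacer> <width> <w1>"`, e.g. `"10 3 ATC"` for
#' the pattern `ATCNNNNNNNNNNGAT`.
#'
#' @param d a `PalindromicDimer`.
#' @return `encodeMotifName`: the compact name string.
#' @examples
#' encodeMotifName(PalindromicDimer("ATC", 10))  # "10 3 ATC"
#' decodeMotifName("0 3 AAA")
#' @export
encodeMotifName <- function(d) {
  stopifnot(is(d, "PalindromicDimer"))
  paste(d@spacer, nchar(d@w1), d@w1)
}

#' @rdname encodeMotifName
#' @param name a compact name string `"<spacer> <width> <w1>"`.
#' @return `decodeMotifName`: the `PalindromicDimer`.
#' @export
decodeMotifName <- function(name) {
  parts <- strsplit(trimws(name), "\\s+")[[1L]]
  if (length(parts) != 3L)
    stop("malformed motif name: ", name)
  spacer <- suppressWarnings(as.integer(parts[1L]))
  w <- suppressWarnings(as.integer(parts[2L]))
  if (is.na(spacer) || is.na(w))
    stop("malformed motif name: ", name)
  if (w != nchar(parts[3L]))
    stop("motif name width field (", w, ") does not match sequence '",
         parts[3L], "'")
  PalindromicDimer(parts[3L], spacer)
}

#' @rdname encodeMotifName
#' @return `expandedPattern`: the full pattern `w1 N^spacer w2`.
#' @export
expandedPattern <- function(d) {
  stopifnot(is(d, "PalindromicDimer"))
  paste0(d@w1, strrep("N", d@spacer), dimerW2(d))
}

#' Count exact (overlapping) occurrences of a word
#'
#' Counts occurrences of `word` on the stored strand of each promoter,
#' overlaps allowed; positions containing N never match. Delegates to
#' [Biostrings::vcountPattern()].
#'
#' @param promoters a `DNAStringSet`/`PromoterSet`.
#' @param word a word over A/C/G/T.
#' @return total integer count over the whole set.
#' @examples
#' countWord(Biostrings::DNAStringSet("AAAA"), "AAA")  # 2
#' @export
countWord <- function(promoters, word) {
  stopifnot(grepl("^[ACGT]+$", word))
  sum(vcountPattern(word, promoters, fixed = TRUE))
}

#' Count instances of one palindromic dimer and locate its sites
#'
#' A dimer instance is a promoter position where `w1` matches and the
#' reverse complement of `w1` matches `spacer` bases further on.
#' Overlapping instances all count; N never matches.
#'
#' @param promoters a `DNAStringSet`/`PromoterSet`.
#' @param dimer a `PalindromicDimer`.
#' @return `list(n_obs, sites)` where `sites` is a `data.frame` with
#'   `promoter_id`, `start` (0-based), `end` (half-open), `motif`,
#'   `matched_seq`.
#' @export
countDimer <- function(promoters, dimer) {
  stopifnot(is(dimer, "PalindromicDimer"))
  w <- nchar(dimer@w1)
  idx <- .buildCodeIndex(promoters, widths = w,
                         gap = motifLength(dimer) + 1L)
  sites <- .dimerSites(idx, promoters, dimer)
  list(n_obs = nrow(sites), sites = sites)
}

.dimerSites <- function(idx, promoters, dimer) {
  w <- nchar(dimer@w1)
  s <- dimer@spacer
  codes <- idx$codes[[as.character(w)]]
  step <- w + s
  K <- length(codes)
  empty <- data.frame(promoter_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      matched_seq = character(0), stringsAsFactors = FALSE)
  if (K <= step) return(empty)
  c1 <- codes[seq_len(K - step)]
  c2 <- codes[(1L + step):K]
  target <- .wordToCode(dimer@w1)
  rcTarget <- .wordToCode(dimerW2(dimer))
  hit <- which(!is.na(c1) & !is.na(c2) & c1 == target & c2 == rcTarget)
  if (!length(hit)) return(empty)
  promIdx <- findInterval(hit, idx$starts)
  start0 <- hit - idx$starts[promIdx]  # 0-based within promoter
  Ld <- motifLength(dimer)
  txt <- substring(as.character(promoters)[promIdx], start0 + 1L,
                   start0 + Ld)
  data.frame(promoter_id = idx$ids[promIdx], start = start0,
             end = start0 + Ld, motif = encodeMotifName(dimer),
             matched_seq = txt, stringsAsFactors = FALSE)
}

#' Effective length: number of placements of a motif
#'
#' `sum over promoters of max(0, L(r) - motifLength + 1)` - the number
#' of independent positions where a motif of the given length can sit.
#'
#' @param promoterLengths integer vector of promoter lengths.
#' @param motifLength motif length in nt.
#' @return integer effective length.
#' @examples
#' effectiveLength(rep(300, 10), 16)  # 2850
#' @export
effectiveLength <- function(promoterLengths, motifLength) {
  stopifnot(motifLength >= 1L)
  sum(pmax(0L, promoterLengths - motifLength + 1L))
}

#' Expected dimer count under the pooled background model
#'
#' Frequency-product form: the per-position frequencies of the two
#' words, estimated over the pooled promoter set, times the number of
#' placements of the dimer:
#' `n_exp = (n_w1 / leffW) * (n_w2 / leffW) * leffD`.
#' The `"simple"` form `n_w1 * n_w2 / leffD` is provided for
#' sensitivity analysis.
#'
#' @param nW1,nW2 total word counts over the pooled promoters.
#' @param leffD effective length for the full dimer.
#' @param leffW effective length for a single word.
#' @param form `"frequency"` (default) or `"simple"`.
#' @return expected count (vectorized).
#' @export
expectedCount <- function(nW1, nW2, leffD, leffW,
                          form = c("frequency", "simple")) {
  form <- match.arg(form)
  if (any(leffD < 0) || any(leffW <= 0))
    stop("effective lengths must be positive")
  if (form == "frequency") (nW1 / leffW) * (nW2 / leffW) * leffD
  else nW1 * nW2 / leffD
}

#' Upper-tail Poisson probability
#'
#' `P(X >= nObs)` for `X ~ Poisson(nExp)`, computed stably through
#' [stats::ppois()] (regularized incomplete gamma). `P(X >= 0) = 1`
#' exactly.
#'
#' @param nObs observed count(s), non-negative.
#' @param nExp expected count(s), non-negative.
#' @param log.p return the natural log of the tail probability
#'   (well-defined far below double underflow; used for ranking).
#' @return tail probability (vectorized).
#' @examples
#' poissonPvalue(1, 1)    # 1 - exp(-1)
#' poissonPvalue(0, 100)  # 1
#' @export
poissonPvalue <- function(nObs, nExp, log.p = FALSE) {
  if (any(nObs < 0) || any(nExp < 0)) stop("negative inputs")
  stats::ppois(nObs - 1, nExp, lower.tail = FALSE, log.p = log.p)
}

#' Flag significant motifs at the observed-family threshold
#'
#' `N_motif` is the number of candidate dimers observed at least once;
#' the threshold is `alpha = 1 / N_motif` and a motif is significant
#' iff its Poisson tail probability is strictly below alpha. With
#' `alphaFrom = "all"` the full candidate count is used instead.
#'
#' @param motifs motif table with columns `n_obs`, `p_value`, `log_p`.
#' @param alphaFrom `"observed"` (default) or `"all"`.
#' @return the table with a logical `significant` column, plus
#'   attributes `alpha` and `n_motif`.
#' @export
callSignificantMotifs <- function(motifs, alphaFrom = c("observed", "all")) {
  alphaFrom <- match.arg(alphaFrom)
  nm <- if (alphaFrom == "observed") sum(motifs$n_obs >= 1L)
        else nrow(motifs)
  if (nm == 0L) {
    warning("no motifs observed; alpha undefined, nothing significant")
    motifs$significant <- logical(nrow(motifs))
    attr(motifs, "alpha") <- NA_real_
    attr(motifs, "n_motif") <- 0L
    return(motifs)
  }
  alpha <- 1 / nm
  lp <- if (!is.null(motifs$log_p)) motifs$log_p else log(motifs$p_value)
  motifs$significant <- lp < log(alpha)
  attr(motifs, "alpha") <- alpha
  attr(motifs, "n_motif") <- as.integer(nm)
  motifs
}

#' Scan promoters for every candidate palindromic dimer
#'
#' The full discovery step: enumerates the candidate space, counts
#' observed instances of every dimer and total occurrences of every
#' word on the stored strand (overlaps allowed, N never matches),
#' computes expected counts under the pooled background model
#' ([expectedCount()]), assigns upper-tail Poisson probabilities, and
#' flags motifs significant at `alpha = 1 / N_motif`.
#'
#' @param promoters a `PromoterSet`/`DNAStringSet`.
#' @param wMin,wMax,spacerMin,spacerMax candidate space bounds
#'   (defaults 3, 5, 0, 30).
#' @param expectedForm `"frequency"` (default) or `"simple"`, see
#'   [expectedCount()].
#' @param alphaFrom `"observed"` (default) or `"all"`, see
#'   [callSignificantMotifs()].
#' @return a [DimerScan] object.
#' @examples
#' set.seed(1)
#' p <- simulatePromoters(50, 300, seed = 1)
#' sc <- scanDimers(p, wMax = 3, spacerMax = 5)
#' sc
#' @export
scanDimers <- function(promoters, wMin = 3L, wMax = 5L, spacerMin = 0L,
                       spacerMax = 30L,
                       expectedForm = c("frequency", "simple"),
                       alphaFrom = c("observed", "all")) {
  expectedForm <- match.arg(expectedForm)
  alphaFrom <- match.arg(alphaFrom)
  if (!is(promoters, "PromoterSet")) promoters <- PromoterSet(promoters)
  cand <- enumerateDimers(wMin, wMax, spacerMin, spacerMax)
  lens <- width(promoters)
  maxLd <- 2L * wMax + spacerMax
  idx <- .buildCodeIndex(promoters, widths = wMin:wMax, gap = maxLd + 1L)

  nObs <- integer(nrow(cand))
  nW <- vector("list", wMax)
  for (w in wMin:wMax) {
    codes <- idx$codes[[as.character(w)]]
    ok <- !is.na(codes)
    nW[[w]] <- tabulate(codes[ok] + 1L, nbins = 4^w)
    rcMap <- .rcCodeMap(w)
    for (s in spacerMin:spacerMax) {
      step <- w + s
      K <- length(codes)
      rows <- which(cand$w == w & cand$spacer == s)
      if (K > step) {
        c1 <- codes[seq_len(K - step)]
        c2 <- codes[(1L + step):K]
        match <- !is.na(c1) & !is.na(c2) & c2 == rcMap[c1 + 1L]
        counts <- tabulate(c1[match] + 1L, nbins = 4^w)
      } else counts <- integer(4^w)
      ## rows are ordered (w1 code, then spacer); pick this spacer's rows
      nObs[rows] <- counts[.wordCodesInOrder(cand$w1[rows])]
    }
  }
  nW1 <- integer(nrow(cand)); nW2 <- integer(nrow(cand))
  leffD <- integer(nrow(cand)); leffW <- integer(nrow(cand))
  for (w in wMin:wMax) {
    rows <- cand$w == w
    nW1[rows] <- nW[[w]][vapply(cand$w1[rows], .wordToCode, 0) + 1L]
    nW2[rows] <- nW[[w]][vapply(cand$w2[rows], .wordToCode, 0) + 1L]
    leffW[rows] <- effectiveLength(lens, w)
  }
  Ld <- 2L * cand$w + cand$spacer
  leffD <- vapply(Ld, function(l) effectiveLength(lens, l), 0)
  nExp <- expectedCount(nW1, nW2, leffD, leffW, form = expectedForm)
  p <- poissonPvalue(nObs, nExp)
  lp <- poissonPvalue(nObs, nExp, log.p = TRUE)
  tab <- data.frame(cand, n_obs = nObs, n_w1 = nW1, n_w2 = nW2,
                    leff_d = leffD, leff_w = leffW, n_exp = nExp,
                    p_value = p, log_p = lp, stringsAsFactors = FALSE)
  tab <- callSignificantMotifs(tab, alphaFrom)
  new("DimerScan", promoters = as(promoters, "PromoterSet"),
      motifs = DataFrame(tab),
      nMotif = attr(tab, "n_motif"),
      alpha = as.numeric(attr(tab, "alpha")),
      params = list(wMin = wMin, wMax = wMax, spacerMin = spacerMin,
                    spacerMax = spacerMax, expectedForm = expectedForm,
                    alphaFrom = alphaFrom))
}

.wordCodesInOrder <- function(words) {
  vapply(words, .wordToCode, 0, USE.NAMES = FALSE) + 1L
}

#' Locate sites of selected motifs in a scanned promoter set
#'
#' @param scan a [DimerScan].
#' @param motifs compact motif names to locate; defaults to the
#'   significant set.
#' @return `data.frame` of site calls (`promoter_id`, `start`, `end`,
#'   `motif`, `matched_seq`), ordered by motif then position.
#' @export
siteCalls <- function(scan, motifs = NULL) {
  stopifnot(is(scan, "DimerScan"))
  if (is.null(motifs)) {
    sig <- significantMotifs(scan)
    motifs <- sig$name
  }
  proms <- scan@promoters
  if (!length(motifs))
    return(data.frame(promoter_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      matched_seq = character(0), stringsAsFactors = FALSE))
  p <- scan@params
  idx <- .buildCodeIndex(proms, widths = p$wMin:p$wMax,
                         gap = 2L * p$wMax + p$spacerMax + 1L)
  out <- lapply(motifs, function(nm)
    .dimerSites(idx, proms, decodeMotifName(nm)))
  do.call(rbind, out)
}

#' Per-promoter regulatory-potential counts
#'
#' Counts, for each scanned promoter, either the number of distinct
#' significant motifs with at least one site in it (default; the
#' "number of different TFBS") or the total number of significant site
#' occurrences. Promoters with no sites count 0.
#'
#' @param scan a [DimerScan], or a site-call `data.frame` (then
#'   `promoterIds` must list all promoters).
#' @param mode `"distinct"` (default) or `"occurrences"`.
#' @param promoterIds promoter universe when `scan` is a site table.
#' @return named integer vector over all promoters.
#' @export
promoterTFBSCounts <- function(scan, mode = c("distinct", "occurrences"),
                               promoterIds = NULL) {
  mode <- match.arg(mode)
  if (is(scan, "DimerScan")) {
    sites <- siteCalls(scan)
    promoterIds <- names(scan@promoters)
  } else {
    sites <- scan
    if (is.null(promoterIds))
      stop("promoterIds required when passing a site table")
  }
  counts <- stats::setNames(integer(length(promoterIds)), promoterIds)
  if (nrow(sites)) {
    if (mode == "distinct") {
      u <- unique(sites[, c("promoter_id", "motif")])
      t <- table(u$promoter_id)
    } else {
      t <- table(sites$promoter_id)
    }
    counts[names(t)] <- as.integer(t)
  }
  counts
}
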