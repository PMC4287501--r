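## Promoter identification: keep long reads with strong protein hits,
## cut a fixed-length upstream window, de-redundify, apply exclusions.

#' Filter reads by minimum length
#'
#' Keeps reads of length `>= minLength` ("shorter than" is strict, so a
#' read exactly at the threshold survives). Order is preserved.
#'
#' @param reads a `DNAStringSet`.
#' @param minLength minimum read length in nt (default 800).
#' @return the surviving reads.
#' @export
filterReadsByLength <- function(reads, minLength = 800L) {
  stopifnot(minLength >= 1L)
  reads[width(reads) >= minLength]
}

#' Select the best accepted coding hit per read
#'
#' Removes hits with alignment length below `minAlignmentAA` amino
#' acids or identity not strictly greater than `minIdentity` percent,
#' then keeps exactly one hit per read: highest bitscore, ties broken by
#' lowest `read_start`, then lexicographic `subject_id`. Reads with no
#' surviving hit are dropped.
#'
#' @param hits alignment hits as returned by [readAlignmentTable()].
#' @param minAlignmentAA minimum alignment length in amino acids
#'   (default 150, inclusive).
#' @param minIdentity identity threshold in percent (default 50,
#'   strict: a 50.0\% hit is rejected).
#' @return `data.frame` of best hits, one row per surviving read, plus
#'   an `all_passing` attribute holding every hit that passed the
#'   thresholds (needed for the non-coding overlap check downstream).
#' @export
selectCodingHits <- function(hits, minAlignmentAA = 150L, minIdentity = 50) {
  pass <- hits[hits$alignment_length_aa >= minAlignmentAA &
               hits$percent_identity > minIdentity, , drop = FALSE]
  if (nrow(pass) == 0L) {
    out <- pass
    attr(out, "all_passing") <- pass
    return(out)
  }
  ord <- order(pass$read_id, -pass$bitscore, pass$read_start,
               pass$subject_id)
  pass <- pass[ord, , drop = FALSE]
  best <- pass[!duplicated(pass$read_id), , drop = FALSE]
  rownames(best) <- NULL
  attr(best, "all_passing") <- pass
  best
}

#' Extract the upstream promoter window for one accepted hit
#'
#' For a plus-frame hit the candidate window is the `requireNoncoding`
#' bases ending at the hit start on the forward strand; for a
#' minus-frame hit it is the bases beginning at the hit end,
#' reverse-complemented so the result reads 5'->3' towards the gene.
#' The window is rejected (returns `NULL` with a `reason` attribute) if
#' the read does not contain `requireNoncoding` bases in that
#' direction, or if the window overlaps any other accepted hit's coding
#' interval on the same read. On acceptance the `upstreamLength` bases
#' adjacent to the coding start are returned.
#'
#' @param read a single `DNAString` (or 1-length `DNAStringSet`).
#' @param hit one-row `data.frame` in the [readAlignmentTable()] layout.
#' @param upstreamLength promoter length to extract (default 300).
#' @param requireNoncoding required non-coding run adjacent to the gene
#'   (default 300); must be `>= upstreamLength`.
#' @param otherHits optional `data.frame` of other accepted hits on the
#'   same read whose coding intervals must not intrude into the window.
#' @return `list(sequence, offset, strand)` with `offset` the 0-based
#'   start of the extracted window on the read's forward strand, or a
#'   rejection object (test with [isRejected()]; its `reason` element
#'   is one of `"insufficient_upstream"`, `"overlaps_coding"`).
#' @export
extractUpstream <- function(read, hit, upstreamLength = 300L,
                            requireNoncoding = 300L, otherHits = NULL) {
  if (is(read, "DNAStringSet")) read <- read[[1L]]
  L <- length(read)
  if (hit$read_start < 0L || hit$read_end > L)
    stop("hit coordinates outside read ", hit$read_id)
  stopifnot(requireNoncoding >= upstreamLength)
  reject <- function(why)
    structure(list(reason = why), class = "promoterRejection")
  if (hit$frame_sign == "+") {
    winStart <- hit$read_start - requireNoncoding
    winEnd <- hit$read_start
    if (winStart < 0L) return(reject("insufficient_upstream"))
  } else {
    winStart <- hit$read_end
    winEnd <- hit$read_end + requireNoncoding
    if (winEnd > L) return(reject("insufficient_upstream"))
  }
  if (!is.null(otherHits) && nrow(otherHits)) {
    overlap <- otherHits$read_start < winEnd & otherHits$read_end > winStart
    if (any(overlap)) return(reject("overlaps_coding"))
  }
  if (hit$frame_sign == "+") {
    s0 <- hit$read_start - upstreamLength
    seq <- as.character(subseq(read, start = s0 + 1L,
                               end = hit$read_start))
    list(sequence = seq, offset = s0, strand = "+")
  } else {
    s0 <- hit$read_end
    seq <- as.character(subseq(read, start = s0 + 1L,
                               end = s0 + upstreamLength))
    list(sequence = revComp(seq), offset = s0, strand = "-")
  }
}

#' Test whether an upstream-extraction result is a rejection
#'
#' @param x a result of [extractUpstream()].
#' @return `TRUE` if the window was rejected; the rejection's `reason`
#'   element says why.
#' @export
isRejected <- function(x) inherits(x, "promoterRejection")

## identity = matches / alignment columns of a Needleman-Wunsch global
## alignment (match +1, mismatch -1, affine gaps); indels count as
## columns via the alignment length
.globalIdentity <- function(a, b) {
  if (a == b) return(1)
  mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                      baseOnly = FALSE)
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "global",
                           substitutionMatrix = mat,
                           gapOpening = 2, gapExtension = 1)
  nmatch(aln) / nchar(aln)
}

#' Remove redundancy among promoters by greedy identity clustering
#'
#' Promoters are visited in a deterministic order (descending count of
#' non-N bases, ties by id); each joins the first existing
#' representative with global-alignment identity `>=` the cutoff, else
#' founds a new cluster. Identity is matches over alignment columns of
#' a global alignment.
#'
#' @param promoters a `PromoterSet` (or named `DNAStringSet`).
#' @param identityCutoff clustering threshold in (0, 1], default 0.98.
#' @return `list(representatives, clusters)`: the representative
#'   `PromoterSet` (original order of first appearance in the visit
#'   order) and a `data.frame` mapping `member` -> `representative`
#'   with the realized `identity`.
#' @export
deduplicatePromoters <- function(promoters, identityCutoff = 0.98) {
  stopifnot(identityCutoff > 0, identityCutoff <= 1)
  n <- length(promoters)
  if (n == 0L)
    return(list(representatives = promoters,
                clusters = data.frame(member = character(0),
                                      representative = character(0),
                                      identity = numeric(0))))
  ids <- names(promoters)
  nonN <- width(promoters) - vcountPattern("N", promoters, fixed = TRUE)
  visit <- order(-nonN, ids)
  seqs <- as.character(promoters)
  repIdx <- integer(0)
  member <- character(n); repOf <- character(n); idy <- numeric(n)
  for (k in seq_along(visit)) {
    i <- visit[k]
    assigned <- FALSE
    for (r in repIdx) {
      pid <- .globalIdentity(seqs[i], seqs[r])
      if (pid >= identityCutoff) {
        member[k] <- ids[i]; repOf[k] <- ids[r]; idy[k] <- pid
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      repIdx <- c(repIdx, i)
      member[k] <- ids[i]; repOf[k] <- ids[i]; idy[k] <- 1
    }
  }
  list(representatives = promoters[sort(repIdx)],
       clusters = data.frame(member = member, representative = repOf,
                             identity = idy, stringsAsFactors = FALSE))
}

#' Remove promoters named in exclusion lists
#'
#' Drops promoters whose own id, or whose source read id, appears in
#' the given lists (used for externally detected eukaryotic reads,
#' ncRNA, internal coding regions, CRISPR arrays). Unknown ids warn but
#' do not error.
#'
#' @param promoters a `PromoterSet`.
#' @param excludedReads character vector of read ids to drop (cascades
#'   to every promoter from that read).
#' @param excludedPromoters character vector of promoter ids to drop.
#' @return the surviving `PromoterSet`, with attribute `removed` giving
#'   per-list removal counts.
#' @export
applyExclusions <- function(promoters, excludedReads = character(0),
                            excludedPromoters = character(0)) {
  ids <- names(promoters)
  src <- sourceRead(promoters)
  byRead <- !is.na(src) & src %in% excludedReads
  byId <- ids %in% excludedPromoters
  unknown <- c(setdiff(excludedReads, src),
               setdiff(excludedPromoters, ids))
  if (length(unknown))
    warning("exclusion id(s) not present in the promoter set: ",
            paste(utils::head(unknown, 5L), collapse = ", "),
            if (length(unknown) > 5L) ", ...")
  out <- promoters[!(byRead | byId)]
  attr(out, "removed") <- c(by_read = sum(byRead & !byId),
                            by_promoter = sum(byId))
  out
}

#' Run the full promoter-identification pipeline
#'
#' Chains the read-length filter, the coding-hit filter, upstream
#' extraction (with the non-coding overlap check against all other
#' accepted hits on the read), greedy de-redundancy, and exclusion
#' lists, and tallies an extraction report whose counts are monotone
#' non-increasing along the pipeline.
#'
#' @param reads a named `DNAStringSet` of metagenomic reads.
#' @param hits alignment hits ([readAlignmentTable()] layout).
#' @param minReadLength,minAlignmentAA,minIdentity,upstreamLength,requireNoncoding,dedupIdentity
#'   stage thresholds; defaults 800 nt, 150 aa, 50 (strict), 300 nt,
#'   300 nt, 0.98.
#' @param environment sample label stamped on every promoter.
#' @param excludedReads,excludedPromoters exclusion lists, see
#'   [applyExclusions()].
#' @return `list(promoters, report, clusters)`: the final
#'   `PromoterSet` (ids `read|strand|offset`), the report
#'   `data.frame(stage, count)`, and the dedup cluster map.
#' @examples
#' reads <- DNAStringSet(c(r1 = paste(rep("ACGT", 250), collapse = "")))
#' hits <- data.frame(read_id = "r1", subject_id = "p", percent_identity = 80,
#'                    alignment_length_aa = 160, read_start = 400L,
#'                    read_end = 880L, frame_sign = "+", bitscore = 300)
#' extractPromoters(reads, hits)$report
#' @export
extractPromoters <- function(reads, hits, minReadLength = 800L,
                             minAlignmentAA = 150L, minIdentity = 50,
                             upstreamLength = 300L, requireNoncoding = 300L,
                             dedupIdentity = 0.98,
                             environment = NA_character_,
                             excludedReads = character(0),
                             excludedPromoters = character(0)) {
  nInput <- length(reads)
  long <- filterReadsByLength(reads, minReadLength)
  best <- selectCodingHits(hits, minAlignmentAA, minIdentity)
  allPassing <- attr(best, "all_passing")
  best <- best[best$read_id %in% names(long), , drop = FALSE]
  nWithHit <- nrow(best)

  seqs <- character(0); srcs <- character(0); strands <- character(0)
  offs <- integer(0); subjects <- character(0)
  nSufficient <- 0L
  if (nWithHit) {
    for (i in seq_len(nWithHit)) {
      h <- best[i, , drop = FALSE]
      others <- allPassing[allPassing$read_id == h$read_id &
                           !(allPassing$read_start == h$read_start &
                             allPassing$read_end == h$read_end &
                             allPassing$subject_id == h$subject_id), ,
                           drop = FALSE]
      res <- extractUpstream(long[[h$read_id]], h, upstreamLength,
                             requireNoncoding, others)
      if (isRejected(res)) {
        if (identical(res$reason, "overlaps_coding"))
          nSufficient <- nSufficient + 1L
        next
      }
      nSufficient <- nSufficient + 1L
      seqs <- c(seqs, res$sequence)
      srcs <- c(srcs, h$read_id)
      strands <- c(strands, res$strand)
      offs <- c(offs, res$offset)
      subjects <- c(subjects, h$subject_id)
    }
  }
  proms <- PromoterSet(stats::setNames(seqs,
                                       paste0(srcs, "|", strands, "|", offs)),
                       sourceRead = srcs, strand = strands, offset = offs,
                       geneSubject = subjects, environment = environment)
  nExtracted <- length(proms)
  dd <- deduplicatePromoters(proms, dedupIdentity)
  reps <- dd$representatives
  final <- applyExclusions(reps, excludedReads, excludedPromoters)
  report <- data.frame(
    stage = c("input_reads", "length_filter", "accepted_hit",
              "sufficient_upstream", "promoters_extracted",
              "after_deduplication", "after_exclusions"),
    count = c(nInput, length(long), nWithHit, nSufficient, nExtracted,
              length(reps), length(final)),
    stringsAsFactors = FALSE
  )
  list(promoters = final, report = report, clusters = dd$clusters)
}
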