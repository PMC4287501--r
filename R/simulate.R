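## Deterministic synthetic-data generators with machine-readable ground
## truth for every pipeline stage. All generators are pure functions of
## (parameters, seed); seeds are mandatory and never global state.

#' Generate i.i.d. background promoters
#'
#' Sequences drawn with `P(G) = P(C) = gc/2`, `P(A) = P(T) =
#' (1 - gc)/2`, independently per position.
#'
#' @param n number of promoters.
#' @param length promoter length in nt (default 300).
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param seed required integer seed.
#' @param environment environment label stamped on the set.
#' @return a `PromoterSet` named `prom_0001 ...`.
#' @examples
#' simulatePromoters(3, 50, seed = 1)
#' @export
simulatePromoters <- function(n, length = 300L, gc = 0.5, seed,
                              environment = "synthetic") {
  stopifnot(n >= 1L, length >= 1L)
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- .withSeed(seed, {
    m <- matrix(sample(names(probs), n * length, replace = TRUE,
                       prob = probs), nrow = n)
    apply(m, 1L, paste, collapse = "")
  })
  ids <- sprintf("prom_%04d", seq_len(n))
  PromoterSet(stats::setNames(seqs, ids), environment = environment)
}

#' Plant a palindromic dimer into a fraction of promoters
#'
#' A uniformly chosen subset of `round(fraction * n)` promoters
#' receives `copies` non-overlapping instances of the pattern
#' `w1 + <random spacer bases> + w2` at uniform positions, overwriting
#' the background. Spacer bases are random, so discovery must rely on
#' the flanking words.
#'
#' @param promoters a `PromoterSet`.
#' @param dimer a [PalindromicDimer].
#' @param fraction fraction of promoters to carry the motif.
#' @param copies instances per carrier promoter (default 1).
#' @param seed required integer seed.
#' @param maxTries placement retries before giving up (default 100).
#' @return `list(promoters, truth)`; `truth` is a
#'   `data.frame(promoter_id, start, end)` of every planted instance
#'   (0-based half-open).
#' @export
plantDimer <- function(promoters, dimer, fraction, copies = 1L, seed,
                       maxTries = 100L) {
  stopifnot(is(dimer, "PalindromicDimer"), fraction >= 0, fraction <= 1)
  n <- length(promoters)
  Ld <- motifLength(dimer)
  if (any(width(promoters) < Ld))
    stop("planted instance does not fit in every promoter")
  nCarrier <- round(fraction * n)
  if (nCarrier == 0L)
    return(list(promoters = promoters,
                truth = data.frame(promoter_id = character(0),
                                   start = integer(0), end = integer(0),
                                   stringsAsFactors = FALSE)))
  seqs <- as.character(promoters)
  ids <- names(promoters)
  res <- .withSeed(seed, {
    carriers <- sort(sample.int(n, nCarrier))
    truth <- list()
    for (i in carriers) {
      L <- nchar(seqs[i])
      placed <- integer(0)  # starts (0-based)
      for (k in seq_len(copies)) {
        ok <- FALSE
        for (t in seq_len(maxTries)) {
          s0 <- sample.int(L - Ld + 1L, 1L) - 1L
          if (!any(s0 < placed + Ld & placed < s0 + Ld)) { ok <- TRUE; break }
        }
        if (!ok)
          stop("cannot place instance without overlap in ", ids[i])
        spacerSeq <- paste(sample(c("A", "C", "G", "T"), dimer@spacer,
                                  replace = TRUE), collapse = "")
        inst <- paste0(dimer@w1, spacerSeq, dimerW2(dimer))
        substr(seqs[i], s0 + 1L, s0 + Ld) <- inst
        placed <- c(placed, s0)
      }
      truth[[as.character(i)]] <-
        data.frame(promoter_id = ids[i], start = sort(placed),
                   end = sort(placed) + Ld, stringsAsFactors = FALSE)
    }
    list(seqs = seqs, truth = do.call(rbind, truth))
  })
  out <- PromoterSet(stats::setNames(res$seqs, ids))
  mcols(out) <- mcols(promoters)
  rownames(res$truth) <- NULL
  list(promoters = out, truth = res$truth)
}

## one planted read class of the extraction fixture
.readClass <- function(class, read_length, pident, len_aa, strand,
                       hit_start, pass_length, pass_hit, pass_upstream,
                       pass_dedup = TRUE, excluded = FALSE,
                       second_hit_start = NA_integer_,
                       second_hit_len_aa = NA_integer_,
                       window_from = NA_character_,
                       window_mutations = 0L) {
  data.frame(class = class, read_length = read_length, pident = pident,
             len_aa = len_aa, strand = strand, hit_start = hit_start,
             pass_length = pass_length, pass_hit = pass_hit,
             pass_upstream = pass_upstream, pass_dedup = pass_dedup,
             excluded = excluded, second_hit_start = second_hit_start,
             second_hit_len_aa = second_hit_len_aa,
             window_from = window_from,
             window_mutations = window_mutations,
             stringsAsFactors = FALSE)
}

#' Generate a read + alignment fixture with known extraction truth
#'
#' Builds a set of synthetic Sanger-scale reads and a consistent mock
#' protein-alignment table such that every read's fate under the
#' extraction filters (800 nt length, 150 aa / >50\% identity hit,
#' 300 nt non-coding upstream, 98\% de-redundancy, exclusion lists) is
#' known by construction. The layout covers the boundary cases: reads
#' of 799 and 800 nt, hits of 149/150 aa and 50.0/50.1\% identity,
#' minus-frame hits, operon-like reads whose upstream window overlaps a
#' second gene, reads with only 250 nt of upstream room, duplicate and
#' near-duplicate (5- and 10-mismatch) promoter windows, and a read on
#' an exclusion list.
#'
#' @param seed required integer seed (background sequence only; the
#'   layout is fixed).
#' @return `list(reads, hits, truth, excludedReads,
#'   expectedPromoters, expectedRepresentatives)`: the reads
#'   (`DNAStringSet`), the alignment table, the per-read truth table
#'   with pass/fail flags and the expected promoter sequence, the
#'   exclusion list, and the expected promoter ids surviving
#'   extraction and then deduplication + exclusion.
#' @export
simulateReadFixture <- function(seed) {
  layout <- rbind(
    .readClass("pass_plus", 1000L, 85, 150L, "+", 400L, TRUE, TRUE, TRUE),
    .readClass("pass_minus", 1000L, 85, 150L, "-", 100L, TRUE, TRUE, TRUE),
    .readClass("short799", 799L, 85, 150L, "+", 320L, FALSE, TRUE, TRUE),
    .readClass("len800", 800L, 85, 150L, "+", 350L, TRUE, TRUE, TRUE),
    .readClass("id50.0", 1000L, 50.0, 150L, "+", 400L, TRUE, FALSE, NA),
    .readClass("id50.1", 1000L, 50.1, 150L, "+", 400L, TRUE, TRUE, TRUE),
    .readClass("aa149", 1000L, 85, 149L, "+", 400L, TRUE, FALSE, NA),
    .readClass("no_upstream", 1000L, 85, 150L, "+", 250L, TRUE, TRUE,
               FALSE),
    .readClass("operon", 1000L, 85, 150L, "+", 400L, TRUE, TRUE, FALSE,
               second_hit_start = 150L, second_hit_len_aa = 150L),
    .readClass("multi_hit", 1500L, 85, 150L, "+", 400L, TRUE, TRUE, TRUE,
               second_hit_start = 900L, second_hit_len_aa = 150L),
    .readClass("dup_a", 1000L, 85, 150L, "+", 400L, TRUE, TRUE, TRUE),
    .readClass("dup_b", 1000L, 85, 150L, "+", 400L, TRUE, TRUE, TRUE,
               pass_dedup = FALSE, window_from = "dup_a",
               window_mutations = 0L),
    .readClass("near_a", 1000L, 85, 150L, "+", 400L, TRUE, TRUE, TRUE),
    .readClass("near_b", 1000L, 85, 150L, "+", 400L, TRUE, TRUE, TRUE,
               pass_dedup = FALSE, window_from = "near_a",
               window_mutations = 5L),
    .readClass("far_a", 1000L, 85, 150L, "+", 400L, TRUE, TRUE, TRUE),
    .readClass("far_b", 1000L, 85, 150L, "+", 400L, TRUE, TRUE, TRUE,
               window_from = "far_a", window_mutations = 10L),
    .readClass("no_hit", 1000L, NA, NA_integer_, NA, NA_integer_, TRUE,
               FALSE, NA),
    .readClass("excluded_read", 1000L, 85, 150L, "+", 400L, TRUE, TRUE,
               TRUE, excluded = TRUE)
  )
  res <- .withSeed(seed, {
    reads <- character(nrow(layout))
    for (i in seq_len(nrow(layout)))
      reads[i] <- paste(sample(c("A", "C", "G", "T"), layout$read_length[i],
                               replace = TRUE), collapse = "")
    names(reads) <- layout$class
    ## copy/mutate the 300-nt upstream window for the dedup classes
    for (i in which(!is.na(layout$window_from))) {
      src <- reads[layout$window_from[i]]
      h <- layout$hit_start[i]
      win <- substr(src, h - 300L + 1L, h)
      nm <- layout$window_mutations[i]
      if (nm > 0L) {
        pos <- sample.int(300L, nm)
        b <- strsplit(win, "", fixed = TRUE)[[1L]]
        for (p in pos)
          b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
        win <- paste(b, collapse = "")
      }
      substr(reads[i], h - 300L + 1L, h) <- win
    }
    reads
  })
  reads <- DNAStringSet(res)

  hitRows <- list()
  for (i in seq_len(nrow(layout))) {
    cl <- layout[i, ]
    if (is.na(cl$pident)) next
    span <- 3L * cl$len_aa
    if (cl$strand == "+") {
      rs <- cl$hit_start; re <- cl$hit_start + span
    } else {
      ## minus-frame gene at the 5' end of the read; promoter downstream
      rs <- cl$hit_start; re <- cl$hit_start + span
    }
    hitRows[[length(hitRows) + 1L]] <-
      data.frame(read_id = cl$class, subject_id = paste0("prot_", cl$class),
                 percent_identity = cl$pident,
                 alignment_length_aa = cl$len_aa, read_start = rs,
                 read_end = re, frame_sign = cl$strand, bitscore = 210,
                 stringsAsFactors = FALSE)
    if (!is.na(cl$second_hit_start)) {
      span2 <- 3L * cl$second_hit_len_aa
      hitRows[[length(hitRows) + 1L]] <-
        data.frame(read_id = cl$class,
                   subject_id = paste0("prot2_", cl$class),
                   percent_identity = cl$pident,
                   alignment_length_aa = cl$second_hit_len_aa,
                   read_start = cl$second_hit_start,
                   read_end = cl$second_hit_start + span2,
                   frame_sign = "+", bitscore = 180,
                   stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hitRows)

  ## expected promoter per surviving read, from the truth flags alone
  layout$promoter_id <- NA_character_
  layout$promoter_seq <- NA_character_
  survives <- layout$pass_length & layout$pass_hit &
    !is.na(layout$pass_upstream) & layout$pass_upstream
  for (i in which(survives)) {
    cl <- layout[i, ]
    rd <- as.character(reads[[cl$class]])
    if (cl$strand == "+") {
      off <- cl$hit_start - 300L
      seq <- substr(rd, off + 1L, cl$hit_start)
    } else {
      off <- cl$hit_start + 3L * cl$len_aa
      seq <- revComp(substr(rd, off + 1L, off + 300L))
    }
    layout$promoter_id[i] <- paste0(cl$class, "|", cl$strand, "|", off)
    layout$promoter_seq[i] <- seq
  }
  expectedPromoters <- layout$promoter_id[survives]
  keptAfterDedup <- survives & layout$pass_dedup
  expectedReps <- layout$promoter_id[keptAfterDedup & !layout$excluded]
  list(reads = reads, hits = hits, truth = layout,
       excludedReads = layout$class[layout$excluded],
       expectedPromoters = expectedPromoters,
       expectedRepresentatives = expectedReps)
}

#' Generate hierarchical function annotations with constructed outcomes
#'
#' Assigns each promoter exactly one two-level SEED-style label path
#' (`"Parent;Child"`). Promoters listed in `enrichedIds` receive the
#' `enrichedLabel` with probability `enrichedProb`; all others (and the
#' remainder) draw uniformly from `backgroundLabels`. With
#' `enrichedProb = 1` the enrichment of `enrichedLabel` among
#' `enrichedIds` is maximal by construction; with `enrichedIds`
#' empty the labels are exchangeable and enrichment p-values are
#' calibrated.
#'
#' @param promoterIds character vector of promoter ids.
#' @param environment per-promoter environment label (recycled).
#' @param enrichedIds promoters biased towards the enriched label.
#' @param enrichedLabel the planted label path (default
#'   `"Stress Response;Oxidative stress"`).
#' @param backgroundLabels pool of background label paths.
#' @param enrichedProb probability a promoter in `enrichedIds` gets the
#'   enriched label (default 1).
#' @param seed required integer seed.
#' @return `data.frame(promoter_id, environment, function_label)`, one
#'   row per promoter.
#' @export
simulateAnnotations <- function(promoterIds, environment = "synthetic",
                                enrichedIds = character(0),
                                enrichedLabel =
                                  "Stress Response;Oxidative stress",
                                backgroundLabels = c(
                                  "Carbohydrates;Di- and oligosaccharides",
                                  "Carbohydrates;Monosaccharides",
                                  "Cofactors;Folate and pterines",
                                  "Membrane Transport;TonB-dependent",
                                  "Protein Metabolism;Ribosome"),
                                enrichedProb = 1, seed) {
  if (any(grepl(";", c(sub(";", "", enrichedLabel),
                       sub(";", "", backgroundLabels)), fixed = TRUE)))
    stop("labels may contain the level separator ';' only once")
  n <- length(promoterIds)
  labels <- .withSeed(seed, {
    lab <- sample(backgroundLabels, n, replace = TRUE)
    hot <- promoterIds %in% enrichedIds
    take <- hot & (stats::runif(n) < enrichedProb)
    lab[take] <- enrichedLabel
    lab
  })
  data.frame(promoter_id = promoterIds,
             environment = rep_len(environment, n),
             function_label = labels, stringsAsFactors = FALSE)
}
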