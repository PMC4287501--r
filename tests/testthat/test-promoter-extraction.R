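mkHit <- function(read_id = "r", start, end, sign = "+", pident = 85,
                  aa = 150L, subject = "prot", bitscore = 200) {
  data.frame(read_id = read_id, subject_id = subject,
             percent_identity = pident, alignment_length_aa = aa,
             read_start = start, read_end = end, frame_sign = sign,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("read length filter keeps reads at the threshold", {
  reads <- Biostrings::DNAStringSet(setNames(
    strrep("A", c(799, 800, 801)), c("a", "b", "c")))
  kept <- filterReadsByLength(reads, 800)
  expect_equal(names(kept), c("b", "c"))
  expect_length(filterReadsByLength(reads[0], 800), 0L)
})

test_that("coding-hit filter is strict on identity, inclusive on length", {
  hits <- rbind(mkHit("r1", 0, 450, pident = 50.0),
                mkHit("r2", 0, 450, pident = 50.1),
                mkHit("r3", 0, 447, aa = 149L),
                mkHit("r4", 0, 450, aa = 150L, pident = 50.1))
  best <- selectCodingHits(hits)
  expect_setequal(best$read_id, c("r2", "r4"))
})

test_that("best hit per read is chosen by bitscore with stated tie-breaks", {
  hits <- rbind(mkHit("r", 500, 950, bitscore = 180, subject = "a"),
                mkHit("r", 0, 450, bitscore = 210, subject = "b"))
  expect_equal(selectCodingHits(hits)$subject_id, "b")
  # bitscore tie: lowest start wins, then subject id
  hits2 <- rbind(mkHit("r", 500, 950, bitscore = 200, subject = "z"),
                 mkHit("r", 0, 450, bitscore = 200, subject = "y"))
  expect_equal(selectCodingHits(hits2)$subject_id, "y")
  hits3 <- rbind(mkHit("r", 0, 450, bitscore = 200, subject = "z"),
                 mkHit("r", 0, 450, bitscore = 200, subject = "y"))
  expect_equal(selectCodingHits(hits3)$subject_id, "y")
})

test_that("upstream windows follow the strand convention exactly", {
  set.seed(2)
  rd <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  read <- Biostrings::DNAString(rd)

  res <- extractUpstream(read, mkHit(start = 400L, end = 850L))
  expect_false(isRejected(res))
  expect_equal(res$sequence, substr(rd, 101, 400))
  expect_equal(res$offset, 100L)
  expect_equal(res$strand, "+")

  resm <- extractUpstream(read, mkHit(start = 100L, end = 550L,
                                      sign = "-"))
  expect_equal(resm$sequence, revComp(substr(rd, 551, 850)))
  expect_equal(resm$offset, 550L)
  expect_equal(resm$strand, "-")

  short <- extractUpstream(read, mkHit(start = 250L, end = 800L))
  expect_true(isRejected(short))
  expect_equal(short$reason, "insufficient_upstream")

  blocked <- extractUpstream(read, mkHit(start = 400L, end = 850L),
                             otherHits = mkHit(start = 150L, end = 600L))
  expect_true(isRejected(blocked))
  expect_equal(blocked$reason, "overlaps_coding")

  expect_error(extractUpstream(read, mkHit(start = 900L, end = 1350L)),
               "outside read")
})

test_that("greedy deduplication applies the identity cutoff", {
  base <- unname(randomSeqs(1, 300, seed = 9))
  mutate <- function(s, k) {
    b <- strsplit(s, "")[[1L]]
    for (p in seq_len(k))
      b[p * 7L] <- setdiff(c("A", "C", "G", "T"), b[p * 7L])[1L]
    paste(b, collapse = "")
  }
  p <- PromoterSet(c(a = base, b = base, c5 = mutate(base, 5),
                     c10 = mutate(base, 10)))
  dd <- deduplicatePromoters(p, 0.98)
  # identical join; 5 mismatches (98.3%) join; 10 mismatches (96.7%) found
  reps <- names(dd$representatives)
  expect_setequal(reps, c("a", "c10"))
  cl <- dd$clusters
  expect_equal(cl$representative[cl$member == "b"], "a")
  expect_equal(cl$representative[cl$member == "c5"], "a")
  expect_equal(cl$identity[cl$member == "c5"], 295 / 300)
  # every removed member has identity >= cutoff with its representative
  moved <- cl[cl$member != cl$representative, ]
  expect_true(all(moved$identity >= 0.98))
  # re-running on the representatives is a fixed point
  dd2 <- deduplicatePromoters(dd$representatives, 0.98)
  expect_equal(names(dd2$representatives), reps)
})

test_that("exclusion lists remove by promoter id and cascade by read", {
  p <- PromoterSet(setNames(randomSeqs(10, 50, seed = 4),
                            paste0("p", 1:10)),
                   sourceRead = paste0("rd", c(1, 1, 2:9)))
  expect_length(applyExclusions(p), 10L)
  expect_length(applyExclusions(p, excludedPromoters = c("p1", "p4", "p9")),
                7L)
  # read-level exclusion removes every promoter from that read
  out <- applyExclusions(p, excludedReads = "rd1")
  expect_length(out, 8L)
  expect_false(any(sourceRead(out) == "rd1"))
  expect_warning(applyExclusions(p, excludedPromoters = "nope"),
                 "not present")
})

test_that("pipeline recovers the fixture truth and reports monotone counts", {
  fx <- simulateReadFixture(seed = 20)
  res <- extractPromoters(fx$reads, fx$hits,
                          excludedReads = fx$excludedReads)
  expect_setequal(names(res$promoters), fx$expectedRepresentatives)
  counts <- res$report$count
  expect_true(all(diff(counts) <= 0))
  # promoter sequences equal the truth-table expectations and each 3'
  # end abuts the coding start in gene orientation
  truth <- fx$truth[!is.na(fx$truth$promoter_id), ]
  got <- as.character(res$promoters)
  for (i in seq_len(nrow(truth))) {
    id <- truth$promoter_id[i]
    if (id %in% names(got))
      expect_equal(unname(got[id]), truth$promoter_seq[i])
  }
  expect_true(all(width(res$promoters) == 300L))
})
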