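test_that("candidate enumeration has closed-form size and palindromy", {
  expect_equal(nrow(enumerateDimers(3, 3, 0, 0)), 64L)
  cand <- enumerateDimers()
  expect_equal(nrow(cand), (4^3 + 4^4 + 4^5) * 31L)
  expect_equal(anyDuplicated(cand$name), 0L)
  # every pattern is its own reverse complement (spot-check a sample)
  idx <- seq(1, nrow(cand), by = 997)
  for (i in idx) {
    pat <- expandedPattern(PalindromicDimer(cand$w1[i], cand$spacer[i]))
    expect_equal(revComp(pat), pat)
  }
  expect_error(enumerateDimers(5, 3), "empty")
})

test_that("motif name codec matches the published shorthand", {
  d <- PalindromicDimer("ATC", 10)
  expect_equal(encodeMotifName(d), "10 3 ATC")
  expect_equal(expandedPattern(d), "ATCNNNNNNNNNNGAT")
  expect_equal(expandedPattern(PalindromicDimer("AAA", 0)), "AAATTT")
  d2 <- decodeMotifName("10 3 ATC")
  expect_equal(dimerW1(d2), "ATC")
  expect_equal(dimerSpacer(d2), 10L)
  expect_equal(dimerW2(d2), "GAT")
  expect_equal(motifLength(d2), 16L)
  expect_error(decodeMotifName("10 4 ATC"), "does not match")
  expect_error(decodeMotifName("gibberish"), "malformed")
  # round-trip over a systematic sample of the candidate space
  cand <- enumerateDimers()
  for (i in seq(1, nrow(cand), by = 499)) {
    d <- decodeMotifName(cand$name[i])
    expect_equal(encodeMotifName(d), cand$name[i])
  }
})

test_that("word counting counts overlaps and never matches N", {
  expect_equal(countWord(Biostrings::DNAStringSet("AAAA"), "AAA"), 2L)
  expect_equal(countWord(Biostrings::DNAStringSet(c("ATCATC", "GGG")),
                         "ATC"), 2L)
  expect_equal(countWord(Biostrings::DNAStringSet("ANA"), "AA"), 0L)
  seqs <- randomSeqs(20, 150, seed = 31)
  set <- Biostrings::DNAStringSet(seqs)
  for (word in c("ATC", "GGGG", "TTATT"))
    expect_equal(countWord(set, word), oracleCountWord(seqs, word))
})

test_that("dimer counting matches the brute-force scanner", {
  p <- Biostrings::DNAStringSet(c(x = "ATCAAAAAAAAAAGAT"))
  cd <- countDimer(p, PalindromicDimer("ATC", 10))
  expect_equal(cd$n_obs, 1L)
  expect_equal(cd$sites$start, 0L)
  expect_equal(cd$sites$end, 16L)
  expect_equal(countDimer(Biostrings::DNAStringSet("AAATTT"),
                          PalindromicDimer("AAA", 0))$n_obs, 1L)
  expect_equal(countDimer(Biostrings::DNAStringSet("AAATT"),
                          PalindromicDimer("AAA", 0))$n_obs, 0L)
  # N anywhere in the two words blocks the match
  expect_equal(countDimer(Biostrings::DNAStringSet("AANTTT"),
                          PalindromicDimer("AAA", 0))$n_obs, 0L)

  seqs <- randomSeqs(10, 200, seed = 77)
  set <- Biostrings::DNAStringSet(seqs)
  set.seed(78)
  cand <- enumerateDimers()
  pick <- cand[sample.int(nrow(cand), 60), ]
  for (i in seq_len(nrow(pick))) {
    d <- PalindromicDimer(pick$w1[i], pick$spacer[i])
    expect_equal(countDimer(set, d)$n_obs,
                 oracleCountDimer(seqs, pick$w1[i], pick$spacer[i]),
                 info = pick$name[i])
  }
})

test_that("dimer counts are invariant under reverse complementing", {
  seqs <- randomSeqs(5, 120, seed = 12)
  fwd <- Biostrings::DNAStringSet(seqs)
  rev <- Biostrings::DNAStringSet(revComp(seqs))
  names(rev) <- names(fwd)
  for (nm in c("0 3 AAA", "4 4 TGAC", "8 5 TGACA", "2 3 GCA")) {
    d <- decodeMotifName(nm)
    f <- countDimer(fwd, d)
    r <- countDimer(rev, d)
    expect_equal(f$n_obs, r$n_obs, info = nm)
    # coordinates mirror: start' = L - end
    expect_equal(sort(r$sites$start),
                 sort(120 - f$sites$end), info = nm)
  }
})

test_that("effective length clamps at zero placements", {
  expect_equal(effectiveLength(rep(300, 10), 16), 2850L)
  expect_equal(effectiveLength(16, 16), 1L)
  expect_equal(effectiveLength(10, 16), 0L)
  expect_equal(effectiveLength(c(10, 300), 16), 285L)
})

test_that("expected counts follow the frequency-product background", {
  expect_equal(expectedCount(0, 10, 100, 200), 0)
  expect_equal(expectedCount(100, 100, 28500, 29800),
               (100 / 29800)^2 * 28500, tolerance = 1e-12)
  expect_equal(expectedCount(100, 100, 28500, 29800), 0.3209,
               tolerance = 1e-3)
  expect_equal(expectedCount(30, 40, 2000, 1500, form = "simple"),
               30 * 40 / 2000)
  expect_error(expectedCount(1, 1, 10, 0), "positive")
})

test_that("observed null counts match the expected-count model", {
  # pooled over all dimers of one geometry the observed total is a
  # sum of near-Bernoulli indicators; compare to the model total
  p <- simulatePromoters(400, 300, seed = 101)
  sc <- scanDimers(p, wMin = 4, wMax = 4, spacerMin = 10, spacerMax = 10)
  m <- motifTable(sc)
  total_obs <- sum(m$n_obs)
  total_exp <- sum(m$n_exp)
  se <- sqrt(total_exp)
  expect_lt(abs(total_obs - total_exp), 3 * se)
})

test_that("Poisson tail is exact at zero and matches partial sums", {
  expect_identical(poissonPvalue(0, 5), 1)
  expect_identical(poissonPvalue(0, 0), 1)
  expect_equal(poissonPvalue(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poissonPvalue(5, 0.5), oraclePoissonTail(5, 0.5),
               tolerance = 1e-10)
  expect_error(poissonPvalue(-1, 1), "negative")
  # strictly decreasing in n_obs, increasing in lambda
  lam <- 2.5
  ps <- poissonPvalue(0:10, lam)
  expect_true(all(diff(ps) < 0))
  ps2 <- poissonPvalue(3, c(0.5, 1, 2, 4))
  expect_true(all(diff(ps2) > 0))
  # log-scale tail agrees where both are representable
  expect_equal(poissonPvalue(5, 0.5, log.p = TRUE),
               log(poissonPvalue(5, 0.5)), tolerance = 1e-10)
})

test_that("significance threshold derives from observed motifs", {
  m <- data.frame(n_obs = c(0L, 1L, 3L, 7L),
                  p_value = c(1, 0.3, 1e-6, 0.2),
                  log_p = log(c(1, 0.3, 1e-6, 0.2)))
  out <- callSignificantMotifs(m)
  expect_equal(attr(out, "n_motif"), 3L)
  expect_equal(attr(out, "alpha"), 1 / 3)
  expect_equal(out$significant, c(FALSE, TRUE, TRUE, TRUE))
  outAll <- callSignificantMotifs(m, alphaFrom = "all")
  expect_equal(attr(outAll, "alpha"), 1 / 4)
  m0 <- data.frame(n_obs = 0L, p_value = 1, log_p = 0)
  expect_warning(res0 <- callSignificantMotifs(m0), "alpha undefined")
  expect_false(any(res0$significant))
})

test_that("a planted dimer dominates a reduced candidate scan", {
  p <- simulatePromoters(150, 300, seed = 55)
  pl <- plantDimer(p, PalindromicDimer("TGCA", 6), 0.3, seed = 56)
  sc <- scanDimers(pl$promoters, wMin = 3, wMax = 4, spacerMin = 0,
                   spacerMax = 10)
  m <- motifTable(sc)
  top <- m[which.min(m$log_p), ]
  expect_equal(top$name, "6 4 TGCA")
  expect_true(top$significant)
  expect_gte(top$n_obs, 45L)
  # site calls recover the planted coordinates
  sites <- siteCalls(sc, "6 4 TGCA")
  truth <- pl$truth
  expect_true(all(paste(truth$promoter_id, truth$start) %in%
                  paste(sites$promoter_id, sites$start)))
})

test_that("per-promoter counts respect mode and conserve occurrences", {
  sites <- data.frame(
    promoter_id = c("p1", "p1", "p1", "p1", "p1", "p3"),
    start = 0L, end = 10L,
    motif = c("a", "a", "b", "b", "c", "a"),
    matched_seq = "x", stringsAsFactors = FALSE)
  ids <- c("p1", "p2", "p3")
  dis <- promoterTFBSCounts(sites, "distinct", promoterIds = ids)
  occ <- promoterTFBSCounts(sites, "occurrences", promoterIds = ids)
  expect_equal(unname(dis), c(3L, 0L, 1L))
  expect_equal(unname(occ), c(5L, 0L, 1L))
  expect_equal(sum(occ), nrow(sites))
})
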