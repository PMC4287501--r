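test_that("metagenome density is homogeneous of degree zero", {
  expect_equal(metagenomeDensity(30, 10, 300), 0.01)
  expect_equal(metagenomeDensity(0, 10, 300), 0)
  expect_equal(metagenomeDensity(60, 20, 300),
               metagenomeDensity(30, 10, 300))
  expect_error(metagenomeDensity(5, 0), ">= 1")
})

test_that("top-k ranking extends over boundary ties and nests", {
  cv <- setNames(c(5, 4, 3, 2, 1), paste0("p", 1:5))
  rb <- rankAndBin(cv, c(20, 40))
  expect_equal(rb$groups$top20, "p1")
  expect_equal(sort(rb$groups$top40), c("p1", "p2"))

  cvTie <- setNames(c(5, 5, 3, 2, 1), paste0("p", 1:5))
  expect_setequal(rankAndBin(cvTie, 20)$groups$top20, c("p1", "p2"))

  # permutation invariance and nesting over the default percent list
  set.seed(8)
  cvBig <- setNames(sample(0:12, 60, TRUE), paste0("q", 1:60))
  rb1 <- rankAndBin(cvBig)
  rb2 <- rankAndBin(sample(cvBig))
  for (g in names(rb1$groups))
    expect_setequal(rb1$groups[[g]], rb2$groups[[g]])
  sizes <- lengths(rb1$groups)
  expect_true(all(diff(sizes) >= 0))
  for (i in seq_len(length(rb1$groups) - 1))
    expect_true(all(rb1$groups[[i]] %in% rb1$groups[[i + 1]]))
  expect_setequal(names(rb1$bins), names(cvBig))
  expect_error(rankAndBin(numeric(0)), "empty")
})

test_that("single-table exact p-values match hypergeometric enumeration", {
  expect_equal(fisherTailP(1, 0, 0, 1, "greater"), 0.5)
  expect_equal(fisherTailP(10, 0, 0, 10, "two.sided"),
               2 * choose(10, 10) * choose(10, 0) / choose(20, 10),
               tolerance = 1e-12)
  set.seed(90)
  for (i in 1:60) {
    cells <- as.vector(stats::rmultinom(1, sample(4:28, 1), rep(1, 4)))
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    expect_equal(fisherTailP(a, b, cc, d, "greater"),
                 oracleFisherGreater(a, b, cc, d), tolerance = 1e-9)
    expect_equal(fisherTailP(a, b, cc, d, "two.sided"),
                 oracleFisherTwoSided(a, b, cc, d), tolerance = 1e-9)
  }
})

test_that("within-environment enrichment builds group-vs-complement tables", {
  # 20 annotated promoters; the top group of 5 holds 4 of the 6 F-labelled
  ids <- paste0("p", 1:20)
  ann <- data.frame(
    promoter_id = ids,
    function_label = c(rep("F;X", 6), rep("G;Y", 14)),
    stringsAsFactors = FALSE)
  groups <- list(top = c("p1", "p2", "p3", "p4", "p7"))
  res <- fisherEnrichment(groups, ann)
  row <- res[res$level == 1 & res$function_label == "F", ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(4, 1, 2, 13))
  expect_equal(row$p_raw, oracleFisherGreater(4, 1, 2, 13),
               tolerance = 1e-9)
  expect_equal(row$odds_direction, "enriched")
  # Bonferroni multiplies by the family size at that level, capped at 1
  fam <- res[res$level == 1, ]
  expect_equal(fam$p_bonferroni, pmin(1, fam$p_raw * nrow(fam)))
  expect_true(all(res$p_bonferroni >= res$p_raw))
  # both hierarchy levels are tested
  expect_setequal(unique(res$level), c(1L, 2L))
  expect_error(
    fisherEnrichment(groups, rbind(ann, ann[1, ])), "one annotation")
})

test_that("balanced tables are never called enriched", {
  ids <- paste0("p", 1:16)
  ann <- data.frame(promoter_id = ids,
                    function_label = rep(c("F", "G"), 8),
                    stringsAsFactors = FALSE)
  res <- fisherEnrichment(list(g = ids[1:8]), ann)
  expect_true(all(res$p_raw >= 0.5))
})

test_that("cross-environment comparison is symmetric and two-sided", {
  ann <- data.frame(promoter_id = c(paste0("a", 1:10), paste0("b", 1:10)),
                    function_label = c(rep("F", 10), rep("G", 10)),
                    stringsAsFactors = FALSE)
  ce <- crossEnvironmentFisher(paste0("a", 1:10), paste0("b", 1:10),
                               ann, "F")
  expect_equal(ce$p_value, 2 * choose(10, 10) / choose(20, 10),
               tolerance = 1e-9)
  flip <- crossEnvironmentFisher(paste0("b", 1:10), paste0("a", 1:10),
                                 ann, "F")
  expect_equal(ce$p_value, flip$p_value)
  # identical composition -> p = 1
  same <- crossEnvironmentFisher(paste0("a", 1:5), paste0("a", 6:10),
                                 ann, "F")
  expect_equal(same$p_value, 1)
  # zero margin flagged
  zm <- crossEnvironmentFisher(paste0("a", 1:5), paste0("a", 6:10),
                               ann, "H")
  expect_equal(zm$p_value, 1)
  expect_equal(zm$note, "zero margin")
  expect_error(crossEnvironmentFisher(character(0), "b1", ann, "F"),
               "non-empty")
})

test_that("Kruskal-Wallis H matches the rank formula and a permutation p", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskalWallisDensity(g)
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$H, oracleKWStatistic(g), tolerance = 1e-12)
  expect_equal(kw$df, 2L)
  expect_equal(kruskalWallisDensity(list(1:3, 1:3))$H, 0)
  ident <- kruskalWallisDensity(list(c(2, 2), c(2, 2)))
  expect_equal(ident$H, 0)
  expect_equal(ident$p, 1)
  expect_error(kruskalWallisDensity(list(1:3)), ">= 2")

  # permutation oracle on a 3 x 5 toy (tie-free)
  toy <- list(c(0.1, 2.3, 1.7, 5.2, 0.9),
              c(3.1, 4.4, 2.8, 6.0, 3.7),
              c(1.2, 0.4, 2.2, 1.9, 0.8))
  obs <- kruskalWallisDensity(toy)
  x <- unlist(toy)
  set.seed(123)
  B <- 1e5
  perm <- replicate(B, {
    xs <- sample(x)
    oracleKWStatistic(list(xs[1:5], xs[6:10], xs[11:15]))
  })
  pPerm <- (sum(perm >= obs$H - 1e-12) + 1) / (B + 1)
  mcErr <- 3 * sqrt(pPerm * (1 - pPerm) / B)
  # the asymptotic chi-square p and the exact permutation p agree to
  # within Monte-Carlo error plus the small-sample approximation gap
  expect_lt(abs(obs$p - pPerm), mcErr + 0.02)
})

test_that("co-occurrence by bin counts shared functions and signs correctly", {
  # high-bin promoters carry environment-unique functions, low-bin
  # promoters a function shared by all three environments
  envs <- rep(c("e1", "e2", "e3"), each = 4)
  ids <- paste0(envs, "_", rep(1:4, 3))
  lab <- ifelse(rep(1:4, 3) <= 2, "shared",
                paste0("unique_", envs, "_", rep(1:4, 3)))
  ann <- data.frame(promoter_id = ids, environment = envs,
                    function_label = lab, stringsAsFactors = FALSE)
  counts <- setNames(ifelse(rep(1:4, 3) <= 2, 1, 9), ids)
  bins <- setNames(ifelse(counts > 5, "high", "low"), ids)
  cb <- cooccurrenceByBin(ann, bins, counts)
  expect_equal(unname(cb$table["low", "3"]), 6L)   # shared in 3 envs
  expect_equal(unname(cb$table["high", "1"]), 6L)  # unique
  expect_lt(cb$spearman$rho, 0)
  expect_lt(cb$spearman$p, 0.01)
  # conservation: cells sum to distinct (environment, function) bin rows
  expect_equal(sum(cb$table), nrow(unique(ann)))
  # degenerate: everything shared -> constant vector warning
  annC <- transform(ann, function_label = "shared")
  expect_warning(cbC <- cooccurrenceByBin(annC, bins,
                                          setNames(rep(2, 12), ids)),
                 "constant")
  expect_true(is.na(cbC$spearman$rho))
  expect_error(cooccurrenceByBin(ann[ann$environment == "e1", ],
                                 bins, counts), ">= 2 environments")
})

test_that("rank correlation equals Pearson on midranks", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(rankCorrelation(x, x)$rho, 1)
  expect_equal(rankCorrelation(1:5, 5:1)$rho, -1)
  set.seed(17)
  a <- rnorm(100); b <- a + rnorm(100, sd = 2)
  rc <- rankCorrelation(a, b)
  expect_equal(rc$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  # t-approximation p
  n <- 100
  tStat <- rc$rho * sqrt((n - 2) / (1 - rc$rho^2))
  expect_equal(rc$p, 2 * pt(-abs(tStat), n - 2), tolerance = 1e-9)
  expect_warning(flat <- rankCorrelation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(flat$rho))
  expect_error(rankCorrelation(1:3, 1:4), "equal length")
})
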