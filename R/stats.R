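## Downstream regulatory-potential statistics: densities, top-k%
## binning, Fisher enrichment with Bonferroni, cross-environment
## comparison, Kruskal-Wallis density tests, co-occurrence by bin,
## rank correlation.

#' Per-metagenome TFBS density
#'
#' `D(x) = n_sites / (N * Tbp)`: sites per base pair of promoter
#' sequence in an environment. Invariant under duplicating every
#' promoter together with its sites.
#'
#' @param nSites total number of sites.
#' @param nPromoters number of promoters `N` (>= 1).
#' @param promoterLength promoter length `Tbp` in bp (default 300).
#' @return density in sites per bp.
#' @examples
#' metagenomeDensity(30, 10)  # 0.01
#' @export
metagenomeDensity <- function(nSites, nPromoters, promoterLength = 300L) {
  if (any(nPromoters < 1L)) stop("nPromoters must be >= 1")
  stopifnot(promoterLength >= 1L)
  nSites / (nPromoters * promoterLength)
}

#' Rank promoters by regulatory potential and bin them
#'
#' Promoters are ranked by TFBS count, descending. For each `k` in
#' `percents`, the top-k\% group is the smallest prefix holding at
#' least `ceiling(k * n / 100)` promoters, extended to include every
#' promoter tying the boundary count - so membership depends only on
#' the counts, never on input order. Three coarse bins (low / medium /
#' high) are cut at count tertiles, boundary ties going to the lower
#' bin.
#'
#' @param counts named integer vector of per-promoter TFBS counts.
#' @param percents top percentages (default `c(1, 5, 10, 20, 30, 40)`).
#' @return `list(groups, bins, thresholds)`: `groups` is a named list
#'   (`top1`, `top5`, ...) of promoter-id vectors, nested and
#'   non-decreasing in size; `bins` a named factor low/medium/high;
#'   `thresholds` the minimum count of each top group.
#' @export
rankAndBin <- function(counts, percents = c(1, 5, 10, 20, 30, 40)) {
  if (length(counts) == 0L) stop("empty promoter count vector")
  if (is.null(names(counts))) stop("counts must be named by promoter id")
  n <- length(counts)
  sorted <- sort(counts, decreasing = TRUE)
  groups <- list(); thresholds <- numeric(0)
  for (k in sort(percents)) {
    m <- ceiling(k * n / 100)
    boundary <- sorted[m]
    ids <- names(counts)[counts >= boundary]
    groups[[paste0("top", k)]] <- ids
    thresholds[paste0("top", k)] <- boundary
  }
  q <- stats::quantile(counts, c(1, 2) / 3, type = 1)
  bins <- cut(counts, breaks = c(-Inf, q[1], q[2], Inf),
              labels = c("low", "medium", "high"), right = TRUE)
  names(bins) <- names(counts)
  list(groups = groups, bins = bins, thresholds = thresholds)
}

#' Exact p-value for a single 2x2 table
#'
#' One-sided (`"greater"`: enrichment of cell `a`) or two-sided
#' Fisher's exact test via [stats::fisher.test()].
#'
#' @param a,b,c,d cell counts; rows are group / complement, columns
#'   has-function / lacks-function.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return the exact p-value.
#' @export
fisherTailP <- function(a, b, c, d,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stats::fisher.test(matrix(c(a, b, c, d), 2L),
                     alternative = alternative)$p.value
}

## explode hierarchical labels "A;B;C" into one row per prefix level
.annotationLevels <- function(annotations) {
  parts <- strsplit(annotations$function_label, ";", fixed = TRUE)
  depth <- lengths(parts)
  idx <- rep(seq_len(nrow(annotations)), depth)
  lvl <- unlist(lapply(depth, seq_len), use.names = FALSE)
  lab <- unlist(lapply(parts, function(p)
    vapply(seq_along(p), function(i) paste(p[seq_len(i)], collapse = ";"),
           "")), use.names = FALSE)
  data.frame(promoter_id = annotations$promoter_id[idx],
             environment = if ("environment" %in% names(annotations))
               annotations$environment[idx] else NA_character_,
             level = lvl, function_label = lab,
             stringsAsFactors = FALSE)
}

#' Within-environment functional enrichment of top regulatory groups
#'
#' For every (group, hierarchy level, function) combination, builds the
#' 2x2 table of in-group / out-group versus has-function /
#' lacks-function over the annotated promoters, tests one-sided
#' enrichment with Fisher's exact test (hypergeometric tail), and
#' applies Bonferroni correction across the functions tested within
#' each (group, level) family.
#'
#' @param groups named list of promoter-id vectors (e.g.
#'   `rankAndBin()$groups`).
#' @param annotations `data.frame` with `promoter_id` and
#'   `function_label` (hierarchy levels separated by `";"`); at most
#'   one label path per promoter.
#' @param alpha significance level after correction (default 0.05).
#' @return `data.frame` with one row per test: `group`, `level`,
#'   `function_label`, `a`, `b`, `c`, `d`, `odds_direction`, `p_raw`,
#'   `p_bonferroni`, `significant`.
#' @export
fisherEnrichment <- function(groups, annotations, alpha = 0.05) {
  if (anyDuplicated(annotations$promoter_id))
    stop("at most one annotation path per promoter")
  lv <- .annotationLevels(annotations)
  universe <- unique(annotations$promoter_id)
  out <- list()
  for (g in names(groups)) {
    inGroup <- universe %in% groups[[g]]
    for (l in sort(unique(lv$level))) {
      sub <- lv[lv$level == l, , drop = FALSE]
      funs <- sort(unique(sub$function_label))
      rows <- lapply(funs, function(f) {
        hasF <- universe %in% sub$promoter_id[sub$function_label == f]
        a <- sum(inGroup & hasF); b <- sum(inGroup & !hasF)
        cc <- sum(!inGroup & hasF); d <- sum(!inGroup & !hasF)
        p <- fisherTailP(a, b, cc, d, "greater")
        expected <- (a + b) * (a + cc) / length(universe)
        data.frame(group = g, level = l, function_label = f,
                   a = a, b = b, c = cc, d = d,
                   odds_direction = if (a > expected) "enriched"
                                    else "depleted",
                   p_raw = p, stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, rows)
      fam$p_bonferroni <- stats::p.adjust(fam$p_raw, "bonferroni")
      fam$significant <- fam$p_bonferroni < alpha
      out[[paste(g, l)]] <- fam
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-environment comparison of one function between top groups
#'
#' Two-sided Fisher's exact test of environment versus
#' has-function / lacks-function, restricted to the two top groups.
#'
#' @param groupA,groupB promoter-id vectors (top groups of the two
#'   environments); must be non-empty.
#' @param annotations `data.frame` with `promoter_id`,
#'   `function_label` (full paths; a promoter has the function if the
#'   label equals any prefix level of its path).
#' @param functionLabel the function to compare.
#' @return one-row `data.frame` with the 2x2 counts and the two-sided
#'   p-value; a zero margin yields `p = 1` with a `note`.
#' @export
crossEnvironmentFisher <- function(groupA, groupB, annotations,
                                   functionLabel) {
  if (!length(groupA) || !length(groupB))
    stop("both groups must be non-empty")
  lv <- .annotationLevels(annotations)
  withF <- unique(lv$promoter_id[lv$function_label == functionLabel])
  a <- sum(groupA %in% withF); b <- length(groupA) - a
  cc <- sum(groupB %in% withF); d <- length(groupB) - cc
  note <- ""
  if ((a + cc) == 0L || (b + d) == 0L) {
    p <- 1
    note <- "zero margin"
  } else {
    p <- fisherTailP(a, b, cc, d, "two.sided")
  }
  data.frame(function_label = functionLabel, a = a, b = b, c = cc, d = d,
             p_value = p, note = note, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis test of per-promoter density across environments
#'
#' Rank-based H with midrank tie correction and a chi-square asymptotic
#' p-value on `groups - 1` degrees of freedom, via
#' [stats::kruskal.test()]. If every observation is identical the test
#' is degenerate and `H = 0, p = 1` is returned by convention.
#'
#' @param values list of numeric vectors (one per environment, each
#'   non-empty), or a single numeric vector with `groups` given.
#' @param groups grouping factor when `values` is a vector.
#' @return `list(H, df, p)`.
#' @examples
#' kruskalWallisDensity(list(1:3, 4:6, 7:9))  # H = 7.2
#' @export
kruskalWallisDensity <- function(values, groups = NULL) {
  if (is.list(values)) {
    if (length(values) < 2L || any(lengths(values) == 0L))
      stop("need >= 2 non-empty groups")
    x <- unlist(values, use.names = FALSE)
    g <- factor(rep(seq_along(values), lengths(values)))
  } else {
    x <- values
    g <- factor(groups)
    if (nlevels(g) < 2L) stop("need >= 2 non-empty groups")
  }
  if (length(unique(x)) == 1L)
    return(list(H = 0, df = nlevels(g) - 1L, p = 1))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Function co-occurrence across environments, by regulatory bin
#'
#' For each low/medium/high bin, counts how many distinct
#' (environment, function) assignments in that bin involve functions
#' present in exactly 1, 2, ... environments, and tests the association
#' between a promoter's TFBS count and the number of environments
#' sharing its function with a Spearman rank correlation.
#'
#' @param annotations `data.frame` with `promoter_id`, `environment`,
#'   `function_label`; at least two environments.
#' @param bins named factor/character of low/medium/high per promoter
#'   (from [rankAndBin()]).
#' @param counts named per-promoter TFBS counts.
#' @return `list(table, spearman)`: `table` is the bin x
#'   n-environments contingency matrix; `spearman` the correlation
#'   (`rho`, `p`), `NA` with a warning if either vector is constant.
#' @export
cooccurrenceByBin <- function(annotations, bins, counts) {
  envs <- unique(annotations$environment)
  if (length(envs) < 2L)
    stop("co-occurrence requires >= 2 environments")
  sharing <- tapply(annotations$environment, annotations$function_label,
                    function(e) length(unique(e)))
  ann <- unique(annotations[, c("promoter_id", "environment",
                                "function_label")])
  ann$bin <- as.character(bins[ann$promoter_id])
  ann$n_env <- as.integer(sharing[ann$function_label])
  tab <- table(bin = factor(ann$bin, levels = c("low", "medium", "high")),
               n_env = factor(ann$n_env, levels = seq_along(envs)))
  x <- as.numeric(counts[ann$promoter_id])
  y <- ann$n_env
  if (length(unique(x)) <= 1L || length(unique(y)) <= 1L) {
    warning("constant vector; co-occurrence correlation undefined")
    sp <- list(rho = NA_real_, p = NA_real_)
  } else {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    sp <- list(rho = unname(ct$estimate), p = ct$p.value)
  }
  list(table = unclass(tab), spearman = sp)
}

#' Spearman rank correlation between two count vectors
#'
#' Rho on midranks with a t-approximation p-value, via
#' [stats::cor.test()] with `exact = FALSE`. Used e.g. to compare
#' per-promoter site counts from two prediction methods.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return `list(rho, p)`; both `NA` with a warning for a constant
#'   vector.
#' @export
rankCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (length(unique(x)) <= 1L || length(unique(y)) <= 1L) {
    warning("constant vector; rank correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
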