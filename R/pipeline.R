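## Orchestration: validated run configuration, stage runners that read
## and write the package's file dialects with reproducible headers, and
## a thin command-line wrapper (inst/exec/palinreg).

.CONFIG_DEFAULTS <- list(
  minReadLength = 800L, minAlignmentAA = 150L, minIdentity = 50,
  upstreamLength = 300L, requireNoncoding = 300L, dedupIdentity = 0.98,
  wMin = 3L, wMax = 5L, spacerMin = 0L, spacerMax = 30L,
  expectedForm = "frequency", alphaFrom = "observed",
  countMode = "distinct", shuffleWindow = 20L,
  percents = c(1, 5, 10, 20, 30, 40), enrichmentAlpha = 0.05,
  seed = NA_integer_)

#' Build a validated run configuration
#'
#' All stage parameters with their defaults: 800 nt minimum read
#' length, 150 aa / >50\% identity hit filter, 300 nt upstream window,
#' 0.98 de-redundancy identity, word width 3-5, spacer 0-30, 20 nt
#' shuffle window, top percentages 1/5/10/20/30/40. Unknown keys are
#' errors; every value is type- and range-checked.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `"RegulomeConfig"`.
#' @examples
#' cfg <- regulomeConfig(minReadLength = 500)
#' cfg$minReadLength
#' @export
regulomeConfig <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration values must be named")
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  with(cfg, {
    stopifnot(minReadLength >= 1, minAlignmentAA >= 1,
              minIdentity >= 0, minIdentity <= 100,
              upstreamLength >= 1, requireNoncoding >= upstreamLength,
              dedupIdentity > 0, dedupIdentity <= 1,
              wMin >= 1, wMin <= wMax, spacerMin >= 0,
              spacerMin <= spacerMax, shuffleWindow >= 1,
              all(percents > 0), all(percents <= 100),
              enrichmentAlpha > 0, enrichmentAlpha < 1)
  })
  cfg$expectedForm <- match.arg(cfg$expectedForm, c("frequency", "simple"))
  cfg$alphaFrom <- match.arg(cfg$alphaFrom, c("observed", "all"))
  cfg$countMode <- match.arg(cfg$countMode, c("distinct", "occurrences"))
  structure(cfg, class = "RegulomeConfig")
}

#' Read a configuration file (flat YAML subset)
#'
#' @param path path to a YAML file of `key: value` pairs using the
#'   [regulomeConfig()] field names.
#' @param ... overrides applied on top of the file values.
#' @return a validated `RegulomeConfig`.
#' @export
readConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  do.call(regulomeConfig, utils::modifyList(vals, list(...)))
}

.configString <- function(cfg) {
  flat <- vapply(cfg, function(v) paste(v, collapse = ","), "")
  paste(paste0(names(flat), "=", flat), collapse = "; ")
}

## reproducible comment header for every output table
.outputHeader <- function(cfg, inputs = character(0), extra = character(0)) {
  sums <- if (length(inputs))
    paste0(basename(inputs), ":", unname(tools::md5sum(inputs)))
  else character(0)
  c(paste0("# palinreg ", as.character(utils::packageVersion("palinreg"))),
    paste0("# config: ", .configString(cfg)),
    if (length(sums)) paste0("# inputs: ", paste(sums, collapse = " ")),
    extra,
    paste0("# timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

.writeTable <- function(tab, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a headered TSV written by the stage runners
#'
#' @param path path to the TSV (comment lines start with `#`).
#' @return `data.frame`.
#' @export
readStageTable <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run the promoter-extraction stage on files
#'
#' Reads a FASTA of reads and a tabular alignment file, runs
#' [extractPromoters()], and writes `promoters.fasta`, `report.tsv` and
#' `clusters.tsv` into `outDir`.
#'
#' @param readsFasta path to the reads FASTA.
#' @param alignmentFile path to the 12-column alignment table.
#' @param outDir output directory (created if missing).
#' @param config a [regulomeConfig()].
#' @param environment sample label for the promoters.
#' @param excludedReadsFile,excludedPromotersFile optional one-id-per-line
#'   exclusion lists.
#' @return the [extractPromoters()] result, invisibly.
#' @export
runExtract <- function(readsFasta, alignmentFile, outDir,
                       config = regulomeConfig(),
                       environment = NA_character_,
                       excludedReadsFile = NULL,
                       excludedPromotersFile = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  reads <- readSequences(readsFasta)
  hits <- readAlignmentTable(alignmentFile)
  exR <- if (!is.null(excludedReadsFile)) readLines(excludedReadsFile)
         else character(0)
  exP <- if (!is.null(excludedPromotersFile))
           readLines(excludedPromotersFile) else character(0)
  res <- extractPromoters(reads, hits,
                          minReadLength = config$minReadLength,
                          minAlignmentAA = config$minAlignmentAA,
                          minIdentity = config$minIdentity,
                          upstreamLength = config$upstreamLength,
                          requireNoncoding = config$requireNoncoding,
                          dedupIdentity = config$dedupIdentity,
                          environment = environment,
                          excludedReads = exR, excludedPromoters = exP)
  if (length(res$promoters) == 0L)
    warning("zero promoters extracted")
  hdr <- .outputHeader(config, c(readsFasta, alignmentFile))
  writeSequences(res$promoters, file.path(outDir, "promoters.fasta"))
  .writeTable(res$report, file.path(outDir, "report.tsv"), hdr)
  .writeTable(res$clusters, file.path(outDir, "clusters.tsv"), hdr)
  invisible(res)
}

#' Run the dimer-discovery stage on a promoter FASTA
#'
#' Scans with [scanDimers()] and writes `motifs.tsv` (full candidate
#' table), `sites.tsv` (sites of significant motifs) and
#' `promoter_counts.tsv` (per-promoter regulatory potential), each with
#' `N_motif` and alpha recorded in the header.
#'
#' @param promoters path to a promoter FASTA, or a `PromoterSet`.
#' @param outDir output directory.
#' @param config a [regulomeConfig()].
#' @param environment sample label written into the counts table.
#' @return the [DimerScan], invisibly.
#' @export
runDiscover <- function(promoters, outDir, config = regulomeConfig(),
                        environment = NA_character_) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.character(promoters)) {
    inputs <- promoters
    promoters <- PromoterSet(readSequences(promoters),
                             environment = environment)
  } else if (!is.na(environment)) {
    if (!is(promoters, "PromoterSet")) promoters <- PromoterSet(promoters)
    mcols(promoters)$environment <- environment
  }
  if (length(promoters) == 0L) {
    warning("empty promoter set; writing empty outputs")
    scan <- NULL
    sites <- data.frame(promoter_id = character(0), start = integer(0),
                        end = integer(0), motif = character(0),
                        matched_seq = character(0))
    counts <- data.frame(promoter_id = character(0),
                         environment = character(0),
                         tfbs_count = integer(0), mode = character(0))
    hdr <- .outputHeader(config, inputs, "# N_motif: 0; alpha: NA")
    .writeTable(sites, file.path(outDir, "sites.tsv"), hdr)
    .writeTable(counts, file.path(outDir, "promoter_counts.tsv"), hdr)
    return(invisible(NULL))
  }
  scan <- scanDimers(promoters, wMin = config$wMin, wMax = config$wMax,
                     spacerMin = config$spacerMin,
                     spacerMax = config$spacerMax,
                     expectedForm = config$expectedForm,
                     alphaFrom = config$alphaFrom)
  hdr <- .outputHeader(config, inputs,
                       paste0("# N_motif: ", nMotif(scan), "; alpha: ",
                              format(scanAlpha(scan), digits = 6)))
  mot <- as.data.frame(motifTable(scan))
  mot$alpha <- scanAlpha(scan)
  .writeTable(mot, file.path(outDir, "motifs.tsv"), hdr)
  sites <- siteCalls(scan)
  .writeTable(sites, file.path(outDir, "sites.tsv"), hdr)
  cnt <- promoterTFBSCounts(scan, config$countMode)
  env <- environmentLabel(scan@promoters)
  counts <- data.frame(promoter_id = names(cnt), environment = env,
                       tfbs_count = as.integer(cnt),
                       mode = config$countMode, stringsAsFactors = FALSE)
  .writeTable(counts, file.path(outDir, "promoter_counts.tsv"), hdr)
  invisible(scan)
}

#' Run the downstream statistics stage
#'
#' From a per-promoter count table and a function-annotation table,
#' computes per-environment densities, top-k\% groups, within-
#' environment Fisher enrichment (Bonferroni-corrected) and, when
#' several environments are annotated, the co-occurrence-by-bin
#' analysis. Writes `density.tsv`, `enrichment.tsv` and
#' `cooccurrence.tsv`.
#'
#' @param countsFile `promoter_counts.tsv` from [runDiscover()] (or a
#'   `data.frame` in that layout).
#' @param annotationsFile TSV with columns `promoter_id`,
#'   `environment`, `function_label` (levels separated by `";"`), or a
#'   `data.frame`.
#' @param outDir output directory.
#' @param config a [regulomeConfig()].
#' @return `list(density, groups, enrichment, cooccurrence)`,
#'   invisibly.
#' @export
runStats <- function(countsFile, annotationsFile, outDir,
                     config = regulomeConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  counts <- if (is.character(countsFile)) {
    inputs <- c(inputs, countsFile); readStageTable(countsFile)
  } else countsFile
  ann <- if (is.character(annotationsFile)) {
    inputs <- c(inputs, annotationsFile); readStageTable(annotationsFile)
  } else annotationsFile
  unknown <- setdiff(ann$promoter_id, counts$promoter_id)
  if (length(unknown))
    warning("annotations reference unknown promoter(s): ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  hdr <- .outputHeader(config, inputs)

  dens <- do.call(rbind, lapply(split(counts, counts$environment),
    function(sub) data.frame(
      environment = sub$environment[1L], tfbs = "all",
      n_sites = sum(sub$tfbs_count), n_promoters = nrow(sub),
      promoter_length = config$upstreamLength,
      density = metagenomeDensity(sum(sub$tfbs_count), nrow(sub),
                                  config$upstreamLength),
      stringsAsFactors = FALSE)))
  .writeTable(dens, file.path(outDir, "density.tsv"), hdr)

  enrAll <- list(); coocc <- NULL
  binsByEnv <- list()
  for (e in unique(counts$environment)) {
    sub <- counts[counts$environment == e, , drop = FALSE]
    cv <- stats::setNames(sub$tfbs_count, sub$promoter_id)
    rb <- rankAndBin(cv, config$percents)
    binsByEnv[[as.character(e)]] <- rb$bins
    annE <- ann[ann$environment == e &
                ann$promoter_id %in% sub$promoter_id, , drop = FALSE]
    if (nrow(annE)) {
      enr <- fisherEnrichment(rb$groups, annE, config$enrichmentAlpha)
      enr <- data.frame(environment = e, enr, stringsAsFactors = FALSE)
      enrAll[[as.character(e)]] <- enr
    }
  }
  enrichment <- if (length(enrAll)) do.call(rbind, enrAll) else NULL
  if (!is.null(enrichment)) {
    rownames(enrichment) <- NULL
    .writeTable(enrichment, file.path(outDir, "enrichment.tsv"), hdr)
  }
  if (length(unique(ann$environment)) >= 2L) {
    bins <- unlist(lapply(binsByEnv, as.character))
    names(bins) <- unlist(lapply(binsByEnv, names))
    cvAll <- stats::setNames(counts$tfbs_count, counts$promoter_id)
    coocc <- cooccurrenceByBin(ann, bins, cvAll)
    cot <- as.data.frame.table(as.table(coocc$table),
                               responseName = "n_functions")
    .writeTable(cot, file.path(outDir, "cooccurrence.tsv"),
                c(hdr, paste0("# spearman_rho: ", coocc$spearman$rho,
                              "; p: ", coocc$spearman$p)))
  }
  invisible(list(density = dens,
                 groups = lapply(binsByEnv, identity),
                 enrichment = enrichment, cooccurrence = coocc))
}

#' Run the validation stage
#'
#' Performs the real-versus-shuffled re-discovery control
#' ([shuffledRediscovery()]) and, when a known-motif library is given,
#' the consensus match-up ([scanKnownMotifs()]). Writes
#' `validation_report.tsv` with the per-promoter real and shuffled
#' counts and the Mann-Whitney result in the header.
#'
#' @param promoters path to a promoter FASTA, or a `PromoterSet`.
#' @param outDir output directory.
#' @param config a [regulomeConfig()]; `config$seed` must be set.
#' @param knownMotifsFile optional TSV, see [readKnownMotifs()].
#' @return the [shuffledRediscovery()] result plus `knownMatch`,
#'   invisibly.
#' @export
runValidate <- function(promoters, outDir, config = regulomeConfig(),
                        knownMotifsFile = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.character(promoters)) {
    inputs <- promoters
    promoters <- PromoterSet(readSequences(promoters))
  }
  if (is.na(config$seed)) stop("config$seed is required for validation")
  res <- shuffledRediscovery(promoters, seed = config$seed,
                             windowSize = config$shuffleWindow,
                             mode = config$countMode,
                             wMin = config$wMin, wMax = config$wMax,
                             spacerMin = config$spacerMin,
                             spacerMax = config$spacerMax,
                             expectedForm = config$expectedForm,
                             alphaFrom = config$alphaFrom)
  known <- NULL
  if (!is.null(knownMotifsFile)) {
    lib <- readKnownMotifs(knownMotifsFile)
    sites <- siteCalls(res$realScan)
    known <- scanKnownMotifs(sites, lib)
  }
  hdr <- .outputHeader(config, inputs, c(
    paste0("# seed: ", config$seed),
    paste0("# real_alpha: ", format(res$realScan@alpha, digits = 6),
           "; shuffled_alpha: ",
           format(res$shuffledScan@alpha, digits = 6)),
    paste0("# mann_whitney_W: ", res$test$statistic, "; p: ",
           format(res$test$p, digits = 6)),
    if (!is.null(known))
      paste0("# known_motif_fraction: ",
             format(known$fraction, digits = 6))))
  .writeTable(res$counts, file.path(outDir, "validation_report.tsv"), hdr)
  res$knownMatch <- known
  invisible(res)
}
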