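#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @import Biostrings
NULL

#' PromoterSet: a set of fixed-orientation promoter sequences
#'
#' A thin extension of [Biostrings::DNAStringSet] that carries, per
#' promoter, the provenance needed by the downstream statistics: the
#' source read, the strand of the downstream gene relative to that read,
#' the 0-based offset of the promoter within the read, the protein
#' subject of the downstream coding hit, and the environment (sample)
#' label. All sequences are stored 5'->3' with respect to the downstream
#' gene, so the last base of each promoter abuts the coding start.
#'
#' Sequences are restricted to the alphabet A, C, G, T, N and names must
#' be unique.
#'
#' @slot .Data inherited `DNAStringSet` internals.
#' @seealso [PromoterSet()], [extractPromoters()]
#' @export
setClass("PromoterSet", contains = "DNAStringSet")

setValidity("PromoterSet", function(object) {
  msgs <- character()
  if (length(object) > 0L) {
    if (is.null(names(object)) || anyNA(names(object)) ||
        any(names(object) == ""))
      msgs <- c(msgs, "all promoters must be named")
    else if (anyDuplicated(names(object)))
      msgs <- c(msgs, "promoter names must be unique")
    af <- alphabetFrequency(object, baseOnly = TRUE)
    # baseOnly collapses everything outside ACGT into "other"; that
    # bucket must be N only
    other <- af[, "other"]
    nN <- vcountPattern("N", object, fixed = TRUE)
    if (any(other != nN))
      msgs <- c(msgs, "sequences may only contain A, C, G, T, N")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PromoterSet
#'
#' @param x a `DNAStringSet`, character vector, or existing `PromoterSet`.
#' @param sourceRead,strand,offset,geneSubject,environment optional
#'   per-promoter metadata vectors, recycled to `length(x)`; stored in
#'   `mcols()` under the names `source_read`, `strand`, `offset`,
#'   `gene_subject`, `environment`.
#' @return a `PromoterSet`.
#' @examples
#' p <- PromoterSet(c(p1 = "ACGTACGT"), environment = "soil")
#' environmentLabel(p)
#' @export
PromoterSet <- function(x, sourceRead = NA_character_, strand = NA_character_,
                        offset = NA_integer_, geneSubject = NA_character_,
                        environment = NA_character_) {
  if (is.character(x)) x <- DNAStringSet(x)
  x <- as(x, "DNAStringSet")
  n <- length(x)
  mc <- DataFrame(
    source_read  = rep_len(as.character(sourceRead), n),
    strand       = rep_len(as.character(strand), n),
    offset       = rep_len(as.integer(offset), n),
    gene_subject = rep_len(as.character(geneSubject), n),
    environment  = rep_len(as.character(environment), n)
  )
  out <- new("PromoterSet", x)
  mcols(out) <- mc
  validObject(out)
  out
}

#' @describeIn PromoterSet environment (sample) label of each promoter.
#' @export
environmentLabel <- function(x) {
  mc <- mcols(x)
  if (is.null(mc) || !"environment" %in% colnames(mc))
    return(rep(NA_character_, length(x)))
  as.character(mc$environment)
}

#' @describeIn PromoterSet source read id of each promoter.
#' @export
sourceRead <- function(x) {
  mc <- mcols(x)
  if (is.null(mc) || !"source_read" %in% colnames(mc))
    return(rep(NA_character_, length(x)))
  as.character(mc$source_read)
}

setMethod("show", "PromoterSet", function(object) {
  cat("PromoterSet of", length(object), "promoters")
  if (length(object)) {
    w <- unique(width(object))
    if (length(w) == 1L) cat(", all", w, "nt")
    env <- unique(environmentLabel(object))
    env <- env[!is.na(env)]
    if (length(env)) cat("; environments:", paste(env, collapse = ", "))
  }
  cat("\n")
  if (length(object)) callNextMethod()
  invisible(NULL)
})

#' PalindromicDimer: a W1-spacer-W2 inverted-repeat motif
#'
#' The motif model is a pair of words where the downstream word is the
#' reverse complement of the upstream word, separated by `spacer`
#' unconstrained bases. `w1` is 3-5 nt and the spacer 0-30 nt by
#' default, so motif lengths run from 6 to 40 nt. The full pattern
#' `w1 . N^spacer . w2` is its own reverse complement, so a single-strand
#' scan finds every instance on either strand.
#'
#' @slot w1 character, the upstream word (A/C/G/T).
#' @slot spacer integer, number of unconstrained bases between the words.
#' @export
setClass("PalindromicDimer",
         representation(w1 = "character", spacer = "integer"))

setValidity("PalindromicDimer", function(object) {
  msgs <- character()
  if (length(object@w1) != 1L || is.na(object@w1))
    msgs <- c(msgs, "w1 must be a single string")
  else if (!grepl("^[ACGT]+$", object@w1))
    msgs <- c(msgs, "w1 must be over A, C, G, T")
  if (length(object@spacer) != 1L || is.na(object@spacer) ||
      object@spacer < 0L)
    msgs <- c(msgs, "spacer must be a single non-negative integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PalindromicDimer
#'
#' @param w1 upstream word (3-5 nt over A/C/G/T in the default model;
#'   any positive length is accepted at construction).
#' @param spacer number of arbitrary bases between `w1` and its reverse
#'   complement.
#' @return a `PalindromicDimer`.
#' @examples
#' d <- PalindromicDimer("ATC", 10)
#' dimerW2(d)          # "GAT"
#' expandedPattern(d)  # "ATCNNNNNNNNNNGAT"
#' @export
PalindromicDimer <- function(w1, spacer) {
  obj <- new("PalindromicDimer", w1 = toupper(as.character(w1)),
             spacer = as.integer(spacer))
  validObject(obj)
  obj
}

#' @describeIn PalindromicDimer the upstream word.
#' @param x,d a `PalindromicDimer`.
#' @export
dimerW1 <- function(d) d@w1

#' @describeIn PalindromicDimer the downstream word, always recomputed
#'   as the reverse complement of `w1`.
#' @export
dimerW2 <- function(d) revComp(d@w1)

#' @describeIn PalindromicDimer the spacer length.
#' @export
dimerSpacer <- function(d) d@spacer

#' @describeIn PalindromicDimer total motif length `2 * nchar(w1) + spacer`.
#' @export
motifLength <- function(d) 2L * nchar(d@w1) + d@spacer

setMethod("show", "PalindromicDimer", function(object) {
  cat("PalindromicDimer", encodeMotifName(object),
      "| pattern:", expandedPattern(object), "\n")
  invisible(NULL)
})

#' DimerScan: the result of a genome-wide palindromic dimer scan
#'
#' Holds the scanned promoters, the full candidate motif table with
#' observed and expected counts and Poisson tail probabilities, the
#' number of observed candidate motifs used for the significance
#' threshold, and the scan parameters.
#'
#' @slot promoters the scanned `PromoterSet` (kept so sites and
#'   per-promoter counts can be recomputed on demand).
#' @slot motifs `DataFrame` with one row per candidate dimer: `name`,
#'   `w`, `spacer`, `w1`, `w2`, `n_obs`, `n_w1`, `n_w2`, `leff_d`,
#'   `leff_w`, `n_exp`, `p_value`, `log_p`, `significant`.
#' @slot nMotif integer, number of candidate dimers observed at least
#'   once (the Bonferroni-style family size).
#' @slot alpha numeric, significance threshold `1 / nMotif`.
#' @slot params list of scan parameters.
#' @seealso [scanDimers()], [significantMotifs()], [siteCalls()],
#'   [promoterTFBSCounts()]
#' @export
setClass("DimerScan",
         representation(promoters = "PromoterSet", motifs = "DataFrame",
                        nMotif = "integer", alpha = "numeric",
                        params = "list"))

setMethod("show", "DimerScan", function(object) {
  m <- object@motifs
  cat("DimerScan over", length(object@promoters), "promoters\n")
  cat("  candidate dimers:", nrow(m),
      "| observed (n_obs >= 1):", object@nMotif, "\n")
  cat("  alpha = 1/N_motif =", format(object@alpha, digits = 4),
      "| significant motifs:", sum(m$significant), "\n")
  cat("  expected-count form:", object@params$expectedForm, "\n")
  invisible(NULL)
})

#' @describeIn DimerScan the full candidate motif table as a `DataFrame`.
#' @param x a `DimerScan`.
#' @export
motifTable <- function(x) {
  stopifnot(is(x, "DimerScan"))
  x@motifs
}

#' @describeIn DimerScan the significance threshold `1 / N_motif`.
#' @export
scanAlpha <- function(x) {
  stopifnot(is(x, "DimerScan"))
  x@alpha
}

#' @describeIn DimerScan number of candidate dimers observed at least once.
#' @export
nMotif <- function(x) {
  stopifnot(is(x, "DimerScan"))
  x@nMotif
}

#' @describeIn DimerScan rows of the motif table flagged significant,
#'   ordered by increasing log-scale p-value.
#' @export
significantMotifs <- function(x) {
  stopifnot(is(x, "DimerScan"))
  m <- x@motifs[x@motifs$significant, , drop = FALSE]
  m[order(m$log_p), , drop = FALSE]
}
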