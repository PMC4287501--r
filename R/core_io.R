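## Sequence + table ingestion shared by every stage.
##
## Conventions: coordinates are 0-based half-open on the forward strand
## of the source read everywhere inside the package; 1-based inclusive
## only at file boundaries (the tabular alignment dialect).

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalize raw sequence strings to the A/C/G/T/N alphabet
#'
#' Uppercases, maps IUPAC ambiguity codes (R, Y, S, W, K, M, B, D, H, V)
#' to N with a counted warning, and errors on anything else. `U` is
#' accepted as `T`.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over A, C, G, T, N.
#' @keywords internal
.normalizeSequences <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", x)
  nAmb <- 0L
  if (any(nzchar(bad))) {
    chars <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
    unknown <- setdiff(chars, .IUPAC_AMBIG)
    if (length(unknown))
      stop("invalid sequence character(s): ",
           paste(unknown, collapse = ", "))
    nAmb <- sum(nchar(bad))
    x <- chartr(paste(.IUPAC_AMBIG, collapse = ""),
                strrep("N", length(.IUPAC_AMBIG)), x)
    warning(nAmb, " IUPAC ambiguity base(s) mapped to N")
  }
  x
}

#' Read nucleotide sequences from FASTA
#'
#' Wraps [Biostrings::readBStringSet()] and then normalizes: sequences
#' are uppercased, IUPAC ambiguity codes are mapped to N with a counted
#' warning, and any other character is an error. Record order is
#' preserved; the FASTA id (first whitespace-delimited token) becomes
#' the name and must be unique; the remainder of the header line is kept
#' as the description.
#'
#' @param path path to a FASTA file.
#' @return a named `DNAStringSet`; descriptions in
#'   `mcols(x)$description`. An empty file yields an empty set with a
#'   warning.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">r1 first read", "acgt"), f)
#' readSequences(f)
#' @export
readSequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBStringSet(path)
  if (length(raw) == 0L) {
    warning("empty FASTA file: ", path)
    out <- DNAStringSet()
    mcols(out) <- DataFrame(description = character(0))
    return(out)
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- .normalizeSequences(as.character(raw))
  out <- DNAStringSet(seqs)
  names(out) <- ids
  mcols(out) <- DataFrame(description = desc)
  out
}

#' Write nucleotide sequences to FASTA
#'
#' Emits 70-column wrapped FASTA via [Biostrings::writeXStringSet()].
#' Descriptions stored in `mcols(x)$description` are appended to the
#' header line.
#'
#' @param x a named `XStringSet` (e.g. `DNAStringSet`, `PromoterSet`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSequences <- function(x, path) {
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    stop("all sequences must be named")
  y <- as(x, "DNAStringSet")
  mc <- mcols(x)
  if (!is.null(mc) && "description" %in% colnames(mc)) {
    d <- as.character(mc$description)
    keep <- !is.na(d) & nzchar(d)
    names(y)[keep] <- paste(names(y)[keep], d[keep])
  }
  writeXStringSet(y, path, width = 70L)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' Watson-Crick complement, reversed; N maps to N. Vectorized over a
#' character vector; delegates to [Biostrings::reverseComplement()].
#'
#' @param x character vector over A, C, G, T, N (case-insensitive).
#' @return character vector of reverse complements.
#' @examples
#' revComp("ATC")   # "GAT"
#' revComp("ACGT")  # "ACGT" (self-reverse-complementary)
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- toupper(as.character(x))
  if (any(grepl("[^ACGTN]", x)))
    stop("revComp: sequences must be over A, C, G, T, N")
  as.character(reverseComplement(DNAStringSet(x)))
}

.OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read a tabular protein-alignment table (BLAST outfmt-6 dialect)
#'
#' Parses the 12-column tab-separated dialect (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`,
#' query coordinates 1-based inclusive) and normalizes query coordinates
#' to 0-based half-open forward-strand intervals. A query with
#' `qstart > qend` is a minus-frame hit: `frame_sign` records the
#' original orientation and `read_start < read_end` always holds after
#' normalization.
#'
#' @param path path to the tab-separated file (no header).
#' @return `data.frame` with columns `read_id`, `subject_id`,
#'   `percent_identity`, `alignment_length_aa`, `read_start`,
#'   `read_end`, `frame_sign`, `bitscore`.
#' @examples
#' f <- tempfile()
#' writeLines("r1\tprotA\t85.5\t200\t29\t0\t101\t400\t1\t100\t1e-50\t210",
#'            f)
#' readAlignmentTable(f)
#' @export
readAlignmentTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty alignment table: ", path)
    return(.emptyHits())
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 12L))
    stop("malformed alignment row (expected 12 tab-separated fields) ",
         "at line ", which(nf != 12L)[1L])
  tab <- utils::read.table(text = lines, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           col.names = .OUTFMT6_COLS,
                           colClasses = c("character", "character",
                                          "numeric", "integer", "integer",
                                          "integer", "integer", "integer",
                                          "integer", "integer", "numeric",
                                          "numeric"))
  if (any(tab$qstart == tab$qend))
    stop("degenerate query coordinates (qstart == qend) at line ",
         which(tab$qstart == tab$qend)[1L])
  if (any(tab$pident < 0 | tab$pident > 100))
    stop("percent identity outside [0, 100] at line ",
         which(tab$pident < 0 | tab$pident > 100)[1L])
  if (any(tab$length < 1L))
    stop("alignment length < 1 at line ", which(tab$length < 1L)[1L])
  minus <- tab$qstart > tab$qend
  data.frame(
    read_id = tab$qseqid,
    subject_id = tab$sseqid,
    percent_identity = tab$pident,
    alignment_length_aa = tab$length,
    read_start = ifelse(minus, tab$qend, tab$qstart) - 1L,
    read_end = ifelse(minus, tab$qstart, tab$qend),
    frame_sign = ifelse(minus, "-", "+"),
    bitscore = tab$bitscore,
    stringsAsFactors = FALSE
  )
}

.emptyHits <- function() {
  data.frame(read_id = character(0), subject_id = character(0),
             percent_identity = numeric(0),
             alignment_length_aa = integer(0),
             read_start = integer(0), read_end = integer(0),
             frame_sign = character(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write alignment hits back to the 12-column tabular dialect
#'
#' Inverse of [readAlignmentTable()] up to the columns the package does
#' not model (mismatch, gapopen, subject coordinates, e-value are
#' emitted as placeholders). Used mainly by the fixture generators.
#'
#' @param hits `data.frame` in the [readAlignmentTable()] layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAlignmentTable <- function(hits, path) {
  minus <- hits$frame_sign == "-"
  qstart <- ifelse(minus, hits$read_end, hits$read_start + 1L)
  qend <- ifelse(minus, hits$read_start + 1L, hits$read_end)
  out <- data.frame(hits$read_id, hits$subject_id, hits$percent_identity,
                    hits$alignment_length_aa, 0L, 0L, qstart, qend,
                    1L, hits$alignment_length_aa, 0, hits$bitscore)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## run expr with a private, restored RNG stream seeded by `seed`
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
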