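# Type IIB enzyme model and in-silico digestion into fixed-length 2bRAD tags.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Define a type IIB restriction enzyme
#'
#' A type IIB enzyme cuts on both sides of a (possibly degenerate, bipartite)
#' recognition site, excising a fragment of fixed length: `flank5` bases
#' 5' of the recognition span, the span itself, and `flank3` bases 3' of it,
#' all read on the strand carrying the site.
#'
#' @param name Enzyme name.
#' @param recognition Recognition pattern in IUPAC nucleotide codes
#'   (e.g. `"ACNNNNNCTCC"` for BsaXI).
#' @param flank5,flank3 Non-negative integers: bases retained 5' and 3' of the
#'   recognition span on the tag's source strand.
#' @return An object of class `enzyme_spec` with fields `name`, `recognition`,
#'   `flank5`, `flank3` and `tag_length = flank5 + nchar(recognition) + flank3`.
#' @examples
#' bsaxi()
#' enzyme_spec("toy", "ACGT", 2, 2)
#' @export
enzyme_spec <- function(name, recognition, flank5, flank3) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(recognition), length(recognition) == 1L,
            nchar(recognition) > 0L)
  recognition <- toupper(recognition)
  bad <- setdiff(strsplit(recognition, "")[[1]], names(IUPAC_CODES))
  if (length(bad))
    stop("recognition pattern contains non-IUPAC characters: ",
         paste(unique(bad), collapse = ", "))
  flank5 <- as.integer(flank5); flank3 <- as.integer(flank3)
  if (is.na(flank5) || is.na(flank3) || flank5 < 0L || flank3 < 0L)
    stop("flank5 and flank3 must be non-negative integers")
  structure(
    list(name = name, recognition = recognition,
         flank5 = flank5, flank3 = flank3,
         tag_length = flank5 + nchar(recognition) + flank3),
    class = "enzyme_spec"
  )
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme_spec> %s: %dN + %s + %dN (tag length %d bp)\n",
              x$name, x$flank5, x$recognition, x$flank3, x$tag_length))
  invisible(x)
}

#' The default BsaXI enzyme
#'
#' BsaXI recognizes the bipartite site AC(N5)CTCC and cleaves on both sides,
#' (9/12) upstream and (10/7) downstream (REBASE offsets). The excised duplex
#' spans 12 bases 5' of the recognition span through 10 bases 3' of it on the
#' strand carrying the site, giving a 33-bp tag.
#'
#' @return An `enzyme_spec`.
#' @export
bsaxi <- function() enzyme_spec("BsaXI", "ACNNNNNCTCC", 12L, 10L)

#' Reverse-complement DNA strings
#'
#' Vectorized over its input; accepts A/C/G/T/N and IUPAC ambiguity codes.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Strand-normalize a tag sequence
#'
#' The canonical form of a tag is the lexicographic minimum of the sequence
#' and its reverse complement; it is the strand-independent identity key used
#' throughout the hologenome database. Idempotent, and invariant under
#' reverse complementation of the input.
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of canonical sequences.
#' @export
canonicalize <- function(x) {
  if (!length(x)) return(character(0))
  if (any(grepl("[^ACGT]", x)))
    stop("canonicalize() requires A/C/G/T sequences only")
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Match a window against an IUPAC pattern
#'
#' Each pattern position admits the bases of its IUPAC class; an `N` in the
#' *window* (an ambiguous genome base) matches nothing, so windows containing
#' N never match.
#'
#' @param pattern IUPAC pattern string.
#' @param window DNA window (A/C/G/T/N) of the same length.
#' @return `TRUE` or `FALSE`.
#' @export
match_iupac <- function(pattern, window) {
  if (nchar(pattern) != nchar(window))
    stop("pattern and window must have equal length")
  pc <- strsplit(toupper(pattern), "")[[1]]
  wc <- strsplit(window, "")[[1]]
  if (any(!wc %in% c("A", "C", "G", "T", "N")))
    stop("window must contain only A/C/G/T/N")
  all(vapply(seq_along(pc),
             function(i) wc[i] %in% IUPAC_CODES[[pc[i]]],
             logical(1)))
}

# Vectorized scan of a char vector for an IUPAC pattern.
# Returns 1-based start positions of all matches.
scan_pattern <- function(chars, pattern) {
  n <- length(chars)
  pc <- strsplit(pattern, "")[[1]]
  m <- length(pc)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & (chars[j:(j + n - m)] %in% IUPAC_CODES[[pc[j]]])
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

#' Locate recognition sites on both strands
#'
#' Scans the forward strand for the recognition pattern and for its reverse
#' complement (a minus-strand site). A span matching on both strands
#' (palindromic site) is reported once, with strand `+`.
#'
#' @param seq A single DNA string (A/C/G/T/N).
#' @param enzyme An [enzyme_spec()].
#' @return A data.frame with columns `start` (0-based, position of the
#'   recognition span on the forward strand) and `strand` (`"+"`/`"-"`),
#'   sorted by `start`.
#' @export
find_recognition_sites <- function(seq, enzyme) {
  stopifnot(inherits(enzyme, "enzyme_spec"),
            is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("seq must be nonempty")
  chars <- strsplit(seq, "")[[1]]
  fwd <- scan_pattern(chars, enzyme$recognition)
  rev <- scan_pattern(chars, revcomp(enzyme$recognition))
  rev <- setdiff(rev, fwd)  # palindromic spans reported once, strand +
  out <- data.frame(
    start = c(fwd, rev) - 1L,
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Digest a sequence into 2bRAD tag loci
#'
#' For every recognition site, excises the fixed-length tag: `flank5` bases
#' upstream of the recognition span through `flank3` bases downstream,
#' read on the site's strand. Sites whose flanks run off a sequence end are
#' skipped, as are tags containing an ambiguous base (N).
#'
#' @param seq A single DNA string.
#' @param enzyme An [enzyme_spec()].
#' @param source_id Identifier recorded for the source sequence.
#' @return A data.frame with one row per tag: `source_id`, `start`, `end`
#'   (0-based half-open on the forward strand), `strand`, `sequence`
#'   (as read on `strand`) and `canonical` (strand-normalized key).
#' @export
extract_tags <- function(seq, enzyme, source_id = "seq") {
  sites <- find_recognition_sites(seq, enzyme)
  m <- nchar(enzyme$recognition)
  n <- nchar(seq)
  empty <- data.frame(source_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), canonical = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(sites)) return(empty)
  plus <- sites$strand == "+"
  # forward-strand coordinates of the excised window
  start <- ifelse(plus, sites$start - enzyme$flank5, sites$start - enzyme$flank3)
  end   <- ifelse(plus, sites$start + m + enzyme$flank3,
                  sites$start + m + enzyme$flank5)
  fits <- start >= 0L & end <= n
  if (!any(fits)) return(empty)
  sites <- sites[fits, , drop = FALSE]
  start <- as.integer(start[fits]); end <- as.integer(end[fits])
  fwdseq <- substring(seq, start + 1L, end)
  keep <- !grepl("N", fwdseq, fixed = TRUE)
  if (!any(keep)) return(empty)
  sites <- sites[keep, , drop = FALSE]
  start <- start[keep]; end <- end[keep]; fwdseq <- fwdseq[keep]
  sequence <- ifelse(sites$strand == "+", fwdseq, revcomp(fwdseq))
  data.frame(source_id = source_id, start = start, end = end,
             strand = sites$strand, sequence = sequence,
             canonical = canonicalize(sequence),
             stringsAsFactors = FALSE)
}

# Digest every record of a named character vector of contigs.
extract_tags_all <- function(contigs, enzyme) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    names(contigs) <- paste0("seq", seq_along(contigs))
  do.call(rbind, lapply(names(contigs), function(id)
    extract_tags(contigs[[id]], enzyme, source_id = id)))
}
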