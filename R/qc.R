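# Read quality filtering and sequenced-tag extraction.
#
# Three filters, applied in order with the first failure reported:
#   1. any ambiguous base call (N)
#   2. a homopolymer run longer than 10 bp (strictly greater)
#   3. more than 20% of bases with quality < 10 (strictly greater)

HOMOPOLYMER_RE <- "(A{11,}|C{11,}|G{11,}|T{11,}|N{11,})"

#' Quality-filter a single read
#'
#' @param bases Read sequence (A/C/G/T/N).
#' @param qual Phred+33-encoded quality string of the same length.
#' @return List with `keep` (logical) and `reason` (`NA`, `"N"`,
#'   `"homopolymer"` or `"low_quality"`).
#' @export
filter_read <- function(bases, qual) {
  if (nchar(bases) != nchar(qual))
    stop("invalid record: sequence and quality lengths differ")
  reason <- qc_reasons(bases, qual)
  list(keep = is.na(reason), reason = reason)
}

# Vectorized filter core: returns NA (keep) or the first failing reason.
qc_reasons <- function(seqs, quals) {
  n <- length(seqs)
  reason <- rep(NA_character_, n)
  has_n <- grepl("N", seqs, fixed = TRUE)
  reason[has_n] <- "N"
  todo <- which(!has_n)
  if (length(todo)) {
    hp <- grepl(HOMOPOLYMER_RE, seqs[todo])
    reason[todo[hp]] <- "homopolymer"
    todo <- todo[!hp]
  }
  if (length(todo)) {
    frac <- vapply(quals[todo],
                   function(q) mean(charToRaw(q) < as.raw(43L)),  # Q < 10
                   numeric(1), USE.NAMES = FALSE)
    reason[todo[frac > 0.20]] <- "low_quality"
  }
  reason
}

#' Extract the sequenced 2bRAD tag from a read
#'
#' Scans both strands of the read for the enzyme's recognition pattern at
#' positions where the full tag window fits inside the read, and returns the
#' canonicalized tag. If several placements exist the leftmost on the forward
#' orientation wins (plus strand before minus at equal position).
#'
#' @param bases Read sequence (should have passed [filter_read()]).
#' @param enzyme An [enzyme_spec()].
#' @return Canonical tag string, or `NA_character_` if no placement exists.
#' @export
extract_sequenced_tag <- function(bases, enzyme) {
  sites <- find_recognition_sites(bases, enzyme)
  if (!nrow(sites)) return(NA_character_)
  m <- nchar(enzyme$recognition)
  n <- nchar(bases)
  plus <- sites$strand == "+"
  start <- ifelse(plus, sites$start - enzyme$flank5, sites$start - enzyme$flank3)
  end <- ifelse(plus, sites$start + m + enzyme$flank3,
                sites$start + m + enzyme$flank5)
  fits <- which(start >= 0L & end <= n)
  if (!length(fits)) return(NA_character_)
  i <- fits[1]  # sites are sorted by start with + before - at equal start
  w <- substr(bases, start[i] + 1L, end[i])
  if (grepl("N", w, fixed = TRUE)) return(NA_character_)
  if (sites$strand[i] == "-") w <- revcomp(w)
  canonicalize(w)
}

# Vectorized tag extraction for reads of identical length.
extract_tags_fixed_length <- function(seqs, enzyme) {
  n <- length(seqs)
  if (!n) return(character(0))
  L <- nchar(seqs[1])
  m <- nchar(enzyme$recognition)
  tl <- enzyme$tag_length
  chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  pat_f <- strsplit(enzyme$recognition, "")[[1]]
  pat_r <- strsplit(revcomp(enzyme$recognition), "")[[1]]
  # candidate placements ordered by recognition start, + before -
  cands <- list()
  for (s in 0:(L - m)) {
    ws_f <- s - enzyme$flank5; we_f <- s + m + enzyme$flank3
    if (ws_f >= 0L && we_f <= L)
      cands[[length(cands) + 1L]] <- list(s = s, strand = "+", ws = ws_f, we = we_f)
    ws_r <- s - enzyme$flank3; we_r <- s + m + enzyme$flank5
    if (ws_r >= 0L && we_r <= L)
      cands[[length(cands) + 1L]] <- list(s = s, strand = "-", ws = ws_r, we = we_r)
  }
  assigned <- integer(n)  # 0 = none
  for (k in seq_along(cands)) {
    cd <- cands[[k]]
    pat <- if (cd$strand == "+") pat_f else pat_r
    open <- assigned == 0L
    if (!any(open)) break
    ok <- open
    for (j in seq_len(m)) {
      ok[ok] <- chars[ok, cd$s + j] %in% IUPAC_CODES[[pat[j]]]
      if (!any(ok)) break
    }
    assigned[ok] <- k
  }
  out <- rep(NA_character_, n)
  hit <- which(assigned > 0L)
  if (length(hit)) {
    ws <- vapply(cands, `[[`, numeric(1), "ws")[assigned[hit]]
    w <- substr(seqs[hit], ws + 1L, ws + tl)
    strand <- vapply(cands, `[[`, character(1), "strand")[assigned[hit]]
    noN <- !grepl("N", w, fixed = TRUE)
    minus <- strand == "-" & noN
    w[minus] <- revcomp(w[minus])
    out[hit[noN]] <- canonicalize(w[noN])
  }
  out
}

#' High-quality read rate
#'
#' @param raw,hq Raw and high-quality read counts.
#' @return Percentage `100 * hq / raw`, rounded to 2 decimals (0 if `raw` is 0).
#' @export
hq_rate <- function(raw, hq) {
  ifelse(raw > 0, round(100 * hq / raw, 2), 0)
}

#' Quality-filter a FASTQ library and extract sequenced tags
#'
#' Applies the three read filters, then extracts the canonical 2bRAD tag of
#' every surviving read that contains a full recognition-site window.
#'
#' @param path FASTQ path (Phred+33; gzip transparent), or a data.frame as
#'   returned by [read_fastq()].
#' @param enzyme An [enzyme_spec()].
#' @return List with `tags` (data.frame `read_id`, `tag`) and `stats`
#'   (class `qc_stats`): `raw_reads`, `hq_reads`, `hq_rate` (2 decimals;
#'   flagged `undefined` when the input is empty), `tags_with_site`, and
#'   per-reason rejection tallies.
#' @export
process_fastq <- function(path, enzyme) {
  reads <- if (is.data.frame(path)) path else read_fastq(path)
  n <- nrow(reads)
  if (n && any(nchar(reads$seq) != nchar(reads$qual)))
    stop("invalid record: sequence and quality lengths differ")
  reason <- if (n) qc_reasons(reads$seq, reads$qual) else character(0)
  keep <- is.na(reason)
  hq <- reads[keep, , drop = FALSE]
  if (nrow(hq)) {
    if (length(unique(nchar(hq$seq))) == 1L) {
      tag <- extract_tags_fixed_length(hq$seq, enzyme)
    } else {
      tag <- vapply(hq$seq, extract_sequenced_tag, character(1),
                    enzyme = enzyme, USE.NAMES = FALSE)
    }
  } else tag <- character(0)
  with_site <- !is.na(tag)
  stats <- structure(list(
    raw_reads = n,
    hq_reads = nrow(hq),
    hq_rate = hq_rate(n, nrow(hq)),
    rate_undefined = n == 0L,
    tags_with_site = sum(with_site),
    rejected = c(N = sum(reason == "N", na.rm = TRUE),
                 homopolymer = sum(reason == "homopolymer", na.rm = TRUE),
                 low_quality = sum(reason == "low_quality", na.rm = TRUE),
                 no_site = sum(!with_site))
  ), class = "qc_stats")
  list(tags = data.frame(read_id = hq$id[with_site], tag = tag[with_site],
                         stringsAsFactors = FALSE),
       stats = stats)
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf(
    "<qc_stats> raw %d | HQ %d (%.2f%%) | with site %d | rejected N=%d hp=%d lowQ=%d\n",
    x$raw_reads, x$hq_reads, x$hq_rate, x$tags_with_site,
    x$rejected[["N"]], x$rejected[["homopolymer"]], x$rejected[["low_quality"]]))
  invisible(x)
}
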