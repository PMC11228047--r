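# Independent oracle implementations used to cross-check the package's
# digestion, marker discovery and read filtering. These deliberately use
# different machinery (regex engine, hash tables, per-read loops) from the
# implementation paths they check.

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_to_regex <- function(pattern) {
  paste(IUPAC_REGEX[strsplit(pattern, "")[[1]]], collapse = "")
}

# Manual reverse complement, independent of Biostrings.
rc_manual <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# All 0-based match starts of an IUPAC pattern via the regex engine
# (overlapping matches through lookahead).
regex_sites <- function(seq, pattern) {
  re <- paste0("(?=", iupac_to_regex(pattern), ")")
  m <- gregexpr(re, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# Naive double-strand digestion oracle.
naive_digest <- function(seq, enzyme) {
  m <- nchar(enzyme$recognition)
  fwd <- regex_sites(seq, enzyme$recognition)
  rev <- setdiff(regex_sites(seq, rc_manual(enzyme$recognition)), fwd)
  sites <- rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+") else NULL,
    if (length(rev)) data.frame(start = rev, strand = "-") else NULL)
  if (is.null(sites)) return(data.frame(start = integer(0),
                                        strand = character(0),
                                        sequence = character(0)))
  sites <- sites[order(sites$start, sites$strand), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    s <- sites$start[i]
    if (sites$strand[i] == "+") {
      a <- s - enzyme$flank5; b <- s + m + enzyme$flank3
    } else {
      a <- s - enzyme$flank3; b <- s + m + enzyme$flank5
    }
    if (a < 0 || b > nchar(seq)) return(NULL)
    w <- substr(seq, a + 1, b)
    if (grepl("N", w, fixed = TRUE)) return(NULL)
    if (sites$strand[i] == "-") w <- rc_manual(w)
    data.frame(start = a, end = b, strand = sites$strand[i], sequence = w,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               strand = character(0), sequence = character(0))
  else out
}

canonical_manual <- function(x) {
  rc <- rc_manual(x)
  ifelse(x <= rc, x, rc)
}

# Brute-force marker finder: hash every tag of every genome and apply the
# definition directly.
brute_markers <- function(genomes, taxonomy, enzyme, rank = "species") {
  occ <- list()
  for (g in names(genomes)) {
    contigs <- genomes[[g]]
    tags <- unlist(lapply(contigs, function(s) naive_digest(s, enzyme)$sequence))
    for (tg in canonical_manual(tags)) {
      occ[[tg]] <- c(occ[[tg]], g)
    }
  }
  lab <- stats::setNames(taxonomy[[rank]], taxonomy$genome_id)
  res <- list()
  for (tg in names(occ)) {
    carriers <- occ[[tg]]
    if (any(duplicated(carriers))) next        # multi-copy in some genome
    taxa <- unique(lab[carriers])
    if (length(taxa) != 1L) next               # shared across taxa
    res[[tg]] <- unname(taxa)
  }
  data.frame(tag = names(res), taxon = unlist(res, use.names = FALSE),
             stringsAsFactors = FALSE)[order(names(res)), , drop = FALSE]
}

# Straightforward per-read re-implementation of the three filters.
naive_filter <- function(seq, qual) {
  chars <- strsplit(seq, "")[[1]]
  if (any(chars == "N")) return("N")
  run <- 1L
  for (i in seq_along(chars)[-1]) {
    run <- if (chars[i] == chars[i - 1]) run + 1L else 1L
    if (run > 10L) return("homopolymer")
  }
  q <- as.integer(charToRaw(qual)) - 33L
  if (sum(q < 10L) / length(q) > 0.20) return("low_quality")
  NA_character_
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Parse simulator truth labels out of read ids.
parse_read_src <- function(ids) {
  src <- sub("^.*\\|src=([^|]+)\\|.*$", "\\1", ids)
  tag <- sub("^.*\\|tag=([^|]+).*$", "\\1", ids)
  data.frame(src = src, tag = tag, stringsAsFactors = FALSE)
}
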