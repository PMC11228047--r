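# File I/O: FASTA (via Biostrings), FASTQ (validated 4-line records),
# taxonomy tables, and small TSV/JSON report writers.

TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order",
                    "family", "genus", "species")

#' Read a (multi-record, possibly wrapped) FASTA file
#'
#' Sequences are upper-cased and validated: bases other than A/C/G/T/N are
#' rejected at parse time.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad))
    stop("sequence(s) with bases other than A/C/G/T/N: ",
         paste(utils::head(names(out)[bad], 3), collapse = ", "))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Minimal strict reader for 4-line FASTQ records; transparently reads
#' gzip-compressed files. Malformed records raise an error naming the
#' offending record number.
#'
#' @param path Path to a FASTQ (optionally .gz) file.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated record ",
         length(lines) %/% 4L + 1L)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")[1]
  if (!is.na(bad))
    stop("malformed FASTQ '", path, "': bad header/separator in record ", bad)
  bad <- which(nchar(seqs) != nchar(qual) | grepl("[^ACGTN]", seqs))[1]
  if (!is.na(bad))
    stop("malformed FASTQ '", path,
         "': sequence/quality mismatch or invalid base in record ", bad)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hdr)),
             seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Data.frame with columns `id`, `seq`, `qual` (quality as an
#'   encoded string).
#' @param path Output path (gzip if it ends in `.gz`).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

# Encode integer Phred scores as a +33 string.
encode_phred <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

# Decode a +33 quality string to integer scores.
decode_phred <- function(s) as.integer(charToRaw(s)) - 33L

#' Read a rank-structured taxonomy table
#'
#' Expects a TSV with a `genome_id` column followed by the seven canonical
#' ranks (kingdom, phylum, class, order, family, genus, species). Unknown
#' intermediate ranks may be encoded as `unclassified_<parent>` labels.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `genome_id` + the seven ranks.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_taxonomy(tx)
}

validate_taxonomy <- function(tx) {
  need <- c("genome_id", TAXONOMY_RANKS)
  miss <- setdiff(need, names(tx))
  if (length(miss))
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tx$genome_id))
    stop("taxonomy table has duplicated genome_id entries")
  incomplete <- !stats::complete.cases(tx[need]) |
    rowSums(tx[need] == "" | is.na(tx[need])) > 0
  if (any(incomplete))
    stop("incomplete lineage for genome(s): ",
         paste(utils::head(tx$genome_id[incomplete], 3), collapse = ", "))
  tx[need]
}

#' @rdname read_taxonomy
#' @param tx Taxonomy data.frame as returned by [read_taxonomy()].
#' @export
write_taxonomy <- function(tx, path) {
  utils::write.table(tx, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
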