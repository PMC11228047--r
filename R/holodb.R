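# Hologenome database construction: host-unique tags, microbial
# taxon-specific single-copy markers, cross-redundancy removal and its
# impact report, and TSV/JSON serialization.

#' Enumerate and de-duplicate host 2bRAD tags
#'
#' Digests the host genome and stratifies the resulting canonical tags into
#' the *distinct* (non-redundant) set and the *unique* set: canonical tags
#' with genome-wide copy number exactly 1, counting a tag and its reverse
#' complement at two loci as two copies.
#'
#' @param genome Named character vector of host contigs, or a FASTA path.
#' @param enzyme An [enzyme_spec()].
#' @return An object of class `host_tagset`: list with `all_loci` (tag locus
#'   data.frame), `distinct` and `unique` (character vectors of canonical
#'   tags), and `enzyme`.
#' @export
build_host_tagset <- function(genome, enzyme) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (!length(genome) || !sum(nchar(genome)))
    stop("empty host genome")
  loci <- extract_tags_all(genome, enzyme)
  if (is.null(loci)) loci <- extract_tags("A", enzyme)  # empty frame
  counts <- table(loci$canonical)
  structure(
    list(all_loci = loci,
         distinct = names(counts),
         unique = names(counts)[counts == 1L],
         enzyme = enzyme),
    class = "host_tagset"
  )
}

#' @export
print.host_tagset <- function(x, ...) {
  cat(sprintf("<host_tagset> %d loci, %d distinct, %d unique (%s)\n",
              nrow(x$all_loci), length(x$distinct), length(x$unique),
              x$enzyme$name))
  invisible(x)
}

#' Build a taxon-specific single-copy marker database
#'
#' A canonical tag is a rank-`R` marker for taxon `T` iff it is single-copy
#' within every genome that carries it and all carrying genomes belong to
#' `T` at rank `R`. Tags violating either condition are discarded.
#'
#' @param genomes Named list of genomes (each a named character vector of
#'   contigs or a single sequence), names being `genome_id`s.
#' @param taxonomy Taxonomy data.frame ([read_taxonomy()]).
#' @param enzyme An [enzyme_spec()].
#' @param rank Target rank (default `"species"`).
#' @return An object of class `marker_db`: `markers` (data.frame `tag`,
#'   `taxon`), per-taxon `theoretical` counts, `genome_markers`,
#'   `genome_stats`, `taxon_lineages`, `taxonomy`, `rank`, `enzyme`.
#' @export
build_marker_db <- function(genomes, taxonomy, enzyme, rank = "species") {
  stopifnot(rank %in% TAXONOMY_RANKS)
  taxonomy <- validate_taxonomy(taxonomy)
  miss <- setdiff(names(genomes), taxonomy$genome_id)
  if (length(miss))
    stop("genome(s) missing from taxonomy: ", paste(miss, collapse = ", "))
  gids <- sort(names(genomes))  # order-independent marker assignment
  per_genome <- lapply(gids, function(g) {
    contigs <- genomes[[g]]
    if (is.null(names(contigs))) names(contigs) <- paste0(g, "_c", seq_along(contigs))
    tags <- extract_tags_all(contigs, enzyme)
    if (is.null(tags) || !nrow(tags))
      return(data.frame(genome_id = character(0), tag = character(0),
                        copies = integer(0), stringsAsFactors = FALSE))
    tb <- table(tags$canonical)
    data.frame(genome_id = g, tag = names(tb), copies = as.integer(tb),
               n_loci = nrow(tags), stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, per_genome)
  lab <- taxonomy[[rank]][match(occ$genome_id, taxonomy$genome_id)]
  # markers: single-copy in every carrier, all carriers in one taxon
  single_ok <- !(occ$tag %in% occ$tag[occ$copies > 1L])
  ntax <- tapply(lab, occ$tag, function(x) length(unique(x)))
  marker_tags <- names(ntax)[ntax == 1L]
  marker_tags <- marker_tags[marker_tags %in% occ$tag[single_ok]]
  markers <- data.frame(
    tag = marker_tags,
    taxon = lab[match(marker_tags, occ$tag)],
    stringsAsFactors = FALSE
  )
  markers <- markers[order(markers$tag), , drop = FALSE]
  rownames(markers) <- NULL
  theoretical <- table(markers$taxon)
  mocc <- occ[occ$tag %in% markers$tag, c("genome_id", "tag"), drop = FALSE]
  rownames(mocc) <- NULL
  gm <- tapply(mocc$tag, mocc$genome_id, function(x) length(unique(x)))
  genome_markers <- data.frame(
    genome_id = gids,
    taxon = taxonomy[[rank]][match(gids, taxonomy$genome_id)],
    n_markers = as.integer(ifelse(is.na(gm[gids]), 0L, gm[gids])),
    stringsAsFactors = FALSE
  )
  gstats <- do.call(rbind, lapply(per_genome, function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(genome_id = d$genome_id[1], n_loci = d$n_loci[1],
               n_distinct = nrow(d),
               frac_single_copy = mean(d$copies == 1L),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(markers = markers,
         theoretical = theoretical,
         marker_occ = mocc,
         genome_markers = genome_markers,
         genome_stats = gstats,
         taxon_lineages = unique(taxonomy[TAXONOMY_RANKS]),
         taxonomy = taxonomy,
         rank = rank, enzyme = enzyme),
    class = "marker_db"
  )
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf("<marker_db> %d %s-level markers for %d taxa (%s)\n",
              nrow(x$markers), x$rank, length(unique(x$markers$taxon)),
              x$enzyme$name))
  invisible(x)
}

#' Merge host tags and microbial markers into a hologenome database
#'
#' Canonical tags present in both the host-unique set and the microbial
#' marker set are deleted from both sides (secondary cross-redundancy
#' removal), and the impact is reported: host tags removed (as a fraction of
#' all non-redundant host tags), microbial genomes left with zero markers,
#' and per-rank fractions of taxa affected (lost at least one marker) or
#' removed (lost all markers).
#'
#' @param host A [build_host_tagset()] result.
#' @param microbial A [build_marker_db()] result.
#' @return An object of class `holodb`.
#' @export
merge_holodb <- function(host, microbial) {
  stopifnot(inherits(host, "host_tagset"), inherits(microbial, "marker_db"))
  if (!identical(host$enzyme$name, microbial$enzyme$name) ||
      !identical(host$enzyme$tag_length, microbial$enzyme$tag_length))
    stop("host and microbial databases were built with different enzymes")
  overlap <- intersect(host$unique, microbial$markers$tag)

  host_tags <- setdiff(host$unique, overlap)
  keep <- !(microbial$markers$tag %in% overlap)
  markers <- microbial$markers[keep, , drop = FALSE]
  removed_markers <- microbial$markers[!keep, , drop = FALSE]

  # per-genome marker loss -> genomes whose marker count fell to zero
  before <- microbial$genome_markers
  occ_after <- microbial$marker_occ[
    !(microbial$marker_occ$tag %in% overlap), , drop = FALSE]
  after_counts <- table(occ_after$genome_id)
  n_after <- as.integer(after_counts[before$genome_id])
  n_after[is.na(n_after)] <- 0L
  genomes_removed <- sum(before$n_markers > 0L & n_after == 0L)
  genomes_with_markers <- sum(before$n_markers > 0L)

  per_rank <- do.call(rbind, lapply(TAXONOMY_RANKS, function(r) {
    map <- microbial$taxon_lineages
    lift <- function(sp) map[[r]][match(sp, map[[microbial$rank]])]
    all_taxa <- unique(microbial$taxonomy[[r]])
    affected <- unique(lift(removed_markers$taxon))
    tot_after <- tapply(rep(1L, nrow(markers)), lift(markers$taxon), sum)
    had_before <- unique(lift(names(microbial$theoretical)))
    removed <- setdiff(had_before, names(tot_after))
    data.frame(rank = r, n_taxa = length(all_taxa),
               taxa_affected = length(affected),
               taxa_removed = length(intersect(removed, affected)),
               frac_affected = length(affected) / max(1L, length(all_taxa)),
               frac_removed = length(intersect(removed, affected)) /
                 max(1L, length(all_taxa)),
               stringsAsFactors = FALSE)
  }))

  removal <- list(
    host_tags_removed = length(overlap),
    host_frac_of_distinct = length(overlap) / max(1L, length(host$distinct)),
    genomes_removed = genomes_removed,
    genomes_frac = genomes_removed / max(1L, genomes_with_markers),
    per_rank = per_rank,
    removed_tags = overlap
  )

  theoretical <- table(markers$taxon)
  db <- structure(
    list(enzyme = host$enzyme, rank = microbial$rank,
         host_tags = sort(host_tags),
         host_stats = list(n_loci = nrow(host$all_loci),
                           n_distinct = length(host$distinct),
                           n_unique = length(host$unique)),
         markers = markers,
         theoretical = theoretical,
         taxon_lineages = microbial$taxon_lineages,
         genome_stats = microbial$genome_stats,
         removal = removal),
    class = "holodb"
  )
  stopifnot(length(intersect(db$host_tags, db$markers$tag)) == 0L)
  db
}

#' @export
print.holodb <- function(x, ...) {
  cat(sprintf(paste0("<holodb> %s (%d-bp tags): %d host-unique tags, ",
                     "%d %s markers for %d taxa; %d cross-redundant tag(s) removed\n"),
              x$enzyme$name, x$enzyme$tag_length, length(x$host_tags),
              nrow(x$markers), x$rank, length(unique(x$markers$taxon)),
              x$removal$host_tags_removed))
  invisible(x)
}

#' Summarize a hologenome database
#'
#' Per-rank marker counts (markers aggregated up the lineage), mean tags per
#' genome and the fraction of tags that are single-copy within genomes.
#'
#' @param db A `holodb`.
#' @return List with `per_rank` (data.frame), `mean_tags_per_genome`,
#'   `frac_single_copy`, and the host tag counts.
#' @export
db_summary <- function(db) {
  stopifnot(inherits(db, "holodb"))
  per_rank <- do.call(rbind, lapply(TAXONOMY_RANKS, function(r) {
    if (!nrow(db$markers))
      return(data.frame(rank = r, n_taxa = 0L, n_markers = 0L,
                        mean_markers_per_taxon = NA_real_,
                        stringsAsFactors = FALSE))
    map <- db$taxon_lineages
    lab <- map[[r]][match(db$markers$taxon, map[[db$rank]])]
    tb <- table(lab)
    data.frame(rank = r, n_taxa = length(tb), n_markers = sum(tb),
               mean_markers_per_taxon = mean(tb), stringsAsFactors = FALSE)
  }))
  gs <- db$genome_stats
  list(per_rank = per_rank,
       mean_tags_per_genome = if (is.null(gs)) NA_real_ else mean(gs$n_loci),
       frac_single_copy = if (is.null(gs)) NA_real_ else
         stats::weighted.mean(gs$frac_single_copy, gs$n_distinct),
       host = db$host_stats)
}

#' Serialize / load a hologenome database
#'
#' Writes one greppable TSV of `(tag, kind, label, lineage)`, a JSON metadata
#' header (enzyme, tag length, counts, removal report) and the per-rank
#' summary TSV.
#'
#' @param db A `holodb`.
#' @param dir Output directory (created if needed).
#' @export
write_holodb <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lin <- db$taxon_lineages
  mlin <- apply(lin[match(db$markers$taxon, lin[[db$rank]]), TAXONOMY_RANKS,
                    drop = FALSE], 1L, paste, collapse = ";")
  tab <- rbind(
    data.frame(tag = db$host_tags, kind = "host", label = "host",
               lineage = "", stringsAsFactors = FALSE),
    data.frame(tag = db$markers$tag, kind = "microbe",
               label = db$markers$taxon,
               lineage = as.character(mlin), stringsAsFactors = FALSE)
  )
  write_tsv(tab, file.path(dir, "holodb.tsv"))
  s <- db_summary(db)
  write_tsv(s$per_rank, file.path(dir, "rank_summary.tsv"))
  write_tsv(db$removal$per_rank, file.path(dir, "removal_report.tsv"))
  meta <- list(
    enzyme = db$enzyme[c("name", "recognition", "flank5", "flank3",
                         "tag_length")],
    rank = db$rank,
    host = db$host_stats,
    n_markers = nrow(db$markers),
    n_taxa = length(unique(db$markers$taxon)),
    mean_tags_per_genome = s$mean_tags_per_genome,
    frac_single_copy = s$frac_single_copy,
    removal = db$removal[c("host_tags_removed", "host_frac_of_distinct",
                           "genomes_removed", "genomes_frac")]
  )
  write_json_file(meta, file.path(dir, "metadata.json"))
  lineages <- unique(lin[TAXONOMY_RANKS])
  write_tsv(lineages, file.path(dir, "lineages.tsv"))
  invisible(dir)
}

#' @rdname write_holodb
#' @export
read_holodb <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  tab <- read_tsv(file.path(dir, "holodb.tsv"))
  enz <- enzyme_spec(meta$enzyme$name, meta$enzyme$recognition,
                     meta$enzyme$flank5, meta$enzyme$flank3)
  mk <- tab[tab$kind == "microbe", , drop = FALSE]
  markers <- data.frame(tag = mk$tag, taxon = mk$label,
                        stringsAsFactors = FALSE)
  lineages <- read_tsv(file.path(dir, "lineages.tsv"))
  removal <- meta$removal
  removal$per_rank <- read_tsv(file.path(dir, "removal_report.tsv"))
  structure(
    list(enzyme = enz, rank = meta$rank,
         host_tags = tab$tag[tab$kind == "host"],
         host_stats = meta$host,
         markers = markers,
         theoretical = table(markers$taxon),
         taxon_lineages = lineages,
         genome_stats = NULL,
         removal = removal),
    class = "holodb")
}
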