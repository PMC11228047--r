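# Tag classification against a hologenome database, host/microbe
# partitioning, and species-level relative-abundance profiling.

# Hamming-match queries against all db tags, both orientations.
# queries/db_tags: character vectors of equal-length sequences; labels gives
# the assignment label of each db tag. Two tie notions are tracked at the
# best distance within the mismatch radius:
#   entry_tie      - >= 2 distinct db entries equally close (pileup discards)
#   label_conflict - >= 2 distinct labels equally close (classifier unassigns)
match_tags_to_db <- function(queries, db_tags, labels, max_mismatch,
                             chunk_size = 2000L) {
  nq <- length(queries)
  res <- data.frame(best = rep(NA_integer_, nq), dist = rep(NA_integer_, nq),
                    entry_tie = rep(FALSE, nq),
                    label_conflict = rep(FALSE, nq),
                    orient = rep(NA_character_, nq), stringsAsFactors = FALSE)
  if (!nq || !length(db_tags)) return(res)
  # exact pass on canonical forms (db tags are canonical and unique)
  can <- canonicalize(queries)
  ex <- match(can, db_tags)
  hit <- !is.na(ex)
  res$best[hit] <- ex[hit]
  res$dist[hit] <- 0L
  res$orient[hit] <- ifelse(queries[hit] == db_tags[ex[hit]], "+", "-")
  if (max_mismatch == 0L || all(hit)) return(res)
  todo <- which(!hit)
  L <- nchar(db_tags[1])
  dbm <- matrix(utf8ToInt(paste(db_tags, collapse = "")),
                nrow = length(db_tags), ncol = L, byrow = TRUE)
  qs <- queries[todo]
  for (ori in c("+", "-")) {
    qseq <- if (ori == "+") qs else revcomp(qs)
    for (lo in seq(1L, length(todo), by = chunk_size)) {
      hi <- min(lo + chunk_size - 1L, length(todo))
      idx <- lo:hi
      qm <- matrix(utf8ToInt(paste(qseq[idx], collapse = "")),
                   nrow = length(idx), ncol = L, byrow = TRUE)
      D <- matrix(0L, length(idx), nrow(dbm))
      for (j in seq_len(L))
        D <- D + outer(qm[, j], dbm[, j], "!=")
      bd <- apply(D, 1L, min)
      sel <- which(bd <= max_mismatch)
      for (s in sel) {
        q <- todo[idx[s]]
        ties <- which(D[s, ] == bd[s])
        conflict <- length(unique(labels[ties])) > 1L
        if (is.na(res$dist[q]) || bd[s] < res$dist[q]) {
          res$dist[q] <- bd[s]
          res$best[q] <- ties[1]
          res$orient[q] <- ori
          res$entry_tie[q] <- length(ties) > 1L
          res$label_conflict[q] <- conflict
        } else if (bd[s] == res$dist[q]) {
          new_ties <- union(ties, res$best[q])
          res$entry_tie[q] <- res$entry_tie[q] || length(new_ties) > 1L
          res$label_conflict[q] <- res$label_conflict[q] || conflict ||
            length(unique(labels[new_ties])) > 1L
        }
      }
    }
  }
  res
}

db_lookup <- function(db) {
  data.frame(
    tag = c(db$host_tags, db$markers$tag),
    label = c(rep("host", length(db$host_tags)), db$markers$taxon),
    kind = rep(c("host", "microbe"),
               c(length(db$host_tags), nrow(db$markers))),
    stringsAsFactors = FALSE
  )
}

#' Assign one sequenced tag to host, a microbial taxon, or unassigned
#'
#' An exact canonical match decides. With `max_mismatch > 0`, a tag is
#' assigned to the unique database entry within the mismatch radius
#' (comparing both orientations) and declared unassigned on ties between
#' entries with different assignments.
#'
#' @param tag A single tag sequence of the database tag length.
#' @param db A `holodb`.
#' @param max_mismatch Mismatch radius (default 0: exact canonical match).
#' @return A single string: `"host"`, a taxon label, or `"unassigned"`.
#' @export
assign_tag <- function(tag, db, max_mismatch = 0L) {
  if (nchar(tag) != db$enzyme$tag_length)
    stop("tag length ", nchar(tag), " does not match database tag length ",
         db$enzyme$tag_length)
  classify_tags(tag, db, max_mismatch)$label
}

# Vectorized classification; returns data.frame(tag, label, db_tag, orient,
# dist, entry_tie) with one row per input tag.
classify_tags <- function(tags, db, max_mismatch = 0L) {
  lk <- db_lookup(db)
  uq <- unique(tags)
  mm <- match_tags_to_db(uq, lk$tag, lk$label, as.integer(max_mismatch))
  lab <- rep("unassigned", length(uq))
  ok <- !is.na(mm$best)
  # a tie between entries sharing one label is still an unambiguous call
  use <- ok & !mm$label_conflict
  lab[use] <- lk$label[mm$best[use]]
  i <- match(tags, uq)
  data.frame(tag = tags,
             label = lab[i],
             db_tag = ifelse(ok, lk$tag[mm$best], NA_character_)[i],
             orient = mm$orient[i],
             dist = mm$dist[i],
             entry_tie = mm$entry_tie[i],
             stringsAsFactors = FALSE)
}

#' Partition a sample's tags into host and microbial fractions
#'
#' Tallies tag assignments and reports mapping rates to host and to
#' microorganisms *over assigned tags* (so the two rates sum to 100).
#'
#' @param tags Character vector of canonical tags (from [process_fastq()]),
#'   or its `tags` data.frame.
#' @param db A `holodb`.
#' @param max_mismatch Mismatch radius for assignment.
#' @return Object of class `partition_result`: per-label counts
#'   (`species_counts`), `n_host`, `n_microbial`, `n_unassigned`,
#'   `host_rate`/`microbial_rate` (percent, 2 decimals; `NA` and
#'   `rate_undefined = TRUE` when nothing is assigned), and the per-tag
#'   assignment table `assignments`.
#' @export
partition_sample <- function(tags, db, max_mismatch = 0L) {
  if (is.data.frame(tags)) tags <- tags$tag
  cls <- classify_tags(tags, db, max_mismatch)
  n_host <- sum(cls$label == "host")
  n_un <- sum(cls$label == "unassigned")
  n_mic <- length(tags) - n_host - n_un
  assigned <- n_host + n_mic
  sp <- cls$label[!(cls$label %in% c("host", "unassigned"))]
  structure(list(
    total = length(tags),
    n_host = n_host, n_microbial = n_mic, n_unassigned = n_un,
    host_rate = if (assigned) round(100 * n_host / assigned, 2) else NA_real_,
    microbial_rate = if (assigned) round(100 * n_mic / assigned, 2) else NA_real_,
    rate_undefined = assigned == 0L,
    species_counts = table(sp),
    assignments = cls
  ), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "<partition_result> %d tags: host %d (%.2f%%), microbial %d (%.2f%%), unassigned %d\n",
    x$total, x$n_host, x$host_rate, x$n_microbial, x$microbial_rate,
    x$n_unassigned))
  invisible(x)
}

#' Species-level relative abundance profile
#'
#' For each species, the raw read density is
#' `d_s = reads_on_markers / theoretical_markers`; a species is retained iff
#' it hits at least `min_markers_hit` distinct markers and its G score
#' `sqrt(reads_on_markers * distinct_markers_hit)` is at least `min_g_score`
#' (a false-positive filter). Retained densities are renormalized to sum
#' to 1.
#'
#' @param partition A [partition_sample()] result.
#' @param db The `holodb` the partition was computed against.
#' @param min_markers_hit Minimum distinct markers hit (default 5).
#' @param min_g_score Minimum G score (default 5).
#' @return Object of class `abundance_profile`: data.frame with one row per
#'   retained species (`species`, `reads_on_markers`, `distinct_markers_hit`,
#'   `theoretical_markers`, `g_score`, `relative_abundance`), plus the
#'   pre-filter table as attribute `"all_species"`.
#' @export
profile_abundance <- function(partition, db, min_markers_hit = 5L,
                              min_g_score = 5) {
  stopifnot(inherits(partition, "partition_result"), inherits(db, "holodb"))
  cls <- partition$assignments
  mic <- cls[!(cls$label %in% c("host", "unassigned")), , drop = FALSE]
  theo <- db$theoretical
  if (nrow(mic)) {
    reads <- tapply(rep(1L, nrow(mic)), mic$label, sum)
    hits <- tapply(mic$db_tag, mic$label, function(x) length(unique(x)))
    sp <- names(reads)
    th <- as.integer(theo[sp])
    stopifnot(!anyNA(th), all(th > 0L))  # guaranteed by holodb invariant
    tab <- data.frame(
      species = sp,
      reads_on_markers = as.integer(reads),
      distinct_markers_hit = as.integer(hits),
      theoretical_markers = th,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- data.frame(species = character(0), reads_on_markers = integer(0),
                      distinct_markers_hit = integer(0),
                      theoretical_markers = integer(0),
                      stringsAsFactors = FALSE)
  }
  tab$g_score <- sqrt(tab$reads_on_markers * as.numeric(tab$distinct_markers_hit))
  keep <- tab$distinct_markers_hit >= min_markers_hit &
    tab$g_score >= min_g_score
  out <- tab[keep, , drop = FALSE]
  dens <- out$reads_on_markers / out$theoretical_markers
  out$relative_abundance <- if (nrow(out)) dens / sum(dens) else numeric(0)
  out <- out[order(-out$relative_abundance, out$species), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_species") <- tab
  class(out) <- c("abundance_profile", "data.frame")
  out
}

#' Pearson correlation of two abundance profiles
#'
#' Profiles are expanded over the union of their species (absent species
#' contribute abundance 0) before computing the standard Pearson
#' correlation.
#'
#' @param p1,p2 [profile_abundance()] results (or data.frames with columns
#'   `species` and `relative_abundance`).
#' @return Pearson's r, or `NA` (with a warning) if the species union has
#'   fewer than 2 members.
#' @export
profile_correlation <- function(p1, p2) {
  union_sp <- sort(unique(c(p1$species, p2$species)))
  if (length(union_sp) < 2L) {
    warning("fewer than 2 species in the union; correlation undefined")
    return(NA_real_)
  }
  x <- p1$relative_abundance[match(union_sp, p1$species)]
  y <- p2$relative_abundance[match(union_sp, p2$species)]
  x[is.na(x)] <- 0; y[is.na(y)] <- 0
  stats::cor(x, y)
}

#' Serialize a partition result as a sequencing-statistics row
#'
#' @param stats A `qc_stats` object.
#' @param partition A `partition_result`.
#' @param sample Sample name.
#' @return One-row data.frame mirroring the per-library sequencing
#'   statistics table (raw reads, HQ reads and rate, tags with site,
#'   mapping rates).
#' @export
partition_report <- function(stats, partition, sample = "sample") {
  data.frame(
    sample = sample,
    raw_reads = stats$raw_reads,
    hq_reads = stats$hq_reads,
    hq_rate = stats$hq_rate,
    tags_with_site = stats$tags_with_site,
    mapping_rate_microbial = partition$microbial_rate,
    mapping_rate_host = partition$host_rate,
    stringsAsFactors = FALSE
  )
}
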