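# Codominant diploid genotyping of host-assigned tags: pileups, a binomial
# maximum-likelihood caller, replicate agreement and allele-sharing
# distances.

BASES <- c("A", "C", "G", "T")
UNKNOWN_GT <- "N/N"

#' Pile up host-assigned reads onto their reference tags
#'
#' Each read is oriented onto its best-matching host reference tag and its
#' bases added to the per-offset base counts. Reads equally close to two or
#' more reference tags are discarded as ambiguous.
#'
#' @param tags Character vector of sequenced tags (canonical), or the `tags`
#'   data.frame from [process_fastq()].
#' @param db A `holodb`.
#' @param max_mismatch Mismatch radius for matching reads to reference tags
#'   (default 2, emulating short-read alignment).
#' @return Named list of pileups, one per covered reference tag: each a list
#'   with `tag` (reference sequence), `counts` (4 x tag_length integer
#'   matrix, rows A/C/G/T) and `depth`.
#' @export
pileup_host_tags <- function(tags, db, max_mismatch = 2L) {
  if (is.data.frame(tags)) tags <- tags$tag
  if (!length(db$host_tags)) return(list())
  lk <- db_lookup(db)
  uq <- unique(tags)
  mm <- match_tags_to_db(uq, lk$tag, lk$label, as.integer(max_mismatch))
  ok <- !is.na(mm$best) & !mm$entry_tie & lk$kind[mm$best] == "host"
  i <- match(tags, uq)
  use <- which(ok[i])
  if (!length(use)) return(list())
  ref <- lk$tag[mm$best[i[use]]]
  orient <- mm$orient[i[use]]
  seqs <- tags[use]
  seqs[orient == "-"] <- revcomp(seqs[orient == "-"])
  L <- db$enzyme$tag_length
  out <- list()
  for (r in unique(ref)) {
    sel <- ref == r
    mat <- matrix(unlist(strsplit(seqs[sel], ""), use.names = FALSE),
                  ncol = L, byrow = TRUE)
    counts <- vapply(BASES, function(b) as.integer(colSums(mat == b)),
                     integer(L))
    out[[r]] <- list(tag = r, counts = t(counts), depth = sum(sel))
  }
  out
}

#' Call a diploid genotype from per-offset base counts
#'
#' Maximum-likelihood codominant call under a simple binomial sequencing
#' error model. For the two most frequent bases with counts `n1 >= n2` and
#' total depth `n`, per-read emission probabilities are `1 - e` for the true
#' allele (errors uniformly spread over the other three bases at `e/3` each)
#' and, under the heterozygote, `0.5 (1 - e) + e/6` for each allele. The
#' genotype with the largest likelihood is returned. Loci with depth below
#' `reliable_depth` are reported unknown ("greater than 4x" coverage rule:
#' at least 5 reads by default). A third allele with count above
#' `3 * error_rate * depth` marks the locus unreliable (unknown).
#'
#' @param counts Integer vector of A/C/G/T counts at one offset (or a
#'   pileup `counts` column).
#' @param error_rate Per-base sequencing error probability (default 0.01).
#' @param reliable_depth Minimum depth for a reliable genotype (default 5).
#' @return List with `call` (e.g. `"A/A"`, `"A/T"`, or `"N/N"` for unknown),
#'   `depth`, and `prob` (posterior probability of the call under equal
#'   genotype priors; `NA` for unknown calls).
#' @export
call_genotype <- function(counts, error_rate = 0.01, reliable_depth = 5L) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 4L)
  depth <- sum(counts)
  if (depth == 0L) stop("call_genotype() requires depth >= 1")
  if (depth < reliable_depth)
    return(list(call = UNKNOWN_GT, depth = depth, prob = NA_real_))
  ord <- order(-counts, seq_along(counts))  # deterministic tie-break A<C<G<T
  n1 <- counts[ord[1]]; n2 <- counts[ord[2]]
  b1 <- BASES[ord[1]]; b2 <- BASES[ord[2]]
  others <- depth - n1 - n2
  if (others > 3 * error_rate * depth)
    return(list(call = UNKNOWN_GT, depth = depth, prob = NA_real_))
  e <- error_rate
  ll_hom1 <- n1 * log(1 - e) + (depth - n1) * log(e / 3)
  ll_hom2 <- n2 * log(1 - e) + (depth - n2) * log(e / 3)
  p_het <- 0.5 * (1 - e) + e / 6
  ll_het <- (n1 + n2) * log(p_het) + others * log(e / 3)
  ll <- c(hom1 = ll_hom1, het = ll_het, hom2 = ll_hom2)
  post <- exp(ll - max(ll)); post <- post / sum(post)
  k <- which.max(ll)
  call <- switch(names(ll)[k],
                 hom1 = paste(b1, b1, sep = "/"),
                 hom2 = paste(b2, b2, sep = "/"),
                 het = paste(sort(c(b1, b2)), collapse = "/"))
  list(call = call, depth = depth, prob = unname(post[k]))
}

#' Call genotypes across all offsets of a set of pileups
#'
#' Every offset of every covered tag is a detected locus (minimum depth 1);
#' loci below the reliable depth are reported unknown.
#'
#' @param pileups Result of [pileup_host_tags()].
#' @inheritParams call_genotype
#' @return Data.frame with columns `locus` (`tag:offset`, 0-based offset),
#'   `call`, `depth`, `prob`.
#' @export
call_genotypes <- function(pileups, error_rate = 0.01, reliable_depth = 5L) {
  rows <- lapply(pileups, function(p) {
    L <- ncol(p$counts)
    calls <- lapply(seq_len(L), function(j)
      call_genotype(p$counts[, j], error_rate, reliable_depth))
    data.frame(locus = paste0(p$tag, ":", seq_len(L) - 1L),
               call = vapply(calls, `[[`, character(1), "call"),
               depth = vapply(calls, `[[`, integer(1), "depth"),
               prob = vapply(calls, `[[`, numeric(1), "prob"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, unname(rows))
  if (is.null(out))
    out <- data.frame(locus = character(0), call = character(0),
                      depth = integer(0), prob = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a samples-by-loci genotype matrix
#'
#' @param calls Named list of [call_genotypes()] data.frames, one per sample.
#' @return Data.frame with `locus` plus one call column per sample; loci
#'   missing from a sample are unknown (`"N/N"`).
#' @export
genotype_matrix <- function(calls) {
  loci <- sort(unique(unlist(lapply(calls, `[[`, "locus"))))
  out <- data.frame(locus = loci, stringsAsFactors = FALSE)
  for (s in names(calls)) {
    v <- calls[[s]]$call[match(loci, calls[[s]]$locus)]
    v[is.na(v)] <- UNKNOWN_GT
    out[[s]] <- v
  }
  out
}

#' Agreement percentage from counts
#'
#' @param same,genotyped Counts of identical calls and of loci genotyped in
#'   both libraries.
#' @return `100 * same / genotyped`, rounded to 2 decimals.
#' @export
agreement_percent <- function(same, genotyped) {
  ifelse(genotyped > 0, round(100 * same / genotyped, 2), NA_real_)
}

#' Replicate / control agreement report
#'
#' Over loci genotyped (non-unknown) in both columns, calls are stratified
#' by the class of the first column's call (homozygote or heterozygote) and
#' counted as same or different; percentages are reported per class and
#' overall.
#'
#' @param g1,g2 Character vectors of genotype calls over the same locus
#'   universe (e.g. two columns of [genotype_matrix()]).
#' @return Data.frame with rows `homozygote`, `heterozygote`, `all` and
#'   columns `genotyped`, `same`, `different`, `agreement`.
#' @export
compare_replicates <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  both <- g1 != UNKNOWN_GT & g2 != UNKNOWN_GT
  g1 <- g1[both]; g2 <- g2[both]
  al <- strsplit(g1, "/", fixed = TRUE)
  hom <- vapply(al, function(a) a[1] == a[2], logical(1))
  same <- g1 == g2
  row <- function(cls, idx) {
    data.frame(class = cls, genotyped = length(idx),
               same = sum(same[idx]), different = sum(!same[idx]),
               agreement = agreement_percent(sum(same[idx]), length(idx)),
               stringsAsFactors = FALSE)
  }
  rbind(row("homozygote", which(hom)),
        row("heterozygote", which(!hom)),
        row("all", seq_along(g1)))
}

#' Allele-sharing genetic distance matrix
#'
#' For each sample pair, over loci called in both samples, each locus
#' contributes `1 - shared_alleles / 2` (0 for identical genotypes, 0.5 when
#' one allele is shared, 1 for none); the distance is the average over
#' comparable loci.
#'
#' @param gm A [genotype_matrix()] (data.frame with `locus` + sample
#'   columns).
#' @return Symmetric numeric matrix with zero diagonal; `NA` (with a
#'   warning) for pairs with no comparable loci.
#' @export
genotype_distance <- function(gm) {
  samples <- setdiff(names(gm), "locus")
  if (length(samples) < 2L) stop("need at least 2 samples")
  allele_mat <- lapply(samples, function(s)
    do.call(rbind, strsplit(gm[[s]], "/", fixed = TRUE)))
  names(allele_mat) <- samples
  known <- matrix(vapply(samples, function(s) gm[[s]] != UNKNOWN_GT,
                         logical(nrow(gm))),
                  nrow = nrow(gm), dimnames = list(NULL, samples))
  d <- matrix(0, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (i in seq_along(samples)) for (j in seq_len(i - 1L)) {
    both <- known[, i] & known[, j]
    if (!any(both)) {
      warning("no comparable loci for pair ", samples[i], " / ", samples[j])
      d[i, j] <- d[j, i] <- NA_real_
      next
    }
    a <- allele_mat[[i]][both, , drop = FALSE]
    b <- allele_mat[[j]][both, , drop = FALSE]
    shared <- shared_alleles(a, b)
    d[i, j] <- d[j, i] <- mean(1 - shared / 2)
  }
  d
}

# Multiset intersection size of two diploid genotypes, rowwise.
shared_alleles <- function(a, b) {
  s <- integer(nrow(a))
  for (base in BASES) {
    s <- s + pmin(rowSums(a == base), rowSums(b == base))
  }
  s
}
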