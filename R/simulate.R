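# Synthetic holobiome generator: host + microbial genomes with planted
# restriction sites, known diploid host SNPs, a community of known
# composition, and error-bearing FASTQ reads with per-read truth labels.
#
# Every random draw flows from the single config seed; genomes are built so
# that in-silico digestion recovers exactly the planted tag set (accidental
# recognition sites arising in spacers are destroyed by point mutation).

#' Simulation configuration
#'
#' Defines the synthetic holobiont "stated world": a diploid host whose
#' genome carries a known number of 2bRAD tags and SNPs, and a microbial
#' community of known species composition.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param enzyme An [enzyme_spec()] (default [bsaxi()]).
#' @param n_host_tags Planted host tag loci (default 200).
#' @param n_snps Host SNPs planted inside tags (default 60, at most one per
#'   tag).
#' @param het_fraction Fraction of SNPs that are heterozygous (default 0.5;
#'   the rest are homozygous for the alternate allele).
#' @param n_species Microbial species (default 20).
#' @param genomes_per_species Conspecific genomes sharing each species' tags
#'   (default 2).
#' @param tags_per_genome Species-private single-copy tags per species
#'   (default 30).
#' @param cross_shared_tags Tags planted into two different species (never
#'   markers; default 10).
#' @param host_shared_tags Tags planted into both the host and one species
#'   (removed during cross-redundancy removal; default 4).
#' @param dup_tags Tags planted twice within one genome (never markers;
#'   default 5).
#' @param abundances Community composition vector (summing to 1) or `NULL`
#'   to draw once from a flat Dirichlet (all concentrations 1).
#' @param microbial_fraction Microbial fraction of the library (default
#'   0.10, matching fecal-type libraries).
#' @param reads_per_sample Total reads per library (default 40000), or
#'   `NULL` with `reads_per_marker` set.
#' @param reads_per_marker If non-`NULL`, derive `reads_per_sample` as
#'   `ceiling(reads_per_marker * n_markers / microbial_fraction)` so the
#'   mean per-marker read count reaches this target.
#' @param error_rate Per-base substitution error probability (default
#'   0.005).
#' @param quality_range Inclusive Phred range qualities are drawn from
#'   (default 30..40, so no base fails the Q<10 filter).
#' @param read_length Read length; defaults to the tag length. Longer reads
#'   embed the tag at a random offset (padded mode).
#' @param spacer_len Spacer between planted tags in simulated genomes
#'   (default 40).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       enzyme = bsaxi(),
                       n_host_tags = 200L,
                       n_snps = 60L,
                       het_fraction = 0.5,
                       n_species = 20L,
                       genomes_per_species = 2L,
                       tags_per_genome = 30L,
                       cross_shared_tags = 10L,
                       host_shared_tags = 4L,
                       dup_tags = 5L,
                       abundances = NULL,
                       microbial_fraction = 0.10,
                       reads_per_sample = 40000L,
                       reads_per_marker = NULL,
                       error_rate = 0.005,
                       quality_range = c(30L, 40L),
                       read_length = NULL,
                       spacer_len = 40L) {
  stopifnot(n_snps <= n_host_tags,
            microbial_fraction >= 0, microbial_fraction <= 1,
            het_fraction >= 0, het_fraction <= 1,
            error_rate >= 0, error_rate < 1,
            spacer_len >= max(enzyme$flank5, enzyme$flank3) + 2L)
  if (!is.null(abundances)) {
    stopifnot(length(abundances) == n_species,
              abs(sum(abundances) - 1) < 1e-8, all(abundances >= 0))
  }
  if (is.null(read_length)) read_length <- enzyme$tag_length
  stopifnot(read_length >= enzyme$tag_length)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# Offsets (1-based, within the recognition span) carrying a non-N pattern
# code for the given orientation.
constrained_offsets <- function(pattern) which(strsplit(pattern, "")[[1]] != "N")

# One clean tag: recognition planted at flank5, degenerate positions random,
# digests to exactly one site and carries no >10 bp homopolymer.
make_tag <- function(enzyme) {
  pc <- strsplit(enzyme$recognition, "")[[1]]
  repeat {
    bases <- sample(BASES, enzyme$tag_length, replace = TRUE)
    for (j in seq_along(pc))
      bases[enzyme$flank5 + j] <- sample(IUPAC_CODES[[pc[j]]], 1)
    tag <- paste(bases, collapse = "")
    if (grepl(HOMOPOLYMER_RE, tag)) next
    sites <- find_recognition_sites(tag, enzyme)
    if (nrow(sites) == 1L && sites$start == enzyme$flank5) return(tag)
  }
}

# k tags with distinct canonical forms.
make_tag_set <- function(k, enzyme, exclude = character(0)) {
  out <- character(0)
  seen <- exclude
  while (length(out) < k) {
    t <- make_tag(enzyme)
    cn <- canonicalize(t)
    if (!(cn %in% seen)) { out <- c(out, t); seen <- c(seen, cn) }
  }
  out
}

# Concatenate tags with spacers, then destroy recognition sites that arose
# by chance anywhere outside the planted spans.
assemble_genome <- function(tags, enzyme, spacer_len) {
  n <- length(tags)
  spacers <- vapply(seq_len(n + 1L), function(i) random_dna(spacer_len),
                    character(1))
  pieces <- character(2L * n + 1L)
  pieces[seq(1L, 2L * n + 1L, by = 2L)] <- spacers
  pieces[seq(2L, 2L * n, by = 2L)] <- tags
  seq <- paste(pieces, collapse = "")
  starts <- spacer_len * seq_len(n) + enzyme$tag_length * (seq_len(n) - 1L)
  planted_sites <- starts + enzyme$flank5       # 0-based recognition starts
  spans <- cbind(starts, starts + enzyme$tag_length)  # 0-based half-open
  seq <- destroy_accidental_sites(seq, enzyme, planted_sites, spans)
  list(seq = seq, tag_starts = starts)
}

destroy_accidental_sites <- function(seq, enzyme, planted_sites, spans,
                                     max_iter = 100L) {
  m <- nchar(enzyme$recognition)
  protected <- function(pos0) {  # 0-based position inside a planted span?
    any(pos0 >= spans[, 1] & pos0 < spans[, 2])
  }
  for (iter in seq_len(max_iter)) {
    sites <- find_recognition_sites(seq, enzyme)
    bad <- sites[!(sites$start %in% planted_sites), , drop = FALSE]
    if (!nrow(bad)) return(seq)
    touched <- FALSE
    for (r in seq_len(nrow(bad))) {
      pat <- if (bad$strand[r] == "+") enzyme$recognition else
        revcomp(enzyme$recognition)
      pc <- strsplit(pat, "")[[1]]
      offs <- seq_len(m)
      free <- offs[!vapply(bad$start[r] + offs - 1L, protected, logical(1))]
      if (!length(free)) next  # overlaps only planted spans; impossible by design
      hard <- free[pc[free] != "N"]
      off <- if (length(hard)) hard[1] else free[1]
      pos <- bad$start[r] + off  # 1-based string position
      alt <- setdiff(BASES, IUPAC_CODES[[pc[off]]])
      if (!length(alt)) alt <- setdiff(BASES, substr(seq, pos, pos))
      substr(seq, pos, pos) <- sample(alt, 1)
      touched <- TRUE
    }
    # remaining sites lie entirely inside protected spans; leave them
    if (!touched) return(seq)
  }
  stop("failed to remove accidental recognition sites")
}

#' Simulate host and microbial genomes with full truth
#'
#' Generates the host genome (planted tag loci, two haplotypes differing at
#' planted SNPs), the microbial genomes (species-private single-copy tags,
#' cross-species shared tags, host-shared tags, within-genome duplicated
#' tags), the taxonomy table, and the community abundance vector.
#'
#' @param cfg A [sim_config()].
#' @return List of class `holobiome_truth`; see fields `host`, `snps`,
#'   `microbes`, `taxonomy`, `truth` (per-species marker tags pre/post
#'   cross-removal) and `abundances`.
#' @export
simulate_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  enz <- cfg$enzyme
  tl <- enz$tag_length

  n_total_private <- cfg$n_species * cfg$tags_per_genome
  all_tags <- make_tag_set(cfg$n_host_tags + n_total_private +
                             cfg$cross_shared_tags + cfg$host_shared_tags +
                             cfg$dup_tags, enz)
  idx <- 0L
  take <- function(k) { out <- all_tags[idx + seq_len(k)]; idx <<- idx + k; out }
  host_tags <- take(cfg$n_host_tags)
  private <- split(take(n_total_private),
                   rep(seq_len(cfg$n_species), each = cfg$tags_per_genome))
  cross <- take(cfg$cross_shared_tags)
  host_shared <- take(cfg$host_shared_tags)
  dup <- take(cfg$dup_tags)

  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  names(private) <- species

  # host genome (reference) and haplotypes
  host_all <- c(host_tags, host_shared)
  host_all <- host_all[sample(length(host_all))]
  hg <- assemble_genome(host_all, enz, cfg$spacer_len)
  host_loci <- data.frame(
    tag_id = sprintf("H%04d", seq_along(host_all)),
    start = hg$tag_starts, end = hg$tag_starts + tl, strand = "+",
    sequence = host_all, canonical = canonicalize(host_all),
    shared_with_microbe = host_all %in% host_shared,
    stringsAsFactors = FALSE)

  # SNPs: at most one per tag, outside constrained recognition offsets,
  # keeping the mutated tag clean (single site, no homopolymer)
  pc <- strsplit(enz$recognition, "")[[1]]
  fixed_pos <- enz$flank5 + constrained_offsets(enz$recognition)
  allowed_off <- setdiff(seq_len(tl), fixed_pos)
  snp_tags <- sample(which(!host_loci$shared_with_microbe), cfg$n_snps)
  snps <- data.frame(tag_id = host_loci$tag_id[snp_tags],
                     tag_idx = snp_tags, offset = NA_integer_,
                     ref = NA_character_, alt = NA_character_,
                     genotype = ifelse(stats::runif(cfg$n_snps) < cfg$het_fraction,
                                       "het", "hom_alt"),
                     stringsAsFactors = FALSE)
  alt_tag <- host_loci$sequence
  for (i in seq_len(nrow(snps))) {
    t0 <- host_loci$sequence[snps$tag_idx[i]]
    repeat {
      off <- sample(allowed_off, 1)
      ref <- substr(t0, off, off)
      alt <- sample(setdiff(BASES, ref), 1)
      cand <- t0
      substr(cand, off, off) <- alt
      sites <- find_recognition_sites(cand, enz)
      if (nrow(sites) == 1L && sites$start == enz$flank5 &&
          !grepl(HOMOPOLYMER_RE, cand) &&
          !(canonicalize(cand) %in% canonicalize(all_tags))) {
        snps$offset[i] <- off; snps$ref[i] <- ref; snps$alt[i] <- alt
        alt_tag[snps$tag_idx[i]] <- cand
        break
      }
    }
  }
  hap1 <- host_loci$sequence
  hap2 <- host_loci$sequence
  hom <- snps$genotype == "hom_alt"
  hap1[snps$tag_idx[hom]] <- alt_tag[snps$tag_idx[hom]]
  hap2[snps$tag_idx] <- alt_tag[snps$tag_idx]

  # microbial genomes: conspecific genomes share the species' tags
  cross_pairs <- cbind(sample(cfg$n_species, cfg$cross_shared_tags, replace = TRUE),
                       integer(cfg$cross_shared_tags))
  for (i in seq_len(cfg$cross_shared_tags))
    cross_pairs[i, 2] <- sample(setdiff(seq_len(cfg$n_species), cross_pairs[i, 1]), 1)
  host_shared_sp <- sample(cfg$n_species, cfg$host_shared_tags, replace = TRUE)
  dup_sp <- sample(cfg$n_species, cfg$dup_tags, replace = TRUE)

  genomes <- list()
  for (s in seq_len(cfg$n_species)) {
    stags <- c(private[[s]],
               cross[cross_pairs[, 1] == s | cross_pairs[, 2] == s],
               host_shared[host_shared_sp == s],
               rep(dup[dup_sp == s], each = 2L))
    for (g in seq_len(cfg$genomes_per_species)) {
      gid <- sprintf("%s_g%d", species[s], g)
      shuffled <- stags[sample(length(stags))]
      genomes[[gid]] <- stats::setNames(
        assemble_genome(shuffled, enz, cfg$spacer_len)$seq,
        paste0(gid, "_c1"))
    }
  }

  # nested taxonomy: genera of 2 species, families of 4, orders of 8, ...
  sidx <- seq_len(cfg$n_species)
  taxonomy <- data.frame(
    genome_id = names(genomes),
    stringsAsFactors = FALSE)
  gsp <- rep(species, each = cfg$genomes_per_species)
  grp <- function(k, prefix) sprintf("%s%02d", prefix, ceiling(match(gsp, species) / k))
  taxonomy$kingdom <- "Bacteria"
  taxonomy$phylum <- grp(32L, "phy")
  taxonomy$class <- grp(16L, "cls")
  taxonomy$order <- grp(8L, "ord")
  taxonomy$family <- grp(4L, "fam")
  taxonomy$genus <- grp(2L, "gen")
  taxonomy$species <- gsp

  ab <- cfg$abundances
  if (is.null(ab)) {
    g <- stats::rgamma(cfg$n_species, shape = 1)
    ab <- g / sum(g)
  }
  names(ab) <- species

  markers_pre <- lapply(seq_len(cfg$n_species), function(s)
    canonicalize(c(private[[s]], host_shared[host_shared_sp == s])))
  markers_post <- lapply(private, canonicalize)
  names(markers_pre) <- species

  structure(list(
    cfg = cfg,
    host = list(genome = c(chr1 = hg$seq), loci = host_loci,
                hap1 = hap1, hap2 = hap2),
    snps = snps,
    microbes = genomes,
    taxonomy = taxonomy,
    abundances = ab,
    truth = list(markers_pre_merge = markers_pre,
                 markers_post_merge = markers_post,
                 cross_shared = canonicalize(cross),
                 host_shared = canonicalize(host_shared),
                 dup_tags = canonicalize(dup))
  ), class = "holobiome_truth")
}

#' @export
print.holobiome_truth <- function(x, ...) {
  cat(sprintf(
    "<holobiome_truth> host: %d tag loci, %d SNPs; %d species x %d genomes\n",
    nrow(x$host$loci), nrow(x$snps), x$cfg$n_species,
    x$cfg$genomes_per_species))
  invisible(x)
}

# Apply iid substitution errors to fixed-length sequences (char vector).
apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  L <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                ncol = L, byrow = TRUE)
  hit <- which(stats::runif(length(mat)) < error_rate)
  if (length(hit)) {
    cur <- match(mat[hit], BASES)
    mat[hit] <- BASES[((cur - 1L + sample(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
    rows <- unique(((hit - 1L) %% nrow(mat)) + 1L)
    seqs[rows] <- apply(mat[rows, , drop = FALSE], 1L, paste, collapse = "")
  }
  seqs
}

#' Simulate one sequencing library from a holobiome truth
#'
#' Each read is one tag: a host locus drawn uniformly from one of the two
#' haplotypes, or a species marker drawn with probability proportional to
#' species abundance times marker count (markers uniform within species).
#' Reads get independent per-base substitution errors, random orientation,
#' and qualities drawn from the configured range; the source is recorded in
#' the read id (`src=host|tag=H0007|hap=2` or `src=sp03|tag=M...`).
#'
#' @param cfg A [sim_config()].
#' @param truth A [simulate_genomes()] result.
#' @param sample_name Library name (used in read ids).
#' @param seed Seed for this library's sampling (derive one per replicate).
#' @param n_reads Number of reads (default from `cfg`).
#' @return Data.frame `id`, `seq`, `qual` (writeable with [write_fastq()]).
#' @export
simulate_reads <- function(cfg, truth, sample_name = "s1",
                           seed = cfg$seed + 1L, n_reads = NULL) {
  stopifnot(inherits(truth, "holobiome_truth"))
  set.seed(seed)
  if (is.null(n_reads)) {
    n_reads <- cfg$reads_per_sample
    if (!is.null(cfg$reads_per_marker)) {
      n_markers <- sum(lengths(truth$truth$markers_post_merge))
      n_reads <- as.integer(ceiling(
        cfg$reads_per_marker * n_markers / max(cfg$microbial_fraction, 1e-9)))
    }
  }
  n_mic <- stats::rbinom(1L, n_reads, cfg$microbial_fraction)
  n_host <- n_reads - n_mic

  loci <- sample(nrow(truth$host$loci), n_host, replace = TRUE)
  hap <- sample(2L, n_host, replace = TRUE)
  host_seq <- ifelse(hap == 1L, truth$host$hap1[loci], truth$host$hap2[loci])
  host_src <- sprintf("src=host|tag=%s|hap=%d", truth$host$loci$tag_id[loci], hap)

  mk <- truth$truth$markers_post_merge
  m_s <- lengths(mk)
  w <- truth$abundances * m_s
  sp <- sample(length(mk), n_mic, replace = TRUE, prob = w)
  mic_seq <- vapply(sp, function(s) mk[[s]][sample.int(m_s[s], 1L)],
                    character(1))
  mic_src <- sprintf("src=%s|tag=%s", names(mk)[sp], mic_seq)

  seqs <- c(host_seq, mic_seq)
  src <- c(host_src, mic_src)
  ord <- sample(length(seqs))
  seqs <- seqs[ord]; src <- src[ord]

  seqs <- apply_errors(seqs, cfg$error_rate)
  flip <- stats::runif(length(seqs)) < 0.5
  seqs[flip] <- revcomp(seqs[flip])
  if (cfg$read_length > cfg$enzyme$tag_length)
    seqs <- pad_reads(seqs, cfg$read_length, cfg$enzyme)
  L <- cfg$read_length
  qmat <- matrix(sample(seq(cfg$quality_range[1], cfg$quality_range[2]),
                        length(seqs) * L, replace = TRUE), ncol = L)
  qual <- apply(qmat, 1L, function(q) rawToChar(as.raw(q + 33L)))
  data.frame(
    id = sprintf("%s_%07d|%s", sample_name, seq_along(seqs), src),
    seq = seqs, qual = qual, stringsAsFactors = FALSE)
}

# Embed tags in longer reads at a random offset; pads are repaired so the
# planted placement stays the only valid one. The embedded tag may be on
# either strand (and, with errors, may have gained or lost sites), so its
# own site list is taken as the planted set.
pad_reads <- function(seqs, read_length, enzyme) {
  tl <- enzyme$tag_length
  vapply(seqs, function(s) {
    extra <- read_length - tl
    left <- sample(0:extra, 1)
    read <- paste0(random_dna(left), s, random_dna(extra - left))
    destroy_accidental_sites(read, enzyme,
                             planted_sites =
                               left + find_recognition_sites(s, enzyme)$start,
                             spans = cbind(left, left + tl))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a complete experiment to disk
#'
#' Writes host/microbial FASTA, taxonomy TSV, per-sample FASTQ and truth
#' TSV/JSON files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @param samples Character vector of sample names (each gets one library).
#' @return Invisibly, a list with the `truth` object and file paths.
#' @export
simulate_experiment <- function(cfg, dir, samples = c("rep1", "rep2")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_genomes(cfg)
  host_fa <- file.path(dir, "host.fa")
  write_fasta(truth$host$genome, host_fa)
  mdir <- file.path(dir, "microbes")
  dir.create(mdir, showWarnings = FALSE)
  mfa <- vapply(names(truth$microbes), function(g) {
    p <- file.path(mdir, paste0(g, ".fa"))
    write_fasta(truth$microbes[[g]], p)
    p
  }, character(1))
  tax <- file.path(dir, "taxonomy.tsv")
  write_taxonomy(truth$taxonomy, tax)
  fq <- vapply(seq_along(samples), function(i) {
    reads <- simulate_reads(cfg, truth, samples[i], seed = cfg$seed + i)
    p <- file.path(dir, paste0(samples[i], ".fq"))
    write_fastq(reads, p)
    p
  }, character(1))
  write_tsv(truth$host$loci, file.path(dir, "truth_host_loci.tsv"))
  write_tsv(truth$snps, file.path(dir, "truth_snps.tsv"))
  write_json_file(list(abundances = as.list(truth$abundances)),
                  file.path(dir, "truth_community.json"))
  invisible(list(truth = truth, host_fasta = host_fa, microbe_fastas = mfa,
                 taxonomy = tax, fastq = stats::setNames(fq, samples)))
}
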