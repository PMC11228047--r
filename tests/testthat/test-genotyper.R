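# Pileups, the binomial ML caller, replicate agreement, genetic distance.

test_that("call_genotype follows the ML model and depth rules", {
  # unanimous evidence -> homozygote
  g <- call_genotype(c(5, 0, 0, 0), error_rate = 0.01, reliable_depth = 5)
  expect_equal(g$call, "A/A")
  expect_gt(g$prob, 0.9)
  # balanced evidence -> heterozygote
  expect_equal(call_genotype(c(5, 0, 0, 5), 0.01, 5)$call, "A/T")
  # depth below the reliable threshold ("greater than 4x") -> unknown
  expect_equal(call_genotype(c(4, 0, 0, 0), 0.01, 5)$call, "N/N")
  expect_equal(call_genotype(c(2, 2, 0, 0), 0.01, 5)$call, "N/N")
  expect_error(call_genotype(c(0, 0, 0, 0)), "depth")
  # a strong third allele flags the locus unreliable
  expect_equal(call_genotype(c(10, 10, 5, 0), 0.01, 5)$call, "N/N")
  # skewed but heterozygous evidence
  expect_equal(call_genotype(c(12, 0, 8, 0), 0.01, 5)$call, "A/G")
})

test_that("the caller agrees with direct likelihood enumeration", {
  enum_call <- function(counts, e) {
    depth <- sum(counts)
    ord <- order(-counts, 1:4)
    n1 <- counts[ord[1]]; n2 <- counts[ord[2]]
    b <- c("A", "C", "G", "T")[ord[1:2]]
    ll <- c(n1 * log(1 - e) + (depth - n1) * log(e / 3),
            (n1 + n2) * log(0.5 * (1 - e) + e / 6) +
              (depth - n1 - n2) * log(e / 3),
            n2 * log(1 - e) + (depth - n2) * log(e / 3))
    switch(which.max(ll),
           paste(b[1], b[1], sep = "/"),
           paste(sort(b), collapse = "/"),
           paste(b[2], b[2], sep = "/"))
  }
  set.seed(50)
  for (i in 1:200) {
    counts <- as.integer(stats::rmultinom(1, sample(5:40, 1),
                                          prob = c(0.5, 0.45, 0.025, 0.025)))
    got <- call_genotype(counts, 0.01, 5)
    if (got$call != "N/N") expect_equal(got$call, enum_call(counts, 0.01))
  }
})

test_that("homozygote calls are monotone in majority evidence", {
  for (minor in c(0L, 1L, 2L)) {
    flipped <- FALSE
    state <- "het"
    for (major in 5:60) {
      g <- call_genotype(c(major, minor, 0, 0), 0.01, 5)
      if (g$call == "A/A") state <- "hom"
      else if (state == "hom") flipped <- TRUE  # hom reverted to het
    }
    expect_false(flipped)
  }
})

test_that("pileup_host_tags aggregates oriented reads and drops ambiguity", {
  enz <- toy_enzyme()
  t1 <- "GGACGTCA"
  host <- build_host_tagset(c(chr1 = toy_genome(t1)), enz)
  taxonomy <- data.frame(genome_id = "gA", kingdom = "Bacteria",
                         phylum = "P1", class = "C1", order = "O1",
                         family = "F1", genus = "G1", species = "A",
                         stringsAsFactors = FALSE)
  db <- merge_holodb(host, build_marker_db(
    list(gA = c(c1 = toy_genome("CAACGTAG"))), taxonomy, enz))
  # 5 identical error-free reads (mixed orientations)
  reads <- c(t1, t1, rc_manual(t1), t1, rc_manual(t1))
  pu <- pileup_host_tags(reads, db)
  expect_length(pu, 1L)
  p <- pu[[1]]
  expect_equal(p$depth, 5L)
  ref <- strsplit(canonicalize(t1), "")[[1]]
  for (j in seq_along(ref))
    expect_equal(unname(p$counts[ref[j], j]), 5L)
  # 3 reference reads + 2 with an alternate base at offset 7 (0-based 6)
  alt <- canonicalize(t1)
  substr(alt, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(alt, 7, 7))[1]
  pu2 <- pileup_host_tags(c(rep(canonicalize(t1), 3), rep(alt, 2)), db)
  p2 <- pu2[[1]]
  expect_equal(unname(p2$counts[substr(canonicalize(t1), 7, 7), 7]), 3L)
  expect_equal(unname(p2$counts[substr(alt, 7, 7), 7]), 2L)
  expect_equal(sum(p2$counts[, 7]), p2$depth)
})

test_that("reads equidistant from two reference tags are discarded", {
  enz <- toy_enzyme()
  t1 <- "GGACGTCA"; t2 <- "GTACGTCC"  # distance 2 apart
  host <- build_host_tagset(c(chr1 = toy_genome(c(t1, t2))), enz)
  taxonomy <- data.frame(genome_id = "gA", kingdom = "Bacteria",
                         phylum = "P1", class = "C1", order = "O1",
                         family = "F1", genus = "G1", species = "A",
                         stringsAsFactors = FALSE)
  db <- merge_holodb(host, build_marker_db(
    list(gA = c(c1 = toy_genome("CAACGTAG"))), taxonomy, enz))
  midway <- "GTACGTCA"  # 1 mismatch from each host tag
  pu <- pileup_host_tags(c(midway), db, max_mismatch = 2)
  expect_length(pu, 0L)
  # unambiguous read still contributes
  pu2 <- pileup_host_tags(c(midway, t1), db, max_mismatch = 0)
  expect_length(pu2, 1L)
  expect_equal(pu2[[1]]$depth, 1L)
})

test_that("compare_replicates stratifies by the first replicate's class", {
  g1 <- c("A/A", "A/A", "A/T", "A/T", "C/C", "N/N", "G/G")
  g2 <- c("A/A", "A/T", "A/T", "T/T", "C/C", "C/C", "N/N")
  rep <- compare_replicates(g1, g2)
  hom <- rep[rep$class == "homozygote", ]
  het <- rep[rep$class == "heterozygote", ]
  tot <- rep[rep$class == "all", ]
  expect_equal(hom$genotyped, 3L)  # A/A, A/A, C/C (G/G unknown in rep2)
  expect_equal(hom$same, 2L)
  expect_equal(het$genotyped, 2L)
  expect_equal(het$same, 1L)
  expect_equal(tot$genotyped, 5L)
  expect_equal(tot$same + tot$different, tot$genotyped)
  expect_equal(tot$agreement, round(100 * 3 / 5, 2))
  # identical matrices agree 100% in every class
  repid <- compare_replicates(g1, g1)
  expect_true(all(repid$agreement[repid$genotyped > 0] == 100))
})

test_that("agreement_percent reproduces printed-count arithmetic", {
  expect_equal(agreement_percent(2256585, 2258257), 99.93)
  expect_equal(agreement_percent(0, 0), NA_real_)
  expect_equal(agreement_percent(1, 3), 33.33)
})

test_that("genotype_distance is the average allele-sharing distance", {
  gm <- data.frame(locus = sprintf("L%d", 1:4),
                   s1 = c("A/A", "A/A", "A/A", "A/A"),
                   s2 = c("A/A", "A/A", "A/A", "T/T"),
                   s3 = c("A/A", "A/A", "A/A", "A/A"),
                   stringsAsFactors = FALSE)
  d <- genotype_distance(gm)
  expect_equal(unname(d["s1", "s3"]), 0)
  expect_equal(unname(d["s1", "s2"]), 1 / 4)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  # single comparable locus, one shared allele
  gm2 <- data.frame(locus = "L1", a = "A/A", b = "A/T",
                    stringsAsFactors = FALSE)
  expect_equal(unname(genotype_distance(gm2)["a", "b"]), 0.5)
  # unknowns are excluded from the comparable set
  gm3 <- data.frame(locus = c("L1", "L2"), a = c("A/A", "N/N"),
                    b = c("C/C", "A/A"), stringsAsFactors = FALSE)
  expect_equal(unname(genotype_distance(gm3)["a", "b"]), 1)
  expect_warning(genotype_distance(
    data.frame(locus = "L1", a = "N/N", b = "A/A")), "no comparable")
})

test_that("planted genotypes are recovered from simulated pileups", {
  cfg <- tiny_cfg(seed = 25, error_rate = 0.01, microbial_fraction = 0,
                  reads_per_sample = 20L * 20L)  # ~20x over 20 host tags
  tr <- simulate_genomes(cfg)
  db <- truth_db(tr)
  reads <- simulate_reads(cfg, tr, "s1", seed = 6)
  tags <- process_fastq(reads, cfg$enzyme)$tags
  pu <- pileup_host_tags(tags, db, max_mismatch = 2)
  gt <- call_genotypes(pu, error_rate = 0.01, reliable_depth = 5)
  # truth lookup: canonical reference tag + offset -> genotype
  truth_call <- function(locus) {
    parts <- strsplit(locus, ":", fixed = TRUE)[[1]]
    tag <- parts[1]; off <- as.integer(parts[2]) + 1L
    i <- match(tag, canonicalize(tr$host$loci$sequence))
    # offsets are on the canonical orientation; map back if flipped
    seq <- tr$host$loci$sequence[i]
    flipped <- canonicalize(seq) != seq
    h1 <- tr$host$hap1[i]; h2 <- tr$host$hap2[i]
    if (flipped) { h1 <- rc_manual(h1); h2 <- rc_manual(h2) }
    paste(sort(c(substr(h1, off, off), substr(h2, off, off))), collapse = "/")
  }
  called <- gt[gt$call != "N/N", ]
  expect_gt(nrow(called), 400)
  truthv <- vapply(called$locus, truth_call, character(1), USE.NAMES = FALSE)
  expect_gte(mean(called$call == truthv), 0.99)
  # het loci exist and are found
  het <- truthv[vapply(strsplit(truthv, "/"), function(a) a[1] != a[2],
                       logical(1))]
  expect_gt(length(het), 0)
})
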