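# Hologenome database: host tag sets, taxon-specific markers, merge/removal.

# Toy-enzyme tags: ACGT at offset 2, hand-picked so canonical forms differ.
TAG_A <- "GGACGTCA"
TAG_B <- "CAACGTAG"
TAG_C <- "GTACGTTC"

test_that("build_host_tagset stratifies distinct and unique tags", {
  enz <- toy_enzyme()
  g <- c(chr1 = toy_genome(c(TAG_A, TAG_B, TAG_A)))
  hs <- build_host_tagset(g, enz)
  expect_equal(nrow(hs$all_loci), 3L)
  expect_setequal(hs$distinct, canonicalize(c(TAG_A, TAG_B)))
  expect_equal(hs$unique, canonicalize(TAG_B))
  # no sites at all
  hs0 <- build_host_tagset(c(chr1 = "TTTTTTTTTTTT"), enz)
  expect_equal(nrow(hs0$all_loci), 0L)
  expect_length(hs0$distinct, 0L)
  expect_error(build_host_tagset(character(0), enz), "empty")
})

test_that("a sequence plus its reverse complement collapses canonically", {
  enz <- toy_enzyme()
  one <- toy_genome(TAG_A)
  g <- c(chr1 = one, chr2 = rc_manual(one))
  hs <- build_host_tagset(g, enz)
  expect_equal(nrow(hs$all_loci), 2L)
  expect_length(hs$distinct, 1L)
  expect_length(hs$unique, 0L)
})

three_genome_fixture <- function(extra_a = character(0)) {
  # g1,g2 (species A) share single-copy TAG_A; g3 (species B) has TAG_B
  genomes <- list(
    g1 = c(c1 = toy_genome(c(TAG_A, extra_a))),
    g2 = c(c1 = toy_genome(c(TAG_A, extra_a))),
    g3 = c(c1 = toy_genome(TAG_B)))
  taxonomy <- data.frame(
    genome_id = c("g1", "g2", "g3"),
    kingdom = "Bacteria", phylum = "P1", class = "C1", order = "O1",
    family = "F1", genus = "G1",
    species = c("A", "A", "B"), stringsAsFactors = FALSE)
  list(genomes = genomes, taxonomy = taxonomy)
}

test_that("build_marker_db applies the single-copy, single-taxon definition", {
  fx <- three_genome_fixture()
  mdb <- build_marker_db(fx$genomes, fx$taxonomy, toy_enzyme())
  expect_equal(mdb$markers$taxon[match(canonicalize(c(TAG_A, TAG_B)),
                                       mdb$markers$tag)],
               c("A", "B"))
  expect_equal(nrow(mdb$markers), 2L)
  # a tag present twice within one genome is excluded even if exclusive
  fx2 <- fx
  fx2$genomes$g1 <- c(c1 = toy_genome(c(TAG_A, TAG_C, TAG_C)))
  mdb2 <- build_marker_db(fx2$genomes, fx2$taxonomy, toy_enzyme())
  expect_false(canonicalize(TAG_C) %in% mdb2$markers$tag)
  # genome missing from taxonomy is a hard error naming it
  expect_error(
    build_marker_db(c(fx$genomes, list(gX = c(c1 = toy_genome(TAG_C)))),
                    fx$taxonomy, toy_enzyme()),
    "gX")
})

test_that("cross-species tags are rescued at the enclosing rank", {
  # TAG_C in species A and B (same genus): not a species marker, but a
  # genus marker for G1
  genomes <- list(
    g1 = c(c1 = toy_genome(c(TAG_A, TAG_C))),
    g3 = c(c1 = toy_genome(c(TAG_B, TAG_C))))
  taxonomy <- three_genome_fixture()$taxonomy
  taxonomy <- taxonomy[taxonomy$genome_id != "g2", ]
  sp <- build_marker_db(genomes, taxonomy, toy_enzyme(), rank = "species")
  expect_false(canonicalize(TAG_C) %in% sp$markers$tag)
  gn <- build_marker_db(genomes, taxonomy, toy_enzyme(), rank = "genus")
  expect_equal(gn$markers$taxon[gn$markers$tag == canonicalize(TAG_C)], "G1")
})

test_that("marker assignment is independent of genome input order", {
  fx <- three_genome_fixture(extra_a = TAG_C)
  mdb1 <- build_marker_db(fx$genomes, fx$taxonomy, toy_enzyme())
  mdb2 <- build_marker_db(rev(fx$genomes), fx$taxonomy, toy_enzyme())
  expect_equal(mdb1$markers, mdb2$markers)
})

test_that("merge_holodb removes cross-redundant tags from both sides", {
  fx <- three_genome_fixture()
  enz <- toy_enzyme()
  mdb <- build_marker_db(fx$genomes, fx$taxonomy, enz)
  # host shares TAG_B, species B's only marker
  host <- build_host_tagset(c(chr1 = toy_genome(c(TAG_B, TAG_C))), enz)
  db <- merge_holodb(host, mdb)
  expect_equal(db$removal$host_tags_removed, 1L)
  expect_equal(db$removal$host_frac_of_distinct, 0.5)
  expect_equal(db$removal$genomes_removed, 1L)  # g3 lost its only marker
  pr <- db$removal$per_rank
  sp_row <- pr[pr$rank == "species", ]
  expect_equal(sp_row$taxa_affected, 1L)
  expect_equal(sp_row$taxa_removed, 1L)
  expect_length(intersect(db$host_tags, db$markers$tag), 0L)
  expect_false(canonicalize(TAG_B) %in% db$markers$tag)
  expect_false(canonicalize(TAG_B) %in% db$host_tags)

  # no overlap: all-zero report, inputs unchanged
  host2 <- build_host_tagset(c(chr1 = toy_genome(TAG_C)), enz)
  db2 <- merge_holodb(host2, mdb)
  expect_equal(db2$removal$host_tags_removed, 0L)
  expect_equal(db2$removal$genomes_removed, 0L)
  expect_equal(sum(db2$removal$per_rank$taxa_affected), 0L)
  expect_equal(nrow(db2$markers), nrow(mdb$markers))

  # overlap on one of two markers of A: affected but not removed
  fx3 <- three_genome_fixture(extra_a = TAG_C)
  mdb3 <- build_marker_db(fx3$genomes, fx3$taxonomy, enz)
  host3 <- build_host_tagset(c(chr1 = toy_genome(TAG_C)), enz)
  db3 <- merge_holodb(host3, mdb3)
  sp3 <- db3$removal$per_rank[db3$removal$per_rank$rank == "species", ]
  expect_equal(sp3$taxa_affected, 1L)
  expect_equal(sp3$taxa_removed, 0L)
  expect_equal(db3$removal$genomes_removed, 0L)
  expect_true(sp3$taxa_removed <= sp3$taxa_affected)

  # enzyme mismatch is a hard error
  host4 <- build_host_tagset(c(chr1 = "TTGGACGGTTCATT"), toy_degenerate())
  expect_error(merge_holodb(host4, mdb), "different enzymes")
})

test_that("marker discovery matches the brute-force oracle on simulations", {
  for (seed in c(2, 5)) {
    cfg <- tiny_cfg(seed = seed)
    tr <- simulate_genomes(cfg)
    mdb <- build_marker_db(tr$microbes, tr$taxonomy, cfg$enzyme)
    want <- brute_markers(tr$microbes, tr$taxonomy, cfg$enzyme)
    expect_equal(mdb$markers$tag, want$tag)
    expect_equal(mdb$markers$taxon, want$taxon)
    # planted species-private tags recovered, planted cross-species excluded
    pre <- tr$truth$markers_pre_merge
    for (s in names(pre))
      expect_setequal(mdb$markers$tag[mdb$markers$taxon == s], pre[[s]])
    expect_false(any(tr$truth$cross_shared %in% mdb$markers$tag))
    expect_false(any(tr$truth$dup_tags %in% mdb$markers$tag))
    # post-merge db matches planted post-merge truth; intersection empty
    db <- truth_db(tr)
    for (s in names(pre))
      expect_setequal(db$markers$tag[db$markers$taxon == s],
                      tr$truth$markers_post_merge[[s]])
    expect_length(intersect(db$host_tags, db$markers$tag), 0L)
  }
})

test_that("db_summary reports sane per-rank counts and fractions", {
  cfg <- tiny_cfg()
  tr <- simulate_genomes(cfg)
  db <- truth_db(tr)
  s <- db_summary(db)
  expect_equal(s$per_rank$rank[7], "species")
  expect_equal(s$per_rank$n_markers,
               rep(nrow(db$markers), 7))  # all markers aggregate at each rank
  expect_true(s$frac_single_copy >= 0 && s$frac_single_copy <= 1)
  expect_true(all(db$removal$per_rank$frac_affected >= 0 &
                    db$removal$per_rank$frac_affected <= 1))
  expect_true(all(db$removal$per_rank$taxa_removed <=
                    db$removal$per_rank$taxa_affected))
  # mean tags per genome equals a hand recount
  hand <- mean(vapply(tr$microbes, function(g)
    nrow(extract_tags(g[[1]], cfg$enzyme)), numeric(1)))
  expect_equal(s$mean_tags_per_genome, hand)
})

test_that("holodb serialization round-trips", {
  cfg <- tiny_cfg(seed = 9)
  tr <- simulate_genomes(cfg)
  db <- truth_db(tr)
  dir <- withr::local_tempdir()
  write_holodb(db, dir)
  db2 <- read_holodb(dir)
  expect_setequal(db2$host_tags, db$host_tags)
  expect_equal(db2$markers[order(db2$markers$tag), ],
               db$markers[order(db$markers$tag), ],
               ignore_attr = TRUE)
  expect_equal(db2$enzyme$tag_length, db$enzyme$tag_length)
  expect_equal(as.vector(db2$theoretical[names(db$theoretical)]),
               as.vector(db$theoretical))
})
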