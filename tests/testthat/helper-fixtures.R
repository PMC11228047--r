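# Shared fixtures: hand-checkable toy enzymes and constructed genomes.

toy_enzyme <- function() enzyme_spec("toy", "ACGT", 2L, 2L)          # 8-bp tags
toy_degenerate <- function() enzyme_spec("toyD", "ACNNTT", 2L, 2L)   # 10-bp tags

# Genome from explicit toy-enzyme tags separated by site-free spacers.
# Tags for toy_enzyme() must carry ACGT at offset 2 and nothing else that
# matches ACGT/its reverse complement across junctions (spacer is all T).
toy_genome <- function(tags, spacer = "TTTTTTTTTT") {
  paste0(spacer, paste(tags, collapse = spacer), spacer)
}

# Small simulation configs used across tests (kept tiny for speed).
tiny_cfg <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_host_tags = 20L, n_snps = 6L, n_species = 4L,
         genomes_per_species = 2L, tags_per_genome = 6L,
         cross_shared_tags = 2L, host_shared_tags = 1L, dup_tags = 1L,
         reads_per_sample = 2000L, microbial_fraction = 0.3),
    list(...))
  do.call(sim_config, args)
}

# Build the holodb for a truth object.
truth_db <- function(truth) {
  host <- build_host_tagset(truth$host$genome, truth$cfg$enzyme)
  mdb <- build_marker_db(truth$microbes, truth$taxonomy, truth$cfg$enzyme)
  merge_holodb(host, mdb)
}
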