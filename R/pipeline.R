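# End-to-end pipeline: qc -> classify -> genotype + profile -> diversity,
# with TSV reports and a JSON metadata sidecar.

#' Run configuration
#'
#' @param db_dir Directory holding a serialized hologenome database
#'   ([write_holodb()]).
#' @param samples Named character vector of FASTQ paths (names are sample
#'   names).
#' @param out_dir Output directory.
#' @param max_mismatch Mismatch radius for host/microbe partitioning
#'   (default 1: accommodates host allelic variation; 0 gives exact
#'   canonical matching).
#' @param pileup_mismatch Mismatch radius for genotyping pileups (default 2).
#' @param error_rate Sequencing error rate for the genotype caller.
#' @param reliable_depth Minimum depth for reliable genotypes (default 5,
#'   the "greater than 4x" rule).
#' @param min_markers_hit,min_g_score Abundance-profile retention filters.
#' @param seed Seed recorded in metadata (the pipeline itself is
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(db_dir, samples, out_dir,
                       max_mismatch = 1L, pileup_mismatch = 2L,
                       error_rate = 0.01, reliable_depth = 5L,
                       min_markers_hit = 5L, min_g_score = 5,
                       seed = 1L) {
  stopifnot(max_mismatch >= 0L, pileup_mismatch >= 0L,
            reliable_depth >= 1L, min_markers_hit >= 0L, min_g_score >= 0,
            error_rate > 0, error_rate < 1)
  samples <- unlist(samples)  # JSON configs deliver a named list
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("samples must be a named vector of FASTQ paths")
  missing <- samples[!file.exists(samples)]
  if (length(missing))
    stop("FASTQ file(s) not found: ", paste(missing, collapse = ", "))
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from JSON
#'
#' @param path JSON file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j)
}

#' Execute the full analysis pipeline
#'
#' For each sample: quality filtering and tag extraction, partitioning
#' against the hologenome database, species-level abundance profiling, and
#' host genotyping. Across samples: a genotype matrix, replicate agreement
#' (consecutive sample pairs), allele-sharing distances with a
#' neighbor-joining tree, alpha diversity, a Bray-Curtis matrix and PCoA.
#' All report numbers are recomputable from the written intermediate files.
#'
#' @param cfg A [run_config()] (or path to its JSON serialization).
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (!dir.exists(cfg$db_dir) ||
      !file.exists(file.path(cfg$db_dir, "holodb.tsv")))
    stop("hologenome database not found in '", cfg$db_dir,
         "'; build one with holorad build-db (see ?build_host_tagset)")
  db <- read_holodb(cfg$db_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- names(cfg$samples)

  qc_rows <- list(); profiles <- list(); calls <- list(); stats_list <- list()
  for (s in samples) {
    message("[holorad] qc: ", s)
    qc <- process_fastq(cfg$samples[[s]], db$enzyme)
    message("[holorad] classify: ", s, " (", nrow(qc$tags), " tags)")
    part <- partition_sample(qc$tags, db, max_mismatch = cfg$max_mismatch)
    prof <- profile_abundance(part, db, min_markers_hit = cfg$min_markers_hit,
                              min_g_score = cfg$min_g_score)
    message("[holorad] genotype: ", s)
    pu <- pileup_host_tags(qc$tags, db, max_mismatch = cfg$pileup_mismatch)
    gt <- call_genotypes(pu, error_rate = cfg$error_rate,
                         reliable_depth = cfg$reliable_depth)
    qc_rows[[s]] <- partition_report(qc$stats, part, s)
    profiles[[s]] <- prof
    calls[[s]] <- gt
    stats_list[[s]] <- qc$stats
    write_tsv(as.data.frame(prof),
              file.path(cfg$out_dir, paste0("profile_", s, ".tsv")))
  }

  seq_stats <- do.call(rbind, unname(qc_rows))
  write_tsv(seq_stats, file.path(cfg$out_dir, "sequencing_stats.tsv"))

  gm <- genotype_matrix(calls)
  write_tsv(gm, file.path(cfg$out_dir, "genotypes.tsv"))

  agreement <- NULL
  if (length(samples) >= 2L) {
    pairs <- cbind(samples[seq(1L, length(samples) - 1L)],
                   samples[seq(2L, length(samples))])
    agreement <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      a <- compare_replicates(gm[[pairs[i, 1]]], gm[[pairs[i, 2]]])
      cbind(pair = paste(pairs[i, ], collapse = "~"), a)
    }))
    write_tsv(agreement, file.path(cfg$out_dir, "agreement.tsv"))
  }

  gdist <- NULL; nwk <- NULL
  if (length(samples) >= 2L) {
    gdist <- genotype_distance(gm)
    write_phylip(gdist, file.path(cfg$out_dir, "gdist.phy"))
    nwk <- nj_tree(gdist)
    writeLines(nwk, file.path(cfg$out_dir, "njtree.nwk"))
  }

  alpha <- do.call(rbind, lapply(samples, function(s) {
    if (!nrow(profiles[[s]]))
      return(data.frame(sample = s, shannon = NA_real_, simpson = NA_real_,
                        richness = 0L, stringsAsFactors = FALSE))
    a <- alpha_diversity(profiles[[s]])
    data.frame(sample = s, shannon = a$shannon, simpson = a$simpson,
               richness = a$richness, stringsAsFactors = FALSE)
  }))
  write_tsv(alpha, file.path(cfg$out_dir, "diversity.tsv"))

  beta <- NULL; ord <- NULL
  if (length(samples) >= 2L) {
    beta <- beta_matrix(profiles)
    write_phylip(beta, file.path(cfg$out_dir, "beta_braycurtis.phy"))
    ord <- pcoa(beta, k = min(2L, length(samples) - 1L))
    ot <- data.frame(sample = rownames(ord$points), ord$points,
                     stringsAsFactors = FALSE)
    write_tsv(ot, file.path(cfg$out_dir, "pcoa.tsv"))
  }

  cfg_json <- file.path(cfg$out_dir, "config.json")
  cfg_export <- cfg[setdiff(names(cfg), "samples")]
  cfg_export$samples <- as.list(cfg$samples)
  write_json_file(cfg_export, cfg_json)
  meta <- list(
    package = "holorad",
    version = as.character(utils::packageVersion("holorad")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    enzyme = db$enzyme[c("name", "recognition", "flank5", "flank3",
                         "tag_length")],
    shannon_log_base = "e",
    samples = lapply(stats_list, function(x)
      x[c("raw_reads", "hq_reads", "hq_rate", "tags_with_site")])
  )
  write_json_file(meta, file.path(cfg$out_dir, "metadata.json"))

  invisible(list(stats = seq_stats, profiles = profiles,
                 genotypes = gm, agreement = agreement,
                 gdist = gdist, njtree = nwk,
                 alpha = alpha, beta = beta, pcoa = ord,
                 out_dir = cfg$out_dir))
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param m Symmetric matrix with dimnames.
#' @param path Output path.
#' @export
write_phylip <- function(m, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(formatC(rownames(m)[i], width = -10),
                       formatC(m[i, ], format = "g", digits = 10)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labs <- vapply(parts, `[[`, character(1), 1L)
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  dimnames(m) <- list(labs, labs)
  m
}
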