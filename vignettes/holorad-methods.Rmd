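---
title: "holorad: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{holorad: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holorad)
```

# Scope

`holorad` analyses a single 2bRAD library from a holobiont sample twice
over: the host fraction is genotyped, the microbial fraction is profiled at
species level. This vignette records the model underlying each stage, the
tunable parameters with their defaults and rationale, what the synthetic
holobiome emulates, and the design choices made where conventions were
genuinely open. No empirical claim is made here that the test suite or the
acceptance script does not itself compute.

# The enzyme model and digestion

A type IIB enzyme is a recognition pattern in IUPAC codes plus two retained
flank lengths; the tag length is `flank5 + |recognition| + flank3`.
Digestion scans the forward strand for the pattern and for its reverse
complement; a span matching both (palindromic site) is reported once with
strand `+`. Tags are excised `flank5` bases upstream through `flank3` bases
downstream of the recognition span *on the site's strand*, in 0-based
half-open forward-strand coordinates. Sites whose window runs off the
sequence, and windows containing N, are skipped. Overlapping sites are all
reported independently: digestion here is a marker-discovery abstraction,
not a physical fragment model.

**BsaXI offsets.** The literature on this workflow specifies the enzyme
(BsaXI) but not its cut offsets. We fix them from REBASE:
`(9/12)ACNNNNNCTCC(10/7)`. Taking the maximal excised duplex span on the
strand carrying the site gives `flank5 = 12`, `flank3 = 10`, i.e. 33-bp
tags. Both flanks are configuration (`enzyme_spec()`), not constants, and
the chosen tag length is recorded in the database metadata. All unit tests
use toy enzymes with hand-checkable offsets.

**Canonical tags.** Tags are sequenced from either strand, so their
database identity is the *canonical* form: the lexicographic minimum of the
sequence and its reverse complement. Canonicalization is idempotent and
strand-invariant; these properties are tested on random sequences.

# Hologenome database

*Host side.* All tag loci of the host genome are enumerated; the
**distinct** (non-redundant) set is the canonical de-duplication, and the
**unique** set contains canonical tags with genome-wide copy number exactly
one — a tag and its reverse complement at two loci count as two copies.
The published workflow distinguishes "non-redundant" from "unique after
de-redundancy" without defining either; we interpret them as
distinct-sequence vs single-copy sets, and flag rather than assert that
this matches the original authors' intent.

*Microbial side.* A canonical tag is a rank-R marker for taxon T iff (i) it
is single-copy within **every** genome carrying it and (ii) all carrying
genomes belong to T at rank R. The source texts leave open whether
single-copy is required in every carrier or only the source genome; we use
the stricter rule, which can only reduce false-positive markers. Marker
assignment is deterministic and independent of genome input order (tested).

*Cross-redundancy removal.* Host **unique** tags are compared against the
species markers; the intersection is deleted from both sides, so the final
database invariant `host ∩ microbial = ∅` holds on every build (asserted at
construction). The removal report counts: host tags removed, as a fraction
of the **distinct** set (the published fraction is quoted against
non-redundant tags); genomes whose marker count fell to zero ("removed");
and per rank, taxa that lost at least one marker ("affected") versus all
markers ("removed"). These definitions are our own formalization of
statistics the source describes but never defines; they reproduce the
shape (few host tags lost, some genomes dropped, species barely affected)
rather than any specific published value, which would require the 173k
RefSeq genomes.

Taxonomy is a 7-column TSV (`genome_id` + kingdom…species);
`unclassified_<parent>` labels are permitted at intermediate ranks. The
database serializes as a greppable TSV plus a JSON metadata header.

# Read QC

Three filters, applied in order with the first failure recorded:

1. any ambiguous base call (N);
2. a homopolymer run longer than 10 bp;
3. more than 20% of bases with quality below Q10 (Phred+33).

Both thresholds are **strict** inequalities — a 10-base run and an exactly
20% low-quality fraction are kept — following the literal wording of the
filter description. The homopolymer rule is applied per run (not to the
read's total homopolymer content), the more natural reading. No trimming
is performed beyond tag excision: "trimming" in this protocol *is* the
extraction of the fixed-length tag around the recognition site. When
several placements fit inside a read, the leftmost on the forward
orientation wins — 2bRAD reads are designed to contain a single tag, so
multiplicity is an error artifact, and determinism matters more than
adjudication. Quality encoding is fixed to Phred+33.

# Partitioning and profiling

Classification default is `max_mismatch = 0`: exact canonical matching,
equivalent to set membership (oracle-tested), which keeps the classifier
fully auditable. A bounded mismatch radius (≤ 2) is available to emulate
short-read-aligner tolerance; a tag is then assigned to the unique entry at
the best distance, and unassigned when entries with *different* assignments
tie (ties among markers of one species still assign to that species). The
pipeline's partition step defaults to `max_mismatch = 1` so host reads
carrying a non-reference allele still count as host.

Mapping rates are reported over **assigned** tags only — the host and
microbial percentages then sum to 100, matching how the published
per-library statistics behave.

The relative-abundance estimator normalizes reads by marker count:
`d_s = reads_on_markers / theoretical_markers`, renormalized over retained
species. Retention requires `distinct_markers_hit >= 5` and G score
`sqrt(reads_on_markers * distinct_markers_hit) >= 5` (both configurable).
The estimator and the G-score filter follow the design of the 2bRAD
microbiome pipeline this workflow delegates to, which the source invokes
but does not restate; the defaults are that pipeline's conventional
false-positive controls. Dropping a species and renormalizing preserves the
abundance ratio of any two retained species (tested).

# Genotyping

Host-assigned reads are oriented onto their best-matching reference tag
(mismatch radius 2 by default, emulating the original SOAP alignment);
reads equally close to two reference tags are discarded as ambiguous.
Every offset of every covered tag is a detected locus (minimum depth 1).

The caller is a simplified binomial maximum-likelihood codominant model
standing in for the published RAD genotyping program, whose model the
source does not restate. With counts `n1 >= n2` for the two most frequent
bases at a locus of depth `n` and error rate ε (default 0.01):

- homozygote k: each read is allele k with probability `1 − ε`, any
  specific other base `ε/3`;
- heterozygote: each read is one of the two alleles with probability
  `0.5(1 − ε) + ε/6` each.

The multinomial coefficient is shared across genotypes and cancels. The
argmax is returned with its posterior under equal priors. Two reliability
rules: depth below `reliable_depth = 5` — the strict reading of "coverage
greater than 4×" — is unknown; and a third-allele count above `3 ε n`
flags the locus unreliable (only biallelic sites are modelled). The caller
is monotone in majority evidence (property-tested) and agrees with direct
likelihood enumeration.

**Agreement stratification.** Replicate agreement counts loci genotyped in
*both* libraries and stratifies by the class (homozygote/heterozygote) of
the **first** column's call; the published tables do not state where a
hom-vs-het discordance is counted, so this convention is ours and is
recorded here rather than claimed as the original. Percentages are
`100 · same / genotyped`, rounded to two decimals — the published
agreement figures are reproduced exactly from their printed counts under
this formula.

**Genetic distance.** Allele-sharing distance: per locus called in both
samples, `1 − shared_alleles/2`, averaged over comparable loci; symmetric
with zero diagonal; pairs with no comparable loci are flagged `NA`.

# Diversity, ordination, trees

Shannon (natural log — the source does not state a base; recorded in
output metadata) with `0·log 0 := 0`; Simpson `1 − Σp²`; Bray–Curtis
`Σ|x−y| / Σ(x+y)` over the species union. PCoA is classical metric
scaling: double-centered Gower matrix, top-k eigenvectors scaled by
`sqrt(eigenvalue)`; negative eigenvalues are dropped from the variance
denominator; `k` beyond the positive spectrum truncates with a warning,
and a fully degenerate (all-zero) matrix yields a flat embedding. The
source ran both PCA and PCoA; one ordination engine covers both (PCA on
abundances is metric scaling of their Euclidean distances).

Neighbor joining is the standard Saitou–Nei agglomeration with
rate-corrected branch lengths. Determinism: equal Q values resolve to the
lexicographically smallest pair of node labels (a node is labelled by the
smallest leaf beneath it). Negative branch lengths are clamped to zero
with the deficit moved to the adjacent branch, so path lengths are
preserved where possible. The output is a Newick string rooted as a
trifurcation (the usual unrooted convention); two taxa at distance d give
`(A:d/2,B:d/2);`. NJ recovers additive matrices exactly and matches the
reference implementation in `ape` on random matrices (both tested).

# The synthetic holobiome

The generator is first-class, tested code; its defaults are the package's
"stated world":

- **enzyme** BsaXI (33-bp tags);
- **host**: 200 planted tag loci separated by 40-bp spacers; 60 SNPs
  planted inside tags (at most one per tag, never at a fixed recognition
  position), 50% heterozygous, the rest homozygous-alternate; two
  haplotypes realize the diploid;
- **community**: 20 species × 2 conspecific genomes × 30 species-private
  single-copy tags; 10 tags shared across species pairs, 4 shared with the
  host, 5 duplicated within a genome — exercising every exclusion rule;
- **library**: microbial fraction 0.10 (fecal-like; gill-like samples run
  2–5%), substitution error rate 0.005 (Illumina-like), qualities uniform
  on Q30–40 so no error-free read fails the quality filter, read length =
  tag length (a padded mode embeds tags in longer reads to exercise
  placement search);
- **depth**: 40,000 reads by default; `reads_per_marker = 50` derives the
  library size so the *mean* species marker receives 50 reads — with
  Dirichlet-distributed abundances a guarantee for the rarest species is
  not meaningful, so the depth target is an average, not a minimum.

Genomes are assembled as planted tags between random spacers; recognition
sites arising by chance are destroyed by point mutations at constrained
pattern positions outside planted spans, so digestion recovers exactly the
planted loci (tested). All randomness flows from the single seed;
replicate libraries take derived seeds. Read ids carry the truth label
(`src=`, `tag=`, `hap=`).

What the simulator does **not** emulate: indels (matching is
mismatch-based on fixed-length tags), PCR duplicates, GC or
position-dependent quality bias, chimeras, contamination, or genuinely
related genomes (conspecific genomes share tags by construction rather
than by descent). A green recovery test therefore establishes correctness
of the *computational* chain — digestion, database logic, filtering,
matching, calling, estimation — not robustness to library-preparation
artifacts absent from the model.

# Numerical conventions

- Rates and agreement percentages are rounded to 2 decimals at the
  reporting boundary only; internal computation is double precision.
- Empty inputs: an empty library reports all-zero statistics with the rate
  flagged undefined (printed 0.00); an empty assigned set flags mapping
  rates `NA`; a species union smaller than 2 makes profile correlation
  `NA` with a warning.
- Ties: base order A < C < G < T breaks ties in the caller's top-two
  selection; the NJ tie-break is described above; leftmost placement wins
  in tag extraction.
- Genome bases other than A/C/G/T/N are rejected at FASTA parse time.
- Configuration serializes as JSON (no YAML parser is available in the
  supported dependency set); reports are TSV with a JSON metadata sidecar
  carrying version, seed and config hash.

# Known limitations

- Mismatch-tolerant matching is exhaustive (vectorized Hamming distance
  against the whole database) — fine at the package's database scales,
  quadratic in principle; a seeded k-mer index would be the next step for
  RefSeq-scale databases.
- The genotype caller models biallelic SNPs only; tri-allelic loci are
  reported unknown rather than resolved.
- Host genotyping assumes the reference tag set is complete; reads from
  loci absent in the reference (presence/absence variation) end up
  unassigned rather than assembled de novo.
- Published real-data headline numbers (mapping-rate ranges, species
  inventories) depend on the original sequencing runs and the RefSeq
  snapshot and are not reproducible at desk scale; the package's claims
  are therefore anchored to printed-count arithmetic and synthetic-truth
  recovery.
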