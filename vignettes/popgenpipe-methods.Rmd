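---
title: "Methods and design notes for popgenpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for popgenpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenpipe)
```

popgenpipe takes analyses from a phased, multi-sample VCF to the input files
of demographic-inference software (IMa3, G-PhoCS, dadi, treemix,
fastsimcoal2, EIGENSTRAT, PLINK-style PED), with the intermediate steps —
site and locus filtering, summary statistics, statistic-binned locus
sampling, recombination-free block extraction, sequence reconstruction —
exposed as composable functions over tibbles. This vignette records the
models implemented, the conventions adopted where the underlying file
formats or statistics leave room, and the reasoning behind the design
choices, so that results are interpretable without reading the source.

## Population models

A *population model* is a named, ordered assignment of individuals to
populations, optionally with a population tree. Several models may share a
JSON model file (an individual may appear in more than one model — e.g. a
2-population and a 4-population design over one cohort — but never in two
populations of the same model; downstream exporters require disjoint
populations). Population order is meaningful: it fixes sample-column order
in every exporter, and `model_individuals()` is defined as the population-
by-population concatenation. The JSON dialect is a top-level array of
`{"name", "tree", "pops": {pop: {"inds": [...]}}}` objects; unknown extra
keys survive a read/write round trip so files can carry their own metadata.
The tree string is checked only for balanced parentheses — it is passed
through verbatim to IMa3, which has its own grammar.

## Coordinates and the variant table

VCF positions are 1-based; BED intervals are 0-based half-open. A VCF record
at position $p$ lies inside a BED interval $(s, e]$ iff $s < p \le e$. These
are the standard conventions of both formats and are applied uniformly
(positional filters, locus splitting, window statistics via
`stats_to_intervals()`).

The in-memory container (`vcf_tbl`) is a tibble of the eight fixed VCF
columns plus one character column of GT strings per sample. Only the GT
FORMAT field is carried ("the canonical dialect"); depth, likelihoods and
other per-genotype annotations are outside the package's scope, so reading
and re-writing a file normalises FORMAT to GT. Phase is preserved
exactly: `0|1` and `0/1` are different genotypes to every consumer that
cares (the four-gamete test and sequence reconstruction reject unphased
heterozygotes; allele-count consumers ignore phase).

## Site filtering

All per-site quantities are computed on the *called alleles of the retained
samples*: after a model-based sample subset, a triallelic record where the
subset carries only two alleles is biallelic for filtering purposes.
Concretely:

* allele class — `invariant` (at most one distinct called allele),
  `biallelic` (two), `multiallelic` (three or more);
* MAF/MAC — frequency/count of the rarest called allele (missing genotypes
  excluded from numerator and denominator); at a biallelic site MAF is
  invariant under swapping the REF/ALT labels;
* missingness — genotypes containing at least one missing allele, as a
  count and as a fraction of retained samples;
* `require_filter = "PASS"` is strict: a record with a missing FILTER column
  fails the requirement;
* an indel is any record whose REF or an ALT is not a single A/C/G/T base.

Filters compose by conjunction and the output is always a subsequence of the
input records, which makes filtering idempotent — both properties are tested
on randomized tables.

## Locus filtering

`filter_loci()` keeps intervals whose qualifying-variant count, missing-data
load, and length pass thresholds. A qualifying variant is a polymorphic
record inside the interval, optionally excluding indels, multiallelic sites,
and variants inside a CpG dinucleotide of the reference. A site at position
$p$ counts as "within a CpG" when the reference reads `CG` at $(p, p+1)$ or
at $(p-1, p)$ — the symmetric rule covers a variant at either base of the
dinucleotide on either strand. Missing data is counted per genotype by
default; `missing_per = "site"` switches to the number of records with any
missing genotype, since toolkits differ and the choice materially changes
thresholds.

## Tajima's D

For a window with $S$ segregating biallelic SNPs and per-site unbiased
heterozygosity $\pi_\text{site} = 2p(1-p)\,n/(n-1)$ summed to $\pi$ (with
$p$ the allele frequency and $n$ the called allele count at the site),

$$D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}}$$

with $a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$ the usual constants of the
statistic, evaluated at the haploid sample size. With complete data the
per-site formula for $\pi$ equals the mean pairwise difference exactly, and
the test suite verifies agreement with an explicit pairwise-counting oracle
to $10^{-10}$. Two deliberate choices:

* the normalising constants need a single $n$; with missing data the called
  count varies by site, so the constants use the full haploid count of the
  table's samples while $\pi$ and $S$ use called alleles per site. On
  complete data the distinction vanishes;
* windows with $S = 0$ (or a non-positive variance term) yield `NA`, never a
  silent 0 — an undefined D and a D of zero mean different things.

Multiallelic sites and indels are excluded (a flag upgrades the exclusion to
an error for pipelines that want to be told).

## Weir–Cockerham FST

Per biallelic SNP, the three variance components are computed from the
per-population called sample sizes $n_i$ (diploid individuals), ALT
frequencies $p_i$ and observed heterozygote frequencies $h_i$: $a$ (among
populations), $b$ (among individuals within populations), $c$ (within
individuals). The windowed estimate is the ratio of sums
$\hat\theta = \sum_s a_s / \sum_s (a_s + b_s + c_s)$ over polymorphic sites,
`NA` when the denominator is empty or zero. Monomorphic sites contribute
$a = b = c = 0$ and are skipped; sites where a population has no called
genotype are skipped with a counter (erroring is reserved for structural
problems: fewer than two populations, or model individuals absent from the
table). The estimate is invariant under population relabeling and REF/ALT
swaps, and the per-site components match an independent transcription of the
defining formulas to $10^{-12}$ in the tests.

The island-model recovery test gives the estimator an end-to-end check: with
per-population allele frequencies drawn from a Beta distribution with
variance $F\,p(1-p)$ around a shared ancestral frequency (the
Balding–Nichols parameterisation, expected FST $= F$), the mean windowed
estimate over 200 replicate windows of 40 SNPs × 8+8 diploids must fall
within ±0.02 of $F = 0.2$.

## Windowed scans and locus sampling

`windowed_scan()` tiles each chromosome from its first record (anchoring at
position 1 is available by flag; first-record anchoring avoids emitting long
runs of empty windows on sparse scaffolds and is the documented default).
Empty windows are emitted with `NA` so that downstream binning sees the gaps,
unless `drop_empty` is set.

`sample_loci()` draws `n` loci from the defined-value rows of a statistic
table. The uniform scheme bins values into `bins` equal-width, right-closed
bins over the observed range and allocates $\lfloor n/\text{bins} \rfloor$
draws per non-empty bin, one extra for the first $n \bmod \text{bins}$
non-empty bins. When a bin holds fewer loci than its quota, all of it is
taken and the deficit moves to later bins with spare capacity — the
alternative (erroring) makes the scheme unusable on skewed statistics, and
silently returning fewer than `n` loci would corrupt downstream bookkeeping.
All sampling runs under R's Mersenne–Twister generator with the "Rejection"
sample kind, seeded per call and restored afterwards, so samples are
reproducible across platforms and sessions.

Statistic tables serialise as TSV with header
`CHROM BIN_START BIN_END N_SITES <STAT>` and the token `nan` for undefined
values; they re-read losslessly and convert to BED-style intervals for
`split_by_loci()`.

## Four-gamete test and block extraction

Two biallelic sites are incompatible with a single non-recombining genealogy
under infinite sites when all four gametes (00, 01, 10, 11) occur among
haplotypes called at both sites. `find_compatible_intervals()` returns every
*maximal* contiguous run of sites that is pairwise compatible; runs may share
boundary sites, and their union covers every site (a single site is
trivially compatible). Internally the minimal valid start for each right
endpoint is maintained by a sweep over a precomputed incompatibility matrix
(four boolean cross-products); correctness is defined by — and tested
against — exhaustive pair enumeration on a thousand random matrices.

Conventions: haplotypes with a missing allele at either site contribute no
gamete to that pair (strict mode errors instead); multiallelic sites are
dropped before matrix construction (strict mode errors); unphased
heterozygotes are always an error, because the test is defined on haplotypes
and phasing belongs upstream. Single-block selection defaults to
longest-by-site-count with leftmost tie-breaking — a deterministic default —
with `leftmost` and seeded `random` alternatives. A locus none of whose
blocks reaches `min_sites` raises a classed rejection
(`popgenpipe_locus_rejected`) so pipelines can count rejected loci rather
than crash.

## BED interval algebra

`merge`, `subtract`, `complement` are per-base set operations (delegated to
IRanges after the 0-based/1-based shift) and therefore drop columns beyond
chrom/start/end; `sort`, `extend`, `sample` carry extra columns through.
Book-ended intervals merge by default, matching the common toolkit default,
with an off switch. Extension is strand-ignorant unless asked, and clips to
the genome file. The whole module is tested against a literal per-base
boolean-mask oracle, plus the identities `merge∘merge = merge`,
`complement∘complement = merge`, and `|merge(a)| + |complement(a)| =`
genome size.

## Sequence reconstruction

Each haplotype of each model individual over a region is the reference
substring with the carried allele substituted at every SNP. Indels are
rejected by default — the IM-style formats require equal-length rows, and
silently skipping indel records would misrepresent the data; an explicit
`on_indel = "skip"` downgrades to a warning. A missing allele becomes `N`
rather than the reference base, so missing data stays visible in the
alignment instead of masquerading as ancestral sequence. Reconstruction is
invariant to record order and is tested against a naive position-by-position
substitution oracle.

## Site frequency spectra

The joint SFS over $k$ populations is a $k$-dimensional array with dimension
sizes $2n_i + 1$. The derived allele is read from the `AA` INFO key when it
matches REF or ALT; otherwise REF is treated as ancestral with a prominent
warning — in that situation the folded spectrum is the honest object, and
`polarization = "folded"` is recommended. Folding merges each cell with its
component-wise complement $2n - x$, moving mass to the cell with the smaller
total derived count (ties to the lexicographically smaller index;
self-complementary cells stay put), which preserves totals exactly. Sites
with any missing genotype among model individuals are skipped and counted —
no hypergeometric projection to smaller sample sizes is attempted in this
version, a documented non-goal. Monomorphic corner cells are excluded by
default and includable by flag, since fastsimcoal2 conventions differ by use
case. Conservation ($\sum$ cells = tallied sites; skipped counters account
for the rest) is asserted on every fixture.

The fastsimcoal2 `.obs` serialisation covers one population (header
`d0_0 … d0_2n` over one count row) and two (joint matrix, rows labelled by
the second population as `d1_*`, columns by the first as `d0_*`, in the
jointDAFpop file style); higher dimensions use the flat dump
(`#dims: …` + flattened counts in R array order), which dadi-style scripts
can reshape.

## Format writers

* **IMa3** — title; population count; names; tree (required — export
  without a population tree is refused); locus count; per locus a header
  `name n_1 … n_k length mutmodel inheritance` and one line per sequence
  with a 10-character, left-justified, space-padded name (non-alphanumerics
  mapped to `_`). Defaults: mutation model `I` (infinite sites — consistent
  with four-gamete pre-filtering) and inheritance scalar 1.0 (autosomal),
  both overridable. Per-locus mutation-rate annotations are not emitted in
  this version.
* **G-PhoCS** — locus count, then `name n length` + `seqname sequence`
  blocks.
* **treemix** — population-name header, then `refCount,altCount` per
  population per biallelic SNP, over called alleles; sites leaving a
  population with zero called alleles are skipped with a counter (strict
  flag errors).
* **dadi SNP table** — reference trinucleotide contexts (`-` padding at
  chromosome edges, `-X-` without a reference, `---` outgroup column when
  absent), `Allele1` (REF) and `Allele2` (ALT) with per-population counts,
  chromosome and position.
* **EIGENSTRAT** — `.geno` digits count copies of the `.snp` column-5 allele
  (REF), `9` for missing; `.snp` uses genetic position 0.0 (no genetic-map
  interpolation); `.ind` takes the population from the model, sex `U`.
* **PED-12/MAP** — REF=1, ALT=2, missing `0 0`; family ID = population.

Every writer has a paired reader in the test suite that reconstructs
counts, sequences or genotypes and compares them with the in-memory source.

## Synthetic data

`simulate_dataset()` generates a reference FASTA, a phased sorted VCF, locus
intervals, a model file, and a truth record, all deterministically from one
seed. Sites are placed on even offsets within loci (≥ 2 bp apart, so planted
CpG dinucleotides never collide with a neighbouring site). Genotypes are
drawn per site from either a shared allele frequency or the Balding–Nichols
island pair targeting an expected FST; planted indels, triallelic sites,
missing genotypes, and FILTER failures are disjoint by construction and
counted exactly in the truth record. SNP sites are forced to be segregating
(bounded deterministic resampling) so that truth counts for "variant site"
filters are exact; at the default sample sizes this conditioning has a
negligible effect on the FST expectation, since monomorphic draws contribute
zero to both terms of the ratio-of-sums estimator anyway.

In block mode, each block's site columns are nested clades (prefixes of a
per-block haplotype permutation), which guarantees four-gamete compatibility
within the block; the permutation of the next block is re-drawn until the
boundary site pair shows all four gametes, so maximal compatible intervals
coincide with the planted blocks exactly.

What the generator deliberately does *not* emulate: linkage disequilibrium
within loci (sites are independent given frequencies), mutation-rate or
recombination-rate variation, realistic indel length spectra, sequencing
error, and demography beyond the single-parameter island model. Passing
tests therefore demonstrate correctness of the computations, not robustness
to every property of real data — in particular the FST recovery test checks
estimator calibration under the model that defines the target, nothing more.

## Problem sizes and numerics

The test suite runs at sizes chosen to finish comfortably on one CPU while
still exercising the asymptotics that matter: 1,000 random haplotype
matrices (4–10 haplotypes × 5–50 sites) for the four-gamete oracle; 100
random windows each for the Tajima and Weir–Cockerham oracles (tolerances
$10^{-10}$ and $10^{-12}$); 200 replicate windows for FST recovery; 200
randomized interval-algebra cases on ≤ 100 kb toy genomes; 500 sites for the
SFS tally; and a 100-locus end-to-end pipeline sampled down to 20 loci. The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
from scratch at comparable sizes.

All floating-point comparisons in the statistics are direct (no fuzzy
accumulation); undefined values are represented as `NA` throughout and as
the token `nan` on disk. Stable sorts are used everywhere ordering is
observable (record order, chromosome order from header contigs, tie-breaks
in block selection), so equal inputs produce byte-identical outputs.

## Known limitations

GT is the only FORMAT field carried; BCF and tabix indexing are out of
scope (plain or gzip VCF text only). The four-gamete module neither
estimates the minimum number of recombination events nor computes LD
statistics. SFS projection, binary PLINK output, and the execution of the
downstream inference tools themselves (phasing, IMa3, ADMIXTURE,
EIGENSTRAT, treemix runs) are out of scope: the package prepares their
inputs and stops there.
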