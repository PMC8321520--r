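# Seeded synthetic fixtures ---------------------------------------------------
#
# Generates a reference FASTA + phased VCF + BED loci + model file with
# controlled statistical structure, plus a truth record of everything that
# was planted (indels, multiallelic sites, missing data, filter failures,
# CpG sites, four-gamete block layout, expected FST), so that filtering,
# statistics and block extraction can be tested against exact expectations.
# All randomness flows from one seed through R's Mersenne-Twister generator
# (sample kind "Rejection"), so outputs are reproducible across platforms.

#' Specify a synthetic dataset
#'
#' @param seed Mandatory integer seed.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param pops Named integer vector: population -> diploid individual count.
#' @param freq_model Per-site allele-frequency model: `list(kind =
#'   "shared", p_range = c(lo, hi))` draws one frequency shared by all
#'   populations; `list(kind = "island", fst = F, p_range = ...)` draws an
#'   ancestral frequency p and then per-population frequencies from
#'   Beta(p(1-F)/F, (1-p)(1-F)/F) — the Balding-Nichols island model whose
#'   expected Weir-Cockerham FST is F.
#' @param n_loci,locus_length,locus_gap Locus layout: `n_loci` intervals of
#'   `locus_length` bp separated by `locus_gap` bp, tiled across
#'   chromosomes in order.
#' @param snps_per_locus SNP sites per locus (placed on even offsets, so
#'   sites are >= 2 bp apart and planted CpG dinucleotides never collide).
#' @param frac_indel,frac_multiallelic,frac_missing,frac_filter_fail,frac_cpg
#'   Fractions of sites to plant as, respectively: indels, triallelic sites,
#'   sites with one missing genotype, sites failing FILTER (= `LowQual`),
#'   and SNPs inside a reference CpG. Converted to exact counts
#'   (`round(frac * total sites)`), disjoint by construction.
#' @param blocks Optional `list(n_blocks =, sites_per_block =)`: build each
#'   locus from that many recombination-free haplotype blocks instead of
#'   independent-site frequencies (see Details).
#' @details In block mode each block's site columns are nested clades of a
#'   random perfect genealogy (guaranteeing four-gamete compatibility within
#'   the block), and adjacent blocks use re-permuted haplotype labels,
#'   re-drawn until the boundary site pair displays all four gametes — so the
#'   maximal compatible intervals are exactly the blocks.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(seed,
                     chrom_lengths = c(chr1 = 100000L),
                     pops = c(A = 4L, B = 4L),
                     freq_model = list(kind = "island", fst = 0.2, p_range = c(0.1, 0.9)),
                     n_loci = 20, locus_length = 2000, locus_gap = 500,
                     snps_per_locus = 10,
                     frac_indel = 0, frac_multiallelic = 0, frac_missing = 0,
                     frac_filter_fail = 0, frac_cpg = 0,
                     blocks = NULL) {
  if (missing(seed)) rlang::abort("a seed is mandatory")
  if (length(pops) < 1 || any(pops < 1)) rlang::abort("need >= 1 population with >= 1 individual")
  if (any(chrom_lengths < 1)) rlang::abort("chromosome lengths must be >= 1")
  fr <- c(frac_indel, frac_multiallelic, frac_missing, frac_filter_fail, frac_cpg)
  if (any(fr < 0 | fr > 1)) rlang::abort("fractions must be in [0, 1]")
  if (!is.null(blocks)) {
    snps_per_locus <- blocks$n_blocks * blocks$sites_per_block
  }
  structure(
    list(
      seed = as.integer(seed), chrom_lengths = chrom_lengths, pops = pops,
      freq_model = freq_model, n_loci = n_loci, locus_length = locus_length,
      locus_gap = locus_gap, snps_per_locus = snps_per_locus,
      frac_indel = frac_indel, frac_multiallelic = frac_multiallelic,
      frac_missing = frac_missing, frac_filter_fail = frac_filter_fail,
      frac_cpg = frac_cpg, blocks = blocks
    ),
    class = "sim_spec"
  )
}

draw_site_freqs <- function(fm, n_pops) {
  p0 <- stats::runif(1, fm$p_range[1], fm$p_range[2])
  if (identical(fm$kind, "shared")) {
    rep(p0, n_pops)
  } else {
    f <- fm$fst
    stats::rbeta(n_pops, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  }
}

# One biallelic genotype column: 0/1 alleles per haplotype, individuals of
# population j drawing from freq p[j]; re-drawn (bounded) until segregating.
draw_biallelic_column <- function(p, pops) {
  n_hap <- 2L * sum(pops)
  pop_of_hap <- rep(rep(seq_along(pops), pops), each = 2)
  for (try in 1:100) {
    al <- stats::rbinom(n_hap, 1L, p[pop_of_hap])
    if (any(al == 1L) && any(al == 0L)) return(al)
  }
  al[1] <- 1L - al[1]
  al
}

# Nested-clade columns for one recombination-free block: site k's derived
# set is a prefix of the block's haplotype permutation.
block_columns <- function(n_hap, n_sites, perm) {
  sizes <- sample(2:(n_hap - 2), n_sites, replace = TRUE)
  lapply(sizes, function(k) {
    col <- integer(n_hap)
    col[perm[seq_len(k)]] <- 1L
    col
  })
}

four_gametes <- function(a, b) {
  length(unique(a * 2L + b)) == 4L
}

other_base <- function(base, k = 1) {
  sample(setdiff(c("A", "C", "G", "T"), base), k)
}

#' Generate a synthetic dataset
#'
#' Deterministically expands a [sim_spec()] into a reference, a phased
#' variant table, locus intervals, a model file, and a truth record listing
#' everything planted.
#'
#' @param spec A `sim_spec`.
#' @return List with elements `ref` (`DNAStringSet`), `vcf` (`vcf_tbl`,
#'   phased, sorted), `loci` (interval tibble with a `name` column),
#'   `models` (`model_file` holding model `"model1"`), `genome` (tibble
#'   `chrom`/`length`) and `truth` (list: planted counts, `expected_fst`,
#'   per-locus `block_layout`, positions of planted CpG sites).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, simulate_dataset_impl(spec))
}

simulate_dataset_impl <- function(spec) {
  pops <- spec$pops
  n_ind <- sum(pops)
  n_hap <- 2L * n_ind
  inds <- unlist(lapply(names(pops), function(p) sprintf("%s_%d", p, seq_len(pops[[p]]))))
  pop_list <- split(inds, rep(names(pops), pops))[names(pops)]

  # reference
  ref_chars <- lapply(spec$chrom_lengths, function(len) {
    sample(c("A", "C", "G", "T"), len, replace = TRUE)
  })

  # locus layout, tiled across chromosomes
  loci <- list()
  for (ch in names(spec$chrom_lengths)) {
    len <- spec$chrom_lengths[[ch]]
    if (len < spec$locus_gap + spec$locus_length) next
    starts <- seq.int(spec$locus_gap, len - spec$locus_length,
      by = spec$locus_length + spec$locus_gap
    )
    for (s in starts) {
      if (length(loci) >= spec$n_loci) break
      loci[[length(loci) + 1L]] <- tibble::tibble(
        chrom = ch, start = as.integer(s), end = as.integer(s + spec$locus_length)
      )
    }
  }
  if (length(loci) < spec$n_loci) {
    rlang::abort("chromosomes too short for the requested locus layout")
  }
  loci <- dplyr::bind_rows(loci)
  loci$name <- sprintf("locus%d", seq_len(nrow(loci)))

  # site positions: even offsets only, so neighbouring sites are >= 2 apart
  site_list <- lapply(seq_len(nrow(loci)), function(i) {
    offs <- sort(sample(seq(2L, spec$locus_length - 2L, by = 2L), spec$snps_per_locus))
    tibble::tibble(locus = i, chrom = loci$chrom[i], pos = loci$start[i] + offs)
  })
  sites <- dplyr::bind_rows(site_list)
  n_sites <- nrow(sites)

  # plant site types (disjoint)
  type <- rep("clean", n_sites)
  counts <- c(
    indel = round(spec$frac_indel * n_sites),
    multiallelic = round(spec$frac_multiallelic * n_sites),
    missing = round(spec$frac_missing * n_sites),
    filter_fail = round(spec$frac_filter_fail * n_sites),
    cpg = round(spec$frac_cpg * n_sites)
  )
  if (is.null(spec$blocks)) {
    pool <- seq_len(n_sites)
    for (ty in names(counts)) {
      k <- counts[[ty]]
      if (k == 0) next
      if (k > length(pool)) rlang::abort("planted fractions exceed available sites")
      chosen <- if (length(pool) == 1) pool else sample(pool, k)
      type[chosen] <- ty
      pool <- setdiff(pool, chosen)
    }
  } else {
    counts[] <- 0L # block mode: clean biallelic sites only
  }

  # plant CpG dinucleotides in the reference (variant at the C position)
  for (i in which(type == "cpg")) {
    ch <- sites$chrom[i]
    ref_chars[[ch]][sites$pos[i]] <- "C"
    ref_chars[[ch]][sites$pos[i] + 1L] <- "G"
  }

  # genotype columns and records
  hap_cols <- vector("list", n_sites)
  rec_ref <- rec_alt <- character(n_sites)
  rec_filter <- rep("PASS", n_sites)
  missing_ind <- rep(NA_integer_, n_sites)
  block_layout <- list()

  if (!is.null(spec$blocks)) {
    nb <- spec$blocks$n_blocks
    spb <- spec$blocks$sites_per_block
    for (li in seq_len(nrow(loci))) {
      rows <- which(sites$locus == li)
      prev_last <- NULL
      for (b in seq_len(nb)) {
        repeat {
          perm <- sample.int(n_hap)
          cols <- block_columns(n_hap, spb, perm)
          # boundary must show all four gametes against the previous block
          if (is.null(prev_last) || four_gametes(prev_last, cols[[1]])) break
        }
        idx <- rows[((b - 1) * spb + 1):(b * spb)]
        hap_cols[idx] <- cols
        prev_last <- cols[[spb]]
        block_layout[[length(block_layout) + 1L]] <- tibble::tibble(
          locus = li, block = b,
          start_bp = sites$pos[idx[1]], end_bp = sites$pos[idx[spb]],
          n_sites = spb
        )
      }
    }
  } else {
    for (i in seq_len(n_sites)) {
      if (type[i] == "indel" || type[i] == "multiallelic") next
      p <- draw_site_freqs(spec$freq_model, length(pops))
      hap_cols[[i]] <- draw_biallelic_column(p, pops)
    }
  }

  gt <- matrix("0|0", nrow = n_sites, ncol = n_ind, dimnames = list(NULL, inds))
  for (i in seq_len(n_sites)) {
    ch <- sites$chrom[i]
    base <- ref_chars[[ch]][sites$pos[i]]
    if (type[i] == "indel") {
      rec_ref[i] <- paste0(base, ref_chars[[ch]][sites$pos[i] + 1L])
      rec_alt[i] <- base
      p <- draw_site_freqs(spec$freq_model, length(pops))
      al <- draw_biallelic_column(p, pops)
    } else if (type[i] == "multiallelic") {
      rec_ref[i] <- base
      rec_alt[i] <- paste(other_base(base, 2), collapse = ",")
      al <- sample(0:2, n_hap, replace = TRUE)
      al[1:3] <- 0:2 # force all three alleles observed
    } else {
      rec_ref[i] <- base
      rec_alt[i] <- other_base(base, 1)
      al <- hap_cols[[i]]
    }
    g <- paste(al[seq(1, n_hap, 2)], al[seq(2, n_hap, 2)], sep = "|")
    if (type[i] == "missing") {
      j <- sample.int(n_ind, 1)
      g[j] <- "./."
      missing_ind[i] <- j
    }
    if (type[i] == "filter_fail") rec_filter[i] <- "LowQual"
    gt[i, ] <- g
  }

  rec <- tibble::tibble(
    chrom = sites$chrom, pos = sites$pos, id = ".",
    ref = rec_ref, alt = rec_alt, qual = 100,
    filter = rec_filter, info = "."
  )
  for (s in inds) rec[[s]] <- gt[, s]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(spec$chrom_lengths), spec$chrom_lengths),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  vcf <- sort_vcf(vcf_tbl(rec, header = header))

  tree <- if (length(pops) >= 2) {
    paste0(Reduce(function(a, b) paste0("(", a, ",", b, ")"), names(pops)), ";")
  } else {
    NULL
  }
  model <- pop_model("model1", pop_list, tree = tree)

  ref <- Biostrings::DNAStringSet(vapply(ref_chars, paste, character(1), collapse = ""))
  names(ref) <- names(spec$chrom_lengths)

  expected_fst <- if (identical(spec$freq_model$kind, "island")) spec$freq_model$fst else 0

  list(
    ref = ref,
    vcf = vcf,
    loci = loci,
    models = model_file(model),
    genome = tibble::tibble(
      chrom = names(spec$chrom_lengths),
      length = as.integer(spec$chrom_lengths)
    ),
    truth = list(
      n_sites = n_sites,
      n_indel = counts[["indel"]],
      n_multiallelic = counts[["multiallelic"]],
      n_missing = counts[["missing"]],
      n_filter_fail = counts[["filter_fail"]],
      n_cpg = counts[["cpg"]],
      n_clean_biallelic = n_sites - sum(counts),
      cpg_pos = sites$pos[type == "cpg"],
      site_type = type,
      expected_fst = expected_fst,
      block_layout = if (length(block_layout) > 0) dplyr::bind_rows(block_layout) else NULL
    )
  )
}

#' Write a simulated dataset to disk
#'
#' Writes `ref.fasta`, `variants.vcf`, `loci.bed`, `genome.txt` and
#' `models.json` under `dir`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$ref, file.path(dir, "ref.fasta"))
  write_vcf(sim$vcf, file.path(dir, "variants.vcf"))
  write_bed(sim$loci, file.path(dir, "loci.bed"))
  readr::write_tsv(sim$genome, file.path(dir, "genome.txt"),
    col_names = FALSE, progress = FALSE
  )
  write_model_file(sim$models, file.path(dir, "models.json"))
  invisible(dir)
}
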