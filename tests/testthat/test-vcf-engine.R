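# A 20-record fixture of known composition: 5 indels, 3 triallelic, 4 with
# missing data, 8 clean biallelic records.
make_mixed_vcf <- function() {
  base <- tibble::tibble(
    chrom = "chr1", pos = seq(10L, 200L, by = 10L), id = ".",
    ref = "A", alt = "T", qual = 50, filter = "PASS", info = ".",
    s1 = "0|1", s2 = "0|0", s3 = "1|1", s4 = "0|1"
  )
  base$ref[1:5] <- "AT"
  base$alt[1:5] <- "A" # indels
  base$alt[6:8] <- "T,G"
  base$s3[6:8] <- "2|1" # triallelic, all alleles observed
  base$s2[9:12] <- "./." # missing data
  vcf_tbl(base)
}

test_that("site filters remove exactly the planted records", {
  v <- make_mixed_vcf()
  spec <- site_filter_spec(
    include_classes = "biallelic", max_missing_count = 0, drop_indels = TRUE
  )
  out <- filter_sites(v, spec)
  expect_equal(nrow(out), 8)
  expect_true(all(out$pos >= 130))

  # single-rule filters
  expect_equal(nrow(filter_sites(v, site_filter_spec(drop_indels = TRUE))), 15)
  expect_equal(
    nrow(filter_sites(v, site_filter_spec(exclude_classes = "multiallelic"))), 17
  )
  expect_equal(
    nrow(filter_sites(v, site_filter_spec(max_missing_frac = 0))), 16
  )
})

test_that("filter-flag and id rules are strict", {
  v <- make_mixed_vcf()
  v$filter[1] <- "LowQual"
  v$filter[2] <- "." # missing FILTER fails a PASS requirement
  out <- filter_sites(v, site_filter_spec(require_filter = "PASS"))
  expect_equal(nrow(out), 18)
  v$id <- sprintf("rs%d", seq_len(nrow(v)))
  expect_equal(
    filter_sites(v, site_filter_spec(include_ids = c("rs3", "rs9")))$id,
    c("rs3", "rs9")
  )
  expect_equal(nrow(filter_sites(v, site_filter_spec(exclude_ids = "rs1"))), 19)
  expect_error(site_filter_spec(include_ids = "a", exclude_ids = "a"), "disjoint")
  expect_error(site_filter_spec(min_maf = 0.6), "MAF")
})

test_that("MAF/MAC are computed on called alleles of retained samples", {
  rec <- tibble::tibble(
    chrom = "chr1", pos = 10L, id = ".", ref = "A", alt = "T",
    qual = NA_real_, filter = "PASS", info = ".",
    s1 = "0|1", s2 = "0|0", s3 = ".|." # called alleles: 0,1,0,0
  )
  v <- vcf_tbl(rec)
  expect_equal(nrow(filter_sites(v, site_filter_spec(min_maf = 0.25))), 1)
  expect_equal(nrow(filter_sites(v, site_filter_spec(min_maf = 0.26))), 0)
  expect_equal(nrow(filter_sites(v, site_filter_spec(min_mac = 2))), 0)
  # restricting samples changes the classification to invariant
  sub <- site_filter_spec(include_classes = "biallelic", samples = c("s2", "s3"))
  expect_equal(nrow(filter_sites(v, sub)), 0)
  expect_error(filter_sites(v, site_filter_spec(samples = "nope")), "not in VCF")
})

test_that("MAF is invariant under REF/ALT label swap at a biallelic site", {
  withr::with_seed(5, {
    for (case in 1:20) {
      H <- matrix(stats::rbinom(8 * 1, 1, stats::runif(1, 0.2, 0.8)), nrow = 8)
      v <- vcf_from_haps(H)
      sw <- v
      sw$ref <- "T"
      sw$alt <- "A"
      for (s in c("s1", "s2", "s3", "s4")) {
        sw[[s]] <- chartr("01", "10", sw[[s]])
      }
      st1 <- filter_sites(v, site_filter_spec(min_maf = 0))
      maf <- function(x, thr) nrow(filter_sites(x, site_filter_spec(min_maf = thr)))
      for (thr in c(0.1, 0.3, 0.5)) expect_equal(maf(v, thr), maf(sw, thr))
    }
  })
})

test_that("site filtering is idempotent and order-preserving (property)", {
  withr::with_seed(99, {
    for (case in 1:25) {
      sim <- simulate_dataset(sim_spec(
        seed = 1000 + case, chrom_lengths = c(chr1 = 20000L),
        pops = c(A = 3L, B = 2L), n_loci = 4, locus_length = 2000,
        locus_gap = 500, snps_per_locus = 6,
        frac_indel = 0.2, frac_multiallelic = 0.1, frac_missing = 0.2
      ))
      spec <- site_filter_spec(
        include_classes = sample(c("biallelic", "invariant", "multiallelic"),
          sample(1:2, 1)
        ),
        max_missing_count = sample(0:2, 1),
        min_maf = stats::runif(1, 0, 0.2),
        drop_indels = sample(c(TRUE, FALSE), 1)
      )
      once <- filter_sites(sim$vcf, spec)
      twice <- filter_sites(once, spec)
      expect_identical(as.data.frame(twice), as.data.frame(once))
      # subsequence of input: record keys in input order
      key <- function(x) paste(x$chrom, x$pos)
      expect_true(all(key(once) %in% key(sim$vcf)))
      expect_false(is.unsorted(match(key(once), key(sim$vcf))))
    }
  })
})

test_that("BED include/exclude filters use half-open coordinates", {
  v <- make_mixed_vcf() # positions 10..200
  bed <- tibble::tibble(chrom = "chr1", start = 10L, end = 40L) # covers 11..40
  out <- filter_sites(v, site_filter_spec(include_bed = bed))
  expect_equal(out$pos, c(20L, 30L, 40L))
  out2 <- filter_sites(v, site_filter_spec(exclude_bed = bed))
  expect_equal(nrow(out2), 17)
})

test_that("locus filtering counts qualifying variants and honours ignores", {
  sim <- simulate_dataset(sim_spec(
    seed = 31, chrom_lengths = c(chr1 = 30000L), pops = c(A = 3L, B = 3L),
    n_loci = 8, locus_length = 2000, locus_gap = 500, snps_per_locus = 5,
    frac_indel = 0.2
  ))
  # threshold at 4: a locus with 3 qualifying variants is removed
  spec <- locus_filter_spec(min_variants = 4, ignore_indels = TRUE)
  kept <- filter_loci(sim$vcf, sim$loci, spec)
  # recompute expected from the truth type labels
  type_by_pos <- stats::setNames(sim$truth$site_type, sort(sim$vcf$pos))
  expected <- vapply(seq_len(nrow(sim$loci)), function(i) {
    pos <- sim$vcf$pos[sim$vcf$pos > sim$loci$start[i] & sim$vcf$pos <= sim$loci$end[i]]
    sum(type_by_pos[as.character(pos)] != "indel") >= 4
  }, logical(1))
  expect_equal(kept$name, sim$loci$name[expected])

  # empty spec keeps everything
  expect_equal(nrow(filter_loci(sim$vcf, sim$loci, locus_filter_spec())), nrow(sim$loci))
  # min length
  expect_equal(
    nrow(filter_loci(sim$vcf, sim$loci, locus_filter_spec(min_length = 3000))), 0
  )
})

test_that("CpG-aware variant counting needs and uses the reference", {
  sim <- simulate_dataset(sim_spec(
    seed = 77, chrom_lengths = c(chr1 = 10000L), pops = c(A = 3L),
    n_loci = 1, locus_length = 2000, locus_gap = 500, snps_per_locus = 5,
    frac_cpg = 0.4 # 2 of 5 sites inside planted CpGs
  ))
  expect_equal(sim$truth$n_cpg, 2L)
  spec <- locus_filter_spec(min_variants = 4, ignore_cpg = TRUE)
  expect_error(filter_loci(sim$vcf, sim$loci, spec), "reference")
  # 5 - 2 = 3 qualifying < 4: locus removed
  expect_equal(nrow(filter_loci(sim$vcf, sim$loci, spec, ref = sim$ref)), 0)
  spec3 <- locus_filter_spec(min_variants = 3, ignore_cpg = TRUE)
  expect_equal(nrow(filter_loci(sim$vcf, sim$loci, spec3, ref = sim$ref)), 1)
  bad_loci <- tibble::tibble(chrom = "chr1", start = 0L, end = 99999L)
  expect_error(filter_loci(sim$vcf, bad_loci, spec3, ref = sim$ref), "beyond")
})

test_that("splitting partitions covered records across disjoint loci", {
  v <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = c(5L, 15L, 25L, 35L, 45L, 55L, 65L, 75L, 85L, 95L),
    ref = "A", alt = "T", s1 = "0|1"
  ))
  loci <- tibble::tibble(
    chrom = "chr1", start = c(0L, 40L, 70L), end = c(40L, 70L, 100L)
  )
  parts <- split_by_loci(v, loci)
  expect_length(parts, 3)
  expect_equal(vapply(parts, nrow, integer(1), USE.NAMES = FALSE), c(4L, 3L, 3L))
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(v))
  # no record in two outputs
  all_pos <- unlist(lapply(parts, function(p) p$pos))
  expect_false(any(duplicated(all_pos)))
  # empty locus -> empty table, header intact
  empty <- split_by_loci(v, tibble::tibble(chrom = "chr1", start = 96L, end = 100L))
  expect_equal(nrow(empty[[1]]), 0)
  expect_s3_class(empty[[1]], "vcf_tbl")
  expect_error(split_by_loci(v, v[0, c("chrom", "pos")] |>
    dplyr::transmute(chrom, start = pos, end = pos)), "empty locus")
  expect_warning(
    split_by_loci(v, tibble::tibble(
      chrom = "chr1", start = c(0L, 30L), end = c(40L, 60L)
    )),
    "overlap"
  )
})

test_that("concat, sort and merge obey their contracts", {
  a <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = c(30L, 10L, 20L, 40L, 50L), ref = "A", alt = "T",
    s1 = "0|1"
  ))
  b <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = c(15L, 35L, 5L), ref = "A", alt = "T", s1 = "1|1"
  ))
  cc <- concat_vcfs(list(a, b))
  expect_equal(nrow(cc), 8)
  expect_error(
    concat_vcfs(list(a, vcf_tbl(tibble::tibble(
      chrom = "chr1", pos = 1L, ref = "A", alt = "T", other = "0|0"
    )))),
    "identical sample"
  )
  s <- sort_vcf(cc)
  expect_equal(s$pos, sort(cc$pos))
  expect_identical(as.data.frame(sort_vcf(s)), as.data.frame(s)) # idempotent
  # chromosome order follows first appearance when no contig header exists
  mix <- vcf_tbl(tibble::tibble(
    chrom = c("chrB", "chrA", "chrB"), pos = c(2L, 1L, 1L), ref = "A", alt = "T"
  ))
  expect_equal(sort_vcf(mix)$chrom, c("chrB", "chrB", "chrA"))
})

test_that("merge unions sites and samples, filling missing genotypes", {
  # two 1-sample tables at 4 shared + 2 private sites
  a <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L), ref = "A", alt = "T",
    s1 = c("0|1", "0|0", "1|1", "0|1", "1|1")
  ))
  b <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 60L), ref = "A", alt = "T",
    s2 = c("0|0", "0|1", "1|1", "0|0", "0|1")
  ))
  m <- merge_vcfs(list(a, b))
  expect_equal(nrow(m), 6)
  expect_equal(vcf_samples(m), c("s1", "s2"))
  expect_equal(m$s2[m$pos == 50], "./.")
  expect_equal(m$s1[m$pos == 60], "./.")
  # brute-force union oracle on the site set
  expect_equal(m$pos, sort(union(a$pos, b$pos)))
  # conflicting REF errors
  b2 <- b
  b2$ref[1] <- "G"
  expect_error(merge_vcfs(list(a, b2)), "conflicting REF")
  # ALT union remaps allele indices
  b3 <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = 10L, ref = "A", alt = "G", s3 = "0|1"
  ))
  m3 <- merge_vcfs(list(a, b3))
  expect_equal(m3$alt[m3$pos == 10], "T,G")
  expect_equal(m3$s3[m3$pos == 10], "0|2")
})

test_that("VCF text round-trips records, samples and phase flags", {
  sim <- simulate_dataset(sim_spec(
    seed = 404, chrom_lengths = c(chr1 = 8000L, chr2 = 15000L),
    pops = c(A = 2L, B = 2L), n_loci = 6, locus_length = 1500,
    locus_gap = 400, snps_per_locus = 5,
    frac_indel = 0.1, frac_multiallelic = 0.1, frac_missing = 0.1
  ))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$vcf, path)
  back <- read_vcf(path)
  expect_equal(vcf_samples(back), vcf_samples(sim$vcf))
  for (col in c("chrom", "pos", "ref", "alt", "filter", vcf_samples(sim$vcf))) {
    expect_equal(back[[col]], sim$vcf[[col]], info = col)
  }
  expect_equal(list_chromosomes(back), c("chr1", "chr2"))
  expect_equal(list_samples(back), c("A_1", "A_2", "B_1", "B_2"))
  # gzip round trip
  pgz <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(sim$vcf, pgz)
  expect_equal(read_vcf(pgz)$pos, sim$vcf$pos)
})
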