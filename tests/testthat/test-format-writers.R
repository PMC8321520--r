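# Shared fixture: reconstructed loci + model from one simulated dataset.
make_loci_fixture <- function(seed = 171, n_loci = 3) {
  sim <- simulate_dataset(sim_spec(
    seed = seed, chrom_lengths = c(chr1 = 30000L), pops = c(A = 2L, B = 2L),
    n_loci = n_loci, locus_length = 1500, locus_gap = 500, snps_per_locus = 6
  ))
  model <- sim$models$model1
  loci <- lapply(seq_len(nrow(sim$loci)), function(i) {
    reconstruct_sequences(
      sim$ref, sim$vcf,
      list(chrom = "chr1", start = sim$loci$start[i], end = sim$loci$end[i]),
      model,
      name = sim$loci$name[i]
    )
  })
  list(sim = sim, model = model, loci = loci)
}

test_that("IM files carry the declared structure and round-trip", {
  fx <- make_loci_fixture()
  p <- withr::local_tempfile(fileext = ".ima")
  write_ima(fx$loci, fx$model, p)
  back <- read_ima_file(p)
  expect_equal(back$n_pops, 2L)
  expect_equal(back$pops, c("A", "B"))
  expect_equal(back$tree, fx$model$tree)
  expect_equal(back$n_loci, 3L)
  for (li in seq_along(back$loci)) {
    bl <- back$loci[[li]]
    expect_equal(bl$counts, c(4L, 4L)) # 2+2 diploids phased
    expect_equal(bl$length, 1500L)
    expect_equal(bl$mut, "I")
    expect_equal(bl$inh, 1.0)
    expect_length(bl$seqs, sum(bl$counts))
    src <- fx$loci[[li]]
    expect_equal(bl$seqs, src$seq)
    expect_equal(bl$seq_names, substr(gsub("[^A-Za-z0-9]", "_", src$hap_id), 1, 10))
  }
  # errors: no tree, empty loci, unequal lengths
  notree <- pop_model("nt", fx$model$pops)
  expect_error(write_ima(fx$loci, notree, p), "tree")
  expect_error(write_ima(list(), fx$model, p), "empty")
  broken <- fx$loci
  broken[[1]]$seq[1] <- "ACGT"
  expect_error(write_ima(broken, fx$model, p), "unequal")
})

test_that("G-PhoCS files declare counts that match their lines", {
  fx <- make_loci_fixture(seed = 181, n_loci = 2)
  p <- withr::local_tempfile(fileext = ".gphocs")
  write_gphocs(fx$loci, p)
  back <- read_gphocs_file(p)
  expect_equal(back$n_loci, 2L)
  for (li in 1:2) {
    bl <- back$loci[[li]]
    expect_equal(bl$n_seq, 8L)
    expect_equal(bl$length, 1500L)
    expect_equal(bl$n_seq, length(bl$seqs))
    expect_equal(bl$seqs, fx$loci[[li]]$seq)
  }
  # awkward locus names sanitize deterministically
  weird <- fx$loci[1]
  attr(weird[[1]], "name") <- "chr1:0-1,500 (odd)"
  write_gphocs(weird, p)
  expect_equal(read_gphocs_file(p)$loci[[1]]$name, "chr1_0-1_500__odd_")
})

test_that("treemix counts match a naive genotype tally", {
  withr::with_seed(190, {
    sim <- simulate_dataset(sim_spec(
      seed = 191, chrom_lengths = c(chr1 = 20000L), pops = c(A = 3L, B = 2L),
      n_loci = 5, locus_length = 1500, locus_gap = 500, snps_per_locus = 6,
      frac_missing = 0.15
    ))
    model <- sim$models$model1
    p <- withr::local_tempfile(fileext = ".treemix")
    write_treemix(sim$vcf, model, p)
    back <- read_treemix_file(p)
    expect_equal(back$pops, c("A", "B"))
    expect_equal(nrow(back$ref), nrow(sim$vcf))
    # naive per-pop tallies over called alleles
    for (i in seq_len(nrow(sim$vcf))) {
      for (j in 1:2) {
        inds <- model$pops[[j]]
        als <- unlist(lapply(inds, function(s) strsplit(sim$vcf[[s]][i], "[/|]")[[1]]))
        als <- als[als != "."]
        expect_equal(back$ref[i, j], sum(als == "0"))
        expect_equal(back$alt[i, j], sum(als == "1"))
        # counts sum to the called alleles of that population
        expect_equal(back$ref[i, j] + back$alt[i, j], length(als))
      }
    }
  })
})

test_that("treemix skips (or rejects) sites with an uncallable population", {
  v <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T",
    a1 = c("0|1", "0|1"), b1 = c("./.", "1|1")
  ))
  m <- pop_model("m", list(A = "a1", B = "b1"))
  p <- withr::local_tempfile(fileext = ".tm")
  write_treemix(v, m, p)
  expect_equal(length(readLines(p)), 2) # header + one surviving site
  expect_error(write_treemix(v, m, p, strict = TRUE), "no called alleles")
  # drop_invariant removes monomorphic lines
  v2 <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T",
    a1 = c("0|0", "0|1"), b1 = c("0|0", "1|1")
  ))
  write_treemix(v2, m, p, drop_invariant = TRUE)
  expect_equal(length(readLines(p)), 2)
})

test_that("dadi SNP tables carry contexts, counts and coordinates", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAC"))
  v <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = c(1L, 5L, 10L), ref = c("A", "A", "C"),
    alt = c("G", "T", "A"),
    a1 = c("0|1", "0|0", "1|1"), b1 = c("0|0", "0|1", "0|1")
  ))
  m <- pop_model("m", list(A = "a1", B = "b1"))
  p <- withr::local_tempfile(fileext = ".dadi")
  write_dadi_snp(v, m, p, ref = ref)
  tab <- utils::read.table(p, header = TRUE, sep = "\t", comment.char = "")
  expect_equal(names(tab)[1:3], c("ingroup", "outgroup", "Allele1"))
  expect_equal(tab$ingroup, c("-AC", "TAC", "AC-")) # edge padding both ends
  expect_equal(tab$outgroup, rep("---", 3))
  expect_equal(tab$A, c(1L, 2L, 0L)) # Allele1 (REF) counts pop A
  expect_equal(tab$A.1, c(1L, 0L, 2L)) # Allele2 (ALT) counts pop A
  expect_equal(tab$Position, c(1L, 5L, 10L))
  # without a reference, contexts are placeholders
  write_dadi_snp(v, m, p)
  tab2 <- utils::read.table(p, header = TRUE, sep = "\t", comment.char = "")
  expect_true(all(tab2$ingroup == "-X-"))
})

test_that("EIGENSTRAT triples parse back to the genotype matrix", {
  withr::with_seed(200, {
    sim <- simulate_dataset(sim_spec(
      seed = 201, chrom_lengths = c(chr1 = 15000L), pops = c(A = 2L, B = 2L),
      n_loci = 4, locus_length = 1200, locus_gap = 400, snps_per_locus = 5,
      frac_missing = 0.2
    ))
    model <- sim$models$model1
    prefix <- withr::local_tempfile()
    write_eigenstrat(sim$vcf, model, prefix)
    es <- read_eigenstrat_files(prefix)
    inds <- model_individuals(model)
    want <- oracle_ref_dosage(sim$vcf, inds)
    got <- es$geno
    got[got == 9L] <- NA_integer_
    expect_equal(got, want, ignore_attr = TRUE)
    expect_equal(es$ind$id, inds)
    expect_equal(es$ind$pop, c("A", "A", "B", "B"))
    expect_equal(es$snp$pos, sim$vcf$pos)
    expect_equal(es$snp$a1, sim$vcf$ref) # column 5 = the counted allele
  })
})

test_that("PED-12/MAP files parse back to the genotype matrix", {
  withr::with_seed(210, {
    sim <- simulate_dataset(sim_spec(
      seed = 211, chrom_lengths = c(chr1 = 15000L), pops = c(A = 2L, B = 2L),
      n_loci = 4, locus_length = 1200, locus_gap = 400, snps_per_locus = 5,
      frac_missing = 0.2
    ))
    model <- sim$models$model1
    prefix <- withr::local_tempfile()
    write_ped(sim$vcf, model, prefix)
    pd <- read_ped_files(prefix)
    inds <- model_individuals(model)
    expect_equal(pd$iid, inds)
    expect_equal(pd$fid, c("A", "A", "B", "B"))
    expect_equal(pd$map$pos, sim$vcf$pos)
    # REF=1/ALT=2 coding: dosage of REF = count of 1s; missing = "0 0" -> NA
    want <- oracle_ref_dosage(sim$vcf, inds)
    for (j in seq_along(inds)) {
      g <- pd$geno[[j]]
      dose <- rowSums(g == 1L)
      dose[g[, 1] == 0L] <- NA_integer_
      expect_equal(dose, want[, j], ignore_attr = TRUE)
    }
  })
})

test_that("missing genotypes use the documented missing codes", {
  v <- vcf_tbl(tibble::tibble(
    chrom = "chr1", pos = 10L, ref = "A", alt = "T",
    a1 = "0/1", b1 = "./."
  ))
  m <- pop_model("m", list(A = "a1", B = "b1"))
  prefix <- withr::local_tempfile()
  write_eigenstrat(v, m, prefix)
  expect_equal(readLines(paste0(prefix, ".geno")), "19")
  write_ped(v, m, prefix)
  ped <- readLines(paste0(prefix, ".ped"))
  expect_match(ped[1], "(1 2|2 1)$")
  expect_match(ped[2], "0 0$")
})
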