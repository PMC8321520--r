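# Export writers: IMa3, G-PhoCS, treemix, dadi, EIGENSTRAT, PED/MAP ----------

# IMa3's sequence-name field is fixed-width: 10 characters, left-justified,
# space-padded, non-alphanumerics mapped to "_".
im_name <- function(x, width = 10) {
  x <- gsub("[^A-Za-z0-9]", "_", x)
  formatC(substr(x, 1, width), width = width, flag = "-")
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

check_alignment <- function(aln) {
  lens <- nchar(aln$seq)
  if (length(unique(lens)) != 1) {
    rlang::abort("unequal sequence lengths within a locus")
  }
  invisible(lens[1])
}

# Order alignment rows population-by-population in model order.
align_in_model_order <- function(aln, model) {
  ord <- order(match(aln$pop, names(model$pops)), match(aln$individual, model_individuals(model)), aln$hap)
  aln[ord, , drop = FALSE]
}

#' Write an IMa3 input file
#'
#' Layout: a title line; the number of populations; the population names in
#' model order; the population-tree line; the number of loci; then, per
#' locus, a header `name n_1 ... n_k length mutmodel inheritance` followed by
#' one line per sequence (10-character left-justified name + sequence).
#'
#' @param loci List of `locus_alignment` objects (all under the same model).
#' @param model A `pop_model`; must carry a population tree (IMa3 requires
#'   one) and at least two populations.
#' @param path Output path.
#' @param mutation_model Single-letter mutation-model code per locus;
#'   default `"I"` (infinite sites — consistent with four-gamete
#'   pre-filtering).
#' @param inheritance Inheritance scalar per locus; default `1.0`
#'   (autosomal).
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_ima <- function(loci, model, path, mutation_model = "I",
                      inheritance = 1.0, title = "popgenpipe IM export") {
  if (length(loci) == 0) rlang::abort("empty locus list")
  if (is.null(model$tree)) rlang::abort("IMa3 export requires a model with a population tree")
  if (length(model$pops) < 2) rlang::abort("IMa3 export requires >= 2 populations")
  lines <- c(
    title,
    as.character(length(model$pops)),
    paste(names(model$pops), collapse = " "),
    model$tree,
    as.character(length(loci))
  )
  for (li in seq_along(loci)) {
    aln <- align_in_model_order(loci[[li]], model)
    len <- check_alignment(aln)
    counts <- vapply(names(model$pops), function(p) sum(aln$pop == p), integer(1))
    lname <- substr(sanitize_name(attr(aln, "name") %||% sprintf("locus%d", li)), 1, 10)
    lines <- c(
      lines,
      paste(c(lname, counts, len, mutation_model, format(inheritance)), collapse = " "),
      paste0(im_name(aln$hap_id), aln$seq)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a G-PhoCS sequence file
#'
#' First line: locus count. Per locus: `name n_sequences length`, then one
#' line `seqname sequence` per haplotype.
#'
#' @param loci List of `locus_alignment` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gphocs <- function(loci, path) {
  if (length(loci) == 0) rlang::abort("empty locus list")
  lines <- as.character(length(loci))
  for (li in seq_along(loci)) {
    aln <- loci[[li]]
    len <- check_alignment(aln)
    lname <- sanitize_name(attr(aln, "name") %||% sprintf("locus%d", li))
    lines <- c(
      lines,
      paste(lname, nrow(aln), len),
      paste(sanitize_name(aln$hap_id), aln$seq)
    )
  }
  writeLines(lines, path)
  invisible(path)
}

# Per-population REF/ALT allele counts at the biallelic SNPs of a table.
# Returns list(counts = tibble(chrom, pos, ref, alt, <pop>_ref, <pop>_alt),
# skipped = named counter). Sites where some population has zero called
# alleles are skipped (or raise when strict).
pop_allele_counts <- function(vcf, model, strict = FALSE) {
  missing <- setdiff(model_individuals(model), vcf_samples(vcf))
  if (length(missing) > 0) {
    rlang::abort(paste0("model individuals absent: ", paste(missing, collapse = ", ")))
  }
  usable <- !is_indel_record(vcf$ref, vcf$alt) & n_alt_alleles(vcf$alt) == 1
  pops <- model$pops
  rows <- list()
  skipped <- c(non_biallelic = sum(!usable), uncallable = 0L)
  for (i in which(usable)) {
    refc <- altc <- integer(length(pops))
    for (j in seq_along(pops)) {
      al <- record_alleles(vcf[i, ], pops[[j]])
      called <- al[!is.na(al)]
      refc[j] <- sum(called == 0)
      altc[j] <- sum(called > 0)
    }
    if (any(refc + altc == 0)) {
      if (strict) rlang::abort(sprintf("no called alleles for a population at %s:%d", vcf$chrom[i], vcf$pos[i]))
      skipped[["uncallable"]] <- skipped[["uncallable"]] + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      chrom = vcf$chrom[i], pos = vcf$pos[i], id = vcf$id[i],
      ref = vcf$ref[i], alt = vcf$alt[i],
      ref_count = list(refc), alt_count = list(altc)
    )
  }
  counts <- dplyr::bind_rows(rows)
  list(counts = counts, skipped = skipped, pops = names(pops))
}

#' Write a treemix input file
#'
#' Space-separated header of population names, then one line per biallelic
#' SNP with `refCount,altCount` per population, counted over called alleles
#' only.
#'
#' @param vcf A `vcf_tbl`.
#' @param model A `pop_model`.
#' @param path Output path.
#' @param drop_invariant Omit sites monomorphic across all populations?
#' @param strict Error (instead of skip) when a population has no called
#'   allele at a site.
#' @return `path`, invisibly; skip counts attached as attribute `"skipped"`.
#' @export
write_treemix <- function(vcf, model, path, drop_invariant = FALSE, strict = FALSE) {
  pc <- pop_allele_counts(vcf, model, strict = strict)
  counts <- pc$counts
  if (drop_invariant && nrow(counts) > 0) {
    mono <- vapply(seq_len(nrow(counts)), function(i) {
      sum(unlist(counts$ref_count[i])) == 0 || sum(unlist(counts$alt_count[i])) == 0
    }, logical(1))
    counts <- counts[!mono, , drop = FALSE]
  }
  body <- vapply(seq_len(nrow(counts)), function(i) {
    paste(sprintf("%d,%d", unlist(counts$ref_count[i]), unlist(counts$alt_count[i])),
      collapse = " "
    )
  }, character(1))
  writeLines(c(paste(pc$pops, collapse = " "), body), path)
  invisible(structure(path, skipped = pc$skipped))
}

# Reference trinucleotide context around a 1-based position; "-" pads edges.
ref_context <- function(ref, chrom, pos) {
  if (is.null(ref) || !chrom %in% names(ref)) {
    return("-X-")
  }
  n <- length(ref[[chrom]])
  left <- if (pos > 1) as.character(Biostrings::subseq(ref[[chrom]], pos - 1, pos - 1)) else "-"
  mid <- as.character(Biostrings::subseq(ref[[chrom]], pos, pos))
  right <- if (pos < n) as.character(Biostrings::subseq(ref[[chrom]], pos + 1, pos + 1)) else "-"
  paste0(left, mid, right)
}

#' Write a dadi SNP data table
#'
#' Tab-separated with columns: ingroup context, outgroup context, `Allele1`
#' plus per-population counts, `Allele2` plus per-population counts, `Gene`
#' (chromosome) and `Position`. Contexts are reference trinucleotides with
#' `-` padding at chromosome edges, `-X-` placeholders without a reference,
#' and `---` for an absent outgroup.
#'
#' @param vcf A `vcf_tbl`.
#' @param model A `pop_model`.
#' @param path Output path.
#' @param ref Optional reference FASTA (path or `DNAStringSet`) for ingroup
#'   contexts.
#' @param outgroup Optional outgroup genome (`DNAStringSet` keyed like the
#'   reference) for outgroup contexts.
#' @param strict See [write_treemix()].
#' @return `path`, invisibly.
#' @export
write_dadi_snp <- function(vcf, model, path, ref = NULL, outgroup = NULL,
                           strict = FALSE) {
  if (!is.null(ref)) ref <- load_reference(ref)
  if (!is.null(outgroup)) outgroup <- load_reference(outgroup)
  pc <- pop_allele_counts(vcf, model, strict = strict)
  counts <- pc$counts
  pops <- pc$pops
  header <- paste(
    c("ingroup", "outgroup", "Allele1", pops, "Allele2", pops, "Gene", "Position"),
    collapse = "\t"
  )
  body <- vapply(seq_len(nrow(counts)), function(i) {
    ing <- ref_context(ref, counts$chrom[i], counts$pos[i])
    outg <- if (is.null(outgroup)) "---" else ref_context(outgroup, counts$chrom[i], counts$pos[i])
    paste(c(
      ing, outg,
      counts$ref[i], unlist(counts$ref_count[i]),
      counts$alt[i], unlist(counts$alt_count[i]),
      counts$chrom[i], counts$pos[i]
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# Diploid REF-allele dosage matrix (records x individuals; NA = missing).
ref_dosage <- function(vcf, inds) {
  usable <- which(!is_indel_record(vcf$ref, vcf$alt) & n_alt_alleles(vcf$alt) == 1)
  dose <- matrix(NA_integer_, nrow = length(usable), ncol = length(inds))
  for (k in seq_along(usable)) {
    al <- record_alleles(vcf[usable[k], ], inds)
    if (ncol(al) < 2) rlang::abort("diploid genotypes required")
    miss <- rowSums(is.na(al)) > 0
    d <- rowSums(al == 0)
    d[miss] <- NA_integer_
    dose[k, ] <- d
  }
  list(rows = usable, dose = dose)
}

#' Write EIGENSTRAT geno/snp/ind files
#'
#' `.geno`: one line per biallelic SNP of per-individual counts (0/1/2) of
#' the `.snp` column-5 allele (REF here), `9` for missing. `.snp`: id,
#' chromosome, genetic position (0.0), physical position, REF, ALT. `.ind`:
#' individual, sex (`U`), population from the model. Non-SNP and
#' multiallelic records are dropped.
#'
#' @param vcf A `vcf_tbl` with diploid genotypes.
#' @param model A `pop_model`.
#' @param prefix Output path prefix; writes `<prefix>.geno/.snp/.ind`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_eigenstrat <- function(vcf, model, prefix) {
  inds <- model_individuals(model)
  missing <- setdiff(inds, vcf_samples(vcf))
  if (length(missing) > 0) rlang::abort("model individuals absent from VCF")
  rd <- ref_dosage(vcf, inds)
  sub <- vcf[rd$rows, , drop = FALSE]
  ids <- ifelse(sub$id == ".", sprintf("%s_%d", sub$chrom, sub$pos), sub$id)
  geno <- apply(rd$dose, 1, function(d) {
    paste(ifelse(is.na(d), "9", as.character(d)), collapse = "")
  })
  snp <- sprintf("%s\t%s\t0.0\t%d\t%s\t%s", ids, sub$chrom, sub$pos, sub$ref, sub$alt)
  pop_of <- model_pop_of(model)
  ind <- sprintf("%s\tU\t%s", inds, pop_of[inds])
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  writeLines(geno, paths[1])
  writeLines(snp, paths[2])
  writeLines(ind, paths[3])
  invisible(stats::setNames(paths, c("geno", "snp", "ind")))
}

#' Write PED-12 and MAP files
#'
#' `.ped`: per individual — family (population), individual ID, father (0),
#' mother (0), sex (0), phenotype (-9), then two allele codes per SNP with
#' REF=1, ALT=2, missing=0 0. `.map`: chromosome, SNP id, genetic position
#' 0, physical position.
#'
#' @inheritParams write_eigenstrat
#' @return Named character vector of the two paths, invisibly.
#' @export
write_ped <- function(vcf, model, prefix) {
  inds <- model_individuals(model)
  missing <- setdiff(inds, vcf_samples(vcf))
  if (length(missing) > 0) rlang::abort("model individuals absent from VCF")
  usable <- which(!is_indel_record(vcf$ref, vcf$alt) & n_alt_alleles(vcf$alt) == 1)
  sub <- vcf[usable, , drop = FALSE]
  ids <- ifelse(sub$id == ".", sprintf("%s_%d", sub$chrom, sub$pos), sub$id)
  pop_of <- model_pop_of(model)
  # allele codes per record x individual: "1 2" style pairs
  codes <- matrix("0 0", nrow = nrow(sub), ncol = length(inds))
  for (i in seq_len(nrow(sub))) {
    al <- record_alleles(sub[i, ], inds)
    if (ncol(al) < 2) rlang::abort("diploid genotypes required")
    for (j in seq_along(inds)) {
      if (anyNA(al[j, ])) next
      codes[i, j] <- paste(ifelse(al[j, 1:2] == 0, "1", "2"), collapse = " ")
    }
  }
  ped <- vapply(seq_along(inds), function(j) {
    paste(c(pop_of[inds[j]], inds[j], "0", "0", "0", "-9", codes[, j]), collapse = " ")
  }, character(1))
  map <- sprintf("%s\t%s\t0\t%d", sub$chrom, ids, sub$pos)
  paths <- paste0(prefix, c(".ped", ".map"))
  writeLines(ped, paths[1])
  writeLines(map, paths[2])
  invisible(stats::setNames(paths, c("ped", "map")))
}
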