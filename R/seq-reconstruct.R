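# Per-haplotype sequence reconstruction --------------------------------------
#
# Rebuilds the two haplotype sequences of each model individual over a
# region: the reference substring with each phased SNP allele substituted at
# its position. This is the substrate for the IMa3 and G-PhoCS exporters,
# which need equal-length alignments — hence indels are rejected by default.

#' Reconstruct haplotype sequences for a region
#'
#' @param ref Reference FASTA: path or `Biostrings::DNAStringSet` (names
#'   truncated at the first whitespace).
#' @param vcf A phased `vcf_tbl` containing the model individuals.
#' @param region One interval: list or one-row tibble with `chrom`, `start`,
#'   `end` (0-based half-open, BED-style).
#' @param model A `pop_model`; haplotypes are emitted population by
#'   population in model order, individuals in population order.
#' @param on_indel `"error"` (default: an indel overlapping the region
#'   aborts, keeping alignment lengths equal) or `"skip"` (drop the record
#'   with a warning).
#' @param name Locus name stored on the alignment (default
#'   `"chrom:start-end"`).
#' @return A `locus_alignment` tibble with columns `individual`, `hap`
#'   (1/2), `pop`, `hap_id` (`"<individual>_<hap>"`), `seq`; attributes
#'   `chrom`, `start`, `end`, `length`, `name`, `n_hap` (per-population
#'   haploid counts). Missing alleles are written as `N`.
#' @export
reconstruct_sequences <- function(ref, vcf, region, model,
                                  on_indel = c("error", "skip"),
                                  name = NULL) {
  on_indel <- match.arg(on_indel)
  ref <- load_reference(ref)
  chrom <- region$chrom
  start <- as.integer(region$start)
  end <- as.integer(region$end)
  if (!chrom %in% names(ref)) rlang::abort(paste0("chrom not in reference: ", chrom))
  if (start < 0 || end > length(ref[[chrom]])) {
    rlang::abort("region outside reference")
  }
  inds <- model_individuals(model)
  missing <- setdiff(inds, vcf_samples(vcf))
  if (length(missing) > 0) {
    rlang::abort(paste0("individual(s) absent from VCF: ", paste(missing, collapse = ", ")))
  }
  if (is.null(name)) name <- sprintf("%s:%d-%d", chrom, start, end)

  refseq <- strsplit(as.character(Biostrings::subseq(ref[[chrom]], start + 1L, end)), "")[[1]]
  sel <- vcf$chrom == chrom & vcf$pos > start & vcf$pos <= end
  sub <- vcf[sel, , drop = FALSE]
  indel <- is_indel_record(sub$ref, sub$alt)
  if (any(indel)) {
    if (on_indel == "error") {
      rlang::abort("indel record inside region; use on_indel = \"skip\" to drop it")
    }
    rlang::warn(sprintf("skipping %d indel record(s) in region %s", sum(indel), name))
    sub <- sub[!indel, , drop = FALSE]
  }

  pop_of <- model_pop_of(model)
  haps <- lapply(inds, function(ind) list(refseq, refseq))
  names(haps) <- inds
  for (i in seq_len(nrow(sub))) {
    alleles <- record_allele_set(sub$ref[i], sub$alt[i])
    offset <- sub$pos[i] - start # 1-based index into refseq
    g <- parse_gt(unlist(sub[i, inds], use.names = FALSE))
    al <- g$alleles
    if (ncol(al) == 1) al <- cbind(al, al[, 1])
    het <- !is.na(al[, 1]) & !is.na(al[, 2]) & al[, 1] != al[, 2]
    if (any(het & !g$phased)) {
      rlang::abort(sprintf(
        "unphased heterozygote at %s:%d; phase before reconstruction",
        chrom, sub$pos[i]
      ))
    }
    for (j in seq_along(inds)) {
      for (k in 1:2) {
        a <- al[j, k]
        base <- if (is.na(a)) "N" else alleles[a + 1L]
        haps[[inds[j]]][[k]][offset] <- base
      }
    }
  }

  out <- tibble::tibble(
    individual = rep(inds, each = 2),
    hap = rep(1:2, length(inds)),
    pop = pop_of[rep(inds, each = 2)],
    hap_id = paste(rep(inds, each = 2), rep(1:2, length(inds)), sep = "_"),
    seq = unlist(lapply(inds, function(ind) {
      vapply(haps[[ind]], paste, character(1), collapse = "")
    }))
  )
  structure(out,
    chrom = chrom, start = start, end = end, length = end - start,
    name = name, n_hap = model_sizes(model, ploidy = 2),
    class = c("locus_alignment", class(tibble::tibble()))
  )
}

#' Write a locus alignment as FASTA
#'
#' @param aln A `locus_alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(aln$seq, aln$hap_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
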