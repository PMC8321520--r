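# Four-gamete test and recombination-free block extraction -------------------
#
# Two biallelic sites are incompatible with a single non-recombining
# genealogy under infinite sites when all four allele combinations (gametes
# 00, 01, 10, 11) occur among the haplotypes called at both sites. This
# module builds a haplotype matrix from a phased variant table, finds every
# maximal run of sites that is pairwise compatible, and extracts the chosen
# block(s) as variant tables.

#' Build a haplotype matrix from a phased variant table
#'
#' Retains biallelic SNP records (one ALT allele, single-base alleles);
#' multiallelic sites are dropped by default. Heterozygous genotypes must be
#' phased — the test is defined on haplotypes. Missing alleles become `NA`
#' entries (or raise with `on_missing = "error"`).
#'
#' @param vcf A `vcf_tbl` for one region on one chromosome.
#' @param on_missing `"ignore"` (default) or `"error"`.
#' @param on_multiallelic `"drop"` (default) or `"error"`.
#' @return A `haplotype_matrix`: list with `alleles` (haplotypes x sites
#'   0/1/NA integer matrix, rownames `"<sample>_<k>"`), `positions` (1-based
#'   bp), `chrom`.
#' @export
haplotype_matrix <- function(vcf, on_missing = c("ignore", "error"),
                             on_multiallelic = c("drop", "error")) {
  on_missing <- match.arg(on_missing)
  on_multiallelic <- match.arg(on_multiallelic)
  stopifnot(length(unique(vcf$chrom)) <= 1)
  samples <- vcf_samples(vcf)
  n_alt <- n_alt_alleles(vcf$alt)
  snp <- !is_indel_record(vcf$ref, vcf$alt)
  multi <- n_alt >= 2
  if (on_multiallelic == "error" && any(multi)) {
    rlang::abort("multiallelic site in four-gamete input")
  }
  keep <- snp & !multi & n_alt == 1
  sub <- vcf[keep, , drop = FALSE]
  cols <- vector("list", nrow(sub))
  ploidy <- 2L
  for (i in seq_len(nrow(sub))) {
    g <- parse_gt(unlist(sub[i, samples], use.names = FALSE))
    al <- g$alleles
    if (ncol(al) == 1) al <- cbind(al, NA_integer_)
    het <- !is.na(al[, 1]) & !is.na(al[, 2]) & al[, 1] != al[, 2]
    if (any(het & !g$phased)) {
      rlang::abort(sprintf(
        "unphased heterozygous genotype at %s:%d; phase the data first",
        sub$chrom[i], sub$pos[i]
      ))
    }
    if (on_missing == "error" && anyNA(al)) {
      rlang::abort(sprintf("missing allele at %s:%d", sub$chrom[i], sub$pos[i]))
    }
    cols[[i]] <- as.integer(t(al[, 1:ploidy]))
  }
  H <- if (length(cols) > 0) do.call(cbind, cols) else matrix(integer(0), nrow = 2 * length(samples), ncol = 0)
  rownames(H) <- paste(rep(samples, each = ploidy), rep(1:ploidy, length(samples)), sep = "_")
  structure(
    list(
      alleles = H, positions = sub$pos,
      chrom = if (nrow(sub) > 0) sub$chrom[1] else NA_character_
    ),
    class = "haplotype_matrix"
  )
}

#' Four-gamete compatibility of two sites
#'
#' @param col_i,col_j Allele columns in `{0, 1, NA}` of equal length.
#'   Haplotypes with a missing allele at either site contribute no gamete.
#' @return `FALSE` iff all four gametes 00, 01, 10, 11 are observed.
#' @export
pair_compatible <- function(col_i, col_j) {
  stopifnot(length(col_i) == length(col_j))
  if (any(stats::na.omit(c(col_i, col_j)) > 1)) {
    rlang::abort("four-gamete test requires biallelic (0/1) columns")
  }
  both <- !is.na(col_i) & !is.na(col_j)
  gametes <- unique(col_i[both] * 2L + col_j[both])
  length(gametes) < 4L
}

# Site-by-site incompatibility matrix via four boolean cross-products.
incompatibility_matrix <- function(H) {
  M0 <- H == 0L
  M1 <- H == 1L
  M0[is.na(M0)] <- FALSE
  M1[is.na(M1)] <- FALSE
  g00 <- crossprod(M0, M0) > 0
  g01 <- crossprod(M0, M1) > 0
  g10 <- crossprod(M1, M0) > 0
  g11 <- crossprod(M1, M1) > 0
  g00 & g01 & g10 & g11
}

#' Maximal four-gamete-compatible intervals
#'
#' Finds every maximal contiguous run of sites within which all site pairs
#' pass the four-gamete test. The union of intervals covers every site (a
#' single site is trivially compatible); intervals are returned in genomic
#' order and may overlap by their boundary sites.
#'
#' @param h A `haplotype_matrix`.
#' @return Tibble with `start_index`, `end_index` (1-based site indices,
#'   inclusive), `start_bp`, `end_bp`, `n_sites`.
#' @export
find_compatible_intervals <- function(h) {
  H <- h$alleles
  m <- ncol(H)
  if (m == 0) {
    return(tibble::tibble(
      start_index = integer(), end_index = integer(),
      start_bp = integer(), end_bp = integer(), n_sites = integer()
    ))
  }
  inc <- incompatibility_matrix(H)
  # l[r]: leftmost start such that [l, r] is all-pairs compatible; it is
  # non-decreasing in r, so a left-pointer sweep suffices.
  l <- integer(m)
  cur <- 1L
  for (r in seq_len(m)) {
    if (r > 1) {
      bad <- which(inc[seq_len(r - 1), r])
      if (length(bad) > 0) cur <- max(cur, max(bad) + 1L)
    }
    l[r] <- cur
  }
  # [l[r], r] is maximal iff it cannot extend right: r == m or l[r+1] > l[r]
  ends <- which(c(l[-1] > l[-m], TRUE))
  tibble::tibble(
    start_index = l[ends], end_index = ends,
    start_bp = h$positions[l[ends]], end_bp = h$positions[ends],
    n_sites = ends - l[ends] + 1L
  )
}

#' Extract recombination-free block(s) from a variant table
#'
#' Subsets the input to the records of the chosen compatible interval(s).
#' With `mode = "all"` one table per interval meeting `min_sites` is
#' returned; with `mode = "single"` the selection rule picks one:
#' `"longest"` (most sites, ties leftmost — the default), `"leftmost"`, or
#' `"random"` (requires `seed`).
#'
#' @param vcf The phased `vcf_tbl` the intervals were derived from.
#' @param intervals Output of [find_compatible_intervals()]; computed from
#'   `vcf` when `NULL`.
#' @param mode `"single"` or `"all"`.
#' @param selection Single-block selection rule.
#' @param min_sites Minimum sites a block must contain.
#' @param seed Seed for `selection = "random"`.
#' @return A `vcf_tbl` (`mode = "single"`) or list of them (`mode = "all"`).
#'   When no interval meets `min_sites` the locus is rejected with a
#'   classed error (`"popgenpipe_locus_rejected"`).
#' @export
extract_block <- function(vcf, intervals = NULL,
                          mode = c("single", "all"),
                          selection = c("longest", "leftmost", "random"),
                          min_sites = 1, seed = NULL) {
  mode <- match.arg(mode)
  selection <- match.arg(selection)
  if (is.null(intervals)) {
    intervals <- find_compatible_intervals(haplotype_matrix(vcf))
  }
  ok <- intervals[intervals$n_sites >= min_sites, , drop = FALSE]
  if (nrow(ok) == 0) {
    rlang::abort(
      sprintf("no compatible interval with >= %d sites; locus rejected", min_sites),
      class = "popgenpipe_locus_rejected"
    )
  }
  take <- function(iv) {
    sel <- vcf$pos >= iv$start_bp & vcf$pos <= iv$end_bp
    as_vcf_tbl(vcf[sel, , drop = FALSE], header = attr(vcf, "header"))
  }
  if (mode == "all") {
    return(lapply(seq_len(nrow(ok)), function(i) take(ok[i, ])))
  }
  pick <- switch(selection,
    longest = which.max(ok$n_sites), # which.max is leftmost-on-ties
    leftmost = 1L,
    random = {
      if (is.null(seed)) rlang::abort("selection = \"random\" requires a seed")
      withr::with_seed(seed, sample.int(nrow(ok), 1L))
    }
  )
  take(ok[pick, ])
}
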