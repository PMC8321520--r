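# Site- and locus-level VCF filtering, splitting, and table utilities -------

#' Site filter specification
#'
#' Bundles the site-level inclusion/exclusion rules applied by
#' [filter_sites()]. All filters default to permissive; any combination may
#' be active simultaneously. Allele classes are judged on the *called*
#' genotypes of the retained samples: "invariant" means at most one distinct
#' called allele, "biallelic" exactly two, "multiallelic" three or more.
#'
#' @param include_classes,exclude_classes Character subsets of
#'   `c("biallelic", "multiallelic", "invariant")`.
#' @param include_bed,exclude_bed Interval tibbles (0-based half-open); a VCF
#'   record at `pos` p falls in `(s, e]` iff `s < p <= e`.
#' @param max_missing_count,max_missing_frac Cap on genotypes with any
#'   missing allele, as a count and as a fraction of retained samples.
#' @param min_maf,max_maf Minor-allele-frequency bounds in `[0, 0.5]`,
#'   computed over called alleles of the retained samples only; at a
#'   multiallelic site the MAF is the frequency of the rarest allele.
#' @param min_mac,max_mac Minor-allele-count bounds.
#' @param drop_indels Remove records whose REF or any ALT is not a single
#'   A/C/G/T base.
#' @param include_ids,exclude_ids SNP ID whitelists/blacklists (disjoint).
#' @param require_filter Exact FILTER value to require (e.g. `"PASS"`);
#'   records with a missing FILTER column fail the requirement.
#' @param samples Sample subset: character vector or a `pop_model`.
#' @return A `site_filter_spec` object.
#' @export
site_filter_spec <- function(include_classes = NULL, exclude_classes = NULL,
                             include_bed = NULL, exclude_bed = NULL,
                             max_missing_count = Inf, max_missing_frac = 1,
                             min_maf = 0, max_maf = 0.5,
                             min_mac = 0, max_mac = Inf,
                             drop_indels = FALSE,
                             include_ids = NULL, exclude_ids = NULL,
                             require_filter = NULL, samples = NULL) {
  classes <- c("biallelic", "multiallelic", "invariant")
  stopifnot(
    is.null(include_classes) || all(include_classes %in% classes),
    is.null(exclude_classes) || all(exclude_classes %in% classes)
  )
  if (min_maf < 0 || max_maf > 0.5 || min_maf > max_maf) {
    rlang::abort("MAF bounds must satisfy 0 <= min <= max <= 0.5")
  }
  if (min_mac < 0) rlang::abort("MAC bounds must be >= 0")
  if (length(intersect(include_ids, exclude_ids)) > 0) {
    rlang::abort("include_ids and exclude_ids must be disjoint")
  }
  if (inherits(samples, "pop_model")) samples <- model_individuals(samples)
  structure(
    list(
      include_classes = include_classes, exclude_classes = exclude_classes,
      include_bed = include_bed, exclude_bed = exclude_bed,
      max_missing_count = max_missing_count, max_missing_frac = max_missing_frac,
      min_maf = min_maf, max_maf = max_maf, min_mac = min_mac, max_mac = max_mac,
      drop_indels = drop_indels,
      include_ids = include_ids, exclude_ids = exclude_ids,
      require_filter = require_filter, samples = samples
    ),
    class = "site_filter_spec"
  )
}

# TRUE per record when pos falls inside any interval of bed (s < pos <= e).
pos_in_bed <- function(chrom, pos, bed) {
  check_intervals(bed)
  res <- logical(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    b <- bed[bed$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0) next
    ir <- IRanges::IRanges(start = b$start + 1L, end = b$end)
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    res[sel] <- IRanges::overlapsAny(q, ir)
  }
  res
}

#' Filter variant sites
#'
#' Applies every active rule of a [site_filter_spec()] and returns exactly
#' the records satisfying all of them, in input order. When the spec names a
#' sample subset, genotype columns are restricted first and all per-site
#' quantities (missingness, MAF, MAC, allele class) are computed on the
#' retained samples only.
#'
#' @param vcf A `vcf_tbl`.
#' @param spec A `site_filter_spec`.
#' @return A filtered `vcf_tbl` (a subsequence of the input records).
#' @export
filter_sites <- function(vcf, spec) {
  stopifnot(inherits(spec, "site_filter_spec"))
  if (!is.null(spec$samples)) vcf <- vcf_select_samples(vcf, spec$samples)
  samples <- vcf_samples(vcf)
  keep <- rep(TRUE, nrow(vcf))
  st <- site_stats(vcf, samples)
  cls <- allele_class(st$n_distinct)

  if (!is.null(spec$include_classes)) keep <- keep & cls %in% spec$include_classes
  if (!is.null(spec$exclude_classes)) keep <- keep & !cls %in% spec$exclude_classes
  if (!is.null(spec$include_bed)) {
    keep <- keep & pos_in_bed(vcf$chrom, vcf$pos, spec$include_bed)
  }
  if (!is.null(spec$exclude_bed)) {
    keep <- keep & !pos_in_bed(vcf$chrom, vcf$pos, spec$exclude_bed)
  }
  keep <- keep & st$n_missing <= spec$max_missing_count
  if (length(samples) > 0) {
    keep <- keep & st$n_missing / length(samples) <= spec$max_missing_frac
  }
  keep <- keep & st$maf >= spec$min_maf & st$maf <= spec$max_maf
  keep <- keep & st$mac >= spec$min_mac & st$mac <= spec$max_mac
  if (spec$drop_indels) keep <- keep & !is_indel_record(vcf$ref, vcf$alt)
  if (!is.null(spec$include_ids)) keep <- keep & vcf$id %in% spec$include_ids
  if (!is.null(spec$exclude_ids)) keep <- keep & !vcf$id %in% spec$exclude_ids
  if (!is.null(spec$require_filter)) {
    keep <- keep & !is.na(vcf$filter) & vcf$filter == spec$require_filter
  }
  as_vcf_tbl(vcf[keep, , drop = FALSE], header = attr(vcf, "header"))
}

#' Locus filter specification
#'
#' Rules for keeping whole loci (BED intervals) based on their variant
#' content, used by [filter_loci()].
#'
#' @param min_variants Minimum qualifying variant sites per locus.
#' @param max_missing Cap on missing data within the locus; counted per
#'   genotype by default (see `missing_per`).
#' @param min_length Minimum locus length in bp.
#' @param ignore_indels,ignore_multiallelic Exclude such records from the
#'   qualifying-variant count.
#' @param ignore_cpg Exclude variants inside a CpG dinucleotide of the
#'   reference (requires `ref` in [filter_loci()]). A site at position p is
#'   "within a CpG" when the reference reads CG at (p, p+1) or (p-1, p).
#' @param missing_per Count missing data per `"genotype"` (default) or per
#'   `"site"` (number of records with any missing genotype).
#' @return A `locus_filter_spec`.
#' @export
locus_filter_spec <- function(min_variants = 0, max_missing = Inf,
                              min_length = 1,
                              ignore_indels = FALSE,
                              ignore_multiallelic = FALSE,
                              ignore_cpg = FALSE,
                              missing_per = c("genotype", "site")) {
  if (min_variants < 0) rlang::abort("min_variants must be >= 0")
  if (min_length < 1) rlang::abort("min_length must be >= 1")
  structure(
    list(
      min_variants = min_variants, max_missing = max_missing,
      min_length = min_length, ignore_indels = ignore_indels,
      ignore_multiallelic = ignore_multiallelic, ignore_cpg = ignore_cpg,
      missing_per = match.arg(missing_per)
    ),
    class = "locus_filter_spec"
  )
}

# TRUE where the reference sequence has a CpG covering each 1-based position.
cpg_positions <- function(refseq, pos) {
  chars <- strsplit(as.character(refseq), "")[[1]]
  n <- length(chars)
  at <- function(i) ifelse(i >= 1 & i <= n, chars[pmax(pmin(i, n), 1)], "")
  (at(pos) == "C" & at(pos + 1) == "G") | (at(pos - 1) == "C" & at(pos) == "G")
}

load_reference <- function(ref) {
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Filter loci by informativeness
#'
#' Keeps the loci whose qualifying-variant count, missing-data load and
#' length satisfy a [locus_filter_spec()]. A "qualifying variant" is a
#' polymorphic record (two or more distinct called alleles) inside the locus
#' that survives the spec's ignore flags.
#'
#' @param vcf A `vcf_tbl`.
#' @param loci Interval tibble (0-based half-open).
#' @param spec A `locus_filter_spec`.
#' @param ref Reference FASTA (path or `DNAStringSet`); required when
#'   `ignore_cpg` is set.
#' @return The subset of `loci` rows that pass, original order preserved.
#' @export
filter_loci <- function(vcf, loci, spec, ref = NULL) {
  stopifnot(inherits(spec, "locus_filter_spec"))
  check_intervals(loci)
  if (spec$ignore_cpg && is.null(ref)) {
    rlang::abort("ignore_cpg requires a reference FASTA")
  }
  if (!is.null(ref)) {
    ref <- load_reference(ref)
    too_long <- loci$end > stats::setNames(Biostrings::width(ref), names(ref))[loci$chrom]
    if (any(too_long, na.rm = TRUE)) {
      rlang::abort("locus extends beyond reference sequence length")
    }
  }
  st <- site_stats(vcf)
  is_var <- st$n_distinct >= 2
  qual <- is_var
  if (spec$ignore_indels) qual <- qual & !is_indel_record(vcf$ref, vcf$alt)
  if (spec$ignore_multiallelic) qual <- qual & st$n_distinct < 3
  if (spec$ignore_cpg) {
    in_cpg <- rep(FALSE, nrow(vcf))
    for (ch in intersect(unique(vcf$chrom), names(ref))) {
      sel <- vcf$chrom == ch
      in_cpg[sel] <- cpg_positions(ref[[ch]], vcf$pos[sel])
    }
    qual <- qual & !in_cpg
  }
  keep <- vapply(seq_len(nrow(loci)), function(i) {
    inside <- vcf$chrom == loci$chrom[i] &
      vcf$pos > loci$start[i] & vcf$pos <= loci$end[i]
    n_var <- sum(qual & inside)
    n_miss <- if (spec$missing_per == "genotype") {
      sum(st$n_missing[inside])
    } else {
      sum(st$n_missing[inside] > 0)
    }
    len <- loci$end[i] - loci$start[i]
    n_var >= spec$min_variants && n_miss <= spec$max_missing &&
      len >= spec$min_length
  }, logical(1))
  loci[keep, , drop = FALSE]
}

#' Split a variant table into per-locus tables
#'
#' @param vcf A `vcf_tbl`.
#' @param loci Interval tibble (0-based half-open); a record at `pos` p
#'   belongs to locus `(s, e]` iff `s < p <= e`. Overlapping loci duplicate
#'   records with a warning.
#' @return Named list of `vcf_tbl`s, one per locus in sorted locus order,
#'   names `"chrom:start-end"`. Empty loci yield empty tables with the
#'   header intact.
#' @export
split_by_loci <- function(vcf, loci) {
  check_intervals(loci)
  if (nrow(loci) == 0) rlang::abort("empty locus list")
  loci <- sort_intervals(loci)
  overlap <- loci |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(ov = .data$start < dplyr::lag(.data$end, default = -1L)) |>
    dplyr::pull(.data$ov)
  if (any(overlap)) {
    rlang::warn("overlapping loci: records may be duplicated across outputs")
  }
  out <- lapply(seq_len(nrow(loci)), function(i) {
    sel <- vcf$chrom == loci$chrom[i] &
      vcf$pos > loci$start[i] & vcf$pos <= loci$end[i]
    as_vcf_tbl(vcf[sel, , drop = FALSE], header = attr(vcf, "header"))
  })
  names(out) <- sprintf("%s:%d-%d", loci$chrom, loci$start, loci$end)
  out
}

# Table utilities -----------------------------------------------------------

#' Concatenate variant tables
#'
#' Pools the records of tables sharing an identical sample list (e.g.
#' per-chromosome files); use [sort_vcf()] afterwards for coordinate order.
#'
#' @param tables List of `vcf_tbl`s.
#' @return A single `vcf_tbl`.
#' @export
concat_vcfs <- function(tables) {
  stopifnot(length(tables) >= 1)
  s0 <- vcf_samples(tables[[1]])
  for (t in tables[-1]) {
    if (!identical(vcf_samples(t), s0)) {
      rlang::abort("concat requires identical sample lists")
    }
  }
  as_vcf_tbl(dplyr::bind_rows(tables), header = attr(tables[[1]], "header"))
}

#' Merge variant tables site-wise
#'
#' Joins tables by site key (chrom, pos, ref), taking the union of samples
#' and of ALT alleles (genotype indices remapped). Genotypes absent from a
#' table are filled as missing; a sample present in several tables must
#' agree at shared sites (a missing genotype yields to a called one).
#'
#' @param tables List of `vcf_tbl`s.
#' @return Merged, sorted `vcf_tbl`.
#' @export
merge_vcfs <- function(tables) {
  stopifnot(length(tables) >= 1)
  all_samples <- unique(unlist(lapply(tables, vcf_samples)))
  keys <- lapply(tables, function(t) paste(t$chrom, t$pos, sep = "\r"))
  # conflicting REF at a shared (chrom,pos) is an error
  refs <- dplyr::bind_rows(lapply(tables, function(t) {
    tibble::tibble(key = paste(t$chrom, t$pos, sep = "\r"), ref = t$ref)
  }))
  bad <- refs |>
    dplyr::distinct() |>
    dplyr::count(.data$key) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad) > 0) rlang::abort("conflicting REF alleles at shared position")

  site_key <- unique(unlist(keys))
  rows <- lapply(site_key, function(k) {
    alts <- character(0)
    base <- NULL
    gts <- stats::setNames(rep("./.", length(all_samples)), all_samples)
    for (ti in seq_along(tables)) {
      t <- tables[[ti]]
      i <- match(k, keys[[ti]])
      if (is.na(i)) next
      rec <- t[i, , drop = FALSE]
      if (is.null(base)) base <- rec[, VCF_FIXED_COLS]
      rec_alts <- setdiff(record_allele_set(rec$ref, rec$alt), rec$ref)
      new_alts <- union(alts, rec_alts)
      # remap this record's allele indices onto the unioned ALT list
      map <- c(0L, match(rec_alts, new_alts))
      alts <- new_alts
      for (s in vcf_samples(t)) {
        g <- gt_field(rec[[s]])
        sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
        idx <- strsplit(g, "[/|]")[[1]]
        remapped <- vapply(idx, function(a) {
          if (a %in% c(".", "")) "." else as.character(map[as.integer(a) + 1L])
        }, character(1))
        g2 <- paste(remapped, collapse = sep)
        old <- gts[[s]]
        old_missing <- all(strsplit(gt_field(old), "[/|]")[[1]] %in% c(".", ""))
        new_missing <- all(remapped %in% c(".", ""))
        if (old_missing) {
          gts[[s]] <- g2
        } else if (!new_missing && gsub("\\|", "/", gt_field(old)) != gsub("\\|", "/", g2)) {
          rlang::abort(sprintf("conflicting genotypes for sample %s during merge", s))
        }
      }
    }
    base$alt <- if (length(alts) == 0) "." else paste(alts, collapse = ",")
    dplyr::bind_cols(base, tibble::as_tibble(as.list(gts)))
  })
  sort_vcf(as_vcf_tbl(dplyr::bind_rows(rows), header = attr(tables[[1]], "header")))
}

# Chromosome display order: header contig lines when present, else first
# appearance in the records.
chrom_order <- function(vcf) {
  header <- attr(vcf, "header")
  contigs <- character(0)
  if (!is.null(header)) {
    m <- regmatches(header, regexec("^##contig=<ID=([^,>]+)", header))
    contigs <- vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
    contigs <- contigs[!is.na(contigs)]
  }
  unique(c(contigs, vcf$chrom))
}

#' Sort a variant table
#'
#' Orders records by chromosome (header contig order when present, else
#' first-appearance order) and position; ties keep input order (stable).
#'
#' @param vcf A `vcf_tbl`.
#' @return Sorted `vcf_tbl`.
#' @export
sort_vcf <- function(vcf) {
  ord <- order(match(vcf$chrom, chrom_order(vcf)), vcf$pos)
  as_vcf_tbl(vcf[ord, , drop = FALSE], header = attr(vcf, "header"))
}
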