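# Variant tables -----------------------------------------------------------
#
# The package-wide container for variant data is a "vcf_tbl": a tibble with
# the eight fixed VCF columns (chrom, pos, id, ref, alt, qual, filter, info)
# followed by one character column per sample holding the GT field only
# ("0|1", "./.", ...). ALT alleles are stored comma-joined as in VCF text;
# "." marks an absent value. Header meta-lines ride along as an attribute.

VCF_FIXED_COLS <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter", "info")

#' Build a variant table
#'
#' Constructs the tibble-based variant container used throughout the package.
#' Genotype columns carry the GT field only; other FORMAT fields are outside
#' the canonical dialect.
#'
#' @param records A data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `qual`, `filter`, `info` plus one character column per sample.
#'   Missing fixed columns are filled with VCF missing values (`"."`/`NA`).
#' @param header Optional character vector of `##` meta lines to preserve.
#' @return A `vcf_tbl` tibble.
#' @export
vcf_tbl <- function(records, header = NULL) {
  records <- tibble::as_tibble(records)
  if (!all(c("chrom", "pos", "ref") %in% names(records))) {
    rlang::abort("records must have at least chrom, pos and ref columns")
  }
  defaults <- list(id = ".", alt = ".", qual = NA_real_, filter = ".", info = ".")
  for (col in names(defaults)) {
    if (!col %in% names(records)) records[[col]] <- defaults[[col]]
  }
  records$pos <- as.integer(records$pos)
  if (any(records$pos < 1L)) rlang::abort("VCF positions are 1-based: pos >= 1")
  if (any(!nzchar(records$ref))) rlang::abort("ref allele must be non-empty")
  samples <- setdiff(names(records), VCF_FIXED_COLS)
  records <- records[, c(VCF_FIXED_COLS, samples)]
  out <- structure(records,
    header = header,
    class = c("vcf_tbl", class(tibble::tibble()))
  )
  out
}

#' @export
print.vcf_tbl <- function(x, ...) {
  cat(sprintf(
    "# A variant table: %d record%s x %d sample%s\n",
    nrow(x), if (nrow(x) == 1) "" else "s",
    length(vcf_samples(x)), if (length(vcf_samples(x)) == 1) "" else "s"
  ))
  NextMethod()
}

# Re-class a plain tibble that still has the vcf column layout.
as_vcf_tbl <- function(x, header = NULL) {
  vcf_tbl(x, header = header)
}

#' Sample IDs of a variant table
#'
#' @param vcf A `vcf_tbl`.
#' @return Character vector of sample column names, in column order.
#' @export
vcf_samples <- function(vcf) {
  setdiff(names(vcf), VCF_FIXED_COLS)
}

#' List the samples or chromosomes in a variant table
#'
#' Mirrors the sample-list / chromosome-list utilities of VCF toolkits.
#'
#' @param vcf A `vcf_tbl`.
#' @return Character vector.
#' @export
list_samples <- function(vcf) vcf_samples(vcf)

#' @rdname list_samples
#' @export
list_chromosomes <- function(vcf) unique(vcf$chrom)

#' Restrict a variant table to a subset of samples
#'
#' @param vcf A `vcf_tbl`.
#' @param samples Character vector of sample IDs (order preserved as given),
#'   or a population model whose individuals are used.
#' @return A `vcf_tbl` with only the requested genotype columns.
#' @export
vcf_select_samples <- function(vcf, samples) {
  if (inherits(samples, "pop_model")) samples <- model_individuals(samples)
  missing <- setdiff(samples, vcf_samples(vcf))
  if (length(missing) > 0) {
    rlang::abort(paste0("samples not in VCF: ", paste(missing, collapse = ", ")))
  }
  as_vcf_tbl(vcf[, c(VCF_FIXED_COLS, samples)], header = attr(vcf, "header"))
}

# Genotype helpers ----------------------------------------------------------

# Strip non-GT subfields and return the bare GT strings for one sample column.
gt_field <- function(x) sub(":.*$", "", x)

# Parse GT strings into an integer allele matrix with one row per genotype and
# `ploidy` columns (NA for "."), plus a phased flag. Genotypes are assumed
# diploid unless they contain a single allele (treated as haploid: second
# column NA, not missing -> callers decide). Used record-wise.
parse_gt <- function(gt) {
  gt <- gt_field(gt)
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")
  n_al <- lengths(parts)
  k <- max(n_al, 1L)
  al <- matrix(NA_integer_, nrow = length(gt), ncol = k)
  for (j in seq_len(k)) {
    v <- vapply(parts, function(p) if (length(p) >= j) p[[j]] else NA_character_, character(1))
    v[v %in% c(".", "")] <- NA_character_
    al[, j] <- suppressWarnings(as.integer(v))
  }
  list(alleles = al, phased = phased, ploidy = n_al)
}

# Allele index matrix for one record across given samples: samples x ploidy.
record_alleles <- function(rec, samples) {
  parse_gt(unlist(rec[samples], use.names = FALSE))$alleles
}

# The alleles of a record: REF then ALTs ("." alt -> none).
record_allele_set <- function(ref, alt) {
  if (is.na(alt) || alt == ".") c(ref) else c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
}

# Per-record summary used by filters and statistics. Returns a tibble with one
# row per record of `vcf` (restricted to `samples`):
#   n_called   called allele copies
#   n_missing  genotypes containing at least one missing allele
#   counts     list-column of named allele-index counts over called copies
#   n_distinct distinct called alleles
#   maf, mac   minor-allele frequency / count over called copies
site_stats <- function(vcf, samples = vcf_samples(vcf)) {
  gt_mat <- as.matrix(vcf[, samples, drop = FALSE])
  n <- nrow(vcf)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    al <- parse_gt(gt_mat[i, ])$alleles
    miss <- rowSums(is.na(al)) > 0
    called <- al[!is.na(al)]
    tab <- table(called)
    nd <- length(tab)
    if (nd >= 2) {
      mac <- min(tab)
      maf <- mac / length(called)
    } else {
      mac <- 0L
      maf <- 0
    }
    out[[i]] <- list(
      n_called = length(called), n_missing = sum(miss),
      counts = tab, n_distinct = nd, maf = maf, mac = as.integer(mac)
    )
  }
  tibble::tibble(
    n_called = vapply(out, `[[`, integer(1), "n_called"),
    n_missing = vapply(out, `[[`, integer(1), "n_missing"),
    counts = lapply(out, `[[`, "counts"),
    n_distinct = vapply(out, `[[`, integer(1), "n_distinct"),
    maf = vapply(out, `[[`, numeric(1), "maf"),
    mac = vapply(out, `[[`, integer(1), "mac")
  )
}

# Record-level predicates (sample-independent).
is_indel_record <- function(ref, alt) {
  alleles <- mapply(record_allele_set, ref, alt, SIMPLIFY = FALSE)
  vapply(alleles, function(a) any(nchar(a) != 1L | !a %in% c("A", "C", "G", "T", "N", ".")), logical(1))
}

n_alt_alleles <- function(alt) {
  ifelse(is.na(alt) | alt == ".", 0L, stringr::str_count(alt, stringr::fixed(",")) + 1L)
}

# Allele class from called genotypes: "invariant" (<=1 distinct called
# allele), "biallelic" (2), "multiallelic" (>=3).
allele_class <- function(n_distinct) {
  dplyr::case_when(
    n_distinct >= 3 ~ "multiallelic",
    n_distinct == 2 ~ "biallelic",
    TRUE ~ "invariant"
  )
}

# Reading and writing -------------------------------------------------------

#' Read a VCF file into a variant table
#'
#' Parses VCF v4.x text (plain or gzip) via \pkg{vcfR} and extracts the GT
#' field of each sample. Other FORMAT fields are dropped (the canonical
#' dialect of this package carries genotypes only).
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return A `vcf_tbl` with the file's `##` header lines attached.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  rec <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID), ".", fix$ID),
    ref = fix$REF,
    alt = ifelse(is.na(fix$ALT), ".", fix$ALT),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER),
    info = ifelse(is.na(fix$INFO), ".", fix$INFO)
  )
  if (ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt[is.na(gt)] <- "./."
    for (s in colnames(gt)) rec[[s]] <- unname(gt[, s])
  }
  header <- grep("^##", v@meta, value = TRUE)
  vcf_tbl(rec, header = header)
}

default_vcf_header <- function(vcf) {
  contigs <- unique(vcf$chrom)
  c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
}

#' Write a variant table as VCF text
#'
#' Serializes the canonical GT-only dialect. A minimal header (fileformat,
#' contig and FORMAT lines) is generated when the table carries none.
#'
#' @param vcf A `vcf_tbl`.
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vcf, path) {
  header <- attr(vcf, "header")
  if (is.null(header)) header <- default_vcf_header(vcf)
  samples <- vcf_samples(vcf)
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples) > 0) cols <- c(cols, "FORMAT", samples)
  body <- character(nrow(vcf))
  qual <- ifelse(is.na(vcf$qual), ".", format(vcf$qual, trim = TRUE, scientific = FALSE))
  fixed <- paste(vcf$chrom, vcf$pos, vcf$id, vcf$ref, vcf$alt, qual,
    vcf$filter, vcf$info,
    sep = "\t"
  )
  if (length(samples) > 0) {
    gt <- do.call(paste, c(unname(as.list(vcf[, samples, drop = FALSE])), sep = "\t"))
    body <- paste(fixed, "GT", gt, sep = "\t")
  } else {
    body <- fixed
  }
  lines <- c(header, paste(cols, collapse = "\t"), body)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
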