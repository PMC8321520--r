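# BED interval algebra ------------------------------------------------------
#
# Intervals are tibbles with columns chrom, start, end (0-based, half-open)
# and optionally name, score, strand. Set operations (merge, subtract,
# complement) are delegated to IRanges after shifting to 1-based closed
# coordinates; extra columns are carried through sample/sort/extend and
# dropped by the set operations, which have no single source feature.

bed_to_iranges <- function(x) {
  split(IRanges::IRanges(start = x$start + 1L, end = x$end), x$chrom)
}

iranges_to_bed <- function(irl) {
  rows <- lapply(names(irl), function(ch) {
    ir <- irl[[ch]]
    if (length(ir) == 0) return(NULL)
    tibble::tibble(
      chrom = ch,
      start = as.integer(IRanges::start(ir) - 1L),
      end = as.integer(IRanges::end(ir))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  }
  sort_intervals(out)
}

check_intervals <- function(x) {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    rlang::abort("intervals need chrom, start, end columns")
  }
  if (any(x$start < 0)) rlang::abort("BED start must be >= 0")
  if (any(x$start >= x$end)) rlang::abort("BED intervals need start < end")
  invisible(x)
}

#' Read and write BED files
#'
#' BED3/BED6 tab-separated text, 0-based half-open coordinates.
#'
#' @param path File path.
#' @return `read_bed()` returns a tibble with `chrom`, `start`, `end` and, if
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path,
    col_names = FALSE, comment = "#",
    show_col_types = FALSE, progress = FALSE
  )
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- nm[seq_len(ncol(x))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  check_intervals(x)
  x
}

#' @param x Interval tibble.
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  readr::write_tsv(x[, keep], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a genome file (chromosome lengths)
#'
#' @param path Tab-separated "chrom<TAB>length" lines.
#' @return A tibble with `chrom` and `length`.
#' @export
read_genome <- function(path) {
  x <- readr::read_tsv(path,
    col_names = c("chrom", "length"),
    show_col_types = FALSE, progress = FALSE
  )
  x$length <- as.integer(x$length)
  if (any(x$length < 1) || anyDuplicated(x$chrom)) {
    rlang::abort("genome file needs unique chroms with positive lengths")
  }
  x
}

#' Sort intervals
#'
#' Orders by (chrom, start, end); extra columns ride along.
#'
#' @param x Interval tibble.
#' @return Sorted tibble.
#' @export
sort_intervals <- function(x) {
  check_intervals(x)
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

#' Merge overlapping intervals
#'
#' Unions overlapping — and, by default, book-ended — intervals per
#' chromosome. Columns beyond chrom/start/end are dropped (a merged feature
#' has no single source).
#'
#' @param x Interval tibble.
#' @param merge_bookended Merge abutting intervals (`end == next start`)?
#'   Default `TRUE`, matching common toolkit behaviour.
#' @return Merged BED3 tibble, sorted.
#' @export
merge_intervals <- function(x, merge_bookended = TRUE) {
  check_intervals(x)
  irl <- bed_to_iranges(x)
  gap <- if (merge_bookended) 1L else 0L
  iranges_to_bed(lapply(irl, IRanges::reduce, min.gapwidth = gap))
}

#' Subtract one interval set from another
#'
#' Per-base set difference `a \ b`, emitted as maximal intervals.
#'
#' @param a,b Interval tibbles.
#' @return BED3 tibble of `a` bases not covered by `b`.
#' @export
subtract_intervals <- function(a, b) {
  check_intervals(a)
  if (nrow(b) > 0) check_intervals(b)
  ira <- lapply(bed_to_iranges(a), IRanges::reduce)
  irb <- bed_to_iranges(b)
  out <- lapply(names(ira), function(ch) {
    if (ch %in% names(irb)) {
      IRanges::setdiff(ira[[ch]], irb[[ch]])
    } else {
      ira[[ch]]
    }
  })
  iranges_to_bed(stats::setNames(out, names(ira)))
}

#' Extend intervals upstream/downstream
#'
#' Grows each interval by `upstream` bp before its start and `downstream` bp
#' after its end (roles swapped on the minus strand when `strand_aware`),
#' clipping to `[0, chromosome length]`.
#'
#' @param x Interval tibble.
#' @param upstream,downstream Non-negative extensions in bp.
#' @param genome Genome tibble (`chrom`, `length`) used for clipping.
#' @param strand_aware Respect a `strand` column? Default `FALSE`.
#' @return Tibble with the same columns as `x`.
#' @export
extend_intervals <- function(x, upstream = 0, downstream = 0, genome,
                             strand_aware = FALSE) {
  check_intervals(x)
  missing_chrom <- setdiff(unique(x$chrom), genome$chrom)
  if (length(missing_chrom) > 0) {
    rlang::abort(paste0("chrom absent from genome: ", paste(missing_chrom, collapse = ", ")))
  }
  len <- stats::setNames(genome$length, genome$chrom)[x$chrom]
  up <- rep(as.integer(upstream), nrow(x))
  down <- rep(as.integer(downstream), nrow(x))
  if (strand_aware && "strand" %in% names(x)) {
    neg <- !is.na(x$strand) & x$strand == "-"
    tmp <- up[neg]
    up[neg] <- down[neg]
    down[neg] <- tmp
  }
  x$start <- pmax(0L, x$start - up)
  x$end <- pmin(as.integer(len), x$end + down)
  x
}

#' Complement of an interval set over a genome
#'
#' @param x Interval tibble (merged internally first).
#' @param genome Genome tibble (`chrom`, `length`). Chromosomes with no
#'   interval contribute their full length.
#' @return BED3 tibble covering exactly the bases of `genome` not in `x`.
#' @export
complement_intervals <- function(x, genome) {
  check_intervals(x)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    ir <- IRanges::IRanges(
      start = x$start[x$chrom == ch] + 1L,
      end = x$end[x$chrom == ch]
    )
    gaps <- IRanges::gaps(IRanges::reduce(ir), start = 1L, end = genome$length[i])
    if (length(gaps) == 0) return(NULL)
    tibble::tibble(
      chrom = ch,
      start = as.integer(IRanges::start(gaps) - 1L),
      end = as.integer(IRanges::end(gaps))
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  }
  sort_intervals(res)
}

#' Randomly sample intervals
#'
#' Seeded simple random sample of rows without replacement; output re-sorted;
#' extra columns carried through.
#'
#' @param x Interval tibble.
#' @param n Number of intervals to draw (`n <= nrow(x)`).
#' @param seed Integer seed (Mersenne-Twister; sample kind "Rejection").
#' @return Tibble of `n` intervals.
#' @export
sample_intervals <- function(x, n, seed) {
  check_intervals(x)
  if (n > nrow(x)) rlang::abort("cannot sample more intervals than available")
  idx <- withr::with_seed(seed, sample.int(nrow(x), n))
  sort_intervals(x[idx, , drop = FALSE])
}
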