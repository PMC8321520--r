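# Windowed population-genetic statistics ------------------------------------
#
# Two estimators are implemented from their original definitions:
#   * Tajima's D (Tajima 1989): D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1)),
#     with the a1..e2 constants functions of the haploid sample size n.
#   * Weir & Cockerham's FST (1984): per-site variance components a (among
#     populations), b (among individuals within populations), c (within
#     individuals), combined over a window as theta = sum(a)/sum(a+b+c).
# Both work on biallelic SNPs; multiallelic sites are excluded (or raise,
# with `on_multiallelic = "error"`). Undefined values are NA, never 0.

# A one-row window-stat tibble.
window_stat <- function(chrom, start, end, stat, value, n_sites) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    n_sites = as.integer(n_sites), stat = stat, value = value
  )
}

subset_window <- function(vcf, chrom, start, end) {
  if (!chrom %in% vcf$chrom) rlang::abort(paste0("unknown chromosome: ", chrom))
  vcf[vcf$chrom == chrom & vcf$pos >= start & vcf$pos <= end, , drop = FALSE]
}

# Tajima (1989) constants for haploid sample size n.
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# Biallelic-SNP site mask and per-site alt-allele frequencies over `samples`.
biallelic_snp_stats <- function(vcf, samples, on_multiallelic = "drop") {
  st <- site_stats(vcf, samples)
  snp <- !is_indel_record(vcf$ref, vcf$alt)
  multi <- st$n_distinct >= 3
  if (on_multiallelic == "error" && any(multi & snp)) {
    rlang::abort("multiallelic site in window (on_multiallelic = \"error\")")
  }
  list(stats = st, usable = snp & !multi)
}

#' Tajima's D for one window
#'
#' Computes D from the per-site unbiased pairwise diversity
#' `pi_site = 2 p (1-p) n/(n-1)` (called alleles only) and the segregating
#' site count S, normalised with the Tajima (1989) constants evaluated at the
#' full haploid sample count of the table's samples. The value is `NA` when
#' S = 0 or the variance term is non-positive.
#'
#' @param vcf A `vcf_tbl` (phased or unphased; only allele counts are used).
#' @param chrom,start,end Window (1-based inclusive bp). Defaults to the full
#'   span of the single chromosome present.
#' @param on_multiallelic `"drop"` (default) excludes multiallelic sites,
#'   `"error"` raises.
#' @return A one-row tibble: `chrom`, `start`, `end`, `n_sites` (segregating
#'   sites used), `stat = "tajimasd"`, `value`.
#' @export
tajimas_d <- function(vcf, chrom = NULL, start = NULL, end = NULL,
                      on_multiallelic = c("drop", "error")) {
  on_multiallelic <- match.arg(on_multiallelic)
  if (is.null(chrom)) {
    chrom <- unique(vcf$chrom)
    stopifnot(length(chrom) == 1)
  }
  if (is.null(start)) start <- min(vcf$pos[vcf$chrom == chrom], 1L)
  if (is.null(end)) end <- max(vcf$pos[vcf$chrom == chrom], start)
  win <- subset_window(vcf, chrom, start, end)
  samples <- vcf_samples(win)
  bs <- biallelic_snp_stats(win, samples, on_multiallelic)
  st <- bs$stats
  seg <- bs$usable & st$n_distinct == 2 & st$n_called >= 2
  S <- sum(seg)
  if (S == 0) {
    return(window_stat(chrom, start, end, "tajimasd", NA_real_, 0L))
  }
  n_called <- st$n_called[seg]
  p <- vapply(which(seg), function(i) {
    tab <- st$counts[[i]]
    tab[[1]] / sum(tab)
  }, numeric(1))
  pi_sites <- 2 * p * (1 - p) * n_called / (n_called - 1)
  pi <- sum(pi_sites)
  n <- 2L * length(samples) # constants at the full haploid sample count
  k <- tajima_constants(n)
  varD <- k$e1 * S + k$e2 * S * (S - 1)
  value <- if (varD <= 0) NA_real_ else (pi - S / k$a1) / sqrt(varD)
  window_stat(chrom, start, end, "tajimasd", value, S)
}

#' Weir-Cockerham FST variance components per site
#'
#' For each usable biallelic SNP in the window, computes the Weir & Cockerham
#' (1984) components from per-population sample sizes `n_i` (called diploid
#' individuals), ALT-allele frequencies `p_i` and observed heterozygote
#' frequencies `h_i`. Sites where any population has zero called genotypes
#' are skipped (counted in the `skipped` attribute); monomorphic sites yield
#' a = b = c = 0 and are flagged unusable for the windowed ratio.
#'
#' @param vcf A `vcf_tbl`.
#' @param model A `pop_model` with at least two populations, all of whose
#'   individuals are samples of `vcf`.
#' @param chrom,start,end Window (1-based inclusive); defaults as in
#'   [tajimas_d()].
#' @return Tibble with one row per retained site: `chrom`, `pos`, `a`, `b`,
#'   `c`, `p_bar`, `n_bar`, `n_c`, `h_bar`, `r`, `usable`.
#' @export
wc_fst_components <- function(vcf, model, chrom = NULL, start = NULL, end = NULL) {
  if (length(model$pops) < 2) rlang::abort("FST needs r >= 2 populations")
  missing <- setdiff(model_individuals(model), vcf_samples(vcf))
  if (length(missing) > 0) {
    rlang::abort(paste0("model individuals absent from VCF: ", paste(missing, collapse = ", ")))
  }
  if (is.null(chrom)) {
    chrom <- unique(vcf$chrom)
    stopifnot(length(chrom) == 1)
  }
  if (is.null(start)) start <- min(vcf$pos[vcf$chrom == chrom], 1L)
  if (is.null(end)) end <- max(vcf$pos[vcf$chrom == chrom], start)
  win <- subset_window(vcf, chrom, start, end)
  pops <- model$pops
  r <- length(pops)
  bs <- biallelic_snp_stats(win, model_individuals(model))
  rows <- lapply(which(bs$usable), function(i) {
    ni <- hi <- pi_ <- numeric(r)
    for (j in seq_len(r)) {
      al <- record_alleles(win[i, ], pops[[j]])
      if (ncol(al) < 2) rlang::abort("FST requires diploid genotypes")
      called <- rowSums(is.na(al)) == 0
      ni[j] <- sum(called)
      if (ni[j] > 0) {
        alc <- al[called, , drop = FALSE]
        pi_[j] <- mean(alc > 0) # ALT frequency
        hi[j] <- mean(alc[, 1] != alc[, 2])
      }
    }
    if (any(ni == 0)) return(NULL) # population uncallable here: skip site
    n_bar <- mean(ni)
    if (r * n_bar - sum(ni) == 0 && r == 1) return(NULL)
    n_c <- (r * n_bar - sum(ni^2) / (r * n_bar)) / (r - 1)
    p_bar <- sum(ni * pi_) / (r * n_bar)
    s2 <- sum(ni * (pi_ - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(ni * hi) / (r * n_bar)
    if (n_bar <= 1 || n_c <= 0) return(NULL)
    a <- (n_bar / n_c) *
      (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    tibble::tibble(
      chrom = win$chrom[i], pos = win$pos[i],
      a = a, b = b, c = cc, p_bar = p_bar, n_bar = n_bar, n_c = n_c,
      h_bar = h_bar, r = r, usable = (p_bar > 0 && p_bar < 1)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      chrom = character(), pos = integer(), a = numeric(), b = numeric(),
      c = numeric(), p_bar = numeric(), n_bar = numeric(), n_c = numeric(),
      h_bar = numeric(), r = integer(), usable = logical()
    )
  }
  out
}

#' Windowed Weir-Cockerham FST
#'
#' The ratio-of-sums estimator `sum(a) / sum(a+b+c)` over the window's usable
#' (polymorphic) sites; `NA` when no site is usable or the denominator is 0.
#'
#' @inheritParams wc_fst_components
#' @return One-row window-stat tibble (`stat = "windowed-fst"`); the per-site
#'   components are attached as attribute `"components"`.
#' @export
wc_fst <- function(vcf, model, chrom = NULL, start = NULL, end = NULL) {
  if (is.null(chrom)) {
    chrom <- unique(vcf$chrom)
    stopifnot(length(chrom) == 1)
  }
  if (is.null(start)) start <- min(vcf$pos[vcf$chrom == chrom], 1L)
  if (is.null(end)) end <- max(vcf$pos[vcf$chrom == chrom], start)
  comp <- wc_fst_components(vcf, model, chrom, start, end)
  use <- comp[comp$usable, , drop = FALSE]
  denom <- sum(use$a + use$b + use$c)
  value <- if (nrow(use) == 0 || denom == 0) NA_real_ else sum(use$a) / denom
  out <- window_stat(chrom, start, end, "windowed-fst", value, nrow(use))
  attr(out, "components") <- comp
  out
}

#' Sliding-window scan of a statistic
#'
#' Tiles each chromosome with windows of `window_size` bp advanced by `step`
#' bp, anchored by default at the first record of the chromosome, and
#' evaluates the chosen statistic per window.
#'
#' @param vcf A `vcf_tbl`.
#' @param stat `"tajimasd"` or `"windowed-fst"`.
#' @param window_size,step Window width and stride in bp (both >= 1).
#' @param model Required for `"windowed-fst"`.
#' @param anchor `"first"` (default) starts tiling at the first record
#'   position per chromosome; `"one"` at position 1.
#' @param drop_empty Drop windows with no data instead of emitting them with
#'   `NA`? Default `FALSE`.
#' @return Window-stat tibble, one row per window.
#' @export
windowed_scan <- function(vcf, stat, window_size, step = window_size,
                          model = NULL, anchor = c("first", "one"),
                          drop_empty = FALSE) {
  anchor <- match.arg(anchor)
  if (!stat %in% c("tajimasd", "windowed-fst")) {
    rlang::abort(paste0("unknown statistic: ", stat))
  }
  if (window_size < 1 || step < 1) rlang::abort("window_size and step must be >= 1")
  if (stat == "windowed-fst" && is.null(model)) {
    rlang::abort("windowed-fst requires a population model")
  }
  out <- lapply(unique(vcf$chrom), function(ch) {
    pos <- vcf$pos[vcf$chrom == ch]
    first <- if (anchor == "first") min(pos) else 1L
    last <- max(pos)
    starts <- seq.int(first, last, by = step)
    dplyr::bind_rows(lapply(starts, function(s) {
      e <- s + window_size - 1L
      if (stat == "tajimasd") {
        tajimas_d(vcf, ch, s, e)
      } else {
        ws <- wc_fst(vcf, model, ch, s, e)
        attr(ws, "components") <- NULL
        ws
      }
    }))
  })
  res <- dplyr::bind_rows(out)
  if (drop_empty) res <- res[res$n_sites > 0, , drop = FALSE]
  res
}

# Statistic tables on disk ---------------------------------------------------

#' Write or read a statistic table
#'
#' Tab-separated with header `CHROM BIN_START BIN_END N_SITES <STAT>`, the
#' token `nan` marking undefined values; re-readable by the locus sampler and
#' convertible to BED-style intervals with [stats_to_intervals()].
#'
#' @param stats Window-stat tibble (single statistic).
#' @param path File path.
#' @export
write_stat_table <- function(stats, path) {
  stopifnot(length(unique(stats$stat)) == 1)
  stat_name <- toupper(unique(stats$stat))
  df <- tibble::tibble(
    CHROM = stats$chrom, BIN_START = stats$start, BIN_END = stats$end,
    N_SITES = stats$n_sites
  )
  df[[stat_name]] <- ifelse(is.na(stats$value), "nan",
    format(stats$value, digits = 15, trim = TRUE)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_stat_table
#' @export
read_stat_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stat_col <- setdiff(names(df), c("CHROM", "BIN_START", "BIN_END", "N_SITES"))[1]
  tibble::tibble(
    chrom = df$CHROM, start = as.integer(df$BIN_START),
    end = as.integer(df$BIN_END), n_sites = as.integer(df$N_SITES),
    stat = tolower(stat_col),
    value = suppressWarnings(as.numeric(ifelse(df[[stat_col]] == "nan", NA, df[[stat_col]])))
  )
}

#' Convert window stats to BED-style intervals
#'
#' Window coordinates are 1-based inclusive; the returned intervals are
#' 0-based half-open, suitable for [split_by_loci()].
#'
#' @param stats Window-stat tibble.
#' @return Interval tibble with the stat `value` carried in a `value` column.
#' @export
stats_to_intervals <- function(stats) {
  tibble::tibble(
    chrom = stats$chrom, start = stats$start - 1L, end = stats$end,
    value = stats$value
  )
}

# Locus subsampling ----------------------------------------------------------

#' Subsample loci by statistic value
#'
#' Draws `n` loci from the rows of a window-stat table with a defined value,
#' either as a simple random sample (`scheme = "random"`) or uniformly across
#' `bins` equal-width bins of the statistic (`scheme = "uniform"`): values
#' are binned over `[min, max]` (right-closed bins) and each non-empty bin
#' contributes `floor(n / bins)` draws, the first `n %% bins` non-empty bins
#' one extra. Should a bin hold fewer loci than its quota, all of them are
#' taken and the deficit is redistributed to later bins with spare capacity,
#' keeping the sample size exactly `n`. Fully reproducible from `seed`
#' (Mersenne-Twister, sample kind "Rejection").
#'
#' @param stats Window-stat tibble.
#' @param scheme `"uniform"` or `"random"`.
#' @param n Sample size (at most the number of defined-value rows).
#' @param bins Number of equal-width bins for the uniform scheme.
#' @param seed Integer seed.
#' @return The sampled rows of `stats`, in original row order.
#' @export
sample_loci <- function(stats, scheme = c("uniform", "random"), n,
                        bins = 10, seed) {
  scheme <- match.arg(scheme)
  defined <- which(!is.na(stats$value))
  if (length(defined) == 0) rlang::abort("all statistic values are undefined")
  if (n > length(defined)) rlang::abort("n exceeds the number of defined-value loci")
  # sample() treats a length-1 numeric first argument as 1:x; avoid that
  sample_vec <- function(x, k) if (length(x) == 1 && k == 1) x else sample(x, k)
  idx <- withr::with_seed(seed, {
    if (scheme == "random") {
      sample_vec(defined, n)
    } else {
      if (bins < 1) rlang::abort("bins must be >= 1")
      v <- stats$value[defined]
      lo <- min(v)
      hi <- max(v)
      width <- (hi - lo) / bins
      bin_of <- if (width == 0) {
        rep(1L, length(v))
      } else {
        pmax(1L, as.integer(ceiling((v - lo) / width)))
      }
      bin_of <- pmin(bin_of, as.integer(bins))
      nonempty <- sort(unique(bin_of))
      quota <- stats::setNames(rep(n %/% bins, length(nonempty)), nonempty)
      extra <- n %% bins
      if (extra > 0) {
        bump <- nonempty[seq_len(min(extra, length(nonempty)))]
        quota[as.character(bump)] <- quota[as.character(bump)] + 1L
      }
      # clip to availability, then redistribute any deficit
      avail <- table(bin_of)[as.character(nonempty)]
      take <- pmin(quota, avail)
      deficit <- n - sum(take)
      while (deficit > 0) {
        spare <- names(take)[take < avail]
        if (length(spare) == 0) break
        for (bname in spare) {
          if (deficit == 0) break
          take[bname] <- take[bname] + 1L
          deficit <- deficit - 1L
        }
      }
      unlist(lapply(seq_along(nonempty), function(j) {
        cand <- defined[bin_of == nonempty[j]]
        k <- take[[j]]
        if (k >= length(cand)) cand else sample_vec(cand, k)
      }), use.names = FALSE)
    }
  })
  stats[sort(idx), , drop = FALSE]
}
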