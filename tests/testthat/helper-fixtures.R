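# Fixture builders and independent oracles used across the suite.

# Build a phased vcf_tbl from a haplotype 0/1 matrix (haplotypes x sites).
# Row 2k-1 / 2k become the two haplotypes of sample k.
vcf_from_haps <- function(H, positions = NULL, chrom = "chr1",
                          ref = "A", alt = "T") {
  n_hap <- nrow(H)
  stopifnot(n_hap %% 2 == 0)
  n_ind <- n_hap / 2
  m <- ncol(H)
  if (is.null(positions)) positions <- seq_len(m) * 10L
  rec <- tibble::tibble(
    chrom = chrom, pos = as.integer(positions), id = ".",
    ref = rep(ref, length.out = m), alt = rep(alt, length.out = m),
    qual = NA_real_, filter = "PASS", info = "."
  )
  for (k in seq_len(n_ind)) {
    a <- H[2 * k - 1, ]
    b <- H[2 * k, ]
    gt <- paste(ifelse(is.na(a), ".", a), ifelse(is.na(b), ".", b), sep = "|")
    rec[[sprintf("s%d", k)]] <- gt
  }
  vcf_tbl(rec)
}

two_pop_model <- function(n1 = 2, n2 = 2, tree = "(P1,P2);") {
  n <- n1 + n2
  pop_model("m2",
    list(
      P1 = sprintf("s%d", seq_len(n1)),
      P2 = sprintf("s%d", n1 + seq_len(n2))
    ),
    tree = tree
  )
}

# --- Tajima's D oracle: explicit pairwise-difference route -----------------
# H: complete 0/1 haplotype matrix. pi is the mean Hamming distance over all
# haplotype pairs (not the per-site 2p(1-p) identity the implementation uses).
oracle_tajimas_d <- function(H) {
  n <- nrow(H)
  seg <- apply(H, 2, function(col) length(unique(col)) == 2)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pairs <- utils::combn(n, 2)
  dists <- apply(pairs, 2, function(ij) sum(H[ij[1], ] != H[ij[2], ]))
  pi <- mean(dists)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi - S / a1) / sqrt(v)
}

# Oracle pi correction note: the pairwise mean equals sum_site 2p(1-p)n/(n-1)
# only after the n/(n-1) factor; mean over C(n,2) pairs applies it exactly.

# --- Weir-Cockerham per-site component oracle ------------------------------
# geno: list over populations of (individuals x 2) allele matrices (0/1, no
# missing rows included). Straight transcription of the 1984 definitions.
oracle_wc_site <- function(geno) {
  r <- length(geno)
  ni <- vapply(geno, nrow, numeric(1))
  pi_ <- vapply(geno, function(g) mean(g), numeric(1))
  hi <- vapply(geno, function(g) mean(g[, 1] != g[, 2]), numeric(1))
  n_bar <- sum(ni) / r
  n_c <- (r * n_bar - sum(ni^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(ni * pi_) / (r * n_bar)
  s2 <- sum(ni * (pi_ - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(ni * hi) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c(a = a, b = b, c = h_bar / 2)
}

# --- Four-gamete oracles ----------------------------------------------------
# Gamete-set enumeration with string pairs; independent of the crossprod
# route inside the package.
oracle_pair_compatible <- function(x, y) {
  both <- !is.na(x) & !is.na(y)
  length(unique(paste(x[both], y[both]))) < 4
}

oracle_incompat_matrix <- function(H) {
  m <- ncol(H)
  inc <- matrix(FALSE, m, m)
  if (m < 2) return(inc)
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      inc[i, j] <- inc[j, i] <- !oracle_pair_compatible(H[, i], H[, j])
    }
  }
  inc
}

# All maximal all-pairs-compatible contiguous intervals, by growing each
# start as far right as possible and keeping starts whose reach increases.
oracle_compatible_intervals <- function(H) {
  m <- ncol(H)
  inc <- oracle_incompat_matrix(H)
  reach <- integer(m)
  for (l in seq_len(m)) {
    r <- l
    while (r < m && !any(inc[l:r, r + 1])) r <- r + 1
    reach[l] <- r
  }
  keep <- c(TRUE, reach[-1] > reach[-m])
  tibble::tibble(start_index = which(keep), end_index = reach[keep])
}

# --- Per-base interval mask oracle -----------------------------------------
# Boolean vector of covered bases (1-based index b covers BED base b-1).
bed_mask <- function(x, chrom, len) {
  mask <- rep(FALSE, len)
  rows <- which(x$chrom == chrom)
  for (i in rows) {
    if (x$end[i] > x$start[i]) {
      mask[(x$start[i] + 1):min(x$end[i], len)] <- TRUE
    }
  }
  mask
}

mask_to_intervals <- function(mask, chrom) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
}

random_bed <- function(n, chroms, len, max_width = 500) {
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(len - max_width, n, replace = TRUE) - 1L
  ) |>
    dplyr::mutate(end = start + sample.int(max_width, n, replace = TRUE)) |>
    popgenpipe::sort_intervals()
}

# Reference-allele dosage matrix straight from GT strings (records x inds).
oracle_ref_dosage <- function(vcf, inds) {
  t(vapply(seq_len(nrow(vcf)), function(i) {
    vapply(inds, function(s) {
      g <- sub(":.*$", "", vcf[[s]][i])
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_integer_)
      sum(al == "0")
    }, integer(1))
  }, integer(length(inds))))
}
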