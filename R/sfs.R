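# Multi-dimensional site frequency spectra -----------------------------------
#
# The joint SFS over k populations is a k-dimensional integer array with
# dimension sizes 2*n_i + 1 (n_i diploid individuals in population i); cell
# (d_1, ..., d_k) counts the sites whose derived-allele copy number in
# population i is d_i. With no ancestral-allele annotation the spectrum
# should be folded to minor-allele counts.

#' Build the joint site frequency spectrum
#'
#' Tallies biallelic SNPs over the model's populations. The derived allele
#' is read from the `AA` INFO key when present (matched against REF/ALT);
#' otherwise REF is treated as ancestral, with a warning — prefer
#' `polarization = "folded"` in that case. Sites with any missing genotype
#' among model individuals, non-SNP/multiallelic records, and (by default)
#' the monomorphic corner cells are skipped; all skip counts are reported.
#'
#' @param vcf A `vcf_tbl`.
#' @param model A `pop_model` whose individuals are all present in `vcf`.
#' @param polarization `"derived"` (default) or `"folded"` (build derived,
#'   then fold).
#' @param exclude_fixed Drop sites falling in the all-ancestral /
#'   all-derived corner cells? Default `TRUE`.
#' @return An `sfs_array`: integer array with `dim = 2*n_i + 1`, attributes
#'   `pops`, `n_hap`, `polarization`, and `skipped` (named counts:
#'   `multiallelic`, `missing`, `fixed`); `sum(sfs)` equals the number of
#'   tallied sites.
#' @export
build_sfs <- function(vcf, model, polarization = c("derived", "folded"),
                      exclude_fixed = TRUE) {
  polarization <- match.arg(polarization)
  if (length(model$pops) < 1) rlang::abort("empty model")
  inds <- model_individuals(model)
  missing_ind <- setdiff(inds, vcf_samples(vcf))
  if (length(missing_ind) > 0) {
    rlang::abort(paste0("model individuals absent: ", paste(missing_ind, collapse = ", ")))
  }
  n_hap <- model_sizes(model, ploidy = 2)
  dims <- unname(n_hap + 1L)
  arr <- array(0L, dim = dims)
  skipped <- c(multiallelic = 0L, missing = 0L, fixed = 0L)

  n_alt <- n_alt_alleles(vcf$alt)
  snp <- !is_indel_record(vcf$ref, vcf$alt)
  usable <- snp & n_alt == 1
  skipped[["multiallelic"]] <- sum(!usable)
  aa <- stringr::str_match(vcf$info, "(?:^|;)AA=([^;]+)")[, 2]
  warned <- FALSE
  for (i in which(usable)) {
    anc <- aa[i]
    alt1 <- strsplit(vcf$alt[i], ",", fixed = TRUE)[[1]][1]
    if (is.na(anc) || !(anc %in% c(vcf$ref[i], alt1))) {
      if (!warned && polarization == "derived") {
        rlang::warn("no usable AA annotation: treating REF as ancestral")
        warned <- TRUE
      }
      anc <- vcf$ref[i]
    }
    derived_is_alt <- anc == vcf$ref[i]
    d <- integer(length(model$pops))
    ok <- TRUE
    for (j in seq_along(model$pops)) {
      al <- record_alleles(vcf[i, ], model$pops[[j]])
      if (anyNA(al)) {
        ok <- FALSE
        break
      }
      n_altcopies <- sum(al > 0)
      d[j] <- if (derived_is_alt) n_altcopies else length(al) - n_altcopies
    }
    if (!ok) {
      skipped[["missing"]] <- skipped[["missing"]] + 1L
      next
    }
    if (exclude_fixed && (all(d == 0L) || all(d == n_hap))) {
      skipped[["fixed"]] <- skipped[["fixed"]] + 1L
      next
    }
    cell <- matrix(d + 1L, nrow = 1)
    arr[cell] <- arr[cell] + 1L
  }
  out <- structure(arr,
    pops = names(model$pops), n_hap = n_hap,
    polarization = "derived", skipped = skipped,
    class = "sfs_array"
  )
  if (polarization == "folded") out <- fold_sfs(out) else out
}

#' Fold a derived site frequency spectrum
#'
#' Merges each cell x with its complement 2n - x (component-wise): mass moves
#' to whichever of the pair has the smaller total derived count (ties by
#' lexicographically smaller index; self-complementary cells stay in place).
#' Total counts are preserved.
#'
#' @param s A derived-polarized `sfs_array`.
#' @return The folded `sfs_array`.
#' @export
fold_sfs <- function(s) {
  if (attr(s, "polarization") == "folded") rlang::abort("spectrum is already folded")
  n_hap <- attr(s, "n_hap")
  dims <- dim(s)
  if (is.null(dims)) dims <- length(s)
  idx <- as.matrix(expand.grid(lapply(dims, seq_len))) # 1-based cell indices
  d <- sweep(idx, 2, 1L) # derived counts
  comp <- sweep(-d, 2, n_hap, FUN = "+") # complements 2n - d
  tot <- rowSums(d)
  tot_c <- rowSums(comp)
  out <- array(0L, dim = dims)
  lex_le <- function(a, b) {
    for (j in seq_along(a)) {
      if (a[j] < b[j]) return(TRUE)
      if (a[j] > b[j]) return(FALSE)
    }
    TRUE
  }
  for (r in seq_len(nrow(idx))) {
    keep <- tot[r] < tot_c[r] ||
      (tot[r] == tot_c[r] && lex_le(d[r, ], comp[r, ]))
    if (!keep) next
    cell <- matrix(idx[r, ], nrow = 1)
    ccell <- matrix(comp[r, ] + 1L, nrow = 1)
    val <- s[cell]
    if (!all(idx[r, ] == comp[r, ] + 1L)) val <- val + s[ccell]
    out[cell] <- val
  }
  structure(out,
    pops = attr(s, "pops"), n_hap = n_hap,
    polarization = "folded", skipped = attr(s, "skipped"),
    class = "sfs_array"
  )
}

#' @export
print.sfs_array <- function(x, ...) {
  cat(sprintf(
    "%s site frequency spectrum over %s (%s sites tallied)\n",
    attr(x, "polarization"),
    paste(sprintf("%s[0..%d]", attr(x, "pops"), attr(x, "n_hap")), collapse = " x "),
    sum(x)
  ))
  print(unclass(array(as.integer(x), dim = dim(x) %||% length(x))))
  invisible(x)
}

#' Tidy a site frequency spectrum
#'
#' @param x An `sfs_array`.
#' @param ... Unused.
#' @return A tibble with one derived-count column per population and `n`
#'   (cell count).
#' @export
tidy.sfs_array <- function(x, ...) {
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  grid <- expand.grid(lapply(dims, seq_len))
  names(grid) <- attr(x, "pops")
  out <- tibble::as_tibble(grid - 1L)
  out$n <- as.integer(x)[as.vector(seq_len(prod(dims)))]
  out
}

#' Write an SFS in the fastsimcoal2 observed-SFS dialect
#'
#' One population: a `"1 observations"` line, a labelled header
#' (`d0_0 ... d0_2n`) and one line of counts. Two populations: the joint
#' matrix with rows labelled by the second population (`d1_*`) and columns by
#' the first (`d0_*`), matching the jointDAFpop file style. Higher dimensions
#' go through [write_sfs_flat()].
#'
#' @param s An `sfs_array` with one or two populations.
#' @param path Output path (name it in the `*DAFpop*.obs` /
#'   `*jointDAFpop1_0.obs` style expected by fastsimcoal2).
#' @param maf Label columns as minor-allele (`MAF`) counts instead of `DAF`?
#'   Labels only; fold with [fold_sfs()] first for true minor-allele counts.
#' @export
write_sfs_obs <- function(s, path, maf = FALSE) {
  n_hap <- attr(s, "n_hap")
  k <- length(n_hap)
  tag <- if (maf) "MAF" else "DAF"
  lines <- c("1 observations")
  if (k == 1) {
    lines <- c(
      lines,
      paste(sprintf("d0_%d", 0:n_hap[1]), collapse = "\t"),
      paste(as.integer(s), collapse = "\t")
    )
  } else if (k == 2) {
    header <- paste(c("", sprintf("d0_%d", 0:n_hap[1])), collapse = "\t")
    lines <- c(lines, header)
    for (j in 0:n_hap[2]) {
      row <- vapply(0:n_hap[1], function(i) s[matrix(c(i, j) + 1L, nrow = 1)], integer(1))
      lines <- c(lines, paste(c(sprintf("d1_%d", j), row), collapse = "\t"))
    }
  } else {
    rlang::abort("obs dialect covers 1 or 2 populations; use write_sfs_flat()")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an SFS as a flat text dump
#'
#' A header line `#dims: n1 n2 ...` followed by the flattened counts (first
#' dimension fastest, R array order) on one line.
#'
#' @param s An `sfs_array`.
#' @param path Output path.
#' @export
write_sfs_flat <- function(s, path) {
  dims <- dim(s)
  if (is.null(dims)) dims <- length(s)
  writeLines(c(
    paste("#dims:", paste(dims, collapse = " ")),
    paste(as.integer(s), collapse = " ")
  ), path)
  invisible(path)
}
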