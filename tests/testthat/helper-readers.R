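# Paired readers for the exporter round-trip tests. Each one re-parses a
# written file into plain structures so counts/sequences/genotypes can be
# compared with the in-memory source.

read_ima_file <- function(path) {
  lines <- readLines(path)
  title <- lines[1]
  n_pops <- as.integer(lines[2])
  pops <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  tree <- lines[4]
  n_loci <- as.integer(lines[5])
  loci <- list()
  i <- 6
  for (li in seq_len(n_loci)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    name <- hdr[1]
    counts <- as.integer(hdr[2:(1 + n_pops)])
    len <- as.integer(hdr[2 + n_pops])
    mut <- hdr[3 + n_pops]
    inh <- as.numeric(hdr[4 + n_pops])
    n_seq <- sum(counts)
    seq_lines <- lines[(i + 1):(i + n_seq)]
    loci[[li]] <- list(
      name = name, counts = counts, length = len, mut = mut, inh = inh,
      seq_names = trimws(substr(seq_lines, 1, 10)),
      seqs = substring(seq_lines, 11)
    )
    i <- i + 1 + n_seq
  }
  list(title = title, n_pops = n_pops, pops = pops, tree = tree,
       n_loci = n_loci, loci = loci)
}

read_gphocs_file <- function(path) {
  lines <- readLines(path)
  n_loci <- as.integer(lines[1])
  loci <- list()
  i <- 2
  for (li in seq_len(n_loci)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    n_seq <- as.integer(hdr[2])
    sl <- strsplit(trimws(lines[(i + 1):(i + n_seq)]), "\\s+")
    loci[[li]] <- list(
      name = hdr[1], n_seq = n_seq, length = as.integer(hdr[3]),
      seq_names = vapply(sl, `[[`, character(1), 1),
      seqs = vapply(sl, `[[`, character(1), 2)
    )
    i <- i + 1 + n_seq
  }
  list(n_loci = n_loci, loci = loci)
}

read_treemix_file <- function(path) {
  lines <- readLines(path)
  pops <- strsplit(lines[1], " ")[[1]]
  body <- lines[-1]
  ref <- alt <- matrix(0L, nrow = length(body), ncol = length(pops))
  for (i in seq_along(body)) {
    cells <- strsplit(strsplit(body[i], " ")[[1]], ",")
    ref[i, ] <- as.integer(vapply(cells, `[[`, character(1), 1))
    alt[i, ] <- as.integer(vapply(cells, `[[`, character(1), 2))
  }
  list(pops = pops, ref = ref, alt = alt)
}

read_eigenstrat_files <- function(prefix) {
  geno_lines <- readLines(paste0(prefix, ".geno"))
  geno <- t(vapply(strsplit(geno_lines, ""), as.integer,
                   integer(nchar(geno_lines[1]))))
  snp <- utils::read.table(paste0(prefix, ".snp"), sep = "\t",
                           col.names = c("id", "chrom", "gen", "pos", "a1", "a2"))
  ind <- utils::read.table(paste0(prefix, ".ind"), sep = "\t",
                           col.names = c("id", "sex", "pop"))
  list(geno = geno, snp = snp, ind = ind)
}

read_ped_files <- function(prefix) {
  ped <- strsplit(readLines(paste0(prefix, ".ped")), " ")
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "id", "gen", "pos"))
  n_snp <- nrow(map)
  geno <- lapply(ped, function(p) {
    al <- as.integer(p[-(1:6)])
    matrix(al, ncol = 2, byrow = TRUE)
  })
  list(
    fid = vapply(ped, `[[`, character(1), 1),
    iid = vapply(ped, `[[`, character(1), 2),
    geno = geno, map = map, n_snp = n_snp
  )
}
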