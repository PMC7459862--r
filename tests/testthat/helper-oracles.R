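# Shared fixtures and independent oracles. The oracles deliberately use
# brute-force enumeration / naive scanning so they share no code path with
# the implementation they check.

make_db <- function(seqs, ids = paste0("s", seq_along(seqs)), ...) {
  seq_db(ids, seqs, ...)
}

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# random IUPAC string with a bounded number of degenerate positions
rand_iupac <- function(len, n_degen = 3,
                       degen_pool = c("R", "Y", "S", "W", "K", "M",
                                      "B", "D", "H", "V", "N")) {
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  pos <- sample(len, min(n_degen, len))
  ch[pos] <- sample(degen_pool, length(pos), replace = TRUE)
  paste(ch, collapse = "")
}

# oracle: count distinct expansions by explicit cartesian enumeration
oracle_n_expansions <- function(iupac) {
  sets <- lapply(strsplit(iupac, "")[[1]], iupac_base_set)
  nrow(unique(expand.grid(sets, stringsAsFactors = FALSE)))
}

# oracle: forward-strand match starts of a degenerate primer by exact
# fixed-string search of every expansion
oracle_fwd_starts <- function(iupac, seq) {
  L <- nchar(iupac)
  n <- nchar(seq) - L + 1L
  if (n < 1L) return(integer(0))
  windows <- substring(seq, 1:n, L:nchar(seq))
  sort(unique(unlist(lapply(expand_iupac(iupac), function(e) {
    which(windows == e)
  }))))
}

oracle_sites <- function(iupac, seq) {
  fwd <- oracle_fwd_starts(iupac, seq)
  rev <- oracle_fwd_starts(revcomp_iupac(iupac), seq)
  list(fwd = fwd, rev = rev)
}

# oracle: GC count min/max by brute force over expansions
oracle_gc_counts <- function(iupac) {
  gc <- vapply(expand_iupac(iupac), function(e) {
    sum(strsplit(e, "")[[1]] %in% c("G", "C"))
  }, 1L)
  c(min(gc), max(gc))
}

# oracle: minimum hairpin free energy by naive triple-loop enumeration of
# every (stem start, stem end, stem length) decomposition, recomputing each
# stack sum from scratch with the same published parameter tables
oracle_fold_dG <- function(seq, cond = folding_conditions()) {
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  temp_k <- cond$fold_temp + 273.15
  na_eq <- (cond$na + 120 * sqrt(cond$mg)) / 1000
  salt_ds <- if (na_eq > 0) 0.368 * log(na_eq) else 0
  dg <- kmerprimer:::.NN_DH - temp_k * (kmerprimer:::.NN_DS + salt_ds) / 1000
  loop_pen <- function(n) kmerprimer:::.loop_dG(n, temp_k)
  best <- Inf
  if (L >= 9) {
    for (i in 1:(L - 8)) for (j in (i + 8):L) {
      smax <- floor((j - i + 1 - 3) / 2)
      if (smax < 3) next
      for (s in 3:smax) {
        ok <- all(vapply(0:(s - 1), function(t) comp[[b[i + t]]] == b[j - t],
                         TRUE))
        if (!ok) next
        e <- sum(vapply(0:(s - 2), function(t) {
          dg[[paste0(b[i + t], b[i + t + 1])]]
        }, 1.0))
        loop <- (j - s) - (i + s) + 1
        best <- min(best, e + loop_pen(loop))
      }
    }
  }
  if (is.infinite(best)) 0.0 else best
}

# the planted motifs used across design/coverage tests: low self-overlap,
# chosen once
FWD_MOTIF <- "ATGACCGTTAGCTTGACCAT"
REV_PRIMER <- "TGGAACCTTGAGCAATGGTC"
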