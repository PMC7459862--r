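# Synthetic sequence-database generator with planted conserved motifs.
# Provides exact ground truth (which sequence carries which motif variant at
# which coordinate) for validating every stage of the design pipeline.

#' Specify a planted conserved motif
#'
#' Describes a motif to plant into a synthetic database: a consensus
#' sequence carried by a fraction of sequences, optional single-base
#' variants carried by sub-fractions of the carriers (variant carrier sets
#' are disjoint, so every carrier differs from the consensus at no more than
#' one position), an optional placement distribution, and an optional paired
#' downstream motif for amplicon tests. The paired motif is given as the
#' reverse primer sequence (5'->3' as synthesized); its reverse complement
#' is planted on the sense strand so that the product length (forward motif
#' start to planted reverse-complement end, inclusive) equals `amplicon`.
#'
#' @param consensus Motif consensus, A/C/G/T.
#' @param carrier_fraction Fraction of database sequences carrying the
#'   motif; the realized carrier count is `round(fraction * n_seqs)`.
#' @param variants Optional data frame with columns `pos`, `alt`,
#'   `fraction`: position (1-based within the motif), alternative base, and
#'   fraction of carriers receiving it.
#' @param placement Optional `c(mean, sd)` of a normal placement of the
#'   motif start (clamped to feasible positions); uniform when `NULL`.
#' @param paired Optional `list(consensus = <reverse primer>, amplicon =
#'   <product length in bp>)`.
#' @return A `planted_motif` specification.
#' @export
planted_motif <- function(consensus, carrier_fraction = 1, variants = NULL,
                          placement = NULL, paired = NULL) {
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus)) stop("consensus must be plain A/C/G/T")
  if (carrier_fraction <= 0 || carrier_fraction > 1) {
    stop("carrier_fraction must be in (0, 1]")
  }
  if (!is.null(variants)) {
    stopifnot(all(c("pos", "alt", "fraction") %in% names(variants)))
    if (any(variants$pos < 1 | variants$pos > nchar(consensus))) {
      stop("variant position outside consensus")
    }
    if (any(variants$fraction <= 0 | variants$fraction > 1)) {
      stop("variant fractions must be in (0, 1]")
    }
    cons_ch <- strsplit(consensus, "", fixed = TRUE)[[1]]
    if (any(toupper(variants$alt) == cons_ch[variants$pos])) {
      stop("variant base equals the consensus base")
    }
  }
  if (!is.null(paired)) {
    stopifnot(all(c("consensus", "amplicon") %in% names(paired)))
    paired$consensus <- toupper(paired$consensus)
    paired$amplicon <- as.integer(paired$amplicon)
    if (grepl("[^ACGT]", paired$consensus)) stop("paired consensus must be A/C/G/T")
    if (paired$amplicon < nchar(consensus) + nchar(paired$consensus)) {
      stop("amplicon too short to hold both motifs without overlap")
    }
  }
  structure(list(consensus = consensus, carrier_fraction = carrier_fraction,
                 variants = variants, placement = placement, paired = paired),
            class = "planted_motif")
}

#' Generate a synthetic sequence database with planted motifs
#'
#' Backgrounds are i.i.d. uniform A/C/G/T of lengths drawn uniformly from
#' `seq_len_range`; each motif is planted per its [planted_motif()]
#' specification. Output is deterministic for a fixed seed, and the global
#' RNG state is restored on exit.
#'
#' @param n_seqs Number of sequences.
#' @param seq_len_range `c(min, max)` sequence length in bp.
#' @param motifs List of [planted_motif()] specifications.
#' @param seed RNG seed.
#' @return `list(db = <seq_db>, manifest = <data frame>)`; the manifest has
#'   one row per planted motif instance: `id`, `motif` (index), `start`
#'   (1-based), `variant` (`"consensus"` or `"<pos><alt>"`), `instance` (the
#'   planted string) and `start_rev` (start of the planted paired motif, NA
#'   when unpaired).
#' @export
generate_database <- function(n_seqs, seq_len_range = c(600, 800),
                              motifs = list(), seed = 1) {
  stopifnot(n_seqs >= 1, length(seq_len_range) == 2,
            seq_len_range[1] <= seq_len_range[2])
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)

  lens <- if (seq_len_range[1] == seq_len_range[2]) {
    rep(seq_len_range[1], n_seqs)
  } else {
    sample(seq.int(seq_len_range[1], seq_len_range[2]), n_seqs, replace = TRUE)
  }
  seqs <- vapply(lens, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, "")

  man <- list()
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    mlen <- nchar(m$consensus)
    span <- if (is.null(m$paired)) mlen else m$paired$amplicon
    if (span > min(lens)) {
      stop("motif ", mi, " (span ", span, " bp) does not fit the shortest ",
           "sequence (", min(lens), " bp)")
    }
    ncar <- round(m$carrier_fraction * n_seqs)
    carriers <- sort(sample.int(n_seqs, ncar))

    # disjoint variant carrier assignment, deterministic counts
    variant_of <- stats::setNames(rep("consensus", ncar), carriers)
    inst_of <- stats::setNames(rep(m$consensus, ncar), carriers)
    if (!is.null(m$variants)) {
      pool <- carriers
      for (vi in seq_len(nrow(m$variants))) {
        nv <- round(m$variants$fraction[vi] * ncar)
        if (nv > length(pool)) stop("variant fractions exceed carrier pool")
        vs <- if (nv > 0) sort(sample(pool, nv)) else integer(0)
        pool <- setdiff(pool, vs)
        for (ci in vs) {
          inst <- inst_of[[as.character(ci)]]
          substr(inst, m$variants$pos[vi], m$variants$pos[vi]) <- toupper(m$variants$alt[vi])
          inst_of[[as.character(ci)]] <- inst
          variant_of[[as.character(ci)]] <- paste0(m$variants$pos[vi],
                                                   toupper(m$variants$alt[vi]))
        }
      }
    }

    rc_paired <- if (is.null(m$paired)) NULL else revcomp_iupac(m$paired$consensus)
    for (ci in carriers) {
      key <- as.character(ci)
      max_start <- lens[ci] - span + 1L
      p0 <- if (is.null(m$placement)) {
        sample.int(max_start, 1L)
      } else {
        as.integer(min(max(1, round(stats::rnorm(1, m$placement[1],
                                                 m$placement[2]))),
                       max_start))
      }
      substr(seqs[ci], p0, p0 + mlen - 1L) <- inst_of[[key]]
      start_rev <- NA_integer_
      if (!is.null(rc_paired)) {
        start_rev <- as.integer(p0 + span - nchar(rc_paired))
        substr(seqs[ci], start_rev, p0 + span - 1L) <- rc_paired
      }
      man[[length(man) + 1L]] <- data.frame(
        id = sprintf("seq%04d", ci), motif = mi, start = p0,
        variant = variant_of[[key]], instance = inst_of[[key]],
        start_rev = start_rev, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(man) > 0) do.call(rbind, man) else
    data.frame(id = character(0), motif = integer(0), start = integer(0),
               variant = character(0), instance = character(0),
               start_rev = integer(0), stringsAsFactors = FALSE)
  list(db = seq_db(sprintf("seq%04d", seq_len(n_seqs)), seqs),
       manifest = manifest)
}
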