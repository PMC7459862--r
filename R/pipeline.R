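# Pipeline configuration and the end-to-end run: preprocessing -> design ->
# properties -> pairing -> coverage/specificity -> taxonomy summaries.
# Every report embeds the full parameter set, and the analysis path is
# RNG-free, so a rerun with the same inputs is byte-identical.

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the design pipeline with the platform
#' defaults: primer length 18-20 bp, product length 200-500 bp, minimum
#' acceptable primer coverage 0.2, k-mer merge overlap 10 bases, folding
#' temperature 57 degrees Celsius, Mg++ 20 mM, Na+ 0 mM.
#'
#' @param primer_len_min,primer_len_max Primer (k-mer) length range in bp.
#' @param product_min,product_max Amplification product length bounds in bp.
#' @param min_coverage Minimum acceptable coverage of an output primer
#'   (proportion); values above 1 are allowed and simply yield no output.
#' @param overlap Merge k-mers overlapping by more than this many bases.
#' @param fold_temp DNA folding temperature, degrees Celsius.
#' @param mg,na Mg++ and Na+ concentrations, mM.
#' @param variant_min_fraction Minimum per-sequence hit fraction for a
#'   Hamming-1 variant to be folded into a primer.
#' @param max_degeneracy Cap on primer degeneracy during variant absorption.
#' @param max_mismatches Mismatch budget of the in-silico matcher.
#' @param top_n Number of high-frequency k-mer ranks considered per k.
#' @param seed RNG seed (used only by the synthetic-data generator).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(primer_len_min = 18, primer_len_max = 20,
                            product_min = 200, product_max = 500,
                            min_coverage = 0.2, overlap = 10,
                            fold_temp = 57, mg = 20, na = 0,
                            variant_min_fraction = 0.01, max_degeneracy = 64,
                            max_mismatches = 0, top_n = 30, seed = 1) {
  cfg <- list(primer_len_min = as.integer(primer_len_min),
              primer_len_max = as.integer(primer_len_max),
              product_min = as.integer(product_min),
              product_max = as.integer(product_max),
              min_coverage = min_coverage, overlap = overlap,
              fold_temp = fold_temp, mg = mg, na = na,
              variant_min_fraction = variant_min_fraction,
              max_degeneracy = as.integer(max_degeneracy),
              max_mismatches = as.integer(max_mismatches),
              top_n = as.integer(top_n), seed = as.integer(seed))
  if (cfg$primer_len_min < 1 || cfg$primer_len_min > cfg$primer_len_max) {
    stop("need 1 <= primer_len_min <= primer_len_max")
  }
  if (cfg$product_min < 1 || cfg$product_min > cfg$product_max) {
    stop("need 1 <= product_min <= product_max")
  }
  if (cfg$min_coverage < 0) stop("min_coverage must be >= 0")
  if (cfg$overlap < 1) stop("overlap must be >= 1")
  if (cfg$variant_min_fraction < 0 || cfg$variant_min_fraction > 1) {
    stop("variant_min_fraction must be in [0, 1]")
  }
  if (cfg$max_degeneracy < 1) stop("max_degeneracy must be >= 1")
  if (cfg$max_mismatches < 0) stop("max_mismatches must be >= 0")
  if (cfg$top_n < 1) stop("top_n must be >= 1")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unspecified keys keep
#' their defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

.param_lines <- function(config) {
  c(sprintf("# kmerprimer %s",
            as.character(utils::packageVersion("kmerprimer"))),
    sprintf("# %s: %s", names(config),
            vapply(unclass(config), format, "")))
}

.write_report <- function(df, path, param_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(param_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# percent with two decimals, Table style
.pct <- function(x) sprintf("%.2f", round_half_up(100 * x))

#' Run the full primer design and assessment pipeline
#'
#' Executes preprocessing (exact-duplicate removal), degenerate primer
#' design, property calculation, pairing by in-silico product length,
#' off-target specificity, and (when annotation is available) covered
#' taxonomy and phenotype summaries. All reports are tab-separated with the
#' full parameter set embedded as leading comment lines.
#'
#' @param target_fasta Path to the target gene FASTA database.
#' @param offtarget_fastas Named character vector of off-target FASTA paths
#'   (names become specificity column suffixes).
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param prefix Primer name prefix, typically the gene name.
#' @param phenotype_map Optional path to a phenotype TSV
#'   (see [read_phenotype_map()]).
#' @param rank Taxonomic rank for the coverage breakdown.
#' @return Invisibly, a list with elements `db`, `primers`, `properties`,
#'   `pairs`, `taxonomy`, `phenotype`, and `files` (paths written).
#' @export
run_pipeline <- function(target_fasta, offtarget_fastas = character(0),
                         config = pipeline_config(), outdir,
                         prefix = "primer", phenotype_map = NULL,
                         rank = "phylum") {
  db <- dedupe_exact(load_fasta(target_fasta))
  offdbs <- lapply(offtarget_fastas, load_fasta)
  if (length(offdbs) > 0 && is.null(names(offdbs))) {
    names(offdbs) <- paste0("offtarget", seq_along(offdbs))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- .param_lines(config)
  files <- character(0)

  primers <- design_primers(db, config, prefix)

  if (length(primers) == 0L) {
    warning("empty design output: no primer reached min_coverage")
    empty <- data.frame(name = character(0), iupac_seq = character(0))
    f <- file.path(outdir, "primers.tsv")
    .write_report(empty, f, params)
    return(invisible(list(db = db, primers = list(),
                          properties = empty, pairs = NULL,
                          taxonomy = NULL, phenotype = NULL, files = f)))
  }

  cond <- folding_conditions(config$fold_temp, config$mg, config$na)
  props <- primer_table(primers)
  rng <- lapply(primers, function(p) {
    g <- gc_range(p); tm <- tm_range(p); dg <- dG_range(p, cond)
    c(g[["min"]], g[["max"]], tm[["min"]], tm[["max"]], dg[["min"]], dg[["max"]])
  })
  rng <- do.call(rbind, rng)
  colnames(rng) <- c("gc_min", "gc_max", "tm_min", "tm_max", "dg_min", "dg_max")
  props <- cbind(props, as.data.frame(rng))
  props$coverage_pct <- .pct(props$coverage)
  for (nm in names(offdbs)) {
    props[[paste0("specificity_", nm)]] <-
      .pct(vapply(primers, specificity, 1.0, offtarget_db = offdbs[[nm]],
                  max_mismatches = config$max_mismatches))
  }
  f_primers <- file.path(outdir, "primers.tsv")
  .write_report(props[, setdiff(names(props), "coverage")], f_primers, params)
  files <- c(files, f_primers)

  pairs <- NULL
  top_covered <- covered_ids(primers[[1]], db, config$max_mismatches)
  if (length(primers) >= 2L) {
    pairs <- pair_and_report(primers, db, config$product_min,
                             config$product_max, config$max_mismatches,
                             rev_sense = TRUE)
    pairs_out <- pairs[, c("fwd", "rev", "fwd_seq", "rev_seq", "n_covered",
                           "product_length_mode")]
    pairs_out$pair_coverage_pct <- .pct(pairs$pair_coverage)
    by_name <- stats::setNames(primers, vapply(primers, function(p) p$name, ""))
    for (nm in names(offdbs)) {
      pairs_out[[paste0("specificity_", nm)]] <- .pct(vapply(
        seq_len(nrow(pairs)), function(i) {
          specificity(list(by_name[[pairs$fwd[i]]], by_name[[pairs$rev[i]]]),
                      offdbs[[nm]], config$max_mismatches,
                      config$product_min, config$product_max,
                      rev_sense = TRUE)
        }, 1.0))
    }
    f_pairs <- file.path(outdir, "pairs.tsv")
    .write_report(pairs_out, f_pairs, params)
    files <- c(files, f_pairs)
    if (pairs$pair_coverage[1] > 0) top_covered <- pairs$covered[[1]]
  }

  taxonomy <- phenotype <- NULL
  if (!all(vapply(db$lineage, is.null, TRUE))) {
    taxonomy <- breakdown_by_rank(db, top_covered, rank)
    f_tax <- file.path(outdir, paste0("taxonomy_", attr(taxonomy, "axis"), ".tsv"))
    .write_report(taxonomy, f_tax, params)
    files <- c(files, f_tax)
    if (!is.null(phenotype_map)) {
      pm <- read_phenotype_map(phenotype_map)
      phenotype <- list(oxygen = breakdown_by_phenotype(db, top_covered, pm, "oxygen"),
                        gram = breakdown_by_phenotype(db, top_covered, pm, "gram"))
      for (ax in names(phenotype)) {
        f_ph <- file.path(outdir, paste0("phenotype_", ax, ".tsv"))
        .write_report(phenotype[[ax]], f_ph, params)
        files <- c(files, f_ph)
      }
    }
  }

  invisible(list(db = db, primers = primers, properties = props,
                 pairs = pairs, taxonomy = taxonomy, phenotype = phenotype,
                 files = files))
}
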