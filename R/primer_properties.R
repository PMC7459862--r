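# Primer property calculations. GC% and Tm are reported as min/max ranges
# over the non-degenerate expansions of a primer, computed directly from
# per-position IUPAC set membership (no enumeration needed). Self-folding
# free energy uses a transparent nearest-neighbor hairpin model.

# round half away from zero, matching fixed-point table style
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

property_range <- function(min_val, max_val, units = "") {
  structure(c(min = min_val, max = max_val), units = units,
            class = c("property_range", "numeric"))
}

#' @export
print.property_range <- function(x, ...) {
  cat(sprintf("%.2f-%.2f %s\n", x[["min"]], x[["max"]], attr(x, "units")))
  invisible(x)
}

# (forced, possible) G/C position counts for an IUPAC string
.gc_bounds <- function(iupac) {
  sets <- .IUPAC_SETS[.iupac_chars(iupac)]
  forced <- vapply(sets, function(b) all(b %in% c("G", "C")), TRUE)
  possible <- vapply(sets, function(b) any(b %in% c("G", "C")), TRUE)
  c(sum(forced), sum(possible))
}

#' GC-content range of a degenerate primer
#'
#' GC% = (G + C) / primer length, as a percentage. The minimum counts only
#' positions whose ambiguity set is entirely G/C; the maximum counts every
#' position whose set contains G or C. This equals the brute-force min/max
#' over all expansions.
#'
#' @param p IUPAC string or `degenerate_primer`.
#' @return A `property_range` (percent, rounded half-up to 2 decimals).
#' @examples
#' gc_range("TTYTAYGACTGGTAYKSYGA")  # 30.00-55.00
#' @export
gc_range <- function(p) {
  s <- as_iupac(p)
  L <- nchar(s)
  b <- .gc_bounds(s)
  property_range(round_half_up(100 * b[1] / L),
                 round_half_up(100 * b[2] / L), "%")
}

#' Annealing-temperature range of a degenerate primer
#'
#' For primers of length <= 20 bp the Wallace rule is applied per expansion:
#' Tm = 4(G + C) + 2(A + T). For longer primers
#' Tm = 62.3 + 0.41 * GC% - 500 / length (GC% on the 0-100 scale). Both
#' rules are monotone in the G+C count, so the range follows from the
#' set-membership GC bounds.
#'
#' @param p IUPAC string or `degenerate_primer`.
#' @return A `property_range` in degrees Celsius (2 decimals).
#' @examples
#' tm_range("TTYTAYGACTGGTAYKSYGA")  # 52.00-62.00
#' @export
tm_range <- function(p) {
  s <- as_iupac(p)
  L <- nchar(s)
  b <- .gc_bounds(s)
  if (L <= 20) {
    tm <- 4 * b + 2 * (L - b)
  } else {
    tm <- 62.3 + 0.41 * (100 * b / L) - 500 / L
  }
  property_range(round_half_up(tm[1]), round_half_up(tm[2]), "°C")
}

#' PCR folding conditions
#'
#' @param fold_temp Folding temperature in degrees Celsius.
#' @param mg Mg++ concentration in mM.
#' @param na Na+ concentration in mM.
#' @return A `folding_conditions` list.
#' @export
folding_conditions <- function(fold_temp = 57, mg = 20, na = 0) {
  if (fold_temp <= 0) stop("fold_temp must be > 0 (°C)")
  if (mg < 0 || na < 0) stop("ionic concentrations must be >= 0")
  structure(list(fold_temp = fold_temp, mg = mg, na = na),
            class = "folding_conditions")
}

# Unified nearest-neighbor stack parameters (SantaLucia 1998), 1 M NaCl.
# Keyed by the 5'->3' top-strand dimer; dH kcal/mol, dS cal/(mol K).
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

# Hairpin-loop free-energy increments at 37 C (kcal/mol) by loop size,
# with Jacobson-Stockmayer extrapolation between/beyond tabulated sizes.
.LOOP_SIZES <- c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30)
.LOOP_DG37 <- c(3.5, 3.5, 3.3, 4.0, 4.1, 4.1, 4.2, 4.3, 4.5, 4.6, 4.7,
                4.8, 4.9, 5.0, 5.1)
.R_KCAL <- 0.0019872

.loop_dG <- function(n, temp_k) {
  i <- findInterval(n, .LOOP_SIZES)
  base_n <- .LOOP_SIZES[i]
  g37 <- .LOOP_DG37[i]
  if (n > base_n) g37 <- g37 + 1.75 * .R_KCAL * 310.15 * log(n / base_n)
  # the loop penalty is entropic: scale linearly with absolute temperature
  g37 * temp_k / 310.15
}

#' Self-folding free energy of a primer
#'
#' Minimum free energy over all hairpin structures with stem length >= 3
#' Watson-Crick pairs and loop length >= 3, scored by nearest-neighbor stack
#' energies dG = dH - T dS at the configured folding temperature plus a
#' loop-size penalty. When Na+ or Mg++ is nonzero a sodium-equivalent
#' entropy correction of 0.368 ln[Na+eq] cal/(mol K) per stack is applied
#' (Na+eq in M, with 1 mM Mg++ counted as 120 sqrt(mM) monovalent). Strongly
#' negative values indicate self-structure that can inhibit PCR.
#'
#' @param seq A non-degenerate DNA string (A/C/G/T), length >= 8.
#' @param cond A [folding_conditions()].
#' @return Free energy in kcal/mol; 0.0 when no qualifying hairpin exists
#'   (including sequences shorter than 8 bp, for which no stem-3/loop-3
#'   hairpin is geometrically possible).
#' @examples
#' fold_dG("GCGCGTTTTCGCGC") < 0
#' @export
fold_dG <- function(seq, cond = folding_conditions()) {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACGT]", seq)) stop("fold_dG requires a non-degenerate A/C/G/T sequence")
  L <- nchar(seq)
  if (L < 8L) {
    message("sequence shorter than 8 bp: no hairpin possible, dG = 0")
    return(0.0)
  }
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wc <- function(i, j) comp[[b[i]]] == b[j]
  temp_k <- cond$fold_temp + 273.15
  na_eq <- (cond$na + 120 * sqrt(cond$mg)) / 1000  # mM -> M
  salt_ds <- if (na_eq > 0) 0.368 * log(na_eq) else 0
  stack_dg <- .NN_DH - temp_k * (.NN_DS + salt_ds) / 1000

  best <- Inf
  # (a, bp) is the innermost (loop-closing) base pair of a stem
  for (a in seq_len(L - 4L)) {
    for (bp in seq.int(a + 4L, L)) {
      if (!wc(a, bp)) next
      loop_len <- bp - a - 1L
      e <- 0
      s <- 1L
      i <- a; j <- bp
      while (i - 1L >= 1L && j + 1L <= L && wc(i - 1L, j + 1L)) {
        e <- e + stack_dg[[paste0(b[i - 1L], b[i])]]
        i <- i - 1L; j <- j + 1L; s <- s + 1L
        if (s >= 3L) {
          cand <- e + .loop_dG(loop_len, temp_k)
          if (cand < best) best <- cand
        }
      }
    }
  }
  if (is.infinite(best)) 0.0 else unname(best)
}

#' Self-folding free-energy range of a degenerate primer
#'
#' Min/max of [fold_dG()] over all non-degenerate expansions.
#'
#' @param p IUPAC string or `degenerate_primer` (degeneracy within the
#'   expansion cap).
#' @param cond A [folding_conditions()].
#' @param max_degeneracy Expansion cap passed to [expand_iupac()].
#' @return A `property_range` in kcal/mol (2 decimals).
#' @export
dG_range <- function(p, cond = folding_conditions(), max_degeneracy = 1024) {
  exps <- expand_iupac(p, max_degeneracy)
  vals <- vapply(exps, fold_dG, 1.0, cond = cond)
  property_range(round_half_up(min(vals)), round_half_up(max(vals)),
                 "kcal/mol")
}
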