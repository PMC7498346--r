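#' Hybridization conditions
#'
#' Buffer and assay conditions under which duplex stability is evaluated.
#' Defaults follow common probe-design practice for small-RNA in situ
#' hybridization: 50 mM monovalent sodium, no magnesium, 25 degC assay
#' temperature. The strand concentration used in the two-state Tm formula
#' defaults to 0.25 uM (a common vendor convention).
#'
#' @param sodium_mM Monovalent cation concentration (mM), > 0 unless
#'   magnesium is supplied.
#' @param magnesium_mM Divalent Mg2+ concentration (mM), folded into an
#'   equivalent sodium concentration for the salt correction.
#' @param temperature_C Assay temperature (degC); carried as metadata.
#' @param oligo_uM Total strand concentration (uM) for the Tm formula.
#' @return A list of class `hybridization_conditions`.
#' @export
hybridization_conditions <- function(sodium_mM = 50, magnesium_mM = 0,
                                     temperature_C = 25, oligo_uM = 0.25) {
  if (sodium_mM < 0 || magnesium_mM < 0) {
    stop("ion concentrations must be >= 0", call. = FALSE)
  }
  if (oligo_uM <= 0) stop("oligo_uM must be > 0", call. = FALSE)
  structure(list(sodium_mM = sodium_mM, magnesium_mM = magnesium_mM,
                 temperature_C = temperature_C, oligo_uM = oligo_uM),
            class = "hybridization_conditions")
}

# two-state Tm result container; dG37 is derived so the triple is always
# internally consistent
.thermo_result <- function(tm_C, dH, dS, mode = "nn") {
  structure(list(tm_C = tm_C, dH = dH, dS = dS,
                 dG37 = dH - 310.15 * dS / 1000, mode = mode),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("Tm %.2f degC  (dH %.1f kcal/mol, dS %.1f cal/mol/K, dG37 %.2f kcal/mol; %s)\n",
              x$tm_C, x$dH, x$dS, x$dG37, x$mode))
  invisible(x)
}

# equivalent monovalent concentration in mol/L
.na_equivalent_M <- function(cond, params) {
  (cond$sodium_mM + params$mg_equivalent_factor * sqrt(cond$magnesium_mM)) / 1000
}

.R_GAS <- 1.987204  # cal/(mol K)

# raw nearest-neighbor sums (no salt correction): list(dH, dS)
.nn_sums <- function(bases, params) {
  n <- length(bases)
  stacks <- paste0(bases[-n], bases[-1])
  dH <- sum(params$dH[stacks])
  dS <- sum(params$dS[stacks])
  for (term in bases[c(1, n)]) {
    key <- if (term %in% c("G", "C")) "GC" else "AT"
    dH <- dH + params$init_dH[[key]]
    dS <- dS + params$init_dS[[key]]
  }
  list(dH = dH, dS = dS)
}

# Tm (degC) from summed dH/dS with salt-corrected entropy
.tm_from_sums <- function(dH, dS, n, cond, params) {
  na_M <- .na_equivalent_M(cond, params)
  if (na_M <= 0) {
    stop("unsupported condition: zero monovalent-equivalent salt", call. = FALSE)
  }
  dS_salt <- dS + params$salt_factor * (n - 1) * log(na_M)
  ct <- cond$oligo_uM * 1e-6
  tm <- 1000 * dH / (dS_salt + .R_GAS * log(ct / 4)) - 273.15
  list(tm_C = tm, dS_salt = dS_salt)
}

#' Nearest-neighbor duplex thermodynamics
#'
#' Predicts the melting temperature of a DNA oligo against its perfect
#' complement with the unified nearest-neighbor model: dH and dS are summed
#' over dinucleotide stacks plus terminal initiation terms, the entropy is
#' corrected for monovalent salt
#' (`dS' = dS + 0.368 (N-1) ln[Na+]`, Mg2+ folded in as equivalent sodium),
#' and `Tm = 1000 dH / (dS' + R ln(Ct/4)) - 273.15`.
#'
#' @param seq DNA sequence, length >= 8 (the two-state model is unreliable
#'   below that).
#' @param cond [hybridization_conditions()].
#' @param params [thermo_params()].
#' @return A `thermo_result` with `tm_C`, `dH` (kcal/mol), salt-corrected
#'   `dS` (cal/(mol K)) and `dG37` (kcal/mol).
#' @export
nn_thermo <- function(seq, cond = hybridization_conditions(),
                      params = thermo_params()) {
  seq <- toupper(seq)
  .check_alphabet(seq, "DNA")
  n <- nchar(seq)
  if (n < 8) stop("sequence too short for nearest-neighbor Tm (< 8 nt)", call. = FALSE)
  bases <- .bases(seq)
  sums <- .nn_sums(bases, params)
  tm <- .tm_from_sums(sums$dH, sums$dS, n, cond, params)
  .thermo_result(tm$tm_C, sums$dH, tm$dS_salt, mode = "nn")
}

#' LNA-adjusted melting temperature
#'
#' Adjusts the nearest-neighbor Tm of a DNA backbone for locked-nucleic-acid
#' (LNA) substitutions at the given positions. Two modes:
#' \describe{
#'   \item{approximate}{adds a configured per-base Tm increment for each LNA
#'     position to the DNA-only Tm; fast, used to rank the exhaustive LNA
#'     placement enumeration.}
#'   \item{refined}{re-runs the nearest-neighbor sum with perturbed dH/dS for
#'     each stack whose 5' base is LNA-modified where the configured
#'     `lna_stacks` table provides values, falling back to the additive
#'     increment for positions it does not cover (the terminal 3' base, or
#'     missing table entries). The mode actually used is recorded in the
#'     result.}
#' }
#' All shipped adjustments are stabilizing, so Tm is non-decreasing in the
#' number of LNA positions.
#'
#' @param seq DNA backbone sequence.
#' @param positions Integer vector of 1-based LNA positions within `seq`
#'   (unique, in bounds). May be empty, in which case the result equals
#'   [nn_thermo()].
#' @param cond,params See [nn_thermo()].
#' @param mode `"approximate"` (default) or `"refined"`.
#' @return A `thermo_result`; `$mode` is `"lna_approximate"` or
#'   `"lna_refined"`.
#' @export
lna_tm <- function(seq, positions = integer(0),
                   cond = hybridization_conditions(),
                   mode = c("approximate", "refined"),
                   params = thermo_params()) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  .check_alphabet(seq, "DNA")
  n <- nchar(seq)
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && (min(positions) < 1L || max(positions) > n)) {
    stop("LNA mask position out of range for backbone", call. = FALSE)
  }
  bases <- .bases(seq)
  if (mode == "approximate") {
    base <- nn_thermo(seq, cond, params)
    tm <- base$tm_C + sum(params$lna_increments[bases[positions]])
    out <- .thermo_result(tm, base$dH, base$dS, mode = "lna_approximate")
    return(out)
  }
  sums <- .nn_sums(bases, params)
  dH <- sums$dH
  dS <- sums$dS
  extra <- 0
  for (p in positions) {
    st <- if (p < n) paste0(bases[p], bases[p + 1]) else NA_character_
    if (!is.na(st) && !is.na(params$lna_ddH[st])) {
      dH <- dH + params$lna_ddH[[st]]
      dS <- dS + params$lna_ddS[[st]]
    } else {
      extra <- extra + params$lna_increments[[bases[p]]]
    }
  }
  tm <- .tm_from_sums(dH, dS, n, cond, params)
  .thermo_result(tm$tm_C + extra, dH, tm$dS_salt, mode = "lna_refined")
}

# duplex/hairpin structure container
.duplex_structure <- function(offset, runs, dG) {
  structure(list(offset = offset, paired_runs = runs, dG = dG),
            class = "duplex_structure")
}

#' @export
print.duplex_structure <- function(x, ...) {
  cat(sprintf("dG %.2f kcal/mol, %d paired run(s)%s\n", x$dG,
              nrow(x$paired_runs),
              if (is.na(x$offset)) "" else sprintf(", offset %d", x$offset)))
  invisible(x)
}

#' Self-dimer screen
#'
#' Scans every ungapped antiparallel alignment of a sequence against a second
#' copy of itself, scores Watson-Crick complementary runs by summing
#' nearest-neighbor stack dG37 (runs of length 1 carry no stack and score 0),
#' and returns the most stable alignment. Used to reject probe candidates
#' that would titrate themselves out of solution.
#'
#' @param seq DNA sequence, length >= 4.
#' @param params [thermo_params()].
#' @return A `duplex_structure`: `offset` is the alignment register `k`
#'   (position i on one strand pairs position `k - i + 2` on the other,
#'   1-based), `paired_runs` a data.frame of `(start, length)` runs with
#'   length >= 2, and `dG` the stack-sum free energy (kcal/mol, <= 0; 0 when
#'   no pairing run of length >= 2 exists, with `offset = NA`).
#' @export
self_dimer <- function(seq, params = thermo_params()) {
  seq <- toupper(seq)
  .check_alphabet(seq, "DNA")
  n <- nchar(seq)
  if (n < 4) stop("sequence too short for self-dimer scan (< 4 nt)", call. = FALSE)
  b <- .bases(seq)
  comp <- .comp_bases(b)
  stack_dG <- params$dG37
  best <- list(dG = 0, offset = NA_integer_,
               runs = data.frame(start = integer(0), length = integer(0)))
  for (k in 0:(2 * n - 2)) {            # i + j = k, 0-based
    i <- max(0L, k - n + 1L):min(k, n - 1L)
    paired <- b[i + 1L] == comp[k - i + 1L]
    if (!any(paired)) next
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= 2L
    if (!any(keep)) next
    dG_k <- 0
    runs <- data.frame(start = integer(0), length = integer(0))
    for (j in which(keep)) {
      i0 <- i[starts[j]]                 # 0-based position in seq
      L <- r$lengths[j]
      st <- paste0(b[(i0 + 1L):(i0 + L - 1L)], b[(i0 + 2L):(i0 + L)])
      dG_k <- dG_k + sum(stack_dG[st])
      runs <- rbind(runs, data.frame(start = i0 + 1L, length = L))
    }
    if (dG_k < best$dG) best <- list(dG = dG_k, offset = k, runs = runs)
  }
  .duplex_structure(best$offset, best$runs, best$dG)
}

#' Hairpin screen
#'
#' Single-stem stem-loop scan: every placement of a stem of length >= 2
#' enclosing a loop of at least `min_loop` unpaired bases is scored as the
#' sum of its nearest-neighbor stack dG37 plus a flat loop penalty
#' (configured `loop_penalty`, default +3 kcal/mol). The most stable
#' placement is returned; structures that do not reach dG < 0 report 0.
#' This is a screening-grade ranking, not a partition-function fold.
#'
#' @param seq DNA sequence, length >= 4 + `min_loop`.
#' @param min_loop Minimum loop length in nt (default 3).
#' @param params [thermo_params()].
#' @return A `duplex_structure`: `paired_runs` holds the two stem arms as
#'   `(start, length)` rows (1-based), `offset` the loop length, `dG` the
#'   stem stack sum plus loop penalty (or 0 for no viable stem, `offset`
#'   `NA`).
#' @export
hairpin <- function(seq, min_loop = 3, params = thermo_params()) {
  seq <- toupper(seq)
  .check_alphabet(seq, "DNA")
  n <- nchar(seq)
  if (n < 4 + min_loop) {
    stop(sprintf("sequence too short for a hairpin with min_loop %d", min_loop),
         call. = FALSE)
  }
  b <- .bases(seq)
  comp <- .comp_bases(b)
  stack_dG <- params$dG37
  best <- list(dG = 0, a = NA, bpos = NA, L = NA)
  for (a in 1:(n - min_loop - 3)) {
    for (bp in (a + min_loop + 3):n) {   # outermost pair (a, bp), 1-based
      if (b[a] != comp[bp]) next
      Lmax <- 1L
      while (a + Lmax < bp - Lmax &&
             (bp - Lmax) - (a + Lmax) - 1L >= min_loop &&
             b[a + Lmax] == comp[bp - Lmax]) {
        Lmax <- Lmax + 1L
      }
      if (Lmax < 2L) next
      st <- paste0(b[a:(a + Lmax - 2L)], b[(a + 1L):(a + Lmax - 1L)])
      dG <- sum(stack_dG[st]) + params$loop_penalty
      if (dG < best$dG) best <- list(dG = dG, a = a, bpos = bp, L = Lmax)
    }
  }
  if (is.na(best$a)) {
    return(.duplex_structure(NA_integer_,
                             data.frame(start = integer(0), length = integer(0)), 0))
  }
  runs <- data.frame(start = c(best$a, best$bpos - best$L + 1L),
                     length = c(best$L, best$L))
  loop <- (best$bpos - best$L) - (best$a + best$L) + 1L
  .duplex_structure(loop, runs, best$dG)
}
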