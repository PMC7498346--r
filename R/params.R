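#' Load the thermodynamic parameter set
#'
#' Reads the nearest-neighbor stack table, duplex initiation terms, salt
#' correction constants, LNA adjustment tables and the hairpin loop penalty
#' from a YAML file. The package ships a default set
#' (`inst/extdata/thermo_params.yml`, unified DNA/DNA nearest-neighbor
#' parameters); pass `path` to use a calibrated table of your own with the
#' same layout.
#'
#' @param path Path to a YAML parameter file, or `NULL` for the shipped
#'   defaults.
#' @return A list of class `thermo_params` with elements `dH`, `dS` (named
#'   vectors over all 16 dinucleotide stacks, kcal/mol and cal/(mol K)),
#'   `dG37` (derived, kcal/mol), `init_dH`/`init_dS` (named by terminal pair
#'   `"AT"`/`"GC"`), `salt_factor`, `mg_equivalent_factor`,
#'   `lna_increments`, `lna_ddH`/`lna_ddS`, and `loop_penalty`.
#' @export
thermo_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "thermo_params.yml", package = "srnapaint")
  }
  raw <- yaml::read_yaml(path)
  stacks <- raw$nn_stacks
  dH <- dS <- structure(numeric(0), names = character(0))
  for (nm in names(stacks)) {
    dH[[nm]] <- stacks[[nm]][1]
    dS[[nm]] <- stacks[[nm]][2]
  }
  # fill reverse-complement equivalents (stack of the complementary strand)
  for (nm in names(stacks)) {
    rcnm <- .revcomp_str(nm)
    if (is.na(dH[rcnm])) {
      dH[[rcnm]] <- dH[[nm]]
      dS[[rcnm]] <- dS[[nm]]
    }
  }
  all16 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  if (!all(all16 %in% names(dH))) {
    stop("nn_stacks incomplete: missing ", paste(setdiff(all16, names(dH)), collapse = ", "))
  }
  dH <- dH[all16]
  dS <- dS[all16]
  lna <- raw$lna_stacks
  lna_ddH <- lna_ddS <- structure(rep(NA_real_, 16), names = all16)
  for (nm in names(lna)) {
    lna_ddH[[nm]] <- lna[[nm]][1]
    lna_ddS[[nm]] <- lna[[nm]][2]
  }
  inc <- unlist(raw$lna_increments)
  if (any(inc < 0)) stop("lna_increments must be non-negative")
  out <- list(
    dH = dH, dS = dS, dG37 = dH - 310.15 * dS / 1000,
    init_dH = c(AT = raw$initiation$AT[1], GC = raw$initiation$GC[1]),
    init_dS = c(AT = raw$initiation$AT[2], GC = raw$initiation$GC[2]),
    salt_factor = raw$salt$entropy_factor,
    mg_equivalent_factor = raw$salt$mg_equivalent_factor,
    lna_increments = inc[c("A", "C", "G", "T")],
    lna_ddH = lna_ddH, lna_ddS = lna_ddS,
    loop_penalty = raw$loop_penalty
  )
  class(out) <- "thermo_params"
  out
}

#' Load a docking-strand library
#'
#' A docking strand is the short oligo appended to the probe; its reverse
#' complement is the dye-carrying imager strand perfused during imaging. The
#' shipped default library (`inst/extdata/docking_synthetic.yml`) contains 13
#' synthetic orthogonal 9-nt P-series sequences intended for testing and as a
#' template; replace it with your own validated sequences for real designs.
#'
#' @param path YAML file with a top-level `docking_strands: {id: sequence}`
#'   mapping, or `NULL` for the shipped synthetic defaults.
#' @return A named list of `docking_strand` objects, each with elements `id`,
#'   `sequence` and `imager` (= reverse complement of `sequence`).
#' @export
docking_strands <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "docking_synthetic.yml", package = "srnapaint")
  }
  raw <- yaml::read_yaml(path)$docking_strands
  out <- lapply(names(raw), function(id) docking_strand(id, raw[[id]]))
  names(out) <- names(raw)
  out
}

#' Construct a single docking strand
#'
#' @param id Label, e.g. `"P0"`.
#' @param sequence DNA sequence of the docking strand (5'->3').
#' @return A `docking_strand` object; `$imager` holds the reverse complement
#'   (the imager strand, dye at the 3' end by convention).
#' @export
docking_strand <- function(id, sequence) {
  sequence <- toupper(sequence)
  .check_alphabet(sequence, "DNA")
  structure(
    list(id = id, sequence = sequence, imager = reverse_complement(sequence)),
    class = "docking_strand"
  )
}

#' @export
print.docking_strand <- function(x, ...) {
  cat(sprintf("docking strand %s: 5'-%s-3' (imager 5'-%s-3')\n",
              x$id, x$sequence, x$imager))
  invisible(x)
}
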