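#' Enumerate probe backbone candidates for a small-RNA target
#'
#' The probe backbone is a 19-22 nt contiguous window of the reverse
#' complement of the target small RNA. Every window is evaluated with the
#' DNA-only nearest-neighbor Tm and flagged against the ceiling (default
#' 60 degC); candidates are returned longest-first, then by lowest Tm, so
#' the preferred backbone (longest window with comfortably sub-ceiling Tm)
#' sorts first. If no window is under the ceiling all windows are returned
#' with `under_ceiling = FALSE` and downstream steps fall back to the
#' minimum-Tm window with a warning.
#'
#' @param target Target small-RNA sequence (RNA or DNA alphabet, >= 19 nt).
#' @param cond [hybridization_conditions()].
#' @param tm_ceiling_C Backbone Tm ceiling in degC (default 60).
#' @param params [thermo_params()].
#' @return A data.frame with columns `sequence`, `start` (1-based offset in
#'   the reverse-complemented target), `length`, `tm_C`, `under_ceiling`.
#' @export
select_backbones <- function(target, cond = hybridization_conditions(),
                             tm_ceiling_C = 60, params = thermo_params()) {
  rc <- toupper(reverse_complement(target))
  n <- nchar(rc)
  if (n < 19) stop("target shorter than 19 nt: no backbone window fits", call. = FALSE)
  rows <- list()
  for (len in 19:22) {
    if (len > n) next
    for (start in 1:(n - len + 1)) {
      s <- substr(rc, start, start + len - 1)
      rows[[length(rows) + 1L]] <-
        data.frame(sequence = s, start = start, length = len,
                   tm_C = nn_thermo(s, cond, params)$tm_C)
    }
  }
  df <- do.call(rbind, rows)
  df$under_ceiling <- df$tm_C < tm_ceiling_C
  df <- df[order(-df$length, df$tm_C, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Rank backbone/LNA-mask candidates by approximate Tm
#'
#' Takes the top `k` (backbone window, LNA mask) pairs by approximate
#' LNA-adjusted Tm ([lna_tm()] mode `"approximate"`). Ties break
#' deterministically: earlier backbone start, then lexicographically smaller
#' mask. This is the reference (materialized) implementation; the full
#' designer uses an equivalent compiled enumeration that never materializes
#' the candidate stream.
#'
#' @param candidates List of `list(backbone = <row of select_backbones()>,
#'   positions = <integer mask>)` pairs, or an iterator as produced by code
#'   combining [select_backbones()] and [enumerate_lna_masks()].
#' @param cond,params See [nn_thermo()].
#' @param k Number of candidates to keep (default 200).
#' @return A data.frame with `backbone`, `start`, `positions` (list column),
#'   `tm_approx_C`, sorted best-first.
#' @export
shortlist <- function(candidates, cond = hybridization_conditions(), k = 200,
                      params = thermo_params()) {
  if (is.function(candidates)) {
    candidates <- .drain_masks(candidates)
  }
  if (length(candidates) == 0) stop("no candidates to shortlist", call. = FALSE)
  tm <- vapply(candidates, function(cc) {
    lna_tm(cc$backbone$sequence, cc$positions, cond, "approximate", params)$tm_C
  }, numeric(1))
  start <- vapply(candidates, function(cc) as.integer(cc$backbone$start), integer(1))
  masku <- vapply(candidates, function(cc) {
    paste(sprintf("%03d", cc$positions), collapse = "")
  }, character(1))
  ord <- order(-tm, start, masku)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(
    backbone = vapply(candidates[ord], function(cc) cc$backbone$sequence, character(1)),
    start = start[ord],
    positions = I(lapply(candidates[ord], `[[`, "positions")),
    tm_approx_C = tm[ord]
  )
}

#' Assemble a full sRNA-PAINT probe
#'
#' Concatenates backbone, linker and docking strand 5'->3' into the full
#' orderable oligo. LNA positions refer to the backbone only (the linker and
#' docking strand never hybridize the target).
#'
#' @param backbone A row of [select_backbones()] output (or any list with
#'   `sequence` and `start`).
#' @param positions 1-based LNA positions within the backbone.
#' @param linker Linker sequence joining backbone and docking strand
#'   (default `"tattcgt"`).
#' @param docking A [docking_strand()].
#' @return A `srna_probe` list: `backbone`, `lna_positions`, `linker`,
#'   `docking`, `full_sequence`, `imager`, plus score slots (`tm_approx_C`,
#'   `tm_refined_C`, `dimer_dG`, `hairpin_dG`, `rank`) filled by
#'   [screen_probe()] / [design_probes()].
#' @export
assemble_probe <- function(backbone, positions, linker = "tattcgt", docking) {
  if (!nzchar(linker)) stop("linker must be non-empty", call. = FALSE)
  .check_alphabet(linker, "DNA")
  if (!inherits(docking, "docking_strand")) {
    stop("docking must be a docking_strand object", call. = FALSE)
  }
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && max(positions) > nchar(backbone$sequence)) {
    stop("LNA positions must lie within the backbone", call. = FALSE)
  }
  structure(list(
    backbone = backbone,
    lna_positions = positions,
    linker = linker,
    docking = docking,
    full_sequence = paste0(backbone$sequence, linker, docking$sequence),
    imager = docking$imager,
    tm_approx_C = NA_real_, tm_refined_C = NA_real_,
    dimer_dG = NA_real_, hairpin_dG = NA_real_, rank = NA_integer_
  ), class = "srna_probe")
}

#' Score an assembled probe
#'
#' Fills the thermodynamic screening scores: self-dimer and hairpin dG of the
#' full oligo (backbone + linker + docking strand), and the refined
#' LNA-adjusted Tm of the backbone alone (only the backbone hybridizes the
#' target, so the docking strand never changes the probe's Tm).
#'
#' @param probe A `srna_probe` from [assemble_probe()].
#' @param cond,params See [nn_thermo()].
#' @return The probe with `dimer_dG`, `hairpin_dG`, `tm_approx_C` and
#'   `tm_refined_C` filled.
#' @export
screen_probe <- function(probe, cond = hybridization_conditions(),
                         params = thermo_params()) {
  full <- toupper(probe$full_sequence)
  probe$dimer_dG <- self_dimer(full, params)$dG
  probe$hairpin_dG <- hairpin(full, params = params)$dG
  probe$tm_approx_C <- lna_tm(probe$backbone$sequence, probe$lna_positions,
                              cond, "approximate", params)$tm_C
  probe$tm_refined_C <- lna_tm(probe$backbone$sequence, probe$lna_positions,
                               cond, "refined", params)$tm_C
  probe
}

# display convention: backbone lowercase with LNA bases as +X, linker
# lowercase, docking strand uppercase
.display_sequence <- function(probe) {
  b <- .bases(tolower(probe$backbone$sequence))
  for (p in probe$lna_positions) b[p] <- paste0("+", toupper(b[p]))
  paste0(paste(b, collapse = ""), tolower(probe$linker),
         toupper(probe$docking$sequence))
}

#' @export
print.srna_probe <- function(x, ...) {
  cat(sprintf("%s  [%s rank %s]\n", .display_sequence(x), x$docking$id,
              ifelse(is.na(x$rank), "-", x$rank)))
  cat(sprintf("  backbone %d nt @%d, %d LNA; Tm approx %.1f / refined %.1f degC; dimer %.2f, hairpin %.2f kcal/mol\n",
              x$backbone$length, x$backbone$start, length(x$lna_positions),
              x$tm_approx_C, x$tm_refined_C, x$dimer_dG, x$hairpin_dG))
  invisible(x)
}

#' Design sRNA-PAINT probes for a target small RNA
#'
#' The full design pipeline: reverse-complement the target and enumerate
#' 19-22 nt backbone windows under the Tm ceiling
#' ([select_backbones()]); exhaust all LNA placements of sizes 5-9 passing
#' the design rules over those windows and keep the top `shortlist_k` by
#' approximate LNA Tm (compiled streaming enumeration); compute the refined
#' Tm for the shortlist; assemble each survivor with the linker and each
#' requested docking strand ([assemble_probe()]); screen self-dimer and
#' hairpin dG of the full oligo ([screen_probe()]); drop candidates more
#' stable than the dG thresholds; and return the `top_n` per docking strand
#' sorted by refined Tm. Fully deterministic for fixed inputs and
#' configuration.
#'
#' @param target Target small-RNA sequence (RNA or DNA, typically 21-24 nt).
#' @param cond [hybridization_conditions()].
#' @param docking_ids Character vector of docking-strand ids to design for.
#' @param top_n Probes returned per docking strand (default 10).
#' @param linker Linker sequence (default `"tattcgt"`).
#' @param sizes LNA mask sizes to enumerate (default `5:9`, must lie within
#'   the validation range).
#' @param shortlist_k Size of the approximate-Tm shortlist (default 200).
#' @param tm_ceiling_C Backbone Tm ceiling (default 60 degC).
#' @param dimer_dG_min,hairpin_dG_min Rejection thresholds in kcal/mol:
#'   candidates with dimer dG below -9 or hairpin dG below -3 are dropped
#'   (configurable).
#' @param docking_library Named list from [docking_strands()].
#' @param params [thermo_params()].
#' @param target_id Label carried into the order sheet.
#' @return A `srna_probe_design` object: per-docking-id lists of ranked
#'   `srna_probe` objects (possibly empty, with a warning recorded in
#'   `$warnings`), convertible with [as.data.frame()] and
#'   [write_order_sheet()].
#' @export
design_probes <- function(target, cond = hybridization_conditions(),
                          docking_ids = c("P0", "P1"), top_n = 10,
                          linker = "tattcgt", sizes = 5:9, shortlist_k = 200,
                          tm_ceiling_C = 60,
                          dimer_dG_min = -9, hairpin_dG_min = -3,
                          docking_library = docking_strands(),
                          params = thermo_params(), target_id = "target") {
  missing_ids <- setdiff(docking_ids, names(docking_library))
  if (length(missing_ids)) {
    stop("unknown docking strand id(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  if (any(sizes < 5L) || any(sizes > 9L)) {
    stop("LNA mask sizes must lie within [5, 9]", call. = FALSE)
  }
  warnings <- character(0)
  backbones <- select_backbones(target, cond, tm_ceiling_C, params)
  if (!any(backbones$under_ceiling)) {
    warnings <- c(warnings, sprintf(
      "no backbone window has Tm < %g degC; proceeding with the minimum-Tm window",
      tm_ceiling_C))
    backbones <- backbones[which.min(backbones$tm_C), , drop = FALSE]
  } else {
    backbones <- backbones[backbones$under_ceiling, , drop = FALSE]
  }

  # compiled streaming enumeration + top-k by approximate Tm
  binput <- lapply(seq_len(nrow(backbones)), function(i) {
    bases <- .bases(backbones$sequence[i])
    list(inc = unname(params$lna_increments[bases]),
         gc = bases %in% c("G", "C"),
         tm = backbones$tm_C[i],
         start = as.integer(backbones$start[i]))
  })
  top <- cpp_shortlist(binput, as.integer(sizes), as.integer(shortlist_k),
                       4L, 3L)
  if (length(top$b_idx) == 0) stop("no valid LNA mask for any backbone", call. = FALSE)

  shortlisted <- lapply(seq_along(top$b_idx), function(j) {
    bi <- top$b_idx[j]
    list(backbone = as.list(backbones[bi, , drop = FALSE]),
         positions = top$positions[[j]],
         tm_approx_C = top$tm[j])
  })

  # screening scores depend only on (backbone window, docking strand), not on
  # the LNA mask (LNA does not change base identity) -> cache per pair
  screen_cache <- new.env(parent = emptyenv())
  get_screen <- function(backbone_seq, dock) {
    key <- paste0(backbone_seq, "|", dock$id)
    if (is.null(screen_cache[[key]])) {
      full <- toupper(paste0(backbone_seq, linker, dock$sequence))
      screen_cache[[key]] <- list(dimer = self_dimer(full, params)$dG,
                                  hairpin = hairpin(full, params = params)$dG)
    }
    screen_cache[[key]]
  }

  tm_refined <- vapply(shortlisted, function(cc) {
    lna_tm(cc$backbone$sequence, cc$positions, cond, "refined", params)$tm_C
  }, numeric(1))

  probes <- list()
  for (id in docking_ids) {
    dock <- docking_library[[id]]
    scr <- lapply(shortlisted, function(cc) get_screen(cc$backbone$sequence, dock))
    dimer <- vapply(scr, `[[`, numeric(1), "dimer")
    hp <- vapply(scr, `[[`, numeric(1), "hairpin")
    keep <- which(dimer >= dimer_dG_min & hp >= hairpin_dG_min)
    if (length(keep) == 0) {
      warnings <- c(warnings, sprintf(
        "no candidate for docking strand %s survives the dG thresholds", id))
      probes[[id]] <- list()
      next
    }
    masku <- vapply(shortlisted[keep], function(cc) {
      paste(sprintf("%03d", cc$positions), collapse = "")
    }, character(1))
    starts <- vapply(shortlisted[keep], function(cc) cc$backbone$start, numeric(1))
    ord <- keep[order(-tm_refined[keep], starts, masku)]
    ord <- ord[seq_len(min(top_n, length(ord)))]
    probes[[id]] <- lapply(seq_along(ord), function(r) {
      cc <- shortlisted[[ord[r]]]
      p <- assemble_probe(cc$backbone, cc$positions, linker, dock)
      p$tm_approx_C <- cc$tm_approx_C
      p$tm_refined_C <- tm_refined[ord[r]]
      p$dimer_dG <- dimer[ord[r]]
      p$hairpin_dG <- hp[ord[r]]
      p$rank <- r
      p
    })
  }
  structure(list(target_id = target_id, target = target, probes = probes,
                 warnings = warnings,
                 config = list(linker = linker, top_n = top_n,
                               shortlist_k = shortlist_k, sizes = sizes,
                               tm_ceiling_C = tm_ceiling_C,
                               dimer_dG_min = dimer_dG_min,
                               hairpin_dG_min = hairpin_dG_min)),
            class = "srna_probe_design")
}

#' @export
print.srna_probe_design <- function(x, ...) {
  cat(sprintf("sRNA-PAINT probe design for '%s' (%d nt target)\n",
              x$target_id, nchar(x$target)))
  for (id in names(x$probes)) {
    cat(sprintf("docking %s: %d probe(s)\n", id, length(x$probes[[id]])))
    for (p in x$probes[[id]][seq_len(min(3, length(x$probes[[id]])))]) print(p)
  }
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Flatten a design into an order sheet
#'
#' One row per probe with the full orderable sequence (backbone lowercase,
#' LNA bases as `+N`, linker lowercase, docking strand uppercase), the
#' 1-based LNA positions, both Tm estimates, the screening dG values and the
#' imager strand to order alongside.
#'
#' @param x A `srna_probe_design`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return A data.frame.
#' @export
as.data.frame.srna_probe_design <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list()
  for (id in names(x$probes)) {
    for (p in x$probes[[id]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = x$target_id, docking_id = id, rank = p$rank,
        full_sequence = .display_sequence(p),
        backbone = p$backbone$sequence,
        lna_positions = paste(p$lna_positions, collapse = ","),
        tm_approx_C = p$tm_approx_C, tm_refined_C = p$tm_refined_C,
        dimer_dG = p$dimer_dG, hairpin_dG = p$hairpin_dG,
        imager_sequence = p$imager
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(target_id = character(0), docking_id = character(0),
                      rank = integer(0), full_sequence = character(0),
                      backbone = character(0), lna_positions = character(0),
                      tm_approx_C = numeric(0), tm_refined_C = numeric(0),
                      dimer_dG = numeric(0), hairpin_dG = numeric(0),
                      imager_sequence = character(0)))
  }
  do.call(rbind, rows)
}

#' Write a tab-separated order sheet
#'
#' @param design A `srna_probe_design` (or a list of them, concatenated).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_order_sheet <- function(design, path) {
  if (inherits(design, "srna_probe_design")) design <- list(design)
  df <- do.call(rbind, lapply(design, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read target sequences from a FASTA file
#'
#' @param path FASTA file of one or more small-RNA targets (RNA or DNA
#'   alphabet).
#' @return Named character vector of sequences.
#' @export
read_targets <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
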