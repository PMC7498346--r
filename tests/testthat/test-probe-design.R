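cond <- hybridization_conditions()

test_that("backbone windows cover all 19-22 nt offsets with correct flags and order", {
  # 24-nt target: 6 + 5 + 4 + 3 = 18 windows
  t24 <- paste(rep(c("A", "U"), 12), collapse = "")
  bb <- select_backbones(t24, cond)
  expect_equal(nrow(bb), 18)
  expect_equal(sort(unique(bb$length)), 19:22)
  # pure-AT windows all melt far below 60 C; preference is longest-first
  expect_true(all(bb$under_ceiling))
  expect_equal(bb$length[1], 22)
  expect_true(all(diff(bb$length) <= 0))
  # within the longest length, lowest Tm first
  l22 <- bb[bb$length == 22, ]
  expect_true(all(diff(l22$tm_C) >= 0))
  # 21-nt target cannot host a 22-mer
  t21 <- random_srna(21, 0.5, seed = 1)
  expect_false(22 %in% select_backbones(t21, cond)$length)
  expect_error(select_backbones("ACGUACGUACGUACGU", cond), "shorter")
  # windows are substrings of the reverse complement
  rc <- reverse_complement(t21)
  b21 <- select_backbones(t21, cond)
  for (i in seq_len(nrow(b21))) {
    expect_equal(substr(rc, b21$start[i], b21$start[i] + b21$length[i] - 1),
                 b21$sequence[i])
  }
})

test_that("LNA mask validation enforces size, run-length and G/C-run rules", {
  bb <- "ATGCATGCATGCATGCATGC"
  expect_true(validate_lna_mask(bb, c(1, 2, 3, 4, 6, 8, 10, 12))$ok)  # max run 4
  v <- validate_lna_mask(bb, c(1, 2, 3, 4, 5))
  expect_false(v$ok)
  expect_match(v$reason, "run of 5")
  v2 <- validate_lna_mask("GGGAATTAAATTAAATTAAA", c(1, 2, 3, 6, 8, 10))
  expect_false(v2$ok)
  expect_match(v2$reason, "G/C")
  # G/C run split by an A-position inside the same LNA stretch is fine
  expect_true(validate_lna_mask("GGAGGTATATATATATATAT", c(1, 2, 3, 4, 7, 9, 11, 13))$ok)
  expect_false(validate_lna_mask(bb, c(1, 3, 5, 7))$ok)   # size 4
  expect_error(validate_lna_mask(bb, 99), "bounds")
})

test_that("mask enumeration is exhaustive, lexicographic and filtered", {
  bb <- "ATATATATAT"   # 10 nt, no G/C rule can fire
  it <- enumerate_lna_masks(bb, sizes = c(5, 6), validate = FALSE)
  raw <- srnapaint:::.drain_masks(it)
  expect_length(raw, choose(10, 5) + choose(10, 6))
  # lexicographic order within a size
  expect_equal(raw[[1]], 1:5)
  expect_equal(raw[[2]], c(1, 2, 3, 4, 6))
  # validated stream equals brute-force filtering
  itv <- enumerate_lna_masks(bb, sizes = c(5, 6))
  valid <- srnapaint:::.drain_masks(itv)
  brute <- Filter(function(m) validate_lna_mask(bb, m)$ok, raw)
  expect_equal(valid, brute)
  expect_true(all(vapply(valid, function(m) validate_lna_mask(bb, m)$ok, logical(1))))
  expect_error(enumerate_lna_masks(bb, sizes = c(5, 11)), "backbone length")
})

test_that("compiled shortlist equals the materialized reference shortlist", {
  target <- random_srna(21, 0.4, seed = 8)
  bb <- select_backbones(target, cond)
  bb <- bb[bb$under_ceiling, ][1:2, ]   # two windows, size-5 masks only
  params <- thermo_params()
  cands <- list()
  for (i in 1:2) {
    masks <- srnapaint:::.drain_masks(enumerate_lna_masks(bb$sequence[i], sizes = 5))
    for (m in masks) {
      cands[[length(cands) + 1]] <- list(backbone = as.list(bb[i, ]), positions = m)
    }
  }
  ref <- shortlist(cands, cond, k = 25, params = params)
  binput <- lapply(1:2, function(i) {
    bases <- strsplit(bb$sequence[i], "")[[1]]
    list(inc = unname(params$lna_increments[bases]),
         gc = bases %in% c("G", "C"),
         tm = bb$tm_C[i], start = as.integer(bb$start[i]))
  })
  top <- srnapaint:::cpp_shortlist(binput, 5L, 25L, 4L, 3L)
  expect_equal(top$tm, ref$tm_approx_C, tolerance = 1e-9)
  expect_equal(bb$start[top$b_idx], ref$start)
  for (j in seq_along(top$positions)) {
    expect_equal(top$positions[[j]], ref$positions[[j]])
  }
  # shortlist contract: non-increasing scores, k capping
  expect_true(all(diff(ref$tm_approx_C) <= 1e-12))
  all_of_them <- shortlist(cands, cond, k = 1e7, params = params)
  expect_equal(nrow(all_of_them), length(cands))
  expect_error(shortlist(list(), cond), "no candidates")
})

test_that("probe assembly concatenates backbone-linker-docking and records the imager", {
  lib <- docking_strands()
  bb <- list(sequence = "ATGCATGCATGCATGCATGC", start = 1L, length = 20L)
  p <- assemble_probe(bb, c(1, 3, 5, 7, 9, 11, 13, 15), docking = lib$P0)
  expect_equal(nchar(p$full_sequence), 20 + 7 + 9)
  expect_equal(p$linker, "tattcgt")
  expect_equal(p$full_sequence, paste0(bb$sequence, "tattcgt", lib$P0$sequence))
  expect_equal(p$imager, reverse_complement(lib$P0$sequence))
  expect_error(assemble_probe(bb, 1:8, linker = "", docking = lib$P0), "non-empty")
  # screening scores equal direct thermo-module calls on the same strings
  ps <- screen_probe(p, cond)
  full <- toupper(p$full_sequence)
  expect_equal(ps$dimer_dG, self_dimer(full)$dG)
  expect_equal(ps$hairpin_dG, hairpin(full)$dG)
  expect_equal(ps$tm_refined_C,
               lna_tm(bb$sequence, p$lna_positions, cond, "refined")$tm_C)
})

test_that("full design equals a brute-force pipeline at reduced scale", {
  params <- thermo_params()
  lib <- docking_strands()
  total_probes <- 0
  for (seed in 21:24) {
    target <- random_srna(21, 0.45, seed = seed)
    d <- design_probes(target, cond, docking_ids = "P0", sizes = 5,
                       shortlist_k = 50, top_n = 5)
    # brute force: materialize every mask of every under-ceiling backbone
    bb <- select_backbones(target, cond)
    if (any(bb$under_ceiling)) bb <- bb[bb$under_ceiling, ]
    else bb <- bb[which.min(bb$tm_C), , drop = FALSE]
    cands <- list()
    for (i in seq_len(nrow(bb))) {
      for (m in srnapaint:::.drain_masks(enumerate_lna_masks(bb$sequence[i], sizes = 5))) {
        cands[[length(cands) + 1]] <- list(backbone = as.list(bb[i, ]), positions = m)
      }
    }
    short <- shortlist(cands, cond, k = 50, params = params)
    rows <- list()
    for (j in seq_len(nrow(short))) {
      full <- toupper(paste0(short$backbone[j], "tattcgt", lib$P0$sequence))
      dim_dG <- self_dimer(full, params)$dG
      hp_dG <- hairpin(full, params = params)$dG
      if (dim_dG >= -9 && hp_dG >= -3) {
        rows[[length(rows) + 1]] <- data.frame(
          backbone = short$backbone[j], start = short$start[j],
          mask = paste(short$positions[[j]], collapse = ","),
          masku = paste(sprintf("%03d", short$positions[[j]]), collapse = ""),
          tm_refined = lna_tm(short$backbone[j], short$positions[[j]], cond,
                              "refined", params)$tm_C,
          dimer = dim_dG, hairpin = hp_dG)
      }
    }
    got <- as.data.frame(d)
    if (length(rows) == 0) {
      expect_equal(nrow(got), 0)
      next
    }
    keep <- do.call(rbind, rows)
    keep <- keep[order(-keep$tm_refined, keep$start, keep$masku), ]
    keep <- keep[seq_len(min(5, nrow(keep))), ]
    total_probes <- total_probes + nrow(keep)
    expect_equal(nrow(got), nrow(keep))
    expect_equal(got$backbone, keep$backbone)
    expect_equal(got$lna_positions, keep$mask)
    expect_equal(got$tm_refined_C, keep$tm_refined, tolerance = 1e-9)
    expect_equal(got$dimer_dG, keep$dimer)
    expect_equal(got$hairpin_dG, keep$hairpin)
  }
  expect_gt(total_probes, 0)   # the comparison actually exercised probes
})

test_that("designs are deterministic and every emitted probe obeys the constraints", {
  lib <- docking_strands()
  for (seed in c(31, 32, 33)) {
    target <- random_srna(sample(21:24, 1), 0.5, seed = seed)
    d1 <- design_probes(target, cond, docking_ids = c("P0", "P4"))
    d2 <- design_probes(target, cond, docking_ids = c("P0", "P4"))
    expect_identical(as.data.frame(d1), as.data.frame(d2))
    for (id in names(d1$probes)) {
      probes <- d1$probes[[id]]
      expect_lte(length(probes), 10)
      tms <- vapply(probes, `[[`, numeric(1), "tm_refined_C")
      expect_true(all(diff(tms) <= 1e-9))   # rank monotone in refined Tm
      for (p in probes) {
        expect_true(p$backbone$length >= 19 && p$backbone$length <= 22)
        expect_true(length(p$lna_positions) >= 5 && length(p$lna_positions) <= 9)
        expect_true(validate_lna_mask(p$backbone$sequence, p$lna_positions)$ok)
        expect_equal(p$linker, "tattcgt")
        expect_true(p$docking$id %in% names(lib))
        expect_gte(p$dimer_dG, -9)
        expect_gte(p$hairpin_dG, -3)
      }
    }
  }
  expect_error(design_probes("ACGUACGUACGUACGUACGUA", cond, docking_ids = "P99"),
               "unknown docking")
})

test_that("order sheets round-trip through TSV with the LNA display convention", {
  target <- random_srna(22, 0.4, seed = 41)
  d <- design_probes(target, cond, docking_ids = "P0")
  df <- as.data.frame(d)
  if (nrow(df) > 0) {
    expect_true(all(grepl("^([acgt]|\\+[ACGT])+[acgt]{7}[ACGT]{9}$", df$full_sequence)))
    expect_equal(lengths(regmatches(df$full_sequence, gregexpr("\\+", df$full_sequence))),
                 lengths(strsplit(df$lna_positions, ",")))
  }
  tmp <- tempfile(fileext = ".tsv")
  write_order_sheet(d, tmp)
  back <- read.delim(tmp)
  expect_equal(nrow(back), nrow(df))
  unlink(tmp)
})
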