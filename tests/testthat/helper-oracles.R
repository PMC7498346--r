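# Independent reference implementations used to cross-check the package.
# These are deliberately written from first principles (own parameter copies,
# exhaustive enumeration) and stay independent of the code paths they check.

# --- nearest-neighbor Tm, hand-summed with an independently typed table ----
.o_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.o_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9)

oracle_nn_tm <- function(s, na_mM = 50, ct_uM = 0.25) {
  b <- strsplit(toupper(s), "")[[1]]
  n <- length(b)
  st <- paste0(b[-n], b[-1])
  H <- sum(.o_dH[st])
  S <- sum(.o_dS[st])
  for (e in b[c(1, n)]) {
    if (e %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  S <- S + 0.368 * (n - 1) * log(na_mM / 1000)
  1000 * H / (S + 1.987204 * log(ct_uM * 1e-6 / 4)) - 273.15
}

.o_dG37 <- .o_dH - 310.15 * .o_dS / 1000
.o_comp <- function(b) chartr("ACGT", "TGCA", b)

# --- brute-force self-dimer over every antiparallel alignment --------------
oracle_self_dimer <- function(s) {
  b <- strsplit(toupper(s), "")[[1]]
  n <- length(b)
  comp <- .o_comp(b)
  best <- 0
  for (k in 0:(2 * n - 2)) {
    dg <- 0
    run <- 0L
    run_start <- NA
    for (i in max(0, k - n + 1):min(k, n - 1)) {
      if (b[i + 1] == comp[k - i + 1]) {
        if (run > 0L && i > 0 && (k - i + 1) <= n) {
          # stack between this pair and the previous one in the run
          dg <- dg + .o_dG37[[paste0(b[i], b[i + 1])]]
        }
        run <- run + 1L
      } else {
        run <- 0L
      }
    }
    if (dg < best) best <- dg
  }
  best
}

# --- brute-force hairpin over every stem placement -------------------------
oracle_hairpin <- function(s, min_loop = 3, loop_penalty = 3.0) {
  b <- strsplit(toupper(s), "")[[1]]
  n <- length(b)
  comp <- .o_comp(b)
  best <- 0
  for (i in 1:n) for (L in 2:floor((n - min_loop) / 2)) {
    if (i + L - 1 > n || i + L + min_loop > n - L + 1) next
    for (j in (i + L + min_loop):(n - L + 1)) {
      ok <- all(vapply(0:(L - 1), function(t) b[i + t] == comp[j + L - 1 - t],
                       logical(1)))
      if (!ok) next
      dg <- sum(vapply(0:(L - 2), function(t) .o_dG37[[paste0(b[i + t], b[i + t + 1])]],
                       numeric(1))) + loop_penalty
      if (dg < best) best <- dg
    }
  }
  best
}

# --- brute-force DBSCAN via reachability closure ---------------------------
oracle_dbscan <- function(p, eps, minpts) {
  n <- nrow(p)
  d <- as.matrix(dist(p))
  nbr <- d <= eps
  core <- rowSums(nbr) >= minpts
  lab <- integer(n)
  # transitive closure of the core adjacency by boolean matrix powering
  adj <- nbr & outer(core, core, "&")
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || lab[i] != 0L) next
    cl <- cl + 1L
    lab[which(core & reach[i, ])] <- cl
  }
  for (i in which(!core)) {
    cand <- which(nbr[i, ] & core)
    if (length(cand)) lab[i] <- lab[cand[which.min(d[i, cand])]]
  }
  lab
}

# canonicalize a clustering: renumber clusters by smallest member index
canonical_labels <- function(lab) {
  out <- lab
  ids <- unique(lab[lab > 0])
  first <- vapply(ids, function(k) min(which(lab == k)), integer(1))
  remap <- ids[order(first)]
  for (r in seq_along(remap)) out[lab == remap[r]] <- r
  out
}

# random DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# small localization table from frame/coord vectors
loc_tab <- function(frame, x = 0, y = 0, photons = 1000, ...) {
  m <- length(frame)
  localization_table(frame, rep_len(x, m), rep_len(y, m),
                     rep_len(photons, m), ...)
}
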