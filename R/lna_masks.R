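#' Validate an LNA placement mask
#'
#' A mask is the set of backbone positions that carry locked-nucleic-acid
#' bases. Design rules: between 5 and 9 LNA bases, no stretch of more than 4
#' consecutive LNA positions, and no stretch of 3 or more consecutive LNA
#' positions that all carry G or C (G/C LNA runs over-stabilize and promote
#' self-structure).
#'
#' @param backbone DNA backbone sequence.
#' @param positions Integer vector of 1-based LNA positions (unique, within
#'   the backbone).
#' @param n_range Allowed mask size range, default `c(5, 9)`.
#' @param max_run Maximum allowed run of consecutive LNA positions (4).
#' @param gc_run Forbidden length of a consecutive all-G/C LNA stretch (3).
#' @return A list with `ok` (logical) and `reason` (`NULL` when valid, else a
#'   message naming the violated rule and its location).
#' @export
validate_lna_mask <- function(backbone, positions, n_range = c(5L, 9L),
                              max_run = 4L, gc_run = 3L) {
  backbone <- toupper(backbone)
  n <- nchar(backbone)
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && (min(positions) < 1L || max(positions) > n)) {
    stop("mask position out of backbone bounds", call. = FALSE)
  }
  k <- length(positions)
  if (k < n_range[1] || k > n_range[2]) {
    return(list(ok = FALSE,
                reason = sprintf("mask size %d outside [%d, %d]", k,
                                 n_range[1], n_range[2])))
  }
  bases <- .bases(backbone)
  grp <- cumsum(c(1L, diff(positions) != 1L))
  for (g in split(positions, grp)) {
    if (length(g) > max_run) {
      return(list(ok = FALSE,
                  reason = sprintf("run of %d consecutive LNA positions at %d-%d (max %d)",
                                   length(g), g[1], g[length(g)], max_run)))
    }
    gc <- bases[g] %in% c("G", "C")
    r <- rle(gc)
    if (any(r$values & r$lengths >= gc_run)) {
      idx <- which(r$values & r$lengths >= gc_run)[1]
      at <- g[sum(r$lengths[seq_len(idx - 1)]) + 1L]
      return(list(ok = FALSE,
                  reason = sprintf("%d consecutive G/C LNA positions starting at %d",
                                   max(r$lengths[idx]), at)))
    }
  }
  list(ok = TRUE, reason = NULL)
}

#' Stream all valid LNA masks for a backbone
#'
#' Exhausts every subset of backbone positions of each size in `sizes` that
#' passes [validate_lna_mask()], as an iterator rather than a materialized
#' list: a 22-nt backbone has on the order of 10^6 subsets of sizes 5-9.
#' Order is deterministic: sizes ascending, subsets in lexicographic order
#' within a size.
#'
#' @param backbone DNA backbone sequence.
#' @param sizes Integer vector of mask sizes to enumerate (default `5:9`).
#' @param validate If `TRUE` (default) only masks passing the design rules
#'   are yielded.
#' @return A function of no arguments; each call returns the next mask as an
#'   integer vector of 1-based positions, or `NULL` when exhausted.
#' @export
enumerate_lna_masks <- function(backbone, sizes = 5:9, validate = TRUE) {
  backbone <- toupper(backbone)
  n <- nchar(backbone)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L) || any(sizes > n)) {
    stop("mask sizes must lie in [1, backbone length]", call. = FALSE)
  }
  si <- 1L
  comb <- NULL   # current combination for sizes[si], or NULL before first
  nxt <- function() {
    repeat {
      if (si > length(sizes)) return(NULL)
      k <- sizes[si]
      if (is.null(comb)) {
        comb <<- seq_len(k)
      } else {
        # lexicographic successor of comb among k-subsets of 1..n
        i <- k
        while (i >= 1L && comb[i] == n - k + i) i <- i - 1L
        if (i < 1L) {
          si <<- si + 1L
          comb <<- NULL
          next
        }
        comb[i] <<- comb[i] + 1L
        if (i < k) comb[(i + 1L):k] <<- comb[i] + seq_len(k - i)
      }
      if (!validate || validate_lna_mask(backbone, comb)$ok) return(comb)
    }
  }
  nxt
}

# drain an iterator into a list (testing / small backbones only)
.drain_masks <- function(it) {
  out <- list()
  while (!is.null(m <- it())) out[[length(out) + 1L]] <- m
  out
}
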