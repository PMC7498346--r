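#' Single-molecule localization table
#'
#' One row per localized blink: acquisition frame (0-based), position in nm,
#' photon count and (optionally) localization precision in nm. Metadata
#' carried as attributes: seconds per frame (`frame_time_s`, default 0.1,
#' i.e. 100 ms exposure), camera pixel size (`pixel_nm`, default 159) and
#' the number of acquisition frames (`n_frames`, default 20000).
#'
#' @param frame Integer vector of 0-based frame indices (>= 0).
#' @param x,y Coordinates in nm.
#' @param photons Photon counts (> 0).
#' @param precision Optional localization precision in nm.
#' @param frame_time_s Seconds per acquisition frame.
#' @param pixel_nm Camera pixel size in nm.
#' @param n_frames Total frames in the acquisition (defaults to
#'   `max(frame) + 1` when larger than 20000).
#' @return A data.frame of class `loc_table`.
#' @export
localization_table <- function(frame, x, y, photons,
                               precision = NULL,
                               frame_time_s = 0.1, pixel_nm = 159,
                               n_frames = 20000) {
  frame <- as.integer(frame)
  if (length(frame) && min(frame) < 0L) stop("frames must be >= 0", call. = FALSE)
  if (length(photons) && any(photons <= 0)) stop("photon counts must be > 0", call. = FALSE)
  df <- data.frame(frame = frame, x = as.numeric(x), y = as.numeric(y),
                   photons = as.numeric(photons))
  if (!is.null(precision)) df$precision <- as.numeric(precision)
  attr(df, "frame_time_s") <- frame_time_s
  attr(df, "pixel_nm") <- pixel_nm
  attr(df, "n_frames") <- max(n_frames, if (length(frame)) max(frame) + 1L else 0L)
  class(df) <- c("loc_table", "data.frame")
  df
}

# subset rows preserving loc_table metadata
.loc_subset <- function(tab, idx) {
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("frame_time_s", "pixel_nm", "n_frames")) {
    attr(out, a) <- attr(tab, a)
  }
  class(out) <- c("loc_table", "data.frame")
  out
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("localization table: %d records, %d frames @ %.3g s/frame\n",
              nrow(x), attr(x, "n_frames"), attr(x, "frame_time_s")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Read / write localization CSV
#'
#' Plain-CSV interchange with header
#' `frame,x_nm,y_nm,photons,precision_nm` (precision optional).
#'
#' @param path CSV file path.
#' @param frame_time_s,pixel_nm,n_frames Metadata (see
#'   [localization_table()]).
#' @return `read_locs_csv`: a `loc_table`; `write_locs_csv`: the path,
#'   invisibly.
#' @export
read_locs_csv <- function(path, frame_time_s = 0.1, pixel_nm = 159,
                          n_frames = 20000) {
  df <- utils::read.csv(path)
  need <- c("frame", "x_nm", "y_nm", "photons")
  if (!all(need %in% names(df))) {
    stop("localization CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  localization_table(df$frame, df$x_nm, df$y_nm, df$photons,
                     precision = if ("precision_nm" %in% names(df)) df$precision_nm,
                     frame_time_s = frame_time_s, pixel_nm = pixel_nm,
                     n_frames = n_frames)
}

#' @rdname read_locs_csv
#' @param tab A `loc_table`.
#' @export
write_locs_csv <- function(tab, path) {
  df <- data.frame(frame = tab$frame, x_nm = tab$x, y_nm = tab$y,
                   photons = tab$photons)
  if (!is.null(tab$precision)) df$precision_nm <- tab$precision
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Photon-count filter
#'
#' Retains localizations whose photon count lies in `[lo, hi]` (both bounds
#' inclusive), removing dim non-specific background and saturated artifacts.
#' Idempotent; metadata preserved.
#'
#' @param tab A `loc_table`.
#' @param lo,hi Photon bounds (defaults 420 and 10000).
#' @return The filtered `loc_table`.
#' @export
filter_photons <- function(tab, lo = 420, hi = 10000) {
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  .loc_subset(tab, tab$photons >= lo & tab$photons <= hi)
}

#' Circular pick region
#'
#' @param center Numeric `(x, y)` center in nm.
#' @param diameter_nm Pick diameter in nm; the default 3180 nm is a 20-pixel
#'   circle at 159 nm/pixel.
#' @return A `pick_region`.
#' @export
pick_region <- function(center, diameter_nm = 3180) {
  if (diameter_nm <= 0) stop("diameter must be > 0", call. = FALSE)
  structure(list(center = as.numeric(center), diameter_nm = diameter_nm),
            class = "pick_region")
}

#' Select localizations within a circular pick
#'
#' Keeps records whose Euclidean distance from the pick center is at most
#' the pick radius (boundary inclusive).
#'
#' @param tab A `loc_table`.
#' @param pick A [pick_region()].
#' @return The subset `loc_table`.
#' @export
pick_circle <- function(tab, pick) {
  stopifnot(inherits(pick, "pick_region"))
  r <- pick$diameter_nm / 2
  d2 <- (tab$x - pick$center[1])^2 + (tab$y - pick$center[2])^2
  .loc_subset(tab, d2 <= r^2)
}

#' Link localizations into binding events
#'
#' Merges temporally contiguous localizations of one pick into binding
#' events: consecutive frames always merge, and gaps of up to `ignore_gap`
#' frames are bridged (a single missed detection does not split an event).
#'
#' @param tab A `loc_table` for a single pick.
#' @param ignore_gap Maximum number of empty frames bridged within one event
#'   (default 1).
#' @return A data.frame with `start_frame`, `end_frame` (inclusive) and
#'   `n_locs`, time-ordered and non-overlapping.
#' @export
link_events <- function(tab, ignore_gap = 1) {
  frames <- sort(unique(tab$frame))
  if (length(frames) == 0) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      n_locs = integer(0)))
  }
  new_event <- c(TRUE, diff(frames) > ignore_gap + 1)
  ev <- cumsum(new_event)
  start <- tapply(frames, ev, min)
  end <- tapply(frames, ev, max)
  counts <- tabulate(findInterval(tab$frame, start), nbins = length(start))
  data.frame(start_frame = as.integer(start), end_frame = as.integer(end),
             n_locs = counts)
}

#' Dark times between binding events
#'
#' The dark time between consecutive events is the number of wholly empty
#' frames separating them, `(start[i+1] - end[i] - 1)`, times the frame
#' time: two events in frames 12 and 14 are separated by exactly one dark
#' frame.
#'
#' @param events Event table from [link_events()].
#' @param frame_time_s Seconds per frame.
#' @return Numeric vector of dark times in seconds (length
#'   `max(0, nrow(events) - 1)`).
#' @export
dark_times <- function(events, frame_time_s = 0.1) {
  n <- nrow(events)
  if (n < 2) return(numeric(0))
  (events$start_frame[-1] - events$end_frame[-n] - 1) * frame_time_s
}

#' Render a 2-D localization histogram
#'
#' Bins localizations on a square grid (default 16 nm bins, the rendering
#' resolution used for full-field super-resolution images). Counts are
#' conserved: the matrix sums to the number of records.
#'
#' @param tab A `loc_table`.
#' @param bin_nm Bin width in nm.
#' @return An integer matrix (rows = x bins, cols = y bins) with attributes
#'   `x0`, `y0` (origin of the first bin) and `bin_nm`.
#' @export
render_histogram <- function(tab, bin_nm = 16) {
  if (bin_nm <= 0) stop("bin_nm must be > 0", call. = FALSE)
  if (nrow(tab) == 0) {
    m <- matrix(0L, 0, 0)
    attr(m, "bin_nm") <- bin_nm
    return(m)
  }
  ix <- floor(tab$x / bin_nm)
  iy <- floor(tab$y / bin_nm)
  x0 <- min(ix); y0 <- min(iy)
  m <- matrix(0L, max(ix) - x0 + 1L, max(iy) - y0 + 1L)
  for (i in seq_along(ix)) {
    m[ix[i] - x0 + 1L, iy[i] - y0 + 1L] <- m[ix[i] - x0 + 1L, iy[i] - y0 + 1L] + 1L
  }
  attr(m, "x0") <- x0 * bin_nm
  attr(m, "y0") <- y0 * bin_nm
  attr(m, "bin_nm") <- bin_nm
  m
}
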