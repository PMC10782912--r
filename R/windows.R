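# Non-overlapping genomic windows: construction, masking, track annotation.
#
# Coordinates are 0-based half-open (BED convention) throughout. Within a
# chromosome, windows tile [0, length) contiguously; only the terminal window
# may be shorter than `window_size` (ceiling convention).

#' Load chromosome sizes
#'
#' Reads a UCSC-style `chrom.sizes` file: two whitespace-delimited columns,
#' chromosome name and length in bp. Input order is preserved.
#'
#' @param path Path to a two-column text file.
#' @return A `chrom_sizes` object: data.frame with columns `chrom`, `length`.
#' @examples
#' f <- tempfile()
#' writeLines(c("chrA 25000", "chrB 8000"), f)
#' load_chrom_sizes(f)
#' @export
load_chrom_sizes <- function(path) {
  df <- read_intervals(path, c("chrom", "length"), numeric_cols = 2L)
  if (nrow(df) == 0L) stop2("empty chrom.sizes file: ", path)
  if (any(df$length <= 0) || any(df$length != floor(df$length)))
    stop2("chromosome lengths must be positive integers")
  if (anyDuplicated(df$chrom))
    stop2("duplicate chromosome name(s): ",
          paste(unique(df$chrom[duplicated(df$chrom)]), collapse = ", "))
  df$length <- as.numeric(df$length)
  class(df) <- c("chrom_sizes", "data.frame")
  df
}

chrom_sizes <- function(chrom, length) {
  df <- data.frame(chrom = as.character(chrom), length = as.numeric(length),
                   stringsAsFactors = FALSE)
  if (any(df$length <= 0)) stop2("chromosome lengths must be > 0")
  if (anyDuplicated(df$chrom)) stop2("duplicate chromosome name(s)")
  class(df) <- c("chrom_sizes", "data.frame")
  df
}

#' Generate non-overlapping windows over a genome
#'
#' Tiles every chromosome with contiguous non-overlapping windows of
#' `window_size` bp; the terminal window of a chromosome is retained even if
#' shorter (ceiling convention), so each chromosome contributes
#' `ceiling(length / window_size)` windows. Windows are indexed `0..N-1` in
#' genome (input) order.
#'
#' @param chrom_sizes A `chrom_sizes` object (see [load_chrom_sizes()]).
#' @param window_size Window width in bp (> 0).
#' @return A `window_set` object.
#' @export
make_windows <- function(chrom_sizes, window_size) {
  if (!inherits(chrom_sizes, "chrom_sizes")) {
    stopifnot(is.data.frame(chrom_sizes),
              all(c("chrom", "length") %in% names(chrom_sizes)))
    class(chrom_sizes) <- c("chrom_sizes", "data.frame")
  }
  if (!is_count(window_size)) stop2("window_size must be a positive integer")
  per <- ceiling(chrom_sizes$length / window_size)
  chrom <- rep(chrom_sizes$chrom, per)
  len <- rep(chrom_sizes$length, per)
  start <- (sequence(per) - 1) * window_size
  end <- pmin(start + window_size, len)
  ws <- list(
    window_size = as.numeric(window_size),
    windows = data.frame(chrom = chrom, start = start, end = end,
                         index = seq_along(chrom) - 1L,
                         masked = FALSE, stringsAsFactors = FALSE),
    chrom_sizes = chrom_sizes,
    gc = NULL, mappability = NULL, covered_fraction = NULL
  )
  class(ws) <- "window_set"
  ws
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "window_set: %d windows of %g bp over %d chromosome(s); %d masked\n",
    nrow(x$windows), x$window_size, nrow(x$chrom_sizes),
    sum(x$windows$masked)))
  if (!is.null(x$gc)) cat("  gc track attached\n")
  if (!is.null(x$mappability)) cat("  mappability track attached\n")
  invisible(x)
}

#' @export
length.window_set <- function(x) nrow(x$windows)

# Per-chromosome window offsets (first global index of each chromosome).
ws_offsets <- function(ws) {
  per <- ceiling(ws$chrom_sizes$length / ws$window_size)
  stats::setNames(cumsum(c(0, per[-length(per)])), ws$chrom_sizes$chrom)
}

# Map intervals onto regular bins. `iv` is a data.frame(chrom, start, end)
# with optional extra columns carried through; returns data.frame(row = input
# row, window = global 0-based index, bp = overlap). Intervals falling on
# chromosomes absent from `ws` are dropped with a warning when warn = TRUE.
interval_to_windows <- function(ws, iv, warn = TRUE) {
  size <- ws$window_size
  cs <- ws$chrom_sizes
  empty <- data.frame(row = integer(0), window = numeric(0), bp = numeric(0))
  orig <- seq_len(nrow(iv))
  known <- iv$chrom %in% cs$chrom
  if (any(!known) && warn)
    warning("interval(s) on unknown chromosome(s) skipped: ",
            paste(unique(iv$chrom[!known]), collapse = ", "))
  iv <- iv[known, , drop = FALSE]; orig <- orig[known]
  if (nrow(iv) == 0L) return(empty)
  clen <- cs$length[match(iv$chrom, cs$chrom)]
  s <- pmax(iv$start, 0)
  e <- pmin(iv$end, clen)
  ok <- e > s
  iv <- iv[ok, , drop = FALSE]; orig <- orig[ok]
  s <- s[ok]; e <- e[ok]; clen <- clen[ok]
  if (nrow(iv) == 0L) return(empty)
  off <- unname(ws_offsets(ws)[iv$chrom])
  b0 <- floor(s / size)
  b1 <- floor((e - 1) / size)
  nb <- b1 - b0 + 1
  bin <- rep(b0, nb) + (sequence(nb) - 1)
  bs <- bin * size
  be <- pmin(bs + size, rep(clen, nb))
  bp <- pmin(rep(e, nb), be) - pmax(rep(s, nb), bs)
  data.frame(row = rep(orig, nb), window = rep(off, nb) + bin, bp = bp)
}

#' Mask windows overlapping exclusion regions
#'
#' Flags a window as masked when the fraction of its length covered by the
#' union of exclusion intervals reaches `min_overlap_fraction`. Masked
#' windows keep their indices but are omitted from downstream coverage
#' matrices. Typical use: excluding segmental-duplication regions whose read
#' mapping is unreliable at low coverage.
#'
#' @param ws A `window_set`.
#' @param exclusion data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), or a path to a BED3 file.
#' @param min_overlap_fraction Mask when overlap / window length >= this
#'   value. With 0, any 1-bp touch masks; with 1, only fully covered windows
#'   are masked. Default 0.5.
#' @return The `window_set` with an updated `masked` flag.
#' @export
mask_windows <- function(ws, exclusion, min_overlap_fraction = 0.5) {
  stopifnot(inherits(ws, "window_set"))
  if (is.character(exclusion) && length(exclusion) == 1L)
    exclusion <- read_intervals(exclusion, c("chrom", "start", "end"))
  if (!is_fraction(min_overlap_fraction))
    stop2("min_overlap_fraction must be in [0, 1]")
  if (nrow(exclusion) == 0L) return(ws)
  # merge per-chromosome so overlapping exclusion intervals never double-count
  merged <- do.call(rbind, lapply(split(exclusion, exclusion$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    hi <- cummax(d$end)
    grp <- cumsum(c(TRUE, d$start[-1] > hi[-nrow(d)]))
    data.frame(chrom = d$chrom[1],
               start = as.numeric(tapply(d$start, grp, min)),
               end = as.numeric(tapply(d$end, grp, max)))
  }))
  hits <- interval_to_windows(ws, merged)
  if (nrow(hits) == 0L) return(ws)
  ov <- tapply(hits$bp, hits$window, sum)
  widx <- as.numeric(names(ov)) + 1
  wlen <- ws$windows$end[widx] - ws$windows$start[widx]
  frac <- as.numeric(ov) / wlen
  if (min_overlap_fraction == 0) {
    newly <- widx[frac > 0]
  } else {
    newly <- widx[frac >= min_overlap_fraction]
  }
  ws$windows$masked[newly] <- TRUE
  ws
}

#' Length-weighted per-window mean of an interval track
#'
#' Aggregates a bedGraph-like track (non-overlapping intervals with a value,
#' e.g. GC fraction or mappability) into per-window means, weighting each
#' interval by the number of bases it contributes to the window. Windows
#' with no track coverage get `NA`; partial coverage is recorded in the
#' returned `covered_fraction` attribute.
#'
#' @param ws A `window_set`.
#' @param track data.frame with columns `chrom`, `start`, `end`, `value`, or
#'   a path to a 4-column bedGraph file.
#' @param range Optional length-2 numeric; when supplied, values outside the
#'   range are an error (use `c(0, 1)` for fraction tracks).
#' @return Numeric vector of per-window means (length = number of windows)
#'   with attribute `covered_fraction`.
#' @export
window_track_values <- function(ws, track, range = c(0, 1)) {
  stopifnot(inherits(ws, "window_set"))
  if (is.character(track) && length(track) == 1L)
    track <- read_intervals(track, c("chrom", "start", "end", "value"),
                            numeric_cols = c(2L, 3L, 4L))
  if (!is.null(range) && nrow(track) > 0 &&
      (any(track$value < range[1]) || any(track$value > range[2])))
    stop2("track value(s) outside declared range [",
          range[1], ", ", range[2], "]")
  n <- nrow(ws$windows)
  hits <- interval_to_windows(ws, track)
  num <- den <- numeric(n)
  if (nrow(hits) > 0L) {
    v <- track$value[hits$row]
    rs_num <- rowsum(v * hits$bp, hits$window)
    rs_den <- rowsum(hits$bp, hits$window)
    at <- as.numeric(rownames(rs_num)) + 1
    num[at] <- rs_num[, 1]
    den[at] <- rs_den[, 1]
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  attr(out, "covered_fraction") <-
    den / (ws$windows$end - ws$windows$start)
  out
}

#' Attach GC and mappability tracks to a window set
#'
#' @param ws A `window_set`.
#' @param gc,mappability Tracks accepted by [window_track_values()] (interval
#'   data.frame or bedGraph path), or a plain numeric vector of per-window
#'   values.
#' @return The annotated `window_set`.
#' @export
annotate_windows <- function(ws, gc = NULL, mappability = NULL) {
  as_track <- function(x, what) {
    if (is.numeric(x) && is.null(dim(x))) {
      if (length(x) != nrow(ws$windows))
        stop2(what, " vector length != number of windows")
      return(x)
    }
    window_track_values(ws, x)
  }
  if (!is.null(gc)) ws$gc <- as_track(gc, "gc")
  if (!is.null(mappability)) ws$mappability <- as_track(mappability, "mappability")
  ws
}

#' Export windows as BED4
#'
#' Writes `chrom start end index` (index as name), optionally restricted to
#' unmasked windows.
#'
#' @param ws A `window_set`.
#' @param path Output path.
#' @param unmasked_only Drop masked windows from the output. Default FALSE.
#' @export
write_windows_bed <- function(ws, path, unmasked_only = FALSE) {
  w <- ws$windows
  if (unmasked_only) w <- w[!w$masked, , drop = FALSE]
  utils::write.table(w[, c("chrom", "start", "end", "index")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
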