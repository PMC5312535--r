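#' Sliding-window grid
#'
#' Defines the sliding-window layout used by the windowed statistics.
#' Windows are 0-based half-open `[k*step, k*step + window_size)`, clipped at
#' the chromosome end; every start below the chromosome length produces a
#' window. The diversity scan of the study design uses 1 Mb windows with a
#' 200 kb step, the F_ST/PBS scan 100 kb windows with a 20 kb step.
#'
#' @param window_size window width in bp.
#' @param step_size step between window starts in bp (`<= window_size`).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return object of class `window_grid`.
#' @export
window_grid <- function(window_size, step_size, chrom_lengths) {
  stopifnot(window_size > 0, step_size > 0, step_size <= window_size,
            length(chrom_lengths) > 0, all(chrom_lengths > 0))
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named by chromosome")
  structure(list(window_size = window_size, step_size = step_size,
                 chrom_lengths = chrom_lengths),
            class = "window_grid")
}

#' Materialise the windows of a grid
#'
#' @param grid a [window_grid].
#' @return data frame with `chrom`, `start`, `end` (0-based half-open, end
#'   clipped at the chromosome length), in genome order.
#' @export
tile_windows <- function(grid) {
  out <- lapply(names(grid$chrom_lengths), function(ch) {
    len <- grid$chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = grid$step_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + grid$window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Index sites (sorted pos within chrom) into the windows of a grid.
# Returns, per window row, the integer indices of panel sites it contains.
window_site_index <- function(panel, grid) {
  wins <- tile_windows(grid)
  idx <- vector("list", nrow(wins))
  for (ch in unique(wins$chrom)) {
    wi <- which(wins$chrom == ch)
    si <- which(panel$chrom == ch)
    if (!length(si)) { idx[wi] <- list(integer(0)); next }
    pos <- panel$pos[si]
    lo <- findInterval(wins$start[wi] - 0.5, pos) + 1L
    hi <- findInterval(wins$end[wi] - 0.5, pos)
    for (k in seq_along(wi))
      idx[[wi[k]]] <- if (lo[k] <= hi[k]) si[lo[k]:hi[k]] else integer(0)
  }
  list(windows = wins, sites = idx)
}
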