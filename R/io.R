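#' Read a BED file of intervals
#'
#' @param path BED file (0-based half-open; first three columns used).
#' @return data.frame `chrom`, `start`, `end` (plus `name`, `score` when
#'   present).
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  x <- x[!grepl("^(track|browser)", x[[1L]]), , drop = FALSE]
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4L) names(x)[4L] <- "name"
  if (ncol(x) >= 5L) names(x)[5L] <- "score"
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optional
#'   `name`, `score` columns (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a window track to disk
#'
#' Writes a stranded bedGraph pair (`<prefix>_fwd.bedGraph`,
#' `<prefix>_rev.bedGraph`, included windows only) and a combined TSV
#' (`<prefix>.tsv`) with all windows and their inclusion flags.
#'
#' @param track `window_track` or `polarity_profile`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_track <- function(track, prefix) {
  inc <- track$included
  bg <- function(value, path) {
    write.table(data.frame(track$chrom[inc], track$start[inc],
                           track$end[inc], value[inc]),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  p1 <- paste0(prefix, "_fwd.bedGraph"); bg(track$fwd, p1)
  p2 <- paste0(prefix, "_rev.bedGraph"); bg(track$rev, p2)
  p3 <- paste0(prefix, ".tsv")
  df <- as.data.frame(track)
  write.table(df, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Read a window track TSV written by [write_track()]
#'
#' @param path TSV path.
#' @param window_size,step grid parameters of the stored track.
#' @return `window_track` (with `polarity` column if stored).
#' @export
read_track_tsv <- function(path, window_size, step) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "fwd", "rev", "included") %in%
                names(df)))
  lens <- tapply(df$end, df$chrom, max)
  structure(df, window_size = window_size, step = step, norm = "raw",
            chrom_lengths = lens,
            class = c("window_track", "data.frame"))
}

#' Plot a polarity profile
#'
#' Dot plot of per-window read polarity along a chromosome, with origin calls
#' optionally marked; the standard display for replication-direction
#' profiles.
#'
#' @param profile `polarity_profile`.
#' @param chrom chromosome to plot (default: first).
#' @param origins optional origin-call data.frame from [call_origins()].
#' @return a ggplot object.
#' @export
plot_polarity <- function(profile, chrom = NULL, origins = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_polarity requires ggplot2")
  if (is.null(chrom)) chrom <- profile$chrom[1L]
  d <- as.data.frame(profile[profile$chrom == chrom & !is.na(profile$polarity), ])
  p <- ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                       y = .data$polarity)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5,
                        ggplot2::aes(colour = .data$polarity > 0)) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "#3366aa",
                                            "TRUE" = "#aa3333"),
                                 guide = "none") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = paste(chrom, "position (bp)"),
                  y = "read polarity (R - F)/(R + F)") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
  if (!is.null(origins) && nrow(origins)) {
    p <- p + ggplot2::geom_vline(xintercept =
                                   origins$position[origins$chrom == chrom],
                                 colour = "grey40", linetype = 3)
  }
  p
}
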