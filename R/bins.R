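#' Build a genome-wide bin table
#'
#' Partitions each chromosome into consecutive fixed-width bins. Bin ids are
#' dense 0-based integers in table order, matching the triplet-matrix dialect
#' used throughout the package (one bin table per resolution). Intervals are
#' 0-based half-open; the last bin of a chromosome may be shorter.
#'
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param resolution bin width in bp (e.g. 5e5 for compartment analysis,
#'   4e4 for TAD analysis).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `bin_id` and
#'   attribute `resolution`, class `bin_table`.
#' @examples
#' bin_table(c(chr1 = 2e6, chr2 = 1e6), resolution = 5e5)
#' @export
bin_table <- function(chrom_sizes, resolution) {
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0), resolution > 0)
  pieces <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = resolution)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + resolution, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$bin_id <- seq_len(nrow(out)) - 1L
  attr(out, "resolution") <- resolution
  class(out) <- c("bin_table", "data.frame")
  out
}

#' Number of bins in a bin table
#' @param bins a `bin_table`.
#' @export
n_bins <- function(bins) nrow(bins)

#' Map genomic positions to bin ids
#'
#' @param bins a `bin_table`.
#' @param chrom,pos vectors of chromosome names and bp positions.
#' @return integer vector of 0-based bin ids; `NA` for positions outside the
#'   assembly (callers decide whether that is an error).
#' @export
locate_bin <- function(bins, chrom, pos) {
  res <- attr(bins, "resolution")
  out <- rep(NA_integer_, length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    cb <- bins[bins$chrom == ch, ]
    if (nrow(cb) == 0L) next
    idx <- findInterval(pos[sel], cb$start)
    ok <- idx >= 1L & pos[sel] < cb$end[pmax(idx, 1L)] & pos[sel] >= 0
    out[sel][ok] <- cb$bin_id[idx[ok]]
  }
  out
}

# split bin ids by chromosome, preserving table order (internal)
bins_by_chrom <- function(bins) split(bins$bin_id, bins$chrom)[unique(bins$chrom)]

#' Read / write a bin table as BED
#'
#' The companion BED file of the triplet matrix dialect: columns chrom,
#' start, end, bin_id (0-based half-open).
#' @param path file path.
#' @param resolution bin width in bp; inferred from the first bin if omitted.
#' @export
read_bins <- function(path, resolution = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "bin_id"),
                          colClasses = c("character", "integer", "integer", "integer"))
  if (is.null(resolution)) resolution <- df$end[1] - df$start[1]
  if (any(df$bin_id != seq_len(nrow(df)) - 1L))
    stop("bin_id column must be dense 0..N-1 in file order")
  attr(df, "resolution") <- resolution
  class(df) <- c("bin_table", "data.frame")
  df
}

#' @rdname read_bins
#' @param bins a `bin_table`.
#' @export
write_bins <- function(bins, path) {
  write_tsv_plain(bins[, c("chrom", "start", "end", "bin_id")], path)
  invisible(path)
}

# write.table without scientific notation (bp coordinates stay integral)
write_tsv_plain <- function(df, path, col.names = FALSE) {
  op <- options(scipen = 15)
  on.exit(options(op))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}
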