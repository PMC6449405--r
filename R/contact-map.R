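#' Binned Hi-C contact map
#'
#' Container for a symmetric binned contact matrix stored as upper-triangle
#' triplets `(i, j, value)` with `i <= j` over a [bin_table()]. Balancing
#' weights are per-bin multiplicative factors; a weight of `NA` marks a
#' masked bin, which is excluded from every downstream statistic.
#'
#' @param bins a `bin_table`.
#' @param i,j 0-based bin ids with `i <= j` (rows with `i > j` are swapped).
#' @param x non-negative values (raw counts, balanced values, or O/E ratios).
#' @param weights per-bin balancing weights (`NA` = masked), or `NULL` for an
#'   unbalanced map.
#' @param balanced logical flag: do `x` already incorporate the weights?
#' @param normalization one of `"raw"`, `"balanced"`, `"oe"`.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(bins, i, j, x, weights = NULL, balanced = FALSE,
                        normalization = if (balanced) "balanced" else "raw") {
  stopifnot(inherits(bins, "bin_table"), length(i) == length(j),
            length(i) == length(x))
  i <- as.integer(i); j <- as.integer(j)
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  nb <- n_bins(bins)
  if (length(i) && (min(i) < 0L || max(j) >= nb))
    stop("bin index out of range for the supplied bin table")
  if (any(x < 0)) stop("contact values must be non-negative")
  key <- i * nb + j
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate entry for bin pair (%d, %d)", i[d], j[d]))
  }
  ord <- order(i, j)
  structure(list(bins = bins, i = i[ord], j = j[ord], x = x[ord],
                 weights = weights, balanced = isTRUE(balanced),
                 normalization = normalization),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d bins (%d chromosomes), %d non-zero entries, %s\n",
              n_bins(x$bins), length(unique(x$bins$chrom)), length(x$x),
              x$normalization))
  if (!is.null(x$weights))
    cat(sprintf("  masked bins: %d\n", sum(is.na(x$weights))))
  invisible(x)
}

#' @export
summary.contact_map <- function(object, ...) {
  m <- masked_bins(object)
  cat(sprintf(
    "contact_map (%s)\n  bins: %d  masked: %d\n  entries: %d  total: %.4g\n",
    object$normalization, n_bins(object$bins), sum(m), length(object$x),
    sum(object$x)))
  invisible(object)
}

#' Logical mask of excluded bins
#' @param map a `contact_map`.
#' @return logical vector, `TRUE` where the bin is masked.
#' @export
masked_bins <- function(map) {
  if (is.null(map$weights)) rep(FALSE, n_bins(map$bins)) else is.na(map$weights)
}

#' Dense symmetric matrix view of a contact map
#'
#' Materializes the full symmetric matrix (toy-genome scale). Masked bins
#' are set to `NA` when `apply_mask` is `TRUE`.
#'
#' @param map a `contact_map`.
#' @param chrom restrict to one chromosome's cis block (optional).
#' @param apply_mask set masked rows/columns to `NA`.
#' @return a numeric matrix.
#' @export
as_dense <- function(map, chrom = NULL, apply_mask = TRUE) {
  nb <- n_bins(map$bins)
  M <- matrix(0, nb, nb)
  idx1 <- map$i + 1L; idx2 <- map$j + 1L
  M[cbind(idx1, idx2)] <- map$x
  M[cbind(idx2, idx1)] <- map$x
  if (apply_mask && !is.null(map$weights)) {
    mask <- which(is.na(map$weights))
    if (length(mask)) { M[mask, ] <- NA; M[, mask] <- NA }
  }
  if (!is.null(chrom)) {
    sel <- which(map$bins$chrom == chrom)
    M <- M[sel, sel, drop = FALSE]
  }
  M
}

# rebuild a contact_map from a dense symmetric matrix, dropping zeros
# and NA cells (internal)
dense_to_map <- function(M, bins, weights = NULL, balanced = FALSE,
                         normalization = "raw") {
  ut <- which(upper.tri(M, diag = TRUE) & !is.na(M) & M != 0, arr.ind = TRUE)
  contact_map(bins, ut[, 1] - 1L, ut[, 2] - 1L, M[ut], weights = weights,
              balanced = balanced, normalization = normalization)
}

#' Read / write the triplet contact-matrix dialect
#'
#' The text dialect is a 3-column whitespace-separated file of
#' `bin_i bin_j value` (0-based upper-triangle ids) together with a
#' companion bin BED (see [read_bins()]). A round trip
#' `read_contact_map(write_contact_map(m))` reproduces `m` exactly.
#'
#' @param matrix_path path to the triplet file.
#' @param bins_path path to the companion bin BED.
#' @return `read_contact_map`: a `contact_map`;
#'   `write_contact_map`: the matrix path, invisibly.
#' @export
read_contact_map <- function(matrix_path, bins_path) {
  bins <- read_bins(bins_path)
  df <- utils::read.table(matrix_path, header = FALSE,
                          col.names = c("i", "j", "x"),
                          colClasses = c("integer", "integer", "numeric"))
  nb <- n_bins(bins)
  bad <- which(df$i < 0L | df$j < 0L | df$i >= nb | df$j >= nb)
  if (length(bad))
    stop(sprintf("%s line %d: bin index out of range", matrix_path, bad[1]))
  bad <- which(df$x < 0)
  if (length(bad))
    stop(sprintf("%s line %d: negative count", matrix_path, bad[1]))
  ii <- pmin(df$i, df$j); jj <- pmax(df$i, df$j)
  key <- ii * nb + jj
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("%s line %d: duplicate entry for pair (%d, %d)",
                 matrix_path, d, ii[d], jj[d]))
  }
  contact_map(bins, df$i, df$j, df$x)
}

#' @rdname read_contact_map
#' @param map a `contact_map`.
#' @export
write_contact_map <- function(map, matrix_path, bins_path = NULL) {
  df <- data.frame(i = map$i, j = map$j, x = map$x)
  write_tsv_plain(df, matrix_path)
  if (!is.null(bins_path)) write_bins(map$bins, bins_path)
  invisible(matrix_path)
}

#' Write a per-bin track as bedGraph
#' @param bins a `bin_table`.
#' @param score numeric per-bin values (`NA` rows are dropped).
#' @param path output path.
#' @export
write_bedgraph <- function(bins, score, path) {
  keep <- !is.na(score)
  write_tsv_plain(data.frame(bins$chrom[keep], bins$start[keep],
                             bins$end[keep], score[keep]), path)
  invisible(path)
}
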