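#' Genome layout: chromosomes and a fixed bin size
#'
#' A genome layout records the ordered chromosomes, their lengths, and the
#' fixed binning used for contact matrices. Bin ids are 1-based and sequential
#' across chromosomes in order, matching the HiC-Pro `_abs.bed` convention.
#' All coordinates in the package are 0-based half-open; a position `p` on a
#' chromosome falls in local bin `floor(p / bin_size)`.
#'
#' @param chromosomes data.frame with columns `name` and `length` (base
#'   pairs), or a named numeric vector of lengths.
#' @param bin_size bin width in base pairs (default 40 kb).
#' @return an object of class `genome_layout` with elements `chromosomes`
#'   (data.frame `name`, `length`, `n_bins`, `first_bin`) and `bin_size`.
#' @examples
#' genome_layout(c(chr1 = 2e6, chr2 = 1e6), bin_size = 4e4)
#' @export
genome_layout <- function(chromosomes, bin_size = 40000L) {
  if (is.numeric(chromosomes) && !is.null(names(chromosomes))) {
    chromosomes <- data.frame(name = names(chromosomes),
                              length = as.numeric(chromosomes))
  }
  if (!is.data.frame(chromosomes) ||
      !all(c("name", "length") %in% names(chromosomes))) {
    stop_input("chromosomes must be a data.frame with 'name' and 'length'")
  }
  name <- as.character(chromosomes$name)
  len <- as.numeric(chromosomes$length)
  if (anyDuplicated(name)) stop_input("chromosome names must be unique")
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop_input("chromosome lengths must be positive")
  }
  bin_size <- as.numeric(bin_size)
  if (!is.finite(bin_size) || bin_size <= 0) {
    stop_input("bin_size must be positive")
  }
  n_bins <- as.integer(ceiling(len / bin_size))
  first_bin <- cumsum(c(1L, n_bins[-length(n_bins)]))
  structure(
    list(chromosomes = data.frame(name = name, length = len, n_bins = n_bins,
                                  first_bin = first_bin,
                                  stringsAsFactors = FALSE),
         bin_size = bin_size),
    class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), bin size %g bp, %d bins\n",
              nrow(x$chromosomes), x$bin_size, layout_n_bins(x)))
  invisible(x)
}

layout_n_bins <- function(layout) sum(layout$chromosomes$n_bins)

# chromosome index for each global bin id
bin_chrom_index <- function(layout, bin) {
  ch <- layout$chromosomes
  idx <- findInterval(bin, ch$first_bin)
  idx[bin < 1L | bin > layout_n_bins(layout)] <- NA_integer_
  idx
}

# global bin id -> (chrom, start, end) 0-based half-open
bin_coords <- function(layout, bin) {
  ch <- layout$chromosomes
  idx <- bin_chrom_index(layout, bin)
  local <- bin - ch$first_bin[idx]  # 0-based local bin
  start <- local * layout$bin_size
  end <- pmin(start + layout$bin_size, ch$length[idx])
  data.frame(chrom = ch$name[idx], start = start, end = end,
             stringsAsFactors = FALSE)
}

# (chrom, pos) -> global bin id
pos_to_bin <- function(layout, chrom, pos) {
  ch <- layout$chromosomes
  idx <- match(chrom, ch$name)
  if (anyNA(idx)) stop_input("unknown chromosome: %s",
                             paste(unique(chrom[is.na(idx)]), collapse = ", "))
  ch$first_bin[idx] + floor(pos / layout$bin_size)
}

layouts_identical <- function(a, b) {
  isTRUE(all.equal(a$bin_size, b$bin_size)) &&
    identical(a$chromosomes$name, b$chromosomes$name) &&
    isTRUE(all.equal(a$chromosomes$length, b$chromosomes$length))
}
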