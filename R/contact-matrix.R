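#' Sparse intra-chromosomal contact matrix
#'
#' Holds binned intra-chromosomal contact counts over a [genome_layout()] as
#' an upper-triangle sparse triplet set, plus the library-wide total valid
#' pair count used as the VPPM denominator. Counts may be real valued (e.g.
#' ICE-balanced matrices); down-sampling requires raw integer counts.
#'
#' @param layout a [genome_layout()].
#' @param entries data.frame with columns `bin1`, `bin2` (global bin ids,
#'   `bin1 <= bin2`, same chromosome) and `count` (non-negative). Triplets
#'   with `bin1 > bin2` are transposed; duplicate positions are summed.
#' @param total_valid_pairs library-wide valid pair count; defaults to the
#'   sum of counts.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(layout, entries, total_valid_pairs = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(entries) == 0L) {
    entries <- data.frame(bin1 = integer(), bin2 = integer(),
                          count = numeric())
  } else {
    bin1 <- pmin(entries$bin1, entries$bin2)
    bin2 <- pmax(entries$bin1, entries$bin2)
    count <- as.numeric(entries$count)
    if (any(!is.finite(count)) || any(count < 0)) {
      stop_input("contact counts must be finite and non-negative")
    }
    nb <- layout_n_bins(layout)
    if (any(bin1 < 1L) || any(bin2 > nb)) {
      stop_input("bin id outside layout (1..%d)", nb)
    }
    if (any(bin_chrom_index(layout, bin1) != bin_chrom_index(layout, bin2))) {
      stop_input("contact_matrix entries must be intra-chromosomal")
    }
    key <- paste(bin1, bin2)
    if (anyDuplicated(key)) {
      agg <- rowsum(count, key)
      kk <- strsplit(rownames(agg), " ", fixed = TRUE)
      bin1 <- as.integer(vapply(kk, `[`, "", 1L))
      bin2 <- as.integer(vapply(kk, `[`, "", 2L))
      count <- as.numeric(agg[, 1L])
    }
    o <- order(bin1, bin2)
    entries <- data.frame(bin1 = as.integer(bin1[o]),
                          bin2 = as.integer(bin2[o]), count = count[o])
  }
  tvp <- total_valid_pairs %||% sum(entries$count)
  if (!is.finite(tvp) || tvp < 0) stop_input("total_valid_pairs must be >= 0")
  structure(list(layout = layout, entries = entries,
                 total_valid_pairs = tvp),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(paste0("contact_matrix: %d entries over %d bins ",
                     "(%d chromosome(s)), sum %g, total valid pairs %g\n"),
              nrow(x$entries), layout_n_bins(x$layout),
              nrow(x$layout$chromosomes), sum(x$entries$count),
              x$total_valid_pairs))
  invisible(x)
}

#' Read a HiC-Pro style bins + sparse matrix pair
#'
#' The bins file is BED-like (`chrom start end bin_id`, 0-based half-open,
#' fixed width except terminal bins, 1-based sequential ids); the matrix file
#' holds whitespace-separated triplets `bin_i bin_j count`.
#' Inter-chromosomal triplets are dropped with a warning giving their count.
#' The library total valid pairs is taken from the key
#' `valid_interaction_rmdup` of an optional `key=value` sidecar stats file,
#' else set to the sum of retained counts.
#'
#' @param bins_path path to the `*_abs.bed` bins file.
#' @param matrix_path path to the `*.matrix` triplet file.
#' @param stats_path optional sidecar stats file.
#' @return a [contact_matrix()].
#' @export
read_hicpro_matrix <- function(bins_path, matrix_path, stats_path = NULL) {
  bins <- utils::read.table(bins_path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "bin_id"),
                            colClasses = c("character", "numeric", "numeric",
                                           "integer"))
  if (nrow(bins) == 0L) stop_input("empty bins file: %s", bins_path)
  if (!identical(bins$bin_id, seq_len(nrow(bins)))) {
    stop_input("bins file %s: bin ids must be 1-based and sequential",
               bins_path)
  }
  widths <- bins$end - bins$start
  # per chromosome, all but the terminal bin must share one width
  by_chrom <- split(seq_len(nrow(bins)), bins$chrom)
  inner <- unlist(lapply(by_chrom, function(i) i[-length(i)]), use.names = FALSE)
  w <- unique(widths[inner])
  if (length(w) > 1L) {
    stop_input("bins file %s: inconsistent bin width (%s)", bins_path,
               paste(w, collapse = ", "))
  }
  bin_size <- if (length(w) == 1L) w else widths[1L]
  chrom_len <- vapply(by_chrom, function(i) max(bins$end[i]), 0)
  # preserve file order of chromosomes
  ord <- unique(bins$chrom)
  layout <- genome_layout(data.frame(name = ord,
                                     length = as.numeric(chrom_len[ord])),
                          bin_size = bin_size)
  raw <- tryCatch(
    utils::read.table(matrix_path, header = FALSE,
                      col.names = c("bin1", "bin2", "count")),
    error = function(e) {
      # an empty matrix file is a valid (all-zero) matrix
      if (length(readLines(matrix_path, warn = FALSE)) == 0L) {
        data.frame(bin1 = integer(), bin2 = integer(), count = numeric())
      } else stop(e)
    })
  if (nrow(raw) > 0L) {
    nb <- nrow(bins)
    bad <- which(raw$bin1 < 1L | raw$bin1 > nb | raw$bin2 < 1L | raw$bin2 > nb)
    if (length(bad)) {
      stop_input("matrix file %s line %d: unknown bin id", matrix_path, bad[1L])
    }
    ci <- match(bins$chrom[raw$bin1], ord)
    cj <- match(bins$chrom[raw$bin2], ord)
    inter <- ci != cj
    if (any(inter)) {
      warning(sprintf("%s: dropped %d inter-chromosomal triplet(s)",
                      matrix_path, sum(inter)), call. = FALSE)
      raw <- raw[!inter, , drop = FALSE]
    }
  }
  tvp <- NULL
  if (!is.null(stats_path)) {
    kv <- read_stats_sidecar(stats_path)
    tvp <- kv[["valid_interaction_rmdup"]]
  }
  contact_matrix(layout, raw, total_valid_pairs = tvp)
}

read_stats_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(parts, function(p) as.numeric(trimws(p[2L])))
  names(vals) <- vapply(parts, function(p) trimws(p[1L]), "")
  vals
}

#' Write a contact matrix in the HiC-Pro dialect
#'
#' Emits `<prefix>_abs.bed`, `<prefix>.matrix` and `<prefix>_stats.txt`
#' (carrying `valid_interaction_rmdup`). Integer counts round-trip exactly.
#'
#' @param mat a [contact_matrix()].
#' @param prefix output path prefix.
#' @return invisibly, the three paths written.
#' @export
write_hicpro_matrix <- function(mat, prefix) {
  layout <- mat$layout
  bins <- bin_coords(layout, seq_len(layout_n_bins(layout)))
  bins$bin_id <- seq_len(nrow(bins))
  bed <- paste0(prefix, "_abs.bed")
  mtx <- paste0(prefix, ".matrix")
  sts <- paste0(prefix, "_stats.txt")
  utils::write.table(format_num_df(bins), bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(format_num_df(mat$entries), mtx, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("valid_interaction_rmdup=%s",
                     format(mat$total_valid_pairs, scientific = FALSE)), sts)
  invisible(c(bins = bed, matrix = mtx, stats = sts))
}

# format numeric columns without scientific notation; integers stay integral
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      x <- df[[j]]
      df[[j]] <- ifelse(x == round(x),
                        format(x, scientific = FALSE, trim = TRUE),
                        format(x, scientific = FALSE, trim = TRUE, digits = 15))
    }
  }
  df
}

#' Binomially down-sample the valid pairs of a contact matrix
#'
#' Each implicit valid pair is retained independently with probability
#' `fraction` (binomial thinning per entry). The library total is scaled to
#' the realized retained count. Mirrors the robustness check in which a
#' down-sampled library is re-analysed to confirm sequencing depth does not
#' drive domain calls.
#'
#' @param mat a [contact_matrix()] with raw integer counts.
#' @param fraction retention probability in \[0, 1\].
#' @param seed integer seed (mandatory; thinning is stochastic).
#' @return a [contact_matrix()] with thinned counts (zero entries dropped).
#' @export
downsample_pairs <- function(mat, fraction, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction < 0 || fraction > 1) {
    stop_input("fraction must be a single value in [0, 1]")
  }
  cnt <- mat$entries$count
  if (any(cnt != round(cnt))) {
    stop_input("downsample_pairs requires raw integer counts")
  }
  kept <- if (fraction == 1) cnt else if (fraction == 0) {
    numeric(length(cnt))
  } else {
    with_seed(seed, stats::rbinom(length(cnt), size = as.integer(round(cnt)),
                                  prob = fraction))
  }
  ent <- mat$entries
  ent$count <- as.numeric(kept)
  ent <- ent[ent$count > 0, , drop = FALSE]
  contact_matrix(mat$layout, ent, total_valid_pairs = sum(kept))
}

#' Distance-decay profile of a contact matrix
#'
#' Mean stored count per realized genomic bin distance, pooled over
#' chromosomes. Distances with no stored entries are omitted.
#'
#' @param mat a [contact_matrix()].
#' @return data.frame with columns `distance` (bp) and `mean_count`.
#' @export
distance_decay_profile <- function(mat) {
  ent <- mat$entries
  if (nrow(ent) == 0L) {
    return(data.frame(distance = numeric(), mean_count = numeric()))
  }
  d <- (ent$bin2 - ent$bin1) * mat$layout$bin_size
  m <- tapply(ent$count, d, mean)
  data.frame(distance = as.numeric(names(m)), mean_count = as.numeric(m),
             row.names = NULL)
}

#' Correlation between two contact matrices
#'
#' Computed over the union of stored positions of the two matrices, with
#' zeros imputed where one matrix lacks an entry. Useful as a batch-effect
#' diagnostic between libraries.
#'
#' @param a,b [contact_matrix()] objects on identical layouts.
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation in \[-1, 1\].
#' @export
matrix_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!layouts_identical(a$layout, b$layout)) {
    stop_input("matrix_correlation requires identical layouts")
  }
  m <- merge(a$entries, b$entries, by = c("bin1", "bin2"), all = TRUE)
  x <- ifelse(is.na(m$count.x), 0, m$count.x)
  y <- ifelse(is.na(m$count.y), 0, m$count.y)
  stats::cor(x, y, method = method)
}

# join entries of two matrices on position; absent entries -> 0
merged_entries <- function(a, b) {
  m <- merge(a$entries, b$entries, by = c("bin1", "bin2"), all = TRUE)
  m$count.x[is.na(m$count.x)] <- 0
  m$count.y[is.na(m$count.y)] <- 0
  m
}
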