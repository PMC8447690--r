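#' Read significant interaction fragments (SIFs)
#'
#' Expects a TSV with columns `chrom1,start1,end1,chrom2,start2,end2,
#' valid_pairs,fdr` (header optional). Inter-chromosomal rows are dropped
#' with a warning giving their count; anchors are ordered by start.
#'
#' @param path input TSV.
#' @return data.frame with columns `chrom`, `start1`, `end1`, `start2`,
#'   `end2`, `valid_pairs`, `fdr`; anchor 1 is leftmost.
#' @export
read_sifs <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && grepl("chrom", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 8L) stop_input("%s: expected 8 columns", path)
  names(df)[1:8] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "valid_pairs", "fdr")
  inter <- df$chrom1 != df$chrom2
  if (any(inter)) {
    warning(sprintf("%s: dropped %d inter-chromosomal SIF(s)", path,
                    sum(inter)), call. = FALSE)
    df <- df[!inter, , drop = FALSE]
  }
  validate_sifs(data.frame(chrom = df$chrom1, start1 = df$start1,
                           end1 = df$end1, start2 = df$start2,
                           end2 = df$end2, valid_pairs = df$valid_pairs,
                           fdr = df$fdr, stringsAsFactors = FALSE))
}

validate_sifs <- function(sifs) {
  if (nrow(sifs) == 0L) return(sifs)
  if (any(sifs$valid_pairs <= 0) || any(sifs$valid_pairs != round(sifs$valid_pairs))) {
    stop_input("SIF valid_pairs must be positive integers")
  }
  if (any(!is.finite(sifs$fdr)) || any(sifs$fdr < 0) || any(sifs$fdr > 1)) {
    stop_input("SIF fdr must be in [0, 1]")
  }
  # order anchors by start
  swap <- sifs$start2 < sifs$start1
  if (any(swap)) {
    tmp_s <- sifs$start1[swap]; tmp_e <- sifs$end1[swap]
    sifs$start1[swap] <- sifs$start2[swap]; sifs$end1[swap] <- sifs$end2[swap]
    sifs$start2[swap] <- tmp_s; sifs$end2[swap] <- tmp_e
  }
  if (any(sifs$end1 > sifs$start2)) {
    stop_input("SIF anchors must not overlap")
  }
  rownames(sifs) <- NULL
  sifs
}

#' Write SIFs as TSV
#' @param sifs SIF data.frame as returned by [read_sifs()].
#' @param path output file.
#' @export
write_sifs <- function(sifs, path) {
  out <- data.frame(chrom1 = sifs$chrom, start1 = sifs$start1,
                    end1 = sifs$end1, chrom2 = sifs$chrom,
                    start2 = sifs$start2, end2 = sifs$end2,
                    valid_pairs = sifs$valid_pairs, fdr = sifs$fdr)
  utils::write.table(format_num_df(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Keep SIFs passing the FDR cutoff
#'
#' Inclusive filter (`fdr <= max_fdr`, default 0.1); input order preserved.
#'
#' @param sifs SIF data.frame.
#' @param max_fdr FDR cutoff.
#' @return the filtered data.frame.
#' @export
filter_sifs <- function(sifs, max_fdr = 0.1) {
  sifs[sifs$fdr <= max_fdr, , drop = FALSE]
}
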