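#' Gene annotation table
#'
#' Validates a table of protein-coding genes with their 5' transcription
#' start sites. `tss` is a 0-based coordinate; `strand` orients "upstream"
#' for the promoter and distal windows.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`, `strand`
#'   (`+`/`-`) and optionally `name`.
#' @return the validated data.frame (class `gene_table`).
#' @export
gene_table <- function(genes) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(genes))) {
    stop_input("genes need columns %s", paste(need, collapse = ", "))
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$tss <- as.numeric(genes$tss)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id)) stop_input("gene_ids must be unique")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop_input("strand must be '+' or '-'")
  }
  if (any(!is.finite(genes$tss)) || any(genes$tss < 0)) {
    stop_input("tss must be non-negative")
  }
  if (is.null(genes$name)) genes$name <- genes$gene_id
  class(genes) <- c("gene_table", "data.frame")
  genes
}

#' Read gene annotation from 6-column BED
#'
#' BED6 (`chrom start end name score strand`), 0-based half-open; the 5'TSS
#' is `start` on the + strand and `end - 1` on the - strand.
#'
#' @param path BED file.
#' @return a [gene_table()].
#' @export
read_genes_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop_input("%s: expected 6-column BED", path)
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  gene_table(data.frame(gene_id = df$name, chrom = df$chrom, tss = tss,
                        strand = df$strand, name = df$name,
                        stringsAsFactors = FALSE))
}

#' Write gene annotation as 6-column BED
#' @param genes a [gene_table()].
#' @param path output file.
#' @param width nominal gene-body width used to emit an interval around the
#'   TSS (the TSS itself is what downstream analysis uses).
#' @export
write_genes_bed <- function(genes, path, width = 1000) {
  start <- ifelse(genes$strand == "+", genes$tss,
                  pmax(0, genes$tss + 1 - width))
  end <- ifelse(genes$strand == "+", genes$tss + width, genes$tss + 1)
  out <- data.frame(chrom = genes$chrom, start = start, end = end,
                    name = genes$gene_id, score = 0, strand = genes$strand)
  utils::write.table(format_num_df(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Promoter window of each gene
#'
#' The promoter spans from `upstream` bp upstream of the 5'TSS to
#' `downstream` bp downstream (defaults 4 kb and 1 kb), following the
#' direction of transcription, clipped to chromosome bounds.
#'
#' @param genes a [gene_table()] (or compatible data.frame).
#' @param upstream,downstream window extent in bp.
#' @param chrom_lengths optional named vector for upper clipping.
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (0-based half-open).
#' @export
promoter_window <- function(genes, upstream = 4000, downstream = 1000,
                            chrom_lengths = NULL) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss + 1 - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + 1 + upstream)
  clip_windows(data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                          start = start, end = end,
                          stringsAsFactors = FALSE),
               genes$chrom, chrom_lengths)
}

#' Distal windows of each gene
#'
#' Two windows per gene: `inner`-`outer` bp upstream and downstream of the
#' 5'TSS (defaults 10-100 kb), strand-aware ("upstream" follows
#' transcription), clipped to chromosome bounds. A window fully clipped away
#' is returned with zero width.
#'
#' @inheritParams promoter_window
#' @param inner,outer distances from the TSS in bp, `inner < outer`.
#' @return data.frame with one row per gene and window (`side` in
#'   `upstream`/`downstream`), columns `gene_id`, `chrom`, `side`, `start`,
#'   `end`.
#' @export
distal_windows <- function(genes, inner = 10000, outer = 100000,
                           chrom_lengths = NULL) {
  stopifnot(inner < outer, inner >= 0)
  plus <- genes$strand == "+"
  tss <- genes$tss
  up <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                   side = "upstream",
                   start = ifelse(plus, tss - outer, tss + 1 + inner),
                   end = ifelse(plus, tss - inner, tss + 1 + outer),
                   stringsAsFactors = FALSE)
  dn <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                   side = "downstream",
                   start = ifelse(plus, tss + inner, tss + 1 - outer),
                   end = ifelse(plus, tss + outer, tss + 1 - inner),
                   stringsAsFactors = FALSE)
  out <- rbind(up, dn)
  clip_windows(out, out$chrom, chrom_lengths)
}

clip_windows <- function(df, chrom, chrom_lengths) {
  df$start <- pmax(0, df$start)
  df$end <- pmax(0, df$end)
  if (!is.null(chrom_lengths)) {
    lim <- unname(chrom_lengths[chrom])
    lim[is.na(lim)] <- Inf
    df$start <- pmin(df$start, lim)
    df$end <- pmin(df$end, lim)
  }
  df$start <- pmin(df$start, df$end)
  df
}
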