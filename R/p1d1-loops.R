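#' Assign an anchor interval to gene promoter / distal roles
#'
#' Returns every gene whose promoter or distal window overlaps the anchor by
#' at least 1 bp, with the role. Promoter priority: if the anchor overlaps
#' any promoter window, all of its distal roles are discarded, so an end
#' covering both the distal region of one gene and the promoter of another
#' counts only as a promoter.
#'
#' @param chrom,start,end the anchor interval (0-based half-open).
#' @param genes a [gene_table()].
#' @param promoter_upstream,promoter_downstream promoter window extents, bp.
#' @param distal_inner,distal_outer distal window distances from the TSS, bp.
#' @param chrom_lengths optional named vector for window clipping.
#' @return data.frame with columns `gene_id`, `role` (`promoter`/`distal`).
#' @export
assign_anchor <- function(chrom, start, end, genes,
                          promoter_upstream = 4000,
                          promoter_downstream = 1000,
                          distal_inner = 10000, distal_outer = 100000,
                          chrom_lengths = NULL) {
  anchors <- data.frame(chrom = chrom, start = start, end = end)
  roles <- assign_anchors(anchors, genes, promoter_upstream,
                          promoter_downstream, distal_inner, distal_outer,
                          chrom_lengths)
  roles[roles$anchor == 1L, c("gene_id", "role"), drop = FALSE]
}

# vectorized role assignment for a data.frame of anchors
assign_anchors <- function(anchors, genes, promoter_upstream,
                           promoter_downstream, distal_inner, distal_outer,
                           chrom_lengths) {
  pw <- promoter_window(genes, promoter_upstream, promoter_downstream,
                        chrom_lengths)
  dw <- distal_windows(genes, distal_inner, distal_outer, chrom_lengths)
  win <- rbind(data.frame(gene_id = pw$gene_id, chrom = pw$chrom,
                          start = pw$start, end = pw$end, role = "promoter",
                          stringsAsFactors = FALSE),
               data.frame(gene_id = dw$gene_id, chrom = dw$chrom,
                          start = dw$start, end = dw$end, role = "distal",
                          stringsAsFactors = FALSE))
  win <- win[win$end > win$start, , drop = FALSE]
  out <- data.frame(anchor = integer(), gene_id = character(),
                    role = character(), stringsAsFactors = FALSE)
  if (nrow(anchors) == 0L || nrow(win) == 0L) return(out)
  for (cm in unique(anchors$chrom)) {
    ai <- which(anchors$chrom == cm)
    wi <- which(win$chrom == cm)
    if (!length(wi)) next
    ra <- IRanges::IRanges(anchors$start[ai] + 1, anchors$end[ai])
    rw <- IRanges::IRanges(win$start[wi] + 1, win$end[wi])
    h <- IRanges::findOverlaps(ra, rw, minoverlap = 1L)
    if (!length(h)) next
    out <- rbind(out, data.frame(
      anchor = ai[S4Vectors::queryHits(h)],
      gene_id = win$gene_id[wi[S4Vectors::subjectHits(h)]],
      role = win$role[wi[S4Vectors::subjectHits(h)]],
      stringsAsFactors = FALSE))
  }
  # promoter priority: an anchor touching any promoter loses its distal roles
  has_prom <- unique(out$anchor[out$role == "promoter"])
  out <- out[out$role == "promoter" | !(out$anchor %in% has_prom), ,
             drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Call promoter-distal (P1D1) loops from SIFs
#'
#' A P1D1 loop is a SIF with one end on the promoter window of an annotated
#' gene and the other end on a distal window of the same gene, after
#' promoter-priority role assignment. Each loop is scored in valid pairs
#' per million: `vppm = valid_pairs / total_valid_pairs * 1e6`. Genes with
#' at least one loop are "looping genes"; genes without loops are absent
#' from the table.
#'
#' @param sifs SIF data.frame (already FDR-filtered; see [filter_sifs()]).
#' @param genes a [gene_table()].
#' @param total_valid_pairs the sample's library-wide valid pair count.
#' @param sample_id label stored on the result.
#' @inheritParams assign_anchor
#' @return an object of class `looping_gene_table`: list with `sample_id`,
#'   `total_valid_pairs`, `loops` (data.frame `gene_id`, `chrom`,
#'   `promoter_start/end`, `distal_start/end`, `valid_pairs`, `vppm`) and
#'   `gene_vppm` (data.frame `gene_id`, `vppm`, `n_loops`).
#' @export
call_p1d1_loops <- function(sifs, genes, total_valid_pairs,
                            sample_id = "sample",
                            promoter_upstream = 4000,
                            promoter_downstream = 1000,
                            distal_inner = 10000, distal_outer = 100000,
                            chrom_lengths = NULL) {
  if (!is.numeric(total_valid_pairs) || total_valid_pairs <= 0) {
    stop_input("total_valid_pairs must be positive")
  }
  a1 <- data.frame(chrom = sifs$chrom, start = sifs$start1, end = sifs$end1)
  a2 <- data.frame(chrom = sifs$chrom, start = sifs$start2, end = sifs$end2)
  r1 <- assign_anchors(a1, genes, promoter_upstream, promoter_downstream,
                       distal_inner, distal_outer, chrom_lengths)
  r2 <- assign_anchors(a2, genes, promoter_upstream, promoter_downstream,
                       distal_inner, distal_outer, chrom_lengths)
  # loop when, within one SIF row, one anchor holds promoter(g) and the
  # other holds distal(g)
  loops <- rbind(pair_with_rows(r1, r2, sifs, prom_is_first = TRUE),
                 pair_with_rows(r2, r1, sifs, prom_is_first = FALSE))
  if (is.null(loops) || nrow(loops) == 0L) {
    loops <- data.frame(gene_id = character(), sif = integer(),
                        chrom = character(), promoter_start = numeric(),
                        promoter_end = numeric(), distal_start = numeric(),
                        distal_end = numeric(), valid_pairs = numeric(),
                        stringsAsFactors = FALSE)
  }
  loops <- loops[order(loops$gene_id, loops$sif), , drop = FALSE]
  rownames(loops) <- NULL
  loops$vppm <- loops$valid_pairs / total_valid_pairs * 1e6
  gv <- if (nrow(loops)) {
    agg <- stats::aggregate(cbind(vppm = loops$vppm),
                            by = list(gene_id = loops$gene_id), FUN = sum)
    agg$n_loops <- as.integer(table(loops$gene_id)[agg$gene_id])
    agg
  } else data.frame(gene_id = character(), vppm = numeric(),
                    n_loops = integer())
  structure(list(sample_id = sample_id,
                 total_valid_pairs = total_valid_pairs,
                 loops = loops, gene_vppm = gv),
            class = "looping_gene_table")
}

# promoter roles of one anchor set joined with distal roles of the other,
# matched on the SIF row and gene
pair_with_rows <- function(prom, dist, sifs, prom_is_first) {
  p <- prom[prom$role == "promoter", c("anchor", "gene_id")]
  d <- dist[dist$role == "distal", c("anchor", "gene_id")]
  m <- merge(p, d, by = c("anchor", "gene_id"))
  if (nrow(m) == 0L) return(NULL)
  i <- m$anchor
  data.frame(gene_id = m$gene_id, sif = i, chrom = sifs$chrom[i],
             promoter_start = if (prom_is_first) sifs$start1[i] else sifs$start2[i],
             promoter_end = if (prom_is_first) sifs$end1[i] else sifs$end2[i],
             distal_start = if (prom_is_first) sifs$start2[i] else sifs$start1[i],
             distal_end = if (prom_is_first) sifs$end2[i] else sifs$end1[i],
             valid_pairs = sifs$valid_pairs[i],
             stringsAsFactors = FALSE)
}

#' @export
print.looping_gene_table <- function(x, ...) {
  cat(sprintf(paste0("looping_gene_table '%s': %d P1D1 loops over %d looping",
                     " genes; total valid pairs %g\n"),
              x$sample_id, nrow(x$loops), nrow(x$gene_vppm),
              x$total_valid_pairs))
  invisible(x)
}

#' Per-gene summed VPPM
#'
#' The looping strength of a gene is the sum of the VPPMs of all its P1D1
#' loops.
#'
#' @param table a `looping_gene_table` from [call_p1d1_loops()].
#' @return data.frame `gene_id`, `vppm`, `n_loops`.
#' @export
gene_vppm_table <- function(table) {
  stopifnot(inherits(table, "looping_gene_table"))
  table$gene_vppm
}

#' Write P1D1 loops as BEDPE
#' @param table a `looping_gene_table`.
#' @param path output file.
#' @export
write_loops_bedpe <- function(table, path) {
  lp <- table$loops
  first_prom <- lp$promoter_start <= lp$distal_start
  out <- data.frame(chrom1 = lp$chrom,
                    start1 = ifelse(first_prom, lp$promoter_start, lp$distal_start),
                    end1 = ifelse(first_prom, lp$promoter_end, lp$distal_end),
                    chrom2 = lp$chrom,
                    start2 = ifelse(first_prom, lp$distal_start, lp$promoter_start),
                    end2 = ifelse(first_prom, lp$distal_end, lp$promoter_end),
                    gene_id = lp$gene_id, valid_pairs = lp$valid_pairs,
                    vppm = lp$vppm)
  utils::write.table(format_num_df(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
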