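# Small in-code fixture builders shared across test files.

mk_layout <- function(lengths = c(chr1 = 2e6), bin_size = 4e4) {
  genome_layout(lengths, bin_size = bin_size)
}

# dense-ish random integer contact matrix on one chromosome
mk_random_matrix <- function(n_bins = 50, seed = 1, max_count = 20,
                             density = 0.4) {
  layout <- mk_layout(c(chr1 = n_bins * 4e4))
  set.seed(seed)
  pairs <- expand.grid(bin1 = seq_len(n_bins), bin2 = seq_len(n_bins))
  pairs <- pairs[pairs$bin1 <= pairs$bin2, ]
  keep <- runif(nrow(pairs)) < density
  ent <- pairs[keep, ]
  ent$count <- sample.int(max_count, nrow(ent), replace = TRUE)
  contact_matrix(layout, ent)
}

# domain call set from a TAD coordinate data.frame (gaps filled implicitly)
mk_domains <- function(tads, chrom_length = 2e7) {
  tads$state <- "tad"
  rows <- tads[, c("chrom", "start", "end", "state")]
  # fill complements as gap so states tile
  out <- list()
  for (cm in unique(rows$chrom)) {
    cc <- rows[rows$chrom == cm, ]
    cc <- cc[order(cc$start), ]
    edges <- c(0, rbind(cc$start, cc$end), chrom_length)
    gs <- edges[seq(1, length(edges) - 1, 2)]
    ge <- edges[seq(2, length(edges), 2)]
    keep <- ge > gs
    out[[cm]] <- rbind(cc, data.frame(chrom = cm, start = gs[keep],
                                      end = ge[keep], state = "gap"))
  }
  domain_call_set(do.call(rbind, out))
}

# random TAD tiling of one chromosome, at most max_tads TADs
mk_random_tads <- function(seed, chrom_length = 1e7, max_tads = 20,
                           chrom = "chr1") {
  set.seed(seed)
  tads <- NULL
  cursor <- runif(1, 0, 4e5)
  while (cursor < chrom_length - 2e5 &&
         length(tads$start) < max_tads) {
    len <- runif(1, 2e5, 1.5e6)
    if (cursor + len > chrom_length) break
    tads <- rbind(tads, data.frame(chrom = chrom, start = round(cursor),
                                   end = round(cursor + len)))
    cursor <- cursor + len + runif(1, 0, 5e5)
  }
  if (is.null(tads)) {
    tads <- data.frame(chrom = chrom, start = 0, end = 5e5)
  }
  tads
}

mk_genes <- function(tss, strand = "+", chrom = "chr1",
                     ids = sprintf("g%03d", seq_along(tss))) {
  gene_table(data.frame(gene_id = ids, chrom = chrom, tss = tss,
                        strand = rep(strand, length.out = length(tss)),
                        stringsAsFactors = FALSE))
}

mk_sif <- function(chrom, s1, e1, s2, e2, valid_pairs = 10, fdr = 0.01) {
  data.frame(chrom = chrom, start1 = s1, end1 = e1, start2 = s2, end2 = e2,
             valid_pairs = valid_pairs, fdr = fdr,
             stringsAsFactors = FALSE)
}

# minimal looping_gene_table carrying only per-gene VPPMs (for SLG tests)
mk_vppm_table <- function(vppm, sample_id = "s") {
  structure(list(sample_id = sample_id, total_valid_pairs = 1e6,
                 loops = NULL,
                 gene_vppm = data.frame(gene_id = names(vppm),
                                        vppm = as.numeric(vppm),
                                        n_loops = 1L,
                                        stringsAsFactors = FALSE)),
            class = "looping_gene_table")
}

# mean within-TAD / between-TAD count ratio at matched bin distances
within_between_ratio <- function(mat, domains, max_d_bins = 10) {
  ent <- mat$entries
  bs <- mat$layout$bin_size
  tads <- domains$calls[domains$calls$state == "tad", ]
  pos <- (ent$bin1 - 1) * bs
  pos2 <- (ent$bin2 - 1) * bs
  tad_of <- function(p) {
    i <- findInterval(p, tads$start)
    ifelse(i >= 1 & p >= tads$start[pmax(i, 1)] &
             (p + bs) <= tads$end[pmax(i, 1)], i, NA_integer_)
  }
  t1 <- tad_of(pos); t2 <- tad_of(pos2)
  d <- ent$bin2 - ent$bin1
  keep <- d <= max_d_bins
  within <- !is.na(t1) & !is.na(t2) & t1 == t2
  ratios <- vapply(seq_len(max_d_bins), function(dd) {
    w <- keep & d == dd & within
    b <- keep & d == dd & !within
    if (!any(w) || !any(b)) return(NA_real_)
    mean(ent$count[w]) / mean(ent$count[b])
  }, 0)
  mean(ratios, na.rm = TRUE)
}

# DEG simulator output uses file-dialect column names; map to reader names
rename_deg <- function(tab) {
  data.frame(gene_id = tab$gene_id, log2_fold_change = tab$log2FoldChange,
             p_value = tab$pvalue)
}
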