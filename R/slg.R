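#' Identify strengthened looping genes (SLGs) between two conditions
#'
#' Over the union of looping genes of the two samples (a gene absent from
#' one sample contributes VPPM 0 there), the per-gene VPPM difference
#' `diff = VPPM_b - VPPM_a` is computed, z-scored, and rescaled to \[0, 1\].
#' Genes scoring at least `cutoff` (default 0.15) with `diff > 0` are the
#' SLGs of condition B; SLGs of condition A are computed symmetrically on
#' the negated negative differences. A gene is strengthened in at most one
#' condition, so the two sets are disjoint differential looping genes
#' (DLGs).
#'
#' Because a z-score is unbounded, mapping into \[0, 1\] needs a policy:
#' `pooled_z_minmax` (default) z-scores all differences jointly and min-max
#' scales within the positive (resp. negated negative) subset;
#' `per_sign_z_minmax` z-scores within each sign subset before min-max
#' scaling. A single-gene subset scores 1.
#'
#' @param a,b `looping_gene_table` objects for the two conditions.
#' @param cutoff normalized-score cutoff in \[0, 1\] (default 0.15).
#' @param policy normalization policy (see Details).
#' @return an object of class `slg_result`: list with `condition_a`,
#'   `condition_b`, `table` (data.frame `gene_id`, `vppm_a`, `vppm_b`,
#'   `diff`, `z`, `score`), `slg_a`, `slg_b` (character vectors), `cutoff`,
#'   `policy`.
#' @export
strengthened_looping_genes <- function(a, b, cutoff = 0.15,
                                       policy = c("pooled_z_minmax",
                                                  "per_sign_z_minmax")) {
  policy <- match.arg(policy)
  stopifnot(inherits(a, "looping_gene_table"),
            inherits(b, "looping_gene_table"))
  if (!is.finite(cutoff) || cutoff < 0 || cutoff > 1) {
    stop_input("cutoff must be in [0, 1]")
  }
  va <- stats::setNames(a$gene_vppm$vppm, a$gene_vppm$gene_id)
  vb <- stats::setNames(b$gene_vppm$vppm, b$gene_vppm$gene_id)
  genes <- sort(union(names(va), names(vb)))
  if (length(genes) < 3L) stop_input("need >= 3 looping genes in the union")
  xa <- ifelse(genes %in% names(va), va[genes], 0)
  xb <- ifelse(genes %in% names(vb), vb[genes], 0)
  diff <- unname(xb - xa)
  if (stats::sd(diff) == 0) {
    stop_input("all VPPM differences identical; no strengthened genes definable")
  }
  z <- as.numeric(scale(diff))
  score <- rep(NA_real_, length(diff))
  pos <- which(diff > 0)
  neg <- which(diff < 0)
  score[pos] <- subset_score(diff[pos], z[pos], policy)
  score[neg] <- subset_score(-diff[neg], -z[neg], policy)
  tab <- data.frame(gene_id = genes, vppm_a = unname(xa),
                    vppm_b = unname(xb), diff = diff, z = z, score = score,
                    stringsAsFactors = FALSE)
  structure(list(condition_a = a$sample_id, condition_b = b$sample_id,
                 table = tab,
                 slg_a = tab$gene_id[!is.na(score) & tab$diff < 0 &
                                       score >= cutoff],
                 slg_b = tab$gene_id[!is.na(score) & tab$diff > 0 &
                                       score >= cutoff],
                 cutoff = cutoff, policy = policy),
            class = "slg_result")
}

# normalized score within one sign subset; `mag` are positive magnitudes
subset_score <- function(mag, z_pooled, policy) {
  n <- length(mag)
  if (n == 0L) return(numeric())
  if (n == 1L) return(1)
  z <- switch(policy,
              pooled_z_minmax = z_pooled,
              per_sign_z_minmax = {
                if (stats::sd(mag) == 0) return(rep(1, n))
                as.numeric(scale(mag))
              })
  rng <- range(z)
  if (rng[1] == rng[2]) return(rep(1, n))
  (z - rng[1]) / (rng[2] - rng[1])
}

#' @export
print.slg_result <- function(x, ...) {
  cat(sprintf(paste0("slg_result: %d strengthened in '%s', %d in '%s' ",
                     "(cutoff %.2f, policy %s) over %d genes\n"),
              length(x$slg_b), x$condition_b, length(x$slg_a),
              x$condition_a, x$cutoff, x$policy, nrow(x$table)))
  invisible(x)
}

#' Write the SLG table as TSV
#' @param slg an `slg_result`.
#' @param path output file.
#' @export
write_slg_table <- function(slg, path) {
  tab <- slg$table
  tab$slg <- ifelse(tab$gene_id %in% slg$slg_b, slg$condition_b,
                    ifelse(tab$gene_id %in% slg$slg_a, slg$condition_a, "."))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition P1D1 loops into common and condition-unique sets
#'
#' Two loops match across samples when they belong to the same gene and
#' their distal anchors overlap by at least 1 bp; matching is one-to-one,
#' greedy by decreasing overlap. Unmatched loops are unique to their sample.
#'
#' @param a,b `looping_gene_table` objects.
#' @return list with data.frames `unique_a`, `unique_b` (loop rows) and
#'   `common` (paired rows with `vppm_a` and `vppm_b`).
#' @export
partition_loops <- function(a, b) {
  la <- a$loops; lb <- b$loops
  used_a <- logical(nrow(la)); used_b <- logical(nrow(lb))
  pairs <- NULL
  for (g in intersect(la$gene_id, lb$gene_id)) {
    ia <- which(la$gene_id == g); ib <- which(lb$gene_id == g)
    ov <- outer(seq_along(ia), seq_along(ib), function(i, j) {
      overlap_width(la$distal_start[ia[i]], la$distal_end[ia[i]],
                    lb$distal_start[ib[j]], lb$distal_end[ib[j]])
    })
    while (any(ov > 0)) {
      k <- which(ov == max(ov), arr.ind = TRUE)[1L, ]
      pairs <- rbind(pairs, data.frame(ia = ia[k[1L]], ib = ib[k[2L]]))
      ov[k[1L], ] <- 0; ov[, k[2L]] <- 0
    }
  }
  if (!is.null(pairs)) {
    used_a[pairs$ia] <- TRUE; used_b[pairs$ib] <- TRUE
  }
  common <- if (is.null(pairs)) {
    cbind(la[0, ], vppm_b = numeric())
  } else {
    cm <- la[pairs$ia, , drop = FALSE]
    cm$vppm_b <- lb$vppm[pairs$ib]
    cm
  }
  names(common)[names(common) == "vppm"] <- "vppm_a"
  rownames(common) <- NULL
  list(unique_a = la[!used_a, , drop = FALSE],
       common = common,
       unique_b = lb[!used_b, , drop = FALSE])
}

#' Looping-strength distributions by loop class, with rank-sum tests
#'
#' Gene-level VPPM sums grouped into sample-A-unique, common (scored in
#' each sample), and sample-B-unique classes, with two-sided Wilcoxon
#' rank-sum p-values between every pair of groups.
#'
#' @param partition output of [partition_loops()].
#' @param a,b the `looping_gene_table` objects the partition came from.
#' @return list with `groups` (named list of per-gene VPPM vectors for
#'   `unique_a`, `common_a`, `common_b`, `unique_b`) and `p_values`
#'   (symmetric matrix).
#' @export
strength_distributions <- function(partition, a, b) {
  gene_sum <- function(df, col) {
    if (nrow(df) == 0L) return(numeric())
    as.numeric(tapply(df[[col]], df$gene_id, sum))
  }
  groups <- list(unique_a = gene_sum(partition$unique_a, "vppm"),
                 common_a = gene_sum(partition$common, "vppm_a"),
                 common_b = gene_sum(partition$common, "vppm_b"),
                 unique_b = gene_sum(partition$unique_b, "vppm"))
  empty <- names(groups)[vapply(groups, length, 0L) == 0L]
  if (length(empty)) {
    stop_input("empty loop class: %s", paste(empty, collapse = ", "))
  }
  nm <- names(groups)
  p <- matrix(NA_real_, 4, 4, dimnames = list(nm, nm))
  for (i in 1:3) for (j in (i + 1):4) {
    p[i, j] <- p[j, i] <- stats::wilcox.test(groups[[i]], groups[[j]],
                                             exact = FALSE)$p.value
  }
  diag(p) <- 1
  list(groups = groups, p_values = p)
}
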