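# Independent brute-force oracles. These deliberately avoid the package's
# interval machinery (IRanges, vectorized joins): plain loops and direct
# window arithmetic, so implementation and oracle share no code path.

# -- TAD-change classification oracle ----------------------------------------
# Applies the same stated rules as classify_changes: overlap edges of at
# least min_overlap bp; events carved greedily from the largest-overlap pair
# (ties: leftmost A start, then B start), taking the side with more members
# (ties: larger total overlap, then the split side); 1-1 events classified by
# identity tolerance / 300 kb conserve bound; unmatched TADs are del/neo.
oracle_classify <- function(a_set, b_set, conserve_max_delta = 3e5,
                            identity_tolerance = 4e4, min_overlap = 1) {
  ta <- a_set$calls[a_set$calls$state == "tad", ]
  tb <- b_set$calls[b_set$calls$state == "tad", ]
  out <- character()
  for (cm in union(ta$chrom, tb$chrom)) {
    a <- ta[ta$chrom == cm, ]; b <- tb[tb$chrom == cm, ]
    na <- nrow(a); nb <- nrow(b)
    ov <- matrix(0, max(na, 1), max(nb, 1))
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      w <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (w >= min_overlap) ov[i, j] <- w
    }
    free_a <- rep(TRUE, na); free_b <- rep(TRUE, nb)
    classify_11 <- function(ia, ib) {
      ds <- abs(a$start[ia] - b$start[ib]); de <- abs(a$end[ia] - b$end[ib])
      delta <- (b$end[ib] - b$start[ib]) - (a$end[ia] - a$start[ia])
      if (max(ds, de) <= identity_tolerance) "no_change"
      else if (abs(delta) <= conserve_max_delta &&
               max(ds, de) <= conserve_max_delta) {
        if (delta >= 0) "conserve_expand" else "conserve_shrink"
      } else "shift"
    }
    emit <- function(ias, ibs) {
      type <- if (length(ias) == 0) "neo"
      else if (length(ibs) == 0) "del"
      else if (length(ias) == 1 && length(ibs) >= 2) "split"
      else if (length(ias) >= 2 && length(ibs) == 1) "fuse"
      else classify_11(ias, ibs)
      paste0(cm, "|", type,
             "|a:", paste(sprintf("%d-%d", a$start[ias], a$end[ias]),
                          collapse = ","),
             "|b:", paste(sprintf("%d-%d", b$start[ibs], b$end[ibs]),
                          collapse = ","))
    }
    repeat {
      best <- NULL
      for (i in seq_len(na)) for (j in seq_len(nb)) {
        if (free_a[i] && free_b[j] && ov[i, j] > 0) {
          if (is.null(best) || ov[i, j] > best$w ||
              (ov[i, j] == best$w &&
               (a$start[i] < a$start[best$i] ||
                (a$start[i] == a$start[best$i] &&
                 b$start[j] < b$start[best$j])))) {
            best <- list(i = i, j = j, w = ov[i, j])
          }
        }
      }
      if (is.null(best)) break
      Bs <- which(free_b & ov[best$i, ] > 0)
      As <- which(free_a & ov[, best$j] > 0)
      side_a <- length(As) > length(Bs)
      if (length(As) == length(Bs) && length(As) > 1) {
        side_a <- sum(ov[As, best$j]) > sum(ov[best$i, Bs])
      }
      if (side_a) {
        out <- c(out, emit(As, best$j))
        free_a[As] <- FALSE; free_b[best$j] <- FALSE
      } else {
        out <- c(out, emit(best$i, Bs))
        free_a[best$i] <- FALSE; free_b[Bs] <- FALSE
      }
    }
    for (i in which(free_a)) out <- c(out, emit(i, integer()))
    for (j in which(free_b)) out <- c(out, emit(integer(), j))
  }
  sort(out)
}

# canonical event strings from a tad_changes object, same encoding
canonical_events <- function(changes) {
  ev <- changes$events
  out <- vapply(seq_len(nrow(ev)), function(k) {
    ma <- ev$members_a[[k]]; mb <- ev$members_b[[k]]
    paste0(ev$chrom[k], "|", ev$type[k],
           "|a:", paste(sprintf("%d-%d", ma$start, ma$end), collapse = ","),
           "|b:", paste(sprintf("%d-%d", mb$start, mb$end), collapse = ","))
  }, "")
  sort(out)
}

# -- P1D1 loop-calling oracle ------------------------------------------------
# Exhaustive all-pairs promoter/distal scan with inline window arithmetic.
oracle_p1d1 <- function(sifs, genes, total_valid_pairs,
                        promoter_upstream = 4000, promoter_downstream = 1000,
                        distal_inner = 10000, distal_outer = 100000) {
  windows_of <- function(g) {
    tss <- genes$tss[g]
    if (genes$strand[g] == "+") {
      list(prom = c(tss - promoter_upstream, tss + promoter_downstream),
           dist = list(c(tss - distal_outer, tss - distal_inner),
                       c(tss + distal_inner, tss + distal_outer)))
    } else {
      list(prom = c(tss + 1 - promoter_downstream,
                    tss + 1 + promoter_upstream),
           dist = list(c(tss + 1 + distal_inner, tss + 1 + distal_outer),
                       c(tss + 1 - distal_outer, tss + 1 - distal_inner)))
    }
  }
  hits <- function(s, e, w) max(s, max(w[1], 0)) < min(e, w[2])
  out <- character()
  for (k in seq_len(nrow(sifs))) {
    roles <- list(list(), list())  # per anchor: gene -> role
    for (an in 1:2) {
      s <- if (an == 1) sifs$start1[k] else sifs$start2[k]
      e <- if (an == 1) sifs$end1[k] else sifs$end2[k]
      prom <- character(); dist <- character()
      for (g in seq_len(nrow(genes))) {
        if (genes$chrom[g] != sifs$chrom[k]) next
        w <- windows_of(g)
        if (hits(s, e, w$prom)) prom <- c(prom, genes$gene_id[g])
        if (hits(s, e, w$dist[[1]]) || hits(s, e, w$dist[[2]])) {
          dist <- c(dist, genes$gene_id[g])
        }
      }
      if (length(prom)) dist <- character()  # promoter priority
      roles[[an]] <- list(prom = prom, dist = dist)
    }
    for (g in union(roles[[1]]$prom, roles[[2]]$prom)) {
      if (g %in% roles[[1]]$prom && g %in% roles[[2]]$dist) {
        out <- c(out, sprintf("%s|%d|%d", g, k, sifs$valid_pairs[k]))
      }
      if (g %in% roles[[2]]$prom && g %in% roles[[1]]$dist) {
        out <- c(out, sprintf("%s|%d|%d", g, k, sifs$valid_pairs[k]))
      }
    }
  }
  sort(out)
}

canonical_loops <- function(table) {
  lp <- table$loops
  sort(sprintf("%s|%d|%d", lp$gene_id, lp$sif, lp$valid_pairs))
}

# random gene/SIF scenario for loop-oracle equivalence (no spacing
# guarantees, so overlapping windows and priority cases arise naturally)
mk_loop_scenario <- function(seed, n_genes = 40, n_sifs = 120,
                             span = 5e6) {
  set.seed(seed)
  genes <- gene_table(data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    tss = round(runif(n_genes, 1.5e5, span - 1.5e5)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE))
  s1 <- round(runif(n_sifs, 0, span - 3e5))
  w1 <- round(runif(n_sifs, 1e3, 6e3))
  gap <- round(runif(n_sifs, 2e3, 1.5e5))
  w2 <- round(runif(n_sifs, 1e3, 6e3))
  sifs <- data.frame(chrom = sample(c("chr1", "chr2"), n_sifs,
                                    replace = TRUE),
                     start1 = s1, end1 = s1 + w1,
                     start2 = s1 + w1 + gap, end2 = s1 + w1 + gap + w2,
                     valid_pairs = sample.int(500, n_sifs, replace = TRUE),
                     fdr = runif(n_sifs, 0, 0.1),
                     stringsAsFactors = FALSE)
  list(genes = genes, sifs = sifs)
}
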