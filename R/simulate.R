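#' Scenario specification for the synthetic-data generator
#'
#' Bundles every parameter of the synthetic pipeline inputs: genome layout,
#' gene placement, TAD size distribution and planted change plan, contact
#' distance decay and within-TAD enrichment, planted promoter-distal loops
#' with controlled strengths, and a differential-expression plan. The
#' defaults describe the desk-scale study conditions used throughout the
#' package tests: one 20 Mb chromosome at 40 kb bins, 60 genes, a sequencing
#' depth of 2e6 valid pairs, one planted TAD-change event of each of the
#' eight types, 5% of genes with 5-fold strengthened loops in condition B,
#' and 30% of genes differentially expressed.
#'
#' @param seed master integer seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param n_chrom,chrom_length,bin_size genome layout (bp).
#' @param n_genes,gene_min_spacing gene placement; spacing (default 250 kb)
#'   keeps promoter/distal windows of distinct genes disjoint.
#' @param tad_median,tad_sdlog log-normal TAD size distribution (bp,
#'   log-sd).
#' @param boundary_width width of boundary calls, bp (one bin).
#' @param change_plan named counts of planted TAD-change events (names among
#'   the eight change types).
#' @param decay_alpha,tad_enrichment,depth contact model: expected count at
#'   bin distance d is proportional to `d^-decay_alpha`, multiplied by
#'   `tad_enrichment` when both bins lie in one TAD, scaled so the expected
#'   total is `depth`; realized counts are Poisson.
#' @param loops_per_gene_rate each gene gets `1 + Poisson(rate)` loops.
#' @param base_strength expected valid pairs per loop at multiplier 1.
#' @param strength_multiplier_a,strength_multiplier_b per-condition
#'   multipliers on loop strength.
#' @param frac_strengthened,effect_size fraction of genes whose loops are
#'   `effect_size`-fold stronger in condition B.
#' @param frac_unique_a,frac_unique_b fraction of non-strengthened loops
#'   emitted in only one condition.
#' @param n_decoys number of non-P1D1 decoy SIFs (distal-distal,
#'   promoter-promoter cross-gene, beyond-range anchors).
#' @param frac_de fraction of genes differentially expressed.
#' @return a validated list of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1,
                          n_chrom = 1, chrom_length = 20e6, bin_size = 40000,
                          n_genes = 60, gene_min_spacing = 250000,
                          tad_median = 8e5, tad_sdlog = 0.4,
                          boundary_width = 40000,
                          change_plan = c(no_change = 1, conserve_expand = 1,
                                          conserve_shrink = 1, shift = 1,
                                          split = 1, fuse = 1, neo = 1,
                                          del = 1),
                          decay_alpha = 1, tad_enrichment = 3, depth = 2e6,
                          loops_per_gene_rate = 0.7, base_strength = 100,
                          strength_multiplier_a = 1,
                          strength_multiplier_b = 1,
                          frac_strengthened = 0.05, effect_size = 5,
                          frac_unique_a = 0.15, frac_unique_b = 0.15,
                          n_decoys = 40, frac_de = 0.3) {
  spec <- as.list(environment())
  fr <- c(frac_strengthened, frac_unique_a, frac_unique_b, frac_de)
  if (any(fr < 0 | fr > 1)) stop_input("fractions must be in [0, 1]")
  if (decay_alpha <= 0) stop_input("decay_alpha must be > 0")
  if (tad_enrichment < 1) stop_input("tad_enrichment must be >= 1")
  if (depth <= 0) stop_input("depth must be > 0")
  if (!all(names(change_plan) %in% CHANGE_TYPES)) {
    stop_input("unknown change type in plan: %s",
               paste(setdiff(names(change_plan), CHANGE_TYPES),
                     collapse = ", "))
  }
  structure(spec, class = "scenario_spec")
}

#' Simulate a genome layout and gene annotation
#'
#' Genes are placed uniformly per chromosome with a minimum spacing
#' (default 250 kb) so that promoter and distal windows of distinct genes
#' never overlap; strands are sampled. A 150 kb margin keeps all windows
#' inside the chromosome.
#'
#' @param spec a [scenario_spec()].
#' @return list with `layout` (a [genome_layout()]) and `genes` (a
#'   [gene_table()]).
#' @export
simulate_genome <- function(spec) {
  layout <- genome_layout(stats::setNames(rep(spec$chrom_length,
                                              spec$n_chrom),
                                          paste0("chr", seq_len(spec$n_chrom))),
                          bin_size = spec$bin_size)
  margin <- 150000
  per <- diff(floor(seq(0, spec$n_genes, length.out = spec$n_chrom + 1)))
  with_seed(spec$seed + 11L, {
    rows <- list()
    gi <- 0L
    for (k in seq_len(spec$n_chrom)) {
      n_c <- per[k]
      if (n_c == 0L) next
      avail <- (spec$chrom_length - 2 * margin) -
        (n_c - 1) * spec$gene_min_spacing
      if (avail < 0) {
        stop_input(paste0("cannot place %d genes with %g bp spacing on a ",
                          "%g bp chromosome"),
                   n_c, spec$gene_min_spacing, spec$chrom_length)
      }
      u <- sort(stats::runif(n_c, 0, avail))
      tss <- round(margin + u + (seq_len(n_c) - 1) * spec$gene_min_spacing)
      rows[[k]] <- data.frame(
        gene_id = sprintf("g%04d", gi + seq_len(n_c)),
        chrom = paste0("chr", k), tss = tss,
        strand = sample(c("+", "-"), n_c, replace = TRUE),
        stringsAsFactors = FALSE)
      gi <- gi + n_c
    }
    list(layout = layout, genes = gene_table(do.call(rbind, rows)))
  })
}

# per-event content widths in bp, all bin-aligned
event_geometry <- function(type, L, bw) {
  half <- function(x) floor(x / 2 / bw) * bw  # bin-aligned half
  switch(type,
    no_change = list(a = cbind(0, L), b = cbind(0, L), width = L),
    conserve_expand = list(a = cbind(0, L), b = cbind(0, L + 200000),
                           width = L + 200000),
    conserve_shrink = list(a = cbind(0, L), b = cbind(0, L - 200000),
                           width = L),
    shift = list(a = cbind(0, L), b = cbind(400000, L + 400000),
                 width = L + 400000),
    split = list(a = cbind(0, L),
                 b = rbind(cbind(0, half(L)), cbind(half(L) + bw, L)),
                 width = L),
    fuse = list(a = rbind(cbind(0, half(L)), cbind(half(L) + bw, L)),
                b = cbind(0, L), width = L),
    neo = list(a = NULL, b = cbind(0, L), width = L),
    del = list(a = cbind(0, L), b = NULL, width = L))
}

#' Simulate a two-condition domain pair with planted change events
#'
#' Tiles the genome with TAD/boundary/gap calls for condition A and applies
#' the requested number of each change type to produce condition B. Events
#' are separated by gaps wider than the 300 kb conserve bound, so every
#' planted event is unambiguous and [classify_changes()] recovers the
#' planted type multiset exactly. All coordinates are bin-aligned.
#'
#' @param spec a [scenario_spec()].
#' @param layout optional [genome_layout()] (defaults to the spec's).
#' @return list with `a`, `b` ([domain_call_set()]s) and `truth`
#'   (data.frame `chrom`, `type`, `slot_start`, `slot_end`).
#' @export
simulate_domain_pair <- function(spec, layout = NULL) {
  layout <- layout %||% simulate_genome(spec)$layout
  bw <- spec$boundary_width
  bs <- spec$bin_size
  pad <- 360000  # > 300 kb conserve bound, bin-aligned for 40 kb bins
  pad <- ceiling(pad / bs) * bs
  plan <- spec$change_plan[spec$change_plan > 0]
  types <- rep(names(plan), plan)
  with_seed(spec$seed + 22L, {
    L_all <- pmin(1600000, pmax(520000,
                                round(stats::rlnorm(length(types),
                                                    log(spec$tad_median),
                                                    spec$tad_sdlog) / bs) * bs))
    calls_a <- list(); calls_b <- list(); truth <- list()
    ch <- layout$chromosomes
    k <- 1L; cursor <- 0
    for (t in seq_along(types)) {
      geom <- event_geometry(types[t], L_all[t], bw)
      need <- pad + geom$width + pad
      while (k <= nrow(ch) && cursor + need > ch$length[k]) {
        k <- k + 1L; cursor <- 0
      }
      if (k > nrow(ch)) {
        stop_input("change plan does not fit the genome; %d of %d events placed",
                   t - 1L, length(types))
      }
      off <- cursor + pad
      cm <- ch$name[k]
      emit <- function(mat) {
        if (is.null(mat)) return(NULL)
        out <- list()
        for (r in seq_len(nrow(mat))) {
          out[[r]] <- data.frame(chrom = cm, start = off + mat[r, 1],
                                 end = off + mat[r, 2], state = "tad",
                                 stringsAsFactors = FALSE)
        }
        # 1-bin boundary between consecutive TADs of a split/fuse side
        if (nrow(mat) == 2L) {
          out[[3L]] <- data.frame(chrom = cm, start = off + mat[1L, 2],
                                  end = off + mat[2L, 1], state = "boundary",
                                  stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
      }
      calls_a[[t]] <- emit(geom$a)
      calls_b[[t]] <- emit(geom$b)
      truth[[t]] <- data.frame(chrom = cm, type = types[t],
                               slot_start = off, slot_end = off + geom$width,
                               stringsAsFactors = FALSE)
      cursor <- cursor + pad + geom$width
    }
    a <- fill_gaps(do.call(rbind, calls_a), layout)
    b <- fill_gaps(do.call(rbind, calls_b), layout)
    list(a = a, b = b, truth = do.call(rbind, truth))
  })
}

# complement explicit calls with gap calls so states tile each chromosome
fill_gaps <- function(calls, layout) {
  if (is.null(calls)) {
    calls <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), state = character())
  }
  ch <- layout$chromosomes
  out <- list()
  for (k in seq_len(nrow(ch))) {
    cc <- calls[calls$chrom == ch$name[k], , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    edges <- c(0, rbind(cc$start, cc$end), ch$length[k])
    starts <- edges[seq(1, length(edges) - 1, by = 2)]
    ends <- edges[seq(2, length(edges), by = 2)]
    keep <- ends > starts
    gaps <- data.frame(chrom = ch$name[k], start = starts[keep],
                       end = ends[keep], state = "gap",
                       stringsAsFactors = FALSE)
    out[[k]] <- rbind(cc, gaps)
  }
  domain_call_set(do.call(rbind, out), layout = layout)
}

#' Simulate a contact matrix with distance decay and TAD enrichment
#'
#' Expected count at bin distance d is `C * d^-alpha`, multiplied by the
#' enrichment factor when both bins lie inside the same TAD; `C` is chosen
#' so the expected genome-wide total equals the spec's depth. Realized
#' counts are Poisson; zero draws are dropped from the sparse set.
#'
#' @param layout a [genome_layout()].
#' @param domains a [domain_call_set()] supplying the TAD blocks.
#' @param spec a [scenario_spec()].
#' @param seed integer seed (defaults to a sub-seed of the spec's).
#' @return a [contact_matrix()] with `total_valid_pairs` equal to the
#'   realized count sum.
#' @export
simulate_contact_matrix <- function(layout, domains, spec,
                                    seed = spec$seed + 33L) {
  ch <- layout$chromosomes
  tads <- tads_of(domains)
  acc <- list()
  for (k in seq_len(nrow(ch))) {
    n <- ch$n_bins[k]
    first <- ch$first_bin[k]
    # TAD membership of each bin (NA when not fully inside one TAD)
    tk <- tads[tads$chrom == ch$name[k], , drop = FALSE]
    bin_start <- (seq_len(n) - 1) * layout$bin_size
    bin_end <- bin_start + layout$bin_size
    tid <- rep(NA_integer_, n)
    if (nrow(tk)) {
      idx <- findInterval(bin_start, tk$start)
      ok <- idx >= 1 & bin_start >= tk$start[pmax(idx, 1)] &
        bin_end <= tk$end[pmax(idx, 1)]
      tid[ok] <- idx[ok]
    }
    for (d in seq_len(n - 1L)) {
      i <- seq_len(n - d)
      j <- i + d
      l <- d^(-spec$decay_alpha) *
        ifelse(!is.na(tid[i]) & !is.na(tid[j]) & tid[i] == tid[j],
               spec$tad_enrichment, 1)
      acc[[length(acc) + 1L]] <- list(i = first + i - 1L,
                                      j = first + j - 1L, l = l)
    }
  }
  ii <- unlist(lapply(acc, `[[`, "i"))
  jj <- unlist(lapply(acc, `[[`, "j"))
  lam <- unlist(lapply(acc, `[[`, "l"))
  lam <- lam * spec$depth / sum(lam)
  counts <- with_seed(seed, stats::rpois(length(lam), lam))
  keep <- counts > 0
  contact_matrix(layout,
                 data.frame(bin1 = ii[keep], bin2 = jj[keep],
                            count = as.numeric(counts[keep])),
                 total_valid_pairs = sum(counts))
}

#' Simulate per-condition SIF tables with planted P1D1 loops
#'
#' Each gene receives `1 + Poisson(rate)` planted loops: one anchor inside
#' the gene's promoter window, the other inside a distal window, with valid
#' pairs Poisson around `base_strength` times the condition multiplier
#' (times `effect_size` in condition B for strengthened genes) and FDR
#' drawn in \[0, 0.1\]. A fraction of non-strengthened loops is emitted in
#' only one condition. Decoy SIFs with non-P1D1 geometry (distal-distal,
#' promoter-promoter across genes, anchors beyond the distal range) carry
#' FDR in \[0, 1\]; the gene spacing guarantees no decoy can form a loop.
#'
#' @param genes a [gene_table()].
#' @param spec a [scenario_spec()].
#' @param seed integer seed (defaults to a sub-seed of the spec's).
#' @return list with `sif_a`, `sif_b` (SIF data.frames) and `truth` (list
#'   with `loops` data.frame, `strengthened_genes`, per-condition planted
#'   loop counts).
#' @export
simulate_sif_tables <- function(genes, spec, seed = spec$seed + 44L) {
  pw <- promoter_window(genes)
  dw <- distal_windows(genes)
  with_seed(seed, {
    n_str <- round(spec$frac_strengthened * nrow(genes))
    strengthened <- sort(sample(genes$gene_id, n_str))
    rows <- list()
    for (g in seq_len(nrow(genes))) {
      gid <- genes$gene_id[g]
      n_loops <- 1L + stats::rpois(1L, spec$loops_per_gene_rate)
      gdw <- dw[dw$gene_id == gid & dw$end - dw$start >= 20000, ,
                drop = FALSE]
      for (l in seq_len(n_loops)) {
        side <- gdw[sample(nrow(gdw), 1L), ]
        p_off <- floor(stats::runif(1, 0, (pw$end[g] - pw$start[g]) - 2000))
        d_off <- floor(stats::runif(1, 0, (side$end - side$start) - 4000))
        u <- stats::runif(1)
        cond <- if (gid %in% strengthened) "common"
        else if (u < spec$frac_unique_a) "a_only"
        else if (u < spec$frac_unique_a + spec$frac_unique_b) "b_only"
        else "common"
        lam <- spec$base_strength * stats::runif(1, 0.8, 1.2)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, chrom = genes$chrom[g],
          p_start = pw$start[g] + p_off, p_end = pw$start[g] + p_off + 2000,
          d_start = side$start + d_off, d_end = side$start + d_off + 4000,
          lambda = lam, cond = cond,
          strengthened = gid %in% strengthened,
          stringsAsFactors = FALSE)
      }
    }
    loops <- do.call(rbind, rows)
    draw <- function(lam) pmax(1L, stats::rpois(length(lam), lam))
    mult_b_eff <- spec$strength_multiplier_b *
      ifelse(loops$strengthened, spec$effect_size, 1)
    loops$count_a <- ifelse(loops$cond != "b_only",
                            draw(loops$lambda * spec$strength_multiplier_a),
                            NA)
    loops$count_b <- ifelse(loops$cond != "a_only",
                            draw(loops$lambda * mult_b_eff), NA)
    loops$fdr <- stats::runif(nrow(loops), 0, 0.1)
    decoys <- make_decoys(genes, pw, dw, spec$n_decoys)
    sif_of <- function(count_col) {
      keep <- !is.na(loops[[count_col]])
      planted <- data.frame(chrom = loops$chrom[keep],
                            start1 = loops$p_start[keep],
                            end1 = loops$p_end[keep],
                            start2 = loops$d_start[keep],
                            end2 = loops$d_end[keep],
                            valid_pairs = loops[[count_col]][keep],
                            fdr = loops$fdr[keep],
                            stringsAsFactors = FALSE)
      dec <- decoys
      if (!is.null(dec)) {
        dec$valid_pairs <- 1L + stats::rpois(nrow(dec), 50)
        planted <- rbind(planted, dec)
      }
      validate_sifs(planted)
    }
    sif_a <- sif_of("count_a")
    sif_b <- sif_of("count_b")
    list(sif_a = sif_a, sif_b = sif_b,
         truth = list(loops = loops, strengthened_genes = strengthened,
                      n_planted_a = sum(!is.na(loops$count_a)),
                      n_planted_b = sum(!is.na(loops$count_b)),
                      n_common = sum(loops$cond == "common")))
  })
}

# decoy SIFs that satisfy no promoter-distal geometry
make_decoys <- function(genes, pw, dw, n_decoys) {
  if (n_decoys == 0L) return(NULL)
  rows <- list()
  kinds <- rep(c("dd", "pp", "far"), length.out = n_decoys)
  for (i in seq_len(n_decoys)) {
    g <- ((i - 1L) %% nrow(genes)) + 1L
    gid <- genes$gene_id[g]
    gdw <- dw[dw$gene_id == gid, , drop = FALSE]
    up <- gdw[gdw$side == "upstream", ]; dn <- gdw[gdw$side == "downstream", ]
    row <- switch(kinds[i],
      dd = if (up$end - up$start >= 4000 && dn$end - dn$start >= 4000) {
        data.frame(chrom = genes$chrom[g], start1 = up$start,
                   end1 = up$start + 4000, start2 = dn$end - 4000,
                   end2 = dn$end, stringsAsFactors = FALSE)
      },
      pp = {
        same <- which(genes$chrom == genes$chrom[g] &
                        genes$gene_id != gid)
        if (length(same)) {
          g2 <- same[1L]
          data.frame(chrom = genes$chrom[g],
                     start1 = pw$start[g], end1 = pw$start[g] + 1000,
                     start2 = pw$start[g2], end2 = pw$start[g2] + 1000,
                     stringsAsFactors = FALSE)
        }
      },
      far = data.frame(chrom = genes$chrom[g],
                       start1 = genes$tss[g] + 110000,
                       end1 = genes$tss[g] + 114000,
                       start2 = genes$tss[g] + 180000,
                       end2 = genes$tss[g] + 184000,
                       stringsAsFactors = FALSE))
    if (!is.null(row) && row$start1 != row$start2) {
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) return(NULL)
  dec <- do.call(rbind, rows)
  dec$valid_pairs <- 1L
  dec$fdr <- stats::runif(nrow(dec))
  dec
}

#' Simulate a differential-expression table with planted effects
#'
#' DE genes get `|log2FC| >= 0.58` (0.58 plus an exponential excess, random
#' sign) and p in \[0, 0.05\]; null genes get either a truncated-normal
#' fold change below 0.58, or p above 0.05, so the planted DEG set is
#' recovered exactly by [filter_degs()] at the default cutoffs.
#'
#' @param genes a [gene_table()].
#' @param spec a [scenario_spec()].
#' @param de_genes optional character vector forcing the DE set (defaults
#'   to a random `frac_de` of the genes).
#' @param seed integer seed (defaults to a sub-seed of the spec's).
#' @return list with `table` (data.frame `gene_id`, `log2FoldChange`,
#'   `pvalue`) and `truth` (the DE gene ids).
#' @export
simulate_deg_table <- function(genes, spec, de_genes = NULL,
                               seed = spec$seed + 55L) {
  with_seed(seed, {
    ids <- genes$gene_id
    if (is.null(de_genes)) {
      de_genes <- sort(sample(ids, round(spec$frac_de * length(ids))))
    }
    is_de <- ids %in% de_genes
    n <- length(ids)
    lfc <- numeric(n); p <- numeric(n)
    lfc[is_de] <- sample(c(-1, 1), sum(is_de), replace = TRUE) *
      (0.58 + stats::rexp(sum(is_de), rate = 1))
    p[is_de] <- stats::runif(sum(is_de), 0, 0.05)
    null_idx <- which(!is_de)
    low_lfc <- stats::runif(length(null_idx)) < 0.5
    for (k in seq_along(null_idx)) {
      i <- null_idx[k]
      if (low_lfc[k]) {
        repeat {
          x <- stats::rnorm(1, 0, 0.2)
          if (abs(x) < 0.58) break
        }
        lfc[i] <- x
        p[i] <- stats::runif(1)
      } else {
        lfc[i] <- stats::rnorm(1, 0, 1)
        p[i] <- 0.05 + stats::runif(1) * 0.95
        if (p[i] == 0.05) p[i] <- 0.051
      }
    }
    list(table = data.frame(gene_id = ids, log2FoldChange = lfc,
                            pvalue = p, stringsAsFactors = FALSE),
         truth = sort(de_genes))
  })
}

#' Emit a complete synthetic scenario to disk
#'
#' Writes every input dialect the pipeline consumes -- HiC-Pro bins +
#' matrix per condition, TopDom-style domain calls per condition, SIF
#' TSVs, a BED6 gene annotation and a DEG TSV -- plus `truth.json`
#' recording all planted ground truth. Byte-identical for identical specs.
#'
#' @param spec a [scenario_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with all in-memory objects, the `truth` list
#'   and the file `paths`.
#' @export
simulate_scenario <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(spec)
  pair <- simulate_domain_pair(spec, genome$layout)
  mat_a <- simulate_contact_matrix(genome$layout, pair$a, spec,
                                   seed = spec$seed + 33L)
  mat_b <- simulate_contact_matrix(genome$layout, pair$b, spec,
                                   seed = spec$seed + 34L)
  sifs <- simulate_sif_tables(genome$genes, spec)
  deg <- simulate_deg_table(genome$genes, spec)
  p <- function(...) file.path(dir, ...)
  write_genes_bed(genome$genes, p("genes.bed"))
  write_topdom(pair$a, p("domains_a.tsv"))
  write_topdom(pair$b, p("domains_b.tsv"))
  write_hicpro_matrix(mat_a, p("matrix_a"))
  write_hicpro_matrix(mat_b, p("matrix_b"))
  write_sifs(sifs$sif_a, p("sifs_a.tsv"))
  write_sifs(sifs$sif_b, p("sifs_b.tsv"))
  utils::write.table(deg$table, p("deg.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(seed = spec$seed,
                change_events = as.list(table(pair$truth$type)),
                n_tads_a = sum(pair$a$calls$state == "tad"),
                n_tads_b = sum(pair$b$calls$state == "tad"),
                strengthened_genes = sifs$truth$strengthened_genes,
                n_planted_loops_a = sifs$truth$n_planted_a,
                n_planted_loops_b = sifs$truth$n_planted_b,
                n_common_loops = sifs$truth$n_common,
                de_genes = deg$truth)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE), p("truth.json"))
  invisible(list(spec = spec, layout = genome$layout, genes = genome$genes,
                 domains = pair[c("a", "b")], domain_truth = pair$truth,
                 matrices = list(a = mat_a, b = mat_b), sifs = sifs,
                 deg = deg, truth = truth,
                 paths = list(dir = dir, genes = p("genes.bed"),
                              domains_a = p("domains_a.tsv"),
                              domains_b = p("domains_b.tsv"),
                              matrix_a = p("matrix_a"),
                              matrix_b = p("matrix_b"),
                              sifs_a = p("sifs_a.tsv"),
                              sifs_b = p("sifs_b.tsv"),
                              deg = p("deg.tsv"),
                              truth = p("truth.json"))))
}
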