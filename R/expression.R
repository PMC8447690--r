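#' Read a differential-expression result table
#'
#' Expects a TSV with a gene id column plus `log2FoldChange` and `pvalue`
#' columns (DESeq2 export names; matched case-insensitively, `lfc`/`p` and
#' `padj` also recognized). An adjusted-p column is carried along but only
#' used when selected via `p_column = "padj"` in [filter_degs()].
#'
#' @param path input TSV (with header).
#' @return data.frame with columns `gene_id`, `log2_fold_change`, `p_value`
#'   and, when present, `p_adjusted`.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  lc <- tolower(names(df))
  gid <- match(TRUE, lc %in% c("gene_id", "gene", "geneid", "id", "row.names"))
  lfc <- match(TRUE, lc %in% c("log2foldchange", "log2fc", "lfc"))
  pv <- match(TRUE, lc %in% c("pvalue", "p_value", "p"))
  if (is.na(gid) || is.na(lfc) || is.na(pv)) {
    stop_input("%s: need gene id, log2FoldChange and pvalue columns", path)
  }
  out <- data.frame(gene_id = as.character(df[[gid]]),
                    log2_fold_change = as.numeric(df[[lfc]]),
                    p_value = as.numeric(df[[pv]]),
                    stringsAsFactors = FALSE)
  adj <- match(TRUE, lc %in% c("padj", "p_adjusted", "fdr"))
  if (!is.na(adj)) out$p_adjusted <- as.numeric(df[[adj]])
  if (any(!is.finite(out$log2_fold_change))) {
    stop_input("%s: non-finite log2 fold changes", path)
  }
  if (any(out$p_value < 0 | out$p_value > 1, na.rm = TRUE)) {
    stop_input("%s: p-values outside [0, 1]", path)
  }
  out
}

#' Filter differentially expressed genes
#'
#' Keeps genes with `|log2FC| >= min_abs_lfc` and `p <= max_p`, both
#' inclusive (defaults 0.58 and 0.05, i.e. an absolute fold change of about
#' 1.5 at nominal significance).
#'
#' @param records data.frame as from [read_deg_table()].
#' @param min_abs_lfc minimum absolute log2 fold change.
#' @param max_p maximum p-value.
#' @param p_column `"p_value"` (raw, default) or `"p_adjusted"`.
#' @return character vector of gene ids passing the filter.
#' @export
filter_degs <- function(records, min_abs_lfc = 0.58, max_p = 0.05,
                        p_column = c("p_value", "p_adjusted")) {
  p_column <- match.arg(p_column)
  if (!p_column %in% names(records)) {
    stop_input("column '%s' absent from DEG table", p_column)
  }
  keep <- abs(records$log2_fold_change) >= min_abs_lfc &
    records[[p_column]] <= max_p
  keep[is.na(keep)] <- FALSE
  records$gene_id[keep]
}

#' Intersect strengthened looping genes with differentially expressed genes
#'
#' Differentially expressed looping genes (DELGs) are the SLGs of a
#' condition that also pass the DEG filter; one report per condition.
#'
#' @param slg an `slg_result` from [strengthened_looping_genes()].
#' @param degs character vector of DEG ids (see [filter_degs()]).
#' @param deg_table optional DEG data.frame used to annotate the report
#'   rows with fold change and p-value.
#' @return list of two `delg_report` objects (`a`, `b`), each with
#'   `condition`, `delg_ids`, and `table` (per-gene `vppm_a`, `vppm_b`,
#'   `diff`, `score`, `lfc`, `p`).
#' @export
intersect_delgs <- function(slg, degs, deg_table = NULL) {
  stopifnot(inherits(slg, "slg_result"))
  one <- function(slg_ids, condition) {
    ids <- sort(intersect(slg_ids, degs))
    tab <- slg$table[match(ids, slg$table$gene_id),
                     c("gene_id", "vppm_a", "vppm_b", "diff", "score"),
                     drop = FALSE]
    if (!is.null(deg_table)) {
      m <- match(ids, deg_table$gene_id)
      tab$lfc <- deg_table$log2_fold_change[m]
      tab$p <- deg_table$p_value[m]
    } else {
      tab$lfc <- rep(NA_real_, nrow(tab))
      tab$p <- rep(NA_real_, nrow(tab))
    }
    rownames(tab) <- NULL
    structure(list(condition = condition, delg_ids = ids, table = tab),
              class = "delg_report")
  }
  list(a = one(slg$slg_a, slg$condition_a),
       b = one(slg$slg_b, slg$condition_b))
}

#' @export
print.delg_report <- function(x, ...) {
  cat(sprintf("delg_report '%s': %d differentially expressed looping genes\n",
              x$condition, length(x$delg_ids)))
  invisible(x)
}

#' Assemble a structured end-to-end run report
#'
#' Gathers the stage outputs of one pipeline run into a single
#' deterministic document (no timestamps): TAD counts and change summary,
#' loop partition sizes, SLG/DELG counts, parameters and seeds.
#'
#' @param tad_summary a `change_summary` (or NULL).
#' @param domain_sets named list of `domain_call_set` objects (or NULL).
#' @param partition output of [partition_loops()] (or NULL).
#' @param loops_a,loops_b `looping_gene_table` objects (or NULL).
#' @param slg an `slg_result` (or NULL).
#' @param degs character vector of DEG ids (or NULL).
#' @param delgs output of [intersect_delgs()] (or NULL).
#' @param params named list of parameters to record.
#' @param seed integer seed recorded in the report.
#' @return a list with a fixed schema (`schema_version`, `tool`, `seed`,
#'   `parameters`, `tads`, `loops`, `slg`, `expression`).
#' @export
build_run_report <- function(tad_summary = NULL, domain_sets = NULL,
                             partition = NULL, loops_a = NULL,
                             loops_b = NULL, slg = NULL, degs = NULL,
                             delgs = NULL, params = list(), seed = NA) {
  count_states <- function(set) {
    tab <- table(factor(set$calls$state, c("tad", "boundary", "gap")))
    as.list(stats::setNames(as.integer(tab), names(tab)))
  }
  list(
    schema_version = "1.0",
    tool = list(name = "tadloop",
                version = as.character(utils::packageVersion("tadloop"))),
    seed = seed,
    parameters = params,
    tads = list(
      calls = if (is.null(domain_sets)) NULL else
        lapply(domain_sets, count_states),
      changes = if (is.null(tad_summary)) NULL else list(
        n_events = tad_summary$n_events,
        counts = as.list(tad_summary$counts),
        fractions = as.list(tad_summary$fractions),
        rc_fraction = tad_summary$rc_fraction,
        dc_fraction = tad_summary$dc_fraction)),
    loops = list(
      n_loops_a = if (is.null(loops_a)) NULL else nrow(loops_a$loops),
      n_loops_b = if (is.null(loops_b)) NULL else nrow(loops_b$loops),
      n_looping_genes_a = if (is.null(loops_a)) NULL else
        nrow(loops_a$gene_vppm),
      n_looping_genes_b = if (is.null(loops_b)) NULL else
        nrow(loops_b$gene_vppm),
      partition = if (is.null(partition)) NULL else list(
        unique_a = nrow(partition$unique_a),
        common = nrow(partition$common),
        unique_b = nrow(partition$unique_b))),
    slg = if (is.null(slg)) NULL else list(
      n_slg_a = length(slg$slg_a), n_slg_b = length(slg$slg_b),
      cutoff = slg$cutoff, policy = slg$policy),
    expression = list(
      n_deg = if (is.null(degs)) NULL else length(degs),
      n_delg_a = if (is.null(delgs)) NULL else length(delgs$a$delg_ids),
      n_delg_b = if (is.null(delgs)) NULL else length(delgs$b$delg_ids)))
}

#' Write a run report as canonical JSON
#'
#' Deterministic for identical inputs: fixed key order, fixed digits, no
#' timestamps.
#'
#' @param report list from [build_run_report()].
#' @param path output file.
#' @export
write_run_report <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}
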