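#' Default pipeline parameters
#'
#' All tunables of the analysis with their standard defaults: the 300 kb
#' conserve bound and one-bin identity tolerance for TAD-change
#' classification, the -4 kb/+1 kb promoter and 10-100 kb distal windows,
#' the inclusive SIF FDR cutoff 0.1, the SLG score cutoff 0.15, the DEG
#' cutoffs |log2FC| >= 0.58 and p <= 0.05, and the LOWESS span 0.3 with
#' pseudocount 1.
#'
#' @return named list of parameters.
#' @export
default_pipeline_params <- function() {
  list(conserve_max_delta = 300000, identity_tolerance = 40000,
       min_overlap = 1,
       promoter_upstream = 4000, promoter_downstream = 1000,
       distal_inner = 10000, distal_outer = 100000,
       sif_max_fdr = 0.1,
       slg_cutoff = 0.15, slg_policy = "pooled_z_minmax",
       deg_min_abs_lfc = 0.58, deg_max_p = 0.05,
       smoothing_fraction = 0.3, pseudocount = 1.0)
}

#' Build and validate a pipeline configuration
#'
#' A configuration is a list (or YAML file) with `seed`, optional
#' `scenario` overrides for the synthetic generator, optional `inputs`
#' paths (`genes`, `domains_a`, `domains_b`, `matrix_a`, `matrix_b`,
#' `sifs_a`, `sifs_b`, `deg`; matrix entries are HiC-Pro path prefixes),
#' and `params` overriding [default_pipeline_params()]. Unknown or
#' out-of-range keys raise a config error naming them.
#'
#' @param config a list, or the path of a YAML file.
#' @return the validated, default-filled config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_input("config must be a list or a YAML path")
  known <- c("schema_version", "seed", "scenario", "inputs", "params")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop_input("unknown config keys: %s",
                              paste(bad, collapse = ", "))
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  bad <- setdiff(names(params), names(default_pipeline_params()))
  if (length(bad)) stop_input("unknown parameter keys: %s",
                              paste(bad, collapse = ", "))
  offenders <- character()
  chk <- function(cond, key) if (!isTRUE(cond)) offenders <<- c(offenders, key)
  chk(params$conserve_max_delta > 0, "conserve_max_delta")
  chk(params$identity_tolerance >= 0, "identity_tolerance")
  chk(params$min_overlap >= 1, "min_overlap")
  chk(params$promoter_upstream >= 0, "promoter_upstream")
  chk(params$promoter_downstream >= 0, "promoter_downstream")
  chk(params$distal_inner >= 0 && params$distal_inner < params$distal_outer,
      "distal_inner/distal_outer")
  chk(params$sif_max_fdr >= 0 && params$sif_max_fdr <= 1, "sif_max_fdr")
  chk(params$slg_cutoff >= 0 && params$slg_cutoff <= 1, "slg_cutoff")
  chk(params$slg_policy %in% c("pooled_z_minmax", "per_sign_z_minmax"),
      "slg_policy")
  chk(params$deg_min_abs_lfc >= 0, "deg_min_abs_lfc")
  chk(params$deg_max_p >= 0 && params$deg_max_p <= 1, "deg_max_p")
  chk(params$smoothing_fraction > 0 && params$smoothing_fraction <= 1,
      "smoothing_fraction")
  chk(params$pseudocount > 0, "pseudocount")
  if (length(offenders)) {
    stop_input("config parameter(s) out of range: %s",
               paste(offenders, collapse = ", "))
  }
  config$params <- params
  config$seed <- config$seed %||% 1L
  config$schema_version <- config$schema_version %||% 1L
  config
}

log_line <- function(out_dir, ...) {
  msg <- sprintf(...)
  message(msg)
  cat(msg, "\n", sep = "", file = file.path(out_dir, "run.log"),
      append = TRUE)
}

resolve_input <- function(config, key) {
  path <- config$inputs[[key]]
  if (is.null(path)) stop_input("config inputs$%s is required here", key)
  probe <- if (key %in% c("matrix_a", "matrix_b")) paste0(path, ".matrix")
  else path
  if (!file.exists(probe)) stop_input("input file not found: %s", probe)
  path
}

read_matrix_input <- function(prefix) {
  stats <- paste0(prefix, "_stats.txt")
  read_hicpro_matrix(paste0(prefix, "_abs.bed"), paste0(prefix, ".matrix"),
                     stats_path = if (file.exists(stats)) stats else NULL)
}

#' Pipeline commands
#'
#' Each command reads its inputs per the config, writes its module's output
#' files under `out_dir` plus a `run.log` with parameters and seeds, and
#' returns its result invisibly. `cmd_simulate` writes a full synthetic
#' scenario and points the returned config's `inputs` at it, so
#' `cmd_run_all` chains simulation and every analysis stage into one
#' deterministic run ending in `report.json`.
#'
#' @param config a [pipeline_config()] list or YAML path.
#' @param out_dir output directory (created if needed).
#' @return see each command; `cmd_run_all` returns the report list.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(scenario_spec,
                  c(list(seed = config$seed), config$scenario %||% list()))
  sc <- simulate_scenario(spec, file.path(out_dir, "scenario"))
  log_line(out_dir, "simulate: seed %d, %d genes, %d planted events",
           spec$seed, nrow(sc$genes), nrow(sc$domain_truth))
  config$inputs <- list(genes = sc$paths$genes,
                        domains_a = sc$paths$domains_a,
                        domains_b = sc$paths$domains_b,
                        matrix_a = sc$paths$matrix_a,
                        matrix_b = sc$paths$matrix_b,
                        sifs_a = sc$paths$sifs_a,
                        sifs_b = sc$paths$sifs_b,
                        deg = sc$paths$deg)
  invisible(list(scenario = sc, config = config))
}

#' @rdname pipeline-commands
#' @export
cmd_normalize <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  target <- read_matrix_input(resolve_input(config, "matrix_a"))
  reference <- read_matrix_input(resolve_input(config, "matrix_b"))
  curve <- fit_lowess_bias(target, reference,
                           smoothing_fraction = config$params$smoothing_fraction,
                           pseudocount = config$params$pseudocount)
  corrected <- apply_bias_correction(target, curve)
  write_hicpro_matrix(corrected, file.path(out_dir, "matrix_a_corrected"))
  utils::write.table(
    data.frame(distance = curve$distance_grid,
               log2_bias = curve$log2_bias),
    file.path(out_dir, "bias_curve.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  log_line(out_dir, "normalize: span %.2f, %d grid points, bias range [%.3g, %.3g]",
           config$params$smoothing_fraction, length(curve$distance_grid),
           min(curve$log2_bias), max(curve$log2_bias))
  invisible(list(curve = curve, corrected = corrected))
}

#' @rdname pipeline-commands
#' @export
cmd_tad_diff <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  a <- read_topdom(resolve_input(config, "domains_a"))
  b <- read_topdom(resolve_input(config, "domains_b"))
  ch <- classify_changes(a, b,
                         conserve_max_delta = config$params$conserve_max_delta,
                         identity_tolerance = config$params$identity_tolerance,
                         min_overlap = config$params$min_overlap)
  sm <- summarize_changes(ch)
  write_change_events(ch, file.path(out_dir, "tad_changes.tsv"))
  writeLines(jsonlite::toJSON(list(counts = as.list(sm$counts),
                                   fractions = as.list(sm$fractions),
                                   rc_fraction = sm$rc_fraction,
                                   dc_fraction = sm$dc_fraction,
                                   n_events = sm$n_events),
                              auto_unbox = TRUE, digits = 10, pretty = TRUE),
             file.path(out_dir, "tad_summary.json"))
  log_line(out_dir, "tad_diff: %d events, RC %.3f / DC %.3f",
           sm$n_events, sm$rc_fraction, sm$dc_fraction)
  invisible(list(changes = ch, summary = sm, a = a, b = b))
}

#' @rdname pipeline-commands
#' @export
cmd_loops <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genes <- read_genes_bed(resolve_input(config, "genes"))
  pr <- config$params
  one <- function(key, mat_key, label) {
    sifs <- filter_sifs(read_sifs(resolve_input(config, key)),
                        max_fdr = pr$sif_max_fdr)
    tvp <- tryCatch(read_matrix_input(resolve_input(config, mat_key))$total_valid_pairs,
                    error = function(e) sum(sifs$valid_pairs))
    call_p1d1_loops(sifs, genes, total_valid_pairs = tvp,
                    sample_id = label,
                    promoter_upstream = pr$promoter_upstream,
                    promoter_downstream = pr$promoter_downstream,
                    distal_inner = pr$distal_inner,
                    distal_outer = pr$distal_outer)
  }
  la <- one("sifs_a", "matrix_a", "condition_a")
  lb <- one("sifs_b", "matrix_b", "condition_b")
  write_loops_bedpe(la, file.path(out_dir, "loops_a.bedpe"))
  write_loops_bedpe(lb, file.path(out_dir, "loops_b.bedpe"))
  utils::write.table(gene_vppm_table(la), file.path(out_dir, "gene_vppm_a.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gene_vppm_table(lb), file.path(out_dir, "gene_vppm_b.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(out_dir, "loops: %d / %d P1D1 loops (A / B)",
           nrow(la$loops), nrow(lb$loops))
  invisible(list(a = la, b = lb))
}

#' @rdname pipeline-commands
#' @export
cmd_slg <- function(config, out_dir) {
  config <- pipeline_config(config)
  loops <- cmd_loops(config, out_dir)
  slg <- strengthened_looping_genes(loops$a, loops$b,
                                    cutoff = config$params$slg_cutoff,
                                    policy = config$params$slg_policy)
  write_slg_table(slg, file.path(out_dir, "slg.tsv"))
  log_line(out_dir, "slg: %d strengthened in B, %d in A (cutoff %.2f)",
           length(slg$slg_b), length(slg$slg_a), slg$cutoff)
  invisible(list(slg = slg, loops = loops))
}

#' @rdname pipeline-commands
#' @export
cmd_delg <- function(config, out_dir) {
  config <- pipeline_config(config)
  res <- cmd_slg(config, out_dir)
  deg_table <- read_deg_table(resolve_input(config, "deg"))
  degs <- filter_degs(deg_table,
                      min_abs_lfc = config$params$deg_min_abs_lfc,
                      max_p = config$params$deg_max_p)
  delgs <- intersect_delgs(res$slg, degs, deg_table)
  utils::write.table(delgs$a$table, file.path(out_dir, "delg_a.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(delgs$b$table, file.path(out_dir, "delg_b.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_line(out_dir, "delg: %d DEGs; %d / %d DELGs (A / B)",
           length(degs), length(delgs$a$delg_ids), length(delgs$b$delg_ids))
  invisible(list(slg = res$slg, loops = res$loops, degs = degs,
                 deg_table = deg_table, delgs = delgs))
}

#' @rdname pipeline-commands
#' @export
cmd_run_all <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$inputs)) {
    config <- cmd_simulate(config, out_dir)$config
  }
  cmd_normalize(config, out_dir)
  tad <- cmd_tad_diff(config, out_dir)
  res <- cmd_delg(config, out_dir)
  partition <- partition_loops(res$loops$a, res$loops$b)
  report <- build_run_report(
    tad_summary = tad$summary,
    domain_sets = list(a = tad$a, b = tad$b),
    partition = partition,
    loops_a = res$loops$a, loops_b = res$loops$b,
    slg = res$slg, degs = res$degs, delgs = res$delgs,
    params = config$params, seed = config$seed)
  write_run_report(report, file.path(out_dir, "report.json"))
  log_line(out_dir, "run_all: report written")
  invisible(report)
}
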