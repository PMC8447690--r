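#' Domain call set: TAD / boundary / gap tiling of a genome
#'
#' Three-state domain calls in the style of TopDom output: per chromosome an
#' ordered, non-overlapping list of intervals each labeled `tad`, `boundary`
#' or `gap`. Uncovered genomic space is implicitly treated as gap.
#'
#' @param calls data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `state` in `tad`/`boundary`/`gap`.
#' @param layout optional [genome_layout()] carried for validation against
#'   other inputs.
#' @return an object of class `domain_call_set`.
#' @export
domain_call_set <- function(calls, layout = NULL) {
  need <- c("chrom", "start", "end", "state")
  if (!all(need %in% names(calls))) {
    stop_input("calls need columns %s", paste(need, collapse = ", "))
  }
  calls <- calls[, need, drop = FALSE]
  calls$chrom <- as.character(calls$chrom)
  calls$start <- as.numeric(calls$start)
  calls$end <- as.numeric(calls$end)
  calls$state <- as.character(calls$state)
  if (!all(calls$state %in% c("tad", "boundary", "gap"))) {
    stop_input("unknown state tag: %s",
               paste(setdiff(unique(calls$state),
                             c("tad", "boundary", "gap")), collapse = ", "))
  }
  if (any(calls$end <= calls$start)) {
    bad <- which(calls$end <= calls$start)[1L]
    stop_input("call with end <= start at %s:%g-%g", calls$chrom[bad],
               calls$start[bad], calls$end[bad])
  }
  calls <- calls[order(calls$chrom, calls$start, calls$end), , drop = FALSE]
  rownames(calls) <- NULL
  for (cm in unique(calls$chrom)) {
    cc <- calls[calls$chrom == cm, , drop = FALSE]
    if (nrow(cc) > 1L) {
      ov <- which(cc$start[-1L] < cc$end[-nrow(cc)])
      if (length(ov)) {
        stop_input("overlapping calls on %s: [%g,%g) and [%g,%g)", cm,
                   cc$start[ov[1L]], cc$end[ov[1L]],
                   cc$start[ov[1L] + 1L], cc$end[ov[1L] + 1L])
      }
    }
  }
  structure(list(calls = calls, layout = layout), class = "domain_call_set")
}

#' @export
print.domain_call_set <- function(x, ...) {
  tab <- table(factor(x$calls$state, c("tad", "boundary", "gap")))
  cat(sprintf(paste0("domain_call_set: %d calls on %d chromosome(s) ",
                     "(%d tad, %d boundary, %d gap)\n"),
              nrow(x$calls), length(unique(x$calls$chrom)),
              tab[["tad"]], tab[["boundary"]], tab[["gap"]]))
  invisible(x)
}

#' Read TopDom-style domain calls
#'
#' Expects a TSV with columns `chrom`, `start`, `end`, `tag` where the tag is
#' one of `domain`, `boundary`, `gap` (case-insensitive; `domain` maps to
#' `tad`, and `tad` itself is also accepted). A header line is detected and
#' skipped automatically.
#'
#' @param path input file.
#' @param layout optional [genome_layout()] attached to the result.
#' @return a [domain_call_set()].
#' @export
read_topdom <- function(path, layout = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    grepl("chrom", strsplit(first, "\t")[[1]][1], ignore.case = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop_input("%s: expected >= 4 columns", path)
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "tag")
  tag <- tolower(as.character(df$tag))
  state <- c(domain = "tad", tad = "tad", boundary = "boundary",
             gap = "gap")[tag]
  if (anyNA(state)) {
    stop_input("%s: unknown tag '%s'", path, tag[which(is.na(state))[1L]])
  }
  domain_call_set(data.frame(chrom = df$chrom, start = df$start,
                             end = df$end, state = unname(state),
                             stringsAsFactors = FALSE),
                  layout = layout)
}

#' Write domain calls as TopDom-style TSV
#' @param set a [domain_call_set()].
#' @param path output file.
#' @export
write_topdom <- function(set, path) {
  df <- set$calls
  df$tag <- c(tad = "domain", boundary = "boundary", gap = "gap")[df$state]
  out <- format_num_df(df[, c("chrom", "start", "end", "tag")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("chrom", "start", "end", "tag"))
  invisible(path)
}

# TADs only, as a data.frame
tads_of <- function(set) {
  set$calls[set$calls$state == "tad", c("chrom", "start", "end"), drop = FALSE]
}

#' Histogram of TAD sizes
#'
#' Counts TAD lengths per size bin; boundary and gap calls are excluded.
#'
#' @param set a [domain_call_set()].
#' @param edges increasing numeric vector of bin edges in bp; lengths falling
#'   outside the edges are not counted. Default edges span 0.1-5 Mb.
#' @return data.frame with `lower`, `upper`, `count`.
#' @export
tad_size_distribution <- function(set,
                                  edges = c(1, 3, 5, 10, 20, 50) * 1e5) {
  stopifnot(length(edges) >= 2L, !is.unsorted(edges, strictly = TRUE))
  len <- with(tads_of(set), end - start)
  counts <- if (length(len)) {
    tab <- table(cut(len, breaks = edges, right = FALSE))
    as.integer(tab)
  } else integer(length(edges) - 1L)
  data.frame(lower = edges[-length(edges)], upper = edges[-1L],
             count = counts)
}
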