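CHANGE_TYPES <- c("no_change", "conserve_expand", "conserve_shrink", "shift",
                  "split", "fuse", "neo", "del")
RC_TYPES <- c("no_change", "conserve_expand", "conserve_shrink")

#' Bipartite TAD overlap graph between two conditions
#'
#' Connects TADs of condition A with TADs of condition B that overlap by at
#' least `min_overlap` bp and returns the connected components per
#' chromosome, plus TADs of either side with no partner.
#'
#' @param a,b [domain_call_set()] objects for the two conditions.
#' @param min_overlap minimum overlap in bp for an edge (default 1).
#' @return list with `components` (each a list with data.frames `a` and `b`)
#'   and data.frames `unmatched_a`, `unmatched_b`.
#' @export
build_overlap_graph <- function(a, b, min_overlap = 1) {
  check_same_layout(a, b)
  ta <- tads_of(a); tb <- tads_of(b)
  comps <- list()
  un_a <- ta[0, ]; un_b <- tb[0, ]
  for (cm in union(ta$chrom, tb$chrom)) {
    ca <- ta[ta$chrom == cm, , drop = FALSE]
    cb <- tb[tb$chrom == cm, , drop = FALSE]
    hits <- overlap_pairs(ca, cb, min_overlap)
    # union-find over na + nb nodes
    parent <- seq_len(nrow(ca) + nrow(cb))
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(hits))) {
      ri <- find(hits$qa[k]); rj <- find(nrow(ca) + hits$qb[k])
      if (ri != rj) parent[rj] <- ri
    }
    roots <- vapply(seq_along(parent), find, 0L)
    touched <- unique(c(hits$qa, nrow(ca) + hits$qb))
    for (r in unique(roots[touched])) {
      idx <- which(roots == r)
      ia <- idx[idx <= nrow(ca)]
      ib <- idx[idx > nrow(ca)] - nrow(ca)
      comps[[length(comps) + 1L]] <- list(a = ca[ia, , drop = FALSE],
                                          b = cb[ib, , drop = FALSE])
    }
    if (nrow(ca)) un_a <- rbind(un_a, ca[!seq_len(nrow(ca)) %in% hits$qa, ])
    if (nrow(cb)) un_b <- rbind(un_b, cb[!seq_len(nrow(cb)) %in% hits$qb, ])
  }
  rownames(un_a) <- rownames(un_b) <- NULL
  list(components = comps, unmatched_a = un_a, unmatched_b = un_b)
}

# overlapping (A index, B index, overlap bp) pairs via IRanges
overlap_pairs <- function(ca, cb, min_overlap) {
  if (nrow(ca) == 0L || nrow(cb) == 0L) {
    return(data.frame(qa = integer(), qb = integer(), ov = numeric()))
  }
  ra <- IRanges::IRanges(start = ca$start + 1, end = ca$end)
  rb <- IRanges::IRanges(start = cb$start + 1, end = cb$end)
  h <- IRanges::findOverlaps(ra, rb, minoverlap = min_overlap)
  qa <- S4Vectors::queryHits(h); qb <- S4Vectors::subjectHits(h)
  data.frame(qa = qa, qb = qb,
             ov = overlap_width(ca$start[qa], ca$end[qa],
                                cb$start[qb], cb$end[qb]))
}

check_same_layout <- function(a, b) {
  if (!is.null(a$layout) && !is.null(b$layout) &&
      !layouts_identical(a$layout, b$layout)) {
    stop_input("domain call sets have different genome layouts")
  }
}

#' Classify TAD changes between two conditions
#'
#' Compares the TADs of condition A against condition B and assigns every
#' TAD of either side to exactly one change event of eight types:
#' `no_change`, `conserve_expand`, `conserve_shrink` (together the
#' "relatively conserved" group), and `shift`, `split`, `fuse`, `neo`,
#' `del` (the "drastically changed" group).
#'
#' Matching is by interval overlap (`>= min_overlap` bp). Events are carved
#' out greedily per chromosome: the overlapping A/B pair with the largest
#' overlap seeds an event consisting of one A TAD and all its unassigned B
#' partners (a split when there are several) or one B TAD and all its
#' unassigned A partners (a fuse); the side with more members wins, ties
#' broken by total overlap and then in favour of the split side, with
#' leftmost-coordinate tie-breaks throughout, so the decomposition is
#' deterministic. A 1-1 match is `no_change` when both boundary
#' displacements are within `identity_tolerance`; otherwise
#' `conserve_expand`/`conserve_shrink` when the length change and the
#' maximum boundary displacement are both within `conserve_max_delta`
#' (300 kb); otherwise `shift`. A TAD with no partner becomes `del` (A side)
#' or `neo` (B side); non-TAD space (boundary, gap, uncovered) needs no
#' special casing since only TADs enter the graph.
#'
#' @param a,b [domain_call_set()] objects (A is the control condition).
#' @param conserve_max_delta largest length change / boundary displacement
#'   still "relatively conserved", bp (default 300 kb).
#' @param identity_tolerance boundary displacement treated as unchanged, bp
#'   (default one 40 kb bin; TopDom boundaries are bin-quantized).
#' @param min_overlap minimum overlap in bp to match TADs (default 1).
#' @return an object of class `tad_changes`: list with `events` (data.frame
#'   with columns `chrom`, `type`, `n_a`, `n_b`, `length_delta`,
#'   `max_displacement` and list-columns `members_a`, `members_b`) and
#'   `params`.
#' @seealso [summarize_changes()]
#' @export
classify_changes <- function(a, b, conserve_max_delta = 300000,
                             identity_tolerance = 40000, min_overlap = 1) {
  check_same_layout(a, b)
  ta <- tads_of(a); tb <- tads_of(b)
  evs <- list()
  for (cm in union(ta$chrom, tb$chrom)) {
    ca <- ta[ta$chrom == cm, , drop = FALSE]; rownames(ca) <- NULL
    cb <- tb[tb$chrom == cm, , drop = FALSE]; rownames(cb) <- NULL
    pairs <- overlap_pairs(ca, cb, min_overlap)
    free_a <- rep(TRUE, nrow(ca)); free_b <- rep(TRUE, nrow(cb))
    repeat {
      act <- pairs[free_a[pairs$qa] & free_b[pairs$qb], , drop = FALSE]
      if (nrow(act) == 0L) break
      o <- order(-act$ov, ca$start[act$qa], cb$start[act$qb])
      pick <- act[o[1L], ]
      Bs <- sort(unique(act$qb[act$qa == pick$qa]))
      As <- sort(unique(act$qa[act$qb == pick$qb]))
      side_a <- length(As) > length(Bs)
      if (length(As) == length(Bs) && length(As) > 1L) {
        ov_split <- sum(act$ov[act$qa == pick$qa])
        ov_fuse <- sum(act$ov[act$qb == pick$qb])
        side_a <- ov_fuse > ov_split
      }
      if (side_a) {
        evs[[length(evs) + 1L]] <- make_event(cm, ca[As, , drop = FALSE],
                                              cb[pick$qb, , drop = FALSE],
                                              conserve_max_delta,
                                              identity_tolerance)
        free_a[As] <- FALSE; free_b[pick$qb] <- FALSE
      } else {
        evs[[length(evs) + 1L]] <- make_event(cm, ca[pick$qa, , drop = FALSE],
                                              cb[Bs, , drop = FALSE],
                                              conserve_max_delta,
                                              identity_tolerance)
        free_a[pick$qa] <- FALSE; free_b[Bs] <- FALSE
      }
    }
    for (i in which(free_a)) {
      evs[[length(evs) + 1L]] <- make_event(cm, ca[i, , drop = FALSE],
                                            cb[0, , drop = FALSE],
                                            conserve_max_delta,
                                            identity_tolerance)
    }
    for (j in which(free_b)) {
      evs[[length(evs) + 1L]] <- make_event(cm, ca[0, , drop = FALSE],
                                            cb[j, , drop = FALSE],
                                            conserve_max_delta,
                                            identity_tolerance)
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else
    make_event("", NULL, NULL, 0, 0)[0, ]
  o <- order(events$chrom,
             vapply(seq_len(nrow(events)), function(i) {
               suppressWarnings(min(events$members_a[[i]]$start,
                                    events$members_b[[i]]$start, Inf))
             }, 0))
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events,
                 params = list(conserve_max_delta = conserve_max_delta,
                               identity_tolerance = identity_tolerance,
                               min_overlap = min_overlap)),
            class = "tad_changes")
}

make_event <- function(chrom, ma, mb, conserve_max_delta,
                       identity_tolerance) {
  na <- if (is.null(ma)) 0L else nrow(ma)
  nb <- if (is.null(mb)) 0L else nrow(mb)
  len_a <- if (na) sum(ma$end - ma$start) else 0
  len_b <- if (nb) sum(mb$end - mb$start) else 0
  delta <- len_b - len_a
  disp <- if (na >= 1L && nb >= 1L) {
    max(abs(min(ma$start) - min(mb$start)), abs(max(ma$end) - max(mb$end)))
  } else NA_real_
  type <- if (na == 0L && nb >= 1L) "neo"
  else if (nb == 0L && na >= 1L) "del"
  else if (na == 1L && nb >= 2L) "split"
  else if (na >= 2L && nb == 1L) "fuse"
  else if (na == 1L && nb == 1L) {
    classify_one_to_one(ma, mb, conserve_max_delta, identity_tolerance)
  } else NA_character_
  df <- data.frame(chrom = chrom, type = type, n_a = na, n_b = nb,
                   length_delta = delta, max_displacement = disp,
                   stringsAsFactors = FALSE)
  df$members_a <- list(ma)
  df$members_b <- list(mb)
  df
}

classify_one_to_one <- function(ma, mb, conserve_max_delta,
                                identity_tolerance) {
  ds <- abs(ma$start - mb$start)
  de <- abs(ma$end - mb$end)
  delta <- (mb$end - mb$start) - (ma$end - ma$start)
  if (max(ds, de) <= identity_tolerance) return("no_change")
  if (abs(delta) <= conserve_max_delta && max(ds, de) <= conserve_max_delta) {
    return(if (delta >= 0) "conserve_expand" else "conserve_shrink")
  }
  "shift"
}

#' @export
print.tad_changes <- function(x, ...) {
  cat(sprintf("tad_changes: %d events\n", nrow(x$events)))
  print(summarize_changes(x))
  invisible(x)
}

#' @export
summary.tad_changes <- function(object, ...) summarize_changes(object)

#' Summarize classified TAD changes
#'
#' Counts and fractions per change type over events, and the relatively
#' conserved (RC: no_change, conserve_expand, conserve_shrink) versus
#' drastically changed (DC: shift, split, fuse, neo, del) fractions.
#'
#' @param events a `tad_changes` object from [classify_changes()], or its
#'   `events` data.frame.
#' @return an object of class `change_summary`: list with `counts`,
#'   `fractions` (named by type, summing to 1), `rc_fraction`,
#'   `dc_fraction`, `n_events`.
#' @export
summarize_changes <- function(events) {
  if (inherits(events, "tad_changes")) events <- events$events
  types <- factor(events$type, levels = CHANGE_TYPES)
  counts <- table(types)
  n <- nrow(events)
  fr <- if (n > 0) as.numeric(counts) / n else rep(NA_real_, length(counts))
  names(fr) <- CHANGE_TYPES
  structure(list(counts = stats::setNames(as.integer(counts), CHANGE_TYPES),
                 fractions = fr,
                 rc_fraction = sum(fr[RC_TYPES]),
                 dc_fraction = sum(fr[setdiff(CHANGE_TYPES, RC_TYPES)]),
                 n_events = n),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  df <- data.frame(type = CHANGE_TYPES, count = x$counts,
                   fraction = round(x$fractions, 4))
  print(df, row.names = FALSE)
  cat(sprintf("RC fraction %.3f, DC fraction %.3f over %d events\n",
              x$rc_fraction, x$dc_fraction, x$n_events))
  invisible(x)
}

#' Write classified change events as TSV
#'
#' Member TADs are encoded as comma-separated `start-end` spans.
#'
#' @param changes a `tad_changes` object.
#' @param path output file.
#' @export
write_change_events <- function(changes, path) {
  ev <- changes$events
  fmt <- function(members) vapply(members, function(m) {
    if (is.null(m) || nrow(m) == 0L) return(".")
    paste(sprintf("%s-%s",
                  format(m$start, scientific = FALSE, trim = TRUE),
                  format(m$end, scientific = FALSE, trim = TRUE)),
          collapse = ",")
  }, "")
  out <- data.frame(chrom = ev$chrom, a_members = fmt(ev$members_a),
                    b_members = fmt(ev$members_b), type = ev$type,
                    length_delta = ev$length_delta,
                    max_displacement = ev$max_displacement)
  utils::write.table(format_num_df(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
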