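#' Read an isoform-composition table
#'
#' Tab-separated with columns `isoform_id, transcript_cluster_id,
#' probe_set_order` (comma-joined probe-set ids in transcript order).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_isoform_table <- function(path) {
  iso <- read.delim(path, colClasses = "character", check.names = FALSE)
  req <- c("isoform_id", "transcript_cluster_id", "probe_set_order")
  miss <- setdiff(req, names(iso))
  if (length(miss)) stop("isoform table missing column(s): ",
                         paste(miss, collapse = ", "))
  iso
}

#' Read a probe-set interval table (0-based half-open)
#'
#' Columns `probe_set_id, start, end, strand`. Needed only for the
#' alternative 5'/3' site and intron-retention event labels.
#'
#' @param path file path.
#' @return data.frame with numeric start/end.
#' @export
read_interval_table <- function(path) {
  iv <- read.delim(path, check.names = FALSE)
  req <- c("probe_set_id", "start", "end", "strand")
  miss <- setdiff(req, names(iv))
  if (length(miss)) stop("interval table missing column(s): ",
                         paste(miss, collapse = ", "))
  iv$probe_set_id <- as.character(iv$probe_set_id)
  iv$start <- as.numeric(iv$start); iv$end <- as.numeric(iv$end)
  iv
}

#' Remove isoforms refuted by the linkage tests
#'
#' An isoform that requires two probe sets to be adjacent is dropped when a
#' linkage test on the junction between them said the link is not supported.
#'
#' @param isoform_list named list of character vectors (probe sets in
#'   transcript order).
#' @param refuted_pairs two-column matrix/data.frame of probe-set pairs
#'   whose adjacency was refuted (order within a pair is ignored).
#' @return pruned isoform list.
#' @export
prune_isoforms <- function(isoform_list, refuted_pairs = NULL) {
  if (is.null(refuted_pairs) || NROW(refuted_pairs) == 0) return(isoform_list)
  refuted_pairs <- as.matrix(refuted_pairs)
  bad_key <- c(paste(refuted_pairs[, 1], refuted_pairs[, 2], sep = "\r"),
               paste(refuted_pairs[, 2], refuted_pairs[, 1], sep = "\r"))
  keep <- vapply(isoform_list, function(iso) {
    if (length(iso) < 2) return(TRUE)
    adj <- paste(iso[-length(iso)], iso[-1], sep = "\r")
    !any(adj %in% bad_key)
  }, TRUE)
  isoform_list[keep]
}

#' Label a candidate with an alternative-splicing event type
#'
#' Deduces the event class from the candidate's position in the cluster's
#' isoforms, after removing isoforms whose required adjacencies were refuted
#' by the junction assessment. Rules, most specific first:
#'
#' * `mutually_exclusive` - another probe set never co-occurs with the
#'   candidate and both appear between the same flanking probe sets (when
#'   intervals are supplied the two must not overlap);
#' * `cassette_exon` - the candidate is internal to one isoform and skipped
#'   (its flanks directly adjacent) in another;
#' * `alt_first` / `alt_last` - the candidate starts/ends one isoform and
#'   another isoform lacking it continues from / ends at the neighbouring
#'   probe set;
#' * `alt_5prime` / `alt_3prime` - requires intervals: an alternative probe
#'   set shares the candidate's 3' (resp. 5') boundary but not the other
#'   (boundaries interpreted on the annotated strand);
#' * `intron_retention` - requires intervals: the candidate spans two probe
#'   sets plus the gap between them, and those two are adjacent in an
#'   isoform lacking the candidate;
#' * `complex_event` - fallback when no basic rule fires unambiguously
#'   (including a candidate found in a single isoform only, or absent from
#'   the annotation).
#'
#' @param candidate probe-set id.
#' @param isoforms isoform table rows for the candidate's transcript cluster
#'   (see [read_isoform_table()]), or a named list of probe-set vectors.
#' @param support optional `support_report` / refuted pair matrix used to
#'   prune isoforms; pass refuted adjacencies as a two-column matrix via
#'   `refuted_pairs`.
#' @param intervals optional interval table (see [read_interval_table()]).
#' @param refuted_pairs two-column matrix of refuted adjacencies.
#' @return an `event_call`: list(`probe_set_id`, `event_type`, `evidence`).
#' @export
classify_event <- function(candidate, isoforms, support = NULL,
                           intervals = NULL, refuted_pairs = NULL) {
  iso_list <- .isoform_list(isoforms)
  iso_list <- prune_isoforms(iso_list, refuted_pairs)
  evidence <- character(0)
  call <- function(type, ev) {
    structure(list(probe_set_id = candidate, event_type = type,
                   evidence = c(evidence, ev)), class = "event_call")
  }

  with_cand <- iso_list[vapply(iso_list, function(i) candidate %in% i, TRUE)]
  without_cand <- iso_list[vapply(iso_list, function(i) !(candidate %in% i),
                                  TRUE)]
  if (length(with_cand) == 0) {
    return(call("complex_event", "not in annotation"))
  }
  if (length(iso_list) == 1) {
    return(call("complex_event",
                "single isoform: no alternative usage derivable"))
  }

  iv <- NULL
  if (!is.null(intervals)) {
    iv <- intervals[!duplicated(intervals$probe_set_id), , drop = FALSE]
    rownames(iv) <- iv$probe_set_id
  }

  # --- mutually exclusive -------------------------------------------------
  others <- setdiff(unique(unlist(iso_list)), candidate)
  for (q in others) {
    co_occur <- any(vapply(iso_list,
                           function(i) all(c(candidate, q) %in% i), TRUE))
    if (co_occur) next
    if (!is.null(iv) && all(c(candidate, q) %in% rownames(iv))) {
      # overlapping probe sets are boundary variants, not ME exons
      if (.overlaps(iv[candidate, ], iv[q, ])) next
    }
    fl_c <- .flank_pairs(with_cand, candidate)
    fl_q <- .flank_pairs(iso_list[vapply(iso_list, function(i) q %in% i,
                                         TRUE)], q)
    shared <- intersect(fl_c, fl_q)
    if (length(shared)) {
      return(call("mutually_exclusive",
                  paste0("never co-occurs with ", q,
                         "; shared flanks ", shared[1])))
    }
  }

  # --- cassette exon ------------------------------------------------------
  for (iso in with_cand) {
    pos <- match(candidate, iso)
    if (pos == 1 || pos == length(iso)) next
    fl <- c(iso[pos - 1], iso[pos + 1])
    skipped <- any(vapply(without_cand, function(v) {
      i1 <- match(fl[1], v); i2 <- match(fl[2], v)
      !is.na(i1) && !is.na(i2) && i2 == i1 + 1
    }, TRUE))
    if (skipped) {
      return(call("cassette_exon",
                  paste0("internal with flanks ", fl[1], ",", fl[2],
                         " adjacent in a skipping isoform")))
    }
  }

  # --- alternative first / last ------------------------------------------
  for (iso in with_cand) {
    if (length(iso) >= 2 && iso[1] == candidate) {
      nxt <- iso[2]
      hit <- any(vapply(without_cand,
                        function(v) length(v) > 0 && v[1] == nxt, TRUE))
      if (hit) {
        return(call("alt_first",
                    paste0("first in an isoform; another isoform starts at ",
                           nxt)))
      }
    }
    if (length(iso) >= 2 && iso[length(iso)] == candidate) {
      prv <- iso[length(iso) - 1]
      hit <- any(vapply(without_cand, function(v) {
        length(v) > 0 && v[length(v)] == prv
      }, TRUE))
      if (hit) {
        return(call("alt_last",
                    paste0("last in an isoform; another isoform ends at ",
                           prv)))
      }
    }
  }

  # --- boundary-metadata classes -----------------------------------------
  if (is.null(iv) || !(candidate %in% rownames(iv))) {
    evidence <- c(evidence,
                  "alt_5prime/alt_3prime/intron_retention unreachable ",
                  "without probe-set interval metadata")
  } else {
    ci <- iv[candidate, ]
    strand <- if (!is.null(ci$strand) && identical(ci$strand, "-")) "-"
              else "+"
    # intron retention first: it is the more specific signature (both
    # boundaries shared plus a covered gap), and a retained intron also
    # shares single boundaries with its flanking exons
    for (v in without_cand) {
      if (length(v) < 2) next
      for (j in seq_len(length(v) - 1)) {
        p1 <- v[j]; p2 <- v[j + 1]
        if (!all(c(p1, p2) %in% rownames(iv))) next
        if (iv[p1, "start"] == ci$start && iv[p2, "end"] == ci$end &&
            iv[p1, "end"] < iv[p2, "start"]) {
          return(call("intron_retention",
                      paste0("spans ", p1, ", ", p2,
                             " and the intervening gap")))
        }
      }
    }
    for (q in others) {
      if (!(q %in% rownames(iv))) next
      co_occur <- any(vapply(iso_list,
                             function(i) all(c(candidate, q) %in% i), TRUE))
      if (co_occur) next
      qi <- iv[q, ]
      same_end <- ci$end == qi$end && ci$start != qi$start
      same_start <- ci$start == qi$start && ci$end != qi$end
      if (strand == "-") {
        tmp <- same_end; same_end <- same_start; same_start <- tmp
      }
      if (same_end) {
        return(call("alt_5prime",
                    paste0("shares 3' boundary with ", q,
                           " but differs at the 5' boundary")))
      }
      if (same_start) {
        return(call("alt_3prime",
                    paste0("shares 5' boundary with ", q,
                           " but differs at the 3' boundary")))
      }
    }
  }

  call("complex_event", "no basic rule fired unambiguously")
}

#' @export
print.event_call <- function(x, ...) {
  cat("event_call:", x$probe_set_id, "->", x$event_type, "\n")
  if (length(x$evidence)) cat(" ", paste(x$evidence, collapse = " "), "\n")
  invisible(x)
}

.isoform_list <- function(isoforms) {
  if (is.list(isoforms) && !is.data.frame(isoforms)) {
    return(lapply(isoforms, as.character))
  }
  out <- lapply(isoforms$probe_set_order, function(s) strsplit(s, ",")[[1]])
  names(out) <- isoforms$isoform_id
  out
}

.flank_pairs <- function(iso_list, ps) {
  unlist(lapply(iso_list, function(iso) {
    pos <- match(ps, iso)
    if (is.na(pos) || pos == 1 || pos == length(iso)) return(character(0))
    paste(iso[pos - 1], iso[pos + 1], sep = "|")
  }))
}

.overlaps <- function(a, b) a$start < b$end && b$start < a$end

#' Classify every supported candidate of a run
#'
#' @param candidates candidate table (needs `transcript_cluster_id`,
#'   `probe_set_id`).
#' @param support support table from [assess_junctions()] (used to skip
#'   `not_supported` candidates unless `annotate_all = TRUE`, and to prune
#'   refuted adjacencies from the junction rows when supplied).
#' @param isoforms isoform table.
#' @param intervals optional interval table.
#' @param junction_calls optional per-junction table from
#'   [assess_junctions()] providing refuted adjacencies.
#' @param annotation junction annotation (to map refuted junctions to their
#'   anchor pairs).
#' @param annotate_all classify even unsupported candidates.
#' @return data.frame `transcript_cluster_id, probe_set_id, event_type,
#'   evidence`.
#' @export
classify_events <- function(candidates, support = NULL, isoforms,
                            intervals = NULL, junction_calls = NULL,
                            annotation = NULL, annotate_all = FALSE) {
  refuted <- NULL
  if (!is.null(junction_calls) && !is.null(annotation) &&
      nrow(junction_calls)) {
    bad <- junction_calls[junction_calls$role %in%
                            c("link_5prime", "link_3prime") &
                          junction_calls$call == "does_not_support", ,
                          drop = FALSE]
    if (nrow(bad)) {
      ann <- as.data.frame(annotation)
      m <- ann[match(unique(bad$junction_id), ann$junction_id), ,
               drop = FALSE]
      m <- m[!is.na(m$anchor_5) & !is.na(m$anchor_3), , drop = FALSE]
      if (nrow(m)) refuted <- cbind(m$anchor_5, m$anchor_3)
    }
  }
  rows <- lapply(seq_len(nrow(candidates)), function(r) {
    cand <- candidates$probe_set_id[r]
    tc <- candidates$transcript_cluster_id[r]
    if (!annotate_all && !is.null(support)) {
      cat_r <- support$category[support$probe_set_id == cand]
      if (length(cat_r) && cat_r[1] == "not_supported") return(NULL)
    }
    iso <- isoforms[isoforms$transcript_cluster_id == tc, , drop = FALSE]
    ec <- classify_event(cand, iso, intervals = intervals,
                         refuted_pairs = refuted)
    data.frame(transcript_cluster_id = tc, probe_set_id = cand,
               event_type = ec$event_type,
               evidence = paste(ec$evidence, collapse = "; "))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(transcript_cluster_id = character(0),
                      probe_set_id = character(0),
                      event_type = character(0), evidence = character(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
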