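#' Rank a vector of per-array values
#'
#' Splicing patterns matter more than absolute expression, so junction
#' assessment works on ranks across arrays (1..n, ties averaged). A constant
#' vector gets all ranks (n+1)/2 and is flagged degenerate via the
#' `"degenerate"` attribute.
#'
#' @param values numeric vector, length >= 2.
#' @return vector of ranks with attribute `degenerate` (logical).
#' @export
rank_transform <- function(values) {
  if (length(values) < 2) stop("need at least 2 values to rank")
  r <- rank(values, ties.method = "average")
  attr(r, "degenerate") <- isTRUE(max(values) - min(values) == 0)
  r
}

#' Median profile of a junction's anchor probe sets
#'
#' Each anchor probe's intensities are first ranked across arrays; the probe
#' ranks of both anchors are then averaged per array and ranked anew,
#' yielding one profile commensurate with the junction's own rank profile.
#' Junction probes must not be included.
#'
#' @param anchor_ranks a probes-by-arrays matrix of per-probe ranks covering
#'   both anchor probe sets, or a list of one matrix per anchor (anchors with
#'   zero probes are rejected by name).
#' @return per-array rank vector (with `degenerate` attribute).
#' @export
median_profile <- function(anchor_ranks) {
  if (is.list(anchor_ranks) && !is.matrix(anchor_ranks)) {
    nm <- names(anchor_ranks)
    for (i in seq_along(anchor_ranks)) {
      if (is.null(anchor_ranks[[i]]) || nrow(anchor_ranks[[i]]) == 0) {
        stop("anchor '", if (!is.null(nm)) nm[i] else i,
             "' has zero probes")
      }
    }
    anchor_ranks <- do.call(rbind, anchor_ranks)
  }
  if (!is.matrix(anchor_ranks) || nrow(anchor_ranks) == 0) {
    stop("anchor rank matrix has zero probes")
  }
  rank_transform(colMeans(anchor_ranks))
}

#' Per-probe rank matrix of a probe set across arrays
#'
#' @param x a `probe_table`.
#' @param probe_set probe-set id.
#' @param arrays array ids defining the rank universe (default: all arrays
#'   of the probe set).
#' @return probes-by-arrays matrix of ranks.
#' @export
probe_rank_matrix <- function(x, probe_set, arrays = NULL) {
  df <- as.data.frame(x)
  df <- df[df$probe_set_id == probe_set, , drop = FALSE]
  if (!nrow(df)) stop("no probes found for probe set '", probe_set, "'")
  if (is.null(arrays)) arrays <- sort(unique(df$array_id))
  probes <- unique(df$probe_id)
  m <- matrix(NA_real_, length(probes), length(arrays),
              dimnames = list(probes, arrays))
  m[cbind(match(df$probe_id, probes), match(df$array_id, arrays))] <-
    df$intensity
  if (anyNA(m)) stop("probe set '", probe_set,
                     "' is missing measurements on some arrays")
  t(apply(m, 1, rank, ties.method = "average"))
}

#' Rank profile of a junction (or any probe set): rank per probe, average
#' per array, re-rank.
#' @noRd
profile_of <- function(x, probe_set, arrays = NULL) {
  median_profile(probe_rank_matrix(x, probe_set, arrays))
}

#' Rank-based linkage test of a junction against its anchors' median profile
#'
#' Stacks the junction's per-array rank profile and the anchors' median
#' profile and compares two fixed-effects models on the ranks: M1 with probe
#' set (junction vs profile) and group main effects only, and M2 adding
#' their interaction. A significant interaction means the junction does not
#' follow the anchors' shared pattern across groups, i.e. it is not an end
#' product of the two probe sets; an insignificant interaction supports the
#' link. With zero interaction sum of squares and zero residual variance the
#' junction agrees perfectly and is supported; with fewer than one residual
#' degree of freedom the test is indeterminate.
#'
#' @param junction_ranks per-array rank profile of the junction.
#' @param profile_ranks per-array median profile of the anchors (same
#'   arrays, same order).
#' @param groups group assignment of the arrays: named vector or data.frame
#'   (`array_id`, `group`); both groups must be represented.
#' @param alpha_link significance level; supported iff p >= alpha_link.
#' @return a `linkage_result`: list(`p_value`, `supported` (TRUE/FALSE/NA),
#'   `n_obs`, `note`).
#' @export
linkage_test <- function(junction_ranks, profile_ranks, groups,
                         alpha_link = 0.05) {
  if (length(junction_ranks) != length(profile_ranks)) {
    stop("junction and profile ranks must cover the same arrays")
  }
  n <- length(junction_ranks)
  arr <- names(junction_ranks)
  if (is.atomic(groups) && is.null(names(groups))) {
    if (length(groups) != n) stop("unnamed groups must match the arrays")
    g <- as.character(groups)
  } else {
    g <- .group_vector(groups)
    g <- if (!is.null(arr)) g[arr] else g[seq_len(n)]
  }
  if (anyNA(g)) stop("group labels missing for some arrays")
  if (length(unique(g)) != 2) stop("both groups must be represented")

  dat <- data.frame(
    r = c(as.numeric(profile_ranks), as.numeric(junction_ranks)),
    entity = factor(rep(c("profile", "junction"), each = n)),
    group = factor(rep(g, 2)))
  m2 <- lm(r ~ entity + group + entity:group, data = dat)
  if (m2$df.residual < 1) {
    return(structure(list(p_value = NA_real_, supported = NA,
                          n_obs = 2L * n,
                          note = "indeterminate: no residual df"),
                     class = "linkage_result"))
  }
  m1 <- lm(r ~ entity + group, data = dat)
  rss1 <- sum(m1$residuals^2)
  rss2 <- sum(m2$residuals^2)
  ss_int <- rss1 - rss2
  eps <- 1e-10 * (sum(dat$r^2) + 1)
  if (rss2 < eps) {
    if (ss_int < eps) {
      return(structure(list(p_value = 1, supported = TRUE, n_obs = 2L * n,
                            note = "perfect agreement (zero interaction)"),
                       class = "linkage_result"))
    }
    return(structure(list(p_value = 0, supported = FALSE, n_obs = 2L * n,
                          note = "zero residual variance with interaction"),
                     class = "linkage_result"))
  }
  if (ss_int < eps) {
    return(structure(list(p_value = 1, supported = TRUE, n_obs = 2L * n,
                          note = "zero interaction sum of squares"),
                     class = "linkage_result"))
  }
  fstat <- (ss_int / 1) / (rss2 / m2$df.residual)
  pval <- pf(fstat, 1, m2$df.residual, lower.tail = FALSE)
  structure(list(p_value = pval, supported = pval >= alpha_link,
                 n_obs = 2L * n, note = ""),
            class = "linkage_result")
}

#' Background model for detection-above-background calls
#'
#' Either a user-supplied pool of background intensities (a numeric vector
#' shared by all arrays, or a data.frame `array_id, intensity` giving one
#' pool per array), or a pool derived from a probe table: per array, all
#' intensities below the `quantile` quantile of that array.
#'
#' @param pool numeric vector or data.frame (`array_id`, `intensity`).
#' @param probe_table probe table to derive a pool from when `pool` is NULL.
#' @param quantile quantile defining "background" intensities (default 0.25).
#' @return object of class `background_model`: named list of per-array pools
#'   plus a `default` pool.
#' @export
background_model <- function(pool = NULL, probe_table = NULL,
                             quantile = 0.25) {
  if (is.null(pool) && is.null(probe_table)) {
    stop("supply a background pool (table or vector) or a probe table ",
         "to derive one from")
  }
  per_array <- list()
  default <- NULL
  if (!is.null(pool)) {
    if (is.data.frame(pool)) {
      per_array <- split(as.numeric(pool$intensity),
                         as.character(pool$array_id))
      default <- as.numeric(pool$intensity)
    } else {
      default <- as.numeric(pool)
    }
  } else {
    df <- as.data.frame(probe_table)
    per_array <- lapply(split(df$intensity, df$array_id), function(v) {
      v[v <= stats::quantile(v, quantile)]
    })
    default <- unlist(per_array, use.names = FALSE)
  }
  if (!length(default)) stop("empty background pool: supply a background ",
                             "table or an intensity threshold")
  structure(list(per_array = per_array, default = default),
            class = "background_model")
}

#' Detection-above-background assessment of a junction
#'
#' Per array, each junction probe gets an empirical p-value
#' `(r + 1) / (B + 1)` where `r` is the number of background-pool values at
#' or above the probe's intensity; the per-probe p-values are combined across
#' the junction's probes with Fisher's method. The junction is present on an
#' array iff the combined p-value is below `alpha_dabg`, and absent overall
#' iff absent on every array. `mode = "threshold"` instead calls presence
#' when the junction's mean probe intensity exceeds a hard cutoff.
#'
#' @param junction_probe_intensities probes-by-arrays matrix (log2 scale,
#'   same scale as the background pool).
#' @param background a [background_model()] (required for empirical mode).
#' @param alpha_dabg presence level (default 0.05).
#' @param mode `"empirical"` or `"threshold"`.
#' @param threshold hard intensity cutoff for threshold mode.
#' @return data.frame `array_id, p_value, present` with attribute
#'   `absent_overall`.
#' @export
dabg_assess <- function(junction_probe_intensities, background = NULL,
                        alpha_dabg = 0.05,
                        mode = c("empirical", "threshold"),
                        threshold = NULL) {
  m <- junction_probe_intensities
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  mode <- match.arg(mode)
  arrays <- colnames(m)
  if (is.null(arrays)) arrays <- as.character(seq_len(ncol(m)))
  if (mode == "threshold") {
    if (is.null(threshold)) stop("threshold mode needs a threshold")
    present <- colMeans(m) > threshold
    out <- data.frame(array_id = arrays, p_value = NA_real_,
                      present = unname(present))
    attr(out, "absent_overall") <- !any(present)
    return(out)
  }
  if (is.null(background)) {
    stop("empirical DABG needs a background model: supply a background ",
         "pool table or use threshold mode")
  }
  stopifnot(inherits(background, "background_model"))
  res <- lapply(seq_along(arrays), function(j) {
    a <- arrays[j]
    bg <- background$per_array[[a]]
    if (is.null(bg) || !length(bg)) bg <- background$default
    B <- length(bg)
    pp <- vapply(m[, j], function(v) (sum(bg >= v) + 1) / (B + 1), 0)
    stat <- -2 * sum(log(pp))
    p <- pchisq(stat, df = 2 * length(pp), lower.tail = FALSE)
    data.frame(array_id = a, p_value = p, present = p < alpha_dabg)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  attr(out, "absent_overall") <- !any(out$present)
  out
}

#' Interpret per-array presence calls of an exclusion junction
#'
#' An exclusion junction measures the isoform that skips the candidate exon:
#' presence in at least one sample supports the alternative-splicing call,
#' absence across all samples contradicts it (the skipped span is always
#' included).
#'
#' @param call data.frame from [dabg_assess()] or a logical presence vector.
#' @return `"supports_AS"` or `"contradicts_AS"`.
#' @export
exclusion_support <- function(call) {
  present <- if (is.data.frame(call)) call$present else as.logical(call)
  if (any(present, na.rm = TRUE)) "supports_AS" else "contradicts_AS"
}

#' Classify a candidate's junction support
#'
#' The four categories: `supported_by_all` (every assessable annotated
#' junction supports the call), `supported_by_at_least_one` (some but not
#' all), `not_supported` (no supporting junction, or contradictions
#' outnumber supports), `no_linking_junctions` (no annotated 5'/3' linking
#' junction at all). Indeterminate junction results are excluded from both
#' numerator and denominator and listed in the report. Reports carry both
#' overlapping flags (`supported_by_all` implies `supported_by_at_least_one`).
#'
#' @param candidate probe-set id of the candidate.
#' @param linkage list of `linkage_result` objects for the candidate's
#'   linking junctions (possibly empty).
#' @param exclusions character vector of [exclusion_support()] outcomes
#'   (possibly empty).
#' @return a `support_report`: list(`probe_set_id`, `category`,
#'   `flag_supported_by_all`, `flag_supported_by_at_least_one`, `n_support`,
#'   `n_contradict`, `n_indeterminate`, `note`).
#' @export
classify_support <- function(candidate, linkage = list(),
                             exclusions = character(0)) {
  if (inherits(linkage, "linkage_result")) linkage <- list(linkage)
  link_flags <- vapply(linkage, function(l) {
    if (is.na(l$supported)) NA else isTRUE(l$supported)
  }, NA)
  excl_flags <- exclusions == "supports_AS"
  n_sup <- sum(link_flags, na.rm = TRUE) + sum(excl_flags)
  n_con <- sum(!link_flags, na.rm = TRUE) + sum(!excl_flags)
  n_ind <- sum(is.na(link_flags))
  note <- ""
  if (length(linkage) == 0) {
    category <- "no_linking_junctions"
  } else if (n_sup + n_con == 0) {
    category <- "not_supported"
    note <- "annotated junctions present but none assessable"
  } else if (n_sup > 0 && n_con == 0) {
    category <- "supported_by_all"
  } else if (n_sup > 0 && n_sup >= n_con) {
    category <- "supported_by_at_least_one"
  } else {
    category <- "not_supported"
    if (n_sup > 0) note <- "contradictions outnumber supports"
  }
  structure(list(
    probe_set_id = candidate,
    category = category,
    # raw-evidence flags: overlapping by construction (all implies at least
    # one), kept even when the category is demoted by contradictions
    flag_supported_by_all = n_sup > 0 && n_con == 0 &&
      length(linkage) > 0,
    flag_supported_by_at_least_one = n_sup > 0 && length(linkage) > 0,
    n_support = n_sup, n_contradict = n_con, n_indeterminate = n_ind,
    note = note), class = "support_report")
}

#' Read a junction annotation table
#'
#' Tab-separated with columns `junction_id, transcript_cluster_id, kind,
#' anchor_5, anchor_3, excluded_span` (span comma-joined; empty fields
#' allowed). `kind` is `link` or `exclusion`; `link_5prime`/`link_3prime`
#' are accepted and mapped to `link` (the 5'/3' role of a linking junction
#' is relative to the candidate: a junction whose 3' anchor is the candidate
#' is that candidate's 5'-end junction, and vice versa).
#'
#' @param path file path.
#' @return validated annotation data.frame.
#' @export
read_junction_annotation <- function(path) {
  ann <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = "")
  validate_junction_annotation(ann)
}

#' @rdname read_junction_annotation
#' @param ann annotation data.frame.
#' @export
validate_junction_annotation <- function(ann) {
  req <- c("junction_id", "transcript_cluster_id", "kind",
           "anchor_5", "anchor_3", "excluded_span")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("junction annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  ann$kind[ann$kind %in% c("link_5prime", "link_3prime")] <- "link"
  if (!all(ann$kind %in% c("link", "exclusion"))) {
    stop("junction kind must be link/link_5prime/link_3prime/exclusion")
  }
  span <- !is.na(ann$excluded_span) & nzchar(ann$excluded_span)
  if (any(ann$kind == "exclusion" & !span)) {
    stop("exclusion junction '",
         ann$junction_id[ann$kind == "exclusion" & !span][1],
         "' has an empty excluded span")
  }
  if (any(ann$kind == "link" & span)) {
    stop("linking junction '", ann$junction_id[ann$kind == "link" & span][1],
         "' must not carry an excluded span")
  }
  ann
}

#' Assess junction support for every candidate
#'
#' Drives the junction-evidence procedure: for each candidate probe set,
#' linking junctions anchored at it are tested with [linkage_test()] against
#' the median profile of their anchors, exclusion junctions whose excluded
#' span covers it are assessed with [dabg_assess()] +
#' [exclusion_support()], and the evidence is folded into a four-category
#' [classify_support()] call. Junction probes must be rows of the probe
#' table under their junction id. Linking junctions with a missing anchor
#' are indeterminate for linkage; exclusion junctions are assessed by DABG
#' regardless of anchors. Blacklisted junctions (e.g. those whose design
#' sequence does not match the probe sets) are excluded from classification.
#'
#' @param x log2-scale `probe_table` containing exon and junction probes.
#' @param candidates candidate table from [select_candidates()] (or any
#'   data.frame with `transcript_cluster_id`, `probe_set_id`).
#' @param annotation junction annotation data.frame
#'   (see [read_junction_annotation()]).
#' @param groups array-to-group assignment.
#' @param alpha_link linkage-test level (default 0.05).
#' @param alpha_dabg DABG presence level (default 0.05).
#' @param background optional [background_model()]; derived from the probe
#'   table (lower quartile per array) when NULL.
#' @param blacklist junction ids to exclude.
#' @return list with `support` (per-candidate summary data.frame:
#'   `transcript_cluster_id, probe_set_id, category, flags, counts`),
#'   `junctions` (per candidate-junction rows with role, p-values, calls)
#'   and `reports` (list of `support_report`).
#' @export
assess_junctions <- function(x, candidates, annotation, groups,
                             alpha_link = 0.05, alpha_dabg = 0.05,
                             background = NULL, blacklist = NULL) {
  ann <- validate_junction_annotation(as.data.frame(annotation))
  if (length(blacklist)) ann <- ann[!(ann$junction_id %in% blacklist), ]
  if (is.null(background)) {
    exon_rows <- !(as.data.frame(x)$probe_set_id %in% ann$junction_id)
    background <- background_model(probe_table = as.data.frame(x)[exon_rows, ])
  }
  df <- as.data.frame(x)
  have_ps <- unique(df$probe_set_id)
  arrays <- sort(unique(df$array_id))
  g <- .group_vector(groups)

  reports <- list()
  jrows <- list()
  for (r in seq_len(nrow(candidates))) {
    cand <- candidates$probe_set_id[r]
    tc <- candidates$transcript_cluster_id[r]
    cann <- ann[ann$transcript_cluster_id == tc, , drop = FALSE]
    links <- cann[cann$kind == "link" &
                    (.eq(cann$anchor_5, cand) | .eq(cann$anchor_3, cand)), ,
                  drop = FALSE]
    excls <- cann[cann$kind == "exclusion" &
                    vapply(cann$excluded_span, function(s) {
                      cand %in% .split_span(s)
                    }, TRUE), , drop = FALSE]

    link_results <- list()
    if (nrow(links)) {
      for (i in seq_len(nrow(links))) {
        jid <- links$junction_id[i]
        a5 <- links$anchor_5[i]; a3 <- links$anchor_3[i]
        role <- if (.eq(links$anchor_3[i], cand)) "link_5prime"
                else "link_3prime"
        if (is.na(a5) || is.na(a3) || !(jid %in% have_ps) ||
            !all(c(a5, a3) %in% have_ps)) {
          lr <- structure(list(p_value = NA_real_, supported = NA,
                               n_obs = 0L,
                               note = "missing anchor or junction probes"),
                          class = "linkage_result")
        } else {
          prof <- median_profile(list(
            `5prime_anchor` = probe_rank_matrix(df, a5, arrays),
            `3prime_anchor` = probe_rank_matrix(df, a3, arrays)))
          junc <- profile_of(df, jid, arrays)
          lr <- linkage_test(setNames(junc, arrays),
                             setNames(prof, arrays), g, alpha_link)
        }
        lr$junction_id <- jid
        link_results[[length(link_results) + 1L]] <- lr
        jrows[[length(jrows) + 1L]] <- data.frame(
          transcript_cluster_id = tc, probe_set_id = cand,
          junction_id = jid, role = role,
          p_value = lr$p_value,
          call = if (is.na(lr$supported)) "indeterminate"
                 else if (lr$supported) "supports" else "does_not_support",
          note = lr$note)
      }
    }
    excl_calls <- character(0)
    if (nrow(excls)) {
      for (i in seq_len(nrow(excls))) {
        jid <- excls$junction_id[i]
        if (!(jid %in% have_ps)) next
        jm <- .intensity_matrix(df, jid, arrays)
        call <- dabg_assess(jm, background, alpha_dabg)
        sup <- exclusion_support(call)
        excl_calls <- c(excl_calls, sup)
        jrows[[length(jrows) + 1L]] <- data.frame(
          transcript_cluster_id = tc, probe_set_id = cand,
          junction_id = jid, role = "exclusion",
          p_value = min(call$p_value),
          call = if (sup == "supports_AS") "supports" else "does_not_support",
          note = sprintf("present in %d/%d arrays",
                         sum(call$present), nrow(call)))
      }
    }
    rep <- classify_support(cand, link_results, excl_calls)
    rep$transcript_cluster_id <- tc
    reports[[length(reports) + 1L]] <- rep
  }

  support <- do.call(rbind, c(lapply(reports, function(s) {
    data.frame(transcript_cluster_id = s$transcript_cluster_id,
               probe_set_id = s$probe_set_id,
               category = s$category,
               supported_by_all = s$flag_supported_by_all,
               supported_by_at_least_one = s$flag_supported_by_at_least_one,
               n_support = s$n_support, n_contradict = s$n_contradict,
               n_indeterminate = s$n_indeterminate, note = s$note)
  }), list(make.row.names = FALSE)))
  junctions <- if (length(jrows)) {
    do.call(rbind, c(jrows, list(make.row.names = FALSE)))
  } else {
    data.frame(transcript_cluster_id = character(0),
               probe_set_id = character(0), junction_id = character(0),
               role = character(0), p_value = numeric(0),
               call = character(0), note = character(0))
  }
  list(support = support, junctions = junctions, reports = reports)
}

.eq <- function(a, b) !is.na(a) & a == b

.split_span <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",")[[1]]
}

.intensity_matrix <- function(df, probe_set, arrays) {
  sub <- df[df$probe_set_id == probe_set, , drop = FALSE]
  probes <- unique(sub$probe_id)
  m <- matrix(NA_real_, length(probes), length(arrays),
              dimnames = list(probes, arrays))
  m[cbind(match(sub$probe_id, probes), match(sub$array_id, arrays))] <-
    sub$intensity
  m
}
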