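#' Run the full splicing-detection pipeline
#'
#' Orchestrates preprocess -> gene-model fits -> candidate selection and
#' group testing -> junction assessment -> event typing. Inputs may be file
#' paths (tab-separated, gzip-transparent) or in-memory tables. Junction
#' probe sets listed in the annotation are excluded from model fitting.
#' Without a junction annotation only step 1 runs and every candidate is
#' categorized `no_linking_junctions`; without an isoform table event typing
#' is skipped.
#'
#' @param probes `probe_table` or path. If on the raw scale it is background
#'   corrected (optionally), quantile normalized and log2 transformed; a
#'   log2-scale input is used as is.
#' @param groups groups table or path (`array_id, group[, pair_id]`).
#' @param annotation junction annotation table or path, or NULL.
#' @param isoforms isoform table or path, or NULL.
#' @param intervals optional probe-set interval table or path.
#' @param background optional background pool (data.frame
#'   `array_id, intensity` or path); derived from the exon probes when NULL.
#' @param threshold exon-score candidate threshold (default 0.5).
#' @param alpha_link linkage-test level.
#' @param alpha_dabg DABG presence level.
#' @param bh_level BH significance level recorded in the manifest.
#' @param paired use the paired t-test (needs `pair_id` in groups).
#' @param background_correction `"none"` or `"rma_convolution"` (raw input
#'   only).
#' @param scale_flag scale of `probes` when read from a file.
#' @param outdir optional directory; when given, all result tables and the
#'   manifest are written there.
#' @return list with `fits` (table), `candidates`, `array_scores`,
#'   `support`, `junction_calls`, `events`, `manifest`, and `gene_fits`
#'   (list of `gene_fit`).
#' @export
run_pipeline <- function(probes, groups, annotation = NULL, isoforms = NULL,
                         intervals = NULL, background = NULL,
                         threshold = 0.5, alpha_link = 0.05,
                         alpha_dabg = 0.05, bh_level = 0.05,
                         paired = FALSE,
                         background_correction = c("none", "rma_convolution"),
                         scale_flag = c("log2", "raw"),
                         outdir = NULL) {
  background_correction <- match.arg(background_correction)
  scale_flag <- match.arg(scale_flag)
  digests <- list()
  grab <- function(obj, reader, label) {
    if (is.character(obj) && length(obj) == 1) {
      if (!file.exists(obj)) stop(label, " file not found: ", obj)
      digests[[label]] <<- unname(tools::md5sum(obj))
      reader(obj)
    } else {
      obj
    }
  }
  probes <- grab(probes, function(p) read_probe_table(p, scale_flag),
                 "probes")
  if (!inherits(probes, "probe_table")) {
    probes <- probe_table(probes, scale_flag)
  }
  groups <- grab(groups, read_groups, "groups")
  annotation <- grab(annotation, read_junction_annotation, "annotation")
  isoforms <- grab(isoforms, read_isoform_table, "isoforms")
  intervals <- grab(intervals, read_interval_table, "intervals")
  background <- grab(background, read_tsv, "background")

  g <- .group_vector(groups)
  arrays <- unique(as.data.frame(probes)$array_id)
  missing_g <- setdiff(arrays, names(g))
  if (length(missing_g)) {
    stop("arrays without a group label: ", paste(missing_g, collapse = ", "))
  }

  if (probe_scale(probes) == "raw") {
    probes <- preprocess_probes(probes, background_correction)
  }

  junction_ids <- if (!is.null(annotation)) annotation$junction_id else
    character(0)
  gene_fits <- fit_genes(probes, exclude_probe_sets = junction_ids)
  fits <- fits_table(gene_fits)
  scores <- array_scores_table(gene_fits)

  candidates <- select_candidates(gene_fits, threshold)
  if (nrow(candidates)) {
    pairing <- if (paired && "pair_id" %in% names(groups)) {
      groups[, c("array_id", "pair_id")]
    } else NULL
    tested <- lapply(unique(candidates$transcript_cluster_id), function(tc) {
      ps <- candidates$probe_set_id[candidates$transcript_cluster_id == tc]
      test_array_scores(gene_fits[[tc]], groups, paired = paired,
                        pairing = pairing, probe_sets = ps)
    })
    tested <- do.call(rbind, c(tested, list(make.row.names = FALSE)))
    idx <- match(candidates$probe_set_id, tested$probe_set_id)
    candidates$p_value <- tested$p_value[idx]
    candidates$mean_diff <- tested$mean_diff[idx]
    candidates$direction <- tested$direction[idx]
    # one BH family across all tested probe sets of the run
    candidates$p_adjusted <- bh_adjust(candidates$p_value)
  }

  support <- NULL; junction_calls <- NULL
  if (!is.null(annotation) && nrow(candidates)) {
    bg <- if (!is.null(background)) background_model(pool = background) else
      NULL
    ja <- assess_junctions(probes, candidates, annotation, groups,
                           alpha_link = alpha_link, alpha_dabg = alpha_dabg,
                           background = bg)
    support <- ja$support
    junction_calls <- ja$junctions
  } else if (nrow(candidates)) {
    support <- data.frame(
      transcript_cluster_id = candidates$transcript_cluster_id,
      probe_set_id = candidates$probe_set_id,
      category = "no_linking_junctions",
      supported_by_all = FALSE, supported_by_at_least_one = FALSE,
      n_support = 0L, n_contradict = 0L, n_indeterminate = 0L,
      note = "no junction annotation supplied")
  }

  events <- NULL
  if (!is.null(isoforms) && nrow(candidates)) {
    events <- classify_events(candidates, support = support,
                              isoforms = isoforms, intervals = intervals,
                              junction_calls = junction_calls,
                              annotation = annotation)
  }

  manifest <- list(
    tool = "spliceScore",
    version = as.character(packageVersion("spliceScore")),
    input_digests = digests,
    parameters = list(threshold = threshold, alpha_link = alpha_link,
                      alpha_dabg = alpha_dabg, bh_level = bh_level,
                      paired = paired,
                      background_correction = background_correction),
    rows = list(probes = nrow(probes), fits = nrow(fits),
                candidates = nrow(candidates),
                support = if (is.null(support)) 0L else nrow(support),
                events = if (is.null(events)) 0L else nrow(events)),
    convergence = table(fits$convergence[!duplicated(
      fits$transcript_cluster_id)]))
  manifest$convergence <- as.list(manifest$convergence)

  result <- list(fits = fits, candidates = candidates,
                 array_scores = scores, support = support,
                 junction_calls = junction_calls, events = events,
                 manifest = manifest, gene_fits = gene_fits)
  if (!is.null(outdir)) write_pipeline_results(result, outdir)
  result
}

#' Write all result tables of a pipeline run
#'
#' @param result list returned by [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return `outdir` invisibly.
#' @export
write_pipeline_results <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$fits, file.path(outdir, "fits.tsv"))
  write_tsv(result$candidates, file.path(outdir, "candidates.tsv"))
  write_tsv(result$array_scores, file.path(outdir, "array_scores.tsv"))
  if (!is.null(result$support)) {
    write_tsv(result$support, file.path(outdir, "support.tsv"))
  }
  if (!is.null(result$junction_calls)) {
    write_tsv(result$junction_calls, file.path(outdir, "junction_calls.tsv"))
  }
  if (!is.null(result$events)) {
    write_tsv(result$events, file.path(outdir, "events.tsv"))
  }
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Write the tables of a simulated dataset
#'
#' @param sim list from [simulate_dataset()].
#' @param outdir output directory.
#' @return `outdir` invisibly.
#' @export
write_sim_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_probe_table(sim$probes, file.path(outdir, "probes.tsv"))
  write_tsv(sim$annotation, file.path(outdir, "junctions.tsv"))
  write_tsv(sim$groups, file.path(outdir, "samples.tsv"))
  write_tsv(sim$isoforms, file.path(outdir, "isoforms.tsv"))
  write_tsv(sim$background, file.path(outdir, "background.tsv"))
  write_tsv(sim$truth$probe_sets, file.path(outdir, "truth_probe_sets.tsv"))
  if (!is.null(sim$truth$junctions)) {
    write_tsv(sim$truth$junctions, file.path(outdir, "truth_junctions.tsv"))
  }
  invisible(outdir)
}
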