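#' Configuration for the synthetic probe-level data generator
#'
#' Defaults emulate a two-condition exon/junction array experiment: genes
#' with 8 probe sets of 4 probes each, 3 arrays per group (the two-tissue
#' triplicate design typical of these platforms), probe affinities around a
#' mid-range log2 baseline, residual noise sigma2 = 0.04, and planted
#' alternatively spliced exons with tau2 = 0.36 (theoretical exon score 0.9)
#' separated by 2 log2 units between groups. `as_fraction` is the fraction
#' of genes carrying one planted AS exon (interior position).
#'
#' @param n_genes number of transcript clusters.
#' @param n_probe_sets_per_gene probe sets (exons) per gene (>= 3 when AS
#'   exons are planted, so the AS exon can be interior).
#' @param n_probes_per_set probes per exon probe set.
#' @param n_arrays_per_group arrays in each of the two groups A and B.
#' @param baseline_log2 grand mean of probe affinities (log2 scale).
#' @param probe_effect_sd sd of probe affinities.
#' @param array_effect_sd sd of per-gene array effects.
#' @param sigma2 residual (within-array) variance.
#' @param as_fraction fraction of genes with one planted AS exon.
#' @param tau2_as between-array variance of planted AS exons.
#' @param tau2_null residual between-array variance of constitutive exons.
#' @param group_shift log2 separation of the AS exon's random effect means
#'   between the enriched and depleted group.
#' @param junction_probes probes per junction probe set.
#' @param junction_mode_mix proportions over c(agree, conflict, absent) for
#'   linking junctions of planted AS exons; must sum to 1.
#' @param background_mean,background_sd log2 background intensity
#'   distribution.
#' @param background_pool_size background draws emitted per array.
#' @param seed master seed; per-gene streams are split from it so adding
#'   genes does not perturb existing ones.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 100,
                       n_probe_sets_per_gene = 8,
                       n_probes_per_set = 4,
                       n_arrays_per_group = 3,
                       baseline_log2 = 7,
                       probe_effect_sd = 1,
                       array_effect_sd = 0.2,
                       sigma2 = 0.04,
                       as_fraction = 0.2,
                       tau2_as = 0.36,
                       tau2_null = 0.002,
                       group_shift = 2,
                       junction_probes = 4,
                       junction_mode_mix = c(agree = 0.8, conflict = 0.1,
                                             absent = 0.1),
                       background_mean = 4,
                       background_sd = 0.5,
                       background_pool_size = 1000,
                       seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$junction_mode_mix) - 1) > 1e-8) {
    stop("junction_mode_mix proportions must sum to 1")
  }
  if (any(c(cfg$sigma2, cfg$tau2_as, cfg$tau2_null) < 0)) {
    stop("variances must be nonnegative")
  }
  if (cfg$sigma2 <= 0) stop("sigma2 must be positive")
  if (cfg$as_fraction < 0 || cfg$as_fraction > 1) {
    stop("as_fraction must lie in [0, 1]")
  }
  if (cfg$n_arrays_per_group < 1 || cfg$n_probes_per_set < 1 ||
      cfg$n_probe_sets_per_gene < 2) {
    stop("need at least 2 probe sets, 1 probe per set and 1 array per group")
  }
  structure(cfg, class = "sim_config")
}

.gene_seed <- function(master, g) {
  as.integer((as.numeric(master) * 1000003 + g * 7919) %% 2147483647)
}

#' Generate a probe-level dataset with planted ground truth
#'
#' Intensities follow the generative form of the gene model: probe affinity
#' + array effect + exon-by-array random deviation + residual noise, on the
#' log2 scale. Planted AS exons get `b_ik ~ N(+shift/2, tau2_as)` in the
#' enriched group and `N(-shift/2, tau2_as)` in the other; constitutive
#' exons get `b_ik ~ N(0, tau2_null)`. Each planted AS exon (always
#' interior) is annotated with a 5'-end and a 3'-end linking junction and an
#' exclusion junction skipping it. Linking-junction probes track the mean of
#' their anchors plus noise in `agree` mode, carry a group-reversed pattern
#' in `conflict` mode (so the junction contradicts the anchors' median
#' profile), and are background draws in `absent` mode. Exclusion-junction
#' probes are expressed exactly in the arrays where the skipped exon is
#' depleted and background elsewhere. A background pool is emitted for DABG
#' calls, and isoform tables encode the planted cassette structure.
#'
#' @param config a [sim_config()].
#' @return list with elements `probes` (log2 `probe_table` incl. junction
#'   probe sets), `annotation` (junction table), `groups`, `isoforms`,
#'   `background` (pool data.frame), and `truth` (list: `probe_sets` with
#'   is_AS/tau2/direction, `junctions` with mode, `genes` with sigma2,
#'   `config`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  nI <- cfg$n_arrays_per_group
  arrays <- c(sprintf("A%02d", seq_len(nI)), sprintf("B%02d", seq_len(nI)))
  grp <- rep(c("A", "B"), each = nI)
  groups <- data.frame(array_id = arrays, group = grp,
                       pair_id = rep(sprintf("P%02d", seq_len(nI)), 2))
  K <- cfg$n_probe_sets_per_gene
  P <- cfg$n_probes_per_set
  n_as <- round(cfg$as_fraction * cfg$n_genes)
  if (n_as > 0 && K < 3) {
    stop("planting an interior AS exon needs at least 3 probe sets per gene")
  }
  # AS genes are the first n_as (deterministic given the config)
  probe_rows <- list(); ann_rows <- list(); iso_rows <- list()
  truth_ps <- list(); truth_j <- list(); truth_g <- list()

  for (g in seq_len(cfg$n_genes)) {
    set.seed(.gene_seed(cfg$seed, g))
    tc <- sprintf("TC%04d", g)
    ps_ids <- sprintf("PSR%04d_%02d", g, seq_len(K))
    is_as_gene <- g <= n_as
    k_as <- if (is_as_gene) sample(2:(K - 1), 1) else NA_integer_
    enriched <- if (is_as_gene) sample(c("A", "B"), 1) else NA_character_

    ci <- rnorm(2 * nI, 0, cfg$array_effect_sd)
    b <- matrix(0, 2 * nI, K)
    for (k in seq_len(K)) {
      if (is_as_gene && k == k_as) {
        mu_b <- ifelse(grp == enriched, cfg$group_shift / 2,
                       -cfg$group_shift / 2)
        b[, k] <- rnorm(2 * nI, mu_b, sqrt(cfg$tau2_as))
      } else {
        b[, k] <- rnorm(2 * nI, 0, sqrt(cfg$tau2_null))
      }
    }
    for (k in seq_len(K)) {
      pj <- rnorm(P, cfg$baseline_log2, cfg$probe_effect_sd)
      for (j in seq_len(P)) {
        eps <- rnorm(2 * nI, 0, sqrt(cfg$sigma2))
        probe_rows[[length(probe_rows) + 1L]] <- data.frame(
          transcript_cluster_id = tc,
          probe_set_id = ps_ids[k],
          probe_id = sprintf("%s_p%02d", ps_ids[k], j),
          array_id = arrays,
          intensity = pj[j] + ci + b[, k] + eps)
      }
      truth_ps[[length(truth_ps) + 1L]] <- data.frame(
        transcript_cluster_id = tc, probe_set_id = ps_ids[k],
        is_AS = is_as_gene && k == k_as,
        tau2 = if (is_as_gene && k == k_as) cfg$tau2_as else cfg$tau2_null,
        group_diff = if (is_as_gene && k == k_as) {
          if (enriched == "A") cfg$group_shift else -cfg$group_shift
        } else 0)
    }
    truth_g[[length(truth_g) + 1L]] <- data.frame(
      transcript_cluster_id = tc, sigma2 = cfg$sigma2)

    # isoforms: full transcript, plus the cassette-skipping isoform for AS
    iso_rows[[length(iso_rows) + 1L]] <- data.frame(
      isoform_id = paste0(tc, "_iso1"), transcript_cluster_id = tc,
      probe_set_order = paste(ps_ids, collapse = ","))
    if (is_as_gene) {
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(
        isoform_id = paste0(tc, "_iso2"), transcript_cluster_id = tc,
        probe_set_order = paste(ps_ids[-k_as], collapse = ","))

      modes <- sample(names(cfg$junction_mode_mix), 2, replace = TRUE,
                      prob = cfg$junction_mode_mix)
      anchors <- list(c(k_as - 1L, k_as), c(k_as, k_as + 1L))
      for (jj in 1:2) {
        jid <- sprintf("JUC%04d_%02d", g, jj)
        aL <- anchors[[jj]][1]; aR <- anchors[[jj]][2]
        # a conflicting junction measures a different isoform: its own
        # group pattern is the reverse of the candidate's enrichment
        rev_pattern <- ifelse(grp == enriched, -cfg$group_shift / 2,
                              cfg$group_shift / 2)
        probe_rows[[length(probe_rows) + 1L]] <-
          .junction_probes(cfg, tc, jid, arrays,
                           mode = modes[jj], ci = ci,
                           signal = (b[, aL] + b[, aR]) / 2,
                           reversed = rev_pattern)
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          junction_id = jid, transcript_cluster_id = tc, kind = "link",
          anchor_5 = ps_ids[aL], anchor_3 = ps_ids[aR],
          excluded_span = NA_character_)
        truth_j[[length(truth_j) + 1L]] <- data.frame(
          junction_id = jid, transcript_cluster_id = tc, mode = modes[jj])
      }
      # exclusion junction skipping the AS exon: expressed where depleted
      jid <- sprintf("JUC%04d_EX", g)
      depleted <- grp != enriched
      pj <- rnorm(cfg$junction_probes, cfg$baseline_log2,
                  cfg$probe_effect_sd)
      vals <- lapply(seq_len(cfg$junction_probes), function(j) {
        v <- rnorm(2 * nI, cfg$background_mean, cfg$background_sd)
        v[depleted] <- pj[j] + ci[depleted] +
          rnorm(sum(depleted), 0, sqrt(cfg$sigma2))
        v
      })
      probe_rows[[length(probe_rows) + 1L]] <- data.frame(
        transcript_cluster_id = tc, probe_set_id = jid,
        probe_id = sprintf("%s_p%02d", jid,
                           rep(seq_len(cfg$junction_probes), each = 2 * nI)),
        array_id = rep(arrays, cfg$junction_probes),
        intensity = unlist(vals))
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        junction_id = jid, transcript_cluster_id = tc, kind = "exclusion",
        anchor_5 = ps_ids[k_as - 1L], anchor_3 = ps_ids[k_as + 1L],
        excluded_span = ps_ids[k_as])
      truth_j[[length(truth_j) + 1L]] <- data.frame(
        junction_id = jid, transcript_cluster_id = tc, mode = "exclusion")
    }
  }

  set.seed(.gene_seed(cfg$seed, 0L))
  background <- data.frame(
    array_id = rep(arrays, each = cfg$background_pool_size),
    intensity = rnorm(2 * nI * cfg$background_pool_size,
                      cfg$background_mean, cfg$background_sd))

  probes <- do.call(rbind, c(probe_rows, list(make.row.names = FALSE)))
  probes <- probe_table(probes, scale_flag = "log2")
  annotation <- if (length(ann_rows)) {
    do.call(rbind, c(ann_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(junction_id = character(0),
               transcript_cluster_id = character(0), kind = character(0),
               anchor_5 = character(0), anchor_3 = character(0),
               excluded_span = character(0))
  }
  validate_junction_annotation(annotation)
  list(probes = probes,
       annotation = annotation,
       groups = groups,
       isoforms = do.call(rbind, c(iso_rows, list(make.row.names = FALSE))),
       background = background,
       truth = list(
         probe_sets = do.call(rbind, c(truth_ps,
                                       list(make.row.names = FALSE))),
         junctions = if (length(truth_j)) {
           do.call(rbind, c(truth_j, list(make.row.names = FALSE)))
         } else NULL,
         genes = do.call(rbind, c(truth_g, list(make.row.names = FALSE))),
         config = cfg))
}

.junction_probes <- function(cfg, tc, jid, arrays, mode, ci, signal,
                             reversed) {
  nP <- cfg$junction_probes
  nA <- length(arrays)
  pj <- rnorm(nP, cfg$baseline_log2, cfg$probe_effect_sd)
  vals <- lapply(seq_len(nP), function(j) {
    eps <- rnorm(nA, 0, sqrt(cfg$sigma2))
    switch(mode,
      agree = pj[j] + ci + signal + eps,
      conflict = pj[j] + ci + reversed + eps,
      absent = rnorm(nA, cfg$background_mean, cfg$background_sd))
  })
  data.frame(transcript_cluster_id = tc, probe_set_id = jid,
             probe_id = sprintf("%s_p%02d", jid,
                                rep(seq_len(nP), each = nA)),
             array_id = rep(arrays, nP),
             intensity = unlist(vals))
}
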