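test_that("rank transform averages ties and flags constants", {
  expect_equal(as.numeric(rank_transform(c(5.1, 2.2, 9.9))), c(2, 1, 3))
  expect_equal(as.numeric(rank_transform(c(4, 4, 7))), c(1.5, 1.5, 3))
  r <- rank_transform(rep(2, 4))
  expect_equal(as.numeric(r), rep(2.5, 4))
  expect_true(attr(r, "degenerate"))
  expect_error(rank_transform(3), "at least 2")
  # invariant to strictly increasing transforms
  set.seed(4)
  x <- rnorm(10)
  expect_equal(as.numeric(rank_transform(x)), as.numeric(rank_transform(exp(x))))
  expect_equal(as.numeric(rank_transform(x)),
               as.numeric(rank_transform(2 * x + 7)))
})

test_that("median profile averages anchor probe ranks then re-ranks", {
  # identical anchor profiles pass through
  r <- c(1, 2, 3, 4)
  m <- rbind(r, r, r)
  expect_equal(as.numeric(median_profile(m)), r)
  # opposite profiles cancel to a flat, degenerate profile
  opp <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  mp <- median_profile(opp)
  expect_equal(as.numeric(mp), rep(2.5, 4))
  expect_true(attr(mp, "degenerate"))
  # random matrix against the hand-rolled average-then-rank reference
  set.seed(9)
  mm <- matrix(sample(1:6, 36, replace = TRUE), 6, 6)
  expect_equal(as.numeric(median_profile(mm)),
               as.numeric(rank(colMeans(mm), ties.method = "average")))
  # empty anchors are rejected by name
  expect_error(median_profile(list(a5 = matrix(1, 1, 3),
                                   a3 = matrix(numeric(0), 0, 3))),
               "a3")
})

test_that("linkage test matches a from-scratch ANOVA decomposition", {
  set.seed(17)
  groups <- rep(c("A", "B"), each = 3)
  for (i in 1:25) {
    # continuous inputs: the test fits whatever profiles it is given, and
    # continuity rules out exact-zero interaction edge cases
    jr <- rnorm(6)
    pr <- rnorm(6)
    got <- linkage_test(jr, pr, setNames(groups, NULL))
    want <- anova_interaction_oracle(
      c(as.numeric(pr), as.numeric(jr)),
      entity = rep(c("p", "j"), each = 6),
      group = rep(groups, 2))
    expect_equal(got$p_value, unname(want), tolerance = 1e-10)
  }
})

test_that("linkage test is symmetric in which entity is the junction", {
  set.seed(23)
  groups <- rep(c("A", "B"), each = 3)
  for (i in 1:10) {
    a <- rnorm(6)
    b <- rnorm(6)
    expect_equal(linkage_test(a, b, groups)$p_value,
                 linkage_test(b, a, groups)$p_value, tolerance = 1e-12)
  }
})

test_that("linkage test handles agreement and conflict patterns", {
  groups <- rep(c("A", "B"), each = 3)
  # junction identical to profile: zero interaction, supported
  r <- c(4, 5, 6, 1, 2, 3)
  res <- linkage_test(r, r, groups)
  expect_true(res$supported)
  expect_equal(res$p_value, 1)

  # flat profile vs group-separated junction (the conflicting-junction
  # scenario): detected in nearly all jittered replicates
  set.seed(31)
  hits <- 0
  for (i in 1:100) {
    prof <- rank_transform(rep(0, 6))    # exact cancellation: tied ranks
    junc <- rank_transform(c(2, 2, 2, -2, -2, -2) + rnorm(6, 0, 0.2))
    if (linkage_test(junc, prof, groups)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 95)

  # too few arrays for residual df: indeterminate
  res2 <- linkage_test(c(1, 2), c(2, 1), c("A", "B"))
  expect_true(is.na(res2$supported))
  expect_match(res2$note, "indeterminate")
})

test_that("DABG calls are calibrated and separate signal from background", {
  set.seed(12)
  bg <- background_model(pool = rnorm(1000, 4, 0.5))
  # junction probes at the background median: absent everywhere
  m <- matrix(4, 4, 6, dimnames = list(NULL, paste0("a", 1:6)))
  call <- dabg_assess(m, bg)
  expect_false(any(call$present))
  expect_true(attr(call, "absent_overall"))
  expect_identical(exclusion_support(call), "contradicts_AS")

  # probes far above the background maximum: present everywhere
  m2 <- matrix(max(bg$default) + 6, 4, 6,
               dimnames = list(NULL, paste0("a", 1:6)))
  call2 <- dabg_assess(m2, bg)
  expect_true(all(call2$present))
  expect_identical(exclusion_support(call2), "supports_AS")

  # probes drawn from the background distribution give uniform p-values
  ps <- replicate(400, {
    mm <- matrix(rnorm(4, 4, 0.5), 4, 1, dimnames = list(NULL, "a1"))
    dabg_assess(mm, bg)$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)

  # threshold mode
  call3 <- dabg_assess(m2, mode = "threshold", threshold = 8)
  expect_true(all(call3$present))
  expect_error(dabg_assess(m2), "background")
})

test_that("exclusion junction calls map presence to AS support", {
  expect_identical(exclusion_support(c(TRUE, rep(FALSE, 5))), "supports_AS")
  expect_identical(exclusion_support(rep(FALSE, 6)), "contradicts_AS")
  expect_identical(exclusion_support(rep(TRUE, 6)), "supports_AS")
})

test_that("support classification reproduces all constructed cases", {
  lr <- function(sup) structure(list(p_value = if (is.na(sup)) NA_real_
                                     else if (sup) 0.5 else 0.01,
                                     supported = sup, n_obs = 12L,
                                     note = ""),
                                class = "linkage_result")
  cases <- list(
    # no linking junctions annotated
    list(link = list(), excl = character(0), want = "no_linking_junctions"),
    list(link = list(), excl = "supports_AS",
         want = "no_linking_junctions"),
    list(link = list(), excl = "contradicts_AS",
         want = "no_linking_junctions"),
    # everything supports
    list(link = list(lr(TRUE)), excl = character(0),
         want = "supported_by_all"),
    list(link = list(lr(TRUE), lr(TRUE)), excl = "supports_AS",
         want = "supported_by_all"),
    list(link = list(lr(TRUE), lr(NA)), excl = character(0),
         want = "supported_by_all"),
    # some but not all support
    list(link = list(lr(TRUE), lr(FALSE)), excl = character(0),
         want = "supported_by_at_least_one"),
    list(link = list(lr(FALSE)), excl = "supports_AS",
         want = "supported_by_at_least_one"),
    list(link = list(lr(TRUE), lr(FALSE)), excl = "supports_AS",
         want = "supported_by_at_least_one"),
    # no support at all, or contradictions dominate
    list(link = list(lr(FALSE)), excl = character(0),
         want = "not_supported"),
    list(link = list(lr(FALSE), lr(FALSE)), excl = "contradicts_AS",
         want = "not_supported"),
    list(link = list(lr(TRUE), lr(FALSE)), excl = "contradicts_AS",
         want = "not_supported"))
  for (cs in cases) {
    rep <- classify_support("psX", cs$link, cs$excl)
    expect_identical(rep$category, cs$want)
    expect_identical(rep$flag_supported_by_all,
                     rep$category == "supported_by_all" ||
                       (rep$n_support > 0 && rep$n_contradict == 0 &&
                          length(cs$link) > 0))
    if (rep$flag_supported_by_all) {
      expect_true(rep$flag_supported_by_at_least_one)
    }
  }
  # indeterminate-only annotations are recorded, not counted
  repNA <- classify_support("psX", list(lr(NA), lr(NA)), character(0))
  expect_identical(repNA$category, "not_supported")
  expect_identical(repNA$n_indeterminate, 2L)
})

test_that("the two patterns of worked candidates classify as published-style
           categories", {
  lr <- function(sup) structure(list(p_value = 0.5, supported = sup,
                                     n_obs = 12L, note = ""),
                                class = "linkage_result")
  # both linking junctions and the exclusion junction agree
  all_sup <- classify_support("cand_a", list(lr(TRUE), lr(TRUE)),
                              c("supports_AS"))
  expect_identical(all_sup$category, "supported_by_all")
  # one linking junction supports, the other does not, one exclusion helps
  partial <- classify_support("cand_b", list(lr(TRUE), lr(FALSE)),
                              c("supports_AS"))
  expect_identical(partial$category, "supported_by_at_least_one")
})

test_that("junction annotation validation enforces the span rules", {
  ann <- data.frame(junction_id = c("j1", "j2"),
                    transcript_cluster_id = "tc",
                    kind = c("link_5prime", "exclusion"),
                    anchor_5 = c("p1", "p1"), anchor_3 = c("p2", "p3"),
                    excluded_span = c(NA, "p2"))
  ok <- validate_junction_annotation(ann)
  expect_identical(ok$kind, c("link", "exclusion"))
  ann2 <- ann; ann2$excluded_span <- c(NA, NA)
  expect_error(validate_junction_annotation(ann2), "empty excluded span")
  ann3 <- ann; ann3$excluded_span <- c("p9", "p2")
  expect_error(validate_junction_annotation(ann3), "must not carry")
})

test_that("agreement- and conflict-mode junctions are resolved end to end", {
  sim <- simulate_dataset(sim_config(
    n_genes = 30, as_fraction = 1, seed = 123,
    junction_mode_mix = c(agree = 0.5, conflict = 0.5, absent = 0)))
  cand <- sim$truth$probe_sets[sim$truth$probe_sets$is_AS, ]
  ja <- assess_junctions(sim$probes, cand, sim$annotation, sim$groups,
                         background = background_model(
                           pool = sim$background))
  calls <- merge(ja$junctions, sim$truth$junctions,
                 by = c("junction_id", "transcript_cluster_id"))
  agree <- calls[calls$mode == "agree", ]
  conflict <- calls[calls$mode == "conflict", ]
  expect_gt(nrow(agree), 5)
  expect_gt(nrow(conflict), 5)
  expect_gte(mean(agree$call == "supports"), 0.9)
  expect_gte(mean(conflict$call == "does_not_support"), 0.8)
  # exclusion junctions of planted AS exons are present where depleted
  excl <- calls[calls$mode == "exclusion", ]
  expect_true(all(excl$call == "supports"))
})
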