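test_that("null clusters yield exon scores near zero", {
  # with tau2 = 0 everywhere, chance between-array correlation still gives
  # occasional positive estimates on 6 arrays; the bulk must sit at zero
  scores <- unlist(lapply(1:20, function(r) {
    df <- gen_cluster(I = 18, K = 4, P = 4, sigma2 = 0.05,
                      tau2 = rep(0, 4), seed = 7000 + r,
                      tc = sprintf("TC%02d", r),
                      groups = rep(c("A", "B"), each = 9))
    fit_gene_model(df)$exon_scores
  }))
  expect_lt(mean(scores), 0.1)
  expect_lt(quantile(scores, 0.95), 0.3)
  expect_gt(mean(scores == 0), 0.3)
})

test_that("fitted variance components agree with the brute-force REML
           oracle on a known cluster", {
  df <- gen_cluster(I = 6, K = 8, P = 4, sigma2 = 0.04,
                    tau2 = c(0.36, rep(0, 7)), seed = 42)
  fit <- fit_gene_model(df)
  orc <- oracle_reml_fit(df, extra_starts = list(
    c(log(0.04), 0.36, rep(0, 7)),
    c(log(fit$residual_variance), unname(fit$exon_variances))))
  expect_lt(abs(fit$residual_variance - orc$sigma2), 1e-4)
  expect_lt(max(abs(unname(fit$exon_variances) - orc$tau2)), 1e-4)
  # the planted AS exon dominates
  expect_gt(fit$exon_scores[1], 0.8)
})

test_that("array-score columns are centered and the exon-score identity
           holds for stored fits", {
  df <- gen_cluster(I = 6, K = 5, P = 3, sigma2 = 0.04,
                    tau2 = c(0.4, 0.1, 0, 0, 0), seed = 77)
  fit <- fit_gene_model(df)
  sums <- colSums(fit$array_scores)
  scale <- max(abs(fit$array_scores)) + 1
  expect_true(all(abs(sums) / scale < 1e-8))
  expect_equal(unname(fit$exon_scores),
               unname(fit$exon_variances /
                        (fit$residual_variance + fit$exon_variances)),
               tolerance = 1e-12)
})

test_that("intensity shifts are absorbed by the fixed effects", {
  df <- gen_cluster(I = 6, K = 4, P = 4, sigma2 = 0.04,
                    tau2 = c(0.3, 0, 0, 0), seed = 5)
  fit <- fit_gene_model(df)
  # constant added to one array -> only c_i moves
  df2 <- df
  sel <- df2$array_id == "a01"
  df2$intensity[sel] <- df2$intensity[sel] + 5
  fit2 <- fit_gene_model(df2)
  expect_lt(abs(fit2$residual_variance - fit$residual_variance), 1e-8)
  expect_lt(max(abs(fit2$exon_variances - fit$exon_variances)), 1e-8)
  expect_lt(max(abs(fit2$exon_scores - fit$exon_scores)), 1e-8)
  expect_gt(fit2$array_effects["a01"] - fit$array_effects["a01"], 4)
  # doubling on the raw scale (constant on log2) changes nothing else
  df3 <- df
  df3$intensity <- df3$intensity + 1
  fit3 <- fit_gene_model(df3)
  expect_lt(max(abs(fit3$exon_scores - fit$exon_scores)), 1e-8)
})

test_that("degenerate clusters are skipped with a recorded status", {
  df <- gen_cluster(I = 4, K = 2, P = 3, seed = 2)
  one <- df[df$probe_set_id == df$probe_set_id[1], ]
  fit <- fit_gene_model(one)
  expect_identical(fit$convergence, "degenerate")
  expect_match(fit$note, "single probe set")
  expect_true(all(is.na(fit$exon_scores)))
})

test_that("exon_score matches the intra-cluster correlation closed form", {
  expect_equal(exon_score(0, 1), 0)
  expect_equal(exon_score(1, 1), 0.5)
  expect_equal(exon_score(3, 1), 0.75)
  expect_error(exon_score(1, 0), "positive")
  expect_error(exon_score(-1, 1), "nonnegative")
  # strictly increasing in tau2 for fixed sigma2
  set.seed(123)
  for (i in 1:1000) {
    s2 <- rexp(1)
    t2 <- sort(rexp(2))
    if (t2[1] == t2[2]) next
    expect_lt(exon_score(t2[1], s2), exon_score(t2[2], s2))
  }
})

test_that("select_candidates applies a strict threshold and sorts by score", {
  tab <- data.frame(
    transcript_cluster_id = "tc",
    probe_set_id = paste0("ps", 1:4),
    tau2 = 1, sigma2 = 1,
    exon_score = c(0.2, 0.5, 0.51, 0.99),
    convergence = "converged")
  out <- select_candidates(tab, 0.5)
  expect_identical(out$probe_set_id, c("ps4", "ps3"))
  expect_identical(nrow(select_candidates(
    transform(tab, exon_score = exon_score / 10), 0.5)), 0L)
  expect_error(select_candidates(tab, 1.5), "0, 1")
})

test_that("planted AS exons rank at the top of the candidate table", {
  fits <- list()
  for (g in 1:50) {
    tau2 <- rep(0, 4)
    if (g <= 5) tau2[1] <- 0.36             # rho = 0.9 against sigma2 0.04
    df <- gen_cluster(I = 6, K = 4, P = 4, sigma2 = 0.04, tau2 = tau2,
                      seed = 1000 + g, tc = sprintf("TC%02d", g))
    fits[[sprintf("TC%02d", g)]] <- fit_gene_model(df)
  }
  cand <- select_candidates(fits, 0.5)
  planted <- sprintf("TC%02d_ps01", 1:5)
  expect_true(all(planted %in% cand$probe_set_id))
  expect_true(all(match(planted, cand$probe_set_id) <= max(5, nrow(cand))))
  # planted exons occupy the top of the ranking
  expect_true(all(cand$probe_set_id[1:5] %in% planted))
})

test_that("array-score group tests match the textbook Welch formula", {
  df <- gen_cluster(I = 6, K = 2, P = 3, seed = 31)
  fit <- fit_gene_model(df)
  groups <- attr(df, "groups")
  # plug in hand-chosen scores to pin the expected value
  fit$array_scores[, 1] <- c(1.0, 0.5, 0.8, -0.9, -1.1, -0.7)
  res <- test_array_scores(fit, groups,
                           probe_sets = colnames(fit$array_scores)[1])
  expect_equal(res$p_value,
               welch_p(c(1.0, 0.5, 0.8), c(-0.9, -1.1, -0.7)),
               tolerance = 1e-10)
  expect_match(res$direction, "enriched_in_A")

  # identical vectors in both groups: degenerate p = 1
  fit$array_scores[, 2] <- rep(c(2, 2, 2), 2)
  res2 <- test_array_scores(fit, groups,
                            probe_sets = colnames(fit$array_scores)[2])
  expect_equal(res2$p_value, 1)
  expect_match(res2$note, "degenerate")

  # strong separation with jitter: p < 0.01
  set.seed(8)
  fit$array_scores[, 1] <- c(2, 2, 2, -2, -2, -2) + rnorm(6, 0, 1e-3)
  res3 <- test_array_scores(fit, groups,
                            probe_sets = colnames(fit$array_scores)[1])
  expect_lt(res3$p_value, 0.01)
})

test_that("paired tests and size-1 groups are handled", {
  df <- gen_cluster(I = 6, K = 2, P = 3, tau2 = c(0.3, 0.1), seed = 14)
  fit <- fit_gene_model(df)
  groups <- attr(df, "groups")
  pairing <- data.frame(array_id = names(groups),
                        pair_id = rep(c("x", "y", "z"), 2))
  res <- test_array_scores(fit, groups, paired = TRUE, pairing = pairing)
  s <- fit$array_scores[, 1]
  d <- s[1:3] - s[4:6]
  expect_equal(res$p_value[1], t.test(d)$p.value, tolerance = 1e-10)

  g1 <- setNames(c("A", rep("B", 5)), names(groups))
  res2 <- test_array_scores(fit, g1)
  expect_true(all(is.na(res2$p_value)))
  expect_match(res2$note[1], "size 1")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_identical(bh_adjust(c(0.2, NA))[2], NA_real_)
  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_reference(p), tolerance = 1e-12)
  }
  # adjusted values are monotone in the raw values
  p <- runif(30)
  adj <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("the fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  # 3 probe sets: with only 2, the array effect absorbs the common
  # component and only the sum of the two variances is identified
  df <- gen_cluster(I = 8, K = 3, P = 4, sigma2 = 0.05,
                    tau2 = c(0.3, 0.05, 0.1), seed = 55)
  fit <- fit_gene_model(df)
  d <- df
  d$exon <- factor(d$probe_set_id)
  for (k in 1:3) d[[paste0("e", k)]] <- as.numeric(d$exon ==
                                                     levels(d$exon)[k])
  lf <- suppressWarnings(suppressMessages(
    lme4::lmer(intensity ~ probe_id + array_id + (0 + e1 | array_id) +
                 (0 + e2 | array_id) + (0 + e3 | array_id),
               data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(lf))
  tau_lme4 <- vc$vcov[match(c("e1", "e2", "e3"), vc$var1)]
  sigma_lme4 <- vc$vcov[is.na(vc$var1)]
  expect_equal(unname(fit$exon_variances), tau_lme4, tolerance = 1e-2)
  expect_equal(fit$residual_variance, sigma_lme4, tolerance = 1e-2)
})
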