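#' Fit the gene-specific mixed model to one transcript cluster
#'
#' For the log2 probe intensities of one gene the model
#' \deqn{y_{ijk} = p_j + c_i + b_{ik} + \varepsilon_{ijk}}
#' decomposes each measurement into a fixed probe affinity \eqn{p_j}, a fixed
#' overall array effect \eqn{c_i}, a random exon-by-array deviation
#' \eqn{b_{ik} \sim N(0, \tau_k^2)} with one variance per exon (probe set),
#' and residual noise \eqn{\varepsilon \sim N(0, \sigma^2)} shared by all
#' exons of the cluster. Between-array variability of exon \eqn{k} beyond the
#' overall array effect is captured by \eqn{\tau_k^2}; the intra-cluster
#' correlation \eqn{\rho_k = \tau_k^2/(\sigma^2+\tau_k^2)} is the exon score.
#'
#' Estimation is REML by an expectation-maximization scheme on Henderson's
#' mixed-model equations: each iteration solves the MME at the current
#' variances, then updates \eqn{\tau_k^2} from the predicted random effects
#' plus their conditional variance and \eqn{\sigma^2} from the residual
#' quadratic form. Fixed effects are identified by sum-to-zero constraints on
#' probes and arrays, the intercept being absorbed into the probe effects.
#' Variance iterates that collapse numerically are clamped at zero. The
#' predicted \eqn{b_{ik}} at the final estimates are returned as array
#' scores.
#'
#' @param gene_data a `probe_table` (or plain data.frame with the same
#'   columns) restricted to a single transcript cluster, log2 scale.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence tolerance on the relative change of the REML
#'   deviance (default 1e-8).
#' @return an object of class `gene_fit`: a list with
#'   `transcript_cluster_id`, `probe_effects`, `array_effects`,
#'   `exon_variances`, `residual_variance`, `array_scores` (arrays x probe
#'   sets), `exon_scores`, `convergence` (`"converged"`, `"max_iter"`, or
#'   `"degenerate"`), `n_iter`, `deviance` (-2 REML log-likelihood) and
#'   `note`.
#' @seealso [exon_score()], [select_candidates()], [test_array_scores()]
#' @export
fit_gene_model <- function(gene_data, max_iter = 500, tol = 1e-8) {
  gene_data <- as.data.frame(gene_data)
  tc <- unique(gene_data$transcript_cluster_id)
  if (length(tc) != 1) {
    stop("fit_gene_model expects exactly one transcript cluster, got ",
         length(tc))
  }
  probe <- factor(gene_data$probe_id)
  array <- factor(gene_data$array_id)
  exon <- factor(gene_data$probe_set_id)
  y <- gene_data$intensity
  n <- length(y)
  J <- nlevels(probe); I <- nlevels(array); K <- nlevels(exon)

  skeleton <- function(status, note) {
    structure(list(
      transcript_cluster_id = tc,
      probe_effects = setNames(rep(NA_real_, J), levels(probe)),
      array_effects = setNames(rep(NA_real_, I), levels(array)),
      exon_variances = setNames(rep(NA_real_, K), levels(exon)),
      residual_variance = NA_real_,
      array_scores = matrix(NA_real_, I, K,
                            dimnames = list(levels(array), levels(exon))),
      exon_scores = setNames(rep(NA_real_, K), levels(exon)),
      convergence = status, n_iter = 0L, deviance = NA_real_, note = note),
      class = "gene_fit")
  }
  if (K < 2) {
    return(skeleton("degenerate",
                    "single probe set: skipped (no within-gene contrast)"))
  }
  if (I < 2) {
    return(skeleton("degenerate", "fewer than 2 arrays"))
  }

  note <- character(0)
  obs_per_exon <- tapply(array, exon, function(a) length(unique(a)))
  if (any(obs_per_exon < 2)) {
    note <- c(note, paste0("probe set(s) with < 2 observed arrays: ",
                           paste(names(obs_per_exon)[obs_per_exon < 2],
                                 collapse = ",")))
  }

  # fixed design: intercept + sum-to-zero probe and array contrasts
  X <- model.matrix(~ probe + array,
                    contrasts.arg = list(probe = "contr.sum",
                                         array = "contr.sum"))
  p <- ncol(X)
  # random design: one indicator column per (exon k, array i), exon-major
  col <- (as.integer(exon) - 1L) * I + as.integer(array)
  q <- K * I
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), col)] <- 1
  exon_of_col <- rep(seq_len(K), each = I)

  # REML depends on the data only through error contrasts, so the fit is
  # run on the fixed-effects residuals: array- or cluster-wide intensity
  # shifts then cancel exactly instead of riding through the optimizer.
  fe <- .lm.fit(X, y)
  beta_ols <- fe$coefficients
  y <- fe$residuals

  XtX <- crossprod(X); XtZ <- crossprod(X, Z); ZtZ <- crossprod(Z)
  Xty <- crossprod(X, y); Zty <- crossprod(Z, y); yty <- sum(y * y)

  s2_tot <- sum(fe$residuals^2) / max(n - p, 1)
  if (s2_tot <= 0) s2_tot <- .Machine$double.eps
  sigma2 <- s2_tot / 2
  tau2 <- rep(s2_tot / 2, K)
  # variance components below this are structural zeros (score < 1e-7)
  floor_tau <- 1e-8 * s2_tot

  # one MME factorization: deviance via the determinant identities
  #   |V| = sigma2^(n-qa) |M| |G|,  |X'V^-1 X| = |C| / (|M| sigma2^p)
  # and Harville's score equations for the analytic gradient.
  mme_eval <- function(sigma2, tau2, need_grad = FALSE) {
    active <- which(tau2 > 0)
    acols <- which(exon_of_col %in% active)
    qa <- length(acols)
    dvec <- sigma2 / tau2[exon_of_col[acols]]
    C <- rbind(cbind(XtX, XtZ[, acols, drop = FALSE]),
               cbind(t(XtZ[, acols, drop = FALSE]),
                     ZtZ[acols, acols, drop = FALSE] + diag(dvec, qa)))
    rhs <- c(Xty, Zty[acols])
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Tinv <- chol2inv(ch)
    sol <- drop(Tinv %*% rhs)
    beta_hat <- sol[seq_len(p)]
    b_act <- sol[p + seq_len(qa)]
    quad <- yty - sum(sol * rhs)           # y'y - u'W'y = sigma2 * y'Py
    dev <- (n - p - qa) * log(sigma2) +
      sum(I * log(tau2[active])) + 2 * sum(log(diag(ch))) +
      quad / sigma2 + (n - p) * log(2 * pi)
    out <- list(dev = dev, beta = beta_hat, b_act = b_act, acols = acols,
                active = active, sigma2 = sigma2, tau2 = tau2)
    if (need_grad) {
      Tbb <- diag(Tinv)[p + seq_len(qa)]
      grp <- factor(exon_of_col[acols], levels = active)
      tr_k <- as.numeric(tapply(Tbb, grp, sum))
      ss_k <- as.numeric(tapply(b_act^2, grp, sum))
      tk <- tau2[active]
      out$grad_tau2 <- I / tk - (sigma2 * tr_k + ss_k) / tk^2
      out$grad_sigma2 <- (n - p - qa) / sigma2 + sum(tr_k / tk) +
        sum(ss_k / tk) / sigma2 - quad / sigma2^2
      out$tr_k <- tr_k
      out$ss_k <- ss_k
    }
    out
  }

  # EM warm start on Henderson's mixed-model equations
  dev <- Inf
  status <- "max_iter"
  iter <- 0L
  ev <- NULL
  lb <- log(floor_tau)
  # the solver alternates monotone EM sweeps (robust anywhere in the
  # parameter space) with quasi-Newton polish rounds of the same REML
  # criterion, until the scaled gradient satisfies the KKT conditions
  for (attempt in 1:6) {
    n_em <- if (attempt == 1) min(max_iter, 50L) else 25L
    for (em in seq_len(n_em)) {
      ev_new <- mme_eval(sigma2, tau2, need_grad = TRUE)
      if (is.null(ev_new)) {
        status <- "degenerate"
        note <- c(note, "mixed-model equations not positive definite")
        break
      }
      iter <- iter + 1L
      conv_em <- abs(ev_new$dev - dev) < tol * (abs(ev_new$dev) + 1)
      dev <- ev_new$dev
      ev <- ev_new
      if (conv_em) break
      # EM updates: tau_k <- (b_k'b_k + sigma2 tr(T_kk)) / I, sigma2 from
      # the residual quadratic form
      tau2_new <- tau2
      tau2_new[ev$active] <- (ev$ss_k + sigma2 * ev$tr_k) / I
      sigma2 <- max((yty - sum(ev$beta * Xty) -
                       sum(ev$b_act * Zty[ev$acols])) / (n - p),
                    .Machine$double.eps)
      tau2_new[tau2_new < floor_tau] <- 0
      tau2 <- tau2_new
    }
    if (status == "degenerate") break

    # quasi-Newton polish (log scale, analytic gradient from the score
    # equations); components pinned at the boundary are structural zeros,
    # fixed before re-optimizing the remaining smooth problem
    opt_ok <- FALSE
    for (round in 1:(K + 1)) {
      act <- which(tau2 > 0)
      obj <- function(par) {
        t2 <- tau2; t2[act] <- exp(par[-1])
        e <- mme_eval(exp(par[1]), t2)
        if (is.null(e)) return(.Machine$double.xmax)
        e$dev
      }
      grd <- function(par) {
        t2 <- tau2; t2[act] <- exp(par[-1])
        e <- mme_eval(exp(par[1]), t2, need_grad = TRUE)
        if (is.null(e)) return(rep(0, length(par)))
        c(e$grad_sigma2 * exp(par[1]), e$grad_tau2 * exp(par[-1]))
      }
      opt <- tryCatch(
        optim(log(c(sigma2, tau2[act])), obj, grd, method = "L-BFGS-B",
              lower = rep(lb, 1 + length(act)),
              upper = rep(30, 1 + length(act)),
              control = list(maxit = max_iter, factr = 1)),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value)) break
      sigma2 <- exp(opt$par[1])
      tau2[act] <- exp(opt$par[-1])
      dev <- opt$value
      opt_ok <- opt$convergence == 0
      pinned <- act[opt$par[-1] < lb + 5]
      if (!length(pinned)) break
      tau2[pinned] <- 0
    }

    # Newton sharpening of the stationary point (Hessian by central
    # differences of the analytic log-scale gradient); keeps the
    # estimates invariant to data shifts at the 1e-9 level
    act <- which(tau2 > 0)
    if (length(act)) {
      lgrad <- function(ls2, lt2) {
        t2 <- tau2; t2[act] <- exp(lt2)
        e <- mme_eval(exp(ls2), t2, need_grad = TRUE)
        if (is.null(e)) return(NULL)
        list(g = c(e$grad_sigma2 * exp(ls2), e$grad_tau2 * exp(lt2)),
             dev = e$dev)
      }
      par <- log(c(sigma2, tau2[act]))
      for (nw in 1:4) {
        cur <- lgrad(par[1], par[-1])
        if (is.null(cur) || max(abs(cur$g)) < 1e-10) break
        np <- length(par)
        H <- matrix(0, np, np)
        h <- 1e-5
        for (j in seq_len(np)) {
          pp <- par; pp[j] <- pp[j] + h
          pm <- par; pm[j] <- pm[j] - h
          gp <- lgrad(pp[1], pp[-1]); gm <- lgrad(pm[1], pm[-1])
          if (is.null(gp) || is.null(gm)) { H <- NULL; break }
          H[, j] <- (gp$g - gm$g) / (2 * h)
        }
        if (is.null(H)) break
        H <- (H + t(H)) / 2
        step <- tryCatch(-solve(H, cur$g), error = function(e) NULL)
        if (is.null(step) || !all(is.finite(step))) break
        if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
        cand <- par + step
        nxt <- lgrad(cand[1], cand[-1])
        if (is.null(nxt) || !is.finite(nxt$dev) ||
            nxt$dev > cur$dev + 1e-10 ||
            max(abs(nxt$g)) >= max(abs(cur$g))) break
        par <- cand
      }
      sigma2 <- exp(par[1])
      tau2[act] <- exp(par[-1])
    }

    ev <- mme_eval(sigma2, tau2, need_grad = TRUE)
    dev <- ev$dev
    gmax <- max(abs(c(ev$grad_sigma2 * sigma2,
                      if (length(ev$active)) {
                        ev$grad_tau2 * tau2[ev$active]
                      })))
    if (opt_ok || (is.finite(gmax) && gmax < 1e-4)) {
      status <- "converged"
      break
    }
  }
  beta_hat <- ev$beta
  b_hat <- rep(0, q)
  b_hat[ev$acols] <- ev$b_act
  if (length(note) && status == "converged") status <- "degenerate"
  if (status == "max_iter") {
    warning("transcript cluster '", tc, "': REML fit did not converge in ",
            max_iter, " iterations; returning last iterate")
  }

  # assemble effects on the original parameterization
  beta_hat <- beta_ols + beta_hat   # OLS fit plus GLS correction
  mu <- beta_hat[1]
  pj <- beta_hat[1 + seq_len(J - 1)]
  ci <- beta_hat[J + seq_len(I - 1)]
  probe_effects <- setNames(mu + c(pj, -sum(pj)), levels(probe))
  array_effects <- setNames(c(ci, -sum(ci)), levels(array))
  b_mat <- matrix(b_hat, nrow = I, ncol = K,
                  dimnames = list(levels(array), levels(exon)))
  tau2 <- setNames(tau2, levels(exon))
  scores <- exon_score(tau2, sigma2)

  structure(list(
    transcript_cluster_id = tc,
    probe_effects = probe_effects,
    array_effects = array_effects,
    exon_variances = tau2,
    residual_variance = sigma2,
    array_scores = b_mat,
    exon_scores = scores,
    convergence = status,
    n_iter = iter,
    deviance = dev,
    note = paste(note, collapse = "; ")),
    class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("gene_fit:", x$transcript_cluster_id,
      "|", length(x$exon_scores), "probe sets,",
      length(x$array_effects), "arrays |", x$convergence,
      sprintf("(%d iter)\n", x$n_iter))
  cat("  sigma2 =", format(x$residual_variance, digits = 4), "\n")
  print(round(x$exon_scores, 3))
  invisible(x)
}

#' Exon score (intra-cluster correlation)
#'
#' \eqn{\rho = \tau^2 / (\sigma^2 + \tau^2)}: the fraction of an exon's
#' variability attributable to between-array differences. A score above 0.5
#' flags the exon as a likely alternative-splicing candidate.
#'
#' @param tau2 nonnegative between-array variance(s) of the exon.
#' @param sigma2 positive shared residual variance of the cluster.
#' @return value(s) in \[0, 1\].
#' @export
exon_score <- function(tau2, sigma2) {
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop("sigma2 must be strictly positive")
  }
  if (any(tau2 < 0, na.rm = TRUE)) stop("tau2 must be nonnegative")
  tau2 / (sigma2 + tau2)
}

#' Fit every transcript cluster of a probe table
#'
#' @param x a `probe_table` on the log2 scale.
#' @param exclude_probe_sets probe-set ids to drop before fitting (e.g.
#'   junction probe sets listed in a junction annotation).
#' @param ... passed to [fit_gene_model()].
#' @return a named list of `gene_fit` objects (one per cluster).
#' @export
fit_genes <- function(x, exclude_probe_sets = NULL, ...) {
  df <- as.data.frame(x)
  if (length(exclude_probe_sets)) {
    df <- df[!(df$probe_set_id %in% exclude_probe_sets), , drop = FALSE]
  }
  fits <- lapply(split(df, df$transcript_cluster_id), fit_gene_model, ...)
  n_bad <- sum(vapply(fits, function(f) f$convergence != "converged", TRUE))
  if (n_bad) {
    message(n_bad, "/", length(fits),
            " cluster(s) did not fully converge (see convergence status)")
  }
  fits
}

#' Summarize fits as one row per probe set
#'
#' @param fits list of `gene_fit` objects.
#' @return data.frame with columns `transcript_cluster_id`, `probe_set_id`,
#'   `tau2`, `sigma2`, `exon_score`, `convergence`.
#' @export
fits_table <- function(fits) {
  if (inherits(fits, "gene_fit")) fits <- list(fits)
  do.call(rbind, c(lapply(unname(fits), function(f) {
    data.frame(transcript_cluster_id = f$transcript_cluster_id,
               probe_set_id = names(f$exon_scores),
               tau2 = unname(f$exon_variances),
               sigma2 = f$residual_variance,
               exon_score = unname(f$exon_scores),
               convergence = f$convergence,
               row.names = NULL)
  }), list(make.row.names = FALSE)))
}

#' Long-format array scores from fits
#'
#' @param fits list of `gene_fit` objects.
#' @return data.frame `transcript_cluster_id, probe_set_id, array_id, score`.
#' @export
array_scores_table <- function(fits) {
  if (inherits(fits, "gene_fit")) fits <- list(fits)
  do.call(rbind, c(lapply(unname(fits), function(f) {
    s <- f$array_scores
    data.frame(transcript_cluster_id = f$transcript_cluster_id,
               probe_set_id = rep(colnames(s), each = nrow(s)),
               array_id = rep(rownames(s), times = ncol(s)),
               score = as.vector(s), row.names = NULL)
  }), list(make.row.names = FALSE)))
}

#' Retain probe sets scoring above the candidate threshold
#'
#' Keeps exactly the probe sets with exon score strictly greater than
#' `threshold` (default 0.5), sorted by score, highest first.
#'
#' @param fits list of `gene_fit` objects (or a `fits_table` data.frame).
#' @param threshold exon-score cutoff in \[0, 1\].
#' @return a candidate table: `transcript_cluster_id, probe_set_id,
#'   exon_score` plus empty testing columns (`p_value`, `p_adjusted`,
#'   `mean_diff`, `direction`) filled by [test_array_scores()] /
#'   [bh_adjust()].
#' @export
select_candidates <- function(fits, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]")
  }
  tab <- if (is.data.frame(fits)) fits else fits_table(fits)
  keep <- !is.na(tab$exon_score) & tab$exon_score > threshold
  out <- tab[keep, c("transcript_cluster_id", "probe_set_id", "exon_score")]
  out <- out[order(-out$exon_score), , drop = FALSE]
  out$p_value <- rep(NA_real_, nrow(out))
  out$p_adjusted <- rep(NA_real_, nrow(out))
  out$mean_diff <- rep(NA_real_, nrow(out))
  out$direction <- rep(NA_character_, nrow(out))
  rownames(out) <- NULL
  out
}

#' Test array-score differences between two groups
#'
#' For each requested probe set, compares the predicted exon-by-array random
#' effects (array scores) between the two groups with a two-sided Welch
#' t-test, or a paired t-test on within-pair differences when `paired = TRUE`.
#' Zero-variance (degenerate) scores give p = 1 with a note; an unpaired
#' group of size 1 gives a missing p-value with a reason.
#'
#' @param fit a `gene_fit`.
#' @param groups named character vector or data.frame (`array_id`, `group`)
#'   assigning each array to one of exactly two groups.
#' @param paired logical; use the paired t-test.
#' @param pairing when paired, a data.frame (`array_id`, `pair_id`) or named
#'   vector giving a bijection between the groups.
#' @param probe_sets subset of probe sets to test (default: all in the fit).
#' @return data.frame `probe_set_id, p_value, mean_diff, direction, note`;
#'   `mean_diff` is mean(group A) - mean(group B) with groups in sorted label
#'   order, `direction` is `enriched_in_<group>` for the higher-scoring group.
#' @export
test_array_scores <- function(fit, groups, paired = FALSE, pairing = NULL,
                              probe_sets = NULL) {
  stopifnot(inherits(fit, "gene_fit"))
  g <- .group_vector(groups)
  arrays <- rownames(fit$array_scores)
  if (!all(arrays %in% names(g))) {
    stop("group labels missing for array(s): ",
         paste(setdiff(arrays, names(g)), collapse = ", "))
  }
  g <- g[arrays]
  lv <- sort(unique(g))
  if (length(lv) != 2) stop("exactly two groups are required, got ",
                            length(lv))
  if (is.null(probe_sets)) probe_sets <- colnames(fit$array_scores)

  pr <- NULL
  if (paired) {
    pr <- .pairing_map(pairing, arrays, g, lv)
  }

  res <- lapply(probe_sets, function(ps) {
    s <- fit$array_scores[, ps]
    a <- s[g == lv[1]]; b <- s[g == lv[2]]
    md <- mean(a) - mean(b)
    dir <- if (md >= 0) paste0("enriched_in_", lv[1]) else
      paste0("enriched_in_", lv[2])
    note <- ""
    pval <- NA_real_
    if (anyNA(s)) {
      note <- "missing array scores"
    } else if (paired) {
      d <- s[pr[, 1]] - s[pr[, 2]]
      if (sd(d) < 1e-12) {
        pval <- 1; note <- "degenerate: zero-variance differences"
      } else {
        pval <- t.test(d)$p.value
      }
    } else if (length(a) < 2 || length(b) < 2) {
      note <- "group of size 1: p-value undefined for unpaired test"
    } else if (sd(a) < 1e-12 && sd(b) < 1e-12) {
      pval <- if (abs(md) < 1e-12) 1 else 0
      note <- "degenerate: zero-variance scores"
    } else {
      pval <- t.test(a, b, var.equal = FALSE)$p.value
    }
    data.frame(probe_set_id = ps, p_value = pval, mean_diff = md,
               direction = dir, note = note)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

.group_vector <- function(groups) {
  if (is.data.frame(groups)) {
    setNames(as.character(groups$group), groups$array_id)
  } else if (!is.null(names(groups))) {
    setNames(as.character(groups), names(groups))
  } else {
    stop("groups must be a named vector or a data.frame(array_id, group)")
  }
}

.pairing_map <- function(pairing, arrays, g, lv) {
  if (is.null(pairing)) stop("paired = TRUE requires a pairing")
  if (is.data.frame(pairing)) {
    pairing <- setNames(as.character(pairing$pair_id), pairing$array_id)
  }
  a1 <- arrays[g == lv[1]]; a2 <- arrays[g == lv[2]]
  p1 <- pairing[a1]; p2 <- pairing[a2]
  if (anyNA(p1) || anyNA(p2) || length(a1) != length(a2) ||
      !setequal(p1, p2) || anyDuplicated(p1) || anyDuplicated(p2)) {
    stop("pairing must be a bijection between the two groups")
  }
  cbind(a1[order(p1)], a2[order(p2)])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values, clipped at 1, input order preserved;
#' missing entries are passed through as missing (and do not count toward the
#' family size).
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs allowed).
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}
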