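# Independent reference implementations used as oracles. These deliberately
# use naive dense-matrix / brute-force routes, separate from the package's
# code paths.

# --- quantile normalization: explicit sort / average / unsort -------------
qn_reference <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    out[, j] <- (ref[floor(r)] + ref[ceiling(r)]) / 2
  }
  out
}

# --- REML deviance with dense V and brute-force optimizer -----------------
reml_design <- function(df) {
  probe <- factor(df$probe_id)
  array <- factor(df$array_id)
  exon <- factor(df$probe_set_id)
  X <- model.matrix(~ probe + array,
                    contrasts.arg = list(probe = "contr.sum",
                                         array = "contr.sum"))
  I <- nlevels(array); K <- nlevels(exon)
  col <- (as.integer(exon) - 1L) * I + as.integer(array)
  Z <- matrix(0, nrow(df), K * I)
  Z[cbind(seq_len(nrow(df)), col)] <- 1
  list(y = df$intensity, X = X, Z = Z,
       exon_of_col = rep(seq_len(K), each = I), K = K)
}

reml_dev_dense <- function(sigma2, tau2, d) {
  n <- length(d$y)
  V <- sigma2 * diag(n) + d$Z %*% diag(tau2[d$exon_of_col],
                                       ncol(d$Z)) %*% t(d$Z)
  Vi <- solve(V)
  XtViX <- t(d$X) %*% Vi %*% d$X
  beta <- solve(XtViX, t(d$X) %*% Vi %*% d$y)
  r <- d$y - d$X %*% beta
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(r) %*% Vi %*% r + (n - ncol(d$X)) * log(2 * pi))
}

# brute-force maximizer of the REML criterion over (sigma2, tau2 >= 0);
# multi-start including an optional externally supplied start
oracle_reml_fit <- function(df, extra_starts = list()) {
  d <- reml_design(df)
  obj <- function(par) {
    reml_dev_dense(exp(par[1]), pmax(par[-1], 0), d)
  }
  s2_0 <- var(d$y)
  starts <- c(list(c(log(s2_0 / 2), rep(s2_0 / 2, d$K)),
                   c(log(s2_0 / 10), rep(s2_0, d$K))),
              extra_starts)
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(st, obj, method = "L-BFGS-B",
            lower = c(-30, rep(0, d$K)), upper = c(10, rep(50, d$K)),
            control = list(maxit = 1000, factr = 1e2)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  list(sigma2 = exp(best$par[1]), tau2 = pmax(best$par[-1], 0),
       deviance = best$value)
}

# --- textbook Welch t-test ------------------------------------------------
welch_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}

# --- step-up BH from the definition ---------------------------------------
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# --- two-way ANOVA interaction F from explicit cell means (balanced) ------
anova_interaction_oracle <- function(r, entity, group) {
  stopifnot(length(unique(table(entity, group))) == 1)  # balanced cells
  cells <- tapply(r, list(entity, group), mean)
  grand <- mean(r)
  ent_m <- tapply(r, entity, mean)
  grp_m <- tapply(r, group, mean)
  n_cell <- table(entity, group)[1, 1]
  ss_int <- 0
  for (e in rownames(cells)) for (g in colnames(cells)) {
    ss_int <- ss_int + n_cell *
      (cells[e, g] - ent_m[e] - grp_m[g] + grand)^2
  }
  fitted <- cells[cbind(as.character(entity), as.character(group))]
  ss_res <- sum((r - fitted)^2)
  df_int <- (nrow(cells) - 1) * (ncol(cells) - 1)
  df_res <- length(r) - nrow(cells) * ncol(cells)
  f <- (ss_int / df_int) / (ss_res / df_res)
  pf(f, df_int, df_res, lower.tail = FALSE)
}

# --- normal+exponential posterior mean by numerical integration -----------
# (integrand normalized at its peak on the log scale so the quadrature
# stays finite for arbitrarily large signals)
normexp_posterior_mean <- function(x, mu, sigma, alpha_mean) {
  logf <- function(s) dexp(s, 1 / alpha_mean, log = TRUE) +
    dnorm(x - s, mu, sigma, log = TRUE)
  lo <- max(0, x - mu - 10 * sigma - 10 * alpha_mean)
  hi <- max(x - mu + 10 * sigma, 10 * alpha_mean, lo + 1)
  grid <- seq(lo, hi, length.out = 4096)
  peak <- max(logf(grid))
  num <- integrate(function(s) s * exp(logf(s) - peak), lo, hi,
                   rel.tol = 1e-10)$value
  den <- integrate(function(s) exp(logf(s) - peak), lo, hi,
                   rel.tol = 1e-10)$value
  num / den
}
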