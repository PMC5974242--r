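# Small in-code fixtures shared across test files.

# one balanced transcript cluster generated from the gene model itself
gen_cluster <- function(I = 6, K = 4, P = 4, sigma2 = 0.04,
                        tau2 = rep(0, K), group_shift = 0,
                        groups = rep(c("A", "B"), each = I / 2),
                        seed = 1, tc = "TC1") {
  set.seed(seed)
  arrays <- sprintf("a%02d", seq_len(I))
  rows <- list()
  ci <- rnorm(I, 0, 0.2)
  for (k in seq_len(K)) {
    mu_b <- if (group_shift != 0 && k == 1) {
      ifelse(groups == "A", group_shift / 2, -group_shift / 2)
    } else 0
    b <- rnorm(I, mu_b, sqrt(tau2[k]))
    pj <- rnorm(P, 7, 1)
    for (j in seq_len(P)) {
      rows[[length(rows) + 1]] <- data.frame(
        transcript_cluster_id = tc,
        probe_set_id = sprintf("%s_ps%02d", tc, k),
        probe_id = sprintf("%s_ps%02d_p%d", tc, k, j),
        array_id = arrays,
        intensity = pj[j] + ci + b + rnorm(I, 0, sqrt(sigma2)))
    }
  }
  df <- do.call(rbind, rows)
  attr(df, "groups") <- setNames(groups, arrays)
  df
}

make_probe_table <- function(m, scale_flag = "raw", tc = "TC1",
                             ps = "PS1") {
  df <- data.frame(
    transcript_cluster_id = tc,
    probe_set_id = ps,
    probe_id = rownames(m)[row(m)],
    array_id = colnames(m)[col(m)],
    intensity = as.vector(m))
  probe_table(df, scale_flag)
}

rand_matrix <- function(nr, nc, seed = 1, dist = function(n) rexp(n, 1/50)) {
  set.seed(seed)
  matrix(dist(nr * nc), nr, nc,
         dimnames = list(sprintf("p%03d", seq_len(nr)),
                         sprintf("a%02d", seq_len(nc))))
}
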