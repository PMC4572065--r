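# Shared helpers: compact genotype-matrix construction and an
# independent group-mean AMOVA oracle used to cross-check the
# distance-based implementation.

# Build a genotype_matrix from a list of per-sample call vectors.
gm_from_rows <- function(rows, accession_id, marker_id = NULL) {
  calls <- do.call(rbind, rows)
  if (is.null(marker_id)) marker_id <- sprintf("M%05d", seq_len(ncol(calls)))
  genotype_matrix(calls,
                  sample_id = sprintf("S%04d", seq_len(nrow(calls))),
                  accession_id = accession_id, marker_id = marker_id)
}

# One-column genotype_matrix from a call vector.
gm_one_marker <- function(calls, accession_id = rep("A1", length(calls))) {
  gm_from_rows(as.list(calls), accession_id, "M00001")
}

# Independent AMOVA oracle: sums of squares from group-mean deviations
# (never from pairwise distances) and variance components from the
# standard unbalanced-design coefficient formulas, coded from scratch.
brute_amova <- function(X, acc, reg = NULL) {
  N <- nrow(X)
  grand <- colMeans(X)
  dev_ss <- function(rows, center)
    sum(sweep(X[rows, , drop = FALSE], 2, center)^2)
  acc_levels <- unique(acc)
  n_p <- vapply(acc_levels, function(a) sum(acc == a), 1)
  acc_mean <- t(vapply(acc_levels,
                       function(a) colMeans(X[acc == a, , drop = FALSE]),
                       numeric(ncol(X))))
  ss_wp <- sum(vapply(acc_levels,
                      function(a) dev_ss(which(acc == a),
                                         acc_mean[match(a, acc_levels), ]),
                      1))
  ss_tot <- dev_ss(seq_len(N), grand)
  P <- length(acc_levels)
  if (is.null(reg)) {
    ss_ap <- ss_tot - ss_wp
    df <- c(AP = P - 1, WP = N - P)
    ms <- c(AP = ss_ap / df[["AP"]], WP = ss_wp / df[["WP"]])
    n0 <- (N - sum(n_p^2) / N) / (P - 1)
    wp <- ms[["WP"]]
    ap <- (ms[["AP"]] - wp) / n0
    return(list(ss = c(AP = ss_ap, WP = ss_wp), ss_total = ss_tot,
                df = df, ms = ms, components = c(AP = ap, WP = wp),
                coefficients = c(n0 = n0)))
  }
  reg_of_acc <- reg[match(acc_levels, acc)]
  reg_levels <- unique(reg)
  R <- length(reg_levels)
  N_r <- vapply(reg_levels, function(r) sum(reg == r), 1)
  reg_mean <- t(vapply(reg_levels,
                       function(r) colMeans(X[reg == r, , drop = FALSE]),
                       numeric(ncol(X))))
  ss_ar <- sum(N_r * rowSums(sweep(reg_mean, 2, grand)^2))
  ss_ap <- sum(n_p * rowSums((acc_mean -
                              reg_mean[match(reg_of_acc, reg_levels), ,
                                       drop = FALSE])^2))
  df <- c(AR = R - 1, AP = P - R, WP = N - P)
  ms <- c(AR = ss_ar / df[["AR"]], AP = ss_ap / df[["AP"]],
          WP = ss_wp / df[["WP"]])
  A <- sum(vapply(reg_levels, function(r)
    sum(n_p[reg_of_acc == r]^2) / N_r[[match(r, reg_levels)]], 1))
  n1 <- (N - A) / (P - R)
  n2 <- (A - sum(n_p^2) / N) / (R - 1)
  n3 <- (N - sum(N_r^2) / N) / (R - 1)
  wp <- ms[["WP"]]
  ap <- (ms[["AP"]] - wp) / n1
  ar <- (ms[["AR"]] - wp - n2 * ap) / n3
  list(ss = c(AR = ss_ar, AP = ss_ap, WP = ss_wp), ss_total = ss_tot,
       df = df, ms = ms, components = c(AR = ar, AP = ap, WP = wp),
       coefficients = c(n1 = n1, n2 = n2, n3 = n3))
}

# Random unbalanced design + encoded-style data for oracle comparisons.
random_amova_case <- function(seed, n_regions = 3) {
  set.seed(seed)
  acc_per_reg <- sample(2:4, n_regions, replace = TRUE)
  sizes <- sample(2:5, sum(acc_per_reg), replace = TRUE)
  acc <- rep(sprintf("A%02d", seq_along(sizes)), sizes)
  reg <- rep(rep(sprintf("R%d", seq_len(n_regions)), acc_per_reg), sizes)
  X <- matrix(sample(c(0, 0.5, 1), length(acc) * 12, replace = TRUE),
              nrow = length(acc))
  list(X = X, acc = acc, reg = reg)
}
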