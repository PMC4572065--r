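## Distance-based hierarchical analysis of molecular variance on the
## allele-presence encoding, with Phi fixation indices and label
## permutation tests.

#' Pairwise squared Euclidean distances over encoded genotypes
#'
#' Under the (1, 0)/(0.5, 0.5)/(0, 1) allele encoding the squared
#' distance between an AA and a BB individual at one marker is 2; this
#' codominant-genotypic distance suppresses intra-individual variation.
#'
#' @param encoded matrix from \code{\link{encode_genotypes}}.
#' @return Symmetric matrix of squared distances with a zero diagonal.
#' @export
squared_distance_matrix <- function(encoded) {
  if (nrow(encoded) < 2) stop("need at least two samples")
  G <- tcrossprod(encoded)
  q <- diag(G)
  D <- outer(q, q, "+") - 2 * G
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

## sum of squares within groups from a squared-distance matrix:
## each group g contributes sum(D[g, g]) / (2 * n_g)
.ss_within <- function(D, labels) {
  f <- factor(labels)
  M1 <- rowsum(D, f)
  gs <- diag(rowsum(t(M1), f))
  n <- tabulate(f)
  sum(gs / (2 * n))
}

## variance decomposition from a squared-distance matrix; regions = NULL
## gives the 2-level analysis
.amova_components <- function(D, accessions, regions = NULL) {
  N <- nrow(D)
  f_acc <- factor(accessions)
  n_p <- tabulate(f_acc)
  P <- nlevels(f_acc)
  ss_tot <- sum(D) / (2 * N)
  ss_wp <- .ss_within(D, f_acc)

  if (is.null(regions)) {
    df <- c(AP = P - 1L, WP = N - P)
    ss <- c(AP = ss_tot - ss_wp, WP = ss_wp)
    ms <- ss / df
    n0 <- (N - sum(n_p^2) / N) / (P - 1)
    wp <- ms[["WP"]]
    ap <- (ms[["AP"]] - wp) / n0
    return(list(df = df, ss = ss, ms = ms, ss_total = ss_tot,
                components = c(AP = ap, WP = wp)))
  }

  f_reg <- factor(regions)
  R <- nlevels(f_reg)
  reg_of_acc <- tapply(as.character(f_reg), f_acc,
                       function(z) unique(z), simplify = FALSE)
  if (any(vapply(reg_of_acc, length, 1L) > 1))
    stop("an accession spans more than one region")
  reg_vec <- vapply(reg_of_acc, identity, "")   # region of each accession
  N_r <- tabulate(f_reg)
  ss_within_r <- .ss_within(D, f_reg)
  df <- c(AR = R - 1L, AP = P - R, WP = N - P)
  ss <- c(AR = ss_tot - ss_within_r, AP = ss_within_r - ss_wp, WP = ss_wp)
  ms <- ss / df
  ## unbalanced-design coefficients
  np2_by_r <- tapply(n_p^2, reg_vec, sum)
  N_r_by <- tapply(n_p, reg_vec, sum)
  A <- sum(np2_by_r / N_r_by)
  n1 <- (N - A) / (P - R)
  n2 <- (A - sum(n_p^2) / N) / (R - 1)
  n3 <- (N - sum(N_r^2) / N) / (R - 1)
  wp <- ms[["WP"]]
  ap <- (ms[["AP"]] - wp) / n1
  ar <- (ms[["AR"]] - wp - n2 * ap) / n3
  list(df = df, ss = ss, ms = ms, ss_total = ss_tot,
       components = c(AR = ar, AP = ap, WP = wp),
       coefficients = c(n1 = n1, n2 = n2, n3 = n3))
}

#' Phi fixation indices from AMOVA variance components
#'
#' \deqn{\Phi_{RT} = AR / (WP + AP + AR)} \deqn{\Phi_{PR} = AP / (AP + WP)}
#' \deqn{\Phi_{PT} = (AP + AR) / (WP + AP + AR)}
#' Negative components are truncated at zero before the ratios are
#' formed.
#'
#' @param AR,AP,WP variance components: among regions, among accessions
#'   within regions, within accessions.
#' @return Named vector \code{c(phi_rt, phi_pr, phi_pt)}.
#' @export
phi_from_components <- function(AR, AP, WP) {
  v <- pmax(c(AR = AR, AP = AP, WP = WP), 0)
  tot <- sum(v)
  if (tot <= 0) stop("degenerate: all variance components are zero")
  c(phi_rt = v[["AR"]] / tot,
    phi_pr = if (v[["AP"]] + v[["WP"]] > 0)
      v[["AP"]] / (v[["AP"]] + v[["WP"]]) else 0,
    phi_pt = (v[["AP"]] + v[["AR"]]) / tot)
}

.phi_2level <- function(AP, WP) {
  v <- pmax(c(AP, WP), 0)
  if (sum(v) <= 0) return(0)
  v[1] / sum(v)
}

#' Hierarchical AMOVA with Phi statistics
#'
#' Distance-based nested analysis of molecular variance.  With region
#' labels the decomposition has three strata (among regions, among
#' accessions within regions, within accessions) with unbalanced-design
#' coefficients; without regions a two-level analysis (among/within
#' accessions) is returned.  Negative variance components are reported
#' raw but truncated at zero for percentages and Phi.
#'
#' @param encoded matrix from \code{\link{encode_genotypes}}.
#' @param accessions per-sample accession labels; defaults to the
#'   attribute carried by \code{encoded}.
#' @param regions optional per-sample region labels; each accession must
#'   lie wholly inside one region.
#' @param n_perm number of label permutations for P values (0 = none).
#' @param seed integer seed for the permutations.
#' @return Object of class \code{amova_result} with the AMOVA table,
#'   variance components, percentages, Phi statistics and permutation P
#'   values.
#' @export
amova_nested <- function(encoded, accessions = NULL, regions = NULL,
                         n_perm = 0, seed = 1L) {
  if (is.null(accessions)) accessions <- attr(encoded, "accession_id")
  if (is.null(accessions) || length(accessions) != nrow(encoded) ||
      anyNA(accessions))
    stop("every sample must carry an accession label")
  if (length(unique(accessions)) < 2)
    stop("AMOVA needs at least two accessions")
  if (!is.null(regions) && (length(regions) != nrow(encoded) ||
                            anyNA(regions)))
    stop("regions must label every sample")
  D <- squared_distance_matrix(encoded)
  cp <- .amova_components(D, accessions, regions)
  comp <- cp$components
  trunc <- pmax(comp, 0)
  tot <- sum(trunc)
  degenerate <- tot <= .Machine$double.eps
  pct <- if (degenerate) trunc * 0 else 100 * trunc / tot
  phi <- if (degenerate) {
    if (is.null(regions)) c(phi_pt = 0) else
      c(phi_rt = 0, phi_pr = 0, phi_pt = 0)
  } else if (is.null(regions)) {
    c(phi_pt = .phi_2level(comp[["AP"]], comp[["WP"]]))
  } else {
    phi_from_components(comp[["AR"]], comp[["AP"]], comp[["WP"]])
  }

  src <- if (is.null(regions))
    c(AP = "Between accessions", WP = "Within accessions") else
    c(AR = "Between regions", AP = "Between accessions",
      WP = "Within accessions")
  tab <- data.frame(Source = c(unname(src[names(cp$df)]), "Total"),
                    df = c(unname(cp$df), nrow(D) - 1L),
                    SS = c(unname(cp$ss), cp$ss_total),
                    MS = c(unname(cp$ms), NA),
                    Est.var = c(unname(trunc), tot),
                    Percent = c(unname(pct), if (degenerate) 0 else 100),
                    stringsAsFactors = FALSE)

  p_values <- NULL
  if (n_perm > 0 && !degenerate) {
    p_values <- vapply(names(phi), function(st)
      permutation_test(encoded, accessions, regions, statistic = st,
                       n_perm = n_perm, seed = seed, .D = D),
      numeric(1))
  }
  structure(list(table = tab, components = comp, components_trunc = trunc,
                 percent = pct, phi = phi, p_values = p_values,
                 n_perm = n_perm, seed = seed, degenerate = degenerate,
                 coefficients = cp$coefficients),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA\n")
  tab <- x$table
  tab$SS <- round(tab$SS, 3); tab$MS <- round(tab$MS, 3)
  tab$Est.var <- round(tab$Est.var, 4); tab$Percent <- round(tab$Percent)
  print(tab, row.names = FALSE)
  phi <- round(x$phi, 3)
  for (nm in names(phi))
    cat(sprintf("  %s = %.3f%s\n", toupper(nm), phi[[nm]],
                if (!is.null(x$p_values))
                  sprintf("  P(rand >= data) = %.3f", x$p_values[[nm]])
                else ""))
  if (x$degenerate) cat("  (degenerate: no molecular variance)\n")
  invisible(x)
}

#' Permutation test for a Phi statistic
#'
#' Permutation schemes follow the usual conventions for hierarchical
#' Phi statistics: \code{phi_pt} permutes individuals among accessions
#' (two-level analysis), \code{phi_pr} permutes individuals among
#' accessions within their region, and \code{phi_rt} permutes whole
#' accessions among regions.  The P value is
#' \eqn{(\#\{perm \ge obs\} + 1) / (n_{perm} + 1)}.
#'
#' @param encoded matrix from \code{\link{encode_genotypes}}.
#' @param accessions,regions per-sample labels.
#' @param statistic one of \code{"phi_pt"}, \code{"phi_pr"},
#'   \code{"phi_rt"}.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param .D precomputed squared-distance matrix (internal use).
#' @return The permutation P value.
#' @export
permutation_test <- function(encoded, accessions = NULL, regions = NULL,
                             statistic = c("phi_pt", "phi_pr", "phi_rt"),
                             n_perm = 999, seed = 1L, .D = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(accessions)) accessions <- attr(encoded, "accession_id")
  stopifnot(n_perm >= 1)
  if (statistic %in% c("phi_pr", "phi_rt") && is.null(regions))
    stop("statistic ", statistic, " requires region labels")
  D <- if (is.null(.D)) squared_distance_matrix(encoded) else .D
  set.seed(seed)

  stat_fun <- switch(statistic,
    phi_pt = function(acc, reg) {
      cmp <- .amova_components(D, acc, NULL)$components
      .phi_2level(cmp[["AP"]], cmp[["WP"]])
    },
    phi_pr = function(acc, reg) {
      cmp <- .amova_components(D, acc, reg)$components
      v <- pmax(cmp, 0)
      if (v[["AP"]] + v[["WP"]] > 0) v[["AP"]] / (v[["AP"]] + v[["WP"]]) else 0
    },
    phi_rt = function(acc, reg) {
      cmp <- .amova_components(D, acc, reg)$components
      v <- pmax(cmp, 0)
      if (sum(v) > 0) v[["AR"]] / sum(v) else 0
    })

  permute <- switch(statistic,
    phi_pt = function() list(acc = sample(accessions), reg = regions),
    phi_pr = function() {
      acc <- accessions
      for (r in unique(regions)) {
        i <- which(regions == r)
        acc[i] <- acc[i][sample.int(length(i))]
      }
      list(acc = acc, reg = regions)
    },
    phi_rt = function() {
      acc_levels <- unique(accessions)
      reg_of_acc <- regions[match(acc_levels, accessions)]
      new_reg <- reg_of_acc[sample.int(length(acc_levels))]
      list(acc = accessions,
           reg = new_reg[match(accessions, acc_levels)])
    })

  obs <- stat_fun(accessions, regions)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    pl <- permute()
    if (stat_fun(pl$acc, pl$reg) >= obs) ge <- ge + 1L
  }
  (ge + 1) / (n_perm + 1)
}

#' Two-region AMOVA treating each region as one population
#'
#' Restricts the data to one pair of regions and runs the two-level
#' analysis with the regions themselves as the populations (1 df
#' between).
#'
#' @param encoded matrix from \code{\link{encode_genotypes}}.
#' @param regions per-sample region labels.
#' @param pair character vector of two region names.
#' @param n_perm,seed passed to \code{\link{amova_nested}}.
#' @return An \code{amova_result} for the pair.
#' @export
pairwise_region_amova <- function(encoded, regions, pair, n_perm = 0,
                                  seed = 1L) {
  stopifnot(length(pair) == 2)
  unknown <- setdiff(pair, unique(regions))
  if (length(unknown))
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  keep <- regions %in% pair
  amova_nested(encoded[keep, , drop = FALSE], regions[keep],
               regions = NULL, n_perm = n_perm, seed = seed)
}
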