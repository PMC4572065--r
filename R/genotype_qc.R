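## Marker validation for array genotypes: cluster-quality triage,
## missingness, Mendelian trio errors against a mapping family, minor
## allele frequency, and an exact heterozygote-excess test per
## accession combined across accessions.

#' Triage markers on cluster-quality statistics
#'
#' A marker fails when the average intensity (R mean) of any occupied
#' cluster is below \code{fail_rmean} or the cluster separation is below
#' \code{fail_sep}; it is flagged for manual review when the separation
#' lies in \code{[fail_sep, review_sep_hi)}; otherwise it passes.
#' Markers without statistics are reported as \code{unscored}, never
#' silently passed.
#'
#' @param stats data frame with \code{marker_id}, columns named
#'   \code{r_mean_*} (one per cluster; \code{NA} = unoccupied) and
#'   \code{cluster_separation}.
#' @param markers optional full marker list; entries absent from
#'   \code{stats} are labelled \code{unscored}.
#' @param fail_rmean minimum acceptable per-cluster R mean.
#' @param fail_sep minimum acceptable cluster separation.
#' @param review_sep_hi upper bound (exclusive) of the review band.
#' @return Data frame with \code{marker_id} and \code{label} in
#'   \code{pass}/\code{review}/\code{fail}/\code{unscored}.
#' @export
apply_cluster_qc <- function(stats, markers = NULL, fail_rmean = 0.2,
                             fail_sep = 0.3, review_sep_hi = 0.45) {
  rcols <- grep("^r_mean", names(stats), value = TRUE)
  if (!length(rcols) || !"cluster_separation" %in% names(stats))
    stop("cluster stats need r_mean_* columns and cluster_separation")
  r <- as.matrix(stats[, rcols, drop = FALSE])
  if (any(rowSums(!is.na(r)) == 0))
    stop("each marker needs at least one occupied cluster")
  low_r <- apply(r < fail_rmean, 1, any, na.rm = TRUE)
  sep <- stats$cluster_separation
  label <- ifelse(low_r | sep < fail_sep, "fail",
                  ifelse(sep < review_sep_hi, "review", "pass"))
  out <- data.frame(marker_id = stats$marker_id, label = label,
                    stringsAsFactors = FALSE)
  if (!is.null(markers)) {
    missing_m <- setdiff(markers, stats$marker_id)
    if (length(missing_m))
      out <- rbind(out, data.frame(marker_id = missing_m,
                                   label = "unscored",
                                   stringsAsFactors = FALSE))
    out <- out[match(markers, out$marker_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Per-marker missingness and the missingness filter
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param max_missing maximum tolerated missing-call fraction; markers
#'   with strictly more are removed.
#' @return \code{missingness} returns the per-marker \code{NC} fraction;
#'   \code{missingness_filter} a list with \code{survivors},
#'   \code{removed} (marker ids) and \code{fraction}.
#' @export
missingness <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  colMeans(unclass(x) == "NC")
}

#' @rdname missingness
#' @export
missingness_filter <- function(x, max_missing = 0.10) {
  fr <- missingness(x)
  list(survivors = colnames(x)[fr <= max_missing],
       removed = colnames(x)[fr > max_missing],
       fraction = fr)
}

#' Minor allele frequency
#'
#' MAF is the rarer allele's share of the non-missing allele calls:
#' \code{AA} contributes two A alleles, \code{AB} one of each, and
#' \code{NC} is excluded from the denominator.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param marker optional single marker name; when given, an all-missing
#'   marker is an error.  When omitted, a vector over all markers is
#'   returned with \code{NA} for all-missing markers.
#' @return Numeric MAF in [0, 0.5].
#' @export
minor_allele_frequency <- function(x, marker = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  calls <- unclass(x)
  if (!is.null(marker)) calls <- calls[, marker, drop = FALSE]
  nA <- colSums((calls == "AA") * 2L + (calls == "AB"))
  nB <- colSums((calls == "BB") * 2L + (calls == "AB"))
  tot <- nA + nB
  maf <- ifelse(tot > 0, pmin(nA, nB) / tot, NA_real_)
  if (!is.null(marker)) {
    if (is.na(maf)) stop("MAF undefined: marker '", marker,
                         "' has no non-missing calls")
    return(unname(maf))
  }
  maf
}

.mendel_possible <- function(g1, g2) {
  ## possible offspring A-allele counts for parent counts g1, g2
  tx <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  unique(as.vector(outer(tx[[as.character(g1)]], tx[[as.character(g2)]], "+")))
}

## offspring-call consistency lookup under biallelic Mendelian rules;
## dimensions: parent1 call x parent2 call x offspring call
.mendel_table <- local({
  calls <- c("AA", "AB", "BB")
  arr <- array(FALSE, c(3, 3, 3), dimnames = list(calls, calls, calls))
  cnt <- c(AA = 2L, AB = 1L, BB = 0L)
  for (p1 in calls) for (p2 in calls) {
    ok <- .mendel_possible(cnt[[p1]], cnt[[p2]])
    for (ch in calls) arr[p1, p2, ch] <- cnt[[ch]] %in% ok
  }
  arr
})

#' Count Mendelian trio errors per marker
#'
#' For each offspring of a parent-parent-child trio, an error is scored
#' when the offspring call is impossible given the two parental calls at
#' a biallelic locus.  Trios with a missing call in the parent or the
#' offspring are skipped at that marker.
#'
#' @param x a \code{\link{genotype_matrix}} containing the family.
#' @param trios list with \code{parent1_id}, \code{parent2_id} and
#'   \code{offspring_ids}.
#' @param markers optional marker subset.
#' @return Named integer vector of error counts per marker.
#' @export
count_trio_errors <- function(x, trios, markers = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ids <- c(trios$parent1_id, trios$parent2_id, trios$offspring_ids)
  unknown <- setdiff(ids, rownames(x))
  if (length(unknown))
    stop("trio sample id(s) not present in genotype matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  calls <- unclass(x)
  if (!is.null(markers)) calls <- calls[, markers, drop = FALSE]
  p1 <- calls[trios$parent1_id, ]
  p2 <- calls[trios$parent2_id, ]
  off <- calls[trios$offspring_ids, , drop = FALSE]
  M <- ncol(calls)
  errs <- integer(M)
  for (j in seq_len(M)) {
    if (p1[j] == "NC" || p2[j] == "NC") next
    ch <- off[, j]
    ch <- ch[ch != "NC"]
    if (!length(ch)) next
    errs[j] <- sum(!.mendel_table[p1[j], p2[j], ch])
  }
  stats::setNames(errs, colnames(calls))
}

#' @rdname count_trio_errors
#' @param max_errors markers with strictly more trio errors are removed.
#' @return \code{trio_error_filter} returns a list with
#'   \code{survivors}, \code{removed} and the \code{errors} vector.
#' @export
trio_error_filter <- function(x, trios, max_errors = 4, markers = NULL) {
  errs <- count_trio_errors(x, trios, markers)
  list(survivors = names(errs)[errs <= max_errors],
       removed = names(errs)[errs > max_errors],
       errors = errs)
}

#' Exact conditional distribution of heterozygote counts
#'
#' Under Hardy-Weinberg, conditional on the sample size \code{n} and the
#' allele count \code{nA}, the number of heterozygotes \code{h} follows
#' the Levene distribution
#' \deqn{P(h \mid n, n_A) = \frac{n!}{n_{AA}!\, h!\, n_{BB}!}\; 2^h\;
#'   \frac{n_A!\, n_B!}{(2n)!}}
#' over the admissible \code{h} (same parity as \code{nA}, at most
#' \code{min(nA, nB)}).
#'
#' @param n number of individuals.
#' @param nA count of A alleles among the \code{2n} allele calls.
#' @return Data frame with columns \code{h} and \code{prob}; the
#'   probabilities sum to 1.
#' @export
levene_het_pmf <- function(n, nA) {
  stopifnot(n >= 1, nA >= 0, nA <= 2 * n)
  nB <- 2 * n - nA
  h <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((nB - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  data.frame(h = h, prob = exp(logp))
}

#' One-sided exact probability of heterozygote excess
#'
#' The probability, under the Levene conditional distribution, of
#' observing at least as many heterozygotes as seen.
#'
#' @param n_AA,n_AB,n_BB observed genotype counts.
#' @return P in (0, 1].
#' @export
het_excess_probability <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop("at least one genotyped individual required")
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  if (nA == 0 || nB == 0)
    stop("heterozygote-excess test undefined for a monomorphic sample")
  pmf <- levene_het_pmf(n, nA)
  sum(pmf$prob[pmf$h >= n_AB])
}

#' Combine per-accession heterozygote-excess tests and filter markers
#'
#' Computes the one-sided exact heterozygote-excess probability within
#' each accession (accessions where the marker is monomorphic or
#' uncalled are skipped), combines them with Fisher's method
#' (\eqn{X^2 = -2\sum \ln P} on \eqn{2k} df) or by the minimum P, and
#' removes markers whose combined probability is strictly below
#' \code{p_threshold}.  Markers with no defined test in any accession
#' are kept.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param p_threshold removal threshold on the combined probability.
#' @param combine \code{"fisher"} or \code{"min"}.
#' @return List with \code{survivors}, \code{removed} and
#'   \code{p_combined} (NA where no test was defined).
#' @export
het_excess_filter <- function(x, p_threshold = 0.5,
                              combine = c("fisher", "min")) {
  combine <- match.arg(combine)
  stopifnot(inherits(x, "genotype_matrix"))
  acc <- attr(x, "accession_id")
  calls <- unclass(x)
  cAA <- rowsum((calls == "AA") + 0L, acc)
  cAB <- rowsum((calls == "AB") + 0L, acc)
  cBB <- rowsum((calls == "BB") + 0L, acc)
  nA <- 2 * cAA + cAB
  nB <- 2 * cBB + cAB
  defined <- nA > 0 & nB > 0

  ## memoised exact P over the unique genotype-count triples
  key <- paste(cAA, cAB, cBB)
  uk <- !duplicated(key) & defined
  pu <- mapply(het_excess_probability, cAA[uk], cAB[uk], cBB[uk])
  pmap <- stats::setNames(pu, key[uk])
  P <- matrix(NA_real_, nrow(cAA), ncol(cAA))
  P[defined] <- pmap[key[defined]]

  p_comb <- apply(P, 2, function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) return(NA_real_)
    if (combine == "min") return(min(p))
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  })
  names(p_comb) <- colnames(calls)
  fail <- !is.na(p_comb) & p_comb < p_threshold
  list(survivors = colnames(calls)[!fail],
       removed = colnames(calls)[fail],
       p_combined = p_comb)
}

#' Concordance between replicate sample pairs
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param pairs data frame (or 2-column matrix) of sample-id pairs.
#' @return List with the overall \code{concordance} (agreements over
#'   comparisons where both calls are non-missing; \code{NA} when there
#'   is no comparable call) and a per-pair data frame.
#' @export
replicate_concordance <- function(x, pairs) {
  stopifnot(inherits(x, "genotype_matrix"))
  pairs <- as.matrix(pairs)
  unknown <- setdiff(as.vector(pairs), rownames(x))
  if (length(unknown))
    stop("replicate sample id(s) not in matrix: ",
         paste(unknown, collapse = ", "))
  calls <- unclass(x)
  per <- apply(pairs, 1, function(pr) {
    a <- calls[pr[1], ]; b <- calls[pr[2], ]
    ok <- a != "NC" & b != "NC"
    c(agree = sum(a[ok] == b[ok]), compared = sum(ok))
  })
  per <- as.data.frame(t(per))
  per$sample1 <- pairs[, 1]; per$sample2 <- pairs[, 2]
  per$concordance <- ifelse(per$compared > 0, per$agree / per$compared, NA)
  total <- sum(per$compared)
  list(concordance = if (total > 0) sum(per$agree) / total else NA_real_,
       per_pair = per[, c("sample1", "sample2", "agree", "compared",
                          "concordance")])
}

#' Per-group call rate
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param by \code{"accession"} or \code{"sample"}.
#' @return Named numeric vector of non-missing call fractions.
#' @export
call_rate <- function(x, by = c("accession", "sample")) {
  by <- match.arg(by)
  stopifnot(inherits(x, "genotype_matrix"))
  calls <- unclass(x) != "NC"
  if (by == "sample") return(rowMeans(calls))
  g <- attr(x, "accession_id")
  counts <- rowsum(rowSums(calls), g)[, 1]
  n <- as.vector(table(g)[names(counts)])
  counts / (n * ncol(x))
}

#' Run the marker-validation cascade
#'
#' Applies, in order: cluster-quality triage (when statistics are
#' supplied), the missingness filter, the Mendelian trio-error filter
#' against a mapping family (when supplied), the minor-allele-frequency
#' filter and the heterozygote-excess filter.  Every removed marker is
#' attributed to the first stage that drops it and the counts telescope.
#'
#' @param x ecotype \code{\link{genotype_matrix}}.
#' @param cluster_stats optional cluster-statistics data frame.
#' @param family optional mapping-family \code{\link{genotype_matrix}}
#'   sharing marker names with \code{x}.
#' @param trios trio definition for \code{family}.
#' @param config named list of threshold overrides; see
#'   \code{\link{default_config}} element \code{genotype_qc}.
#' @return A \code{qc_report}: per-stage counts, removed and surviving
#'   marker lists, the review list, per-accession call rates and the
#'   filtered genotype matrix.
#' @export
run_qc <- function(x, cluster_stats = NULL, family = NULL, trios = NULL,
                   config = list()) {
  cfg <- utils::modifyList(default_config()$genotype_qc, config)
  stopifnot(inherits(x, "genotype_matrix"))
  current <- colnames(x)
  stages <- list(); removed <- list(); review <- character(0)

  add_stage <- function(name, input, gone)
    data.frame(stage = name, input = input, removed = length(gone),
               surviving = input - length(gone), stringsAsFactors = FALSE)

  if (!is.null(cluster_stats)) {
    lab <- apply_cluster_qc(cluster_stats, markers = current,
                            cfg$fail_rmean, cfg$fail_sep, cfg$review_sep_hi)
    gone <- lab$marker_id[lab$label == "fail"]
    review <- lab$marker_id[lab$label == "review"]
    removed$cluster <- gone
    stages$cluster <- add_stage("cluster", length(current), gone)
    current <- setdiff(current, gone)
  }

  ms <- missingness_filter(keep_markers(x, current), cfg$max_missing)
  removed$missingness <- ms$removed
  stages$missingness <- add_stage("missingness", length(current), ms$removed)
  current <- ms$survivors

  if (!is.null(family) && !is.null(trios)) {
    fam_markers <- intersect(current, colnames(family))
    tf <- trio_error_filter(family, trios, cfg$max_trio_errors, fam_markers)
    removed$trio <- tf$removed
    stages$trio <- add_stage("trio_errors", length(current), tf$removed)
    current <- setdiff(current, tf$removed)
  }

  maf <- minor_allele_frequency(keep_markers(x, current))
  gone <- current[!is.na(maf) & maf < cfg$min_maf]
  removed$maf <- gone
  stages$maf <- add_stage("maf", length(current), gone)
  current <- setdiff(current, gone)

  he <- het_excess_filter(keep_markers(x, current), cfg$het_excess_p,
                          cfg$het_excess_combine)
  removed$het_excess <- he$removed
  stages$het_excess <- add_stage("het_excess", length(current), he$removed)
  current <- setdiff(current, he$removed)

  out <- keep_markers(x, current)
  structure(list(stages = do.call(rbind, c(stages, make.row.names = FALSE)),
                 removed = removed, survivors = current, review = review,
                 call_rates = call_rate(out), filtered = out),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker validation cascade:\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("%d markers survive; %d flagged for manual cluster review\n",
              length(x$survivors), length(x$review)))
  invisible(x)
}
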