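cluster_row <- function(marker_id, r = c(1, 1, 1), sep = 0.9) {
  data.frame(marker_id = marker_id, r_mean_aa = r[1], r_mean_ab = r[2],
             r_mean_bb = r[3], cluster_separation = sep,
             stringsAsFactors = FALSE)
}

test_that("cluster triage applies the fail and review boundaries", {
  cs <- rbind(cluster_row("M1", r = c(0.19, 1, 1)),
              cluster_row("M2", r = c(0.2, 1, 1)),
              cluster_row("M3", sep = 0.29),
              cluster_row("M4", sep = 0.3),
              cluster_row("M5", sep = 0.44),
              cluster_row("M6", sep = 0.45),
              cluster_row("M7", r = c(NA, 0.5, 0.5)))
  lab <- apply_cluster_qc(cs)
  expect_equal(lab$label,
               c("fail", "pass", "fail", "review", "review", "pass", "pass"))
  lab2 <- apply_cluster_qc(cs, markers = c("M1", "M8"))
  expect_equal(lab2$label, c("fail", "unscored"))
  all_na <- cluster_row("M9", r = c(NA, NA, NA))
  expect_error(apply_cluster_qc(all_na), "occupied cluster")
})

test_that("missingness removes strictly above the threshold", {
  # 72/716 missing (10.06 %) is removed; 71/716 (9.92 %) is kept
  calls <- matrix("AA", 716, 2, dimnames = list(NULL, c("Mhi", "Mlo")))
  calls[1:72, 1] <- "NC"
  calls[1:71, 2] <- "NC"
  gm <- genotype_matrix(calls, sample_id = sprintf("S%03d", 1:716),
                        accession_id = rep("A1", 716))
  mf <- missingness_filter(gm, 0.10)
  expect_equal(mf$removed, "Mhi")
  expect_equal(mf$survivors, "Mlo")
  expect_equal(unname(missingness(gm)), c(72, 71) / 716)
})

test_that("minor allele frequency counts alleles, skipping NC", {
  gm <- gm_one_marker(c("AA", "AA", "AB", "NC"))
  expect_equal(minor_allele_frequency(gm, "M00001"), 1 / 6)
  expect_equal(unname(minor_allele_frequency(gm_one_marker(rep("AB", 4)))),
               0.5)
  expect_equal(unname(minor_allele_frequency(gm_one_marker(rep("BB", 4)))),
               0)
  all_nc <- gm_one_marker(rep("NC", 3))
  expect_true(is.na(minor_allele_frequency(all_nc)))
  expect_error(minor_allele_frequency(all_nc, "M00001"), "no non-missing")
})

test_that("trio errors follow biallelic Mendelian rules", {
  fam <- gm_from_rows(list(c("AA", "AB", "AA", "NC", "AA"),
                           c("BB", "AB", "AA", "AA", "AA"),
                           c("AA", "AA", "BB", "BB", "NC"),
                           c("AB", "BB", "AB", "AA", "AA")),
                      accession_id = rep("F", 4))
  rownames(fam) <- c("P1", "P2", "O1", "O2")
  trios <- list(parent1_id = "P1", parent2_id = "P2",
                offspring_ids = c("O1", "O2"))
  errs <- count_trio_errors(fam, trios)
  # M1: AAxBB -> AA impossible (1), AB fine; M2: ABxAB anything possible;
  # M3: AAxAA -> BB and AB impossible (2); M4: NC parent skipped;
  # M5: NC offspring skipped, AA fine
  expect_equal(unname(errs), c(1L, 0L, 2L, 0L, 0L))
  expect_error(count_trio_errors(fam, list(parent1_id = "PX",
                                           parent2_id = "P2",
                                           offspring_ids = "O1")),
               "not present")
})

test_that("the trio filter removes strictly more than max_errors", {
  fam <- gen_qc_cascade_fixture(n_markers = 40, n_trio_fail = 6,
                                n_maf_fail = 0, n_het_fail = 0,
                                n_accessions = 4, n_progeny = 30, seed = 3)
  tf <- trio_error_filter(fam$family, fam$trios)
  expect_equal(length(tf$removed), 6)
  expect_true(all(tf$errors[tf$removed] == 5))
})

test_that("the Levene heterozygote distribution is a proper pmf", {
  for (n in 1:12) for (nA in 0:(2 * n)) {
    pmf <- levene_het_pmf(n, nA)
    expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
    expect_true(all(pmf$h %% 2 == nA %% 2))
  }
})

test_that("worked heterozygote-excess probabilities are exact", {
  # n = 2, nA = 2: h in {0, 2} with P(2) = 2/3; observing 2 hets -> 2/3
  expect_equal(het_excess_probability(0, 2, 0), 2 / 3)
  # observing 0 hets is the least extreme outcome: P = 1
  expect_equal(het_excess_probability(1, 0, 1), 1)
  expect_error(het_excess_probability(3, 0, 0), "monomorphic")
})

test_that("the Levene pmf matches a permutation simulation", {
  set.seed(91)
  n <- 5; nA <- 4
  alleles <- c(rep("A", nA), rep("B", 2 * n - nA))
  hets <- replicate(20000, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  pmf <- levene_het_pmf(n, nA)
  emp <- table(factor(hets, levels = pmf$h)) / length(hets)
  expect_lt(max(abs(as.vector(emp) - pmf$prob)), 0.02)
})

test_that("Fisher combination across accessions matches direct computation", {
  gm <- gm_from_rows(list(c("AB"), c("AB"), c("AA"), c("BB"),
                          c("AB"), c("AA"), c("AB"), c("AB")),
                     accession_id = rep(c("A1", "A2"), each = 4),
                     marker_id = "M1")
  p1 <- het_excess_probability(1, 2, 1)
  p2 <- het_excess_probability(1, 3, 0)
  want <- pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
  hf <- het_excess_filter(gm, p_threshold = 0.5)
  expect_equal(unname(hf$p_combined), want)
  hf_min <- het_excess_filter(gm, combine = "min")
  expect_equal(unname(hf_min$p_combined), min(p1, p2))
  # the published combination example: P = 0.2 and 0.9 give ~0.488 < 0.5
  expect_lt(pchisq(-2 * (log(0.2) + log(0.9)), 4, lower.tail = FALSE), 0.5)
})

test_that("markers with no defined excess test are kept, excess removed", {
  gm <- gm_from_rows(rep(list(c("AA", "AB")), 6),
                     accession_id = rep("A1", 6),
                     marker_id = c("Mmono", "Mhet"))
  calls <- unclass(gm)
  calls[, "Mmono"] <- "AA"
  calls[, "Mhet"] <- "AB"
  gm2 <- genotype_matrix(calls, sample_id = rownames(gm),
                         accession_id = rep("A1", 6))
  hf <- het_excess_filter(gm2, 0.5)
  expect_true("Mmono" %in% hf$survivors)   # no test defined -> kept
  expect_true("Mhet" %in% hf$removed)      # all-het: strong excess
  expect_true(is.na(hf$p_combined[["Mmono"]]))
})

test_that("replicate concordance counts non-missing agreements", {
  calls <- matrix("AA", 4, 1000,
                  dimnames = list(c("S1", "S1r", "S2", "S2r"), NULL))
  calls[, 5] <- c("AA", "AB", "AA", "AA")
  gm <- genotype_matrix(calls,
                        accession_id = rep("A1", 4),
                        marker_id = sprintf("M%04d", 1:1000))
  rc <- replicate_concordance(gm, rbind(c("S1", "S1r"), c("S2", "S2r")))
  expect_equal(rc$per_pair$concordance, c(0.999, 1))
  expect_equal(rc$concordance, 1999 / 2000)
  all_nc <- genotype_matrix(matrix("NC", 2, 3,
                                   dimnames = list(c("a", "b"), NULL)),
                            accession_id = c("A1", "A1"),
                            marker_id = c("M1", "M2", "M3"))
  expect_true(is.na(replicate_concordance(all_nc,
                                          rbind(c("a", "b")))$concordance))
})

test_that("call rate is the fraction of non-missing calls per group", {
  calls <- matrix("AA", 8, 100)
  calls[1, 1] <- "NC"
  gm <- genotype_matrix(calls, sample_id = sprintf("S%d", 1:8),
                        accession_id = rep(c("A1", "A2"), each = 4),
                        marker_id = sprintf("M%03d", 1:100))
  cr <- call_rate(gm)
  expect_equal(unname(cr), c(399 / 400, 1))
  expect_equal(unname(call_rate(gm, by = "sample")[1]), 0.99)
})

test_that("the validation cascade telescopes and is idempotent", {
  fx <- gen_qc_cascade_fixture(n_markers = 200, n_trio_fail = 8,
                               n_maf_fail = 12, n_het_fail = 5,
                               n_accessions = 15, n_progeny = 30, seed = 10)
  qr <- run_qc(fx$genotypes, cluster_stats = fx$cluster_stats,
               family = fx$family, trios = fx$trios)
  st <- qr$stages
  expect_equal(st$surviving, st$input - st$removed)
  expect_equal(st$input[-1], st$surviving[-nrow(st)])
  expect_equal(sort(unlist(qr$removed, use.names = FALSE)),
               sort(setdiff(colnames(fx$genotypes), qr$survivors)))
  # running the cascade again on the filtered matrix removes nothing
  qr2 <- run_qc(qr$filtered, family = keep_markers(fx$family, qr$survivors),
                trios = fx$trios)
  expect_equal(sum(qr2$stages$removed), 0)
  expect_equal(sort(qr2$survivors), sort(qr$survivors))
})

test_that("a clean panel passes the cascade untouched", {
  fx <- gen_qc_cascade_fixture(n_markers = 50, n_trio_fail = 0,
                               n_maf_fail = 0, n_het_fail = 0,
                               n_accessions = 6, n_progeny = 20, seed = 4)
  qr <- run_qc(fx$genotypes, cluster_stats = fx$cluster_stats,
               family = fx$family, trios = fx$trios)
  expect_equal(sum(qr$stages$removed), 0)
  expect_equal(length(qr$survivors), 50)
})
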