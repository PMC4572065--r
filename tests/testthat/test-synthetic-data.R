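test_that("the generator is a deterministic function of the seed", {
  p <- sim_params(n_regions = 2, accessions_per_region = 3,
                  individuals_per_accession = 4, n_markers = 50, seed = 42)
  g1 <- gen_hierarchical_genotypes(p)
  g2 <- gen_hierarchical_genotypes(p)
  expect_identical(unclass(g1$genotypes), unclass(g2$genotypes))
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$accession_info, g2$accession_info)
  g3 <- gen_hierarchical_genotypes(sim_params(
    n_regions = 2, accessions_per_region = 3,
    individuals_per_accession = 4, n_markers = 50, seed = 43))
  expect_false(identical(unclass(g1$genotypes), unclass(g3$genotypes)))
})

test_that("the study design yields 716 individuals in 90 accessions", {
  p <- study_design_params(n_markers = 60, missing_rate = 0, seed = 1)
  g <- gen_hierarchical_genotypes(p)
  expect_equal(nrow(g$genotypes), 716)
  expect_equal(ncol(g$genotypes), 60)
  expect_equal(length(unique(accession_of(g$genotypes))), 90)
  expect_equal(sort(unique(table(accession_of(g$genotypes)))), c(4, 8))
  expect_equal(length(unique(g$accession_info$Region)), 4)
  expect_false(any(unclass(g$genotypes) == "NC"))
})

test_that("missing calls appear at the configured rate", {
  p <- sim_params(n_regions = 1, accessions_per_region = 10,
                  individuals_per_accession = 8, n_markers = 200,
                  missing_rate = 0.1, seed = 5)
  g <- gen_hierarchical_genotypes(p)
  obs <- mean(unclass(g$genotypes) == "NC")
  expect_lt(abs(obs - 0.1), 0.02)
})

test_that("zero differentiation passes the ancestral frequency through", {
  p <- sim_params(n_regions = 1, accessions_per_region = 20,
                  individuals_per_accession = 8, n_markers = 300,
                  f_rt = 0, f_pr = 0, cline_fraction = 0,
                  missing_rate = 0, seed = 3)
  g <- gen_hierarchical_genotypes(p)
  expect_equal(max(abs(sweep(g$truth$accession_freq, 2, g$truth$p0))), 0)
  phi <- amova_nested(encode_genotypes(g$genotypes))$phi[["phi_pt"]]
  expect_lt(phi, 0.05)
})

test_that("realized Phi recovers the target differentiation (two-level)", {
  phis <- vapply(1:10, function(s) {
    p <- sim_params(n_regions = 1, accessions_per_region = 90,
                    individuals_per_accession = 8, n_markers = 500,
                    f_rt = 0, f_pr = 0.3, cline_fraction = 0,
                    missing_rate = 0, seed = s)
    g <- gen_hierarchical_genotypes(p)
    amova_nested(encode_genotypes(g$genotypes))$phi[["phi_pt"]]
  }, numeric(1))
  expect_lt(abs(mean(phis) - 0.3), 0.05)
})

test_that("genotype marginal frequencies converge to the truth record", {
  p <- sim_params(n_regions = 1, accessions_per_region = 30,
                  individuals_per_accession = 8, n_markers = 400,
                  f_rt = 0, f_pr = 0.1, cline_fraction = 0,
                  missing_rate = 0, seed = 9)
  g <- gen_hierarchical_genotypes(p)
  enc <- encode_genotypes(g$genotypes)
  phat <- colMeans(enc[, seq(1, ncol(enc), by = 2)])
  pbar <- colMeans(g$truth$accession_freq)
  tol <- 3 * sqrt(pbar * (1 - pbar) / (2 * nrow(enc)))
  expect_gte(mean(abs(phat - pbar) <= tol), 0.98)
})

test_that("clinal flags cover the configured fraction of markers", {
  p <- sim_params(n_regions = 2, accessions_per_region = 5,
                  individuals_per_accession = 4, n_markers = 200,
                  cline_fraction = 0.25, seed = 8)
  g <- gen_hierarchical_genotypes(p)
  expect_equal(nrow(g$truth$clinal), 50)
  expect_true(all(g$truth$clinal$axis %in% c("longitude", "latitude")))
})

test_that("an error-free mapping family is Mendelian-clean", {
  fam <- gen_mapping_family(parent_maf_spec = c(0.3, 0.7), n_progeny = 60,
                            error_rate = 0, n_markers = 200, seed = 2)
  errs <- count_trio_errors(fam$genotypes, fam$trios)
  expect_true(all(errs == 0))
  expect_equal(nrow(fam$truth), 0)
  # AA x BB parents can only produce AB offspring
  calls <- unclass(fam$genotypes)
  opp <- which((calls["P1", ] == "AA" & calls["P2", ] == "BB") |
               (calls["P1", ] == "BB" & calls["P2", ] == "AA"))
  expect_gt(length(opp), 0)
  expect_true(all(calls[fam$trios$offspring_ids, opp] == "AB"))
})

test_that("trio screening recovers exactly the detectable injected errors", {
  fam <- gen_mapping_family(parent_maf_spec = c(0.2, 0.8), n_progeny = 100,
                            error_rate = 0.05, n_markers = 300, seed = 4)
  expect_gt(nrow(fam$truth), 0)
  expect_true(any(fam$truth$detectable))
  expect_true(any(!fam$truth$detectable))
  errs <- count_trio_errors(fam$genotypes, fam$trios)
  want <- table(factor(fam$truth$marker_id[fam$truth$detectable],
                       levels = names(errs)))
  expect_equal(unname(errs), as.vector(want))
})

test_that("the variant report plants each violation exactly once per SNP", {
  vr <- gen_variant_report(n_contigs = 40, seed = 11)
  tr <- vr$truth$markers
  expect_true(all(is.na(tr$removed_by) |
                  tr$removed_by %in% c("coverage", "snp_quality",
                                       "neighbourhood_quality",
                                       "variant_freq", "nonspecific",
                                       "shared_polymorphism", "annotation",
                                       "spacing", "flank", "designability")))
  expect_equal(length(setdiff(vr$truth$survivors, tr$marker_name)), 0)
  expect_identical(gen_variant_report(n_contigs = 40, seed = 11)$variants,
                   vr$variants)
  empty <- gen_variant_report(n_contigs = 5, snp_density = 0, seed = 1)
  expect_equal(nrow(empty$variants), 0)
})

test_that("cluster-statistics truth labels agree with the triage filter", {
  ids <- sprintf("M%05d", 1:500)
  cs <- gen_cluster_stats(ids, fail_fractions = c(r_mean = 0.1,
                                                  separation = 0.1,
                                                  review = 0.1), seed = 6)
  lab <- apply_cluster_qc(cs$stats)
  want <- ifelse(cs$truth$label %in% c("r_mean", "separation"), "fail",
                 cs$truth$label)
  expect_equal(lab$label, want)
})

test_that("the validation-cascade fixture removes the planted counts", {
  fx <- gen_qc_cascade_fixture(n_markers = 300, n_trio_fail = 10,
                               n_maf_fail = 20, n_het_fail = 5,
                               n_accessions = 20, n_progeny = 40, seed = 2)
  qr <- run_qc(fx$genotypes, cluster_stats = fx$cluster_stats,
               family = fx$family, trios = fx$trios)
  expect_equal(length(qr$survivors), fx$truth$final)
  expect_true(all(fx$truth$classes[qr$survivors] == "pass"))
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(sim_params(f_pr = 1), "f_rt and f_pr")
  expect_error(sim_params(missing_rate = -0.1), "missing_rate")
  expect_error(sim_params(cline_fraction = 2), "cline_fraction")
  expect_error(gen_mapping_family(error_rate = 1), "error_rate")
})
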