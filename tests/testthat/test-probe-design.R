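# A minimal variant row with every required column and passing values.
variant_row <- function(contig_id = "Contig1", position = 100L,
                        coverage = 80, variant_frequency = 50,
                        snp_quality = 40, neighbourhood_quality = 30,
                        source_genotype = "G1", nonspecific_flag = FALSE,
                        ref_allele = "A", var_allele = "C") {
  data.frame(contig_id = contig_id, position = position,
             ref_allele = ref_allele, var_allele = var_allele,
             coverage = coverage, variant_frequency = variant_frequency,
             snp_quality = snp_quality,
             neighbourhood_quality = neighbourhood_quality,
             source_genotype = source_genotype,
             nonspecific_flag = nonspecific_flag,
             stringsAsFactors = FALSE)
}

test_that("variant thresholds are inclusive on the passing side", {
  v <- rbind(variant_row(position = 1L, coverage = 50),
             variant_row(position = 2L, coverage = 49),
             variant_row(position = 3L, snp_quality = 30),
             variant_row(position = 4L, snp_quality = 29.9),
             variant_row(position = 5L, neighbourhood_quality = 20),
             variant_row(position = 6L, neighbourhood_quality = 19.9),
             variant_row(position = 7L, variant_frequency = 25),
             variant_row(position = 8L, variant_frequency = 24.9),
             variant_row(position = 9L, nonspecific_flag = TRUE))
  fv <- filter_variant_calls(v)
  expect_equal(fv$survivors$position, c(1L, 3L, 5L, 7L))
  expect_equal(fv$removed$reason,
               c("coverage", "snp_quality", "neighbourhood_quality",
                 "variant_freq", "nonspecific"))
  expect_equal(unname(fv$counts), c(1L, 1L, 1L, 1L, 1L))
})

test_that("a removed variant records its first failing criterion", {
  v <- variant_row(coverage = 10, snp_quality = 5, nonspecific_flag = TRUE)
  expect_equal(filter_variant_calls(v)$removed$reason, "coverage")
  expect_error(filter_variant_calls(v[, -5]), "missing required column")
})

test_that("shared polymorphism needs two distinct source genotypes", {
  v <- rbind(variant_row(position = 10L, source_genotype = "G1"),
             variant_row(position = 10L, source_genotype = "G1"),
             variant_row(position = 20L, source_genotype = "G1"),
             variant_row(position = 20L, source_genotype = "G2"))
  sp <- shared_polymorphism_filter(v)
  expect_equal(sp$markers$position, 20L)
  expect_equal(sp$markers$n_sources, 2L)
  expect_equal(sp$removed$position, 10L)
  # the same position with a different allele pair is a different marker
  v2 <- rbind(variant_row(position = 10L, source_genotype = "G1",
                          var_allele = "C"),
              variant_row(position = 10L, source_genotype = "G2",
                          var_allele = "G"))
  expect_equal(nrow(shared_polymorphism_filter(v2)$markers), 0)
})

test_that("shared-polymorphism counting matches a dictionary oracle", {
  set.seed(31)
  n <- 200
  v <- variant_row()[rep(1, n), ]
  v$contig_id <- sprintf("Contig%d", sample(1:8, n, replace = TRUE))
  v$position <- sample(c(100L, 200L, 300L), n, replace = TRUE)
  v$source_genotype <- sprintf("G%d", sample(1:5, n, replace = TRUE))
  sp <- shared_polymorphism_filter(v)
  key <- paste(v$contig_id, v$position)
  oracle <- vapply(split(v$source_genotype, key),
                   function(s) length(unique(s)), 1L)
  keep <- names(oracle)[oracle >= 2]
  expect_setequal(paste(sp$markers$contig_id, sp$markers$position), keep)
  expect_equal(sort(sp$markers$n_sources),
               sort(unname(oracle[oracle >= 2])))
})

test_that("annotation screening flags frameshifts and blacklisted hits", {
  blast <- data.frame(
    contig_id = c("C1", "C1", "C2", "C3", "C3"),
    subject_id = c("S1", "S1", "S2", "S3", "S4"),
    description = c("kinase", "kinase", "chloroplast ribosomal protein",
                    "unknown protein", "another protein"),
    stringsAsFactors = FALSE)
  an <- annotation_filter(blast, c("C1", "C2", "C3", "C4"))
  expect_setequal(an$allowed, c("C3", "C4"))   # no annotation at all passes
  expect_equal(an$removed$reason[an$removed$contig_id == "C1"], "frameshift")
  expect_equal(an$removed$reason[an$removed$contig_id == "C2"], "blacklist")
})

test_that("spacing removes both members of a close pair (strict <)", {
  m <- data.frame(contig_id = "C1", position = c(100L, 130L, 300L),
                  stringsAsFactors = FALSE)
  sf <- spacing_filter(m, min_gap = 50)
  expect_equal(sf$markers$position, 300L)
  expect_equal(sort(sf$removed$position), c(100L, 130L))
  # exactly min_gap apart passes
  m2 <- data.frame(contig_id = "C1", position = c(100L, 150L))
  expect_equal(spacing_filter(m2, 50)$markers$position, c(100L, 150L))
  # keep = "best" greedily retains the left-most of each conflict
  expect_equal(spacing_filter(m, 50, keep = "best")$markers$position,
               c(100L, 300L))
})

test_that("spacing agrees with a quadratic all-pairs oracle", {
  set.seed(17)
  m <- data.frame(contig_id = sprintf("C%d", sample(1:4, 80, replace = TRUE)),
                  position = sample(1:600, 80), stringsAsFactors = FALSE)
  sf <- spacing_filter(m, min_gap = 50)
  bad <- vapply(seq_len(nrow(m)), function(i)
    any(m$contig_id == m$contig_id[i] &
        abs(m$position - m$position[i]) < 50 &
        seq_len(nrow(m)) != i), logical(1))
  expect_setequal(paste(sf$markers$contig_id, sf$markers$position),
                  paste(m$contig_id, m$position)[!bad])
})

test_that("flank extraction uses min(preferred, available) per side", {
  set.seed(5)
  contig <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
  mk <- function(pos) data.frame(contig_id = "C1", position = pos,
                                 allele1 = substr(contig, pos, pos),
                                 allele2 = "N", stringsAsFactors = FALSE)
  mk2 <- function(pos) {
    m <- mk(pos); m$allele2 <- setdiff(c("A", "C", "G", "T"),
                                       m$allele1)[1]; m
  }
  cand <- build_probe_candidates(c(C1 = contig),
                                 rbind(mk2(30), mk2(61), mk2(100)))
  expect_equal(cand$status, c("removed", "survived", "survived"))
  expect_equal(nchar(cand$left_flank), c(29, 60, 60))
  expect_equal(nchar(cand$right_flank), c(60, 60, 60))
  # position 55 of a 120 bp contig: 54 left, 60 right, still designable
  short <- substr(contig, 1, 120)
  m55 <- mk2(55);
  c55 <- build_probe_candidates(c(C1 = short), m55)
  expect_equal(c55$status, "survived")
  expect_equal(nchar(c55$left_flank), 54)
  expect_equal(nchar(c55$right_flank), 60)
  # the rendered probe round-trips and matches the contig slices
  pp <- parse_probe_seq(c55$probe_seq)
  expect_equal(pp$left_flank, substr(short, 1, 54))
  expect_equal(pp$right_flank, substr(short, 56, 115))
  expect_setequal(c(pp$allele1, pp$allele2),
                  c(m55$allele1, m55$allele2))
})

test_that("flank extraction validates its inputs", {
  m <- data.frame(contig_id = "CX", position = 10L, allele1 = "A",
                  allele2 = "C", stringsAsFactors = FALSE)
  expect_error(build_probe_candidates(c(C1 = "ACGT"), m), "unknown contig")
  m2 <- data.frame(contig_id = "C1", position = 2L, allele1 = "G",
                   allele2 = "T", stringsAsFactors = FALSE)
  expect_error(build_probe_candidates(c(C1 = "ACGT"), m2),
               "does not match either allele")
})

test_that("designability keeps scores at or above the threshold", {
  cand <- data.frame(marker_name = c("C1_10", "C1_90"),
                     stringsAsFactors = FALSE)
  sc <- c(C1_10 = 0.6, C1_90 = 0.59)
  df <- designability_filter(cand, sc)
  expect_equal(df$panel$marker_name, "C1_10")
  expect_equal(df$removed$marker_name, "C1_90")
  expect_error(designability_filter(cand, c(C1_10 = 0.9)),
               "missing designability")
})

test_that("the full cascade reproduces the generator's planted truth", {
  vr <- gen_variant_report(n_contigs = 50, seed = 23)
  dp <- design_panel(vr$variants, vr$contigs, vr$blast, vr$designability)
  expect_setequal(dp$panel$marker_name, vr$truth$survivors)
  truth_removed <- vr$truth$markers[!is.na(vr$truth$markers$removed_by), ]
  got <- setNames(dp$removed$reason, dp$removed$marker_name)
  want <- setNames(truth_removed$removed_by, truth_removed$marker_name)
  expect_equal(got[sort(names(got))], want[sort(names(want))])
  # the per-stage counts telescope
  rp <- dp$report
  expect_equal(rp$surviving, rp$input - rp$removed)
  expect_equal(rp$input[-1], rp$surviving[-nrow(rp)])
  expect_equal(rp$surviving[nrow(rp)], nrow(dp$panel))
})

test_that("tightening a variant threshold never adds variant survivors", {
  # (the cascade as a whole is not monotone: dropping a marker early can
  # rescue its close spacing-neighbour, so monotonicity is a property of
  # the per-row variant filter, which is what is asserted here)
  vr <- gen_variant_report(n_contigs = 40, seed = 29)
  base <- filter_variant_calls(vr$variants)
  tight <- filter_variant_calls(vr$variants, min_coverage = 90)
  expect_lte(nrow(tight$survivors), nrow(base$survivors))
  key <- function(v) paste(v$contig_id, v$position, v$source_genotype)
  expect_true(all(key(tight$survivors) %in% key(base$survivors)))
})

test_that("an empty variant table yields an empty panel, not an error", {
  vr <- gen_variant_report(n_contigs = 4, snp_density = 0, seed = 1)
  dp <- design_panel(vr$variants, vr$contigs, vr$blast, vr$designability)
  expect_equal(nrow(dp$panel), 0)
  expect_true(all(dp$report$removed == 0))
})

test_that("marker names parse back to contig and position", {
  pm <- parse_marker_name(c("Contig12_345", "C_1_99"))
  expect_equal(pm$contig_id, c("Contig12", "C_1"))
  expect_equal(pm$position, c(345L, 99L))
  expect_error(parse_marker_name("nounderscore"), "unparseable")
})
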