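#' Simulation parameters for hierarchically structured genotypes
#'
#' Describes a sampling design of regions, accessions within regions and
#' individuals within accessions, together with the two differentiation
#' parameters of a Balding-Nichols beta hierarchy and an optional
#' geographic allele-frequency cline.
#'
#' @param n_regions number of regions.
#' @param accessions_per_region number of accessions in each region; a
#'   single count or a vector of length \code{n_regions}.
#' @param individuals_per_accession default number of individuals sampled
#'   per accession.
#' @param deviating_sizes optional named integer vector overriding the
#'   size of individual accessions (names are 1-based accession indices).
#' @param n_markers number of biallelic markers.
#' @param f_rt differentiation among regions, in [0, 1).
#' @param f_pr differentiation among accessions within regions, in [0, 1).
#' @param cline_fraction fraction of markers carrying a geographic cline.
#' @param cline_strength logit-scale slope per standardised coordinate
#'   unit for clinal markers.
#' @param missing_rate probability that any one call is set to \code{NC}.
#' @param seed integer seed driving all randomness of the generator.
#' @return A validated list of class \code{sim_params}.
#' @export
sim_params <- function(n_regions = 4,
                       accessions_per_region = c(12, 45, 16, 17),
                       individuals_per_accession = 8,
                       deviating_sizes = NULL,
                       n_markers = 2185,
                       f_rt = 0.08,
                       f_pr = 0.25,
                       cline_fraction = 0.5,
                       cline_strength = 1.0,
                       missing_rate = 0.02,
                       seed = 1L) {
  if (length(accessions_per_region) == 1L)
    accessions_per_region <- rep(accessions_per_region, n_regions)
  stopifnot(length(accessions_per_region) == n_regions,
            all(accessions_per_region >= 1), n_markers >= 1,
            individuals_per_accession >= 1)
  for (f in c(f_rt = f_rt, f_pr = f_pr))
    if (f < 0 || f >= 1) stop("f_rt and f_pr must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (cline_fraction < 0 || cline_fraction > 1)
    stop("cline_fraction must lie in [0, 1]")
  n_acc <- sum(accessions_per_region)
  sizes <- rep(individuals_per_accession, n_acc)
  if (!is.null(deviating_sizes)) {
    idx <- as.integer(names(deviating_sizes))
    if (anyNA(idx) || any(idx < 1 | idx > n_acc))
      stop("deviating_sizes names must be valid accession indices")
    sizes[idx] <- as.integer(deviating_sizes)
  }
  structure(list(n_regions = n_regions,
                 accessions_per_region = accessions_per_region,
                 accession_sizes = sizes,
                 n_markers = as.integer(n_markers),
                 f_rt = f_rt, f_pr = f_pr,
                 cline_fraction = cline_fraction,
                 cline_strength = cline_strength,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Parameters matching the reference ecotype study design
#'
#' Convenience constructor: 90 accessions in 4 regions (12/45/16/17),
#' 8 individuals per accession except one accession of 4 (716 individuals
#' in total), 2185 markers, and differentiation levels in the regime of
#' the published AMOVA (Phi_RT near 0.08, Phi_PR near 0.25).
#'
#' @param ... overrides passed on to \code{\link{sim_params}}.
#' @return A \code{sim_params} object.
#' @export
study_design_params <- function(...) {
  args <- list(...)
  defaults <- list(n_regions = 4,
                   accessions_per_region = c(12, 45, 16, 17),
                   individuals_per_accession = 8,
                   deviating_sizes = c("90" = 4L),
                   n_markers = 2185, f_rt = 0.08, f_pr = 0.25)
  do.call(sim_params, utils::modifyList(defaults, args))
}

.clamp01 <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

## Beta draw around a mean with a Balding-Nichols concentration; f = 0 is
## an exact pass-through (no draw), per-element means are recycled by row.
.bn_beta <- function(mean_mat, f) {
  if (f == 0) return(mean_mat)
  m <- .clamp01(mean_mat)
  shape1 <- m * (1 - f) / f
  shape2 <- (1 - m) * (1 - f) / f
  matrix(stats::rbeta(length(m), shape1, shape2), nrow = nrow(m),
         dimnames = dimnames(m))
}

#' Simulate a hierarchically structured genotype matrix
#'
#' Draws allele frequencies through a two-level Balding-Nichols beta
#' hierarchy (ancestral frequency, region frequency, accession
#' frequency), optionally tilts a fraction of markers along a
#' longitudinal or latitudinal cline on the logit scale, and samples
#' genotypes per individual as Binomial(2, p) under Hardy-Weinberg.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param coords optional data frame with columns \code{longitude} and
#'   \code{latitude}, one row per accession; drawn uniformly within
#'   \code{lon_bounds} and \code{lat_bounds} when absent.
#' @param lon_bounds,lat_bounds sampling bounds for accession
#'   coordinates, in decimal degrees.
#' @return A list with components \code{genotypes}
#'   (\code{\link{genotype_matrix}}), \code{accession_info} (data frame
#'   with ID, Accession, Country, Longitude, Latitude, Altitude, Region),
#'   and \code{truth} (ancestral and per-accession allele frequencies,
#'   clinal-marker flags, coordinates).
#' @export
gen_hierarchical_genotypes <- function(params, coords = NULL,
                                       lon_bounds = c(-10, 42),
                                       lat_bounds = c(36, 62)) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n_acc <- sum(params$accessions_per_region)
  sizes <- params$accession_sizes
  M <- params$n_markers
  region_of_acc <- rep(paste0("R", seq_len(params$n_regions)),
                       params$accessions_per_region)
  acc_ids <- sprintf("A%03d", seq_len(n_acc))
  marker_ids <- sprintf("M%05d", seq_len(M))

  if (is.null(coords)) {
    coords <- data.frame(longitude = stats::runif(n_acc, lon_bounds[1], lon_bounds[2]),
                         latitude  = stats::runif(n_acc, lat_bounds[1], lat_bounds[2]))
  }
  stopifnot(nrow(coords) == n_acc)
  altitude <- round(stats::runif(n_acc, 0, 2000))

  ## f_pr and f_rt are target Phi levels on the codominant (genotypic)
  ## scale; the beta concentrations are calibrated so that the realized
  ## Phi_PR and Phi_RT of a distance AMOVA match them in expectation
  ## (genotype-level distances halve the within-accession variance
  ## relative to allele counts, which would otherwise inflate Phi).
  F_pr <- params$f_pr / (2 - params$f_pr)
  cc <- (1 + F_pr) / 2
  F_rt <- params$f_rt * cc / (1 - params$f_rt + params$f_rt * cc)

  p0 <- stats::runif(M, 0.1, 0.9)
  p_region <- .bn_beta(matrix(p0, nrow = params$n_regions, ncol = M,
                              byrow = TRUE), F_rt)
  p_acc <- .bn_beta(p_region[match(region_of_acc,
                                   paste0("R", seq_len(params$n_regions))), ,
                             drop = FALSE], F_pr)
  rownames(p_acc) <- acc_ids

  n_clinal <- round(params$cline_fraction * M)
  clinal <- data.frame(marker = character(0), axis = character(0))
  if (n_clinal > 0) {
    cl_idx <- sort(sample.int(M, n_clinal))
    ## two in three clinal markers follow longitude: the east-west cline
    ## dominates, so the leading component tracks longitude
    axis <- rep(c("longitude", "longitude", "latitude"),
                length.out = n_clinal)
    z_lon <- as.numeric(scale(coords$longitude))
    z_lat <- as.numeric(scale(coords$latitude))
    for (k in seq_along(cl_idx)) {
      z <- if (axis[k] == "longitude") z_lon else z_lat
      j <- cl_idx[k]
      p_acc[, j] <- stats::plogis(stats::qlogis(.clamp01(p_acc[, j])) +
                                  params$cline_strength * z)
    }
    clinal <- data.frame(marker = marker_ids[cl_idx], axis = axis,
                         stringsAsFactors = FALSE)
  }

  acc_of_ind <- rep(seq_len(n_acc), sizes)
  N <- length(acc_of_ind)
  prob <- p_acc[acc_of_ind, , drop = FALSE]
  counts <- matrix(stats::rbinom(N * M, 2L, as.vector(prob)), nrow = N)
  calls <- matrix(c("BB", "AB", "AA")[counts + 1L], nrow = N)
  if (params$missing_rate > 0)
    calls[stats::runif(N * M) < params$missing_rate] <- "NC"

  sample_ids <- paste0(acc_ids[acc_of_ind], "_",
                       unlist(lapply(sizes, seq_len)))
  gm <- genotype_matrix(calls, sample_id = sample_ids,
                        accession_id = acc_ids[acc_of_ind],
                        marker_id = marker_ids)
  info <- data.frame(ID = acc_ids,
                     Accession = paste0("Ba", 10000 + seq_len(n_acc)),
                     Country = region_of_acc,
                     Longitude = coords$longitude,
                     Latitude = coords$latitude,
                     Altitude = altitude,
                     Region = region_of_acc,
                     stringsAsFactors = FALSE)
  truth <- list(p0 = stats::setNames(p0, marker_ids),
                accession_freq = p_acc,
                clinal = clinal,
                coords = coords)
  list(genotypes = gm, accession_info = info, truth = truth)
}

.call_to_count <- c(BB = 0L, AB = 1L, AA = 2L)
.count_to_call <- c("BB", "AB", "AA")

#' Simulate a biparental mapping family
#'
#' Two parents are drawn under Hardy-Weinberg at a per-marker allele
#' frequency, each progeny call is formed from one allele transmitted by
#' each parent, and genotyping errors are injected by replacing a call
#' with a uniformly chosen different call.  Every injected error is
#' logged together with a flag saying whether it is detectable as a
#' Mendelian trio error given the parents.
#'
#' @param parent_maf_spec range (length-2 numeric) from which each
#'   marker's parental allele frequency is drawn uniformly.
#' @param n_progeny number of progeny.
#' @param error_rate per-call probability of an injected genotyping
#'   error, in [0, 1).
#' @param n_markers number of markers.
#' @param seed integer seed.
#' @return A list with \code{genotypes} (parents \code{P1}, \code{P2}
#'   then progeny), \code{trios} (a trio definition usable by
#'   \code{\link{count_trio_errors}}), and \code{truth} (data frame of
#'   injected errors with their detectability flag).
#' @export
gen_mapping_family <- function(parent_maf_spec = c(0.1, 0.5),
                               n_progeny = 193, error_rate = 0,
                               n_markers = 500, seed = 1L) {
  stopifnot(n_progeny >= 1, n_markers >= 1)
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must lie in [0, 1)")
  set.seed(seed)
  M <- as.integer(n_markers)
  marker_ids <- sprintf("M%05d", seq_len(M))
  p <- stats::runif(M, parent_maf_spec[1], parent_maf_spec[2])
  g1 <- stats::rbinom(M, 2L, p)
  g2 <- stats::rbinom(M, 2L, p)

  transmit <- function(g, n) {
    ## allele contributed by a parent with A-count g, for n progeny
    out <- matrix(0L, nrow = n, ncol = M)
    out[, g == 2L] <- 1L
    het <- which(g == 1L)
    if (length(het))
      out[, het] <- matrix(stats::rbinom(n * length(het), 1L, 0.5), nrow = n)
    out
  }
  prog <- transmit(g1, n_progeny) + transmit(g2, n_progeny)
  calls <- matrix(.count_to_call[prog + 1L], nrow = n_progeny)

  truth <- data.frame(sample_id = character(0), marker_id = character(0),
                      original_call = character(0), injected_call = character(0),
                      detectable = logical(0), stringsAsFactors = FALSE)
  if (error_rate > 0) {
    err <- which(matrix(stats::runif(n_progeny * M) < error_rate,
                        nrow = n_progeny), arr.ind = TRUE)
    if (nrow(err)) {
      orig <- calls[err]
      alt <- vapply(orig, function(cl)
        sample(setdiff(c("AA", "AB", "BB"), cl), 1L), character(1))
      calls[err] <- alt
      det <- !mapply(function(j, cl) {
        .call_to_count[[cl]] %in% .mendel_possible(g1[j], g2[j])
      }, err[, 2], alt)
      prog_ids <- sprintf("O%03d", err[, 1])
      truth <- data.frame(sample_id = prog_ids,
                          marker_id = marker_ids[err[, 2]],
                          original_call = unname(orig),
                          injected_call = unname(alt),
                          detectable = unname(det),
                          stringsAsFactors = FALSE)
    }
  }
  all_calls <- rbind(.count_to_call[g1 + 1L], .count_to_call[g2 + 1L], calls)
  ids <- c("P1", "P2", sprintf("O%03d", seq_len(n_progeny)))
  gm <- genotype_matrix(all_calls, sample_id = ids,
                        accession_id = rep("FAM", nrow(all_calls)),
                        marker_id = marker_ids)
  trios <- list(parent1_id = "P1", parent2_id = "P2",
                offspring_ids = sprintf("O%03d", seq_len(n_progeny)))
  list(genotypes = gm, trios = trios, truth = truth)
}

.blacklist_default <- c("chloroplast", "mitochondri", "plastid",
                        "retrotransposon", "transposon", "gag-pol",
                        "reverse transcriptase", "polyprotein")

#' Simulate a transcriptome variant report with planted filter violations
#'
#' Generates random contig sequences, plants SNPs at positions that pass
#' the spacing and flanking requirements, then assigns a fraction of
#' SNPs (or whole contigs) a single planted violation so that each
#' probe-design filter is exercised.  The truth record states, for every
#' planted SNP, which filter (if any) removes it under the documented
#' cascade order, and the exact expected survivor set.
#'
#' @param n_contigs number of contigs.
#' @param contig_length range (length-2) of contig lengths in bp.
#' @param snp_density expected SNPs per bp of contig.
#' @param coverage_spec,quality_spec ranges for passing read coverage and
#'   SNP quality scores.
#' @param blacklist_fraction fraction of contigs annotated with an
#'   organellar/retroelement keyword.
#' @param frameshift_fraction fraction of contigs given two HSPs to the
#'   same BLAST subject.
#' @param violation_fractions named numeric vector of per-SNP violation
#'   probabilities for \code{coverage}, \code{snp_quality},
#'   \code{neighbourhood_quality}, \code{variant_freq},
#'   \code{nonspecific}, \code{shared_polymorphism}, \code{spacing},
#'   \code{flank}, \code{designability}; the remainder passes.
#' @param n_sources number of sequenced source genotypes.
#' @param seed integer seed.
#' @return A list with \code{contigs} (named character vector of
#'   sequences), \code{variants} (one row per SNP per source genotype),
#'   \code{blast} (tabular annotation with a description column),
#'   \code{designability} (per-marker score table) and \code{truth}.
#' @export
gen_variant_report <- function(n_contigs = 60,
                               contig_length = c(300, 900),
                               snp_density = 0.01,
                               coverage_spec = c(50, 150),
                               quality_spec = c(30, 45),
                               blacklist_fraction = 0.05,
                               frameshift_fraction = 0.05,
                               violation_fractions = c(
                                 coverage = 0.04, snp_quality = 0.04,
                                 neighbourhood_quality = 0.04,
                                 variant_freq = 0.04, nonspecific = 0.04,
                                 shared_polymorphism = 0.04, spacing = 0.04,
                                 flank = 0.04, designability = 0.04),
                               n_sources = 5, seed = 1L) {
  stopifnot(blacklist_fraction >= 0, frameshift_fraction >= 0,
            blacklist_fraction + frameshift_fraction <= 1,
            snp_density >= 0, all(violation_fractions >= 0),
            sum(violation_fractions) <= 1)
  set.seed(seed)
  sources <- paste0("G", seq_len(n_sources))
  bases <- c("A", "C", "G", "T")
  cats <- c(names(violation_fractions), "pass")
  probs <- c(violation_fractions, pass = 1 - sum(violation_fractions))

  contig_rows <- list(); var_rows <- list(); blast_rows <- list()
  truth_rows <- list(); desig_rows <- list()
  for (i in seq_len(n_contigs)) {
    L <- sample(seq(contig_length[1], contig_length[2]), 1L)
    cid <- paste0("Contig", i)
    seq_i <- paste(sample(bases, L, replace = TRUE), collapse = "")
    contig_rows[[cid]] <- seq_i

    u <- stats::runif(1)
    ctype <- if (u < blacklist_fraction) "blacklist"
             else if (u < blacklist_fraction + frameshift_fraction) "frameshift"
             else "clean"
    if (ctype == "blacklist") {
      blast_rows[[length(blast_rows) + 1L]] <- data.frame(
        contig_id = cid, subject_id = paste0("sp|BAD", i),
        description = sample(c("putative chloroplast protein",
                               "retrotransposon gag-pol polyprotein",
                               "mitochondrial carrier protein"), 1L),
        stringsAsFactors = FALSE)
    } else if (ctype == "frameshift") {
      blast_rows[[length(blast_rows) + 1L]] <- data.frame(
        contig_id = cid, subject_id = rep(paste0("sp|FS", i), 2L),
        description = "hypothetical protein", stringsAsFactors = FALSE)
    } else if (stats::runif(1) < 0.7) {
      blast_rows[[length(blast_rows) + 1L]] <- data.frame(
        contig_id = cid, subject_id = paste0("sp|OK", i),
        description = "hypothetical protein", stringsAsFactors = FALSE)
    }

    slots <- seq(111, L - 60, by = 111)
    if (!length(slots) || snp_density == 0) next
    n_snp <- min(stats::rpois(1, snp_density * L), length(slots))
    if (n_snp == 0) next
    used <- sort(sample(slots, n_snp))
    flank_done <- FALSE
    for (pos in used) {
      cat_k <- if (ctype == "clean") sample(cats, 1L, prob = probs) else "pass"
      positions <- pos
      if (cat_k == "flank") {
        if (flank_done) cat_k <- "pass" else { positions <- 5L; flank_done <- TRUE }
      }
      if (cat_k == "spacing") positions <- c(pos, pos + 30L)

      for (p_j in positions) {
        ref <- substr(seq_i, p_j, p_j)
        var <- sample(setdiff(bases, ref), 1L)
        k_src <- if (cat_k == "shared_polymorphism") 1L
                 else sample(2:n_sources, 1L)
        src <- sample(sources, k_src)
        cov <- round(stats::runif(k_src, coverage_spec[1], coverage_spec[2]))
        sq <- stats::runif(k_src, quality_spec[1], quality_spec[2])
        nq <- stats::runif(k_src, 20, 40)
        vf <- stats::runif(k_src, 30, 70)
        nsp <- rep(FALSE, k_src)
        if (cat_k == "coverage") cov <- round(stats::runif(k_src, 0, 49))
        if (cat_k == "snp_quality") sq <- stats::runif(k_src, 0, 29.5)
        if (cat_k == "neighbourhood_quality") nq <- stats::runif(k_src, 0, 19.5)
        if (cat_k == "variant_freq") vf <- stats::runif(k_src, 0, 24.5)
        if (cat_k == "nonspecific") nsp <- rep(TRUE, k_src)
        score <- if (cat_k == "designability") stats::runif(1, 0, 0.59)
                 else stats::runif(1, 0.6, 1)
        mname <- paste0(cid, "_", p_j)
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          contig_id = cid, position = p_j, ref_allele = ref,
          var_allele = var, coverage = cov, variant_frequency = vf,
          snp_quality = sq, neighbourhood_quality = nq,
          source_genotype = src, nonspecific_flag = nsp,
          stringsAsFactors = FALSE)
        desig_rows[[length(desig_rows) + 1L]] <- data.frame(
          marker_name = mname, designability = score,
          stringsAsFactors = FALSE)
        removed_by <- if (ctype != "clean") "annotation"
                      else if (cat_k == "pass") NA_character_
                      else cat_k
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          contig_id = cid, position = p_j, marker_name = mname,
          removed_by = removed_by, stringsAsFactors = FALSE)
      }
    }
  }
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(contig_id = character(0), position = integer(0),
               ref_allele = character(0), var_allele = character(0),
               coverage = numeric(0), variant_frequency = numeric(0),
               snp_quality = numeric(0), neighbourhood_quality = numeric(0),
               source_genotype = character(0), nonspecific_flag = logical(0))
  truth_df <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(contig_id = character(0), position = integer(0),
               marker_name = character(0), removed_by = character(0))
  blast <- if (length(blast_rows)) do.call(rbind, blast_rows) else
    data.frame(contig_id = character(0), subject_id = character(0),
               description = character(0))
  desig <- if (length(desig_rows)) do.call(rbind, desig_rows) else
    data.frame(marker_name = character(0), designability = numeric(0))
  list(contigs = unlist(contig_rows),
       variants = variants, blast = blast, designability = desig,
       truth = list(markers = truth_df,
                    survivors = truth_df$marker_name[is.na(truth_df$removed_by)]))
}

#' Simulate cluster-quality statistics for array markers
#'
#' Each marker is assigned one of four categories: pass, low average
#' cluster intensity (R mean below 0.2), low cluster separation (below
#' 0.3) or a separation in the review band [0.3, 0.45).
#'
#' @param marker_ids marker names.
#' @param fail_fractions named numeric vector with elements
#'   \code{r_mean}, \code{separation} and \code{review}; must sum to at
#'   most 1, the remainder passes.
#' @param seed integer seed.
#' @return A list with \code{stats} (data frame: marker_id, r_mean_aa,
#'   r_mean_ab, r_mean_bb, cluster_separation) and \code{truth}
#'   (data frame of expected pass/review/fail labels).
#' @export
gen_cluster_stats <- function(marker_ids,
                              fail_fractions = c(r_mean = 0, separation = 0,
                                                 review = 0),
                              seed = 1L) {
  stopifnot(all(fail_fractions >= 0), sum(fail_fractions) <= 1)
  set.seed(seed)
  n <- length(marker_ids)
  cat_names <- c(names(fail_fractions), "pass")
  probs <- c(fail_fractions, pass = 1 - sum(fail_fractions))
  cats <- sample(cat_names, n, replace = TRUE, prob = probs)

  r <- matrix(stats::runif(3 * n, 0.3, 1.5), ncol = 3)
  sep <- stats::runif(n, 0.45, 0.9)
  i_rm <- which(cats == "r_mean")
  if (length(i_rm))
    r[cbind(i_rm, sample.int(3, length(i_rm), replace = TRUE))] <-
      stats::runif(length(i_rm), 0.01, 0.19)
  i_sep <- which(cats == "separation")
  sep[i_sep] <- stats::runif(length(i_sep), 0.05, 0.295)
  i_rev <- which(cats == "review")
  sep[i_rev] <- stats::runif(length(i_rev), 0.3, 0.4495)

  label <- ifelse(cats %in% c("r_mean", "separation"), "fail",
                  ifelse(cats == "review", "review", "pass"))
  list(stats = data.frame(marker_id = marker_ids,
                          r_mean_aa = r[, 1], r_mean_ab = r[, 2],
                          r_mean_bb = r[, 3], cluster_separation = sep,
                          stringsAsFactors = FALSE),
       truth = data.frame(marker_id = marker_ids, label = label,
                          stringsAsFactors = FALSE))
}

#' Construct a marker-validation fixture with known exclusion counts
#'
#' Builds an ecotype genotype matrix plus a mapping family in which an
#' exact, chosen number of markers fails each stage of the validation
#' cascade: markers with more than four Mendelian trio errors in the
#' family, markers with a global minor allele frequency below 5 %, and
#' markers failing the heterozygote-excess test, with all remaining
#' markers passing every stage.  Useful for verifying the cascade's
#' bookkeeping against planted truth.
#'
#' @param n_markers total number of markers entering the cascade.
#' @param n_trio_fail markers with more than \code{max_trio_errors}
#'   heritability errors in the family.
#' @param n_maf_fail markers (among the remainder) with MAF below 5 \%.
#' @param n_het_fail markers (among the remainder) with strong
#'   heterozygote excess in every accession.
#' @param n_accessions number of ecotype accessions (8 individuals
#'   each, the last with 4).
#' @param n_progeny progeny in the mapping family.
#' @param seed integer seed (placement of planted markers).
#' @return List with \code{genotypes}, \code{family}, \code{trios},
#'   \code{cluster_stats} (all passing) and \code{truth} (expected
#'   survivor counts after each stage).
#' @export
gen_qc_cascade_fixture <- function(n_markers = 2501, n_trio_fail = 43,
                                   n_maf_fail = 239, n_het_fail = 34,
                                   n_accessions = 90, n_progeny = 193,
                                   seed = 1L) {
  stopifnot(n_trio_fail + n_maf_fail + n_het_fail <= n_markers)
  set.seed(seed)
  sizes <- c(rep(8L, n_accessions - 1L), 4L)
  acc_ids <- sprintf("A%03d", rep(seq_len(n_accessions), sizes))
  N <- length(acc_ids)
  marker_ids <- sprintf("M%05d", seq_len(n_markers))
  cls <- sample(rep(c("trio", "maf", "het", "pass"),
                    c(n_trio_fail, n_maf_fail, n_het_fail,
                      n_markers - n_trio_fail - n_maf_fail - n_het_fail)))

  ## pass pattern: half AA, half BB within each accession -> MAF 0.5,
  ## zero heterozygotes (no excess), Mendelian-clean AA x BB parents
  pass_col <- unlist(lapply(sizes, function(s)
    rep(c("AA", "BB"), c(ceiling(s / 2), floor(s / 2)))))
  maf_col <- rep("AA", N)
  ## one heterozygote in each of 10 accessions: MAF = 10/(2N) < 5 %,
  ## each accession's exact test has a single admissible outcome (P = 1)
  first_of_acc <- cumsum(c(1L, sizes))[seq_len(min(10L, n_accessions))]
  maf_col[first_of_acc] <- "AB"
  het_col <- rep("AB", N)

  calls <- matrix("", N, n_markers)
  calls[, cls == "pass" | cls == "trio"] <- pass_col
  calls[, cls == "maf"] <- maf_col
  calls[, cls == "het"] <- het_col
  gm <- genotype_matrix(calls, sample_id = sprintf("S%04d", seq_len(N)),
                        accession_id = acc_ids, marker_id = marker_ids)

  fam <- matrix("", n_progeny + 2L, n_markers)
  fam[, cls == "pass"] <- rep(c("AA", "BB", rep("AB", n_progeny)),
                              times = sum(cls == "pass"))
  ## > 4 errors: homozygous AA x AA parents with 5 heterozygous progeny
  fam[, cls == "trio"] <- rep(c("AA", "AA", rep("AB", 5L),
                                rep("AA", n_progeny - 5L)),
                              times = sum(cls == "trio"))
  fam[, cls == "maf"] <- "AA"
  fam[, cls == "het"] <- "AB"
  family <- genotype_matrix(fam,
                            sample_id = c("P1", "P2",
                                          sprintf("O%03d", seq_len(n_progeny))),
                            accession_id = rep("FAM", n_progeny + 2L),
                            marker_id = marker_ids)
  cstats <- data.frame(marker_id = marker_ids, r_mean_aa = 1,
                       r_mean_ab = 1, r_mean_bb = 1,
                       cluster_separation = 0.9, stringsAsFactors = FALSE)
  list(genotypes = gm, family = family,
       trios = list(parent1_id = "P1", parent2_id = "P2",
                    offspring_ids = sprintf("O%03d", seq_len(n_progeny))),
       cluster_stats = cstats,
       truth = list(classes = stats::setNames(cls, marker_ids),
                    after_trio = n_markers - n_trio_fail,
                    after_maf = n_markers - n_trio_fail - n_maf_fail,
                    final = n_markers - n_trio_fail - n_maf_fail - n_het_fail))
}
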