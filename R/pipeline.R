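## End-to-end orchestration: one configuration object carries every
## threshold of every stage, with the published assay-validation values
## as the zero-config defaults, and a single seed drives all randomness.

#' Default run configuration
#'
#' Nested list of every tunable threshold with its default.  The
#' probe-design and marker-validation defaults are the assay's
#' published values: coverage >= 50, SNP quality >= 30, neighbourhood
#' quality >= 20, variant frequency >= 25 %, polymorphism in >= 2
#' source genotypes, >= 50 bp marker spacing, 50--60 bp flanks,
#' designability >= 0.6, cluster R mean >= 0.2, separation >= 0.3
#' (review below 0.45), missingness <= 10 %, <= 4 trio errors,
#' MAF >= 5 %, heterozygote-excess combined P >= 0.5.
#'
#' @return Named list with elements \code{stages}, \code{seed},
#'   \code{inputs}, \code{simulate}, \code{probe_design},
#'   \code{genotype_qc}, \code{diversity}, \code{amova}.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "qc", "diversity", "amova"),
    seed = 1L,
    inputs = list(genotypes = NULL, accessions = NULL, variants = NULL,
                  contigs = NULL, blast = NULL, designability = NULL,
                  cluster_stats = NULL, family = NULL),
    simulate = list(n_regions = 4, accessions_per_region = c(12, 45, 16, 17),
                    individuals_per_accession = 8,
                    deviating_sizes = c("90" = 4L),
                    n_markers = 2185, f_rt = 0.08, f_pr = 0.25,
                    cline_fraction = 0.5, cline_strength = 1.0,
                    missing_rate = 0.02,
                    family = list(n_progeny = 193, error_rate = 0.005),
                    variant_report = list(n_contigs = 60,
                                          snp_density = 0.01)),
    probe_design = list(min_coverage = 50, min_snp_quality = 30,
                        min_neighbourhood_quality = 20,
                        min_variant_freq = 25, drop_nonspecific = TRUE,
                        min_sources = 2,
                        blacklist_keywords = .blacklist_default,
                        min_gap = 50, spacing_keep = "none",
                        min_flank = 50, preferred_flank = 60,
                        min_designability = 0.6),
    genotype_qc = list(fail_rmean = 0.2, fail_sep = 0.3,
                       review_sep_hi = 0.45, max_missing = 0.10,
                       max_trio_errors = 4, min_maf = 0.05,
                       het_excess_p = 0.5, het_excess_combine = "fisher"),
    diversity = list(n_components = 10, top_k = 50, adjust_missing = FALSE),
    amova = list(n_perm = 999))
}

#' Read a run configuration from YAML
#'
#' Values present in the file override \code{\link{default_config}};
#' everything else keeps its default.
#'
#' @param path YAML file path.
#' @return Full configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

.in_range <- function(x, lo, hi) is.numeric(x) && x >= lo && x <= hi

#' Validate a run configuration
#'
#' @param config configuration list (partial configurations are merged
#'   over \code{\link{default_config}} first).
#' @return Character vector of violations, each naming the field, the
#'   offending value and the allowed range; empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  v <- character(0)
  bad <- function(field, value, allowed)
    sprintf("%s = %s (allowed: %s)", field,
            paste(format(value), collapse = ","), allowed)

  unknown <- setdiff(cfg$stages,
                     c("simulate", "design", "qc", "diversity", "amova"))
  if (length(unknown))
    v <- c(v, bad("stages", unknown,
                  "simulate, design, qc, diversity, amova"))
  rng <- list(
    c("probe_design$min_designability", cfg$probe_design$min_designability, 0, 1),
    c("genotype_qc$max_missing", cfg$genotype_qc$max_missing, 0, 1),
    c("genotype_qc$min_maf", cfg$genotype_qc$min_maf, 0, 0.5),
    c("genotype_qc$het_excess_p", cfg$genotype_qc$het_excess_p, 0, 1),
    c("simulate$f_rt", cfg$simulate$f_rt, 0, 0.999),
    c("simulate$f_pr", cfg$simulate$f_pr, 0, 0.999),
    c("simulate$missing_rate", cfg$simulate$missing_rate, 0, 0.999),
    c("simulate$cline_fraction", cfg$simulate$cline_fraction, 0, 1))
  for (r in rng) {
    val <- as.numeric(r[[2]])
    if (!.in_range(val, as.numeric(r[[3]]), as.numeric(r[[4]])))
      v <- c(v, bad(r[[1]], val, sprintf("[%s, %s]", r[[3]], r[[4]])))
  }
  if (cfg$amova$n_perm < 0)
    v <- c(v, bad("amova$n_perm", cfg$amova$n_perm, ">= 0"))

  needs_genotypes <- any(c("qc", "diversity", "amova") %in% cfg$stages) &&
    !"simulate" %in% cfg$stages
  if (needs_genotypes && is.null(cfg$inputs$genotypes))
    v <- c(v, "inputs$genotypes is required when qc/diversity/amova run without simulate")
  if ("design" %in% cfg$stages && !"simulate" %in% cfg$stages) {
    for (f in c("variants", "contigs", "blast", "designability"))
      if (is.null(cfg$inputs[[f]]))
        v <- c(v, sprintf("inputs$%s is required when design runs without simulate", f))
  }
  for (f in names(cfg$inputs)) {
    p <- cfg$inputs[[f]]
    if (!is.null(p) && !file.exists(p))
      v <- c(v, sprintf("inputs$%s does not exist: %s", f, p))
  }
  v
}

#' Run the pipeline end to end
#'
#' Executes the selected stages (\code{simulate}, \code{design},
#' \code{qc}, \code{diversity}, \code{amova}) from one configuration,
#' writing every artifact to \code{out_dir} and logging progress to
#' standard error.  All randomness flows from the single configuration
#' seed, so a repeated run writes byte-identical data files.
#'
#' @param config configuration list merged over
#'   \code{\link{default_config}}.
#' @param seed optional override of the configuration seed.
#' @param out_dir output directory, created when absent.
#' @return The run manifest (invisibly): files written with MD5 hashes,
#'   per-stage counts, the seed and the package version.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = tempfile()) {
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  problems <- validate_config(cfg)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = cfg$stages,
                   package_version = as.character(utils::packageVersion("ecotypeSNP")),
                   files = character(0), counts = list())
  note <- function(...) message("[ecotypeSNP] ", ...)
  emit <- function(obj, name, writer) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    manifest$files <<- c(manifest$files, p)
    p
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  gm <- NULL; info <- NULL; fam <- NULL; trios <- NULL; cstats <- NULL

  if ("simulate" %in% cfg$stages) run_stage("simulate", {
    note("simulate: generating hierarchical genotypes")
    sp <- do.call(sim_params,
                  c(cfg$simulate[setdiff(names(cfg$simulate),
                                         c("family", "variant_report"))],
                    list(seed = cfg$seed)))
    sim <- gen_hierarchical_genotypes(sp)
    gm <- sim$genotypes; info <- sim$accession_info
    famspec <- cfg$simulate$family
    famr <- gen_mapping_family(n_progeny = famspec$n_progeny,
                               error_rate = famspec$error_rate,
                               n_markers = sp$n_markers,
                               seed = cfg$seed + 1L)
    fam <- famr$genotypes; trios <- famr$trios
    cs <- gen_cluster_stats(colnames(gm), seed = cfg$seed + 2L)
    cstats <- cs$stats
    emit(gm, "genotypes.tsv", write_genotypes)
    emit(info, "accessions.csv", write_accessions)
    emit(fam, "family_genotypes.tsv", write_genotypes)
    emit(cstats, "cluster_stats.tsv", write_cluster_stats)
    emit(list(clinal = sim$truth$clinal,
              family_errors = famr$truth,
              trios = trios), "simulation_truth.json", write_report_json)
    manifest$counts$simulate <- list(n_samples = nrow(gm),
                                     n_markers = ncol(gm),
                                     n_family = nrow(fam))
  })

  if ("design" %in% cfg$stages) run_stage("design", {
    note("design: probe-selection cascade")
    if (!is.null(cfg$inputs$variants)) {
      variants <- read_variants(cfg$inputs$variants)
      contigs <- read_fasta(cfg$inputs$contigs)
      blast <- read_blast(cfg$inputs$blast)
      desig <- utils::read.delim(cfg$inputs$designability,
                                 stringsAsFactors = FALSE)
    } else {
      vr <- do.call(gen_variant_report,
                    c(cfg$simulate$variant_report, list(seed = cfg$seed + 3L)))
      variants <- vr$variants; contigs <- vr$contigs
      blast <- vr$blast; desig <- vr$designability
      emit(vr$truth$markers, "variant_truth.tsv", write_variants)
    }
    res <- design_panel(variants, contigs, blast, desig,
                        config = cfg$probe_design)
    emit(res$panel, "probe_panel.csv",
         function(x, p) utils::write.csv(x, p, row.names = FALSE))
    emit(list(report = res$report, removed = res$removed),
         "design_report.json", write_report_json)
    manifest$counts$design <- list(input = res$report$input[1],
                                   panel = nrow(res$panel))
  })

  if (any(c("qc", "diversity", "amova") %in% cfg$stages) && is.null(gm))
    run_stage("load", {
      gm <- read_genotypes(cfg$inputs$genotypes)
      if (!is.null(cfg$inputs$accessions))
        info <- read_accessions(cfg$inputs$accessions)
      if (!is.null(cfg$inputs$cluster_stats))
        cstats <- read_cluster_stats(cfg$inputs$cluster_stats)
      if (!is.null(cfg$inputs$family))
        fam <- read_genotypes(cfg$inputs$family)
    })

  if ("qc" %in% cfg$stages) run_stage("qc", {
    note("qc: marker-validation cascade")
    if (!is.null(fam) && is.null(trios))
      trios <- list(parent1_id = rownames(fam)[1],
                    parent2_id = rownames(fam)[2],
                    offspring_ids = rownames(fam)[-(1:2)])
    qr <- run_qc(gm, cluster_stats = cstats, family = fam, trios = trios,
                  config = cfg$genotype_qc)
    emit(qr$stages, "qc_stages.tsv", write_variants)
    emit(list(stages = qr$stages, removed = qr$removed,
              review = qr$review, call_rates = as.list(qr$call_rates)),
         "qc_report.json", write_report_json)
    emit(qr$filtered, "genotypes_filtered.tsv", write_genotypes)
    manifest$counts$qc <- list(input = qr$stages$input[1],
                               surviving = length(qr$survivors))
    gm <- qr$filtered
  })

  pca <- NULL
  if ("diversity" %in% cfg$stages) run_stage("diversity", {
    note("diversity: allele frequencies, PCA, geography")
    enc <- encode_genotypes(gm)
    freqs <- accession_allele_frequencies(enc,
                                          adjust_missing = cfg$diversity$adjust_missing)
    pca <- pca_frequencies(freqs, cfg$diversity$n_components)
    emit(data.frame(ID = rownames(pca$scores), pca$scores),
         "pca_scores.csv",
         function(x, p) utils::write.csv(x, p, row.names = FALSE))
    emit(data.frame(column = rownames(pca$loadings), pca$loadings),
         "pca_loadings.csv",
         function(x, p) utils::write.csv(x, p, row.names = FALSE))
    cors <- list()
    if (!is.null(info)) {
      for (co in c("longitude", "latitude", "altitude")) {
        for (pc in 1:2) {
          res <- tryCatch(correlate_pc_with_geography(pca, info, pc, co),
                          error = function(e) NULL)
          if (!is.null(res)) cors[[paste0("PC", pc, "_", co)]] <- res
        }
      }
      emit(cors, "geo_correlations.json", write_report_json)
    }
    topk <- min(cfg$diversity$top_k, ncol(gm))
    emit(top_loading_markers(pca, 1, topk), "top_markers_pc1.csv",
         function(x, p) utils::write.csv(x, p, row.names = FALSE))
    manifest$counts$diversity <-
      list(explained_pc1 = pca$explained[1],
           r_squared = lapply(cors, `[[`, "r_squared"))
  })

  if ("amova" %in% cfg$stages) run_stage("amova", {
    note("amova: hierarchical variance decomposition")
    enc <- encode_genotypes(gm)
    regions <- NULL
    if (!is.null(info) && "Region" %in% names(info))
      regions <- info$Region[match(attr(gm, "accession_id"), info$ID)]
    am <- amova_nested(enc, regions = regions,
                       n_perm = cfg$amova$n_perm, seed = cfg$seed + 4L)
    emit(am$table, "amova_table.csv",
         function(x, p) utils::write.csv(x, p, row.names = FALSE))
    emit(list(phi = as.list(am$phi),
              p_values = if (is.null(am$p_values)) NULL
                         else as.list(am$p_values),
              components = as.list(am$components),
              n_perm = am$n_perm),
         "amova_phi.json", write_report_json)
    manifest$counts$amova <- list(phi = as.list(round(am$phi, 4)))
  })

  manifest$md5 <- as.list(tools::md5sum(manifest$files))
  write_report_json(manifest, file.path(out_dir, "manifest.json"))
  note("done: ", length(manifest$files), " artifact(s) in ", out_dir)
  invisible(manifest)
}
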