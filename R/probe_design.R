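## Probe selection for a fixed-content Infinium-style SNP array:
## variant-level quality filters, shared-polymorphism subselection,
## contig annotation screening, marker spacing, flanking-sequence
## extraction and designability-score selection, applied in that order.

.variant_cols <- c("contig_id", "position", "ref_allele", "var_allele",
                   "coverage", "variant_frequency", "snp_quality",
                   "neighbourhood_quality", "source_genotype",
                   "nonspecific_flag")

.check_variant_table <- function(variants) {
  miss <- setdiff(.variant_cols, names(variants))
  if (length(miss))
    stop("variant table is missing required column(s): ",
         paste(miss, collapse = ", "))
  invisible(variants)
}

.marker_name <- function(contig_id, position) paste0(contig_id, "_", position)

#' Parse a marker name of the form Contig<X>_<Y>
#'
#' @param marker_name character vector of names following the
#'   \code{"ContigX_Y"} convention, where Y is the 1-based base position
#'   of the SNP within contig X.
#' @return Data frame with columns \code{contig_id} and \code{position}.
#' @export
parse_marker_name <- function(marker_name) {
  m <- regmatches(marker_name, regexec("^(.*)_([0-9]+)$", marker_name))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("unparseable marker name(s): ",
         paste(utils::head(marker_name[bad], 5), collapse = ", "))
  data.frame(contig_id = vapply(m, `[`, "", 2L),
             position = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Filter variant calls on coverage, quality and frequency
#'
#' A variant observation survives only if it passes every criterion:
#' read coverage, SNP quality, neighbourhood quality and variant
#' frequency at least the stated thresholds (inclusive), and, when
#' \code{drop_nonspecific} is set, no non-specific read mapping.  Each
#' removed row records the first failing criterion in the order
#' coverage, snp_quality, neighbourhood_quality, variant_freq,
#' nonspecific.
#'
#' @param variants variant-call data frame (one row per SNP per source
#'   genotype) with the documented columns.
#' @param min_coverage,min_snp_quality,min_neighbourhood_quality
#'   minimum read coverage and phred-scaled quality thresholds.
#' @param min_variant_freq minimum variant frequency, in percent.
#' @param drop_nonspecific drop observations flagged as non-specific
#'   read mappings.
#' @return List with \code{survivors}, \code{removed} (with a
#'   \code{reason} column) and \code{counts} (removals per criterion).
#' @export
filter_variant_calls <- function(variants, min_coverage = 50,
                                 min_snp_quality = 30,
                                 min_neighbourhood_quality = 20,
                                 min_variant_freq = 25,
                                 drop_nonspecific = TRUE) {
  .check_variant_table(variants)
  stopifnot(min_coverage >= 0, min_snp_quality >= 0,
            min_neighbourhood_quality >= 0, min_variant_freq >= 0)
  reason <- rep(NA_character_, nrow(variants))
  fails <- list(
    coverage = variants$coverage < min_coverage,
    snp_quality = variants$snp_quality < min_snp_quality,
    neighbourhood_quality =
      variants$neighbourhood_quality < min_neighbourhood_quality,
    variant_freq = variants$variant_frequency < min_variant_freq,
    nonspecific = if (drop_nonspecific) variants$nonspecific_flag
                  else rep(FALSE, nrow(variants)))
  for (nm in names(fails))
    reason[is.na(reason) & fails[[nm]]] <- nm
  removed <- variants[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(survivors = variants[is.na(reason), , drop = FALSE],
       removed = removed,
       counts = vapply(names(fails),
                       function(nm) sum(reason == nm, na.rm = TRUE), 1L))
}

#' Keep markers polymorphic in at least two source genotypes
#'
#' Collapses the per-source variant observations to unique markers keyed
#' on (contig, position, sorted allele pair) and keeps markers observed
#' in at least \code{min_sources} distinct source genotypes.
#'
#' @param variants surviving variant rows.
#' @param min_sources minimum number of distinct source genotypes.
#' @return List with \code{markers} (one row per surviving marker, with
#'   the union source count) and \code{removed}.
#' @export
shared_polymorphism_filter <- function(variants, min_sources = 2) {
  .check_variant_table(variants)
  if (nrow(variants) == 0)
    return(list(markers = data.frame(contig_id = character(0),
                                     position = integer(0),
                                     allele1 = character(0),
                                     allele2 = character(0),
                                     marker_name = character(0),
                                     n_sources = integer(0)),
                removed = data.frame()))
  a1 <- pmin(variants$ref_allele, variants$var_allele)
  a2 <- pmax(variants$ref_allele, variants$var_allele)
  key <- paste(variants$contig_id, variants$position, a1, a2, sep = "\r")
  n_src <- vapply(split(variants$source_genotype, key),
                  function(s) length(unique(s)), 1L)
  first <- !duplicated(key)
  markers <- data.frame(contig_id = variants$contig_id[first],
                        position = variants$position[first],
                        allele1 = a1[first], allele2 = a2[first],
                        stringsAsFactors = FALSE)
  markers$marker_name <- .marker_name(markers$contig_id, markers$position)
  markers$n_sources <- as.integer(n_src[key[first]])
  keep <- markers$n_sources >= min_sources
  list(markers = markers[keep, , drop = FALSE],
       removed = markers[!keep, , drop = FALSE])
}

#' Screen contigs on BLAST annotation
#'
#' A contig is removed when any BLAST subject occurs in more than one
#' HSP for that contig (evidence of frameshift/misassembly) or when any
#' hit description matches an organellar/retroelement keyword
#' (case-insensitive).  Contigs without any annotation are retained.
#'
#' @param blast tabular BLAST annotation with columns \code{contig_id},
#'   \code{subject_id} and \code{description} (one row per HSP).
#' @param contig_ids the contigs under consideration.
#' @param blacklist_keywords character vector of keywords flagging
#'   likely organellar or repetitive sequence.
#' @return List with \code{allowed} (contig ids kept) and \code{removed}
#'   (data frame with a \code{reason} of \code{frameshift} or
#'   \code{blacklist}).
#' @export
annotation_filter <- function(blast, contig_ids,
                              blacklist_keywords = .blacklist_default) {
  removed <- data.frame(contig_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (nrow(blast)) {
    blast <- blast[blast$contig_id %in% contig_ids, , drop = FALSE]
    keys <- paste(blast$contig_id, blast$subject_id, sep = "\r")
    fs <- unique(blast$contig_id[keys %in% keys[duplicated(keys)]])
    pat <- paste(blacklist_keywords, collapse = "|")
    bl <- unique(blast$contig_id[grepl(pat, blast$description,
                                       ignore.case = TRUE)])
    bl <- setdiff(bl, fs)   # frameshift takes precedence as the reason
    removed <- rbind(
      data.frame(contig_id = fs, reason = rep("frameshift", length(fs)),
                 stringsAsFactors = FALSE),
      data.frame(contig_id = bl, reason = rep("blacklist", length(bl)),
                 stringsAsFactors = FALSE))
  }
  list(allowed = setdiff(contig_ids, removed$contig_id), removed = removed)
}

#' Remove SNPs closer together than a minimum spacing
#'
#' Both members of any within-contig pair closer than \code{min_gap}
#' bases are removed (strict inequality: a distance of exactly
#' \code{min_gap} passes).  With \code{keep = "best"} the member with
#' the lower position in each conflicting pair is retained instead.
#'
#' @param markers marker data frame with \code{contig_id} and
#'   \code{position}.
#' @param min_gap minimum spacing in bases.
#' @param keep \code{"none"} removes both members of a close pair;
#'   \code{"best"} greedily keeps the left-most member.
#' @return List with \code{markers} (survivors) and \code{removed}.
#' @export
spacing_filter <- function(markers, min_gap = 50,
                           keep = c("none", "best")) {
  keep <- match.arg(keep)
  if (nrow(markers) == 0) return(list(markers = markers, removed = markers))
  drop <- logical(nrow(markers))
  for (ct in split(seq_len(nrow(markers)), markers$contig_id)) {
    pos <- markers$position[ct]
    o <- order(pos)
    idx <- ct[o]; pos <- pos[o]
    if (keep == "none") {
      close_next <- diff(pos) < min_gap
      bad <- logical(length(pos))
      bad[which(close_next)] <- TRUE
      bad[which(close_next) + 1L] <- TRUE
      drop[idx[bad]] <- TRUE
    } else {
      last_kept <- -Inf
      for (k in seq_along(pos)) {
        if (pos[k] - last_kept < min_gap) drop[idx[k]] <- TRUE
        else last_kept <- pos[k]
      }
    }
  }
  list(markers = markers[!drop, , drop = FALSE],
       removed = markers[drop, , drop = FALSE])
}

#' Extract flanking sequence and build probe candidates
#'
#' For each marker the flanking sequence on each side is the lesser of
#' \code{preferred_flank} and the bases available on the contig; a
#' candidate is rejected when either side offers fewer than
#' \code{min_flank} bases.  The probe target is rendered as
#' \code{LEFT[A1/A2]RIGHT} with the alleles in alphabetical order.
#'
#' @param contigs named character vector (or \code{DNAStringSet}) of
#'   contig sequences.
#' @param markers marker data frame with \code{contig_id},
#'   \code{position}, \code{allele1}, \code{allele2}.
#' @param min_flank minimum flank length in bases.
#' @param preferred_flank preferred flank length in bases.
#' @return Data frame of probe candidates with \code{marker_name},
#'   flanks, alleles, \code{probe_seq}, \code{status}
#'   (\code{survived}/\code{removed}) and \code{reason}.
#' @export
build_probe_candidates <- function(contigs, markers, min_flank = 50,
                                   preferred_flank = 60) {
  if (inherits(contigs, "DNAStringSet"))
    contigs <- stats::setNames(as.character(contigs), names(contigs))
  if (nrow(markers) == 0)
    return(data.frame(marker_name = character(0), left_flank = character(0),
                      right_flank = character(0), allele1 = character(0),
                      allele2 = character(0), probe_seq = character(0),
                      status = character(0), reason = character(0)))
  miss <- setdiff(unique(markers$contig_id), names(contigs))
  if (length(miss))
    stop("marker(s) reference unknown contig(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  seqs <- contigs[markers$contig_id]
  L <- nchar(seqs)
  if (any(markers$position < 1 | markers$position > L))
    stop("marker position outside contig bounds")
  base <- substr(seqs, markers$position, markers$position)
  ok <- base == markers$allele1 | base == markers$allele2
  mn <- .marker_name(markers$contig_id, markers$position)
  if (any(!ok))
    stop("contig base does not match either allele for marker(s): ",
         paste(utils::head(mn[!ok], 5), collapse = ", "))
  left_len <- pmin(preferred_flank, markers$position - 1L)
  right_len <- pmin(preferred_flank, L - markers$position)
  left <- substr(seqs, markers$position - left_len, markers$position - 1L)
  right <- substr(seqs, markers$position + 1L, markers$position + right_len)
  rejected <- left_len < min_flank | right_len < min_flank
  a1 <- pmin(markers$allele1, markers$allele2)
  a2 <- pmax(markers$allele1, markers$allele2)
  data.frame(marker_name = mn,
             left_flank = left, right_flank = right,
             allele1 = a1, allele2 = a2,
             probe_seq = paste0(left, "[", a1, "/", a2, "]", right),
             status = ifelse(rejected, "removed", "survived"),
             reason = ifelse(rejected, "flank", NA_character_),
             stringsAsFactors = FALSE)
}

#' Parse a rendered probe target sequence
#'
#' Inverse of the \code{LEFT[A1/A2]RIGHT} rendering used by
#' \code{\link{build_probe_candidates}}.
#'
#' @param probe_seq character vector of probe target strings.
#' @return Data frame with \code{left_flank}, \code{allele1},
#'   \code{allele2}, \code{right_flank}.
#' @export
parse_probe_seq <- function(probe_seq) {
  m <- regmatches(probe_seq,
                  regexec("^([ACGTN]*)\\[([ACGT])/([ACGT])\\]([ACGTN]*)$",
                          probe_seq))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("unparseable probe sequence(s)")
  data.frame(left_flank = vapply(m, `[`, "", 2L),
             allele1 = vapply(m, `[`, "", 3L),
             allele2 = vapply(m, `[`, "", 4L),
             right_flank = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}

#' Select probe candidates on designability score
#'
#' @param candidates probe-candidate data frame with \code{marker_name}.
#' @param scores either a named numeric vector or a data frame with
#'   columns \code{marker_name} and \code{designability}.
#' @param min_score minimum accepted score (inclusive).
#' @return List with \code{panel} (candidates scoring at least
#'   \code{min_score}, with a \code{designability} column) and
#'   \code{removed}.
#' @export
designability_filter <- function(candidates, scores, min_score = 0.6) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$designability, scores$marker_name)
  s <- scores[candidates$marker_name]
  if (anyNA(s))
    stop("missing designability score(s) for marker(s): ",
         paste(utils::head(candidates$marker_name[is.na(s)], 5),
               collapse = ", "))
  candidates$designability <- as.numeric(s)
  keep <- candidates$designability >= min_score
  removed <- candidates[!keep, , drop = FALSE]
  if (nrow(removed)) removed$reason <- "designability"
  list(panel = candidates[keep, , drop = FALSE], removed = removed)
}

#' Run the full probe-selection cascade
#'
#' Applies, in order: the variant-level quality filters, the
#' shared-polymorphism subselection, the contig annotation screen, the
#' marker spacing filter, flanking-sequence extraction and the
#' designability selection.  Each marker removed is attributed to the
#' first stage that drops it.
#'
#' @param variants variant-call table (one row per SNP per source).
#' @param contigs named character vector or \code{DNAStringSet}.
#' @param blast tabular BLAST annotation.
#' @param designability per-marker designability scores (data frame or
#'   named vector).
#' @param config named list of threshold overrides; see
#'   \code{\link{default_config}} element \code{probe_design} for the
#'   recognised names and defaults.
#' @return List with \code{panel} (surviving probe candidates),
#'   \code{report} (per-stage input/removed/surviving marker counts) and
#'   \code{removed} (marker name and first-failing reason).
#' @export
design_panel <- function(variants, contigs, blast, designability,
                         config = list()) {
  cfg <- utils::modifyList(default_config()$probe_design, config)
  .check_variant_table(variants)
  all_markers <- unique(.marker_name(variants$contig_id, variants$position))
  removed <- data.frame(marker_name = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  note_removed <- function(mn, reason)
    rbind(removed, data.frame(marker_name = mn, reason = reason,
                              stringsAsFactors = FALSE))
  stages <- list()

  ## 1. variant-level quality filters (marker drops when all its
  ##    observations drop; reason = first removed row's criterion)
  vf <- filter_variant_calls(variants, cfg$min_coverage, cfg$min_snp_quality,
                             cfg$min_neighbourhood_quality,
                             cfg$min_variant_freq, cfg$drop_nonspecific)
  surv_m <- unique(.marker_name(vf$survivors$contig_id,
                                vf$survivors$position))
  gone <- setdiff(all_markers, surv_m)
  if (length(gone)) {
    rm_m <- .marker_name(vf$removed$contig_id, vf$removed$position)
    reason1 <- vapply(gone, function(m) vf$removed$reason[match(m, rm_m)], "")
    removed <- note_removed(gone, unname(reason1))
  }
  stages[[1]] <- data.frame(stage = "variant_filters",
                            input = length(all_markers),
                            removed = length(gone),
                            surviving = length(surv_m))

  ## 2. shared polymorphism
  sp <- shared_polymorphism_filter(vf$survivors, cfg$min_sources)
  if (nrow(sp$removed))
    removed <- note_removed(sp$removed$marker_name, "shared_polymorphism")
  stages[[2]] <- data.frame(stage = "shared_polymorphism",
                            input = length(surv_m),
                            removed = nrow(sp$removed),
                            surviving = nrow(sp$markers))
  markers <- sp$markers

  ## 3. contig annotation
  an <- annotation_filter(blast, unique(markers$contig_id),
                          cfg$blacklist_keywords)
  drop3 <- markers$contig_id %in% an$removed$contig_id
  if (any(drop3))
    removed <- note_removed(markers$marker_name[drop3], "annotation")
  stages[[3]] <- data.frame(stage = "annotation", input = nrow(markers),
                            removed = sum(drop3),
                            surviving = sum(!drop3))
  markers <- markers[!drop3, , drop = FALSE]

  ## 4. spacing
  spc <- spacing_filter(markers, cfg$min_gap, cfg$spacing_keep)
  if (nrow(spc$removed))
    removed <- note_removed(spc$removed$marker_name, "spacing")
  stages[[4]] <- data.frame(stage = "spacing", input = nrow(markers),
                            removed = nrow(spc$removed),
                            surviving = nrow(spc$markers))
  markers <- spc$markers

  ## 5. flanking sequence
  cand <- build_probe_candidates(contigs, markers, cfg$min_flank,
                                 cfg$preferred_flank)
  flank_gone <- cand$marker_name[cand$status == "removed"]
  if (length(flank_gone)) removed <- note_removed(flank_gone, "flank")
  cand <- cand[cand$status == "survived", , drop = FALSE]
  stages[[5]] <- data.frame(stage = "flank", input = nrow(markers),
                            removed = length(flank_gone),
                            surviving = nrow(cand))

  ## 6. designability
  ds <- designability_filter(cand, designability, cfg$min_designability)
  if (nrow(ds$removed)) removed <- note_removed(ds$removed$marker_name,
                                                "designability")
  stages[[6]] <- data.frame(stage = "designability", input = nrow(cand),
                            removed = nrow(ds$removed),
                            surviving = nrow(ds$panel))

  list(panel = ds$panel, report = do.call(rbind, stages), removed = removed)
}
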