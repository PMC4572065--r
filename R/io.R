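## Readers and writers for the plain-text interchange formats: FASTA
## contigs, variant and BLAST tables (TSV), accession metadata (CSV),
## cluster statistics (TSV) and JSON reports.

#' Read and write contig FASTA
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @return \code{read_fasta} returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}

#' Read and write the variant-call table
#'
#' One row per putative SNP per source genotype, tab-separated, with
#' the documented header.
#'
#' @param x variant data frame.
#' @param path file path.
#' @export
write_variants <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_variant_table(v)
  v
}

#' Read and write the BLAST annotation table
#'
#' Tabular (outfmt-6-like) with at least \code{contig_id},
#' \code{subject_id} and a \code{description} column.
#'
#' @param x BLAST data frame.
#' @param path file path.
#' @export
write_blast <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_blast
#' @export
read_blast <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Read and write accession metadata
#'
#' CSV with columns ID, Accession, Country, Longitude, Latitude,
#' Altitude, Region.
#'
#' @param x accession data frame.
#' @param path file path.
#' @export
write_accessions <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_accessions
#' @export
read_accessions <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Read and write cluster statistics
#'
#' @param x cluster-statistics data frame.
#' @param path file path.
#' @export
write_cluster_stats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_stats
#' @export
read_cluster_stats <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Write a report object as JSON
#'
#' @param x a list or data frame.
#' @param path file path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
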