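#' Codominant genotype matrix
#'
#' Container for array genotype calls: individuals in rows, markers in
#' columns, with the call alphabet \code{AA}, \code{AB}, \code{BB} and
#' \code{NC} (no call).  Every sample carries an accession assignment,
#' the unit at which allele frequencies are later computed.
#'
#' @param calls character matrix of calls, samples in rows, markers in
#'   columns.  Dimnames, when present, are used as sample and marker ids.
#' @param sample_id character vector of sample identifiers.
#' @param accession_id character vector assigning each sample to an
#'   accession.
#' @param marker_id character vector of marker names.
#' @return An object of class \code{genotype_matrix}: the call matrix with
#'   \code{accession_id} attached as an attribute.
#' @export
genotype_matrix <- function(calls, sample_id = rownames(calls),
                            accession_id, marker_id = colnames(calls)) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("'calls' must be a character matrix")
  if (is.null(sample_id))
    sample_id <- sprintf("S%04d", seq_len(nrow(calls)))
  if (is.null(marker_id))
    marker_id <- sprintf("M%05d", seq_len(ncol(calls)))
  if (length(sample_id) != nrow(calls))
    stop("length(sample_id) must equal nrow(calls)")
  if (length(marker_id) != ncol(calls))
    stop("length(marker_id) must equal ncol(calls)")
  if (length(accession_id) != nrow(calls))
    stop("every sample needs an accession: length(accession_id) != nrow(calls)")
  bad <- !calls %in% c("AA", "AB", "BB", "NC")
  if (any(bad))
    stop("invalid genotype call(s): ",
         paste(utils::head(unique(calls[bad]), 5), collapse = ", "))
  dimnames(calls) <- list(sample_id, marker_id)
  structure(calls, accession_id = as.character(accession_id),
            class = c("genotype_matrix", class(calls)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x), "samples x", ncol(x), "markers,",
      length(unique(attr(x, "accession_id"))), "accessions\n")
  nc <- mean(x == "NC")
  cat(sprintf("  missing (NC) rate: %.3f\n", nc))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a \code{genotype_matrix}.
#' @export
accession_of <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  stats::setNames(attr(x, "accession_id"), rownames(x))
}

#' Subset a genotype matrix by marker
#'
#' Keeps the listed markers (columns) and preserves accession assignments.
#'
#' @param x a \code{genotype_matrix}.
#' @param markers character vector of marker names to keep.
#' @return A \code{genotype_matrix} restricted to \code{markers}.
#' @export
keep_markers <- function(x, markers) {
  stopifnot(inherits(x, "genotype_matrix"))
  missing_m <- setdiff(markers, colnames(x))
  if (length(missing_m))
    stop("unknown marker(s): ", paste(utils::head(missing_m, 5), collapse = ", "))
  genotype_matrix(unclass(x)[, markers, drop = FALSE],
                  sample_id = rownames(x),
                  accession_id = attr(x, "accession_id"),
                  marker_id = markers)
}

#' Subset a genotype matrix by sample
#'
#' @param x a \code{genotype_matrix}.
#' @param samples character vector of sample ids to keep.
#' @return A \code{genotype_matrix} restricted to \code{samples}.
#' @export
keep_samples <- function(x, samples) {
  stopifnot(inherits(x, "genotype_matrix"))
  idx <- match(samples, rownames(x))
  if (anyNA(idx))
    stop("unknown sample id(s): ",
         paste(utils::head(samples[is.na(idx)], 5), collapse = ", "))
  genotype_matrix(unclass(x)[idx, , drop = FALSE],
                  sample_id = samples,
                  accession_id = attr(x, "accession_id")[idx],
                  marker_id = colnames(x))
}

#' Read and write genotype matrices as TSV
#'
#' The on-disk layout is one row per sample with columns
#' \code{sample_id}, \code{accession_id}, then one column per marker
#' holding \code{AA}/\code{AB}/\code{BB}/\code{NC}.
#'
#' @param x a \code{genotype_matrix}.
#' @param path file path.
#' @return \code{read_genotypes} returns a \code{genotype_matrix};
#'   \code{write_genotypes} returns \code{path} invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  df <- data.frame(sample_id = rownames(x),
                   accession_id = attr(x, "accession_id"),
                   unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "accession_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("genotype table is missing column(s): ", paste(miss, collapse = ", "))
  mk <- setdiff(names(df), need)
  genotype_matrix(as.matrix(df[, mk, drop = FALSE]),
                  sample_id = df$sample_id,
                  accession_id = df$accession_id,
                  marker_id = mk)
}
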