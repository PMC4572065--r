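## Allele-specific-presence encoding, per-accession allele frequencies,
## PCA of the frequency matrix and its correlation with geography.

#' Encode genotype calls as allele-specific presence
#'
#' For the A allele of each marker, \code{AA} is coded 1, \code{AB} 0.5
#' and \code{BB} 0, and vice versa for the B allele.  Missing calls
#' (\code{NC}) are coded 0 for both alleles and are not imputed.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @return Numeric matrix, samples by \code{2 * n_markers}, with
#'   columns \code{<marker>_A} and \code{<marker>_B}; the accession
#'   assignment is carried along as attribute \code{accession_id}.
#' @export
encode_genotypes <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  calls <- unclass(x)
  a_val <- c(AA = 1, AB = 0.5, BB = 0, NC = 0)
  b_val <- c(AA = 0, AB = 0.5, BB = 1, NC = 0)
  M <- ncol(calls)
  enc <- matrix(0, nrow(calls), 2L * M)
  enc[, 2L * seq_len(M) - 1L] <- a_val[calls]
  enc[, 2L * seq_len(M)] <- b_val[calls]
  colnames(enc) <- as.vector(rbind(paste0(colnames(calls), "_A"),
                                   paste0(colnames(calls), "_B")))
  rownames(enc) <- rownames(calls)
  attr(enc, "accession_id") <- attr(x, "accession_id")
  enc
}

#' Per-accession relative allele frequencies
#'
#' Sums the encoded allele values over the individuals of each accession
#' and divides by the number of individuals in the accession.  Missing
#' calls remain in the denominator (they were encoded 0), exactly as the
#' frequencies are defined; \code{adjust_missing = TRUE} instead divides
#' each allele column by the number of non-missing calls.
#'
#' @param encoded matrix from \code{\link{encode_genotypes}}.
#' @param accession_id per-sample accession labels; defaults to the
#'   attribute carried by \code{encoded}.
#' @param adjust_missing use non-missing counts as denominators.
#' @return Accessions x (2 x markers) frequency matrix.
#' @export
accession_allele_frequencies <- function(encoded, accession_id = NULL,
                                         adjust_missing = FALSE) {
  if (is.null(accession_id)) accession_id <- attr(encoded, "accession_id")
  if (is.null(accession_id) || length(accession_id) != nrow(encoded))
    stop("every sample needs an accession label")
  sums <- rowsum(encoded, accession_id)
  if (!adjust_missing)
    return(sums / as.vector(table(accession_id)[rownames(sums)]))
  ## non-missing: A and B columns of a marker sum to 1 per called sample
  M <- ncol(encoded) / 2L
  called <- encoded[, 2L * seq_len(M) - 1L, drop = FALSE] +
    encoded[, 2L * seq_len(M), drop = FALSE]
  n_called <- rowsum(called, accession_id)
  denom <- n_called[, rep(seq_len(M), each = 2L), drop = FALSE]
  out <- sums / denom
  out[denom == 0] <- 0
  out
}

#' Principal component analysis of an allele-frequency matrix
#'
#' Columns are centred (not scaled) and the singular value
#' decomposition taken; scores are the left singular vectors scaled by
#' the singular values.  The sign of each component is fixed so that
#' its largest-magnitude loading is positive.
#'
#' @param freqs accessions x columns frequency matrix.
#' @param n_components number of components to keep (default all).
#' @return Object of class \code{freq_pca} with \code{scores},
#'   \code{loadings}, \code{explained} (variance fractions) and
#'   \code{center}.
#' @export
pca_frequencies <- function(freqs, n_components = NULL) {
  if (nrow(freqs) < 2) stop("PCA needs at least two accessions")
  ctr <- colMeans(freqs)
  X <- sweep(freqs, 2, ctr)
  if (all(abs(X) < 1e-12)) stop("PCA needs at least one non-constant column")
  sv <- svd(X)
  d <- sv$d
  k_max <- sum(d > max(d) * 1e-12)
  k <- if (is.null(n_components)) k_max else min(n_components, k_max)
  load <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d[seq_len(k)], k)
  ## deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  dimnames(scores) <- list(rownames(freqs), paste0("PC", seq_len(k)))
  dimnames(load) <- list(colnames(freqs), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = load,
                 explained = d^2 / sum(d^2), center = ctr),
            class = "freq_pca")
}

#' @export
print.freq_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat("PCA of allele frequencies:", nrow(x$scores), "accessions,",
      nrow(x$loadings), "columns,", k, "components kept\n")
  cat("explained variance:",
      paste0(sprintf("%.1f%%", 100 * x$explained[seq_len(min(k, 5))]),
             collapse = ", "), "...\n")
  invisible(x)
}

#' Correlate a principal component with a geographic coordinate
#'
#' Pearson correlation of accession scores with longitude, latitude or
#' altitude; accessions missing the coordinate are dropped pairwise.
#' The two-sided P value comes from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} df.
#'
#' @param pca a \code{\link{pca_frequencies}} result.
#' @param accession_info data frame with \code{ID} and the coordinate
#'   columns \code{Longitude}, \code{Latitude}, \code{Altitude}.
#' @param component component number.
#' @param coordinate one of \code{"longitude"}, \code{"latitude"},
#'   \code{"altitude"}.
#' @return List with \code{r}, \code{r_squared}, \code{p_value}, \code{n}.
#' @export
correlate_pc_with_geography <- function(pca, accession_info,
                                        component = 1,
                                        coordinate = c("longitude",
                                                       "latitude",
                                                       "altitude")) {
  coordinate <- match.arg(coordinate)
  if (component > ncol(pca$scores)) stop("component not available")
  col <- c(longitude = "Longitude", latitude = "Latitude",
           altitude = "Altitude")[[coordinate]]
  if (!col %in% names(accession_info))
    stop("accession_info lacks column ", col)
  idx <- match(rownames(pca$scores), accession_info$ID)
  if (anyNA(idx)) stop("accession_info does not cover all accessions")
  coord <- accession_info[[col]][idx]
  score <- pca$scores[, component]
  ok <- !is.na(coord)
  coord <- coord[ok]; score <- score[ok]
  n <- length(coord)
  if (n < 3) stop("need at least 3 accessions with the coordinate")
  if (stats::sd(coord) == 0 || stats::sd(score) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(score, coord)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, r_squared = r^2, p_value = p, n = n)
}

#' Markers contributing most to a principal component
#'
#' The A and B allele columns of one marker are collapsed to a single
#' entry carrying the larger absolute loading; markers are ranked by
#' absolute loading (descending), ties broken by marker name.
#'
#' @param pca a \code{\link{pca_frequencies}} result.
#' @param component component number.
#' @param k number of markers to return.
#' @param annotations optional data frame with \code{marker_name} (or
#'   \code{contig_id}) and annotation columns to join on.
#' @return Data frame with \code{marker_name}, \code{loading} (signed,
#'   from the dominating allele column) and \code{abs_loading}.
#' @export
top_loading_markers <- function(pca, component = 1, k = 50,
                                annotations = NULL) {
  if (component > ncol(pca$loadings)) stop("component not available")
  load <- pca$loadings[, component]
  marker <- sub("_(A|B)$", "", names(load))
  ord <- order(-abs(load))
  load <- load[ord]; marker <- marker[ord]
  first <- !duplicated(marker)   # per marker, keep the larger |loading|
  out <- data.frame(marker_name = marker[first],
                    loading = unname(load[first]),
                    abs_loading = abs(unname(load[first])),
                    stringsAsFactors = FALSE)
  if (k > nrow(out)) stop("k exceeds the number of distinct markers")
  out <- out[order(-out$abs_loading, out$marker_name), , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  if (!is.null(annotations)) {
    by <- if ("marker_name" %in% names(annotations)) "marker_name" else
      "contig_id"
    if (by == "contig_id")
      out$contig_id <- parse_marker_name(out$marker_name)$contig_id
    out <- merge(out, annotations, by = by, all.x = TRUE, sort = FALSE)
    out <- out[order(-out$abs_loading, out$marker_name), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
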