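#' Construct a paired count matrix container
#'
#' Bundles a gene-by-sample matrix of non-negative integer counts with
#' per-sample metadata. In a paired design every patient contributes exactly
#' one sample per site (e.g., one damaged and one intact cartilage sample
#' from the same knee).
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param meta data.frame with one row per sample and columns
#'   \code{sample}, \code{patient}, \code{site}, and optionally
#'   \code{batch}. \code{site} must have exactly two levels.
#' @param paired logical; if \code{TRUE} (default) the one-sample-per-
#'   patient-per-site invariant is enforced.
#'
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts} and \code{meta}, metadata rows aligned to columns.
#' @export
count_matrix <- function(counts, meta, paired = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    ps_stop("counts must have gene rownames and sample colnames", "invalid_input")
  if (any(counts < 0) || any(counts != round(counts)))
    ps_stop("counts must be non-negative integers", "invalid_input")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample", "patient", "site")
  if (!all(req %in% names(meta)))
    ps_stop("metadata must contain columns sample, patient, site", "invalid_input")
  if (!setequal(meta$sample, colnames(counts)))
    ps_stop("metadata samples do not match count matrix columns", "invalid_input")
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- meta$sample
  if (length(unique(meta$site)) != 2L)
    ps_stop("paired design requires exactly two site labels", "design_error")
  if (paired) {
    tab <- table(meta$patient, meta$site)
    if (any(tab != 1L))
      ps_stop("every patient must contribute exactly one sample per site",
              "design_error")
  }
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d patients, sites: %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$meta$patient)),
              paste(sort(unique(x$meta$site)), collapse = "/")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
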