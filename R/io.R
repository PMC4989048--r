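# File-format readers and writers. All tabular formats are plain TSV with
# a header row; writers emit canonical (sorted, whitespace-normalised)
# output so regenerated files are bit-identical under a fixed seed.

#' Write / read a counts TSV (genes x samples, gene id in column 1)
#'
#' @param counts a \code{\link{count_matrix}} or numeric matrix.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_counts_tsv
#' @return \code{read_counts_tsv}: an integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene")
    ps_stop(sprintf("%s: first column must be 'gene'", path), "parse_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)))
    ps_stop(sprintf("%s: non-numeric count at line %d",
                    path, which(rowSums(is.na(m)) > 0)[1] + 1L), "parse_error")
  rownames(m) <- df$gene
  m
}

#' Write / read a sample metadata TSV (sample, patient, site, batch)
#'
#' @param meta data.frame of per-sample metadata.
#' @param path file path.
#' @export
write_metadata_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "patient", "site")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    ps_stop(sprintf("%s: missing metadata column(s): %s", path,
                    paste(miss, collapse = ", ")), "parse_error")
  df
}

#' Write / read an edge-list TSV (source, target, layer, weight)
#'
#' @param edges data.frame with columns \code{from}, \code{to}, optional
#'   \code{layer}, \code{weight}.
#' @param path file path.
#' @param layer layer label used when the data.frame lacks one.
#' @export
write_edges_tsv <- function(edges, path, layer = NA_character_) {
  df <- data.frame(source = edges$from, target = edges$to,
                   layer = if ("layer" %in% names(edges)) edges$layer else layer,
                   weight = if ("weight" %in% names(edges)) edges$weight else 1,
                   stringsAsFactors = FALSE)
  df <- df[order(df$source, df$target, df$layer), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_edges_tsv
#' @return \code{read_edges_tsv}: data.frame with columns \code{from},
#'   \code{to}, \code{layer}, \code{weight}.
#' @export
read_edges_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("source", "target")
  if (!all(req %in% names(df)))
    ps_stop(sprintf("%s: edge list needs 'source' and 'target' columns", path),
            "parse_error")
  w <- if ("weight" %in% names(df)) suppressWarnings(as.numeric(df$weight))
       else rep(1, nrow(df))
  bad <- which(is.na(w) | is.na(df$source) | is.na(df$target) |
                 df$source == "" | df$target == "")
  if (length(bad) > 0)
    ps_stop(sprintf("%s: malformed edge at line %d (source/target/weight)",
                    path, bad[1] + 1L), "parse_error")
  data.frame(from = as.character(df$source), to = as.character(df$target),
             layer = if ("layer" %in% names(df)) df$layer else NA_character_,
             weight = w, stringsAsFactors = FALSE)
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines[order(names(sets))], path)
}

#' Read gene sets from GMT format
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write / read promoter sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read a differential-expression result TSV
#'
#' Columns: gene, baseMean, log2FoldChange, stat, pvalue, padj.
#'
#' @param de a \code{de_result}.
#' @param path file path.
#' @export
write_de_tsv <- function(de, path) {
  write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "baseMean", "log2FoldChange", "stat", "pvalue", "padj")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    ps_stop(sprintf("%s: missing DE column(s): %s", path,
                    paste(miss, collapse = ", ")), "parse_error")
  class(df) <- c("de_result", "data.frame")
  df
}

#' Write the sub-network summary table
#'
#' Columns: id, size, score, empirical_p, top_go, genes (comma-joined).
#'
#' @param subs list of \code{subnetwork}s.
#' @param path file path.
#' @export
write_subnetworks_tsv <- function(subs, path) {
  df <- do.call(rbind, lapply(seq_along(subs), function(i) {
    s <- subs[[i]]
    data.frame(id = sprintf("SN%03d", i), size = s$size, score = s$score,
               empirical_p = s$empirical_p,
               top_go = ifelse(is.na(s$top_go_term), "", s$top_go_term),
               genes = paste(s$genes, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df))
    df <- data.frame(id = character(0), size = integer(0), score = numeric(0),
                     empirical_p = numeric(0), top_go = character(0),
                     genes = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a regulon result as JSON
#'
#' @param reg a \code{\link{run_regulon}} result.
#' @param path file path.
#' @export
write_regulon_json <- function(reg, path) {
  out <- list(
    selected = reg$selected,
    selection = reg$selection,
    regulons = lapply(reg$regulons, function(r)
      list(tf = r$tf, targets = r$targets)),
    tf_edges = reg$tf_edges)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
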