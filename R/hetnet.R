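#' Build a heterogeneous gene-phenotype network
#'
#' Assembles protein-protein (PPI), phenotype-phenotype and
#' protein-phenotype (bridge) edge lists into a single typed, weighted,
#' undirected graph. PPI edges are restricted to proteins in
#' \code{expressed}; bridges from unexpressed proteins are dropped with
#' them; phenotype nodes are retained even when isolated. Self-loops are
#' removed and duplicate edges collapsed keeping the maximum weight.
#'
#' @param ppi data.frame of protein-protein edges (\code{from}, \code{to},
#'   optional \code{weight}).
#' @param pheno data.frame of phenotype-phenotype edges.
#' @param bridges data.frame of protein-phenotype edges with the protein in
#'   \code{from} and the phenotype in \code{to}.
#' @param expressed character vector of expressed protein identifiers; PPI
#'   is restricted to these. \code{NULL} keeps all proteins.
#' @return an igraph object of class \code{hetnet} with vertex attribute
#'   \code{type} in \{protein, phenotype\} and edge attributes
#'   \code{weight} and \code{layer} in \{ppi, pheno_pheno, protein_pheno\}.
#' @export
build_heterogeneous_network <- function(ppi, pheno, bridges, expressed = NULL) {
  norm_edges <- function(df, layer) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(from = character(0), to = character(0),
                        weight = numeric(0), layer = character(0)))
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(df)))
      ps_stop(sprintf("%s edge list needs columns from, to", layer),
              "malformed_edge")
    w <- if ("weight" %in% names(df)) as.numeric(df$weight) else rep(1, nrow(df))
    if (any(!is.finite(w)) || any(w < 0))
      ps_stop(sprintf("%s edge weights must be finite and non-negative", layer),
              "malformed_edge")
    data.frame(from = as.character(df$from), to = as.character(df$to),
               weight = w, layer = layer, stringsAsFactors = FALSE)
  }
  ppi <- norm_edges(ppi, "ppi")
  pheno <- norm_edges(pheno, "pheno_pheno")
  bridges <- norm_edges(bridges, "protein_pheno")

  proteins <- unique(c(ppi$from, ppi$to, bridges$from, expressed))
  phenos <- unique(c(pheno$from, pheno$to, bridges$to))
  clash <- intersect(proteins, phenos)
  if (length(clash) > 0)
    ps_stop(sprintf(
      "identifier(s) appear as both protein and phenotype (malformed bridge?): %s",
      paste(head(clash, 3), collapse = ", ")), "malformed_edge")

  if (!is.null(expressed)) {
    ppi <- ppi[ppi$from %in% expressed & ppi$to %in% expressed, , drop = FALSE]
    bridges <- bridges[bridges$from %in% expressed, , drop = FALSE]
    proteins <- intersect(proteins, expressed)
  }
  edges <- rbind(ppi, pheno, bridges)
  edges <- edges[edges$from != edges$to, , drop = FALSE]  # no self-loops
  if (nrow(edges) > 0) {
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    key <- paste(a, b, edges$layer, sep = "\r")
    keep_w <- tapply(edges$weight, key, max)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$weight <- as.numeric(keep_w[paste(pmin(edges$from, edges$to),
                                            pmax(edges$from, edges$to),
                                            edges$layer, sep = "\r")])
  }
  vertices <- data.frame(
    name = c(sort(proteins), sort(phenos)),
    type = c(rep("protein", length(proteins)), rep("phenotype", length(phenos))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  class(g) <- c("hetnet", class(g))
  g
}

# internal: protein-only subgraph carrying only PPI edges
ppi_layer <- function(net) {
  keep <- igraph::E(net)[igraph::E(net)$layer == "ppi"]
  g <- igraph::subgraph_from_edges(net, keep, delete.vertices = FALSE)
  igraph::induced_subgraph(g, igraph::V(g)[igraph::V(g)$type == "protein"])
}

#' @export
print.hetnet <- function(x, ...) {
  tp <- table(igraph::V(x)$type)
  tl <- table(igraph::E(x)$layer)
  cat(sprintf("hetnet: %d proteins, %d phenotypes; edges: %s\n",
              tp[["protein"]],
              if ("phenotype" %in% names(tp)) tp[["phenotype"]] else 0L,
              paste(sprintf("%s=%d", names(tl), tl), collapse = ", ")))
  invisible(x)
}
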