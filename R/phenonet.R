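#' Differential-expression node scores
#'
#' Per-gene evidence score \code{-log10(padj) * |log2FC|}, capped at
#' \code{cap}. Genes absent from the result (or with missing statistics)
#' score 0.
#'
#' @param de a \code{de_result}.
#' @param genes optional identifiers to score (default: genes in \code{de}).
#' @param cap maximum score (default 8; caps the -log10 blow-up of
#'   adjusted p-values near 0).
#' @return named non-negative numeric vector.
#' @export
score_nodes <- function(de, genes = NULL, cap = 8) {
  if (is.null(genes)) genes <- de$gene
  s <- setNames(numeric(length(genes)), genes)
  i <- match(genes, de$gene)
  ok <- !is.na(i) & !is.na(de$padj[i]) & !is.na(de$log2FoldChange[i])
  s[ok] <- pmin(-log10(pmax(de$padj[i[ok]], 1e-300)) *
                  abs(de$log2FoldChange[i[ok]]), cap)
  s
}

#' Random walk with restart on the heterogeneous network
#'
#' Iterates \code{p <- (1 - r) W p + r e} on the column-normalised weighted
#' adjacency matrix \code{W}, where \code{e} is the uniform distribution
#' over the seed nodes, until the L1 change falls below \code{tol}.
#' Columns of nodes without edges (dangling) teleport to the seeds.
#'
#' @param net a \code{\link{build_heterogeneous_network}} graph.
#' @param seeds character vector of seed node identifiers (typically the
#'   disease-anchor phenotypes).
#' @param restart restart probability in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return named numeric vector of visitation probabilities over all nodes
#'   (sums to 1).
#' @export
rwr <- function(net, seeds, restart = 0.7, tol = 1e-10, max_iter = 10000L) {
  if (restart <= 0 || restart > 1)
    ps_stop("restart must lie in (0, 1]", "invalid_parameter")
  nodes <- igraph::V(net)$name
  if (length(seeds) == 0) ps_stop("seeds must be non-empty", "unknown_seed")
  if (!all(seeds %in% nodes))
    ps_stop(sprintf("seed(s) not in network: %s",
                    paste(head(setdiff(seeds, nodes), 3), collapse = ", ")),
            "unknown_seed")
  w <- rwr_transition_matrix(net, seeds)
  e <- setNames(numeric(length(nodes)), nodes)
  e[seeds] <- 1 / length(seeds)
  p <- e
  for (it in seq_len(max_iter)) {
    p_new <- (1 - restart) * as.vector(w %*% p) + restart * e
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  setNames(as.vector(p), nodes)
}

# internal: column-normalised weighted adjacency; dangling columns teleport
# to the (uniform) seed distribution. Shared by rwr() and its linear-solve
# oracle in the tests.
#' Column-normalised RWR transition matrix
#'
#' @param net a \code{hetnet} graph.
#' @param seeds seed identifiers (receive the mass of dangling columns).
#' @return dense transition matrix (columns sum to 1).
#' @export
rwr_transition_matrix <- function(net, seeds) {
  a <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE)
  nodes <- igraph::V(net)$name
  cs <- colSums(a)
  dangling <- cs == 0
  if (any(dangling)) {
    a[, dangling] <- 0
    a[seeds, dangling] <- 1 / length(seeds)
    cs[dangling] <- 1
  }
  sweep(a, 2, cs, `/`)
}

# internal subnetwork record
subnetwork <- function(genes, score) {
  structure(list(genes = sort(genes), size = length(genes), score = score,
                 empirical_p = NA_real_, top_go_term = NA_character_,
                 top_go_p = NA_real_),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork: %d genes, score %.4g, empirical p %s, top GO: %s\n",
              x$size, x$score,
              if (is.na(x$empirical_p)) "NA" else format(x$empirical_p),
              if (is.na(x$top_go_term)) "NA" else x$top_go_term))
  invisible(x)
}

# internal: combined node score = minmax(DE score) x minmax(RWR score)
# over protein nodes; a constant component is neutral (all ones).
combined_node_scores <- function(net, de_scores, rwr_scores) {
  prots <- igraph::V(net)$name[igraph::V(net)$type == "protein"]
  mm <- function(x) {
    x <- ifelse(is.na(x), 0, x)
    rng <- range(x)
    if (rng[2] - rng[1] < .Machine$double.eps) return(rep(1, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  d <- de_scores[prots]; names(d) <- prots
  r <- rwr_scores[prots]; names(r) <- prots
  setNames(mm(unname(d)) * mm(unname(r)), prots)
}

#' Greedy extraction of high-scoring connected candidate sub-networks
#'
#' Proteins are ranked by combined score (the product of the min-max scaled
#' differential-expression score and min-max scaled RWR visitation
#' probability). From each top-ranked not-yet-used protein, the candidate
#' grows by repeatedly adding the PPI-adjacent protein that maximises the
#' size-normalised aggregate sum(scores)/sqrt(size) (the classic active-
#' module aggregate; a plain mean can never grow past the top-ranked
#' seed), stopping at \code{max_size} or when no addition increases the
#' aggregate. Growth claims nodes exclusively (a protein belongs to at
#' most one candidate), so emitted candidates are node-disjoint; the
#' downstream merge step handles overlap arising when candidate lists
#' from separate analyses are combined. The reported aggregate score is
#' the mean combined node score. Ties break lexicographically.
#'
#' @param net a \code{hetnet} graph.
#' @param de_scores \code{\link{score_nodes}} output.
#' @param rwr_scores \code{\link{rwr}} output.
#' @param max_size maximum initial sub-network size (default 7).
#' @return list of \code{subnetwork} objects (may be empty).
#' @export
extract_subnetworks <- function(net, de_scores, rwr_scores, max_size = 7L) {
  if (max_size < 1) ps_stop("max_size must be >= 1", "invalid_parameter")
  g <- ppi_layer(net)
  prots <- igraph::V(g)$name
  if (length(prots) == 0) return(list())
  comb <- combined_node_scores(net, de_scores, rwr_scores)[prots]
  adj <- igraph::as_adj_list(g)
  names(adj) <- prots
  ord <- prots[order(-comb, prots)]
  used <- character(0)
  out <- list()
  for (seed in ord) {
    if (seed %in% used || comb[seed] <= 0) next
    s <- seed
    cur_sum <- unname(comb[seed])
    cur_agg <- cur_sum
    while (length(s) < max_size) {
      frontier <- setdiff(unique(unlist(lapply(adj[s], function(v)
        prots[as.integer(v)]))), c(s, used))
      if (length(frontier) == 0) break
      aggs <- (cur_sum + comb[frontier]) / sqrt(length(s) + 1)
      best <- frontier[order(-aggs, frontier)][1]
      if (aggs[best] <= cur_agg) break
      s <- c(s, best)
      cur_sum <- cur_sum + unname(comb[best])
      cur_agg <- unname(aggs[best])
    }
    out[[length(out) + 1L]] <- subnetwork(s, cur_sum / length(s))
    used <- union(used, s)
  }
  out
}

# internal: adjacency list of the PPI layer as integer vectors
ppi_adjacency <- function(net) {
  g <- ppi_layer(net)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  list(graph = g, nodes = igraph::V(g)$name, adj = adj)
}

#' Sample connected null sub-networks of a given size
#'
#' Random-walk growth on the PPI layer: a uniformly chosen start protein is
#' extended by uniformly chosen frontier neighbours until the target size
#' is reached (restarting if the component is exhausted). Used to build the
#' resampling null for \code{\link{empirical_pvalue}}.
#'
#' @param net a \code{hetnet} graph.
#' @param size sub-network size.
#' @param n number of samples.
#' @return list of character vectors of protein ids.
#' @export
sample_null_subnetworks <- function(net, size, n) {
  pl <- ppi_adjacency(net)
  nn <- length(pl$nodes)
  comp <- igraph::components(pl$graph)
  if (max(comp$csize) < size)
    ps_stop("requested size exceeds the largest PPI connected component",
            "unsamplable")
  ok_start <- which(comp$csize[comp$membership] >= size)
  adj <- pl$adj
  lapply(seq_len(n), function(i) {
    idx <- sample_connected_idx(adj, ok_start, size)
    pl$nodes[idx]
  })
}

# internal: one random-walk-grown connected node set (integer indices)
sample_connected_idx <- function(adj, ok_start, size) {
  start <- ok_start[sample.int(length(ok_start), 1L)]
  s <- integer(size)
  s[1] <- start
  frontier <- adj[[start]]
  k <- 1L
  while (k < size) {
    frontier <- frontier[!frontier %in% s[seq_len(k)]]
    if (length(frontier) == 0L) {  # cannot happen if component large enough
      return(sample_connected_idx(adj, ok_start, size))
    }
    nxt <- frontier[sample.int(length(frontier), 1L)]
    k <- k + 1L
    s[k] <- nxt
    frontier <- c(frontier, adj[[nxt]])
  }
  s
}

#' Empirical p-value of a candidate sub-network by resampling
#'
#' Compares the candidate's aggregate score (mean combined node score) with
#' the scores of \code{n_samples} random connected sub-networks of the same
#' size drawn from the PPI layer; p = (1 + #\{null >= observed\}) /
#' (n_samples + 1).
#'
#' @param candidate a \code{subnetwork}.
#' @param net a \code{hetnet} graph.
#' @param node_scores named combined node scores over proteins (see
#'   \code{\link{combined_scores}}).
#' @param n_samples number of null samples (the headline analysis uses
#'   10,000).
#' @return the candidate with \code{empirical_p} attached.
#' @export
empirical_pvalue <- function(candidate, net, node_scores, n_samples = 10000L) {
  if (n_samples < 1) ps_stop("n_samples must be >= 1", "invalid_parameter")
  null_sets <- sample_null_subnetworks(net, candidate$size, n_samples)
  obs <- mean(node_scores[candidate$genes])
  null_scores <- vapply(null_sets, function(gs) mean(node_scores[gs]), 0)
  candidate$empirical_p <- (1 + sum(null_scores >= obs)) / (n_samples + 1)
  candidate
}

#' Combined node scores over protein nodes
#'
#' Product of min-max scaled DE score and min-max scaled RWR probability; a
#' constant component is treated as neutral.
#'
#' @param net a \code{hetnet} graph.
#' @param de_scores \code{\link{score_nodes}} output.
#' @param rwr_scores \code{\link{rwr}} output.
#' @return named numeric vector over protein nodes.
#' @export
combined_scores <- function(net, de_scores, rwr_scores) {
  combined_node_scores(net, de_scores, rwr_scores)
}

#' Filter candidates by empirical p and merge overlapping survivors
#'
#' Candidates with p > \code{alpha} are dropped; surviving candidates that
#' share at least one protein are merged iteratively (union of nodes; the
#' merged p is the minimum of the members). The final list is sorted by p.
#'
#' @param candidates list of \code{subnetwork}s carrying \code{empirical_p}.
#' @param alpha empirical-p threshold (default 0.05).
#' @return list of merged \code{subnetwork}s.
#' @export
filter_and_merge <- function(candidates, alpha = 0.05) {
  keep <- Filter(function(s) !is.na(s$empirical_p) && s$empirical_p <= alpha,
                 candidates)
  if (length(keep) == 0) return(list())
  merged <- keep
  repeat {
    done <- TRUE
    for (i in seq_along(merged)) {
      if (done == FALSE) break
      for (j in seq_along(merged)) {
        if (j <= i) next
        if (length(intersect(merged[[i]]$genes, merged[[j]]$genes)) > 0) {
          a <- merged[[i]]; b <- merged[[j]]
          m <- subnetwork(union(a$genes, b$genes),
                          (a$score * a$size + b$score * b$size) /
                            length(union(a$genes, b$genes)))
          m$empirical_p <- min(a$empirical_p, b$empirical_p)
          merged[[i]] <- m
          merged[[j]] <- NULL
          done <- FALSE
          break
        }
      }
    }
    if (done) break
  }
  merged[order(vapply(merged, function(s) s$empirical_p, 0),
               vapply(merged, function(s) paste(s$genes, collapse = ","), ""))]
}

#' Annotate a sub-network with its top enriched gene set
#'
#' One-sided hypergeometric enrichment of the sub-network's genes in each
#' set over the given universe; the minimum-p set name is attached as the
#' top term (ties broken by set name).
#'
#' @param sub a \code{subnetwork}.
#' @param sets named list of character vectors (GO biological process
#'   style).
#' @param universe character vector of all candidate genes.
#' @return the sub-network with \code{top_go_term} and \code{top_go_p}.
#' @export
annotate_top_go <- function(sub, sets, universe) {
  if (length(sets) == 0) {
    warning("empty gene-set collection; annotation skipped")
    return(sub)
  }
  genes <- intersect(sub$genes, universe)
  n_u <- length(universe)
  ps <- vapply(sets, function(set) {
    set <- intersect(set, universe)
    k <- length(intersect(genes, set))
    phyper(k - 1, length(set), n_u - length(set), length(genes),
           lower.tail = FALSE)
  }, 0)
  ord <- order(ps, names(sets))
  sub$top_go_term <- names(sets)[ord[1]]
  sub$top_go_p <- unname(ps[ord[1]])
  sub
}

#' Phenotype-guided differential sub-network discovery
#'
#' Full stage: DE node scoring, random walk with restart from the seed
#' phenotypes, greedy candidate extraction, empirical resampling p-values,
#' p-filtering with overlap merging, and top gene-set annotation.
#'
#' @param net a \code{hetnet} graph.
#' @param de a \code{de_result}.
#' @param seeds seed phenotype identifiers.
#' @param gene_sets named list of gene sets for annotation (optional).
#' @param max_size maximum initial sub-network size (default 7).
#' @param n_samples null sub-networks per candidate (default 10,000).
#' @param alpha empirical-p threshold (default 0.05).
#' @param restart RWR restart probability (default 0.7).
#' @return list of significant annotated \code{subnetwork}s sorted by p.
#' @export
find_subnetworks <- function(net, de, seeds, gene_sets = NULL, max_size = 7L,
                             n_samples = 10000L, alpha = 0.05, restart = 0.7) {
  prots <- igraph::V(net)$name[igraph::V(net)$type == "protein"]
  de_sc <- score_nodes(de, genes = prots)
  rwr_sc <- rwr(net, seeds, restart = restart)
  comb <- combined_node_scores(net, de_sc, rwr_sc)
  cands <- extract_subnetworks(net, de_sc, rwr_sc, max_size = max_size)
  cands <- lapply(cands, empirical_pvalue, net = net, node_scores = comb,
                  n_samples = n_samples)
  sig <- filter_and_merge(cands, alpha = alpha)
  if (!is.null(gene_sets) && length(sig) > 0)
    sig <- lapply(sig, annotate_top_go, sets = gene_sets, universe = prots)
  sig
}
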