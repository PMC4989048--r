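#' Rank genes within one species by motif-cluster score
#'
#' Descending score order; ties receive the average rank.
#'
#' @param scores named numeric vector of per-gene scores.
#' @return named numeric vector of ranks (1 = best).
#' @export
rank_genes_per_species <- function(scores) {
  rank(-scores, ties.method = "average")
}

#' Robust rank aggregation of per-species rankings
#'
#' For each gene, the normalised ranks across the L lists (genes missing
#' from a list receive normalised rank 1) are sorted ascending; for each
#' k = 1..L the Beta(k, L - k + 1) lower-tail probability of the k-th
#' order statistic is evaluated, and the gene's rho score is L times the
#' minimum of these (a Bonferroni correction over k), clipped to 1. The
#' aggregate ranking ascends by rho.
#'
#' @param rankings list of named rank vectors (1 = best), as produced by
#'   \code{\link{rank_genes_per_species}}.
#' @param universe optional gene universe; defaults to the union of the
#'   ranked genes.
#' @return data.frame with columns \code{gene}, \code{rho}, \code{rank},
#'   sorted ascending by rho (ties by gene id).
#' @export
aggregate_ranks <- function(rankings, universe = NULL) {
  if (length(rankings) == 0) ps_stop("need at least one ranking", "invalid_input")
  if (is.null(universe)) universe <- sort(unique(unlist(lapply(rankings, names))))
  L <- length(rankings)
  rmat <- matrix(1, nrow = length(universe), ncol = L,
                 dimnames = list(universe, NULL))
  for (j in seq_len(L)) {
    r <- rankings[[j]]
    hit <- intersect(names(r), universe)
    rmat[hit, j] <- r[hit] / length(r)
  }
  rho <- apply(rmat, 1, function(r) {
    r <- sort(r)
    min(1, L * min(pbeta(r, seq_len(L), L - seq_len(L) + 1)))
  })
  out <- data.frame(gene = universe, rho = unname(rho),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rho, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' AUC recovery of a gene set within the top of a ranked list
#'
#' Over the top X = ceiling(top_fraction x n) ranks, the area under the
#' cumulative recovery curve: AUC = (1 / (X |set|)) * sum_{i=1..X}
#' |set within the top i|.
#'
#' @param ranking character vector of gene ids in rank order (best first),
#'   or an \code{\link{aggregate_ranks}} data.frame.
#' @param gene_set non-empty character vector.
#' @param top_fraction fraction of the list scanned (default 0.03).
#' @return AUC in [0, 1].
#' @export
auc_recovery <- function(ranking, gene_set, top_fraction = 0.03) {
  if (is.data.frame(ranking)) ranking <- ranking$gene
  if (length(gene_set) == 0) ps_stop("gene_set must be non-empty", "invalid_input")
  if (top_fraction <= 0 || top_fraction > 1)
    ps_stop("top_fraction must lie in (0, 1]", "invalid_parameter")
  n <- length(ranking)
  x <- ceiling(top_fraction * n)
  hits <- ranking[seq_len(x)] %in% gene_set
  sum(cumsum(hits)) / (x * length(unique(gene_set)))
}

#' z-scores of AUC recovery across a motif/TF collection
#'
#' @param aucs named numeric vector of per-motif (or per-TF) AUCs.
#' @param z_cut pass threshold (default 3, inclusive).
#' @return data.frame with columns \code{id}, \code{auc}, \code{z},
#'   \code{pass}. The standardisation uses the population standard
#'   deviation of the collection. A zero standard deviation yields
#'   all-zero z and no pass.
#' @export
motif_zscores <- function(aucs, z_cut = 3) {
  n <- length(aucs)
  if (n < 2) ps_stop("need at least two motifs", "invalid_input")
  s <- sd(aucs) * sqrt((n - 1) / n)
  z <- if (is.na(s) || s == 0) rep(0, length(aucs)) else (aucs - mean(aucs)) / s
  data.frame(id = names(aucs), auc = unname(aucs), z = unname(z),
             pass = unname(z) >= z_cut, stringsAsFactors = FALSE)
}

#' Motif evidence channel
#'
#' Scores every promoter of every pseudo-species against every motif with
#' the windowed cluster score, ranks genes per species, aggregates the
#' species rankings per motif by robust rank aggregation, computes the AUC
#' recovery of the DEG set, and standardises across the motif collection.
#'
#' @param motifs named list of \code{\link{motif_model}}s.
#' @param promoters list per species of named promoter sequences.
#' @param degs DEG identifiers.
#' @param top_fraction AUC recovery fraction (default 0.03).
#' @param window_bp cluster window (default 500).
#' @param z_cut z threshold (default 3).
#' @return list with \code{table} (motif, tf, auc, z, pass) and
#'   \code{rankings} (named list per TF of aggregated ranked gene vectors).
#' @export
motif_channel <- function(motifs, promoters, degs, top_fraction = 0.03,
                          window_bp = 500L, z_cut = 3) {
  concats <- lapply(promoters, function(seqs)
    concat_promoters(lapply(seqs, encode_dna)))
  rankings <- lapply(motifs, function(m) {
    prep <- motif_scan_prepare(m)
    per_species <- lapply(concats, function(cc)
      rank_genes_per_species(score_promoters_batch(prep, cc, window_bp)))
    aggregate_ranks(per_species)$gene
  })
  aucs <- vapply(rankings, auc_recovery, 0, gene_set = degs,
                 top_fraction = top_fraction)
  tab <- motif_zscores(aucs, z_cut = z_cut)
  names(tab)[1] <- "motif"
  tab$tf <- vapply(motifs[tab$motif], function(m) m$tf, "")
  tf_rank <- setNames(rankings[tab$motif], tab$tf)
  list(table = tab[, c("motif", "tf", "auc", "z", "pass")],
       rankings = tf_rank)
}

#' ChIP evidence channel from externally supplied ranked target lists
#'
#' @param chip named list per TF of gene ids in rank order (best first).
#' @param degs DEG identifiers.
#' @param top_fraction,z_cut see \code{\link{motif_channel}}.
#' @return list with \code{table} (tf, auc, z, pass) and \code{rankings}.
#' @export
chip_channel <- function(chip, degs, top_fraction = 0.03, z_cut = 3) {
  aucs <- vapply(chip, auc_recovery, 0, gene_set = degs,
                 top_fraction = top_fraction)
  tab <- motif_zscores(aucs, z_cut = z_cut)
  names(tab)[1] <- "tf"
  list(table = tab, rankings = chip)
}

#' Text-mining evidence channel (hypergeometric)
#'
#' Per TF, the one-sided hypergeometric probability of the observed overlap
#' between its text-mined targets and the DEG set over the universe, BH
#' adjusted across TFs; pass when q <= \code{q_cut}.
#'
#' @param tf_edges data.frame with columns \code{tf}, \code{gene}.
#' @param degs DEG identifiers (subset of universe).
#' @param universe gene universe.
#' @param tfs optional TF identifiers to report (default: those in
#'   \code{tf_edges}); TFs without in-universe targets get p = 1.
#' @param q_cut BH-q pass threshold (default 0.1).
#' @return data.frame with \code{tf}, \code{n_targets}, \code{overlap},
#'   \code{p}, \code{q}, \code{pass}.
#' @export
textmining_channel <- function(tf_edges, degs, universe, tfs = NULL,
                               q_cut = 0.1) {
  if (!all(degs %in% universe))
    ps_stop("degs must be a subset of the universe", "invalid_input")
  if (is.null(tfs)) tfs <- sort(unique(tf_edges$tf))
  n <- length(universe)
  m <- length(unique(degs))
  res <- do.call(rbind, lapply(tfs, function(tf) {
    targets <- intersect(unique(tf_edges$gene[tf_edges$tf == tf]), universe)
    k <- length(intersect(targets, degs))
    p <- if (length(targets) == 0) 1 else
      phyper(k - 1, m, n - m, length(targets), lower.tail = FALSE)
    data.frame(tf = tf, n_targets = length(targets), overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_adjust(res$p)
  res$pass <- res$q <= q_cut
  res
}

#' Coexpression evidence channel
#'
#' For each TF, candidate genes are ranked by descending correlation with
#' the TF; AUC recovery of the DEG set is standardised across the TF
#' collection.
#'
#' @param coexpression symmetric correlation matrix over genes and TFs.
#' @param tfs TF identifiers (rows/columns of the matrix).
#' @param degs DEG identifiers.
#' @param top_fraction,z_cut see \code{\link{motif_channel}}.
#' @return list with \code{table} (tf, auc, z, pass) and \code{rankings}.
#' @export
coexpression_channel <- function(coexpression, tfs, degs, top_fraction = 0.03,
                                 z_cut = 3) {
  missing_tf <- setdiff(tfs, rownames(coexpression))
  if (length(missing_tf) > 0)
    ps_stop(sprintf("TF(s) missing from coexpression matrix: %s",
                    paste(head(missing_tf, 3), collapse = ", ")), "unknown_tf")
  genes <- setdiff(rownames(coexpression), tfs)
  rankings <- lapply(setNames(tfs, tfs), function(tf) {
    r <- coexpression[tf, genes]
    names(sort(r, decreasing = TRUE))
  })
  aucs <- vapply(rankings, auc_recovery, 0, gene_set = degs,
                 top_fraction = top_fraction)
  tab <- motif_zscores(aucs, z_cut = z_cut)
  names(tab)[1] <- "tf"
  list(table = tab, rankings = rankings)
}

#' Integrate evidence channels by the at-least-two rule
#'
#' @param channels named list of per-channel tables, each with columns
#'   \code{tf} and \code{pass} (e.g., motif, chip, textmining,
#'   coexpression).
#' @param min_channels selection threshold (default 2).
#' @return data.frame with \code{tf}, \code{n_pass}, \code{channels}
#'   (comma-joined passing channel names) and \code{selected}.
#' @export
integrate_evidence <- function(channels, min_channels = 2L) {
  tfs <- sort(unique(unlist(lapply(channels, function(d) d$tf))))
  pass_mat <- vapply(names(channels), function(nm) {
    d <- channels[[nm]]
    out <- setNames(rep(FALSE, length(tfs)), tfs)
    out[d$tf] <- d$pass
    out
  }, logical(length(tfs)))
  pass_mat <- matrix(pass_mat, nrow = length(tfs),
                     dimnames = list(tfs, names(channels)))
  n_pass <- rowSums(pass_mat)
  data.frame(tf = tfs, n_pass = unname(n_pass),
             channels = vapply(tfs, function(tf)
               paste(colnames(pass_mat)[pass_mat[tf, ]], collapse = ","), ""),
             selected = unname(n_pass) >= min_channels,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Recover the DEG targets of a selected TF from a ranked list
#'
#' Targets are the DEGs ranked within the top X = ceiling(top_fraction x n)
#' of the TF's ranked target list.
#'
#' @param tf TF identifier.
#' @param ranking character vector of gene ids in rank order (best first).
#' @param degs DEG identifiers.
#' @param top_fraction top fraction (default 0.03).
#' @return list of class \code{regulon}: \code{tf}, \code{targets},
#'   \code{top_genes} (the top-X slice used).
#' @export
recover_targets <- function(tf, ranking, degs, top_fraction = 0.03) {
  if (is.data.frame(ranking)) ranking <- ranking$gene
  x <- ceiling(top_fraction * length(ranking))
  top <- ranking[seq_len(x)]
  structure(list(tf = tf, targets = sort(intersect(top, degs)),
                 top_genes = top), class = "regulon")
}

#' Hypergeometric overlap of regulon targets with sub-network genes
#'
#' One-sided upper-tail hypergeometric probability of the overlap between
#' the union of recovered regulon targets and the genes of the discovered
#' sub-networks, over the gene universe.
#'
#' @param regulons list of \code{\link{recover_targets}} results.
#' @param subnet_genes identifiers of genes in the sub-networks.
#' @param universe gene universe.
#' @return list with \code{p}, \code{overlap}, \code{n_targets},
#'   \code{n_subnet}.
#' @export
tf_pathway_overlap <- function(regulons, subnet_genes, universe) {
  if (length(universe) == 0) ps_stop("universe must be non-empty", "invalid_input")
  targets <- intersect(unique(unlist(lapply(regulons, function(r) r$targets))),
                       universe)
  subnet_genes <- intersect(unique(subnet_genes), universe)
  k <- length(intersect(targets, subnet_genes))
  p <- phyper(k - 1, length(subnet_genes),
              length(universe) - length(subnet_genes), length(targets),
              lower.tail = FALSE)
  list(p = p, overlap = k, n_targets = length(targets),
       n_subnet = length(subnet_genes))
}

#' Full multi-evidence upstream-TF inference stage
#'
#' Runs the four evidence channels on an evidence bundle (see
#' \code{\link{simulate_regulon_evidence}} for the expected shape), selects
#' TFs supported by at least \code{min_channels} channels, and recovers
#' their DEG targets from the best-passing ranked channel. TF-to-TF
#' regulatory edges are emitted when a selected TF appears in the top slice
#' of another selected TF's ranking.
#'
#' @param bundle list with \code{motifs}, \code{promoters}, \code{chip},
#'   \code{textmining}, \code{coexpression}, \code{universe}; any channel
#'   may be NULL to skip it.
#' @param degs DEG identifiers.
#' @param top_fraction,window_bp,z_cut,tm_q channel parameters.
#' @param min_channels selection rule (default 2).
#' @return list with \code{channels} (per-channel tables),
#'   \code{selection}, \code{selected} (TF ids), \code{regulons},
#'   \code{tf_edges} (data.frame from, to).
#' @export
run_regulon <- function(bundle, degs, top_fraction = 0.03, window_bp = 500L,
                        z_cut = 3, tm_q = 0.1, min_channels = 2L) {
  channels <- list()
  rankings <- list()  # per channel, per TF
  zs <- list()
  if (!is.null(bundle$motifs)) {
    mc <- motif_channel(bundle$motifs, bundle$promoters, degs,
                        top_fraction = top_fraction, window_bp = window_bp,
                        z_cut = z_cut)
    channels$motif <- mc$table
    rankings$motif <- mc$rankings
    zs$motif <- setNames(mc$table$z, mc$table$tf)
  }
  if (!is.null(bundle$chip)) {
    cc <- chip_channel(bundle$chip, degs, top_fraction = top_fraction,
                       z_cut = z_cut)
    channels$chip <- cc$table
    rankings$chip <- cc$rankings
    zs$chip <- setNames(cc$table$z, cc$table$tf)
  }
  if (!is.null(bundle$textmining)) {
    channels$textmining <- textmining_channel(bundle$textmining, degs,
                                              bundle$universe,
                                              tfs = bundle$tfs, q_cut = tm_q)
  }
  if (!is.null(bundle$coexpression)) {
    xc <- coexpression_channel(bundle$coexpression, bundle$tfs, degs,
                               top_fraction = top_fraction, z_cut = z_cut)
    channels$coexpression <- xc$table
    rankings$coexpression <- xc$rankings
    zs$coexpression <- setNames(xc$table$z, xc$table$tf)
  }
  selection <- integrate_evidence(channels, min_channels = min_channels)
  selected <- selection$tf[selection$selected]

  regulons <- list()
  for (tf in selected) {
    # best-passing ranked channel; fall back to the best z, then text-mining
    cand <- names(rankings)
    passed <- cand[vapply(cand, function(ch) {
      d <- channels[[ch]]
      isTRUE(d$pass[match(tf, d$tf)])
    }, TRUE)]
    pool <- if (length(passed) > 0) passed else cand
    if (length(pool) > 0) {
      best <- pool[which.max(vapply(pool, function(ch) zs[[ch]][tf], 0))]
      regulons[[tf]] <- recover_targets(tf, rankings[[best]][[tf]], degs,
                                        top_fraction = top_fraction)
    } else {
      tm_targets <- intersect(
        unique(bundle$textmining$gene[bundle$textmining$tf == tf]), degs)
      regulons[[tf]] <- structure(list(tf = tf, targets = sort(tm_targets),
                                       top_genes = character(0)),
                                  class = "regulon")
    }
  }
  tf_edges <- do.call(rbind, lapply(selected, function(tf) {
    hit <- intersect(selected, regulons[[tf]]$top_genes)
    if (length(hit) == 0) return(NULL)
    data.frame(from = tf, to = hit, stringsAsFactors = FALSE)
  }))
  if (is.null(tf_edges))
    tf_edges <- data.frame(from = character(0), to = character(0))
  list(channels = channels, selection = selection, selected = selected,
       regulons = regulons, tf_edges = tf_edges)
}
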