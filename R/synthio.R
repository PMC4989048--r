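#' Configuration for the paired-count simulator
#'
#' The generator emulates an eight-patient paired two-site RNA-seq design:
#' each patient contributes one damaged (DMC) and one intact (PLC) sample.
#' Counts are negative binomial with a gene-level log-normal baseline, a
#' per-patient scalar effect shared by both samples of a patient (which is
#' what makes the paired covariate necessary downstream), a planted site
#' effect on differentially expressed genes, and a planted batch shift on a
#' subset of genes.
#'
#' @param n_patients number of patients (>= 2); each gives two samples.
#' @param n_genes number of genes.
#' @param de_fraction proportion of genes carrying a true site effect.
#' @param de_log2fc_mean magnitude (log2 units) of the planted site effect;
#'   the sign of each DE gene is random.
#' @param dispersion_range length-2 positive numeric; per-gene NB dispersion
#'   alpha (Var = mu + alpha mu^2) is drawn uniformly from this range. The
#'   default c(0.01, 0.2) is the residual (within-patient) dispersion left
#'   after the patient effect, spanning technical to moderate biological
#'   variability (biological CV roughly 10-45 percent).
#' @param batch_gene_fraction proportion of genes shifted in the second batch.
#' @param batch_log2_shift magnitude (log2 units) of the batch shift.
#' @param library_size_range length-2 numeric; per-sample target library
#'   sizes (total counts) are drawn uniformly from this range.
#' @param patient_effect_sdlog sdlog of the per-patient log-normal scalar;
#'   0 disables the patient effect.
#' @param baseline_meanlog,baseline_sdlog parameters of the log-normal
#'   baseline mean distribution.
#' @param seed integer seed making the generator a pure function.
#'
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_patients = 8L, n_genes = 2000L, de_fraction = 0.1,
                       de_log2fc_mean = 1, dispersion_range = c(0.01, 0.2),
                       batch_gene_fraction = 0.2, batch_log2_shift = 1,
                       library_size_range = c(1e6, 2e6),
                       patient_effect_sdlog = 0.3,
                       baseline_meanlog = 4, baseline_sdlog = 2,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
              de_fraction = de_fraction, de_log2fc_mean = de_log2fc_mean,
              dispersion_range = dispersion_range,
              batch_gene_fraction = batch_gene_fraction,
              batch_log2_shift = batch_log2_shift,
              library_size_range = library_size_range,
              patient_effect_sdlog = patient_effect_sdlog,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog, seed = as.integer(seed))
  if (cfg$n_patients < 2L || cfg$n_genes < 1L)
    ps_stop("n_patients must be >= 2 and n_genes >= 1", "invalid_config")
  props <- c(cfg$de_fraction, cfg$batch_gene_fraction)
  if (any(props < 0) || any(props > 1))
    ps_stop("proportions must lie in [0, 1]", "invalid_config")
  if (any(cfg$dispersion_range <= 0))
    ps_stop("dispersion_range must be strictly positive", "invalid_config")
  if (any(cfg$library_size_range <= 0))
    ps_stop("library_size_range must be strictly positive", "invalid_config")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a paired two-site RNA-seq count matrix with planted truth
#'
#' @param config a \code{\link{sim_config}}.
#'
#' @return A list with elements \code{counts} (a \code{\link{count_matrix}})
#'   and \code{truth}, a data.frame with per-gene columns \code{gene},
#'   \code{is_de}, \code{true_log2fc} (site effect, damaged vs intact) and
#'   \code{is_batch_affected}.
#' @export
simulate_paired_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes; np <- config$n_patients
  genes <- sprintf("GENE%05d", seq_len(ng))
  patients <- sprintf("P%02d", seq_len(np))

  # per-gene baseline means and dispersions
  mu0 <- rlnorm(ng, meanlog = config$baseline_meanlog, sdlog = config$baseline_sdlog)
  alpha <- runif(ng, config$dispersion_range[1], config$dispersion_range[2])

  # planted truth
  n_de <- round(config$de_fraction * ng)
  de_idx <- if (n_de > 0) sort(sample.int(ng, n_de)) else integer(0)
  lfc <- numeric(ng)
  if (n_de > 0)
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$de_log2fc_mean
  n_batch <- round(config$batch_gene_fraction * ng)
  batch_idx <- if (n_batch > 0) sort(sample.int(ng, n_batch)) else integer(0)
  is_batch_gene <- seq_len(ng) %in% batch_idx

  # design: two samples per patient; batch assigned by patient (A/B halves)
  meta <- data.frame(
    sample = as.vector(t(outer(patients, c("DMC", "PLC"), paste, sep = "_"))),
    patient = rep(patients, each = 2L),
    site = rep(c("DMC", "PLC"), np),
    batch = rep(ifelse(seq_len(np) <= ceiling(np / 2), "A", "B"), each = 2L),
    stringsAsFactors = FALSE)

  pat_eff <- rlnorm(np, meanlog = 0, sdlog = config$patient_effect_sdlog)
  names(pat_eff) <- patients

  # expected count matrix before library scaling
  mu <- matrix(mu0, nrow = ng, ncol = nrow(meta))
  for (j in seq_len(nrow(meta))) {
    m <- mu[, j] * pat_eff[meta$patient[j]]
    if (meta$site[j] == "DMC") m <- m * 2^lfc
    if (meta$batch[j] == "B") m[is_batch_gene] <- m[is_batch_gene] * 2^config$batch_log2_shift
    mu[, j] <- m
  }
  lib_target <- runif(nrow(meta), config$library_size_range[1],
                      config$library_size_range[2])
  mu <- sweep(mu, 2, lib_target / colSums(mu), `*`)

  counts <- matrix(rnbinom(length(mu), mu = mu, size = rep(1 / alpha, ncol(mu))),
                   nrow = ng, dimnames = list(genes, meta$sample))

  truth <- data.frame(gene = genes, is_de = lfc != 0, true_log2fc = lfc,
                      is_batch_affected = is_batch_gene,
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(counts, meta), truth = truth)
}

#' Simulate a heterogeneous gene-phenotype network with a planted module
#'
#' Builds a preferential-attachment protein-protein interaction (PPI) layer
#' (heavy-tailed degrees), a shallow balanced-tree phenotype layer, and
#' protein-phenotype annotation bridges. A connected PPI subgraph of
#' \code{module_size} proteins is planted as the disease module: its members
#' are annotated to the designated seed phenotypes and flagged in the truth.
#'
#' @param n_proteins number of protein nodes.
#' @param n_phenotypes number of phenotype nodes (tree layer).
#' @param module_size size of the planted module (<= n_proteins).
#' @param seed integer seed.
#' @param n_seeds number of seed phenotypes to designate (default 4,
#'   matching a four-anchor disease phenotype panel; capped at
#'   n_phenotypes).
#' @param annotation_prob probability that a non-module protein receives a
#'   random phenotype annotation (background bridges).
#' @param n_gene_sets number of random GO-like gene sets to emit alongside
#'   one set built over the planted module.
#'
#' @return list(net = \code{hetnet}, truth = list(module, seed_phenotypes),
#'   gene_sets = named list of character vectors (universe = all proteins)).
#' @export
simulate_hetnet <- function(n_proteins, n_phenotypes, module_size, seed = 1L,
                            n_seeds = 4L, annotation_prob = 0.1,
                            n_gene_sets = 10L) {
  if (module_size > n_proteins)
    ps_stop("module_size must not exceed n_proteins", "invalid_config")
  if (module_size < 1L || n_proteins < 1L || n_phenotypes < 1L)
    ps_stop("n_proteins, n_phenotypes, module_size must be positive", "invalid_config")
  set.seed(seed)
  proteins <- sprintf("GENE%05d", seq_len(n_proteins))
  phenos <- sprintf("PH:%07d", seq_len(n_phenotypes))
  n_seeds <- min(n_seeds, n_phenotypes)

  g <- igraph::sample_pa(n_proteins, power = 1, m = min(2, n_proteins - 1),
                         directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- proteins
  ppi_el <- igraph::as_edgelist(g)
  ppi <- data.frame(from = ppi_el[, 1], to = ppi_el[, 2], weight = 1,
                    stringsAsFactors = FALSE)

  # planted module: random-walk growth guarantees a connected induced subgraph
  adj <- igraph::as_adj_list(g)
  start <- sample.int(n_proteins, 1L)
  mod <- start
  while (length(mod) < module_size) {
    frontier <- setdiff(unique(unlist(lapply(adj[mod], as.integer))), mod)
    if (length(frontier) == 0L) {  # component exhausted; jump to a new start
      frontier <- setdiff(seq_len(n_proteins), mod)
      # connect the jump target to the module to keep it connected
      tgt <- frontier[sample.int(length(frontier), 1L)]
      ppi <- rbind(ppi, data.frame(from = proteins[mod[length(mod)]],
                                   to = proteins[tgt], weight = 1))
      mod <- c(mod, tgt)
    } else {
      mod <- c(mod, frontier[sample.int(length(frontier), 1L)])
    }
  }
  module <- sort(proteins[mod])

  # phenotype layer: balanced tree of depth ~2
  children <- max(2L, ceiling(sqrt(n_phenotypes)))
  tr <- igraph::make_tree(n_phenotypes, children = children, mode = "undirected")
  igraph::V(tr)$name <- phenos
  pheno <- if (igraph::ecount(tr) > 0) {
    el <- igraph::as_edgelist(tr)
    data.frame(from = el[, 1], to = el[, 2], weight = 1, stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0), weight = numeric(0))

  # seed phenotypes: leaf-most terms
  seed_phenos <- rev(phenos)[seq_len(n_seeds)]

  # bridges: module genes annotated to seed phenotypes; background noise
  bridges <- data.frame(from = module,
                        to = seed_phenos[1 + (seq_along(module) - 1) %% n_seeds],
                        weight = 1, stringsAsFactors = FALSE)
  bg <- setdiff(proteins, module)
  keep <- runif(length(bg)) < annotation_prob
  if (any(keep))
    bridges <- rbind(bridges, data.frame(
      from = bg[keep], to = sample(phenos, sum(keep), replace = TRUE),
      weight = 1, stringsAsFactors = FALSE))

  net <- build_heterogeneous_network(ppi, pheno, bridges, expressed = proteins)

  # GO-like sets: one over the planted module plus random background sets
  sets <- list(GO_PLANTED_MODULE = unique(c(module,
    sample(bg, min(3L, length(bg))))))
  for (i in seq_len(n_gene_sets)) {
    sets[[sprintf("GO_RANDOM_%03d", i)]] <-
      sort(sample(proteins, min(n_proteins, sample(10:30, 1L))))
  }

  list(net = net,
       truth = list(module = module, seed_phenotypes = seed_phenos),
       gene_sets = sets)
}

#' Simulate a multi-channel regulatory-evidence bundle with planted regulons
#'
#' Emulates the four evidence sources used for upstream-TF inference:
#' (a) position weight matrices plus promoter sequences over several
#' pseudo-species, with exact consensus motif instances planted in
#' true-target promoters; (b) per-TF ranked target lists in which true
#' targets are rank-enriched (ChIP channel); (c) TF-to-gene text-mining
#' edges covering true targets plus noise; and (d) a coexpression matrix
#' with elevated TF-target correlation.
#'
#' @param n_tfs number of transcription factors (motif collection size).
#' @param n_genes number of genes in the universe.
#' @param planted_tf_count number of TFs given a true regulon.
#' @param targets_per_tf number of true targets per planted TF.
#' @param seed integer seed.
#' @param n_species number of pseudo-species promoter sets.
#' @param promoter_length promoter length in bp (default 2200, i.e., a
#'   2000 bp upstream + 200 bp downstream TSS window).
#' @param motif_width PWM width in bp.
#' @param conservation probability a true-target promoter carries a planted
#'   consensus instance in a given species.
#' @param chip_strength score boost given to true targets in the ChIP
#'   ranking (units of the standard normal noise).
#' @param tm_coverage fraction of true targets covered by text-mining edges.
#' @param coexpr_strength latent-factor loading of true targets on their
#'   TF's expression profile.
#' @param deg_extra_fraction size of the non-target DEG padding, as a
#'   fraction of the number of true-target DEGs.
#' @param null_deg_factor when no regulon is planted, the DEG list is a
#'   random gene set of the size a signal configuration with this many
#'   planted regulons would produce, so the no-signal configuration
#'   differs from the signal one only in the absence of planted structure
#'   (default 4, the study's TF count).
#'
#' @return list(bundle, truth). \code{bundle} has elements \code{motifs}
#'   (list of \code{\link{motif_model}}), \code{promoters} (list per
#'   species of named character vectors), \code{chip} (list per TF of
#'   ranked gene ids, best first), \code{textmining} (data.frame tf, gene),
#'   \code{coexpression} (correlation matrix over genes and TFs),
#'   \code{degs} (character), \code{universe} (character), \code{tfs}
#'   (character). \code{truth} has \code{tfs} (planted TF ids) and
#'   \code{targets} (named list of true target sets).
#' @export
simulate_regulon_evidence <- function(n_tfs, n_genes, planted_tf_count,
                                      targets_per_tf, seed = 1L,
                                      n_species = 3L, promoter_length = 2200L,
                                      motif_width = 8L, conservation = 0.8,
                                      chip_strength = 3, tm_coverage = 0.8,
                                      coexpr_strength = 0.8,
                                      deg_extra_fraction = 0.5,
                                      null_deg_factor = 4) {
  if (planted_tf_count > n_tfs)
    ps_stop("planted_tf_count must not exceed n_tfs", "invalid_config")
  if (targets_per_tf > n_genes)
    ps_stop("targets_per_tf must not exceed n_genes", "invalid_config")
  set.seed(seed)
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  planted <- tfs[seq_len(planted_tf_count)]

  targets <- lapply(setNames(planted, planted), function(tf)
    sort(sample(genes, targets_per_tf)))

  # (a) motifs and promoters with planted consensus instances
  bases <- c("A", "C", "G", "T")
  motifs <- lapply(setNames(tfs, paste0("M_", tfs)), function(tf) {
    cons <- sample(bases, motif_width, replace = TRUE)
    pwm <- matrix(0.03, nrow = 4, ncol = motif_width,
                  dimnames = list(bases, NULL))
    for (j in seq_len(motif_width)) pwm[cons[j], j] <- 0.91
    motif_model(id = paste0("M_", tf), pwm = pwm, tf = tf)
  })
  consensus <- vapply(motifs, function(m)
    paste(rownames(m$pwm)[apply(m$pwm, 2, which.max)], collapse = ""), "")
  names(consensus) <- vapply(motifs, function(m) m$tf, "")

  promoters <- lapply(seq_len(n_species), function(sp) {
    seqs <- vapply(seq_len(n_genes), function(i)
      paste(sample(bases, promoter_length, replace = TRUE), collapse = ""), "")
    names(seqs) <- genes
    for (tf in planted) {
      ins <- consensus[[tf]]
      for (gn in targets[[tf]]) {
        if (runif(1) > conservation) next
        n_copies <- sample(1:2, 1L)
        for (k in seq_len(n_copies)) {
          s <- if (runif(1) < 0.5) ins else revcomp(ins)
          pos <- sample.int(promoter_length - motif_width + 1L, 1L)
          substr(seqs[[gn]], pos, pos + motif_width - 1L) <- s
        }
      }
    }
    seqs
  })
  names(promoters) <- sprintf("species%d", seq_len(n_species))

  # (b) ChIP channel: ranked lists with rank-enriched true targets
  chip <- lapply(setNames(tfs, tfs), function(tf) {
    sc <- rnorm(n_genes)
    names(sc) <- genes
    if (tf %in% planted) sc[targets[[tf]]] <- sc[targets[[tf]]] + chip_strength
    names(sort(sc, decreasing = TRUE))
  })

  # (c) text-mining TF->gene edges: covered true targets plus uniform noise
  tm <- do.call(rbind, lapply(tfs, function(tf) {
    covered <- if (tf %in% planted) {
      t0 <- targets[[tf]]
      t0[runif(length(t0)) < tm_coverage]
    } else character(0)
    noise <- sample(genes, max(1L, round(0.5 * targets_per_tf)))
    data.frame(tf = tf, gene = unique(c(covered, noise)),
               stringsAsFactors = FALSE)
  }))

  # (d) coexpression over genes + TFs via latent factors
  m <- 30L
  expr <- matrix(rnorm((n_genes + n_tfs) * m), ncol = m,
                 dimnames = list(c(genes, tfs), NULL))
  for (tf in planted) {
    z <- rnorm(m)
    expr[tf, ] <- z + 0.3 * rnorm(m)
    expr[targets[[tf]], ] <- coexpr_strength * matrix(z, nrow = targets_per_tf,
                                                      ncol = m, byrow = TRUE) +
      sqrt(1 - coexpr_strength^2) * matrix(rnorm(targets_per_tf * m), ncol = m)
  }
  coexpression <- cor(t(expr))

  true_degs <- sort(unique(unlist(targets)))
  n_extra <- if (planted_tf_count > 0) {
    max(1L, round(deg_extra_fraction * length(true_degs)))
  } else {
    # no-signal configuration: a DEG list of the size a signal run with
    # null_deg_factor regulons would give, with no structure behind it
    max(1L, round((1 + deg_extra_fraction) * targets_per_tf * null_deg_factor))
  }
  extra <- sample(setdiff(genes, true_degs), min(n_extra, n_genes - length(true_degs)))
  degs <- sort(unique(c(true_degs, extra)))

  bundle <- list(motifs = motifs, promoters = promoters, chip = chip,
                 textmining = tm, coexpression = coexpression,
                 degs = degs, universe = genes, tfs = tfs)
  list(bundle = bundle, truth = list(tfs = planted, targets = targets,
                                     degs = degs))
}
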