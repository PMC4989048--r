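#' Pipeline configuration
#'
#' Collects the stage toggles, thresholds and paths of the end-to-end
#' analysis. Defaults carry the headline parameters: 10 percent FDR and
#' 1.5-fold DEG thresholds, one unwanted-variation factor, maximum initial
#' sub-network size 7, 10,000 null sub-networks at an empirical-p threshold
#' of 0.05, AUC-recovery top fraction 0.03 with z >= 3 and text-mining
#' BH q <= 0.1, and the at-least-two-channel TF selection rule. Every
#' stochastic stage draws a sub-seed derived from the master seed.
#'
#' @param input_dir directory of input files (see
#'   \code{\link{write_sim_inputs}} for the layout).
#' @param out_dir output directory.
#' @param stages character subset of c("de", "subnet", "regulon") to run.
#' @param fdr,fc,ruv_k,min_mean_norm_count DE-stage parameters.
#' @param max_size,nulls,alpha_subnet,restart sub-network-stage parameters.
#' @param top_fraction,z_cut,tm_q,min_channels regulon-stage parameters.
#' @param seed master seed.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            stages = c("de", "subnet", "regulon"),
                            fdr = 0.10, fc = 1.5, ruv_k = 1L,
                            min_mean_norm_count = 1,
                            max_size = 7L, nulls = 10000L,
                            alpha_subnet = 0.05, restart = 0.7,
                            top_fraction = 0.03, z_cut = 3, tm_q = 0.1,
                            min_channels = 2L, seed = 1L) {
  stopifnot(fdr > 0, fdr <= 1, fc >= 1, alpha_subnet > 0, alpha_subnet <= 1,
            max_size >= 1, nulls >= 1, top_fraction > 0, top_fraction <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write a simulated input bundle to a directory
#'
#' Materialises the outputs of the three synthetic generators in the
#' standard formats consumed by \code{\link{run_pipeline}}: counts and
#' metadata TSVs, edge-list TSVs, a seed-phenotype list, a GMT gene-set
#' collection, a MEME motif file, per-species promoter FASTAs, ChIP /
#' text-mining / coexpression TSVs, and the planted truth as JSON.
#'
#' @param dir target directory (created if needed).
#' @param sim a \code{\link{simulate_paired_counts}} result.
#' @param hetsim a \code{\link{simulate_hetnet}} result.
#' @param regsim a \code{\link{simulate_regulon_evidence}} result
#'   (optional).
#' @return \code{dir}, invisibly.
#' @export
write_sim_inputs <- function(dir, sim, hetsim, regsim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_counts_tsv(sim$counts, fp("counts.tsv"))
  write_metadata_tsv(sim$counts$meta, fp("meta.tsv"))
  jsonlite::write_json(sim$truth, fp("truth_counts.json"), auto_unbox = TRUE,
                       digits = NA)

  net <- hetsim$net
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("from", "to")
  for (ly in unique(el$layer))
    write_edges_tsv(el[el$layer == ly, ],
                    fp(c(ppi = "ppi.tsv", pheno_pheno = "pheno.tsv",
                         protein_pheno = "bridges.tsv")[[ly]]), layer = ly)
  writeLines(hetsim$truth$seed_phenotypes, fp("seeds.txt"))
  write_gmt(hetsim$gene_sets, fp("sets.gmt"))
  jsonlite::write_json(hetsim$truth, fp("truth_network.json"),
                       auto_unbox = TRUE, digits = NA)

  if (!is.null(regsim)) {
    b <- regsim$bundle
    write_meme(b$motifs, fp("motifs.meme"))
    for (sp in names(b$promoters))
      write_fasta(b$promoters[[sp]], fp(sprintf("promoters_%s.fasta", sp)))
    chip <- do.call(rbind, lapply(names(b$chip), function(tf)
      data.frame(tf = tf, gene = b$chip[[tf]],
                 rank = seq_along(b$chip[[tf]]), stringsAsFactors = FALSE)))
    write.table(chip, fp("chip.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(b$textmining, fp("textmine.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(id = rownames(b$coexpression), b$coexpression,
                           check.names = FALSE),
                fp("coexpr.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(b$tfs, fp("tfs.txt"))
    jsonlite::write_json(regsim$truth, fp("truth_regulon.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

# internal: read an evidence bundle from the standard layout
read_evidence_bundle <- function(dir) {
  fp <- function(x) file.path(dir, x)
  motifs <- read_meme(fp("motifs.meme"))
  prom_files <- sort(list.files(dir, pattern = "^promoters_.*\\.fasta$"))
  promoters <- lapply(prom_files, function(f) read_fasta(file.path(dir, f)))
  names(promoters) <- sub("^promoters_(.*)\\.fasta$", "\\1", prom_files)
  chip_df <- read.delim(fp("chip.tsv"), stringsAsFactors = FALSE)
  chip <- lapply(split(chip_df, chip_df$tf), function(d)
    d$gene[order(d$rank)])
  textmining <- read.delim(fp("textmine.tsv"), stringsAsFactors = FALSE)
  cx <- read.delim(fp("coexpr.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  coexpression <- as.matrix(cx[, -1, drop = FALSE])
  rownames(coexpression) <- cx$id
  tfs <- readLines(fp("tfs.txt"))
  universe <- setdiff(rownames(coexpression), tfs)
  list(motifs = motifs, promoters = promoters, chip = chip,
       textmining = textmining, coexpression = coexpression,
       tfs = tfs, universe = universe)
}

# internal: run the regulon stage separately on up and down DEGs and
# union-report selection and recovered targets.
run_regulon_updown <- function(bundle, up, down, top_fraction = 0.03,
                               window_bp = 500L, z_cut = 3, tm_q = 0.1,
                               min_channels = 2L) {
  runs <- list()
  if (length(up) > 0)
    runs$up <- run_regulon(bundle, up, top_fraction = top_fraction,
                           window_bp = window_bp, z_cut = z_cut, tm_q = tm_q,
                           min_channels = min_channels)
  if (length(down) > 0)
    runs$down <- run_regulon(bundle, down, top_fraction = top_fraction,
                             window_bp = window_bp, z_cut = z_cut,
                             tm_q = tm_q, min_channels = min_channels)
  selected <- sort(unique(unlist(lapply(runs, function(r) r$selected))))
  regulons <- list()
  for (tf in selected) {
    targets <- sort(unique(unlist(lapply(runs, function(r)
      if (tf %in% names(r$regulons)) r$regulons[[tf]]$targets else NULL))))
    top_genes <- unique(unlist(lapply(runs, function(r)
      if (tf %in% names(r$regulons)) r$regulons[[tf]]$top_genes else NULL)))
    regulons[[tf]] <- structure(list(tf = tf, targets = targets,
                                     top_genes = top_genes),
                                class = "regulon")
  }
  tf_edges <- unique(do.call(rbind, c(lapply(runs, function(r) r$tf_edges),
                                      make.row.names = FALSE)))
  if (is.null(tf_edges))
    tf_edges <- data.frame(from = character(0), to = character(0))
  list(runs = runs, selected = selected, regulons = regulons,
       tf_edges = tf_edges)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the toggled stages (differential expression, sub-network
#' discovery, regulon inference) on a directory of standard-format inputs,
#' writes per-stage result files plus a machine-readable JSON report to the
#' output directory, and returns the report. Identical configuration and
#' seed reproduce identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the run report (list), invisibly written to
#'   \code{report.json}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  op <- function(x) file.path(config$out_dir, x)
  report <- list(package_version =
                   as.character(utils::packageVersion("phenosubnet")),
                 parameters = config[setdiff(names(config),
                                             c("input_dir", "out_dir"))],
                 stages = list())
  fp <- function(x) file.path(config$input_dir, x)

  degs <- NULL
  expressed <- NULL
  if ("de" %in% config$stages) {
    m <- read_counts_tsv(fp("counts.tsv"))
    meta <- read_metadata_tsv(fp("meta.tsv"))
    cm <- count_matrix(m, meta)
    res <- run_paired_de(cm, fdr = config$fdr, fc = config$fc,
                         ruv_k = config$ruv_k,
                         min_mean_norm_count = config$min_mean_norm_count)
    write_de_tsv(res$de, op("de.tsv"))
    writeLines(res$degs$up, op("degs_up.txt"))
    writeLines(res$degs$down, op("degs_down.txt"))
    degs <- res$degs
    expressed <- res$de$gene
    de_full <- res$de
    report$stages$de <- list(n_analysed = res$n_analysed,
                             n_up = res$summary$n_up,
                             n_down = res$summary$n_down,
                             n_total = res$summary$n_total,
                             pct_up = res$summary$pct_up,
                             pct_down = res$summary$pct_down)
  }

  if ("subnet" %in% config$stages) {
    if (is.null(degs)) ps_stop("subnet stage requires the de stage", "stage_error")
    ppi <- read_edges_tsv(fp("ppi.tsv"))
    pheno <- read_edges_tsv(fp("pheno.tsv"))
    bridges <- read_edges_tsv(fp("bridges.tsv"))
    seeds <- readLines(fp("seeds.txt"))
    sets <- if (file.exists(fp("sets.gmt"))) read_gmt(fp("sets.gmt")) else NULL
    net <- build_heterogeneous_network(ppi, pheno, bridges,
                                       expressed = expressed)
    set.seed(config$seed + 1L)
    subs <- find_subnetworks(net, de_full, seeds, gene_sets = sets,
                             max_size = config$max_size,
                             n_samples = config$nulls,
                             alpha = config$alpha_subnet,
                             restart = config$restart)
    write_subnetworks_tsv(subs, op("subnetworks.tsv"))
    subnet_genes <- unique(unlist(lapply(subs, function(s) s$genes)))
    report$stages$subnet <- list(
      n_candidates_significant = length(subs),
      sizes = vapply(subs, function(s) s$size, 0L),
      n_genes = length(subnet_genes))
  }

  if ("regulon" %in% config$stages) {
    if (is.null(degs)) ps_stop("regulon stage requires the de stage", "stage_error")
    bundle <- read_evidence_bundle(config$input_dir)
    set.seed(config$seed + 2L)
    reg <- run_regulon_updown(bundle, up = intersect(degs$up, bundle$universe),
                              down = intersect(degs$down, bundle$universe),
                              top_fraction = config$top_fraction,
                              z_cut = config$z_cut, tm_q = config$tm_q,
                              min_channels = config$min_channels)
    write_regulon_json(list(selected = reg$selected,
                            selection = if (!is.null(reg$runs$up))
                              reg$runs$up$selection else reg$runs$down$selection,
                            regulons = reg$regulons,
                            tf_edges = reg$tf_edges), op("regulon.json"))
    n_regulated <- length(unique(unlist(lapply(reg$regulons,
                                               function(r) r$targets))))
    report$stages$regulon <- list(selected = reg$selected,
                                  n_selected = length(reg$selected),
                                  n_deg_targets = n_regulated)
    if ("subnet" %in% config$stages &&
        report$stages$subnet$n_genes > 0 && length(reg$regulons) > 0) {
      ov <- tf_pathway_overlap(reg$regulons, subnet_genes,
                               universe = expressed)
      report$stages$regulon$subnet_overlap_p <- ov$p
    }
  }

  jsonlite::write_json(report, op("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
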