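#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median, over genes with
#' strictly positive counts in every sample, of the ratio of the gene's
#' count to its across-sample geometric mean.
#'
#' @param counts a \code{\link{count_matrix}} or a numeric matrix.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors_median_of_ratios <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref))
    ps_stop("no gene has positive counts in every sample; size factors unestimable",
            "unestimable_factor")
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - loggeo)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    ps_stop("non-finite or non-positive size factor", "unestimable_factor")
  sf
}

#' Remove genes with low mean normalised counts
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param min_mean_norm_count keep genes whose mean normalised count is at
#'   least this threshold (inclusive). Gene order is preserved.
#' @return a filtered \code{\link{count_matrix}}.
#' @export
filter_low_expression <- function(counts, min_mean_norm_count) {
  if (min_mean_norm_count < 0)
    ps_stop("min_mean_norm_count must be non-negative", "invalid_parameter")
  sf <- size_factors_median_of_ratios(counts)
  norm <- sweep(counts$counts, 2, sf, `/`)
  keep <- rowMeans(norm) >= min_mean_norm_count
  count_matrix(counts$counts[keep, , drop = FALSE], counts$meta)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted p-values (q-values), clipped to 1, order-preserving.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    ps_stop("p-values must lie in [0, 1]", "invalid_parameter")
  p.adjust(p_values, method = "BH")
}

#' Select in-silico negative-control genes from a first-pass fit
#'
#' Removes the \code{n_exclude} genes with the smallest first-pass p-values
#' and returns the remainder as negative controls for unwanted-variation
#' factor estimation. Ties and missing p-values (ranked last) are broken by
#' gene identifier.
#'
#' @param first_pass a \code{\link{nb_wald_paired_test}} result.
#' @param n_exclude number of most-significant genes to remove (default
#'   5000).
#' @return character vector of control gene identifiers.
#' @export
select_control_genes <- function(first_pass, n_exclude = 5000L) {
  genes <- first_pass$gene
  if (n_exclude >= length(genes))
    ps_stop("n_exclude must be smaller than the number of genes", "invalid_parameter")
  if (n_exclude < 0) ps_stop("n_exclude must be non-negative", "invalid_parameter")
  p <- first_pass$pvalue
  p[is.na(p)] <- Inf
  ord <- order(p, genes)
  sort(genes[ord][seq(n_exclude + 1L, length(genes))])
}

#' Estimate unwanted-variation factors from control genes
#'
#' Computes the first \code{k} left-singular directions of the row-centred
#' (per-gene) log2 normalised control-gene counts, oriented so the scores
#' are per sample, in the spirit of control-gene factor analysis for batch
#' correction.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param controls character vector of control gene ids (subset of rows).
#' @param k number of factors (>= 1).
#' @param pseudocount added before the log transform (default 0.5).
#' @return list with \code{w} (samples x k score matrix), \code{k},
#'   \code{control_gene_ids}.
#' @export
estimate_unwanted_factors <- function(counts, controls, k = 1L,
                                      pseudocount = 0.5) {
  if (k < 1) ps_stop("k must be >= 1", "invalid_parameter")
  if (length(controls) == 0) ps_stop("controls must be non-empty", "invalid_parameter")
  if (!all(controls %in% rownames(counts$counts)))
    ps_stop("controls must be a subset of the count matrix genes", "invalid_parameter")
  if (k > min(ncol(counts$counts), length(controls)))
    ps_stop("k exceeds min(samples, controls)", "invalid_parameter")
  sf <- size_factors_median_of_ratios(counts)
  z <- log2(sweep(counts$counts[controls, , drop = FALSE], 2, sf, `/`) + pseudocount)
  zc <- z - rowMeans(z)
  sv <- svd(t(zc), nu = k, nv = 0)
  w <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  dimnames(w) <- list(colnames(counts$counts), paste0("W", seq_len(k)))
  list(w = w, k = as.integer(k), control_gene_ids = controls,
       singular_values = sv$d)
}

# internal: per-gene dispersion by the Pearson moment equation after a
# Poisson first fit -- solve sum((y - mu)^2 / (mu + a mu^2)) = n - p for a
# -- shrunk 50/50 (linear) toward a smooth a0 + a1/mu trend fitted on
# binned 10%-trimmed means. The linear shrink keeps a floor of half the
# trend for the many near-zero per-gene estimates at this sample size.
estimate_dispersions <- function(counts, design, offset, base_mean) {
  ng <- nrow(counts)
  n <- ncol(counts)
  p <- qr(design)$rank
  df_resid <- max(n - p, 1)
  alpha_g <- rep(NA_real_, ng)
  for (g in seq_len(ng)) {
    y <- counts[g, ]
    if (all(y == 0)) next
    fit <- tryCatch(suppressWarnings(glm.fit(design, y,
                                             family = stats::poisson(),
                                             offset = offset)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    mu <- pmax(fit$fitted.values, 1e-8)
    f <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - df_resid
    alpha_g[g] <- if (f(0) <= 0) 1e-8
      else if (f(50) > 0) 50
      else stats::uniroot(f, c(0, 50))$root
  }
  usable <- which(!is.na(alpha_g) & base_mean > 0)
  trend <- rep(if (length(usable)) median(alpha_g[usable]) else 0.1, ng)
  if (length(usable) >= 40) {
    bins <- cut(rank(base_mean[usable], ties.method = "first"),
                breaks = 20, labels = FALSE)
    bm <- tapply(base_mean[usable], bins, median)
    ba <- tapply(alpha_g[usable], bins, mean, trim = 0.1)
    fit <- tryCatch(lm(ba ~ I(1 / bm)), error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(coef(fit)))) {
      a0 <- max(coef(fit)[1], 1e-6)
      a1 <- max(coef(fit)[2], 0)
      trend <- a0 + a1 / pmax(base_mean, 1e-8)
    }
  }
  alpha <- (pmax(alpha_g, 1e-8) + pmax(trend, 1e-8)) / 2
  alpha[is.na(alpha)] <- median(alpha, na.rm = TRUE)
  pmin(pmax(alpha, 1e-8), 10)
}

#' Paired negative-binomial Wald test for a two-site design
#'
#' Fits, per gene, a negative-binomial log-linear model with an intercept,
#' patient indicators, the site indicator (damaged vs intact), and optional
#' unwanted-variation covariates; the log library-size factor enters as an
#' offset. Gene-level dispersions are per-gene moment estimates shrunk
#' 50/50 toward a smooth mean-dispersion trend. The site coefficient is
#' tested with a Wald statistic referred to a t distribution with
#' moderated degrees of freedom equal to residual plus prior df; with the
#' equal-weight dispersion shrinkage the prior contributes as much
#' information as the data, giving 2 (n - p) df. P-values are BH adjusted.
#'
#' @param counts a \code{\link{count_matrix}} with a valid paired design.
#' @param sf size factors; computed with
#'   \code{\link{size_factors_median_of_ratios}} if \code{NULL}.
#' @param uf optional \code{\link{estimate_unwanted_factors}} result whose
#'   scores are added as covariates.
#' @param ref_site the reference (intact) site label; the reported
#'   log2 fold change is the other site relative to this one. Defaults to
#'   \code{"PLC"} when present, else the alphabetically first site.
#' @return a data.frame of class \code{de_result} with columns \code{gene},
#'   \code{baseMean}, \code{log2FoldChange}, \code{stat}, \code{pvalue},
#'   \code{padj}. All-zero genes get NA statistics.
#' @export
nb_wald_paired_test <- function(counts, sf = NULL, uf = NULL, ref_site = NULL) {
  meta <- counts$meta
  if (length(unique(meta$patient)) < 2L)
    ps_stop("paired test requires at least two patients", "design_error")
  tab <- table(meta$patient, meta$site)
  if (any(tab != 1L))
    ps_stop("non-paired metadata: each patient needs one sample per site",
            "design_error")
  if (is.null(sf)) sf <- size_factors_median_of_ratios(counts)
  sites <- sort(unique(meta$site))
  if (is.null(ref_site)) ref_site <- if ("PLC" %in% sites) "PLC" else sites[1]
  if (!ref_site %in% sites) ps_stop("unknown ref_site", "design_error")
  alt_site <- setdiff(sites, ref_site)

  patient <- factor(meta$patient)
  site_ind <- as.numeric(meta$site == alt_site)
  x <- cbind(`(Intercept)` = 1,
             stats::model.matrix(~patient)[, -1, drop = FALSE])
  if (!is.null(uf)) x <- cbind(x, uf$w)
  x <- cbind(x, site = site_ind)
  site_col <- ncol(x)
  p <- ncol(x)
  off <- log(sf)

  m <- counts$counts
  norm <- sweep(m, 2, sf, `/`)
  base_mean <- rowMeans(norm)
  alpha <- estimate_dispersions(m, x, off, base_mean)
  df_mod <- 2 * max(nrow(x) - qr(x)$rank, 1)  # residual + prior df

  ng <- nrow(m)
  lfc <- stat <- pval <- rep(NA_real_, ng)
  for (g in seq_len(ng)) {
    y <- m[g, ]
    if (all(y == 0)) next
    fam <- MASS::negative.binomial(theta = 1 / alpha[g], link = "log")
    fit <- tryCatch(
      suppressWarnings(glm.fit(x, y, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || fit$rank < 1) next
    pivot <- fit$qr$pivot[seq_len(fit$rank)]
    if (!(site_col %in% pivot)) next  # site coefficient aliased
    covmat <- tryCatch(
      chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]),
      error = function(e) NULL)
    if (is.null(covmat)) next
    i <- match(site_col, pivot)
    beta <- fit$coefficients[site_col]
    se <- sqrt(covmat[i, i])
    if (!is.finite(beta) || !is.finite(se) || se <= 0) next
    lfc[g] <- beta / log(2)
    stat[g] <- beta / se
    pval[g] <- 2 * stats::pt(-abs(stat[g]), df = df_mod)
  }
  padj <- rep(NA_real_, ng)
  ok <- !is.na(pval)
  padj[ok] <- bh_adjust(pval[ok])
  res <- data.frame(gene = rownames(m), baseMean = base_mean,
                    log2FoldChange = lfc, stat = stat, pvalue = pval,
                    padj = padj, stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  attr(res, "contrast") <- c(alt_site, "vs", ref_site)
  res
}

#' Call differentially expressed genes by fold change and adjusted p
#'
#' Inclusive thresholds: up-regulated genes satisfy fold change >=
#' \code{fc_threshold} and adjusted p <= \code{alpha}; down-regulated genes
#' satisfy fold change <= 1/\code{fc_threshold} (log2 fold change <=
#' -log2(fc_threshold)).
#'
#' @param de a \code{de_result}.
#' @param fc_threshold fold-change threshold (>= 1; default 1.5).
#' @param alpha adjusted-p bound (default 0.1, a 10 percent FDR).
#' @return list with character vectors \code{up} and \code{down}.
#' @export
call_degs <- function(de, fc_threshold = 1.5, alpha = 0.1) {
  if (fc_threshold < 1) ps_stop("fc_threshold must be >= 1", "invalid_parameter")
  if (alpha <= 0) ps_stop("alpha must be positive", "invalid_parameter")
  l2 <- log2(fc_threshold)
  ok <- !is.na(de$padj) & !is.na(de$log2FoldChange)
  up <- de$gene[ok & de$log2FoldChange >= l2 & de$padj <= alpha]
  down <- de$gene[ok & de$log2FoldChange <= -l2 & de$padj <= alpha]
  list(up = up, down = down)
}

#' Summarise DEG counts and percentages
#'
#' @param up up-regulated genes: a character vector or a single count.
#' @param down down-regulated genes: a character vector or a single count.
#' @param n_analysed total number of genes analysed.
#' @return list with \code{n_up}, \code{n_down}, \code{n_total},
#'   \code{pct_up}, \code{pct_down} (percentages of \code{n_analysed},
#'   rounded to one decimal).
#' @export
deg_summary <- function(up, down, n_analysed) {
  n_up <- if (is.numeric(up) && length(up) == 1L) as.integer(up) else length(up)
  n_down <- if (is.numeric(down) && length(down) == 1L) as.integer(down) else length(down)
  if (n_analysed <= 0) ps_stop("n_analysed must be positive", "invalid_parameter")
  if (n_analysed < n_up + n_down)
    ps_stop("n_analysed must be at least |up| + |down|", "invalid_parameter")
  list(n_up = n_up, n_down = n_down, n_total = n_up + n_down,
       pct_up = round(100 * n_up / n_analysed, 1),
       pct_down = round(100 * n_down / n_analysed, 1))
}

#' Fragments per kilobase of transcript per million mapped reads
#'
#' FPKM = count / (gene length in kb x mapped reads in millions), with the
#' per-sample mapped total taken as the column sum.
#'
#' @param counts a \code{\link{count_matrix}} or numeric matrix.
#' @param gene_lengths positive gene lengths in bp, aligned to rows.
#' @return matrix of FPKM values.
#' @export
fpkm <- function(counts, gene_lengths) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (length(gene_lengths) != nrow(m))
    ps_stop("gene_lengths must align to count rows", "invalid_input")
  if (any(gene_lengths <= 0)) ps_stop("gene lengths must be positive", "invalid_input")
  lib <- colSums(m)
  if (any(lib <= 0)) ps_stop("each sample needs a positive total count", "invalid_input")
  sweep(sweep(m, 1, gene_lengths / 1e3, `/`), 2, lib / 1e6, `/`)
}

#' Two-stage paired differential expression with control-gene correction
#'
#' Convenience wrapper for the full paired analysis: low-expression
#' filtering, size factors, a first-pass uncorrected NB Wald fit,
#' negative-control selection (removing the most significant genes),
#' unwanted-variation factor estimation from the controls, a corrected
#' second-pass fit, and DEG calling.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param fdr adjusted-p bound for DEG calling (default 0.10).
#' @param fc fold-change threshold (default 1.5).
#' @param ruv_k number of unwanted-variation factors (default 1; 0 skips
#'   correction).
#' @param n_exclude genes removed before control selection; default 5000,
#'   capped at half the filtered gene count.
#' @param min_mean_norm_count low-expression filter threshold (default 1).
#' @param ref_site passed to \code{\link{nb_wald_paired_test}}.
#' @return list with elements \code{de} (second-pass \code{de_result}),
#'   \code{first_pass}, \code{controls}, \code{uf}, \code{degs},
#'   \code{summary}, \code{n_analysed}.
#' @export
run_paired_de <- function(counts, fdr = 0.1, fc = 1.5, ruv_k = 1L,
                          n_exclude = 5000L, min_mean_norm_count = 1,
                          ref_site = NULL) {
  counts <- filter_low_expression(counts, min_mean_norm_count)
  ng <- nrow(counts$counts)
  sf <- size_factors_median_of_ratios(counts)
  first <- nb_wald_paired_test(counts, sf = sf, uf = NULL, ref_site = ref_site)
  uf <- NULL
  de <- first
  if (ruv_k >= 1L) {
    n_exclude <- min(n_exclude, floor(ng / 2))
    controls <- select_control_genes(first, n_exclude = n_exclude)
    uf <- estimate_unwanted_factors(counts, controls, k = ruv_k)
    de <- nb_wald_paired_test(counts, sf = sf, uf = uf, ref_site = ref_site)
  } else {
    controls <- character(0)
  }
  degs <- call_degs(de, fc_threshold = fc, alpha = fdr)
  list(de = de, first_pass = first, controls = controls, uf = uf,
       degs = degs, summary = deg_summary(degs$up, degs$down, ng),
       n_analysed = ng)
}
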