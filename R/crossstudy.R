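#' Construct a per-study DEG record
#'
#' @param label study label.
#' @param universe genes measured by the study.
#' @param up,down DEG identifier vectors (disjoint, within the universe).
#' @param log2fc optional named per-gene log2 fold changes.
#' @return list of class \code{study_degs}.
#' @export
study_degs <- function(label, universe, up, down, log2fc = NULL) {
  if (length(intersect(up, down)) > 0)
    ps_stop("up and down DEG sets must be disjoint", "invalid_input")
  if (!all(c(up, down) %in% universe))
    ps_stop("DEG sets must be subsets of the study universe", "invalid_input")
  structure(list(label = label, universe = unique(universe),
                 up = unique(up), down = unique(down), log2fc = log2fc),
            class = "study_degs")
}

#' Harmonise study universes to their intersection
#'
#' Restricts every study's universe and DEG sets to the genes measured in
#' all studies, the conservative universe for valid hypergeometric
#' comparison.
#'
#' @param studies list of \code{\link{study_degs}}.
#' @return list with \code{universe} and \code{studies} (restricted).
#' @export
harmonize_universe <- function(studies) {
  if (length(studies) < 2) ps_stop("need at least two studies", "invalid_input")
  universe <- Reduce(intersect, lapply(studies, function(s) s$universe))
  if (length(universe) == 0)
    ps_stop("study universes have an empty intersection", "incompatible_universes")
  studies <- lapply(studies, function(s)
    study_degs(s$label, universe, intersect(s$up, universe),
               intersect(s$down, universe), s$log2fc))
  list(universe = universe, studies = studies)
}

#' One-sided hypergeometric overlap probability
#'
#' Upper-tail probability P(X >= |a intersect b|) of the observed overlap
#' of two gene sets drawn from a common universe.
#'
#' @param a,b gene sets (subsets of \code{universe}).
#' @param universe gene universe.
#' @return p-value.
#' @export
hypergeometric_overlap <- function(a, b, universe) {
  if (length(universe) == 0) ps_stop("universe must be non-empty", "invalid_input")
  a <- unique(a); b <- unique(b)
  if (!all(a %in% universe) || !all(b %in% universe))
    ps_stop("sets must be subsets of the universe", "invalid_input")
  k <- length(intersect(a, b))
  phyper(k - 1, length(a), length(universe) - length(a), length(b),
         lower.tail = FALSE)
}

#' Multi-study DEG intersections and overlap significance
#'
#' Computes direction-aware pairwise and full intersections (up with up,
#' down with down), per-pair hypergeometric overlap p-values, and the
#' common-gene fold-change table across studies. Universes are harmonised
#' first.
#'
#' @param studies list of \code{\link{study_degs}} (>= 2).
#' @param direction_aware if \code{FALSE}, overlap significance is
#'   computed on the union of up and down DEGs per study (direction-blind,
#'   the default significance mode); intersections are always reported
#'   direction-aware.
#' @return list with \code{universe}, \code{pairwise} (data.frame study_a,
#'   study_b, n_overlap, p), \code{common} (direction-aware full
#'   intersection), and \code{common_log2fc} (gene x study matrix; NA when
#'   a study lacks fold changes).
#' @export
overlap_sets <- function(studies, direction_aware = FALSE) {
  h <- harmonize_universe(studies)
  studies <- h$studies
  labels <- vapply(studies, function(s) s$label, "")
  n <- length(studies)
  deg_union <- lapply(studies, function(s) c(s$up, s$down))

  pair <- list()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    si <- studies[[i]]; sj <- studies[[j]]
    inter_dir <- c(intersect(si$up, sj$up), intersect(si$down, sj$down))
    if (direction_aware) {
      p <- hypergeometric_overlap(si$up, sj$up, h$universe) # up-with-up tail
      n_ov <- length(inter_dir)
    } else {
      p <- hypergeometric_overlap(deg_union[[i]], deg_union[[j]], h$universe)
      n_ov <- length(intersect(deg_union[[i]], deg_union[[j]]))
    }
    pair[[length(pair) + 1L]] <- data.frame(
      study_a = labels[i], study_b = labels[j], n_overlap = n_ov,
      n_direction_aware = length(inter_dir), p = p, stringsAsFactors = FALSE)
  }
  pairwise <- do.call(rbind, pair)

  common_up <- Reduce(intersect, lapply(studies, function(s) s$up))
  common_down <- Reduce(intersect, lapply(studies, function(s) s$down))
  common <- sort(c(common_up, common_down))
  fc <- matrix(NA_real_, nrow = length(common), ncol = n,
               dimnames = list(common, labels))
  for (j in seq_len(n)) {
    lf <- studies[[j]]$log2fc
    if (!is.null(lf)) {
      hit <- intersect(common, names(lf))
      fc[hit, j] <- lf[hit]
    }
  }
  list(universe = h$universe, pairwise = pairwise, common = common,
       common_log2fc = fc)
}
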