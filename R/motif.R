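#' Construct a motif model
#'
#' @param id motif identifier.
#' @param pwm 4 x width matrix of per-base probabilities, rows named
#'   A, C, G, T; columns must sum to 1.
#' @param bg background base frequencies (default uniform); must sum to 1.
#' @param tf transcription factor the motif is annotated to.
#' @return list of class \code{motif_model}.
#' @export
motif_model <- function(id, pwm, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        tf = NA_character_) {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4) ps_stop("PWM must have 4 rows (A, C, G, T)", "invalid_input")
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(pwm) - 1) > 1e-6))
    ps_stop("PWM columns must sum to 1", "invalid_input")
  if (abs(sum(bg) - 1) > 1e-6) ps_stop("background must sum to 1", "invalid_input")
  structure(list(id = id, pwm = pwm, bg = setNames(as.numeric(bg),
                                                   c("A", "C", "G", "T")),
                 tf = tf), class = "motif_model")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Windowed motif-cluster score of a promoter sequence
#'
#' Scans both strands with the log2-odds of the PWM against the background.
#' Positions scoring above 0 are candidate motif instances; overlapping
#' instances are resolved greedily by descending score. The promoter score
#' is the maximum, over all sliding windows of \code{window_bp}, of the sum
#' of the retained instance scores inside the window, capturing the
#' "cluster of motif instances" signal of cis-regulatory modules.
#'
#' @param motif a \code{\link{motif_model}}.
#' @param sequence a single DNA string (upper case A/C/G/T).
#' @param window_bp cluster window width in bp (default 500).
#' @return non-negative numeric score (0 when no position scores above 0;
#'   0 with a warning when the sequence is shorter than the motif).
#' @export
score_promoter <- function(motif, sequence, window_bp = 500L) {
  score_promoter_encoded(motif, encode_dna(sequence), window_bp)
}

# internal: A/C/G/T -> 1..4, anything else -> 5 (scores -Inf-like)
encode_dna <- function(sequence) {
  code <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

# internal: precompute the log-odds lookup tables of a motif once per
# collection scan (both strands, with a 5th row that kills windows
# containing ambiguous bases)
motif_scan_prepare <- function(motif) {
  w <- ncol(motif$pwm)
  lo <- log2(pmax(motif$pwm, 1e-4) / motif$bg)
  lo_rc <- rbind(lo[4:1, w:1, drop = FALSE], N = -1e9)
  lo <- rbind(lo, N = -1e9)
  list(w = w, lo = lo, lo_rc = lo_rc)
}

# internal: cluster score on a pre-encoded sequence (avoids re-splitting
# the same promoter and re-deriving log-odds for every motif x sequence)
score_promoter_encoded <- function(motif, code, window_bp = 500L,
                                   prep = NULL) {
  if (is.null(prep)) prep <- motif_scan_prepare(motif)
  w <- prep$w
  lo <- prep$lo
  lo_rc <- prep$lo_rc
  L <- length(code)
  if (L < w) {
    warning("sequence shorter than motif; score 0")
    return(0)
  }
  np <- L - w + 1L
  # per-position log-odds via shifted cumulative lookups, one pass per column
  fwd <- rev <- numeric(np)
  for (j in seq_len(w)) {
    cj <- code[j:(j + np - 1L)]
    fwd <- fwd + lo[cj + (j - 1L) * 5L]
    rev <- rev + lo_rc[cj + (j - 1L) * 5L]
  }
  keep_f <- fwd > 0
  keep_r <- rev > 0
  if (!any(keep_f) && !any(keep_r)) return(0)
  cluster_from_hits(c(which(keep_f), which(keep_r)),
                    c(fwd[keep_f], rev[keep_r]), w, window_bp, L)
}

# internal: greedy non-overlap resolution of positive hits followed by the
# best sliding-window sum
cluster_from_hits <- function(pos, sc, w, window_bp, L) {
  if (length(pos) == 1L) return(sc)
  o <- order(pos)
  if (window_bp >= L && !anyDuplicated(pos) && all(diff(pos[o]) >= w))
    return(sum(sc))  # fast path: disjoint hits, whole sequence in window
  ord <- order(-sc, pos)
  pos <- pos[ord]
  sc <- sc[ord]
  occ_start <- occ_end <- integer(0)
  keep <- logical(length(pos))
  for (i in seq_along(pos)) {
    p0 <- pos[i]
    if (!any(p0 <= occ_end & (p0 + w - 1L) >= occ_start)) {
      keep[i] <- TRUE
      occ_start <- c(occ_start, p0)
      occ_end <- c(occ_end, p0 + w - 1L)
    }
  }
  pos <- pos[keep]
  sc <- sc[keep]
  ord <- order(pos)
  pos <- pos[ord]
  sc <- sc[ord]
  if (window_bp >= L) return(sum(sc))
  # max over windows: hits fully inside [W, W + window_bp - 1]
  span <- window_bp - w
  cs <- cumsum(sc)
  best <- 0
  for (i in seq_along(pos)) {
    j <- findInterval(pos[i] + span, pos)
    tot <- cs[j] - if (i > 1) cs[i - 1] else 0
    if (tot > best) best <- tot
  }
  best
}

# internal: concatenate encoded promoters into one vector, padded with
# ambiguous symbols so no scan window can straddle two sequences. The pad
# must be at least motif_width - 1; 32 covers any realistic PWM.
concat_promoters <- function(codes, pad = 32L) {
  n <- length(codes)
  len <- lengths(codes)
  starts <- cumsum(c(1L, head(len, -1) + pad))
  vec <- rep(5L, sum(len) + pad * (n - 1L))
  for (i in seq_len(n)) vec[starts[i]:(starts[i] + len[i] - 1L)] <- codes[[i]]
  list(vec = vec, starts = starts, len = len, n = n, names = names(codes))
}

# internal: scan a concatenated promoter set against one motif (compiled
# inner loop); returns the named per-sequence cluster score.
score_promoters_batch <- function(prep, concat, window_bp) {
  out <- scan_concat_cpp(concat$vec, prep$lo, prep$lo_rc,
                         as.integer(window_bp),
                         as.integer(concat$starts), as.integer(concat$len))
  setNames(out, concat$names)
}

#' Write motifs in minimal MEME motif format
#'
#' @param motifs list of \code{\link{motif_model}}s.
#' @param path output file path.
#' @export
write_meme <- function(motifs, path) {
  bg <- motifs[[1]]$bg
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", names(bg), bg), collapse = " "), ""),
             con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$id, m$tf), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m$pwm)), con)
    for (j in seq_len(ncol(m$pwm)))
      writeLines(paste(sprintf("%.6f", m$pwm[, j]), collapse = " "), con)
    writeLines("", con)
  }
}

#' Read motifs from a (minimal) MEME motif format file
#'
#' Parses the MEME version 4 motif subset written by
#' \code{\link{write_meme}}: background frequencies, MOTIF blocks with an
#' optional alternate (TF) name, and letter-probability matrices.
#'
#' @param path MEME file path.
#' @return named list of \code{\link{motif_model}}s.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi) > 0 && bgi[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    if (length(tok) >= 8)
      bg <- setNames(as.numeric(tok[c(2, 4, 6, 8)]), tok[c(1, 3, 5, 7)])
  }
  out <- list()
  mi <- grep("^MOTIF\\s", lines)
  for (i in mi) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    id <- tok[2]
    tf <- if (length(tok) >= 3) tok[3] else NA_character_
    hi <- i + which(grepl("^letter-probability matrix", lines[(i + 1):length(lines)]))[1]
    wm <- regmatches(lines[hi], regexpr("w=\\s*\\d+", lines[hi]))
    w <- as.integer(sub("w=\\s*", "", wm))
    rows <- lines[(hi + 1):(hi + w)]
    pwm <- matrix(unlist(lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]))), nrow = 4)
    rownames(pwm) <- c("A", "C", "G", "T")
    out[[id]] <- motif_model(id = id, pwm = pwm, bg = bg, tf = tf)
  }
  out
}
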