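# Independent brute-force oracles used to check the package's statistics.

# Benjamini-Hochberg by the defining formula: q_i = min over j with
# rank(p_j) >= rank(p_i) of m * p_(j) / j, clipped to 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Upper-tail hypergeometric by exhaustive enumeration of all draws of b
# elements from a universe of size n containing a marked set of size a.
hyper_bruteforce <- function(k, a, b, n) {
  # P(overlap >= k) = sum_{i >= k} C(a, i) C(n - a, b - i) / C(n, b)
  i <- max(k, 0):min(a, b)
  sum(choose(a, i) * choose(n - a, b - i)) / choose(n, b)
}

# Order-statistic probability via binomial sums (independent of pbeta):
# P(r_(k) <= x) for L iid U(0,1) = sum_{j=k}^{L} C(L, j) x^j (1-x)^(L-j).
orderstat_cdf_bruteforce <- function(x, k, L) {
  j <- k:L
  sum(choose(L, j) * x^j * (1 - x)^(L - j))
}

# rho score from the order-statistic definition, via the binomial-sum CDF
rra_rho_bruteforce <- function(r_norm) {
  L <- length(r_norm)
  r <- sort(r_norm)
  min(1, L * min(vapply(seq_len(L), function(k)
    orderstat_cdf_bruteforce(r[k], k, L), 0)))
}

# small deterministic paired count fixture with exact multiplicative
# structure (model fits with zero residuals)
noiseless_counts <- function() {
  base <- c(g1 = 10, g2 = 20, g3 = 40, g4 = 80, g5 = 160)
  pat <- c(P1 = 1, P2 = 2, P3 = 1, P4 = 2)
  lfc <- c(g1 = 0, g2 = 1, g3 = 0, g4 = 0, g5 = 0)
  meta <- data.frame(
    sample = as.vector(t(outer(names(pat), c("DMC", "PLC"), paste, sep = "_"))),
    patient = rep(names(pat), each = 2),
    site = rep(c("DMC", "PLC"), 4),
    stringsAsFactors = FALSE)
  m <- sapply(seq_len(nrow(meta)), function(j) {
    base * pat[meta$patient[j]] * (if (meta$site[j] == "DMC") 2^lfc else 1)
  })
  colnames(m) <- meta$sample
  count_matrix(m, meta)
}

# tiny heterogeneous network: 5 proteins in a path + hub, 2 phenotypes
tiny_hetnet <- function() {
  ppi <- data.frame(from = c("A", "B", "C", "D"),
                    to = c("B", "C", "D", "E"), weight = 1)
  pheno <- data.frame(from = "PH:1", to = "PH:2", weight = 1)
  bridges <- data.frame(from = c("A", "B"), to = c("PH:1", "PH:1"), weight = 1)
  build_heterogeneous_network(ppi, pheno, bridges,
                              expressed = c("A", "B", "C", "D", "E"))
}
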