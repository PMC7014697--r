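# Independent oracles and small fixture builders shared across tests.
# Each oracle is written from the model definition, deliberately avoiding
# the package's own code paths.

# Dense generalized-least-squares / likelihood oracle on the ORIGINAL
# (untransformed) scale: V = h2/(1-h2) K + I.
gls_oracle <- function(y, X, K, h2) {
  n <- length(y)
  V <- (h2 / (1 - h2)) * K + diag(n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  list(beta = drop(beta), rss = rss,
       neg2loglik = n * log(rss / n) +
         as.numeric(determinant(V, logarithm = TRUE)$modulus))
}

# Brute-force greedy all-pairs four-gamete-test partitioner. Gamete
# classes are counted via string tables rather than arithmetic indexing.
fgt_oracle_pair <- function(a, b, cutoff) {
  fr <- table(paste0(a, b)) / length(a)
  sum(fr >= cutoff) <= 3
}
fgt_oracle_blocks <- function(calls, chrom, cutoff) {
  m <- ncol(calls)
  assign_to <- rep(NA_integer_, m)
  bnum <- 0L
  i <- 1L
  while (i <= m) {
    members <- i
    j <- i + 1L
    while (j <= m && chrom[j] == chrom[i]) {
      ok <- TRUE
      for (k in members)
        if (!fgt_oracle_pair(calls[, k], calls[, j], cutoff)) { ok <- FALSE; break }
      if (!ok) break
      members <- c(members, j)
      j <- j + 1L
    }
    if (length(members) >= 2) {
      bnum <- bnum + 1L
      assign_to[members] <- bnum
    }
    i <- j
  }
  assign_to  # NA = unblocked
}

# Minimal genotype object builder for hand-made call matrices.
toy_geno <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) {
    pos <- integer(m)
    for (ch in unique(chrom)) pos[chrom == ch] <- seq_len(sum(chrom == ch)) * 100L
  }
  genotype_matrix(calls, paste0("s", seq_len(nrow(calls))),
                  data.frame(id = paste0("m", seq_len(m)), chrom = chrom,
                             pos = pos))
}

toy_block <- function(marker_indices, id = "B1", chrom = "1") {
  structure(list(block_id = id, chromosome = chrom,
                 marker_indices = marker_indices,
                 span_bp = c(min(marker_indices) * 100L,
                             max(marker_indices) * 100L),
                 n_snps = length(marker_indices), alleles = NULL),
            class = "haplotype_block")
}

# Identity-kinship eigen system (collapses the mixed model to OLS).
identity_eig <- function(n) {
  structure(list(values = rep(1, n), vectors = diag(n)),
            class = "eigen_system")
}

# A small simulated panel with kinship and eigen system, memoised per
# (n, m, seed) within a test file.
sim_panel <- function(n, m, seed, h2 = 0.5, qtl = list(), ...) {
  spec <- sim_spec(n_samples = n, n_snps = m, seed = seed, h2_poly = h2,
                   qtl = qtl, ...)
  G <- simulate_genotypes(spec)
  K <- compute_rrm(G)
  eig <- spectral_decompose(K)
  list(spec = spec, G = G, K = K, eig = eig)
}

# Random full-rank 0/1 unit design with the requested df on n samples:
# df + 1 categories, indicator coding dropping the last.
random_category_design <- function(n, df) {
  repeat {
    g <- sample.int(df + 1L, n, replace = TRUE)
    X <- matrix(0, n, df)
    for (j in seq_len(df)) X[g == j, j] <- 1
    if (qr(cbind(1, X))$rank == df + 1L) return(X)
  }
}
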