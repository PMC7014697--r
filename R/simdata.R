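# Simulator of LD-structured inbred-line genotypes and polygenic + QTL
# phenotypes. Founder-pool copying within blocks generates haplotype
# structure resembling a diverse inbred panel (most blocks under 10 SNPs,
# a handful of common alleles each) without a demographic model.

#' Simulation specification
#'
#' @param n_samples number of inbred lines.
#' @param n_snps number of markers.
#' @param block_length_mean mean LD-block length in markers (geometric
#'   length model; default 6, so most blocks have fewer than 10 SNPs).
#' @param maf_range range of founder allele frequencies (default
#'   c(0.1, 0.5)).
#' @param within_block_r copying fidelity in \[0, 1): each sample copies a
#'   founder haplotype within a block; each marker is independently
#'   re-drawn from its base frequency with probability 1 - within_block_r
#'   (default 0.98, giving a few common alleles per block plus rare
#'   mutation-derived patterns; 0 gives fully independent markers).
#' @param n_founders founder haplotypes per block (default 4, yielding
#'   roughly 3-6 common alleles per block after mutation).
#' @param h2_poly polygenic heritability of the simulated trait.
#' @param qtl list of planted QTLs; each element is either
#'   `list(marker = j, frac = f)` (a SNP explaining fraction `f` of
#'   phenotypic variance) or `list(block = b, frac = f)` (the b-th
#'   simulated LD block, with a distinct effect per founder pattern).
#' @param n_chrom number of chromosomes (default 1).
#' @param seed integer seed; all randomness derives from it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_samples = 200L, n_snps = 1000L,
                     block_length_mean = 6, maf_range = c(0.1, 0.5),
                     within_block_r = 0.98, n_founders = 4L,
                     h2_poly = 0.5, qtl = list(), n_chrom = 1L,
                     seed = 1L) {
  frac <- sum(vapply(qtl, `[[`, numeric(1), "frac"))
  if (h2_poly + frac >= 1)
    stop("h2_poly + QTL variance fractions must be < 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps),
                 block_length_mean = block_length_mean,
                 maf_range = maf_range, within_block_r = within_block_r,
                 n_founders = as.integer(n_founders), h2_poly = h2_poly,
                 qtl = qtl, n_chrom = as.integer(n_chrom),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate inbred-line genotypes with LD-block structure
#'
#' Block boundaries are drawn from a geometric length model. Within each
#' block a founder pool of haplotype patterns is drawn marker-wise at a
#' frequency from `maf_range`; each sample copies one founder and mutates
#' each marker with probability 1 - `within_block_r`. Blocks are mutually
#' independent. Deterministic for a fixed seed.
#'
#' @param spec a [sim_spec].
#' @return A [genotype_matrix] with attribute `"sim_blocks"`: a
#'   data.frame of the true block ranges, and `"founder_of"`: an
#'   n_samples x n_blocks matrix of founder assignments.
#' @export
simulate_genotypes <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_samples
  m <- spec$n_snps
  # block lengths: 1 + geometric so the mean is block_length_mean
  lens <- integer(0)
  while (sum(lens) < m)
    lens <- c(lens, 1L + stats::rgeom(max(64L, m %/% 2L),
                                      1 / spec$block_length_mean))
  ends <- cumsum(lens)
  lens <- lens[ends - lens < m]
  if (sum(lens) > m) lens[length(lens)] <- m - sum(lens[-length(lens)])
  nb <- length(lens)
  calls <- matrix(0L, n, m)
  founder_of <- matrix(0L, n, nb)
  start <- 1L
  blocks_df <- data.frame(block = seq_len(nb), start = NA_integer_,
                          end = NA_integer_)
  for (b in seq_len(nb)) {
    L <- lens[b]
    cols <- start:(start + L - 1L)
    p <- stats::runif(L, spec$maf_range[1], spec$maf_range[2])
    founders <- matrix(stats::rbinom(spec$n_founders * L, 1L,
                                     rep(p, each = spec$n_founders)),
                       nrow = spec$n_founders)
    pick <- sample.int(spec$n_founders, n, replace = TRUE)
    g <- founders[pick, , drop = FALSE]
    # with prob (1 - r) a call is re-drawn from the marker's base
    # frequency instead of copied, so r = 0 gives independent markers
    mut <- matrix(stats::runif(n * L) < (1 - spec$within_block_r), n, L)
    idx <- which(mut, arr.ind = TRUE)
    g[mut] <- stats::rbinom(nrow(idx), 1L, p[idx[, 2]])
    calls[, cols] <- g
    founder_of[, b] <- pick
    blocks_df$start[b] <- start
    blocks_df$end[b] <- start + L - 1L
    start <- start + L
  }
  # spread markers over chromosomes at ~1 kb spacing, blocks kept intact
  chrom_of_block <- sort(rep_len(seq_len(spec$n_chrom), nb))
  chrom <- rep(chrom_of_block, lens)
  pos <- integer(m)
  for (ch in seq_len(spec$n_chrom)) {
    i <- which(chrom == ch)
    pos[i] <- cumsum(sample(500:1500, length(i), replace = TRUE))
  }
  map <- data.frame(id = sprintf("chr%d_s%07d", chrom, pos),
                    chrom = as.character(chrom), pos = pos,
                    stringsAsFactors = FALSE)
  G <- genotype_matrix(calls, sprintf("line%04d", seq_len(n)), map)
  attr(G, "sim_blocks") <- blocks_df
  attr(G, "founder_of") <- founder_of
  G
}

#' Simulate a phenotype with polygenic, QTL and residual components
#'
#' Implements the generative mixed model y = 1 mu + X beta + a + eps with
#' a ~ N(0, K sig_a^2) and eps ~ N(0, I sig_e^2). Each realised component
#' is rescaled to its exact target sample-variance fraction (polygenic:
#' `h2_poly`; each QTL: its `frac`; residual: the remainder), so the
#' empirical variance decomposition matches the specification. Block
#' QTLs assign a distinct N(0,1) effect to every founder pattern of the
#' chosen simulated block. True parameters are recorded in the
#' `"sim_truth"` attribute.
#'
#' @param G the [genotype_matrix] from [simulate_genotypes].
#' @param spec the [sim_spec].
#' @param K a `kinship_matrix` (from [compute_rrm]) or `NULL` to compute
#'   it from `G`.
#' @param K_sqrt optional precomputed symmetric square root of K (e.g.
#'   `U diag(sqrt(S)) U'`), saving the per-draw decomposition when many
#'   replicate phenotypes are generated on one panel.
#' @return A `phenotype_vector` for trait `"simtrait"`.
#' @export
simulate_phenotype <- function(G, spec, K = NULL, K_sqrt = NULL) {
  set.seed(spec$seed + 500000L)
  n <- nrow(G$calls)
  comps <- list()
  fracs <- numeric(0)
  if (spec$h2_poly > 0) {
    if (is.null(K_sqrt)) {
      if (is.null(K)) K <- compute_rrm(G)
      e <- eigen((K$K + t(K$K)) / 2, symmetric = TRUE)
      K_sqrt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    }
    a <- drop(K_sqrt %*% stats::rnorm(n))
    comps <- c(comps, list(a))
    fracs <- c(fracs, spec$h2_poly)
  }
  qtl_truth <- list()
  for (q in spec$qtl) {
    if (!is.null(q$marker)) {
      g <- G$calls[, q$marker]
      qtl_truth[[length(qtl_truth) + 1L]] <-
        list(type = "snp", marker = q$marker, frac = q$frac)
    } else {
      fo <- attr(G, "founder_of")
      if (is.null(fo)) stop("block QTLs need a genotype object from simulate_genotypes()")
      eff <- stats::rnorm(max(fo[, q$block]))
      g <- eff[fo[, q$block]]
      qtl_truth[[length(qtl_truth) + 1L]] <-
        list(type = "block", block = q$block, frac = q$frac,
             founder_effects = eff)
    }
    if (stats::var(g) == 0)
      stop("planted QTL is monomorphic in this simulation; change the seed")
    comps <- c(comps, list(g))
    fracs <- c(fracs, q$frac)
  }
  comps <- c(comps, list(stats::rnorm(n)))
  fracs <- c(fracs, 1 - sum(fracs))
  y <- 0
  for (i in seq_along(comps)) {
    v <- comps[[i]] - mean(comps[[i]])
    y <- y + v * sqrt(fracs[i] / stats::var(v))
  }
  pv <- phenotype_vector("simtrait", y + 10, rownames(G$calls))
  attr(pv, "sim_truth") <- list(h2_poly = spec$h2_poly, qtl = qtl_truth,
                                fracs = fracs)
  pv
}

#' Write simulated data to disk
#'
#' Writes the genotype table + marker map, the phenotype table, and a
#' JSON truth sidecar recording the simulation parameters.
#'
#' @param G,y,spec simulated objects.
#' @param prefix output path prefix; files `<prefix>_geno.tsv`,
#'   `<prefix>_map.tsv`, `<prefix>_pheno.tsv`, `<prefix>_truth.json`.
#' @export
write_simdata <- function(G, y, spec, prefix) {
  write_genotypes(G, paste0(prefix, "_geno.tsv"), paste0(prefix, "_map.tsv"))
  utils::write.table(data.frame(sample = y$sample_ids, simtrait = y$values),
                     paste0(prefix, "_pheno.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(spec = unclass(spec),
                            truth = attr(y, "sim_truth")),
                       paste0(prefix, "_truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(prefix)
}
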