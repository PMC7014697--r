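# Realized relationship matrix and its one-off spectral decomposition.

#' Compute the realized relationship matrix from genome-wide markers
#'
#' VanRaden-style construction on 0/1 inbred coding: each polymorphic
#' marker column is centered by its allele-1 frequency p_j and the
#' cross-product is scaled by c = sum_j p_j (1 - p_j), the haploid-
#' equivalent normalisation (diag(K) then sits near 1 + an inbreeding-like
#' excess). Any positive rescaling of K is absorbed by the heritability
#' parameter, so this choice does not affect test statistics.
#'
#' Monomorphic columns carry no relatedness information and are skipped
#' (and excluded from c). With `exclude_chrom`, markers on that chromosome
#' are left out of K (leave-one-chromosome-out); the default single global
#' K matches the one-decomposition pipeline.
#'
#' @param G a [genotype_matrix].
#' @param exclude_chrom optional chromosome name to leave out.
#' @return A `kinship_matrix`: list with `K` (n x n symmetric),
#'   `n_markers_used`, `scaling_c`, `sample_ids`.
#' @export
compute_rrm <- function(G, exclude_chrom = NULL) {
  calls <- G$calls
  if (!is.null(exclude_chrom))
    calls <- calls[, G$map$chrom != exclude_chrom, drop = FALSE]
  p <- colMeans(calls)
  poly <- p > 0 & p < 1
  if (sum(poly) < 2)
    stop("fewer than 2 polymorphic markers; cannot build a kinship matrix")
  M <- sweep(calls[, poly, drop = FALSE], 2L, p[poly])
  cc <- sum(p[poly] * (1 - p[poly]))
  K <- tcrossprod(M) / cc
  K <- (K + t(K)) / 2
  structure(list(K = K, n_markers_used = sum(poly), scaling_c = cc,
                 sample_ids = rownames(calls)),
            class = "kinship_matrix")
}

#' Spectral decomposition of the kinship matrix
#'
#' Computed once per dataset; rotating phenotype and designs by the
#' eigenvectors diagonalises the mixed-model covariance so every
#' subsequent unit test is a weighted regression.
#'
#' @param K a `kinship_matrix` or a plain symmetric matrix.
#' @return An `eigen_system`: `values` (non-increasing, tiny negatives
#'   clipped to 0) and `vectors` (orthonormal columns).
#' @export
spectral_decompose <- function(K) {
  Km <- if (inherits(K, "kinship_matrix")) K$K else K
  if (max(abs(Km - t(Km))) > 1e-8)
    stop("kinship matrix is not symmetric within tolerance")
  e <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  if (any(e$values < -1e-10 * max(1, abs(e$values[1]))))
    stop("kinship matrix has a substantially negative eigenvalue (",
         format(min(e$values)), "); input is numerically corrupted")
  e$values[e$values < 0] <- 0
  structure(list(values = e$values, vectors = e$vectors),
            class = "eigen_system")
}

#' Persist / load a kinship matrix as plain text with a JSON sidecar
#'
#' The matrix is written at full precision, one row per line; the sidecar
#' records sample ids, the marker count and the scaling constant.
#'
#' @param K a `kinship_matrix`.
#' @param path matrix file; the sidecar goes to `<path>.json`.
#' @export
write_kinship <- function(K, path) {
  utils::write.table(format(K$K, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(sample_ids = K$sample_ids,
                            n_markers_used = K$n_markers_used,
                            scaling_c = K$scaling_c),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  K <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(K) <- list(side$sample_ids, side$sample_ids)
  structure(list(K = K, n_markers_used = side$n_markers_used,
                 scaling_c = side$scaling_c, sample_ids = side$sample_ids),
            class = "kinship_matrix")
}
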