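# Four-Gamete-Test haplotype blocks, allele enumeration, unit design matrices.

#' Four gamete test for a marker pair
#'
#' In an inbred panel each line is an observed haplotype, so the four
#' two-locus gamete classes (0,0), (0,1), (1,0), (1,1) are counted directly.
#' A pair shows evidence of historical recombination iff all four classes
#' are present; classes with frequency below `cutoff` are treated as
#' unobserved (genotyping error / very rare recombinant).
#'
#' @param col_i,col_j 0/1 vectors of equal length.
#' @param cutoff minimum gamete-class frequency for a class to count as
#'   observed (default 0.01).
#' @return `TRUE` if at most 3 gamete classes reach `cutoff` (no
#'   recombination evidence; the pair may share a block).
#' @export
four_gamete_pass <- function(col_i, col_j, cutoff = 0.01) {
  n <- length(col_i)
  stopifnot(length(col_j) == n)
  cls <- tabulate(2L * col_i + col_j + 1L, nbins = 4L) / n
  sum(cls >= cutoff) <= 3L
}

#' Partition markers into haplotype blocks with the four gamete test
#'
#' Greedy left-to-right extension per chromosome: a candidate marker joins
#' the open block only if it passes [four_gamete_pass] against *every*
#' marker already in the block (all-pairs criterion, not adjacent-only
#' chaining, so recombinant pairs cannot hide inside long blocks). A block
#' closes when extension fails; single-marker "blocks" are recorded as
#' unblocked markers. Blocks never straddle chromosome boundaries.
#'
#' @param G a [genotype_matrix].
#' @param cutoff gamete-class frequency cutoff in (0, 0.5), default 0.01.
#' @return A `block_set`: list of `haplotype_block` objects plus
#'   `unblocked_marker_indices`.
#' @export
build_blocks <- function(G, cutoff = 0.01) {
  stopifnot(cutoff > 0, cutoff < 0.5)
  calls <- G$calls
  map <- G$map
  m <- ncol(calls)
  blocks <- list()
  unblocked <- integer(0)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    i <- 1L
    nb <- 0L
    while (i <= length(idx)) {
      members <- idx[i]
      j <- i + 1L
      while (j <= length(idx)) {
        cand <- calls[, idx[j]]
        ok <- all(vapply(members, function(k)
          four_gamete_pass(calls[, k], cand, cutoff), logical(1)))
        if (!ok) break
        members <- c(members, idx[j])
        j <- j + 1L
      }
      if (length(members) >= 2L) {
        nb <- nb + 1L
        blocks[[length(blocks) + 1L]] <- structure(list(
          block_id = paste0("Chr", ch, "Block", nb),
          chromosome = ch,
          marker_indices = members,
          span_bp = c(map$pos[members[1]], map$pos[members[length(members)]]),
          n_snps = length(members),
          alleles = NULL), class = "haplotype_block")
      } else {
        unblocked <- c(unblocked, members)
      }
      i <- j
    }
  }
  structure(list(blocks = blocks, unblocked_marker_indices = unblocked,
                 cutoff = cutoff, rare_freq = NA_real_),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  ns <- vapply(x$blocks, function(b) b$n_snps, integer(1))
  cat("block_set:", length(x$blocks), "blocks covering", sum(ns),
      "SNPs;", length(x$unblocked_marker_indices), "unblocked markers\n")
  invisible(x)
}

#' Enumerate haplotype alleles of a block and merge rare ones
#'
#' Distinct multi-SNP row patterns over the block's markers become alleles
#' with frequency equal to their carrier fraction. All patterns with
#' frequency below `rare_freq` are pooled into a single allele labelled
#' `<block_id>_rare`; a lone sub-threshold pattern (nothing to pool with)
#' keeps its ordinary label. Alleles are sorted by descending frequency
#' (ties broken lexicographically by pattern, the pooled rare class last)
#' and labelled `<block_id>_1`, `<block_id>_2`, ...
#'
#' @param G a [genotype_matrix].
#' @param block a `haplotype_block` from [build_blocks].
#' @param rare_freq pooling threshold in \[0, 0.5), default 0.02.
#' @return The block with its `alleles` field filled: each allele has
#'   `allele_id`, `pattern` (0/1 string or `"rare"`), `frequency`,
#'   `carriers` (sample indices).
#' @export
enumerate_alleles <- function(G, block, rare_freq = 0.02) {
  stopifnot(rare_freq >= 0, rare_freq < 0.5)
  sub <- G$calls[, block$marker_indices, drop = FALSE]
  pat <- apply(sub, 1L, paste0, collapse = "")
  n <- length(pat)
  tab <- table(pat)
  if (length(tab) < 2L)
    stop("block ", block$block_id, " is monomorphic (a single haplotype ",
         "pattern); upstream block construction is inconsistent")
  freq <- as.numeric(tab) / n
  pats <- names(tab)
  rare <- freq < rare_freq
  alleles <- list()
  if (sum(rare) >= 2L) {
    keep_p <- pats[!rare]
    keep_f <- freq[!rare]
    rare_f <- sum(freq[rare])
    rare_carriers <- unname(which(pat %in% pats[rare]))
    df <- data.frame(pattern = c(keep_p, "rare"),
                     frequency = c(keep_f, rare_f),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(pattern = pats, frequency = freq,
                     stringsAsFactors = FALSE)
    rare_carriers <- integer(0)
  }
  ord <- order(-df$frequency, df$pattern)
  df <- df[ord, , drop = FALSE]
  for (k in seq_len(nrow(df))) {
    p <- df$pattern[k]
    if (p == "rare") {
      alleles[[k]] <- list(allele_id = paste0(block$block_id, "_rare"),
                           pattern = "rare", frequency = df$frequency[k],
                           carriers = rare_carriers)
    } else {
      alleles[[k]] <- list(allele_id = paste0(block$block_id, "_", k),
                           pattern = p, frequency = df$frequency[k],
                           carriers = unname(which(pat == p)))
    }
  }
  block$alleles <- alleles
  block
}

#' Enumerate alleles for every block in a block set
#'
#' @param G a [genotype_matrix].
#' @param blocks a `block_set`.
#' @param rare_freq pooling threshold, see [enumerate_alleles].
#' @return The `block_set` with alleles filled in and `rare_freq` recorded.
#' @export
enumerate_all_alleles <- function(G, blocks, rare_freq = 0.02) {
  blocks$blocks <- lapply(blocks$blocks, function(b)
    enumerate_alleles(G, b, rare_freq))
  blocks$rare_freq <- rare_freq
  blocks
}

#' Encode genetic units as regression design matrices
#'
#' Produces one design per tested unit. SNPs use the 0/1 genotype column
#' directly. Haplotype alleles use a 0/1 carrier indicator. Haplotype
#' blocks use k - 1 indicator columns for k alleles; the last allele in
#' the sorted order (lowest frequency, the rare class when present) is
#' dropped so the design plus intercept is identifiable.
#'
#' @param G a [genotype_matrix].
#' @param blocks a `block_set` with alleles enumerated (ignored for
#'   `unit_kind = "snp"`).
#' @param unit_kind `"snp"`, `"hap_allele"`, or `"hap_block"`.
#' @return list of `unit_design` objects with fields `unit_id`,
#'   `unit_kind`, `columns` (n x df_beta matrix), `df_beta`, `chromosome`,
#'   `span_bp`.
#' @export
encode_units <- function(G, blocks = NULL, unit_kind = c("snp", "hap_allele", "hap_block")) {
  unit_kind <- match.arg(unit_kind)
  n <- nrow(G$calls)
  if (unit_kind == "snp") {
    return(lapply(seq_len(ncol(G$calls)), function(j) {
      structure(list(unit_id = G$map$id[j], unit_kind = "snp",
                     columns = G$calls[, j, drop = FALSE], df_beta = 1L,
                     chromosome = G$map$chrom[j],
                     span_bp = c(G$map$pos[j], G$map$pos[j])),
                class = "unit_design")
    }))
  }
  stopifnot(!is.null(blocks))
  out <- list()
  for (b in blocks$blocks) {
    if (is.null(b$alleles))
      stop("alleles not enumerated for block ", b$block_id,
           "; call enumerate_all_alleles() first")
    k <- length(b$alleles)
    if (unit_kind == "hap_allele") {
      for (a in b$alleles) {
        col <- matrix(0, n, 1)
        col[a$carriers, 1] <- 1
        out[[length(out) + 1L]] <- structure(list(
          unit_id = a$allele_id, unit_kind = "hap_allele", columns = col,
          df_beta = 1L, chromosome = b$chromosome, span_bp = b$span_bp),
          class = "unit_design")
      }
    } else {
      X <- matrix(0, n, k - 1L)
      for (j in seq_len(k - 1L)) X[b$alleles[[j]]$carriers, j] <- 1
      colnames(X) <- vapply(b$alleles[seq_len(k - 1L)],
                            function(a) a$allele_id, character(1))
      out[[length(out) + 1L]] <- structure(list(
        unit_id = b$block_id, unit_kind = "hap_block", columns = X,
        df_beta = k - 1L, chromosome = b$chromosome, span_bp = b$span_bp,
        n_snps = b$n_snps, n_alleles = k),
        class = "unit_design")
    }
  }
  out
}

#' Write a block set as a tab-separated table
#'
#' One row per block: block id, chromosome, inclusive bp span, SNP count,
#' allele count, and comma-separated allele frequencies. With
#' `bed = TRUE` a BED-compatible 0-based half-open export is written
#' instead (start = start_bp - 1, end = end_bp).
#'
#' @param blocks a `block_set` with alleles enumerated.
#' @param path output file.
#' @param bed write BED coordinates instead of the native table.
#' @export
write_blocks <- function(blocks, path, bed = FALSE) {
  rows <- lapply(blocks$blocks, function(b) {
    k <- if (is.null(b$alleles)) NA_integer_ else length(b$alleles)
    fr <- if (is.null(b$alleles)) "" else
      paste(sprintf("%.6g", vapply(b$alleles, `[[`, numeric(1), "frequency")),
            collapse = ",")
    data.frame(block_id = b$block_id, chrom = b$chromosome,
               start_bp = b$span_bp[1], end_bp = b$span_bp[2],
               n_snps = b$n_snps, n_alleles = k, allele_freqs = fr,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (bed) {
    bed_df <- data.frame(chrom = df$chrom, start = df$start_bp - 1L,
                         end = df$end_bp, name = df$block_id)
    utils::write.table(bed_df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
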