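#' @keywords internal
"_PACKAGE"

#' Construct a genotype matrix object
#'
#' Container for 0/1 genotype calls of homozygous inbred lines together with
#' their marker map. Inbred lines carry one of two homozygous genotypes at
#' each SNP, coded 0 and 1, so genotypes coincide with haplotypes and no
#' phasing is needed.
#'
#' @param calls integer matrix, n samples x m markers, entries in \{0, 1\}.
#' @param sample_ids character vector of n unique sample identifiers.
#' @param map data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   one row per marker, sorted by (chrom, pos).
#' @return An object of class `genotype_matrix` with fields `calls`
#'   (dimnames set to sample and marker ids) and `map`.
#' @export
genotype_matrix <- function(calls, sample_ids, map) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (anyNA(calls))
    stop("genotype matrix contains missing calls; impute genotypes before loading (imputation is out of scope)")
  bad <- which(!(calls %in% c(0L, 1L)))
  if (length(bad))
    stop("genotype calls must be 0 or 1; first offending entry at linear index ", bad[1])
  if (length(sample_ids) != nrow(calls))
    stop("sample_ids length does not match number of rows")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos") %in% names(map)))
  if (nrow(map) != ncol(calls))
    stop("marker map rows do not match number of genotype columns")
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (any(map$pos < 1L)) stop("marker positions must be >= 1")
  .check_sorted_map(map)
  dimnames(calls) <- list(sample_ids, map$id)
  structure(list(calls = calls, map = map), class = "genotype_matrix")
}

.check_sorted_map <- function(map) {
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker positions on chromosome ", ch,
           " are not strictly increasing; sort the input first")
  }
  # chromosomes must appear in contiguous runs
  r <- rle(map$chrom)$values
  if (anyDuplicated(r))
    stop("markers of one chromosome appear in non-contiguous runs; sort the input by (chrom, pos)")
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls),
      "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read a genotype matrix from VCF or a plain 0/1 table
#'
#' VCF genotypes must be homozygous diploid (`0/0`, `1/1`, phased variants
#' accepted) or haploid (`0`, `1`); the reference homozygote is coded 0.
#' The table format is tab-separated with marker ids in the first row and
#' sample ids in the first column; a marker map (`id`, `chrom`, `pos`,
#' tab-separated) must accompany it via `map_path`.
#'
#' @param path input file.
#' @param format `"vcf"` or `"table"`.
#' @param map_path marker map file, required for `format = "table"`.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("vcf", "table"), map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") .read_genotypes_vcf(path) else {
    if (is.null(map_path)) stop("map_path is required for table input")
    .read_genotypes_table(path, map_path)
  }
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  if (is.null(dim(gt))) {
    gt <- t(as.matrix(gt))
    rownames(gt) <- NULL
  }
  # rows are markers, columns samples
  g <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow = nrow(g), ncol = ncol(g))
  calls[g == "0/0" | g == "0"] <- 0L
  calls[g == "1/1" | g == "1"] <- 1L
  het <- which(g == "0/1" | g == "1/0", arr.ind = TRUE)
  if (nrow(het))
    stop("heterozygous call at marker ", fix[het[1, 1], "ID"],
         ", sample ", colnames(g)[het[1, 2]],
         "; this tool assumes fully inbred (homozygous) lines")
  if (anyNA(calls)) {
    miss <- which(is.na(calls), arr.ind = TRUE)
    stop("missing genotype at marker ", fix[miss[1, 1], "ID"],
         ", sample ", colnames(g)[miss[1, 2]],
         "; impute missing genotypes before loading")
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[is.na(ids) | ids == ".", "CHROM"], "_",
           fix[is.na(ids) | ids == ".", "POS"])
  map <- data.frame(id = ids, chrom = as.character(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  genotype_matrix(t(calls), colnames(g), map)
}

.read_genotypes_table <- function(path, map_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(map)[1:3] <- c("id", "chrom", "pos")
  m <- as.matrix(tab)
  map <- map[match(colnames(m), map$id), , drop = FALSE]
  if (anyNA(map$id))
    stop("marker map is missing entries for some table columns")
  genotype_matrix(m, rownames(tab), map)
}

#' Write a genotype matrix as a 0/1 table plus marker map
#'
#' Inverse of [read_genotypes] with `format = "table"`.
#'
#' @param G a [genotype_matrix].
#' @param path output table file.
#' @param map_path output map file.
#' @export
write_genotypes <- function(G, path, map_path) {
  df <- data.frame(sample = rownames(G$calls), G$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(G$map[, c("id", "chrom", "pos")], map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read one trait from a delimited phenotype table
#'
#' The table must have a sample-id column (first column) and one or more
#' trait columns. Rows with a missing value for the requested trait are
#' dropped with a message reporting the count.
#'
#' @param path delimited text file (tab or comma separated, autodetected).
#' @param trait trait column name.
#' @return A `phenotype_vector`: list with `trait_name`, `values`,
#'   `sample_ids`.
#' @export
read_phenotypes <- function(path, trait) {
  if (!file.exists(path)) stop("file not found: ", path)
  l1 <- readLines(path, n = 1)
  sep <- if (grepl("\t", l1)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!trait %in% names(tab)[-1])
    stop("trait '", trait, "' not found; available traits: ",
         paste(names(tab)[-1], collapse = ", "))
  v <- as.numeric(tab[[trait]])
  keep <- is.finite(v)
  if (sum(!keep))
    message("read_phenotypes: dropped ", sum(!keep),
            " sample(s) with missing '", trait, "'")
  phenotype_vector(trait, v[keep], as.character(tab[[1]])[keep])
}

#' @rdname read_phenotypes
#' @param trait_name,values,sample_ids fields of the phenotype vector.
#' @export
phenotype_vector <- function(trait_name, values, sample_ids) {
  stopifnot(length(values) == length(sample_ids))
  if (!all(is.finite(values))) stop("phenotype values must be finite")
  if (length(values) < 3) stop("need at least 3 phenotyped samples")
  structure(list(trait_name = trait_name, values = as.numeric(values),
                 sample_ids = as.character(sample_ids)),
            class = "phenotype_vector")
}

#' Restrict genotypes and phenotype to their common samples
#'
#' Both objects are subset to the intersection of sample ids, in the
#' genotype object's sample order.
#'
#' @param G a [genotype_matrix].
#' @param y a `phenotype_vector`.
#' @return list with elements `G` and `y`.
#' @export
align_samples <- function(G, y) {
  common <- intersect(rownames(G$calls), y$sample_ids)
  if (!length(common))
    stop("no samples shared between genotypes and phenotype '", y$trait_name, "'")
  keep_g <- rownames(G$calls) %in% common
  ord <- rownames(G$calls)[keep_g]
  G2 <- structure(list(calls = G$calls[keep_g, , drop = FALSE], map = G$map),
                  class = "genotype_matrix")
  idx <- match(ord, y$sample_ids)
  y2 <- phenotype_vector(y$trait_name, y$values[idx], ord)
  list(G = G2, y = y2)
}

#' Remove markers below a minor-allele-frequency threshold
#'
#' MAF is the column mean of the 0/1 calls folded at 0.5. The boundary is
#' inclusive: markers with MAF exactly equal to `min_maf` are kept.
#'
#' @param G a [genotype_matrix].
#' @param min_maf threshold in \[0, 0.5\].
#' @return The filtered [genotype_matrix].
#' @export
filter_maf <- function(G, min_maf) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  p <- colMeans(G$calls)
  maf <- pmin(p, 1 - p)
  keep <- maf >= min_maf
  structure(list(calls = G$calls[, keep, drop = FALSE],
                 map = G$map[keep, , drop = FALSE]),
            class = "genotype_matrix")
}
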