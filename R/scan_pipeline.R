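# Genome-wide scan orchestration: exact / EMMAX / two-pass modes,
# Bonferroni thresholds, genomic control, result output.

#' Scan configuration
#'
#' @param unit_kind `"snp"`, `"hap_allele"`, or `"hap_block"`.
#' @param mode `"two_pass"` (default: EMMAX screen, then exact
#'   re-optimisation of units passing the screen), `"emmax"`, or
#'   `"exact"`.
#' @param screen_alpha per-unit p-value screen of the two-pass mode
#'   (default 0.05; units with EMMAX p below it are re-tested exactly).
#' @param alpha genome-wide significance level for the Bonferroni
#'   threshold (default 0.05).
#' @param fgt_cutoff four-gamete-test class-frequency cutoff (default 0.01).
#' @param rare_freq rare-allele pooling threshold (default 0.02).
#' @param min_maf minor-allele-frequency filter (default 0, no filtering).
#' @param screen_top_k optionally also re-test the k smallest EMMAX
#'   p-values regardless of the screen (default 0, off).
#' @param chisq_pvalues use the large-sample chi-square p-values.
#' @param seed integer seed recorded in the result.
#' @return A `scan_config` list.
#' @export
scan_config <- function(unit_kind = c("snp", "hap_allele", "hap_block"),
                        mode = c("two_pass", "emmax", "exact"),
                        screen_alpha = 0.05, alpha = 0.05,
                        fgt_cutoff = 0.01, rare_freq = 0.02, min_maf = 0,
                        screen_top_k = 0L, chisq_pvalues = FALSE,
                        seed = NA_integer_) {
  stopifnot(screen_alpha >= 0, screen_alpha <= 1, alpha > 0, alpha < 1)
  structure(list(unit_kind = match.arg(unit_kind), mode = match.arg(mode),
                 screen_alpha = screen_alpha, alpha = alpha,
                 fgt_cutoff = fgt_cutoff, rare_freq = rare_freq,
                 min_maf = min_maf, screen_top_k = as.integer(screen_top_k),
                 chisq_pvalues = chisq_pvalues, seed = seed),
            class = "scan_config")
}

#' Bonferroni genome-wide significance threshold
#'
#' @param n_tests number of tested units.
#' @param alpha significance level.
#' @return the threshold on the -log10(p) scale, -log10(alpha / n_tests).
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  -log10(alpha / n_tests)
}

#' Genomic-control inflation factor
#'
#' Each p-value is converted to its 1-df chi-square quantile and the
#' median is divided by the chi-square(1) median (qchisq(0.5, 1) ~
#' 0.4549), which puts scans mixing units of different df on a common
#' scale. Lambda near 1 indicates well-calibrated tests; lambda well
#' above 1 indicates confounding inflation.
#'
#' @param p vector of p-values, or a `scan_result`.
#' @return lambda (scalar).
#' @export
genomic_control_lambda <- function(p) {
  if (inherits(p, "scan_result")) p <- p$results$p
  if (length(p) < 20) stop("need at least 20 tests for genomic control")
  zero <- p <= 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " degenerate p = 0 value(s) from lambda")
    p <- p[!zero]
  }
  q <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(q) / stats::qchisq(0.5, df = 1)
}

#' Run a genome-wide association scan
#'
#' Fits the null mixed model once to estimate the genomic heritability,
#' rotates all unit design columns into the kinship eigenbasis in one
#' batch, then tests every unit:
#' \describe{
#'   \item{emmax}{one weighted regression per unit at the genomic
#'     heritability;}
#'   \item{exact}{per-unit heritability optimisation for all units;}
#'   \item{two_pass}{EMMAX screen over all units, then exact re-testing
#'     of units with screen p <= `screen_alpha`; re-tested results
#'     overwrite the screen results.}
#' }
#' Degenerate (rank-deficient) units are skipped with a message, never
#' silently. Output is in genome order.
#'
#' @param G an aligned [genotype_matrix].
#' @param y the aligned `phenotype_vector` (or numeric vector).
#' @param blocks a `block_set` with alleles enumerated (required unless
#'   `cfg$unit_kind == "snp"`).
#' @param cfg a [scan_config].
#' @param eig the `eigen_system` of the kinship matrix.
#' @return A `scan_result`: `results` (data.frame in genome order),
#'   `threshold_neg_log10`, `lambda_gc`, `n_tests`, `h2_genomic`, `mode`,
#'   `pass2_unit_ids`, `n_fits`, `scan_equivalents`.
#' @export
run_scan <- function(G, y, blocks = NULL, cfg = scan_config(), eig) {
  units <- encode_units(G, blocks, cfg$unit_kind)
  td <- transform_phenotype(y, eig)
  reset_fit_count()
  null_fit <- fit_null(td)
  fits_null <- fit_count()
  h2g <- null_fit$h2_genomic

  # one batch rotation of every unit column (the FaST-LMM economy:
  # a single O(n^2 m) multiply instead of per-unit O(n^2) rotations)
  allcols <- do.call(cbind, lapply(units, `[[`, "columns"))
  allcols_t <- crossprod(eig$vectors, allcols)
  offs <- cumsum(c(0L, vapply(units, function(u) ncol(u$columns), integer(1))))
  unit_cols_t <- function(i) allcols_t[, (offs[i] + 1L):offs[i + 1L], drop = FALSE]

  reset_fit_count()
  n_units <- length(units)
  res <- vector("list", n_units)
  skipped <- character(0)
  fit0_emmax <- wls_fit(td, matrix(td$intercept_t, ncol = 1), h2g)

  run_one <- function(i, exact) {
    tryCatch({
      if (exact)
        test_unit_exact(td, units[[i]], h2_start = h2g,
                        X_t_unit = unit_cols_t(i), chisq = cfg$chisq_pvalues)
      else
        test_unit_emmax(td, units[[i]], h2_fixed = h2g,
                        X_t_unit = unit_cols_t(i), fit0 = fit0_emmax,
                        chisq = cfg$chisq_pvalues)
    }, error = function(e) {
      skipped <<- c(skipped, paste0(units[[i]]$unit_id, ": ",
                                    conditionMessage(e)))
      NULL
    })
  }

  pass2_ids <- character(0)
  if (cfg$mode == "exact") {
    for (i in seq_len(n_units)) res[[i]] <- run_one(i, exact = TRUE)
  } else {
    for (i in seq_len(n_units)) res[[i]] <- run_one(i, exact = FALSE)
    if (cfg$mode == "two_pass") {
      pvals <- vapply(res, function(r) if (is.null(r)) NA_real_ else r$p,
                      numeric(1))
      sel <- which(!is.na(pvals) & pvals <= cfg$screen_alpha)
      if (cfg$screen_top_k > 0L) {
        topk <- order(pvals)[seq_len(min(cfg$screen_top_k, n_units))]
        sel <- union(sel, topk[!is.na(pvals[topk])])
      }
      for (i in sel) {
        r2 <- run_one(i, exact = TRUE)
        if (!is.null(r2)) {
          res[[i]] <- r2
          pass2_ids <- c(pass2_ids, r2$unit_id)
        }
      }
    }
  }
  if (length(skipped))
    message("run_scan: skipped ", length(skipped), " degenerate unit(s): ",
            paste(utils::head(skipped, 5), collapse = "; "))
  res <- res[!vapply(res, is.null, logical(1))]
  df <- if (length(res))
    do.call(rbind, lapply(res, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  else
    data.frame(unit_id = character(0), unit_kind = character(0),
               chromosome = character(0), start_bp = numeric(0),
               end_bp = numeric(0), n_snps = integer(0),
               n_alleles = integer(0), df_beta = integer(0),
               df_eps = integer(0), F = numeric(0), p = numeric(0),
               neg_log10_p = numeric(0), h2_used = numeric(0),
               beta = numeric(0), explained_var_pct = numeric(0),
               mode = character(0), stringsAsFactors = FALSE)
  rownames(df) <- NULL
  n_tests <- nrow(df)
  n_fits <- fit_count()
  structure(list(results = df,
                 threshold_neg_log10 = if (n_tests >= 1)
                   bonferroni_threshold(n_tests, cfg$alpha) else NA_real_,
                 lambda_gc = if (n_tests >= 20) genomic_control_lambda(df$p)
                             else NA_real_,
                 n_tests = n_tests, h2_genomic = h2g,
                 mode = cfg$mode, pass2_unit_ids = pass2_ids,
                 n_fits = n_fits, n_fits_null = fits_null,
                 scan_equivalents = n_fits / n_units,
                 skipped = skipped, config = cfg),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("scan_result:", x$n_tests, x$config$unit_kind, "units, mode",
      x$mode, "\n")
  cat("  genomic h2 =", signif(x$h2_genomic, 4),
      "| lambda_GC =", signif(x$lambda_gc, 4),
      "| threshold -log10(p) =", signif(x$threshold_neg_log10, 4), "\n")
  cat("  regression-scan equivalents i =", signif(x$scan_equivalents, 3),
      "(", x$n_fits, "fits /", x$n_tests, "units )\n")
  nsig <- sum(x$results$neg_log10_p >= x$threshold_neg_log10)
  cat("  significant units:", nsig, "\n")
  invisible(x)
}

#' Write scan results as a tab-separated table
#'
#' Header comment lines record the test count, Bonferroni threshold,
#' genomic-control lambda, and genomic heritability; one row per unit
#' follows with a `significant` flag against the threshold.
#'
#' @param res a `scan_result`.
#' @param path output file.
#' @export
write_results <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# n_tests=", res$n_tests),
    paste0("# threshold_neg_log10=", format(res$threshold_neg_log10, digits = 10)),
    paste0("# lambda_gc=", format(res$lambda_gc, digits = 10)),
    paste0("# h2_genomic=", format(res$h2_genomic, digits = 10)),
    paste0("# mode=", res$mode)), con)
  df <- res$results
  df$significant <- df$neg_log10_p >= res$threshold_neg_log10
  utils::write.table(format(df, digits = 10, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @return `read_results(path)` returns the results data.frame with the
#'   header fields as attributes.
#' @export
read_results <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  while (length(l <- readLines(con, n = 1)) && startsWith(l, "#"))
    hdr <- c(hdr, sub("^# ", "", l))
  df <- utils::read.table(con, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  # the first non-comment line read in the loop is the column header
  names(df) <- strsplit(l, "\t")[[1]]
  kv <- strsplit(hdr, "=")
  for (x in kv) attr(df, x[1]) <- utils::type.convert(x[2], as.is = TRUE)
  for (col in c("start_bp", "end_bp", "df_beta", "df_eps", "F", "p",
                "neg_log10_p", "h2_used", "beta", "explained_var_pct"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' QQ and Manhattan plot data
#'
#' @param res a `scan_result`.
#' @return list of two data.frames: `qq` with `expected` (-log10 of the
#'   (i - 0.5)/n plotting positions) and `observed` (sorted descending
#'   -log10 p), and `manhattan` with `coord` (cumulative genome
#'   coordinate), `chrom`, `pos`, `neg_log10_p`.
#' @export
qq_manhattan_data <- function(res) {
  df <- res$results
  n <- nrow(df)
  obs <- sort(df$neg_log10_p, decreasing = TRUE)
  expd <- -log10((seq_len(n) - 0.5) / n)
  chroms <- unique(df$chromosome)
  offset <- 0
  coord <- numeric(n)
  for (ch in chroms) {
    i <- df$chromosome == ch
    coord[i] <- offset + df$start_bp[i]
    offset <- offset + max(df$end_bp[i])
  }
  list(qq = data.frame(expected = expd, observed = obs),
       manhattan = data.frame(coord = coord, chrom = df$chromosome,
                              pos = df$start_bp,
                              neg_log10_p = df$neg_log10_p))
}
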