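#' GWAS summary statistics tables
#'
#' A `sumstats` object is a validated per-variant association table for one
#' GWAS: one row per biallelic variant with the effect-allele estimate `beta`,
#' its standard error `se`, the two alleles, and (optionally) the
#' effect-allele frequency `eaf`, the association p-value `pval` and the
#' per-variant sample size `samplesize`. The phenotype and its measurement
#' unit are carried as free-text attributes; the unit matters because effect
#' estimates from two studies can only be differenced on a common scale.
#'
#' Validation enforces: unique variant IDs (first occurrence kept), single
#' upper-case A/C/G/T alleles with effect != other (indels and multi-character
#' alleles are rejected rather than harmonised), finite `beta`, `se > 0`.
#' Out-of-range optional fields (`eaf` outside (0,1), `pval` outside (0,1],
#' non-positive `samplesize`) are set to `NA` rather than dropping the row.
#'
#' @param x data.frame with (at least) columns `SNP`, `effect_allele`,
#'   `other_allele`, `beta`, `se`; optionally `eaf`, `pval`, `samplesize`.
#' @param phenotype_label free-text phenotype name.
#' @param unit_label free-text measurement unit (e.g. `"Kg"`, `"SD"`).
#' @param sample_size_default positive integer used to fill missing
#'   `samplesize` values, or `NULL`.
#'
#' @return A data.frame of class `sumstats` with the standard columns, the
#'   number of dropped rows in attribute `n_dropped`, and the labels in
#'   attributes `phenotype_label` / `unit_label`.
#' @seealso [read_sumstats()], [harmonise()]
#' @export
#' @examples
#' sumstats(data.frame(SNP = "rs1", effect_allele = "a", other_allele = "g",
#'                     beta = 0.1, se = 0.02))
sumstats <- function(x, phenotype_label = "", unit_label = "",
                     sample_size_default = NULL) {
  stopifnot(is.data.frame(x))
  req <- c("SNP", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  n_in <- nrow(x)
  for (opt in c("eaf", "pval", "samplesize")) if (is.null(x[[opt]])) x[[opt]] <- NA_real_

  out <- data.frame(
    SNP           = as.character(x$SNP),
    effect_allele = toupper(trimws(as.character(x$effect_allele))),
    other_allele  = toupper(trimws(as.character(x$other_allele))),
    beta          = as.numeric(x$beta),
    se            = as.numeric(x$se),
    eaf           = suppressWarnings(as.numeric(x$eaf)),
    pval          = suppressWarnings(as.numeric(x$pval)),
    samplesize    = suppressWarnings(as.numeric(x$samplesize)),
    stringsAsFactors = FALSE
  )

  bases <- c("A", "C", "G", "T")
  ok <- !is.na(out$SNP) & nzchar(out$SNP) &
    out$effect_allele %in% bases & out$other_allele %in% bases &
    out$effect_allele != out$other_allele &
    is.finite(out$beta) & is.finite(out$se) & out$se > 0
  ok[is.na(ok)] <- FALSE
  out <- out[ok, , drop = FALSE]
  out <- out[!duplicated(out$SNP), , drop = FALSE]
  n_dropped <- n_in - nrow(out)
  if (nrow(out) == 0L) stop("no valid summary-statistics rows after validation")
  if (n_dropped > 0L) {
    message("sumstats: dropped ", n_dropped, " of ", n_in, " row(s) failing validation")
  }

  out$eaf[!is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1)] <- NA_real_
  out$pval[!is.na(out$pval) & (out$pval <= 0 | out$pval > 1)] <- NA_real_
  out$samplesize[!is.na(out$samplesize) & out$samplesize <= 0] <- NA_real_
  if (!is.null(sample_size_default)) {
    stopifnot(is.numeric(sample_size_default), sample_size_default > 0)
    out$samplesize[is.na(out$samplesize)] <- sample_size_default
  }

  rownames(out) <- NULL
  structure(out,
            phenotype_label = as.character(phenotype_label),
            unit_label = as.character(unit_label),
            n_dropped = n_dropped,
            class = c("sumstats", "data.frame"))
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated file with a header row into a validated [sumstats]
#' object. The default column dialect is the common GWAS convention
#' (`SNP`, `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `pval`,
#' `samplesize`); other dialects are handled with `column_map`. Missing values
#' must be encoded as `NA`.
#'
#' @param path path to a tab-separated text file.
#' @param column_map optional named character vector mapping standard names to
#'   the file's column names, e.g. `c(SNP = "rsid", beta = "b")`. Unmapped
#'   standard names are looked up verbatim.
#' @inheritParams sumstats
#' @return A [sumstats] object. Rows failing validation are dropped with a
#'   message; a file with no usable rows is an error, as is a missing
#'   required column.
#' @export
read_sumstats <- function(path, column_map = NULL, phenotype_label = "",
                          unit_label = "", sample_size_default = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                           data.table = FALSE, showProgress = FALSE)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    stopifnot(!is.null(names(column_map)))
    bad <- setdiff(column_map, names(dat))
    if (length(bad) > 0L) {
      stop("column map refers to absent column(s): ", paste(bad, collapse = ", "))
    }
    for (std in names(column_map)) names(dat)[names(dat) == column_map[[std]]] <- std
  }
  req <- c("SNP", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(req, names(dat))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  sumstats(dat, phenotype_label = phenotype_label, unit_label = unit_label,
           sample_size_default = sample_size_default)
}

#' Write a summary-statistics table
#'
#' Tab-separated, header row, `NA` for missing values; the inverse of
#' [read_sumstats()] for the default column dialect.
#'
#' @param x a [sumstats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  df <- as.data.frame(x)
  for (col in c("beta", "se", "eaf", "pval")) df[[col]] <- format_num(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# full-precision decimal formatting for round-trippable text output
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = TRUE)
  }, character(1))
  out
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d variant(s)\n", nrow(x)))
  if (nzchar(attr(x, "phenotype_label"))) {
    cat("  phenotype: ", attr(x, "phenotype_label"),
        if (nzchar(attr(x, "unit_label"))) paste0(" (", attr(x, "unit_label"), ")"),
        "\n", sep = "")
  }
  if (attr(x, "n_dropped") > 0) {
    cat("  rows dropped at validation: ", attr(x, "n_dropped"), "\n", sep = "")
  }
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

#' Write a same-population test result to file
#'
#' Writes one tab-separated row per variant (difference, standard error, z,
#' p-value) followed by a `#`-prefixed summary footer holding the pooled
#' fixed-effects estimate, both combined p-values, Fisher's chi-square and
#' degrees of freedom, the number of variants, alpha and the verdict. The file
#' round-trips through [read_results()] at full double precision.
#'
#' @param result a `samepop_test` object from [run_test()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "samepop_test"))
  per_snp <- result$per_snp
  if (is.null(per_snp) || nrow(per_snp) == 0L) stop("nothing to write: empty per-SNP results")
  cmb <- result$combined
  body <- per_snp
  for (col in c("d", "se_d", "z", "p")) body[[col]] <- format_num(body[[col]])
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  footer_fields <- c("k", "d_pooled", "se_pooled", "z_pooled", "p_fixed",
                     "fisher_chi2", "fisher_df", "p_fisher")
  for (f in footer_fields) {
    writeLines(sprintf("# %s\t%s", f, format_num(cmb[[f]])), con)
  }
  writeLines(sprintf("# alpha\t%s", format_num(result$alpha)), con)
  writeLines(sprintf("# detected\t%s", result$detected), con)
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path path to a results file.
#' @return A `samepop_test` object (per-SNP table, combined results, verdict).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_footer <- startsWith(lines, "# ")
  body <- utils::read.delim(text = lines[!is_footer], stringsAsFactors = FALSE)
  names(body)[1] <- "variant_id"
  body$variant_id <- as.character(body$variant_id)
  kv <- do.call(rbind, strsplit(sub("^# ", "", lines[is_footer]), "\t", fixed = TRUE))
  vals <- stats::setNames(kv[, 2], kv[, 1])
  num <- function(f) as.numeric(vals[[f]])
  combined <- list(k = as.integer(num("k")), d_pooled = num("d_pooled"),
                   se_pooled = num("se_pooled"), z_pooled = num("z_pooled"),
                   p_fixed = num("p_fixed"), fisher_chi2 = num("fisher_chi2"),
                   fisher_df = as.integer(num("fisher_df")), p_fisher = num("p_fisher"))
  structure(list(per_snp = body, combined = combined,
                 detected = as.logical(vals[["detected"]]),
                 alpha = num("alpha")),
            class = "samepop_test")
}
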