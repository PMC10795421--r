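#' Per-variant difference test
#'
#' Tests whether one variant's allele effect differs between two GWAS
#' samples. Under the null hypothesis that both samples estimate the same
#' effect, `d = beta1 - beta2` has standard error
#' `se_d = sqrt(se1^2 + se2^2)` (the estimates come from non-overlapping
#' samples and are independent), and `z = d / se_d` is standard normal. A
#' non-zero difference is evidence that the two samples are not drawn from
#' the same population — for example because an effect modifier such as sex
#' or age has a different prevalence in the two samples.
#'
#' All arguments are vectorised; estimates must be harmonised to the same
#' effect allele and reported on the same scale (see [harmonise()] and
#' [scale_diagnostic()]).
#'
#' @param beta1,se1 effect estimate and standard error in sample 1.
#' @param beta2,se2 effect estimate and standard error in sample 2.
#' @param variant_id optional variant identifier(s).
#' @return data.frame with columns `variant_id`, `d`, `se_d`, `z`, `p`
#'   (two-sided standard-normal p-value).
#' @export
#' @examples
#' snp_difference(0.50, 0.10, 0.20, 0.10)  # z = 2.12, p = 0.034
snp_difference <- function(beta1, se1, beta2, se2, variant_id = NULL) {
  if (!all(is.finite(beta1), is.finite(beta2))) stop("effect estimates must be finite")
  if (!all(is.finite(se1), is.finite(se2)) || any(se1 <= 0) || any(se2 <= 0)) {
    stop("standard errors must be finite and > 0")
  }
  k <- length(beta1)
  stopifnot(length(se1) == k, length(beta2) == k, length(se2) == k)
  if (is.null(variant_id)) variant_id <- paste0("snp", seq_len(k))
  d <- beta1 - beta2
  se_d <- sqrt(se1^2 + se2^2)
  z <- d / se_d
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(variant_id = as.character(variant_id), d = d, se_d = se_d,
             z = z, p = p, stringsAsFactors = FALSE)
}

#' Fixed-effects meta-analysis of per-variant differences
#'
#' Pools per-variant differences with inverse-variance weights
#' `w_j = 1 / se_d_j^2`: `d_pooled = sum(w d) / sum(w)`,
#' `se_pooled = 1 / sqrt(sum(w))`, and a two-sided standard-normal p-value
#' for `z = d_pooled / se_pooled`. Valid when the variants are independent
#' (not in linkage disequilibrium) — a documented precondition, not checked.
#'
#' @param results data.frame with columns `d` and `se_d` as returned by
#'   [snp_difference()], one row per variant, at least one row.
#' @return list with `d_pooled`, `se_pooled`, `z_pooled`, `p_fixed`.
#' @export
fixed_effects_combine <- function(results) {
  stopifnot(is.data.frame(results), all(c("d", "se_d") %in% names(results)))
  if (nrow(results) == 0L) stop("no per-variant results to combine")
  if (any(!is.finite(results$se_d)) || any(results$se_d <= 0)) {
    stop("all difference standard errors must be finite and > 0")
  }
  w <- 1 / results$se_d^2
  d_pooled <- sum(w * results$d) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  z_pooled <- d_pooled / se_pooled
  list(d_pooled = d_pooled, se_pooled = se_pooled, z_pooled = z_pooled,
       p_fixed = 2 * stats::pnorm(-abs(z_pooled)))
}

#' Fisher's method for combining independent p-values
#'
#' `chi2 = -2 * sum(log(p))` is chi-square distributed with `2k` degrees of
#' freedom when the k p-values are independent and uniform under the null.
#' Unlike the fixed-effects pooled difference, Fisher's method is sensitive
#' to a difference at any variant even when differences of opposite sign
#' cancel in the pooled estimate.
#'
#' @param pvalues numeric vector of p-values, each in (0, 1]. A p-value of
#'   exactly zero is rejected; floor such values at
#'   `.Machine$double.xmin` before calling.
#' @return list with `fisher_chi2`, `fisher_df` (`= 2k`), `p_fisher`.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no p-values to combine")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]; floor exact zeros at .Machine$double.xmin")
  }
  k <- length(pvalues)
  chi2 <- -2 * sum(log(pvalues))
  list(fisher_chi2 = chi2, fisher_df = 2L * k,
       p_fisher = stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE))
}

#' Run the same-population falsification test
#'
#' The full test on a harmonised pair: per-variant difference z-tests, the
#' fixed-effects pooled difference, and Fisher's combination of the
#' per-variant p-values. The verdict `detected` is `p_fixed < alpha`;
#' Fisher's p-value is always co-reported. A detected difference is evidence
#' against treating the two GWASs as samples from the same population; a
#' non-detection does not prove the assumption (falsification test).
#'
#' @param pair a [harmonise()]d pair with at least one variant.
#' @param alpha two-sided significance level in (0, 1).
#' @return An object of class `samepop_test`: list with `per_snp`
#'   (data.frame from [snp_difference()]), `combined` (k, pooled estimate,
#'   both combination results), `detected`, `alpha`.
#' @export
run_test <- function(pair, alpha = 0.05) {
  stopifnot(inherits(pair, "harmonised_pair"), nrow(pair) >= 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1)")
  }
  per_snp <- snp_difference(pair$beta1, pair$se1, pair$beta2, pair$se2,
                            variant_id = pair$variant_id)
  fe <- fixed_effects_combine(per_snp)
  pv <- per_snp$p
  if (any(pv == 0)) {
    warning("per-variant p-value underflowed to 0; floored at .Machine$double.xmin for Fisher's method",
            call. = FALSE)
    pv[pv == 0] <- .Machine$double.xmin
  }
  fi <- fisher_combine(pv)
  combined <- c(list(k = nrow(per_snp)), fe, fi)
  structure(list(per_snp = per_snp, combined = combined,
                 detected = fe$p_fixed < alpha, alpha = alpha),
            class = "samepop_test")
}

#' @export
print.samepop_test <- function(x, ...) {
  cmb <- x$combined
  cat("Same-population falsification test\n")
  cat(sprintf("  variants combined (k): %d\n", cmb$k))
  print.data.frame(x$per_snp, row.names = FALSE, digits = 4)
  cat(sprintf("  fixed effects: pooled difference %.4g (SE %.4g), z = %.3f, p = %.4g\n",
              cmb$d_pooled, cmb$se_pooled, cmb$z_pooled, cmb$p_fixed))
  cat(sprintf("  Fisher's method: chi2 = %.4g on %d df, p = %.4g\n",
              cmb$fisher_chi2, cmb$fisher_df, cmb$p_fisher))
  cat(sprintf("VERDICT: %s (fixed-effects p %s alpha = %g)\n",
              if (x$detected) "difference detected - same-population assumption questionable"
              else "no difference detected",
              if (x$detected) "<" else ">=", x$alpha))
  invisible(x)
}
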