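#' Harmonise two GWAS summary-statistics tables
#'
#' Aligns the two studies on shared variant IDs and orients the second study's
#' effect estimate to the first study's effect allele, so the per-variant
#' difference `beta1 - beta2` is meaningful. For each shared variant:
#'
#' * same effect/other alleles: kept unchanged;
#' * swapped alleles: `beta2` negated and `eaf2` replaced by `1 - eaf2`;
#' * strand-flipped alleles (reverse complements): complemented, then the two
#'   rules above applied;
#' * palindromic variants (A/T or C/G): identity and strand flip are
#'   indistinguishable from the alleles, so orientation is inferred from the
#'   effect-allele frequencies when both are farther than `eaf_tolerance`
#'   from 0.5; otherwise handled per `palindromic_policy`;
#' * irreconcilable allele sets: dropped and counted.
#'
#' Matching is by variant ID only. Unit labels are compared case-insensitively
#' and a mismatch raises a warning (labels are unreliable; the numeric check
#' is [scale_diagnostic()]).
#'
#' @param s1,s2 [sumstats] objects sharing at least one variant ID.
#' @param palindromic_policy `"drop_ambiguous"` (default) drops palindromic
#'   variants whose strand cannot be resolved from the allele frequencies
#'   (either frequency missing or within `eaf_tolerance` of 0.5);
#'   `"drop_all"` drops every palindromic variant; `"keep"` assumes both
#'   studies report the same strand and applies the plain allele rules.
#' @param eaf_tolerance half-width of the frequency window around 0.5 inside
#'   which a palindromic variant counts as ambiguous; in (0, 0.5).
#' @return A data.frame of class `harmonised_pair` with columns `variant_id`,
#'   `beta1`, `se1`, `beta2`, `se2`, `eaf1`, `eaf2`, and attributes
#'   `n_dropped_palindromic`, `n_dropped_mismatch`.
#' @export
#' @examples
#' s1 <- sumstats(data.frame(SNP = "rs1", effect_allele = "A",
#'                           other_allele = "G", beta = 0.10, se = 0.02))
#' s2 <- sumstats(data.frame(SNP = "rs1", effect_allele = "G",
#'                           other_allele = "A", beta = 0.08, se = 0.02))
#' harmonise(s1, s2)$beta2  # -0.08: swapped alleles flip the sign
harmonise <- function(s1, s2,
                      palindromic_policy = c("drop_ambiguous", "drop_all", "keep"),
                      eaf_tolerance = 0.08) {
  stopifnot(inherits(s1, "sumstats"), inherits(s2, "sumstats"))
  palindromic_policy <- match.arg(palindromic_policy)
  if (!is.numeric(eaf_tolerance) || eaf_tolerance <= 0 || eaf_tolerance >= 0.5) {
    stop("eaf_tolerance must be in (0, 0.5)")
  }

  u1 <- attr(s1, "unit_label"); u2 <- attr(s2, "unit_label")
  if (nzchar(u1) && nzchar(u2) && tolower(u1) != tolower(u2)) {
    warning("unit labels differ between studies ('", u1, "' vs '", u2,
            "'); differences on mismatched scales are not interpretable", call. = FALSE)
  }

  shared <- intersect(s1$SNP, s2$SNP)
  if (length(shared) == 0L) stop("the two studies share no variant IDs")
  r1 <- s1[match(shared, s1$SNP), , drop = FALSE]
  r2 <- s2[match(shared, s2$SNP), , drop = FALSE]

  comp <- function(a) chartr("ACGT", "TGCA", a)
  e1 <- r1$effect_allele; o1 <- r1$other_allele
  e2 <- r2$effect_allele; o2 <- r2$other_allele
  palindromic <- e1 == comp(o1)

  # nominal orientation from the alleles as reported
  direct <- e2 == e1 & o2 == o1
  swap   <- e2 == o1 & o2 == e1
  fdirect <- !palindromic & comp(e2) == e1 & comp(o2) == o1
  fswap   <- !palindromic & comp(e2) == o1 & comp(o2) == e1

  flip <- rep(NA, length(shared))            # NA = irreconcilable
  flip[direct | fdirect] <- FALSE
  flip[swap | fswap] <- TRUE

  drop_pal <- rep(FALSE, length(shared))
  if (palindromic_policy == "drop_all") {
    drop_pal <- palindromic & !is.na(flip)
  } else if (palindromic_policy == "drop_ambiguous") {
    idx <- which(palindromic & !is.na(flip))
    if (length(idx) > 0L) {
      f1 <- r1$eaf[idx]
      f2 <- r2$eaf[idx]
      f2[flip[idx]] <- 1 - f2[flip[idx]]     # frequency on the nominal orientation
      resolvable <- !is.na(f1) & !is.na(f2) &
        abs(f1 - 0.5) > eaf_tolerance & abs(f2 - 0.5) > eaf_tolerance
      drop_pal[idx[!resolvable]] <- TRUE
      # opposite sides of 0.5 on the nominal orientation => reported on
      # opposite strands, which for a palindromic variant toggles the swap
      toggle <- resolvable & (f1 - 0.5) * (f2 - 0.5) < 0
      flip[idx[toggle]] <- !flip[idx[toggle]]
    }
  }

  keep <- !is.na(flip) & !drop_pal
  n_mismatch <- sum(is.na(flip))
  n_pal <- sum(drop_pal)
  if (!any(keep)) stop("no harmonisable variants")

  beta2 <- ifelse(flip, -r2$beta, r2$beta)
  eaf2  <- ifelse(flip, 1 - r2$eaf, r2$eaf)
  out <- data.frame(variant_id = shared, beta1 = r1$beta, se1 = r1$se,
                    beta2 = beta2, se2 = r2$se, eaf1 = r1$eaf, eaf2 = eaf2,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            n_dropped_palindromic = n_pal,
            n_dropped_mismatch = n_mismatch,
            unit_label = u1,
            class = c("harmonised_pair", "data.frame"))
}

#' @export
print.harmonised_pair <- function(x, ...) {
  cat(sprintf("Harmonised pair: %d variant(s) (%d palindromic dropped, %d mismatched dropped)\n",
              nrow(x), attr(x, "n_dropped_palindromic"), attr(x, "n_dropped_mismatch")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Numeric scale-mismatch diagnostic
#'
#' Two GWASs of the same phenotype reported on different measurement scales
#' (e.g. kilograms vs standard-deviation units) produce a spurious
#' "difference" even when the populations are identical. This diagnostic
#' compares the typical effect magnitude of the two studies: it computes
#' `ratio = median(|beta1|) / median(|beta2|)` (a zero median is replaced by
#' the smallest positive `|beta|` in the pair) and warns when the ratio falls
#' outside `[1/fold_threshold, fold_threshold]`. It never blocks the analysis.
#'
#' @param pair a [harmonise()]d pair.
#' @param fold_threshold fold difference in median effect magnitude beyond
#'   which the flag is raised; must be > 1.
#' @return list with elements `ratio` and `warn`.
#' @export
scale_diagnostic <- function(pair, fold_threshold = 5) {
  stopifnot(inherits(pair, "harmonised_pair"), nrow(pair) >= 1L)
  if (!is.numeric(fold_threshold) || fold_threshold <= 1) {
    stop("fold_threshold must be > 1")
  }
  m1 <- stats::median(abs(pair$beta1))
  m2 <- stats::median(abs(pair$beta2))
  pos <- abs(c(pair$beta1, pair$beta2))
  pos <- pos[pos > 0]
  if (length(pos) == 0L) return(list(ratio = 1, warn = FALSE))
  floor_val <- min(pos)
  if (m1 == 0) m1 <- floor_val
  if (m2 == 0) m2 <- floor_val
  ratio <- m1 / m2
  warn <- ratio > fold_threshold || ratio < 1 / fold_threshold
  if (warn) {
    warning(sprintf(paste0("median |beta| differs %.3g-fold between studies; ",
                           "the two GWASs may be on different scales"), ratio),
            call. = FALSE)
  }
  list(ratio = ratio, warn = warn)
}
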