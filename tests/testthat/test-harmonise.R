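test_that("allele orientation rules: identity, swap, strand flip, flip+swap", {
  s1 <- make_ss("rs1", "A", "G", 0.10, 0.02)

  # identical alleles: kept unchanged
  h <- harmonise(s1, make_ss("rs1", "A", "G", 0.08, 0.02))
  expect_equal(h$beta2, 0.08)

  # swapped alleles: sign flips
  h <- harmonise(s1, make_ss("rs1", "G", "A", 0.08, 0.02))
  expect_equal(h$beta2, -0.08)

  # strand-flipped (reverse complement) alleles: kept after complementing
  h <- harmonise(s1, make_ss("rs1", "T", "C", 0.08, 0.02))
  expect_equal(h$beta2, 0.08)

  # strand flip + swap: sign flips
  h <- harmonise(s1, make_ss("rs1", "C", "T", 0.08, 0.02))
  expect_equal(h$beta2, -0.08)

  # swapped alleles also reflect the frequency
  s2 <- make_ss("rs1", "G", "A", 0.08, 0.02, eaf = 0.25)
  expect_equal(harmonise(s1, s2)$eaf2, 0.75)
})

test_that("palindromic variants are resolved by frequency or handled per policy", {
  # ambiguous: both frequencies within the tolerance window around 0.5
  s1 <- make_ss("rs1", "A", "T", 0.10, 0.02, eaf = 0.50)
  s2 <- make_ss("rs1", "A", "T", 0.08, 0.02, eaf = 0.49)
  expect_error(harmonise(s1, s2, eaf_tolerance = 0.08), "no harmonisable")
  both <- function(a, b) list(
    sumstats(rbind(as.data.frame(a), data.frame(SNP = "rs9", effect_allele = "A",
      other_allele = "G", beta = 0.1, se = 0.02, eaf = 0.2, pval = NA, samplesize = NA))),
    sumstats(rbind(as.data.frame(b), data.frame(SNP = "rs9", effect_allele = "A",
      other_allele = "G", beta = 0.1, se = 0.02, eaf = 0.2, pval = NA, samplesize = NA))))
  ss <- both(s1, s2)
  h <- harmonise(ss[[1]], ss[[2]], eaf_tolerance = 0.08)
  expect_equal(nrow(h), 1L)
  expect_identical(attr(h, "n_dropped_palindromic"), 1L)

  # resolvable, same strand: frequencies on the same side of 0.5
  s1 <- make_ss("rs1", "A", "T", 0.10, 0.02, eaf = 0.20)
  s2 <- make_ss("rs1", "A", "T", 0.08, 0.02, eaf = 0.22)
  h <- harmonise(s1, s2)
  expect_equal(h$beta2, 0.08)

  # resolvable, opposite strands: frequencies on opposite sides -> sign flips
  s2 <- make_ss("rs1", "A", "T", 0.08, 0.02, eaf = 0.78)
  h <- harmonise(s1, s2)
  expect_equal(h$beta2, -0.08)
  expect_equal(h$eaf2, 0.22)

  # missing frequency under drop_ambiguous -> dropped
  s2 <- make_ss("rs1", "A", "T", 0.08, 0.02)
  expect_error(harmonise(s1, s2), "no harmonisable")

  # drop_all discards even resolvable palindromic variants
  s2 <- make_ss("rs1", "A", "T", 0.08, 0.02, eaf = 0.22)
  expect_error(harmonise(s1, s2, palindromic_policy = "drop_all"), "no harmonisable")

  # keep trusts the reported strand
  h <- harmonise(s1, s2, palindromic_policy = "keep")
  expect_equal(h$beta2, 0.08)
  h <- harmonise(s1, make_ss("rs1", "T", "A", 0.08, 0.02, eaf = 0.8),
                 palindromic_policy = "keep")
  expect_equal(h$beta2, -0.08)
})

test_that("irreconcilable allele sets are dropped and counted; counts conserve", {
  s1 <- sumstats(data.frame(SNP = c("rs1", "rs2", "rs3"),
                            effect_allele = c("A", "A", "A"),
                            other_allele = c("G", "G", "G"),
                            beta = 0.1, se = 0.02))
  s2 <- sumstats(data.frame(SNP = c("rs1", "rs2", "rs4"),
                            effect_allele = c("A", "A", "A"),
                            other_allele = c("G", "C", "G"),
                            beta = 0.1, se = 0.02))
  h <- harmonise(s1, s2)
  expect_equal(h$variant_id, "rs1")
  expect_identical(attr(h, "n_dropped_mismatch"), 1L)   # rs2: A/G vs A/C
  # kept + dropped == shared IDs (rs4 and rs3 are not shared at all)
  expect_equal(nrow(h) + attr(h, "n_dropped_mismatch") +
               attr(h, "n_dropped_palindromic"), 2L)
  # disjoint ID sets are a hard error
  expect_error(harmonise(s1, sumstats(data.frame(SNP = "rs9", effect_allele = "A",
    other_allele = "G", beta = 1, se = 1))), "share no variant")
})

test_that("harmonisation invariants hold over randomised tables", {
  set.seed(42)
  for (i in 1:60) {
    k <- sample(3:15, 1)
    s1 <- random_ss(k)
    df2 <- as.data.frame(s1)
    swap <- sample(c(TRUE, FALSE), k, replace = TRUE)
    ea <- df2$effect_allele
    df2$effect_allele[swap] <- df2$other_allele[swap]
    df2$other_allele[swap] <- ea[swap]
    df2$beta <- stats::rnorm(k, 0, 0.2)
    df2$eaf[swap] <- 1 - df2$eaf[swap]
    s2 <- sumstats(df2)

    h12 <- harmonise(s1, s2)
    # sign-flip rule is exact for swapped variants
    expect_equal(h12$beta2[match(df2$SNP[swap], h12$variant_id)],
                 -df2$beta[swap])
    # counts conserve
    expect_equal(nrow(h12) + attr(h12, "n_dropped_palindromic") +
                 attr(h12, "n_dropped_mismatch"), k)
    # involution: harmonising the other way negates every difference once both
    # are expressed on the same reference allele (h21 reports on s2's effect
    # allele, which is the opposite allele exactly for the swapped variants)
    h21 <- harmonise(s2, s1)
    m <- match(h12$variant_id, h21$variant_id)
    orient <- ifelse(swap[match(h12$variant_id, df2$SNP)], -1, 1)
    d21_on_s1_allele <- orient * (h21$beta1 - h21$beta2)[m]
    expect_equal(h12$beta1 - h12$beta2, -d21_on_s1_allele)
    # per-variant evidence is direction-invariant (the pooled fixed-effects
    # difference is not, since each variant's sign convention follows the
    # chosen effect allele; Fisher's method is orientation-free)
    r12 <- suppressWarnings(run_test(h12))   # wide random betas can underflow p
    r21 <- suppressWarnings(run_test(h21))
    expect_equal(r12$per_snp$p, r21$per_snp$p[m], tolerance = 1e-12)
    expect_equal(r12$combined$p_fisher, r21$combined$p_fisher, tolerance = 1e-12)
  }
})

test_that("unit-label mismatch warns but does not abort", {
  s1 <- make_ss("rs1", "A", "G", 0.10, 0.02, unit = "Kg")
  s2 <- make_ss("rs1", "A", "G", 0.08, 0.02, unit = "SD")
  expect_warning(h <- harmonise(s1, s2), "unit labels differ")
  expect_equal(nrow(h), 1L)
  # case-insensitive comparison: no warning
  s2 <- make_ss("rs1", "A", "G", 0.08, 0.02, unit = "kg")
  expect_silent(harmonise(s1, s2))
})

test_that("scale diagnostic flags fold differences in median effect magnitude", {
  pair <- function(b1, b2) {
    k <- length(b1)
    harmonise(make_ss(sprintf("rs%d", 1:k), "A", "G", b1, rep(0.02, k)),
              make_ss(sprintf("rs%d", 1:k), "A", "G", b2, rep(0.02, k)))
  }
  d <- scale_diagnostic(pair(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3)))
  expect_equal(d$ratio, 1.0)
  expect_false(d$warn)

  expect_warning(d <- scale_diagnostic(pair(c(0.5, 1.0), c(0.05, 0.10)),
                                       fold_threshold = 5), "different scales")
  expect_equal(d$ratio, 10.0)
  expect_true(d$warn)

  d <- scale_diagnostic(pair(c(0.3, 0.6), c(0.1, 0.2)), fold_threshold = 5)
  expect_equal(d$ratio, 3.0)
  expect_false(d$warn)

  # the flag is symmetric: a small ratio warns too
  expect_warning(d <- scale_diagnostic(pair(c(0.05, 0.10), c(0.5, 1.0)),
                                       fold_threshold = 5))
  expect_equal(d$ratio, 0.1)

  # zero median falls back to the smallest positive magnitude
  d <- scale_diagnostic(pair(c(0, 0, 0.4), c(0.2, 0.3, 0.4)), fold_threshold = 10)
  expect_equal(d$ratio, 0.2 / 0.3)
})
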