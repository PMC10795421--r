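# Independent re-implementations of the tail probabilities used by the test,
# kept deliberately separate from the package's pnorm/pchisq calls.

# two-sided standard-normal tail by numerical integration of the density
ptail_oracle <- function(z) {
  2 * stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
                       abs(z), Inf, rel.tol = 1e-13)$value
}

# chi-square survival function for even df via the Erlang closed form
chisq_sf_even_oracle <- function(x, df) {
  stopifnot(df %% 2 == 0)
  k <- df / 2
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# quick sumstats builder with sensible defaults
make_ss <- function(snp, ea, oa, beta, se, eaf = NA_real_, unit = "SD", ...) {
  sumstats(data.frame(SNP = snp, effect_allele = ea, other_allele = oa,
                      beta = beta, se = se, eaf = eaf, stringsAsFactors = FALSE),
           unit_label = unit, ...)
}

# random well-formed sumstats table of k non-palindromic variants
random_ss <- function(k, ids = sprintf("rs%d", seq_len(k))) {
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  al <- pairs[sample.int(4L, k, replace = TRUE)]
  sumstats(data.frame(
    SNP = ids,
    effect_allele = vapply(al, `[`, "", 1L),
    other_allele = vapply(al, `[`, "", 2L),
    beta = stats::rnorm(k, 0, 0.2),
    se = stats::runif(k, 0.01, 0.2),
    eaf = stats::runif(k, 0.05, 0.95),
    stringsAsFactors = FALSE))
}

# 99% binomial (normal-approximation) CI for an observed proportion
binom_ci99 <- function(x, n) {
  p <- x / n
  hw <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  c(p - hw, p + hw)
}
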