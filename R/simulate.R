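#' Parameters for the sex-structured effect-modification simulation
#'
#' The simulation emulates a common two-sample MR setting: one GWAS measured
#' in a mixed-sex population and one in a single sex, with a genetic effect
#' that is modified by sex. Each individual carries a genotype
#' `G ~ Binomial(2, maf)` and a sex indicator `S`; the phenotype is
#'
#' `Y = beta * G + beta * em * G * S + epsilon`,  `epsilon ~ Normal(0, 1)`,
#'
#' so the allele effect is `beta` in one sex and `beta * (1 + em)` in the
#' other. Sample 1 is mixed-sex (`S ~ Bernoulli(sex_prop_mixed)`); sample 2
#' is entirely the lower-effect sex (`S = 0`). The average allele effect
#' therefore differs between samples by a factor `1 + em * sex_prop_mixed`:
#' with a 50/50 mixed sample, the percent change in average effect is half
#' the effect-modification parameter (`change_pct = 100 * em / 2`).
#'
#' `beta` is set from the target variance explained by the instrument,
#' `var_explained = beta^2 * 2 * maf * (1 - maf) / (beta^2 * 2 * maf * (1 - maf) + 1)`,
#' using the lower-effect sex's `beta` and the unit-variance noise term; the
#' small additional variance contributed by the interaction is ignored.
#'
#' Exactly one of `em` and `change_pct` must be supplied (or both,
#' consistently): they are linked by `change_pct = 100 * em * sex_prop_mixed`.
#'
#' @param n1,n2 individuals in the mixed-sex and single-sex GWAS. The default
#'   368,000 per GWAS is a one-time calibration of the design's power curve
#'   (see the package vignette); together with `maf = 0.3` it fixes the
#'   operating characteristics of the shipped power grid.
#' @param maf minor-allele frequency of the instrument, in (0, 0.5].
#' @param em effect-modification parameter (>= 0): the higher-effect sex's
#'   allele effect is `beta * (1 + em)`.
#' @param change_pct target percent change in average allele effect between
#'   the two samples (>= 0).
#' @param var_explained target variance explained by the instrument in the
#'   mixed sample, in (0, 1).
#' @param sex_prop_mixed proportion of the higher-effect sex in the mixed
#'   sample, in (0, 1); 0.5 gives the 50/50 design.
#' @param n_snps number of independent instruments (1 for the single-SNP
#'   design). Each instrument is simulated as an independent replicate of the
#'   design (independent genotypes and noise), so the per-SNP differences are
#'   exactly independent.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(n1 = 368000L, n2 = 368000L, maf = 0.3,
                              em = NULL, change_pct = NULL,
                              var_explained = 0.01, sex_prop_mixed = 0.5,
                              n_snps = 1L, seed = NULL) {
  stopifnot(n1 >= 10, n2 >= 10, n1 == round(n1), n2 == round(n2),
            is.numeric(maf), maf > 0, maf <= 0.5,
            is.numeric(var_explained), length(var_explained) == 1L,
            is.numeric(sex_prop_mixed), sex_prop_mixed > 0, sex_prop_mixed < 1,
            n_snps >= 1, n_snps == round(n_snps))
  if (var_explained <= 0 || var_explained >= 1) {
    stop("var_explained must be in (0, 1): outside this range no positive noise variance exists")
  }
  if (is.null(em) && is.null(change_pct)) {
    stop("supply em or change_pct")
  }
  if (is.null(em)) em <- change_pct / (100 * sex_prop_mixed)
  if (is.null(change_pct)) change_pct <- 100 * em * sex_prop_mixed
  stopifnot(is.numeric(em), em >= 0)
  if (abs(change_pct - 100 * em * sex_prop_mixed) > 1e-8) {
    stop("em and change_pct are inconsistent: change_pct = 100 * em * sex_prop_mixed")
  }
  if (!is.null(seed)) stopifnot(seed == round(seed))
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), maf = maf,
                 em = em, change_pct = change_pct,
                 var_explained = var_explained,
                 sex_prop_mixed = sex_prop_mixed,
                 n_snps = as.integer(n_snps),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_params")
}

# base-sex allele effect implied by the target variance explained (sigma = 1)
instrument_beta <- function(maf, var_explained) {
  sqrt(var_explained / ((1 - var_explained) * 2 * maf * (1 - maf)))
}

# OLS of Y on G from per-individual draws; returns c(beta, se, eaf)
ols_individual <- function(n, maf, b, em, q_sex) {
  g <- stats::rbinom(n, 2L, maf)
  s <- if (q_sex > 0) stats::rbinom(n, 1L, q_sex) else integer(n)
  y <- b * g + b * em * g * s + stats::rnorm(n)
  sx <- sum(g); sy <- sum(y)
  sxx <- sum(g * g) - sx^2 / n
  if (sxx <= 0) stop("degenerate genotype draw: no variance in G")
  sxy <- sum(g * y) - sx * sy / n
  syy <- sum(y * y) - sy^2 / n
  beta_hat <- sxy / sxx
  sse <- max(syy - sxy^2 / sxx, 0)
  c(beta = beta_hat, se = sqrt(sse / (n - 2) / sxx), eaf = sx / (2 * n))
}

# distributionally exact OLS draw from per-cell sufficient statistics:
# genotype-by-sex cell counts ~ multinomial; cell sums of Y ~ normal;
# within-cell sums of squares ~ chisq(n_cell - 1)
ols_sufficient <- function(n, maf, b, em, q_sex) {
  pg <- stats::dbinom(0:2, 2L, maf)
  if (q_sex > 0) {
    probs <- c(pg * (1 - q_sex), pg * q_sex)
    g <- rep(0:2, 2L); s <- rep(c(0, 1), each = 3L)
  } else {
    probs <- pg; g <- 0:2; s <- c(0, 0, 0)
  }
  cnt <- as.vector(stats::rmultinom(1L, n, probs))
  mu <- b * g * (1 + em * s)
  cell_sum <- stats::rnorm(length(cnt), cnt * mu, sqrt(cnt))
  cell_sum[cnt == 0L] <- 0
  ssw <- stats::rchisq(length(cnt), pmax(cnt - 1L, 0L))
  sy <- sum(cell_sum)
  syy <- sum(ssw) + sum(ifelse(cnt > 0L, cell_sum^2 / cnt, 0)) - sy^2 / n
  sx <- sum(g * cnt)
  sxx <- sum(g^2 * cnt) - sx^2 / n
  if (sxx <= 0) stop("degenerate genotype draw: no variance in G")
  sxy <- sum(g * cell_sum) - sx * sy / n
  beta_hat <- sxy / sxx
  sse <- max(syy - sxy^2 / sxx, 0)
  c(beta = beta_hat, se = sqrt(sse / (n - 2) / sxx), eaf = sx / (2 * n))
}

#' Simulate a pair of GWAS summary-statistics tables
#'
#' Draws one mixed-sex and one single-sex GWAS under the generating model of
#' [simulation_params()] and returns per-variant least-squares association
#' estimates as two [sumstats] tables, alleles already aligned (same effect
#' allele in both samples).
#'
#' Two samplers are available. `"individual"` draws every individual's
#' genotype, sex and phenotype and runs the regression literally.
#' `"sufficient"` draws the regression's sufficient statistics per
#' genotype-by-sex cell (cell counts are multinomial; within-cell phenotype
#' sums are normal; within-cell sums of squares are scaled chi-square), which
#' has exactly the same sampling distribution at a cost independent of the
#' sample size; it is the default and is what the grid runners use.
#'
#' @param params a [simulation_params()] object.
#' @param method `"sufficient"` (default) or `"individual"`.
#' @return list with components `mixed` and `single`, each a [sumstats]
#'   object of `params$n_snps` variants.
#' @export
simulate_pair <- function(params, method = c("sufficient", "individual")) {
  stopifnot(inherits(params, "simulation_params"))
  method <- match.arg(method)
  if (!is.null(params$seed)) set.seed(params$seed)
  draw <- if (method == "individual") ols_individual else ols_sufficient
  b <- instrument_beta(params$maf, params$var_explained)
  k <- params$n_snps
  est1 <- matrix(0, k, 3L); est2 <- matrix(0, k, 3L)
  for (j in seq_len(k)) {
    est1[j, ] <- draw(params$n1, params$maf, b, params$em, params$sex_prop_mixed)
    est2[j, ] <- draw(params$n2, params$maf, b, params$em, 0)
  }
  make <- function(est, n) {
    sumstats(data.frame(
      SNP = sprintf("rs%d", seq_len(k)),
      effect_allele = "A", other_allele = "G",
      beta = est[, 1L], se = est[, 2L], eaf = est[, 3L],
      pval = 2 * stats::pnorm(-abs(est[, 1L] / est[, 2L])),
      samplesize = n, stringsAsFactors = FALSE),
      phenotype_label = "simulated phenotype", unit_label = "model units")
  }
  list(mixed = make(est1, params$n1), single = make(est2, params$n2))
}

#' Power / type-I-error grid of the difference test
#'
#' For every cell of a (percent change in average effect) x (percent variance
#' explained) grid, repeatedly simulates a mixed-sex / single-sex GWAS pair,
#' harmonises it, runs the same-population test, and records the accuracy of
#' the verdict: in the no-change row accuracy is the percentage of iterations
#' in which the test correctly does NOT detect a difference; in every other
#' row it is the percentage in which it does. Detection uses the
#' fixed-effects p-value at `alpha`; Fisher's-method detection rates are
#' recorded alongside.
#'
#' Reproducibility: one master seed (`base_params$seed`, default 1) generates
#' a deterministic sub-seed for every (cell, iteration), so results are
#' bit-identical for identical inputs and each cell is independent of grid
#' layout.
#'
#' @param change_levels percent changes in average effect (grid rows), e.g.
#'   `c(0, 2.5, 5, 12.5, 25, 37.5, 50)`.
#' @param var_levels percent variance explained by the instrument (grid
#'   columns), e.g. `c(1, 5, 10)`.
#' @param iterations simulated pairs per cell.
#' @param base_params [simulation_params()] supplying everything except the
#'   two grid dimensions.
#' @param alpha two-sided significance level.
#' @param method sampler passed to [simulate_pair()].
#' @return matrix of class `power_grid` (rows = change levels, cols =
#'   variance levels, cells = accuracy in percent) with attributes
#'   `detection_fixed` and `detection_fisher` (raw detection percentages),
#'   `iterations`, `alpha`, `params`.
#' @export
run_grid <- function(change_levels, var_levels, iterations = 1000L,
                     base_params = simulation_params(change_pct = 0),
                     alpha = 0.05, method = "sufficient") {
  stopifnot(length(change_levels) >= 1L, all(is.finite(change_levels)),
            all(change_levels >= 0),
            length(var_levels) >= 1L, all(is.finite(var_levels)),
            all(var_levels > 0), all(var_levels < 100),
            iterations >= 1L, inherits(base_params, "simulation_params"))
  master_seed <- if (is.null(base_params$seed)) 1L else base_params$seed
  n_cells <- length(change_levels) * length(var_levels)
  set.seed(master_seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max, n_cells * iterations),
                      nrow = n_cells)

  det_fe <- det_fi <- matrix(NA_real_, length(change_levels), length(var_levels),
                             dimnames = list(sprintf("%g%%", change_levels),
                                             sprintf("%g%%", var_levels)))
  cell <- 0L
  for (ci in seq_along(var_levels)) {
    for (ri in seq_along(change_levels)) {
      cell <- cell + 1L
      hit_fe <- hit_fi <- logical(iterations)
      for (it in seq_len(iterations)) {
        p <- base_params
        p$change_pct <- change_levels[ri]
        p$em <- change_levels[ri] / (100 * p$sex_prop_mixed)
        p$var_explained <- var_levels[ci] / 100
        p$seed <- sub_seeds[cell, it]
        pair <- simulate_pair(p, method = method)
        h <- harmonise(pair$mixed, pair$single)
        # high-power cells routinely underflow per-variant p-values to 0;
        # run_test floors them for Fisher and warns, which is noise here
        res <- suppressWarnings(run_test(h, alpha = alpha))
        hit_fe[it] <- res$detected
        hit_fi[it] <- res$combined$p_fisher < alpha
      }
      det_fe[ri, ci] <- 100 * mean(hit_fe)
      det_fi[ri, ci] <- 100 * mean(hit_fi)
    }
  }
  accuracy <- det_fe
  null_rows <- change_levels == 0
  accuracy[null_rows, ] <- 100 - det_fe[null_rows, , drop = FALSE]
  structure(accuracy,
            detection_fixed = det_fe, detection_fisher = det_fi,
            iterations = as.integer(iterations), alpha = alpha,
            change_levels = change_levels, var_levels = var_levels,
            params = base_params, seed = master_seed,
            class = c("power_grid", "matrix"))
}

#' Multi-instrument power grid
#'
#' As [run_grid()] but each iteration simulates `n_snps` independent
#' instruments and combines their differences by fixed-effects meta-analysis
#' (Fisher's method reported in parallel).
#'
#' @inheritParams run_grid
#' @param n_snps number of independent instruments, at least 2.
#' @return a `power_grid`, see [run_grid()].
#' @export
run_grid_multi_snp <- function(change_levels, var_levels, iterations = 1000L,
                               base_params = simulation_params(change_pct = 0),
                               alpha = 0.05, n_snps = 5L, method = "sufficient") {
  stopifnot(n_snps >= 2L)
  base_params$n_snps <- as.integer(n_snps)
  run_grid(change_levels, var_levels, iterations = iterations,
           base_params = base_params, alpha = alpha, method = method)
}

#' @export
print.power_grid <- function(x, ...) {
  it <- attr(x, "iterations")
  cat(sprintf("Accuracy grid over %d iterations/cell (alpha = %g, n_snps = %d)\n",
              it, attr(x, "alpha"), attr(x, "params")$n_snps))
  cat("rows: % change in average effect; cols: % variance explained\n")
  cat("(0% row: % of iterations correctly NOT detecting; other rows: % detecting)\n")
  m <- matrix(sprintf("%.1f", unclass(x)), nrow(x), dimnames = dimnames(x))
  print(m, quote = FALSE)
  invisible(x)
}

#' Write a power grid as tab-separated text
#'
#' `#`-prefixed metadata lines (all simulation parameters, alpha, iterations,
#' seed) followed by the accuracy matrix with row and column labels.
#'
#' @param grid a `power_grid` from [run_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "power_grid"))
  p <- attr(grid, "params")
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(n1 = p$n1, n2 = p$n2, maf = p$maf,
            sex_prop_mixed = p$sex_prop_mixed, n_snps = p$n_snps,
            iterations = attr(grid, "iterations"), alpha = attr(grid, "alpha"),
            seed = attr(grid, "seed"))
  for (nm in names(meta)) writeLines(sprintf("# %s\t%s", nm, format(meta[[nm]], digits = 15)), con)
  df <- data.frame(change = rownames(grid), unclass(grid), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
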