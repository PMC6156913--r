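#' Build a synthetic haplotype pool
#'
#' Constructs H haplotypes over M = M_rare + M_common variants together with
#' haplotype frequencies, emulating the allele-frequency spectrum of a small
#' sequenced gene: a few frequent backbone haplotypes and a long tail of
#' rare ones. Haplotype frequencies follow a jittered power law; each
#' variant's minor allele is placed on a random subset of haplotypes whose
#' total frequency lands in the requested MAF range, so variants sharing
#' haplotypes acquire weak haplotype-structure correlation rather than being
#' independent columns. This pool is synthetic: it matches the shape
#' (variant counts and MAF ranges) of a sequenced-gene pool, not any
#' particular gene's frequencies.
#'
#' @param M_rare,M_common number of rare and common variants (defaults 8, 2).
#' @param maf_rare,maf_common target MAF ranges; defaults [0.001, 0.01) and
#'   [0.05, 0.5].
#' @param H number of haplotypes (default 64).
#' @param seed integer seed.
#' @return object of class \code{haplotype_pool}: \code{haplotypes}
#'   (H x M 0/1 matrix), \code{freq} (length H, sums to 1), \code{maf}
#'   (implied per-variant MAFs), \code{is_rare} (logical per variant).
#' @export
haplotype_pool <- function(M_rare = 8, M_common = 2,
                           maf_rare = c(0.001, 0.01),
                           maf_common = c(0.05, 0.5),
                           H = 64, seed = NULL) {
  M <- M_rare + M_common
  if (M < 1) stop("need at least one variant")
  if (H < 2) stop("need at least two haplotypes")
  with_seed(seed, {
    # power-law frequencies with lognormal jitter: many tiny, a few large
    raw <- (1 / seq_len(H))^1.5 * exp(stats::rnorm(H, 0, 0.4))
    freq <- raw / sum(raw)

    ranges <- c(rep(list(maf_rare), M_rare), rep(list(maf_common), M_common))
    hap <- matrix(0L, H, M)
    maf <- numeric(M)
    for (m in seq_len(M)) {
      lo <- ranges[[m]][1]; hi <- ranges[[m]][2]
      target <- stats::runif(1, lo, hi)
      done <- FALSE
      for (try in seq_len(200)) {
        ord <- sample.int(H)
        cum <- 0; members <- integer(0)
        for (h in ord) {
          if (cum >= target) break
          if (cum + freq[h] < hi) {
            cum <- cum + freq[h]
            members <- c(members, h)
          }
        }
        if (cum >= lo && cum < hi && length(members)) {
          hap[members, m] <- 1L
          maf[m] <- cum
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("infeasible MAF spectrum: could not place a variant with MAF in [",
             lo, ", ", hi, ") on ", H, " haplotypes")
    }
    colnames(hap) <- c(if (M_rare) paste0("rare", seq_len(M_rare)),
                       if (M_common) paste0("common", seq_len(M_common)))
    structure(list(haplotypes = hap, freq = freq, maf = maf,
                   is_rare = c(rep(TRUE, M_rare), rep(FALSE, M_common))),
              class = "haplotype_pool")
  })
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes x %d variants (%d rare, %d common)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              sum(x$is_rare), sum(!x$is_rare)))
  cat("  implied MAFs:", paste(signif(x$maf, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Draw diploid genotypes from a haplotype pool
#'
#' Each individual is the sum of two haplotypes drawn independently with the
#' pool frequencies, giving minor-allele dosages in \{0, 1, 2\}.
#'
#' @param pool a \code{\link{haplotype_pool}}.
#' @param n number of individuals.
#' @param seed integer seed.
#' @return a \code{genotype_matrix}; the variant metadata carries the pool's
#'   \code{is_rare} designation.
#' @export
draw_genotypes <- function(pool, n, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"))
  H <- nrow(pool$haplotypes)
  counts <- with_seed(seed, {
    h1 <- sample.int(H, n, replace = TRUE, prob = pool$freq)
    h2 <- sample.int(H, n, replace = TRUE, prob = pool$freq)
    pool$haplotypes[h1, , drop = FALSE] + pool$haplotypes[h2, , drop = FALSE]
  })
  meta <- data.frame(id = colnames(pool$haplotypes),
                     is_rare = pool$is_rare,
                     pool_maf = pool$maf,
                     stringsAsFactors = FALSE)
  genotype_matrix(counts, samples = paste0("S", seq_len(n)), variants = meta)
}

#' Simulation configuration
#'
#' Bundles every parameter of the trait model
#' \code{Y = 0.5 Z1 + 0.5 Z2 + alpha1 E + G alpha2 + E (G_r beta) +
#' E G_c beta_c + eps}, with \code{Z1 ~ N(0,1)}, \code{Z2 ~ Bernoulli(0.5)},
#' \code{E ~ N(0,1)} (or Bernoulli(0.5) in binary-environment mode) and
#' \code{eps ~ N(0,1)}. Interaction effects \code{beta} act on a subset of
#' the rare variants with |beta_j| = c and half the signs positive (rounded
#' up); one designated common variant carries a positive interaction effect
#' of twice that magnitude.
#'
#' @param n sample size (default 2000).
#' @param M_rare,M_common gene shape (defaults 8 rare + 2 common).
#' @param rare_threshold MAF cutoff used by the tests (default 0.01).
#' @param alpha1 environment main effect (default 0.015).
#' @param main_effect include genotype main effects with |alpha2| = 0.3 and
#'   random signs (TRUE) or set alpha2 = 0 (FALSE).
#' @param c interaction magnitude |beta_j| (0 gives the null scenario).
#' @param n_nonzero_beta number of rare variants with nonzero interaction
#'   effect (default 4).
#' @param env \code{"normal"} (standard normal exposure) or \code{"binary"}
#'   (Bernoulli(0.5)).
#' @param replicates Monte Carlo replicates for experiments (default 1000).
#' @param permutations permutations per test (default 10000).
#' @param H haplotype pool size (default 64).
#' @param seed master seed for an experiment.
#' @export
sim_config <- function(n = 2000, M_rare = 8, M_common = 2,
                       rare_threshold = 0.01, alpha1 = 0.015,
                       main_effect = TRUE, c = 0, n_nonzero_beta = 4,
                       env = c("normal", "binary"),
                       replicates = 1000, permutations = 10000,
                       H = 64, seed = NULL) {
  env <- match.arg(env)
  if (c < 0) stop("interaction magnitude c must be >= 0")
  if (n_nonzero_beta > M_rare)
    stop("number of nonzero interaction effects exceeds the rare variant count")
  structure(list(n = n, M_rare = M_rare, M_common = M_common,
                 rare_threshold = rare_threshold, alpha1 = alpha1,
                 main_effect = main_effect, c = c,
                 n_nonzero_beta = n_nonzero_beta, env = env,
                 replicates = replicates, permutations = permutations,
                 H = H, seed = seed),
            class = "sim_config")
}

#' Simulate a trait from genotypes under the interaction model
#'
#' @param G a \code{genotype_matrix} drawn by \code{\link{draw_genotypes}}
#'   (the variant metadata identifies rare vs common variants).
#' @param cfg a \code{\link{sim_config}}.
#' @param seed integer seed for covariates, environment, coefficients signs
#'   and noise.
#' @return a \code{sample_table} with trait y, environment E and covariates
#'   Z1, Z2; the realized coefficient vectors are attached as attribute
#'   \code{"coefficients"}.
#' @export
simulate_trait <- function(G, cfg, seed = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(cfg, "sim_config"))
  n <- nrow(G$counts); M <- ncol(G$counts)
  is_rare <- G$variants$is_rare
  if (is.null(is_rare))
    is_rare <- G$variants$maf < cfg$rare_threshold
  with_seed(seed, {
    Z1 <- stats::rnorm(n)
    Z2 <- stats::rbinom(n, 1, 0.5)
    E <- if (cfg$env == "binary") stats::rbinom(n, 1, 0.5) else stats::rnorm(n)
    eps <- stats::rnorm(n)

    alpha2 <- rep(0, M)
    if (cfg$main_effect)
      alpha2 <- 0.3 * sample(c(-1, 1), M, replace = TRUE)

    beta <- rep(0, M)
    if (cfg$c > 0 && cfg$n_nonzero_beta > 0) {
      rare_idx <- which(is_rare)
      if (cfg$n_nonzero_beta > length(rare_idx))
        stop("number of nonzero interaction effects exceeds the rare variant count")
      causal <- sample(rare_idx, cfg$n_nonzero_beta)
      k <- cfg$n_nonzero_beta
      npos <- ceiling(k / 2)                    # 50% positive, rounded up
      signs <- sample(c(rep(1, npos), rep(-1, k - npos)))
      beta[causal] <- cfg$c * signs
      common_idx <- which(!is_rare)
      if (length(common_idx))
        beta[common_idx[1]] <- 2 * cfg$c        # positive, twice |beta_j|
    }

    y <- 0.5 * Z1 + 0.5 * Z2 + cfg$alpha1 * E +
      as.numeric(G$counts %*% alpha2) +
      E * as.numeric(G$counts %*% beta) + eps

    st <- sample_table(G$samples, y, E, Z = cbind(Z1 = Z1, Z2 = Z2),
                       trait_kind = "continuous")
    attr(st, "coefficients") <- list(alpha1 = cfg$alpha1, alpha2 = alpha2,
                                     beta = beta)
    st
  })
}

# One simulated replicate: fresh genotypes and trait, then both tests on a
# single shared permutation stream.
sim_replicate <- function(pool, cfg, rep_seed) {
  geno <- draw_genotypes(pool, cfg$n, seed = derive_seed(rep_seed, "geno"))
  pheno <- simulate_trait(geno, cfg, seed = derive_seed(rep_seed, "trait"))
  tryCatch({
    prep <- prepare_test_data(geno, pheno)
    part <- partition_variants(prep$mafs, cfg$rare_threshold)
    plan <- permutation_plan(cfg$permutations,
                             seed = derive_seed(rep_seed, "perm"))
    perms <- permute_residuals(prep$resid, plan, partition = part)
    c(tow = pvalue_tow(perms$T[1], perms$T[-1]),
      vw = pvalue_vw(perms$T_r, perms$T_c)$p_value)
  }, error = function(e) {
    if (grepl("no testable interaction", conditionMessage(e)))
      c(tow = NA_real_, vw = NA_real_)
    else stop(e)
  })
}

# Replicated p-values for a scenario; rows = replicates.
sim_pvalues <- function(cfg, pool = NULL) {
  if (is.null(pool))
    pool <- haplotype_pool(cfg$M_rare, cfg$M_common, H = cfg$H,
                           seed = derive_seed(cfg$seed, "pool"))
  ps <- vapply(seq_len(cfg$replicates), function(i) {
    sim_replicate(pool, cfg, derive_seed(cfg$seed, paste0("rep", i)))
  }, numeric(2))
  t(ps)
}

#' Empirical Type I error experiment
#'
#' Runs the null scenario (all interaction effects zero): per replicate a
#' fresh genotype sample is drawn from one haplotype pool, a null trait is
#' simulated, and both TOW-SE and VW-TOW-SE are evaluated by permutation.
#' Rejection fractions are reported with exact (Clopper-Pearson) binomial
#' 95% intervals.
#'
#' @param cfg a \code{\link{sim_config}}; its \code{c} is forced to 0.
#' @param alphas nominal levels (default 0.05, 0.01, 0.001).
#' @return data.frame: scenario, test, alpha, rate, ci_lo, ci_hi,
#'   replicates, permutations.
#' @export
run_type1_experiment <- function(cfg, alphas = c(0.05, 0.01, 0.001)) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$c <- 0
  pv <- sim_pvalues(cfg)
  scenario <- if (cfg$main_effect) "null_with_main_effect" else "null_no_main_effect"
  rows <- list()
  for (test in colnames(pv)) {
    p <- pv[, test]
    p <- p[!is.na(p)]
    for (a in alphas) {
      k <- sum(p <= a)
      ci <- stats::binom.test(k, length(p))$conf.int
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scenario,
        test = c(tow = "TOW-SE", vw = "VW-TOW-SE")[test],
        alpha = a, rate = k / length(p), ci_lo = ci[1], ci_hi = ci[2],
        replicates = length(p), permutations = cfg$permutations,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Empirical power experiment over a grid of effect sizes
#'
#' For each interaction magnitude c in the grid, simulates traits with
#' nonzero rare-variant interaction effects |beta_j| = c (half positive) and
#' a positive common-variant effect 2c, and reports the rejection fraction
#' of each test at the given level.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param c_grid effect-size grid (default \code{c(0.02, 0.04, 0.06, 0.08, 0.1)}).
#' @param alpha rejection level (default 0.05).
#' @return data.frame: scenario, test, c, power, ci_lo, ci_hi, replicates,
#'   permutations.
#' @export
run_power_experiment <- function(cfg, c_grid = c(0.02, 0.04, 0.06, 0.08, 0.1),
                                 alpha = 0.05) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(c_grid < 0)) stop("effect sizes must be >= 0")
  pool <- haplotype_pool(cfg$M_rare, cfg$M_common, H = cfg$H,
                         seed = derive_seed(cfg$seed, "pool"))
  scenario <- if (cfg$main_effect) "power_with_main_effect" else "power_no_main_effect"
  rows <- list()
  for (cc in c_grid) {
    cfg_c <- cfg
    cfg_c$c <- cc
    cfg_c$seed <- derive_seed(cfg$seed, paste0("c", cc))
    pv <- sim_pvalues(cfg_c, pool = pool)
    for (test in colnames(pv)) {
      p <- pv[, test]; p <- p[!is.na(p)]
      k <- sum(p <= alpha)
      ci <- stats::binom.test(k, length(p))$conf.int
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scenario,
        test = c(tow = "TOW-SE", vw = "VW-TOW-SE")[test],
        c = cc, power = k / length(p), ci_lo = ci[1], ci_hi = ci[2],
        replicates = length(p), permutations = cfg$permutations,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
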