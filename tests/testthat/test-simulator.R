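test_that("haplotype pool respects the requested MAF spectrum", {
  pool <- haplotype_pool(M_rare = 8, M_common = 2, seed = 61)
  expect_equal(sum(pool$freq), 1, tolerance = 1e-12)
  expect_true(all(pool$freq >= 0))
  expect_true(all(pool$maf[pool$is_rare] >= 0.001 &
                    pool$maf[pool$is_rare] < 0.01))
  expect_true(all(pool$maf[!pool$is_rare] >= 0.05 &
                    pool$maf[!pool$is_rare] <= 0.5))
  # implied MAF equals the frequency mass of carrier haplotypes
  expect_equal(pool$maf,
               as.numeric(crossprod(pool$haplotypes, pool$freq)),
               tolerance = 1e-12)
})

test_that("an infeasible spectrum errors instead of silently drifting", {
  # two haplotypes cannot represent a MAF below the smaller frequency
  expect_error(haplotype_pool(M_rare = 1, M_common = 0, H = 2, seed = 62),
               "infeasible MAF spectrum")
})

test_that("degenerate single-haplotype pools propagate to constant genotypes", {
  mk_pool <- function(allele) {
    structure(list(haplotypes = matrix(allele, 2, 1,
                                       dimnames = list(NULL, "v1")),
                   freq = c(1, 0), maf = sum(allele * c(1, 0)),
                   is_rare = FALSE),
              class = "haplotype_pool")
  }
  g0 <- draw_genotypes(mk_pool(c(0L, 0L)), 20, seed = 63)
  expect_true(all(g0$counts == 0))
  g2 <- draw_genotypes(mk_pool(c(1L, 1L)), 20, seed = 63)
  # an all-carrier column is folded onto the minor allele at ingest
  expect_true(all(g2$counts == 0) && g2$variants$flipped)
})

test_that("sampled dosages reproduce the implied MAFs", {
  pool <- haplotype_pool(seed = 64)
  g <- draw_genotypes(pool, 1e5, seed = 65)
  # dosage ~ Binomial(2, q): empirical allele frequency within 3 MC SE
  for (m in seq_along(pool$maf)) {
    q <- pool$maf[m]
    se <- sqrt(q * (1 - q) / (2 * 1e5))
    expect_lt(abs(mean(g$counts[, m]) / 2 - q), 3 * se + 1e-12)
  }
})

test_that("null trait variance matches its analytic composition", {
  # Y = 0.5 Z1 + 0.5 Z2 + alpha1 E + eps under the null without main effects:
  # Var(Y) = 0.25 + 0.25 * 0.25 + alpha1^2 + 1
  pool <- haplotype_pool(seed = 66)
  g <- draw_genotypes(pool, 1e5, seed = 67)
  cfg <- sim_config(n = 1e5, main_effect = FALSE, c = 0)
  st <- simulate_trait(g, cfg, seed = 68)
  v_expected <- 0.25 + 0.25 * 0.25 + 0.015^2 + 1
  se <- v_expected * sqrt(2 / (1e5 - 1))
  expect_lt(abs(var(st$y) - v_expected), 3 * se)
})

test_that("trait generation is reproducible and validates its configuration", {
  pool <- haplotype_pool(seed = 69)
  g <- draw_genotypes(pool, 500, seed = 70)
  cfg <- sim_config(n = 500, c = 0.05)
  s1 <- simulate_trait(g, cfg, seed = 71)
  s2 <- simulate_trait(g, cfg, seed = 71)
  expect_identical(s1$y, s2$y)
  expect_error(sim_config(c = -1), ">= 0")
  expect_error(sim_config(n_nonzero_beta = 9, M_rare = 8),
               "exceeds the rare variant count")
})

test_that("interaction coefficients follow the effect-size rules", {
  pool <- haplotype_pool(seed = 72)
  g <- draw_genotypes(pool, 300, seed = 73)
  cfg <- sim_config(n = 300, c = 0.04, n_nonzero_beta = 5)
  st <- simulate_trait(g, cfg, seed = 74)
  co <- attr(st, "coefficients")
  beta_rare <- co$beta[g$variants$is_rare]
  nz <- beta_rare[beta_rare != 0]
  expect_length(nz, 5)
  expect_true(all(abs(nz) == 0.04))
  expect_equal(sum(nz > 0), 3)            # 50% positive, rounded up
  beta_common <- co$beta[!g$variants$is_rare]
  expect_equal(sum(beta_common != 0), 1)
  expect_equal(beta_common[beta_common != 0], 0.08)  # positive, twice |beta_j|
  expect_true(all(abs(co$alpha2) == 0.3))            # main-effect scenario
})

test_that("small Type I error runs stay inside the exact binomial band", {
  cfg <- sim_config(n = 300, replicates = 200, permutations = 300, seed = 75)
  res <- run_type1_experiment(cfg, alphas = c(0.05, 0.1))
  expect_true(all(res$rate >= 0 & res$rate <= 1))
  for (i in seq_len(nrow(res))) {
    band <- qbinom(c(0.005, 0.995), res$replicates[i], res$alpha[i]) /
      res$replicates[i]
    expect_gte(res$rate[i], band[1])
    expect_lte(res$rate[i], band[2])
  }
  # degenerate level rejects everything
  res1 <- run_type1_experiment(
    sim_config(n = 150, replicates = 20, permutations = 100, seed = 76),
    alphas = 1)
  expect_true(all(res1$rate == 1))
})

test_that("experiment runners are reproducible under a fixed master seed", {
  cfg <- sim_config(n = 200, replicates = 10, permutations = 100, seed = 77)
  r1 <- run_type1_experiment(cfg, alphas = 0.05)
  r2 <- run_type1_experiment(cfg, alphas = 0.05)
  expect_identical(r1, r2)
  p1 <- run_power_experiment(cfg, c_grid = c(0, 0.3), alpha = 0.05)
  p2 <- run_power_experiment(cfg, c_grid = c(0, 0.3), alpha = 0.05)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 4)   # one row per test per effect size
})
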