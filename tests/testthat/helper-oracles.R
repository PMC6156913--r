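# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths: scores are evaluated from the printed
# definitions, permutation nulls by literal enumeration / double loops.

# Full normalized score statistic S(w) for an arbitrary weight vector:
# S(w) = n * (sum (y - ybar)(x - xbar))^2 / (sum (y - ybar)^2 sum (x - xbar)^2)
# with x_i = sum_m w_m x_im.
oracle_score_S <- function(y, X, w) {
  x <- as.numeric(X %*% w)
  yc <- y - mean(y)
  xc <- x - mean(x)
  length(y) * sum(yc * xc)^2 / (sum(yc^2) * sum(xc^2))
}

# TOW statistic via the weighted-combination definition: compute the optimal
# weights from their printed formula, build the combined column, and take the
# centered cross-product with the residual trait.
oracle_T_combination <- function(y, X) {
  yc <- y - mean(y)
  w0 <- apply(X, 2, function(x) {
    xc <- x - mean(x)
    sum(yc * xc) / sum(xc^2)
  })
  x0 <- as.numeric(X %*% w0)
  sum(yc * (x0 - mean(x0)))
}

# All permutations of 1:n (row per permutation), by recursion.
oracle_all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub)))
  }))
}

# Exhaustive permutation T values (identity included), statistic computed
# per permutation from the closed form written out longhand.
oracle_exhaustive_T <- function(y, X) {
  perms <- oracle_all_perms(length(y))
  apply(perms, 1, function(p) {
    yp <- y[p]
    yc <- yp - mean(yp)
    sum(apply(X, 2, function(x) {
      xc <- x - mean(x)
      sum(yc * xc)^2 / sum(xc^2)
    }))
  })
}

# Brute-force corrected VW min-p: literal double loop over permutations and
# grid points, with the observed-first convention of the engine.
oracle_vw_corrected_p <- function(Tr_all, Tc_all, grid, exhaustive = FALSE) {
  B <- length(Tr_all) - 1
  zr <- (Tr_all - mean(Tr_all[-1])) / sd(Tr_all[-1])
  zc <- (Tc_all - mean(Tc_all[-1])) / sd(Tc_all[-1])
  p_of <- function(v_all, i, add_one) {
    cnt <- sum(v_all[-1] >= v_all[i])
    if (add_one) (1 + cnt) / (1 + B) else cnt / B
  }
  minp <- function(i, add_one) {
    min(sapply(grid, function(l) {
      v_all <- l * zr + (1 - l) * zc
      p_of(v_all, i, add_one)
    }))
  }
  obs <- minp(1, !exhaustive)
  perm_min <- sapply(seq_len(B) + 1, function(i) minp(i, FALSE))
  cnt <- sum(perm_min <= obs)
  if (exhaustive) cnt / B else (1 + cnt) / (1 + B)
}

# Residualized-data container built directly (bypasses the model fitting),
# for feeding hand-picked residual vectors to the statistic code.
make_resid <- function(y_res, X_res) {
  X_res <- as.matrix(X_res)
  structure(list(y_res = as.numeric(y_res), X_res = X_res,
                 n = length(y_res), M = ncol(X_res),
                 link = "identity", pruned = character(0)),
            class = "residualized_data")
}

# Random small residual instance (already mean-centered is not required).
random_resid <- function(n, M) {
  make_resid(rnorm(n), matrix(rnorm(n * M), n, M))
}

# Write a small VCF from a list of per-variant GT string vectors.
write_test_vcf <- function(path, samples, gts, ids = NULL, alts = NULL) {
  Mv <- length(gts)
  if (is.null(ids)) ids <- paste0("v", seq_len(Mv))
  if (is.null(alts)) alts <- rep("G", Mv)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (j in seq_len(Mv)) {
    lines <- c(lines, paste(c("1", 100 + j, ids[j], "A", alts[j], ".",
                              "PASS", ".", "GT", gts[[j]]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
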