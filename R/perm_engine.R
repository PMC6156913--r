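# Evaluate `code` under a temporary RNG state seeded by `seed`; the caller's
# RNG state is untouched. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit stream seed derived from a master seed and a label,
# so multi-set runs are order independent.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(as.character(label)))
    h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Create a permutation plan
#'
#' Fixes the number of permutations and the seed so that the permutation
#' stream is reproducible run to run. In exhaustive mode all n! orderings
#' (including the identity) are enumerated instead of sampled; p-values are
#' then exact counts without the add-one correction.
#'
#' @param B number of random permutations (default 10000); ignored when
#'   \code{exhaustive = TRUE}.
#' @param seed integer seed or NULL (use the current RNG stream).
#' @param exhaustive enumerate all n! orderings (n <= 8 enforced).
#' @export
permutation_plan <- function(B = 10000, seed = NULL, exhaustive = FALSE) {
  if (!exhaustive && B < 1) stop("B must be >= 1")
  structure(list(B = as.integer(B), seed = seed, exhaustive = exhaustive),
            class = "permutation_plan")
}

# All n! permutations of 1:n as an n! x n matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
  dimnames(out) <- NULL
  out
}

# n x B matrix of permuted sample indices for the plan.
plan_indices <- function(plan, n) {
  if (plan$exhaustive) {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    return(t(all_permutations(n)))
  }
  with_seed(plan$seed,
            vapply(seq_len(plan$B), function(b) sample.int(n), integer(n)))
}

#' Permuted TOW-SE statistics
#'
#' Re-evaluates the TOW-SE statistic under permutations of the residual
#' trait against the fixed residual interaction matrix. Only the residual
#' trait is reshuffled: both it and the interaction residuals are already
#' orthogonal to the nuisance design, so reshuffling breaks exactly the
#' trait-interaction association under test. One shared permutation stream
#' serves the full set and both MAF strata, which is what the VW-TOW-SE
#' correction requires (paired permuted statistics).
#'
#' @param resid a \code{residualized_data} object.
#' @param plan a \code{\link{permutation_plan}}.
#' @param partition optional \code{\link{partition_variants}} result; when
#'   supplied, per-stratum statistics are returned from the same stream.
#' @return list with \code{T} (length B + 1; the observed statistic first,
#'   then one value per permutation), and when \code{partition} is given
#'   \code{T_r} and \code{T_c} (NULL for a stratum with no retained columns);
#'   plus \code{retained}, \code{B}, \code{exhaustive}.
#' @export
permute_residuals <- function(resid, plan, partition = NULL) {
  parts <- tow_parts(resid)
  n <- resid$n
  idx <- plan_indices(plan, n)
  B <- ncol(idx)
  Y <- matrix(parts$yc[idx], nrow = n)
  C_all <- crossprod(parts$Xc, cbind(parts$yc, Y))  # M_ret x (B + 1)
  contrib <- C_all^2 / parts$V
  out <- list(T = colSums(contrib), retained = parts$retained,
              B = B, exhaustive = plan$exhaustive)
  if (!is.null(partition)) {
    rr <- which(parts$retained %in% partition$rare)
    cc <- which(parts$retained %in% partition$common)
    out$T_r <- if (length(rr)) colSums(contrib[rr, , drop = FALSE]) else NULL
    out$T_c <- if (length(cc)) colSums(contrib[cc, , drop = FALSE]) else NULL
  }
  out
}

#' Permutation p-value for a TOW-SE statistic
#'
#' Add-one one-sided convention for sampled permutations:
#' \code{p = (1 + #\{T_b >= T_obs\}) / (1 + B)}, which cannot be zero and is
#' valid for any B. With an exhaustive, identity-including enumeration the
#' exact count \code{#\{T_b >= T_obs\} / n!} is returned instead.
#'
#' @param T_obs observed statistic.
#' @param T_perm permuted statistics (length B).
#' @param exhaustive see \code{\link{permutation_plan}}.
#' @export
pvalue_tow <- function(T_obs, T_perm, exhaustive = FALSE) {
  B <- length(T_perm)
  if (B < 1) stop("need at least one permutation")
  cnt <- sum(T_perm >= T_obs)
  if (exhaustive) cnt / B else (1 + cnt) / (1 + B)
}

#' Corrected permutation p-value for VW-TOW-SE
#'
#' The VW-TOW-SE statistic is itself a minimum of p-values over the lambda
#' grid, so its null distribution must be evaluated on the same permutation
#' set: for each permutation b, the minimum over lambda of the rank-based
#' p-value of its own \code{T_lambda} within the permuted set is computed,
#' and the corrected p-value is the (add-one) fraction of permutations whose
#' minimum is at least as small as the observed minimum. This single-layer
#' correction needs no nested permutations because \code{p_lambda} is a rank
#' statistic of the shared stream.
#'
#' @param perm_Tr,perm_Tc observed-first vectors of stratum statistics from
#'   one shared \code{\link{permutation_plan}} (see
#'   \code{\link{permute_residuals}}); one may be NULL (empty stratum), in
#'   which case the result equals \code{pvalue_tow} on the other stratum.
#' @param lambda_grid mixing grid in [0, 1].
#' @param exhaustive see \code{\link{permutation_plan}}.
#' @return list(p_value, stat) with \code{stat} the \code{vw_statistic}.
#' @export
pvalue_vw <- function(perm_Tr, perm_Tc, lambda_grid = seq(0, 1, by = 0.1),
                      exhaustive = FALSE) {
  ev <- vw_perm_eval(perm_Tr, perm_Tc, lambda_grid, exhaustive)
  B <- ev$stat$B
  cnt <- sum(ev$minp_perm <= ev$stat$value)
  p <- if (exhaustive) cnt / B else (1 + cnt) / (1 + B)
  list(p_value = p, stat = ev$stat)
}
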