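#' Partition variants into rare and common strata
#'
#' Strict inequality defines the rare stratum: MAF < threshold. A variant
#' with MAF exactly at the threshold is common.
#'
#' @param mafs per-variant minor allele frequencies in [0, 0.5].
#' @param threshold rare/common MAF cutoff (default 0.01).
#' @return object of class \code{variant_partition}: \code{rare} and
#'   \code{common} column indices and the \code{threshold}.
#' @export
partition_variants <- function(mafs, threshold = 0.01) {
  mafs <- as.numeric(mafs)
  if (any(mafs < 0 | mafs > 0.5))
    stop("MAFs must lie in [0, 0.5] (minor-allele oriented)")
  structure(list(rare = which(mafs < threshold),
                 common = which(mafs >= threshold),
                 threshold = threshold),
            class = "variant_partition")
}

#' Convex combination of standardized stratum statistics
#'
#' \code{T_lambda = lambda * T_r_std + (1 - lambda) * T_c_std}, mixing the
#' standardized rare- and common-variant TOW-SE statistics.
#'
#' @param T_r_std standardized rare-stratum statistic.
#' @param T_c_std standardized common-stratum statistic.
#' @param lam mixing weight in [0, 1] (1 = rare only, 0 = common only).
#' @return scalar (vectorized over its arguments).
#' @export
t_lambda <- function(T_r_std, T_c_std, lam) {
  if (any(lam < 0 | lam > 1)) stop("lambda must lie in [0, 1]")
  lam * T_r_std + (1 - lam) * T_c_std
}

# Standardize a vector of (observed, permuted...) statistics by the mean and
# sd of the permuted ones. A zero permutation sd marks a degenerate stratum:
# its standardized statistic is set to 0 (it then contributes nothing to any
# T_lambda) with a warning.
standardize_by_perms <- function(T_all, label = "stratum") {
  perms <- T_all[-1]
  s <- stats::sd(perms)
  if (!is.finite(s) || s <= 0) {
    warning("zero permutation standard deviation in ", label,
            "; standardized statistic set to 0 (degenerate stratum)")
    return(rep(0, length(T_all)))
  }
  (T_all - mean(perms)) / s
}

#' Minimum p-value over the variable-weight grid
#'
#' Given paired observed-plus-permuted TOW-SE statistics for the rare and
#' common strata (from one shared permutation stream), standardizes each
#' stratum by its permutation mean and sd, forms \code{T_lambda} on the grid,
#' computes the rank-based p-value of the observed \code{T_lambda} within the
#' permuted ones at each grid point, and returns the minimum. This minimum is
#' the VW-TOW-SE statistic; its own significance requires the permutation
#' correction of \code{\link{pvalue_vw}}.
#'
#' @param perm_Tr,perm_Tc numeric vectors of length B + 1: the observed
#'   statistic first, then the B permuted statistics. One of the two may be
#'   NULL (empty stratum), in which case the minimum is taken over the single
#'   usable endpoint and the result reduces to plain TOW-SE.
#' @param lambda_grid mixing weights in [0, 1] (default \code{seq(0, 1, 0.1)}).
#' @param exhaustive if TRUE the permuted set is a full enumeration that
#'   includes the identity, and p-values are exact counts without the add-one
#'   correction.
#' @return object of class \code{vw_statistic}: \code{value} (min p),
#'   \code{p_lambda}, \code{lambda_grid}, \code{T_r}, \code{T_c},
#'   \code{sd_Tr}, \code{sd_Tc}, \code{B}.
#' @export
vw_min_p <- function(perm_Tr, perm_Tc, lambda_grid = seq(0, 1, by = 0.1),
                     exhaustive = FALSE) {
  vw_perm_eval(perm_Tr, perm_Tc, lambda_grid, exhaustive)$stat
}

# Workhorse shared by vw_min_p and pvalue_vw: per-lambda p-values for the
# observed statistic and the per-permutation min-p distribution.
vw_perm_eval <- function(perm_Tr, perm_Tc, lambda_grid, exhaustive = FALSE) {
  if (is.null(perm_Tr) && is.null(perm_Tc))
    stop("both strata empty: nothing to test")
  if (any(lambda_grid < 0 | lambda_grid > 1))
    stop("lambda grid must lie in [0, 1]")
  # an empty stratum pins lambda to the usable endpoint (plain TOW-SE on the
  # other stratum); the zero placeholder is not a degenerate stratum
  rare_empty <- is.null(perm_Tr); common_empty <- is.null(perm_Tc)
  if (rare_empty) { lambda_grid <- 0; perm_Tr <- rep(0, length(perm_Tc)) }
  if (common_empty) { lambda_grid <- 1; perm_Tc <- rep(0, length(perm_Tr)) }
  if (length(perm_Tr) != length(perm_Tc))
    stop("rare and common strata must share one permutation stream")
  B <- length(perm_Tr) - 1L
  if (B < 2L) stop("need at least 2 permutations")

  Zr <- if (rare_empty) perm_Tr else standardize_by_perms(perm_Tr, "rare stratum")
  Zc <- if (common_empty) perm_Tc else standardize_by_perms(perm_Tc, "common stratum")

  L <- length(lambda_grid)
  p_obs <- numeric(L)
  minp_perm <- rep(Inf, B)
  for (l in seq_len(L)) {
    v <- t_lambda(Zr, Zc, lambda_grid[l])
    s <- sort(v[-1])
    cnt_ge <- B - findInterval(v, s, left.open = TRUE)  # ties counted with >=
    if (exhaustive) {
      p_obs[l] <- cnt_ge[1] / B
    } else {
      p_obs[l] <- (1 + cnt_ge[1]) / (1 + B)
    }
    minp_perm <- pmin(minp_perm, cnt_ge[-1] / B)
  }
  stat <- structure(list(value = min(p_obs),
                         p_lambda = p_obs,
                         lambda_grid = lambda_grid,
                         T_r = perm_Tr[1], T_c = perm_Tc[1],
                         sd_Tr = stats::sd(perm_Tr[-1]),
                         sd_Tc = stats::sd(perm_Tc[-1]),
                         B = B),
                    class = "vw_statistic")
  list(stat = stat, minp_perm = minp_perm, exhaustive = exhaustive)
}

#' @export
print.vw_statistic <- function(x, ...) {
  cat(sprintf("VW-TOW-SE statistic: min_lambda p_lambda = %.6g over %d grid points (B = %d)\n",
              x$value, length(x$lambda_grid), x$B))
  invisible(x)
}
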