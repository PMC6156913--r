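#' Optimal per-variant interaction weights
#'
#' The score statistic for a weighted combination of residual interaction
#' columns is maximized (for approximately independent columns) by
#' \code{w_m = C_m / V_m}, where \code{C_m} is the centered cross-product of
#' the residual trait with column m and \code{V_m} its centered sum of
#' squares. Large weights therefore go to interaction terms strongly
#' associated with the trait and to low-variance (rare-variant) terms, with
#' the sign adjusting the direction of association.
#'
#' @param resid a \code{residualized_data} object.
#' @return numeric vector of M weights; columns with (numerically) zero
#'   variance get \code{NA} (no interaction information).
#' @export
optimal_weights <- function(resid) {
  parts <- tow_parts(resid)
  w <- rep(NA_real_, resid$M)
  w[parts$retained] <- parts$C / parts$V
  names(w) <- colnames(resid$X_res)
  w
}

# Shared centered cross-products: C_m, V_m and the retained-column mask.
# Zero-variance columns (e.g. a variant carried only where E = 0, or an
# interaction column lying in the span of the adjustment design) are dropped:
# their optimal weight is 0/0 and they carry no interaction information.
tow_parts <- function(resid) {
  stopifnot(inherits(resid, "residualized_data"))
  yc <- resid$y_res - mean(resid$y_res)
  Xc <- sweep(resid$X_res, 2, colMeans(resid$X_res))
  V <- colSums(Xc^2)
  retained <- V > 1e-12 * max(V, 1)
  if (!any(retained))
    stop("no testable interaction: all interaction columns have zero variance")
  Xc <- Xc[, retained, drop = FALSE]
  V <- V[retained]
  C <- as.numeric(crossprod(Xc, yc))
  list(yc = yc, Xc = Xc, C = C, V = V, retained = which(retained))
}

#' TOW-SE score statistic
#'
#' Test statistic for the Optimally Weighted combination of SNP-Environment
#' interactions: \code{T = sum_m C_m^2 / V_m} over retained columns, the
#' centered cross-product of the residual trait with the optimally weighted
#' combination of residual interaction columns. The normalizing prefactor of
#' the underlying score statistic is permutation invariant and omitted, so
#' significance is assessed by permutation only.
#'
#' @param resid a \code{residualized_data} object.
#' @return object of class \code{tow_statistic}: \code{value} (T >= 0),
#'   \code{weights} (optimal weights, NA for dropped columns),
#'   \code{per_variant_contrib} (\code{C_m^2 / V_m}), \code{retained} and
#'   \code{dropped} column indices.
#' @export
tow_statistic <- function(resid) {
  parts <- tow_parts(resid)
  contrib_ret <- parts$C^2 / parts$V
  contrib <- rep(NA_real_, resid$M)
  contrib[parts$retained] <- contrib_ret
  w <- rep(NA_real_, resid$M)
  w[parts$retained] <- parts$C / parts$V
  ids <- colnames(resid$X_res)
  names(contrib) <- ids; names(w) <- ids
  structure(list(value = sum(contrib_ret),
                 weights = w,
                 per_variant_contrib = contrib,
                 retained = parts$retained,
                 dropped = setdiff(seq_len(resid$M), parts$retained)),
            class = "tow_statistic")
}

#' @export
print.tow_statistic <- function(x, ...) {
  cat(sprintf("TOW-SE statistic: T = %.6g (%d variant(s) retained, %d dropped)\n",
              x$value, length(x$retained), length(x$dropped)))
  invisible(x)
}
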