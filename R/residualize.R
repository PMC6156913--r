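#' SNP-by-environment interaction matrix
#'
#' Entry (i, m) is \code{E_i * g_im}: the per-sample product of the
#' environmental variable with the minor-allele dosage at variant m.
#'
#' @param geno a \code{genotype_matrix} or a plain n x M dosage matrix.
#' @param env numeric environmental variable, length n.
#' @return n x M numeric matrix.
#' @export
build_interaction_matrix <- function(geno, env) {
  G <- if (inherits(geno, "genotype_matrix")) geno$counts else as.matrix(geno)
  if (nrow(G) != length(env))
    stop("environment length (", length(env),
         ") does not match sample count (", nrow(G), ")")
  G * as.numeric(env)
}

#' Remove degenerate design columns
#'
#' Drops constant columns and exact duplicates from an adjustment design
#' before fitting; remaining collinearity is reported as an error by the
#' caller. Pruning everything is legal (the intercept is handled separately).
#'
#' @param X numeric matrix whose columns are candidate adjustment terms.
#' @param tol relative tolerance for constancy.
#' @return list(X = retained columns, removed = named character vector of
#'   removal reasons).
#' @export
prune_degenerate <- function(X, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("col", seq_len(ncol(X)))
  removed <- character(0)
  if (ncol(X) == 0) return(list(X = X, removed = removed))

  keep <- rep(TRUE, ncol(X))
  scale <- pmax(apply(abs(X), 2, max), 1)
  const <- apply(X, 2, function(x) diff(range(x)) <= tol * max(abs(x), 1))
  removed <- c(removed, stats::setNames(rep("constant", sum(const)),
                                        colnames(X)[const]))
  keep[const] <- FALSE
  idx <- which(keep)
  if (length(idx) > 1) {
    for (a in seq_along(idx)[-1]) {
      j <- idx[a]
      for (b in seq_len(a - 1)) {
        i <- idx[b]
        if (!keep[i]) next
        if (max(abs(X[, j] - X[, i])) <= tol * max(scale[i], scale[j])) {
          removed <- c(removed, stats::setNames(
            paste0("duplicate of ", colnames(X)[i]), colnames(X)[j]))
          keep[j] <- FALSE
          break
        }
      }
    }
  }
  list(X = X[, keep, drop = FALSE], removed = removed)
}

#' Residualize the trait and interaction terms on the nuisance design
#'
#' Implements the adjustment step of the interaction score test: both the
#' trait and every SNP-by-environment interaction column are regressed on an
#' intercept, the confounder covariates Z, the per-variant genotype main
#' effects G, and the environment E; the test then operates purely on the
#' residuals, in which only interaction signal remains.
#'
#' For a continuous trait (identity link) the trait residual is the least
#' squares residual. For a binary trait (logit link) the trait residual is
#' the response residual \code{y - p_hat} from the null logistic fit (no
#' interaction terms); interaction columns are always adjusted by least
#' squares, which keeps the permutation scheme identical across trait kinds.
#'
#' @param y numeric trait vector.
#' @param EG n x M interaction matrix (see \code{\link{build_interaction_matrix}}).
#' @param Z covariate matrix or NULL.
#' @param G genotype dosage matrix or NULL.
#' @param E environment vector or NULL.
#' @param link \code{"identity"} or \code{"logit"}.
#' Degenerate adjustment columns (constants, exact duplicates) are pruned
#' before fitting; any remaining exact collinearity is resolved by dropping
#' the dependent columns through the QR pivot, which leaves the fitted
#' column space - and hence every residual - unchanged. All removals are
#' reported in the \code{pruned} field.
#'
#' @return object of class \code{residualized_data}: \code{y_res} (length n),
#'   \code{X_res} (n x M), \code{n}, \code{M}, \code{pruned} (named vector of
#'   adjustment columns removed or dropped, with reasons).
#' @export
residualize <- function(y, EG, Z = NULL, G = NULL, E = NULL,
                        link = c("identity", "logit")) {
  link <- match.arg(link)
  y <- as.numeric(y)
  EG <- as.matrix(EG)
  n <- length(y)
  if (nrow(EG) != n) stop("y and EG disagree on sample count")
  for (nm in c("Z", "G", "E")) {
    v <- get(nm)
    if (!is.null(v) && NROW(v) != n)
      stop(nm, " does not match sample count")
  }

  adj <- NULL
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
    adj <- cbind(adj, Z)
  }
  if (!is.null(G)) {
    G <- if (inherits(G, "genotype_matrix")) G$counts else as.matrix(G)
    if (is.null(colnames(G))) colnames(G) <- paste0("G", seq_len(ncol(G)))
    adj <- cbind(adj, G)
  }
  if (!is.null(E)) {
    E <- matrix(as.numeric(E), ncol = 1, dimnames = list(NULL, "E"))
    adj <- cbind(adj, E)
  }

  pruned <- character(0)
  if (!is.null(adj)) {
    pr <- prune_degenerate(adj)
    adj <- pr$X
    pruned <- pr$removed
  }
  design <- cbind(`(Intercept)` = rep(1, n), adj)

  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    # exact linear dependence beyond duplicates (frequent among sparse rare
    # variant dosage columns); residuals depend only on the design's column
    # space, so dependent columns are dropped via the QR pivot and reported
    drop_idx <- qr_d$pivot[seq.int(qr_d$rank + 1L, ncol(design))]
    pruned <- c(pruned, stats::setNames(
      rep("collinear, dropped from adjustment", length(drop_idx)),
      colnames(design)[drop_idx]))
  }

  if (link == "identity") {
    y_res <- qr.resid(qr_d, y)
  } else {
    if (!all(y %in% c(0, 1)))
      stop("logit link requires a {0,1} trait")
    fit <- stats::glm.fit(design, y, family = stats::binomial())
    if (!fit$converged) stop("null logistic fit did not converge")
    y_res <- y - fit$fitted.values
  }
  X_res <- qr.resid(qr_d, EG)
  X_res <- as.matrix(X_res)
  colnames(X_res) <- colnames(EG)

  structure(list(y_res = as.numeric(y_res), X_res = X_res,
                 n = n, M = ncol(EG), link = link, pruned = pruned),
            class = "residualized_data")
}

#' @export
print.residualized_data <- function(x, ...) {
  cat(sprintf("residualized_data: n = %d, M = %d (%s link)\n",
              x$n, x$M, x$link))
  if (length(x$pruned))
    cat("  pruned adjustment columns:",
        paste(names(x$pruned), collapse = ", "), "\n")
  invisible(x)
}
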