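# Align, subset to a SNP set, build and residualize interaction columns.
prepare_test_data <- function(geno, pheno, snp_set = NULL) {
  if (!is.null(snp_set)) {
    ids <- if (inherits(snp_set, "snp_set")) snp_set$ids else as.character(snp_set)
    if (!is.null(ids)) {
      idx <- match(ids, geno$variants$id)
      if (anyNA(idx))
        stop("SNP set refers to unknown variant id(s): ",
             paste(ids[is.na(idx)], collapse = ", "))
      geno$counts <- geno$counts[, idx, drop = FALSE]
      geno$variants <- geno$variants[idx, , drop = FALSE]
    }
  }
  al <- align_samples(geno, pheno)
  geno <- al$geno; pheno <- al$pheno
  EG <- build_interaction_matrix(geno, pheno$E)
  link <- if (pheno$trait_kind == "binary") "logit" else "identity"
  resid <- residualize(pheno$y, EG, Z = pheno$Z, G = geno$counts,
                       E = pheno$E, link = link)
  list(geno = geno, pheno = pheno, resid = resid,
       mafs = geno$variants$maf, n = al$n, dropped = al$dropped)
}

result_skeleton <- function(test, prep, set_name) {
  list(set = set_name, test = test, n = prep$n, M = prep$resid$M)
}

#' TOW-SE interaction test for one SNP set
#'
#' Tests whether the SNP-set by environment interaction contributes to the
#' trait, using the optimally weighted combination of interaction residuals
#' and a permutation null.
#'
#' @param geno a \code{genotype_matrix}.
#' @param pheno a \code{sample_table} aligned (or alignable) with \code{geno}.
#' @param snp_set optional \code{\link{snp_set}} or id vector selecting the
#'   tested variants (default: all variants in \code{geno}).
#' @param B number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive use all n! permutations (tiny n only).
#' @return object of class \code{gxe_test_result}.
#' @export
tow_se_test <- function(geno, pheno, snp_set = NULL, B = 10000, seed = NULL,
                        exhaustive = FALSE) {
  set_name <- if (inherits(snp_set, "snp_set")) snp_set$name else "all"
  prep <- prepare_test_data(geno, pheno, snp_set)
  plan <- permutation_plan(B, seed = seed, exhaustive = exhaustive)
  perms <- permute_residuals(prep$resid, plan)
  stat <- tow_statistic(prep$resid)
  res <- result_skeleton("TOW-SE", prep, set_name)
  res$statistic <- stat$value
  res$B <- perms$B
  res$p_value <- pvalue_tow(perms$T[1], perms$T[-1], exhaustive = exhaustive)
  res$weights <- stat$weights
  res$diagnostics <- list(dropped_variants = stat$dropped,
                          dropped_samples = prep$dropped)
  structure(res, class = "gxe_test_result")
}

#' VW-TOW-SE interaction test for one SNP set
#'
#' Splits the set into rare (MAF < threshold) and common variants, computes
#' the stratum TOW-SE statistics on one shared permutation stream, mixes the
#' standardized statistics over the lambda grid and evaluates the minimum
#' p-value with its permutation correction. With an empty stratum the test
#' reduces to TOW-SE on the other stratum.
#'
#' @inheritParams tow_se_test
#' @param maf_threshold rare/common MAF cutoff (default 0.01, strict \code{<}
#'   defines rare).
#' @param lambda_grid mixing weights in [0, 1] (default \code{seq(0, 1, 0.1)}).
#' @return object of class \code{gxe_test_result} with stratum details.
#' @export
vw_tow_se_test <- function(geno, pheno, snp_set = NULL, B = 10000,
                           seed = NULL, maf_threshold = 0.01,
                           lambda_grid = seq(0, 1, by = 0.1),
                           exhaustive = FALSE) {
  set_name <- if (inherits(snp_set, "snp_set")) snp_set$name else "all"
  prep <- prepare_test_data(geno, pheno, snp_set)
  part <- partition_variants(prep$mafs, maf_threshold)
  plan <- permutation_plan(B, seed = seed, exhaustive = exhaustive)
  perms <- permute_residuals(prep$resid, plan, partition = part)
  pv <- pvalue_vw(perms$T_r, perms$T_c, lambda_grid, exhaustive = exhaustive)
  res <- result_skeleton("VW-TOW-SE", prep, set_name)
  res$statistic <- pv$stat$value
  res$B <- perms$B
  res$p_value <- pv$p_value
  res$M_rare <- length(part$rare)
  res$M_common <- length(part$common)
  res$vw <- pv$stat
  res$diagnostics <- list(
    dropped_variants = setdiff(seq_len(prep$resid$M), perms$retained),
    dropped_samples = prep$dropped,
    degenerate_strata = c(if (is.null(perms$T_r)) "rare",
                          if (is.null(perms$T_c)) "common"))
  structure(res, class = "gxe_test_result")
}

#' Run one or both interaction tests on a collection of SNP sets
#'
#' @param geno a \code{genotype_matrix}.
#' @param pheno a \code{sample_table}.
#' @param sets list of \code{\link{snp_set}} objects (or NULL for one test of
#'   all variants).
#' @param test \code{"tow-se"}, \code{"vw-tow-se"} or \code{"both"}.
#' @param B,seed,maf_threshold,lambda_grid passed to the individual tests;
#'   each set gets its own permutation stream derived from \code{seed} and
#'   the set name, so results do not depend on set order.
#' @param bonferroni add a Bonferroni-adjusted p-value column (adjusted
#'   within each test kind across sets).
#' @return data.frame with one row per set and test: set, test, n, M,
#'   M_rare, M_common, statistic, B, p_value, status (\code{"ok"} or
#'   \code{"degenerate"}), and optionally p_bonferroni.
#' @export
gxe_interaction_test <- function(geno, pheno, sets = NULL,
                                 test = c("both", "tow-se", "vw-tow-se"),
                                 B = 10000, seed = NULL, maf_threshold = 0.01,
                                 lambda_grid = seq(0, 1, by = 0.1),
                                 bonferroni = TRUE) {
  test <- match.arg(test)
  if (is.null(sets)) sets <- list(snp_set("all", ids = geno$variants$id))
  rows <- list()
  for (s in sets) {
    sseed <- if (is.null(seed)) NULL else derive_seed(seed, s$name)
    for (kind in intersect(c("tow-se", "vw-tow-se"),
                           if (test == "both") c("tow-se", "vw-tow-se") else test)) {
      row <- tryCatch({
        r <- if (kind == "tow-se")
          tow_se_test(geno, pheno, s, B = B, seed = sseed)
        else
          vw_tow_se_test(geno, pheno, s, B = B, seed = sseed,
                         maf_threshold = maf_threshold,
                         lambda_grid = lambda_grid)
        data.frame(set = r$set, test = r$test, n = r$n, M = r$M,
                   M_rare = if (is.null(r$M_rare)) NA_integer_ else r$M_rare,
                   M_common = if (is.null(r$M_common)) NA_integer_ else r$M_common,
                   statistic = r$statistic, B = r$B, p_value = r$p_value,
                   status = "ok", stringsAsFactors = FALSE)
      }, error = function(e) {
        if (grepl("no testable interaction", conditionMessage(e))) {
          warning("set '", s$name, "' is degenerate: ", conditionMessage(e))
          data.frame(set = s$name, test = toupper(kind), n = NA_integer_,
                     M = length(s$ids), M_rare = NA_integer_,
                     M_common = NA_integer_, statistic = NA_real_,
                     B = NA_integer_, p_value = NA_real_,
                     status = "degenerate", stringsAsFactors = FALSE)
        } else stop(e)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (bonferroni) {
    out$p_bonferroni <- NA_real_
    for (kind in unique(out$test)) {
      sel <- out$test == kind & !is.na(out$p_value)
      out$p_bonferroni[sel] <- pmin(1, out$p_value[sel] * sum(sel))
    }
  }
  out
}

#' @export
print.gxe_test_result <- function(x, ...) {
  cat(sprintf("%s test, set '%s': n = %d, M = %d\n", x$test, x$set, x$n, x$M))
  if (!is.null(x$M_rare))
    cat(sprintf("  strata: %d rare / %d common\n", x$M_rare, x$M_common))
  cat(sprintf("  statistic = %.6g, B = %d, p = %.4g\n",
              x$statistic, x$B, x$p_value))
  if (length(x$diagnostics$dropped_variants))
    cat("  dropped interaction column(s):",
        paste(x$diagnostics$dropped_variants, collapse = ", "), "\n")
  invisible(x)
}
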