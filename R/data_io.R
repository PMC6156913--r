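#' Construct a genotype matrix object
#'
#' Container for minor-allele dosage data: an \code{n x M} integer matrix of
#' 0/1/2 counts with sample identifiers on rows and variant metadata on
#' columns. Minor-allele orientation (per-variant MAF <= 0.5) is enforced;
#' variants stored on the major allele are flipped and the flip recorded.
#'
#' @param counts numeric matrix, samples x variants, entries 0/1/2 (NA allowed
#'   only when \code{missing = "mean"} or \code{"complete"} resolves them).
#' @param samples character vector of sample identifiers (defaults to rownames).
#' @param variants data.frame of variant metadata with at least an \code{id}
#'   column; optional \code{chrom}, \code{pos}.
#' @param missing missing-genotype policy: \code{"mean"} replaces NA with the
#'   variant's observed dosage mean (preserves MAF), \code{"complete"} drops
#'   samples carrying any NA, \code{"fail"} errors on any NA.
#' @return an object of class \code{genotype_matrix} with elements
#'   \code{counts}, \code{samples}, \code{variants} (including \code{maf} and
#'   \code{flipped} columns), and \code{n_dropped} (samples removed by the
#'   complete-case policy).
#' @export
genotype_matrix <- function(counts, samples = rownames(counts),
                            variants = NULL,
                            missing = c("mean", "complete", "fail")) {
  missing <- match.arg(missing)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(counts)))
  samples <- as.character(samples)
  if (length(samples) != nrow(counts))
    stop("length of 'samples' does not match number of rows")
  if (is.null(variants)) {
    ids <- colnames(counts)
    if (is.null(ids)) ids <- paste0("V", seq_len(ncol(counts)))
    variants <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  if (!"id" %in% names(variants)) stop("variant metadata needs an 'id' column")
  if (nrow(variants) != ncol(counts))
    stop("variant metadata rows do not match number of genotype columns")

  bad <- !is.na(counts) & !(counts %in% c(0, 1, 2))
  if (any(bad))
    stop("genotype dosages must be 0, 1, 2 or NA; offending variants: ",
         paste(unique(variants$id[ceiling(which(bad) / nrow(counts))]),
               collapse = ", "))

  all_missing <- apply(counts, 2, function(x) all(is.na(x)))
  if (any(all_missing))
    stop("variant(s) with all genotypes missing: ",
         paste(variants$id[all_missing], collapse = ", "))

  n_dropped <- 0L
  if (anyNA(counts)) {
    if (missing == "fail") {
      stop("missing genotypes present and policy is 'fail'")
    } else if (missing == "complete") {
      keep <- !apply(counts, 1, anyNA)
      n_dropped <- sum(!keep)
      counts <- counts[keep, , drop = FALSE]
      samples <- samples[keep]
      if (nrow(counts) == 0L) stop("all samples dropped by complete-case policy")
    } else {
      for (j in seq_len(ncol(counts))) {
        miss <- is.na(counts[, j])
        if (any(miss)) counts[miss, j] <- mean(counts[!miss, j])
      }
    }
  }

  # fold to the minor allele: dosage d -> 2 - d where alt frequency > 0.5
  f <- colMeans(counts) / 2
  flip <- f > 0.5
  if (any(flip)) counts[, flip] <- 2 - counts[, flip]
  variants$flipped <- flip
  variants$maf <- pmin(f, 1 - f)

  rownames(counts) <- samples
  colnames(counts) <- variants$id
  structure(list(counts = counts, samples = samples, variants = variants,
                 n_dropped = n_dropped),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  MAF range: [%.4g, %.4g]; %d variant(s) flipped to minor allele\n",
              min(x$variants$maf), max(x$variants$maf), sum(x$variants$flipped)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Minor allele frequency of a dosage vector
#'
#' Computes \code{min(f, 1 - f)} where \code{f = sum(dosages) / (2n)}, i.e.
#' the frequency folded onto the minor allele.
#'
#' @param column numeric vector of dosages in \{0, 1, 2\}.
#' @return frequency in [0, 0.5].
#' @examples
#' compute_maf(c(0, 1, 2, 0))  # 0.375
#' compute_maf(c(2, 2, 2, 1))  # 0.125 after folding
#' @export
compute_maf <- function(column) {
  column <- column[!is.na(column)]
  if (length(column) == 0L) stop("cannot compute MAF of an empty column")
  if (any(!(column %in% c(0, 1, 2))) && any(column < 0 | column > 2))
    stop("dosages must lie in [0, 2]")
  f <- sum(column) / (2 * length(column))
  min(f, 1 - f)
}

#' Load genotypes from a VCF or plain dosage table
#'
#' Reads diploid biallelic genotype records and returns a
#' \code{\link{genotype_matrix}} oriented to the minor allele. For VCF input
#' only the GT field is used and phase is ignored; multiallelic records are
#' rejected. The plain-table dialect is TSV with the sample identifier in the
#' first column and one 0/1/2 (or NA) column per variant.
#'
#' @param path path to a \code{.vcf} file or a TSV dosage table.
#' @param snp_set optional \code{\link{snp_set}} (or character vector of
#'   variant ids) restricting and ordering the variants; unknown ids error.
#' @param format \code{"auto"} (by extension), \code{"vcf"}, or \code{"table"}.
#' @param missing missing-genotype policy, see \code{\link{genotype_matrix}}.
#' @return a \code{genotype_matrix}.
#' @export
load_genotypes <- function(path, snp_set = NULL,
                           format = c("auto", "vcf", "table"),
                           missing = c("mean", "complete", "fail")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "table"

  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi))
      stop("non-biallelic site(s): ",
           paste(ifelse(is.na(fix$ID[multi]) | fix$ID[multi] == ".",
                        paste0(fix$CHROM[multi], ":", fix$POS[multi]),
                        fix$ID[multi]), collapse = ", "))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ids <- fix$ID
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
    # GT strings like 0/1, 0|1, ./.; count alt alleles, phase ignored
    dose <- apply(gt, 2, function(col) {
      alleles <- strsplit(col, "[/|]")
      vapply(alleles, function(a) {
        if (length(a) != 2L || any(a == ".") || any(is.na(a))) return(NA_real_)
        sum(a == "1")
      }, numeric(1))
    })
    if (is.null(dim(dose))) dose <- matrix(dose, nrow = nrow(gt))
    counts <- t(dose)
    rownames(counts) <- colnames(gt)
    colnames(counts) <- ids
    meta <- data.frame(id = ids, chrom = fix$CHROM,
                       pos = as.integer(fix$POS), stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- as.character(tab[[1]])
    meta <- data.frame(id = colnames(counts), stringsAsFactors = FALSE)
  }

  if (!is.null(snp_set)) {
    want <- if (inherits(snp_set, "snp_set")) snp_set$ids else as.character(snp_set)
    if (inherits(snp_set, "snp_set") && !is.null(snp_set$region)) {
      if (!all(c("chrom", "pos") %in% names(meta)))
        stop("region-based SNP sets require VCF input with coordinates")
      r <- snp_set$region
      keep <- meta$chrom == r$chrom & meta$pos >= r$start & meta$pos <= r$end
      if (!any(keep)) stop("no variants in region ", r$chrom, ":", r$start,
                           "-", r$end)
      idx <- which(keep)
    } else {
      idx <- match(want, meta$id)
      if (anyNA(idx))
        stop("unknown variant id(s): ", paste(want[is.na(idx)], collapse = ", "))
    }
    counts <- counts[, idx, drop = FALSE]
    meta <- meta[idx, , drop = FALSE]
  }
  genotype_matrix(counts, variants = meta, missing = missing)
}

#' Write a genotype matrix as a plain dosage table
#'
#' TSV dialect: first column \code{sample}, one column per variant with the
#' stored (minor-allele oriented) dosage. \code{load_genotypes} on the output
#' reproduces the counts exactly.
#'
#' @param geno a \code{genotype_matrix}.
#' @param path output path.
#' @export
write_genotype_table <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  tab <- data.frame(sample = geno$samples, geno$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a sample table
#'
#' Per-sample trait, environmental exposure and confounder covariates. Binary
#' traits must be coded \{0, 1\}. A continuous environment is centered by
#' default so the environment main effect is interpretable and interaction
#' columns are on a stable scale.
#'
#' @param samples character sample identifiers.
#' @param y trait values (continuous, or \{0,1\} for binary).
#' @param E environmental variable (continuous or \{0,1\}).
#' @param Z optional covariate matrix/data.frame (n rows) or NULL.
#' @param trait_kind \code{"continuous"} or \code{"binary"}.
#' @param center_env center a continuous environment (default TRUE; binary
#'   \{0,1\} environments are left as-is).
#' @return object of class \code{sample_table}.
#' @export
sample_table <- function(samples, y, E, Z = NULL,
                         trait_kind = c("continuous", "binary"),
                         center_env = TRUE) {
  trait_kind <- match.arg(trait_kind)
  samples <- as.character(samples)
  y <- as.numeric(y); E <- as.numeric(E)
  n <- length(samples)
  if (length(y) != n || length(E) != n)
    stop("samples, y and E must have equal length")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    storage.mode(Z) <- "double"
    if (nrow(Z) != n) stop("Z must have one row per sample")
    if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  }
  if (trait_kind == "binary" && !all(stats::na.omit(y) %in% c(0, 1)))
    stop("binary traits must contain exactly the values {0, 1}")
  is_binary_env <- all(stats::na.omit(E) %in% c(0, 1))
  if (center_env && !is_binary_env) E <- E - mean(E, na.rm = TRUE)
  structure(list(samples = samples, y = y, E = E, Z = Z,
                 trait_kind = trait_kind),
            class = "sample_table")
}

#' Read a phenotype/covariate table
#'
#' TSV with a header row; columns are selected by name for the sample id,
#' trait, environment and covariates.
#'
#' @param path TSV path.
#' @param trait,env column names for the trait and environment.
#' @param covariates character vector of covariate column names (may be empty).
#' @param id column name holding sample identifiers (default: first column).
#' @param trait_kind \code{"auto"} infers binary when the trait takes only
#'   values \{0,1\}; otherwise \code{"continuous"} or \code{"binary"}.
#' @param center_env see \code{\link{sample_table}}.
#' @return a \code{sample_table}.
#' @export
read_sample_table <- function(path, trait, env, covariates = character(),
                              id = NULL, trait_kind = "auto",
                              center_env = TRUE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(id)) id <- names(tab)[1]
  need <- c(id, trait, env, covariates)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (trait_kind == "auto") {
    yv <- stats::na.omit(tab[[trait]])
    trait_kind <- if (all(yv %in% c(0, 1))) "binary" else "continuous"
  }
  Z <- if (length(covariates)) tab[covariates] else NULL
  sample_table(tab[[id]], tab[[trait]], tab[[env]], Z,
               trait_kind = trait_kind, center_env = center_env)
}

#' Define a SNP set
#'
#' A named group of variants tested jointly (a gene or pathway region),
#' either as an explicit ordered id list or as a 1-based inclusive genomic
#' region resolved against a VCF at load time.
#'
#' @param name set name.
#' @param ids character vector of variant identifiers (NULL for region sets).
#' @param region optional list(chrom, start, end), 1-based inclusive.
#' @export
snp_set <- function(name, ids = NULL, region = NULL) {
  if (is.null(ids) && is.null(region)) stop("snp_set needs ids or a region")
  if (!is.null(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    region$start <- as.integer(region$start); region$end <- as.integer(region$end)
    if (region$end < region$start) stop("region end precedes start")
  }
  structure(list(name = as.character(name),
                 ids = if (is.null(ids)) NULL else as.character(ids),
                 region = region),
            class = "snp_set")
}

#' Read SNP-set definitions
#'
#' One set per line. Two accepted layouts:
#' \code{set_name<TAB>id1,id2,...} or a BED-style triplet
#' \code{set_name<TAB>chrom<TAB>start<TAB>end} (1-based inclusive) resolved
#' against the VCF at test time.
#'
#' @param path file path.
#' @return list of \code{\link{snp_set}} objects.
#' @export
read_snp_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) == 2L) {
      snp_set(parts[1], ids = trimws(strsplit(parts[2], ",")[[1]]))
    } else if (length(parts) == 4L) {
      snp_set(parts[1], region = list(chrom = parts[2],
                                      start = as.integer(parts[3]),
                                      end = as.integer(parts[4])))
    } else {
      stop("malformed SNP-set line: ", ln)
    }
  })
}

#' Align a genotype matrix with a sample table
#'
#' Restricts both objects to the intersection of their samples, in the
#' genotype matrix's order, and drops samples with missing trait, environment
#' or covariate values (complete-case). Idempotent.
#'
#' @param geno a \code{genotype_matrix}.
#' @param pheno a \code{sample_table}.
#' @return list(geno, pheno, n, dropped) where \code{dropped} counts samples
#'   removed relative to the genotype input.
#' @export
align_samples <- function(geno, pheno) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(pheno, "sample_table"))
  shared <- intersect(geno$samples, pheno$samples)
  if (length(shared) == 0L) stop("no samples shared between genotypes and phenotypes")
  idx_p <- match(shared, pheno$samples)
  ok <- !is.na(pheno$y[idx_p]) & !is.na(pheno$E[idx_p])
  if (!is.null(pheno$Z)) ok <- ok & !apply(pheno$Z[idx_p, , drop = FALSE], 1, anyNA)
  shared <- shared[ok]
  if (length(shared) == 0L) stop("no samples left after dropping missing phenotype rows")
  idx_g <- match(shared, geno$samples)
  idx_p <- match(shared, pheno$samples)

  g2 <- geno
  g2$counts <- geno$counts[idx_g, , drop = FALSE]
  g2$samples <- shared
  g2$variants$maf <- apply(g2$counts, 2, compute_maf)
  p2 <- pheno
  p2$samples <- shared
  p2$y <- pheno$y[idx_p]; p2$E <- pheno$E[idx_p]
  if (!is.null(pheno$Z)) p2$Z <- pheno$Z[idx_p, , drop = FALSE]
  list(geno = g2, pheno = p2, n = length(shared),
       dropped = length(geno$samples) - length(shared))
}

#' Write a results table
#'
#' @param results data.frame of per-set test results.
#' @param path output TSV path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
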