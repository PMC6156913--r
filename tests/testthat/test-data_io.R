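test_that("VCF loading counts minor alleles and enforces orientation", {
  path <- write_test_vcf(tempfile(fileext = ".vcf"),
                         samples = c("A", "B", "C", "D"),
                         gts = list(c("0/0", "0/1", "1/1", "0/0"),
                                    c("1/1", "1/1", "1/1", "0/1")))
  g <- load_genotypes(path)
  expect_equal(unname(g$counts[, "v1"]), c(0, 1, 2, 0))
  # alt frequency 7/8 folds onto the minor allele
  expect_equal(unname(g$counts[, "v2"]), c(0, 0, 0, 1))
  expect_equal(g$variants$maf, c(3 / 8, 1 / 8))
  expect_equal(g$variants$flipped, c(FALSE, TRUE))
})

test_that("missing genotypes are mean-imputed (or dropped) per policy", {
  path <- write_test_vcf(tempfile(fileext = ".vcf"),
                         samples = c("A", "B", "C"),
                         gts = list(c("0/0", "./.", "1/1")))
  g <- load_genotypes(path, missing = "mean")
  expect_equal(unname(g$counts[, 1]), c(0, 1, 2))  # (0 + 2) / 2 = 1
  g2 <- load_genotypes(path, missing = "complete")
  expect_equal(g2$samples, c("A", "C"))
  expect_equal(g2$n_dropped, 1L)
  expect_error(load_genotypes(path, missing = "fail"), "missing")
})

test_that("bad sites and ids are rejected with names", {
  multi <- write_test_vcf(tempfile(fileext = ".vcf"),
                          samples = c("A", "B"),
                          gts = list(c("0/1", "0/0")), alts = "G,T")
  expect_error(load_genotypes(multi), "non-biallelic.*v1")
  ok <- write_test_vcf(tempfile(fileext = ".vcf"),
                       samples = c("A", "B"),
                       gts = list(c("0/1", "0/0")))
  expect_error(load_genotypes(ok, snp_set = c("v1", "nope")),
               "unknown variant id.*nope")
  allmiss <- write_test_vcf(tempfile(fileext = ".vcf"),
                            samples = c("A", "B"),
                            gts = list(c("./.", "./.")))
  expect_error(load_genotypes(allmiss), "all genotypes missing")
})

test_that("MAF computation folds to the minor allele", {
  expect_equal(compute_maf(c(0, 1, 2, 0)), 0.375)
  expect_equal(compute_maf(c(0, 0, 0, 0)), 0)
  expect_equal(compute_maf(c(2, 2, 2, 1)), 1 / 8)
  expect_error(compute_maf(numeric(0)), "empty")
  set.seed(1)
  for (i in 1:50) {
    m <- compute_maf(sample(0:2, sample(2:40, 1), replace = TRUE))
    expect_gte(m, 0); expect_lte(m, 0.5)
  }
})

test_that("sample alignment intersects, drops incomplete rows, and is idempotent", {
  g <- genotype_matrix(matrix(c(0, 1, 2, 1, 0, 1), 3, 2,
                              dimnames = list(c("A", "B", "C"), c("v1", "v2"))))
  p <- sample_table(c("B", "C", "D"), y = c(1, 2, 3), E = c(0.1, 0.2, 0.3))
  al <- align_samples(g, p)
  expect_equal(al$geno$samples, c("B", "C"))
  expect_equal(al$n, 2)
  expect_equal(al$pheno$y, c(1, 2))

  # missing trait value drops that sample (complete case)
  p2 <- sample_table(c("A", "B", "C"), y = c(1, NA, 3), E = c(1, 2, 3))
  expect_equal(align_samples(g, p2)$n, 2)

  al2 <- align_samples(al$geno, al$pheno)
  expect_equal(al2$geno$counts, al$geno$counts)
  expect_equal(al2$pheno$y, al$pheno$y)
  expect_equal(al2$dropped, 0)

  p3 <- sample_table(c("X", "Y"), y = c(1, 2), E = c(1, 2))
  expect_error(align_samples(g, p3), "no samples shared")
})

test_that("plain-table round trip reproduces counts exactly", {
  set.seed(4)
  counts <- matrix(sample(0:2, 30, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                   10, 3, dimnames = list(paste0("S", 1:10), paste0("v", 1:3)))
  g <- genotype_matrix(counts)
  path <- tempfile(fileext = ".tsv")
  write_genotype_table(g, path)
  g2 <- load_genotypes(path, format = "table")
  expect_identical(g2$counts, g$counts)
  expect_equal(g2$variants$maf, g$variants$maf)
})

test_that("sample_table validates binary traits and centers continuous environment", {
  expect_error(sample_table(c("A", "B"), y = c(1, 2), E = c(0, 1),
                            trait_kind = "binary"),
               "\\{0, 1\\}")
  st <- sample_table(c("A", "B", "C"), y = 1:3, E = c(10, 20, 30))
  expect_equal(mean(st$E), 0)            # centered continuous exposure
  stb <- sample_table(c("A", "B"), y = 1:2, E = c(0, 1))
  expect_equal(stb$E, c(0, 1))           # binary exposure untouched
})

test_that("SNP-set files accept id lists and region triplets", {
  path <- tempfile()
  writeLines(c("setA\tv1,v2, v3", "setB\tchr1\t100\t200"), path)
  sets <- read_snp_sets(path)
  expect_length(sets, 2)
  expect_equal(sets[[1]]$ids, c("v1", "v2", "v3"))
  expect_equal(sets[[2]]$region$start, 100L)
  writeLines("bad line without tabs", path)
  expect_error(read_snp_sets(path), "malformed")
})

test_that("region SNP sets resolve against VCF coordinates", {
  path <- write_test_vcf(tempfile(fileext = ".vcf"),
                         samples = c("A", "B", "C"),
                         gts = list(c("0/0", "0/1", "0/0"),
                                    c("0/1", "0/1", "0/0")))
  s <- snp_set("reg", region = list(chrom = "1", start = 101, end = 101))
  g <- load_genotypes(path, snp_set = s)
  expect_equal(ncol(g$counts), 1L)
  expect_equal(g$variants$id, "v1")
})
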