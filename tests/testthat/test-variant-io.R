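# Build a small VCF with INFO annotations directly as text.
write_test_vcf <- function(path, rows, samples = c("s1", "s2")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=100000>",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

test_that("read_vcf keeps biallelic SNPs and logs the rest", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c(
    "chr1\t100\t.\tA\tT\t50\t.\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tA\tT,G\t50\t.\t.\tGT\t0/1\t0/2",   # multiallelic
    "chr1\t300\t.\tAT\tA\t50\t.\t.\tGT\t0/1\t0/0",    # indel
    "chr1\t400\t.\tC\tG\t50\t.\t.\tGT\t1/1\t./."
  ))
  gm <- read_vcf(f)
  expect_equal(n_sites(gm), 2)
  expect_equal(gm$pos, c(100L, 400L))
  drop <- attr(gm, "dropped")
  expect_equal(drop$n[drop$reason == "multiallelic"], 1)
  expect_equal(drop$n[drop$reason == "indel_or_other"], 1)
  expect_true(is.na(gm$gt[2, 2]))
  expect_false(is_phased(gm))  # "/" separators
})

test_that("phase is captured only when all separators are pipes", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c("chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0|1\t1|1",
                      "chr1\t200\t.\tA\tG\t.\t.\t.\tGT\t1|0\t0|0"))
  gm <- read_vcf(f)
  expect_true(is_phased(gm))
  expect_equal(unname(gm$hap[1, ]), c(0L, 1L, 1L, 1L))
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f2, c("chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0|1\t1/1"))
  expect_false(is_phased(read_vcf(f2)))
})

test_that("unsorted positions are rejected", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c("chr1\t200\t.\tA\tT\t.\t.\t.\tGT\t0/1\t0/0",
                      "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0/1\t0/0"))
  expect_error(read_vcf(f), "increasing")
})

test_that("hard filters are strict inequalities with pass-on-missing", {
  si <- tibble::tibble(
    QUAL = c(99.9, 100.0, 150, NA, 150, 150, 150),
    QD = c(5, 2.0, 1.9, 5, NA, 5, 5),
    MQ = c(50, 40.0, 50, 50, 50, 50, 50),
    FS = c(10, 60.0, 10, 10, 10, 60.1, 10),
    SOR = c(1, 3.0, 1, 1, 1, 1, 3.1),
    MQRankSum = c(0, -12.5, 0, 0, 0, 0, 0),
    ReadPosRankSum = c(0, -8.0, 0, 0, 0, 0, 0)
  )
  n <- 7
  gt <- matrix(0L, n, 2, dimnames = list(NULL, c("s1", "s2")))
  gm <- geno_matrix(rep("chr1", n), seq_len(n) * 10, rep("A", n),
                    rep("T", n), gt, site_info = si)
  out <- apply_hard_filters(gm)
  # row 1 fails QUAL<100; row 2 sits exactly on every threshold and passes;
  # rows 3,6,7 fail one rule each; rows 4,5 have NA in a tested field and pass
  expect_equal(out$pos, c(20L, 40L, 50L))
})

test_that("hard filters equal a row-wise re-evaluation on random tables", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 40
    si <- tibble::tibble(
      QUAL = sample(c(NA, runif(5, 0, 200)), n, replace = TRUE),
      QD = sample(c(NA, runif(5, 0, 10)), n, replace = TRUE),
      MQ = sample(c(NA, runif(5, 20, 60)), n, replace = TRUE),
      FS = sample(c(NA, runif(5, 0, 120)), n, replace = TRUE),
      SOR = sample(c(NA, runif(5, 0, 6)), n, replace = TRUE),
      MQRankSum = sample(c(NA, runif(5, -20, 5)), n, replace = TRUE),
      ReadPosRankSum = sample(c(NA, runif(5, -12, 5)), n, replace = TRUE)
    )
    gt <- matrix(0L, n, 2, dimnames = list(NULL, c("s1", "s2")))
    gm <- geno_matrix(rep("chr1", n), seq_len(n), rep("A", n), rep("T", n),
                      gt, site_info = si)
    keep_oracle <- vapply(seq_len(n), function(i) {
      r <- si[i, ]
      ok <- function(x, f) is.na(x) || f(x)
      ok(r$QUAL, function(x) x >= 100) && ok(r$QD, function(x) x >= 2) &&
        ok(r$MQ, function(x) x >= 40) && ok(r$FS, function(x) x <= 60) &&
        ok(r$SOR, function(x) x <= 3) &&
        ok(r$MQRankSum, function(x) x >= -12.5) &&
        ok(r$ReadPosRankSum, function(x) x >= -8)
    }, TRUE)
    expect_equal(apply_hard_filters(gm)$pos, which(keep_oracle))
  }
})

test_that("hard filters without site_info warn and pass through", {
  gm <- random_gm(S = 5, n = 3, seed = 1)
  expect_warning(out <- apply_hard_filters(gm), "site_info")
  expect_equal(out$pos, gm$pos)
})

test_that("frequency filters honour the strict MAF and missingness bounds", {
  # 20 diploids, 2 alt alleles of 40 -> MAF exactly 0.05: retained
  gt <- matrix(0L, 1, 20, dimnames = list(NULL, sprintf("s%02d", 1:20)))
  gt[1, 1] <- 2L
  gm <- geno_matrix("chr1", 10L, "A", "T", gt)
  expect_equal(n_sites(apply_frequency_filters(gm)), 1)
  gt2 <- gt; gt2[1, 1] <- 1L  # MAF 1/40 < 0.05: removed
  gm2 <- geno_matrix("chr1", 10L, "A", "T", gt2)
  expect_equal(n_sites(apply_frequency_filters(gm2)), 0)
  # 10 diploids, 1 missing genotype -> exactly 10% missing: retained
  gt3 <- matrix(1L, 1, 10, dimnames = list(NULL, sprintf("s%02d", 1:10)))
  gt3[1, 10] <- NA
  gm3 <- geno_matrix("chr1", 10L, "A", "T", gt3)
  expect_equal(n_sites(apply_frequency_filters(gm3)), 1)
  gt4 <- gt3; gt4[1, 9] <- NA  # 20% missing: removed
  gm4 <- geno_matrix("chr1", 10L, "A", "T", gt4)
  expect_equal(n_sites(apply_frequency_filters(gm4)), 0)
})

test_that("frequency filters equal brute-force recomputation and are idempotent", {
  set.seed(7)
  for (rep in 1:10) {
    S <- 50; n <- 12
    gt <- matrix(sample(c(0L, 1L, 2L, NA), S * n, replace = TRUE,
                        prob = c(0.45, 0.25, 0.2, 0.1)), S, n)
    colnames(gt) <- sprintf("s%02d", seq_len(n))
    gm <- geno_matrix(rep("chr1", S), seq_len(S) * 3, rep("A", S),
                      rep("T", S), gt)
    keep <- vapply(seq_len(S), function(i) {
      g <- gt[i, ]
      called <- sum(!is.na(g))
      if (called == 0) return(FALSE)
      p <- sum(g, na.rm = TRUE) / (2 * called)
      min(p, 1 - p) >= 0.05 && mean(is.na(g)) <= 0.10
    }, TRUE)
    out <- apply_frequency_filters(gm)
    expect_equal(out$pos, gm$pos[keep])
    again <- apply_frequency_filters(out)
    expect_identical(again$pos, out$pos)
    expect_identical(again$gt, out$gt)
  }
})

test_that("population split preserves sites and conserves allele counts", {
  gm <- random_gm(S = 40, n = 5, seed = 3)
  pm <- tibble::tibble(sample = samples(gm),
                       population = c("A", "A", "A", "B", "B"))
  views <- split_populations(gm, pm)
  expect_named(views, c("A", "B"))
  expect_equal(n_samples(views$A), 3)
  expect_equal(n_samples(views$B), 2)
  expect_equal(views$A$pos, gm$pos)
  tot <- rowSums(views$A$gt) + rowSums(views$B$gt)
  expect_equal(tot, rowSums(gm$gt))
  # haplotype columns stay with their samples
  expect_equal(unname(views$B$hap[, 1:2]), unname(gm$hap[, 7:8]))
  # single population: identity view
  pm1 <- tibble::tibble(sample = samples(gm), population = "only")
  v1 <- split_populations(gm, pm1)
  expect_equal(v1$only$gt, gm$gt)
})

test_that("popmap errors cover unknown and missing samples", {
  gm <- random_gm(S = 5, n = 3, seed = 2)
  pm_bad <- tibble::tibble(sample = c(samples(gm), "ghost"),
                           population = "A")
  expect_error(split_populations(gm, pm_bad), "absent from the matrix")
  pm_short <- tibble::tibble(sample = samples(gm)[1:2], population = "A")
  expect_error(split_populations(gm, pm_short), "missing from popmap")
})

test_that("write_vcf/read_vcf round-trips site annotations", {
  si <- tibble::tibble(QUAL = c(120, 80), QD = c(5, NA), MQ = c(45, 41),
                       FS = c(NA, 2), SOR = c(1, 2),
                       MQRankSum = c(0.5, NA), ReadPosRankSum = c(NA, -1))
  gt <- matrix(c(0L, 1L, 2L, NA), 2, 2, dimnames = list(NULL, c("a", "b")))
  gm <- geno_matrix(c("chr1", "chr1"), c(5L, 9L), c("A", "C"), c("T", "G"),
                    gt, site_info = si,
                    chrom_len = c(chr1 = 1000))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  gm2 <- read_vcf(f)
  expect_equal(gm2$site_info$QUAL, si$QUAL)
  expect_equal(gm2$site_info$QD, si$QD)
  expect_equal(gm2$site_info$ReadPosRankSum, si$ReadPosRankSum)
  expect_equal(unname(gm2$gt), unname(gm$gt))
  expect_equal(gm2$chrom_len, c(chr1 = 1000))
})
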