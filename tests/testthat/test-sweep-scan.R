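test_that("window ranking respects the >= 10 SNP rule", {
  tab <- tibble::tibble(chrom = "chr1",
                        start = c(1, 10001, 20001),
                        end = c(10000, 20000, 30000),
                        n_snps = c(9, 10, 25),
                        partial = c(FALSE, FALSE, FALSE))
  out <- filter_windows(tab)
  expect_equal(out$ranked, c(FALSE, TRUE, TRUE))
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(30:80, 1)
    tab_r <- tibble::tibble(chrom = "c", start = seq_len(n), end = seq_len(n),
                            n_snps = sample(0:30, n, replace = TRUE))
    out_r <- filter_windows(tab_r)
    expect_equal(sum(out_r$ranked), sum(tab_r$n_snps >= 10))
  }
})

test_that("empirical thresholds are nearest-rank with a strict-tail policy", {
  expect_equal(empirical_threshold(1:100), 95)
  expect_equal(sum((1:100) > empirical_threshold(1:100)), 5)
  # constant sample: threshold equals the constant, zero strict outliers
  v <- rep(7, 30)
  expect_equal(empirical_threshold(v), 7)
  expect_equal(sum(v > empirical_threshold(v)), 0)
  expect_error(empirical_threshold(1:19), "at least 20")
  set.seed(97)
  for (rep in 1:200) {
    v <- rnorm(sample(20:200, 1))
    q <- sample(c(0.9, 0.95, 0.99), 1)
    expect_equal(empirical_threshold(v, q), oracle_threshold(v, q))
  }
})

make_grid_tables <- function(n = 40, seed = 1) {
  set.seed(seed)
  grid <- tibble::tibble(chrom = "chr1",
                         start = (seq_len(n) - 1) * 10000 + 1,
                         end = seq_len(n) * 10000,
                         n_snps = sample(5:30, n, replace = TRUE),
                         partial = FALSE)
  fst <- grid; fst$fst <- runif(n)
  fst$fst_unweighted <- fst$fst
  ratio <- grid
  ratio$pi_ratio <- rexp(n) + 0.2
  ratio$pi_ratio[sample(n, 2)] <- NA
  ratio$log2_pi_ratio <- log2(ratio$pi_ratio)
  ratio$pi_ref <- 1e-3; ratio$pi_focal <- 1e-3
  ihh <- grid; ihh$ihh12 <- rnorm(n); ihh$n_scored <- grid$n_snps
  list(fst = fst, ratio = ratio, ihh = ihh)
}

test_that("the outlier conjunction equals explicit set intersection", {
  for (seed in 1:10) {
    tabs <- make_grid_tables(seed = seed)
    out <- outlier_intersection(tabs$fst, tabs$ratio, tabs$ihh)
    thr <- attr(out, "thresholds")
    ranked <- out$ranked
    set_fst <- which(ranked & !is.na(out$fst) &
                       out$fst > thr$threshold[thr$statistic == "fst"])
    set_ratio <- which(ranked & !is.na(out$pi_ratio) &
                         out$pi_ratio > thr$threshold[thr$statistic == "pi_ratio"])
    set_ihh <- which(ranked & !is.na(out$ihh12) &
                       out$ihh12 > thr$threshold[thr$statistic == "ihh12"])
    expect_equal(which(out$signal),
                 intersect(intersect(set_fst, set_ratio), set_ihh))
    # exceeding only two thresholds is not a signal under the default rule
    two_not_three <- setdiff(intersect(set_fst, set_ratio), set_ihh)
    expect_false(any(out$signal[two_not_three]))
  }
})

test_that("undefined statistics never qualify as outliers", {
  tabs <- make_grid_tables(seed = 5)
  tabs$ratio$pi_ratio[1:5] <- NA
  out <- outlier_intersection(tabs$fst, tabs$ratio, tabs$ihh)
  expect_false(any(out$signal[1:5]))
  tabs2 <- make_grid_tables(seed = 5)
  tabs2$ratio$start <- tabs2$ratio$start + 1
  expect_error(outlier_intersection(tabs2$fst, tabs2$ratio, tabs2$ihh),
               "grid")
})

test_that("adjacent and overlapping windows merge; separated ones do not", {
  w <- tibble::tibble(chrom = "chr1", start = c(10000, 20000),
                      end = c(19999, 29999), fst = c(0.5, 0.7))
  m <- merge_regions(w)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 10000)
  expect_equal(m$end, 29999)
  expect_equal(m$fst_max, 0.7)
  w2 <- tibble::tibble(chrom = "chr1", start = c(10000, 30000),
                       end = c(19999, 39999), fst = c(0.5, 0.7))
  expect_equal(nrow(merge_regions(w2)), 2)
  # random window sets against a bp-membership union oracle
  set.seed(101)
  for (rep in 1:20) {
    k <- sample(1:12, 1)
    starts <- sample(seq(1, 400, by = 20), k)
    ends <- starts + 19
    m_r <- merge_regions(tibble::tibble(chrom = "c", start = starts,
                                        end = ends))
    orc <- oracle_merge(starts, ends)
    expect_equal(m_r$start, orc$start)
    expect_equal(m_r$end, orc$end)
  }
})

test_that("gene overlap uses 1-based inclusive single-bp semantics", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(5000, 5000), end = c(8000, 7999),
                          strand = "+")
  regions <- tibble::tibble(chrom = "chr1", start = 8000, end = 12000,
                            n_windows = 1L)
  ann <- annotate_genes(regions, genes)
  expect_equal(ann$genes[[1]], "g1")
  expect_equal(ann$n_genes, 1L)
  # random features against the all-pairs oracle, invariant to feature order
  set.seed(103)
  for (rep in 1:20) {
    ng <- 15
    gs <- sample.int(1000, ng)
    genes_r <- tibble::tibble(gene_id = sprintf("g%02d", 1:ng), chrom = "c",
                              start = gs, end = gs + sample.int(80, ng),
                              strand = "+")
    rs <- sample.int(1000, 3)
    regions_r <- tibble::tibble(chrom = "c", start = rs, end = rs + 100,
                                n_windows = 1L)
    ann_r <- annotate_genes(regions_r, genes_r)
    ann_shuf <- annotate_genes(regions_r, genes_r[sample(ng), ])
    for (i in 1:3) {
      orc <- genes_r$gene_id[mapply(oracle_overlap, genes_r$start,
                                    genes_r$end, rs[i], rs[i] + 100)]
      expect_setequal(ann_r$genes[[i]], orc)
      expect_equal(ann_r$genes[[i]], ann_shuf$genes[[i]])
    }
  }
})

test_that("GFF3 gene features survive the read path", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=gene:G1;Name=G1",
               "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=exon:E1",
               "chr1\tsrc\tgene\t900\t1200\t.\t-\t.\tID=gene:G2;Name=G2"),
             f)
  genes <- read_genes(f)
  expect_equal(genes$gene_id, c("G1", "G2"))
  expect_equal(genes$strand, c("+", "-"))
})

test_that("run_scan recovers a planted sweep and is deterministic", {
  p <- sim_params(n_anc = 400, pop_sizes = c(400, 2000),
                  split_gens = c(125, 125), n_sample = 20, seq_len = 1e6,
                  mu = 9.375e-7, rec = 6.25e-7, seed = 418, burnin = 3200,
                  pop_names = c("focal", "wild"),
                  sweep = list(pop = "focal", pos = 495000, s = 0.1,
                               gen = 0, min_freq = 0.95))
  sim <- simulate_genomes(p)
  expect_gte(sim$truth$final_freq, 0.95)
  d <- withr::local_tempdir()
  paths <- write_fixture(sim, d)
  res <- run_scan(paths[["vcf"]], paths[["popmap"]], focal = "focal",
                  reference = "wild", gff = paths[["gff"]])
  expect_s3_class(res, "sweep_scan")
  expect_gt(sum(res$windows$signal), 0)
  hit <- any(res$regions$start <= 495000 & res$regions$end >= 495000)
  expect_true(hit)
  # the synthetic gene centred on the sweep is annotated
  expect_true("SWEEP_TARGET" %in% unlist(res$regions$genes))
  g <- glance(res)
  expect_equal(g$n_signal, sum(res$windows$signal))
  expect_s3_class(tidy(res), "tbl_df")
  # re-running the scan writes byte-identical outputs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- write_scan(res, d1)
  res2 <- run_scan(paths[["vcf"]], paths[["popmap"]], focal = "focal",
                   reference = "wild", gff = paths[["gff"]])
  f2 <- write_scan(res2, d2)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     label = paste("content of", nm))
  }
})

test_that("thresholds are computed only over ranked windows", {
  tabs <- make_grid_tables(seed = 11)
  tabs$fst$n_snps <- c(rep(3, 15), rep(20, 25))
  tabs$ratio$n_snps <- tabs$fst$n_snps
  tabs$ihh$n_snps <- tabs$fst$n_snps
  out <- outlier_intersection(tabs$fst, tabs$ratio, tabs$ihh)
  thr <- attr(out, "thresholds")
  expect_equal(thr$threshold[thr$statistic == "fst"],
               oracle_threshold(tabs$fst$fst[16:40], 0.95))
  expect_false(any(out$signal[1:15]))
})
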