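#' Flag windows eligible for outlier ranking
#'
#' Adds a logical `ranked` column: windows with at least `min_snps` SNPs
#' that are not trailing partial windows take part in empirical-threshold
#' ranking; all windows are retained in the table.
#'
#' @param table A window table with an `n_snps` column (and optionally
#'   `partial`).
#' @param min_snps Minimum SNPs per ranked window (default 10; a 10-SNP
#'   window is retained, a 9-SNP window is not).
#' @return The table with a `ranked` column.
#' @export
filter_windows <- function(table, min_snps = 10) {
  stopifnot("n_snps" %in% names(table))
  partial <- if ("partial" %in% names(table)) table$partial else FALSE
  table$ranked <- table$n_snps >= min_snps & !partial
  table
}

#' Empirical upper-tail threshold
#'
#' The inverse-ECDF (nearest-rank) quantile of the finite values: with
#' `q = 0.95`, the value at rank `ceiling(0.95 n)` of the sorted sample.
#' Outliers are values strictly greater than the threshold, so a constant
#' sample yields no outliers.
#'
#' @param values Numeric vector (NA/Inf ignored); at least 20 finite values
#'   are required for the tail to be defined.
#' @param q Quantile (default 0.95, the top-5% tail).
#' @return The threshold (numeric scalar).
#' @export
empirical_threshold <- function(values, q = 0.95) {
  v <- values[is.finite(values)]
  if (length(v) < 20L) {
    stop("need at least 20 finite values to define the ", q, " tail")
  }
  unname(stats::quantile(v, probs = q, type = 1, names = FALSE))
}

#' Three-statistic outlier intersection
#'
#' Joins windowed F_ST, diversity-ratio and iHH12 tables on a shared grid,
#' computes the empirical top-tail threshold of each statistic over the
#' ranked windows, and flags as selection signals the windows strictly
#' exceeding all three thresholds. Comparisons against an undefined
#' statistic fail, so such windows never qualify. The diversity-ratio
#' threshold operates on the raw ratio (log2 is display-only).
#'
#' @param fst_table Output of [windowed_fst()].
#' @param ratio_table Output of [pi_ratio()].
#' @param ihh12_table Output of [normalize_and_window()].
#' @param q Upper-tail quantile (default 0.95).
#' @param min_snps Minimum SNPs per ranked window (default 10).
#' @param rule `"all"` (default) requires all three statistics to exceed
#'   their thresholds; `"two_of_three"` requires any two.
#' @return A tibble with the grid columns, `n_snps`, `fst`, `pi_ratio`,
#'   `ihh12`, `ranked` and logical `signal`; thresholds are attached as
#'   `attr(, "thresholds")`.
#' @export
outlier_intersection <- function(fst_table, ratio_table, ihh12_table,
                                 q = 0.95, min_snps = 10,
                                 rule = c("all", "two_of_three")) {
  rule <- match.arg(rule)
  check_same_grid(fst_table, ratio_table)
  check_same_grid(fst_table, ihh12_table)
  tab <- tibble::tibble(
    chrom = fst_table$chrom, start = fst_table$start, end = fst_table$end,
    n_snps = fst_table$n_snps,
    partial = if ("partial" %in% names(fst_table)) fst_table$partial else FALSE,
    fst = fst_table$fst, pi_ratio = ratio_table$pi_ratio,
    log2_pi_ratio = ratio_table$log2_pi_ratio, ihh12 = ihh12_table$ihh12
  )
  tab <- filter_windows(tab, min_snps)
  thr <- c(
    fst = empirical_threshold(tab$fst[tab$ranked], q),
    pi_ratio = empirical_threshold(tab$pi_ratio[tab$ranked], q),
    ihh12 = empirical_threshold(tab$ihh12[tab$ranked], q)
  )
  exceeds <- cbind(
    fst = !is.na(tab$fst) & tab$fst > thr[["fst"]],
    pi_ratio = !is.na(tab$pi_ratio) & tab$pi_ratio > thr[["pi_ratio"]],
    ihh12 = !is.na(tab$ihh12) & tab$ihh12 > thr[["ihh12"]]
  )
  need <- if (rule == "all") 3L else 2L
  tab$signal <- tab$ranked & rowSums(exceeds) >= need
  attr(tab, "thresholds") <- tibble::tibble(
    statistic = names(thr), threshold = unname(thr), q = q)
  tab
}

#' Merge outlier windows into sweep regions
#'
#' Overlapping or boundary-adjacent outlier windows on one chromosome are
#' merged into maximal regions; per-region maxima and means of the
#' statistics present are recorded.
#'
#' @param windows A window table (typically the `signal` rows of
#'   [outlier_intersection()]).
#' @return A tibble with `chrom`, `start`, `end`, `n_windows` and, for each
#'   of `fst`, `pi_ratio`, `ihh12` present in the input, `<stat>_max` and
#'   `<stat>_mean`.
#' @export
merge_regions <- function(windows) {
  stats_present <- intersect(c("fst", "pi_ratio", "ihh12"), names(windows))
  if (!nrow(windows)) {
    out <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_windows = integer())
    for (s in stats_present) {
      out[[paste0(s, "_max")]] <- numeric()
      out[[paste0(s, "_mean")]] <- numeric()
    }
    return(out)
  }
  gr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start, windows$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = IRanges::start(red), end = IRanges::end(red),
    n_windows = as.integer(table(factor(grp, levels = seq_along(red))))
  )
  for (s in stats_present) {
    out[[paste0(s, "_max")]] <- as.vector(tapply(windows[[s]], factor(grp, levels = seq_along(red)),
                                                 function(v) suppressWarnings(max(v, na.rm = TRUE))))
    out[[paste0(s, "_mean")]] <- as.vector(tapply(windows[[s]], factor(grp, levels = seq_along(red)),
                                                  function(v) mean(v, na.rm = TRUE)))
  }
  out
}

#' Read gene features from GFF3
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `strand` for
#'   features of type `gene`.
#' @export
read_genes <- function(path) {
  g <- rtracklayer::import(path)
  g <- g[g$type == "gene"]
  id <- if (!is.null(g$ID)) g$ID else g$Name
  id <- sub("^gene:", "", id)
  tibble::tibble(gene_id = id,
                 chrom = as.character(GenomicRanges::seqnames(g)),
                 start = IRanges::start(g), end = IRanges::end(g),
                 strand = as.character(GenomicRanges::strand(g)))
}

#' Annotate sweep regions with overlapping genes
#'
#' A gene is assigned to a region iff their 1-based inclusive spans
#' intersect by at least one bp.
#'
#' @param regions A region table from [merge_regions()].
#' @param genes A gene table from [read_genes()] or a GFF3 path.
#' @return `regions` with added list-column `genes` (character vectors of
#'   gene IDs, in genomic order) and `n_genes`.
#' @export
annotate_genes <- function(regions, genes) {
  if (is.character(genes)) genes <- read_genes(genes)
  genes <- dplyr::arrange(tibble::as_tibble(genes), .data$chrom, .data$start)
  if (!nrow(regions)) {
    regions$genes <- list()
    regions$n_genes <- integer()
    return(regions)
  }
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hit <- GenomicRanges::findOverlaps(rg, gg)
  regions$genes <- lapply(seq_len(nrow(regions)), function(i) {
    genes$gene_id[S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == i]]
  })
  regions$n_genes <- lengths(regions$genes)
  regions
}

#' Run the composite selective-sweep scan
#'
#' The full pipeline for one focal-versus-reference comparison: read and
#' filter the VCF, split populations (several reference populations are
#' pooled into a single control by taking the union of their samples),
#' compute windowed diversity, the reference/focal diversity ratio,
#' weighted F_ST, per-SNP iHH12 with genome-wide normalisation and window
#' averaging, plus windowed Tajima's D in the focal population (reported
#' for context; it does not enter the outlier conjunction). Windows with at
#' least `min_snps` SNPs are ranked, the top-`(1-q)` tail of each of the
#' three statistics defines its threshold, windows exceeding all three are
#' merged into regions and annotated with overlapping genes.
#'
#' @param vcf Path to a VCF, or a [geno_matrix()].
#' @param popmap Popmap path or tibble (`sample`, `population`).
#' @param focal Focal population label.
#' @param reference Reference population label(s); multiple labels are
#'   pooled.
#' @param gff Optional GFF3 path or gene tibble for annotation.
#' @param window Window size in bp (default 10 kb).
#' @param q Upper-tail quantile (default 0.95).
#' @param min_snps Minimum SNPs per ranked window (default 10).
#' @param maf,max_missing Site filters applied at the meta-population level
#'   (defaults 0.05 and 0.10); `NULL` disables.
#' @param hard_filter Apply the GATK-style hard filters when `site_info` is
#'   present (default TRUE).
#' @param ehh_cutoff,max_extend iHH12 profile truncation parameters.
#' @param rule Outlier conjunction rule, see [outlier_intersection()].
#' @param out_dir Optional directory; when given, [write_scan()] is called.
#' @return An object of class `sweep_scan`: a list with `windows` (all
#'   statistics and signal flags), `thresholds`, `tajima` (focal windowed
#'   Tajima's D, or NULL if genotypes are incomplete), `regions`,
#'   `genome_fst` and `params`.
#' @export
run_scan <- function(vcf, popmap, focal, reference, gff = NULL,
                     window = 10000, q = 0.95, min_snps = 10, maf = 0.05,
                     max_missing = 0.10, hard_filter = TRUE,
                     ehh_cutoff = 0.05, max_extend = 1e6,
                     rule = c("all", "two_of_three"), out_dir = NULL) {
  rule <- match.arg(rule)
  gm <- if (inherits(vcf, "geno_matrix")) vcf else read_vcf(vcf)
  popmap <- as_popmap(popmap)
  if (hard_filter && !is.null(gm$site_info)) gm <- apply_hard_filters(gm)
  if (!is.null(maf)) {
    gm <- apply_frequency_filters(gm, maf_min = maf,
                                  max_missing = max_missing)
  }
  miss <- setdiff(c(focal, reference), unique(popmap$population))
  if (length(miss)) {
    stop("population(s) not in popmap: ", paste(miss, collapse = ", "))
  }
  pooled <- popmap
  pooled$population[pooled$population %in% reference] <- "reference_pool"
  keep <- pooled$population %in% c(focal, "reference_pool")
  gm_used <- subset_samples(gm, pooled$sample[keep])
  views <- split_populations(gm_used, pooled[keep, ])
  gm_focal <- views[[focal]]
  gm_ref <- views[["reference_pool"]]

  pi_f <- windowed_pi(gm_focal, window)
  pi_r <- windowed_pi(gm_ref, window)
  ratio <- pi_ratio(pi_r, pi_f)
  fst <- windowed_fst(gm_focal, gm_ref, window)
  taj <- tryCatch(windowed_tajima_d(gm_focal, window),
                  error = function(e) NULL)
  scores <- ihh12_scan(gm_focal, cutoff = ehh_cutoff,
                       max_extend = max_extend)
  ihh_tbl <- normalize_and_window(scores, window,
                                  chrom_len = gm_focal$chrom_len)
  windows <- outlier_intersection(fst, ratio, ihh_tbl, q = q,
                                  min_snps = min_snps, rule = rule)
  windows$pi_focal <- ratio$pi_focal
  windows$pi_ref <- ratio$pi_ref
  if (!is.null(taj)) windows$tajima_d <- taj$tajima_d
  regions <- merge_regions(windows[windows$signal, , drop = FALSE])
  if (!is.null(gff)) regions <- annotate_genes(regions, gff)
  res <- structure(
    list(windows = windows, thresholds = attr(windows, "thresholds"),
         regions = regions, genome_fst = attr(fst, "genome"),
         focal = focal, reference = reference,
         params = list(window = window, q = q, min_snps = min_snps,
                       maf = maf, max_missing = max_missing,
                       hard_filter = hard_filter, ehh_cutoff = ehh_cutoff,
                       max_extend = max_extend, rule = rule)),
    class = "sweep_scan")
  if (!is.null(out_dir)) write_scan(res, out_dir)
  res
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("<sweep_scan> ", x$focal, " vs ",
      paste(x$reference, collapse = "+"), "\n", sep = "")
  cat("  ", nrow(x$windows), " windows (", sum(x$windows$ranked),
      " ranked), ", sum(x$windows$signal), " signal windows, ",
      nrow(x$regions), " regions\n", sep = "")
  thr <- x$thresholds
  cat("  thresholds: ",
      paste(sprintf("%s > %.4g", thr$statistic, thr$threshold),
            collapse = ", "), "\n", sep = "")
  cat("  genome-wide weighted FST: ",
      sprintf("%.4f", x$genome_fst$weighted_fst), "\n", sep = "")
  invisible(x)
}

#' Write scan outputs
#'
#' Emits `windows.tsv`, `thresholds.tsv`, `regions.tsv`, `regions.bed`
#' (0-based half-open) and `manifest.json` into a directory. Output is
#' deterministic: re-running the same scan writes byte-identical files.
#'
#' @param x A `sweep_scan`.
#' @param dir Output directory (created if needed).
#' @return Named vector of paths, invisibly.
#' @export
write_scan <- function(x, dir) {
  stopifnot(inherits(x, "sweep_scan"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(windows = file.path(dir, "windows.tsv"),
             thresholds = file.path(dir, "thresholds.tsv"),
             regions = file.path(dir, "regions.tsv"),
             bed = file.path(dir, "regions.bed"),
             manifest = file.path(dir, "manifest.json"))
  write_tsv_det(x$windows, paths[["windows"]])
  write_tsv_det(x$thresholds, paths[["thresholds"]])
  reg <- x$regions
  if ("genes" %in% names(reg)) {
    reg$genes <- vapply(reg$genes, paste, "", collapse = ",")
  }
  write_tsv_det(reg, paths[["regions"]])
  bed <- data.frame(chrom = reg$chrom, start = reg$start - 1L,
                    end = reg$end)
  write_tsv_det(bed, paths[["bed"]], col_names = FALSE)
  manifest <- c(list(focal = x$focal, reference = x$reference),
                x$params,
                list(genome_fst = x$genome_fst,
                     thresholds = as.data.frame(x$thresholds)))
  con <- file(paths[["manifest"]], "wb")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), con, sep = "\n")
  close(con)
  invisible(paths)
}

write_tsv_det <- function(df, path, col_names = TRUE) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                        format(df[[j]], digits = 10, trim = TRUE,
                               scientific = FALSE))
    }
  }
  con <- file(path, "wb")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col_names, eol = "\n")
  close(con)
  invisible(path)
}
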