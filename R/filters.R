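#' Apply GATK-style hard filters to sites
#'
#' Removes sites failing any of the standard hard-filter rules:
#' `QUAL < 100`, `QD < 2`, `MQ < 40`, `FS > 60`, `SOR > 3`,
#' `MQRankSum < -12.5`, `ReadPosRankSum < -8`. All comparisons are strict,
#' so a site sitting exactly on a threshold is retained. A site whose
#' annotation for a given rule is missing passes that rule (mirroring how
#' rank-sum annotations are undefined at many sites); if `site_info` is
#' absent entirely the input is returned unchanged with a warning.
#'
#' @param gm A [geno_matrix()] with `site_info`.
#' @return The filtered `geno_matrix`; per-rule removal counts are attached
#'   as `attr(, "removal_log")` (a tibble with columns `rule`, `n_failed`).
#' @export
apply_hard_filters <- function(gm) {
  si <- gm$site_info
  empty_log <- tibble::tibble(rule = character(), n_failed = integer())
  if (is.null(si)) {
    warning("no site_info present; hard filters not applied")
    attr(gm, "removal_log") <- empty_log
    return(gm)
  }
  col <- function(f) if (f %in% names(si)) si[[f]] else rep(NA_real_, nrow(si))
  lt <- function(x, t) !is.na(x) & x < t
  gt_ <- function(x, t) !is.na(x) & x > t
  rules <- list(
    QUAL = lt(col("QUAL"), 100), QD = lt(col("QD"), 2),
    MQ = lt(col("MQ"), 40), FS = gt_(col("FS"), 60),
    SOR = gt_(col("SOR"), 3), MQRankSum = lt(col("MQRankSum"), -12.5),
    ReadPosRankSum = lt(col("ReadPosRankSum"), -8)
  )
  fail <- Reduce(`|`, rules)
  out <- subset_sites(gm, !fail)
  attr(out, "removal_log") <- tibble::tibble(
    rule = names(rules),
    n_failed = vapply(rules, sum, integer(1), USE.NAMES = FALSE)
  )
  attr(out, "dropped") <- attr(gm, "dropped")
  out
}

#' Filter sites on minor allele frequency and missingness
#'
#' MAF and the missing-genotype fraction are evaluated across the union of
#' all samples (the meta-population), not per population. A site is removed
#' if its MAF is strictly below `maf_min` or its missing fraction is
#' strictly above `max_missing`; sites with no called genotypes are removed.
#'
#' @param gm A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.05; a site at
#'   exactly 0.05 is retained).
#' @param max_missing Maximum tolerated missing-genotype fraction (default
#'   0.10; a site at exactly 0.10 is retained).
#' @return The filtered `geno_matrix` with `attr(, "removal_log")`.
#' @export
apply_frequency_filters <- function(gm, maf_min = 0.05, max_missing = 0.10) {
  g <- gm$gt
  called <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(called > 0, alt / (2 * called), NA_real_)
  maf <- pmin(p, 1 - p)
  miss <- rowMeans(is.na(g))
  fail_all_missing <- called == 0
  fail_maf <- !fail_all_missing & maf < maf_min
  fail_miss <- miss > max_missing
  out <- subset_sites(gm, !(fail_all_missing | fail_maf | fail_miss))
  attr(out, "removal_log") <- tibble::tibble(
    rule = c("all_missing", "maf", "missingness"),
    n_failed = c(sum(fail_all_missing), sum(fail_maf), sum(fail_miss))
  )
  attr(out, "dropped") <- attr(gm, "dropped")
  out
}

#' Split a genotype matrix by population
#'
#' Column-subsets the matrix into one view per population, preserving the
#' site set and order (no per-population re-filtering).
#'
#' @param gm A [geno_matrix()].
#' @param popmap A data frame with columns `sample` and `population`, or a
#'   path to a popmap TSV. Must cover every sample of `gm` exactly once, and
#'   every popmap sample must exist in `gm`.
#' @return A named list of `geno_matrix` views, in order of first appearance
#'   of each population in the popmap.
#' @export
split_populations <- function(gm, popmap) {
  popmap <- as_popmap(popmap)
  if (anyDuplicated(popmap$sample)) {
    stop("popmap lists a sample more than once")
  }
  unknown <- setdiff(popmap$sample, samples(gm))
  if (length(unknown)) {
    stop("popmap contains sample(s) absent from the matrix: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(samples(gm), popmap$sample)
  if (length(absent)) {
    stop("sample(s) missing from popmap: ", paste(absent, collapse = ", "))
  }
  pops <- unique(popmap$population)
  out <- lapply(pops, function(p) {
    subset_samples(gm, popmap$sample[popmap$population == p])
  })
  stats::setNames(out, pops)
}

as_popmap <- function(popmap) {
  if (is.character(popmap) && length(popmap) == 1L) popmap <- read_popmap(popmap)
  popmap <- tibble::as_tibble(popmap)
  stopifnot(all(c("sample", "population") %in% names(popmap)))
  popmap
}
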