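#' Weir-Cockerham variance components at one site
#'
#' Computes the among-population (`a`), among-individuals-within-population
#' (`b`) and within-individual (`c`) variance components of the
#' Weir & Cockerham (1984) F_ST estimator for one biallelic site with
#' diploid data, from per-population genotyped sample sizes, alt-allele
#' frequencies and observed heterozygote frequencies. The per-site estimate
#' is `a / (a + b + c)`, undefined where the denominator is zero.
#'
#' @param counts A data frame with one row per population and columns `n`
#'   (genotyped diploids), `p` (alt-allele frequency) and `h` (observed
#'   heterozygote frequency).
#' @return A one-row tibble with the intermediates `r`, `n_bar`, `n_c`,
#'   `p_bar`, `s2`, `h_bar`, the components `a`, `b`, `c` and `fst`.
#' @export
wc_site_components <- function(counts) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("n", "p", "h") %in% names(counts)))
  cmp <- wc_components_vec(
    n = matrix(counts$n, nrow = 1),
    p = matrix(counts$p, nrow = 1),
    h = matrix(counts$h, nrow = 1)
  )
  tibble::tibble(r = nrow(counts), n_bar = cmp$n_bar[1], n_c = cmp$n_c[1],
                 p_bar = cmp$p_bar[1], s2 = cmp$s2[1], h_bar = cmp$h_bar[1],
                 a = cmp$a[1], b = cmp$b[1], c = cmp$c[1],
                 fst = cmp$a[1] / (cmp$a[1] + cmp$b[1] + cmp$c[1]))
}

## Vectorised W&C (1984) components: n, p, h are sites x populations
## matrices. Sites where any population has zero genotyped individuals or
## where n_bar <= 1 are returned as NA (to be skipped and logged upstream).
wc_components_vec <- function(n, p, h) {
  r <- ncol(n)
  n_bar <- rowMeans(n)
  n_c <- (r * n_bar - rowSums(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- rowSums(n * p) / (r * n_bar)
  s2 <- rowSums(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n * h) / (r * n_bar)
  q_bar <- 1 - p_bar
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * q_bar - s2 * (r - 1) / r - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * q_bar - s2 * (r - 1) / r - h_bar * (2 * n_bar - 1) / (4 * n_bar))
  cc <- h_bar / 2
  bad <- apply(n, 1L, min) == 0 | n_bar <= 1 | n_c <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(n_bar = n_bar, n_c = n_c, p_bar = p_bar, s2 = s2, h_bar = h_bar,
       a = a, b = b, c = cc)
}

pop_site_summaries <- function(gms) {
  n <- vapply(gms, function(g) rowSums(!is.na(g$gt)), numeric(n_sites(gms[[1]])))
  alt <- vapply(gms, function(g) rowSums(g$gt, na.rm = TRUE),
                numeric(n_sites(gms[[1]])))
  het <- vapply(gms, function(g) rowSums(g$gt == 1L, na.rm = TRUE),
                numeric(n_sites(gms[[1]])))
  if (n_sites(gms[[1]]) == 1L) {
    n <- matrix(n, nrow = 1); alt <- matrix(alt, nrow = 1)
    het <- matrix(het, nrow = 1)
  }
  p <- ifelse(n > 0, alt / (2 * n), 0)
  h <- ifelse(n > 0, het / n, 0)
  list(n = n, p = p, h = h)
}

#' Per-site Weir-Cockerham F_ST
#'
#' @param ... Two or more [geno_matrix()] population views sharing the same
#'   site grid (or a single list of them).
#' @return A tibble with `chrom`, `pos`, `a`, `b`, `c` and per-site `fst`
#'   (`NA` where the site is uninformative or a population has no genotyped
#'   individuals).
#' @export
site_fst <- function(...) {
  gms <- list(...)
  if (length(gms) == 1L && is.list(gms[[1]]) &&
      !inherits(gms[[1]], "geno_matrix")) {
    gms <- gms[[1]]
  }
  if (length(gms) < 2L) stop("at least two populations are required")
  S <- n_sites(gms[[1]])
  for (g in gms[-1]) {
    if (n_sites(g) != S || !all(g$pos == gms[[1]]$pos)) {
      stop("populations must share the same site grid")
    }
  }
  sm <- pop_site_summaries(gms)
  cmp <- wc_components_vec(sm$n, sm$p, sm$h)
  denom <- cmp$a + cmp$b + cmp$c
  tibble::tibble(chrom = gms[[1]]$chrom, pos = gms[[1]]$pos,
                 a = cmp$a, b = cmp$b, c = cmp$c,
                 fst = ifelse(!is.na(denom) & denom != 0, cmp$a / denom,
                              NA_real_))
}

#' Windowed weighted Weir-Cockerham F_ST
#'
#' The weighted (ratio-of-sums) window estimate
#' `sum(a) / sum(a + b + c)` over the informative sites of each window,
#' with the unweighted mean of per-site ratios alongside for diagnostics.
#' The genome-wide weighted mean (same ratio over all sites) is attached as
#' `attr(, "genome")`, both raw and clamped at zero.
#'
#' @param gmA,gmB Two population [geno_matrix()] views on a shared site grid.
#' @param window Window size in bp (default 10 kb).
#' @return A tibble with `chrom`, `start`, `end`, `n_snps`, `fst`
#'   (weighted; `NA` when no informative site), `fst_unweighted` and
#'   `partial`.
#' @export
windowed_fst <- function(gmA, gmB, window = 10000) {
  per_site <- site_fst(gmA, gmB)
  grid <- window_grid(gmA, window)
  idx <- window_index(grid, per_site$chrom, per_site$pos, window)
  denom <- per_site$a + per_site$b + per_site$c
  inf <- !is.na(denom) & denom != 0
  grid$n_snps <- tabulate_at(idx, rep(1, nrow(per_site)), nrow(grid))
  sum_a <- tabulate_at(idx[inf], per_site$a[inf], nrow(grid))
  sum_abc <- tabulate_at(idx[inf], denom[inf], nrow(grid))
  n_inf <- tabulate_at(idx[inf], rep(1, sum(inf)), nrow(grid))
  grid$fst <- ifelse(n_inf > 0, sum_a / sum_abc, NA_real_)
  grid$fst_unweighted <- ifelse(
    n_inf > 0,
    tabulate_at(idx[inf], per_site$fst[inf], nrow(grid)) / n_inf, NA_real_)
  out <- grid[, c("chrom", "start", "end", "n_snps", "fst",
                  "fst_unweighted", "partial")]
  gw <- sum(per_site$a[inf]) / sum(denom[inf])
  attr(out, "genome") <- list(weighted_fst = gw,
                              weighted_fst_clamped = max(0, gw),
                              n_informative_sites = sum(inf))
  out
}
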