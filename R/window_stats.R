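#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity from an alt-allele count `k` among `n`
#' called alleles: `k * (n - k) / choose(n, 2)`, the mean number of pairwise
#' differences at the site.
#'
#' @param k Alt-allele count(s).
#' @param n Total called allele count(s) (vectorised; recycled).
#' @return Numeric vector of per-site diversity; `NA` where `n < 2`.
#' @export
site_pi <- function(k, n) {
  out <- k * (n - k) / choose(n, 2)
  out[n < 2] <- NA_real_
  out
}

## Shared non-overlapping window grid, tiled from position 1 per chromosome.
## The trailing window is truncated to the chromosome length (when known)
## and flagged partial; without a known length the last window ends at the
## last variant's containing window boundary and is treated as full.
make_windows <- function(chroms, chrom_len, pos, window) {
  grids <- lapply(chroms, function(ch) {
    len <- if (!is.null(chrom_len) && ch %in% names(chrom_len)) {
      chrom_len[[ch]]
    } else {
      max(pos[attr(pos, "chrom") == ch], 0)
    }
    n_win <- max(1L, ceiling(len / window))
    start <- (seq_len(n_win) - 1L) * window + 1
    end_full <- start + window - 1
    end <- pmin(end_full, len)
    tibble::tibble(chrom = ch, start = start, end = end,
                   partial = end < end_full)
  })
  dplyr::bind_rows(grids)
}

window_grid <- function(gm, window) {
  pos <- gm$pos
  attr(pos, "chrom") <- gm$chrom
  chroms <- if (!is.null(gm$chrom_len)) {
    union(names(gm$chrom_len), unique(gm$chrom))
  } else {
    unique(gm$chrom)
  }
  make_windows(chroms, gm$chrom_len, pos, window)
}

## Map each site onto a window grid row index (grid built with make_windows).
window_index <- function(grid, chrom, pos, window) {
  key <- paste0(chrom, ":", (pos - 1) %/% window)
  gkey <- paste0(grid$chrom, ":", (grid$start - 1) %/% window)
  match(key, gkey)
}

#' Windowed nucleotide diversity
#'
#' Per-bp nucleotide diversity in non-overlapping windows: the sum of
#' per-site diversity ([site_pi()]) over the window's SNPs divided by the
#' window span, so monomorphic bp count as invariant sequence. Windows
#' without SNPs are reported with `pi = 0`. Per-site allele totals use
#' non-missing calls only; sites with fewer than two called alleles
#' contribute zero.
#'
#' @param gm A [geno_matrix()], typically one population's view.
#' @param window Window size in bp (default 10 kb).
#' @return A tibble with columns `chrom`, `start`, `end`, `n_snps`, `pi`
#'   and `partial` (trailing truncated window flag).
#' @export
windowed_pi <- function(gm, window = 10000) {
  grid <- window_grid(gm, window)
  idx <- window_index(grid, gm$chrom, gm$pos, window)
  called <- 2 * rowSums(!is.na(gm$gt))
  alt <- rowSums(gm$gt, na.rm = TRUE)
  sp <- site_pi(alt, called)
  sp[is.na(sp)] <- 0
  grid$n_snps <- tabulate_at(idx, rep(1, length(idx)), nrow(grid))
  grid$pi <- tabulate_at(idx, sp, nrow(grid)) / (grid$end - grid$start + 1)
  grid[, c("chrom", "start", "end", "n_snps", "pi", "partial")]
}

tabulate_at <- function(idx, values, nbins) {
  out <- numeric(nbins)
  ok <- !is.na(idx) & !is.na(values)
  if (any(ok)) {
    tmp <- rowsum(values[ok], idx[ok])
    out[as.integer(rownames(tmp))] <- tmp[, 1]
  }
  out
}

#' Tajima (1989) coefficients
#'
#' The sample-size constants of Tajima's D for `n` haplotypes:
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i` in `1..n-1`,
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2 + a2)`.
#'
#' @param n Number of haplotypes (>= 3).
#' @return A one-row tibble with `n, a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_coefficients <- function(n) {
  if (n < 3) stop("Tajima's D variance is degenerate for n < 3")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  tibble::tibble(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1,
                 c2 = c2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D
#'
#' Per window, `S` is the count of segregating sites, `pi_abs` the mean
#' number of pairwise differences (absolute, not per-bp) and
#' `D = (pi_abs - S/a1) / sqrt(e1 S + e2 S (S-1))`; windows with `S = 0`
#' are undefined (`NA`). Requires complete genotypes so that the haplotype
#' count `n` is constant (impute or phase upstream).
#'
#' @inheritParams windowed_pi
#' @return A tibble with `chrom`, `start`, `end`, `n_snps`, `S`, `theta_w`
#'   (per-bp Watterson estimate), `tajima_d` and `partial`.
#' @export
windowed_tajima_d <- function(gm, window = 10000) {
  if (anyNA(gm$gt)) {
    stop("missing genotypes present; Tajima's D requires complete data ",
         "(impute missing calls upstream)")
  }
  n <- 2L * n_samples(gm)
  co <- tajima_coefficients(n)
  grid <- window_grid(gm, window)
  idx <- window_index(grid, gm$chrom, gm$pos, window)
  k <- rowSums(gm$gt)
  seg <- k > 0 & k < n
  grid$n_snps <- tabulate_at(idx, rep(1, length(idx)), nrow(grid))
  grid$S <- tabulate_at(idx, as.numeric(seg), nrow(grid))
  pi_abs <- tabulate_at(idx, k * (n - k) / choose(n, 2), nrow(grid))
  grid$theta_w <- grid$S / (co$a1 * (grid$end - grid$start + 1))
  denom <- sqrt(co$e1 * grid$S + co$e2 * grid$S * (grid$S - 1))
  grid$tajima_d <- ifelse(grid$S > 0, (pi_abs - grid$S / co$a1) / denom,
                          NA_real_)
  grid[, c("chrom", "start", "end", "n_snps", "S", "theta_w", "tajima_d",
           "partial")]
}

#' Between-population diversity ratio per window
#'
#' `pi_ratio = pi_ref / pi_focal` on a shared window grid, with the
#' reference (wild or control) population in the numerator so that a
#' diversity loss in the focal population gives ratios above 1. Windows
#' where the focal diversity is zero are undefined and excluded from
#' outlier ranking; `log2_pi_ratio` is provided for display.
#'
#' @param ref_table,focal_table Window tables from [windowed_pi()] computed
#'   on the same grid.
#' @return A tibble with the grid columns, `n_snps`, `pi_ref`, `pi_focal`,
#'   `pi_ratio`, `log2_pi_ratio` and `partial`.
#' @export
pi_ratio <- function(ref_table, focal_table) {
  check_same_grid(ref_table, focal_table)
  out <- focal_table[, c("chrom", "start", "end", "n_snps", "partial")]
  out$pi_ref <- ref_table$pi
  out$pi_focal <- focal_table$pi
  out$pi_ratio <- ifelse(out$pi_focal > 0, out$pi_ref / out$pi_focal,
                         NA_real_)
  out$log2_pi_ratio <- log2(out$pi_ratio)
  out[, c("chrom", "start", "end", "n_snps", "pi_ref", "pi_focal",
          "pi_ratio", "log2_pi_ratio", "partial")]
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || !all(a$chrom == b$chrom) ||
      !all(a$start == b$start) || !all(a$end == b$end)) {
    stop("window tables are not on the same grid")
  }
  invisible(TRUE)
}
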