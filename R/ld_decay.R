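## r2 between one site and a block of later sites, vectorised. On phased
## input this is the squared haplotype correlation, identical to
## D^2 / (pA qA pB qB); on genotype input the squared genotype correlation.
r2_block <- function(M, i, js) {
  x <- M[i, ]
  y <- M[js, , drop = FALSE]
  n <- length(x)
  sx <- x - mean(x)
  sy <- y - rowMeans(y)
  num <- as.vector(sy %*% sx)
  den <- sqrt(sum(sx^2) * rowSums(sy^2))
  (num / den)^2
}

prep_ld_input <- function(x, maf) {
  if (inherits(x, "geno_matrix")) {
    if (is_phased(x) && !anyNA(x$hap)) {
      M <- x$hap; mode <- "haplotype"
    } else {
      if (anyNA(x$gt)) stop("genotype r2 requires complete genotypes")
      M <- x$gt; mode <- "genotype"
    }
    pos <- x$pos; chrom <- x$chrom
  } else {
    M <- x; mode <- "haplotype"
    pos <- attr(x, "positions")
    if (is.null(pos)) pos <- seq_len(nrow(M))
    chrom <- rep("chr", nrow(M))
  }
  p <- rowMeans(M) / ifelse(mode == "genotype", 2, 1)
  keep <- pmin(p, 1 - p) >= maf
  list(M = M[keep, , drop = FALSE], pos = pos[keep], chrom = chrom[keep],
       mode = mode)
}

#' Linkage disequilibrium decay curve
#'
#' Mean r2 of all site pairs within `max_dist`, binned by pairwise
#' distance. r2 is computed from phased haplotypes when available and from
#' genotype correlation otherwise (reported in the `mode` attribute). Sites
#' below the `maf` cutoff are excluded before pairing.
#'
#' @param x A [geno_matrix()] or a 0/1 haplotype matrix (positions in
#'   `attr(, "positions")`).
#' @param max_dist Maximum pair separation in bp (default 300 kb).
#' @param bin Distance bin width in bp (default 1 kb).
#' @param maf Minor-allele-frequency cutoff applied before pairing.
#' @return A tibble with `dist_lo`, `dist_hi` (half-open bin `[lo, hi)`),
#'   `mean_r2` and `n_pairs`; `attr(, "mode")` records the r2 mode.
#' @export
decay_curve <- function(x, max_dist = 300000, bin = 1000, maf = 0.05) {
  inp <- prep_ld_input(x, maf)
  if (nrow(inp$M) < 2L) stop("need at least two sites after MAF filtering")
  sums <- numeric(0); counts <- numeric(0)
  nbins <- ceiling(max_dist / bin)
  sums <- numeric(nbins); counts <- numeric(nbins)
  for (ch in unique(inp$chrom)) {
    sel <- which(inp$chrom == ch)
    pos <- inp$pos[sel]
    S <- length(sel)
    for (ii in seq_len(max(0L, S - 1L))) {
      jmax <- ii + findInterval(pos[ii] + max_dist, pos[(ii + 1L):S])
      if (jmax <= ii) next
      js <- (ii + 1L):jmax
      r2 <- r2_block(inp$M, sel[ii], sel[js])
      b <- pmin(nbins, (pos[js] - pos[ii]) %/% bin + 1L)
      ok <- !is.na(r2)
      if (any(ok)) {
        agg <- rowsum(r2[ok], b[ok])
        cnt <- rowsum(rep(1, sum(ok)), b[ok])
        bi <- as.integer(rownames(agg))
        sums[bi] <- sums[bi] + agg[, 1]
        counts[bi] <- counts[bi] + cnt[, 1]
      }
    }
  }
  out <- tibble::tibble(
    dist_lo = (seq_len(nbins) - 1L) * bin,
    dist_hi = seq_len(nbins) * bin,
    mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
    n_pairs = as.integer(counts)
  )
  attr(out, "mode") <- inp$mode
  out
}

#' Mean r2 of adjacent SNP pairs
#'
#' Mean r2 over all consecutive site pairs within each chromosome, after
#' the MAF cutoff.
#'
#' @inheritParams decay_curve
#' @return A numeric scalar; the per-pair values are attached as
#'   `attr(, "pairs")`.
#' @export
adjacent_pair_r2 <- function(x, maf = 0.05) {
  inp <- prep_ld_input(x, maf)
  if (nrow(inp$M) < 2L) stop("need at least two sites after MAF filtering")
  rows <- list()
  for (ch in unique(inp$chrom)) {
    sel <- which(inp$chrom == ch)
    if (length(sel) < 2L) next
    for (ii in seq_len(length(sel) - 1L)) {
      r2 <- r2_block(inp$M, sel[ii], sel[ii + 1L])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = ch, pos_i = inp$pos[sel[ii]], pos_j = inp$pos[sel[ii + 1L]],
        r2 = r2)
    }
  }
  pairs <- dplyr::bind_rows(rows)
  out <- mean(pairs$r2, na.rm = TRUE)
  attr(out, "pairs") <- pairs
  out
}
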