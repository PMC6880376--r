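## Resolve a phased haplotype matrix (sites x haplotypes, 0/1, no missing)
## and its positions from either a geno_matrix or a plain matrix.
as_hap_matrix <- function(x, positions = NULL) {
  if (inherits(x, "geno_matrix")) {
    if (!is_phased(x)) stop("phased haplotypes are required (unphased input)")
    H <- x$hap
    positions <- x$pos
    chrom <- x$chrom
  } else {
    H <- x
    if (is.null(positions)) positions <- seq_len(nrow(H))
    chrom <- rep("chr", nrow(H))
  }
  if (anyNA(H)) {
    stop("haplotypes contain missing alleles; impute upstream")
  }
  if (ncol(H) < 2L) stop("at least two haplotypes are required")
  list(H = H, pos = positions, chrom = chrom)
}

## EHH12 from haplotype class counts: pool the two largest classes.
ehh12_value <- function(class_sizes, n) {
  t <- sort(class_sizes, decreasing = TRUE)
  top <- sum(t[seq_len(min(2L, length(t)))])
  rest <- if (length(t) > 2L) t[-(1:2)] else integer()
  (choose(top, 2) + sum(choose(rest, 2))) / choose(n, 2)
}

#' EHH12 profile around a core site
#'
#' Extending site-by-site left and right from the core, haplotypes are
#' partitioned by identity over the extended span and
#' `EHH12 = (choose(n1 + n2, 2) + sum(choose(nk, 2) for k > 2)) / choose(n, 2)`
#' with `n1 >= n2` the two largest class counts. Each side is truncated at
#' the first value below `cutoff` or beyond `max_extend` bp from the core.
#' EHH12 is 1 at the core and non-increasing outward.
#'
#' @param x A phased [geno_matrix()] or a sites x haplotypes 0/1 matrix.
#' @param core Site index of the core SNP.
#' @param cutoff EHH12 truncation threshold (default 0.05).
#' @param max_extend Maximum extension from the core in bp (default 1 Mb).
#' @param positions Site positions when `x` is a plain matrix.
#' @return An object of class `ehh12_profile`: a list with `core`,
#'   `core_pos`, `n` and a tibble `profile` (`pos`, `dist`, signed `side`,
#'   `ehh12`), plus the parameters.
#' @export
ehh12_profile <- function(x, core, cutoff = 0.05, max_extend = 1e6,
                          positions = NULL) {
  hm <- as_hap_matrix(x, positions)
  H <- hm$H; pos <- hm$pos
  S <- nrow(H); n <- ncol(H)
  stopifnot(core >= 1, core <= S)
  chrom <- hm$chrom
  on_chrom <- which(chrom == chrom[core])

  extend_side <- function(step) {
    cls <- H[core, ] + 1L
    out_pos <- integer(); out_ehh <- numeric()
    j <- core
    repeat {
      j <- j + step
      if (j < min(on_chrom) || j > max(on_chrom)) break
      if (abs(pos[j] - pos[core]) > max_extend) break
      comb <- cls * 2L + H[j, ]
      cls <- match(comb, unique(comb))
      e <- ehh12_value(tabulate(cls), n)
      out_pos <- c(out_pos, pos[j]); out_ehh <- c(out_ehh, e)
      if (e < cutoff) break
    }
    tibble::tibble(pos = out_pos, ehh12 = out_ehh)
  }
  left <- extend_side(-1L)
  right <- extend_side(1L)
  prof <- dplyr::bind_rows(
    dplyr::mutate(left, side = -1L),
    tibble::tibble(pos = pos[core], ehh12 = 1, side = 0L),
    dplyr::mutate(right, side = 1L)
  )
  prof$dist <- abs(prof$pos - pos[core])
  prof <- prof[order(prof$pos), c("pos", "dist", "side", "ehh12")]
  structure(list(core = core, core_pos = pos[core], n = n,
                 profile = prof, cutoff = cutoff, max_extend = max_extend),
            class = "ehh12_profile")
}

#' @export
print.ehh12_profile <- function(x, ...) {
  cat("<ehh12_profile> core site ", x$core, " at ", x$core_pos, " bp, ",
      x$n, " haplotypes, ", nrow(x$profile) - 1L, " flanking points\n",
      sep = "")
  invisible(x)
}

#' Integrated EHH12 (iHH12)
#'
#' Trapezoidal integral of the EHH12 profile over physical distance, summed
#' over the two sides. Where a segment crosses below the cutoff the
#' integration stops at the linearly interpolated crossing point; a side
#' with no flanking sites contributes zero.
#'
#' @param profile An [ehh12_profile()].
#' @return The iHH12 area in bp-units (numeric scalar, >= 0).
#' @export
ihh12 <- function(profile) {
  stopifnot(inherits(profile, "ehh12_profile"))
  side_area <- function(side_sign) {
    p <- profile$profile[profile$profile$side == side_sign, ]
    d <- c(0, p$dist); e <- c(1, p$ehh12)
    o <- order(d); d <- d[o]; e <- e[o]
    area <- 0
    for (i in seq_len(length(d) - 1L)) {
      if (e[i + 1] >= profile$cutoff) {
        area <- area + (e[i] + e[i + 1]) / 2 * (d[i + 1] - d[i])
      } else {
        x <- d[i] + (d[i + 1] - d[i]) * (e[i] - profile$cutoff) /
          (e[i] - e[i + 1])
        area <- area + (e[i] + profile$cutoff) / 2 * (x - d[i])
        break
      }
    }
    area
  }
  side_area(-1L) + side_area(1L)
}

#' Genome-wide per-SNP iHH12 scores
#'
#' Computes [ihh12()] with each SNP in turn as the core site.
#'
#' @inheritParams ehh12_profile
#' @return A tibble with `chrom`, `pos` and `ihh12`.
#' @export
ihh12_scan <- function(x, cutoff = 0.05, max_extend = 1e6, positions = NULL) {
  hm <- as_hap_matrix(x, positions)
  scores <- ihh12_scan_cpp(hm$H, as.numeric(hm$pos),
                           as.integer(factor(hm$chrom,
                                             levels = unique(hm$chrom))),
                           cutoff, max_extend)
  tibble::tibble(chrom = hm$chrom, pos = hm$pos, ihh12 = scores)
}

#' Normalise per-SNP scores and average in windows
#'
#' z-normalises the scores over all scored SNPs genome-wide (population
#' standard deviation, denominator `n`) and averages the normalised scores
#' in non-overlapping windows. Windows without a scored SNP are undefined.
#'
#' @param scores A tibble with `chrom`, `pos` and `ihh12` (from
#'   [ihh12_scan()]).
#' @param window Window size in bp (default 10 kb).
#' @param chrom_len Optional named chromosome lengths for the window grid.
#' @return A tibble with `chrom`, `start`, `end`, `n_scored`, `ihh12`
#'   (window mean normalised score) and `partial`.
#' @export
normalize_and_window <- function(scores, window = 10000, chrom_len = NULL) {
  v <- scores$ihh12
  fin <- is.finite(v)
  if (sum(fin) < 2L) stop("need at least two finite scores to normalise")
  m <- mean(v[fin])
  s <- sqrt(mean((v[fin] - m)^2))
  if (s == 0) stop("degenerate score set: standard deviation is zero")
  z <- (v - m) / s
  gm_like <- list(chrom = scores$chrom, pos = scores$pos,
                  chrom_len = chrom_len)
  grid <- window_grid(gm_like, window)
  idx <- window_index(grid, scores$chrom, scores$pos, window)
  grid$n_scored <- tabulate_at(idx[fin], rep(1, sum(fin)), nrow(grid))
  grid$ihh12 <- ifelse(grid$n_scored > 0,
                       tabulate_at(idx[fin], z[fin], nrow(grid)) /
                         grid$n_scored, NA_real_)
  grid[, c("chrom", "start", "end", "n_scored", "ihh12", "partial")]
}

#' Pairwise linkage disequilibrium between two sites
#'
#' From phased haplotype counts: `D = f(AB) - pA pB`,
#' `D' = D / Dmax` with `Dmax = min(pA qB, qA pB)` for `D > 0` and
#' `min(pA pB, qA qB)` for `D < 0`, and `r2 = D^2 / (pA qA pB qB)`. The
#' "A"/"B" alleles are the alt (1) alleles at each site.
#'
#' @param x A phased [geno_matrix()] or 0/1 haplotype matrix.
#' @param site_i,site_j Site indices; both must be polymorphic.
#' @param positions Site positions when `x` is a plain matrix.
#' @return A one-row tibble with `D`, `D_prime`, `r2` and `distance` (bp).
#' @export
ld_pair <- function(x, site_i, site_j, positions = NULL) {
  hm <- as_hap_matrix(x, positions)
  a <- hm$H[site_i, ]; b <- hm$H[site_j, ]
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("both sites must be polymorphic")
  }
  qA <- 1 - pA; qB <- 1 - pB
  D <- mean(a == 1L & b == 1L) - pA * pB
  dmax <- if (D > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  dp <- if (D == 0) 0 else D / dmax
  tibble::tibble(D = D, D_prime = dp, r2 = D^2 / (pA * qA * pB * qB),
                 distance = abs(hm$pos[site_j] - hm$pos[site_i]))
}

#' Haplotype frequencies over a set of sites
#'
#' Tabulates the haplotype strings spelled by the REF/ALT alleles at a
#' subset of sites, per population, with counts and frequencies; the
#' pairwise D'/r2 among the subset sites within each population is attached
#' as `attr(, "ld")` to flag perfect-LD site sets.
#'
#' @param gm A phased [geno_matrix()] with complete calls at the subset.
#' @param sites Positions (bp) of the subset sites, or a list
#'   `list(chrom =, pos =)`; all must exist in `gm`.
#' @param popmap Sample-to-population map (tibble or path).
#' @return A tibble with `population`, `haplotype`, `count` and `freq`.
#' @export
haplotype_frequencies <- function(gm, sites, popmap) {
  if (!is_phased(gm)) stop("phased input required")
  if (is.list(sites) && !is.null(sites$pos)) {
    idx <- match(paste(sites$chrom, sites$pos),
                 paste(gm$chrom, gm$pos))
  } else {
    idx <- match(sites, gm$pos)
  }
  if (length(idx) == 0L) stop("empty site subset")
  if (anyNA(idx)) stop("site subset contains positions absent from the matrix")
  popmap <- as_popmap(popmap)
  sub <- subset_sites(gm, idx)
  if (anyNA(sub$hap)) stop("missing alleles at subset sites; impute upstream")
  alleles <- ifelse(sub$hap == 1L, sub$alt, sub$ref)
  hap_str <- apply(alleles, 2L, paste, collapse = "")
  hap_sample <- rep(samples(gm), each = 2L)
  hap_pop <- popmap$population[match(hap_sample, popmap$sample)]
  tab <- tibble::tibble(population = hap_pop, haplotype = hap_str) |>
    dplyr::count(.data$population, .data$haplotype, name = "count") |>
    dplyr::group_by(.data$population) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$population, dplyr::desc(.data$count))
  attr(tab, "ld") <- subset_ld_pairs(sub, popmap)
  tab
}

subset_ld_pairs <- function(sub, popmap) {
  pops <- unique(popmap$population)
  S <- n_sites(sub)
  if (S < 2L) return(tibble::tibble())
  out <- list()
  for (p in pops) {
    g <- subset_samples(sub, popmap$sample[popmap$population == p])
    for (i in seq_len(S - 1L)) {
      for (j in seq((i + 1L), S)) {
        poly <- !mean(g$hap[i, ]) %in% c(0, 1) &&
          !mean(g$hap[j, ]) %in% c(0, 1)
        row <- if (poly) {
          ld_pair(g, i, j)
        } else {
          tibble::tibble(D = NA_real_, D_prime = NA_real_, r2 = NA_real_,
                         distance = abs(g$pos[j] - g$pos[i]))
        }
        row$population <- p
        row$pos_i <- g$pos[i]; row$pos_j <- g$pos[j]
        out[[length(out) + 1L]] <- row
      }
    }
  }
  dplyr::bind_rows(out)[, c("population", "pos_i", "pos_j", "D", "D_prime",
                            "r2", "distance")]
}

#' Per-population allele frequencies
#'
#' Alt- and ref-allele frequencies over non-missing alleles, per population
#' and site; populations with no genotyped individual at a site get `NA`.
#'
#' @param gm A [geno_matrix()].
#' @param popmap Sample-to-population map (tibble or path).
#' @param sites Optional positions to restrict to.
#' @return A tibble with `population`, `chrom`, `pos`, `ref`, `alt`,
#'   `n_alleles`, `alt_count`, `alt_freq`, `ref_freq`.
#' @export
allele_frequencies <- function(gm, popmap, sites = NULL) {
  popmap <- as_popmap(popmap)
  if (!is.null(sites)) {
    idx <- match(sites, gm$pos)
    if (anyNA(idx)) stop("sites contain positions absent from the matrix")
    gm <- subset_sites(gm, idx)
  }
  pops <- unique(popmap$population)
  out <- lapply(pops, function(p) {
    g <- subset_samples(gm, popmap$sample[popmap$population == p])
    n_all <- 2L * rowSums(!is.na(g$gt))
    alt_cnt <- rowSums(g$gt, na.rm = TRUE)
    freq <- ifelse(n_all > 0, alt_cnt / n_all, NA_real_)
    tibble::tibble(population = p, chrom = g$chrom, pos = g$pos,
                   ref = g$ref, alt = g$alt, n_alleles = n_all,
                   alt_count = alt_cnt, alt_freq = freq,
                   ref_freq = 1 - freq)
  })
  dplyr::bind_rows(out)
}
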