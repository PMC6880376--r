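# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (explicit enumeration, no shared code with the package
# internals) so that agreement is meaningful.

# Mean pairwise difference at one site by enumerating all haplotype pairs.
oracle_site_pi <- function(haps) {
  n <- length(haps)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) diffs <- diffs + (haps[i] != haps[j])
  }
  diffs / choose(n, 2)
}

# Tajima's D for one window by full pairwise enumeration and a literal
# transcription of the published constants.
oracle_tajima_d <- function(H) {
  n <- ncol(H)
  S <- sum(apply(H, 1, function(r) length(unique(r)) > 1))
  if (S == 0) return(NA_real_)
  pi_abs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) pi_abs <- pi_abs + sum(H[, i] != H[, j])
  }
  pi_abs <- pi_abs / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_abs - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) a, b, c for one site: independent transcription
# of the per-allele equations from per-population genotype vectors
# (0/1/2/NA).
oracle_wc <- function(geno_by_pop) {
  r <- length(geno_by_pop)
  n_i <- vapply(geno_by_pop, function(g) sum(!is.na(g)), 1)
  p_i <- vapply(geno_by_pop, function(g) sum(g, na.rm = TRUE), 1) / (2 * n_i)
  h_i <- vapply(geno_by_pop, function(g) sum(g == 1, na.rm = TRUE), 1) / n_i
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, fst = a / (a + b + cc))
}

# EHH12 at a given one-sided extension by materialising haplotype strings.
oracle_ehh12 <- function(H, core, upto) {
  n <- ncol(H)
  span <- min(core, upto):max(core, upto)
  key <- apply(H[span, , drop = FALSE], 2, paste, collapse = "")
  cnt <- sort(as.integer(table(key)), decreasing = TRUE)
  top <- sum(cnt[seq_len(min(2, length(cnt)))])
  rest <- if (length(cnt) > 2) cnt[-(1:2)] else integer()
  (choose(top, 2) + sum(choose(rest, 2))) / choose(n, 2)
}

# D, D', r2 from the explicit 2x2 gamete contingency table.
oracle_ld <- function(a, b) {
  n <- length(a)
  pAB <- sum(a == 1 & b == 1) / n
  pA <- mean(a); pB <- mean(b)
  D <- pAB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  list(D = D, D_prime = if (D == 0) 0 else D / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# Nearest-rank upper quantile by sort-and-slice.
oracle_threshold <- function(v, q) {
  v <- sort(v[is.finite(v)])
  v[ceiling(q * length(v))]
}

# Interval union by bp-level membership on small coordinates.
oracle_merge <- function(starts, ends) {
  covered <- sort(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
  if (!length(covered)) return(data.frame(start = integer(), end = integer()))
  brk <- which(diff(covered) > 1)
  data.frame(start = covered[c(1, brk + 1)], end = covered[c(brk, length(covered))])
}

# All-pairs 1-based inclusive interval intersection test.
oracle_overlap <- function(s1, e1, s2, e2) max(s1, s2) <= min(e1, e2)

# PLINK-style ROH state by materialising every scanning window explicitly.
oracle_roh_state <- function(pos, gt, window_snp = 50, window_kb = 5000,
                             window_het = 1, window_missing = 5,
                             hit_threshold = 0.05) {
  S <- length(pos)
  if (S < window_snp) return(rep(FALSE, S))
  wins <- lapply(seq_len(S - window_snp + 1), function(i) i:(i + window_snp - 1))
  valid <- vapply(wins, function(w) pos[max(w)] - pos[min(w)] + 1 <=
                    window_kb * 1000, TRUE)
  hom <- vapply(wins, function(w) {
    sum(gt[w] == 1, na.rm = TRUE) <= window_het &&
      sum(is.na(gt[w])) <= window_missing
  }, TRUE) & valid
  vapply(seq_len(S), function(j) {
    cover <- which(vapply(wins, function(w) j %in% w, TRUE))
    cover <- cover[valid[cover]]
    length(cover) > 0 && mean(hom[cover]) >= hit_threshold
  }, TRUE)
}

# Small random phased geno_matrix for property tests.
random_gm <- function(S = 30, n = 8, chrom = "chr1", maf_floor = 0,
                      chrom_len = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(sample.int(max(S * 50, 1000), S))
  hap <- matrix(0L, S, 2 * n)
  for (i in seq_len(S)) {
    repeat {
      row <- rbinom(2 * n, 1, runif(1, 0.1, 0.9))
      f <- mean(row)
      if (f > 0 && f < 1 && min(f, 1 - f) >= maf_floor) break
    }
    hap[i, ] <- row
  }
  smp <- sprintf("s%02d", seq_len(n))
  colnames(hap) <- paste0(rep(smp, each = 2), c(".1", ".2"))
  gt <- hap[, seq(1, 2 * n, 2), drop = FALSE] + hap[, seq(2, 2 * n, 2), drop = FALSE]
  colnames(gt) <- smp
  geno_matrix(chrom = rep(chrom, S), pos = pos, ref = rep("A", S),
              alt = rep("T", S), gt = gt, hap = hap, chrom_len = chrom_len)
}
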