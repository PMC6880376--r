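#' Parameters for the run-of-homozygosity scan
#'
#' Defaults follow the standard PLINK scanning-window settings: 50-SNP
#' windows capped at 5 Mb, at most 1 heterozygote and 5 missing calls per
#' homozygous window, a 5% hit threshold for the per-SNP state, and emitted
#' segments of at least 10 SNPs and 100 kb with at most 10 kb per SNP and
#' splits at inter-SNP gaps above 100 kb.
#'
#' @param window_snp SNPs per scanning window.
#' @param window_kb Maximum scanning-window span (kb).
#' @param window_het Maximum heterozygous calls for a homozygous window.
#' @param window_missing Maximum missing calls for a homozygous window.
#' @param hit_threshold Minimum fraction of containing homozygous windows
#'   for a SNP to be in the ROH state.
#' @param min_snp Minimum SNPs per emitted segment.
#' @param min_kb Minimum segment length (kb).
#' @param max_kb_per_snp Maximum segment length per SNP (kb), a density cap.
#' @param max_gap_kb Maximum inter-SNP gap within a segment (kb).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50, window_kb = 5000, window_het = 1,
                       window_missing = 5, hit_threshold = 0.05,
                       min_snp = 10, min_kb = 100, max_kb_per_snp = 10,
                       max_gap_kb = 100) {
  p <- list(window_snp = window_snp, window_kb = window_kb,
            window_het = window_het, window_missing = window_missing,
            hit_threshold = hit_threshold, min_snp = min_snp,
            min_kb = min_kb, max_kb_per_snp = max_kb_per_snp,
            max_gap_kb = max_gap_kb)
  stopifnot(all(unlist(p) > 0), hit_threshold <= 1)
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' PLINK-style scanning-window ROH detection per individual and
#' chromosome: every `window_snp`-SNP window (with span at most
#' `window_kb`) is called homozygous iff it contains at most `window_het`
#' heterozygous and `window_missing` missing calls; a SNP is in the ROH
#' state iff the fraction of valid windows containing it that are
#' homozygous is at least `hit_threshold`; maximal runs of in-state SNPs
#' are split at inter-SNP gaps above `max_gap_kb` and then filtered by
#' `min_snp`, `min_kb` and the `max_kb_per_snp` density cap. Segment
#' endpoints are the first and last in-state SNP positions.
#'
#' @param gm A [geno_matrix()] (all samples are scanned unless `samples`
#'   restricts them).
#' @param params An [roh_params()] object.
#' @param samples Optional subset of sample names.
#' @return A tibble with `sample`, `chrom`, `start`, `end`, `n_snps`,
#'   `n_het` and `length` (bp).
#' @export
detect_roh <- function(gm, params = roh_params(), samples = NULL) {
  if (is.null(samples)) samples <- colnames(gm$gt)
  out <- list()
  for (ch in unique(gm$chrom)) {
    on_ch <- gm$chrom == ch
    pos <- gm$pos[on_ch]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("positions must be strictly increasing on ", ch)
    }
    for (smp in samples) {
      track <- gm$gt[on_ch, smp]
      segs <- roh_track(pos, track, params)
      if (nrow(segs)) {
        segs$sample <- smp
        segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_snps = integer(), n_het = integer(),
                          length = integer()))
  }
  dplyr::bind_rows(out)[, c("sample", "chrom", "start", "end", "n_snps",
                            "n_het", "length")]
}

## Core scanning-window state machine for one genotype track.
roh_track <- function(pos, gt, params) {
  S <- length(pos)
  w <- params$window_snp
  empty <- tibble::tibble(start = integer(), end = integer(),
                          n_snps = integer(), n_het = integer(),
                          length = integer())
  if (S < w) return(empty)
  het <- !is.na(gt) & gt == 1L
  mis <- is.na(gt)
  n_win <- S - w + 1L
  roll <- function(x) {
    cs <- cumsum(c(0, x))
    cs[(w + 1L):(S + 1L)] - cs[1:n_win]
  }
  span <- pos[w:S] - pos[1:n_win] + 1L
  valid <- span <= params$window_kb * 1000
  hit <- valid & roll(het) <= params$window_het &
    roll(mis) <= params$window_missing
  ## windows covering SNP j: start indices max(1, j-w+1) .. min(j, n_win)
  cum_hit <- cumsum(c(0, hit))
  cum_val <- cumsum(c(0, valid))
  lo <- pmax(1L, seq_len(S) - w + 1L)
  hi <- pmin(seq_len(S), n_win)
  den <- ifelse(hi >= lo, cum_val[hi + 1L] - cum_val[lo], 0)
  num <- ifelse(hi >= lo, cum_hit[hi + 1L] - cum_hit[lo], 0)
  state <- den > 0 & num / den >= params$hit_threshold

  ## maximal runs of in-state SNPs, split at large gaps
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (i in which(r$values)) {
    sidx <- starts[i]:ends[i]
    gap_break <- which(diff(pos[sidx]) > params$max_gap_kb * 1000)
    piece_start <- c(1L, gap_break + 1L)
    piece_end <- c(gap_break, length(sidx))
    for (k in seq_along(piece_start)) {
      pidx <- sidx[piece_start[k]:piece_end[k]]
      n_snps <- length(pidx)
      len <- pos[pidx[n_snps]] - pos[pidx[1L]] + 1L
      if (n_snps >= params$min_snp && len >= params$min_kb * 1000 &&
          len / n_snps <= params$max_kb_per_snp * 1000) {
        segs[[length(segs) + 1L]] <- tibble::tibble(
          start = pos[pidx[1L]], end = pos[pidx[n_snps]],
          n_snps = n_snps, n_het = sum(het[pidx]), length = len)
      }
    }
  }
  if (!length(segs)) empty else dplyr::bind_rows(segs)
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` per individual is the summed (overlap-merged) ROH length divided
#' by the genome length; the population value is the mean over its
#' individuals.
#'
#' @param segments ROH segments from [detect_roh()].
#' @param genome_length Genome length in bp (default 2.92e9, the assembly
#'   length used for goat ROH work).
#' @param popmap Optional sample-to-population map; when given, samples
#'   without segments are included at `froh = 0` and a per-population
#'   summary is attached as `attr(, "population")`.
#' @return A tibble with `sample`, `roh_bp` and `froh` (plus `population`
#'   when a popmap is supplied).
#' @export
f_roh <- function(segments, genome_length = 2.92e9, popmap = NULL) {
  if (genome_length <= 0) stop("genome_length must be positive")
  merged <- merge_sample_segments(segments)
  ind <- merged |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(roh_bp = sum(.data$end - .data$start + 1)) |>
    dplyr::ungroup()
  if (!is.null(popmap)) {
    popmap <- as_popmap(popmap)
    ind <- dplyr::left_join(popmap, ind, by = "sample") |>
      dplyr::mutate(roh_bp = dplyr::coalesce(.data$roh_bp, 0))
  }
  ind$froh <- ind$roh_bp / genome_length
  if (!is.null(popmap)) {
    attr(ind, "population") <- ind |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(froh = mean(.data$froh), n = dplyr::n()) |>
      dplyr::ungroup()
  }
  ind
}

merge_sample_segments <- function(segments) {
  segments <- tibble::as_tibble(segments)
  if (!nrow(segments)) return(segments)
  parts <- split(segments, paste(segments$sample, segments$chrom))
  dplyr::bind_rows(lapply(parts, function(d) {
    rr <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    tibble::tibble(sample = d$sample[1], chrom = d$chrom[1],
                   start = IRanges::start(rr),
                   end = IRanges::end(rr))
  }))
}

#' ROH length classes
#'
#' Counts and proportions of segments in the four standard length classes
#' 0-250 kb, 250-500 kb, 500-1000 kb and >= 1 Mb (half-open boundaries
#' `[lo, hi)`).
#'
#' @param segments ROH segments from [detect_roh()].
#' @return A tibble with `class`, `n` and `prop` (zero proportions for an
#'   empty input).
#' @export
roh_size_classes <- function(segments) {
  labels <- c("0-250kb", "250-500kb", "500-1000kb", ">1000kb")
  breaks <- c(0, 250e3, 500e3, 1e6, Inf)
  len <- if (nrow(segments)) segments$end - segments$start + 1 else numeric()
  cls <- cut(len, breaks = breaks, labels = labels, right = FALSE)
  n <- as.integer(table(factor(cls, levels = labels)))
  tibble::tibble(class = labels, n = n,
                 prop = if (sum(n) > 0) n / sum(n) else rep(0, 4L))
}
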