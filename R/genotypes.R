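#' Construct a genotype matrix object
#'
#' The central container for biallelic SNP data: per-site coordinates and
#' alleles, a sites x samples matrix of alt-allele dosages (0/1/2, `NA` for
#' missing), optional phased haplotypes and optional per-site quality
#' annotations (QUAL, QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum).
#'
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt Single-character REF/ALT alleles per site.
#' @param gt Integer matrix, sites x samples, values in \{0, 1, 2, NA\};
#'   column names are sample identifiers.
#' @param hap Optional integer matrix, sites x (2 * samples), phased
#'   haplotype alleles in \{0, 1\} (`NA` where the genotype call is missing).
#'   Columns for sample `s` must be named `s.1` and `s.2`.
#' @param site_info Optional data frame of per-site quality annotations.
#' @param chrom_len Optional named numeric vector of chromosome lengths (bp).
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(chrom, pos, ref, alt, gt, hap = NULL,
                        site_info = NULL, chrom_len = NULL) {
  pos <- as.integer(pos)
  stopifnot(length(chrom) == length(pos), nrow(gt) == length(pos))
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  if (!all(gt %in% c(0L, 1L, 2L, NA))) {
    stop("genotype values must be 0, 1, 2 or NA")
  }
  if (!is.null(hap)) {
    stopifnot(nrow(hap) == length(pos), ncol(hap) == 2L * ncol(gt))
    ok <- is.na(hap) | hap == 0L | hap == 1L
    if (!all(ok)) stop("haplotype alleles must be 0/1 or NA")
    g2 <- hap[, seq(1L, ncol(hap), by = 2L), drop = FALSE] +
      hap[, seq(2L, ncol(hap), by = 2L), drop = FALSE]
    both <- !is.na(g2) & !is.na(gt)
    if (any(g2[both] != gt[both])) {
      stop("haplotype alleles do not sum to the genotype dosage")
    }
  }
  structure(
    list(chrom = as.character(chrom), pos = pos,
         ref = as.character(ref), alt = as.character(alt),
         gt = gt, hap = hap,
         site_info = if (is.null(site_info)) NULL else tibble::as_tibble(site_info),
         chrom_len = chrom_len),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", n_sites(x), " sites x ", n_samples(x), " samples",
      if (is_phased(x)) " (phased)" else "", "\n", sep = "")
  cat("  chromosomes: ", paste(unique(x$chrom), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Dimensions and accessors for genotype matrices
#'
#' @param gm A `geno_matrix`.
#' @return `n_sites()` and `n_samples()` return integers; `samples()` the
#'   sample names; `is_phased()` whether phased haplotypes are stored.
#' @export
n_sites <- function(gm) length(gm$pos)

#' @rdname n_sites
#' @export
n_samples <- function(gm) ncol(gm$gt)

#' @rdname n_sites
#' @export
samples <- function(gm) colnames(gm$gt)

#' @rdname n_sites
#' @export
is_phased <- function(gm) !is.null(gm$hap)

## Subset a geno_matrix to a logical/integer site index, keeping all
## parallel per-site slots in register.
subset_sites <- function(gm, keep) {
  gm$chrom <- gm$chrom[keep]
  gm$pos <- gm$pos[keep]
  gm$ref <- gm$ref[keep]
  gm$alt <- gm$alt[keep]
  gm$gt <- gm$gt[keep, , drop = FALSE]
  if (!is.null(gm$hap)) gm$hap <- gm$hap[keep, , drop = FALSE]
  if (!is.null(gm$site_info)) gm$site_info <- gm$site_info[keep, , drop = FALSE]
  gm
}

## Subset to a set of samples (columns), preserving sites.
subset_samples <- function(gm, keep_samples) {
  idx <- match(keep_samples, samples(gm))
  if (anyNA(idx)) {
    stop("unknown sample(s): ",
         paste(keep_samples[is.na(idx)], collapse = ", "))
  }
  gm$gt <- gm$gt[, idx, drop = FALSE]
  if (!is.null(gm$hap)) {
    hcols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    gm$hap <- gm$hap[, hcols, drop = FALSE]
  }
  gm
}

hard_filter_fields <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF (v4.2, GT format field required) and retains biallelic SNP
#' records only; multiallelic sites, indels and non-variant records are
#' dropped and counted in the removal log. Phase is captured when every
#' non-missing genotype uses the `|` separator. Half-calls and non-diploid
#' genotypes are treated as missing, with a warning. QUAL and the standard
#' GATK site annotations (QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum) are
#' parsed into `site_info` when present.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param region Optional region string `"chrom"` or `"chrom:start-end"`.
#' @return A [geno_matrix()]; the counts of dropped records are available via
#'   `attr(, "dropped")`.
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  meta <- v@meta
  chrom_len <- parse_contig_lengths(meta)
  if (nrow(fix) == 0L) {
    smp <- colnames(v@gt)
    smp <- smp[smp != "FORMAT"]
    gm <- geno_matrix(character(), integer(), character(), character(),
                      matrix(integer(), 0L, length(smp),
                             dimnames = list(NULL, smp)),
                      chrom_len = chrom_len)
    attr(gm, "dropped") <- tibble::tibble(reason = character(), n = integer())
    return(gm)
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  is_multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  is_snp <- !is_multi & !is.na(alt) & alt != "." &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  dropped <- tibble::tibble(
    reason = c("multiallelic", "indel_or_other"),
    n = c(sum(is_multi), sum(!is_snp & !is_multi))
  )
  keep <- which(is_snp)
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- keep[chrom[keep] == rg$chrom &
                   pos[keep] >= rg$start & pos[keep] <= rg$end]
  }

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gt_raw[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
  for (ch in unique(chrom)) {
    if (is.unsorted(pos[chrom == ch], strictly = TRUE)) {
      stop("VCF positions are not strictly increasing on ", ch)
    }
  }

  parsed <- parse_gt_strings(gt_raw)
  site_info <- tibble::tibble(QUAL = suppressWarnings(as.numeric(fix[keep, "QUAL"])))
  for (f in hard_filter_fields) {
    site_info[[f]] <- if (length(keep)) {
      suppressWarnings(as.numeric(vcfR::extract.info(v, element = f)[keep]))
    } else {
      numeric(0)
    }
  }
  gm <- geno_matrix(chrom, pos, ref, alt, parsed$gt, hap = parsed$hap,
                    site_info = site_info, chrom_len = chrom_len)
  attr(gm, "dropped") <- dropped
  gm
}

parse_region <- function(region) {
  if (grepl(":", region, fixed = TRUE)) {
    parts <- strsplit(region, "[:-]")[[1]]
    list(chrom = parts[1], start = as.integer(parts[2]),
         end = as.integer(parts[3]))
  } else {
    list(chrom = region, start = 1L, end = .Machine$integer.max)
  }
}

parse_contig_lengths <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  ids <- sub('.*ID=([^,>]+).*', "\\1", ln)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
  out <- stats::setNames(lens, ids)
  out[!is.na(out)]
}

## Turn a matrix of GT strings into dosage (and haplotype, if fully phased)
## matrices. Unparseable, haploid or half-call entries become missing.
parse_gt_strings <- function(gt_raw) {
  smp <- colnames(gt_raw)
  u <- unique(as.vector(gt_raw))
  a1 <- rep(NA_integer_, length(u))
  a2 <- rep(NA_integer_, length(u))
  phased <- rep(NA, length(u))
  bad <- character()
  for (i in seq_along(u)) {
    s <- u[i]
    if (is.na(s) || s %in% c(".", "./.", ".|.")) next
    al <- strsplit(s, "[/|]")[[1]]
    if (length(al) != 2L || anyNA(suppressWarnings(as.integer(al)))) {
      if (!s %in% c(".", "./.", ".|.")) bad <- c(bad, s)
      next
    }
    v <- as.integer(al)
    if (any(v > 1L)) next  # non-biallelic allele index; treat as missing
    a1[i] <- v[1]; a2[i] <- v[2]
    phased[i] <- grepl("|", s, fixed = TRUE)
  }
  if (length(bad)) {
    warning("treating non-diploid/half-call genotypes as missing: ",
            paste(unique(bad), collapse = " "))
  }
  idx <- match(as.vector(gt_raw), u)
  m1 <- matrix(a1[idx], nrow(gt_raw), ncol(gt_raw))
  m2 <- matrix(a2[idx], nrow(gt_raw), ncol(gt_raw))
  gt <- m1 + m2
  colnames(gt) <- smp
  all_phased <- all(phased[idx], na.rm = TRUE) && nrow(gt_raw) > 0
  hap <- NULL
  if (all_phased) {
    hap <- matrix(NA_integer_, nrow(gt_raw), 2L * length(smp))
    hap[, seq(1L, ncol(hap), 2L)] <- m1
    hap[, seq(2L, ncol(hap), 2L)] <- m2
    colnames(hap) <- paste0(rep(smp, each = 2L), c(".1", ".2"))
  }
  list(gt = gt, hap = hap)
}

#' Write a genotype matrix to VCF
#'
#' Writes a plain-text VCF v4.2. Phased calls use `|`, unphased `/`; missing
#' genotypes are written `./.`. QUAL and INFO annotations are emitted from
#' `site_info` when present.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "wb")  # binary mode: byte-identical output across platforms
  on.exit(close(con))
  wline <- function(...) writeLines(paste0(...), con, sep = "\n")
  wline("##fileformat=VCFv4.2")
  wline("##source=sweepkit")
  if (!is.null(gm$chrom_len)) {
    for (ch in names(gm$chrom_len)) {
      wline("##contig=<ID=", ch, ",length=",
            format(gm$chrom_len[[ch]], scientific = FALSE), ">")
    }
  }
  si <- gm$site_info
  info_fields <- character()
  if (!is.null(si)) {
    info_fields <- intersect(hard_filter_fields, names(si))
    info_fields <- info_fields[vapply(info_fields,
                                      function(f) any(!is.na(si[[f]])), TRUE)]
    for (f in info_fields) {
      wline("##INFO=<ID=", f, ",Number=1,Type=Float,Description=\"", f, "\">")
    }
  }
  wline("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  wline(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", samples(gm)), collapse = "\t"))
  S <- n_sites(gm)
  if (S == 0L) return(invisible(path))
  qual <- rep(".", S)
  if (!is.null(si) && "QUAL" %in% names(si)) {
    qual <- ifelse(is.na(si$QUAL), ".", format(si$QUAL, trim = TRUE))
  }
  info <- rep(".", S)
  if (length(info_fields)) {
    parts <- lapply(info_fields, function(f) {
      ifelse(is.na(si[[f]]), NA_character_,
             paste0(f, "=", format(si[[f]], trim = TRUE)))
    })
    info <- apply(do.call(cbind, parts), 1L, function(r) {
      r <- r[!is.na(r)]
      if (length(r)) paste(r, collapse = ";") else "."
    })
  }
  gt_str <- format_gt_strings(gm)
  rows <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, qual, ".", info, "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

format_gt_strings <- function(gm) {
  S <- n_sites(gm); n <- n_samples(gm)
  out <- matrix("./.", S, n)
  if (is_phased(gm)) {
    h1 <- gm$hap[, seq(1L, 2L * n, 2L), drop = FALSE]
    h2 <- gm$hap[, seq(2L, 2L * n, 2L), drop = FALSE]
    ok <- !is.na(h1) & !is.na(h2)
    out[ok] <- paste0(h1[ok], "|", h2[ok])
  } else {
    g <- gm$gt
    out[!is.na(g) & g == 0L] <- "0/0"
    out[!is.na(g) & g == 1L] <- "0/1"
    out[!is.na(g) & g == 2L] <- "1/1"
  }
  out
}

#' Read a sample-to-population map
#'
#' Two-column tab-separated text, no header: sample identifier, population
#' label.
#'
#' @param path Path to the popmap file.
#' @return A tibble with columns `sample` and `population`.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "population"),
                          colClasses = "character")
  tibble::as_tibble(df)
}
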