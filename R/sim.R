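#' Parameters for the forward Wright-Fisher simulator
#'
#' Defines the demography and mutational process of a simulated set of
#' diploid populations that descend star-like from a common ancestor: the
#' ancestral population is run to mutation-drift equilibrium, each daughter
#' population is founded from the same ancestral snapshot and then drifts
#' (and optionally sweeps) independently for its own number of generations.
#'
#' @param n_anc Diploid size of the ancestral population.
#' @param pop_sizes Integer vector of diploid sizes, one per daughter
#'   population. A daughter with `pop_sizes == n_anc` is founded as an exact
#'   copy of the ancestral population, so `split_gens = 0` yields identical
#'   daughters; smaller/larger daughters are founded by sampling ancestral
#'   diploids with replacement.
#' @param split_gens Generations of independent drift in each daughter since
#'   the split (recycled to `length(pop_sizes)`).
#' @param n_sample Diploids sampled per population at the end (recycled).
#' @param seq_len Chromosome length in bp.
#' @param mu Per-bp, per-generation mutation rate (infinite sites; collided
#'   positions are redrawn).
#' @param rec Per-bp, per-generation recombination rate; crossover counts
#'   per gamete are Poisson(`rec * seq_len`) with uniform breakpoints.
#' @param sweep Optional list describing a hard sweep:
#'   `pop` (index or name of the focal population), `pos` (bp), `s`
#'   (selection coefficient; additive fitness 1, 1+s, 1+2s), `gen`
#'   (generation after the split at which a single copy is introduced),
#'   `min_freq` (retry until the final frequency reaches this, default 0)
#'   and `max_attempts` (re-introductions after loss, default 100).
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param seed Integer random seed.
#' @param pop_names Population labels (default `pop1`, `pop2`, ...).
#' @param burnin Ancestral burn-in generations (default `10 * n_anc`).
#' @param chrom Chromosome name used in output (default `"chr1"`).
#'
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_anc = 100, pop_sizes = c(100, 100), split_gens = 20,
                       n_sample = 20, seq_len = 2e6, mu = 2.5e-6,
                       rec = 2.5e-6, sweep = NULL, missing_rate = 0,
                       seed = 1, pop_names = NULL, burnin = 10 * n_anc,
                       chrom = "chr1") {
  npop <- length(pop_sizes)
  split_gens <- rep_len(as.integer(split_gens), npop)
  n_sample <- rep_len(as.integer(n_sample), npop)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_along(pop_sizes))
  stopifnot(length(pop_names) == npop)
  if (n_anc < 2 || any(pop_sizes < 2) || any(n_sample < 2)) {
    stop("all population and sample sizes must be >= 2")
  }
  if (any(n_sample > pop_sizes)) stop("n_sample cannot exceed pop_sizes")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (any(split_gens < 0) || seq_len < 1 || mu < 0 || rec < 0) {
    stop("invalid demographic parameters")
  }
  if (!is.null(sweep)) {
    sweep <- utils::modifyList(list(min_freq = 0, max_attempts = 100), sweep)
    if (is.character(sweep$pop)) sweep$pop <- match(sweep$pop, pop_names)
    if (is.na(sweep$pop) || sweep$pop < 1 || sweep$pop > npop) {
      stop("sweep$pop does not name a simulated population")
    }
    if (sweep$pos < 1 || sweep$pos > seq_len) {
      stop("sweep position must lie in [1, seq_len]")
    }
    if (sweep$s <= 0) stop("sweep selection coefficient must be > 0")
    if (is.null(sweep$gen)) sweep$gen <- 0L
    if (sweep$gen < 0 || sweep$gen >= split_gens[sweep$pop]) {
      stop("sweep$gen must lie in [0, split_gens of the focal population)")
    }
  }
  structure(
    list(n_anc = as.integer(n_anc), pop_sizes = as.integer(pop_sizes),
         split_gens = split_gens, n_sample = n_sample,
         seq_len = as.integer(seq_len), mu = mu, rec = rec, sweep = sweep,
         missing_rate = missing_rate, seed = as.integer(seed),
         pop_names = pop_names, burnin = as.integer(burnin), chrom = chrom),
    class = "sim_params"
  )
}

#' Simulate multi-population diploid genomes
#'
#' Forward Wright-Fisher simulation under [sim_params()]. Returns phased
#' haplotypes for the sampled diploids of each population over the shared
#' set of segregating sites, together with the ground truth (selected site,
#' final beneficial-allele frequency in the full focal population,
#' introduction attempts, pairwise separation generations). Identical
#' parameters (including `seed`) give identical output.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_result` with elements `params`, `positions`,
#'   `haplotypes` (list of sites x 2n 0/1 matrices per population),
#'   `missing` (list of sites x n logical masks) and `truth`.
#' @export
simulate_genomes <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  sw <- params$sweep
  res <- wf_simulate_cpp(
    params$n_anc, params$pop_sizes, params$split_gens, params$n_sample,
    params$seq_len, params$mu, params$rec, params$burnin,
    if (is.null(sw)) -1L else as.integer(sw$pop - 1L),
    if (is.null(sw)) 0L else as.integer(sw$pos),
    if (is.null(sw)) 0 else sw$s,
    if (is.null(sw)) 0L else as.integer(sw$gen),
    if (is.null(sw)) 0 else sw$min_freq,
    if (is.null(sw)) 0L else as.integer(sw$max_attempts)
  )
  names(res$haplotypes) <- params$pop_names
  S <- length(res$positions)
  missing <- lapply(seq_along(params$pop_names), function(p) {
    matrix(runif(S * params$n_sample[p]) < params$missing_rate,
           S, params$n_sample[p])
  })
  names(missing) <- params$pop_names
  g <- params$split_gens
  sep <- outer(g, g, "+")
  diag(sep) <- 0
  dimnames(sep) <- list(params$pop_names, params$pop_names)
  truth <- list(
    selected_pos = if (is.null(sw)) NULL else sw$pos,
    selected_pop = if (is.null(sw)) NULL else params$pop_names[sw$pop],
    final_freq = if (is.null(sw)) NULL else res$sweep_final_freq,
    attempts = if (is.null(sw)) NULL else res$sweep_attempts,
    pairwise_split_gens = sep
  )
  structure(list(params = params, positions = res$positions,
                 haplotypes = res$haplotypes, missing = missing,
                 truth = truth),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", length(x$positions), " segregating sites, ",
      length(x$haplotypes), " population(s)\n", sep = "")
  if (!is.null(x$truth$selected_pos)) {
    cat("  sweep in ", x$truth$selected_pop, " at ", x$truth$selected_pos,
        " bp, final freq ", signif(x$truth$final_freq, 4),
        " (", x$truth$attempts, " attempt(s))\n", sep = "")
  }
  invisible(x)
}

#' Convert a simulation to a genotype matrix
#'
#' Concatenates the sampled diploids of all populations into one phased
#' [geno_matrix()], applying the simulated missing-genotype mask (masked
#' calls have `NA` dosage and `NA` haplotype alleles). Sample names are
#' `<population>_<index>`. REF is `A` and ALT `T` at every site (the
#' ancestral allele is the reference).
#'
#' @param sim A `sim_result`.
#' @return A [geno_matrix()].
#' @export
as_geno_matrix <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  pops <- names(sim$haplotypes)
  hap <- do.call(cbind, unname(sim$haplotypes))
  S <- length(sim$positions)
  smp <- unlist(lapply(pops, function(p) {
    sprintf("%s_%02d", p, seq_len(ncol(sim$haplotypes[[p]]) / 2L))
  }))
  colnames(hap) <- paste0(rep(smp, each = 2L), c(".1", ".2"))
  mask <- do.call(cbind, unname(sim$missing))
  if (S > 0L) {
    hmask <- mask[, rep(seq_len(ncol(mask)), each = 2L), drop = FALSE]
    hap[hmask] <- NA_integer_
  }
  gt <- hap[, seq(1L, ncol(hap), 2L), drop = FALSE] +
    hap[, seq(2L, ncol(hap), 2L), drop = FALSE]
  colnames(gt) <- smp
  geno_matrix(chrom = rep(sim$params$chrom, S), pos = sim$positions,
              ref = rep("A", S), alt = rep("T", S), gt = gt, hap = hap,
              chrom_len = stats::setNames(sim$params$seq_len,
                                          sim$params$chrom))
}

#' Population map of a simulation
#'
#' @param sim A `sim_result`.
#' @return A tibble with columns `sample` and `population`, matching the
#'   sample names of [as_geno_matrix()].
#' @export
sim_popmap <- function(sim) {
  pops <- names(sim$haplotypes)
  tibble::tibble(
    sample = unlist(lapply(pops, function(p) {
      sprintf("%s_%02d", p, seq_len(ncol(sim$haplotypes[[p]]) / 2L))
    })),
    population = rep(pops, vapply(sim$haplotypes, function(m) ncol(m) / 2L, 1))
  )
}

#' Write simulation fixtures to disk
#'
#' Emits a phased VCF v4.2, a popmap TSV, a toy GFF3 (synthetic genes tiled
#' every `gene_every` bp, plus one gene centred on the selected site when a
#' sweep was simulated) and the ground truth as JSON. Output is
#' deterministic: the same `sim_result` always produces byte-identical
#' files.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory (created if needed).
#' @param gene_every Spacing of the synthetic gene tiling in bp.
#' @param gene_width Width of each synthetic gene in bp.
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(sim, dir, gene_every = 50000, gene_width = 20000) {
  stopifnot(inherits(sim, "sim_result"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory ", dir)
  }
  gm <- as_geno_matrix(sim)
  paths <- c(vcf = file.path(dir, "sim.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.json"))
  write_vcf(gm, paths[["vcf"]])
  pm <- sim_popmap(sim)
  con <- file(paths[["popmap"]], "wb")
  writeLines(paste(pm$sample, pm$population, sep = "\t"), con, sep = "\n")
  close(con)
  write_toy_gff(sim, paths[["gff"]], gene_every, gene_width)
  truth <- sim$truth
  truth$pairwise_split_gens <- as.data.frame(truth$pairwise_split_gens)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

write_toy_gff <- function(sim, path, gene_every, gene_width) {
  L <- sim$params$seq_len
  ch <- sim$params$chrom
  s0 <- 1 + (gene_every - gene_width) %/% 2
  starts <- if (s0 <= L) seq(s0, L, by = gene_every) else numeric(0)
  ends <- pmin(starts + gene_width - 1, L)
  ids <- sprintf("SYNGENE%03d", seq_along(starts))
  sel <- sim$truth$selected_pos
  if (!is.null(sel)) {
    s0 <- max(1, sel - gene_width %/% 2)
    starts <- c(starts, s0)
    ends <- c(ends, min(L, s0 + gene_width - 1))
    ids <- c(ids, "SWEEP_TARGET")
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]; ids <- ids[o]
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con, sep = "\n")
  writeLines(sprintf("##sequence-region %s 1 %d", ch, L), con, sep = "\n")
  writeLines(sprintf("%s\tsweepkit_sim\tgene\t%d\t%d\t.\t+\t.\tID=gene:%s;Name=%s",
                     ch, starts, ends, ids, ids), con, sep = "\n")
  invisible(path)
}
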