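#' Build a genome map with evenly spaced loci
#'
#' Constructs the genetic map used throughout the simulator: `n_chrom`
#' chromosomes of given genetic lengths, each carrying `loci_per_chrom`
#' biallelic loci evenly spaced over the interval `(0, length]`. The default
#' is a maize-like genome of 10 chromosomes totalling 1796 cM with 500 loci
#' per chromosome (5000 loci). Only the total map length is published for the
#' composite map this emulates, so the default splits it into equal
#' chromosomes; per-chromosome lengths can be supplied instead.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param lengths_cM numeric vector of chromosome genetic lengths in
#'   centimorgans; recycled to length `n_chrom` if scalar.
#' @param loci_per_chrom number of loci per chromosome (>= 2), scalar or one
#'   value per chromosome.
#' @return An object of class `gs_genome`: a list with the chromosome map
#'   (`n_chrom`, `lengths_cM`, `total_cM`, `total_M`) and the locus set
#'   (`loci`, a data frame with columns `chrom` and `pos_cM`; `n_loci`;
#'   0-based per-chromosome index bounds used internally).
#' @examples
#' g <- build_genome()
#' g$total_cM   # 1796
#' g$n_loci     # 5000
#' @export
build_genome <- function(n_chrom = 10, lengths_cM = rep(179.6, n_chrom),
                         loci_per_chrom = 500) {
  if (length(n_chrom) != 1 || is.na(n_chrom) || n_chrom < 1)
    stop("n_chrom must be a single integer >= 1", call. = FALSE)
  n_chrom <- as.integer(n_chrom)
  if (length(lengths_cM) == 1) lengths_cM <- rep(lengths_cM, n_chrom)
  if (length(lengths_cM) != n_chrom)
    stop("lengths_cM must have one entry per chromosome", call. = FALSE)
  if (any(!is.finite(lengths_cM)) || any(lengths_cM <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  if (length(loci_per_chrom) == 1) loci_per_chrom <- rep(loci_per_chrom, n_chrom)
  if (any(!is.finite(loci_per_chrom)) || any(loci_per_chrom < 2))
    stop("loci_per_chrom must be >= 2", call. = FALSE)
  loci_per_chrom <- as.integer(loci_per_chrom)

  pos <- unlist(lapply(seq_len(n_chrom), function(c) {
    seq_len(loci_per_chrom[c]) / loci_per_chrom[c] * lengths_cM[c]
  }), use.names = FALSE)
  chrom <- rep(seq_len(n_chrom), loci_per_chrom)
  last <- cumsum(loci_per_chrom)
  structure(list(
    n_chrom = n_chrom,
    lengths_cM = as.numeric(lengths_cM),
    total_cM = sum(lengths_cM),
    total_M = sum(lengths_cM) / 100,
    loci = data.frame(chrom = chrom, pos_cM = pos),
    n_loci = sum(loci_per_chrom),
    loci_per_chrom = loci_per_chrom,
    chrom_first = as.integer(last - loci_per_chrom),  # 0-based
    chrom_last = as.integer(last - 1L)
  ), class = "gs_genome")
}

#' @export
print.gs_genome <- function(x, ...) {
  cat("<gs_genome> ", x$n_chrom, " chromosomes, ", x$total_cM, " cM, ",
      x$n_loci, " loci\n", sep = "")
  invisible(x)
}

#' Geometric series of QTL effect magnitudes
#'
#' Additive-effect magnitudes for `l` QTL following the geometric-series
#' construction `a^k`, `k = 1, ..., l`, with common ratio
#' `a = (l - 1) / (l + 1)`. The series is strictly decreasing with all values
#' in (0, 1), so a trait controlled by many loci has a few moderately large
#' effects and a long tail of small ones.
#'
#' @param l number of QTL (>= 2; at `l = 1` the ratio degenerates to zero).
#' @return numeric vector of `l` effect magnitudes.
#' @examples
#' geometric_effects(3)  # 0.5, 0.25, 0.125
#' @export
geometric_effects <- function(l) {
  if (length(l) != 1 || is.na(l) || l < 2)
    stop("l must be a single integer >= 2", call. = FALSE)
  a <- (l - 1) / (l + 1)
  a^seq_len(l)
}

#' Assign a trait architecture onto a genome
#'
#' Designates `n_markers` loci as markers (evenly spaced within each
#' chromosome) and `n_qtl` loci as QTL (drawn uniformly without replacement
#' from the remaining loci, so markers and QTL are disjoint). QTL effect
#' magnitudes follow [geometric_effects()]; for each QTL the favorable allele
#' is assigned to parent 1 or parent 2 with probability 1/2, encoded in the
#' sign of the effect.
#'
#' Markers are split as evenly as possible across chromosomes; when
#' `n_markers` is not divisible by the chromosome count, the first chromosomes
#' receive one extra marker.
#'
#' @param genome a `gs_genome` from [build_genome()].
#' @param n_qtl number of QTL (default 100).
#' @param n_markers number of marker loci (default 200).
#' @return An object of class `trait_arch`: list with `qtl_idx` (sorted locus
#'   indices), `qtl_eff` (signed additive effects of the parent-2 allele),
#'   and `marker_idx`.
#' @export
assign_architecture <- function(genome, n_qtl = 100, n_markers = 200) {
  stopifnot(inherits(genome, "gs_genome"))
  if (n_qtl + n_markers > genome$n_loci)
    stop("n_qtl + n_markers exceeds the number of loci", call. = FALSE)
  per <- rep(n_markers %/% genome$n_chrom, genome$n_chrom)
  extra <- n_markers %% genome$n_chrom
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  marker_idx <- unlist(lapply(seq_len(genome$n_chrom), function(c) {
    genome$chrom_first[c] + 1L +
      as.integer(round(seq(1, genome$loci_per_chrom[c], length.out = per[c]))) - 1L
  }), use.names = FALSE)
  qtl_idx <- sort(sample(setdiff(seq_len(genome$n_loci), marker_idx), n_qtl))
  eff <- geometric_effects(n_qtl) * sample(c(-1, 1), n_qtl, replace = TRUE)
  structure(list(qtl_idx = qtl_idx, qtl_eff = eff, marker_idx = marker_idx),
            class = "trait_arch")
}

new_population <- function(hap1, hap2, generation) {
  structure(list(hap1 = hap1, hap2 = hap2, generation = generation),
            class = "gs_population")
}

#' @export
print.gs_population <- function(x, ...) {
  cat("<gs_population> ", n_ind(x), " individuals (", x$generation, "), ",
      nrow(x$hap1), " loci\n", sep = "")
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `gs_population`.
#' @return integer count.
#' @export
n_ind <- function(pop) ncol(pop$hap1)

#' Founder F1 individual between two fully polymorphic inbred parents
#'
#' The two parents are taken to be homozygous for the parent-1 and parent-2
#' allele, respectively, at every locus, so their F1 is heterozygous
#' everywhere. Haplotypes are coded 0 (parent-1 allele) and 1 (parent-2
#' allele).
#'
#' @param genome a `gs_genome`.
#' @return a `gs_population` with one individual, generation `"F1"`.
#' @export
founder_f1 <- function(genome) {
  L <- genome$n_loci
  new_population(matrix(0L, L, 1), matrix(1L, L, 1), "F1")
}

# Low-level gamete sampler: one meiotic gamete per entry of `parents`.
make_gametes <- function(pop, parents, genome) {
  cpp_gametes(pop$hap1, pop$hap2, as.integer(parents), genome$loci$pos_cM,
              genome$chrom_first, genome$chrom_last, genome$lengths_cM)
}

#' Simulate one meiotic gamete
#'
#' Per chromosome, the crossover count is Poisson with mean equal to the
#' genetic length in Morgans, breakpoints are uniform along the chromosome,
#' and the starting strand is chosen with probability 1/2 (no interference;
#' recombination fractions follow Haldane's mapping function).
#'
#' @param pop a `gs_population`.
#' @param ind index of the parent individual.
#' @param genome the `gs_genome` the population was simulated on.
#' @return integer vector of allele codes (0/1) over all loci.
#' @export
meiosis <- function(pop, ind = 1, genome) {
  stopifnot(inherits(pop, "gs_population"), ind >= 1, ind <= n_ind(pop))
  drop(make_gametes(pop, ind, genome))
}

#' Produce a population of doubled-haploid lines from an F1
#'
#' Each DH line is a single meiotic gamete of the F1 with its chromosome
#' complement doubled, hence homozygous at every locus.
#'
#' @param f1 a `gs_population` holding the F1 individual (heterozygous at all
#'   loci).
#' @param N number of DH lines to produce.
#' @param genome the `gs_genome`.
#' @return a `gs_population` of `N` DH lines, generation `"DH"`.
#' @export
make_dh_population <- function(f1, N, genome) {
  stopifnot(inherits(f1, "gs_population"), N >= 1)
  if (any(f1$hap1[, 1] == f1$hap2[, 1]))
    stop("f1 must be heterozygous at every locus", call. = FALSE)
  g <- make_gametes(f1, rep(1L, N), genome)
  new_population(g, g, "DH")
}

#' Random mating
#'
#' Each progeny is formed from two distinct parents drawn uniformly (parents
#' are sampled with replacement across progenies, never selfed), receiving
#' one meiotic gamete from each.
#'
#' @param pop a `gs_population` with at least 2 individuals.
#' @param n_progeny number of progeny to produce.
#' @param genome the `gs_genome`.
#' @param generation generation tag for the progeny population.
#' @return a `gs_population` of `n_progeny` individuals.
#' @export
random_mate <- function(pop, n_progeny, genome, generation = "S0") {
  N <- n_ind(pop)
  if (N < 2) stop("random mating needs at least 2 individuals", call. = FALSE)
  p1 <- sample.int(N, n_progeny, replace = TRUE)
  p2 <- sample.int(N - 1L, n_progeny, replace = TRUE)
  p2[p2 >= p1] <- p2[p2 >= p1] + 1L
  new_population(make_gametes(pop, p1, genome), make_gametes(pop, p2, genome),
                 generation)
}

# Cross specified pairs of individuals (one F1 per pair, one gamete per
# parent). For fully inbred parents the gamete equals the parental haplotype.
cross_pairs <- function(pop, p1, p2, genome, generation = "F1") {
  new_population(make_gametes(pop, p1, genome), make_gametes(pop, p2, genome),
                 generation)
}

#' True genetic values of a population
#'
#' The additive genetic value of individual `i` is the sum over QTL of its
#' genotype code (-1/0/+1 copies of the parent-2 allele) times the signed QTL
#' effect. An F1, heterozygous everywhere, has value 0 by construction.
#'
#' @param pop a `gs_population`.
#' @param arch a `trait_arch` from [assign_architecture()].
#' @return list with `values` (numeric vector), `mean`, and `var` (sample
#'   variance, denominator n - 1; `NA` for a single individual).
#' @export
genetic_values <- function(pop, arch) {
  stopifnot(inherits(pop, "gs_population"), inherits(arch, "trait_arch"))
  z <- pop$hap1[arch$qtl_idx, , drop = FALSE] +
       pop$hap2[arch$qtl_idx, , drop = FALSE] - 1L
  a <- drop(crossprod(z, arch$qtl_eff))
  list(values = a, mean = mean(a), var = if (length(a) > 1) var(a) else NA_real_)
}

#' Marker genotype matrix
#'
#' Genotype codes at the marker loci, one row per individual, one column per
#' marker, coded -1 / 0 / +1 for parent-1 homozygote, heterozygote, parent-2
#' homozygote. DH rows never contain zeros.
#'
#' @inheritParams genetic_values
#' @return integer matrix (individuals x markers).
#' @export
marker_matrix <- function(pop, arch) {
  stopifnot(inherits(pop, "gs_population"), inherits(arch, "trait_arch"))
  t(pop$hap1[arch$marker_idx, , drop = FALSE] +
    pop$hap2[arch$marker_idx, , drop = FALSE]) - 1L
}

#' Export a population and its locus map as tab-separated text
#'
#' Writes the genotype codes (loci in rows, individuals in columns) and a
#' locus map table (chromosome, position in cM). These are simulated abstract
#' biallelic loci, so no standard file-format semantics are claimed.
#'
#' @param pop a `gs_population`.
#' @param genome the `gs_genome`.
#' @param geno_path,map_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_population <- function(pop, genome, geno_path, map_path) {
  geno <- pop$hap1 + pop$hap2 - 1L
  colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  write.table(cbind(locus = seq_len(nrow(geno)), geno), geno_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(locus = seq_len(genome$n_loci), genome$loci), map_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(geno_path, map_path))
}
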