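#' Build an evenly spaced genetic map
#'
#' Distributes `n_snps` loci across `n_chromosomes` chromosomes as evenly as
#' integer division allows and spaces them uniformly in genetic distance.
#' Chromosome lengths are proportional to their locus counts so that the map
#' totals `total_length` centimorgan. The defaults mirror the simulated
#' marker panel: 50,000 biallelic SNPs (the size of a standard equine 50k
#' genotyping array) on 31 autosomes spanning 2500 cM.
#'
#' @param n_chromosomes number of autosomes (>= 1).
#' @param n_snps total number of loci (>= `n_chromosomes`).
#' @param total_length total map length in centimorgan (> 0).
#' @return An object of class `genetic_map`: a data frame with columns
#'   `chr` (1-based chromosome), `pos` (cM within chromosome, starting at 0)
#'   and `id`, plus attributes `chr_nloci` and `chr_len` (cM per chromosome).
#' @examples
#' map <- build_genetic_map(2, 4, 200)
#' map$pos  # two loci per chromosome, 100 cM apart
#' @export
build_genetic_map <- function(n_chromosomes = 31L, n_snps = 50000L,
                              total_length = 2500) {
  if (n_chromosomes < 1 || n_snps < n_chromosomes || total_length <= 0)
    stop("need n_chromosomes >= 1, n_snps >= n_chromosomes, total_length > 0")
  n_chromosomes <- as.integer(n_chromosomes)
  n_snps <- as.integer(n_snps)
  base <- n_snps %/% n_chromosomes
  extra <- n_snps %% n_chromosomes
  nloci <- rep(base, n_chromosomes) + c(rep(1L, extra),
                                        rep(0L, n_chromosomes - extra))
  chr_len <- total_length * nloci / n_snps
  chr <- rep(seq_len(n_chromosomes), nloci)
  pos <- unlist(lapply(seq_len(n_chromosomes), function(c) {
    k <- nloci[c]
    if (k == 1) 0 else seq(0, chr_len[c], length.out = k)
  }), use.names = FALSE)
  map <- data.frame(chr = chr, pos = pos,
                    id = paste0("snp", seq_len(n_snps)))
  attr(map, "chr_nloci") <- nloci
  attr(map, "chr_len") <- chr_len
  attr(map, "chr_start") <- c(0L, cumsum(nloci)[-n_chromosomes])
  class(map) <- c("genetic_map", "data.frame")
  map
}

map_nloci <- function(map) nrow(map)

# restrict a map to a subset of loci while keeping the full chromosome
# lengths, so that recombination along the chromosome is unchanged and the
# marginal gamete process at the retained loci is exact
subset_map <- function(map, loci) {
  loci <- sort(loci)
  sub <- map[loci, , drop = FALSE]
  nchr <- length(attr(map, "chr_len"))
  nloci <- tabulate(sub$chr, nbins = nchr)
  attr(sub, "chr_nloci") <- as.integer(nloci)
  attr(sub, "chr_len") <- attr(map, "chr_len")
  attr(sub, "chr_start") <- as.integer(c(0L, cumsum(nloci)[-nchr]))
  class(sub) <- c("genetic_map", "data.frame")
  rownames(sub) <- NULL
  sub
}

#' Generate a founder population in linkage equilibrium
#'
#' Per-locus target allele frequencies are drawn uniformly from
#' `[maf_low, maf_high]` and alleles are then sampled independently per
#' haplotype, i.e. founders are unrelated and in linkage equilibrium.
#'
#' @param n_animals number of founder animals (>= 1).
#' @param map a [build_genetic_map()] object.
#' @param maf_low,maf_high bounds of the uniform allele-frequency
#'   distribution, `0 < maf_low <= maf_high <= 0.5`.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `founder_population`: list with `haplotypes`
#'   (raw matrix, one column per animal, first L entries haplotype 1, next L
#'   haplotype 2), `target_freq`, `freq` (realized allele frequencies) and
#'   the `map`.
#' @export
generate_founders <- function(n_animals, map, maf_low = 0.05,
                              maf_high = 0.5, seed = NULL) {
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  if (!is.null(seed)) set.seed(seed)
  L <- map_nloci(map)
  target <- runif(L, maf_low, maf_high)
  haps <- cpp_founder_genomes(as.integer(n_animals), target)
  freq <- cpp_allele_freq_matrix(haps)
  structure(list(haplotypes = haps, target_freq = target, freq = freq,
                 map = map),
            class = "founder_population")
}

#' Simulate one meiosis
#'
#' Crossover counts per chromosome are Poisson with mean equal to the
#' chromosome length in Morgan, crossover positions are uniform (no
#' interference, Haldane model), the starting parental strand is chosen with
#' probability 1/2 and chromosomes segregate independently.
#'
#' @param parent raw vector of length `2 * L` (the two phased haplotypes) as
#'   stored in a `founder_population`, or a list with elements `h1` and `h2`.
#' @param map the genetic map the genome was simulated on.
#' @param detail if `TRUE`, also return the crossover count per chromosome.
#' @return A raw vector of length L (the gamete); with `detail = TRUE` a list
#'   with `gamete` and `crossovers`.
#' @export
meiosis <- function(parent, map, detail = FALSE) {
  if (is.list(parent)) parent <- c(parent$h1, parent$h2)
  L <- map_nloci(map)
  if (length(parent) != 2 * L) stop("parent genome length does not match map")
  res <- cpp_meiosis(parent, attr(map, "chr_start"), attr(map, "chr_nloci"),
                     attr(map, "chr_len"), map$pos)
  if (detail) res else res$gamete
}

#' Create an offspring genome from two parents
#'
#' One haplotype is a gamete from the sire, the other a gamete from the dam.
#'
#' @param sire,dam raw vectors of length `2 * L` (phased parental genomes).
#' @param map the genetic map.
#' @return Raw vector of length `2 * L` (sire gamete then dam gamete).
#' @export
make_offspring <- function(sire, dam, map) {
  if (is.list(sire)) sire <- c(sire$h1, sire$h2)
  if (is.list(dam)) dam <- c(dam$h1, dam$h2)
  c(meiosis(sire, map), meiosis(dam, map))
}

#' Genotype dosages of stored genomes
#'
#' @param genomes list of raw genome vectors (length `2 * L` each) or a raw
#'   matrix with one genome per column.
#' @param map the genetic map.
#' @return Integer dosage matrix (animals x loci), entries 0/1/2.
#' @export
genotype_dosage <- function(genomes, map) {
  if (is.matrix(genomes))
    genomes <- lapply(seq_len(ncol(genomes)), function(j) genomes[, j])
  L <- map_nloci(map)
  Z <- cpp_centered_dosage(genomes, seq_along(genomes), numeric(L))
  storage.mode(Z) <- "integer"
  t(Z)
}

#' Export genotypes as PLINK-style .ped/.map text files
#'
#' Writes tab-separated `.ped` (family, id, sire, dam, sex, phenotype, then
#' two alleles per locus coded 1/2) and `.map` (chromosome, id, genetic
#' position, bp surrogate = cM x 1e6) files, with 1-based locus positions.
#'
#' @param genomes list or raw matrix of phased genomes.
#' @param map the genetic map.
#' @param prefix output path prefix (files `<prefix>.ped`, `<prefix>.map`).
#' @param ids optional animal identifiers.
#' @return The two file paths, invisibly.
#' @export
write_plink <- function(genomes, map, prefix, ids = NULL) {
  if (is.matrix(genomes))
    genomes <- lapply(seq_len(ncol(genomes)), function(j) genomes[, j])
  L <- map_nloci(map)
  n <- length(genomes)
  if (is.null(ids)) ids <- seq_len(n)
  mapfile <- paste0(prefix, ".map")
  pedfile <- paste0(prefix, ".ped")
  write.table(data.frame(map$chr, map$id, map$pos,
                         as.integer(round(map$pos * 1e6)) + 1L),
              mapfile, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  con <- file(pedfile, "w")
  on.exit(close(con))
  for (a in seq_len(n)) {
    g <- as.integer(genomes[[a]]) + 1L  # alleles 1/2
    inter <- character(2 * L)
    inter[c(TRUE, FALSE)] <- g[seq_len(L)]
    inter[c(FALSE, TRUE)] <- g[L + seq_len(L)]
    cat("FAM", "\t", ids[a], "\t0\t0\t0\t-9\t",
        paste(inter, collapse = "\t"), "\n", sep = "", file = con)
  }
  invisible(c(pedfile, mapfile))
}
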