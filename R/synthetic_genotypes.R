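# Synthetic genotype dosages in Hardy-Weinberg proportions, with a phenotype
# carrying a planted effect of the standardized genetic risk score.

#' Specification of a synthetic genotype panel
#'
#' @param n_individuals Number of individuals.
#' @param n_variants Number of variants.
#' @param maf_range Interval within (0, 0.5] from which allele frequencies are
#'   drawn uniformly.
#' @param effect_per_sd_grs Planted phenotype effect per standard deviation of
#'   the genetic risk score.
#' @param seed Integer seed.
#' @return An object of class `genotype_spec`.
#' @export
genotype_spec <- function(n_individuals = 500L, n_variants = 100L,
                          maf_range = c(0.05, 0.5), effect_per_sd_grs = 0.2,
                          seed = 1L) {
  n_individuals <- assert_count(n_individuals, "n_individuals", min = 1L)
  n_variants <- assert_count(n_variants, "n_variants", min = 1L)
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  assert_scalar_number(effect_per_sd_grs, "effect_per_sd_grs")
  seed <- assert_count(seed, "seed", min = 0L)
  structure(list(n_individuals = n_individuals, n_variants = n_variants,
                 maf_range = maf_range, effect_per_sd_grs = effect_per_sd_grs,
                 seed = seed),
            class = "genotype_spec")
}

#' Simulate a GWAS-style variant weight table
#'
#' @param n_variants Number of variants.
#' @param seed Integer seed.
#' @return A data.frame (variant_id, chrom, pos, effect_allele, other_allele,
#'   weight) with positive weights, as used for trait-increasing allele sums.
#' @export
simulate_weight_table <- function(n_variants, seed = 1L) {
  n_variants <- assert_count(n_variants, "n_variants", min = 1L)
  with_seed(seed, {
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, n_variants, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
    data.frame(variant_id = sprintf("rs%06d", sample.int(999999L, n_variants)),
               chrom = sample(1:22, n_variants, replace = TRUE),
               pos = sample.int(5e7L, n_variants),
               effect_allele = ea, other_allele = unname(oa),
               weight = abs(rnorm(n_variants, 0.03, 0.015)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate genotype dosages and a phenotype with a planted GRS effect
#'
#' Genotypes are drawn in Hardy-Weinberg proportions (dosage = number of
#' effect alleles, Binomial(2, p)) at allele frequencies drawn from
#' `maf_range`; monomorphic draws are redrawn so every realized frequency lies
#' strictly in (0, 1). The phenotype is
#' `effect_per_sd_grs * standardized GRS + N(0, 1)` noise.
#'
#' @param spec A [genotype_spec()].
#' @param weights A weight table with one row per variant (see
#'   [simulate_weight_table()]).
#' @return A list with `dosages` (a [dosage_matrix()]: variants x individuals,
#'   coded by effect allele), `phenotype` (data.frame individual_id, phenotype),
#'   `grs` (the generating scores) and `spec`.
#' @export
simulate_genotypes <- function(spec, weights) {
  stopifnot(inherits(spec, "genotype_spec"))
  if (nrow(weights) != spec$n_variants)
    stop("`weights` must have one row per variant (", spec$n_variants, ")",
         call. = FALSE)
  with_seed(spec$seed, {
    nv <- spec$n_variants; ni <- spec$n_individuals
    G <- matrix(0L, nv, ni)
    freq <- numeric(nv)
    for (v in seq_len(nv)) {
      for (try in seq_len(100L)) {
        p <- runif(1, spec$maf_range[1], spec$maf_range[2])
        g <- rbinom(ni, 2L, p)
        f <- mean(g) / 2
        if (f > 0 && f < 1) break
      }
      if (f <= 0 || f >= 1)
        stop("could not draw a polymorphic variant; increase n_individuals",
             call. = FALSE)
      G[v, ] <- g
      freq[v] <- f
    }
    rownames(G) <- weights$variant_id
    colnames(G) <- sprintf("ind_%04d", seq_len(ni))

    variants <- data.frame(variant_id = weights$variant_id,
                           chrom = weights$chrom, pos = weights$pos,
                           coded_allele = weights$effect_allele,
                           other_allele = weights$other_allele,
                           frequency = freq, missingness = 0,
                           info_score = 1,
                           stringsAsFactors = FALSE)
    dm <- dosage_matrix(G, variants)

    score <- as.numeric(crossprod(G, weights$weight))
    s <- sd(score)
    score_std <- if (s > 0) (score - mean(score)) / s else rep(0, ni)
    phen <- spec$effect_per_sd_grs * score_std + rnorm(ni)

    list(dosages = dm,
         phenotype = data.frame(individual_id = colnames(G), phenotype = phen,
                                stringsAsFactors = FALSE),
         grs = score, spec = spec)
  })
}

#' Write dosages as TSV with a sidecar variant table
#'
#' @param dm A [dosage_matrix()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @export
write_genotype_fixtures <- function(dm, dir, prefix = "geno") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dos <- data.frame(variant_id = rownames(dm$dosages), dm$dosages,
                    check.names = FALSE)
  write.table(dos, file.path(dir, paste0(prefix, "_dosages.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dm$variants, file.path(dir, paste0(prefix, "_variants.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
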