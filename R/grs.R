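# Genetic risk scores: variant QC filters, allele alignment to the
# trait-increasing allele, weighted allele-dosage sums, and association tests.

#' Dosage matrix container
#'
#' @param dosages Numeric matrix, variants x individuals, entries in \[0, 2\]
#'   or NA; rownames are variant ids.
#' @param variants Metadata data.frame with one row per variant: variant_id,
#'   chrom, pos, coded_allele, other_allele, frequency, missingness,
#'   info_score.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), nrow(dosages) == nrow(variants))
  required <- c("variant_id", "coded_allele", "other_allele", "frequency",
                "missingness", "info_score")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols))
    stop("variant metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(dosages) && any(!is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (is.null(rownames(dosages))) rownames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, variants = variants),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d variants x %d individuals\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Variant QC thresholds
#'
#' Defaults follow standard imputation-era GWAS practice: imputation info
#' above 0.3, missingness at most 0.05, Hardy-Weinberg exact p at least 1e-6,
#' minor allele frequency at least 0.05, and removal of duplicated positions.
#'
#' @param max_missingness,min_hwe_p,min_maf,min_info Thresholds.
#' @return An object of class `variant_filter_config`.
#' @export
variant_filter_config <- function(max_missingness = 0.05, min_hwe_p = 1e-6,
                                  min_maf = 0.05, min_info = 0.3) {
  assert_scalar_number(max_missingness, "max_missingness", 0, 1)
  assert_scalar_number(min_hwe_p, "min_hwe_p", 0, 1)
  assert_scalar_number(min_maf, "min_maf", 0, 0.5)
  assert_scalar_number(min_info, "min_info", 0, 1)
  structure(list(max_missingness = max_missingness, min_hwe_p = min_hwe_p,
                 min_maf = min_maf, min_info = min_info),
            class = "variant_filter_config")
}

#' Exact Hardy-Weinberg test
#'
#' Exact p-value by summation over all heterozygote counts compatible with
#' the observed allele counts, each weighted by its conditional probability
#' given allele counts; the p-value sums the probabilities not exceeding that
#' of the observed configuration. Monomorphic sites return 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts (total >= 1).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  cpp_hwe_exact_p(as.integer(n_hom_ref), as.integer(n_het),
                  as.integer(n_hom_alt))
}

#' Apply the variant QC filters
#'
#' Filters are applied in order: imputation info, missingness, Hardy-Weinberg
#' (on best-guess genotype counts, i.e. dosages rounded to the nearest
#' integer), minor allele frequency, then duplicate-position removal (first
#' occurrence kept). Every exclusion is logged with its reason.
#'
#' @param dm A [dosage_matrix()].
#' @param config A [variant_filter_config()].
#' @return A list: `dosages` (filtered `dosage_matrix`) and `exclusions`
#'   (data.frame variant_id, reason). Idempotent: re-filtering removes
#'   nothing.
#' @export
filter_variants <- function(dm, config = variant_filter_config()) {
  stopifnot(inherits(dm, "dosage_matrix"))
  v <- dm$variants
  n <- nrow(v)
  reason <- rep(NA_character_, n)

  reason[is.na(reason) & v$info_score <= config$min_info] <- "info"
  reason[is.na(reason) & v$missingness > config$max_missingness] <- "missingness"

  for (i in which(is.na(reason))) {
    g <- round(dm$dosages[i, ])
    counts <- c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
    if (sum(counts) >= 1 &&
        hwe_exact_p(counts[1], counts[2], counts[3]) < config$min_hwe_p)
      reason[i] <- "hwe"
  }

  maf <- pmin(v$frequency, 1 - v$frequency)
  reason[is.na(reason) & maf < config$min_maf] <- "maf"

  if (all(c("chrom", "pos") %in% names(v))) {
    # duplicate positions judged among variants surviving the filters above
    keyed <- paste(v$chrom, v$pos)
    alive <- which(is.na(reason))
    reason[alive[duplicated(keyed[alive])]] <- "duplicate_position"
  }

  keep <- is.na(reason)
  exclusions <- data.frame(variant_id = v$variant_id[!keep],
                           reason = reason[!keep], stringsAsFactors = FALSE)
  list(dosages = dosage_matrix(dm$dosages[keep, , drop = FALSE],
                               v[keep, , drop = FALSE]),
       exclusions = exclusions)
}

STRAND_AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

#' Align dosages to the effect (trait-increasing) allele
#'
#' Where the coded allele already equals the weight table's effect allele the
#' dosage is unchanged; where it equals the other allele the dosage flips to
#' `2 - dosage` and the allele labels swap. Variants whose alleles match
#' neither are dropped with a warning. Strand-ambiguous (A/T, C/G) variants
#' are flagged in the metadata but retained by default. Aligning twice equals
#' aligning once.
#'
#' @param dm A [dosage_matrix()].
#' @param weights Weight table (variant_id, effect_allele, other_allele,
#'   weight).
#' @param drop_ambiguous Drop strand-ambiguous variants (default FALSE).
#' @return An aligned `dosage_matrix` restricted to variants present in the
#'   weight table, with a `strand_ambiguous` metadata column.
#' @export
align_alleles <- function(dm, weights, drop_ambiguous = FALSE) {
  stopifnot(inherits(dm, "dosage_matrix"))
  if (anyDuplicated(weights$variant_id))
    stop("weight table has duplicated variant ids", call. = FALSE)
  if (any(weights$effect_allele == weights$other_allele))
    stop("weight table has rows with effect_allele == other_allele",
         call. = FALSE)
  v <- dm$variants
  idx <- match(v$variant_id, weights$variant_id)
  present <- !is.na(idx)
  v <- v[present, , drop = FALSE]
  D <- dm$dosages[present, , drop = FALSE]
  w <- weights[idx[present], , drop = FALSE]

  same <- v$coded_allele == w$effect_allele & v$other_allele == w$other_allele
  flip <- v$coded_allele == w$other_allele & v$other_allele == w$effect_allele
  mismatch <- !(same | flip)
  if (any(mismatch)) {
    warning(sum(mismatch), " variant(s) dropped: alleles match neither ",
            "orientation of the weight table", call. = FALSE)
    v <- v[!mismatch, , drop = FALSE]
    D <- D[!mismatch, , drop = FALSE]
    same <- same[!mismatch]; flip <- flip[!mismatch]
  }
  if (any(flip)) {
    D[flip, ] <- 2 - D[flip, ]
    tmp <- v$coded_allele[flip]
    v$coded_allele[flip] <- v$other_allele[flip]
    v$other_allele[flip] <- tmp
    v$frequency[flip] <- 1 - v$frequency[flip]
  }
  v$strand_ambiguous <- paste(v$coded_allele, v$other_allele, sep = "/") %in%
    STRAND_AMBIGUOUS
  if (drop_ambiguous) {
    keep <- !v$strand_ambiguous
    v <- v[keep, , drop = FALSE]
    D <- D[keep, , drop = FALSE]
  }
  dosage_matrix(D, v)
}

#' Compute per-individual genetic risk scores
#'
#' `score_j = sum_i weight_i * dosage_ij` over the variants shared between
#' the aligned dosage matrix and the weight table. Missing dosages are
#' mean-imputed per variant (reported via the `n_imputed` attribute).
#'
#' @param dm An aligned [dosage_matrix()] (see [align_alleles()]).
#' @param weights Weight table.
#' @return Named numeric vector of scores (one per individual), with
#'   attributes `n_variants` and `n_imputed`.
#' @export
compute_grs <- function(dm, weights) {
  stopifnot(inherits(dm, "dosage_matrix"))
  idx <- match(dm$variants$variant_id, weights$variant_id)
  present <- !is.na(idx)
  if (!any(present))
    stop("no variants shared between dosages and weight table", call. = FALSE)
  D <- dm$dosages[present, , drop = FALSE]
  w <- weights$weight[idx[present]]
  n_imputed <- 0L
  if (anyNA(D)) {
    for (i in seq_len(nrow(D))) {
      miss <- is.na(D[i, ])
      if (any(miss)) {
        D[i, miss] <- mean(D[i, ], na.rm = TRUE)
        n_imputed <- n_imputed + sum(miss)
      }
    }
  }
  score <- as.numeric(crossprod(D, w))
  names(score) <- colnames(D)
  attr(score, "n_variants") <- nrow(D)
  attr(score, "n_imputed") <- n_imputed
  score
}

#' Association of a GRS with a phenotype
#'
#' Linear model of the phenotype (optionally RINT-standardized) on the score
#' plus covariates, reporting the effect per 1-unit higher GRS with a 95%
#' confidence interval.
#'
#' @param scores Named numeric vector from [compute_grs()].
#' @param phenotype Numeric vector aligned with `scores` (or a data.frame
#'   with individual_id and phenotype columns, matched by name).
#' @param covariates Optional data.frame of covariates.
#' @param rint Apply [rank_inverse_normal()] to the phenotype first.
#' @return A one-row data.frame (beta, se, ci_low, ci_high, p, n).
#' @export
grs_association <- function(scores, phenotype, covariates = NULL,
                            rint = FALSE) {
  if (is.data.frame(phenotype)) {
    m <- match(names(scores), phenotype$individual_id)
    if (anyNA(m)) stop("phenotype is missing individuals present in scores",
                       call. = FALSE)
    phenotype <- phenotype$phenotype[m]
  }
  if (length(phenotype) != length(scores))
    stop("scores and phenotype have different lengths", call. = FALSE)
  y <- if (rint) rank_inverse_normal(phenotype) else phenotype
  design <- data.frame(grs = as.numeric(scores))
  if (!is.null(covariates)) design <- cbind(design, covariates)
  fit <- fit_linear_model(y, design)
  hit <- fit[fit$term == "grs", ]
  df <- length(y) - nrow(fit)
  ci <- hit$beta + c(-1, 1) * qt(0.975, df) * hit$se
  data.frame(beta = hit$beta, se = hit$se, ci_low = ci[1], ci_high = ci[2],
             p = hit$p, n = length(y))
}
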