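# Genotyping QC battery: trio Mendelian consistency and parent-parent-child
# (P-P-C) heritability, genotype concordance against references and
# duplicates (full / half / fully discordant, i.e. IBS 2/1/0), imputation
# INFO scoring, and masked-SNP imputation accuracy stratified by MAF bin.
# All displayed percentages are rounded half-up to 2 decimals; raw
# fractions are always retained in the returned objects.

#' Mendelian-error indicator at biallelic sites
#'
#' Returns 1 where the child genotype cannot be composed of one allele
#' from each parent (e.g. both parents homozygous reference while the
#' child is heterozygous), 0 where it can, `NA` where any member is
#' missing. Genotypes are alt-allele counts 0/1/2; all markers are treated
#' as autosomal-diploid.
#'
#' @param father,mother,child equal-length genotype vectors.
#' @return integer vector of 0/1/NA.
#' @export
#' @examples
#' mendelian_errors(0, 0, 1)  # hom x hom -> het child: error
#' mendelian_errors(1, 1, 2)  # het x het: every child is compatible
mendelian_errors <- function(father, mother, child) {
  err <- (father == 0L & mother == 0L & child != 0L) |
         (father == 2L & mother == 2L & child != 2L) |
         (((father == 0L & mother == 2L) |
           (father == 2L & mother == 0L)) & child != 1L) |
         ((father == 0L | mother == 0L) & child == 2L) |
         ((father == 2L | mother == 2L) & child == 0L)
  err[is.na(father) | is.na(mother) | is.na(child)] <- NA
  as.integer(err)
}

#' P-P-C heritability from an error count
#'
#' `100 * (total_snps - errors) / total_snps`: the percentage of post-QC
#' SNPs at which the child is Mendelian-consistent with both parents.
#'
#' @param errors Mendelian error count(s).
#' @param total_snps fixed post-QC SNP total used as denominator.
#' @return unrounded percentage(s).
#' @export
ppc_heritability <- function(errors, total_snps) {
  if (any(errors < 0) || any(errors > total_snps))
    stop("errors must lie in [0, total_snps]")
  100 * (total_snps - errors) / total_snps
}

#' Trio Mendelian-consistency report
#'
#' One row per complete trio: error count over all sites with all three
#' genotypes present, and P-P-C heritability computed against the fixed
#' post-QC SNP total (the conventional denominator); the stricter
#' non-missing-denominator heritability is reported alongside.
#'
#' @param gm a [genotype_matrix()] containing parents and children.
#' @param pedigree a [pedigree_table()].
#' @param total_snps post-QC SNP total for the heritability denominator
#'   (default: marker count of `gm`).
#' @return `data.frame` of class `trio_report`: family/father/mother/child
#'   ids, `snps_compared`, `skipped_missing`, `error_count`,
#'   `ppc_heritability` (display-rounded), `ppc_heritability_raw`,
#'   `heritability_nonmissing`.
#' @export
trio_report <- function(gm, pedigree, total_snps = NULL) {
  total_snps <- total_snps %||% ncol(gm$genotypes)
  trios <- complete_trios(pedigree, rownames(gm$genotypes))
  if (!nrow(trios)) stop("no complete genotyped trio in pedigree")
  G <- gm$genotypes
  rows <- lapply(seq_len(nrow(trios)), function(i) {
    err <- mendelian_errors(G[trios$father_id[i], ],
                            G[trios$mother_id[i], ],
                            G[trios$child_id[i], ])
    compared <- sum(!is.na(err))
    n_err <- sum(err, na.rm = TRUE)
    raw <- ppc_heritability(n_err, total_snps)
    data.frame(trios[i, ],
               snps_compared = compared,
               skipped_missing = ncol(G) - compared,
               error_count = n_err,
               ppc_heritability = round_half_up(raw, 2),
               ppc_heritability_raw = raw,
               heritability_nonmissing = if (compared)
                 round_half_up(100 * (compared - n_err) / compared, 2)
                 else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trio_report", "data.frame")
  out
}

#' Classify a genotype pair by shared alleles
#'
#' Unordered allele-multiset comparison, equivalent to identity-by-state:
#' 2 shared alleles is `"full"`, 1 is `"half"`, 0 is `"discordant"`.
#'
#' @param genotype_a,genotype_b alt-allele counts 0/1/2 (vectors recycle).
#' @return character vector in \{"full","half","discordant"\}, `NA` where
#'   either genotype is missing.
#' @export
concordance_classify <- function(genotype_a, genotype_b) {
  ibs <- 2L - abs(genotype_a - genotype_b)
  c("discordant", "half", "full")[ibs + 1L]
}

#' Genotype concordance between two matrices
#'
#' Compares every sample-SNP combination present and non-missing in both
#' matrices (per-pair missingness exclusion). Samples are matched by id,
#' markers by id with (chrom, pos, ref, alt) identity enforced - allele
#' mismatches are errors, never silently flipped. Counts are reported
#' overall and per stratum when marker and/or sample strata are given.
#'
#' @param gm_a,gm_b [genotype_matrix()] objects.
#' @param marker_strata optional named character vector, marker id to
#'   stratum label (e.g. region or chromosome).
#' @param sample_strata optional named character vector, sample id to
#'   group label (e.g. population).
#' @return `data.frame` of class `concordance_report`, one row per
#'   (snp_set, group) combination including the `"All"`/`"ALL"` margins:
#'   `n_samples`, `combinations_tested`, `full`, `half`, `discordant`,
#'   `concordance_pct` (display-rounded), `concordance_raw`.
#' @export
concordance_report <- function(gm_a, gm_b, marker_strata = NULL,
                               sample_strata = NULL) {
  samples <- intersect(rownames(gm_a$genotypes), rownames(gm_b$genotypes))
  markers <- intersect(colnames(gm_a$genotypes), colnames(gm_b$genotypes))
  if (!length(samples) || !length(markers))
    stop("no overlapping samples/markers to compare")
  ia <- match(markers, gm_a$markers$marker_id)
  ib <- match(markers, gm_b$markers$marker_id)
  mism <- gm_a$markers$chrom[ia] != gm_b$markers$chrom[ib] |
    gm_a$markers$pos[ia] != gm_b$markers$pos[ib] |
    gm_a$markers$ref[ia] != gm_b$markers$ref[ib] |
    gm_a$markers$alt[ia] != gm_b$markers$alt[ib]
  if (any(mism))
    stop("marker identity mismatch at ", markers[mism][1],
         "; alleles must be pre-harmonized")
  A <- gm_a$genotypes[samples, markers, drop = FALSE]
  B <- gm_b$genotypes[samples, markers, drop = FALSE]
  ok <- !is.na(A) & !is.na(B)
  d <- abs(A - B)
  full <- ok & d == 0L
  half <- ok & d == 1L
  disc <- ok & d == 2L
  snp_sets <- c("All",
                if (!is.null(marker_strata))
                  sort(unique(marker_strata[markers])))
  groups <- c("ALL",
              if (!is.null(sample_strata))
                sort(unique(sample_strata[samples])))
  rows <- list()
  for (ss in snp_sets) {
    mcols <- if (ss == "All") rep(TRUE, length(markers))
             else !is.na(marker_strata[markers]) &
                  marker_strata[markers] == ss
    for (gg in groups) {
      srows <- if (gg == "ALL") rep(TRUE, length(samples))
               else !is.na(sample_strata[samples]) &
                    sample_strata[samples] == gg
      n_full <- sum(full[srows, mcols])
      n_half <- sum(half[srows, mcols])
      n_disc <- sum(disc[srows, mcols])
      tested <- n_full + n_half + n_disc
      raw <- if (tested) 100 * n_full / tested else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        snp_set = ss, group = gg, n_samples = sum(srows),
        combinations_tested = tested, full = n_full, half = n_half,
        discordant = n_disc,
        concordance_pct = round_half_up(raw, 2),
        concordance_raw = raw)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("concordance_report", "data.frame")
  out
}

#' Duplicate-pair concordance summary
#'
#' Compares each sample to its duplicate over all sites non-missing in
#' both, and summarizes the fully / half / fully-discordant fractions
#' (printed to 3 decimals, the convention for duplicate QC).
#'
#' @param gm a [genotype_matrix()] holding both members of every pair.
#' @param pairs `data.frame` with `sample_id`, `duplicate_id`.
#' @return list of class `duplicate_report`: `per_pair` (`data.frame` of
#'   counts per pair) and `overall` (pooled counts and percentages).
#' @export
duplicate_concordance <- function(gm, pairs) {
  G <- gm$genotypes
  per <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- G[pairs$sample_id[i], ]
    b <- G[pairs$duplicate_id[i], ]
    ok <- !is.na(a) & !is.na(b)
    d <- abs(a[ok] - b[ok])
    data.frame(sample_id = pairs$sample_id[i],
               duplicate_id = pairs$duplicate_id[i],
               compared = sum(ok), full = sum(d == 0L),
               half = sum(d == 1L), discordant = sum(d == 2L))
  })
  per <- do.call(rbind, per)
  tot <- sum(per$compared)
  overall <- data.frame(
    pairs = nrow(per), compared = tot,
    full_pct = round_half_up(100 * sum(per$full) / tot, 3),
    half_pct = round_half_up(100 * sum(per$half) / tot, 3),
    discordant_pct = round_half_up(100 * sum(per$discordant) / tot, 3))
  structure(list(per_pair = per, overall = overall),
            class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  with(x$overall, cat(sprintf(
    "duplicate_report: %d pairs, %d comparisons | full %.3f%%, half %.3f%%, discordant %.3f%%\n",
    pairs, compared, full_pct, half_pct, discordant_pct)))
  invisible(x)
}

#' Imputation INFO score for one marker
#'
#' The standard ratio-of-variances quality metric: with expected dosage
#' `e_i = p1_i + 2 p2_i` and dosage variance `v_i = p1_i + 4 p2_i - e_i^2`
#' per sample, and estimated allele frequency `theta = sum(e_i) / (2N)`,
#' `INFO = 1 - mean(v) / (2 theta (1 - theta))`. 1 means perfectly certain
#' posteriors; uniform posteriors give -1/3 (clipped to 0). `theta` of 0
#' or 1 is flagged monomorphic with undefined INFO.
#'
#' @param posteriors N x 3 matrix (or data.frame with columns p0, p1, p2)
#'   of genotype posteriors, rows summing to 1.
#' @return list: `raw`, `clipped`, `theta`, `n`, `monomorphic`.
#' @export
info_score <- function(posteriors) {
  p <- as.matrix(if (is.data.frame(posteriors))
    posteriors[, c("p0", "p1", "p2")] else posteriors)
  if (ncol(p) != 3L) stop("posteriors must have 3 columns (p0, p1, p2)")
  if (nrow(p) < 1L) stop("need at least one sample")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("posterior triples must sum to 1")
  e <- p[, 2L] + 2 * p[, 3L]
  v <- p[, 2L] + 4 * p[, 3L] - e^2
  n <- nrow(p)
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1)
    return(list(raw = NA_real_, clipped = NA_real_, theta = theta,
                n = n, monomorphic = TRUE))
  raw <- 1 - mean(v) / (2 * theta * (1 - theta))
  list(raw = raw, clipped = max(raw, 0), theta = theta, n = n,
       monomorphic = FALSE)
}

#' INFO scores for every marker in a posterior table
#'
#' @param posteriors long table (marker_id, sample_id, p0, p1, p2) as
#'   produced by [simulate_posteriors()] or [read_posteriors()].
#' @return `data.frame`: marker_id, info_raw, info_clipped, theta, n,
#'   monomorphic.
#' @export
info_scores <- function(posteriors) {
  sp <- split(posteriors[, c("p0", "p1", "p2")], posteriors$marker_id)
  out <- do.call(rbind, lapply(names(sp), function(id) {
    s <- info_score(sp[[id]])
    data.frame(marker_id = id, info_raw = s$raw,
               info_clipped = s$clipped, theta = s$theta, n = s$n,
               monomorphic = s$monomorphic)
  }))
  rownames(out) <- NULL
  out
}

#' Masked-SNP imputation accuracy
#'
#' Masks a random fraction of directly genotyped markers, takes the
#' best-guess genotype (posterior argmax, ties to the smaller dosage) at
#' the masked sites, and reports concordance with the hidden truth:
#' per MAF bin of width 0.01, overall, and restricted to markers with
#' INFO above `info_threshold` (the headline figure).
#'
#' @param truth a [genotype_matrix()] of directly genotyped calls.
#' @param posteriors long posterior table covering the truth matrix.
#' @param mask_fraction fraction of markers to mask (default 0.002,
#'   i.e. 0.2%; at least one marker is always masked).
#' @param info_threshold INFO filter for the headline accuracy
#'   (default 0.8, strict inequality).
#' @param seed integer seed for the mask draw.
#' @return list of class `imputation_eval`: `masked_markers`,
#'   `per_marker` (maf, bin, comparisons, correct, accuracy, info),
#'   `bins` (per-MAF-bin accuracy), `overall_accuracy_pct`,
#'   `filtered_accuracy_pct` (INFO-filtered), `n_info_pass`,
#'   `mask_fraction`, `info_threshold`, `seed`.
#' @export
masked_imputation_eval <- function(truth, posteriors,
                                   mask_fraction = 0.002,
                                   info_threshold = 0.8, seed = 1L) {
  if (mask_fraction <= 0 || mask_fraction >= 1)
    stop("mask_fraction must lie in (0, 1)")
  G <- truth$genotypes
  marker_ids <- colnames(G)
  n_mask <- max(1L, round(length(marker_ids) * mask_fraction))
  masked <- local_seed(derive_seed(seed, 5),
                       sort(sample(marker_ids, n_mask)))
  post <- posteriors[posteriors$marker_id %in% masked, , drop = FALSE]
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  sp <- split(post, post$marker_id)
  per <- lapply(masked, function(id) {
    pm <- sp[[id]]
    if (is.null(pm) || !nrow(pm))
      return(data.frame(marker_id = id, maf = maf[[id]],
                        comparisons = 0L, correct = 0L,
                        accuracy_pct = NA_real_, info_raw = NA_real_))
    truth_g <- G[pm$sample_id, id]
    ok <- !is.na(truth_g)
    P <- as.matrix(pm[, c("p0", "p1", "p2")])
    best <- max.col(P, ties.method = "first") - 1L  # ties -> smaller dosage
    inf <- info_score(P)
    data.frame(marker_id = id, maf = maf[[id]],
               comparisons = sum(ok),
               correct = sum(best[ok] == truth_g[ok]),
               accuracy_pct = if (any(ok))
                 100 * sum(best[ok] == truth_g[ok]) / sum(ok)
                 else NA_real_,
               info_raw = inf$raw)
  })
  per <- do.call(rbind, per)
  per$bin <- maf_bin(per$maf)
  occupied <- !is.na(per$bin) & per$comparisons > 0L
  bins <- do.call(rbind, lapply(split(per[occupied, ],
                                      per$bin[occupied]), function(b)
    data.frame(bin = b$bin[1], n_snps = nrow(b),
               comparisons = sum(b$comparisons),
               accuracy_pct = round_half_up(
                 100 * sum(b$correct) / sum(b$comparisons), 2))))
  rownames(bins) <- NULL
  overall <- 100 * sum(per$correct) / sum(per$comparisons)
  pass <- !is.na(per$info_raw) & per$info_raw > info_threshold
  filt <- if (any(pass & per$comparisons > 0))
    100 * sum(per$correct[pass]) / sum(per$comparisons[pass])
  else NA_real_
  structure(list(masked_markers = masked,
                 per_marker = per,
                 bins = bins,
                 overall_accuracy_pct = round_half_up(overall, 2),
                 overall_accuracy_raw = overall,
                 filtered_accuracy_pct = round_half_up(filt, 2),
                 filtered_accuracy_raw = filt,
                 n_info_pass = sum(pass),
                 mask_fraction = mask_fraction,
                 info_threshold = info_threshold,
                 seed = seed),
            class = "imputation_eval")
}

# MAF bins of width 0.01 partitioning (0, 0.5]; 0 (monomorphic) -> NA
maf_bin <- function(maf) {
  idx <- ceiling(maf * 100)
  idx[maf <= 0] <- NA_integer_
  ifelse(is.na(idx), NA_character_,
         sprintf("(%.2f,%.2f]", (idx - 1) / 100, idx / 100))
}

#' @export
print.imputation_eval <- function(x, ...) {
  cat(sprintf(
    "imputation_eval: %d markers masked (%.2f%%) | accuracy %.2f%% overall, %.2f%% at INFO > %.2g (%d SNPs)\n",
    length(x$masked_markers), 100 * x$mask_fraction,
    x$overall_accuracy_pct, x$filtered_accuracy_pct,
    x$info_threshold, x$n_info_pass))
  invisible(x)
}

#' Write QC reports as TSV
#'
#' @param report a `trio_report`, `concordance_report`, or the `bins` /
#'   `per_marker` component of an `imputation_eval`.
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
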