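#' Phased haplotype panel
#'
#' The substrate for allele-frequency and LD computation: a 0/1 allele
#' matrix with two haplotype rows per sample, a marker manifest, and
#' sample-to-population labels.
#'
#' @param haplotypes integer matrix of 0/1 alleles, one row per haplotype
#'   (two consecutive rows per sample), one column per marker.
#' @param markers marker manifest `data.frame` (see [marker_manifest()]),
#'   one row per column of `haplotypes`, sorted by (chrom, pos).
#' @param samples `data.frame` with columns `sample_id`, `population`,
#'   one row per sample.
#' @return An object of class `haplotype_panel`: a list with elements
#'   `haplotypes`, `markers`, `samples`.
#' @export
haplotype_panel <- function(haplotypes, markers, samples) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (!all(haplotypes %in% c(0L, 1L)))
    stop("haplotype alleles must be 0/1 with no missing values")
  if (nrow(haplotypes) != 2L * nrow(samples))
    stop("haplotype matrix must have 2 rows per sample")
  if (ncol(haplotypes) != nrow(markers))
    stop("haplotype matrix has ", ncol(haplotypes),
         " columns but manifest has ", nrow(markers), " markers")
  markers <- validate_manifest(markers)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in panel samples")
  colnames(haplotypes) <- markers$marker_id
  rownames(haplotypes) <- paste(rep(samples$sample_id, each = 2L),
                                rep(1:2, nrow(samples)), sep = ".")
  structure(list(haplotypes = haplotypes,
                 markers = markers,
                 samples = as.data.frame(samples)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  pops <- table(x$samples$population)
  cat("haplotype_panel:", nrow(x$samples), "samples,",
      nrow(x$markers), "markers\n")
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Extract the haplotype rows belonging to one population
#'
#' @param panel a [haplotype_panel()].
#' @param population population label present in `panel$samples$population`.
#' @return integer matrix of haplotypes (2 per sample) by markers.
#' @export
pop_haplotypes <- function(panel, population) {
  keep <- panel$samples$population == population
  if (!any(keep)) stop("population '", population, "' not in panel")
  panel$haplotypes[rep(keep, each = 2L), , drop = FALSE]
}

#' Collapse a phased panel to an unphased genotype matrix
#'
#' @param panel a [haplotype_panel()].
#' @return a [genotype_matrix()] of alt-allele counts.
#' @export
panel_genotypes <- function(panel) {
  H <- panel$haplotypes
  n <- nrow(panel$samples)
  G <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(G) <- panel$samples$sample_id
  genotype_matrix(G, panel$markers, panel$samples)
}

#' Unphased biallelic genotype matrix
#'
#' Genotypes are alt-allele counts 0/1/2; missing genotypes are `NA`
#' (never 0, so frequency arithmetic stays unambiguous).
#'
#' @param genotypes integer matrix, samples in rows, markers in columns;
#'   values in \{0,1,2,NA\}.
#' @param markers marker manifest aligned to the columns.
#' @param samples optional `data.frame` with `sample_id` (and optionally
#'   `population`); defaults to the rownames of `genotypes`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, markers, samples = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotypes must be alt-allele counts 0/1/2 or NA")
  markers <- validate_manifest(markers)
  if (ncol(genotypes) != nrow(markers))
    stop("genotype matrix / manifest dimension mismatch")
  if (is.null(samples)) {
    if (is.null(rownames(genotypes)))
      rownames(genotypes) <- sprintf("S%04d", seq_len(nrow(genotypes)))
    samples <- data.frame(sample_id = rownames(genotypes))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- markers$marker_id
  structure(list(genotypes = genotypes,
                 markers = markers,
                 samples = as.data.frame(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$genotypes))
  cat("genotype_matrix:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "markers;",
      sprintf("%.2f%% missing\n", 100 * miss))
  invisible(x)
}

#' Construct or validate a marker manifest
#'
#' A manifest is a plain `data.frame` with one row per biallelic marker:
#' `marker_id` (unique), `chrom`, `pos` (1-based bp), `ref`, `alt`
#' (single characters), `modules` (comma-separated content-module labels),
#' and optional per-population columns `maf_<POP>` (minor allele frequency,
#' in \[0, 0.5\]) and `mac_<POP>` (minor allele count).
#'
#' @param marker_id,chrom,pos,ref,alt vectors of equal length.
#' @param modules character vector of comma-separated module labels.
#' @param ... additional per-population `maf_*` / `mac_*` columns.
#' @return validated manifest `data.frame`.
#' @export
marker_manifest <- function(marker_id, chrom, pos, ref = "A", alt = "G",
                            modules = "", ...) {
  validate_manifest(data.frame(marker_id = as.character(marker_id),
                               chrom = as.character(chrom),
                               pos = as.integer(pos),
                               ref = ref, alt = alt,
                               modules = modules, ...))
}

validate_manifest <- function(m) {
  m <- as.data.frame(m)
  need <- c("marker_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$marker_id))
    stop("duplicate marker_id in manifest: ",
         paste(unique(m$marker_id[duplicated(m$marker_id)])[1:3],
               collapse = ", "))
  if (any(m$pos < 1L)) stop("positions must be 1-based (>= 1)")
  maf_cols <- grep("^maf_", names(m), value = TRUE)
  for (cc in maf_cols) {
    bad <- !is.na(m[[cc]]) & (m[[cc]] < 0 | m[[cc]] > 0.5)
    if (any(bad)) stop("column ", cc, " outside [0, 0.5]")
  }
  if (!"modules" %in% names(m)) m$modules <- ""
  rownames(m) <- NULL
  m
}

# population labels carried by a manifest's maf_* columns
manifest_populations <- function(m) {
  sub("^maf_", "", grep("^maf_", names(m), value = TRUE))
}

#' Pedigree table (PLINK .fam dialect)
#'
#' @param family_id,individual_id,father_id,mother_id character vectors;
#'   `"0"` denotes a missing parent.
#' @param sex integer (1 male, 2 female, 0 unknown).
#' @param phenotype numeric, `-9` for missing.
#' @return `data.frame` of class `pedigree_table`.
#' @export
pedigree_table <- function(family_id, individual_id, father_id = "0",
                           mother_id = "0", sex = 0L, phenotype = -9) {
  ped <- data.frame(family_id = as.character(family_id),
                    individual_id = as.character(individual_id),
                    father_id = as.character(father_id),
                    mother_id = as.character(mother_id),
                    sex = as.integer(sex),
                    phenotype = phenotype)
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual_id in pedigree")
  self <- ped$individual_id == ped$father_id |
          ped$individual_id == ped$mother_id
  if (any(self)) stop("individual listed as its own parent: ",
                      ped$individual_id[self][1])
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Complete trios in a pedigree
#'
#' A trio is complete iff both parents resolve to genotyped individuals.
#'
#' @param pedigree a [pedigree_table()].
#' @param genotyped character vector of genotyped individual ids.
#' @return `data.frame` with `family_id`, `father_id`, `mother_id`,
#'   `child_id`, one row per complete trio.
#' @export
complete_trios <- function(pedigree, genotyped) {
  has <- pedigree$father_id != "0" & pedigree$mother_id != "0" &
    pedigree$individual_id %in% genotyped &
    pedigree$father_id %in% genotyped &
    pedigree$mother_id %in% genotyped
  data.frame(family_id = pedigree$family_id[has],
             father_id = pedigree$father_id[has],
             mother_id = pedigree$mother_id[has],
             child_id = pedigree$individual_id[has])
}
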