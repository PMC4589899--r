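# Readers/writers for the standard text formats the toolkit touches:
# VCF 4.x (GT only, via vcfR), PLINK .ped/.map and .fam, TSV marker
# manifests, posterior tables, and the YAML run configuration.
# Positions are 1-based everywhere; region predicates use closed intervals.

#' Read a phased haplotype panel from a VCF
#'
#' Biallelic, fully phased GT records become two 0/1 haplotype rows per
#' sample. Multiallelic or unphased records are an error in strict mode,
#' otherwise skipped with a message.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param population_map named character vector mapping sample id to
#'   population label; samples absent from the map get `"ALL"`. `NULL`
#'   puts every sample in `"ALL"`.
#' @param strict reject (`TRUE`, default) or skip (`FALSE`) multiallelic
#'   and unphased records.
#' @return a [haplotype_panel()].
#' @export
read_haplotype_vcf <- function(path, population_map = NULL, strict = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_frame(v)
  gt <- vcf_gt_matrix(v)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  multi <- grepl(",", fix$ALT)
  unphased <- apply(gt, 1L, function(g) any(grepl("/", g, fixed = TRUE)))
  missing_gt <- apply(gt, 1L, function(g) any(is.na(g) | grepl("\\.", g)))
  bad <- multi | unphased | missing_gt
  if (strict && any(bad)) {
    why <- ifelse(multi, "multiallelic",
                  ifelse(unphased, "unphased GT", "missing GT"))
    stop("record ", ids[which(bad)[1]], " rejected: ", why[which(bad)[1]])
  }
  if (any(bad)) {
    message("skipping ", sum(bad), " multiallelic/unphased/missing record(s)")
    fix <- fix[!bad, , drop = FALSE]
    gt <- gt[!bad, , drop = FALSE]
    ids <- ids[!bad]
  }
  if (anyDuplicated(ids))
    stop("duplicate marker id in VCF: ", ids[duplicated(ids)][1])
  samples <- colnames(gt)
  alleles <- strsplit(as.vector(t(gt)), "|", fixed = TRUE)
  len <- lengths(alleles)
  if (any(len != 2L))
    stop("inconsistent ploidy: expected diploid GT, got '",
         as.vector(t(gt))[which(len != 2L)[1]], "'")
  al <- suppressWarnings(as.integer(unlist(alleles)))
  if (anyNA(al) || any(al > 1L))
    stop("non-biallelic allele code in GT field")
  # unlist order: marker-major over (sample, hap); reshape to hap x marker
  H <- matrix(al, nrow = 2L * length(samples), ncol = nrow(fix))
  pops <- if (is.null(population_map)) rep("ALL", length(samples))
          else unname(ifelse(samples %in% names(population_map),
                             population_map[samples], "ALL"))
  markers <- marker_manifest(ids, fix$CHROM, as.integer(fix$POS),
                             fix$REF, fix$ALT)
  haplotype_panel(H, markers,
                  data.frame(sample_id = samples, population = pops))
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel a [haplotype_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_haplotype_vcf <- function(panel, path) {
  H <- panel$haplotypes
  n <- nrow(panel$samples)
  a1 <- H[seq(1L, 2L * n, 2L), , drop = FALSE]
  a2 <- H[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow = n)
  write_vcf_body(panel$markers, gt, panel$samples$sample_id, path)
}

#' Write a genotype matrix as an unphased VCF
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  g <- gm$genotypes
  gt <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  ok <- !is.na(g)
  gt[ok] <- codes[as.character(g[ok])]
  write_vcf_body(gm$markers, gt, gm$samples$sample_id, path)
}

# vcfR drops dimensions for single-record files; keep matrix shape
vcf_fix_frame <- function(v) {
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  as.data.frame(fix, stringsAsFactors = FALSE)
}

vcf_gt_matrix <- function(v) {
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  if (is.null(dim(gt))) gt <- t(gt)
  gt
}

# gt: samples x markers character matrix of GT strings
write_vcf_body <- function(markers, gt, sample_ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=tagarray",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sample_ids),
                     collapse = "\t")), con)
  body <- cbind(markers$chrom, markers$pos, markers$marker_id,
                markers$ref, markers$alt, ".", "PASS", ".", "GT",
                t(gt))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read unphased genotypes from VCF or PLINK .ped/.map
#'
#' Genotypes are coded as alt-allele counts (0/1/2); missing genotypes are
#' `NA`. For the ped dialect, allele symbols must be in \{A,C,G,T,0\}; a
#' supplied manifest fixes ref/alt orientation and marker order, otherwise
#' the major allele observed in the file becomes ref.
#'
#' @param path input file (`.vcf` or `.ped`).
#' @param dialect `"vcf"` or `"plink_ped"`.
#' @param manifest optional marker manifest giving ref/alt per marker.
#' @param map_path for the ped dialect, the companion `.map` file; defaults
#'   to `path` with its extension replaced by `.map`.
#' @return a [genotype_matrix()]; for the ped dialect the sample table
#'   carries the pedigree columns.
#' @export
read_genotypes <- function(path, dialect = c("vcf", "plink_ped"),
                           manifest = NULL, map_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") read_genotypes_vcf(path, manifest)
  else read_genotypes_ped(path, manifest, map_path)
}

read_genotypes_vcf <- function(path, manifest = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_frame(v)
  gt <- vcf_gt_matrix(v)
  if (any(grepl(",", fix$ALT))) stop("multiallelic records not supported")
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  if (anyDuplicated(ids)) stop("duplicate marker id in VCF")
  count_alt <- function(g) {
    al <- strsplit(g, "[|/]")
    vapply(al, function(a) {
      if (any(a == "." | is.na(a))) NA_integer_ else sum(a == "1")
    }, integer(1))
  }
  G <- t(apply(gt, 1L, count_alt))          # markers x samples
  G[is.na(gt)] <- NA_integer_
  G <- t(G)                                  # samples x markers
  rownames(G) <- colnames(gt)
  mk <- marker_manifest(ids, fix$CHROM, as.integer(fix$POS),
                        fix$REF, fix$ALT)
  gm <- genotype_matrix(G, mk)
  if (!is.null(manifest)) gm <- align_to_manifest(gm, manifest)
  gm
}

read_genotypes_ped <- function(path, manifest = NULL, map_path = NULL) {
  map_path <- map_path %||% sub("\\.ped$", ".map", path)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  names(map) <- c("chrom", "marker_id", "cm", "pos")[seq_len(ncol(map))]
  ped <- utils::read.table(path, header = FALSE, colClasses = "character")
  n_markers <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_markers)
    stop(".ped has ", ncol(ped), " columns; expected ",
         6L + 2L * n_markers, " for ", n_markers, " markers")
  fam <- ped[, 1:6]
  names(fam) <- c("family_id", "sample_id", "father_id", "mother_id",
                  "sex", "phenotype")
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  valid <- c("A", "C", "G", "T", "0")
  if (!all(al %in% valid))
    stop("ped allele symbol outside {A,C,G,T,0}: '",
         al[!al %in% valid][1], "'")
  a1 <- al[, seq(1L, 2L * n_markers, 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * n_markers, 2L), drop = FALSE]
  if (!is.null(manifest)) {
    idx <- match(map$marker_id, manifest$marker_id)
    if (anyNA(idx))
      stop("marker ", map$marker_id[which(is.na(idx))[1]],
           " absent from manifest")
    ref <- manifest$ref[idx]; alt <- manifest$alt[idx]
    mk <- manifest[idx, , drop = FALSE]
    # reorder to manifest order when it covers the same markers
    ord <- order(idx)
  } else {
    # major allele observed -> ref
    ref <- character(n_markers); alt <- character(n_markers)
    for (j in seq_len(n_markers)) {
      obs <- c(a1[, j], a2[, j]); obs <- obs[obs != "0"]
      tab <- sort(table(obs), decreasing = TRUE)
      ref[j] <- if (length(tab)) names(tab)[1] else "A"
      alt[j] <- if (length(tab) > 1L) names(tab)[2] else
        setdiff(c("A", "C", "G", "T"), ref[j])[1]
    }
    mk <- marker_manifest(map$marker_id, map$chrom, as.integer(map$pos),
                          ref, alt)
    ord <- seq_len(n_markers)
  }
  G <- matrix(NA_integer_, nrow(ped), n_markers)
  for (j in seq_len(n_markers)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    known <- x1 != "0" & x2 != "0"
    bad <- known & (!(x1 %in% c(ref[j], alt[j])) |
                    !(x2 %in% c(ref[j], alt[j])))
    if (any(bad))
      stop("allele mismatch at ", map$marker_id[j], ": observed ",
           x1[bad][1], "/", x2[bad][1], " vs ref=", ref[j],
           " alt=", alt[j])
    G[known, j] <- (x1[known] == alt[j]) + (x2[known] == alt[j])
  }
  G <- G[, ord, drop = FALSE]
  mk <- mk[ord, , drop = FALSE]
  rownames(G) <- fam$sample_id
  genotype_matrix(G, mk, fam)
}

align_to_manifest <- function(gm, manifest) {
  idx <- match(manifest$marker_id, gm$markers$marker_id)
  if (anyNA(idx))
    stop("manifest marker ", manifest$marker_id[which(is.na(idx))[1]],
         " not present in genotype data")
  sub <- gm$markers[idx, ]
  mism <- sub$chrom != manifest$chrom | sub$pos != manifest$pos |
    sub$ref != manifest$ref | sub$alt != manifest$alt
  if (any(mism))
    stop("marker identity mismatch (id/chrom/pos/ref/alt) at ",
         manifest$marker_id[mism][1],
         "; no strand harmonization is attempted")
  genotype_matrix(gm$genotypes[, idx, drop = FALSE],
                  manifest, gm$samples)
}

#' Write a genotype matrix as PLINK .ped/.map
#'
#' @param gm a [genotype_matrix()]; pedigree columns in `gm$samples` are
#'   used when present.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @return `prefix`, invisibly.
#' @export
write_plink_ped <- function(gm, prefix) {
  mk <- gm$markers
  utils::write.table(data.frame(mk$chrom, mk$marker_id, 0L, mk$pos),
                     paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  s <- gm$samples
  fam <- data.frame(
    family_id = s$family_id %||% s$sample_id,
    sample_id = s$sample_id,
    father_id = s$father_id %||% rep("0", nrow(s)),
    mother_id = s$mother_id %||% rep("0", nrow(s)),
    sex = s$sex %||% rep(0L, nrow(s)),
    phenotype = s$phenotype %||% rep(-9, nrow(s)))
  G <- gm$genotypes
  n <- nrow(G); m <- ncol(G)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (j in seq_len(m)) {
    g <- G[, j]; ok <- !is.na(g)
    a1[ok, j] <- ifelse(g[ok] >= 1L, mk$alt[j], mk$ref[j])
    a2[ok, j] <- ifelse(g[ok] == 2L, mk$alt[j], mk$ref[j])
  }
  inter <- matrix("", n, 2L * m)
  inter[, seq(1L, 2L * m, 2L)] <- a1
  inter[, seq(2L, 2L * m, 2L)] <- a2
  utils::write.table(cbind(fam, inter), paste0(prefix, ".ped"),
                     sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read / write a marker manifest TSV
#'
#' Header columns: `marker_id, chrom, pos, ref, alt, modules`, plus any
#' `maf_<POP>` / `mac_<POP>` pairs.
#'
#' @param path TSV file.
#' @return manifest `data.frame`.
#' @export
read_marker_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = NA, stringsAsFactors = FALSE)
  m$chrom <- as.character(m$chrom)
  if ("modules" %in% names(m)) m$modules[is.na(m$modules)] <- ""
  validate_manifest(m)
}

#' @rdname read_marker_manifest
#' @param manifest manifest to write.
#' @export
write_marker_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a pedigree (.fam dialect)
#'
#' Whitespace-delimited, six columns: family, individual, father, mother,
#' sex, phenotype; `"0"` marks a missing parent.
#'
#' @param path .fam file.
#' @return a [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  p <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(p) < 4L) stop(".fam needs at least 4 columns")
  pedigree_table(p[[1]], p[[2]], p[[3]], p[[4]],
                 sex = if (ncol(p) >= 5L) as.integer(p[[5]]) else 0L,
                 phenotype = if (ncol(p) >= 6L) as.numeric(p[[6]]) else -9)
}

#' @rdname read_pedigree
#' @param pedigree a [pedigree_table()] to write.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write genotype-posterior tables
#'
#' Long TSV with columns `marker_id, sample_id, p0, p1, p2`; each triple
#' sums to 1.
#'
#' @param path TSV file.
#' @return `data.frame` of posteriors.
#' @export
read_posteriors <- function(path) {
  p <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("marker_id", "sample_id", "p0", "p1", "p2")
  if (!all(need %in% names(p)))
    stop("posterior table must have columns ",
         paste(need, collapse = ", "))
  s <- p$p0 + p$p1 + p$p2
  if (any(abs(s - 1) > 1e-6))
    stop("posterior triples must sum to 1 (max deviation ",
         format(max(abs(s - 1))), ")")
  p
}

#' @rdname read_posteriors
#' @param posteriors posterior `data.frame` to write.
#' @export
write_posteriors <- function(posteriors, path) {
  utils::write.table(posteriors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a run configuration
#'
#' A single declarative YAML file carrying thresholds, windows, seeds and
#' population cutoffs; unspecified keys fall back to package defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return named list of resolved settings.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    r2_threshold = 0.8,
    window_bp = 250000L,
    budget = 782000L,
    min_mac_exclusive = 5L,
    maf_cutoffs = list(CEU = 0.02, AFR = 0.05),
    mask_fraction = 0.002,
    info_threshold = 0.8,
    seed = 1L)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user)
}
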