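# Coverage of a reference panel by an array design: for every eligible
# panel marker, the maximum r-squared to any array marker within a window
# (1 for markers directly on the array), summarized as threshold curves
# and mean max-r2, whole-genome or per region.

#' Maximum r-squared from each panel target to the array
#'
#' Targets are the panel markers polymorphic in `population` whose MAF is
#' strictly greater than `maf_cutoff`. A target directly on the array
#' scores 1; otherwise the maximum r-squared over polymorphic array
#' markers within `window_bp` on the same chromosome; 0 if none.
#'
#' @param array_markers character vector of array marker ids.
#' @param panel a [haplotype_panel()].
#' @param population population label.
#' @param window_bp LD horizon (default 250 kb).
#' @param maf_cutoff strict MAF cutoff for target eligibility (default 0,
#'   i.e. all polymorphic markers).
#' @return named numeric vector of max r-squared per eligible target.
#' @export
max_r2_per_target <- function(array_markers, panel, population,
                              window_bp = 250000L, maf_cutoff = 0) {
  mk <- panel$markers
  Hp <- pop_haplotypes(panel, population)
  cnt <- colSums(Hp)
  n2 <- nrow(Hp)
  maf <- pmin(cnt, n2 - cnt) / n2
  poly <- cnt > 0L & cnt < n2
  eligible <- which(poly & maf > maf_cutoff)
  if (!length(eligible))
    return(stats::setNames(numeric(0), character(0)))
  on_array <- mk$marker_id %in% array_markers
  arr_idx <- which(on_array & poly)       # only polymorphic array markers
  Z <- scale(Hp[, poly, drop = FALSE]) / sqrt(n2 - 1)
  colmap <- match(seq_len(ncol(Hp)), which(poly))  # panel col -> Z col
  out <- stats::setNames(numeric(length(eligible)),
                         mk$marker_id[eligible])
  arr_pos <- mk$pos[arr_idx]
  arr_chrom <- mk$chrom[arr_idx]
  for (k in seq_along(eligible)) {
    t <- eligible[k]
    if (on_array[t]) { out[k] <- 1; next }
    near <- arr_idx[arr_chrom == mk$chrom[t] &
                    abs(arr_pos - mk$pos[t]) <= window_bp]
    if (!length(near)) { out[k] <- 0; next }
    r2 <- as.vector(crossprod(Z[, colmap[t]],
                              Z[, colmap[near], drop = FALSE]))^2
    out[k] <- min(max(r2), 1)
  }
  out
}

#' Coverage curve over an r-squared threshold grid
#'
#' @param max_r2 named vector from [max_r2_per_target()].
#' @param threshold_grid thresholds (default 0, 0.05, ..., 1).
#' @param population,maf_cutoff,region labels recorded in the report.
#' @param window_bp LD horizon recorded in the report.
#' @return object of class `coverage_report`: list with `curve`
#'   (`data.frame` threshold / fraction), `mean_max_r2`, `n_eligible` and
#'   the labels. Fractions are the share of eligible targets with max r2
#'   at or above each threshold (non-increasing in the threshold).
#' @export
coverage_curve <- function(max_r2, threshold_grid = seq(0, 1, by = 0.05),
                           population = NA_character_, maf_cutoff = NA,
                           region = NA_character_, window_bp = NA) {
  n <- length(max_r2)
  frac <- vapply(threshold_grid,
                 function(t) if (n == 0L) NA_real_ else mean(max_r2 >= t),
                 numeric(1))
  structure(list(curve = data.frame(threshold = threshold_grid,
                                    fraction = frac),
                 mean_max_r2 = if (n == 0L) NA_real_ else mean(max_r2),
                 n_eligible = n,
                 population = population,
                 maf_cutoff = maf_cutoff,
                 region = region,
                 window_bp = window_bp),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "coverage_report: pop=%s maf>%s region=%s | %d targets, mean max-r2 %.4f\n",
    x$population, format(x$maf_cutoff), x$region, x$n_eligible,
    x$mean_max_r2))
  sel <- x$curve$threshold %in% c(0, 0.2, 0.5, 0.8, 1)
  print(x$curve[sel, ], row.names = FALSE)
  invisible(x)
}

#' Array coverage of a panel population
#'
#' Convenience wrapper: [max_r2_per_target()] then [coverage_curve()].
#'
#' @inheritParams max_r2_per_target
#' @param threshold_grid thresholds for the curve.
#' @return a `coverage_report`.
#' @export
array_coverage <- function(array_markers, panel, population,
                           maf_cutoff = 0.05, window_bp = 250000L,
                           threshold_grid = seq(0, 1, by = 0.05)) {
  v <- max_r2_per_target(array_markers, panel, population, window_bp,
                         maf_cutoff)
  coverage_curve(v, threshold_grid, population, maf_cutoff,
                 region = "genome", window_bp = window_bp)
}

#' Genomic region presets and filters
#'
#' `genomic_region()` builds a closed 1-based interval; `mhc_region()` is
#' the extended MHC preset, chr6:25,500,000-34,000,000 (hg19);
#' `in_region()` tests manifest rows for membership (closed on both ends).
#'
#' @param chrom chromosome label.
#' @param start,end closed interval bounds (1-based bp).
#' @param label region name.
#' @return `genomic_region()`: a list with `chrom`, `start`, `end`,
#'   `label`; `in_region()`: logical vector.
#' @export
genomic_region <- function(chrom, start, end, label = NA_character_) {
  if (end < start) stop("region end before start")
  list(chrom = as.character(chrom), start = as.integer(start),
       end = as.integer(end), label = label)
}

#' @rdname genomic_region
#' @export
mhc_region <- function() {
  genomic_region("6", 25500000L, 34000000L, "extended_MHC")
}

#' @rdname genomic_region
#' @param manifest marker manifest.
#' @param region a [genomic_region()].
#' @export
in_region <- function(manifest, region) {
  manifest$chrom == region$chrom &
    manifest$pos >= region$start & manifest$pos <= region$end
}

#' Per-region coverage reports
#'
#' Targets are filtered to each closed region before the coverage
#' computation; a region spanning the whole panel reproduces the
#' whole-panel report.
#'
#' @inheritParams max_r2_per_target
#' @param regions list of [genomic_region()] objects.
#' @param threshold_grid thresholds for the curves.
#' @return named list of `coverage_report`, one per region label.
#' @export
regional_coverage <- function(array_markers, panel, regions, population,
                              maf_cutoff = 0.05, window_bp = 250000L,
                              threshold_grid = seq(0, 1, by = 0.05)) {
  v <- max_r2_per_target(array_markers, panel, population, window_bp,
                         maf_cutoff)
  mk <- panel$markers
  out <- list()
  for (i in seq_along(regions)) {
    rg <- regions[[i]]
    lab <- if (is.null(rg$label) || is.na(rg$label))
      paste0(rg$chrom, ":", rg$start, "-", rg$end) else rg$label
    keep <- names(v) %in% mk$marker_id[in_region(mk, rg)]
    out[[lab]] <- coverage_curve(v[keep], threshold_grid, population,
                                 maf_cutoff, region = lab, window_bp)
  }
  out
}

#' Write coverage reports as TSV
#'
#' @param reports a `coverage_report` or list of them.
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(reports, path) {
  if (inherits(reports, "coverage_report")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(r)
    data.frame(population = r$population, maf_cutoff = r$maf_cutoff,
               region = r$region, window_bp = r$window_bp,
               n_eligible = r$n_eligible, mean_max_r2 = r$mean_max_r2,
               threshold = r$curve$threshold,
               fraction = r$curve$fraction)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
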