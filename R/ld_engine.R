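# Per-population allele frequencies and windowed pairwise LD (r-squared),
# the substrate for tagging and coverage. r2 follows the haplotype
# definition D^2 / (p_i(1-p_i) p_j(1-p_j)); the windowed store computes it
# via column correlations of the 0/1 haplotype matrix (algebraically the
# same quantity) and is checked against the direct formula in tests.

#' Per-population allele frequencies
#'
#' @param panel a [haplotype_panel()].
#' @param population population label present in the panel.
#' @return `data.frame` with `marker_id`, `af` (alt-allele frequency),
#'   `maf`, `mac`, `n_hap`.
#' @export
allele_frequency <- function(panel, population) {
  Hp <- pop_haplotypes(panel, population)
  cnt <- colSums(Hp)
  n2 <- nrow(Hp)
  data.frame(marker_id = panel$markers$marker_id,
             af = cnt / n2,
             maf = pmin(cnt, n2 - cnt) / n2,
             mac = as.integer(pmin(cnt, n2 - cnt)),
             n_hap = n2)
}

#' Pairwise r-squared between two haplotype vectors
#'
#' `r2 = D^2 / (p_i(1-p_i) p_j(1-p_j))` with `D = p_ij - p_i p_j`, where
#' `p_ij` is the frequency of haplotypes carrying the alt allele at both
#' sites. The result is clamped to \[0,1\] against rounding. Monomorphic
#' input is an error: callers must exclude such markers.
#'
#' @param hap_i,hap_j equal-length 0/1 vectors, both polymorphic.
#' @return r-squared in \[0,1\].
#' @export
#' @examples
#' pairwise_r2(c(0, 0, 0, 1), c(0, 0, 1, 1))  # 1/3
pairwise_r2 <- function(hap_i, hap_j) {
  if (length(hap_i) != length(hap_j))
    stop("haplotype vectors must have equal length")
  p_i <- mean(hap_i)
  p_j <- mean(hap_j)
  if (p_i %in% c(0, 1) || p_j %in% c(0, 1))
    stop("r2 is undefined for monomorphic markers")
  D <- mean(hap_i * hap_j) - p_i * p_j
  r2 <- D^2 / (p_i * (1 - p_i) * p_j * (1 - p_j))
  min(max(r2, 0), 1)
}

#' Build a windowed LD store for one population
#'
#' Computes r-squared for every pair of polymorphic markers on the same
#' chromosome within `window_bp` of each other (closed bound on the
#' position difference). Monomorphic markers are excluded entirely.
#'
#' @param panel a [haplotype_panel()] whose manifest is sorted by
#'   (chrom, pos).
#' @param population population label.
#' @param window_bp LD horizon in base pairs (default 250 kb).
#' @return object of class `ld_store`: list with `population`,
#'   `window_bp`, `markers` (manifest rows of the polymorphic markers,
#'   with that population's `maf` attached) and `pairs` (`data.frame`
#'   `id_i`, `id_j`, `r2`, each unordered pair stored once).
#' @export
build_ld_store <- function(panel, population, window_bp = 250000L) {
  mk <- panel$markers
  ord <- order(mk$chrom, mk$pos)
  if (any(ord != seq_len(nrow(mk))))
    stop("manifest must be sorted by (chrom, pos)")
  Hp <- pop_haplotypes(panel, population)
  cnt <- colSums(Hp)
  poly <- cnt > 0L & cnt < nrow(Hp)
  mk_poly <- mk[poly, , drop = FALSE]
  mk_poly$maf <- pmin(cnt[poly], nrow(Hp) - cnt[poly]) / nrow(Hp)
  X <- Hp[, poly, drop = FALSE]
  # column-standardize once; r2 between columns = squared dot product
  Z <- scale(X)
  Z <- Z / sqrt(nrow(Z) - 1)
  n_poly <- ncol(X)
  out_i <- vector("list", n_poly)
  pos <- mk_poly$pos
  chrom <- mk_poly$chrom
  for (i in seq_len(n_poly)) {
    j_max <- i
    while (j_max < n_poly && chrom[j_max + 1L] == chrom[i] &&
           pos[j_max + 1L] - pos[i] <= window_bp)
      j_max <- j_max + 1L
    if (j_max > i) {
      J <- (i + 1L):j_max
      r2 <- as.vector(crossprod(Z[, i], Z[, J, drop = FALSE]))^2
      r2 <- pmin(pmax(r2, 0), 1)
      out_i[[i]] <- data.frame(id_i = mk_poly$marker_id[i],
                               id_j = mk_poly$marker_id[J],
                               r2 = r2)
    }
  }
  pairs <- do.call(rbind, out_i)
  if (is.null(pairs))
    pairs <- data.frame(id_i = character(), id_j = character(),
                        r2 = numeric())
  rownames(pairs) <- NULL
  structure(list(population = population,
                 window_bp = as.integer(window_bp),
                 markers = mk_poly,
                 pairs = pairs),
            class = "ld_store")
}

#' @export
print.ld_store <- function(x, ...) {
  cat("ld_store:", x$population, "-", nrow(x$markers),
      "polymorphic markers,", nrow(x$pairs), "pairs within",
      x$window_bp, "bp\n")
  invisible(x)
}

#' Look up stored r-squared values
#'
#' @param store an [build_ld_store()] result.
#' @param id_i,id_j marker id vectors (recycled).
#' @return numeric vector: stored r2, 1 for `id_i == id_j` when
#'   polymorphic, `NA` for pairs outside the window or monomorphic.
#' @export
ld_lookup <- function(store, id_i, id_j) {
  n <- max(length(id_i), length(id_j))
  id_i <- rep_len(id_i, n); id_j <- rep_len(id_j, n)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tab <- stats::setNames(store$pairs$r2,
                         key(store$pairs$id_i, store$pairs$id_j))
  out <- unname(tab[key(id_i, id_j)])
  self <- id_i == id_j & id_i %in% store$markers$marker_id
  out[self] <- 1
  out
}

#' Write / read an LD store as TSV
#'
#' Columns: `population, id_i, id_j, r2`; window recorded as a `#window_bp`
#' comment line.
#'
#' @param store an `ld_store`.
#' @param path TSV file.
#' @return `path` / the restored `ld_store` (the marker table is reduced to
#'   the ids seen in pairs unless `markers` is supplied).
#' @export
write_ld_store <- function(store, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#window_bp=", store$window_bp), con)
  utils::write.table(
    data.frame(population = store$population, store$pairs),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ld_store
#' @param markers optional manifest for the restored store.
#' @export
read_ld_store <- function(path, markers = NULL) {
  first <- readLines(path, n = 1L)
  window_bp <- as.integer(sub("#window_bp=", "", first, fixed = TRUE))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           stringsAsFactors = FALSE)
  if (is.null(markers)) {
    ids <- unique(c(tab$id_i, tab$id_j))
    markers <- marker_manifest(ids, "NA", seq_along(ids))
  }
  structure(list(population = tab$population[1] %||% NA_character_,
                 window_bp = window_bp,
                 markers = markers,
                 pairs = tab[, c("id_i", "id_j", "r2")]),
            class = "ld_store")
}
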