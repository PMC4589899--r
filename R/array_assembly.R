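# Tiered, non-redundant assembly of an array design from prioritized
# content modules, with a marker budget, MAC and region content filters,
# and a full audit log (contributed / skipped-as-duplicate / truncated
# counts per module).

#' Declare a content module for assembly
#'
#' @param label module name (e.g. "GWAS_backbone", "HLA_tags").
#' @param manifest marker manifest contributing the module's markers.
#' @param mandatory if `TRUE`, truncating this module against the budget
#'   is an error rather than a logged truncation.
#' @return list of class `array_module`.
#' @export
array_module <- function(label, manifest, mandatory = FALSE) {
  structure(list(label = label, manifest = validate_manifest(manifest),
                 mandatory = isTRUE(mandatory)),
            class = "array_module")
}

#' Assemble an array design from prioritized modules
#'
#' Modules contribute markers in priority order; a marker already present
#' (by position identity `chrom:pos:ref:alt`, or by `marker_id`) is
#' skipped, so no redundant markers are added. Contribution stops when the
#' budget is reached; remaining markers of the current and later modules
#' are logged as truncated. Truncating a mandatory module is an error.
#'
#' @param modules list of [array_module()] objects (or bare manifests,
#'   which become non-mandatory modules named module_1, module_2, ...),
#'   ordered by priority.
#' @param budget maximum marker count on the final design (default
#'   782,000, a genome-wide custom-array scale).
#' @param identity `"position"` (chrom/pos/ref/alt; falls back to id when
#'   any of those is missing) or `"id"`.
#' @return object of class `array_design`: `markers` (final manifest),
#'   `audit` (per-module contributed / skipped_duplicate / truncated),
#'   `budget`, `identity`.
#' @export
assemble_array <- function(modules, budget = 782000L,
                           identity = c("position", "id")) {
  identity <- match.arg(identity)
  if (budget < 1L) stop("budget must be >= 1")
  modules <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    if (inherits(m, "array_module")) m
    else array_module(paste0("module_", i), m)
  })
  key_of <- function(mk) {
    if (identity == "id") return(mk$marker_id)
    k <- paste(mk$chrom, mk$pos, mk$ref, mk$alt, sep = ":")
    bad <- is.na(mk$chrom) | is.na(mk$pos) | is.na(mk$ref) | is.na(mk$alt)
    k[bad] <- mk$marker_id[bad]
    k
  }
  seen <- character(0)
  final <- list()
  audit <- NULL
  for (mod in modules) {
    mk <- mod$manifest
    keys <- key_of(mk)
    dup_in <- duplicated(keys)
    dup_seen <- keys %in% seen
    new <- !dup_in & !dup_seen
    room <- budget - length(seen)
    take <- which(new)
    truncated <- 0L
    if (length(take) > room) {
      truncated <- length(take) - room
      if (mod$mandatory)
        stop("budget ", budget, " exceeded by mandatory module '",
             mod$label, "' (", truncated, " markers over)")
      take <- take[seq_len(room)]
    }
    contributed <- length(take)
    if (contributed) {
      contrib <- mk[take, , drop = FALSE]
      contrib$modules <- ifelse(is.na(contrib$modules) |
                                  contrib$modules == "",
                                mod$label,
                                paste(contrib$modules, mod$label,
                                      sep = ","))
      final[[length(final) + 1L]] <- contrib
      seen <- c(seen, keys[take])
    }
    audit <- rbind(audit, data.frame(
      module = mod$label,
      input = nrow(mk),
      contributed = contributed,
      skipped_duplicate = sum(dup_in | dup_seen),
      truncated = truncated))
  }
  cols <- Reduce(intersect, lapply(final, names)) %||%
    c("marker_id", "chrom", "pos", "ref", "alt", "modules")
  markers <- if (length(final))
    do.call(rbind, lapply(final, function(x) x[, cols, drop = FALSE]))
  else utils::head(modules[[1]]$manifest, 0)
  rownames(markers) <- NULL
  structure(list(markers = validate_manifest(markers),
                 audit = audit, budget = as.integer(budget),
                 identity = identity),
            class = "array_design")
}

#' @export
print.array_design <- function(x, ...) {
  cat("array_design:", nrow(x$markers), "markers (budget",
      x$budget, "), identity =", x$identity, "\n")
  print(x$audit, row.names = FALSE)
  invisible(x)
}

#' Minor-allele-count content filter
#'
#' Keeps markers whose reference-database MAC is strictly greater than
#' `min_mac_exclusive` (default 5, i.e. "more than five observations").
#' Markers with no reference entry are dropped and logged.
#'
#' @param manifest marker manifest.
#' @param reference_mac named integer vector, marker id to observed MAC in
#'   the reference database.
#' @param min_mac_exclusive exclusive lower bound (keep mac > this).
#' @return filtered manifest with a `filter_log` attribute
#'   (kept / dropped_low_mac / dropped_missing counts).
#' @export
mac_filter <- function(manifest, reference_mac, min_mac_exclusive = 5L) {
  mac <- reference_mac[manifest$marker_id]
  missing <- is.na(mac)
  keep <- !missing & mac > min_mac_exclusive
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- data.frame(
    kept = sum(keep),
    dropped_low_mac = sum(!missing & mac <= min_mac_exclusive),
    dropped_missing = sum(missing),
    min_mac_exclusive = min_mac_exclusive)
  out
}

#' Select manifest markers inside a genomic region
#'
#' Closed-interval position filter on the matching chromosome.
#'
#' @param manifest marker manifest.
#' @param region a [genomic_region()], e.g. [mhc_region()].
#' @return sub-manifest of markers inside the region.
#' @export
region_select <- function(manifest, region) {
  out <- manifest[in_region(manifest, region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an assembly audit log as TSV
#'
#' @param design an [assemble_array()] result.
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_assembly_audit <- function(design, path) {
  utils::write.table(design$audit, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
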