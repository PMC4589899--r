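# Cross-population greedy tag-SNP selection: each step picks the candidate
# tagging the most not-yet-covered targets summed over all populations
# simultaneously (rather than one population at a time), plus the booster
# pass that augments an existing array for common-variant coverage.

#' Per-candidate, per-population tagging sets
#'
#' Candidate `c` tags target `t` in population `p` iff `r2(c, t) >=
#' threshold` in `p`'s LD store, or `c == t` and `t` is polymorphic in `p`
#' (direct genotyping counts as r2 = 1). A marker monomorphic in a
#' population tags nothing there and is not a target there.
#'
#' @param ld_stores named list of [build_ld_store()] results, one per
#'   population.
#' @param candidates character vector of candidate marker ids.
#' @param targets target marker ids: a character vector shared by all
#'   populations, or a named list giving per-population target sets.
#' @param r2_threshold tagging threshold in (0, 1\] (default 0.8).
#' @return object of class `tagging_sets`: candidate table (id, chrom,
#'   pos, canonical order), per-population target index sets and
#'   per-candidate covered-target index/r2 lists.
#' @export
tagging_sets <- function(ld_stores, candidates, targets,
                         r2_threshold = 0.8) {
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  if (is.null(names(ld_stores)))
    names(ld_stores) <- vapply(ld_stores, `[[`, "", "population")
  pops <- names(ld_stores)
  if (!is.list(targets))
    targets <- stats::setNames(rep(list(targets), length(pops)), pops)
  target_ids <- sort(unique(unlist(targets)))
  # candidate table in canonical (pos, id) order for tie-breaking
  info <- NULL
  for (st in ld_stores) {
    hit <- st$markers$marker_id %in% candidates
    info <- rbind(info, st$markers[hit, c("marker_id", "chrom", "pos")])
  }
  info <- unique(info)
  missing <- setdiff(candidates, info$marker_id)
  if (length(missing))  # monomorphic everywhere: keep, tags nothing
    info <- rbind(info, data.frame(marker_id = missing,
                                   chrom = NA_character_,
                                   pos = .Machine$integer.max))
  info <- info[order(info$pos, info$marker_id), , drop = FALSE]
  rownames(info) <- NULL
  sets <- list(); target_idx <- list()
  for (pop in pops) {
    st <- ld_stores[[pop]]
    poly <- st$markers$marker_id
    targ_p <- intersect(targets[[pop]], poly)
    t_index <- match(targ_p, target_ids)
    names(t_index) <- targ_p
    cand_p <- intersect(candidates, poly)
    pr <- st$pairs[st$pairs$r2 >= r2_threshold, , drop = FALSE]
    # candidate->target edges: self-tagging plus both pair orientations
    self_ids <- intersect(cand_p, targ_p)
    e_cand <- c(self_ids, pr$id_i, pr$id_j)
    e_targ <- c(self_ids, pr$id_j, pr$id_i)
    e_r2 <- c(rep(1, length(self_ids)), pr$r2, pr$r2)
    keep <- e_cand %in% cand_p & e_targ %in% targ_p
    f <- factor(e_cand[keep], levels = info$marker_id)
    idx_split <- split(unname(t_index[e_targ[keep]]), f)
    r2_split <- split(e_r2[keep], f)
    sets[[pop]] <- stats::setNames(
      mapply(function(i, r) list(idx = i, r2 = r),
             idx_split, r2_split, SIMPLIFY = FALSE),
      info$marker_id)
    target_idx[[pop]] <- unname(t_index)
  }
  structure(list(populations = pops,
                 target_ids = target_ids,
                 target_idx = target_idx,
                 candidate_info = info,
                 sets = sets,
                 r2_threshold = r2_threshold),
            class = "tagging_sets")
}

#' Greedy cross-population tag-SNP selection
#'
#' Iteratively selects the candidate that covers the most not-yet-covered
#' targets summed across all populations simultaneously; stops when every
#' reachable target is covered in every population where it is polymorphic,
#' or when the budget is reached. Ties are broken by smaller genomic
#' position, then lexicographic marker id. Implemented with lazy gain
#' re-evaluation (valid because coverage gain is submodular), which is
#' exact including the tie-break order.
#'
#' @param tsets a [tagging_sets()] object.
#' @param budget maximum number of selections (`NULL` = unlimited).
#' @param preselected marker ids whose coverage is already banked (used by
#'   [booster_select()]); they consume no budget and are not re-reported.
#' @return object of class `tag_selection`: `selected` (ordered ids),
#'   `covered` (per population, `data.frame` target/tag/r2), `residual`
#'   (per population, uncovered target ids), `gain_log` (per step, newly
#'   covered counts per population).
#' @export
greedy_multipop_select <- function(tsets, budget = NULL,
                                   preselected = character()) {
  stopifnot(inherits(tsets, "tagging_sets"))
  if (!is.null(budget) && budget < 1L) stop("budget must be >= 1")
  pops <- tsets$populations
  if (!length(unlist(tsets$target_idx)))
    return(empty_selection(tsets))
  n_univ <- length(tsets$target_ids)
  cand <- tsets$candidate_info$marker_id
  uncovered <- lapply(pops, function(p) {
    u <- rep(FALSE, n_univ); u[tsets$target_idx[[p]]] <- TRUE; u
  })
  names(uncovered) <- pops
  cover_tag <- lapply(pops, function(p) character(n_univ))
  cover_r2 <- lapply(pops, function(p) rep(NA_real_, n_univ))
  names(cover_tag) <- names(cover_r2) <- pops
  bank <- function(id) {
    for (p in pops) {
      cv <- tsets$sets[[p]][[id]]
      new <- cv$idx[uncovered[[p]][cv$idx]]
      if (length(new)) {
        uncovered[[p]][new] <<- FALSE
        cover_tag[[p]][new] <<- id
        cover_r2[[p]][new] <<- cv$r2[match(new, cv$idx)]
      }
    }
  }
  for (id in preselected) if (id %in% cand) bank(id)
  gain_of <- function(id)
    sum(vapply(pops, function(p) {
      cv <- tsets$sets[[p]][[id]]
      sum(uncovered[[p]][cv$idx])
    }, numeric(1)))
  avail <- setdiff(cand, preselected)
  gains <- vapply(avail, gain_of, numeric(1))   # exact at start
  fresh <- rep(TRUE, length(avail))
  selected <- character(0)
  gain_log <- NULL
  while (length(avail) &&
         (is.null(budget) || length(selected) < budget)) {
    repeat {
      i <- which.max(gains)        # avail is in canonical order: first max
      if (fresh[i]) break
      gains[i] <- gain_of(avail[i])
      fresh[i] <- TRUE
    }
    if (gains[i] == 0) break
    id <- avail[i]
    step_gain <- vapply(pops, function(p) {
      cv <- tsets$sets[[p]][[id]]
      sum(uncovered[[p]][cv$idx])
    }, numeric(1))
    bank(id)
    selected <- c(selected, id)
    gain_log <- rbind(gain_log,
                      data.frame(rank = length(selected), marker_id = id,
                                 as.list(stats::setNames(
                                   step_gain, paste0("gain_", pops))),
                                 gain_total = sum(step_gain)))
    avail <- avail[-i]
    gains <- gains[-i]
    fresh <- rep(FALSE, length(avail))
  }
  finish_selection(tsets, selected, uncovered, cover_tag, cover_r2,
                   gain_log)
}

empty_selection <- function(tsets) {
  pops <- tsets$populations
  structure(list(
    selected = character(0),
    covered = stats::setNames(lapply(pops, function(p)
      data.frame(target = character(), tag = character(),
                 r2 = numeric())), pops),
    residual = stats::setNames(lapply(pops, function(p) character(0)),
                               pops),
    gain_log = data.frame(),
    r2_threshold = tsets$r2_threshold),
    class = "tag_selection")
}

finish_selection <- function(tsets, selected, uncovered, cover_tag,
                             cover_r2, gain_log) {
  pops <- tsets$populations
  covered <- list(); residual <- list()
  for (p in pops) {
    idx <- tsets$target_idx[[p]]
    done <- idx[!uncovered[[p]][idx]]
    covered[[p]] <- data.frame(target = tsets$target_ids[done],
                               tag = cover_tag[[p]][done],
                               r2 = cover_r2[[p]][done])
    residual[[p]] <- tsets$target_ids[idx[uncovered[[p]][idx]]]
  }
  structure(list(selected = selected,
                 covered = covered,
                 residual = residual,
                 gain_log = if (is.null(gain_log)) data.frame()
                            else gain_log,
                 r2_threshold = tsets$r2_threshold),
            class = "tag_selection")
}

#' @export
print.tag_selection <- function(x, ...) {
  cat("tag_selection:", length(x$selected), "markers selected\n")
  for (p in names(x$covered))
    cat(sprintf("  %s: %d targets covered, %d residual\n", p,
                nrow(x$covered[[p]]), length(x$residual[[p]])))
  invisible(x)
}

#' Booster selection: augment an existing array for common variants
#'
#' Targets are the common variants passing their population's MAF cutoff
#' that the existing array does not yet cover at the tagging threshold;
#' the greedy pass then picks the minimal marker set with the best added
#' coverage, reporting the incremental gain of each pick.
#'
#' @param existing_array character vector of marker ids already on the
#'   array.
#' @param ld_stores named list of [build_ld_store()] results.
#' @param maf_cutoffs named fractions per population (defaults CEU 0.02,
#'   AFR 0.05 convention): a marker is a target in population `p` iff its
#'   MAF there is strictly greater than `maf_cutoffs[[p]]`.
#' @param budget maximum boosters (`NULL` = unlimited).
#' @param r2_threshold tagging threshold (default 0.8).
#' @return a `tag_selection` of booster markers only; its `gain_log` holds
#'   the per-pick incremental coverage.
#' @export
booster_select <- function(existing_array, ld_stores,
                           maf_cutoffs = c(CEU = 0.02, AFR = 0.05),
                           budget = NULL, r2_threshold = 0.8) {
  if (is.null(names(ld_stores)))
    names(ld_stores) <- vapply(ld_stores, `[[`, "", "population")
  pops <- names(ld_stores)
  miss <- setdiff(pops, names(maf_cutoffs))
  if (length(miss))
    stop("no MAF cutoff supplied for population(s): ",
         paste(miss, collapse = ", "))
  targets <- lapply(pops, function(p) {
    mk <- ld_stores[[p]]$markers
    mk$marker_id[mk$maf > maf_cutoffs[[p]]]
  })
  names(targets) <- pops
  all_ids <- unique(unlist(lapply(ld_stores,
                                  function(s) s$markers$marker_id)))
  candidates <- union(setdiff(all_ids, existing_array),
                      intersect(existing_array, all_ids))
  tsets <- tagging_sets(ld_stores, candidates, targets, r2_threshold)
  greedy_multipop_select(tsets, budget = budget,
                         preselected = intersect(existing_array,
                                                 candidates))
}

#' Write a tag selection as TSV
#'
#' One row per pick: rank, marker id, per-population gains, cumulative
#' total coverage.
#'
#' @param selection a `tag_selection`.
#' @param path TSV file.
#' @return `path`, invisibly.
#' @export
write_tag_selection <- function(selection, path) {
  log <- selection$gain_log
  if (nrow(log)) log$cumulative <- cumsum(log$gain_total)
  utils::write.table(log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
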