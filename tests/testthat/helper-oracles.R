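# Independent oracles and fixture builders. Everything here is written
# naively (double loops, direct formulas) on purpose: these implementations
# must stay independent of the package code paths they check.

# r2 from the 2x2 haplotype table, straight from the definition
oracle_r2 <- function(x, y) {
  p1 <- mean(x)
  p2 <- mean(y)
  p11 <- mean(x == 1 & y == 1)
  D <- p11 - p1 * p2
  min(max(D^2 / (p1 * (1 - p1) * p2 * (1 - p2)), 0), 1)
}

# panel from an explicit haplotype matrix (rows = haplotypes, 2 per sample)
toy_panel <- function(H, pos = NULL, chrom = "1", populations = "ALL") {
  H <- as.matrix(H)
  m <- ncol(H)
  n <- nrow(H) / 2
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  markers <- marker_manifest(sprintf("T%03d", seq_len(m)), chrom, pos)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        population = rep_len(populations, n))
  haplotype_panel(H, markers, samples)
}

# genotype matrix from a plain matrix with default marker metadata
toy_gm <- function(G, pos = NULL, chrom = "1") {
  G <- as.matrix(G)
  if (is.null(pos)) pos <- seq_len(ncol(G)) * 1000L
  mk <- marker_manifest(sprintf("T%03d", seq_len(ncol(G))), chrom, pos)
  if (is.null(rownames(G))) rownames(G) <- sprintf("S%02d", seq_len(nrow(G)))
  genotype_matrix(G, mk)
}

# brute-force per-population tagging sets by double loop over marker pairs
oracle_tagging <- function(panel, candidates, targets, threshold,
                           window_bp) {
  mk <- panel$markers
  out <- list()
  for (pop in unique(panel$samples$population)) {
    H <- pop_haplotypes(panel, pop)
    p <- colMeans(H)
    poly <- p > 0 & p < 1
    names(poly) <- mk$marker_id
    targ_p <- targets[poly[targets]]
    sets <- list()
    for (cid in candidates) {
      if (!poly[[cid]]) {
        sets[[cid]] <- character(0)
        next
      }
      ci <- match(cid, mk$marker_id)
      s <- character(0)
      for (tid in targ_p) {
        ti <- match(tid, mk$marker_id)
        if (tid == cid) {
          s <- c(s, tid)
        } else if (mk$chrom[ci] == mk$chrom[ti] &&
                   abs(mk$pos[ci] - mk$pos[ti]) <= window_bp &&
                   oracle_r2(H[, ci], H[, ti]) >= threshold) {
          s <- c(s, tid)
        }
      }
      sets[[cid]] <- s
    }
    out[[pop]] <- list(sets = sets, targets = targ_p)
  }
  out
}

# naive full-scan greedy with (pos, id) tie-break
oracle_greedy <- function(tg, cand_df, budget = Inf) {
  uncovered <- lapply(tg, function(x) x$targets)
  ord <- order(cand_df$pos, cand_df$marker_id)
  cand <- cand_df$marker_id[ord]
  selected <- character(0)
  gain_log <- numeric(0)
  while (length(cand) && length(selected) < budget) {
    gains <- vapply(cand, function(cc)
      sum(vapply(names(tg), function(p)
        length(intersect(tg[[p]]$sets[[cc]], uncovered[[p]])),
        numeric(1))), numeric(1))
    if (max(gains) == 0) break
    best <- cand[which.max(gains)]  # first max = canonical tie-break
    gain_log <- c(gain_log, max(gains))
    for (p in names(tg))
      uncovered[[p]] <- setdiff(uncovered[[p]], tg[[p]]$sets[[best]])
    selected <- c(selected, best)
    cand <- setdiff(cand, best)
  }
  list(selected = selected,
       gain_log = gain_log,
       covered = vapply(names(tg), function(p)
         length(tg[[p]]$targets) - length(uncovered[[p]]), numeric(1)))
}

# exhaustive best coverage over all b-subsets of candidates
oracle_best_subset <- function(tg, candidates, b) {
  best <- 0
  for (cs in utils::combn(candidates, b, simplify = FALSE)) {
    cov <- sum(vapply(names(tg), function(p)
      length(unique(unlist(tg[[p]]$sets[cs]))), numeric(1)))
    best <- max(best, cov)
  }
  best
}

# a small LD-blocked two-population panel used by several suites
fixture_panel <- function(seed = 42, n_blocks = 5, markers_per_block = 10,
                          n = 30, corr = 0.9) {
  spec <- simulation_spec(
    populations = c(CEU = n, YRI = n),
    n_blocks = n_blocks, markers_per_block = markers_per_block,
    within_block_correlation = corr, seed = seed,
    n_trios = 2, n_duplicate_pairs = 5)
  simulate_panel(spec)
}
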