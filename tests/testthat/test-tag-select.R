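# Cross-population greedy selection against a naive full-scan oracle,
# plus the booster pass and the classic submodular-coverage guarantees.

two_pop_stores <- function(panel, window_bp = 250000L, ...) {
  pops <- unique(panel$samples$population)
  setNames(lapply(pops, function(p)
    build_ld_store(panel, p, window_bp = window_bp)), pops)
}

test_that("tagging sets match brute-force recomputation from haplotypes", {
  panel <- fixture_panel(seed = 61, n_blocks = 4, markers_per_block = 8)
  ids <- panel$markers$marker_id
  stores <- two_pop_stores(panel)
  ts <- tagging_sets(stores, ids, ids, r2_threshold = 0.8)
  oracle <- oracle_tagging(panel, ids, ids, 0.8, 250000L)
  for (pop in names(stores)) {
    for (cid in ids) {
      got <- sort(ts$target_ids[ts$sets[[pop]][[cid]]$idx])
      expect_equal(got, sort(oracle[[pop]]$sets[[cid]]),
                   label = paste(pop, cid))
    }
  }
})

test_that("a candidate monomorphic in a population tags nothing there", {
  # marker 3 monomorphic in pop B only
  HA <- cbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L))
  HB <- cbind(c(0L, 1L, 1L, 0L), c(0L, 1L, 1L, 0L), c(0L, 0L, 0L, 0L))
  panel <- toy_panel(rbind(HA, HB), populations = rep(c("A", "B"), each = 2))
  ids <- panel$markers$marker_id
  stores <- two_pop_stores(panel)
  ts <- tagging_sets(stores, ids, ids, r2_threshold = 0.8)
  expect_equal(length(ts$sets$B[["T003"]]$idx), 0L)
  expect_equal(length(ts$sets$A[["T003"]]$idx), 3L)
  # and it is not a target in B either: B needs only T001-T002 covered
  sel <- greedy_multipop_select(ts)
  expect_equal(length(sel$residual$B), 0L)
  expect_false("T003" %in% sel$covered$B$target)
})

test_that("threshold 1 on a perfect-copy block tags the whole block", {
  spec <- simulation_spec(populations = c(CEU = 20), n_blocks = 1,
                          markers_per_block = 5,
                          within_block_correlation = 1, fst = 0, seed = 3)
  panel <- simulate_panel(spec)
  store <- build_ld_store(panel, "CEU")
  poly <- store$markers$marker_id
  ts <- tagging_sets(list(CEU = store), poly, poly, r2_threshold = 1)
  for (cid in poly)
    expect_setequal(ts$target_ids[ts$sets$CEU[[cid]]$idx], poly)
})

test_that("trivial selections behave: self-tag only, empty targets, bad budget", {
  H <- cbind(c(0L, 1L, 0L, 1L))
  panel <- toy_panel(H)
  store <- build_ld_store(panel, "ALL")
  ts <- tagging_sets(list(ALL = store), "T001", "T001")
  sel <- greedy_multipop_select(ts)
  expect_equal(sel$selected, "T001")
  expect_equal(sel$covered$ALL$r2, 1)

  ts_empty <- tagging_sets(list(ALL = store), "T001", character(0))
  expect_equal(greedy_multipop_select(ts_empty)$selected, character(0))
  expect_error(greedy_multipop_select(ts, budget = 0), "budget")
})

test_that("greedy trace equals the naive oracle on random two-population panels", {
  for (seed in c(71, 72, 73)) {
    panel <- fixture_panel(seed = seed, n_blocks = 3,
                           markers_per_block = 6, corr = 0.8)
    ids <- panel$markers$marker_id
    stores <- two_pop_stores(panel)
    ts <- tagging_sets(stores, ids, ids, r2_threshold = 0.7)
    sel <- greedy_multipop_select(ts)
    oracle <- oracle_greedy(
      oracle_tagging(panel, ids, ids, 0.7, 250000L),
      panel$markers[, c("marker_id", "pos")])
    expect_identical(sel$selected, oracle$selected)
    expect_equal(sel$gain_log$gain_total, oracle$gain_log)
    # gain log is non-increasing (submodularity) and sums to total covered
    expect_true(all(diff(sel$gain_log$gain_total) <= 0))
    expect_equal(sum(sel$gain_log$gain_total),
                 sum(vapply(sel$covered, nrow, numeric(1))))
  }
})

test_that("unlimited budget covers every target reachable at the threshold", {
  panel <- fixture_panel(seed = 81, n_blocks = 4)
  ids <- panel$markers$marker_id
  stores <- two_pop_stores(panel)
  ts <- tagging_sets(stores, ids, ids, r2_threshold = 0.8)
  sel <- greedy_multipop_select(ts)
  # candidates = all markers and self-tagging counts, so every target
  # polymorphic in a population is reachable there
  for (pop in names(stores))
    expect_equal(sel$residual[[pop]], character(0))
  # every covered pair really meets the threshold
  for (pop in names(stores))
    expect_true(all(sel$covered[[pop]]$r2 >= 0.8))
})

test_that("selection is deterministic and duplicate-free", {
  panel <- fixture_panel(seed = 91)
  ids <- panel$markers$marker_id
  stores <- two_pop_stores(panel)
  ts <- tagging_sets(stores, ids, ids)
  s1 <- greedy_multipop_select(ts)
  s2 <- greedy_multipop_select(ts)
  expect_identical(s1$selected, s2$selected)
  expect_false(anyDuplicated(s1$selected) > 0)
})

test_that("first pick is globally optimal and coverage meets the 1-1/e bound", {
  for (seed in c(101, 102)) {
    panel <- fixture_panel(seed = seed, n_blocks = 2,
                           markers_per_block = 6, corr = 0.7)
    ids <- panel$markers$marker_id[1:12]
    stores <- two_pop_stores(panel)
    tg <- oracle_tagging(panel, ids, ids, 0.7, 250000L)
    ts <- tagging_sets(stores, ids, ids, r2_threshold = 0.7)
    for (b in c(1L, 3L)) {
      sel <- greedy_multipop_select(ts, budget = b)
      greedy_cov <- sum(vapply(sel$covered, nrow, numeric(1)))
      best <- oracle_best_subset(tg, ids, b)
      expect_gte(greedy_cov, (1 - exp(-1)) * best)
      if (b == 1L) expect_equal(greedy_cov, best)  # step 1 is optimal
    }
  }
})

test_that("booster adds nothing when the array already covers all targets", {
  panel <- fixture_panel(seed = 111)
  stores <- two_pop_stores(panel)
  boost <- booster_select(panel$markers$marker_id, stores,
                          maf_cutoffs = c(CEU = 0.05, YRI = 0.05))
  expect_equal(boost$selected, character(0))
})

test_that("booster targets respect per-population MAF cutoffs and report gains", {
  panel <- fixture_panel(seed = 112, n_blocks = 6)
  stores <- two_pop_stores(panel)
  cutoffs <- c(CEU = 0.1, YRI = 0.2)
  existing <- panel$markers$marker_id[1:5]
  boost <- booster_select(existing, stores, cutoffs)
  # no selected booster repeats the existing array
  expect_equal(intersect(boost$selected, existing), character(0))
  # every covered target passes its population cutoff
  for (pop in names(stores)) {
    mk <- stores[[pop]]$markers
    common <- mk$marker_id[mk$maf > cutoffs[[pop]]]
    expect_true(all(boost$covered[[pop]]$target %in% common))
    expect_equal(boost$residual[[pop]], character(0))
  }
  expect_true(all(diff(boost$gain_log$gain_total) <= 0))
  expect_error(booster_select(existing, stores, c(CEU = 0.1)),
               "YRI")
})

test_that("booster first pick beats any single alternative", {
  panel <- fixture_panel(seed = 113, n_blocks = 3, markers_per_block = 5)
  stores <- two_pop_stores(panel)
  cutoffs <- c(CEU = 0.05, YRI = 0.05)
  existing <- panel$markers$marker_id[1:3]
  boost <- booster_select(existing, stores, cutoffs, budget = 1)
  if (length(boost$selected)) {
    got <- sum(boost$gain_log$gain_total)
    for (alt in setdiff(panel$markers$marker_id, existing)) {
      alt_gain <- sum(vapply(names(stores), function(pop) {
        mk <- stores[[pop]]$markers
        common <- mk$marker_id[mk$maf > cutoffs[[pop]]]
        H <- pop_haplotypes(panel, pop)
        covered_by <- function(tag, targ) {
          i <- match(tag, panel$markers$marker_id)
          j <- match(targ, panel$markers$marker_id)
          tag == targ || (tag %in% mk$marker_id && targ %in% mk$marker_id &&
            abs(panel$markers$pos[i] - panel$markers$pos[j]) <= 250000L &&
            oracle_r2(H[, i], H[, j]) >= 0.8)
        }
        uncov <- Filter(function(t)
          !any(vapply(existing, covered_by, logical(1), targ = t)),
          common)
        sum(vapply(uncov, function(t) covered_by(alt, t), logical(1)))
      }, numeric(1)))
      expect_gte(got, alt_gain)
    }
  }
})

test_that("selection TSV export carries ranks, gains and cumulative coverage", {
  panel <- fixture_panel(seed = 121)
  stores <- two_pop_stores(panel)
  ids <- panel$markers$marker_id
  sel <- greedy_multipop_select(tagging_sets(stores, ids, ids))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tag_selection(sel, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab$marker_id, sel$selected)
  expect_equal(tab$cumulative[nrow(tab)],
               sum(vapply(sel$covered, nrow, numeric(1))))
})
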