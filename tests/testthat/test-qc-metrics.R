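# QC battery: Mendelian checks, P-P-C heritability, concordance
# classification and reports, INFO scoring, masked-imputation accuracy.

test_that("Mendelian incompatibility covers the canonical genotype cases", {
  # hom x hom -> het child is the textbook error; het x het allows all
  expect_equal(mendelian_errors(0L, 0L, 1L), 1L)
  expect_equal(mendelian_errors(0L, 0L, 0L), 0L)
  expect_equal(mendelian_errors(0L, 2L, 0L), 1L)   # child must be het
  expect_equal(mendelian_errors(0L, 2L, 1L), 0L)
  expect_equal(mendelian_errors(1L, 1L, 0L), 0L)
  expect_equal(mendelian_errors(1L, 1L, 1L), 0L)
  expect_equal(mendelian_errors(1L, 1L, 2L), 0L)
  expect_equal(mendelian_errors(0L, 1L, 2L), 1L)   # no alt from parent 1
  expect_equal(mendelian_errors(2L, 1L, 0L), 1L)
  expect_true(is.na(mendelian_errors(NA, 0L, 0L)))
  # exhaustive: error iff child outside the reachable offspring set
  allele_sets <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  for (f in 0:2) for (m in 0:2) for (c_ in 0:2) {
    reachable <- unique(as.vector(outer(allele_sets[[f + 1L]],
                                        allele_sets[[m + 1L]], `+`)))
    expect_equal(mendelian_errors(f, m, c_),
                 as.integer(!(c_ %in% reachable)),
                 label = sprintf("f=%d m=%d c=%d", f, m, c_))
  }
})

test_that("P-P-C heritability reproduces printed-count arithmetic", {
  expect_equal(round_half_up(ppc_heritability(3757, 767203), 2), 99.51)
  expect_equal(round_half_up(ppc_heritability(264, 767203), 2), 99.97)
  expect_equal(round_half_up(ppc_heritability(0, 767203), 2), 100)
  expect_error(ppc_heritability(-1, 100), "\\[0, total_snps\\]")
})

test_that("trio reports count errors against the fixed post-QC denominator", {
  # 2 trios x 6 markers built by hand; trio 2 has 2 errors + 1 missing site
  G <- rbind(
    dad1 = c(0L, 0L, 1L, 2L, 1L, 0L),
    mom1 = c(0L, 1L, 1L, 2L, 0L, 0L),
    kid1 = c(0L, 0L, 2L, 2L, 1L, 0L),
    dad2 = c(0L, 0L, 2L, 2L, 1L, 1L),
    mom2 = c(0L, 0L, 2L, 0L, 1L, 1L),
    kid2 = c(1L, 0L, 2L, 0L, NA, 2L))   # errors at markers 1 and 4
  gm <- toy_gm(G)
  ped <- pedigree_table(
    family_id = c("T1", "T1", "T1", "T2", "T2", "T2"),
    individual_id = rownames(G),
    father_id = c("0", "0", "dad1", "0", "0", "dad2"),
    mother_id = c("0", "0", "mom1", "0", "0", "mom2"))
  rep <- trio_report(gm, ped, total_snps = 6L)
  expect_equal(rep$error_count, c(0L, 2L))
  expect_equal(rep$snps_compared, c(6L, 5L))
  expect_equal(rep$skipped_missing, c(0L, 1L))
  expect_equal(rep$ppc_heritability, c(100, round_half_up(400 / 6, 2)))
  # exact identity on unrounded values: error rate + heritability = 1
  expect_equal(rep$error_count / 6 + rep$ppc_heritability_raw / 100,
               c(1, 1))
  # the non-missing denominator is the stricter companion metric
  expect_equal(rep$heritability_nonmissing[2], round_half_up(300 / 5, 2))
})

test_that("on synthetic trios the reported errors equal the ledger exactly", {
  panel <- fixture_panel(seed = 201, n_blocks = 6)
  trios <- simulate_trios(panel, n_trios = 4, error_rate = 0.05,
                          seed = 31)
  rep <- trio_report(trios$genotypes, trios$pedigree)
  led <- table(factor(trios$ledger$family_id, levels = rep$family_id))
  expect_equal(rep$error_count, as.integer(led))
})

test_that("concordance classification is IBS-based and symmetric", {
  expect_equal(concordance_classify(1L, 1L), "full")
  expect_equal(concordance_classify(0L, 1L), "half")
  expect_equal(concordance_classify(0L, 2L), "discordant")
  for (a in 0:2) for (b in 0:2)
    expect_equal(concordance_classify(a, b), concordance_classify(b, a))
  expect_true(is.na(concordance_classify(NA_integer_, 1L)))
})

test_that("concordance reports match hand enumeration and conserve counts", {
  # 3 samples x 4 markers; one half and one discordant mismatch
  A <- rbind(s1 = c(0L, 1L, 2L, 1L),
             s2 = c(2L, 2L, 0L, 0L),
             s3 = c(1L, 0L, 1L, 2L))
  B <- A
  B["s1", 2] <- 0L   # 1 vs 0 -> half
  B["s3", 4] <- 0L   # 2 vs 0 -> discordant
  gma <- toy_gm(A)
  gmb <- toy_gm(B)
  rep <- concordance_report(gma, gmb)
  expect_equal(rep$combinations_tested, 12L)
  expect_equal(rep$full, 10L)
  expect_equal(rep$half, 1L)
  expect_equal(rep$discordant, 1L)
  expect_equal(rep$concordance_pct, round_half_up(1000 / 12, 2))
  # identical matrices: 100% full
  same <- concordance_report(gma, gma)
  expect_equal(same$full, 12L)
  expect_equal(same$concordance_pct, 100)
  # missing genotypes leave the denominator
  Bm <- B
  Bm["s2", 1] <- NA
  repm <- concordance_report(gma, toy_gm(Bm))
  expect_equal(repm$combinations_tested, 11L)
  # full + half + discordant = tested in every stratum
  strat <- concordance_report(
    gma, gmb,
    marker_strata = c(T001 = "MHC", T002 = "MHC", T003 = "rest",
                      T004 = "rest"),
    sample_strata = c(s1 = "EUR", s2 = "EUR", s3 = "AFR"))
  expect_true(all(with(strat, full + half + discordant ==
                         combinations_tested)))
  mhc_eur <- strat[strat$snp_set == "MHC" & strat$group == "EUR", ]
  expect_equal(mhc_eur$combinations_tested, 4L)
  expect_equal(mhc_eur$half, 1L)
  # mismatched alleles refuse to compare
  mk_bad <- gmb$markers
  mk_bad$alt[1] <- "T"
  expect_error(
    concordance_report(gma, genotype_matrix(B, mk_bad)),
    "pre-harmonized")
})

test_that("INFO score follows the dosage-variance formula", {
  # certain posteriors: zero variance -> 1
  certain <- matrix(c(1, 0, 0, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(info_score(certain)$raw, 1)
  # uniform posteriors: raw -1/3, clipped 0
  unif <- matrix(1 / 3, 4, 3)
  s <- info_score(unif)
  expect_equal(s$raw, -1 / 3)
  expect_equal(s$clipped, 0)
  # all-ref posteriors: theta = 0 -> monomorphic flag
  mono <- matrix(c(1, 0, 0), 3, 3, byrow = TRUE)
  expect_true(info_score(mono)$monomorphic)
  expect_true(is.na(info_score(mono)$raw))
  expect_error(info_score(matrix(c(0.5, 0.2, 0.2), 1)), "sum to 1")
})

test_that("INFO decreases under symmetric posterior flattening", {
  gm <- panel_genotypes(fixture_panel(seed = 211))
  post <- simulate_posteriors(gm, noise = 0.1, seed = 3)
  # pick a balanced marker so INFO stays defined along the whole path
  af <- colMeans(gm$genotypes) / 2
  id <- names(which.min(abs(af - 0.5)))
  one <- post[post$marker_id == id, ]
  P <- as.matrix(one[, c("p0", "p1", "p2")])
  infos <- vapply(seq(0, 1, by = 0.2), function(lam) {
    info_score((1 - lam) * P + lam / 3)$raw
  }, numeric(1))
  expect_true(all(diff(infos) <= 1e-12))
})

test_that("masked evaluation equals the construction oracle", {
  gm <- panel_genotypes(fixture_panel(seed = 221, n_blocks = 10))
  post <- simulate_posteriors(gm, noise = 0, seed = 5)
  ev <- masked_imputation_eval(gm, post, mask_fraction = 0.1, seed = 9)
  m <- length(ev$masked_markers)
  expect_equal(m, round(0.1 * ncol(gm$genotypes)))
  # degenerate posteriors: 100% in every occupied bin and overall
  expect_equal(ev$overall_accuracy_pct, 100)
  expect_true(all(ev$bins$accuracy_pct == 100))
  # flip the best guess at k masked markers -> accuracy 100*(m-k)/m
  k <- 3L
  flipped <- post
  for (id in ev$masked_markers[seq_len(k)]) {
    rows <- flipped$marker_id == id
    tr <- gm$genotypes[flipped$sample_id[rows], id]
    wrong <- (tr + 1L) %% 3L
    oh <- matrix(0, sum(rows), 3L)
    oh[cbind(seq_len(sum(rows)), wrong + 1L)] <- 1
    flipped[rows, c("p0", "p1", "p2")] <- oh
  }
  ev2 <- masked_imputation_eval(gm, flipped, mask_fraction = 0.1,
                                seed = 9)
  expect_equal(ev2$overall_accuracy_raw, 100 * (m - k) / m,
               tolerance = 1e-9)
  # same seed -> same mask
  expect_identical(ev$masked_markers, ev2$masked_markers)
})

test_that("best-guess ties resolve to the smaller dosage", {
  G <- matrix(c(0L, 1L), 1, 2, dimnames = list("s1", NULL))
  gm <- toy_gm(G)
  post <- data.frame(marker_id = c("T001", "T002"), sample_id = "s1",
                     p0 = c(0.5, 0.2), p1 = c(0.5, 0.4), p2 = c(0, 0.4))
  ev <- masked_imputation_eval(gm, post, mask_fraction = 0.99, seed = 1)
  per <- ev$per_marker
  # T001: tie p0=p1 -> guess 0 = truth; T002: tie p1=p2 -> guess 1 = truth
  expect_equal(per$correct[per$marker_id == "T001"], 1L)
  expect_equal(per$correct[per$marker_id == "T002"], 1L)
})

test_that("percentage rounding is half-up at 2 and 3 decimals", {
  expect_equal(round_half_up(99.975, 2), 99.98)
  expect_equal(round_half_up(0.3415, 3), 0.342)
  expect_equal(round_half_up(99.515, 2), 99.52)
  expect_equal(round_half_up(-1.005, 2), -1.01)
})
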