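# Seeded generator of multi-population haplotype panels with block LD,
# trios with controlled Mendelian-error injection, duplicate pairs and
# imputation posteriors. The LD model is founder-copying within blocks:
# each block carries a small set of founder haplotypes; every haplotype
# copies one founder and redraws each site independently with probability
# (1 - within_block_correlation). Cross-block sites are independent and
# blocks are spaced further apart than any tagging window, so cross-block
# r-squared is ~0 and excluded by windowed LD stores.

#' Simulation specification
#'
#' Bundles every knob of the synthetic study in one validated object.
#' Defaults mirror a HapMap-style QC experiment: 85 samples in three
#' continental populations, eight trios (four CEU, four YRI), fifty
#' duplicate pairs, a per-site Mendelian error rate of 0.3%, a duplicate
#' corruption rate of 0.34%, 1% missingness, and 0.2% masking with mild
#' imputation noise.
#'
#' @param populations named integer vector of sample sizes per population.
#' @param n_blocks number of LD blocks.
#' @param markers_per_block markers per block.
#' @param within_block_correlation founder-copy fidelity in \[0,1\]; 1 means
#'   haplotypes are exact founder copies (intra-block r-squared of 1 at
#'   polymorphic sites), 0 means sites are independent draws.
#' @param maf_distribution either `list(type="uniform", min=, max=)` or
#'   `list(type="fixed", value=)` for the ancestral minor allele frequency.
#' @param fst drift between populations (Balding-Nichols F); 0 disables.
#' @param n_founders founder haplotypes per block (2 keeps intra-block LD
#'   perfect at full correlation).
#' @param mendelian_error_rate per-site probability of replacing a child
#'   genotype with an incompatible one.
#' @param duplicate_error_rate per-site single-allele corruption rate for
#'   duplicates.
#' @param genotype_missing_rate per-site missingness for duplicates.
#' @param imputation_noise posterior uncertainty in \[0,1\] (see
#'   [simulate_posteriors()]).
#' @param n_trios,n_duplicate_pairs trio and duplicate-pair counts.
#' @param trio_populations named integer vector allocating trios to
#'   populations (`NULL` = spread across populations with enough founders).
#' @param marker_spacing_bp,block_gap_bp physical layout of the single
#'   simulated chromosome.
#' @param seed master seed; every downstream draw is derived from it.
#' @return validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(populations = c(CEU = 48L, ASN = 24L, YRI = 13L),
                            n_blocks = 50L,
                            markers_per_block = 20L,
                            within_block_correlation = 0.95,
                            maf_distribution = list(type = "uniform",
                                                    min = 0.05, max = 0.5),
                            fst = 0.05,
                            n_founders = 2L,
                            mendelian_error_rate = 0.003,
                            duplicate_error_rate = 0.0034,
                            genotype_missing_rate = 0.01,
                            imputation_noise = 0.06,
                            n_trios = 8L,
                            n_duplicate_pairs = 50L,
                            trio_populations = NULL,
                            marker_spacing_bp = 1000L,
                            block_gap_bp = 1000000L,
                            seed = 1L) {
  if (is.null(names(populations)) || any(names(populations) == ""))
    stop("`populations` must be a named vector of sample sizes")
  if (any(populations < 1L)) stop("each population needs n_samples >= 1")
  if (n_blocks < 1L || markers_per_block < 1L)
    stop("panel must contain at least one block and one marker")
  for (r in c(within_block_correlation, fst, mendelian_error_rate,
              duplicate_error_rate, genotype_missing_rate,
              imputation_noise))
    if (!is.numeric(r) || is.na(r) || r < 0 || r > 1)
      stop("all rates/fractions must lie in [0,1]")
  if (!maf_distribution$type %in% c("uniform", "fixed"))
    stop("maf_distribution$type must be 'uniform' or 'fixed'")
  structure(list(populations = populations,
                 n_blocks = as.integer(n_blocks),
                 markers_per_block = as.integer(markers_per_block),
                 within_block_correlation = within_block_correlation,
                 maf_distribution = maf_distribution,
                 fst = fst,
                 n_founders = as.integer(n_founders),
                 mendelian_error_rate = mendelian_error_rate,
                 duplicate_error_rate = duplicate_error_rate,
                 genotype_missing_rate = genotype_missing_rate,
                 imputation_noise = imputation_noise,
                 n_trios = as.integer(n_trios),
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 trio_populations = trio_populations,
                 marker_spacing_bp = as.integer(marker_spacing_bp),
                 block_gap_bp = as.integer(block_gap_bp),
                 seed = seed),
            class = "simulation_spec")
}

#' Simulate a multi-population haplotype panel
#'
#' @param spec a [simulation_spec()].
#' @return a [haplotype_panel()] whose manifest carries realized
#'   per-population `maf_<POP>` / `mac_<POP>` columns and a `block` column.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  local_seed(derive_seed(spec$seed, 1), {
    pops <- names(spec$populations)
    n_hap <- 2L * as.integer(spec$populations)
    total_hap <- sum(n_hap)
    m <- spec$n_blocks * spec$markers_per_block
    H <- matrix(0L, total_hap, m)
    corr <- spec$within_block_correlation
    draw_maf <- function(k) {
      md <- spec$maf_distribution
      if (md$type == "fixed") rep(md$value, k)
      else stats::runif(k, md$min, md$max)
    }
    hap_row_offsets <- c(0L, cumsum(n_hap))
    for (b in seq_len(spec$n_blocks)) {
      cols <- (b - 1L) * spec$markers_per_block +
        seq_len(spec$markers_per_block)
      p_anc <- draw_maf(spec$markers_per_block)
      founders <- matrix(
        stats::rbinom(spec$n_founders * length(cols), 1L,
                      rep(p_anc, each = spec$n_founders)),
        nrow = spec$n_founders)
      w <- stats::rgamma(spec$n_founders, 1)
      for (k in seq_along(pops)) {
        nh <- n_hap[k]
        rows <- hap_row_offsets[k] + seq_len(nh)
        p_pop <- if (spec$fst > 0) {
          f <- spec$fst
          stats::rbeta(length(cols), p_anc * (1 - f) / f,
                       (1 - p_anc) * (1 - f) / f)
        } else p_anc
        fidx <- sample.int(spec$n_founders, nh, replace = TRUE,
                           prob = w / sum(w))
        base <- founders[fidx, , drop = FALSE]
        copy <- matrix(stats::runif(nh * length(cols)) < corr,
                       nh, length(cols))
        noise <- matrix(stats::rbinom(nh * length(cols), 1L,
                                      rep(p_pop, each = nh)),
                        nh, length(cols))
        H[rows, cols] <- ifelse(copy, base, noise)
      }
    }
    block <- rep(seq_len(spec$n_blocks), each = spec$markers_per_block)
    within <- rep(seq_len(spec$markers_per_block), spec$n_blocks)
    pos <- (block - 1L) * spec$block_gap_bp +
      (within - 1L) * spec$marker_spacing_bp + 1L
    ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    markers <- marker_manifest(sprintf("M%05d", seq_len(m)), "1", pos,
                               ref, alt, modules = "core",
                               block = block)
    samples <- data.frame(
      sample_id = unlist(lapply(seq_along(pops), function(k)
        sprintf("%s%03d", pops[k], seq_len(spec$populations[k])))),
      population = rep(pops, as.integer(spec$populations)))
    panel <- haplotype_panel(H, markers, samples)
    panel$markers <- add_realized_frequencies(panel)
    panel
  })
}

# append realized per-population maf_/mac_ columns to the manifest
add_realized_frequencies <- function(panel) {
  mk <- panel$markers
  for (pop in unique(panel$samples$population)) {
    Hp <- pop_haplotypes(panel, pop)
    cnt <- colSums(Hp)
    n2 <- nrow(Hp)
    af <- cnt / n2
    mk[[paste0("maf_", pop)]] <- pmin(af, 1 - af)
    mk[[paste0("mac_", pop)]] <- as.integer(pmin(cnt, n2 - cnt))
  }
  mk
}

#' Simulate trios from panel founders, with Mendelian-error injection
#'
#' Each child receives one transmitted haplotype per parent; transmission
#' is block-wise (a random parental haplotype per LD block, i.e. free
#' recombination between blocks, none within). After transmission each
#' child genotype is replaced, with probability `error_rate`, by a
#' uniformly chosen genotype that is Mendelian-incompatible with the
#' parental pair; sites where every genotype is compatible (both parents
#' heterozygous) are skipped. The returned ledger records every injected
#' error and is an exact oracle for downstream Mendelian-error counts.
#'
#' @param panel a [haplotype_panel()] whose manifest has a `block` column
#'   (as produced by [simulate_panel()]; absent, each marker is its own
#'   block).
#' @param n_trios number of parent-parent-child trios.
#' @param error_rate per-site injection probability.
#' @param seed integer seed.
#' @param populations named integer vector allocating trios to populations;
#'   `NULL` spreads them across panel populations with enough founders.
#' @return list with `genotypes` (a [genotype_matrix()] of parents and
#'   children), `pedigree` (a [pedigree_table()]), and `ledger`
#'   (`data.frame`: family_id, child_id, marker_id, original, injected).
#' @export
simulate_trios <- function(panel, n_trios = 8L, error_rate = 0.003,
                           seed = 1L, populations = NULL) {
  stop_if_not_fraction(error_rate, "error_rate")
  local_seed(derive_seed(seed, 2), {
    alloc <- allocate_trios(panel, n_trios, populations)
    block <- panel$markers$block %||% seq_len(nrow(panel$markers))
    m <- nrow(panel$markers)
    H <- panel$haplotypes
    sample_ids <- panel$samples$sample_id
    geno <- list(); meta <- list(); ped <- list(); ledger <- list()
    used <- character(0)
    fid_n <- 0L
    for (pop in names(alloc)) {
      pool <- setdiff(sample_ids[panel$samples$population == pop], used)
      chosen <- sample(pool, 2L * alloc[[pop]])
      used <- c(used, chosen)
      for (t in seq_len(alloc[[pop]])) {
        fid_n <- fid_n + 1L
        fid <- sprintf("F%03d", fid_n)
        fa <- chosen[2L * t - 1L]; mo <- chosen[2L * t]
        ch <- paste0(fid, "_child")
        gf <- trio_member_genotypes(H, sample_ids, fa)
        gm_ <- trio_member_genotypes(H, sample_ids, mo)
        gc_ <- transmit(H, sample_ids, fa, block) +
               transmit(H, sample_ids, mo, block)
        inj <- inject_mendelian_errors(gf, gm_, gc_, error_rate,
                                       panel$markers$marker_id, fid, ch)
        gc_ <- inj$child
        ledger[[fid]] <- inj$ledger
        geno[[fa]] <- gf; geno[[mo]] <- gm_; geno[[ch]] <- gc_
        meta[[fid]] <- data.frame(
          sample_id = c(fa, mo, ch), population = pop, family_id = fid,
          father_id = c("0", "0", fa), mother_id = c("0", "0", mo),
          sex = c(1L, 2L, 0L), role = c("father", "mother", "child"))
        ped[[fid]] <- pedigree_table(
          family_id = fid, individual_id = c(fa, mo, ch),
          father_id = c("0", "0", fa), mother_id = c("0", "0", mo),
          sex = c(1L, 2L, 0L))
      }
    }
    samples <- do.call(rbind, meta)
    G <- do.call(rbind, geno[samples$sample_id])
    rownames(G) <- samples$sample_id
    pedigree <- do.call(rbind, ped)
    class(pedigree) <- c("pedigree_table", "data.frame")
    led <- do.call(rbind, ledger)
    if (is.null(led))
      led <- data.frame(family_id = character(), child_id = character(),
                        marker_id = character(), original = integer(),
                        injected = integer())
    rownames(led) <- NULL
    list(genotypes = genotype_matrix(G, panel$markers, samples),
         pedigree = pedigree, ledger = led)
  })
}

allocate_trios <- function(panel, n_trios, populations) {
  sizes <- table(panel$samples$population)
  if (is.null(populations)) {
    # spread trios over populations with spare founders, largest first
    alloc <- stats::setNames(rep(0L, length(sizes)), names(sizes))
    ordered <- names(sort(sizes, decreasing = TRUE))
    left <- n_trios
    while (left > 0L) {
      placed <- FALSE
      for (pop in ordered) {
        if (left == 0L) break
        if (2L * (alloc[[pop]] + 1L) <= sizes[[pop]]) {
          alloc[[pop]] <- alloc[[pop]] + 1L
          left <- left - 1L
          placed <- TRUE
        }
      }
      if (!placed) stop("not enough founder samples for ", n_trios,
                        " trios")
    }
    as.list(alloc[alloc > 0L])
  } else {
    for (pop in names(populations)) {
      if (!pop %in% names(sizes)) stop("population ", pop, " not in panel")
      if (sizes[[pop]] < 2L * populations[[pop]])
        stop("population ", pop, " has ", sizes[[pop]],
             " samples; needs >= ", 2L * populations[[pop]],
             " founders for ", populations[[pop]], " trios")
    }
    as.list(populations)
  }
}

trio_member_genotypes <- function(H, sample_ids, id) {
  i <- 2L * match(id, sample_ids) - 1L
  H[i, ] + H[i + 1L, ]
}

# one transmitted haplotype: per block pick one of the parent's two strands
transmit <- function(H, sample_ids, id, block) {
  i <- 2L * match(id, sample_ids) - 1L
  blocks <- unique(block)
  pick <- sample(c(0L, 1L), length(blocks), replace = TRUE)
  strand <- pick[match(block, blocks)]          # per-marker 0/1
  ifelse(strand == 0L, H[i, ], H[i + 1L, ])
}

compatible_children <- function(gf, gm) {
  fa <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  unique(as.vector(outer(fa[[as.character(gf)]],
                         fa[[as.character(gm)]], `+`)))
}

inject_mendelian_errors <- function(gf, gm, gc, rate, marker_ids,
                                    fid, child_id) {
  ledger <- data.frame(family_id = character(), child_id = character(),
                       marker_id = character(), original = integer(),
                       injected = integer())
  if (rate > 0) {
    hit <- which(stats::runif(length(gc)) < rate)
    skipped <- 0L
    for (s in hit) {
      incompat <- setdiff(0:2, compatible_children(gf[s], gm[s]))
      if (!length(incompat)) { skipped <- skipped + 1L; next }
      new <- if (length(incompat) == 1L) incompat else sample(incompat, 1L)
      ledger <- rbind(ledger, data.frame(
        family_id = fid, child_id = child_id, marker_id = marker_ids[s],
        original = gc[s], injected = new))
      gc[s] <- new
    }
    if (skipped > 0L)
      warning(skipped, " error site(s) skipped in ", fid,
              ": both parents heterozygous, no incompatible genotype")
  }
  list(child = gc, ledger = ledger)
}

#' Simulate duplicate sample pairs with controlled corruption
#'
#' Each chosen sample gets a duplicate whose genotypes are independently
#' corrupted per site: with probability `error_rate` a single-allele change
#' (0 to 1, 2 to 1, 1 to 0 or 2), and with probability `missing_rate` set to
#' missing. Corrupted sites are therefore half-concordant with the original,
#' so the expected non-fully-concordant fraction among compared sites equals
#' `error_rate`.
#'
#' @param gm a [genotype_matrix()].
#' @param pairs number of duplicate pairs to create.
#' @param error_rate,missing_rate per-site corruption and missingness.
#' @param seed integer seed.
#' @param exclude sample ids ineligible for duplication (e.g. trio
#'   founders, to keep QC fixtures unconfounded).
#' @return list with `genotypes` (originals plus `<id>_dup` samples) and
#'   `pairs` (`data.frame`: sample_id, duplicate_id).
#' @export
simulate_duplicates <- function(gm, pairs = 50L, error_rate = 0.0034,
                                missing_rate = 0.01, seed = 1L,
                                exclude = character()) {
  stop_if_not_fraction(error_rate, "error_rate")
  stop_if_not_fraction(missing_rate, "missing_rate")
  local_seed(derive_seed(seed, 3), {
    eligible <- setdiff(gm$samples$sample_id, exclude)
    if (length(eligible) < pairs)
      stop("only ", length(eligible), " eligible samples for ",
           pairs, " duplicate pairs")
    chosen <- sample(eligible, pairs)
    m <- ncol(gm$genotypes)
    dup <- matrix(NA_integer_, pairs, m)
    for (i in seq_len(pairs)) {
      g <- gm$genotypes[chosen[i], ]
      err <- stats::runif(m) < error_rate & !is.na(g)
      if (any(err)) {
        g[err] <- ifelse(g[err] == 1L,
                         sample(c(0L, 2L), sum(err), replace = TRUE),
                         1L)
      }
      g[stats::runif(m) < missing_rate] <- NA_integer_
      dup[i, ] <- g
    }
    rownames(dup) <- paste0(chosen, "_dup")
    G <- rbind(gm$genotypes, dup)
    samples <- rbind(
      gm$samples[, "sample_id", drop = FALSE],
      data.frame(sample_id = rownames(dup)))
    list(genotypes = genotype_matrix(G, gm$markers, samples),
         pairs = data.frame(sample_id = chosen,
                            duplicate_id = paste0(chosen, "_dup")))
  })
}

#' Simulate imputation posteriors around a truth matrix
#'
#' For each non-missing genotype, a point-mass genotype is kept with
#' probability `1 - noise` or resampled from Hardy-Weinberg at the
#' marker's alt-allele frequency with probability `noise`; the posterior
#' is then `(1-noise) * onehot + noise * uniform`. `noise = 0` gives
#' degenerate posteriors on the truth (INFO 1 at polymorphic sites);
#' `noise = 1` gives uniform posteriors; best-guess concordance with the
#' truth decays monotonically in between.
#'
#' @param gm truth [genotype_matrix()].
#' @param noise fraction in \[0,1\].
#' @param seed integer seed.
#' @return posterior `data.frame` (marker_id, sample_id, p0, p1, p2).
#' @export
simulate_posteriors <- function(gm, noise = 0.06, seed = 1L) {
  stop_if_not_fraction(noise, "noise")
  local_seed(derive_seed(seed, 4), {
    G <- gm$genotypes
    af <- colMeans(G, na.rm = TRUE) / 2
    idx <- which(!is.na(G), arr.ind = TRUE)
    g <- G[idx]
    p <- af[idx[, 2L]]
    resample <- stats::runif(length(g)) < noise
    hw <- stats::rbinom(length(g), 2L, p)
    gstar <- ifelse(resample, hw, g)
    onehot <- matrix(0, length(g), 3L)
    onehot[cbind(seq_along(g), gstar + 1L)] <- 1
    post <- (1 - noise) * onehot + noise / 3
    data.frame(marker_id = colnames(G)[idx[, 2L]],
               sample_id = rownames(G)[idx[, 1L]],
               p0 = post[, 1L], p1 = post[, 2L], p2 = post[, 3L])
  })
}

#' Run the whole synthetic study
#'
#' Convenience wrapper chaining [simulate_panel()], [simulate_trios()],
#' [simulate_duplicates()] (on panel samples, trio founders excluded) and
#' [simulate_posteriors()] under one master seed.
#'
#' @param spec a [simulation_spec()].
#' @return list: `panel`, `trios`, `duplicates`, `posteriors`.
#' @export
simulate_study <- function(spec) {
  panel <- simulate_panel(spec)
  trios <- simulate_trios(panel, spec$n_trios,
                          spec$mendelian_error_rate, seed = spec$seed,
                          populations = spec$trio_populations)
  founders <- with(trios$pedigree,
                   unique(c(father_id, mother_id)))
  gm <- panel_genotypes(panel)
  dups <- simulate_duplicates(gm, spec$n_duplicate_pairs,
                              spec$duplicate_error_rate,
                              spec$genotype_missing_rate,
                              seed = spec$seed,
                              exclude = setdiff(founders, "0"))
  post <- simulate_posteriors(gm, spec$imputation_noise, seed = spec$seed)
  list(panel = panel, trios = trios, duplicates = dups, posteriors = post)
}
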