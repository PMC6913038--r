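test_that("population bookkeeping: sizes, determinism, haplotype sums", {
  cfg <- sim_config(n_sires = 2, progeny_per_sire = 20, n_chip_loci = 60,
                    block_markers = 10, n_sequenced_sires = 2,
                    n_sequenced_ancestors = 0, seed = 11)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$pedigree), 42L)          # 2 sires + 40 heifers
  expect_equal(sum(is.na(pop$pedigree$sire_id)), 2L)

  pop2 <- simulate_population(cfg)
  expect_identical(pop, pop2)                    # same seed, same bytes

  # chip dosage of every founder equals the sum of its two haplotypes
  for (id in names(pop$truth$sire_haplotypes)) {
    expect_equal(unname(pop$genotypes$dosages[id, ]),
                 unname(colSums(pop$truth$sire_haplotypes[[id]])))
  }
})

test_that("paternal block alleles are transmitted 50/50 and intact", {
  cfg <- sim_config(n_sires = 1, progeny_per_sire = 200, n_chip_loci = 60,
                    block_markers = 10, n_sequenced_sires = 1,
                    n_sequenced_ancestors = 0, seed = 5)
  pop <- simulate_population(cfg)
  side <- pop$truth$offspring_paternal_side[, 1L]
  freq <- mean(side == 1L)
  se <- sqrt(0.25 / 200)
  expect_lt(abs(freq - 0.5), 3 * se)             # binomial oracle

  # no intra-block recombination: offspring dosage minus transmitted
  # haplotype is itself a founder-pool haplotype at every block locus
  idx <- pop$truth$block_idx[[1L]]
  pool <- pop$truth$pools[[1L]]$seqs
  hs <- pop$truth$sire_haplotypes[["S01"]]
  kids <- rownames(pop$truth$offspring_paternal_side)
  for (o in kids[1:25]) {
    pat <- hs[side[[o]], idx]
    res <- pop$genotypes$dosages[o, idx] - pat
    expect_true(all(res %in% c(0L, 1L)))
    key <- paste(res, collapse = "")
    expect_true(key %in% apply(pool, 1L, paste, collapse = ""))
  }
})

test_that("founder allele frequencies track their target MAF", {
  cfg <- sim_config(n_sires = 6, progeny_per_sire = 2, n_chip_loci = 200,
                    block_markers = 10, n_sequenced_ancestors = 60,
                    seed = 3)
  pop <- simulate_population(cfg)
  founders <- names(pop$truth$sire_haplotypes)
  bg <- setdiff(seq_len(200), pop$truth$block_idx[[1L]])
  emp <- colMeans(pop$genotypes$dosages[founders, bg]) / 2
  n_copies <- 2 * length(founders)
  se <- sqrt(pmax(emp * (1 - emp), 0.25 * emp == 0) / n_copies)
  lo <- 0.1 - 3 * se; hi <- 0.5 + 3 * se
  expect_true(all(emp >= lo & emp <= hi))
  expect_gt(cor(emp, pop$truth$maf[bg]), 0.8)
})

test_that("liability model: prevalence, QTN group contrast, degenerate noise", {
  # all effects zero, threshold zero: prevalence 1/2
  cfg0 <- sim_config(n_sires = 10, progeny_per_sire = 200,
                     n_chip_loci = 60, block_markers = 10,
                     qtn_effect_liability = 0, polygenic_variance = 0,
                     cg_sd = 0, age_beta = 0, hp_threshold = 0,
                     n_sequenced_sires = 6, n_sequenced_ancestors = 0,
                     seed = 21)
  pop0 <- simulate_population(cfg0)
  ph0 <- simulate_phenotypes(pop0$truth, pop0$pedigree, cfg0)
  n <- nrow(ph0)
  expect_equal(n, 2000L)
  expect_lt(abs(mean(ph0$hp) - 0.5), 3 * sqrt(0.25 / n))

  # planted 1-SD QTN: liability gap between paternal carrier and
  # non-carrier gametes approximates the effect (group-means oracle)
  cfg1 <- sim_config(n_sires = 10, progeny_per_sire = 200,
                     n_chip_loci = 60, block_markers = 10,
                     qtn_effect_liability = 1.0, cg_sd = 0, age_beta = 0,
                     n_sequenced_sires = 6, n_sequenced_ancestors = 0,
                     seed = 22)
  pop1 <- simulate_population(cfg1)
  ph1 <- simulate_phenotypes(pop1$truth, pop1$pedigree, cfg1)
  liab <- attr(ph1, "liability")
  carriers <- pop1$truth$qtn$carriers[[1L]]
  ids <- rownames(pop1$truth$offspring_paternal_pool)
  pat_car <- pop1$truth$offspring_paternal_pool[, 1L] %in% carriers
  # condition on the maternal side by subtracting its QTN contribution
  mat_car <- pop1$truth$offspring_maternal_pool[, 1L] %in% carriers
  adj <- liab[ids] - as.numeric(mat_car)
  gap <- mean(adj[pat_car]) - mean(adj[!pat_car])
  v <- var(adj[pat_car]) / sum(pat_car) + var(adj[!pat_car]) / sum(!pat_car)
  expect_lt(abs(gap - 1.0), 3 * sqrt(v))

  # zero noise: outcome is a deterministic function of dosage and fixed
  # effects
  cfg2 <- sim_config(n_sires = 2, progeny_per_sire = 30, n_chip_loci = 60,
                     block_markers = 10, residual_variance = 0,
                     polygenic_variance = 0, n_sequenced_sires = 2,
                     n_sequenced_ancestors = 0, seed = 23)
  pop2 <- simulate_population(cfg2)
  ph2 <- simulate_phenotypes(pop2$truth, pop2$pedigree, cfg2)
  off <- pop2$pedigree[!is.na(pop2$pedigree$sire_id), ]
  cg <- paste(off$herd, off$birth_year, sep = "_")
  lhat <- pop2$truth$cg_effects[cg] +
    cfg2$age_beta * (off$age_at_ai - mean(off$age_at_ai)) +
    pop2$truth$offspring_qtn_dosage[off$animal_id, 1L] *
      cfg2$qtn_effect_liability
  expect_equal(ph2$hp, as.integer(lhat > cfg2$hp_threshold))
})

test_that("sequence panel: QTN dosages, discordance, decoy toggle", {
  st <- fixture_study()
  cfg <- fixture_cfg()
  cls <- attr(st$sequence, "variant_class")
  qtn_row <- which(cls == "qtn")
  zyg <- st$truth$sire_qtn_zygosity[, 1L]
  sires <- sprintf("S%02d", seq_len(cfg$n_sequenced_sires))
  # a truth-heterozygous sire carries QTN dosage 1 by construction
  expect_equal(unname(st$sequence$dosage[qtn_row, sires]),
               unname(zyg[sires]))

  # discordant variants: some pair of copies of one founder allele differs
  hp <- attr(st$sequence, "hap_presence")
  panel <- colnames(st$sequence$dosage)
  copies <- cbind(st$truth$sire_pool[panel, 1L, 1L],
                  st$truth$sire_pool[panel, 2L, 1L])
  for (v in which(cls == "discordant")) {
    pres <- hp[[v]]
    disc <- FALSE
    for (k in unique(as.vector(copies))) {
      vals <- pres[copies == k]
      if (length(unique(vals)) > 1L) disc <- TRUE
    }
    expect_true(disc)
  }
  # and concordant ones never do
  for (v in which(cls %in% c("qtn", "concordant"))) {
    pres <- hp[[v]]
    for (k in unique(as.vector(copies))) {
      expect_length(unique(pres[copies == k]), 1L)
    }
  }

  cfg0 <- sim_config(prop_concordant_decoys = 0, seed = 9)
  pop0 <- simulate_population(cfg0)
  vs0 <- simulate_sequence_panel(pop0$truth, cfg0)
  expect_setequal(unique(attr(vs0, "variant_class")),
                  c("qtn", "discordant"))
})

test_that("truth records survive a JSON round-trip", {
  st <- fixture_study()
  path <- tempfile(fileext = ".json")
  write_truth(st$truth, path)
  back <- read_truth(path)
  expect_equal(back$qtn$pos, st$truth$qtn$pos)
  expect_equal(unname(back$sire_qtn_zygosity),
               unname(st$truth$sire_qtn_zygosity), ignore_attr = TRUE)
  expect_equal(back$pools[[1L]]$seqs, st$truth$pools[[1L]]$seqs,
               ignore_attr = TRUE)
  expect_equal(back$cg_effects, st$truth$cg_effects)
  expect_equal(unname(back$sire_haplotypes[["S01"]]),
               unname(st$truth$sire_haplotypes[["S01"]]), ignore_attr = TRUE)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(seed = 1, maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(seed = 1, n_sequenced_sires = 99), "n_sequenced")
  expect_error(sim_config(seed = 1, n_chip_loci = 5), "smaller than")
  expect_error(sim_config(), "seed is mandatory")
})
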