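test_that("haploblock definition selects members by inclusive containment", {
  map <- data.frame(chrom = "5",
                    pos = c(70420628L, 71000000L, 74518588L, 80000000L),
                    ref = "A", alt = "B")
  regions <- data.frame(trait = "HP", chrom = "5",
                        start_bp = 70420628L, end_bp = 74518588L)
  b <- define_haploblocks(map, regions)[[1L]]
  expect_equal(length(b$markers), 3L)            # both ends inclusive

  one <- define_haploblocks(map, data.frame(
    trait = "HP", chrom = "5", start_bp = 71000000L,
    end_bp = 71000000L))[[1L]]
  expect_equal(length(one$markers), 1L)          # start == end at a marker

  expect_error(define_haploblocks(map, data.frame(
    trait = "HP", chrom = "5", start_bp = 1L, end_bp = 2L)),
    "contains no markers")
})

test_that("block widths in Mb match the published geometry", {
  tab <- qtl_block_table()
  w <- block_width_mb(tab)
  expect_equal(w[tab$chrom == "5"], 4.10)
  expect_equal(w[tab$chrom == "8"], 3.50)
  expect_equal(block_width_mb(data.frame(start_bp = 5L, end_bp = 5L)), 0)
})

test_that("homozygous sires phase trivially; linkage resolves heterozygous loci", {
  # forced: homozygous across the block
  dos <- rbind(S = c(0L, 2L, 2L, 0L),
               k1 = c(0L, 1L, 2L, 1L), k2 = c(1L, 2L, 1L, 0L),
               k3 = c(0L, 1L, 1L, 1L))
  g <- make_gm(dos)
  ped <- data.frame(animal_id = rownames(dos),
                    sire_id = c(NA, "S", "S", "S"), dam_id = NA,
                    herd = "H", birth_year = 2016L, age_at_ai = 15)
  blocks <- define_haploblocks(g$map, data.frame(
    trait = "HP", chrom = "1", start_bp = 1L, end_bp = 1e6))
  ph <- phase_sire_blocks(g, ped, blocks, min_progeny = 3)
  hp <- ph[[1L]][["S"]]
  expect_equal(unname(hp[1L, ]), c(0L, 1L, 1L, 0L))
  expect_equal(hp[1L, ], hp[2L, ])

  # four-animal hand example: sire double-heterozygote, progeny dosages
  # 0/0 and 2/2 pin the two paternal gametes in coupling phase
  dos2 <- rbind(S = c(1L, 1L),
                k1 = c(0L, 0L), k2 = c(0L, 0L),
                k3 = c(2L, 2L), k4 = c(2L, 2L))
  g2 <- make_gm(dos2)
  ped2 <- data.frame(animal_id = rownames(dos2),
                     sire_id = c(NA, rep("S", 4)), dam_id = NA,
                     herd = "H", birth_year = 2016L, age_at_ai = 15)
  blocks2 <- define_haploblocks(g2$map, data.frame(
    trait = "HP", chrom = "1", start_bp = 1L, end_bp = 1e6))
  hp2 <- phase_sire_blocks(g2, ped2, blocks2)[[1L]][["S"]]
  pair <- list(unname(hp2[1L, ]), unname(hp2[2L, ]))
  expect_true(list(c(1L, 1L)) %in% pair && list(c(0L, 0L)) %in% pair)
})

test_that("half-sib phasing recovers simulator truth at 20 progeny per sire", {
  cfg <- sim_config(n_sires = 100, progeny_per_sire = 20, n_chip_loci = 40,
                    block_markers = 20, n_sequenced_sires = 6,
                    n_sequenced_ancestors = 0, seed = 77)
  pop <- simulate_population(cfg)
  regions <- data.frame(trait = "HP", chrom = pop$truth$blocks$chrom,
                        start_bp = pop$truth$blocks$start_bp,
                        end_bp = pop$truth$blocks$end_bp)
  blocks <- define_haploblocks(pop$genotypes$map, regions)
  ph <- phase_sire_blocks(pop$genotypes, pop$pedigree, blocks)
  idx <- blocks[[1L]]$markers
  hits <- 0L
  sires <- names(ph[[1L]])
  for (s in sires) {
    est <- ph[[1L]][[s]]
    tr <- pop$truth$sire_haplotypes[[s]][, idx]
    same <- identical(unname(est[1L, ]), unname(tr[1L, ])) &&
      identical(unname(est[2L, ]), unname(tr[2L, ]))
    flip <- identical(unname(est[1L, ]), unname(tr[2L, ])) &&
      identical(unname(est[2L, ]), unname(tr[1L, ]))
    if (same || flip) hits <- hits + 1L
  }
  expect_gte(hits / length(sires), 0.99)
})

test_that("paternal allele assignment distinguishes match, mismatch, ambiguity", {
  hA <- c(1L, 0L, 1L); hB <- c(0L, 1L, 0L)
  pair <- rbind(hA, hB)
  # offspring = hA + hA: consistent with hA; also with hB only if the
  # residue stays in {0,1}, which it does not here
  expect_equal(assign_paternal_allele(hA + hA, pair)$which, 1L)
  # dosage 2 where both paternal alleles carry 0: impossible transmission
  expect_equal(assign_paternal_allele(c(2L, 2L, 2L),
                                      rbind(c(0L, 0L, 0L), c(0L, 1L, 0L)))$status,
               "mismatch")
  # maternal copy equal to the other paternal allele: both fit
  expect_equal(assign_paternal_allele(hA + hB, pair)$status, "ambiguous")

  # simulator truth: unambiguous verdicts equal the transmitted haplotype
  st <- fixture_study()
  blocks <- fixture_blocks()
  idx <- blocks[[1L]]$markers
  checked <- 0L
  for (o in head(names(st$truth$offspring_sire), 80)) {
    s <- st$truth$offspring_sire[[o]]
    tr_pair <- st$truth$sire_haplotypes[[s]][, idx]
    asn <- assign_paternal_allele(st$genotypes$dosages[o, idx], tr_pair)
    if (asn$status == "assigned" &&
        !identical(unname(tr_pair[1L, ]), unname(tr_pair[2L, ]))) {
      expect_equal(asn$which, unname(st$truth$offspring_paternal_side[o, 1L]))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("allele catalog filters rare alleles at the three-offspring rule", {
  st <- fixture_study()
  blocks <- fixture_blocks()
  ph <- phase_sire_blocks(st$genotypes, st$pedigree, blocks)
  cat0 <- build_allele_catalog(ph, blocks, st$genotypes, st$pedigree)

  # error-free genotypes: no mismatches at all
  expect_equal(sum(cat0$assignments$status == "mismatch"), 0L)

  cat3 <- filter_alleles(cat0, min_offspring = 3)
  a <- cat3$assignments
  key <- paste(a$block, a$sire, a$label)
  cnt <- table(key[a$status == "assigned"])
  # retained iff the (sire, allele) family has >= 3 daughters
  for (k in names(cnt)) {
    rows <- which(key == k & a$status == "assigned")
    expect_equal(unique(a$usable[rows]), unname(cnt[k]) >= 3L)
  }
  # boundary: a count of exactly min_offspring survives
  cat_hi <- filter_alleles(cat0, min_offspring = min(cnt))
  expect_true(all(cat_hi$counts$n >= min(cnt)))
})

test_that("design matrix H respects dosage bookkeeping", {
  st <- fixture_study()
  blocks <- fixture_blocks()
  phx <- phase_sire_blocks(st$genotypes, st$pedigree, blocks)
  cat3 <- filter_alleles(
    build_allele_catalog(phx, blocks, st$genotypes, st$pedigree), 3)
  bn <- names(blocks)[1L]
  animals <- st$phenotypes$animal_id
  H <- build_design(cat3, bn, st$genotypes, animals)

  expect_true(all(rowSums(H) <= 2L))
  assigned <- !(animals %in% attr(H, "unassigned"))
  expect_true(all(rowSums(H)[assigned] >= 1L))

  # paternal contributions alone reproduce the catalog counts
  usable <- cat3$assignments[cat3$assignments$block == bn &
                               cat3$assignments$usable, ]
  pat_counts <- table(factor(usable$label, levels = colnames(H)))
  expect_true(all(colSums(H) >= as.integer(pat_counts)))

  # an offspring whose maternal block copy equals the paternal one is a
  # homozygote: its row carries a 2 in that allele's column
  hom <- names(which(st$truth$offspring_paternal_pool[, 1L] ==
                       st$truth$offspring_maternal_pool[, 1L]))
  hom <- intersect(hom, animals[assigned])
  if (length(hom)) {
    expect_true(all(apply(H[hom, , drop = FALSE], 1L, max) == 2L))
  }
})
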