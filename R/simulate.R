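# Half-sib population simulator with planted QTN. Emulates the study design
# the analysis assumes: sires carry two phased haplotypes per haploblock,
# each daughter inherits one paternal block haplotype intact (no intra-block
# recombination) plus a maternal haplotype drawn from a founder pool, and a
# binary liability trait and a count trait are each driven by a QTN residing
# on specific haplotype alleles of its block.

#' Simulation configuration
#'
#' Validates and returns the knob set for the half-sib simulator. All draws
#' are reproducible from `seed`: the population, phenotype and sequence-panel
#' generators use `seed`, `seed + 1` and `seed + 2` respectively so each stage
#' is independently re-runnable.
#'
#' @param n_sires number of sires.
#' @param progeny_per_sire daughters per sire.
#' @param n_chip_loci total chip loci, including haploblock members.
#' @param n_haploblocks number of QTL haploblocks (one per chromosome).
#' @param block_width_bp haploblock width in bp.
#' @param block_markers chip markers per haploblock.
#' @param maf_range length-2 range of minor allele frequencies for background
#'   loci and founder block haplotypes.
#' @param founder_block_alleles number of distinct founder haplotype alleles
#'   per block.
#' @param qtn_effect_liability QTN allele substitution effect on the liability
#'   scale (residual-SD units).
#' @param qtn_effect_nf QTN effect on the follicle count, in follicles.
#' @param polygenic_variance variance of the animal polygenic deviation on the
#'   liability scale.
#' @param residual_variance liability residual variance (1 identifies the
#'   threshold model).
#' @param hp_threshold liability threshold above which the binary trait is 1.
#' @param nf_mean,nf_residual_variance mean and residual variance of the count
#'   trait.
#' @param age_mean,age_sd age at insemination (months).
#' @param age_beta regression of liability on centered age.
#' @param n_herds,n_years contemporary-group structure (herd x birth-year).
#' @param cg_sd SD of contemporary-group effects on the liability scale.
#' @param n_sequenced_sires sires with whole-genome sequence (taken as the
#'   first sires; must be <= `n_sires`).
#' @param n_sequenced_ancestors additional sequenced founder animals without
#'   progeny (more distant relatives carrying the same founder haplotypes);
#'   they enlarge the sequenced panel the fragment regression runs on.
#' @param seq_variants_per_block sequence variants emitted per block
#'   (one planted QTN plus decoys).
#' @param prop_concordant_decoys fraction of decoy variants perfectly linked
#'   to a single haplotype allele; the remainder are made discordant to
#'   exercise the regression reliability filter.
#' @param seed integer seed; mandatory.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 6, progeny_per_sire = 50,
                       n_chip_loci = 600, n_haploblocks = 1,
                       block_width_bp = 4e6, block_markers = 20,
                       maf_range = c(0.1, 0.5), founder_block_alleles = 4,
                       qtn_effect_liability = 1.0, qtn_effect_nf = 4,
                       polygenic_variance = 0.3, residual_variance = 1.0,
                       hp_threshold = 1, nf_mean = 25,
                       nf_residual_variance = 25,
                       age_mean = 16, age_sd = 1.5, age_beta = 0.05,
                       n_herds = 3, n_years = 2, cg_sd = 0.2,
                       n_sequenced_sires = 6, n_sequenced_ancestors = 20,
                       seq_variants_per_block = 30,
                       prop_concordant_decoys = 0.5, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- list(n_sires = n_sires, progeny_per_sire = progeny_per_sire,
              n_chip_loci = n_chip_loci, n_haploblocks = n_haploblocks,
              block_width_bp = block_width_bp, block_markers = block_markers,
              maf_range = maf_range,
              founder_block_alleles = founder_block_alleles,
              qtn_effect_liability = qtn_effect_liability,
              qtn_effect_nf = qtn_effect_nf,
              polygenic_variance = polygenic_variance,
              residual_variance = residual_variance,
              hp_threshold = hp_threshold, nf_mean = nf_mean,
              nf_residual_variance = nf_residual_variance,
              age_mean = age_mean, age_sd = age_sd, age_beta = age_beta,
              n_herds = n_herds, n_years = n_years, cg_sd = cg_sd,
              n_sequenced_sires = n_sequenced_sires,
              n_sequenced_ancestors = n_sequenced_ancestors,
              seq_variants_per_block = seq_variants_per_block,
              prop_concordant_decoys = prop_concordant_decoys,
              seed = as.integer(seed))
  counts <- c("n_sires", "progeny_per_sire", "n_chip_loci", "n_haploblocks",
              "block_markers", "founder_block_alleles", "n_herds", "n_years",
              "seq_variants_per_block")
  for (nm in counts) {
    if (cfg[[nm]] < 1) stop("sim_config: ", nm, " must be positive")
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("sim_config: maf_range must be increasing within (0, 0.5]")
  }
  if (polygenic_variance < 0 || residual_variance < 0 ||
      nf_residual_variance < 0) {
    stop("sim_config: variances must be >= 0")
  }
  if (n_sequenced_sires > n_sires) {
    stop("sim_config: n_sequenced_sires must be <= n_sires")
  }
  if (n_sequenced_ancestors < 0) {
    stop("sim_config: n_sequenced_ancestors must be >= 0")
  }
  if (prop_concordant_decoys < 0 || prop_concordant_decoys > 1) {
    stop("sim_config: prop_concordant_decoys must lie in [0, 1]")
  }
  if (n_chip_loci < n_haploblocks * block_markers) {
    stop("sim_config: n_chip_loci smaller than total block markers")
  }
  class(cfg) <- "sim_config"
  cfg
}

# genome layout shared by all stages: each block sits on its own chromosome
# starting at 10 Mb with evenly spaced markers; background loci fill the
# remainder of each chromosome.
.sim_layout <- function(cfg) {
  B <- cfg$n_haploblocks
  m <- cfg$block_markers
  n_bg <- cfg$n_chip_loci - B * m
  chrom <- as.character(seq_len(B))
  blocks <- data.frame(
    block = seq_len(B), chrom = chrom,
    start_bp = 10e6, end_bp = 10e6 + cfg$block_width_bp,
    stringsAsFactors = FALSE)
  block_pos <- lapply(seq_len(B), function(b) {
    round(seq(blocks$start_bp[b], blocks$end_bp[b], length.out = m))
  })
  per_chrom_bg <- diff(round(seq(0, n_bg, length.out = B + 1L)))
  list(blocks = blocks, block_pos = block_pos, per_chrom_bg = per_chrom_bg)
}

#' Simulate a half-sib population
#'
#' Sires receive two phased genomes; block haplotypes are drawn from a small
#' founder pool of distinct allele sequences so that alleles recur across
#' sires, and background loci are independent Bernoulli draws at their MAF.
#' Each daughter inherits one intact paternal block haplotype per block (no
#' intra-block recombination; free recombination elsewhere) and a maternal
#' genome drawn from founder frequencies. Chip dosage is always the sum of
#' the two underlying haplotypes.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `pedigree` (pedigree_table), `genotypes`
#'   ([genotype_matrix()]) and `truth` (class `truth_record`): founder pool
#'   sequences/frequencies and QTN carrier flags per block, QTN bp positions,
#'   per-sire haplotype pool labels and full phased genomes, per-offspring
#'   transmitted paternal pool label, per-animal QTN dosage, per-sire QTN
#'   zygosity, and the true fixed effects used downstream.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lay <- .sim_layout(cfg)
  B <- cfg$n_haploblocks; m <- cfg$block_markers
  K <- cfg$founder_block_alleles

  # marker map
  map_list <- list()
  for (b in seq_len(B)) {
    bg_n <- lay$per_chrom_bg[b]
    # background positions outside [start, end] of the block
    left <- sort(sample.int(9e6 - 1e5, ceiling(bg_n / 2)) + 1e5)
    right <- sort(sample.int(40e6, floor(bg_n / 2)) +
                  lay$blocks$end_bp[b] + 1e5)
    pos <- sort(c(left, lay$block_pos[[b]], right))
    map_list[[b]] <- data.frame(chrom = lay$blocks$chrom[b], pos = pos,
                                ref = "A", alt = "B",
                                stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map_list)
  L <- nrow(map)
  maf <- runif(L, cfg$maf_range[1], cfg$maf_range[2])

  # founder block pools: K distinct sequences, Dirichlet-ish frequencies
  pools <- vector("list", B)
  block_idx <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- which(map$chrom == lay$blocks$chrom[b] &
                 map$pos %in% lay$block_pos[[b]])
    block_idx[[b]] <- idx
    seqs <- matrix(rbinom(K * m, 1L, runif(K * m, cfg$maf_range[1],
                                           1 - cfg$maf_range[1])),
                   nrow = K)
    # founder alleles must stay distinguishable at ~1 Mb scale: force
    # pairwise-distinct sub-sequences within every 1 Mb marker segment
    seg_of <- pmin(max(1L, ceiling(cfg$block_width_bp / 1e6)),
                   (lay$block_pos[[b]] - lay$blocks$start_bp[b]) %/% 1e6 + 1L)
    for (sg in unique(seg_of)) {
      cols <- which(seg_of == sg)
      repeat {
        keys <- apply(seqs[, cols, drop = FALSE], 1L, paste, collapse = "")
        dup <- which(duplicated(keys))
        if (length(dup) == 0L) break
        flip <- sample(cols, 1L)
        seqs[dup[1L], flip] <- 1L - seqs[dup[1L], flip]
      }
    }
    w <- rgamma(K, shape = 3); freq <- w / sum(w)
    carriers <- sort(sample.int(K, max(1L, floor(K / 2))))
    qtn_pos <- lay$blocks$start_bp[b] +
      sample.int(cfg$block_width_bp - 1L, 1L)
    while (qtn_pos %in% map$pos[idx]) {
      qtn_pos <- lay$blocks$start_bp[b] +
        sample.int(cfg$block_width_bp - 1L, 1L)
    }
    pools[[b]] <- list(seqs = seqs, freq = freq, carriers = carriers,
                       qtn_pos = qtn_pos)
  }
  bg_idx <- setdiff(seq_len(L), unlist(block_idx))

  draw_founder_hap <- function() {
    h <- integer(L)
    h[bg_idx] <- rbinom(length(bg_idx), 1L, maf[bg_idx])
    pool_lab <- integer(B)
    for (b in seq_len(B)) {
      k <- sample.int(K, 1L, prob = pools[[b]]$freq)
      pool_lab[b] <- k
      h[block_idx[[b]]] <- pools[[b]]$seqs[k, ]
    }
    list(h = h, pool = pool_lab)
  }

  sire_ids <- sprintf("S%02d", seq_len(cfg$n_sires))
  anc_ids <- if (cfg$n_sequenced_ancestors > 0)
    sprintf("A%02d", seq_len(cfg$n_sequenced_ancestors)) else character(0)
  founder_ids <- c(sire_ids, anc_ids)
  n_founder <- length(founder_ids)
  n_off <- cfg$n_sires * cfg$progeny_per_sire
  off_ids <- sprintf("D%04d", seq_len(n_off))

  sire_haps <- vector("list", n_founder); names(sire_haps) <- founder_ids
  sire_pool <- array(NA_integer_, c(n_founder, 2L, B),
                     dimnames = list(founder_ids, NULL, NULL))
  for (s in seq_len(n_founder)) {
    h1 <- draw_founder_hap(); h2 <- draw_founder_hap()
    sire_haps[[s]] <- rbind(h1$h, h2$h)
    sire_pool[s, 1L, ] <- h1$pool
    sire_pool[s, 2L, ] <- h2$pool
  }

  dosages <- matrix(NA_integer_, nrow = n_founder + n_off, ncol = L,
                    dimnames = list(c(founder_ids, off_ids), NULL))
  for (s in seq_len(n_founder)) {
    dosages[s, ] <- sire_haps[[s]][1L, ] + sire_haps[[s]][2L, ]
  }

  off_sire <- rep(sire_ids, each = cfg$progeny_per_sire)
  off_pat_side <- matrix(NA_integer_, n_off, B)  # which sire haplotype, per block
  off_mat_pool <- matrix(NA_integer_, n_off, B)
  off_pat_hap <- matrix(0L, n_off, L)
  for (o in seq_len(n_off)) {
    s <- match(off_sire[o], sire_ids)
    hs <- sire_haps[[s]]
    # background: free recombination between sire's two haplotypes
    pick <- rbinom(length(bg_idx), 1L, 0.5)
    pat <- integer(L)
    pat[bg_idx] <- ifelse(pick == 0L, hs[1L, bg_idx], hs[2L, bg_idx])
    for (b in seq_len(B)) {
      side <- sample.int(2L, 1L)
      off_pat_side[o, b] <- side
      pat[block_idx[[b]]] <- hs[side, block_idx[[b]]]
    }
    mat <- draw_founder_hap()
    off_mat_pool[o, ] <- mat$pool
    off_pat_hap[o, ] <- pat
    dosages[n_founder + o, ] <- pat + mat$h
  }

  herd <- sample(sprintf("H%d", seq_len(cfg$n_herds)), n_off, replace = TRUE)
  year <- sample(2015L + seq_len(cfg$n_years), n_off, replace = TRUE)
  age <- round(rnorm(n_off, cfg$age_mean, cfg$age_sd), 1)
  ped <- data.frame(
    animal_id = c(founder_ids, off_ids),
    sire_id = c(rep(NA_character_, n_founder), off_sire),
    dam_id = NA_character_,
    herd = c(rep(NA_character_, n_founder), herd),
    birth_year = c(rep(NA_integer_, n_founder), year),
    age_at_ai = c(rep(NA_real_, n_founder), age),
    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree_table", "data.frame")

  # true fixed effects (used by simulate_phenotypes)
  cg_levels <- as.vector(outer(sprintf("H%d", seq_len(cfg$n_herds)),
                               2015L + seq_len(cfg$n_years), paste, sep = "_"))
  cg_effects <- setNames(rnorm(length(cg_levels), 0, cfg$cg_sd), cg_levels)

  # QTN dosages
  sire_qtn_zyg <- matrix(NA_integer_, n_founder, B,
                         dimnames = list(founder_ids, NULL))
  off_qtn_dos <- matrix(NA_integer_, n_off, B, dimnames = list(off_ids, NULL))
  for (b in seq_len(B)) {
    carrier <- seq_len(K) %in% pools[[b]]$carriers
    sire_qtn_zyg[, b] <- carrier[sire_pool[, 1L, b]] +
      carrier[sire_pool[, 2L, b]]
    pat_pool <- sire_pool[cbind(match(off_sire, sire_ids),
                                off_pat_side[, b], b)]
    off_qtn_dos[, b] <- carrier[pat_pool] + carrier[off_mat_pool[, b]]
  }

  truth <- structure(list(
    blocks = lay$blocks, block_idx = block_idx,
    pools = pools, maf = maf,
    qtn = data.frame(block = seq_len(B), chrom = lay$blocks$chrom,
                     pos = vapply(pools, function(p) p$qtn_pos, 0),
                     carriers = I(lapply(pools, function(p) p$carriers))),
    sire_haplotypes = sire_haps, sire_pool = sire_pool,
    sire_qtn_zygosity = sire_qtn_zyg,
    offspring_sire = setNames(off_sire, off_ids),
    offspring_paternal_side = `dimnames<-`(off_pat_side,
                                           list(off_ids, NULL)),
    offspring_paternal_pool = matrix(
      sire_pool[cbind(rep(match(off_sire, sire_ids), B),
                      as.vector(off_pat_side),
                      rep(seq_len(B), each = n_off))],
      n_off, B, dimnames = list(off_ids, NULL)),
    offspring_maternal_pool = `dimnames<-`(off_mat_pool, list(off_ids, NULL)),
    offspring_qtn_dosage = off_qtn_dos,
    cg_effects = cg_effects, age_beta = cfg$age_beta,
    config = cfg), class = "truth_record")

  g <- genotype_matrix(dosages, map)
  list(pedigree = ped, genotypes = g, truth = truth)
}

#' Simulate phenotypes from a truth record
#'
#' Liability for the binary trait: `l = cg + age_beta * (age - mean age) +
#' qtn_dosage * effect + polygenic + N(0, residual)`; the observed score is
#' `1` iff `l > hp_threshold`. The count trait is a rounded Gaussian floored
#' at zero with its own QTN effect. Only daughters are phenotyped. Liabilities
#' are attached as `attr(, "liability")` for oracle checks.
#'
#' @param truth `truth_record` from [simulate_population()].
#' @param pedigree the matching pedigree.
#' @param cfg the same [sim_config()].
#' @return `phenotype_table` for the daughters.
#' @export
simulate_phenotypes <- function(truth, pedigree, cfg) {
  stopifnot(inherits(truth, "truth_record"))
  set.seed(cfg$seed + 1L)
  off <- pedigree[!is.na(pedigree$sire_id), , drop = FALSE]
  n <- nrow(off)
  cg <- paste(off$herd, off$birth_year, sep = "_")
  qd <- truth$offspring_qtn_dosage[off$animal_id, 1L]
  poly <- rnorm(n, 0, sqrt(cfg$polygenic_variance))
  liab <- truth$cg_effects[cg] +
    cfg$age_beta * (off$age_at_ai - mean(off$age_at_ai)) +
    qd * cfg$qtn_effect_liability + poly +
    rnorm(n, 0, sqrt(cfg$residual_variance))
  hp <- as.integer(liab > cfg$hp_threshold)
  nf <- pmax(0, round(cfg$nf_mean + qd * cfg$qtn_effect_nf + poly +
                        rnorm(n, 0, sqrt(cfg$nf_residual_variance))))
  ph <- data.frame(animal_id = off$animal_id, hp = hp, nf = as.integer(nf),
                   stringsAsFactors = FALSE)
  class(ph) <- c("phenotype_table", "data.frame")
  attr(ph, "liability") <- setNames(as.numeric(liab), off$animal_id)
  ph
}

#' Simulate a sequenced-sire variant panel
#'
#' Emits block-local sequence variants for the first `n_sequenced_sires`
#' sires: (a) the planted QTN, present on exactly the carrier founder
#' haplotype alleles of its block; (b) concordant decoys, each perfectly
#' linked to a single founder allele; (c) discordant variants whose presence
#' differs between copies of the same founder allele, violating haplotype
#' determinism so the regression reliability filter has something to catch.
#' Dosages are consistent with each sire's two block haplotypes. The
#' haplotype-copy presence table is attached as `attr(, "hap_presence")` and
#' the variant class labels as `attr(, "variant_class")`.
#'
#' @param truth `truth_record` from [simulate_population()].
#' @param cfg the same [sim_config()].
#' @return A [variant_set()] over the sequenced sires.
#' @export
simulate_sequence_panel <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_record"))
  set.seed(cfg$seed + 2L)
  B <- nrow(truth$blocks)
  K <- cfg$founder_block_alleles
  all_ids <- rownames(truth$sire_pool)
  sires <- c(all_ids[seq_len(cfg$n_sequenced_sires)],
             grep("^A", all_ids, value = TRUE))
  ns <- length(sires)

  rows <- list(); dos <- list(); cls <- character(0); hp_tab <- list()
  for (b in seq_len(B)) {
    pool <- truth$pools[[b]]
    n_var <- cfg$seq_variants_per_block
    n_dec <- n_var - 1L
    n_conc <- round(cfg$prop_concordant_decoys * n_dec)
    n_disc <- n_dec - n_conc
    # distinct positions inside the block, off the chip markers and QTN
    blk <- truth$blocks[b, ]
    pos_pool <- setdiff(seq.int(blk$start_bp + 1L, blk$end_bp - 1L),
                        pool$qtn_pos)
    pos <- sort(sample(pos_pool, n_dec))
    # sire block pool labels per haplotype copy
    copies <- cbind(truth$sire_pool[sires, 1L, b],
                    truth$sire_pool[sires, 2L, b])

    # QTN row
    carrier <- seq_len(K) %in% pool$carriers
    v_pos <- c(pool$qtn_pos, pos)
    v_cls <- c("qtn", rep("concordant", n_conc), rep("discordant", n_disc))
    ord <- order(v_pos)
    v_pos <- v_pos[ord]; v_cls <- v_cls[ord]
    conc_allele_iter <- 0L
    for (i in seq_along(v_pos)) {
      if (v_cls[i] == "qtn") {
        pres_pool <- carrier
        hap_pres <- cbind(pres_pool[copies[, 1L]], pres_pool[copies[, 2L]])
      } else if (v_cls[i] == "concordant") {
        conc_allele_iter <- conc_allele_iter + 1L
        tag <- ((conc_allele_iter - 1L) %% K) + 1L
        pres_pool <- seq_len(K) == tag
        hap_pres <- cbind(pres_pool[copies[, 1L]], pres_pool[copies[, 2L]])
      } else {
        # discordant: force two copies of one shared allele to disagree
        hap_pres <- matrix(rbinom(ns * 2L, 1L, 0.5) == 1L, ns, 2L)
        tab <- table(as.vector(copies))
        shared <- as.integer(names(tab)[tab >= 2L])
        if (length(shared)) {
          a <- shared[1L]
          hits <- which(copies == a)
          hap_pres[hits[1L]] <- TRUE
          hap_pres[hits[2L]] <- FALSE
        }
        pres_pool <- rep(NA, K)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = blk$chrom, pos = v_pos[i], ref = "A", alt = "C",
        qual = round(runif(1, 30, 90), 1), type = "SNP",
        stringsAsFactors = FALSE)
      dos[[length(dos) + 1L]] <- as.integer(hap_pres[, 1L]) +
        as.integer(hap_pres[, 2L])
      cls <- c(cls, v_cls[i])
      hp_tab[[length(hp_tab) + 1L]] <- hap_pres
    }
  }
  variants <- do.call(rbind, rows)
  dosage <- do.call(rbind, dos)
  colnames(dosage) <- sires
  depth <- matrix(rpois(length(dosage), 15) + 4L, nrow(dosage),
                  dimnames = dimnames(dosage))
  vs <- variant_set(variants, dosage, depth)
  attr(vs, "variant_class") <- cls
  attr(vs, "hap_presence") <- hp_tab
  vs
}

#' Simulate a complete study
#'
#' Convenience wrapper running [simulate_population()],
#' [simulate_phenotypes()] and [simulate_sequence_panel()] with one
#' configuration.
#'
#' @param cfg a [sim_config()].
#' @return list with `pedigree`, `genotypes`, `truth`, `phenotypes`,
#'   `sequence`.
#' @export
simulate_study <- function(cfg) {
  pop <- simulate_population(cfg)
  ph <- simulate_phenotypes(pop$truth, pop$pedigree, cfg)
  vs <- simulate_sequence_panel(pop$truth, cfg)
  c(pop, list(phenotypes = ph, sequence = vs))
}

#' Write / read a truth record as JSON
#'
#' Lossless round-trip of the simulator's truth bookkeeping for archival runs.
#' @param truth `truth_record`.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  payload <- truth
  payload$sire_haplotypes <- lapply(payload$sire_haplotypes, unclass)
  payload$config <- unclass(payload$config)
  payload$cg_effects <- as.list(payload$cg_effects)  # keep the names
  jsonlite::write_json(unclass(payload), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth` returns the truth record rebuilt from JSON (pool
#'   sequences, QTN table, zygosities, transmitted-allele bookkeeping and
#'   fixed effects).
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  x$blocks <- as.data.frame(x$blocks)
  car <- x$qtn$carriers
  if (is.matrix(car)) {
    car <- lapply(seq_len(nrow(car)), function(i) car[i, ])
  } else if (!is.list(car)) {
    car <- list(car)                     # single block: one carrier vector
  }
  x$qtn <- data.frame(block = x$qtn$block,
                      chrom = as.character(x$qtn$chrom),
                      pos = x$qtn$pos, carriers = I(car))
  # jsonlite stores matrices row-major and simplifies them back; coerce the
  # odd list-of-rows case defensively
  fix_mat <- function(m, nr) {
    if (is.matrix(m)) m else matrix(unlist(m), nrow = nr, byrow = TRUE)
  }
  x$pools <- lapply(x$pools, function(p) {
    p$seqs <- fix_mat(p$seqs, length(p$freq)); p
  })
  x$sire_haplotypes <- lapply(x$sire_haplotypes, fix_mat, nr = 2L)
  x$sire_qtn_zygosity <- as.matrix(as.data.frame(x$sire_qtn_zygosity))
  x$cg_effects <- unlist(x$cg_effects)
  structure(x, class = "truth_record")
}
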