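# End-to-end orchestration: simulate (or load) -> QC -> phase -> Bayes B fit
# -> contrasts -> fine mapping -> gene assignment / ORA, with a JSON run
# manifest and deterministic seeding throughout.

#' Assemble a pipeline configuration
#'
#' @param out output directory (created if absent).
#' @param seed integer seed propagated to every stochastic stage.
#' @param sim a [sim_config()] to simulate inputs, or `NULL` to read them
#'   from `paths`.
#' @param paths named list of input files (`genotypes`, `pedigree`,
#'   `phenotypes`, `variants`, `genes`, `gene_sets`) when not simulating.
#' @param trait `"hp"` or `"nf"`.
#' @param stages character vector of stages to run, in canonical order:
#'   `qc`, `phase`, `fit`, `contrast`, `finemap`, `ora`.
#' @param alpha contrast significance threshold.
#' @param pi,chain_length,burn_in,thin Bayes B chain controls.
#' @param fragment_width_bp,min_occurrences,se_max,tol fine-mapping knobs.
#' @param qual_min,dp_min variant-call filter.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out, seed, sim = NULL, paths = list(),
                            trait = c("hp", "nf"),
                            stages = c("qc", "phase", "fit", "contrast",
                                       "finemap", "ora"),
                            alpha = 0.10, pi = 0.999,
                            chain_length = 6000L, burn_in = 1000L,
                            thin = 5L, fragment_width_bp = 1e6,
                            min_occurrences = 3L, se_max = 1e-4,
                            tol = 1e-6, qual_min = 20, dp_min = 4) {
  trait <- match.arg(trait)
  known <- c("qc", "phase", "fit", "contrast", "finemap", "ora")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out = out, seed = as.integer(seed), sim = sim,
                 paths = paths, trait = trait, stages = stages,
                 alpha = alpha, pi = pi,
                 chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 fragment_width_bp = fragment_width_bp,
                 min_occurrences = min_occurrences, se_max = se_max,
                 tol = tol, qual_min = qual_min, dp_min = dp_min),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()]; a `sim:` mapping is passed to [sim_config()].
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Run the fine-mapping pipeline
#'
#' Executes the requested stages in canonical order, writing artifacts and
#' a manifest (parameters, per-stage record counts, timings) under
#' `cfg$out`. A rerun with an identical configuration and seed reproduces
#' the outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly; artifacts are written to `cfg$out`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, trait = cfg$trait, stages = list())
  t_all <- proc.time()[3]
  note <- function(name, ...) {
    manifest$stages[[name]] <<- c(list(stage = name, ...),
                                  list(elapsed_s = round(proc.time()[3] - t0,
                                                         3)))
  }

  # ---- inputs ------------------------------------------------------------
  t0 <- proc.time()[3]
  if (!is.null(cfg$sim)) {
    study <- simulate_study(cfg$sim)
    ped <- study$pedigree; g <- study$genotypes; ph <- study$phenotypes
    vs <- study$sequence; truth <- study$truth
    regions <- data.frame(trait = toupper(cfg$trait),
                          chrom = truth$blocks$chrom,
                          start_bp = truth$blocks$start_bp,
                          end_bp = truth$blocks$end_bp)
    write_pedigree(ped, file.path(cfg$out, "pedigree.csv"))
    write_phenotypes(ph, file.path(cfg$out, "phenotypes.csv"))
    note("simulate", n_animals = nrow(ped), n_loci = ncol(g$dosages),
         n_variants = nrow(vs$variants))
  } else {
    g <- read_genotypes(cfg$paths$genotypes)
    ped <- read_pedigree(cfg$paths$pedigree)
    ph <- read_phenotypes(cfg$paths$phenotypes)
    vs <- if (!is.null(cfg$paths$variants)) read_variants(cfg$paths$variants)
    truth <- NULL
    regions <- read.table(cfg$paths$regions, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
    note("load", n_animals = nrow(ped), n_loci = ncol(g$dosages))
  }
  blocks <- define_haploblocks(g$map, regions)

  # ---- qc ------------------------------------------------------------------
  if ("qc" %in% cfg$stages) {
    t0 <- proc.time()[3]
    n_in <- sum(!is.na(ped$sire_id))
    ped <- verify_pedigree(ped, g)
    cgs <- form_contemporary_groups(ped)
    n_ph_in <- nrow(ph)
    ph <- filter_records(ph, cgs, ped, trait = cfg$trait)
    if (!is.null(vs)) {
      nv_in <- nrow(vs$variants)
      vs <- filter_sequence_variants(vs, cfg$qual_min, cfg$dp_min)
    } else nv_in <- NA
    note("qc", pairs_in = n_in, pairs_removed = sum(attr(ped, "audit")$removed),
         records_in = n_ph_in, records_retained = nrow(ph),
         variants_in = nv_in,
         variants_retained = if (!is.null(vs)) nrow(vs$variants) else NA)
    write_phenotypes(ph, file.path(cfg$out, "phenotypes_filtered.csv"))
  } else cgs <- form_contemporary_groups(ped)

  # ---- phase ---------------------------------------------------------------
  catalog <- NULL
  if ("phase" %in% cfg$stages) {
    t0 <- proc.time()[3]
    phased <- phase_sire_blocks(g, ped, blocks)
    catalog <- build_allele_catalog(phased, blocks, g, ped)
    catalog <- filter_alleles(catalog, cfg$min_occurrences)
    write.table(catalog$alleles, file.path(cfg$out, "allele_catalog.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("phase", n_alleles = nrow(catalog$alleles),
         n_assigned = sum(catalog$assignments$status == "assigned"),
         n_usable = sum(catalog$assignments$usable))
  }

  # ---- fit + contrast per block ---------------------------------------------
  fits <- list(); contrasts_df <- NULL
  if ("fit" %in% cfg$stages) {
    if (is.null(catalog)) stop("stage 'fit' requires stage 'phase'")
    for (bn in names(blocks)) {
      t0 <- proc.time()[3]
      dat <- .assemble_block_data(bn, blocks, catalog, g, ped, ph, cgs,
                                  cfg$trait)
      if (is.null(dat)) next
      mc <- model_config(pi = cfg$pi, chain_length = cfg$chain_length,
                         burn_in = cfg$burn_in, thin = cfg$thin,
                         seed = cfg$seed,
                         trait_type = if (cfg$trait == "hp") "binary"
                                      else "continuous")
      fits[[bn]] <- fit_bayesb(dat$y, dat$F, dat$H, dat$X, mc)
      note(paste0("fit_", bn), n_records = length(dat$y),
           n_alleles = ncol(dat$H), n_snps = ncol(dat$X))
      if ("contrast" %in% cfg$stages) {
        cc <- run_contrasts(fits[[bn]], catalog, bn, cfg$alpha)
        contrasts_df <- rbind(contrasts_df, cc)
      }
    }
    if (!is.null(contrasts_df)) {
      seg_rep <- segregation_report(contrasts_df)
      write.table(contrasts_df, file.path(cfg$out, "contrasts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(seg_rep$table, file.path(cfg$out, "segregation.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
      manifest$stages$contrast <- list(
        stage = "contrast",
        het_sires = as.list(seg_rep$het_sires),
        superior_alleles = as.list(seg_rep$superior_alleles_trait))
    }
  }

  # ---- finemap ---------------------------------------------------------------
  conc <- NULL
  if ("finemap" %in% cfg$stages) {
    if (is.null(vs) || is.null(contrasts_df)) {
      manifest$stages$finemap <- list(stage = "finemap",
                                      skipped = "needs variants + contrasts")
    } else {
      t0 <- proc.time()[3]
      bn <- names(blocks)[1L]
      seq_animals <- colnames(vs$dosage)
      haps <- .sequenced_haplotypes(seq_animals, bn, blocks, g, ped, truth)
      fm <- finemap_block(blocks[[bn]], g$map, vs, haps,
                          cfg$fragment_width_bp, cfg$min_occurrences,
                          cfg$tol, cfg$se_max)
      st <- contrasts_df[contrasts_df$block == bn &
                           contrasts_df$sire %in% seq_animals, ]
      status <- data.frame(sire = st$sire,
                           status = ifelse(st$significant, "het", "hom"),
                           stringsAsFactors = FALSE)
      conc <- concordant_variants(fm, status)
      conc_tab <- data.frame(
        sire = rep(names(conc$per_sire),
                   vapply(conc$per_sire, length, 0L)),
        pos = unlist(conc$per_sire, use.names = FALSE))
      write.table(conc_tab, file.path(cfg$out, "concordant_variants.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      note("finemap", n_variants = nrow(fm$variants),
           n_concordant_intersection = length(conc$intersection))
    }
  } else if ("ora" %in% cfg$stages) {
    message("stage 'ora' skipped: fine mapping is toggled off")
    manifest$stages$ora <- list(stage = "ora",
                                skipped = "finemap toggled off")
  }

  # ---- ora --------------------------------------------------------------------
  if ("ora" %in% cfg$stages && "finemap" %in% cfg$stages &&
      !is.null(conc) && !is.null(cfg$paths$genes) &&
      !is.null(cfg$paths$gene_sets)) {
    t0 <- proc.time()[3]
    genes <- read_genes(cfg$paths$genes)
    hits <- assign_variants_to_genes(
      data.frame(chrom = blocks[[1L]]$chrom, pos = conc$intersection),
      genes)
    targets <- unique(stats::na.omit(hits$per_variant$gene_id))
    res <- run_ora(targets, genes$gene_id, cfg$paths$gene_sets)
    write.table(res, file.path(cfg$out, "ora_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("ora", n_terms = nrow(res), n_significant = sum(res$significant))
  }

  manifest$elapsed_s <- round(proc.time()[3] - t_all, 3)
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

# build y, F, H, X for one block
.assemble_block_data <- function(bn, blocks, catalog, g, ped, ph, cgs,
                                 trait) {
  H_all_animals <- ph$animal_id
  H <- build_design(catalog, bn, g, H_all_animals)
  keep <- rowSums(H) > 0L
  if (sum(keep) < 10L) return(NULL)
  animals <- H_all_animals[keep]
  H <- H[keep, , drop = FALSE]
  H <- H[, colSums(H) > 0L, drop = FALSE]
  y <- ph[[trait]][match(animals, ph$animal_id)]
  cg <- cgs$cg[match(animals, cgs$animal_id)]
  age <- ped$age_at_ai[match(animals, ped$animal_id)]
  Fm <- model.matrix(~ 0 + factor(cg))
  colnames(Fm) <- sub("factor\\(cg\\)", "cg:", colnames(Fm))
  Fm <- cbind(Fm, age_c = age - mean(age))
  X <- g$dosages[animals, -blocks[[bn]]$markers, drop = FALSE]
  list(y = y, F = Fm, H = H, X = X, animals = animals)
}

# phased block haplotypes of the sequenced sires: simulator truth when
# available, else the half-sib phase
.sequenced_haplotypes <- function(seq_sires, bn, blocks, g, ped,
                                  truth = NULL) {
  idx <- blocks[[bn]]$markers
  out <- list()
  if (!is.null(truth)) {
    for (s in intersect(seq_sires, names(truth$sire_haplotypes))) {
      out[[s]] <- truth$sire_haplotypes[[s]][, idx, drop = FALSE]
    }
  } else {
    phased <- phase_sire_blocks(g, ped, blocks[bn])
    for (s in intersect(seq_sires, names(phased[[bn]]))) {
      if (!is.null(phased[[bn]][[s]])) out[[s]] <- phased[[bn]][[s]]
    }
  }
  out
}
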