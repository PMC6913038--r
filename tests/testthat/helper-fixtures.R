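# Shared fixtures. The default desk-scale study is simulated once per test
# run and reused by the read-only tests.

.fixture_env <- new.env(parent = emptyenv())

fixture_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- sim_config(seed = 42)
    .fixture_env$study <- simulate_study(cfg)
    .fixture_env$cfg <- cfg
  }
  .fixture_env$study
}

fixture_cfg <- function() {
  fixture_study()
  .fixture_env$cfg
}

fixture_blocks <- function() {
  st <- fixture_study()
  regions <- data.frame(trait = "HP", chrom = st$truth$blocks$chrom,
                        start_bp = st$truth$blocks$start_bp,
                        end_bp = st$truth$blocks$end_bp)
  define_haploblocks(st$genotypes$map, regions)
}

# tiny genotype matrix builder
make_gm <- function(dosages, chrom = "1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 1000L
  genotype_matrix(dosages,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "B"))
}

# truth haplotypes of the sequenced panel over a block
sequenced_truth_haps <- function(st, block) {
  ids <- colnames(st$sequence$dosage)
  lapply(setNames(ids, ids), function(s) {
    st$truth$sire_haplotypes[[s]][, block$markers, drop = FALSE]
  })
}

# truth zygosity status table for the sequenced proper sires
truth_status <- function(st) {
  cfg <- st$truth$config
  sires <- sprintf("S%02d", seq_len(cfg$n_sequenced_sires))
  zyg <- st$truth$sire_qtn_zygosity[sires, 1L]
  data.frame(sire = sires,
             status = ifelse(zyg == 1L, "het", "hom"),
             stringsAsFactors = FALSE)
}
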