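# Pedigree verification by opposite homozygosity and the record edits
# applied before model fitting: contemporary-group formation, removal of
# groups without phenotypic variability, and the within-group age outlier
# cut.

#' Opposite-homozygote rate of a sire-offspring pair
#'
#' Fraction of loci at which one member is dosage 0 and the other dosage 2,
#' among loci where both are non-missing. Such conflicts are impossible under
#' true parentage barring genotyping error. When no locus is informative the
#' rate is defined as 0 and flagged via `attr(, "no_informative")`.
#'
#' @param sire_dosages,offspring_dosages equal-length dosage vectors over
#'   shared loci.
#' @return numeric rate in \[0, 1\].
#' @export
opposite_homozygote_rate <- function(sire_dosages, offspring_dosages) {
  if (length(sire_dosages) != length(offspring_dosages)) {
    stop("dosage vectors must have equal length")
  }
  both <- !is.na(sire_dosages) & !is.na(offspring_dosages)
  n <- sum(both)
  if (n == 0L) {
    warning("no shared non-missing loci; rate defined as 0")
    return(structure(0, no_informative = TRUE))
  }
  conf <- sum((sire_dosages[both] == 0L & offspring_dosages[both] == 2L) |
              (sire_dosages[both] == 2L & offspring_dosages[both] == 0L))
  structure(conf / n, no_informative = FALSE)
}

#' Verify recorded sires against genotypes
#'
#' For every genotyped sire-offspring pair, computes the
#' [opposite_homozygote_rate()] (a Mendelian-error rate) and sets the
#' recorded sire to missing when the rate strictly exceeds `threshold`
#' (default 0.1%). Pairs lacking genotypes on either side are never edited.
#' The audit log of tested pairs is attached as `attr(, "audit")`.
#'
#' @param ped pedigree table.
#' @param g [genotype_matrix()] holding sires and offspring.
#' @param threshold Mendelian error rate above which the link is severed.
#' @return pedigree with offending `sire_id` set to `NA`.
#' @export
verify_pedigree <- function(ped, g, threshold = 0.001) {
  ids <- rownames(g$dosages)
  test <- which(!is.na(ped$sire_id) & ped$animal_id %in% ids &
                ped$sire_id %in% ids)
  audit <- data.frame(animal_id = character(0), sire_id = character(0),
                      rate = numeric(0), removed = logical(0))
  for (i in test) {
    r <- opposite_homozygote_rate(g$dosages[ped$sire_id[i], ],
                                  g$dosages[ped$animal_id[i], ])
    removed <- as.numeric(r) > threshold
    audit <- rbind(audit, data.frame(
      animal_id = ped$animal_id[i], sire_id = ped$sire_id[i],
      rate = as.numeric(r), removed = removed))
    if (removed) ped$sire_id[i] <- NA_character_
  }
  attr(ped, "audit") <- audit
  ped
}

#' Form contemporary groups
#'
#' A contemporary group is the subclass combination of birth year within
#' herd. Animals missing either field are excluded with a warning; empty
#' subclass combinations are simply never emitted.
#'
#' @param ped pedigree table with `herd` and `birth_year`.
#' @return data.frame (`cg_assignment`) with `animal_id` and `cg`; the number
#'   of distinct groups is attached as `attr(, "n_groups")`.
#' @export
form_contemporary_groups <- function(ped) {
  ok <- !is.na(ped$herd) & !is.na(ped$birth_year)
  dropped <- ped$animal_id[!ok & (!is.na(ped$sire_id))]
  if (length(dropped)) {
    warning(length(dropped), " animal(s) excluded from CG formation ",
            "(missing herd or birth year)")
  }
  out <- data.frame(animal_id = ped$animal_id[ok],
                    cg = paste(ped$herd[ok], ped$birth_year[ok], sep = "_"),
                    stringsAsFactors = FALSE)
  attr(out, "n_groups") <- length(unique(out$cg))
  class(out) <- c("cg_assignment", "data.frame")
  out
}

#' Apply the phenotypic-variability and age edits
#'
#' Whole contemporary groups whose trait values show no variability (fewer
#' than two distinct observed values, including groups of size one) are
#' removed. Then, within each surviving group, animals whose age deviates
#' from the group mean by more than `sd_limit` group standard deviations
#' (computed before any removals, n-1 denominator) are dropped. The removal
#' log is attached as `attr(, "removals")`. Output is always a subset of the
#' input and the operation is idempotent.
#'
#' @param pheno phenotype table.
#' @param cg contemporary-group assignment from [form_contemporary_groups()].
#' @param ped pedigree table supplying `age_at_ai`.
#' @param trait `"hp"` or `"nf"`.
#' @param sd_limit age cut in group SD units (default 3.5).
#' @return filtered phenotype table.
#' @export
filter_records <- function(pheno, cg, ped, trait = c("hp", "nf"),
                           sd_limit = 3.5) {
  trait <- match.arg(trait)
  df <- merge(pheno, cg, by = "animal_id")
  df <- merge(df, ped[, c("animal_id", "age_at_ai")], by = "animal_id")
  df <- df[!is.na(df[[trait]]), , drop = FALSE]

  removals <- list()
  # 1. groups without phenotypic variability
  nvals <- tapply(df[[trait]], df$cg, function(v) length(unique(v)))
  dead_cg <- names(nvals)[nvals < 2L]
  if (length(dead_cg)) {
    removals$no_variability <- df$animal_id[df$cg %in% dead_cg]
    df <- df[!(df$cg %in% dead_cg), , drop = FALSE]
  }
  # 2. age outliers, group SD computed before removals
  if (nrow(df)) {
    mu <- tapply(df$age_at_ai, df$cg, mean)
    sdv <- tapply(df$age_at_ai, df$cg, sd)
    dev <- abs(df$age_at_ai - mu[df$cg])
    lim <- sd_limit * sdv[df$cg]
    out <- !is.na(dev) & !is.na(lim) & dev > lim
    if (any(out)) {
      removals$age_outlier <- df$animal_id[out]
      df <- df[!out, , drop = FALSE]
    }
  }
  res <- pheno[pheno$animal_id %in% df$animal_id, , drop = FALSE]
  attr(res, "removals") <- removals
  class(res) <- c("phenotype_table", "data.frame")
  res
}
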