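# Posterior contrasts between the two haplotype-allele effects carried by
# each sire, the heterozygosity call at alpha < 0.10, and the sire x block
# segregation report.

#' Contrast two haplotype-allele effects from raw draws
#'
#' Given per-draw effect values for two alleles, forms the per-draw
#' difference `delta = h_a1 - h_a2` and the posterior sign probability
#' `p = min(P(delta >= 0), P(delta <= 0))`; the sire is called heterozygous
#' (significant) when `p < alpha`, i.e. when at least `1 - alpha` of the
#' posterior mass agrees in sign. The superior allele is the one favoured by
#' the posterior mean. `p` is invariant to the sign convention and to the
#' reference-allele choice in the fitted design.
#'
#' @param d1,d2 numeric draw vectors for alleles `a1` and `a2`.
#' @param a1,a2 allele labels.
#' @param alpha significance threshold on the minority-sign mass.
#' @return list of class `contrast_result` with fields `a1`, `a2`, `mean`,
#'   `p`, `significant`, `superior`, `inferior`.
#' @export
contrast_from_draws <- function(d1, d2, a1, a2, alpha = 0.10) {
  if (identical(a1, a2)) {
    return(structure(list(a1 = a1, a2 = a2, mean = 0, p = 0.5,
                          significant = FALSE, superior = a1, inferior = a2,
                          reason = "homozygous"),
                     class = "contrast_result"))
  }
  delta <- d1 - d2
  # both tail masses can be 1 only for a degenerate all-zero contrast
  p <- min(mean(delta >= 0), mean(delta <= 0), 0.5)
  m <- mean(delta)
  sup <- if (m >= 0) a1 else a2
  inf <- if (m >= 0) a2 else a1
  structure(list(a1 = a1, a2 = a2, mean = m, p = p,
                 significant = p < alpha, superior = sup, inferior = inf,
                 reason = NA_character_),
            class = "contrast_result")
}

#' @exportS3Method print contrast_result
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast %s vs. %s: mean %.4f, p = %.4f (%s)\n",
              x$a1, x$a2, x$mean, x$p,
              if (x$significant) "heterozygous" else "NS"))
  invisible(x)
}

#' Contrast a sire's two haplotype alleles in a fitted model
#'
#' Pulls the two alleles' retained draws from a [fit_bayesb()] result (the
#' reference allele contributes zeros) and applies [contrast_from_draws()].
#' Alleles filtered out upstream (absent from the fitted design) yield a
#' non-significant result with a reason code instead of an error.
#'
#' @param fit a `bayesb_fit` with haplotype effects.
#' @param a1,a2 the sire's two allele labels.
#' @param alpha threshold (default 0.10).
#' @return `contrast_result`.
#' @export
haplotype_contrast <- function(fit, a1, a2, alpha = 0.10) {
  stopifnot(inherits(fit, "bayesb_fit"))
  if (is.null(fit$hap_draws)) stop("fit has no haplotype effects")
  labs <- colnames(fit$hap_draws)
  a1c <- as.character(a1); a2c <- as.character(a2)
  if (!(a1c %in% labs) || !(a2c %in% labs)) {
    return(structure(list(a1 = a1, a2 = a2, mean = NA_real_, p = 0.5,
                          significant = FALSE, superior = NA, inferior = NA,
                          reason = "allele_filtered"),
                     class = "contrast_result"))
  }
  contrast_from_draws(fit$hap_draws[, a1c], fit$hap_draws[, a2c],
                      a1, a2, alpha)
}

#' Contrast every sire's allele pair at a block
#'
#' @param fit `bayesb_fit` for the block.
#' @param cat a (filtered) `allele_catalog`.
#' @param block_name block to report.
#' @param alpha threshold.
#' @return data.frame with one row per sire: `sire`, `block`, `trait`, `a1`,
#'   `a2`, `mean`, `p`, `significant`, `superior`, `inferior`.
#' @export
run_contrasts <- function(fit, cat, block_name, alpha = 0.10) {
  pairs <- cat$sire_pairs[cat$sire_pairs$block == block_name, , drop = FALSE]
  trait <- cat$blocks[[block_name]]$trait
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    cr <- haplotype_contrast(fit, pairs$a1[i], pairs$a2[i], alpha)
    data.frame(sire = pairs$sire[i], block = block_name, trait = trait,
               a1 = pairs$a1[i], a2 = pairs$a2[i], mean = cr$mean, p = cr$p,
               significant = cr$significant,
               superior = if (cr$significant) cr$superior else NA_integer_,
               inferior = if (cr$significant) cr$inferior else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a sire x block segregation-call table
#'
#' Parses a TSV whose first column is `sire` and remaining columns are block
#' names (e.g. `HP_BTA5`); cells are either `NS` or `"a vs. b"` with the
#' superior allele listed first. The trait is the block-name prefix before
#' the first underscore.
#'
#' @param path TSV file.
#' @return long data.frame with `sire`, `block`, `trait`, `significant`,
#'   `superior`, `inferior`, suitable for [segregation_report()].
#' @export
read_segregation_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "sire") stop("first column must be 'sire'")
  blocks <- names(tab)[-1L]
  out <- list()
  for (bn in blocks) {
    trait <- sub("_.*$", "", bn)
    for (i in seq_len(nrow(tab))) {
      cell <- trimws(tab[[bn]][i])
      if (toupper(cell) == "NS") {
        out[[length(out) + 1L]] <- data.frame(
          sire = tab$sire[i], block = bn, trait = trait,
          significant = FALSE, superior = NA_integer_,
          inferior = NA_integer_, stringsAsFactors = FALSE)
      } else {
        mm <- regmatches(cell, regexec("^([0-9]+) vs\\. ([0-9]+)$", cell))[[1]]
        if (length(mm) != 3L) stop("unparseable cell '", cell, "' in ", bn)
        out[[length(out) + 1L]] <- data.frame(
          sire = tab$sire[i], block = bn, trait = trait,
          significant = TRUE, superior = as.integer(mm[2]),
          inferior = as.integer(mm[3]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Segregation report across sires and blocks
#'
#' Formats one entry per (sire, block) — `"a vs. b"` with the superior
#' allele first, or `NS` — and tallies, per block, the number of
#' heterozygous sires and, per block and per trait, the number of distinct
#' superior alleles.
#'
#' @param results long data.frame with columns `sire`, `block`, `trait`,
#'   `significant`, `superior`, `inferior` (from [run_contrasts()] or
#'   [read_segregation_table()]).
#' @return object of class `segregation_report`: `table` (sires x blocks
#'   character matrix), `het_sires` (named count per block),
#'   `superior_alleles_block` (distinct superior alleles per block),
#'   `superior_alleles_trait` (per trait).
#' @export
segregation_report <- function(results) {
  need <- c("sire", "block", "trait", "significant", "superior", "inferior")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results lack column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(results[, c("sire", "block")])) {
    stop("more than one entry for some (sire, block)")
  }
  sires <- unique(results$sire)
  blocks <- unique(results$block)
  tab <- matrix("NS", length(sires), length(blocks),
                dimnames = list(as.character(sires), blocks))
  sig <- results[results$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    tab[as.character(sig$sire[i]), sig$block[i]] <-
      paste(sig$superior[i], "vs.", sig$inferior[i])
  }
  het <- vapply(blocks, function(bn) sum(sig$block == bn), 0L)
  sup_block <- vapply(blocks, function(bn) {
    length(unique(sig$superior[sig$block == bn]))
  }, 0L)
  traits <- unique(results$trait)
  sup_trait <- vapply(traits, function(tr) {
    length(unique(sig$superior[sig$trait == tr]))
  }, 0L)
  structure(list(table = tab, het_sires = het,
                 superior_alleles_block = sup_block,
                 superior_alleles_trait = sup_trait),
            class = "segregation_report")
}

#' @exportS3Method print segregation_report
print.segregation_report <- function(x, ...) {
  cat("Heterozygous sires per block:\n")
  print(x$het_sires)
  cat("Distinct superior alleles per trait:\n")
  print(x$superior_alleles_trait)
  invisible(x)
}
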