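# Sequence-variant imputation onto chip haplotype fragments: partition a
# haploblock into ~1 Mb fragments, regress each variant's alt-allele dosage
# on fragment-allele dosages (OLS without intercept), call presence/absence
# only for coefficients that are 0 or 1 with tiny standard errors, and keep
# variants concordant with each sire's QTL segregation status under the
# single-QTN assumption.

#' Partition a haploblock into fragments
#'
#' Contiguous windows `[start, start + width)` anchored at the block start,
#' the last truncated at the block end. Every member marker lands in exactly
#' one fragment.
#'
#' @param block a `haploblock`.
#' @param map the marker map the block indexes into.
#' @param width_bp fragment width (default 1 Mb).
#' @return object of class `fragment_catalog`: `fragments` data.frame
#'   (`frag`, `chrom`, `start`, `end`), `marker_frag` (fragment id per
#'   member marker), `block`.
#' @export
partition_fragments <- function(block, map, width_bp = 1e6) {
  stopifnot(width_bp > 0)
  span <- block$end_bp - block$start_bp
  n_frag <- max(1L, ceiling(span / width_bp))
  start <- block$start_bp + (seq_len(n_frag) - 1L) * width_bp
  end <- pmin(start + width_bp - 1, block$end_bp)
  frags <- data.frame(frag = seq_len(n_frag), chrom = block$chrom,
                      start = start, end = end)
  pos <- map$pos[block$markers]
  marker_frag <- pmin(n_frag, (pos - block$start_bp) %/% width_bp + 1L)
  structure(list(fragments = frags, marker_frag = as.integer(marker_frag),
                 block = block), class = "fragment_catalog")
}

#' Build the fragment-allele dosage matrix Q
#'
#' For each fragment, the distinct haplotype sub-sequences observed among
#' the sequenced animals' phased block haplotypes become candidate columns;
#' only alleles observed on at least `min_occurrences` haplotype copies are
#' retained (a column per retained allele, dosage = copies carried). Animals
#' carrying a dropped allele are flagged partially resolved. Fragments with
#' no retained allele are skipped with a warning.
#'
#' @param frag_cat a [partition_fragments()] result.
#' @param haplotypes named list: animal id -> 2 x m matrix of phased 0/1
#'   chip haplotypes over the block's member markers.
#' @param min_occurrences occurrence threshold (default 3, inclusive).
#' @return list of class `fragment_design`: `Q` (animals x retained
#'   alleles), `alleles` data.frame (`frag`, `column`, `sequence`, `count`),
#'   `partial` (logical per animal), `skipped` (fragment ids),
#'   `hap_alleles` (animals x 2 x fragments array of column indices or NA).
#' @export
build_Q <- function(frag_cat, haplotypes, min_occurrences = 3L) {
  animals <- names(haplotypes)
  n_frag <- nrow(frag_cat$fragments)
  cols <- list()
  hap_col <- array(NA_integer_, c(length(animals), 2L, n_frag),
                   dimnames = list(animals, NULL, NULL))
  partial <- setNames(rep(FALSE, length(animals)), animals)
  skipped <- integer(0)

  for (f in seq_len(n_frag)) {
    loci <- which(frag_cat$marker_frag == f)
    if (length(loci) == 0L) { skipped <- c(skipped, f); next }
    seqs <- character(0)
    hap_key <- matrix(NA_character_, length(animals), 2L)
    for (a in seq_along(animals)) {
      h <- haplotypes[[a]]
      for (cpy in 1:2) {
        sub <- h[cpy, loci]
        if (anyNA(sub)) next
        hap_key[a, cpy] <- paste(sub, collapse = "")
      }
    }
    tab <- table(hap_key)
    keep <- names(tab)[tab >= min_occurrences]
    if (length(keep) == 0L) {
      skipped <- c(skipped, f)
      warning("fragment ", f, " of block ", frag_cat$block$name,
              ": no haplotype allele observed on >= ", min_occurrences,
              " occasions; fragment skipped")
      next
    }
    for (k in seq_along(keep)) {
      cols[[length(cols) + 1L]] <- data.frame(
        frag = f, sequence = keep[k], count = as.integer(tab[keep[k]]),
        stringsAsFactors = FALSE)
    }
    base_col <- length(cols) - length(keep)
    for (a in seq_along(animals)) {
      for (cpy in 1:2) {
        key <- hap_key[a, cpy]
        if (is.na(key) || !(key %in% keep)) {
          partial[a] <- TRUE
        } else {
          hap_col[a, cpy, f] <- base_col + match(key, keep)
        }
      }
    }
  }
  alleles <- if (length(cols)) do.call(rbind, cols) else
    data.frame(frag = integer(0), sequence = character(0),
               count = integer(0))
  alleles$column <- seq_len(nrow(alleles))
  cn <- if (nrow(alleles)) paste0("f", alleles$frag, ".",
                                  ave(alleles$frag, alleles$frag,
                                      FUN = seq_along)) else character(0)
  Q <- matrix(0L, length(animals), nrow(alleles),
              dimnames = list(animals, cn))
  for (a in seq_along(animals)) {
    for (f in seq_len(n_frag)) {
      for (cpy in 1:2) {
        cc <- hap_col[a, cpy, f]
        if (!is.na(cc)) Q[a, cc] <- Q[a, cc] + 1L
      }
    }
  }
  structure(list(Q = Q, alleles = alleles, partial = partial,
                 skipped = skipped, hap_alleles = hap_col,
                 frag_cat = frag_cat), class = "fragment_design")
}

#' Regress one variant's dosage on fragment-allele dosages
#'
#' Ordinary least squares without intercept: `y = Q d + e`. Animals with
#' missing dosage are dropped pairwise. With fewer observations than
#' columns every coefficient is unreliable (no exception). Rank deficiency
#' is resolved by the minimum-norm solution; coefficients with support in
#' the null space are flagged unreliable. Standard errors come from the
#' residual variance and are defined as 0 when the residuals vanish
#' identically (including the saturated `n == rank` case).
#'
#' @param y alt-allele dosage vector (length = animals).
#' @param Q fragment-allele dosage matrix.
#' @return list with `d` (coefficients), `se`, and `flagged` (logical:
#'   rank-deficiency taint).
#' @export
regress_variant <- function(y, Q) {
  Q <- as.matrix(Q)
  keep <- !is.na(y)
  y <- as.numeric(y[keep]); Q <- Q[keep, , drop = FALSE]
  p <- ncol(Q); n <- nrow(Q)
  if (p == 0L) stop("Q has no retained columns")
  if (n < p) {
    return(list(d = rep(NA_real_, p), se = rep(Inf, p),
                flagged = rep(TRUE, p)))
  }
  sv <- svd(Q)
  tol <- max(dim(Q)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  flagged <- rep(FALSE, p)
  if (r == 0L) {
    return(list(d = rep(NA_real_, p), se = rep(Inf, p),
                flagged = rep(TRUE, p)))
  }
  dinv <- c(1 / sv$d[seq_len(r)], rep(0, p - r))
  d <- sv$v %*% (dinv * crossprod(sv$u, y))
  d <- as.numeric(d)
  if (r < p) {
    null_v <- sv$v[, (r + 1L):p, drop = FALSE]
    flagged <- rowSums(abs(null_v) > 1e-8) > 0
  }
  res <- y - Q %*% d
  rss <- sum(res^2)
  rdf <- n - r
  if (rss < 1e-10 * max(1, sum(y^2))) {
    se <- rep(0, p)
  } else if (rdf == 0L) {
    se <- rep(Inf, p)
  } else {
    sigma2 <- rss / rdf
    # (Q'Q)^+ diagonal via the SVD
    vd <- sv$v %*% diag(dinv^2, p)
    se <- sqrt(sigma2 * rowSums(vd * sv$v))
  }
  se[flagged] <- Inf
  list(d = d, se = se, flagged = flagged)
}

#' Call presence/absence of a variant on each fragment allele
#'
#' A coefficient imputes the variant as absent (0) or present (1) on its
#' allele only when it equals 0 or 1 to within `tol` and its standard error
#' is strictly below `se_max`; anything else — intermediate values, inflated
#' errors, rank-deficiency flags — is unreliable, tainting only that
#' allele's verdict.
#'
#' @param d,se coefficient and standard-error vectors from
#'   [regress_variant()].
#' @param tol numeric tolerance on "exactly 0 or 1" (default 1e-6).
#' @param se_max strict upper bound on the standard error (default 1e-4).
#' @return character vector of verdicts: `"absent"`, `"present"`,
#'   `"unreliable"`.
#' @export
call_assignment <- function(d, se, tol = 1e-6, se_max = 1e-4) {
  stopifnot(length(d) == length(se))
  verdict <- rep("unreliable", length(d))
  ok <- !is.na(d) & !is.na(se) & se < se_max
  near0 <- ok & abs(d) <= tol
  near1 <- ok & abs(d - 1) <= tol
  verdict[near0] <- "absent"
  verdict[near1] <- "present"
  verdict
}

#' Fine-map one haploblock against a sequence panel
#'
#' Runs the whole fragment pipeline: partitions the block, builds `Q` from
#' the sequenced animals' phased block haplotypes, regresses every SNP
#' variant inside the block on the allele columns of the fragment containing
#' it, and calls per-allele verdicts. Restricting each variant's regression
#' to its own fragment keeps the coefficients identifiable: for fully
#' resolved diploid animals the allele dosages of every fragment sum to 2,
#' so columns of different fragments are exactly collinear in a block-wide
#' design, whereas within one fragment the presence/absence coefficients
#' are estimable (and exactly 0/1 for haplotype-determined variants).
#'
#' @param block a `haploblock`.
#' @param map marker map.
#' @param vs a [variant_set()] (indels are ignored; only SNPs are
#'   considered).
#' @param haplotypes named list animal -> 2 x m phased block haplotypes for
#'   the sequenced animals.
#' @param width_bp fragment width.
#' @param min_occurrences allele occurrence threshold for `Q`.
#' @param tol,se_max verdict thresholds (see [call_assignment()]).
#' @return object of class `finemap_fit`: `design` (the `fragment_design`),
#'   `variants` (SNPs inside the block), `d`, `se` (variants x columns),
#'   `verdicts` (character matrix), `params`.
#' @export
finemap_block <- function(block, map, vs, haplotypes, width_bp = 1e6,
                          min_occurrences = 3L, tol = 1e-6, se_max = 1e-4) {
  fc <- partition_fragments(block, map, width_bp)
  des <- build_Q(fc, haplotypes, min_occurrences)
  if (ncol(des$Q) == 0L) stop("no retained fragment alleles in block ",
                              block$name)
  inb <- vs$variants$type == "SNP" &
    as.character(vs$variants$chrom) == block$chrom &
    vs$variants$pos >= block$start_bp & vs$variants$pos <= block$end_bp
  variants <- vs$variants[inb, , drop = FALSE]
  dosage <- vs$dosage[inb, , drop = FALSE]
  animals <- rownames(des$Q)
  dosage <- dosage[, animals, drop = FALSE]
  nv <- nrow(variants); p <- ncol(des$Q)
  var_frag <- pmin(nrow(fc$fragments),
                   (variants$pos - block$start_bp) %/% width_bp + 1L)
  d_mat <- se_mat <- matrix(NA_real_, nv, p,
                            dimnames = list(NULL, colnames(des$Q)))
  verdicts <- matrix("unreliable", nv, p,
                     dimnames = list(NULL, colnames(des$Q)))
  # animals with an unresolved copy in a fragment carry dosage from an
  # allele that has no column there; they are left out of that fragment's
  # regressions rather than allowed to contaminate the exact fit
  frag_rows <- lapply(seq_len(nrow(fc$fragments)), function(f) {
    which(!is.na(des$hap_alleles[, 1L, f]) &
            !is.na(des$hap_alleles[, 2L, f]))
  })
  for (v in seq_len(nv)) {
    cols <- which(des$alleles$frag == var_frag[v])
    rows <- frag_rows[[var_frag[v]]]
    if (length(cols) == 0L || length(rows) == 0L) next
    fit <- regress_variant(dosage[v, rows],
                           des$Q[rows, cols, drop = FALSE])
    d_mat[v, cols] <- fit$d
    se_mat[v, cols] <- fit$se
    verdicts[v, cols] <- call_assignment(fit$d, fit$se, tol, se_max)
  }
  structure(list(design = des, variants = variants, d = d_mat, se = se_mat,
                 verdicts = verdicts, var_frag = as.integer(var_frag),
                 params = list(width_bp = width_bp,
                               min_occurrences = min_occurrences,
                               tol = tol, se_max = se_max)),
            class = "finemap_fit")
}

#' @exportS3Method print finemap_fit
print.finemap_fit <- function(x, ...) {
  cat("finemap_fit:", nrow(x$variants), "SNPs x", ncol(x$d),
      "fragment alleles;",
      sum(apply(x$verdicts != "unreliable", 1, all)),
      "variants fully called\n")
  invisible(x)
}

#' Variants concordant with sire segregation status
#'
#' Under the single-QTN assumption, a sire heterozygous for the QTL must be
#' heterozygous at the QTN and a homozygous sire homozygous. For each
#' heterozygous sequenced sire the function retains variants whose verdicts
#' at the sire's two fragment alleles (in the variant's own fragment) are
#' present on exactly one of them; any variant whose verdicts make a
#' known-homozygous sequenced sire heterozygous is excluded globally. The
#' per-sire sets are intersected over `sires` (default: all heterozygous
#' sequenced sires with reliable verdicts).
#'
#' @param fm a [finemap_block()] result.
#' @param status data.frame with `sire` and `status` (`"het"`, `"hom"`, or
#'   `"unknown"`) for the sequenced animals.
#' @param sires optional sire ids over which to intersect.
#' @return object of class `concordant_set`: `per_sire` (named list of
#'   variant positions), `intersection` (positions), `excluded` (positions
#'   removed by the homozygous rule), `skipped_sires` (het sires lacking
#'   reliable verdicts, with reasons).
#' @export
concordant_variants <- function(fm, status, sires = NULL) {
  stopifnot(inherits(fm, "finemap_fit"))
  animals <- rownames(fm$design$Q)
  status <- status[status$sire %in% animals, , drop = FALSE]
  nv <- nrow(fm$variants)
  var_frag <- fm$var_frag

  # verdict pair of one animal at one variant; NA when not callable
  pair_verdicts <- function(animal, v) {
    f <- var_frag[v]
    ccs <- fm$design$hap_alleles[animal, , f]
    if (anyNA(ccs)) return(NULL)
    fm$verdicts[v, ccs]
  }

  excluded <- logical(nv)
  hom_sires <- status$sire[status$status == "hom"]
  for (sire in hom_sires) {
    for (v in seq_len(nv)) {
      vp <- pair_verdicts(sire, v)
      if (is.null(vp) || any(vp == "unreliable")) next
      if (vp[1L] != vp[2L]) excluded[v] <- TRUE
    }
  }

  het_sires <- status$sire[status$status == "het"]
  per_sire <- list(); skipped <- character(0)
  for (sire in het_sires) {
    hits <- integer(0)
    any_callable <- FALSE
    for (v in seq_len(nv)) {
      vp <- pair_verdicts(sire, v)
      if (is.null(vp) || any(vp == "unreliable")) next
      any_callable <- TRUE
      if (excluded[v]) next
      if (sum(vp == "present") == 1L) hits <- c(hits, v)
    }
    if (!any_callable) {
      skipped <- c(skipped, sire)
      next
    }
    per_sire[[sire]] <- fm$variants$pos[hits]
  }
  use <- if (is.null(sires)) names(per_sire) else
    intersect(as.character(sires), names(per_sire))
  inter <- if (length(use)) Reduce(intersect, per_sire[use]) else integer(0)
  structure(list(per_sire = per_sire, intersection = inter,
                 excluded = fm$variants$pos[excluded],
                 skipped_sires = skipped),
            class = "concordant_set")
}

#' @exportS3Method print concordant_set
print.concordant_set <- function(x, ...) {
  cat("concordant_set:", length(x$per_sire), "sire(s);",
      "per-sire counts:",
      paste(vapply(x$per_sire, length, 0L), collapse = ", "),
      "; intersection:", length(x$intersection), "variant(s)\n")
  invisible(x)
}
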