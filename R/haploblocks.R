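# Haploblock definition, half-sib phasing of sire haplotypes, assignment of
# each daughter's paternally inherited block allele, the rare-allele filter,
# and construction of the haplotype-allele dosage design matrix H.

#' Define haploblocks on a marker map
#'
#' Member markers are those whose position lies inside the region, inclusive
#' on both ends. A region containing no markers is an error.
#'
#' @param map marker map (`chrom`, `pos`) — typically `g$map`.
#' @param regions data.frame with columns `trait`, `chrom`, `start_bp`,
#'   `end_bp` and optionally `name`.
#' @return list of `haploblock` objects (fields `name`, `trait`, `chrom`,
#'   `start_bp`, `end_bp`, `markers` = map row indices).
#' @export
define_haploblocks <- function(map, regions) {
  if (!"name" %in% names(regions)) {
    regions$name <- paste(regions$trait, regions$chrom, sep = "_")
  }
  blocks <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (r$start_bp > r$end_bp) stop("region ", r$name, ": start > end")
    idx <- which(as.character(map$chrom) == as.character(r$chrom) &
                 map$pos >= r$start_bp & map$pos <= r$end_bp)
    if (length(idx) == 0L) {
      stop("region ", r$name, " (", r$chrom, ":", r$start_bp, "-", r$end_bp,
           ") contains no markers")
    }
    blocks[[i]] <- structure(
      list(name = r$name, trait = r$trait, chrom = as.character(r$chrom),
           start_bp = r$start_bp, end_bp = r$end_bp, markers = idx),
      class = "haploblock")
  }
  names(blocks) <- regions$name
  blocks
}

#' Haploblock width in megabases
#'
#' `(end_bp - start_bp) / 1e6`, rounded to two decimals. Accepts a single
#' `haploblock` or a data.frame with `start_bp`/`end_bp` columns (vectorised).
#'
#' @param b haploblock or data.frame.
#' @return numeric Mb width(s).
#' @export
block_width_mb <- function(b) {
  if (inherits(b, "haploblock")) {
    return(round((b$end_bp - b$start_bp) / 1e6, 2))
  }
  round((b$end_bp - b$start_bp) / 1e6, 2)
}

#' Bundled coordinates of the six fertility QTL haploblocks
#'
#' The previously reported QTL windows this analysis takes as given: three
#' heifer-pregnancy blocks (BTA 5, 14, 18) and three antral-follicle-count
#' blocks (BTA 8, 11, 22), with their published bp bounds and chip marker
#' counts.
#'
#' @return data.frame with `trait`, `chrom`, `start_bp`, `end_bp`, `n_snps`.
#' @export
qtl_block_table <- function() {
  data.frame(
    trait = c("HP", "HP", "HP", "NF", "NF", "NF"),
    chrom = c("5", "14", "18", "8", "11", "22"),
    start_bp = c(70420628L, 20344343L, 54016934L,
                 4159163L, 69411914L, 11935606L),
    end_bp = c(74518588L, 24418370L, 57969493L,
               7663923L, 73659167L, 15926677L),
    n_snps = c(99L, 97L, 97L, 99L, 99L, 95L),
    stringsAsFactors = FALSE)
}

#' Phase sire haplotypes within haploblocks from half-sib progeny
#'
#' For each sire and block, reconstructs the two haplotype sequences that are
#' consistent with the sire's own genotype and maximally consistent with the
#' progeny genotypes. Homozygous sire loci are forced; heterozygous loci are
#' linked greedily in map order: each progeny's paternal gamete identity is
#' voted from already-resolved loci (dosage 0 or 2 in the progeny pins the
#' paternal allele), and the new locus is phased by the majority vote of
#' progeny with a known gamete. Loci with no informative progeny, or with a
#' tied vote, remain `NA` (unresolved) and are skipped in downstream
#' consistency checks.
#'
#' @param g [genotype_matrix()].
#' @param ped pedigree table (links daughters to sires).
#' @param blocks list of haploblocks from [define_haploblocks()].
#' @param min_progeny minimum genotyped progeny needed to phase a sire.
#' @return nested list `phased[[block_name]][[sire_id]]` = 2 x m matrix of
#'   0/1/NA; a sire whose genotype is missing over more than half the block
#'   is skipped with a warning (entry `NULL`).
#' @export
phase_sire_blocks <- function(g, ped, blocks, min_progeny = 3L) {
  ids <- rownames(g$dosages)
  off <- ped[!is.na(ped$sire_id) & ped$animal_id %in% ids &
             ped$sire_id %in% ids, , drop = FALSE]
  fam <- split(off$animal_id, off$sire_id)
  fam <- fam[vapply(fam, length, 0L) >= min_progeny]

  out <- vector("list", length(blocks))
  names(out) <- names(blocks)
  for (bn in names(blocks)) {
    idx <- blocks[[bn]]$markers
    m <- length(idx)
    res <- list()
    for (sire in names(fam)) {
      gs <- g$dosages[sire, idx]
      if (sum(is.na(gs)) > m / 2) {
        warning("sire ", sire, " skipped in block ", bn,
                ": genotype missing over >50% of the block")
        res[sire] <- list(NULL)
        next
      }
      kids <- g$dosages[fam[[sire]], idx, drop = FALSE]
      res[[sire]] <- .phase_one_sire(gs, kids)
    }
    out[[bn]] <- res
  }
  out
}

# phase one sire over one block. gs: dosage vector; kids: progeny x loci.
.phase_one_sire <- function(gs, kids) {
  m <- length(gs)
  hA <- hB <- rep(NA_integer_, m)
  hom <- !is.na(gs) & gs %in% c(0L, 2L)
  hA[hom] <- hB[hom] <- as.integer(gs[hom] / 2L)
  het <- which(!is.na(gs) & gs == 1L)
  if (length(het) == 0L) {
    return(rbind(hA, hB))
  }
  # progeny paternal-allele constraints at sire-het loci: dosage 0 -> 0,
  # dosage 2 -> 1, else unknown
  P <- matrix(NA_integer_, nrow(kids), m)
  P[, het][kids[, het, drop = FALSE] == 0L] <- 0L
  P[, het][kids[, het, drop = FALSE] == 2L] <- 1L

  gametes <- function(resolved) {
    # 1 = carries hA, 2 = carries hB, per progeny, voted over resolved loci
    gam <- rep(NA_integer_, nrow(kids))
    for (o in seq_len(nrow(kids))) {
      vA <- sum(P[o, resolved] == hA[resolved], na.rm = TRUE)
      vB <- sum(P[o, resolved] == hB[resolved], na.rm = TRUE)
      if (vA > vB) gam[o] <- 1L else if (vB > vA) gam[o] <- 2L
    }
    gam
  }
  link <- function(l, resolved) {
    gam <- gametes(resolved)
    inf <- which(!is.na(gam) & !is.na(P[, l]))
    if (length(inf) == 0L) return(NA_integer_)
    v1 <- sum((gam[inf] == 1L & P[inf, l] == 1L) |
              (gam[inf] == 2L & P[inf, l] == 0L))
    v0 <- length(inf) - v1
    if (v1 > v0) 1L else if (v0 > v1) 0L else NA_integer_
  }

  # greedy chain in map order, then refinement passes: once most loci are
  # phased, progeny gametes are pinned well enough to recover the
  # stragglers that had no informative link early on
  resolved <- integer(0)
  for (l in het) {
    if (length(resolved) == 0L) {
      hA[l] <- 1L; hB[l] <- 0L           # anchor
      resolved <- l
      next
    }
    phi <- link(l, resolved)
    if (!is.na(phi)) {
      hA[l] <- phi; hB[l] <- 1L - phi
      resolved <- c(resolved, l)
    }
  }
  repeat {
    open <- setdiff(het, resolved)
    if (length(open) == 0L) break
    progressed <- FALSE
    for (l in open) {
      phi <- link(l, resolved)
      if (!is.na(phi)) {
        hA[l] <- phi; hB[l] <- 1L - phi
        resolved <- c(resolved, l)
        progressed <- TRUE
      }
    }
    if (!progressed) break               # genuinely unresolvable: stays NA
  }
  rbind(hA, hB)
}

#' Assign the paternally inherited haplotype allele of one offspring
#'
#' A sire haplotype `h` is consistent with the offspring when
#' `dosage - h` lies in \{0, 1\} at every non-missing member locus (the
#' remainder being a plausible maternal allele). Exactly one consistent
#' haplotype yields that assignment; none yields `"mismatch"`; both (for a
#' sire with two distinct alleles) yields `"ambiguous"`. Loci unresolved in
#' the sire phase (NA) are skipped.
#'
#' @param offspring_dosages dosage vector over the block's member loci.
#' @param sire_pair 2 x m matrix of the sire's phased haplotypes.
#' @return list with `status` (`"assigned"`, `"mismatch"`, `"ambiguous"`)
#'   and `which` (1 or 2, row of `sire_pair`, when assigned).
#' @export
assign_paternal_allele <- function(offspring_dosages, sire_pair) {
  consistent <- function(h) {
    use <- !is.na(offspring_dosages) & !is.na(h)
    if (!any(use)) return(NA)
    all((offspring_dosages[use] - h[use]) %in% c(0L, 1L))
  }
  cA <- consistent(sire_pair[1L, ])
  cB <- consistent(sire_pair[2L, ])
  if (is.na(cA) || is.na(cB)) return(list(status = "ambiguous", which = NA))
  same <- identical(sire_pair[1L, ], sire_pair[2L, ])
  if (cA && cB) {
    if (same) return(list(status = "assigned", which = 1L))
    return(list(status = "ambiguous", which = NA))
  }
  if (cA) return(list(status = "assigned", which = 1L))
  if (cB) return(list(status = "assigned", which = 2L))
  list(status = "mismatch", which = NA)
}

#' Build the haplotype-allele catalog for a set of blocks
#'
#' Enumerates the distinct, fully resolved sire haplotype sequences of each
#' block and labels them by order of first appearance, numbering running
#' across the blocks of a trait (so labels are globally unique within a
#' trait). Assigns each genotyped daughter her paternal allele via
#' [assign_paternal_allele()] and tallies offspring per (sire, allele).
#'
#' @param phased output of [phase_sire_blocks()].
#' @param blocks list of haploblocks.
#' @param g [genotype_matrix()].
#' @param ped pedigree table.
#' @return object of class `allele_catalog` with elements `alleles`
#'   (block, label, sequence string), `sire_pairs` (block, sire, a1, a2),
#'   `assignments` (block, animal, sire, label, status), `counts`
#'   (block, sire, label, n), and `blocks`.
#' @export
build_allele_catalog <- function(phased, blocks, g, ped) {
  ids <- rownames(g$dosages)
  alleles <- list(); sire_pairs <- list(); assignments <- list()
  next_label <- list()                       # per trait running counter

  for (bn in names(blocks)) {
    blk <- blocks[[bn]]
    idx <- blk$markers
    trait <- blk$trait
    if (is.null(next_label[[trait]])) next_label[[trait]] <- 1L
    seq_labels <- character(0)               # sequence string -> label
    lab_of <- function(seqv) {
      key <- paste(seqv, collapse = "")
      if (!key %in% names(seq_labels)) {
        seq_labels[[key]] <<- as.character(next_label[[trait]])
        next_label[[trait]] <<- next_label[[trait]] + 1L
      }
      as.integer(seq_labels[[key]])
    }
    for (sire in names(phased[[bn]])) {
      hp <- phased[[bn]][[sire]]
      if (is.null(hp) || anyNA(hp)) next     # unresolved sire: excluded here
      a1 <- lab_of(hp[1L, ]); a2 <- lab_of(hp[2L, ])
      sire_pairs[[length(sire_pairs) + 1L]] <- data.frame(
        block = bn, sire = sire, a1 = a1, a2 = a2, stringsAsFactors = FALSE)
      kids <- ped$animal_id[!is.na(ped$sire_id) & ped$sire_id == sire &
                            ped$animal_id %in% ids]
      for (kid in kids) {
        asn <- assign_paternal_allele(g$dosages[kid, idx], hp)
        lab <- if (asn$status == "assigned") c(a1, a2)[asn$which]
               else NA_integer_
        assignments[[length(assignments) + 1L]] <- data.frame(
          block = bn, animal = kid, sire = sire, label = lab,
          status = asn$status, stringsAsFactors = FALSE)
      }
    }
    for (key in names(seq_labels)) {
      alleles[[length(alleles) + 1L]] <- data.frame(
        block = bn, label = as.integer(seq_labels[[key]]), sequence = key,
        stringsAsFactors = FALSE)
    }
  }
  alleles <- do.call(rbind, alleles)
  sire_pairs <- do.call(rbind, sire_pairs)
  assignments <- do.call(rbind, assignments)
  counts <- aggregate(
    list(n = assignments$status == "assigned"),
    by = list(block = assignments$block, sire = assignments$sire,
              label = ifelse(is.na(assignments$label), -1L,
                             assignments$label)),
    FUN = sum)
  counts <- counts[counts$label > 0L & counts$n > 0L, , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(alleles = alleles, sire_pairs = sire_pairs,
                 assignments = assignments, counts = counts,
                 blocks = blocks),
            class = "allele_catalog")
}

#' @exportS3Method print allele_catalog
print.allele_catalog <- function(x, ...) {
  cat("allele_catalog:", nrow(x$alleles), "distinct alleles across",
      length(unique(x$alleles$block)), "block(s);",
      sum(x$assignments$status == "assigned"), "of",
      nrow(x$assignments), "offspring assigned\n")
  invisible(x)
}

#' Drop rare alleles and unusable assignments
#'
#' Offspring whose paternal assignment is a mismatch, ambiguous, or maps to
#' a (sire, allele) combination observed in fewer than `min_offspring`
#' daughters of that sire are excluded from downstream design matrices.
#' Allele labels are preserved; only usability flags change.
#'
#' @param cat an `allele_catalog`.
#' @param min_offspring minimum daughters per (sire, allele) (default 3,
#'   inclusive: exactly 3 is retained).
#' @return the catalog with a logical `usable` column added to
#'   `$assignments` and the retained counts in `$counts`.
#' @export
filter_alleles <- function(cat, min_offspring = 3L) {
  a <- cat$assignments
  key <- paste(a$block, a$sire, a$label, sep = "\r")
  ckey <- paste(cat$counts$block, cat$counts$sire, cat$counts$label,
                sep = "\r")
  n_of <- setNames(cat$counts$n, ckey)
  a$usable <- a$status == "assigned" & !is.na(a$label) &
    !is.na(n_of[key]) & n_of[key] >= min_offspring
  cat$assignments <- a
  cat$counts <- cat$counts[cat$counts$n >= min_offspring, , drop = FALSE]
  cat$min_offspring <- min_offspring
  cat
}

#' Build the haplotype-allele dosage design matrix H
#'
#' One column per retained allele of the block; a daughter's paternal
#' assignment contributes 1 to its allele's column. The maternal contribution
#' adds another 1 only when the maternal residue (offspring dosage minus the
#' paternal haplotype) is itself a 0/1 vector matching a catalog allele of
#' the block exactly; otherwise only the paternal copy is counted.
#'
#' @param cat a filtered `allele_catalog` (see [filter_alleles()]).
#' @param block_name which block.
#' @param g [genotype_matrix()].
#' @param animals animal ids for the rows (typically the phenotyped
#'   daughters); animals without a usable assignment get a zero row and are
#'   reported in `attr(, "unassigned")`.
#' @return integer matrix `length(animals)` x `n alleles`, columns named by
#'   allele label.
#' @export
build_design <- function(cat, block_name, g, animals) {
  if (is.null(cat$assignments$usable)) {
    stop("catalog not filtered; call filter_alleles() first")
  }
  blk <- cat$blocks[[block_name]]
  idx <- blk$markers
  al <- cat$alleles[cat$alleles$block == block_name, , drop = FALSE]
  seq_of <- lapply(strsplit(al$sequence, ""), as.integer)
  names(seq_of) <- as.character(al$label)
  labs <- sort(al$label)
  H <- matrix(0L, length(animals), length(labs),
              dimnames = list(animals, as.character(labs)))
  asn <- cat$assignments
  asn <- asn[asn$block == block_name & asn$usable, , drop = FALSE]
  asn <- asn[match(animals, asn$animal), , drop = FALSE]
  unassigned <- animals[is.na(asn$animal)]
  for (i in seq_along(animals)) {
    if (is.na(asn$animal[i])) next
    lab <- as.character(asn$label[i])
    H[i, lab] <- H[i, lab] + 1L
    pat <- seq_of[[lab]]
    dos <- g$dosages[animals[i], idx]
    res <- dos - pat
    if (!anyNA(res) && all(res %in% c(0L, 1L))) {
      mkey <- paste(res, collapse = "")
      hit <- al$label[al$sequence == mkey]
      if (length(hit) == 1L) {
        H[i, as.character(hit)] <- H[i, as.character(hit)] + 1L
      }
    }
  }
  attr(H, "unassigned") <- unassigned
  attr(H, "block") <- block_name
  H
}
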