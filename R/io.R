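# Readers/writers for the external formats the pipeline touches, plus the
# sequence-variant quality filter. Coordinates are 1-based inclusive
# everywhere internally; BED input is converted on ingest.

#' Construct a genotype matrix
#'
#' Container for allele dosages (animals x loci) together with a marker map.
#' Loci are sorted by (chromosome, position); dosages must be 0, 1, 2 or NA.
#'
#' @param dosages integer matrix, animals in rows (rownames are animal ids),
#'   loci in columns. Values in \{0, 1, 2\} or `NA` for missing.
#' @param map data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`, one row per locus, aligned with the columns of `dosages`.
#' @return An object of class `genotype_matrix` with elements `dosages` and
#'   `map`.
#' @export
genotype_matrix <- function(dosages, map) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) {
    stop("dosages must carry animal ids as rownames")
  }
  if (anyDuplicated(rownames(dosages))) {
    stop("duplicate animal id in genotype matrix: ",
         rownames(dosages)[duplicated(rownames(dosages))][1L])
  }
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(map))
  if (length(miss)) stop("marker map lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(map) != ncol(dosages)) {
    stop("marker map rows (", nrow(map), ") != dosage columns (",
         ncol(dosages), ")")
  }
  bad <- !(dosages %in% c(0L, 1L, 2L)) & !is.na(dosages)
  if (any(bad)) stop("dosage values outside {0,1,2,NA}")
  storage.mode(dosages) <- "integer"
  if (any(map$pos < 1L)) stop("marker positions must be 1-based (>= 1)")
  ord <- order(as.character(map$chrom), map$pos)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  colnames(dosages) <- paste(map$chrom, map$pos, sep = ":")
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' @exportS3Method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "animals x", ncol(x$dosages),
      "loci on", length(unique(x$map$chrom)), "chromosome(s)\n")
  nmiss <- sum(is.na(x$dosages))
  cat("  missing calls:", nmiss,
      sprintf("(%.2f%%)\n", 100 * nmiss / length(x$dosages)))
  invisible(x)
}

# dosage from a GT string: number of non-reference allele codes.
.gt_to_dosage <- function(gt) {
  gt <- sub(":.*$", "", gt)
  out <- integer(length(gt))
  alleles <- strsplit(gt, "[/|]")
  for (i in seq_along(alleles)) {
    a <- alleles[[i]]
    if (length(a) == 0L || any(a == ".") || any(is.na(a))) {
      out[i] <- NA_integer_
    } else {
      out[i] <- sum(a != "0")
    }
  }
  out
}

#' Read chip genotypes from VCF or a dosage table
#'
#' `.vcf` files are parsed with \pkg{vcfR}; heterozygous calls map to dosage 1
#' regardless of phase. Any other extension is read as a tab-separated dosage
#' table whose first four columns are `chrom`, `pos`, `ref`, `alt` followed by
#' one column per animal. Output loci are sorted by (chromosome, position).
#'
#' @param path input file.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("failed to parse VCF '", path,
                                           "': ", conditionMessage(e)))
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) stop("VCF '", path, "' contains no records")
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(gt) || ncol(gt) == 0L) stop("VCF '", path, "' has no samples")
    if (anyDuplicated(colnames(gt))) {
      stop("duplicate sample id in '", path, "': ",
           colnames(gt)[duplicated(colnames(gt))][1L])
    }
    dos <- apply(gt, 2L, .gt_to_dosage)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L,
                                         dimnames = list(NULL, colnames(gt)))
    dos <- t(dos)                       # animals x loci
    map <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
    genotype_matrix(dos, map)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab)[1:4])) {
      stop("dosage table '", path,
           "' must start with columns chrom, pos, ref, alt")
    }
    samp <- setdiff(names(tab), need)
    if (length(samp) == 0L) stop("dosage table '", path, "' has no samples")
    if (anyDuplicated(samp)) stop("duplicate sample id in '", path, "'")
    dos <- t(as.matrix(tab[, samp, drop = FALSE]))
    rownames(dos) <- samp
    genotype_matrix(dos, tab[, need])
  }
}

#' Write chip genotypes
#'
#' `.vcf` paths get a minimal VCF 4.2 with GT fields (`|`-phased records can
#' be requested per animal via `phased`); anything else is written as the
#' tab-separated dosage table accepted by [read_genotypes()]. Heterozygous
#' dosages are emitted as `0/1`.
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @param phased optional named list: for an animal id, a 2 x loci 0/1 matrix
#'   of haplotypes written as phased GT.
#' @export
write_genotypes <- function(g, path, phased = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    ids <- rownames(g$dosages)
    hdr <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"))
    gt_txt <- c("0/0", "0/1", "1/1")
    lines <- character(nrow(g$map))
    for (l in seq_len(nrow(g$map))) {
      cells <- character(length(ids))
      for (a in seq_along(ids)) {
        d <- g$dosages[a, l]
        if (is.na(d)) {
          cells[a] <- "./."
        } else if (!is.null(phased) && ids[a] %in% names(phased)) {
          h <- phased[[ids[a]]]
          cells[a] <- paste(h[1L, l], h[2L, l], sep = "|")
        } else {
          cells[a] <- gt_txt[d + 1L]
        }
      }
      lines[l] <- paste(c(g$map$chrom[l], g$map$pos[l], ".", g$map$ref[l],
                          g$map$alt[l], ".", "PASS", ".", "GT", cells),
                        collapse = "\t")
    }
    writeLines(c(hdr, lines), path)
  } else {
    tab <- cbind(g$map[, c("chrom", "pos", "ref", "alt")],
                 as.data.frame(t(g$dosages)))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# walk ancestors; error on a cycle through `start`
.check_no_self_ancestry <- function(ped) {
  parents <- split(c(ped$sire_id, ped$dam_id),
                   rep(ped$animal_id, 2L))
  for (start in ped$animal_id) {
    seen <- character(0)
    frontier <- start
    while (length(frontier)) {
      up <- unique(unlist(parents[frontier], use.names = FALSE))
      up <- up[!is.na(up) & up != ""]
      if (start %in% up) stop("pedigree cycle: animal '", start,
                              "' is its own ancestor")
      up <- setdiff(up, seen)
      seen <- c(seen, up)
      frontier <- intersect(up, names(parents))
    }
  }
  invisible(TRUE)
}

#' Read a pedigree table
#'
#' Expects a delimited file with header columns `animal_id`, `sire_id`,
#' `dam_id`, `herd`, `birth_year`, `age_at_ai` (months). Empty parent fields
#' become `NA`. Fails on cycles (an animal being its own ancestor) and on
#' negative ages.
#'
#' @param path CSV/TSV file.
#' @return data.frame of class `pedigree_table`.
#' @export
read_pedigree <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  ped <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("animal_id", "sire_id", "dam_id", "herd", "birth_year",
            "age_at_ai")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop("pedigree lacks column(s): ",
                         paste(miss, collapse = ", "))
  ped$animal_id <- as.character(ped$animal_id)
  ped$sire_id <- as.character(ped$sire_id); ped$sire_id[ped$sire_id == ""] <- NA
  ped$dam_id <- as.character(ped$dam_id);   ped$dam_id[ped$dam_id == ""] <- NA
  if (anyDuplicated(ped$animal_id)) stop("duplicate animal_id in pedigree")
  if (any(!is.na(ped$age_at_ai) & ped$age_at_ai < 0)) {
    stop("negative age_at_ai in pedigree")
  }
  .check_no_self_ancestry(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Write a pedigree table
#' @param ped pedigree data.frame.
#' @param path output CSV (or TSV by extension).
#' @export
write_pedigree <- function(ped, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(ped, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Columns: `animal_id`, `hp` (binary 0/1 or NA), `nf` (non-negative integer
#' count or NA). A contemporary-group column `cg` is accepted if present but
#' normally assigned later by [form_contemporary_groups()].
#'
#' @param path CSV/TSV file.
#' @return data.frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  ph <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("animal_id", "hp", "nf")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ph$animal_id <- as.character(ph$animal_id)
  if (any(!is.na(ph$hp) & !(ph$hp %in% c(0, 1)))) {
    stop("hp must be 0, 1 or missing")
  }
  if (any(!is.na(ph$nf) & ph$nf < 0)) stop("nf must be non-negative")
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' Write a phenotype table
#' @param ph phenotype data.frame.
#' @param path output CSV (or TSV by extension).
#' @export
write_phenotypes <- function(ph, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(ph, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation intervals
#'
#' BED (0-based half-open, converted to 1-based inclusive on ingest) and
#' GFF3/GTF (`type == "gene"` records) are parsed with \pkg{rtracklayer};
#' `.csv`/`.tsv` files are read directly and must carry columns `gene_id`,
#' `chrom`, `start`, `end` (1-based inclusive) and optionally `symbol`.
#'
#' @param path annotation file.
#' @return data.frame of class `gene_table` with columns `gene_id`, `symbol`,
#'   `chrom`, `start`, `end`.
#' @export
read_genes <- function(path) {
  if (grepl("\\.(bed|gff3?|gtf)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading BED/GFF requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    md <- as.data.frame(gr)
    if (grepl("\\.gff3?$|\\.gtf$", path, ignore.case = TRUE) &&
        "type" %in% names(md)) {
      md <- md[md$type == "gene", , drop = FALSE]
    }
    gid <- if ("ID" %in% names(md)) as.character(md$ID)
           else if ("gene_id" %in% names(md)) as.character(md$gene_id)
           else if ("name" %in% names(md)) as.character(md$name)
           else paste0("gene_", seq_len(nrow(md)))
    sym <- if ("Name" %in% names(md)) as.character(md$Name)
           else if ("gene_name" %in% names(md)) as.character(md$gene_name)
           else gid
    genes <- data.frame(gene_id = gid, symbol = sym,
                        chrom = as.character(md$seqnames),
                        start = md$start, end = md$end,
                        stringsAsFactors = FALSE)
  } else {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    genes <- read.table(path, header = TRUE, sep = sep,
                        stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    miss <- setdiff(need, names(genes))
    if (length(miss)) stop("gene table lacks column(s): ",
                           paste(miss, collapse = ", "))
    if (!"symbol" %in% names(genes)) genes$symbol <- genes$gene_id
    genes <- genes[, c("gene_id", "symbol", "chrom", "start", "end")]
    genes$chrom <- as.character(genes$chrom)
  }
  if (any(genes$start > genes$end)) stop("gene with start > end")
  class(genes) <- c("gene_table", "data.frame")
  genes
}

#' Construct a sequence variant set
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `qual` (phred), `type` (`"SNP"` or `"indel"`).
#' @param dosage variants x animals matrix of alt-allele dosages (0/1/2/NA)
#'   for the sequenced panel; column names are animal ids.
#' @param depth variants x animals matrix of per-sample read depth.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(variants, dosage, depth) {
  need <- c("chrom", "pos", "ref", "alt", "qual", "type")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(variants$pos < 1L)) stop("variant positions must be 1-based")
  dosage <- as.matrix(dosage); depth <- as.matrix(depth)
  stopifnot(nrow(dosage) == nrow(variants), nrow(depth) == nrow(variants),
            identical(dim(dosage), dim(depth)))
  if (is.null(colnames(dosage))) stop("dosage matrix needs animal ids")
  bad <- !(dosage %in% c(0L, 1L, 2L)) & !is.na(dosage)
  if (any(bad)) stop("variant dosages outside {0,1,2,NA}")
  rownames(variants) <- NULL
  structure(list(variants = variants, dosage = dosage, depth = depth),
            class = "variant_set")
}

#' @exportS3Method print variant_set
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x", ncol(x$dosage),
      "sequenced animals;", sum(x$variants$type == "SNP"), "SNPs,",
      sum(x$variants$type != "SNP"), "indels\n")
  invisible(x)
}

#' Read sequenced-sire variant calls from VCF
#'
#' Keeps QUAL and per-sample DP; GT dosage is the count of non-reference
#' alleles. Records where REF and ALT are both single bases are typed `SNP`,
#' anything else `indel`.
#'
#' @param path VCF file.
#' @return A [variant_set()].
#' @export
read_variants <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path,
                                         "': ", conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt),
                                dimnames = dimnames(gt))
  dos <- apply(gt, 2L, .gt_to_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L,
                                       dimnames = list(NULL, colnames(gt)))
  type <- ifelse(nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L, "SNP", "indel")
  variant_set(
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
               alt = fix$ALT, qual = as.numeric(fix$QUAL), type = type,
               stringsAsFactors = FALSE),
    dosage = dos, depth = dp)
}

#' Write a variant set as VCF with GT:DP fields
#'
#' Phase separators are preserved as `|` when `phased = TRUE` and the dosage
#' is homozygous or missing-phase information is irrelevant; heterozygotes
#' are written `0|1` in that case.
#'
#' @param vs a [variant_set()].
#' @param path output `.vcf` path.
#' @param phased write `|`-separated genotypes.
#' @export
write_variants <- function(vs, path, phased = FALSE) {
  stopifnot(inherits(vs, "variant_set"))
  ids <- colnames(vs$dosage)
  sepc <- if (phased) "|" else "/"
  gt_txt <- paste0(c("0", "0", "1"), sepc, c("0", "1", "1"))
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  lines <- character(nrow(vs$variants))
  for (i in seq_len(nrow(vs$variants))) {
    cells <- character(length(ids))
    for (a in seq_along(ids)) {
      d <- vs$dosage[i, a]
      g <- if (is.na(d)) paste0(".", sepc, ".") else gt_txt[d + 1L]
      dp <- vs$depth[i, a]
      cells[a] <- paste0(g, ":", if (is.na(dp)) "." else dp)
    }
    lines[i] <- paste(c(vs$variants$chrom[i], vs$variants$pos[i], ".",
                        vs$variants$ref[i], vs$variants$alt[i],
                        format(vs$variants$qual[i], trim = TRUE), "PASS", ".",
                        "GT:DP", cells), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Filter sequence variants on call quality and read depth
#'
#' Retains variants with site QUAL at or above `qual_min`. The depth filter
#' is applied per sample: calls with depth below `dp_min` are set to missing,
#' and a variant is dropped when every sample call becomes missing. Input
#' order is preserved. The operation is idempotent and monotone: raising
#' either threshold never adds variants.
#'
#' @param vs a [variant_set()].
#' @param qual_min minimum phred site quality (default 20).
#' @param dp_min minimum per-sample read depth (default 4).
#' @return filtered [variant_set()].
#' @export
filter_sequence_variants <- function(vs, qual_min = 20, dp_min = 4) {
  stopifnot(inherits(vs, "variant_set"), qual_min >= 0, dp_min >= 0)
  keep <- !is.na(vs$variants$qual) & vs$variants$qual >= qual_min
  dos <- vs$dosage
  if (dp_min > 0) {
    # unknown depth cannot demonstrate DP >= dp_min, so it fails too
    low <- is.na(vs$depth) | vs$depth < dp_min
    dos[low] <- NA_integer_
  }
  keep <- keep & rowSums(!is.na(dos)) > 0L
  variant_set(vs$variants[keep, , drop = FALSE],
              dos[keep, , drop = FALSE],
              vs$depth[keep, , drop = FALSE])
}
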