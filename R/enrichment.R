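# Gene assignment by interval containment and hypergeometric
# over-representation analysis over user-supplied gene sets (GMT files).

#' Assign variants to genes by containment
#'
#' A variant is assigned to a gene only when its position lies within the
#' gene's genomic interval, `start <= pos <= end` (1-based inclusive);
#' overlapping genes each receive the variant, and variants hitting no gene
#' are labelled intergenic.
#'
#' @param positions data.frame with `chrom` and `pos` (e.g. from a
#'   `concordant_set`, or any variant table).
#' @param genes a `gene_table` from [read_genes()].
#' @return list with `per_variant` (data.frame `chrom`, `pos`, `gene_id` —
#'   one row per hit, `gene_id` `NA` for intergenic variants) and
#'   `per_gene` (data.frame `gene_id`, `symbol`, `n_variants`).
#' @export
assign_variants_to_genes <- function(positions, genes) {
  if (!all(c("chrom", "pos") %in% names(positions))) {
    stop("positions need columns chrom and pos")
  }
  rows <- list()
  for (i in seq_len(nrow(positions))) {
    hit <- which(genes$chrom == as.character(positions$chrom[i]) &
                 genes$start <= positions$pos[i] &
                 genes$end >= positions$pos[i])
    if (length(hit) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = positions$chrom[i], pos = positions$pos[i],
        gene_id = NA_character_, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = positions$chrom[i], pos = positions$pos[i],
        gene_id = genes$gene_id[hit], stringsAsFactors = FALSE)
    }
  }
  per_variant <- do.call(rbind, rows)
  hits <- per_variant[!is.na(per_variant$gene_id), , drop = FALSE]
  cnt <- table(hits$gene_id)
  per_gene <- data.frame(gene_id = names(cnt),
                         n_variants = as.integer(cnt),
                         stringsAsFactors = FALSE)
  per_gene$symbol <- genes$symbol[match(per_gene$gene_id, genes$gene_id)]
  list(per_variant = per_variant,
       per_gene = per_gene[, c("gene_id", "symbol", "n_variants")])
}

#' Hypergeometric over-representation p-value
#'
#' Probability of observing `g` or more target genes in a term of size `k`,
#' for `S` target genes among `N` analysed: the upper tail of the
#' hypergeometric distribution, accumulated in log space from binomial
#' coefficients (`lchoose`). `g = 0` gives `p = 1` by the empty-sum
#' convention.
#'
#' @param S total target genes.
#' @param N total genes analysed (universe).
#' @param k genes in the term.
#' @param g target genes in the term.
#' @return p-value in \[0, 1\].
#' @export
ora_pvalue <- function(S, N, k, g) {
  if (any(c(S, N, k, g) < 0)) stop("counts must be non-negative")
  if (S > N || k > N) stop("S and k must not exceed N")
  if (g > min(S, k)) stop("g must not exceed min(S, k)")
  if (g == 0) return(1)
  i <- seq.int(g, min(S, k))
  log_terms <- lchoose(S, i) + lchoose(N - S, k - i) - lchoose(N, k)
  mx <- max(log_terms)
  p <- exp(mx) * sum(exp(log_terms - mx))
  min(max(p, 0), 1)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line, tab-separated, fields `term`,
#' `description`, then member gene ids.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    out[[parts[1L]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Over-representation analysis over a list of gene sets
#'
#' Gene ids are deduplicated; each term is intersected with the universe
#' before counting. Results are sorted by p-value, flagged significant at
#' 0.05 (no multiplicity correction is applied).
#'
#' @param target_genes character vector of target gene ids.
#' @param universe character vector of analysed gene ids.
#' @param term_sets named list of gene-id vectors, or a GMT path.
#' @return data.frame of class `ora_result` with `term`, `S`, `N`, `k`,
#'   `g`, `p_value`, `significant`.
#' @export
run_ora <- function(target_genes, universe, term_sets) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  if (is.character(term_sets) && length(term_sets) == 1L &&
      file.exists(term_sets)) {
    term_sets <- read_gmt(term_sets)
  }
  target <- intersect(unique(as.character(target_genes)), universe)
  S <- length(target); N <- length(universe)
  rows <- lapply(names(term_sets), function(tm) {
    members <- intersect(unique(term_sets[[tm]]), universe)
    k <- length(members)
    g <- length(intersect(members, target))
    data.frame(term = tm, S = S, N = N, k = k, g = g,
               p_value = ora_pvalue(S, N, k, g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < 0.05
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}
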