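# Model configuration, the fitting front end around the compiled Gibbs
# sampler, and methods on the fitted object.

#' Bayes B model configuration
#'
#' @param pi mixture null-probability: a SNP effect is exactly zero with
#'   probability `pi` (default 0.999).
#' @param chain_length total MCMC iterations. The full-scale protocol is
#'   90000 iterations with 2000 burn-in, keeping every 100th of the
#'   remaining 88000 (880 retained draws); the desk-scale default is
#'   6000/1000/5.
#' @param burn_in iterations discarded before retention.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed RNG seed; mandatory for reproducibility.
#' @param trait_type `"binary"` (liability threshold model, residual
#'   variance fixed at 1, threshold at 0) or `"continuous"`.
#' @param nu_s,nu_e prior degrees of freedom for the locus and residual
#'   scaled inverse chi-squared variances.
#' @param genetic_var,residual_var optional prior guesses; defaults are
#'   derived from the phenotypic variance at fit time (half each).
#' @return list of class `bayesb_config`.
#' @export
model_config <- function(pi = 0.999, chain_length = 6000L, burn_in = 1000L,
                         thin = 5L, seed,
                         trait_type = c("continuous", "binary"),
                         nu_s = 4.2, nu_e = 10,
                         genetic_var = NULL, residual_var = NULL) {
  if (missing(seed)) stop("model_config: seed is mandatory")
  trait_type <- match.arg(trait_type)
  if (pi <= 0 || pi >= 1) stop("pi must lie strictly in (0, 1)")
  if (burn_in >= chain_length) stop("burn_in must be < chain_length")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(pi = pi, chain_length = as.integer(chain_length),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), trait_type = trait_type,
                 nu_s = nu_s, nu_e = nu_e, genetic_var = genetic_var,
                 residual_var = residual_var),
            class = "bayesb_config")
}

#' Fit the Bayes B haploblock model
#'
#' Fits `y = F b + H h + X s + e` by single-site Gibbs sampling: `b` holds
#' contemporary-group effects and an age regression (flat priors), `h` the
#' fixed effects of the haplotype alleles of one block, and `s` genome-wide
#' SNP effects under a mixture prior in which each effect is zero with
#' probability `pi` and otherwise normal with its own scaled-inverse-
#' chi-squared variance. Binary traits use latent liabilities truncated at
#' zero with residual variance fixed at 1. The intercept is absorbed into
#' the contemporary-group effects, and the first haplotype column is dropped
#' as the reference (contrasts between alleles are invariant to this
#' choice); its effect is reported as 0.
#'
#' @param y numeric response (0/1 for binary traits). Missing values are
#'   dropped together with their design rows.
#' @param F fixed-effect design matrix (contemporary groups, age).
#' @param H haplotype-allele dosage design (columns named by allele label),
#'   or `NULL`.
#' @param X SNP dosage matrix excluding the fitted block's members. Missing
#'   dosages are imputed at twice the observed allele frequency and all
#'   columns are centred.
#' @param config a [model_config()].
#' @param keep_liab retain latent liability draws (binary trait only).
#' @return object of class `bayesb_fit`: retained draws of the fixed and
#'   haplotype effects (`fixed_draws`, `hap_draws` — the latter includes the
#'   reference column as zeros), SNP draws (`snp_draws`), posterior SNP
#'   inclusion rates (`delta_mean`), residual variance draws, and metadata.
#' @export
fit_bayesb <- function(y, F, H = NULL, X, config, keep_liab = FALSE) {
  stopifnot(inherits(config, "bayesb_config"))
  F <- as.matrix(F)
  if (!is.null(H)) H <- as.matrix(H)
  X <- as.matrix(X)
  keep <- !is.na(y)
  y <- y[keep]; F <- F[keep, , drop = FALSE]; X <- X[keep, , drop = FALSE]
  if (!is.null(H)) H <- H[keep, , drop = FALSE]
  n <- length(y)
  if (n < 2L) stop("need at least 2 non-missing records")

  hap_labels <- ref_label <- NULL
  Hred <- NULL
  if (!is.null(H) && ncol(H) > 0L) {
    if (is.null(colnames(H))) colnames(H) <- seq_len(ncol(H))
    hap_labels <- colnames(H)
    ref_label <- hap_labels[1L]
    Hred <- H[, -1L, drop = FALSE]
  }
  W <- cbind(F, Hred)
  qr_w <- qr(W)
  if (qr_w$rank < ncol(W)) {
    bad <- colnames(W)[qr_w$pivot[(qr_w$rank + 1L):ncol(W)]]
    stop("fixed design is rank deficient; confounded column(s): ",
         paste(bad, collapse = ", "))
  }

  # centred imputation of missing SNP dosages at twice the allele frequency
  pbar <- colMeans(X, na.rm = TRUE)       # = 2 * allele frequency
  pbar[is.nan(pbar)] <- 0
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    xj[is.na(xj)] <- pbar[j]
    X[, j] <- xj - pbar[j]
  }

  binary <- config$trait_type == "binary"
  vary <- stats::var(y)
  if (binary) {
    if (!all(y %in% c(0, 1))) stop("binary trait must be coded 0/1")
    gvar <- if (is.null(config$genetic_var)) 0.5 else config$genetic_var
    scale_e <- 1
    y_init <- ifelse(y == 1, 0.5, -0.5)
  } else {
    gvar <- if (is.null(config$genetic_var)) max(vary / 2, 1e-8)
            else config$genetic_var
    evar <- if (is.null(config$residual_var)) max(vary / 2, 1e-8)
            else config$residual_var
    scale_e <- evar * (config$nu_e - 2) / config$nu_e
    y_init <- y
  }
  sum2pq <- sum(apply(X, 2L, stats::var)) + 1e-12
  scale_s <- gvar * (config$nu_s - 2) / config$nu_s /
    ((1 - config$pi) * sum2pq)

  set.seed(config$seed)
  res <- bayesb_gibbs(as.numeric(y_init), as.integer(y), binary,
                      W, X, config$pi, config$chain_length, config$burn_in,
                      config$thin, config$nu_s, scale_s, config$nu_e,
                      scale_e, keep_liab && binary)

  colnames(res$fixed) <- colnames(W)
  hap_draws <- NULL
  if (!is.null(hap_labels)) {
    hap_draws <- matrix(0, nrow(res$fixed), length(hap_labels),
                        dimnames = list(NULL, hap_labels))
    if (length(hap_labels) > 1L) {
      hap_draws[, hap_labels[-1L]] <-
        res$fixed[, colnames(Hred), drop = FALSE]
    }
  }
  colnames(res$snp) <- colnames(X)
  structure(list(
    fixed_draws = res$fixed[, colnames(F), drop = FALSE],
    hap_draws = hap_draws, ref_allele = ref_label,
    snp_draws = res$snp, delta_mean = as.numeric(res$delta_mean),
    sigma_e_draws = as.numeric(res$sigma_e),
    liab_draws = if (keep_liab && binary) res$liab else NULL,
    y = y, W = W, F_cols = colnames(F),
    n = n, n_snp = ncol(X), n_retained = res$n_retained,
    config = config), class = "bayesb_fit")
}

#' @exportS3Method print bayesb_fit
print.bayesb_fit <- function(x, ...) {
  cat("Bayes B fit (", x$config$trait_type, " trait)\n", sep = "")
  cat("  records:", x$n, " SNPs:", x$n_snp,
      if (!is.null(x$hap_draws))
        paste(" haplotype alleles:", ncol(x$hap_draws)), "\n")
  cat("  chain:", x$config$chain_length, "iterations, burn-in",
      x$config$burn_in, ", thin", x$config$thin, "->", x$n_retained,
      "retained draws\n")
  cat("  pi:", x$config$pi, "\n")
  invisible(x)
}

#' @exportS3Method coef bayesb_fit
coef.bayesb_fit <- function(object, ...) {
  out <- colMeans(object$fixed_draws)
  if (!is.null(object$hap_draws)) {
    h <- colMeans(object$hap_draws)
    names(h) <- paste0("hap", names(h))
    out <- c(out, h)
  }
  out
}

#' @exportS3Method fitted bayesb_fit
fitted.bayesb_fit <- function(object, ...) {
  bbar <- colMeans(cbind(object$fixed_draws,
                         if (!is.null(object$hap_draws))
                           object$hap_draws[, -1L, drop = FALSE]))
  as.numeric(object$W %*% bbar)
}

#' @exportS3Method residuals bayesb_fit
residuals.bayesb_fit <- function(object, ...) {
  if (object$config$trait_type == "binary") {
    stop("residuals are defined on the liability scale; refit with ",
         "keep_liab = TRUE and use liab_draws")
  }
  object$y - fitted(object)
}

#' @exportS3Method summary bayesb_fit
summary.bayesb_fit <- function(object, ...) {
  s <- posterior_summary(object)
  structure(list(fit = object, table = s), class = "summary.bayesb_fit")
}

#' @exportS3Method print summary.bayesb_fit
print.summary.bayesb_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPosterior summaries (fixed and haplotype effects):\n")
  print(round(x$table, 4))
  invisible(x)
}

#' @exportS3Method plot bayesb_fit
plot.bayesb_fit <- function(x, what = c("sigma_e", "hap"), ...) {
  what <- match.arg(what)
  if (what == "sigma_e") {
    graphics::plot(x$sigma_e_draws, type = "l",
                   xlab = "retained draw", ylab = "residual variance", ...)
  } else {
    if (is.null(x$hap_draws)) stop("fit has no haplotype effects")
    graphics::matplot(x$hap_draws, type = "l", lty = 1,
                      xlab = "retained draw",
                      ylab = "haplotype allele effect", ...)
  }
  invisible(x)
}

#' Posterior summaries of retained draws
#'
#' Mean, SD and the central 90% interval of each fixed and haplotype-allele
#' effect, computed over retained draws only. Interval endpoints are order
#' statistics of the sorted draws (type-1 quantiles).
#'
#' @param x a `bayesb_fit` or a draws matrix (draws in rows).
#' @return matrix with columns `mean`, `sd`, `q05`, `q95`.
#' @export
posterior_summary <- function(x) {
  draws <- if (inherits(x, "bayesb_fit")) {
    cbind(x$fixed_draws, x$hap_draws)
  } else {
    as.matrix(x)
  }
  if (nrow(draws) < 10L) stop("need at least 10 retained draws")
  qs <- apply(draws, 2L, quantile, probs = c(0.05, 0.95), type = 1,
              names = FALSE)
  cbind(mean = colMeans(draws), sd = apply(draws, 2L, sd),
        q05 = qs[1L, ], q95 = qs[2L, ])
}
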