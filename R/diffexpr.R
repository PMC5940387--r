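# Differential expression: per-sample standardization followed by a
# two-group moderated t-statistic. Gene-wise variances are shrunk toward a
# common prior variance; the prior (s0^2, d0) is estimated from all genes
# by moment matching of log sample variances against the scaled
# inverse-chi-square model, the standard empirical-Bayes construction for
# expression microarrays.

#' Standardize each sample column to mean 0, sd 1
#'
#' @param es An `xt_expr` object (genes x samples, log scale).
#' @return An `xt_expr` with every column centered and scaled (sd with the
#'   n-1 denominator). Idempotent up to floating-point error.
#' @export
standardize <- function(es) {
  if (ncol(es$values) < 2L) .stopf("standardization needs >= 2 samples")
  sds <- apply(es$values, 2, stats::sd)
  if (any(sds == 0))
    .stopf("zero-variance sample column: %s",
           paste(colnames(es$values)[sds == 0][1:3], collapse = ", "))
  v <- scale(es$values)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  expr_set(v, es$labels)
}

# Inverse of the trigamma function by Newton iteration on 1/x, as used to
# moment-match the log-variance distribution.
.trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-8) break
    }
    y
  }, numeric(1))
}

# Empirical-Bayes estimate of the prior variance s0^2 and prior degrees of
# freedom d0 from gene-wise sample variances s2 on df degrees of freedom.
.estimate_prior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2L) return(list(df_prior = 0, var_prior = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) * (sum(ok) - 1) / sum(ok) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # no excess spread beyond chi-square sampling noise: infinite shrinkage
    return(list(df_prior = Inf,
                var_prior = exp(mean(e))))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, var_prior = s0)
}

#' Moderated two-group differential expression test
#'
#' For every gene, the difference of tumor and control means on the log2
#' scale is tested with a pooled-variance t-statistic whose gene-wise
#' variance is replaced by the posterior variance
#' `(d0*s0^2 + d*s2) / (d0 + d)` under a scaled inverse-chi-square prior
#' estimated from all genes; the statistic is referred to a t distribution
#' on `d + d0` degrees of freedom. A gene is flagged differentially
#' expressed when `p_value < p_cut` and `|log2fc| > log2(fc_cut)`;
#' Benjamini-Hochberg q-values are reported but do not enter the flag.
#'
#' @param es An `xt_expr` object (typically after [standardize()]).
#' @param p_cut Raw p-value threshold (default 0.05).
#' @param fc_cut Fold-change threshold on the natural scale (default 1.5,
#'   applied as `|log2fc| > log2(fc_cut)`).
#' @param prior_df Optional override of the prior degrees of freedom;
#'   `0` gives the ordinary pooled two-sample t, `Inf` full shrinkage to
#'   the common variance.
#' @return Data frame (class `xt_de`) with columns `gene`, `log2fc`,
#'   `t_mod`, `p_value`, `q_value`, `direction` (`up`/`down`/`none`),
#'   `var_sample`, `var_post`; attributes `df_prior`, `var_prior`,
#'   `df_residual`.
#' @export
moderated_de_test <- function(es, p_cut = 0.05, fc_cut = 1.5,
                              prior_df = NULL) {
  tum <- samples_of(es, "tumor"); ctl <- samples_of(es, "control")
  n1 <- length(tum); n2 <- length(ctl)
  if (n1 < 2L || n2 < 2L)
    .stopf("each class needs >= 2 samples (tumor %d, control %d)", n1, n2)
  x1 <- es$values[, tum, drop = FALSE]
  x2 <- es$values[, ctl, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  prior <- .estimate_prior(s2, df)
  if (!is.null(prior_df)) prior$df_prior <- prior_df
  d0 <- prior$df_prior; s0 <- prior$var_prior
  if (is.infinite(d0)) {
    s2_post <- rep(s0, length(s2)); df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2; df_total <- df
  } else {
    s2_post <- (d0 * s0 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  log2fc <- m1 - m2
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  q <- stats::p.adjust(p, method = "BH")
  flagged <- p < p_cut & abs(log2fc) > log2(fc_cut)
  direction <- ifelse(flagged & log2fc > 0, "up",
                      ifelse(flagged & log2fc < 0, "down", "none"))
  out <- data.frame(gene = rownames(es$values), log2fc = log2fc,
                    t_mod = t_mod, p_value = p, q_value = q,
                    direction = direction,
                    var_sample = s2, var_post = s2_post,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s0
  attr(out, "df_residual") <- df
  class(out) <- c("xt_de", "data.frame")
  out
}

#' Flagged differentially expressed genes of a DE table
#' @param de An `xt_de` table from [moderated_de_test()].
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return Character vector of gene symbols.
#' @export
de_genes <- function(de, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") de$direction != "none" else de$direction == direction
  de$gene[keep]
}
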