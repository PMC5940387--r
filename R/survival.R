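# Survival stratification: patients are tagged "altered" when any
# signature gene deviates beyond z_cut reference standard deviations,
# then the two groups are compared with Kaplan-Meier curves and the
# two-group log-rank test (chi-square, 1 df).

#' Tag samples as altered/unaltered on a gene signature
#'
#' A sample is altered when at least one signature gene satisfies
#' `|(exp - mu_ref) / sigma_ref| >= z_cut` (boundary inclusive). The
#' reference distribution defaults to the control samples of `es`.
#'
#' @param es An `xt_expr` of the patients to tag.
#' @param signature Gene symbols.
#' @param z_cut Z-score threshold (default 2; a larger value is advisable
#'   for large panels, see the vignette).
#' @param ref_means,ref_sds Optional named reference mean/sd per gene
#'   (e.g. from a training cohort's controls).
#' @return Named character vector mapping sample to `"altered"` /
#'   `"unaltered"`.
#' @export
tag_altered <- function(es, signature, z_cut = 2.0,
                        ref_means = NULL, ref_sds = NULL) {
  signature <- toupper(signature)
  if (!is.numeric(z_cut) || z_cut < 0) .stopf("'z_cut' must be >= 0")
  genes <- intersect(signature, rownames(es$values))
  if (length(genes) == 0L) .stopf("no signature gene present in the matrix")
  if (is.null(ref_means) || is.null(ref_sds)) {
    ctl <- samples_of(es, "control")
    if (length(ctl) < 2L)
      .stopf("no reference distribution: supply ref_means/ref_sds or >= 2 control samples")
    x <- es$values[genes, ctl, drop = FALSE]
    ref_means <- rowMeans(x)
    ref_sds <- apply(x, 1, stats::sd)
  } else {
    ref_means <- ref_means[genes]; ref_sds <- ref_sds[genes]
    if (any(is.na(ref_means)) || any(is.na(ref_sds)))
      .stopf("reference mean/sd missing for some signature genes")
  }
  usable <- ref_sds > 0
  if (!all(usable))
    .warnf("%d signature gene(s) with zero reference sd skipped", sum(!usable))
  genes <- genes[usable]
  if (length(genes) == 0L) .stopf("no usable signature gene (all zero reference sd)")
  z <- abs((es$values[genes, , drop = FALSE] - ref_means[genes]) / ref_sds[genes])
  altered <- apply(z, 2, function(col) any(col >= z_cut))
  stats::setNames(ifelse(altered, "altered", "unaltered"), colnames(es$values))
}

.surv_records <- function(records) {
  if (!all(c("time_days", "event", "group") %in% names(records)))
    .stopf("records need columns time_days, event, group")
  if (any(records$time_days < 0)) .stopf("negative survival times")
  records
}

#' Kaplan-Meier curve of one group
#'
#' Product-limit estimator; with no censoring it reduces to the
#' complement of the empirical distribution function.
#'
#' @param records Data frame `time_days`, `event` (1 = death), `group`.
#' @param group Which group to estimate (default: all records).
#' @return Data frame `time`, `n_risk`, `n_event`, `surv` (step points;
#'   survival starts at 1 and is non-increasing).
#' @export
km_curve <- function(records, group = NULL) {
  records <- .surv_records(records)
  if (!is.null(group)) records <- records[records$group == group, , drop = FALSE]
  if (nrow(records) == 0L) .stopf("no records in group '%s'", group %||% "(all)")
  fit <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on 1 degree of freedom comparing the
#' altered and unaltered groups.
#'
#' @param records Data frame `time_days`, `event`, `group` with both
#'   groups present.
#' @return List: `statistic`, `p_value`, `n` (per-group sizes). All
#'   records censored gives statistic 0, p 1, with a warning.
#' @export
logrank <- function(records) {
  records <- .surv_records(records)
  groups <- unique(records$group)
  if (length(groups) != 2L) .stopf("need exactly two non-empty groups, got %d", length(groups))
  n <- table(records$group)
  if (sum(records$event) == 0L) {
    .warnf("no events in either group; log-rank undefined, reporting 0/1")
    return(list(statistic = 0, p_value = 1, n = n))
  }
  sd <- survival::survdiff(survival::Surv(time_days, event) ~ group, data = records)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n = n)
}
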