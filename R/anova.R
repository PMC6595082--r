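#' Group comparison of atrophy rates by ANOVA with Tukey HSD
#'
#' Tests whether mean PVC differs between diagnostic groups, using the
#' subject-level (left/right-averaged) A and B scan measurements.
#'
#' Two modes are provided.  `"pooled"` (default) treats the pooled A and B
#' observations as the analysis unit: a one-way ANOVA on all observations,
#' giving the error-degrees-of-freedom pattern `F(k-1, n_obs - k)` (e.g.
#' `F(2, 157)` for 160 observations in 3 groups).  `"mixed"` is the
#' principled repeated-measures alternative: a group x scan mixed-design
#' ANOVA with subject as the between-unit error term; the group effect is
#' then tested against between-subject variability.  Tukey honestly
#' significant difference post-hoc pairwise comparisons are reported in both
#' modes (on pooled observations in pooled mode, on subject means in mixed
#' mode).
#'
#' @param data data.frame with columns `subject_id`, `group`, `scan`, `pvc`
#'   (e.g. the output of [subject_pvc()], possibly filtered to one method).
#' @param mode `"pooled"` or `"mixed"`.
#' @return An `anova_result`: list with `F`, `df_between`, `df_error`,
#'   `p_value`, `posthoc` (data.frame of Tukey-adjusted pairwise contrasts),
#'   `mode`, and for mixed mode the within-subject `scan` and interaction
#'   tests.
#' @export
group_anova <- function(data, mode = c("pooled", "mixed")) {
  mode <- match.arg(mode)
  req <- c("subject_id", "group", "scan", "pvc")
  if (!all(req %in% names(data)))
    stop("data must have columns ", paste(req, collapse = ", "))
  data$group <- factor(data$group)
  k <- nlevels(data$group)
  if (k < 2L) stop("need at least two groups")
  counts <- table(data$group)
  if (any(counts < 2L)) stop("every group needs at least two observations")

  if (mode == "pooled") {
    fit <- aov(pvc ~ group, data = data)
    tab <- summary(fit)[[1]]
    res <- list(F = tab["group", "F value"],
                df_between = tab["group", "Df"],
                df_error = tab["Residuals", "Df"],
                p_value = tab["group", "Pr(>F)"],
                posthoc = tukey_table(fit))
  } else {
    data$subject_id <- factor(data$subject_id)
    data$scan <- factor(data$scan)
    fit <- aov(pvc ~ group * scan + Error(subject_id), data = data)
    s <- summary(fit)
    between <- s[["Error: subject_id"]][[1]]
    within <- s[["Error: Within"]][[1]]
    rn <- function(tab, term) trimws(rownames(tab)) == term
    subj_means <- aggregate(pvc ~ subject_id + group, data = data, FUN = mean)
    res <- list(F = between[rn(between, "group"), "F value"],
                df_between = between[rn(between, "group"), "Df"],
                df_error = between[rn(between, "Residuals"), "Df"],
                p_value = between[rn(between, "group"), "Pr(>F)"],
                scan = list(
                  F = within[rn(within, "scan"), "F value"],
                  p_value = within[rn(within, "scan"), "Pr(>F)"]),
                interaction = list(
                  F = within[rn(within, "group:scan"), "F value"],
                  p_value = within[rn(within, "group:scan"), "Pr(>F)"]),
                posthoc = tukey_table(aov(pvc ~ group, data = subj_means)))
  }
  res$mode <- mode
  res$groups <- levels(data$group)
  structure(res, class = "anova_result")
}

tukey_table <- function(fit) {
  tk <- TukeyHSD(fit, "group")$group
  data.frame(contrast = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s-mode ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$mode, x$df_between, x$df_error, x$F, x$p_value))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$posthoc, digits = 4)
  invisible(x)
}
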