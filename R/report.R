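#' Full statistics report for a cohort of PVC records
#'
#' Runs the complete evaluation battery on a cohort table and assembles the
#' standard report blocks:
#'
#' * `group_summary` -- per-method, per-group mean and SD of pooled A+B
#'   subject-level PVC with observation counts;
#' * `anova` -- per-method group ANOVA with Tukey HSD post-hoc p-values;
#' * `reproducibility` -- per-method A-vs-B average distance;
#' * `power` -- effect sizes and required per-group sample sizes for the
#'   requested contrasts;
#' * `distance_matrix` -- between-method agreement (only when the table
#'   contains two or more methods).
#'
#' The report is deterministic for fixed inputs.
#'
#' @param table a [cohort_table()].
#' @param contrasts list of two-group contrasts for the power block
#'   (default CTRL vs MCI and CTRL vs AD where those groups exist).
#' @param anova_mode `"pooled"` or `"mixed"` (see [group_anova()]).
#' @param threshold exclusion threshold in percent (default: the table's).
#' @param alpha,power passed to [power_analysis()].
#' @return A `cohort_report` list with the blocks above plus `config`.
#' @export
cohort_report <- function(table, contrasts = NULL,
                          anova_mode = c("pooled", "mixed"),
                          threshold = NULL, alpha = 0.05, power = 0.80) {
  stopifnot(inherits(table, "cohort_table"))
  anova_mode <- match.arg(anova_mode)
  if (is.null(threshold)) threshold <- attr(table, "threshold")
  table <- apply_exclusion(table, threshold)
  sp <- subject_pvc(table)
  methods <- sort(unique(sp$method))
  groups <- unique(as.character(sp$group))
  if (is.null(contrasts)) {
    contrasts <- list()
    if (all(c("CTRL", "MCI") %in% groups)) contrasts <- c(contrasts, list(c("CTRL", "MCI")))
    if (all(c("CTRL", "AD") %in% groups)) contrasts <- c(contrasts, list(c("CTRL", "AD")))
    if (!length(contrasts) && length(groups) == 2L)
      contrasts <- list(groups)
  }

  summary_block <- do.call(rbind, lapply(methods, function(m) {
    d <- sp[sp$method == m, ]
    agg <- do.call(rbind, lapply(split(d, as.character(d$group)), function(g)
      data.frame(method = m, group = g$group[1], mu = mean(g$pvc),
                 sigma = sd(g$pvc), n_obs = nrow(g),
                 stringsAsFactors = FALSE)))
    rownames(agg) <- NULL
    agg
  }))

  anova_block <- lapply(setNames(methods, methods), function(m)
    group_anova(sp[sp$method == m, ], mode = anova_mode))

  repro_block <- scan_reproducibility(table)

  power_block <- do.call(rbind, lapply(contrasts, function(ct) {
    pt <- power_table(contrast = ct, stats = summary_block,
                      alpha = alpha, power = power)
    pt$contrast <- paste(ct, collapse = "-")
    pt
  }))

  dist_block <- if (length(methods) >= 2L) distance_matrix(table) else NULL

  structure(list(group_summary = summary_block, anova = anova_block,
                 reproducibility = repro_block, power = power_block,
                 distance_matrix = dist_block,
                 exclusion_summary = attr(table, "exclusion_summary"),
                 config = list(threshold = threshold, anova_mode = anova_mode,
                               alpha = alpha, power = power)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Group summary (subject-level PVC, pooled A+B):\n")
  print(x$group_summary, digits = 4)
  cat("\nReproducibility D_Ave (A vs B, %):\n")
  print(round(x$reproducibility, 3))
  cat("\nSample sizes:\n")
  print(x$power, digits = 3)
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits `report.json` (all blocks), `group_summary.csv`, `power.csv`, and
#' -- when a distance matrix is present -- `distance_matrix.csv` plus a
#' colour-coded heat map image.
#'
#' @param report a [cohort_report()].
#' @param out_dir output directory (created if needed).
#' @return Invisible character vector of written paths.
#' @export
write_cohort_report <- function(report, out_dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  anova_json <- lapply(report$anova, function(a) {
    out <- list(mode = a$mode, F = a$F, df_between = a$df_between,
                df_error = a$df_error, p_value = a$p_value,
                tukey = a$posthoc)
    if (!is.null(a$scan)) out$scan <- a$scan
    if (!is.null(a$interaction)) out$interaction <- a$interaction
    out
  })
  json <- list(group_summary = report$group_summary,
               anova = anova_json,
               reproducibility_d_ave = as.list(report$reproducibility),
               power = report$power,
               config = report$config)
  if (!is.null(report$distance_matrix))
    json$distance_matrix <- list(methods = rownames(report$distance_matrix),
                                 values = report$distance_matrix)
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  paths <- c(paths, jp)
  gp <- file.path(out_dir, "group_summary.csv")
  write.csv(report$group_summary, gp, row.names = FALSE)
  pp <- file.path(out_dir, "power.csv")
  write.csv(report$power, pp, row.names = FALSE)
  paths <- c(paths, gp, pp)
  if (!is.null(report$distance_matrix)) {
    dm <- export_distance_matrix(report$distance_matrix,
                                 file.path(out_dir, "distance_matrix.csv"),
                                 file.path(out_dir, "distance_matrix.pdf"))
    paths <- c(paths, unlist(dm))
  }
  invisible(paths)
}
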