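#' Average distance between paired atrophy measurements
#'
#' The reproducibility / agreement statistic of the pipeline: the root mean
#' squared difference `sqrt(mean((x - y)^2))` between paired PVC values.
#' Applied to back-to-back A and B scan replicates it measures test-retest
#' reproducibility (true change between replicates is zero, so any distance
#' is method noise); applied to two methods on the same pooled record set it
#' measures between-method agreement.  Units are percent PVC.
#'
#' @param pvc_a,pvc_b numeric vectors of paired PVC values (pairing by
#'   subject, and by side when sides are not averaged).
#' @return The average distance (percent).
#' @examples
#' d_ave_scans(c(0, 2), c(2, 0))  # 2
#' @export
d_ave_scans <- function(pvc_a, pvc_b) {
  if (length(pvc_a) != length(pvc_b)) stop("paired vectors differ in length")
  if (length(pvc_a) < 1L) stop("need at least one pair")
  if (any(!is.finite(pvc_a)) || any(!is.finite(pvc_b)))
    stop("non-finite PVC values")
  sqrt(mean((pvc_a - pvc_b)^2))
}

#' @rdname d_ave_scans
#' @param pvc_m1,pvc_m2 PVC values of two methods over the same pooled
#'   A+B record set (same subjects, same order).
#' @export
d_ave_methods <- function(pvc_m1, pvc_m2) {
  if (length(pvc_m1) != length(pvc_m2))
    stop("mismatched record sets between methods")
  d_ave_scans(pvc_m1, pvc_m2)
}

#' Reproducibility distance of a cohort table
#'
#' Convenience wrapper pairing each subject's A and B scan PVCs (after
#' left/right averaging and exclusion masking) and returning the
#' per-method average distance.
#'
#' @param table a [cohort_table()].
#' @return Named numeric vector, one average distance per method.
#' @export
scan_reproducibility <- function(table) {
  sp <- subject_pvc(table)
  out <- sapply(split(sp, sp$method), function(df) {
    w <- stats::reshape(df[, c("subject_id", "scan", "pvc")],
                        idvar = "subject_id", timevar = "scan",
                        direction = "wide")
    w <- w[stats::complete.cases(w), , drop = FALSE]
    if (nrow(w) == 0) return(NA_real_)
    d_ave_scans(w$pvc.A, w$pvc.B)
  })
  out
}

#' Between-method agreement distance matrix
#'
#' Computes the pairwise average distance between every pair of methods over
#' the pooled A+B subject-level PVC records shared by all methods, and
#' optionally renders it as a heat map.  The diagonal is zero and the matrix
#' is symmetric.
#'
#' @param table a [cohort_table()] containing two or more methods, or a list
#'   of single-method cohort tables over the same subjects.
#' @return A symmetric numeric matrix with methods as dimnames.
#' @export
distance_matrix <- function(table) {
  if (is.list(table) && !inherits(table, "data.frame")) {
    table <- do.call(rbind, lapply(table, as.data.frame))
    table <- cohort_table(table)
  }
  sp <- subject_pvc(table)
  methods <- sort(unique(sp$method))
  if (length(methods) < 2L) stop("need at least two methods")
  sp$key <- paste(sp$subject_id, sp$scan)
  wide <- lapply(split(sp, sp$method), function(df)
    setNames(df$pvc, df$key))
  common <- Reduce(intersect, lapply(wide, names))
  if (length(common) == 0) stop("methods share no records")
  m <- matrix(0, length(methods), length(methods),
              dimnames = list(methods, methods))
  for (i in seq_along(methods))
    for (j in seq_along(methods))
      if (i < j) {
        d <- d_ave_methods(wide[[methods[i]]][common],
                           wide[[methods[j]]][common])
        m[i, j] <- m[j, i] <- d
      }
  m
}

#' Plot a method-agreement distance matrix
#'
#' @param m symmetric matrix from [distance_matrix()].
#' @return A ggplot object (colour-coded matrix of distances in percent).
#' @export
plot_distance_matrix <- function(m) {
  df <- expand.grid(method1 = rownames(m), method2 = colnames(m))
  df$distance <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method1, y = .data$method2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$distance)), size = 3) +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b",
                                 name = "D (%)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Between-method atrophy-rate agreement") +
    ggplot2::theme_minimal()
}

#' Export a distance matrix to CSV and an image
#'
#' @param m matrix from [distance_matrix()].
#' @param csv_path CSV output path.
#' @param image_path image output path (`.pdf` always works headless;
#'   `.png` is used when the device is available).
#' @return Invisible list of the written paths.
#' @export
export_distance_matrix <- function(m, csv_path, image_path = NULL) {
  write.csv(as.data.frame(m), csv_path, row.names = TRUE)
  if (!is.null(image_path)) {
    p <- plot_distance_matrix(m)
    ok <- tryCatch({
      ggplot2::ggsave(image_path, p, width = 5.5, height = 4.5)
      TRUE
    }, error = function(e) {
      log_event("heatmap device failed (%s); writing PDF instead",
                conditionMessage(e))
      FALSE
    })
    if (!ok) {
      image_path <- paste0(tools::file_path_sans_ext(image_path), ".pdf")
      ggplot2::ggsave(image_path, p, width = 5.5, height = 4.5)
    }
  }
  invisible(list(csv = csv_path, image = image_path))
}
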