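#' Pearson correlation matrix of conformer features and photo-properties
#'
#' Product-moment correlations between every pair of the selected
#' columns, computed pairwise-complete (rows with missing values are
#' dropped per pair, with counts reported). Constant columns have no
#' defined correlation; their entries are `NA` (flagged with a warning),
#' never coerced to zero.
#'
#' @param table data.frame of per-frame features joined with excitation
#'   quantities (e.g. `energy_eV`, `osc_strength`, `cos_psi`,
#'   `abs_cos_phi1`, ...)
#' @param columns columns to correlate; default: the canonical ordering
#'   energy, strength, cos_psi, |cos phi1|, |cos phi2|, then any other
#'   numeric columns except `frame_index`
#' @return a `correlation_matrix`: list with `r` (symmetric matrix,
#'   unit diagonal), `n` (rows used), `labels`, `n_dropped`
#' @export
pearson_matrix <- function(table, columns = NULL) {
  if (is.null(columns)) {
    canonical <- c("energy_eV", "osc_strength", "cos_psi",
                   "abs_cos_phi1", "abs_cos_phi2")
    num <- names(table)[vapply(table, is.numeric, TRUE)]
    columns <- c(intersect(canonical, num),
                 setdiff(num, c(canonical, "frame_index")))
  }
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(table[, columns, drop = FALSE])
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing values handled pairwise")
  if (sum(complete) < 3L) stop("need at least 3 complete rows")
  const <- apply(x[complete, , drop = FALSE], 2, function(v) stats::sd(v) == 0)
  if (any(const))
    warning("constant column(s) have undefined correlations: ",
            paste(columns[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                   method = "pearson"))
  diag(r)[!const] <- 1
  structure(list(r = r, n = sum(complete), labels = columns,
                 n_dropped = n_dropped),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("Pearson correlation matrix (n = ", x$n, ")\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

#' Export a feature/photo-property scatter
#'
#' Paired columns for one feature against one target (the Fig-9-style
#' view of how ring planarity tunes the excitation energy), with the
#' least-squares line and Pearson r.
#'
#' @param table joined feature table
#' @param feature,target column names
#' @param csv_path optional path; when given the points are written as
#'   CSV
#' @param plot_path optional path; when given a ggplot scatter with the
#'   fitted line and an r annotation is saved
#' @return list: `data` (two-column data.frame), `slope`, `intercept`,
#'   `r`
#' @export
energy_feature_scatter <- function(table, feature, target,
                                   csv_path = NULL, plot_path = NULL) {
  for (col in c(feature, target))
    if (!col %in% names(table)) stop("unknown column: ", col)
  d <- data.frame(x = table[[feature]], y = table[[target]])
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) == 0L) stop("no complete rows for ", feature, " vs ", target)
  names(d) <- c(feature, target)
  fit <- stats::lm(d[[target]] ~ d[[feature]])
  r <- stats::cor(d[[feature]], d[[target]])
  if (!is.null(csv_path)) utils::write.csv(d, csv_path, row.names = FALSE)
  if (!is.null(plot_path)) {
    p <- ggplot2::ggplot(d, ggplot2::aes(.data[[feature]], .data[[target]])) +
      ggplot2::geom_point(alpha = 0.3, size = 0.6) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::labs(subtitle = sprintf("Pearson r = %.3f (n = %d)", r, nrow(d))) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(plot_path, p, width = 5, height = 4, dpi = 150)
  }
  list(data = d, slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r = r)
}

#' Export a correlation heatmap
#'
#' Writes the coefficient matrix as CSV and, optionally, a heatmap with
#' a diverging colour scale centred at 0 spanning [-1, 1] (strong
#' positive and negative correlations saturate at the two ends;
#' undefined cells stay blank).
#'
#' @param mat a [pearson_matrix()] result
#' @param csv_path output CSV path
#' @param plot_path optional heatmap image path (png/pdf by extension)
#' @return `csv_path`, invisibly
#' @export
heatmap_export <- function(mat, csv_path, plot_path = NULL) {
  stopifnot(inherits(mat, "correlation_matrix"))
  utils::write.csv(as.data.frame(mat$r), csv_path, row.names = TRUE)
  if (!is.null(plot_path)) {
    df <- expand.grid(var1 = mat$labels, var2 = mat$labels,
                      stringsAsFactors = FALSE)
    df$r <- as.vector(mat$r)
    df$var1 <- factor(df$var1, levels = mat$labels)
    df$var2 <- factor(df$var2, levels = rev(mat$labels))
    p <- ggplot2::ggplot(df, ggplot2::aes(var1, var2, fill = r)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "#01665e", mid = "#f5f5f5",
                                    high = "#8c510a", midpoint = 0,
                                    limits = c(-1, 1), na.value = "white") +
      ggplot2::labs(x = NULL, y = NULL, fill = "r") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    ggplot2::ggsave(plot_path, p, width = 5.5, height = 4.5, dpi = 150)
  }
  invisible(csv_path)
}

#' Read a correlation matrix back from its CSV export
#'
#' @param csv_path path written by [heatmap_export()]
#' @return a `correlation_matrix` (with `n` unknown, `NA`)
#' @export
read_correlation_csv <- function(csv_path) {
  d <- utils::read.csv(csv_path, row.names = 1, check.names = FALSE)
  r <- as.matrix(d)
  structure(list(r = r, n = NA_integer_, labels = colnames(r),
                 n_dropped = NA_integer_),
            class = "correlation_matrix")
}
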