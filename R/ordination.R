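#' Principal component analysis of the per-plot environment block
#'
#' Correlation-matrix PCA (variables standardized to mean 0, SD 1 with the
#' n-1 denominator) of a numeric per-plot table, as appropriate when the
#' variables mix ordinal indicator scores with indices on disparate scales.
#' Rows with missing cells are dropped with a warning, zero-variance
#' variables likewise. Components with eigenvalue > 1 are retained (Kaiser
#' criterion). Loadings are the correlations between each variable and each
#' component's scores; the sign of every component is fixed so its
#' largest-|loading| variable loads positive.
#'
#' @param plot_table data frame of per-plot variables; a `plot_id` column,
#'   if present, becomes the row labels.
#' @return object of class `env_pca` with `eigenvalues`, `explained_pct`,
#'   `loadings`, `scores`, `retained`, `n` (plots used), `dropped_plots`,
#'   `dropped_variables`.
#' @export
pca_environment <- function(plot_table) {
  df <- as.data.frame(plot_table)
  ids <- if ("plot_id" %in% names(df)) as.character(df$plot_id)
         else rownames(df)
  df <- df[setdiff(names(df), "plot_id")]
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("plot_table must be numeric (apart from plot_id)")
  }
  complete <- stats::complete.cases(df)
  dropped_plots <- ids[!complete]
  if (length(dropped_plots)) {
    warning("dropping ", length(dropped_plots),
            " plot(s) with missing values")
  }
  x <- as.matrix(df[complete, , drop = FALSE])
  rownames(x) <- ids[complete]
  sds <- apply(x, 2, stats::sd)
  dropped_vars <- colnames(x)[sds == 0]
  if (length(dropped_vars)) {
    warning("dropping zero-variance variable(s): ",
            paste(dropped_vars, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (nrow(x) < 3) stop("need at least 3 complete plots")
  if (ncol(x) < 2) stop("need at least 2 variables")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  loadings <- sweep(pc$rotation, 2, pc$sdev, `*`)
  scores <- pc$x
  for (k in seq_along(eig)) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(eigenvalues = eig,
                 explained_pct = 100 * eig / sum(eig),
                 loadings = loadings,
                 scores = scores,
                 retained = sum(eig > 1),
                 n = nrow(x),
                 dropped_plots = dropped_plots,
                 dropped_variables = dropped_vars),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, digits = 3, ...) {
  cat("Correlation-matrix PCA:", x$n, "plots,", nrow(x$loadings),
      "variables\n")
  cat("Retained (eigenvalue > 1):", x$retained, "components\n")
  tab <- rbind(eigenvalue = x$eigenvalues,
               `explained %` = x$explained_pct)
  colnames(tab) <- colnames(x$loadings)
  print(round(tab[, seq_len(min(6, ncol(tab))), drop = FALSE], digits))
  invisible(x)
}

#' Mask non-significant loadings
#'
#' A loading `r` (a variable-component correlation over `n` plots) is kept
#' when the two-sided p-value of \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2`
#' degrees of freedom is below `alpha`; otherwise it is masked (NA), the
#' usual way significance-filtered loading tables are displayed.
#'
#' @param res an [pca_environment()] result, or a loading matrix.
#' @param n number of plots used (taken from `res` when available).
#' @param alpha significance level (default 0.05).
#' @return loading matrix with non-significant entries set to NA.
#' @export
filter_significant_loadings <- function(res, n = NULL, alpha = 0.05) {
  loadings <- if (inherits(res, "env_pca")) res$loadings else as.matrix(res)
  if (is.null(n)) n <- if (inherits(res, "env_pca")) res$n else
    stop("n must be supplied")
  if (n <= 2) stop("n must exceed 2")
  r <- pmin(pmax(loadings, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[abs(r) >= 1] <- 0
  out <- loadings
  out[p >= alpha] <- NA_real_
  out
}

#' Per-group mean and SD of every variable
#'
#' @param plot_table numeric per-plot data frame (optionally with `plot_id`).
#' @param groups plot group labels (named by plot_id or aligned with rows).
#' @return data frame with `group`, `variable`, `n`, `mean`, `sd` (sample
#'   SD, missing for single-plot groups), ordered by group label.
#' @export
summarize_by_group <- function(plot_table, groups) {
  df <- as.data.frame(plot_table)
  ids <- if ("plot_id" %in% names(df)) as.character(df$plot_id)
         else rownames(df)
  df <- df[setdiff(names(df), "plot_id")]
  g <- resolve_groups(groups, ids)
  labs <- sort(unique(g))
  rows <- list()
  for (lab in labs) {
    sub <- df[g == lab, , drop = FALSE]
    for (v in names(df)) {
      val <- sub[[v]][!is.na(sub[[v]])]
      rows[[length(rows) + 1L]] <- data.frame(
        group = lab, variable = v, n = length(val),
        mean = if (length(val)) mean(val) else NA_real_,
        sd = if (length(val) >= 2) stats::sd(val) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
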