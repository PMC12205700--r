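#' Per-plot hemeroby and naturalness indices
#'
#' The hemeroby index of a plot is the community-weighted mean hemeroby
#' grade of its species (grades on the 7-step ordinal scale, 1 = ahemerobic
#' ... 7 = metahemerobic); with `"cover"` weighting (the default) weights are
#' projective covers, with `"presence"` weighting all species count equally.
#' The naturalness index is the share of the contributing weight (cover or
#' count) carried by species of grade `<= natural_threshold`
#' (default 3, i.e. ahemerobic to mesohemerobic), so it ranges over [0, 1]
#' and is high in near-natural stands. The two indices are deliberately not
#' mirror images of one another: a plot of uniformly mesohemerobic species
#' and a plot mixing pristine and artificial elements can share a hemeroby
#' mean yet differ in naturalness.
#'
#' @param rs a [releve_set()].
#' @param table an [indicator_table()] with a `hemeroby_grade` column.
#' @param weighting `"cover"` (default) or `"presence"`.
#' @param min_species minimum number of graded species for a reportable
#'   plot index (default 3).
#' @param natural_threshold highest grade still counted as natural
#'   (integer 1-6, default 3).
#' @return data frame with `plot_id`, `hemeroby_index`, `naturalness_index`,
#'   `n_species_used`, `cover_fraction_scored`.
#' @export
plot_hemeroby <- function(rs, table, weighting = c("cover", "presence"),
                          min_species = 3, natural_threshold = 3) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(rs, "releve_set"), inherits(table, "indicator_table"))
  if (!"hemeroby_grade" %in% names(table)) {
    stop("indicator table has no hemeroby_grade column")
  }
  if (!natural_threshold %in% 1:6) {
    stop("natural_threshold must be an integer in 1..6")
  }
  m <- match_species(table, rs$covers$species)
  grade <- table$hemeroby_grade[m$index]
  plots <- rs$plots$plot_id
  out <- data.frame(plot_id = plots,
                    hemeroby_index = NA_real_,
                    naturalness_index = NA_real_,
                    n_species_used = 0L,
                    cover_fraction_scored = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(plots)) {
    sel <- rs$covers$plot_id == plots[i]
    g <- grade[sel]
    cv <- rs$covers$cover[sel]
    ok <- !is.na(g)
    out$n_species_used[i] <- sum(ok)
    out$cover_fraction_scored[i] <- sum(cv[ok]) / sum(cv)
    if (sum(ok) < min_species) next
    w <- if (weighting == "cover") cv[ok] else rep(1, sum(ok))
    out$hemeroby_index[i] <- sum(w * g[ok]) / sum(w)
    out$naturalness_index[i] <- sum(w[g[ok] <= natural_threshold]) / sum(w)
  }
  skipped <- out$plot_id[is.na(out$hemeroby_index)]
  if (length(skipped)) {
    warning("hemeroby: ", length(skipped), " plot(s) below min_species = ",
            min_species, ", index set missing: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }
  out
}

#' Per-group hemeroby and naturalness contrasts
#'
#' Mean and sample SD (n-1 denominator) of both indices per group of plots,
#' ordered by group label. Groups with fewer than two plots with a computed
#' index get a missing SD.
#'
#' @param results output of [plot_hemeroby()].
#' @param groups named vector (plot_id -> group label) or vector aligned
#'   with `results$plot_id`.
#' @return data frame with group, n, hemeroby mean/sd, naturalness mean/sd.
#' @export
group_hemeroby_contrast <- function(results, groups) {
  g <- resolve_groups(groups, results$plot_id)
  if (length(unique(g)) < 2) stop("need at least 2 groups")
  labs <- sort(unique(as.character(g)))
  rows <- lapply(labs, function(lab) {
    d <- results[g == lab & !is.na(results$hemeroby_index), , drop = FALSE]
    data.frame(group = lab, n = nrow(d),
               hemeroby_mean = mean(d$hemeroby_index),
               hemeroby_sd = if (nrow(d) >= 2) stats::sd(d$hemeroby_index)
                             else NA_real_,
               naturalness_mean = mean(d$naturalness_index),
               naturalness_sd = if (nrow(d) >= 2)
                 stats::sd(d$naturalness_index) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Accept either a vector aligned with ids or a named plot_id -> label map.
resolve_groups <- function(groups, ids) {
  if (!is.null(names(groups)) && all(ids %in% names(groups))) {
    out <- groups[ids]
  } else {
    if (length(groups) != length(ids)) {
      stop("groups must be named by plot_id or aligned with plots")
    }
    out <- groups
  }
  as.character(out)
}
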