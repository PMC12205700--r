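#' Community indicator score of each plot on one scale
#'
#' Aggregates the species indicator scores of the species recorded in each
#' plot. `"presence"` weighting (the default, classical phytoindication
#' practice) takes the arithmetic mean of the scores of species present;
#' `"cover"` weighting takes the cover-weighted mean
#' \eqn{\sum c_i s_i / \sum c_i}. Plots with fewer than `min_species` scored
#' species get a missing score with a warning: a one- or two-species
#' "community" cannot indicate its environment reliably.
#'
#' @param rs a [releve_set()].
#' @param table an [indicator_table()].
#' @param scale_id a single scale id (see [scale_definitions()]).
#' @param weighting `"presence"` or `"cover"`.
#' @param min_species minimum number of scored species for a reportable plot
#'   score (default 3).
#' @return named numeric vector of plot scores with attribute
#'   `n_species_used` (named integer vector).
#' @export
community_score <- function(rs, table, scale_id,
                            weighting = c("presence", "cover"),
                            min_species = 3) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(rs, "releve_set"), inherits(table, "indicator_table"))
  if (length(scale_id) != 1 ||
      !scale_id %in% scale_definitions("all")$scale_id) {
    stop("unknown scale_id: ", scale_id)
  }
  if (!scale_id %in% names(table)) {
    stop("indicator table has no column for scale ", scale_id)
  }
  m <- match_species(table, rs$covers$species)
  sp_score <- table[[scale_id]][m$index]
  plots <- rs$plots$plot_id
  score <- stats::setNames(rep(NA_real_, length(plots)), plots)
  n_used <- stats::setNames(rep(0L, length(plots)), plots)
  ok <- !is.na(sp_score)
  if (any(ok)) {
    sub <- data.frame(plot_id = rs$covers$plot_id[ok],
                      cover = rs$covers$cover[ok], s = sp_score[ok])
    agg <- split(sub, sub$plot_id)
    for (pid in names(agg)) {
      d <- agg[[pid]]
      n_used[pid] <- nrow(d)
      if (nrow(d) >= min_species) {
        score[pid] <- if (weighting == "presence") mean(d$s)
                      else sum(d$cover * d$s) / sum(d$cover)
      }
    }
  }
  skipped <- plots[is.na(score)]
  if (length(skipped)) {
    warning(scale_id, ": ", length(skipped),
            " plot(s) below min_species = ", min_species,
            ", score set missing: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }
  attr(score, "n_species_used") <- n_used
  score
}

#' Community indicator scores on several scales
#'
#' @inheritParams community_score
#' @param scales character vector of scale ids (default: all scales present
#'   in `table`).
#' @return data frame with `plot_id` and one column per scale; attribute
#'   `n_species_used` holds the per-plot, per-scale counts.
#' @export
plot_scores <- function(rs, table, scales = NULL,
                        weighting = c("presence", "cover"),
                        min_species = 3) {
  weighting <- match.arg(weighting)
  if (is.null(scales)) {
    scales <- intersect(scale_definitions("all")$scale_id, names(table))
  }
  out <- data.frame(plot_id = rs$plots$plot_id, stringsAsFactors = FALSE)
  ns <- list()
  for (sc in scales) {
    v <- suppressWarnings(
      community_score(rs, table, sc, weighting, min_species))
    out[[sc]] <- unname(v[out$plot_id])
    ns[[sc]] <- attr(v, "n_species_used")[out$plot_id]
  }
  attr(out, "n_species_used") <- ns
  out
}

# scale_id -> (output column, conversion). Each conversion is implemented
# exactly as printed; no post-hoc rescaling.
regime_conversions <- list(
  Hd = list(name = "W_mm", units = "mm",
            label = "productive moisture, 1 m soil layer",
            fn = function(s) 18.65 * exp(0.15 * s)),
  fH = list(name = "omega", units = "dimensionless",
            label = "soil moisture irregularity coefficient",
            fn = function(s) 0.042 * s - 0.032),
  Ae = list(name = "P_porosity", units = "printed-formula output",
            label = "air-filled porosity",
            fn = function(s) (100 - s^4) / (100 * (s^4 + 1700))),
  Rc = list(name = "pH", units = "pH units",
            label = "soil solution pH",
            fn = function(s) {
              if (any(s <= 0, na.rm = TRUE)) {
                stop("domain error: Rc must be > 0 for the log conversion")
              }
              2.26 * log(s) + 1.88
            }),
  Sl = list(name = "S_salt", units = "ug/l",
            label = "salt content of the soil solution",
            fn = function(s) 2^(0.6 * s + 1)),
  Ca = list(name = "CaO_MgO_pct", units = "%",
            label = "carbonate content as CaO+MgO",
            fn = function(s) 14 * s^4.5 / (s^4.5 + 45000)),
  Nt = list(name = "N_gkg", units = "g/kg",
            label = "soil nitrogen content",
            fn = function(s) 5 * s^3.7 / (s^3.7 + 345)),
  Tm = list(name = "RB", units = "gJ m-2 yr-1",
            label = "radiation balance",
            fn = function(s) 0.21 * s),
  Om = list(name = "Hum_mm", units = "mm/day",
            label = "precipitation minus evaporation",
            fn = function(s) 0.54 * s - 7),
  Kn = list(name = "SKn", units = "Ivanov scale",
            label = "Ivanov continentality",
            fn = function(s) 10 * s + 41),
  Cr = list(name = "Temp_coldest_C", units = "degC",
            label = "mean temperature of the coldest month",
            fn = function(s) 3.83 * s - 38.17),
  Lc = list(name = "log_lighting", units = "log10 relative light",
            label = "decimal log of relative light level",
            fn = function(s) 0.22 * s),
  L = list(name = "log_lighting", units = "log10 relative light",
           label = "decimal log of relative light level",
           fn = function(s) 0.22 * s)
)

#' Convert a community indicator score to a physical quantity
#'
#' Applies the published score-to-physical-unit conversion of the given
#' scale: productive moisture `W = 18.65 exp(0.15 Hd)` (mm), moisture
#' irregularity `omega = 0.042 fH - 0.032`, air-filled porosity
#' `P = (100 - Ae^4) / (100 (Ae^4 + 1700))`, `pH = 2.26 ln(Rc) + 1.88`,
#' salt content `S = 2^(0.6 Sl + 1)` (ug/l), carbonates
#' `CaO+MgO = 14 Ca^4.5 / (Ca^4.5 + 45000)` (%), nitrogen
#' `N = 5 Nt^3.7 / (Nt^3.7 + 345)` (g/kg), radiation balance
#' `RB = 0.21 Tm` (gJ m-2 yr-1), ombroclimate `Hum = 0.54 Om - 7` (mm/day),
#' Ivanov continentality `SKn = 10 Kn + 41`, coldest-month temperature
#' `Temp = 3.83 Cr - 38.17` (degC) and relative light
#' `log_lighting = 0.22 L` (decimal log; applied to either the Didukh Lc or
#' the Ellenberg L score).
#'
#' The conversion is defined for any positive real score; scores outside the
#' scale's ordinal range are converted anyway but flagged with a warning.
#' Note the porosity formula is reported exactly as printed even though its
#' magnitude is far below a literal percentage; treat `P_porosity` as
#' formula output, not a calibrated porosity measurement.
#'
#' @param scale_id one of the ids above.
#' @param score numeric vector of scores.
#' @return numeric vector of converted values.
#' @export
#' @examples
#' convert_regime("Hd", 10)   # ~83.6 mm productive moisture
#' convert_regime("Rc", 1)    # pH 1.88
convert_regime <- function(scale_id, score) {
  conv <- regime_conversions[[as.character(scale_id)]]
  if (is.null(conv)) stop("no conversion defined for scale ", scale_id)
  score <- as.numeric(score)
  if (scale_id %in% scale_definitions("all")$scale_id) {
    g <- n_gradations(scale_id)
    off <- !is.na(score) & (score < 1 | score > g)
    if (any(off)) {
      warning(scale_id, ": ", sum(off), " score(s) outside [1, ", g,
              "]; converted anyway")
    }
  }
  conv$fn(score)
}

#' Per-plot ecological regimes table
#'
#' Computes the community score of every plot on the twelve edaphic/climatic
#' factors and appends the physical-unit conversion of each
#' (see [convert_regime()]). Column names are fixed: raw score columns carry
#' the scale id, converted columns the physical name (`W_mm`, `omega`,
#' `P_porosity`, `pH`, `S_salt`, `CaO_MgO_pct`, `N_gkg`, `RB`, `Hum_mm`,
#' `SKn`, `Temp_coldest_C`, `log_lighting`).
#'
#' @inheritParams community_score
#' @param light_scale which score feeds the light conversion: the Didukh
#'   `"Lc"` factor (default) or the Ellenberg `"L"` value.
#' @return data frame of raw scores and converted regimes, one row per plot.
#' @export
plot_regimes <- function(rs, table, weighting = c("presence", "cover"),
                         min_species = 3, light_scale = c("Lc", "L")) {
  weighting <- match.arg(weighting)
  light_scale <- match.arg(light_scale)
  didukh <- scale_definitions("didukh")$scale_id
  scales <- intersect(didukh, names(table))
  if (light_scale == "L" && "L" %in% names(table)) {
    scales <- union(setdiff(scales, "Lc"), "L")
  }
  scores <- plot_scores(rs, table, scales, weighting, min_species)
  out <- scores
  for (sc in setdiff(names(scores), "plot_id")) {
    conv <- regime_conversions[[sc]]
    if (!is.null(conv)) out[[conv$name]] <- convert_regime(sc, scores[[sc]])
  }
  out
}

#' Classify productive moisture supply
#'
#' Bins productive moisture of the one-metre soil layer for agricultural
#' suitability: below 60 mm very low, 60-90 low, 90-130 satisfactory,
#' 130-160 good, 160 mm and above very good. Boundaries are lower-inclusive
#' half-open intervals (130 mm classifies as good).
#'
#' @param W_mm numeric vector of productive moisture (mm), non-negative.
#' @return ordered factor with levels very_low < low < satisfactory < good
#'   < very_good.
#' @export
#' @examples
#' classify_moisture(c(59.9, 130, 200))
classify_moisture <- function(W_mm) {
  W_mm <- as.numeric(W_mm)
  if (any(W_mm < 0, na.rm = TRUE)) stop("W_mm must be non-negative")
  cut(W_mm, breaks = c(0, 60, 90, 130, 160, Inf), right = FALSE,
      include.lowest = TRUE, ordered_result = TRUE,
      labels = c("very_low", "low", "satisfactory", "good", "very_good"))
}
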