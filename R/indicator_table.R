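#' Construct a validated indicator table
#'
#' An indicator table holds, per species, optional ordinal scores on each
#' indicator scale plus an optional hemeroby grade on the 7-step ordinal
#' scale (1 = ahemerobic, untouched ... 7 = metahemerobic, fully artificial).
#' Missing scores are first-class empty cells; 0 is out of range on every
#' scale and never used as a sentinel.
#'
#' @param df data frame with a `species` column, zero or more scale columns
#'   named as in [scale_definitions()], and optionally `hemeroby_grade`.
#' @param mode `"strict"` (default) rejects out-of-range scores with an error
#'   listing the offending cells; `"lenient"` nulls them with a warning.
#' @return a data frame of class `indicator_table`.
#' @export
indicator_table <- function(df, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!is.data.frame(df)) stop("df must be a data frame")
  if (!"species" %in% names(df)) {
    stop("format error: missing 'species' column")
  }
  df$species <- trimws(gsub("[[:space:]]+", " ", as.character(df$species)))
  key <- normalize_species_names(df$species)
  if (anyDuplicated(key)) {
    stop("duplicate species after normalization: ",
         paste(unique(df$species[duplicated(key)]), collapse = ", "))
  }
  defs <- scale_definitions("all")
  scale_cols <- intersect(names(df), defs$scale_id)
  known <- c("species", scale_cols, "hemeroby_grade")
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
    df <- df[known[known %in% names(df)]]
  }

  bad <- character(0)
  for (sc in scale_cols) {
    v <- suppressWarnings(as.numeric(df[[sc]]))
    g <- n_gradations(sc)
    out_of_range <- !is.na(v) & (v < 1 | v > g)
    if (any(out_of_range)) {
      bad <- c(bad, paste0(df$species[out_of_range], " [", sc, "=",
                           v[out_of_range], ", range 1-", g, "]"))
      if (mode == "lenient") v[out_of_range] <- NA_real_
    }
    df[[sc]] <- v
  }
  if ("hemeroby_grade" %in% names(df)) {
    h <- suppressWarnings(as.numeric(df$hemeroby_grade))
    out_of_range <- !is.na(h) & (h < 1 | h > 7 | h != round(h))
    if (any(out_of_range)) {
      bad <- c(bad, paste0(df$species[out_of_range], " [hemeroby_grade=",
                           h[out_of_range], ", integer 1-7]"))
      if (mode == "lenient") h[out_of_range] <- NA_real_
    }
    df$hemeroby_grade <- as.integer(round(h))
    df$hemeroby_grade[is.na(h)] <- NA_integer_
  }
  if (length(bad)) {
    if (mode == "strict") {
      stop("validation error: scores out of range:\n  ",
           paste(bad, collapse = "\n  "))
    }
    warning("nulled out-of-range scores:\n  ", paste(bad, collapse = "\n  "))
  }
  rownames(df) <- NULL
  structure(df, class = c("indicator_table", "data.frame"))
}

#' Load a species indicator-value table from CSV
#'
#' Expected layout: column 1 `species`, then one column per scale id, then
#' optionally `hemeroby_grade`; UTF-8, decimal point, empty cell = missing.
#'
#' @param path path to the CSV file.
#' @param scale_set character vector of scale ids to retain (default: every
#'   known scale present in the file).
#' @inheritParams indicator_table
#' @return an `indicator_table`.
#' @export
#' @examples
#' f <- system.file("extdata", "synthetic_indicator_values.csv",
#'                  package = "phytoind")
#' tab <- load_indicator_table(f)
#' nrow(tab)
load_indicator_table <- function(path, scale_set = NULL,
                                 mode = c("strict", "lenient")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!"species" %in% names(df)) {
    stop("format error: missing 'species' column in ", path)
  }
  if (!is.null(scale_set)) {
    keep <- c("species", intersect(names(df), c(scale_set, "hemeroby_grade")))
    df <- df[keep]
  }
  indicator_table(df, mode = match.arg(mode))
}

#' Write an indicator table to CSV
#'
#' Inverse of [load_indicator_table()]: missing scores become empty cells.
#'
#' @param table an `indicator_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_indicator_table <- function(table, path) {
  stopifnot(inherits(table, "indicator_table"))
  utils::write.csv(table, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Match species names against an indicator table
#'
#' Matching is exact after whitespace/case normalization; unmatched names are
#' reported, never silently dropped, and never fuzzy-matched.
#'
#' @param table an `indicator_table`.
#' @param names character vector of species names to look up.
#' @return a list with `index` (named integer vector, NA where unmatched),
#'   `matched` and `unmatched` character vectors.
#' @export
match_species <- function(table, names) {
  stopifnot(inherits(table, "indicator_table"))
  key <- normalize_species_names(table$species)
  idx <- match(normalize_species_names(names), key)
  names(idx) <- names
  list(index = idx,
       matched = names[!is.na(idx)],
       unmatched = names[is.na(idx)])
}

#' @export
print.indicator_table <- function(x, ...) {
  defs <- scale_definitions("all")
  sc <- intersect(names(x), defs$scale_id)
  cat("Indicator table:", nrow(x), "species,", length(sc), "scales",
      if ("hemeroby_grade" %in% names(x)) "+ hemeroby grade" else "", "\n")
  cat("Scales:", paste(sc, collapse = " "), "\n")
  invisible(x)
}
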