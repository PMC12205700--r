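#' Braun-Blanquet cover-abundance code midpoints
#'
#' Fixed percentage midpoints used to convert Braun-Blanquet codes to
#' projective cover at ingest: r=0.1, +=0.5, 1=2.5, 2=15, 3=37.5, 4=62.5,
#' 5=87.5.
#'
#' @return named numeric vector of midpoints (%).
#' @export
braun_blanquet_midpoints <- function() {
  c("r" = 0.1, "+" = 0.5, "1" = 2.5, "2" = 15, "3" = 37.5,
    "4" = 62.5, "5" = 87.5)
}

#' Convert Braun-Blanquet codes to percent cover
#'
#' @param code character vector of codes from `{r, +, 1, 2, 3, 4, 5}`.
#' @return numeric vector of midpoint covers (%).
#' @export
bb_to_cover <- function(code) {
  mids <- braun_blanquet_midpoints()
  code <- trimws(as.character(code))
  out <- mids[code]
  if (anyNA(out[!is.na(code) & code != ""])) {
    bad <- unique(code[!code %in% names(mids) & code != ""])
    stop("unknown Braun-Blanquet code(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

#' Construct a releve set
#'
#' A releve set is a sparse plot x species table of projective cover
#' (% of plot area, in (0, 100]): absences are not stored. Summed plot cover
#' may exceed 100 (layered vegetation) and is never renormalized.
#'
#' @param covers data frame with columns `plot_id`, `species`, `cover`.
#' @param plots optional data frame of plot metadata with `plot_id` and
#'   optionally `x`, `y` (metres), `date`.
#' @param plot_area_m2 plot area in square metres (default 16, a 4 x 4 m
#'   quadrat).
#' @return an object of class `releve_set` with elements `covers`, `plots`,
#'   `plot_area_m2`.
#' @export
releve_set <- function(covers, plots = NULL, plot_area_m2 = 16) {
  stopifnot(is.data.frame(covers))
  need <- c("plot_id", "species", "cover")
  if (!all(need %in% names(covers))) {
    stop("covers needs columns: ", paste(need, collapse = ", "))
  }
  covers <- covers[need]
  covers$plot_id <- as.character(covers$plot_id)
  covers$species <- trimws(gsub("[[:space:]]+", " ",
                                as.character(covers$species)))
  covers$cover <- as.numeric(covers$cover)
  covers <- covers[!is.na(covers$cover) & covers$cover > 0, , drop = FALSE]
  if (nrow(covers) == 0L) stop("empty releve set: no positive covers")
  if (any(covers$cover > 100)) {
    bad <- covers[covers$cover > 100, ]
    stop("validation error: cover > 100% for ",
         paste(bad$plot_id, bad$species, sep = "/", collapse = ", "))
  }
  key <- paste(covers$plot_id, normalize_species_names(covers$species),
               sep = "\r")
  if (anyDuplicated(key)) {
    dups <- covers[duplicated(key), c("plot_id", "species")]
    stop("duplicate (plot, species) pairs: ",
         paste(dups$plot_id, dups$species, sep = "/", collapse = ", "))
  }
  plot_ids <- unique(covers$plot_id)
  if (is.null(plots)) {
    plots <- data.frame(plot_id = plot_ids, stringsAsFactors = FALSE)
  } else {
    plots$plot_id <- as.character(plots$plot_id)
    if (anyDuplicated(plots$plot_id)) stop("duplicate plot_ids in metadata")
    missing_meta <- setdiff(plot_ids, plots$plot_id)
    if (length(missing_meta)) {
      stop("plots missing from metadata: ",
           paste(missing_meta, collapse = ", "))
    }
    plots <- plots[plots$plot_id %in% plot_ids, , drop = FALSE]
    plots <- plots[match(plot_ids, plots$plot_id), , drop = FALSE]
  }
  rownames(covers) <- rownames(plots) <- NULL
  structure(list(covers = covers, plots = plots,
                 plot_area_m2 = plot_area_m2),
            class = "releve_set")
}

#' @export
print.releve_set <- function(x, ...) {
  cat("Releve set:", nrow(x$plots), "plots,",
      length(unique(normalize_species_names(x$covers$species))), "species,",
      nrow(x$covers), "occurrences\n")
  cat("Plot area:", x$plot_area_m2, "m^2\n")
  invisible(x)
}

#' Plot x species cover matrix of a releve set
#'
#' @param x a `releve_set`.
#' @param ... unused.
#' @return dense numeric matrix (plots x species), 0 = absent.
#' @export
as.matrix.releve_set <- function(x, ...) {
  plots <- x$plots$plot_id
  species <- sort(unique(x$covers$species))
  m <- matrix(0, length(plots), length(species),
              dimnames = list(plots, species))
  m[cbind(match(x$covers$plot_id, plots),
          match(x$covers$species, species))] <- x$covers$cover
  m
}

detect_cover_coding <- function(values) {
  values <- trimws(as.character(values))
  values <- values[!is.na(values) & values != "" & values != "0"]
  if (all(values %in% names(braun_blanquet_midpoints()))) "braun_blanquet"
  else "percent"
}

parse_covers <- function(values, coding) {
  if (coding == "auto") coding <- detect_cover_coding(values)
  if (coding == "braun_blanquet") bb_to_cover(values)
  else suppressWarnings(as.numeric(values))
}

#' Read releve data from CSV
#'
#' Long layout: columns `plot_id`, `species`, `cover` and optionally `x`,
#' `y`, `date`. Wide layout: first column `plot_id`, remaining columns are
#' species; empty/zero cells are absences. Covers may be percentages or
#' Braun-Blanquet codes; coding is auto-detected from cell content and can
#' be overridden.
#'
#' @param path CSV path.
#' @param layout `"long"` or `"wide"`.
#' @param cover_coding `"auto"`, `"percent"` or `"braun_blanquet"`.
#' @param plot_area_m2 passed to [releve_set()].
#' @return a `releve_set`.
#' @export
read_releves <- function(path, layout = c("long", "wide"),
                         cover_coding = c("auto", "percent",
                                          "braun_blanquet"),
                         plot_area_m2 = 16) {
  layout <- match.arg(layout)
  cover_coding <- match.arg(cover_coding)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (layout == "long") {
    need <- c("plot_id", "species", "cover")
    if (!all(need %in% names(df))) {
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    }
    covers <- df[need]
    covers$cover <- parse_covers(covers$cover, cover_coding)
    meta_cols <- intersect(c("plot_id", "x", "y", "date"), names(df))
    plots <- NULL
    if (length(meta_cols) > 1) {
      plots <- unique(df[meta_cols])
      for (cc in intersect(c("x", "y"), names(plots))) {
        plots[[cc]] <- as.numeric(plots[[cc]])
      }
    }
    releve_set(covers, plots, plot_area_m2)
  } else {
    if (ncol(df) < 2) stop("wide layout needs plot_id plus species columns")
    names(df)[1] <- "plot_id"
    cells <- unlist(df[-1], use.names = FALSE)
    coding <- if (cover_coding == "auto") detect_cover_coding(cells)
              else cover_coding
    long <- do.call(rbind, lapply(names(df)[-1], function(sp) {
      data.frame(plot_id = df$plot_id, species = sp, cover_raw = df[[sp]],
                 stringsAsFactors = FALSE)
    }))
    long <- long[!is.na(long$cover_raw) & trimws(long$cover_raw) != "" &
                   trimws(long$cover_raw) != "0", , drop = FALSE]
    long$cover <- parse_covers(long$cover_raw, coding)
    # preserve the file's plot order
    long <- long[order(match(long$plot_id, df$plot_id)), ]
    releve_set(long[c("plot_id", "species", "cover")],
               plot_area_m2 = plot_area_m2)
  }
}

#' Write releve data to CSV
#'
#' @param rs a `releve_set`.
#' @param path output path.
#' @param layout `"long"` or `"wide"`.
#' @return the path, invisibly.
#' @export
write_releves <- function(rs, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(rs, "releve_set"))
  if (layout == "long") {
    out <- rs$covers
    extra <- setdiff(names(rs$plots), "plot_id")
    if (length(extra)) {
      out <- merge(out, rs$plots, by = "plot_id", sort = FALSE)
    }
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    m <- as.matrix(rs)
    out <- data.frame(plot_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    # empty cell = absent
    for (j in seq(2, ncol(out))) {
      v <- out[[j]]
      out[[j]] <- ifelse(v == 0, "", as.character(v))
    }
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Summary statistics of a releve set
#'
#' Reports species count, per-plot richness and per-plot summed cover
#' (mean, sample SD with the n-1 denominator, min, max). Summed cover is
#' reported as stored; values above 100% are possible in layered vegetation.
#'
#' @param rs a `releve_set`.
#' @return a list with `n_plots`, `n_species`, `richness` and `total_cover`
#'   (each a named vector mean/sd/min/max).
#' @export
summarize_releves <- function(rs) {
  stopifnot(inherits(rs, "releve_set"))
  rich <- tapply(rs$covers$species, rs$covers$plot_id, length)
  tot <- tapply(rs$covers$cover, rs$covers$plot_id, sum)
  stat <- function(v) c(mean = mean(v), sd = stats::sd(v),
                        min = min(v), max = max(v))
  list(n_plots = nrow(rs$plots),
       n_species = length(unique(normalize_species_names(rs$covers$species))),
       richness = stat(as.numeric(rich)),
       total_cover = stat(as.numeric(tot)))
}
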