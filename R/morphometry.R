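#' Construct a terrain grid
#'
#' A terrain grid is a 2-D matrix of elevations (metres above mean sea
#' level) on square cells; `NA` cells are nodata and are never water.
#'
#' @param elevations numeric matrix (rows = northings, cols = eastings).
#' @param cell_size cell edge length in metres (> 0).
#' @return object of class `terrain_grid`.
#' @export
terrain_grid <- function(elevations, cell_size) {
  elevations <- as.matrix(elevations)
  if (!is.numeric(elevations) || length(elevations) == 0) {
    stop("elevations must be a non-empty numeric matrix")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("cell_size must be a positive number")
  }
  structure(list(elevations = elevations, cell_size = cell_size),
            class = "terrain_grid")
}

#' @export
print.terrain_grid <- function(x, ...) {
  e <- x$elevations
  cat("Terrain grid:", nrow(e), "x", ncol(e), "cells of", x$cell_size,
      "m;", sum(is.na(e)), "nodata cells\n")
  cat("Elevation range:", paste(signif(range(e, na.rm = TRUE), 5),
                                collapse = " - "), "m\n")
  invisible(x)
}

#' Read a terrain grid from an ESRI ASCII raster
#'
#' @param path path to an ESRI ASCII grid (.asc) file.
#' @return a `terrain_grid`.
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 6)
  header <- list()
  n_header <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) == 2 && is.na(suppressWarnings(as.numeric(parts[1])))) {
      header[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_header <- n_header + 1
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(header))) {
    stop("ESRI ASCII header must declare ", paste(need, collapse = ", "))
  }
  vals <- scan(path, skip = n_header, quiet = TRUE)
  if (length(vals) != header$ncols * header$nrows) {
    stop("grid body has ", length(vals), " values, expected ",
         header$ncols * header$nrows)
  }
  m <- matrix(vals, nrow = header$nrows, ncol = header$ncols, byrow = TRUE)
  if (!is.null(header$nodata_value)) {
    m[m == header$nodata_value] <- NA_real_
  }
  terrain_grid(m, header$cellsize)
}

#' Write a terrain grid as an ESRI ASCII raster
#'
#' @param grid a `terrain_grid`.
#' @param path output path.
#' @param nodata_value value written for NA cells (default -9999).
#' @return the path, invisibly.
#' @export
write_esri_ascii <- function(grid, path, nodata_value = -9999) {
  stopifnot(inherits(grid, "terrain_grid"))
  e <- grid$elevations
  e[is.na(e)] <- nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(e)),
               paste("nrows", nrow(e)),
               paste("xllcorner", 0),
               paste("yllcorner", 0),
               paste("cellsize", grid$cell_size),
               paste("NODATA_value", nodata_value)), con)
  utils::write.table(e, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Inundate a terrain grid at a water-surface elevation
#'
#' A cell is water when its elevation is strictly below the level (cells at
#' exactly the level stay dry; nodata is never water). Water cells are
#' grouped into bodies by 8-connectivity, so diagonal channels connect.
#'
#' @param grid a [terrain_grid()].
#' @param level water-surface elevation (m MSL), finite.
#' @return integer label matrix (0 = dry/nodata, 1..k = water body id) with
#'   attribute `n_bodies`.
#' @export
inundate <- function(grid, level) {
  stopifnot(inherits(grid, "terrain_grid"), is.finite(level))
  e <- grid$elevations
  wet <- !is.na(e) & e < level
  labels <- label_components(wet)
  labels
}

# 8-connectivity connected components by union-find over wet cells.
label_components <- function(wet) {
  nr <- nrow(wet); nc <- ncol(wet)
  idx <- which(wet)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0) {
    attr(labels, "n_bodies") <- 0L
    return(labels)
  }
  parent <- seq_along(idx)
  pos <- match(seq_len(nr * nc), idx)  # cell -> wet index or NA
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  # union with already-visited neighbours (left column and same-column up)
  offsets <- rbind(c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  for (k in seq_along(idx)) {
    for (o in seq_len(nrow(offsets))) {
      rr <- rows[k] + offsets[o, 1]
      cc <- cols[k] + offsets[o, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        j <- pos[(cc - 1) * nr + rr]
        if (!is.na(j)) union(k, j)
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  comp <- as.integer(factor(roots, levels = unique(roots)))
  labels[idx] <- comp
  attr(labels, "n_bodies") <- max(comp)
  labels
}

#' Measure water-body morphometry
#'
#' Given a water mask from [inundate()]: surface area is the wet-cell count
#' times the cell area; volume is the summed water depth (level minus
#' elevation) over wet cells times the cell area; shoreline length counts
#' every wet-cell edge facing a dry cell, a nodata cell or the grid border,
#' times the cell size. Cell-edge shorelines carry a known grid bias
#' relative to vector shorelines and are exactly reproducible.
#'
#' @param grid the [terrain_grid()] used for the mask.
#' @param mask label matrix from [inundate()] on the same grid.
#' @param level the water-surface elevation used (m MSL).
#' @param scenario optional scenario label.
#' @return one-row data frame: scenario, water_level, shoreline_length_m,
#'   surface_area_m2, volume_m3, n_bodies.
#' @export
measure_waterbody <- function(grid, mask, level, scenario = NA_character_) {
  stopifnot(inherits(grid, "terrain_grid"))
  e <- grid$elevations
  if (!identical(dim(e), dim(mask))) stop("mask does not match grid")
  cs <- grid$cell_size
  wet <- mask > 0
  area <- sum(wet) * cs^2
  volume <- if (any(wet)) sum((level - e[wet])) * cs^2 else 0
  # pad with dry border: edges to out-of-grid count as shoreline
  padded <- matrix(FALSE, nrow(wet) + 2, ncol(wet) + 2)
  padded[2:(nrow(wet) + 1), 2:(ncol(wet) + 1)] <- wet
  core <- padded[2:(nrow(wet) + 1), 2:(ncol(wet) + 1), drop = FALSE]
  up    <- padded[1:nrow(wet),           2:(ncol(wet) + 1), drop = FALSE]
  down  <- padded[3:(nrow(wet) + 2),     2:(ncol(wet) + 1), drop = FALSE]
  left  <- padded[2:(nrow(wet) + 1),     1:ncol(wet),       drop = FALSE]
  right <- padded[2:(nrow(wet) + 1),     3:(ncol(wet) + 2), drop = FALSE]
  edges <- sum(core & !up) + sum(core & !down) +
           sum(core & !left) + sum(core & !right)
  data.frame(scenario = scenario, water_level = level,
             shoreline_length_m = edges * cs,
             surface_area_m2 = area,
             volume_m3 = volume,
             n_bodies = attr(mask, "n_bodies") %||% max(mask),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Morphometry across water-level scenarios
#'
#' @param grid a [terrain_grid()].
#' @param levels named numeric vector: scenario label -> water level (m MSL).
#' @return data frame, one row per scenario (see [measure_waterbody()]).
#' @export
waterbody_morphometry <- function(grid, levels) {
  if (is.null(names(levels)) || any(names(levels) == "")) {
    stop("levels must be a named vector of scenario -> water level")
  }
  do.call(rbind, lapply(names(levels), function(sc) {
    mask <- inundate(grid, levels[[sc]])
    measure_waterbody(grid, mask, levels[[sc]], scenario = sc)
  }))
}

#' Round half away from zero
#'
#' Plain decimal rounding with ties going up in magnitude (0.05 -> 0.1),
#' unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percent-decrease table between scenarios
#'
#' For each (from, to) scenario pair and each morphometric measure, the
#' percent decrease `(from - to) / from * 100`, rounded half-up to one
#' decimal. A zero `from` value yields a missing entry.
#'
#' @param measurements data frame with a `scenario` column and numeric
#'   measure columns (e.g. from [waterbody_morphometry()]).
#' @param pairs list of `c(from, to)` scenario label pairs.
#' @param measures measure columns to difference (default: the numeric
#'   columns apart from `water_level` and `n_bodies`).
#' @return data frame: measure, from, to, from_value, to_value, change_pct.
#' @export
#' @examples
#' m <- data.frame(scenario = c("spring", "summer"),
#'                 surface_area_m2 = c(1929062, 1413644))
#' change_table(m, list(c("spring", "summer")))
change_table <- function(measurements, pairs, measures = NULL) {
  stopifnot(is.data.frame(measurements), "scenario" %in% names(measurements))
  if (is.null(measures)) {
    num <- vapply(measurements, is.numeric, logical(1))
    measures <- setdiff(names(measurements)[num],
                        c("water_level", "n_bodies"))
  }
  if (!is.list(pairs)) pairs <- list(pairs)
  rows <- list()
  for (p in pairs) {
    if (length(p) != 2) stop("each pair must be c(from, to)")
    i <- match(p[1], measurements$scenario)
    j <- match(p[2], measurements$scenario)
    if (is.na(i) || is.na(j)) {
      stop("unknown scenario label(s): ",
           paste(p[is.na(c(i, j))], collapse = ", "))
    }
    for (v in measures) {
      from <- measurements[[v]][i]
      to <- measurements[[v]][j]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = v, from = p[1], to = p[2],
        from_value = from, to_value = to,
        change_pct = if (from == 0) NA_real_
                     else round_half_up((from - to) / from * 100, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
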