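#' Indicator scale definitions
#'
#' The twelve Didukh edaphic/climatic factors and six Ellenberg factors used
#' throughout the package, with their number of ordinal gradations. A species
#' score on a scale with `g` gradations must lie in `[1, g]`.
#'
#' Didukh factors: soil humidity (Hd, 23 gradations), soil moisture
#' variability (fH, 12), soil aeration (Ae, 15), soil acidity (Rc, 15),
#' salt regime (Sl, 19), carbonate content (Ca, 13), nitrogen content
#' (Nt, 11), thermal regime (Tm, 17), ombroregime (Om, 23), continentality
#' (Kn, 17), cryoregime (Cr, 15) and light (Lc, 9). Ellenberg factors:
#' light (L), temperature (T), continentality (K), moisture (F), reaction
#' (R) and nutrients (N) on their conventional 9-step scales (12 for F).
#'
#' @param system one of `"didukh"`, `"ellenberg"` or `"all"`.
#' @return a data frame with columns `scale_id`, `system`, `n_gradations`,
#'   `description`.
#' @export
#' @examples
#' scale_definitions("didukh")
scale_definitions <- function(system = c("all", "didukh", "ellenberg")) {
  system <- match.arg(system)
  didukh <- data.frame(
    scale_id = c("Hd", "fH", "Ae", "Rc", "Sl", "Ca", "Nt", "Tm", "Om",
                 "Kn", "Cr", "Lc"),
    system = "didukh",
    n_gradations = c(23L, 12L, 15L, 15L, 19L, 13L, 11L, 17L, 23L, 17L,
                     15L, 9L),
    description = c(
      "soil humidity", "soil moisture variability", "soil aeration",
      "soil acidity", "salt regime", "carbonate content",
      "nitrogen content", "thermal regime", "ombroregime",
      "climate continentality", "cryoregime", "light intensity"),
    stringsAsFactors = FALSE)
  ellenberg <- data.frame(
    scale_id = c("L", "T", "K", "F", "R", "N"),
    system = "ellenberg",
    n_gradations = c(9L, 9L, 9L, 12L, 9L, 9L),
    description = c("light", "temperature", "continentality", "moisture",
                    "reaction", "nutrients"),
    stringsAsFactors = FALSE)
  out <- switch(system,
                didukh = didukh,
                ellenberg = ellenberg,
                all = rbind(didukh, ellenberg))
  rownames(out) <- NULL
  out
}

#' Number of gradations of an indicator scale
#'
#' @param scale_id scale identifier (see [scale_definitions()]).
#' @return integer vector of gradation counts.
#' @export
n_gradations <- function(scale_id) {
  defs <- scale_definitions("all")
  idx <- match(scale_id, defs$scale_id)
  if (anyNA(idx)) {
    stop("unknown scale_id: ", paste(scale_id[is.na(idx)], collapse = ", "))
  }
  defs$n_gradations[idx]
}

#' Normalize species names for matching
#'
#' Strips leading/trailing whitespace, collapses internal whitespace runs to
#' a single space and case-folds. Used for every species lookup in the
#' package; no fuzzy or synonym matching is ever attempted.
#'
#' @param x character vector of species names.
#' @return character vector of normalized keys.
#' @export
#' @examples
#' normalize_species_names("  Phragmites   australis ")
normalize_species_names <- function(x) {
  x <- gsub("[[:space:]]+", " ", as.character(x))
  x <- trimws(x)
  tolower(x)
}
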