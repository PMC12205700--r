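#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()], with
#' documented defaults. Unknown keys passed to [run_pipeline()] are
#' rejected.
#'
#' Keys: `releves_path` / `releves_layout`, `indicator_path` (both optional;
#' when missing the synthetic generator supplies inputs), `dem_path` and
#' `water_levels` (named list scenario -> level; optional morphometry
#' stage), `change_pairs` (list of c(from, to)), `output_dir`, `weighting`
#' (presence|cover), `hemeroby_weighting`, `min_species`, `cut_levels`,
#' `max_levels`, `min_group`, `alpha`, `phi_threshold`,
#' `natural_threshold`, `n_groups` (cut of the division tree; NULL =
#' terminal leaves), `seed`.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(releves_path = NULL,
       releves_layout = "long",
       indicator_path = NULL,
       dem_path = NULL,
       water_levels = NULL,
       change_pairs = NULL,
       output_dir = "phytoind_output",
       weighting = "presence",
       hemeroby_weighting = "cover",
       min_species = 3,
       cut_levels = c(0, 2, 5, 10, 20),
       max_levels = 6,
       min_group = 5,
       alpha = 0.05,
       phi_threshold = 0.25,
       natural_threshold = 3,
       n_groups = NULL,
       seed = 1)
}

#' Run the full vegetation-assessment pipeline
#'
#' Orchestrates releve ingestion (or synthetic generation), phytoindication
#' scoring and regime conversion, hemeroby/naturalness indices, TWINSPAN
#' classification, fidelity and the synoptic table, PCA of the
#' environment/hemeroby block, and (when a DEM and water levels are given)
#' water-body morphometry with the percent-change table. Every intermediate
#' artifact is written as plain CSV/JSON into `output_dir` together with a
#' run manifest (config hash, package version, seed, per-stage row counts).
#' Identical config and inputs give identical outputs.
#'
#' @param config named list overriding [pipeline_defaults()], or a path to a
#'   JSON file with those keys.
#' @return invisibly, a list with the computed objects and `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$min_species >= 1, cfg$min_group >= 1, cfg$max_levels >= 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$phi_threshold >= -1, cfg$phi_threshold <= 1,
            cfg$natural_threshold %in% 1:6)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(cfg$output_dir, f)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stages <- list()
  mark <- function(stage, rows) stages[[stage]] <<- rows

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null",
                               digits = NA, pretty = TRUE)
  writeLines(cfg_json, out_path("config.json"))

  # stage 1: inputs
  labels <- NULL
  if (is.null(cfg$releves_path) || is.null(cfg$indicator_path)) {
    say("stage releve_io: generating synthetic inputs (seed ", cfg$seed, ")")
    scen <- community_scenario()
    tab <- generate_indicator_table(scen, seed = cfg$seed)
    gen <- generate_releves(scen, tab, seed = cfg$seed)
    rs <- gen$releves
    labels <- gen$labels
    write_indicator_table(tab, out_path("indicator_table.csv"))
    write_releves(rs, out_path("releves.csv"), layout = "long")
    utils::write.csv(data.frame(plot_id = names(labels),
                                association = labels),
                     out_path("true_labels.csv"), row.names = FALSE)
  } else {
    say("stage releve_io: reading ", cfg$releves_path)
    rs <- read_releves(cfg$releves_path, layout = cfg$releves_layout)
    tab <- load_indicator_table(cfg$indicator_path)
  }
  mark("releve_io", nrow(rs$covers))
  summ <- summarize_releves(rs)
  jsonlite::write_json(summ, out_path("releve_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 2: phytoindication
  say("stage phytoindication: community scores and regime conversions")
  regimes <- suppressWarnings(
    plot_regimes(rs, tab, weighting = cfg$weighting,
                 min_species = cfg$min_species))
  if ("W_mm" %in% names(regimes)) {
    regimes$moisture_class <- as.character(classify_moisture(regimes$W_mm))
  }
  mark("phytoindication", nrow(regimes))

  # stage 3: hemeroby
  say("stage hemeroby: per-plot indices")
  hem <- suppressWarnings(
    plot_hemeroby(rs, tab, weighting = cfg$hemeroby_weighting,
                  min_species = cfg$min_species,
                  natural_threshold = cfg$natural_threshold))
  plot_table <- merge(regimes, hem, by = "plot_id", sort = FALSE)
  utils::write.csv(plot_table, out_path("plot_regimes.csv"),
                   row.names = FALSE, na = "")
  mark("hemeroby", nrow(hem))

  # stage 4: classification
  say("stage classification: pseudospecies + TWINSPAN")
  psm <- make_pseudospecies(rs, cut_levels = cfg$cut_levels)
  tree <- twinspan(psm, max_levels = cfg$max_levels,
                   min_group = cfg$min_group)
  groups <- twinspan_groups(tree, k = cfg$n_groups)
  twinspan_to_json(tree, out_path("twinspan.json"))
  utils::write.csv(data.frame(plot_id = names(groups), group = groups),
                   out_path("groups.csv"), row.names = FALSE)
  mark("classification", tree$n_groups)

  # stage 5: fidelity + synoptic table (needs >= 2 groups)
  fid <- syn <- NULL
  if (length(unique(groups)) >= 2) {
    say("stage fidelity: phi and synoptic table over ",
        length(unique(groups)), " groups")
    fid <- suppressWarnings(fidelity(rs, groups))
    syn <- synoptic_table(rs, groups, fid, alpha = cfg$alpha,
                          phi_threshold = cfg$phi_threshold)
    utils::write.csv(fid, out_path("fidelity.csv"), row.names = FALSE,
                     na = "")
    utils::write.csv(data.frame(species = rownames(syn$percentages),
                                syn$percentages, check.names = FALSE),
                     out_path("synoptic.csv"), row.names = FALSE)
    utils::write.csv(syn$diagnostics, out_path("diagnostic_species.csv"),
                     row.names = FALSE)
    mark("fidelity", nrow(fid))
  } else {
    say("stage fidelity: skipped (single group)")
    mark("fidelity", 0L)
  }

  # stage 6: ordination
  say("stage ordination: PCA of environment + hemeroby block")
  didukh <- intersect(scale_definitions("didukh")$scale_id,
                      names(plot_table))
  pca_vars <- c("plot_id", didukh, "hemeroby_index", "naturalness_index")
  pca_in <- plot_table[intersect(pca_vars, names(plot_table))]
  pca <- suppressWarnings(pca_environment(pca_in))
  masked <- filter_significant_loadings(pca, alpha = cfg$alpha)
  utils::write.csv(data.frame(component = colnames(pca$loadings),
                              eigenvalue = pca$eigenvalues,
                              explained_pct = pca$explained_pct),
                   out_path("pca_eigenvalues.csv"), row.names = FALSE)
  utils::write.csv(data.frame(variable = rownames(masked), masked,
                              check.names = FALSE),
                   out_path("pca_loadings_significant.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(data.frame(plot_id = rownames(pca$scores), pca$scores,
                              check.names = FALSE),
                   out_path("pca_scores.csv"), row.names = FALSE)
  grp_means <- summarize_by_group(pca_in, groups[pca_in$plot_id])
  utils::write.csv(grp_means, out_path("group_means.csv"),
                   row.names = FALSE, na = "")
  mark("ordination", pca$retained)

  # stage 7: morphometry (optional)
  morpho <- changes <- NULL
  if (!is.null(cfg$dem_path) && !is.null(cfg$water_levels)) {
    say("stage morphometry: DEM inundation at ",
        length(cfg$water_levels), " levels")
    grid <- read_esri_ascii(cfg$dem_path)
    morpho <- waterbody_morphometry(grid, unlist(cfg$water_levels))
    utils::write.csv(morpho, out_path("morphometry.csv"), row.names = FALSE)
    if (!is.null(cfg$change_pairs)) {
      changes <- change_table(morpho, cfg$change_pairs)
      utils::write.csv(changes, out_path("morphometry_changes.csv"),
                       row.names = FALSE, na = "")
    }
    mark("morphometry", nrow(morpho))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phytoind")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(out_path("config.json"))),
    stages = stages)
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, out_path("run.log"))
  say("pipeline complete: ", length(stages), " stages")

  invisible(list(releves = rs, indicator_table = tab, summary = summ,
                 regimes = regimes, hemeroby = hem, tree = tree,
                 groups = groups, fidelity = fid, synoptic = syn,
                 pca = pca, loadings_significant = masked,
                 group_means = grp_means, morphometry = morpho,
                 changes = changes, true_labels = labels,
                 manifest = manifest))
}
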