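#' Define a synthetic community scenario
#'
#' The generator emulates a set of plant associations arranged along three
#' latent gradients (moisture, dominant; trophic status; light), each
#' association holding a pool of species whose niche optima scatter around
#' the association optimum. Defaults reproduce the structure the analysis
#' pipeline assumes: 12 associations, 135 plots, 146 species, per-plot
#' richness around 12.1 (SD 4.6, forced into 5-28) and summed projective
#' cover around 50%, with dry sites coupled to high hemeroby (ruderal,
#' disturbance-tolerant communities on dry open substrates) so that the
#' moisture gradient, hemeroby and naturalness co-vary the way floodplain
#' drawdown vegetation does.
#'
#' @param n_associations number of associations (default 12).
#' @param n_species total species pool (default 146).
#' @param n_plots total plots (default 135, spread as evenly as possible).
#' @param richness_mean,richness_sd per-plot richness distribution
#'   (default 12.1 / 4.6).
#' @param richness_range richness truncation bounds (default c(5, 28)).
#' @param cover_meanlog,cover_sdlog lognormal per-species cover parameters
#'   (default 0.94 / 1.0, giving plot totals near 50%); draws above 100% are
#'   redrawn (truncation, not renormalization).
#' @param niche_breadth species niche SD on the latent gradients
#'   (default 0.05 on the unit gradient).
#' @param pool_sd scatter of species optima around their association optimum
#'   (default 0.025).
#' @param plot_jitter scatter of plot positions around the association
#'   optimum (default 0.02).
#' @param dry_disturbed_coupling couple dryness to high hemeroby grades
#'   (default TRUE; without it hemeroby is uninformative noise around the
#'   middle grade).
#' @param n_indicators_per_association species per association planted
#'   exactly at the association optimum, to act as recoverable diagnostic
#'   species (default 3).
#' @return object of class `community_scenario`.
#' @export
community_scenario <- function(n_associations = 12,
                               n_species = 146,
                               n_plots = 135,
                               richness_mean = 12.1,
                               richness_sd = 4.6,
                               richness_range = c(5, 28),
                               cover_meanlog = 0.94,
                               cover_sdlog = 1.0,
                               niche_breadth = 0.05,
                               pool_sd = 0.025,
                               plot_jitter = 0.02,
                               dry_disturbed_coupling = TRUE,
                               n_indicators_per_association = 3) {
  stopifnot(n_associations >= 1, n_species >= n_associations,
            n_plots >= n_associations, niche_breadth > 0,
            richness_range[1] >= 1,
            richness_range[1] <= richness_range[2])
  k <- n_associations
  moisture <- seq(0.08, 0.92, length.out = k)
  # fixed decorrelated spreads for the secondary gradients
  perm_t <- ((seq_len(k) - 1) * 5) %% k + 1
  perm_l <- ((seq_len(k) - 1) * 7) %% k + 1
  trophy <- seq(0.1, 0.9, length.out = k)[order(perm_t)]
  light <- seq(0.1, 0.9, length.out = k)[order(perm_l)]
  hemeroby_location <- if (dry_disturbed_coupling) {
    pmin(7, pmax(1, 1 + 6 * (1 - moisture)))
  } else rep(4, k)
  pool <- rep(floor(n_species / k), k)
  pool[seq_len(n_species - sum(pool))] <- pool[seq_len(n_species -
                                                         sum(pool))] + 1
  plots <- rep(floor(n_plots / k), k)
  plots[seq_len(n_plots - sum(plots))] <- plots[seq_len(n_plots -
                                                          sum(plots))] + 1
  structure(list(
    n_associations = k,
    n_species = n_species,
    n_plots = n_plots,
    associations = data.frame(
      association = seq_len(k),
      moisture = moisture, trophy = trophy, light = light,
      hemeroby_location = hemeroby_location,
      pool_size = pool, n_plots = plots),
    richness_mean = richness_mean, richness_sd = richness_sd,
    richness_range = richness_range,
    cover_meanlog = cover_meanlog, cover_sdlog = cover_sdlog,
    niche_breadth = niche_breadth, pool_sd = pool_sd,
    plot_jitter = plot_jitter,
    dry_disturbed_coupling = dry_disturbed_coupling,
    n_indicators_per_association = n_indicators_per_association),
    class = "community_scenario")
}

#' @export
print.community_scenario <- function(x, ...) {
  cat("Community scenario:", x$n_associations, "associations,",
      x$n_species, "species,", x$n_plots, "plots\n")
  cat("Richness target:", x$richness_mean, "+/-", x$richness_sd,
      "in [", x$richness_range[1], ",", x$richness_range[2], "]\n")
  cat("Dry-disturbed coupling:",
      if (x$dry_disturbed_coupling) "on" else "off", "\n")
  invisible(x)
}

#' Generate a synthetic species indicator table
#'
#' Species indicator scores are drawn around their association's latent
#' gradient position: moisture drives Hd (and, inversely, fH, Ae, Kn, Tm and
#' weakly Cr; Om follows moisture), trophy drives Nt, light drives Lc, and
#' Rc/Sl/Ca are mostly position-independent noise, echoing the loading
#' structure a moisture-dominated floodplain gradient produces. Ellenberg
#' columns (F, N, L, T, K, R) mirror the corresponding factors on their own
#' ranges. Hemeroby grades are drawn around the association's hemeroby
#' location and clipped to 1-7. Output is byte-identical for a fixed seed.
#'
#' @param scenario a [community_scenario()].
#' @param seed integer RNG seed.
#' @return an [indicator_table()] with attributes `association` (species ->
#'   association id), `optima` (species latent positions) and
#'   `indicator_species` (planted diagnostic species per association).
#' @export
generate_indicator_table <- function(scenario = community_scenario(),
                                     seed = 1) {
  stopifnot(inherits(scenario, "community_scenario"))
  set.seed(seed, kind = "Mersenne-Twister")
  a <- scenario$associations
  assoc <- rep(a$association, times = a$pool_size)
  ns <- scenario$n_species
  species <- sprintf("Species %03d", seq_len(ns))
  is_indicator <- stats::ave(seq_len(ns), assoc, FUN = seq_along) <=
    scenario$n_indicators_per_association
  jit <- function() ifelse(is_indicator, 0,
                           stats::rnorm(ns, 0, scenario$pool_sd))
  m <- pmin(1, pmax(0, a$moisture[assoc] + jit()))
  t_ <- pmin(1, pmax(0, a$trophy[assoc] + jit()))
  l <- pmin(1, pmax(0, a$light[assoc] + jit()))

  noise <- function(sd = 0.8) stats::rnorm(ns, 0, sd)
  sc <- function(v, g) pmin(g, pmax(1, v))
  df <- data.frame(
    species = species,
    Hd = sc(1 + 22 * m + noise(), 23),
    fH = sc(1 + 11 * (1 - m) + noise(0.6), 12),
    Ae = sc(1 + 14 * (1 - m) + noise(), 15),
    Rc = sc(stats::rnorm(ns, 8, 2), 15),
    Sl = sc(7 + 2 * t_ + noise(1.5), 19),
    Ca = sc(5 + 3 * (1 - m) + noise(1.2), 13),
    Nt = sc(1 + 10 * t_ + noise(0.6), 11),
    Tm = sc(5 + 8 * (1 - m) + noise(), 17),
    Om = sc(1 + 22 * m + noise(), 23),
    Kn = sc(2 + 12 * (1 - m) + noise(), 17),
    Cr = sc(6 + 4 * (1 - m) + noise(1.2), 15),
    Lc = sc(1 + 8 * l + noise(0.5), 9),
    L = sc(1 + 8 * l + noise(0.5), 9),
    T = sc(3 + 5 * (1 - m) + noise(0.8), 9),
    K = sc(2 + 6 * (1 - m) + noise(0.8), 9),
    F = sc(1 + 11 * m + noise(0.6), 12),
    R = sc(stats::rnorm(ns, 5, 1.2), 9),
    N = sc(1 + 8 * t_ + noise(0.6), 9),
    stringsAsFactors = FALSE)
  grade <- round(stats::rnorm(ns, a$hemeroby_location[assoc], 0.7))
  df$hemeroby_grade <- as.integer(pmin(7, pmax(1, grade)))
  tab <- indicator_table(df)
  attr(tab, "association") <- stats::setNames(assoc, species)
  attr(tab, "optima") <- data.frame(species = species, moisture = m,
                                    trophy = t_, light = l,
                                    stringsAsFactors = FALSE)
  attr(tab, "indicator_species") <- data.frame(
    species = species[is_indicator],
    association = assoc[is_indicator], stringsAsFactors = FALSE)
  tab
}

#' Generate a synthetic releve set with true labels
#'
#' Each plot belongs to an association and sits at a jittered copy of its
#' latent optimum; species enter the plot with probability proportional to
#' the Gaussian niche overlap between plot position and species optimum
#' (bandwidth `niche_breadth`). Per-plot richness is drawn from the
#' scenario's normal distribution and redrawn until inside
#' `richness_range`; covers are truncated lognormal draws.
#'
#' @param scenario a [community_scenario()].
#' @param table indicator table from [generate_indicator_table()] (carries
#'   the species latent optima).
#' @param seed integer RNG seed.
#' @return list with `releves` (a [releve_set()]), `labels` (named integer
#'   vector plot_id -> association), and `indicator_species` (copied from
#'   the table).
#' @export
generate_releves <- function(scenario = community_scenario(),
                             table = NULL, seed = 1) {
  stopifnot(inherits(scenario, "community_scenario"))
  if (is.null(table)) table <- generate_indicator_table(scenario, seed)
  opt <- attr(table, "optima")
  if (is.null(opt)) stop("table must come from generate_indicator_table()")
  if (scenario$richness_range[1] > scenario$n_species) {
    stop("infeasible richness range for species pool size")
  }
  set.seed(seed + 1000003L, kind = "Mersenne-Twister")
  a <- scenario$associations
  assoc_of_plot <- rep(a$association, times = a$n_plots)
  np <- scenario$n_plots
  plot_ids <- sprintf("plot_%03d", seq_len(np))
  sp_pos <- as.matrix(opt[c("moisture", "trophy", "light")])
  bw2 <- 2 * scenario$niche_breadth^2
  covers <- vector("list", np)
  for (i in seq_len(np)) {
    centre <- unlist(a[assoc_of_plot[i],
                       c("moisture", "trophy", "light")])
    pos <- centre + stats::rnorm(3, 0, scenario$plot_jitter)
    d2 <- (sp_pos[, 1] - pos[1])^2 + (sp_pos[, 2] - pos[2])^2 +
      (sp_pos[, 3] - pos[3])^2
    w <- exp(-d2 / bw2)
    w <- pmax(w, 1e-12)
    repeat {
      k <- round(stats::rnorm(1, scenario$richness_mean,
                              scenario$richness_sd))
      if (k >= scenario$richness_range[1] &&
          k <= min(scenario$richness_range[2], scenario$n_species)) break
    }
    sp <- sample(opt$species, k, prob = w)
    cv <- stats::rlnorm(k, scenario$cover_meanlog, scenario$cover_sdlog)
    while (any(cv > 100)) {
      cv[cv > 100] <- stats::rlnorm(sum(cv > 100), scenario$cover_meanlog,
                                    scenario$cover_sdlog)
    }
    covers[[i]] <- data.frame(plot_id = plot_ids[i], species = sp,
                              cover = cv, stringsAsFactors = FALSE)
  }
  rs <- releve_set(do.call(rbind, covers))
  list(releves = rs,
       labels = stats::setNames(assoc_of_plot, plot_ids),
       indicator_species = attr(table, "indicator_species"))
}

#' Generate a synthetic terrain grid with depressions
#'
#' A smooth base surface (optionally with gentle cosine relief) carved by
#' paraboloid depressions, analogues of floodplain lakes. Each depression of
#' radius `r` and depth `d` has the closed-form water volume
#' \eqn{\pi r^2 d / 2} when filled to its rim on a flat base; the analytic
#' volumes and rim levels are attached as ground truth (exact for
#' `relief_amplitude = 0`).
#'
#' @param nx,ny grid dimensions (>= 10).
#' @param n_depressions number of depressions.
#' @param depth_range min/max depression depth (m).
#' @param radius_range min/max depression radius (m).
#' @param cell_size cell edge (m), default 12.5.
#' @param base_elevation flat base height (m MSL), default 20.
#' @param relief_amplitude amplitude of smooth background relief (m),
#'   default 0 (flat base, exact analytic volumes).
#' @param seed integer RNG seed.
#' @return a [terrain_grid()] with attribute `depressions` (data frame of
#'   centres, radius, depth, rim level and analytic volume).
#' @export
generate_terrain <- function(nx = 120, ny = 120, n_depressions = 3,
                             depth_range = c(1, 4),
                             radius_range = c(80, 200),
                             cell_size = 12.5, base_elevation = 20,
                             relief_amplitude = 0, seed = 1) {
  stopifnot(nx >= 10, ny >= 10, n_depressions >= 0)
  set.seed(seed + 2000003L, kind = "Mersenne-Twister")
  xs <- (seq_len(nx) - 0.5) * cell_size
  ys <- (seq_len(ny) - 0.5) * cell_size
  base <- matrix(base_elevation, ny, nx)
  if (relief_amplitude > 0) {
    wx <- 2 * pi / (nx * cell_size)
    wy <- 2 * pi / (ny * cell_size)
    base <- base + relief_amplitude *
      outer(ys, xs, function(y, x) sin(1.7 * wx * x) * cos(1.3 * wy * y))
  }
  elev <- base
  deps <- NULL
  if (n_depressions > 0) {
    centres <- matrix(NA_real_, 0, 2)
    radius <- depth <- numeric(0)
    tries <- 0
    while (nrow(centres) < n_depressions && tries < 2000) {
      tries <- tries + 1
      r <- stats::runif(1, radius_range[1], radius_range[2])
      cx <- stats::runif(1, r + cell_size, nx * cell_size - r - cell_size)
      cy <- stats::runif(1, r + cell_size, ny * cell_size - r - cell_size)
      if (nrow(centres) > 0) {
        sep <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
        if (any(sep < r + radius + cell_size)) next
      }
      centres <- rbind(centres, c(cx, cy))
      radius <- c(radius, r)
      depth <- c(depth, stats::runif(1, depth_range[1], depth_range[2]))
    }
    if (nrow(centres) < n_depressions) {
      stop("could not place ", n_depressions,
           " non-overlapping depressions; enlarge the grid")
    }
    for (i in seq_len(nrow(centres))) {
      d2 <- outer(ys, xs, function(y, x)
        (x - centres[i, 1])^2 + (y - centres[i, 2])^2)
      bowl <- base_elevation - depth[i] * (1 - d2 / radius[i]^2)
      inside <- d2 < radius[i]^2
      elev[inside] <- pmin(elev[inside], bowl[inside])
    }
    deps <- data.frame(x = centres[, 1], y = centres[, 2],
                       radius = radius, depth = depth,
                       rim_level = base_elevation,
                       analytic_volume_m3 = pi * radius^2 * depth / 2)
  }
  grid <- terrain_grid(elev, cell_size)
  attr(grid, "depressions") <- deps
  grid
}
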