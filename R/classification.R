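#' Expand a releve set into a pseudospecies matrix
#'
#' Each species is recoded as a set of binary "pseudospecies", one per cover
#' cut level reached: a species at cover `c` switches on the pseudospecies of
#' every cut level `<= c` (nested expansion; the level-0 pseudospecies is
#' plain presence). Default cut levels are 0, 2, 5, 10 and 20 % cover.
#'
#' @param rs a [releve_set()].
#' @param cut_levels strictly increasing cover thresholds (%), first must
#'   be 0.
#' @return binary matrix (plots x pseudospecies) of class
#'   `pseudospecies_matrix`; columns are named `species@cut` and carry
#'   attributes `species`, `cut` and `cut_levels`. Pseudospecies reached by
#'   no plot are not materialized.
#' @export
make_pseudospecies <- function(rs, cut_levels = c(0, 2, 5, 10, 20)) {
  stopifnot(inherits(rs, "releve_set"))
  if (length(cut_levels) < 1 || any(diff(cut_levels) <= 0)) {
    stop("cut_levels must be strictly increasing")
  }
  if (cut_levels[1] != 0) stop("first cut level must be 0")
  plots <- rs$plots$plot_id
  species <- sort(unique(rs$covers$species))
  cols <- list(); col_species <- character(0); col_cut <- numeric(0)
  pres <- as.matrix(rs)[plots, species, drop = FALSE]
  for (sp in species) {
    cv <- pres[, sp]
    for (cl in cut_levels) {
      on <- if (cl == 0) cv > 0 else cv >= cl
      if (!any(on)) break  # nested: higher cuts can only be emptier
      cols[[paste0(sp, "@", cl)]] <- as.integer(on)
      col_species <- c(col_species, sp)
      col_cut <- c(col_cut, cl)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- plots
  structure(m, species = col_species, cut = col_cut,
            cut_levels = cut_levels,
            class = c("pseudospecies_matrix", class(m)))
}

#' First correspondence-analysis axis by reciprocal averaging
#'
#' Power iteration on the row/column averaging operator of a non-negative
#' plot x species matrix, with the trivial constant solution deflated at
#' every step. Converges to the axis-1 eigenvalue (in (0, 1)) and the
#' row (site) and column (species) scores.
#'
#' @param A non-negative matrix without all-zero rows or columns.
#' @param tol convergence tolerance on the site scores (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return list with `eigenvalue`, `site_scores` (weighted mean 0, weighted
#'   variance 1), `species_scores`, `iterations`.
#' @export
ca_axis1 <- function(A, tol = 1e-10, max_iter = 10000) {
  A <- as.matrix(A)
  r <- rowSums(A); cs <- colSums(A)
  if (any(r == 0)) stop("degenerate matrix: all-zero row(s)")
  if (any(cs == 0)) stop("degenerate matrix: all-zero column(s)")
  tot <- sum(A)
  deflate <- function(x) x - sum(r * x) / tot
  wnorm <- function(x) sqrt(sum(r * x^2) / tot)
  # deterministic start: column-index averages, falling back to row index
  x <- deflate(as.vector(A %*% seq_len(ncol(A))) / r)
  if (wnorm(x) < 1e-12) x <- deflate(seq_len(nrow(A)))
  if (wnorm(x) < 1e-12) {
    return(list(eigenvalue = 0, site_scores = rep(0, nrow(A)),
                species_scores = rep(0, ncol(A)), iterations = 0L))
  }
  x <- x / wnorm(x)
  lambda <- 0
  for (it in seq_len(max_iter)) {
    u <- as.vector(crossprod(A, x)) / cs
    x_new <- deflate(as.vector(A %*% u) / r)
    lambda <- wnorm(x_new)
    if (lambda < 1e-14) {
      return(list(eigenvalue = 0, site_scores = rep(0, nrow(A)),
                  species_scores = u, iterations = it))
    }
    x_new <- x_new / lambda
    # sign fixed by the first nonzero coordinate for determinism
    piv <- which(abs(x_new) > 1e-12)[1]
    if (!is.na(piv) && x_new[piv] < 0) x_new <- -x_new
    if (max(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  list(eigenvalue = lambda, site_scores = stats::setNames(x, rownames(A)),
       species_scores = stats::setNames(u, colnames(A)), iterations = it)
}

#' TWINSPAN-style divisive classification
#'
#' Recursively divides the plots of a pseudospecies matrix: at each node the
#' first correspondence-analysis axis is extracted by reciprocal averaging
#' ([ca_axis1()]), plots are split at the axis centroid (a plot exactly at
#' the centroid goes to the negative side), and up to `n_indicators`
#' indicator pseudospecies maximizing the between-side indicator value are
#' recorded for the division. Division stops at `max_levels`, when a side
#' would fall below `min_group` plots, or when the node carries no
#' compositional signal (axis eigenvalue ~ 0). The indicator pseudospecies
#' characterize each division; the partition itself is the ordination split,
#' so agreement with other TWINSPAN implementations is at the partition
#' level, not label by label.
#'
#' @param psm a [make_pseudospecies()] matrix (or any binary plot matrix).
#' @param max_levels maximum division depth (default 6).
#' @param min_group minimum plots per side for a division to be accepted
#'   (default 5).
#' @param n_indicators maximum indicator pseudospecies per division
#'   (default 5).
#' @param tol,max_iter passed to [ca_axis1()].
#' @return an object of class `twinspan_tree`: a nested node list (each
#'   internal node has `plots`, `eigenvalue`, `indicators`, `negative`,
#'   `positive`; each leaf has `plots` and `group`), plus bookkeeping.
#' @export
twinspan <- function(psm, max_levels = 6, min_group = 5, n_indicators = 5,
                     tol = 1e-10, max_iter = 10000) {
  m <- as.matrix(psm)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  if (any(rowSums(m) == 0)) {
    stop("degenerate matrix: plot(s) with zero pseudospecies: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  divide <- function(plot_idx, depth) {
    leaf <- list(plots = rownames(m)[plot_idx], group = NA_integer_)
    if (depth >= max_levels || length(plot_idx) < 2 * min_group) return(leaf)
    sub <- m[plot_idx, colSums(m[plot_idx, , drop = FALSE]) > 0,
             drop = FALSE]
    if (ncol(sub) < 2) return(leaf)
    ca <- ca_axis1(sub, tol = tol, max_iter = max_iter)
    if (ca$eigenvalue <= 1e-10) return(leaf)
    # weighted mean of site scores is 0 by construction: the centroid
    neg <- ca$site_scores <= 0
    if (sum(neg) < min_group || sum(!neg) < min_group) return(leaf)
    n_neg <- colSums(sub[neg, , drop = FALSE] > 0)
    n_pos <- colSums(sub[!neg, , drop = FALSE] > 0)
    indval <- n_pos / sum(!neg) - n_neg / sum(neg)
    ord <- order(abs(indval), decreasing = TRUE)
    take <- utils::head(ord[abs(indval[ord]) > 0], n_indicators)
    indicators <- data.frame(
      pseudospecies = colnames(sub)[take],
      sign = ifelse(indval[take] > 0, 1L, -1L),
      indicator_value = unname(indval[take]),
      stringsAsFactors = FALSE)
    list(plots = rownames(m)[plot_idx],
         eigenvalue = ca$eigenvalue,
         indicators = indicators,
         negative = divide(plot_idx[neg], depth + 1),
         positive = divide(plot_idx[!neg], depth + 1))
  }
  root <- divide(seq_len(nrow(m)), 0L)
  # number leaves left to right
  counter <- 0L
  number <- function(node) {
    if (is.null(node$negative)) {
      counter <<- counter + 1L
      node$group <- counter
      node
    } else {
      node$negative <- number(node$negative)
      node$positive <- number(node$positive)
      node
    }
  }
  root <- number(root)
  structure(list(root = root, n_plots = nrow(m), n_groups = counter,
                 max_levels = max_levels, min_group = min_group),
            class = "twinspan_tree")
}

#' @export
print.twinspan_tree <- function(x, ...) {
  cat("TWINSPAN division tree:", x$n_plots, "plots,", x$n_groups,
      "terminal groups (max_levels =", x$max_levels,
      ", min_group =", x$min_group, ")\n")
  show <- function(node, depth) {
    pad <- strrep("  ", depth)
    if (is.null(node$negative)) {
      cat(pad, "* group ", node$group, ": ", length(node$plots),
          " plots\n", sep = "")
    } else {
      cat(pad, "+ division (eig ", signif(node$eigenvalue, 3), "): ",
          paste(node$indicators$pseudospecies,
                ifelse(node$indicators$sign > 0, "(+)", "(-)"),
                collapse = " "), "\n", sep = "")
      show(node$negative, depth + 1)
      show(node$positive, depth + 1)
    }
  }
  show(x$root, 0)
  invisible(x)
}

#' Terminal or k-group membership from a division tree
#'
#' With `k = NULL` returns the terminal-leaf membership. With `k` given, the
#' hierarchy is cut to `k` groups by replaying divisions in decreasing order
#' of their axis-1 eigenvalue (strongest compositional splits first), the
#' standard way to extract a fixed number of groups from a divisive tree.
#'
#' @param tree a [twinspan()] tree.
#' @param k number of groups wanted, or `NULL` for all terminal groups.
#' @return named integer vector plot_id -> group (groups numbered in plot
#'   order of first appearance).
#' @export
twinspan_groups <- function(tree, k = NULL) {
  stopifnot(inherits(tree, "twinspan_tree"))
  if (is.null(k)) {
    out <- integer(0)
    walk <- function(node) {
      if (is.null(node$negative)) {
        out[node$plots] <<- node$group
      } else {
        walk(node$negative); walk(node$positive)
      }
    }
    walk(tree$root)
    return(out[plots_in_order(tree)])
  }
  if (k < 1) stop("k must be >= 1")
  frontier <- list(tree$root)
  while (length(frontier) < k) {
    eig <- vapply(frontier, function(nd)
      if (is.null(nd$negative)) -Inf else nd$eigenvalue, numeric(1))
    if (all(!is.finite(eig))) break  # no further divisions available
    i <- which.max(eig)
    nd <- frontier[[i]]
    frontier <- c(frontier[-i], list(nd$negative), list(nd$positive))
  }
  out <- integer(0)
  for (i in seq_along(frontier)) out[frontier[[i]]$plots] <- i
  ids <- plots_in_order(tree)
  out <- out[ids]
  # renumber by order of first appearance for determinism
  stats::setNames(as.integer(factor(out, levels = unique(out))), ids)
}

plots_in_order <- function(tree) tree$root$plots

#' Serialize a division tree to JSON
#'
#' @param tree a [twinspan()] tree.
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to a file).
#' @export
twinspan_to_json <- function(tree, path = NULL) {
  strip <- function(node) {
    if (is.null(node$negative)) {
      list(plots = node$plots, group = node$group)
    } else {
      list(plots = node$plots,
           eigenvalue = node$eigenvalue,
           indicators = node$indicators,
           negative = strip(node$negative),
           positive = strip(node$positive))
    }
  }
  js <- jsonlite::toJSON(strip(tree$root), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Species fidelity to vegetation groups (phi coefficient)
#'
#' For each species and group, builds the 2x2 occurrence table (`N` plots in
#' total, `N_p` in the group, `n` occupied by the species, `n_p` occupied
#' within the group) and computes the phi coefficient
#' \deqn{\phi = \frac{N n_p - n N_p}{\sqrt{n N_p (N - n)(N - N_p)}}.}
#' With `equalize = TRUE` (default) the counts are first rescaled to a
#' virtual design in which the target group holds `target_fraction` of all
#' plots, which removes the dependence of phi on unequal group sizes; the
#' two-sided Fisher exact p-value is always computed from the raw table.
#'
#' @param x a [releve_set()] (presence taken from stored covers) or a
#'   binary/logical plot x species matrix.
#' @param groups plot group labels (named by plot_id or aligned).
#' @param equalize rescale to equal virtual group sizes (default TRUE).
#' @param target_fraction virtual share of the target group (default 0.5).
#' @param species optional subset of species to evaluate.
#' @return data frame with species, group, phi, N, N_p, n, n_p, p_value.
#' @export
fidelity <- function(x, groups, equalize = TRUE, target_fraction = 0.5,
                     species = NULL) {
  pres <- if (inherits(x, "releve_set")) as.matrix(x) > 0 else as.matrix(x) > 0
  g <- resolve_groups(groups, rownames(pres))
  labs <- sort(unique(g))
  if (length(labs) < 2) stop("need at least 2 groups")
  if (!is.null(species)) {
    missing_sp <- setdiff(species, colnames(pres))
    if (length(missing_sp)) {
      warning("species absent from data skipped: ",
              paste(missing_sp, collapse = ", "))
    }
    pres <- pres[, intersect(species, colnames(pres)), drop = FALSE]
  }
  empty <- colSums(pres) == 0
  if (any(empty)) {
    warning("species absent everywhere skipped: ",
            paste(colnames(pres)[empty], collapse = ", "))
    pres <- pres[, !empty, drop = FALSE]
  }
  N <- nrow(pres)
  n <- colSums(pres)
  rows <- vector("list", length(labs) * ncol(pres))
  ri <- 0L
  for (lab in labs) {
    in_g <- g == lab
    N_p <- sum(in_g)
    n_p <- colSums(pres[in_g, , drop = FALSE])
    for (j in seq_len(ncol(pres))) {
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        species = colnames(pres)[j], group = lab,
        phi = phi_coefficient(N, N_p, n[j], n_p[j], equalize,
                              target_fraction),
        N = N, N_p = N_p, n = unname(n[j]), n_p = unname(n_p[j]),
        p_value = stats::fisher.test(matrix(c(
          n_p[j], N_p - n_p[j],
          n[j] - n_p[j], N - N_p - n[j] + n_p[j]), 2))$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# phi on (optionally group-size-equalized) counts; constants give phi = 0,
# other zero denominators are undefined (NA).
phi_coefficient <- function(N, N_p, n, n_p, equalize = TRUE,
                            target_fraction = 0.5) {
  if (equalize) {
    N_p2 <- target_fraction * N
    n_p2 <- if (N_p > 0) n_p * N_p2 / N_p else 0
    n_out <- if (N_p < N) (n - n_p) * (N - N_p2) / (N - N_p) else 0
    N_p <- N_p2; n_p <- n_p2; n <- n_p2 + n_out
  }
  if (n == N || n == 0) return(if (n == N) 0 else NA_real_)
  den <- sqrt(n * N_p * (N - n) * (N - N_p))
  if (den == 0) return(NA_real_)
  (N * n_p - n * N_p) / den
}

#' Synoptic table with diagnostic species
#'
#' Per-group percentage occurrence of every species, with a species flagged
#' diagnostic for its best group (highest phi) when the fidelity is both
#' statistically significant (`p < alpha`) and substantial
#' (`phi >= phi_threshold`).
#'
#' @param rs a [releve_set()] or binary plot x species matrix.
#' @param groups plot group labels.
#' @param fid fidelity table from [fidelity()] (computed if omitted).
#' @param alpha significance level (default 0.05).
#' @param phi_threshold minimum phi for a diagnostic species (default 0.25).
#' @return list of class `synoptic_table`: `percentages` (species x group
#'   matrix), `diagnostics` (data frame species, group, phi, p_value,
#'   diagnostic flag).
#' @export
synoptic_table <- function(rs, groups, fid = NULL, alpha = 0.05,
                           phi_threshold = 0.25) {
  pres <- if (inherits(rs, "releve_set")) as.matrix(rs) > 0
          else as.matrix(rs) > 0
  g <- resolve_groups(groups, rownames(pres))
  labs <- sort(unique(g))
  if (is.null(fid)) fid <- suppressWarnings(fidelity(rs, groups))
  pct <- sapply(labs, function(lab) {
    100 * colSums(pres[g == lab, , drop = FALSE]) / sum(g == lab)
  })
  pct <- matrix(pct, nrow = ncol(pres),
                dimnames = list(colnames(pres), labs))
  best <- do.call(rbind, lapply(split(fid, fid$species), function(d) {
    d <- d[!is.na(d$phi), , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d <- d[order(-d$phi, d$group), , drop = FALSE][1, ]
    d$diagnostic <- d$p_value < alpha & d$phi >= phi_threshold
    d[c("species", "group", "phi", "p_value", "diagnostic")]
  }))
  rownames(best) <- NULL
  structure(list(percentages = pct, diagnostics = best,
                 alpha = alpha, phi_threshold = phi_threshold),
            class = "synoptic_table")
}

#' @export
print.synoptic_table <- function(x, ...) {
  cat("Synoptic table:", nrow(x$percentages), "species x",
      ncol(x$percentages), "groups;",
      sum(x$diagnostics$diagnostic), "diagnostic species (p <", x$alpha,
      ", phi >=", x$phi_threshold, ")\n")
  invisible(x)
}
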