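# small in-code fixtures shared across test files

tiny_indicator_df <- function() {
  data.frame(
    species = c("Phragmites australis", "Salix alba", "Bromus tectorum",
                "Typha angustifolia", "Portulaca oleracea"),
    Hd = c(18, 14, 5, 20, 6),
    Rc = c(8, 7, 9, 8, 10),
    Nt = c(7, 5, 3, 8, 4),
    hemeroby_grade = c(2L, 3L, 6L, 2L, 5L),
    stringsAsFactors = FALSE)
}

tiny_table <- function() indicator_table(tiny_indicator_df())

tiny_releves <- function() {
  releve_set(data.frame(
    plot_id = c("p1", "p1", "p1", "p2", "p2", "p2"),
    species = c("Phragmites australis", "Salix alba", "Typha angustifolia",
                "Bromus tectorum", "Portulaca oleracea", "Salix alba"),
    cover = c(50, 25, 25, 40, 40, 20),
    stringsAsFactors = FALSE))
}

# releve set with two disjoint species blocks of n plots each
block_releves <- function(n = 10, richness = 4, seed = 7) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(2 * n)) {
    block <- if (i <= n) "A" else "B"
    sp <- paste0(block, "_sp", sample(1:8, richness))
    rows[[i]] <- data.frame(plot_id = sprintf("%s%02d", block, i),
                            species = sp,
                            cover = stats::runif(richness, 1, 60),
                            stringsAsFactors = FALSE)
  }
  releve_set(do.call(rbind, rows))
}

# independent flood-fill oracle for connected components (8-connectivity)
flood_fill_labels <- function(wet) {
  nr <- nrow(wet); nc <- ncol(wet)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(wet)) {
    if (labels[start] != 0) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      r <- ((cell - 1) %% nr) + 1
      c <- ((cell - 1) %/% nr) + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if ((dr | dc) && rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          j <- (cc - 1) * nr + rr
          if (wet[j] && labels[j] == 0) {
            labels[j] <- nxt
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  attr(labels, "n_bodies") <- nxt
  labels
}

# brute-force per-cell morphometry oracle
brute_morphometry <- function(elev, level, cell_size) {
  nr <- nrow(elev); nc <- ncol(elev)
  wet <- function(r, c) {
    r >= 1 && r <= nr && c >= 1 && c <= nc &&
      !is.na(elev[r, c]) && elev[r, c] < level
  }
  area <- 0; vol <- 0; edges <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!wet(r, c)) next
    area <- area + 1
    vol <- vol + (level - elev[r, c])
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      if (!wet(r + d[1], c + d[2])) edges <- edges + 1
    }
  }
  list(area = area * cell_size^2, volume = vol * cell_size^2,
       shoreline = edges * cell_size)
}
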