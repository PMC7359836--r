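# Independent oracles and small fixture builders used across the suite.

# Dense Floyd-Warshall all-pairs shortest paths over an edge list; the
# brute-force oracle for the Dijkstra-based least-cost matrices.
floyd_warshall <- function(n, from, to, w) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_along(from)) {
    d[from[e], to[e]] <- min(d[from[e], to[e]], w[e])
    d[to[e], from[e]] <- d[from[e], to[e]]
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

# Edge list of a cost graph as plain vectors (cell indices, weights).
graph_edges <- function(cg) {
  el <- igraph::as_edgelist(cg$graph, names = TRUE)
  list(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
       w = igraph::E(cg$graph)$weight)
}

# Uniform small landscape: every cell suitable, optional class overrides.
flat_landscape <- function(n_rows, n_cols, cell_size = 1,
                           origin_lat = (n_rows - 1) * cell_size / 2,
                           classes = NULL) {
  grid <- landscape_grid(n_rows, n_cols, origin_lon = 0,
                         origin_lat = origin_lat, cell_size = cell_size)
  if (is.null(classes)) classes <- rep(0L, n_rows * n_cols)
  list(grid = grid,
       suit = suitability_raster(classes == 0L, grid),
       class = cost_class_raster(classes, grid))
}

# Weir-Cockerham theta via the ANOVA mean-squares route, computed from
# individual-level sums of squares -- an independent derivation of the same
# estimator used to cross-check the frequency-formula implementation.
wc_theta_ms <- function(table, popA, popB) {
  df <- table$data[table$data$population %in% c(popA, popB), , drop = FALSE]
  df <- df[!is.na(df$allele1) & !is.na(df$allele2), , drop = FALSE]
  r <- 2
  num <- 0; den <- 0
  for (locus in table$loci) {
    sub <- df[df$locus == locus, , drop = FALSE]
    n_i <- c(sum(sub$population == popA), sum(sub$population == popB))
    if (any(n_i == 0)) next
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (al in unique(c(sub$allele1, sub$allele2))) {
      x1 <- as.numeric(sub$allele1 == al)
      x2 <- as.numeric(sub$allele2 == al)
      xbar_ind <- (x1 + x2) / 2
      p_i <- c(mean(xbar_ind[sub$population == popA]),
               mean(xbar_ind[sub$population == popB]))
      pbar <- sum(n_i * p_i) / sum(n_i)
      ssg <- sum((x1 - xbar_ind)^2 + (x2 - xbar_ind)^2)
      ssi <- 2 * sum((xbar_ind - p_i[match(sub$population,
                                           c(popA, popB))])^2)
      ssp <- 2 * sum(n_i * (p_i - pbar)^2)
      msg <- ssg / sum(n_i)
      msi <- ssi / sum(n_i - 1)
      msp <- ssp / (r - 1)
      s_a <- (msp - msi) / (2 * nc)
      s_b <- (msi - msg) / 2
      s_c <- msg
      num <- num + s_a
      den <- den + s_a + s_b + s_c
    }
  }
  num / den
}

# Small genotype table built directly from a list of per-population
# genotype specs: list(pop = list(c(a1, a2), ...)) per locus.
make_genotypes <- function(loci) {
  rows <- list()
  for (locus in names(loci)) {
    for (pop in names(loci[[locus]])) {
      g <- loci[[locus]][[pop]]
      for (j in seq_along(g)) {
        rows[[length(rows) + 1]] <- data.frame(
          population = pop, individual = paste0(pop, "_", j),
          locus = locus,
          allele1 = ifelse(g[[j]][1] == 0, NA_integer_, g[[j]][1]),
          allele2 = ifelse(g[[j]][2] == 0, NA_integer_, g[[j]][2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  paleodiverge:::new_genotype_table(do.call(rbind, rows))
}

# Genotype table where two populations are fixed for alternative alleles.
fixed_alt_genotypes <- function(n = 10) {
  make_genotypes(list(loc1 = list(
    popA = replicate(n, c(1, 1), simplify = FALSE),
    popB = replicate(n, c(2, 2), simplify = FALSE))))
}

# Rigid Procrustes error: best rotation/reflection of X onto Y after
# centering (no scaling); used for the PCoA configuration-recovery checks.
procrustes_error <- function(X, Y) {
  X <- scale(X, scale = FALSE)
  Y <- scale(Y, scale = FALSE)
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  sqrt(sum((X %*% R - Y)^2))
}

# Random symmetric zero-diagonal labelled matrix.
random_dist_matrix <- function(n, labels = paste0("s", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}
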