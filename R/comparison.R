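#' Principal coordinate analysis of a distance matrix
#'
#' Classical (Gower) scaling: the squared distances are double-centered
#' (`B = -1/2 J D^2 J`, `J = I - 11'/n`) and eigendecomposed; coordinates
#' are the eigenvectors scaled by the square roots of the positive
#' eigenvalues. No Cailliez or Lingoes correction is applied: negative
#' eigenvalues (a non-Euclidean input) are reported as-is and the per-axis
#' variance shares are computed over the positive eigenvalues only.
#'
#' @param D symmetric zero-diagonal labelled distance matrix.
#' @return object of class `pcoa_result`: `coordinates` (n x k matrix, k =
#'   number of positive eigenvalues, rownames = labels), `eigenvalues` (all
#'   n, descending), `pct_variance` (length k, shares of the positive
#'   eigenvalue total, summing to 1).
#' @export
pcoa <- function(D) {
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  D <- as.matrix(D)
  n <- nrow(D)
  labs <- rownames(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-12 & e$values > 0
  k <- sum(pos)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = k)
  dimnames(coords) <- list(labs, paste0("axis", seq_len(k)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 pct_variance = e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(3, length(x$pct_variance))
  cat(sprintf("pcoa_result: %d points, axis variance shares %s\n",
              nrow(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$pct_variance[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' UPGMA dendrogram as a Newick string
#'
#' Average-linkage hierarchical clustering of the distance matrix, rendered
#' as a rooted ultrametric tree: each tip sits at height half the merge
#' distance (so two labels at distance 2 become `(A:1,B:1);`). Labels are
#' sorted alphabetically before clustering so merge-order ties break
#' deterministically.
#'
#' @param D symmetric labelled distance matrix, >= 2 labels.
#' @return Newick string with branch lengths, semicolon-terminated.
#' @export
upgma_newick <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2) stop("need at least 2 labels", call. = FALSE)
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::write.tree(ape::as.phylo(hc))
}

#' Mantel test with Spearman correlation
#'
#' Correlates the strictly-lower-triangle entries of two labelled distance
#' matrices by Spearman rank correlation; significance is assessed by
#' jointly permuting the rows and columns of `D2`. Labels are intersected
#' first (sites absent from either matrix are dropped). The p-value uses
#' the add-one convention on the two-sided statistic:
#' `p = (count(|rho_perm| >= |rho|) + 1) / (n_perm + 1)`.
#'
#' @param D1,D2 labelled symmetric matrices.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return object of class `mantel_result` with `rho`, `p_value`,
#'   `n_permutations`, `seed`, `n` (common labels), `r_squared` (of the
#'   linear fit of the `D1` entries on the `D2` entries, a convenience
#'   statistic).
#' @export
mantel_spearman <- function(D1, D2, n_perm = 999, seed = 1) {
  common <- intersect(rownames(D1), rownames(D2))
  if (length(common) < 3)
    stop("fewer than 3 common labels", call. = FALSE)
  A <- as.matrix(D1)[common, common]
  B <- as.matrix(D2)[common, common]
  lt <- lower.tri(A)
  rho <- stats::cor(A[lt], B[lt], method = "spearman")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old))
  set.seed(seed)
  n <- length(common)
  count <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(n)
    rp <- stats::cor(A[lt], B[idx, idx][lt], method = "spearman")
    if (abs(rp) >= abs(rho)) count <- count + 1L
  }
  fit <- stats::lm(A[lt] ~ B[lt])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  structure(list(rho = rho, p_value = (count + 1) / (n_perm + 1),
                 n_permutations = n_perm, seed = seed, n = n,
                 r_squared = r2),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "mantel_result: Spearman rho = %.3f, p = %.4g (%d permutations, n = %d), R2 = %.3f\n",
    x$rho, x$p_value, x$n_permutations, x$n, x$r_squared))
  invisible(x)
}

#' Assign sampling sites to occupied simulation cells
#'
#' Each site is assigned to the nearest occupied cell center within
#' `buffer_km` great-circle kilometers (default 200 km); sites with no
#' occupied cell inside the buffer are left unassigned and excluded from
#' downstream comparison. Exact distance ties go to the lowest cell index.
#'
#' @param sites data frame with columns `site`, `lon`, `lat`.
#' @param occupied integer vector of occupied cell indices.
#' @param grid a [landscape_grid()].
#' @param buffer_km assignment buffer radius in km.
#' @return data frame `site`, `cell` (NA if unassigned), `dist_km`.
#' @export
assign_sites_to_cells <- function(sites, occupied, grid, buffer_km = 200) {
  stopifnot(all(c("site", "lon", "lat") %in% names(sites)),
            !anyDuplicated(sites$site))
  occupied <- sort(as.integer(occupied))
  centers <- cell_centers(grid, occupied)
  out <- data.frame(site = sites$site, cell = NA_integer_,
                    dist_km = NA_real_)
  for (i in seq_len(nrow(sites))) {
    d <- great_circle_km(c(sites$lon[i], sites$lat[i]), centers)
    best <- which.min(d)  # first minimum = lowest cell index on ties
    if (d[best] <= buffer_km) {
      out$cell[i] <- occupied[best]
      out$dist_km[i] <- d[best]
    }
  }
  out
}

#' Map PCoA coordinates to RGB colors
#'
#' Positions on the first two PCoA axes are min-max scaled to [0, 1] and
#' rendered as an RGB triple per label: red = axis 1, blue = 1 - axis 1,
#' and green a 50/50 blend of a neutral 0.5 with axis 2. Rank-1
#' configurations are padded with a zero second axis; a degenerate
#' (constant) axis scales to 0.5. Deterministic, and invariant to global
#' translation of the coordinates.
#'
#' @param coords a [pcoa()] result (or a coordinate matrix with >= 1
#'   column).
#' @return matrix with columns `r`, `g`, `b` in [0, 1], rownames = labels.
#' @export
pcoa_colors <- function(coords) {
  if (inherits(coords, "pcoa_result")) coords <- coords$coordinates
  if (ncol(coords) < 2)
    coords <- cbind(coords, matrix(0, nrow(coords), 2 - ncol(coords)))
  scale01 <- function(v) {
    r <- range(v)
    if (diff(r) < 1e-12) return(rep(0.5, length(v)))
    (v - r[1]) / diff(r)
  }
  a1 <- scale01(coords[, 1])
  a2 <- scale01(coords[, 2])
  out <- cbind(r = a1, g = 0.5 * 0.5 + 0.5 * a2, b = 1 - a1)
  rownames(out) <- rownames(coords)
  out
}

#' Read a sampling-site table
#'
#' @param path CSV with columns `site`, `lon`, `lat` (extra columns such as
#'   a population label are kept).
#' @return data frame of sites.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "lon", "lat") %in% names(df)))
    stop("site table must have columns site, lon, lat", call. = FALSE)
  if (anyDuplicated(df$site)) stop("duplicate site ids", call. = FALSE)
  if (any(abs(df$lat) > 90)) stop("invalid latitude", call. = FALSE)
  df
}
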