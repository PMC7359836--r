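#' Parameters for the two-refugia glacial scenario
#'
#' A stylized glacial cycle on a lon-lat grid near the equator (so 1-degree
#' cells are ~111 km and dispersal parameters in km keep their meaning):
#' during the glacial phase two disjoint suitable blocks (the refugia) are
#' separated by a glacier band wide enough that no least-cost path between
#' them falls inside a plausible per-step dispersal reach; in the
#' postglacial phase the glacier retreats and a suitable corridor connects
#' the blocks.
#'
#' @param n_rows,n_cols grid dimensions (default 30 x 30 at 1 degree).
#' @param glacial_steps,postglacial_steps step counts of the two phases.
#' @param refugium_a,refugium_b lists `list(rows =, cols =)` of the two
#'   suitable blocks.
#' @param barrier_cols columns of the glacier band during glacial steps.
#' @param corridor list `list(rows =, cols =)` of the postglacial corridor.
#' @param cell_size degrees per cell.
#' @param step_years years per step.
#' @return object of class `scenario_params`.
#' @export
scenario_params <- function(n_rows = 30, n_cols = 30,
                            glacial_steps = 100, postglacial_steps = 50,
                            refugium_a = list(rows = 11:20, cols = 3:8),
                            refugium_b = list(rows = 11:20, cols = 23:28),
                            barrier_cols = 11:20,
                            corridor = list(rows = 14:17, cols = 9:22),
                            cell_size = 1, step_years = 100) {
  p <- structure(as.list(environment()), class = "scenario_params")
  blk <- function(b) as.vector(outer(b$rows, b$cols,
                                     function(r, co) paste(r, co)))
  a <- blk(refugium_a); b <- blk(refugium_b)
  bar <- as.vector(outer(seq_len(n_rows), barrier_cols, paste))
  if (length(intersect(a, b)) || length(intersect(a, bar)) ||
      length(intersect(b, bar)))
    stop("refugium and barrier geometries overlap", call. = FALSE)
  if (max(refugium_a$rows, refugium_b$rows, corridor$rows) > n_rows ||
      max(refugium_a$cols, refugium_b$cols, corridor$cols,
          barrier_cols) > n_cols)
    stop("geometry outside grid", call. = FALSE)
  p
}

#' Two-refugia glacial landscape series
#'
#' @param params a [scenario_params()].
#' @return a [suitability_series()] of `glacial_steps + postglacial_steps`
#'   steps, oldest (fully glacial) first. Deterministic.
#' @export
two_refugia_scenario <- function(params = scenario_params()) {
  p <- params
  # center the grid on the equator
  origin_lat <- (p$n_rows - 1) * p$cell_size / 2
  grid <- landscape_grid(p$n_rows, p$n_cols, origin_lon = 0,
                         origin_lat = origin_lat, cell_size = p$cell_size)
  base_suit <- matrix(FALSE, p$n_rows, p$n_cols)
  base_suit[p$refugium_a$rows, p$refugium_a$cols] <- TRUE
  base_suit[p$refugium_b$rows, p$refugium_b$cols] <- TRUE

  glacial_class <- matrix(CLASS_CODES[["UNSUITABLE_LAND"]],
                          p$n_rows, p$n_cols)
  glacial_class[, p$barrier_cols] <- CLASS_CODES[["GLACIER"]]
  glacial_class[base_suit] <- CLASS_CODES[["SUITABLE"]]

  post_suit <- base_suit
  post_suit[p$corridor$rows, p$corridor$cols] <- TRUE
  post_class <- matrix(CLASS_CODES[["UNSUITABLE_LAND"]],
                       p$n_rows, p$n_cols)
  post_class[post_suit] <- CLASS_CODES[["SUITABLE"]]

  n <- p$glacial_steps + p$postglacial_steps
  su <- c(rep(list(suitability_raster(base_suit, grid)), p$glacial_steps),
          rep(list(suitability_raster(post_suit, grid)),
              p$postglacial_steps))
  cc <- c(rep(list(cost_class_raster(glacial_class, grid)),
              p$glacial_steps),
          rep(list(cost_class_raster(post_class, grid)),
              p$postglacial_steps))
  suitability_series(su, cc, step_years = p$step_years,
                     years_bp = (n - seq_len(n)) * p$step_years)
}

#' Random dynamic landscape (property-test input source)
#'
#' Independent Bernoulli suitability at the first step; each later step
#' keeps the previous cell state with probability `persistence`, otherwise
#' redraws, giving temporally correlated landscapes with a stationary
#' suitable fraction. Unsuitable cells get a random class among unsuitable
#' land, glacier and sea.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_steps number of steps.
#' @param suitability_fraction stationary suitable fraction in (0, 1].
#' @param seed integer seed.
#' @param persistence probability a cell keeps its state between steps.
#' @param cell_size degrees per cell.
#' @return a [suitability_series()].
#' @export
random_scenario <- function(n_rows, n_cols, n_steps,
                            suitability_fraction, seed,
                            persistence = 0.8, cell_size = 1) {
  stopifnot(suitability_fraction > 0, suitability_fraction <= 1)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old))
  set.seed(seed)
  grid <- landscape_grid(n_rows, n_cols, origin_lon = 0,
                         origin_lat = (n_rows - 1) * cell_size / 2,
                         cell_size = cell_size)
  n <- n_rows * n_cols
  su <- vector("list", n_steps)
  cc <- vector("list", n_steps)
  state <- stats::runif(n) < suitability_fraction
  for (s in seq_len(n_steps)) {
    if (s > 1) {
      redraw <- stats::runif(n) >= persistence
      state[redraw] <- stats::runif(sum(redraw)) < suitability_fraction
    }
    cls <- sample(CLASS_CODES[c("UNSUITABLE_LAND", "GLACIER", "SEA")],
                  n, replace = TRUE)
    cls[state] <- CLASS_CODES[["SUITABLE"]]
    su[[s]] <- suitability_raster(state, grid)
    cc[[s]] <- cost_class_raster(cls, grid)
  }
  suitability_series(su, cc)
}

#' Synthetic diploid genotype tables
#'
#' A hierarchical allele-frequency model in the spirit of the
#' Balding-Nichols parameterization: each locus draws an ancestral
#' frequency vector (flat Dirichlet over `n_alleles` alleles); each
#' population perturbs it with a Dirichlet whose concentration is
#' `(1 - divergence_level) / divergence_level`, so the expected
#' among-population FST is approximately `divergence_level`. Individuals
#' are diploid draws from their population's frequencies. At
#' `divergence_level = 0` all populations share the ancestral frequencies;
#' at 1 each population fixes a single allele.
#'
#' @param n_pops,n_loci,n_ind numbers of populations, loci and individuals
#'   per population.
#' @param divergence_level in [0, 1].
#' @param seed integer seed.
#' @param n_alleles alleles per locus.
#' @return a `genotype_table`.
#' @export
synthetic_genotypes <- function(n_pops = 4, n_loci = 16, n_ind = 30,
                                divergence_level = 0.2, seed = 1,
                                n_alleles = 6) {
  stopifnot(divergence_level >= 0, divergence_level <= 1, n_pops >= 2)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old))
  set.seed(seed)
  rdirichlet <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    g / sum(g)
  }
  pops <- paste0("pop", seq_len(n_pops))
  loci <- paste0("loc", seq_len(n_loci))
  rows <- vector("list", n_loci * n_pops)
  k <- 0
  for (l in seq_len(n_loci)) {
    anc <- rdirichlet(rep(1, n_alleles))
    for (pp in seq_len(n_pops)) {
      pf <- if (divergence_level == 0) anc
      else if (divergence_level == 1) {
        f <- numeric(n_alleles)
        f[sample.int(n_alleles, 1, prob = anc)] <- 1
        f
      } else rdirichlet(anc * (1 - divergence_level) / divergence_level)
      a <- matrix(sample.int(n_alleles, 2 * n_ind, replace = TRUE,
                             prob = pf), ncol = 2)
      k <- k + 1
      rows[[k]] <- data.frame(
        population = pops[pp],
        individual = sprintf("%s_ind%02d", pops[pp], seq_len(n_ind)),
        locus = loci[l], allele1 = a[, 1], allele2 = a[, 2],
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(match(df$population, pops), df$individual,
                 match(df$locus, loci)), ]
  rownames(df) <- NULL
  new_genotype_table(df)
}
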