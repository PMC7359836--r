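#' Simulation configuration
#'
#' Parameters of the divergence simulator. Divergence is bookkept in free
#' units: every step, each pair of occupied cells in *different* connection
#' components accumulates `drift_multiplier * delta_flow` units of divergence
#' (drift), while each pair in the *same* component loses `delta_flow` units
#' (gene flow), floored at zero. Only the ratio (default 3: drift three times
#' as fast as homogenization) is biologically meaningful; `delta_flow` sets
#' the unit. A burn-in replays the oldest landscape `burn_in_steps` times
#' (default 50) so refugial populations start the dynamic run already
#' differentiated.
#'
#' Dispersal is drawn per cell in km/year but a step spans `step_years`
#' years; least-cost paths are thresholded against
#' `dispersal * dispersal_threshold_years` km per step
#' (default `= step_years`, i.e. a century of movement opportunity).
#'
#' @param delta_flow divergence units removed per connected step (> 0).
#' @param drift_multiplier accumulation/reduction ratio (> 0), default 3.
#' @param burn_in_steps number of burn-in repetitions of the oldest step.
#' @param step_years years per landscape step.
#' @param dispersal_threshold_years years of movement allowed per step when
#'   thresholding least-cost paths; default `step_years`.
#' @param connection_rule `"max"` (either population can reach the other) or
#'   `"min"`.
#' @param neighborhood 4 or 8.
#' @param seed integer run seed.
#' @param cost a [cost_params()].
#' @param kernel a [dispersal_kernel()].
#' @param redraw_each_step if `TRUE`, redraw every cell's dispersal each
#'   step instead of fixing it at colonization.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(delta_flow = 1, drift_multiplier = 3,
                       burn_in_steps = 50, step_years = 100,
                       dispersal_threshold_years = step_years,
                       connection_rule = c("max", "min"),
                       neighborhood = 8, seed = 1,
                       cost = cost_params(), kernel = dispersal_kernel(),
                       redraw_each_step = FALSE) {
  connection_rule <- match.arg(connection_rule)
  if (delta_flow <= 0) stop("delta_flow must be > 0", call. = FALSE)
  if (drift_multiplier <= 0)
    stop("drift_multiplier must be > 0", call. = FALSE)
  if (burn_in_steps < 0) stop("burn_in_steps must be >= 0", call. = FALSE)
  structure(list(delta_flow = delta_flow,
                 drift_multiplier = drift_multiplier,
                 burn_in_steps = as.integer(burn_in_steps),
                 step_years = step_years,
                 dispersal_threshold_years = dispersal_threshold_years,
                 connection_rule = connection_rule,
                 neighborhood = neighborhood, seed = as.integer(seed),
                 cost = cost, kernel = kernel,
                 redraw_each_step = isTRUE(redraw_each_step)),
            class = "sim_config")
}

new_sim_state <- function(step_index, occupied, dispersal, D) {
  structure(list(step_index = step_index, occupied = occupied,
                 dispersal_km_yr = dispersal, D = D),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: step %d, %d occupied cells, max divergence %g\n",
              x$step_index, length(x$occupied),
              if (length(x$D)) max(x$D) else 0))
  invisible(x)
}

#' Initialize the simulator state
#'
#' Occupies every suitable cell of the oldest landscape step with a
#' zero-divergence population and draws each cell's dispersal distance from
#' the kernel under the run seed.
#'
#' @param series a [suitability_series()].
#' @param config a [sim_config()].
#' @return a `sim_state`.
#' @export
initialize_state <- function(series, config) {
  occupied <- which(series$suitability[[1]]$values)
  if (length(occupied) == 0)
    stop("empty initial landscape: oldest step has no suitable cell",
         call. = FALSE)
  set.seed(config$seed)
  # the RNG stream is left advanced on purpose: the simulator continues it
  disp <- draw_cell_dispersal(occupied, config$kernel)
  D <- matrix(0, length(occupied), length(occupied),
              dimnames = list(occupied, occupied))
  new_sim_state(0L, occupied, disp, D)
}

#' Remove populations whose cell became unsuitable
#'
#' @param state a `sim_state`.
#' @param suitability the step's suitability raster.
#' @return the state with extinct cells (and their divergence rows/columns)
#'   dropped; may have zero occupied cells (global extinction).
#' @export
apply_extinction <- function(state, suitability) {
  keep <- suitability$values[state$occupied]
  if (all(keep)) return(state)
  occ <- state$occupied[keep]
  new_sim_state(state$step_index, occ,
                state$dispersal_km_yr[as.character(occ)],
                state$D[as.character(occ), as.character(occ),
                        drop = FALSE])
}

#' Colonize suitable unoccupied cells
#'
#' Every suitable unoccupied cell whose least-cost path from at least one
#' occupied source is strictly below that source's per-step dispersal reach
#' becomes occupied. A colonist inherits the full divergence row of its
#' cheapest source (ties broken by the lowest source cell index), so two
#' colonists' mutual divergence equals the divergence between their sources
#' (zero if they share one), and a colonist is identical to its source.
#' Colonists draw their own dispersal distance from the kernel.
#'
#' @param state a `sim_state`.
#' @param costD least-cost matrix covering occupied and candidate cells.
#' @param suitable_unoccupied integer vector of candidate cell indices.
#' @param per_step_km named per-cell dispersal reach in km per step for the
#'   occupied cells.
#' @param kernel a [dispersal_kernel()] for the colonists' draws.
#' @return the augmented `sim_state`.
#' @export
colonize <- function(state, costD, suitable_unoccupied, per_step_km,
                     kernel) {
  targets <- sort(setdiff(as.integer(suitable_unoccupied), state$occupied))
  if (length(targets) == 0 || length(state$occupied) == 0) return(state)
  occ <- state$occupied  # sorted ascending
  sub <- costD[as.character(occ), as.character(targets), drop = FALSE]
  reach <- sub < per_step_km[as.character(occ)]  # recycles by column
  colonized <- targets[colSums(reach) > 0]
  if (length(colonized) == 0) return(state)
  src <- vapply(which(colSums(reach) > 0), function(j) {
    cand <- which(reach[, j])
    occ[cand[which.min(sub[cand, j])]]  # first min = lowest cell id on ties
  }, integer(1))
  names(src) <- colonized

  new_occ <- sort(c(occ, colonized))
  # representative of each cell: itself if old, its source if colonist
  rep_cell <- ifelse(new_occ %in% occ, new_occ, src[as.character(new_occ)])
  D2 <- state$D[as.character(rep_cell), as.character(rep_cell),
                drop = FALSE]
  dimnames(D2) <- list(new_occ, new_occ)
  diag(D2) <- 0
  draws <- draw_cell_dispersal(colonized, kernel)
  disp <- c(state$dispersal_km_yr, draws)[as.character(new_occ)]
  new_sim_state(state$step_index, new_occ, disp, D2)
}

#' Apply one step of drift and gene flow to the divergence matrix
#'
#' Pairs of occupied cells in the same connection component lose
#' `delta_flow` divergence units (floored at zero); pairs in different
#' components gain `drift_multiplier * delta_flow`.
#'
#' @param state a `sim_state`.
#' @param component named component labels covering all occupied cells (as
#'   from [connection_edges()]).
#' @param config a [sim_config()].
#' @return the updated `sim_state`.
#' @export
update_divergence <- function(state, component, config) {
  lab <- component[as.character(state$occupied)]
  if (anyNA(lab))
    stop("component labels must cover all occupied cells", call. = FALSE)
  same <- outer(lab, lab, "==")
  D <- state$D
  D[same] <- pmax(D[same] - config$delta_flow, 0)
  D[!same] <- D[!same] + config$drift_multiplier * config$delta_flow
  diag(D) <- 0
  new_sim_state(state$step_index, state$occupied, state$dispersal_km_yr, D)
}

# one full update cycle on a fixed landscape:
# colonize -> connect -> drift/gene-flow
step_cycle <- function(state, lcm, suitable_cells, config) {
  reach <- state$dispersal_km_yr * config$dispersal_threshold_years
  state <- colonize(state, lcm, setdiff(suitable_cells, state$occupied),
                    reach, config$kernel)
  if (config$redraw_each_step)
    state$dispersal_km_yr <- draw_cell_dispersal(state$occupied,
                                                 config$kernel)
  reach <- state$dispersal_km_yr * config$dispersal_threshold_years
  costD <- lcm[as.character(state$occupied), as.character(state$occupied),
               drop = FALSE]
  conn <- connection_edges(costD, reach, rule = config$connection_rule)
  list(state = update_divergence(state, conn$component, config),
       conn = conn)
}

#' Burn-in on the oldest landscape
#'
#' Replays the oldest landscape step `burn_in_steps` times (colonization
#' within the static landscape, connection, drift/gene-flow) so isolated
#' refugia accumulate divergence before the dynamic run.
#'
#' @param state an initialized `sim_state`.
#' @param series a [suitability_series()] (its first step is replayed).
#' @param config a [sim_config()].
#' @return the burnt-in `sim_state`.
#' @export
burn_in <- function(state, series, config) {
  if (config$burn_in_steps == 0) return(state)
  graph <- build_cost_graph(series$suitability[[1]],
                            series$cost_class[[1]], config$cost,
                            config$neighborhood)
  suitable <- which(series$suitability[[1]]$values)
  lcm <- least_cost_matrix(graph, suitable)
  for (b in seq_len(config$burn_in_steps))
    state <- step_cycle(state, lcm, suitable, config)$state
  state
}

#' Run the full divergence simulation
#'
#' Initializes on the oldest landscape, burns in, then advances through the
#' series oldest to newest. Each step applies, in order: (1) habitat change
#' with local extinction of populations on newly unsuitable cells; (2)
#' colonization of suitable cells within least-cost dispersal reach; (3)
#' connection of occupied cells and the drift / gene-flow update of the
#' pairwise divergence matrix. Deterministic for a fixed seed.
#'
#' @param series a validated [suitability_series()].
#' @param config a [sim_config()].
#' @param snapshot_steps integer steps at which to store occupancy,
#'   component labels and (if `snapshot_D`) the divergence matrix.
#' @param snapshot_D store D at snapshot steps.
#' @return object of class `sim_result`: `state` (final), `log` (data frame
#'   with per-step occupied and component counts), `snapshots`, `config`,
#'   `series_years_bp`.
#' @export
run_simulation <- function(series, config, snapshot_steps = integer(),
                           snapshot_D = FALSE) {
  val <- validate_series(series)
  if (length(val$violations))
    stop("invalid series: ", val$violations[1], call. = FALSE)
  old_rng <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_rng(old_rng))

  state <- initialize_state(series, config)
  state <- burn_in(state, series, config)

  cache_key <- function(s) paste(c(series$suitability[[s]]$values,
                                   series$cost_class[[s]]$values),
                                 collapse = "")
  cache <- new.env(parent = emptyenv())
  get_lcm <- function(s, suitable) {
    key <- cache_key(s)
    if (!is.null(cache[[key]])) return(cache[[key]])
    graph <- build_cost_graph(series$suitability[[s]],
                              series$cost_class[[s]], config$cost,
                              config$neighborhood)
    cache[[key]] <- least_cost_matrix(graph, suitable)
    cache[[key]]
  }

  n_steps <- length(series)
  log <- data.frame(step = integer(n_steps), years_bp = numeric(n_steps),
                    n_occupied = integer(n_steps),
                    n_components = integer(n_steps))
  snapshots <- list()
  for (s in seq_len(n_steps)) {
    state$step_index <- s
    state <- apply_extinction(state, series$suitability[[s]])
    if (length(state$occupied) == 0)
      stop(structure(class = c("paleodiverge_extinction", "error",
                               "condition"),
                     list(message = sprintf(
                            "global extinction at step %d", s),
                          call = NULL, step = s)))
    suitable <- which(series$suitability[[s]]$values)
    lcm <- get_lcm(s, suitable)
    res <- step_cycle(state, lcm, suitable, config)
    state <- res$state
    comp <- res$conn$component
    log[s, ] <- list(s, series$years_bp[s], length(state$occupied),
                     length(unique(comp)))
    if (s %in% snapshot_steps) {
      snapshots[[as.character(s)]] <- list(
        step = s, occupied = state$occupied, component = comp,
        dispersal_km_yr = state$dispersal_km_yr,
        D = if (snapshot_D) state$D else NULL)
    }
  }
  structure(list(state = state, log = log, snapshots = snapshots,
                 config = config, series_years_bp = series$years_bp),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "sim_result: %d steps, final occupancy %d cells, %d connection component(s)\n",
    nrow(x$log), length(x$state$occupied),
    x$log$n_components[nrow(x$log)]))
  invisible(x)
}

#' Zero-divergence clusters of a divergence matrix
#'
#' Populations whose accumulated divergence has been fully eroded by gene
#' flow form clusters: connected components of the graph joining pairs with
#' divergence <= `tol`. Within a connection component that persists long
#' enough, all pairwise divergence reaches exactly zero, so these clusters
#' are the model's "genetic clusters".
#'
#' @param D symmetric divergence matrix with dimnames.
#' @param tol numeric tolerance for zero.
#' @return named integer vector of cluster labels (lowest member cell
#'   index), one per row of `D`.
#' @export
zero_divergence_clusters <- function(D, tol = 1e-9) {
  cells <- as.integer(rownames(D))
  adj <- D <= tol
  adj[!upper.tri(adj)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  label_components(cells, cbind(cells[idx[, 1]], cells[idx[, 2]]))
}
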