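# small, fast two-refugia scenario used throughout this file
small_refugia <- function(glacial = 6, post = 4) {
  scenario_params(n_rows = 12, n_cols = 16, glacial_steps = glacial,
                  postglacial_steps = post,
                  refugium_a = list(rows = 5:8, cols = 2:4),
                  refugium_b = list(rows = 5:8, cols = 13:15),
                  barrier_cols = 6:11,
                  corridor = list(rows = 6:7, cols = 5:12))
}

test_that("initialization occupies the oldest suitable cells at zero divergence", {
  series <- two_refugia_scenario(small_refugia())
  cfg <- sim_config(burn_in_steps = 0, seed = 3)
  st <- initialize_state(series, cfg)
  suitable <- which(series$suitability[[1]]$values)
  expect_identical(st$occupied, suitable)
  expect_true(all(st$D == 0))
  expect_equal(dim(st$D), c(length(suitable), length(suitable)))
  expect_length(st$dispersal_km_yr, length(suitable))
  st2 <- initialize_state(series, cfg)
  expect_identical(st, st2)

  l <- flat_landscape(2, 2)
  empty <- suitability_series(
    list(suitability_raster(rep(0, 4), l$grid)),
    list(cost_class_raster(rep(1L, 4), l$grid)))
  expect_error(initialize_state(empty, cfg), "empty initial landscape")
})

test_that("extinction removes exactly the newly unsuitable populations", {
  series <- two_refugia_scenario(small_refugia())
  cfg <- sim_config(burn_in_steps = 0, seed = 3)
  st <- initialize_state(series, cfg)
  unchanged <- apply_extinction(st, series$suitability[[1]])
  expect_identical(unchanged, st)

  grid <- series$grid
  vals <- series$suitability[[1]]$values
  gone <- st$occupied[1]
  vals[gone] <- FALSE
  st2 <- apply_extinction(st, suitability_raster(vals, grid))
  expect_identical(st2$occupied, setdiff(st$occupied, gone))
  expect_equal(nrow(st2$D), length(st$occupied) - 1L)
  expect_false(as.character(gone) %in% rownames(st2$D))

  st3 <- apply_extinction(st, suitability_raster(rep(0, n_cells(grid)),
                                                 grid))
  expect_length(st3$occupied, 0)
})

test_that("colonists inherit the divergence row of their cheapest source", {
  # two occupied cells 1 and 3 on a 1x3 equatorial strip, mutual D = 12
  l <- flat_landscape(1, 3, origin_lat = 0)
  cg <- build_cost_graph(l$suit, l$class, cost_params())
  lcm <- least_cost_matrix(cg, 1:3)
  kern <- dispersal_kernel(4.3, 2.5)
  st <- paleodiverge:::new_sim_state(
    0L, c(1L, 3L), c("1" = 5, "3" = 5),
    matrix(c(0, 12, 12, 0), 2, dimnames = list(c(1, 3), c(1, 3))))

  # both sources reach cell 2 (112 km < 150 km); both colonists of a
  # shared target inherit from the cheapest source
  st2 <- colonize(st, lcm, 2L, c("1" = 150, "3" = 150), kern)
  expect_identical(st2$occupied, 1:3)
  expect_equal(st2$D["1", "2"], 0)   # source 1 is nearest (tie -> lowest)
  expect_equal(st2$D["2", "3"], 12)  # inherits source 1's row
  expect_true("2" %in% names(st2$dispersal_km_yr))

  # out of range of every source: not colonized
  st3 <- colonize(st, lcm, 2L, c("1" = 100, "3" = 100), kern)
  expect_identical(st3$occupied, c(1L, 3L))

  # two colonists from the two different sources carry the sources' D
  l5 <- flat_landscape(1, 5, origin_lat = 0)
  cg5 <- build_cost_graph(l5$suit, l5$class, cost_params())
  lcm5 <- least_cost_matrix(cg5, 1:5)
  st5 <- paleodiverge:::new_sim_state(
    0L, c(1L, 5L), c("1" = 5, "5" = 5),
    matrix(c(0, 12, 12, 0), 2, dimnames = list(c(1, 5), c(1, 5))))
  st6 <- colonize(st5, lcm5, c(2L, 4L), c("1" = 150, "5" = 150), kern)
  expect_identical(st6$occupied, c(1L, 2L, 4L, 5L))
  expect_equal(st6$D["2", "4"], 12)  # sources 1 and 5 had D = 12
  expect_equal(st6$D["1", "2"], 0)
  expect_equal(st6$D["4", "5"], 0)
})

test_that("drift and gene flow update follows the 3:1 rule with a zero floor", {
  cfg <- sim_config(burn_in_steps = 0, seed = 1)
  st <- paleodiverge:::new_sim_state(
    0L, c(1L, 2L), c("1" = 1, "2" = 1),
    matrix(0, 2, 2, dimnames = list(1:2, 1:2)))
  # isolated pair starting at 0 gains 3 per step
  isolated <- c("1" = 1L, "2" = 2L)
  connected <- c("1" = 1L, "2" = 1L)
  st1 <- update_divergence(st, isolated, cfg)
  expect_equal(st1$D["1", "2"], 3)
  # connected pair at 3 drops to 2
  st2 <- update_divergence(st1, connected, cfg)
  expect_equal(st2$D["1", "2"], 2)
  # floor at zero
  st0 <- update_divergence(st, connected, cfg)
  expect_equal(st0$D["1", "2"], 0)
  expect_error(update_divergence(st, c("1" = 1L), cfg), "cover")
})

test_that("isolation/contact schedules follow the closed-form trajectory", {
  set.seed(17)
  for (rep in 1:50) {
    a <- sample(0:20, 1)
    b <- sample(0:20, 1)
    df <- runif(1, 0.5, 2)
    cfg <- sim_config(delta_flow = df, burn_in_steps = 0, seed = 1)
    st <- paleodiverge:::new_sim_state(
      0L, c(1L, 2L), c("1" = 1, "2" = 1),
      matrix(0, 2, 2, dimnames = list(1:2, 1:2)))
    for (i in seq_len(a))
      st <- update_divergence(st, c("1" = 1L, "2" = 2L), cfg)
    for (i in seq_len(b))
      st <- update_divergence(st, c("1" = 1L, "2" = 1L), cfg)
    expect_equal(st$D["1", "2"], max(0, 3 * a - b) * df,
                 tolerance = 1e-12)
  }
})

test_that("burn-in accumulates divergence only between refugia", {
  series <- two_refugia_scenario(small_refugia())
  cfg <- sim_config(burn_in_steps = 10, seed = 5)
  st <- burn_in(initialize_state(series, cfg), series, cfg)
  blocks <- zero_divergence_clusters(st$D)
  expect_length(unique(blocks), 2)
  between <- st$D[outer(blocks, blocks, "!=")]
  expect_true(all(between == 10 * 3 * 1))   # 50 x 3 x delta in full scale
  within <- st$D[outer(blocks, blocks, "==")]
  expect_true(all(within == 0))

  # a single connected refugium stays at zero divergence
  one <- scenario_params(n_rows = 8, n_cols = 8, glacial_steps = 2,
                         postglacial_steps = 1,
                         refugium_a = list(rows = 3:6, cols = 2:3),
                         refugium_b = list(rows = 3:6, cols = 4:5),
                         barrier_cols = 7,
                         corridor = list(rows = 4:5, cols = 6))
  s1 <- two_refugia_scenario(one)
  st1 <- burn_in(initialize_state(s1, cfg), s1, cfg)
  expect_true(all(st1$D == 0))

  cfg0 <- sim_config(burn_in_steps = 0, seed = 5)
  st0 <- initialize_state(series, cfg0)
  expect_identical(burn_in(st0, series, cfg0), st0)
})

test_that("the divergence matrix stays symmetric, non-negative, zero-diagonal", {
  series <- random_scenario(6, 6, 8, suitability_fraction = 0.6, seed = 2)
  # guard against an all-unsuitable first step in the random draw
  skip_if(sum(series$suitability[[1]]$values) == 0)
  cfg <- sim_config(burn_in_steps = 3, seed = 9,
                    kernel = dispersal_kernel(2, 2.5))
  res <- tryCatch(run_simulation(series, cfg,
                                 snapshot_steps = 1:8, snapshot_D = TRUE),
                  paleodiverge_extinction = function(e) NULL)
  skip_if(is.null(res))
  for (sn in res$snapshots) {
    if (is.null(sn$D)) next
    expect_equal(sn$D, t(sn$D))
    expect_true(all(sn$D >= 0))
    expect_true(all(diag(sn$D) == 0))
    expect_identical(as.integer(rownames(sn$D)), sn$occupied)
  }
})

test_that("full runs are deterministic and detect global extinction", {
  series <- two_refugia_scenario(small_refugia())
  cfg <- sim_config(burn_in_steps = 4, seed = 11)
  r1 <- run_simulation(series, cfg)
  r2 <- run_simulation(series, cfg)
  expect_identical(r1$state, r2$state)
  expect_identical(r1$log, r2$log)

  # landscape that disappears at step 2
  l <- flat_landscape(2, 3)
  dead <- suitability_series(
    list(l$suit, suitability_raster(rep(0, 6), l$grid)),
    list(l$class, cost_class_raster(rep(1L, 6), l$grid)))
  err <- tryCatch(run_simulation(dead, sim_config(burn_in_steps = 0,
                                                  seed = 1)),
                  paleodiverge_extinction = function(e) e)
  expect_s3_class(err, "paleodiverge_extinction")
  expect_equal(err$step, 2L)
  expect_match(conditionMessage(err), "global extinction at step 2")
})

test_that("persistent connection drives within-component divergence to exactly zero", {
  # refugia connect after the corridor opens; within-component divergence
  # must reach 0 within ceil(maxD/delta_flow) connected steps and stay 0
  series <- two_refugia_scenario(small_refugia(glacial = 5, post = 40))
  cfg <- sim_config(burn_in_steps = 2, seed = 13)
  n <- length(series)
  res <- run_simulation(series, cfg, snapshot_steps = 1:n,
                        snapshot_D = TRUE)
  merged <- which(res$log$n_components == 1)[1]  # first fully joined step
  expect_false(is.na(merged))
  maxD <- max(res$snapshots[[as.character(merged)]]$D)
  deadline <- merged + ceiling(maxD / cfg$delta_flow)
  expect_lte(deadline, n)
  reached <- FALSE
  for (s in (merged + 1):n) {
    sn <- res$snapshots[[as.character(s)]]
    comp <- sn$component
    same <- outer(comp, comp, "==")
    diag(same) <- FALSE
    if (s >= deadline) {
      expect_true(all(sn$D[same] == 0),
                  label = sprintf("within-component D zero at step %d", s))
      reached <- TRUE
    }
  }
  expect_true(reached)
})

test_that("relabelling occupied cells permutes the divergence matrix", {
  st <- paleodiverge:::new_sim_state(
    0L, c(2L, 5L, 9L), c("2" = 1, "5" = 1, "9" = 1),
    matrix(c(0, 1, 2, 1, 0, 4, 2, 4, 0), 3,
           dimnames = list(c(2, 5, 9), c(2, 5, 9))))
  cfg <- sim_config(burn_in_steps = 0, seed = 1)
  comp <- c("2" = 2L, "5" = 2L, "9" = 9L)
  out <- update_divergence(st, comp, cfg)
  # same update with rows stored in a different order
  perm <- c(3L, 1L, 2L)
  stp <- paleodiverge:::new_sim_state(
    0L, st$occupied[perm], st$dispersal_km_yr[perm],
    st$D[perm, perm])
  outp <- update_divergence(stp, comp, cfg)
  expect_equal(outp$D[rownames(out$D), colnames(out$D)], out$D)
})
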