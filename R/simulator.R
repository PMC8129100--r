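#' Cell population state
#'
#' Positions and type labels of all mobile cells. Coordinates are um, with
#' z = 0 at the substrate; the slit origin is at a slit corner and the disk
#' origin at the disk centre.
#'
#' @param positions N x 3 numeric matrix (x, y, z in um; z >= 0).
#' @param types character vector of `"N"` (neuron) / `"A"` (astrocyte).
#' @return An object of class `cell_population`.
#' @export
cell_population <- function(positions, types) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have three columns")
  storage.mode(positions) <- "double"
  types <- as.character(types)
  if (length(types) != nrow(positions))
    stop("types must match the number of positions")
  if (!all(types %in% c("N", "A")))
    stop("types must be 'N' or 'A'")
  if (nrow(positions) && any(positions[, 3] < 0))
    stop("z coordinates must be >= 0")
  colnames(positions) <- c("x", "y", "z")
  structure(list(positions = positions, types = types),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("Cell population: %d cells (%d neurons, %d astrocytes)\n",
              length(x$types), sum(x$types == "N"), sum(x$types == "A")))
  invisible(x)
}

#' Fixed substrate anchor points
#'
#' Immobile adhesion points on the z = 0 substrate plane.
#'
#' @param positions M x 2 numeric matrix (x, y in um).
#' @return An object of class `anchor_field`.
#' @export
anchor_field <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) && ncol(positions) != 2)
    stop("anchor positions must have two columns")
  if (!nrow(positions)) positions <- matrix(numeric(0), 0, 2)
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y")
  structure(list(positions = positions), class = "anchor_field")
}

anchor_matrix <- function(anchors) {
  if (is.null(anchors)) return(matrix(numeric(0), 0, 2))
  if (inherits(anchors, "anchor_field")) return(anchors$positions)
  as.matrix(anchors)
}

#' Confinement geometry
#'
#' Hard lateral walls and a floor at z = 0; the top is open. A slit is a
#' rectangular channel of given length and width; a disk is a cylinder of
#' given diameter centred on the origin. `height` is the initial seeding
#' height, not a ceiling.
#'
#' @param kind `"slit"` or `"disk"`.
#' @param length,width slit dimensions (um).
#' @param diameter disk diameter (um).
#' @param height initial seeding height (um).
#' @return An object of class `confinement`.
#' @export
confinement <- function(kind = c("slit", "disk"), length = 4000, width = 200,
                        diameter = 400, height = 100) {
  kind <- match.arg(kind)
  dims <- if (kind == "slit") c(length, width, height) else c(diameter, height)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("confinement dimensions must be > 0")
  structure(list(kind = kind, length = length, width = width,
                 diameter = diameter, height = height),
            class = "confinement")
}

confinement_volume <- function(conf) {
  if (conf$kind == "slit") conf$length * conf$width * conf$height
  else pi * (conf$diameter / 2)^2 * conf$height
}

confinement_floor_area <- function(conf) {
  if (conf$kind == "slit") conf$length * conf$width
  else pi * (conf$diameter / 2)^2
}

#' Simulation configuration
#'
#' @param confinement a [confinement()].
#' @param cell_density cells per um^3.
#' @param astrocyte_fraction fraction of cells marked as astrocytes.
#' @param min_cell_spacing minimum cell centre-to-centre distance at
#'   seeding (um).
#' @param anchor_density substrate anchor points per um^2.
#' @param min_anchor_spacing minimum anchor spacing (um).
#' @param force_params a [force_parameters()].
#' @param schedule a [stiffness_schedule()].
#' @param seed RNG seed governing placement (and any symmetry-breaking).
#' @param snapshot_every snapshot cadence in steps (0 = final state only).
#' @param max_displacement maximum force-driven displacement per step (um),
#'   a bounded migration speed; 0 (the default) leaves the displacement
#'   rule unbounded. The bound is available because the unbounded rule
#'   lets condensed aggregates exchange cells violently; in practice it
#'   changes neither cluster counts nor sorting trends, so the unbounded
#'   rule stays the default.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(confinement = neuroaggsim::confinement(),
                              cell_density = 1e-4,
                              astrocyte_fraction = 0.2,
                              min_cell_spacing = 10,
                              anchor_density = 2e-3,
                              min_anchor_spacing = 10,
                              force_params = force_preset("optimized"),
                              schedule = stiffness_schedule(),
                              seed = 1L,
                              snapshot_every = 0L,
                              max_displacement = 0) {
  stopifnot(inherits(confinement, "confinement"),
            inherits(force_params, "force_parameters"),
            inherits(schedule, "stiffness_schedule"))
  if (!is.finite(cell_density) || cell_density <= 0)
    stop("cell_density must be > 0")
  if (astrocyte_fraction < 0 || astrocyte_fraction > 1)
    stop("astrocyte_fraction must be in [0, 1]")
  if (anchor_density <= 0) stop("anchor_density must be > 0")
  structure(list(confinement = confinement, cell_density = cell_density,
                 astrocyte_fraction = astrocyte_fraction,
                 min_cell_spacing = min_cell_spacing,
                 anchor_density = anchor_density,
                 min_anchor_spacing = min_anchor_spacing,
                 force_params = force_params, schedule = schedule,
                 seed = as.integer(seed),
                 snapshot_every = as.integer(snapshot_every),
                 max_displacement = max_displacement),
            class = "simulation_config")
}

conf_kind_code <- function(conf) if (conf$kind == "slit") 0L else 1L

#' Seed a culture with random cells and anchors
#'
#' Places `round(density * volume)` cells uniformly at random in the
#' confinement with a hard-core minimum spacing (rejection sampling), marks
#' a random subset as astrocytes, and places
#' `round(anchor_density * floor area)` anchors on the substrate plane with
#' their own minimum spacing. Fully reproducible from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return List with elements `population` ([cell_population()]) and
#'   `anchors` ([anchor_field()]).
#' @export
initialize_culture <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  conf <- config$confinement
  n_cells <- round(config$cell_density * confinement_volume(conf))
  n_astro <- round(config$astrocyte_fraction * n_cells)
  n_anchor <- round(config$anchor_density * confinement_floor_area(conf))
  set.seed(config$seed)
  disk <- conf$kind == "disk"
  cells <- cpp_place_points(n_cells, if (disk) 1L else 0L,
                            conf$length, conf$width, conf$height,
                            conf$diameter / 2, config$min_cell_spacing,
                            10000L)
  anchors <- cpp_place_points(n_anchor, if (disk) 3L else 2L,
                              conf$length, conf$width, conf$height,
                              conf$diameter / 2, config$min_anchor_spacing,
                              10000L)
  types <- rep("N", n_cells)
  types[sample.int(n_cells, n_astro)] <- "A"
  list(population = cell_population(cells, types),
       anchors = anchor_field(anchors))
}

#' Advance the population by one step
#'
#' Displaces every cell by `displace(net_force(...), k, g)` and clamps the
#' result to the lateral confinement and to z >= 0. Counts and type labels
#' are unchanged.
#'
#' @param population a [cell_population()].
#' @param anchors an [anchor_field()].
#' @param params a [force_parameters()].
#' @param k movement freedom for this step.
#' @param conf a [confinement()].
#' @param max_displacement per-step displacement bound (um); 0 disables.
#' @return The displaced [cell_population()].
#' @export
sim_step <- function(population, anchors, params, k, conf,
                     max_displacement = 0) {
  stopifnot(inherits(population, "cell_population"),
            inherits(conf, "confinement"))
  if (k < 0 || k > 1) stop("k must be in [0, 1]")
  f <- net_forces_all(population, anchors, params)
  if (any(!is.finite(f))) {
    bad <- which(!is.finite(rowSums(f)))[1]
    stop(sprintf("non-finite force on cell %d", bad))
  }
  disp <- k * f
  if (max_displacement > 0) {
    mag <- sqrt(rowSums(disp^2))
    over <- mag > max_displacement
    if (any(over))
      disp[over, ] <- disp[over, ] * (max_displacement / mag[over])
  }
  pos <- population$positions
  pos[, 1] <- pos[, 1] + disp[, 1]
  pos[, 2] <- pos[, 2] + disp[, 2]
  pos[, 3] <- pos[, 3] + disp[, 3] - params$g
  pos <- clamp_positions(pos, conf)
  cell_population(pos, population$types)
}

clamp_positions <- function(pos, conf) {
  if (conf$kind == "slit") {
    pos[, 1] <- pmin(pmax(pos[, 1], 0), conf$length)
    pos[, 2] <- pmin(pmax(pos[, 2], 0), conf$width)
  } else {
    r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    rad <- conf$diameter / 2
    out <- r > rad
    if (any(out)) {
      scale <- rad / r[out]
      pos[out, 1] <- pos[out, 1] * scale
      pos[out, 2] <- pos[out, 2] * scale
    }
  }
  pos[, 3] <- pmax(pos[, 3], 0)
  pos
}

#' Run a full simulation
#'
#' Seeds the culture from `config`, then advances it `total_time` steps,
#' recomputing the movement freedom each step. Deterministic given
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return An object of class `simulation_result`: list with `initial`,
#'   `final` (both [cell_population()]), `anchors`, `snapshots` (list of
#'   populations at the snapshot cadence, always including the final
#'   state), `snapshot_steps`, and the echoed `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  init <- initialize_culture(config)
  pop <- init$population
  sched <- config$schedule
  conf <- config$confinement
  res <- cpp_run_simulation(pop$positions,
                            as.integer(pop$types == "A"),
                            anchor_matrix(init$anchors),
                            unclass(config$force_params),
                            total_time = sched$total_time,
                            stiffening_delay = sched$stiffening_delay,
                            stiffening_constant = sched$stiffening_constant,
                            conf_kind = conf_kind_code(conf),
                            L = conf$length, W = conf$width,
                            rad = conf$diameter / 2,
                            snapshot_every = config$snapshot_every,
                            max_step = config$max_displacement)
  snaps <- lapply(res$snapshots, cell_population, types = pop$types)
  structure(list(initial = pop,
                 final = snaps[[length(snaps)]],
                 anchors = init$anchors,
                 snapshots = snaps,
                 snapshot_steps = res$steps,
                 config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulation result: %d cells, %s confinement, %d steps (%d snapshots)\n",
    length(x$final$types), x$config$confinement$kind,
    x$config$schedule$total_time, length(x$snapshots)))
  invisible(x)
}

#' Parameter sweep with per-run morphometrics
#'
#' Runs the simulation for each variation (a named list of overrides applied
#' to the base configuration) times `replicates`, and summarises every run
#' with the standard morphometrics: percent contraction, neuron cluster
#' count, mean cluster CCDP peak, and superficial / deep astrocyte ratios.
#' Replicate r of variation v runs with seed `base_seed + (r - 1)`;
#' variation overrides may themselves set `seed` to change the base.
#'
#' Recognised override names: any [simulation_config()] field, plus
#' `force_params` (a [force_parameters()]) and `equilibrium_target` (um;
#' sets the repulsion strength via [repulsion_for_equilibrium()] using the
#' neuron-neuron effective attraction).
#'
#' @param base_config a [simulation_config()].
#' @param variations named list of override lists; names become the
#'   `variation` column.
#' @param replicates runs per variation.
#' @return Data frame with one row per run: variation, replicate, seed,
#'   n_cells, contraction_pct, n_clusters, ccdp_peak_um,
#'   superficial_astro_ratio, deep_max_astro_ratio, plus the four AS
#'   constants used. Failed runs carry `NA` metrics and the error message.
#' @export
sweep_simulations <- function(base_config, variations, replicates = 1L) {
  stopifnot(inherits(base_config, "simulation_config"))
  if (length(variations) == 0) stop("at least one variation is required")
  if (is.null(names(variations)) || any(!nzchar(names(variations))))
    names(variations) <- paste0("v", seq_along(variations))
  rows <- list()
  for (v in names(variations)) {
    cfg <- apply_overrides(base_config, variations[[v]])
    for (r in seq_len(replicates)) {
      run_cfg <- cfg
      run_cfg$seed <- cfg$seed + (r - 1L)
      row <- tryCatch(summarise_run(run_simulation(run_cfg)),
                      error = function(e) {
                        data.frame(n_cells = NA_integer_,
                                   contraction_pct = NA_real_,
                                   n_clusters = NA_integer_,
                                   ccdp_peak_um = NA_real_,
                                   superficial_astro_ratio = NA_real_,
                                   deep_max_astro_ratio = NA_real_,
                                   error = conditionMessage(e))
                      })
      if (is.null(row$error)) row$error <- NA_character_
      AS <- run_cfg$force_params$AS
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(variation = v, replicate = r, seed = run_cfg$seed,
                   AS_NN = AS["N", "N"], AS_NA = AS["N", "A"],
                   AS_AN = AS["A", "N"], AS_AA = AS["A", "A"]),
        row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

apply_overrides <- function(config, overrides) {
  if (is.null(overrides)) return(config)
  overrides <- as.list(overrides)
  if (!is.null(overrides$equilibrium_target)) {
    fp <- config$force_params
    A_eff <- fp$A * fp$AS["N", "N"]
    R <- repulsion_for_equilibrium(overrides$equilibrium_target, A_eff,
                                   fp$tau_a, fp$tau_r)
    fp$R <- R
    config$force_params <- fp
    overrides$equilibrium_target <- NULL
  }
  for (nm in names(overrides)) {
    if (!nm %in% names(config))
      stop(sprintf("unknown override '%s'", nm))
    config[[nm]] <- overrides[[nm]]
  }
  config
}

summarise_run <- function(result) {
  pop <- result$final
  seg <- segment_clusters(pop)
  cc <- tryCatch(cluster_ccdp(pop, seg),
                 error = function(e) NULL)
  peak <- if (is.null(cc)) ccdp_peak(ccdp_of_population(pop)) else
    ccdp_peak(cc$mean_profile)
  dp <- depth_profile(pop)
  data.frame(n_cells = length(pop$types),
             contraction_pct = contraction(result$initial, pop),
             n_clusters = length(seg$cluster_intervals),
             ccdp_peak_um = peak,
             superficial_astro_ratio = dp$superficial_ratio,
             deep_max_astro_ratio = dp$deep_max_ratio,
             error = NA_character_)
}
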