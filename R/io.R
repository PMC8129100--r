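MODEL_KEYS <- c("A", "tau_a", "R", "tau_r", "S", "tau_s",
                "AS_NN", "AS_NA", "AS_AN", "AS_AA", "g",
                "total_time", "stiffening_delay", "stiffening_constant")
CONFIG_KEYS <- c("preset", "model", "confinement", "cell_density",
                 "astrocyte_fraction", "min_cell_spacing",
                 "anchor_density", "min_anchor_spacing", "seed",
                 "snapshot_every")
CONFINEMENT_KEYS <- c("kind", "length", "width", "diameter", "height")

#' Load and validate a simulation configuration
#'
#' Reads a YAML (or JSON) file into a [simulation_config()]. The optional
#' `preset` key (`"optimized"` or `"initial"`) fills the full published
#' parameter list; the flat `model` section may override any of the force
#' and schedule keys (`A`, `tau_a`, `R`, `tau_r`, `S`, `tau_s`, `AS_NN`,
#' `AS_NA`, `AS_AN`, `AS_AA`, `g`, `total_time`, `stiffening_delay`,
#' `stiffening_constant`). Unknown keys are rejected.
#'
#' @param path config file path.
#' @return A [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  config_from_list(raw)
}

#' Build a simulation configuration from a plain list
#'
#' @param raw named list with the keys accepted by [load_config()].
#' @return A [simulation_config()].
#' @export
config_from_list <- function(raw) {
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  preset <- raw$preset %||% "optimized"
  fp <- force_preset(preset)
  sched <- stiffness_schedule()
  if (!is.null(raw$model)) {
    unknown <- setdiff(names(raw$model), MODEL_KEYS)
    if (length(unknown))
      stop("unknown model keys: ", paste(unknown, collapse = ", "))
    m <- raw$model
    fp_args <- list(A = m$A %||% fp$A, tau_a = m$tau_a %||% fp$tau_a,
                    R = m$R %||% fp$R, tau_r = m$tau_r %||% fp$tau_r,
                    S = m$S %||% fp$S, tau_s = m$tau_s %||% fp$tau_s,
                    AS_NN = m$AS_NN %||% fp$AS["N", "N"],
                    AS_NA = m$AS_NA %||% fp$AS["N", "A"],
                    AS_AN = m$AS_AN %||% fp$AS["A", "N"],
                    AS_AA = m$AS_AA %||% fp$AS["A", "A"],
                    g = m$g %||% fp$g)
    fp <- do.call(force_parameters, fp_args)
    sched <- stiffness_schedule(
      total_time = m$total_time %||% sched$total_time,
      stiffening_delay = m$stiffening_delay %||% sched$stiffening_delay,
      stiffening_constant = m$stiffening_constant %||%
        sched$stiffening_constant)
  }
  conf <- confinement()
  if (!is.null(raw$confinement)) {
    unknown <- setdiff(names(raw$confinement), CONFINEMENT_KEYS)
    if (length(unknown))
      stop("unknown confinement keys: ", paste(unknown, collapse = ", "))
    conf <- do.call(confinement, raw$confinement)
  }
  simulation_config(
    confinement = conf,
    cell_density = raw$cell_density %||% 1e-4,
    astrocyte_fraction = raw$astrocyte_fraction %||% 0.2,
    min_cell_spacing = raw$min_cell_spacing %||% 10,
    anchor_density = raw$anchor_density %||% 2e-3,
    min_anchor_spacing = raw$min_anchor_spacing %||% 10,
    force_params = fp, schedule = sched,
    seed = raw$seed %||% 1L,
    snapshot_every = raw$snapshot_every %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a configuration back to a plain list
#'
#' Inverse of [config_from_list()]; suitable for `yaml::write_yaml()` when
#' echoing the configuration alongside run outputs.
#'
#' @param config a [simulation_config()].
#' @return Named list with the flat `model` section.
#' @export
config_to_list <- function(config) {
  fp <- config$force_params
  s <- config$schedule
  conf <- config$confinement
  list(model = list(A = fp$A, tau_a = fp$tau_a, R = fp$R, tau_r = fp$tau_r,
                    S = fp$S, tau_s = fp$tau_s,
                    AS_NN = fp$AS["N", "N"], AS_NA = fp$AS["N", "A"],
                    AS_AN = fp$AS["A", "N"], AS_AA = fp$AS["A", "A"],
                    g = fp$g, total_time = s$total_time,
                    stiffening_delay = s$stiffening_delay,
                    stiffening_constant = s$stiffening_constant),
       confinement = list(kind = conf$kind, length = conf$length,
                          width = conf$width, diameter = conf$diameter,
                          height = conf$height),
       cell_density = config$cell_density,
       astrocyte_fraction = config$astrocyte_fraction,
       min_cell_spacing = config$min_cell_spacing,
       anchor_density = config$anchor_density,
       min_anchor_spacing = config$min_anchor_spacing,
       seed = config$seed,
       snapshot_every = config$snapshot_every)
}

SNAPSHOT_HEADER <- paste(
  "# coordinates in um; origin at slit corner (slit) or disk centre",
  "(disk); z = 0 at substrate; right-handed axes")

#' Write a population snapshot as CSV
#'
#' Columns: step, cell_id, type, x, y, z (um). A leading comment line
#' records the coordinate convention.
#'
#' @param population a [cell_population()].
#' @param path output file.
#' @param step step number recorded in the `step` column.
#' @export
write_snapshot <- function(population, path, step = NA_integer_) {
  stopifnot(inherits(population, "cell_population"))
  n <- length(population$types)
  df <- data.frame(step = rep(step, n), cell_id = seq_len(n),
                   type = population$types,
                   x = sprintf("%.17g", population$positions[, 1]),
                   y = sprintf("%.17g", population$positions[, 2]),
                   z = sprintf("%.17g", population$positions[, 3]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SNAPSHOT_HEADER, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a population snapshot CSV
#'
#' @param path file written by [write_snapshot()].
#' @return A [cell_population()]; the `step` column is attached as the
#'   `"step"` attribute.
#' @export
read_snapshot <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("step", "cell_id", "type", "x", "y", "z")
  if (!identical(names(df), need))
    stop(sprintf("malformed snapshot %s: expected columns %s", path,
                 paste(need, collapse = ", ")))
  pop <- cell_population(cbind(as.numeric(df$x), as.numeric(df$y),
                               as.numeric(df$z)), df$type)
  attr(pop, "step") <- df$step
  pop
}

#' Write / read substrate anchors as CSV
#'
#' @param anchors an [anchor_field()].
#' @param path file path.
#' @export
write_anchors <- function(anchors, path) {
  stopifnot(inherits(anchors, "anchor_field"))
  df <- data.frame(anchor_id = seq_len(nrow(anchors$positions)),
                   x = anchors$positions[, 1], y = anchors$positions[, 2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SNAPSHOT_HEADER, con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  df <- read.csv(path, comment.char = "#")
  anchor_field(as.matrix(df[, c("x", "y")]))
}

#' Write a run manifest
#'
#' Records the echoed configuration, seeds, package version, stage
#' wall-times and an inventory (with MD5 checksums) of the run's output
#' files. Written atomically (temp file + rename): a manifest present on
#' disk describes a completed run.
#'
#' @param dir run output directory.
#' @param config the [simulation_config()] used.
#' @param seeds named list/vector of seeds used.
#' @param timings named numeric vector of stage wall-times (s).
#' @param files character vector of output file paths to inventory.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, config, seeds, timings = numeric(0),
                           files = character(0)) {
  inventory <- lapply(files, function(f) {
    list(file = basename(f),
         md5 = unname(tools::md5sum(f)),
         bytes = file.info(f)$size)
  })
  manifest <- list(package_version = as.character(packageVersion("neuroaggsim")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config_to_list(config),
                   seeds = as.list(seeds),
                   wall_times_s = as.list(timings),
                   outputs = inventory)
  path <- file.path(dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, path)
  invisible(path)
}
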