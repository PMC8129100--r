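#' @useDynLib neuroaggsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm sd mad cor median quantile plogis
#' @importFrom utils head tail write.csv read.csv packageVersion
NULL

LN001 <- log(0.01)

#' Force parameters for the aggregation model
#'
#' Bundles the strengths and length constants of the three exponential force
#' laws (cell-cell attraction, cell-cell repulsion, cell-substrate adhesion),
#' the four type-pair attraction constants, and the constant downward
#' gravity displacement. Every force magnitude has the form
#' `strength * 0.01^(d / tau)`: the length constant `tau` is the distance at
#' which the force has dropped to 1% of its maximum.
#'
#' The type-pair attraction constants scale the attraction *felt* by a cell:
#' `AS_NN` is the attraction felt by a neuron due to another neuron, `AS_NA`
#' by a neuron due to an astrocyte, `AS_AN` by an astrocyte due to a neuron,
#' and `AS_AA` by an astrocyte due to another astrocyte. Repulsion has no
#' type dependence.
#'
#' @param A attraction strength (dimensionless force units).
#' @param tau_a attraction length constant (um).
#' @param R repulsion strength.
#' @param tau_r repulsion length constant (um).
#' @param S substrate-adhesion strength.
#' @param tau_s adhesion length constant (um).
#' @param AS_NN,AS_NA,AS_AN,AS_AA type-pair attraction constants.
#' @param g constant downward displacement per step (um/step), applied
#'   unscaled by movement freedom.
#' @return An object of class `force_parameters`.
#' @seealso [force_preset()] for the published parameter sets.
#' @export
force_parameters <- function(A = 1, tau_a = 320, R = 2.27, tau_r = 200,
                             S = 0.01, tau_s = 30,
                             AS_NN = 1, AS_NA = 0.9, AS_AN = 0.8,
                             AS_AA = 0.7, g = 1e-4) {
  strengths <- c(A = A, R = R, S = S,
                 AS_NN = AS_NN, AS_NA = AS_NA, AS_AN = AS_AN, AS_AA = AS_AA)
  if (any(!is.finite(strengths)) || any(strengths < 0))
    stop("force strengths must be finite and >= 0")
  taus <- c(tau_a = tau_a, tau_r = tau_r, tau_s = tau_s)
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("length constants must be finite and > 0")
  if (!is.finite(g)) stop("g must be finite")
  AS <- matrix(c(AS_NN, AS_AN, AS_NA, AS_AA), 2, 2,
               dimnames = list(c("N", "A"), c("N", "A")))
  structure(list(A = A, tau_a = tau_a, R = R, tau_r = tau_r,
                 S = S, tau_s = tau_s, AS = AS, g = g),
            class = "force_parameters")
}

#' @export
print.force_parameters <- function(x, ...) {
  cat("Force parameters\n")
  cat(sprintf("  attraction: A = %g, tau_a = %g um\n", x$A, x$tau_a))
  cat(sprintf("  repulsion:  R = %g, tau_r = %g um\n", x$R, x$tau_r))
  cat(sprintf("  adhesion:   S = %g, tau_s = %g um\n", x$S, x$tau_s))
  cat(sprintf("  AS (felt-by x due-to): N-N %g, N-A %g, A-N %g, A-A %g\n",
              x$AS["N", "N"], x$AS["N", "A"], x$AS["A", "N"], x$AS["A", "A"]))
  cat(sprintf("  gravity g = %g um/step\n", x$g))
  invisible(x)
}

#' Published force-parameter presets
#'
#' Two named parameter sets are shipped: `"initial"` and `"optimized"`. They
#' differ only in the repulsion length constant (140 vs 200 um); neither is
#' re-fit by this package.
#'
#' @param name `"initial"` or `"optimized"`.
#' @return A [force_parameters()] object.
#' @export
force_preset <- function(name = c("optimized", "initial")) {
  name <- match.arg(name)
  force_parameters(tau_r = if (name == "initial") 140 else 200)
}

#' Stiffening schedule of the movement-freedom parameter
#'
#' @param total_time total number of simulation steps.
#' @param stiffening_delay step at which movement freedom reaches 0.5.
#' @param stiffening_constant logistic width (steps) of the drop.
#' @return An object of class `stiffness_schedule`.
#' @export
stiffness_schedule <- function(total_time = 350, stiffening_delay = 300,
                               stiffening_constant = 20) {
  if (!is.finite(total_time) || total_time <= 0)
    stop("total_time must be > 0")
  if (!is.finite(stiffening_constant) || stiffening_constant <= 0)
    stop("stiffening_constant must be > 0")
  structure(list(total_time = as.integer(total_time),
                 stiffening_delay = stiffening_delay,
                 stiffening_constant = stiffening_constant),
            class = "stiffness_schedule")
}

#' Exponential force magnitude
#'
#' Shared shape of all three force laws: `strength * 0.01^(d / tau)`. The
#' magnitude equals `strength` at contact and 1% of `strength` at one length
#' constant.
#'
#' @param d distance (um), >= 0.
#' @param strength force strength at d = 0.
#' @param tau length constant (um), > 0.
#' @return Force magnitude(s), vectorised over `d`.
#' @export
force_magnitude <- function(d, strength, tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0))
    stop("tau must be > 0")
  if (any(d < 0)) stop("d must be >= 0")
  strength * exp(LN001 * d / tau)
}

#' Movement freedom at a given step
#'
#' Logistic decay from 1 toward 0 modelling culture stiffening:
#' `k(t) = 1 - exp(u) / (1 + exp(u))` with
#' `u = (t - stiffening_delay) / stiffening_constant`. Equals 0.5 at the
#' stiffening delay.
#'
#' @param t simulation step (may be a vector).
#' @param schedule a [stiffness_schedule()].
#' @return Movement freedom in (0, 1).
#' @export
movement_freedom <- function(t, schedule) {
  stopifnot(inherits(schedule, "stiffness_schedule"))
  vapply(t, cpp_movement_freedom, numeric(1),
         delay = schedule$stiffening_delay,
         constant = schedule$stiffening_constant)
}

#' Displacement of a cell in one step
#'
#' `(dx, dy, dz) = (k*Fx, k*Fy, k*Fz - g)`. Gravity is a constant downward
#' displacement and is not scaled by the movement freedom.
#'
#' @param force length-3 force vector.
#' @param k movement freedom in `[0, 1]`.
#' @param g downward displacement per step (um).
#' @return Length-3 displacement vector (um).
#' @export
displace <- function(force, k, g) {
  stopifnot(length(force) == 3, k >= 0, k <= 1)
  c(k * force[1], k * force[2], k * force[3] - g)
}

#' Net force on one cell
#'
#' Sums, over every other cell, the type-scaled attraction toward that cell
#' minus the repulsion (pushing away), plus the adhesion toward every
#' substrate anchor point. Magnitudes decay with Euclidean 3D distance and
#' act along the unit vector joining the two points. Gravity is not part of
#' the net force; it enters in [displace()].
#'
#' @param i cell index (1-based).
#' @param population a [cell_population()].
#' @param anchors an [anchor_field()] (may have zero rows).
#' @param params a [force_parameters()].
#' @return Length-3 named force vector.
#' @export
net_force <- function(i, population, anchors, params) {
  stopifnot(inherits(population, "cell_population"),
            inherits(params, "force_parameters"))
  n <- nrow(population$positions)
  if (n == 0) stop("population is empty")
  if (i < 1 || i > n) stop("cell index out of range")
  f <- cpp_net_forces(population$positions,
                      as.integer(population$types == "A"),
                      anchor_matrix(anchors), unclass(params))
  stats::setNames(f[i, ], c("Fx", "Fy", "Fz"))
}

net_forces_all <- function(population, anchors, params) {
  cpp_net_forces(population$positions,
                 as.integer(population$types == "A"),
                 anchor_matrix(anchors), unclass(params))
}

#' Distance at which attraction and repulsion balance
#'
#' Solves `A_eff * 0.01^(d/tau_a) = R * 0.01^(d/tau_r)` in closed form:
#' `d* = log(R / A_eff) / (log(0.01) * (1/tau_a - 1/tau_r))`. This is the
#' force equilibrium point: the pairwise net force between two cells
#' vanishes there, and it sets the characteristic cell-to-cell spacing of
#' the aggregated culture.
#'
#' @param A_eff effective attraction strength (strength times the type-pair
#'   constant of the interacting pair).
#' @param tau_a attraction length constant (um).
#' @param R repulsion strength.
#' @param tau_r repulsion length constant (um); must differ from `tau_a`.
#' @return Equilibrium distance (um), >= 0.
#' @export
equilibrium_distance <- function(A_eff, tau_a, R, tau_r) {
  if (A_eff <= 0 || R <= 0) stop("A_eff and R must be > 0")
  if (tau_a <= 0 || tau_r <= 0) stop("length constants must be > 0")
  if (tau_a == tau_r)
    stop("no unique equilibrium when tau_a == tau_r")
  d <- log(R / A_eff) / (LN001 * (1 / tau_a - 1 / tau_r))
  if (d < 0)
    stop(sprintf("no non-negative equilibrium for these parameters (d* = %.3f)", d))
  d
}

#' Repulsion strength that places the equilibrium at a target distance
#'
#' Exact inverse of [equilibrium_distance()]:
#' `R = A_eff * 0.01^(target_d * (1/tau_a - 1/tau_r))`.
#'
#' @param target_d desired equilibrium distance (um), >= 0.
#' @inheritParams equilibrium_distance
#' @return Repulsion strength `R`.
#' @export
repulsion_for_equilibrium <- function(target_d, A_eff, tau_a, tau_r) {
  if (target_d < 0) stop("target_d must be >= 0")
  if (tau_a <= 0 || tau_r <= 0) stop("length constants must be > 0")
  if (tau_a == tau_r) stop("tau_a and tau_r must differ")
  R <- A_eff * exp(LN001 * target_d * (1 / tau_a - 1 / tau_r))
  if (R <= 0 || !is.finite(R)) stop("target equilibrium is unattainable")
  R
}
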