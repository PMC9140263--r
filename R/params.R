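#' Bioenergetic model parameters
#'
#' Container for every constant entering the bioenergetic budget: the Kleiber
#' allometric maintenance rate and the drag-based cost of transport
#' P = lambda / (2 eps_A eps_P) * rho * S * C_d * V^3.
#'
#' The wetted surface area is allometric, `S = a * M^b`, and is recomputed
#' whenever the mass changes (pass `mass`, never `S`, to override).
#'
#' @param mass Body mass M (kg). Default 30000 (a ~13 m adult female
#'   humpback whale).
#' @param drag_coef Drag coefficient C_d (dimensionless), default 0.003.
#' @param surface_a,surface_b Wetted-surface allometry `S = a M^b` (m^2),
#'   defaults 0.054 and 0.696.
#' @param eff_propulsive Propulsive efficiency eps_P in (0, 1], default 0.8.
#' @param eff_aerobic Aerobic efficiency eps_A in (0, 1], default 0.2.
#' @param drag_ratio Ratio of active to passive drag lambda, default 0.7.
#' @param density_seawater Seawater density rho (kg/m^3), default 1027.
#' @param kleiber_coef Kleiber coefficient (kcal/day per kg^0.75), default 70.
#' @param kleiber_exp Kleiber mass exponent, default 0.75.
#' @param kcal_to_joule Conversion factor, default 4186.8 J/kcal.
#'
#' @return An object of class `bioenergetic_params` (a validated list with
#'   the derived wetted surface `surface_area` in m^2).
#' @examples
#' p <- bioenergetic_params()
#' p$surface_area    # ~70.5 m^2 at 30 t
#' @export
bioenergetic_params <- function(mass = 30000,
                                drag_coef = 0.003,
                                surface_a = 0.054,
                                surface_b = 0.696,
                                eff_propulsive = 0.8,
                                eff_aerobic = 0.2,
                                drag_ratio = 0.7,
                                density_seawater = 1027,
                                kleiber_coef = 70,
                                kleiber_exp = 0.75,
                                kcal_to_joule = 4186.8) {
  p <- list(mass = mass, drag_coef = drag_coef,
            surface_a = surface_a, surface_b = surface_b,
            eff_propulsive = eff_propulsive, eff_aerobic = eff_aerobic,
            drag_ratio = drag_ratio, density_seawater = density_seawater,
            kleiber_coef = kleiber_coef, kleiber_exp = kleiber_exp,
            kcal_to_joule = kcal_to_joule)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("all bioenergetic parameters must be finite scalars")
  if (any(unlist(p) <= 0)) stop("all bioenergetic parameters must be > 0")
  if (eff_propulsive > 1 || eff_aerobic > 1)
    stop("efficiencies must lie in (0, 1]")
  p$surface_area <- surface_a * mass^surface_b
  structure(p, class = "bioenergetic_params")
}

#' @export
print.bioenergetic_params <- function(x, ...) {
  cat("Bioenergetic parameters:\n")
  cat(sprintf("  mass M            %10.0f kg\n", x$mass))
  cat(sprintf("  wetted surface S  %10.2f m^2  (%.3f * M^%.3f)\n",
              x$surface_area, x$surface_a, x$surface_b))
  cat(sprintf("  drag coef C_d     %10.4f\n", x$drag_coef))
  cat(sprintf("  eps_P, eps_A      %10.2f, %.2f\n",
              x$eff_propulsive, x$eff_aerobic))
  cat(sprintf("  lambda            %10.2f\n", x$drag_ratio))
  cat(sprintf("  rho seawater      %10.0f kg/m^3\n", x$density_seawater))
  cat(sprintf("  Kleiber           %10.0f kcal/day/kg^%.2f\n",
              x$kleiber_coef, x$kleiber_exp))
  invisible(x)
}

#' Pipeline run configuration
#'
#' Central configuration shared by the pipeline stages. All thresholds are
#' strictly positive and the prediction interval must divide 24 h so that
#' daily aggregation (four 6-h steps per UTC day by default) is exact.
#'
#' @param interval_hours Regular prediction interval (hours), default 6.
#' @param vmax Maximum plausible speed for the pre-filter (m/s), default 9.
#' @param resting_threshold Swim-speed threshold separating resting from
#'   transiting (m/s), default 0.5 (inclusive on the resting side).
#' @param projection_center Numeric `c(lon, lat)` for the azimuthal
#'   equidistant working projection; default `c(-20, 45)` (mid North
#'   Atlantic).
#' @param energetics A [bioenergetic_params()] object (or a list of
#'   overrides passed to it).
#' @param seed Integer random seed recorded in the manifest.
#' @return Object of class `run_config`.
#' @export
run_config <- function(interval_hours = 6, vmax = 9,
                       resting_threshold = 0.5,
                       projection_center = c(-20, 45),
                       energetics = bioenergetic_params(),
                       seed = 1L) {
  if (is.list(energetics) && !inherits(energetics, "bioenergetic_params"))
    energetics <- do.call(bioenergetic_params, energetics)
  stopifnot(interval_hours > 0, vmax > 0, resting_threshold > 0,
            length(projection_center) == 2,
            all(is.finite(projection_center)))
  if (24 %% interval_hours != 0)
    stop("interval_hours must divide 24")
  structure(list(interval_hours = interval_hours, vmax = vmax,
                 resting_threshold = resting_threshold,
                 projection_center = as.numeric(projection_center),
                 energetics = energetics, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys: `interval_hours`, `vmax`, `resting_threshold`,
#' `projection_center` (list of lon, lat), `seed`, and an `energetics`
#' mapping whose entries are passed to [bioenergetic_params()].
#'
#' @param path Path to a YAML file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("interval_hours", "vmax",
                                  "resting_threshold", "projection_center",
                                  "seed"))]
  if (!is.null(y$projection_center))
    args$projection_center <- unlist(y$projection_center)
  if (!is.null(y$energetics))
    args$energetics <- do.call(bioenergetic_params, y$energetics)
  do.call(run_config, args)
}
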