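#' Poiseuille hydraulic resistance of a straight tube
#'
#' `R_hyd = 8 mu L / (pi R^4)` in Pa s / m^3; geometric inputs in mm.
#'
#' @param length tube length (mm).
#' @param radius tube radius (mm).
#' @param viscosity dynamic viscosity (Pa s).
#' @return resistance in Pa s / m^3.
#' @export
poiseuille_resistance <- function(length, radius, viscosity = 3.5e-3) {
  if (length <= 0 || radius <= 0) stop("length and radius must be > 0")
  8 * viscosity * (length * 1e-3) / (pi * (radius * 1e-3)^4)
}

#' Lumped Poiseuille pressure network of an end-to-side AVF
#'
#' Ohm/Hagen-Poiseuille analogy for the pressure ordering across a fistula:
#' nodes are the feeding-artery inlet, the anastomosis, and the distal
#' artery, with the venous outflow as the zero-pressure reference. Edges
#' carry Poiseuille resistances of the three limbs, an anastomotic
#' resistance in series with the vein (scaled by `anastomosis_scale`; a
#' larger anastomotic area means a smaller scale), a collateral arterial
#' path from the inlet to the distal bed, and a peripheral runoff from the
#' distal node. The inflow `Q` is prescribed at the inlet and the node
#' pressures follow from nodal (Kirchhoff) analysis.
#'
#' A maturing fistula should maintain `P_inlet > P_distal ~ P_anastomosis >
#' P_vein`; when the anastomotic/venous resistance is so low that the
#' anastomosis pressure falls below the distal-artery pressure, flow in the
#' distal limb reverses towards the anastomosis (steal) and the
#' `distal_reversal` flag is raised.
#'
#' @param lengths named numeric (mm): `feeding`, `vein`, `distal`.
#' @param radii named numeric (mm): `feeding`, `vein`, `distal`.
#' @param inflow inlet flow (ml/min).
#' @param viscosity dynamic viscosity (Pa s).
#' @param anastomosis_scale multiplier on the reference anastomotic
#'   resistance (a 10 mm juxta-anastomotic segment at half the vein radius);
#'   decrease it to model a larger anastomotic area.
#' @param collateral_scale,peripheral_scale multipliers on the feeding-limb
#'   resistance giving the collateral-path and peripheral-runoff
#'   resistances. The defaults place the reversal threshold between the
#'   nominal and the very-large-anastomosis regimes for arm-vessel
#'   dimensions.
#' @return object of class `pressure_network`: node pressures (Pa), edge
#'   flows (ml/min, positive in the reference direction), and
#'   `distal_reversal`.
#' @export
lumped_pressure_network <- function(lengths, radii, inflow,
                                    viscosity = 3.5e-3,
                                    anastomosis_scale = 1,
                                    collateral_scale = 20,
                                    peripheral_scale = 9) {
  need <- c("feeding", "vein", "distal")
  if (!all(need %in% names(lengths)) || !all(need %in% names(radii)))
    stop("lengths and radii must name feeding, vein and distal limbs")
  if (any(unlist(lengths[need]) <= 0) || any(unlist(radii[need]) <= 0))
    stop("lengths and radii must be positive")
  if (inflow < 0) stop("inflow must be >= 0")
  if (anastomosis_scale <= 0) stop("anastomosis_scale must be > 0")
  Q <- inflow * ml_min_to_m3s
  Rf <- poiseuille_resistance(lengths[["feeding"]], radii[["feeding"]], viscosity)
  Rv <- poiseuille_resistance(lengths[["vein"]], radii[["vein"]], viscosity)
  Rd <- poiseuille_resistance(lengths[["distal"]], radii[["distal"]], viscosity)
  Ra <- anastomosis_scale * poiseuille_resistance(10, radii[["vein"]] / 2, viscosity)
  Rcol <- collateral_scale * Rf
  Rper <- peripheral_scale * Rf
  # nodes: 1 inlet, 2 anastomosis, 3 distal; ground = venous outlet (0 Pa)
  # edges: 1-2 (Rf), 2-ground (Ra + Rv), 2-3 (Rd), 1-3 (Rcol), 3-ground (Rper)
  G <- matrix(0, 3, 3)
  add <- function(i, j, g) {
    G[i, i] <<- G[i, i] + g
    if (j > 0) {
      G[j, j] <<- G[j, j] + g
      G[i, j] <<- G[i, j] - g
      G[j, i] <<- G[j, i] - g
    }
  }
  add(1, 2, 1 / Rf)
  add(2, 0, 1 / (Ra + Rv))
  add(2, 3, 1 / Rd)
  add(1, 3, 1 / Rcol)
  add(3, 0, 1 / Rper)
  rhs <- c(Q, 0, 0)
  p <- tryCatch(solve(G, rhs), error = function(e) stop("singular pressure network"))
  p <- as.numeric(p)
  names(p) <- c("inlet", "anastomosis", "distal")
  flows <- c(feeding = (p[[1]] - p[[2]]) / Rf,
             vein = p[[2]] / (Ra + Rv),
             distal = (p[[2]] - p[[3]]) / Rd,  # positive: towards distal bed
             collateral = (p[[1]] - p[[3]]) / Rcol,
             peripheral = p[[3]] / Rper) / ml_min_to_m3s
  structure(list(pressures = p, flows = flows,
                 resistances = c(feeding = Rf, vein = Rv, distal = Rd,
                                 anastomosis = Ra, collateral = Rcol,
                                 peripheral = Rper),
                 distal_reversal = unname(p["anastomosis"] < p["distal"] - 1e-9)),
            class = "pressure_network")
}

#' @export
print.pressure_network <- function(x, ...) {
  cat("lumped pressure network (venous outlet = 0 Pa)\n")
  cat(sprintf("  P_inlet = %.1f Pa, P_anastomosis = %.1f Pa, P_distal = %.1f Pa\n",
              x$pressures[1], x$pressures[2], x$pressures[3]))
  cat(sprintf("  distal flow %s (%.1f ml/min %s the distal bed)\n",
              if (x$distal_reversal) "REVERSED (steal)" else "antegrade",
              abs(x$flows["distal"]),
              if (x$flows["distal"] >= 0) "towards" else "from"))
  invisible(x)
}

#' Pressure drop across a straight tube at a given flow
#'
#' `dP = 8 mu L Q / (pi R^4)` (Pa); convenience wrapper used by the network
#' examples.
#'
#' @inheritParams poiseuille_resistance
#' @param flow volumetric flow (ml/min).
#' @return pressure drop in Pa.
#' @export
poiseuille_pressure_drop <- function(length, radius, flow, viscosity = 3.5e-3) {
  poiseuille_resistance(length, radius, viscosity) * flow * ml_min_to_m3s
}
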