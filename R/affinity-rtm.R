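# Minimum-affinity, diffusion-limited model of organic oxidation.
#
# When a catabolic reaction runs at its minimum biologically harvestable
# affinity, its rate is throttled by the local concentration of the
# accumulating product (HCO3- here):
#   P(z) = P_max (1 - c(z)/c_A_min)
# and the steady-state balance with diffusion,
#   0 = D c''(z) + P(z),  c(0) = c_top,  c'(inf) = 0,
# has the closed-form solution
#   c(z) = c_A_min + (c_top - c_A_min) exp(-z/L),  L = sqrt(D c_A_min / P_max)
# so the production rate decays exponentially with depth with e-folding
# length L. A finite-difference boundary-value solver serves as the
# independent numerical oracle for the closed form.

#' Parameters of the minimum-affinity diffusion model
#'
#' @param p_max Maximum HCO3- production rate (mol/m3/yr), attained where
#'   the product concentration is zero (top of the column when
#'   `c_top = 0`).
#' @param c_a_min HCO3- concentration at which the reaction affinity drops
#'   to the biological minimum and production stops (mol/m3).
#' @param diffusivity HCO3- diffusion constant D (m2/yr).
#' @param c_top Boundary concentration at the sediment-water interface
#'   (mol/m3), in `[0, c_a_min]`.
#' @return An object of class `affinity_params`.
#' @export
affinity_params <- function(p_max, c_a_min, diffusivity, c_top = 0) {
  stopifnot(p_max > 0, c_a_min > 0, diffusivity > 0,
            c_top >= 0, c_top <= c_a_min)
  structure(list(p_max = p_max, c_a_min = c_a_min,
                 diffusivity = diffusivity, c_top = c_top),
            class = "affinity_params")
}

#' E-folding length of the affinity-limited rate profile
#'
#' `L = sqrt(D * c_a_min / p_max)`.
#'
#' @param params An [affinity_params()].
#' @return Length in m.
#' @export
#' @examples
#' efolding_length(affinity_params(1e-4, 1, 0.01))  # 10 m
efolding_length <- function(params) {
  stopifnot(inherits(params, "affinity_params"))
  sqrt(params$diffusivity * params$c_a_min / params$p_max)
}

#' Closed-form concentration profile
#'
#' `c(z) = c_a_min + (c_top - c_a_min) exp(-z/L)`; satisfies the
#' steady-state ODE with the stated boundary conditions.
#'
#' @param params An [affinity_params()].
#' @param z Depths (m), >= 0.
#' @return Concentrations (mol/m3).
#' @export
analytic_concentration <- function(params, z) {
  stopifnot(inherits(params, "affinity_params"), all(z >= 0))
  L <- efolding_length(params)
  params$c_a_min + (params$c_top - params$c_a_min) * exp(-z / L)
}

#' Closed-form production-rate profile
#'
#' `P(z) = p_max (1 - c(z)/c_a_min) = p_max (1 - c_top/c_a_min)
#' exp(-z/L)`; the pure-exponential printed form is the `c_top = 0` case.
#'
#' @param params An [affinity_params()].
#' @param z Depths (m), >= 0.
#' @return Production rates (mol/m3/yr), non-negative and monotone
#'   decreasing in z for `c_top < c_a_min`.
#' @export
analytic_rate <- function(params, z) {
  params$p_max * (1 - analytic_concentration(params, z) / params$c_a_min)
}

#' Finite-difference steady-state oracle
#'
#' Solves the linear two-point boundary-value problem
#' `0 = D c'' + p_max (1 - c/c_a_min)` with `c(0) = c_top` and zero
#' gradient at `depth_max`, on `n_nodes` uniform nodes (second-order
#' differences, ghost-node Neumann closure). Used to arbitrate the
#' closed form.
#'
#' @param params An [affinity_params()].
#' @param depth_max Domain depth (m); should be several e-folding lengths
#'   for the closed bottom to approximate the half-space solution.
#' @param n_nodes Number of nodes (>= 10).
#' @return A list with `depth`, `conc` (mol/m3), `rate` (mol/m3/yr).
#' @export
fd_steady_state <- function(params, depth_max, n_nodes = 1000L) {
  stopifnot(inherits(params, "affinity_params"), n_nodes >= 10)
  z <- seq(0, depth_max, length.out = n_nodes)
  h <- z[2] - z[1]
  D <- params$diffusivity
  a <- params$p_max / params$c_a_min      # linear reaction coefficient
  # unknowns c_2..c_N: D (c_{i-1} - 2 c_i + c_{i+1})/h^2 - a c_i = -p_max
  m <- n_nodes - 1L
  lower <- rep(D, m); upper <- rep(D, m)
  diag_ <- rep(-2 * D - a * h^2, m)
  rhs <- rep(-params$p_max * h^2, m)
  rhs[1] <- rhs[1] - D * params$c_top
  lower[1] <- 0
  lower[m] <- 2 * D; upper[m] <- 0        # ghost: c_{N+1} = c_{N-1}
  conc <- c(params$c_top, solve_tridiag(lower, diag_, upper, rhs))
  list(depth = z, conc = conc,
       rate = params$p_max * (1 - conc / params$c_a_min))
}

#' Is a reaction affinity biologically harvestable?
#'
#' The affinity A = -deltaG must supply at least the minimum conservable
#' energy per mole of electrons transferred (about 2-5 kJ per mol e-).
#' The comparison is boundary-inclusive (affinity equal to the threshold
#' is harvestable).
#'
#' @param delta_g Gibbs energy change of the reaction (kJ/mol reaction);
#'   negative for exergonic reactions.
#' @param electrons_transferred Moles of electrons transferred per mole of
#'   reaction (> 0).
#' @param a_min_per_electron Threshold(s) in kJ per mol e-; default
#'   `c(2, 5)`, the commonly cited bracket.
#' @return A list: `affinity_per_electron` (kJ/mol e-), `harvestable`
#'   (named logical, one per threshold), and `margin` (kJ/mol e- above
#'   each threshold).
#' @export
#' @examples
#' is_harvestable(-40, 8)  # 5 kJ/mol e-: harvestable at both thresholds
is_harvestable <- function(delta_g, electrons_transferred,
                           a_min_per_electron = c(2, 5)) {
  stopifnot(electrons_transferred > 0, all(a_min_per_electron > 0))
  ape <- -delta_g / electrons_transferred
  margin <- ape - a_min_per_electron
  names(margin) <- paste0("kJ", a_min_per_electron)
  list(affinity_per_electron = ape,
       harvestable = margin >= 0,
       margin = margin)
}
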