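# Allometric boundary conditions: inflow scaling and the diameter-exponent
# flow split distributed over a bifurcating tree.

#' Allometric inlet flow from the left-main mean diameter
#'
#' Cycle-mean inlet flow from the scaling law `Q = 1.43 d^2.55`, evaluated
#' with `d` in millimetres and `Q` in mL/min (the convention of the coronary
#' scaling-law literature; convert with [ml_min_to_m3_s()]).
#'
#' @param mean_diameter_mm Mean diameter of the left main branch (mm).
#' @param coefficient,exponent Scaling-law constants.
#' @return Cycle-mean flow (mL/min).
#' @examples
#' inflow_rate(2)  # 1.43 * 2^2.55
#' @export
inflow_rate <- function(mean_diameter_mm, coefficient = 1.43,
                        exponent = 2.55) {
  stopifnot_positive(mean_diameter_mm, "mean_diameter_mm")
  coefficient * mean_diameter_mm ^ exponent
}

#' Flow-split ratio between daughter branches
#'
#' `Q_side / Q_main = (d_side / d_main)^2.27`, the empirically adjusted
#' Murray-type split used at each bifurcation.
#'
#' @param d_side,d_main Mean diameters of the side and main daughter branch
#'   (any common unit).
#' @param exponent Split exponent.
#' @return Dimensionless flow ratio `Q_side / Q_main`.
#' @export
split_ratio <- function(d_side, d_main, exponent = 2.27) {
  stopifnot_positive(d_side, "d_side")
  stopifnot_positive(d_main, "d_main")
  (d_side / d_main) ^ exponent
}

#' Convert mL/min to m^3/s
#' @param q Flow in mL/min.
#' @return Flow in m^3/s.
#' @export
ml_min_to_m3_s <- function(q) q * 1e-6 / 60

#' Distribute an inlet flow over a vessel tree
#'
#' Recursively applies [split_ratio()] at every junction with mass
#' conservation `Q_parent = Q_main + Q_side`. Branch diameters for the split
#' are the arc-length-weighted mean diameters of a proximal window of each
#' daughter branch.
#'
#' @param tree A [vessel_tree()] whose branches carry radii.
#' @param inlet_flow Cycle-mean inlet flow (any unit; outputs share it).
#' @param proximal_fraction Fraction of each daughter branch length used for
#'   its mean diameter (default the proximal third).
#' @param exponent Split exponent passed to [split_ratio()].
#' @return A tibble (branch, diameter, flow, fraction_of_inlet, is_outlet)
#'   with one row per branch; outlet flows sum to `inlet_flow`.
#' @export
distribute_outflows <- function(tree, inlet_flow, proximal_fraction = 1 / 3,
                                exponent = 2.27) {
  stopifnot(inherits(tree, "vessel_tree"))
  stopifnot_positive(inlet_flow, "inlet_flow")
  prox_d <- function(id) {
    br <- tree$branches[[id]]
    if (is.null(br[["radius"]])) abort("all branches need radii for the flow split.")
    L <- br$arc_length[nrow(br)]
    mean_diameter(br, window = c(0, max(L * proximal_fraction,
                                        br$arc_length[2])))
  }
  diam <- purrr::map_dbl(setNames(names(tree$branches),
                                  names(tree$branches)), prox_d)
  flow <- setNames(rep(NA_real_, length(diam)), names(diam))
  flow[tree$inlet] <- inlet_flow
  recurse <- function(id) {
    row <- tree$bifurcations[tree$bifurcations$parent == id, ]
    if (!nrow(row)) return(invisible())
    main <- row$child_main
    side <- row$child_side
    if (is.na(side)) {
      flow[main] <<- flow[id]
      recurse(main)
      return(invisible())
    }
    r <- split_ratio(diam[side], diam[main], exponent = exponent)
    flow[side] <<- flow[id] * r / (1 + r)
    flow[main] <<- flow[id] / (1 + r)
    recurse(main)
    recurse(side)
  }
  recurse(tree$inlet)
  ids <- names(flow)
  tibble(branch = ids, diameter = unname(diam[ids]),
         flow = unname(flow),
         fraction_of_inlet = unname(flow) / inlet_flow,
         is_outlet = ids %in% tree_outlets(tree))
}
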