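#' Build the reference whole-body circulation network
#'
#' Reads the reference compartment table and flow topology (60-kg, 1.7-m adult
#' male; left-heart output 6500 ml/min) shipped under `inst/extdata/` and
#' returns a `pbpk_network`. Both files are plain TSV and can be substituted
#' to change organ parameters.
#'
#' The network models the full circulation loop: peripheral (antecubital)
#' vein -> right heart -> lungs -> left heart -> ascending aorta -> systemic
#' organs (including stomach, spleen, pancreas and myocardium as distinct
#' compartments, with a portal route into the liver) -> veins -> right heart.
#' Each compartment row carries its blood flow (ml/min), intravascular and
#' extracellular volumes (ml), the number of tanks-in-series sub-compartments,
#' and a transcapillary exchange coefficient (1/min).
#'
#' @param compartment_file,edge_file Paths to the compartment table and the
#'   directed-edge table; default to the packaged reference files.
#' @param injection_site Compartment receiving the injection.
#' @return An object of class `pbpk_network`: list with `compartments`
#'   (data.frame), `edges` (data.frame from/to/flow), `injection_site`,
#'   `roi_map` (named character vector label -> compartment), and `weight`
#'   (kg the table describes).
#' @export
build_reference_network <- function(compartment_file = NULL, edge_file = NULL,
                                    injection_site = "peripheral_vein") {
  if (is.null(compartment_file))
    compartment_file <- system.file("extdata", "compartments.tsv",
                                    package = "ctbolus", mustWork = TRUE)
  if (is.null(edge_file))
    edge_file <- system.file("extdata", "edges.tsv",
                             package = "ctbolus", mustWork = TRUE)
  comp <- utils::read.delim(compartment_file, comment.char = "#",
                            stringsAsFactors = FALSE)
  edges <- utils::read.delim(edge_file, comment.char = "#",
                             stringsAsFactors = FALSE)
  need <- c("name", "blood_flow", "v_iv", "v_ec", "n_sub", "k_tc")
  if (!all(need %in% names(comp)))
    stop("malformed compartment table: need columns ",
         paste(need, collapse = ", "))
  for (col in c("blood_flow", "v_iv", "v_ec", "n_sub", "k_tc")) {
    bad <- which(!is.finite(comp[[col]]) | comp[[col]] < 0)
    if (length(bad))
      stop("malformed compartment entry '", comp$name[bad[1]],
           "': invalid ", col)
  }
  if (any(comp$n_sub < 1))
    stop("malformed compartment entry '",
         comp$name[which(comp$n_sub < 1)[1]], "': n_sub must be >= 1")
  if (anyDuplicated(comp$name))
    stop("malformed compartment table: duplicated compartment '",
         comp$name[duplicated(comp$name)][1], "'")
  unknown <- setdiff(c(edges$from, edges$to), comp$name)
  if (length(unknown))
    stop("edge refers to unknown compartment '", unknown[1], "'")
  net <- structure(list(
    compartments = comp,
    edges = edges,
    injection_site = injection_site,
    roi_map = c(ascending_aorta = "ascending_aorta",
                abdominal_aorta = "abdominal_aorta"),
    weight = 60
  ), class = "pbpk_network")
  check_flow_balance(net)
  net
}

#' @export
print.pbpk_network <- function(x, ...) {
  cat(sprintf("pbpk_network: %d compartments, %d edges, left-heart output %.0f ml/min (%.0f kg table)\n",
              nrow(x$compartments), nrow(x$edges), left_heart_output(x), x$weight))
  invisible(x)
}

#' Left-heart output flow of a network
#'
#' @param network A `pbpk_network`.
#' @param compartment Name of the left-heart compartment.
#' @return Total outflow in ml/min.
#' @export
left_heart_output <- function(network, compartment = "left_heart") {
  sum(network$edges$flow[network$edges$from == compartment])
}

#' Check flow conservation at every compartment
#'
#' Every compartment's total edge inflow must equal its total edge outflow and
#' its tabulated `blood_flow`, to within `tol` relative.
#'
#' @param network A `pbpk_network`.
#' @param tol Relative tolerance.
#' @return Invisibly, a data.frame of per-compartment inflow/outflow; errors
#'   if the balance is violated.
#' @export
check_flow_balance <- function(network, tol = 1e-6) {
  comp <- network$compartments
  inflow <- vapply(comp$name, function(n)
    sum(network$edges$flow[network$edges$to == n]), numeric(1))
  outflow <- vapply(comp$name, function(n)
    sum(network$edges$flow[network$edges$from == n]), numeric(1))
  scale <- pmax(inflow, outflow, 1e-12)
  bad <- which(abs(inflow - outflow) / scale > tol)
  if (length(bad))
    stop("flow imbalance at compartment '", comp$name[bad[1]], "': inflow ",
         inflow[bad[1]], " != outflow ", outflow[bad[1]], " ml/min")
  bad <- which(abs(outflow - comp$blood_flow) / scale > tol)
  if (length(bad))
    stop("compartment '", comp$name[bad[1]],
         "': tabulated blood_flow disagrees with edge outflow")
  invisible(data.frame(name = comp$name, inflow = inflow, outflow = outflow))
}

#' Scale a network to a body weight
#'
#' All blood flows and intravascular/extracellular volumes are multiplied by
#' `weight / reference weight` (direct proportionality to body weight); the
#' sub-compartment counts and exchange coefficients are unchanged, so flow
#' balance is preserved exactly.
#'
#' @param network A `pbpk_network` (usually the reference network).
#' @param weight Target body weight in kg (> 0).
#' @return The scaled `pbpk_network` (its `weight` field updated).
#' @export
scale_to_weight <- function(network, weight) {
  if (weight <= 0) stop("weight must be positive")
  f <- weight / network$weight
  network$compartments$blood_flow <- network$compartments$blood_flow * f
  network$compartments$v_iv <- network$compartments$v_iv * f
  network$compartments$v_ec <- network$compartments$v_ec * f
  network$edges$flow <- network$edges$flow * f
  network$weight <- weight
  network
}

#' Adjust a network to a target cardiac output
#'
#' Multiplies every flow by `target_co / (current left-heart output)`;
#' volumes are unchanged. After adjustment the left-heart output equals
#' `target_co` exactly, whatever weight scaling preceded.
#'
#' @param network A `pbpk_network` (usually already weight-scaled).
#' @param target_co Target cardiac output in ml/min (> 0).
#' @return The adjusted `pbpk_network`.
#' @export
adjust_to_cardiac_output <- function(network, target_co) {
  if (target_co <= 0) stop("target_co must be positive")
  f <- target_co / left_heart_output(network)
  network$compartments$blood_flow <- network$compartments$blood_flow * f
  network$edges$flow <- network$edges$flow * f
  network
}

#' Network scaled and adjusted for one patient
#'
#' Convenience wrapper: weight-scales the reference network to the patient's
#' weight, then adjusts all flows to the patient's cardiac output (measured,
#' derived from cardiac index, or estimated).
#'
#' @param patient A [patient_model()].
#' @param network Base network; defaults to [build_reference_network()].
#' @return A `pbpk_network`.
#' @export
patient_network <- function(patient, network = build_reference_network()) {
  stopifnot(inherits(patient, "patient_model"))
  adjust_to_cardiac_output(scale_to_weight(network, patient$weight),
                           patient$cardiac_output)
}
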