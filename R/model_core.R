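#' Reaction kinetics of the invasion model
#'
#' Evaluates the reaction triple
#' \deqn{F = u(1-u) - \delta_1 u w, \quad
#'       G = \rho v(1-v)(v-a) - \delta_2 v w, \quad
#'       H = \delta_3 (v - w).}
#' Inputs are recycled to a common length, so whole profiles can be passed.
#'
#' @param u,v,w normal cell density, tumor cell density, acid concentration.
#' @param params a [model_params()] object.
#' @return A list with numeric components \code{F}, \code{G}, \code{H}.
#' @examples
#' p <- load_preset("fig1")$params
#' reaction_terms(1, 0, 0, p)   # P2 is a kinetic equilibrium
#' @export
reaction_terms <- function(u, v, w, params) {
  if (any(!is.finite(u)) || any(!is.finite(v)) || any(!is.finite(w)))
    stop("non-finite state passed to reaction_terms")
  list(F = u * (1 - u) - params$delta1 * u * w,
       G = params$rho * v * (1 - v) * (v - a_of(params)) - params$delta2 * v * w,
       H = params$delta3 * (v - w))
}

a_of <- function(params) params$a  # tiny accessor, keeps formulas readable

# Jacobian of the kinetics (F, G, H) wrt (u, v, w) at a single state.
kinetics_jacobian <- function(u, v, w, params) {
  a <- params$a
  matrix(c(
    1 - 2 * u - params$delta1 * w, 0, -params$delta1 * u,
    0, params$rho * (-3 * v^2 + 2 * (1 + a) * v - a) - params$delta2 * w,
    -params$delta2 * v,
    0, params$delta3, -params$delta3
  ), nrow = 3, byrow = TRUE)
}

#' Nontrivial tumor equilibrium densities
#'
#' The spatially homogeneous tumor densities solving
#' \eqn{\rho(1-V)(V-a) = \delta_2 V}, i.e. the roots
#' \deqn{V^\pm = \frac{\rho(1+a)-\delta_2 \pm
#'   \sqrt{(\rho(1+a)-\delta_2)^2 - 4\rho^2 a}}{2\rho}.}
#'
#' @param params a [model_params()] object.
#' @return Named numeric vector \code{c(V_plus, V_minus)}, or \code{NULL}
#'   when the discriminant is negative (acid kills the tumor state: no
#'   nontrivial equilibria, hence no bistable front).
#' @export
equilibrium_V <- function(params) {
  b <- params$rho * (1 + params$a) - params$delta2
  disc <- b^2 - 4 * params$rho^2 * params$a
  if (disc < 0) return(NULL)
  s <- sqrt(disc)
  c(V_plus = (b + s) / (2 * params$rho), V_minus = (b - s) / (2 * params$rho))
}

#' Homogeneous steady states and their stability
#'
#' Enumerates the background states
#' \eqn{P_1=(0,0,0)}, \eqn{P_2=(1,0,0)},
#' \eqn{P_3^\pm=(1-\delta_1 V^\pm, V^\pm, V^\pm)},
#' \eqn{P_4^\pm=(0, V^\pm, V^\pm)}, flags biological admissibility
#' (components real, \eqn{V>0}, and \eqn{1-\delta_1 V^+ > 0} for
#' \eqn{P_3^\pm}), and classifies each state's stability from the
#' eigenvalues of the 3x3 kinetics Jacobian.
#'
#' @param params a [model_params()] object.
#' @return A data frame of class \code{"steady_states"} with columns
#'   \code{label}, \code{U}, \code{V}, \code{W}, \code{relevant},
#'   \code{stability} (\code{"stable"}/\code{"unstable"}) and
#'   \code{max_re_eig}.
#' @examples
#' steady_states(load_preset("fig1")$params)
#' @export
steady_states <- function(params) {
  states <- list(P1 = c(0, 0, 0), P2 = c(1, 0, 0))
  relevant <- c(P1 = TRUE, P2 = TRUE)
  Vpm <- equilibrium_V(params)
  if (!is.null(Vpm)) {
    Vp <- Vpm[["V_plus"]]; Vm <- Vpm[["V_minus"]]
    states[["P3+"]] <- c(1 - params$delta1 * Vp, Vp, Vp)
    states[["P3-"]] <- c(1 - params$delta1 * Vm, Vm, Vm)
    states[["P4+"]] <- c(0, Vp, Vp)
    states[["P4-"]] <- c(0, Vm, Vm)
    relevant[["P3+"]] <- Vp > 0 && params$delta1 * Vp < 1
    relevant[["P3-"]] <- Vm > 0 && params$delta1 * Vp < 1
    relevant[["P4+"]] <- Vp > 0
    relevant[["P4-"]] <- Vm > 0
  }
  res <- do.call(rbind, lapply(names(states), function(lab) {
    s <- states[[lab]]
    ev <- eigen(kinetics_jacobian(s[1], s[2], s[3], params),
                only.values = TRUE)$values
    mre <- max(Re(ev))
    data.frame(label = lab, U = s[1], V = s[2], W = s[3],
               relevant = relevant[[lab]],
               stability = if (mre < 0) "stable" else "unstable",
               max_re_eig = mre, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  class(res) <- c("steady_states", "data.frame")
  res
}

#' @export
print.steady_states <- function(x, ...) {
  cat("Homogeneous steady states:\n")
  print.data.frame(transform(x, max_re_eig = signif(max_re_eig, 4)),
                   row.names = FALSE, digits = 6)
  invisible(x)
}

#' Dispersion relation of a homogeneous state
#'
#' Eigenvalue of largest real part of the Jacobian of the spatially
#' modulated linearization about a homogeneous state, at longitudinal
#' wavenumber \code{k}: kinetics Jacobian minus
#' \eqn{k^2 \mathrm{diag}(0,\, 1+\kappa-U,\, \varepsilon^{-2})}.
#' Useful for locating the essential spectrum of a front's end states;
#' not used by the front construction itself.
#'
#' @param state numeric length-3 vector (U, V, W).
#' @param k numeric vector of wavenumbers.
#' @param params a [model_params()] object.
#' @return Numeric vector: max real part of the three eigenvalues at each k.
#' @export
dispersion_relation <- function(state, k, params) {
  J <- kinetics_jacobian(state[1], state[2], state[3], params)
  D <- c(0, 1 + params$kappa - state[1], 1 / params$eps^2)
  vapply(k, function(kk) {
    max(Re(eigen(J - kk^2 * diag(D), only.values = TRUE)$values))
  }, 0)
}

#' Classify the invasion regime
#'
#' Partition of parameter space by the character of the invaded state and
#' the front geometry: \emph{benign} when normal cells survive behind the
#' front (\eqn{\delta_1 V^+ < 1}), otherwise \emph{malignant}, split into
#' \emph{no-gap} and \emph{gap} according to whether the fast interface
#' jump happens before or after the acid level crosses \eqn{1/\delta_1}
#' (i.e. \eqn{w_* \lessgtr 1/\delta_1}).  In the gap case an acellular zone
#' (only acid, no cells) opens between the retreating normal tissue and the
#' advancing tumor.
#'
#' @param params a [model_params()] object.
#' @param tol degeneracy tolerance on \eqn{|\delta_1 w_* - 1|} for the
#'   crossover classification.
#' @return A list of class \code{"regime"} with \code{kind} (one of
#'   \code{"benign"}, \code{"malignant_no_gap"}, \code{"malignant_gap"},
#'   \code{"degenerate_crossover"}, \code{"no_front"}), \code{w_star}
#'   (\code{NA} for \code{no_front}) and \code{malignancy_index}
#'   (\eqn{\delta_1 V^+}).
#' @examples
#' classify_regime(load_preset("fig1")$params)$kind   # "malignant_gap"
#' @export
classify_regime <- function(params, tol = 1e-8) {
  Vpm <- equilibrium_V(params)
  if (is.null(Vpm) || Vpm[["V_plus"]] <= 0)
    return(structure(list(kind = "no_front", w_star = NA_real_,
                          malignancy_index = NA_real_), class = "regime"))
  mi <- params$delta1 * Vpm[["V_plus"]]
  ws <- solve_w_star(params)[["w_star"]]
  kind <- if (mi < 1) "benign"
  else if (abs(params$delta1 * ws - 1) < tol) "degenerate_crossover"
  else if (ws > 1 / params$delta1) "malignant_gap"
  else "malignant_no_gap"
  structure(list(kind = kind, w_star = ws, malignancy_index = mi),
            class = "regime")
}

#' @export
print.regime <- function(x, ...) {
  cat("Regime:", x$kind, "\n")
  if (!is.na(x$malignancy_index))
    cat(sprintf("  delta1 * V+ = %.6g, w* = %.6g\n",
                x$malignancy_index, x$w_star))
  invisible(x)
}
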