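#' Model parameters for the acid-mediated invasion model
#'
#' Bundles the seven dimensionless parameters of the modified
#' Gatenby--Gawlinski model with Allee effect,
#' \deqn{U_\tau = U(1-U) - \delta_1 U W,}
#' \deqn{V_\tau = \rho V(1-V)(V-a) - \delta_2 V W +
#'       \nabla\cdot((1+\kappa-U)\nabla V),}
#' \deqn{W_\tau = \delta_3 (V - W) + \varepsilon^{-2}\Delta W,}
#' where \eqn{U} is normal cell density, \eqn{V} tumor cell density and
#' \eqn{W} the lactic acid concentration.  Every downstream stage (steady
#' states, singular front, traveling-wave solver, stability, 2D simulation)
#' takes one of these objects, so it is the single source of truth for a run.
#'
#' @param a Allee threshold of the tumor growth law, in (0,1).  Per-capita
#'   tumor growth is negative below density \code{a}.
#' @param kappa Regularization \eqn{\kappa > 0} of the cross-dependent
#'   nonlinear diffusion \eqn{(1+\kappa-U)}: normal tissue slows but never
#'   blocks tumor motility.
#' @param delta1 Acid toxicity to normal cells, \eqn{\delta_1 > 0}; the
#'   malignancy dial.
#' @param delta2 Acid toxicity to tumor cells, \eqn{\delta_2 \ge 0}.  The
#'   model assumes \eqn{\delta_2 < \delta_1}; violating it triggers a warning
#'   (not an error) so parameter-plane sweeps remain runnable.
#' @param delta3 Acid production/decay rate \eqn{\delta_3 > 0}.
#' @param rho Tumor proliferation rate \eqn{\rho > 0} relative to normal
#'   cells.
#' @param eps Acid-diffusion scale separation \eqn{0 < \varepsilon \ll 1};
#'   acid diffuses a factor \eqn{\varepsilon^{-2}} faster than cells.
#'
#' @return An object of class \code{"model_params"} (a named list).
#' @examples
#' p <- model_params(a = 0.35, kappa = 0.1, delta1 = 12.5, delta2 = 0.1,
#'                   delta3 = 70, rho = 1, eps = 0.0063)
#' p
#' @seealso [load_preset()] for parameter sets used in published figures,
#'   [steady_states()], [classify_regime()], [singular_front()],
#'   [solve_front()].
#' @export
model_params <- function(a, kappa, delta1, delta2, delta3, rho, eps) {
  # strip any incoming names so downstream named vectors stay addressable
  a <- as.numeric(a); kappa <- as.numeric(kappa)
  delta1 <- as.numeric(delta1); delta2 <- as.numeric(delta2)
  delta3 <- as.numeric(delta3); rho <- as.numeric(rho)
  eps <- as.numeric(eps)
  vals <- c(a = a, kappa = kappa, delta1 = delta1, delta2 = delta2,
            delta3 = delta3, rho = rho, eps = eps)
  if (any(!is.finite(vals)))
    stop("all model parameters must be finite numbers")
  if (a <= 0 || a >= 1) stop("Allee threshold 'a' must lie in (0, 1)")
  if (kappa <= 0) stop("'kappa' must be positive")
  if (delta1 <= 0) stop("'delta1' must be positive")
  if (delta2 < 0) stop("'delta2' must be nonnegative")
  if (delta3 <= 0) stop("'delta3' must be positive")
  if (rho <= 0) stop("'rho' must be positive")
  if (eps <= 0) stop("'eps' must be positive")
  if (delta2 >= delta1)
    warning("model assumption delta2 < delta1 violated (delta2 = ",
            delta2, ", delta1 = ", delta1, "); continuing anyway")
  structure(list(a = a, kappa = kappa, delta1 = delta1, delta2 = delta2,
                 delta3 = delta3, rho = rho, eps = eps, nu = 0),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Acid-mediated invasion model parameters (dimensionless):\n")
  cat(sprintf("  a = %g, kappa = %g, delta1 = %g, delta2 = %g\n",
              x$a, x$kappa, x$delta1, x$delta2))
  cat(sprintf("  delta3 = %g, rho = %g, eps = %g  (frame exponent nu = %d)\n",
              x$delta3, x$rho, x$eps, x$nu))
  invisible(x)
}

#' Modify some fields of a parameter set
#'
#' @param params a \code{model_params} object.
#' @param ... named replacements among a, kappa, delta1, delta2, delta3,
#'   rho, eps.
#' @return A new validated \code{model_params} object.
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  keep <- c("a", "kappa", "delta1", "delta2", "delta3", "rho", "eps")
  bad <- setdiff(names(repl), keep)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  base <- unclass(params)[keep]
  base[names(repl)] <- repl
  do.call(model_params, base)
}

# Preset parameter sets transcribed from published figure captions.
.presets <- list(
  fig1      = list(a = 0.35, kappa = 0.1, delta1 = 12.5, delta2 = 0.1,
                   delta3 = 70, rho = 1, eps = 0.0063,
                   note = "2D fingering simulation / Fig 8 third row",
                   expect = list(regime = "malignant_gap", lambda2_sign = 1L)),
  fig7      = list(a = 0.1, kappa = 0.1, delta1 = NA_real_, delta2 = 0.1,
                   delta3 = 70, rho = 1, eps = 0.0063,
                   note = "gap width vs delta1 sweep, delta1 in (0.1, 15)",
                   expect = list()),
  fig8_row1 = list(a = 0.1, kappa = 0.1, delta1 = 12.5, delta2 = 0.1,
                   delta3 = 70, rho = 1, eps = 0.0063,
                   note = "1D-stable gap profile",
                   expect = list(regime = "malignant_gap", lambda2_sign = 1L)),
  fig8_row2 = list(a = 0.25, kappa = 0.1, delta1 = 12.5, delta2 = 0.1,
                   delta3 = 70, rho = 1, eps = 0.0063,
                   note = "1D-stable gap profile",
                   expect = list(regime = "malignant_gap", lambda2_sign = 1L)),
  fig8_row3 = list(a = 0.35, kappa = 0.1, delta1 = 12.5, delta2 = 0.1,
                   delta3 = 70, rho = 1, eps = 0.0063,
                   note = "identical to fig1",
                   expect = list(regime = "malignant_gap", lambda2_sign = 1L)),
  fig8_row4 = list(a = 0.25, kappa = 0.05, delta1 = 11.5, delta2 = 3,
                   delta3 = 1, rho = 15, eps = 0.05,
                   note = "fast-growing finger case",
                   expect = list(regime = "malignant_gap", lambda2_sign = 1L)),
  fig9      = list(a = 0.1, kappa = 0.1, delta1 = NA_real_, delta2 = 0.1,
                   delta3 = 70, rho = 1, eps = 0.0063,
                   note = "continuation in delta1 over (0.05, 15)",
                   expect = list()),
  fig10     = list(a = NA_real_, kappa = 0.1, delta1 = 0.6, delta2 = 0.1,
                   delta3 = 70, rho = 1, eps = 0.0063,
                   note = "a-sweep; run also with delta1 = 12.5",
                   expect = list()),
  fig11     = list(a = 0.1, kappa = 0.1, delta1 = NA_real_, delta2 = NA_real_,
                   delta3 = 70, rho = 1, eps = 0.0063,
                   note = "(delta1, delta2) stability boundary; eps also 1e-5",
                   expect = list())
)

#' Load a published-figure parameter preset
#'
#' Returns the exact parameter tuple used in one of the reference figures,
#' together with its provenance note and the qualitative outcome expected
#' there (regime, sign of the transverse coefficient) where one is stated.
#' Sweep presets (fig7, fig9, fig10, fig11) leave the swept parameter(s)
#' \code{NA}; fill them with \code{\link{update_params}} or the \code{...}
#' override.
#'
#' @param name preset name; one of
#'   \code{"fig1"}, \code{"fig7"}, \code{"fig8_row1"} ... \code{"fig8_row4"},
#'   \code{"fig9"}, \code{"fig10"}, \code{"fig11"}.
#' @param ... optional named parameter overrides (e.g. \code{delta1 = 4} to
#'   instantiate a sweep preset at one point).
#' @return A list of class \code{"preset"} with elements \code{name},
#'   \code{params} (\code{model_params}, when fully specified), \code{note}
#'   and \code{expect}.
#' @examples
#' load_preset("fig1")$params
#' load_preset("fig9", delta1 = 4)$params
#' @export
load_preset <- function(name, ...) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.presets), collapse = ", "))
  p <- .presets[[name]]
  over <- list(...)
  raw <- p[c("a", "kappa", "delta1", "delta2", "delta3", "rho", "eps")]
  raw[names(over)] <- over
  params <- if (any(is.na(unlist(raw)))) NULL else do.call(model_params, raw)
  structure(list(name = name, params = params, raw = raw,
                 note = p$note, expect = p$expect),
            class = "preset")
}

#' @export
print.preset <- function(x, ...) {
  cat("Preset '", x$name, "': ", x$note, "\n", sep = "")
  if (is.null(x$params)) {
    cat("  (sweep preset; unset: ",
        paste(names(x$raw)[is.na(unlist(x$raw))], collapse = ", "), ")\n",
        sep = "")
  } else {
    print(x$params)
  }
  invisible(x)
}

#' Read model parameters from a flat key = value config file
#'
#' Parses a plain-text configuration with one \code{key = value} (or
#' \code{key: value}) pair per line; keys are the seven parameter names
#' \code{a, kappa, delta1, delta2, delta3, rho, eps}.  Lines starting with
#' \code{#} are comments.  Named arguments override file values, mirroring
#' command-line-flag precedence.
#'
#' @param path path to the config file.
#' @param ... named overrides applied after reading.
#' @return A \code{model_params} object.
#' @export
read_params_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[=:]")
  keys <- vapply(kv, function(x) trimws(x[[1]]), "")
  vals <- vapply(kv, function(x) as.numeric(trimws(x[[2]])), 0)
  keep <- c("a", "kappa", "delta1", "delta2", "delta3", "rho", "eps")
  unknown <- setdiff(keys, keep)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  over <- list(...)
  args[names(over)] <- over
  missing <- setdiff(keep, names(args))
  if (length(missing))
    stop("config missing parameter(s): ", paste(missing, collapse = ", "))
  do.call(model_params, args[keep])
}
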