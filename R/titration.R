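# FRET titration Kd fitting and DOSY hydrodynamic radius.

#' Emission ratio predicted by the exact 1:1 binding isotherm
#'
#' For donor-labelled species at total concentration `D_total` titrated
#' with acceptor-labelled species at `A_total`, the 1:1 complex
#' concentration is the physical root of the binding quadratic,
#' `C = (b - sqrt(b^2 - 4 D A)) / 2` with `b = D + A + Kd` (no
#' weak-binding approximation). The observed donor/acceptor emission
#' ratio interpolates linearly with the bound donor fraction:
#' `ratio = r_free + (r_bound - r_free) * C / D_total`.
#'
#' @param Kd Dissociation constant (same units as the concentrations,
#'   e.g. uM).
#' @param D_total Fixed (donor) concentration.
#' @param A_total Titrant (acceptor) concentration, vectorised.
#' @param r_free Emission ratio of the free donor.
#' @param r_bound Emission ratio at donor saturation.
#' @return Predicted emission ratio(s).
#' @export
binding_model <- function(Kd, D_total, A_total, r_free, r_bound) {
  stopifnot(Kd > 0, D_total > 0)
  if (any(A_total < 0)) stop("concentrations must be non-negative")
  b <- D_total + A_total + Kd
  disc <- pmax(0, b^2 - 4 * D_total * A_total)
  complex <- (b - sqrt(disc)) / 2
  r_free + (r_bound - r_free) * complex / D_total
}

#' Fit a dissociation constant to a FRET emission-ratio titration
#'
#' Nonlinear least squares of [binding_model()] over
#' `(Kd, r_free, r_bound)`, multi-started over `Kd` decades so the fit
#' does not depend on the initial guess. Degenerate (flat) titrations
#' give an explicit non-identifiability error.
#'
#' @param data `data.frame` with columns `conc_uM` (titrant
#'   concentration, strictly increasing non-negative) and `ratio`;
#'   optional `err` column used as weights.
#' @param D_total Fixed partner concentration, uM.
#' @param kd_starts Numeric vector of Kd starting values, uM.
#' @return Object of class `binding_fit`: list with `Kd`, `r_free`,
#'   `r_bound`, `se` (named standard errors), `vcov`, `fitted`,
#'   `residuals`, `data`.
#' @export
fit_kd <- function(data, D_total = 50,
                   kd_starts = c(1, 10, 100, 1000)) {
  miss <- setdiff(c("conc_uM", "ratio"), names(data))
  if (length(miss))
    stop("titration data: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) < 4) stop("need at least 4 titration points")
  if (any(data$conc_uM < 0) || is.unsorted(data$conc_uM, strictly = TRUE))
    stop("conc_uM must be non-negative and strictly increasing")
  if (diff(range(data$ratio)) < 1e-3 * max(abs(data$ratio), 1))
    stop("titration is flat: Kd is not identifiable from these data")
  w <- if ("err" %in% names(data)) 1 / data$err^2 else rep(1, nrow(data))
  best <- NULL
  for (kd0 in kd_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ratio ~ binding_model(Kd, D_total, conc_uM, r_free, r_bound),
        data = data, weights = w,
        start = list(Kd = kd0, r_free = data$ratio[1],
                     r_bound = data$ratio[nrow(data)]),
        lower = c(Kd = 1e-6, r_free = -Inf, r_bound = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || stats::deviance(fit) < stats::deviance(best)))
      best <- fit
  }
  if (is.null(best))
    stop("Kd fit failed from every starting value; ",
         "data may be non-identifiable")
  cf <- stats::coef(best)
  vc <- tryCatch(stats::vcov(best), error = function(e)
    matrix(NA_real_, 3, 3, dimnames = list(names(cf), names(cf))))
  structure(list(Kd = unname(cf["Kd"]), r_free = unname(cf["r_free"]),
                 r_bound = unname(cf["r_bound"]),
                 se = sqrt(diag(vc)), vcov = vc,
                 fitted = stats::fitted(best),
                 residuals = stats::residuals(best),
                 data = data, D_total = D_total),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Kd = %.4g uM (se %.3g), r_free = %.3g, r_bound = %.3g\n",
              x$Kd, x$se[["Kd"]], x$r_free, x$r_bound))
  invisible(x)
}

#' Hydrodynamic radius from a translational diffusion coefficient
#'
#' Stokes-Einstein: `R_h = kB * T / (6 pi eta D_tr)`. The default
#' viscosity is that of water at 298 K; the viscosity of the actual
#' solvent (e.g. a deuterated detergent solution) should be supplied for
#' quantitative work.
#'
#' @param D_tr Translational diffusion coefficient, m^2/s.
#' @param temperature Temperature, K.
#' @param viscosity Dynamic viscosity, Pa s.
#' @return Hydrodynamic radius in metres.
#' @examples
#' hydrodynamic_radius(1e-10, 303, 7.97e-4) * 1e9  # ~2.78 nm
#' @export
hydrodynamic_radius <- function(D_tr, temperature = 298,
                                viscosity = 8.9e-4) {
  if (any(D_tr <= 0) || temperature <= 0 || viscosity <= 0)
    stop("D_tr, temperature and viscosity must be positive")
  kB <- 1.380649e-23
  kB * temperature / (6 * pi * viscosity * D_tr)
}
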