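# Isotropic Lipari-Szabo model-free analysis of backbone 15N relaxation.

#' Physical constants for 15N relaxation
#'
#' Gyromagnetic ratios, N-H bond length and 15N CSA used in the dipolar
#' and CSA relaxation expressions. Frequencies follow the standard
#' positive-magnitude convention (`omega = |gamma| * B`); the signed
#' `gammaH / gammaN` ratio enters only the NOE expression.
#'
#' @param field Magnetic field in Tesla (default 18.8, i.e. 800 MHz 1H).
#' @param r_NH N-H bond length in metres.
#' @param csa 15N chemical shift anisotropy (dimensionless, e.g.
#'   `-160e-6`).
#' @return List with `omegaH`, `omegaN` (rad/s), `d2` (squared dipolar
#'   coupling constant, rad^2/s^2), `c2` (squared CSA constant),
#'   `gamma_ratio` (signed `gammaH / gammaN`).
#' @export
nmr_constants <- function(field = 18.8, r_NH = 1.02e-10, csa = -160e-6) {
  gammaH <- 2.6752218744e8   # rad/s/T
  gammaN <- -2.7116e7        # rad/s/T (signed)
  hbar <- 1.054571817e-34
  mu0_4pi <- 1e-7
  omegaH <- gammaH * field
  omegaN <- abs(gammaN) * field
  d <- mu0_4pi * hbar * gammaH * abs(gammaN) / r_NH^3
  cc <- omegaN * csa / sqrt(3)
  list(omegaH = omegaH, omegaN = omegaN, d2 = d^2, c2 = cc^2,
       gamma_ratio = gammaH / gammaN, field = field)
}

#' Lipari-Szabo isotropic spectral density
#'
#' `J(w) = (2/5) * (S2 * tau_m / (1 + (w tau_m)^2)
#'                  + (1 - S2) * tau / (1 + (w tau)^2))`
#' with `1/tau = 1/tau_m + 1/tau_e`.
#'
#' @param omega Angular frequency, rad/s (vectorised).
#' @param S2 Generalised order parameter in `[0, 1]`.
#' @param tau_e Effective internal correlation time, seconds (0 allowed).
#' @param tau_m Overall rotational correlation time, seconds.
#' @return Spectral density in s/rad.
#' @export
spectral_density <- function(omega, S2, tau_e, tau_m) {
  stopifnot(S2 >= 0, S2 <= 1, tau_m > 0, tau_e >= 0)
  j <- S2 * tau_m / (1 + (omega * tau_m)^2)
  if (tau_e > 0 && S2 < 1) {
    tau <- tau_e * tau_m / (tau_e + tau_m)
    j <- j + (1 - S2) * tau / (1 + (omega * tau)^2)
  }
  0.4 * j
}

#' Predict 15N R1, R2 and heteronuclear NOE
#'
#' Standard dipolar + CSA expressions for an amide 15N relaxed by its
#' attached proton:
#' `R1 = (d2/4) (J(wH-wN) + 3 J(wN) + 6 J(wH+wN)) + c2 J(wN)`,
#' `R2 = (d2/8) (4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN))
#'       + (c2/6) (4 J(0) + 3 J(wN))`,
#' `NOE = 1 + (d2/4) (gammaH/gammaN) (6 J(wH+wN) - J(wH-wN)) / R1`.
#' No chemical-exchange (Rex) contribution is included.
#'
#' @param S2,tau_e,tau_m Model-free parameters (see
#'   [spectral_density()]).
#' @param field Magnetic field in Tesla.
#' @param const Optional precomputed [nmr_constants()].
#' @return Named numeric: `R1` (1/s), `R2` (1/s), `NOE`.
#' @export
predict_rates <- function(S2, tau_e, tau_m, field = 18.8,
                          const = nmr_constants(field)) {
  J <- function(w) spectral_density(w, S2, tau_e, tau_m)
  wH <- const$omegaH; wN <- const$omegaN
  R1 <- const$d2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) +
    const$c2 * J(wN)
  R2 <- const$d2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                          6 * J(wH + wN)) +
    const$c2 / 6 * (4 * J(0) + 3 * J(wN))
  sigma <- const$d2 / 4 * (6 * J(wH + wN) - J(wH - wN))
  c(R1 = R1, R2 = R2, NOE = 1 + const$gamma_ratio * sigma / R1)
}

# Vectorised rates: S2, tau_e vectors (one per residue), shared tau_m.
# Returns a 3 x n matrix (R1, R2, NOE columns per residue).
rates_matrix <- function(S2, tau_e, tau_m, const) {
  wH <- const$omegaH; wN <- const$omegaN
  ws <- c(0, wN, wH - wN, wH, wH + wN)
  jm <- function(w) {  # length(w) x n matrix of J values
    tau <- tau_e * tau_m / (tau_e + tau_m)
    0.4 * (outer(1 / (1 + (w * tau_m)^2), S2 * tau_m) +
             outer(rep(1, length(w)), (1 - S2)) *
             (outer(rep(1, length(w)), tau) /
                (1 + outer(w^2, tau^2))))
  }
  J <- jm(ws)  # rows: 0, wN, wH-wN, wH, wH+wN
  R1 <- const$d2 / 4 * (J[3, ] + 3 * J[2, ] + 6 * J[5, ]) +
    const$c2 * J[2, ]
  R2 <- const$d2 / 8 * (4 * J[1, ] + J[3, ] + 3 * J[2, ] + 6 * J[4, ] +
                          6 * J[5, ]) +
    const$c2 / 6 * (4 * J[1, ] + 3 * J[2, ])
  sigma <- const$d2 / 4 * (6 * J[5, ] - J[3, ])
  rbind(R1 = R1, R2 = R2, NOE = 1 + const$gamma_ratio * sigma / R1)
}

#' Extract the overall correlation time from an R2/R1 ratio
#'
#' Solves `R2/R1` predicted for a rigid residue (`S2 = 1`, `tau_e = 0`)
#' equal to the observed ratio, for `tau_m` on `[0.5, 50]` ns. The ratio
#' is monotone increasing in `tau_m` outside extreme narrowing, so the
#' root is unique.
#'
#' @param R1,R2 Observed rates, 1/s.
#' @param field Magnetic field, Tesla.
#' @param interval Search interval for `tau_m`, seconds.
#' @return `tau_m` in seconds.
#' @export
tau_m_from_ratio <- function(R1, R2, field = 18.8,
                             interval = c(0.5e-9, 50e-9)) {
  stopifnot(R1 > 0, R2 > 0)
  const <- nmr_constants(field)
  target <- R2 / R1
  f <- function(tm) {
    r <- predict_rates(1, 0, tm, const = const)
    r[["R2"]] / r[["R1"]] - target
  }
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo * hi > 0)
    stop("R2/R1 ratio ", signif(target, 4),
         " is outside the range achievable for tau_m in [",
         interval[1] * 1e9, ", ", interval[2] * 1e9, "] ns")
  stats::uniroot(f, interval, tol = 1e-15)$root
}

#' Fit isotropic model-free parameters to a relaxation dataset
#'
#' Two stages. First the overall correlation time `tau_m` is initialised
#' from the mean of the per-residue [tau_m_from_ratio()] estimates
#' (residues of one species share one `tau_m`). Then all parameters --
#' the shared `tau_m` plus per-residue `(S2, tau_e)` -- are refined by
#' joint least squares on the relative deviations of (R1, R2, NOE),
#' which removes the small bias of the ratio estimate when `S2 < 1` or
#' `tau_e > 0`. `S2` is constrained to `[0, 1]` and the correlation
#' times to be positive by the parameterisation.
#'
#' @param data `data.frame` with columns `residue`, `R1`, `R2`, `NOE`
#'   and optionally `R1_err`, `R2_err`, `NOE_err` (used as weights when
#'   present, otherwise relative residuals are used).
#' @param field Magnetic field, Tesla.
#' @param tau_e_init Initial internal correlation time, seconds.
#' @param tau_e_max Upper bound on the internal correlation time,
#'   seconds. The simple model-free spectral density assumes internal
#'   motions much faster than overall tumbling; unbounded fits can trade
#'   a lower order parameter against a spuriously slow internal motion
#'   (`tau_e` approaching `tau_m`), so `tau_e` is constrained to fast
#'   motions by default.
#' @return Object of class `modelfree_fit`: list with `tau_m` (s),
#'   `tau_m_ratio` (the stage-1 estimate), `params`
#'   (`data.frame(residue, S2, tau_e)`), `fitted` (predicted rates),
#'   `residuals`, `rss`, `convergence`.
#' @export
fit_model_free <- function(data, field = 18.8, tau_e_init = 50e-12,
                           tau_e_max = 500e-12) {
  need <- c("residue", "R1", "R2", "NOE")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("relaxation data: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) < 1) stop("need at least one usable residue")
  if (any(!is.finite(data$R1)) || any(!is.finite(data$R2)) ||
      any(data$R1 <= 0) || any(data$R2 <= 0))
    stop("R1 and R2 must be positive and finite")
  const <- nmr_constants(field)
  nres <- nrow(data)
  tm0 <- mean(vapply(seq_len(nres), function(i)
    tau_m_from_ratio(data$R1[i], data$R2[i], field), numeric(1)))

  obs <- rbind(data$R1, data$R2, data$NOE)
  scale <- if (all(c("R1_err", "R2_err", "NOE_err") %in% names(data)) &&
               all(data$R1_err > 0) && all(data$R2_err > 0) &&
               all(data$NOE_err > 0))
    rbind(data$R1_err, data$R2_err, data$NOE_err)
  else abs(obs)

  i_s2 <- 2 + 2 * (seq_len(nres) - 1)
  i_te <- i_s2 + 1
  unpack <- function(p) {
    list(tau_m = exp(p[1]), S2 = stats::plogis(p[i_s2]),
         tau_e = tau_e_max * stats::plogis(p[i_te]))
  }
  obj <- function(p) {
    th <- unpack(p)
    pred <- rates_matrix(th$S2, th$tau_e, th$tau_m, const)
    sum(((pred - obs) / scale)^2)
  }
  make_p0 <- function(tm, s2, te) {
    p0 <- numeric(1 + 2 * nres)
    p0[1] <- log(tm)
    p0[i_s2] <- stats::qlogis(pmin(0.995, pmax(0.005, s2)))
    p0[i_te] <- stats::qlogis(min(0.99, max(0.01, te / tau_e_max)))
    p0
  }
  # multi-start guards against the extreme-narrowing local minimum
  starts <- list(
    make_p0(tm0, pmin(0.99, pmax(0.05, data$R2 / max(data$R2) * 0.85)),
            tau_e_init),
    make_p0(tm0, rep(0.5, nres), 20e-12),
    make_p0(1.3 * tm0, rep(0.9, nres), 100e-12))
  fit <- NULL
  for (p0 in starts) {
    f1 <- stats::optim(p0, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    f2 <- stats::optim(f1$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
    if (f2$value < f1$value) f1 <- f2
    if (is.null(fit) || f1$value < fit$value) fit <- f1
  }
  f3 <- stats::optim(fit$par, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14))
  if (f3$value < fit$value) fit <- f3
  th <- unpack(fit$par)
  pred <- rates_matrix(th$S2, th$tau_e, th$tau_m, const)
  dimnames(pred) <- list(c("R1", "R2", "NOE"), data$residue)
  structure(list(
    tau_m = th$tau_m, tau_m_ratio = tm0,
    params = data.frame(residue = data$residue, S2 = th$S2,
                        tau_e = th$tau_e, stringsAsFactors = FALSE),
    fitted = pred, residuals = pred - obs, rss = fit$value,
    convergence = fit$convergence, field = field),
    class = "modelfree_fit")
}

#' @export
print.modelfree_fit <- function(x, ...) {
  cat(sprintf("<modelfree_fit> tau_m = %.3f ns (ratio estimate %.3f ns), %d residue(s)\n",
              x$tau_m * 1e9, x$tau_m_ratio * 1e9, nrow(x$params)))
  df <- x$params
  df$tau_e_ps <- df$tau_e * 1e12
  print(df[c("residue", "S2", "tau_e_ps")], digits = 3)
  invisible(x)
}
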