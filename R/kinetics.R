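#' Photophysical parameters of the donor/acceptor pair
#'
#' The transfer kinetics are fully determined by rate ratios, so the donor
#' decay rate only sets the time unit; the default corresponds to a 1000 ps
#' donor lifetime. Forster radii are required only in physical-distance
#' mode (distances in nm); in normalized mode the configuration already
#' carries distances in units of the respective radius.
#'
#' @param k_d donor intrinsic decay rate (default `1/1000` ps^-1).
#' @param k_a acceptor intrinsic decay rate (default 0; the first-passage
#'   solve requires 0, the time-integration path supports any value).
#' @param r0_da,r0_dd Forster radii in nm for donor-acceptor and
#'   donor-donor pairs (needed for physical-distance configurations).
#' @param q_d donor emission quantum yield (optional, radius computation).
#' @param refractive_index solvent refractive index (optional).
#' @param overlap_j_da,overlap_j_dd spectral overlap integrals in
#'   M^-1 cm^-1 nm^4 (optional).
#' @return a `photophysical_params` list.
#' @export
photophysical_params <- function(k_d = 1 / 1000, k_a = 0, r0_da = NULL,
                                 r0_dd = NULL, q_d = NULL,
                                 refractive_index = NULL,
                                 overlap_j_da = NULL, overlap_j_dd = NULL) {
  if (!is.numeric(k_d) || k_d <= 0) stop("k_d must be > 0", call. = FALSE)
  if (!is.numeric(k_a) || k_a < 0) stop("k_a must be >= 0", call. = FALSE)
  for (r in list(r0_da, r0_dd))
    if (!is.null(r) && r <= 0) stop("Forster radii must be > 0", call. = FALSE)
  structure(list(k_d = k_d, k_a = k_a, r0_da = r0_da, r0_dd = r0_dd,
                 q_d = q_d, refractive_index = refractive_index,
                 overlap_j_da = overlap_j_da, overlap_j_dd = overlap_j_dd),
            class = "photophysical_params")
}

#' Forster radius from spectroscopic quantities
#'
#' Computes the isotropic (`kappa^2 = 2/3`) Forster radius
#' \deqn{\bar R_0^6 = \frac{9000\,\ln 10\;\bar\kappa^2\,Q_D}
#'   {128\,\pi^5 N_A\,n^4}\,J}
#' with the overlap integral `J` supplied in M^-1 cm^-1 nm^4 and the result
#' in nm. Equivalent to the familiar rule
#' `R0[A] = 0.211 (kappa^2 n^-4 Q_D J)^(1/6)`.
#'
#' @param q_d donor emission quantum yield.
#' @param refractive_index solvent refractive index.
#' @param overlap_j spectral overlap integral, M^-1 cm^-1 nm^4.
#' @param kappa2 orientation factor (default the isotropic average 2/3).
#' @return Forster radius in nm.
#' @examples
#' forster_radius(0.5, 1.4, 1e15)
#' @export
forster_radius <- function(q_d, refractive_index, overlap_j, kappa2 = 2 / 3) {
  if (any(c(q_d, refractive_index, overlap_j, kappa2) <= 0))
    stop("all Forster-radius inputs must be > 0", call. = FALSE)
  n_avogadro <- 6.02214076e23
  # J in M^-1 cm^-1 nm^4 -> M^-1 cm^-1 cm^4 is 1e-28; cm^6 -> nm^6 is 1e42.
  r0_nm6 <- 9000 * log(10) * kappa2 * q_d * overlap_j * 1e-28 * 1e42 /
    (128 * pi^5 * n_avogadro * refractive_index^4)
  r0_nm6^(1 / 6)
}

#' Convert a configuration into FRET rate constants
#'
#' Each rate follows the ideal-dipole Forster expression
#' `k = (3/2) k_d kappa^2 Delta^-6`, where `Delta` is the distance in units
#' of the isotropic Forster radius of that pair type. In normalized mode
#' the configuration distances are already `Delta` values; in physical mode
#' (`config$physical` is `TRUE`) distances are in nm and are divided by
#' `params$r0_da` / `params$r0_dd`.
#'
#' Rates are capped at `rate_cap * k_d`: a truncated-Gaussian distance draw
#' arbitrarily close to zero produces a `Delta^-6` rate of any magnitude,
#' which makes the first-passage matrix numerically singular while the
#' physical answer (the hop happens with probability ~1) is insensitive to
#' the exact value. The default cap perturbs absorption probabilities by
#' O(1e-9), far below Monte Carlo error.
#'
#' @param config a `fret_configuration` (see [sample_configuration()]).
#' @param params a [photophysical_params()].
#' @param rate_cap cap on transfer rates, in units of `k_d`.
#' @return a `rate_system`: list with `k_da` (length `n_D`), `k_dd`
#'   (symmetric matrix, zero diagonal), `k_d`, `k_a`, `n_donors`.
#' @examples
#' cfg <- sample_configuration(build_model("D2A"), 1, 1, case_spec("i"))
#' build_rate_system(cfg)$k_da # both equal k_d: (3/2)(2/3)(1) = 1
#' @export
build_rate_system <- function(config, params = photophysical_params(),
                              rate_cap = 1e9) {
  stopifnot(inherits(config, "fret_configuration"),
            inherits(params, "photophysical_params"))
  n <- length(config$delta_da)
  delta_da <- config$delta_da
  delta_dd <- config$delta_dd
  if (isTRUE(config$physical)) {
    if (is.null(params$r0_da) || (n > 1 && is.null(params$r0_dd)))
      stop("physical-distance configurations need r0_da/r0_dd", call. = FALSE)
    delta_da <- delta_da / params$r0_da
    if (n > 1) delta_dd <- delta_dd / params$r0_dd
  }
  if (any(delta_da == 0) || any(delta_dd[upper.tri(delta_dd)] == 0))
    stop("zero interchromophore distance gives a singular rate", call. = FALSE)
  cap <- rate_cap * params$k_d
  k_da <- pmin(1.5 * params$k_d * config$kappa2_da / delta_da^6, cap)
  k_dd <- matrix(0, n, n)
  if (n > 1) {
    off <- upper.tri(delta_dd)
    k_dd[off] <- pmin(1.5 * params$k_d * config$kappa2_dd[off] /
                        delta_dd[off]^6, cap)
    k_dd <- k_dd + t(k_dd)
  }
  structure(list(k_da = k_da, k_dd = k_dd, k_d = params$k_d,
                 k_a = params$k_a, n_donors = n),
            class = "rate_system")
}

#' Probability that the excitation is absorbed by the acceptor
#'
#' Treats the kinetic network as a continuous-time Markov chain on the
#' donor sites with two absorbing sinks (acceptor capture and intrinsic
#' donor decay) and solves the linear first-passage system
#' \deqn{h_i = \frac{k_{D_iA} + \sum_j k_{D_iD_j} h_j}
#'   {k_D + k_{D_iA} + \sum_j k_{D_iD_j}}}
#' exactly. This is the production path; [integrate_populations()] is the
#' equivalent (slower) time-integration of the kinetic equations used as a
#' cross-check.
#'
#' @param system a [build_rate_system()] result with `k_a = 0`.
#' @param initial_donor donor index the excitation starts on; `NULL`
#'   returns the full per-donor vector.
#' @return absorption probability (scalar, or vector over initial donors).
#' @examples
#' cfg <- sample_configuration(build_model("D1A"), 1, 1, case_spec("i"))
#' absorption_probability(build_rate_system(cfg)) # 1/(1 + 1^6) = 0.5
#' @export
absorption_probability <- function(system, initial_donor = NULL) {
  stopifnot(inherits(system, "rate_system"))
  if (system$k_a != 0)
    stop("first-passage solve requires k_a = 0; use integrate_populations",
         call. = FALSE)
  if (system$k_d <= 0)
    stop("k_d must be > 0 for a well-posed absorption problem", call. = FALSE)
  n <- system$n_donors
  A <- diag(system$k_d + system$k_da + rowSums(system$k_dd), n) - system$k_dd
  h <- solve(A, system$k_da)
  if (is.null(initial_donor)) h else h[[initial_donor]]
}

#' Time courses of the excited-state populations
#'
#' Propagates the linear kinetic equations for the donor and acceptor
#' excited-state populations with a matrix exponential (exact for a linear
#' system, up to the exponential's own tolerance). With `k_a = 0` the
#' acceptor population at a horizon much longer than the donor lifetime
#' converges to the absorption probability; with `k_a > 0` the cumulative
#' captured flux (column `captured`) plays that role.
#'
#' @param system a [build_rate_system()] result.
#' @param initial_donor index of the initially excited donor.
#' @param horizon final time (default 20 donor lifetimes).
#' @param n_times number of equally spaced output times.
#' @return data.frame with columns `time`, `D1..Dn`, `A`, `captured`,
#'   `ground`.
#' @export
integrate_populations <- function(system, initial_donor = 1, horizon = NULL,
                                  n_times = 201) {
  stopifnot(inherits(system, "rate_system"))
  if (!all(is.finite(c(system$k_da, system$k_dd))))
    stop("non-finite rates", call. = FALSE)
  n <- system$n_donors
  if (is.null(horizon)) horizon <- 20 / system$k_d
  # states: donors 1..n, excited acceptor, cumulative captured flux
  M <- matrix(0, n + 2, n + 2)
  M[seq_len(n), seq_len(n)] <- t(system$k_dd)
  diag(M)[seq_len(n)] <- -(system$k_d + system$k_da + rowSums(system$k_dd))
  M[n + 1, seq_len(n)] <- system$k_da
  M[n + 1, n + 1] <- -system$k_a
  M[n + 2, seq_len(n)] <- system$k_da
  times <- seq(0, horizon, length.out = n_times)
  P <- as.matrix(Matrix::expm(M * (times[2] - times[1])))
  x <- matrix(0, n_times, n + 2)
  x[1, initial_donor] <- 1
  for (k in seq_len(n_times - 1)) x[k + 1, ] <- P %*% x[k, ]
  out <- data.frame(time = times)
  for (i in seq_len(n)) out[[paste0("D", i)]] <- x[, i]
  out$A <- x[, n + 1]
  out$captured <- x[, n + 2]
  # everything that has decayed (donor or acceptor) to the ground state
  out$ground <- 1 - rowSums(x[, seq_len(n), drop = FALSE]) - x[, n + 1]
  out
}

#' @export
print.rate_system <- function(x, ...) {
  cat("<rate_system> ", x$n_donors, " donor(s); k_d = ", x$k_d,
      ", k_a = ", x$k_a, "\n  k_da: ",
      paste(signif(head(x$k_da, 5), 4), collapse = ", "),
      if (x$n_donors > 5) ", ...", "\n", sep = "")
  invisible(x)
}
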