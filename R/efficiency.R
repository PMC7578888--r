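# Ensemble Monte Carlo engine: eta_FRET estimation, sweeps, shell
# diagnostics. The hot path samples whole chunks of replicates vectorized in
# R and solves the per-replicate first-passage systems in C++.

# Low-level Monte Carlo kernel on normalized distances.
# da_mean/da_sd: length-n vectors (sd 0 => deterministic distance);
# pair_mean/pair_sd: length-npair vectors aligned with `pairs` rows;
# static_kappa: draw kappa2 per pair (TRUE) or use 2/3 (FALSE).
# Returns the pooled per-donor Phi sample (length n * n_replicates).
mc_phi_sample <- function(n_donors, pairs, da_mean, da_sd, pair_mean,
                          pair_sd, static_kappa, kappa_scheme, n_replicates,
                          k_d, rate_cap, chunk_size = 5000L) {
  n <- n_donors
  np <- nrow(pairs)
  cap <- rate_cap * k_d
  phi <- numeric(n * n_replicates)
  done <- 0L
  pairs_i <- matrix(as.integer(pairs), ncol = 2)
  draw_block <- function(mean, sd, rows, m) {
    if (all(sd == 0)) return(matrix(mean, rows, m))
    x <- matrix(rnorm(rows * m, mean, sd), rows, m)
    bad <- which(x <= 0)
    while (length(bad) > 0) {
      mu <- matrix(mean, rows, m)[bad]
      s <- matrix(sd, rows, m)[bad]
      x[bad] <- rnorm(length(bad), mu, s)
      bad <- bad[x[bad] <= 0]
    }
    x
  }
  draw_kappa <- function(rows, m) {
    if (!static_kappa) return(matrix(2 / 3, rows, m))
    if (kappa_scheme == "solid_angle") {
      ct <- runif(rows * m, -1, 1)
      co <- runif(rows * m, -1, 1)
    } else {
      ct <- cos(runif(rows * m, 0, 2 * pi))
      co <- cos(runif(rows * m, 0, 2 * pi))
    }
    matrix((1 + 3 * ct^2) * co^2, rows, m)
  }
  while (done < n_replicates) {
    m <- min(chunk_size, n_replicates - done)
    dda <- draw_block(da_mean, da_sd, n, m)
    kda <- pmin(1.5 * k_d * draw_kappa(n, m) / dda^6, cap)
    kdd <- if (np > 0) {
      ddd <- draw_block(pair_mean, pair_sd, np, m)
      pmin(1.5 * k_d * draw_kappa(np, m) / ddd^6, cap)
    } else matrix(0, 0, m)
    ph <- phi_batch_cpp(kda, kdd, pairs_i, k_d)
    phi[(done * n + 1):((done + m) * n)] <- as.vector(ph)
    done <- done + m
  }
  phi
}

#' Monte Carlo estimate of the ensemble FRET efficiency
#'
#' Estimates `eta_FRET` for a model geometry at given mean normalized
#' distances under a heterogeneity case. Per replicate one structural
#' configuration is drawn; the excitation is placed on *every* donor in
#' turn (equal excitation probabilities) and each per-donor efficiency
#' `Phi_FRET` contributes to the ensemble mean. Case (i) is deterministic
#' (single distances, averaged orientations), so a single configuration is
#' evaluated and the SEM is exactly zero.
#'
#' @param geometry a [build_model()] / [build_equidistant_model()] result.
#' @param mean_delta_da mean normalized donor-acceptor distance.
#' @param mean_delta_dd mean normalized nearest-neighbour donor-donor
#'   distance (ignored when there is a single donor).
#' @param spec a [case_spec()].
#' @param n_replicates Monte Carlo replicates (the reference setting is
#'   100000; reduce for interactive work).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param params a [photophysical_params()].
#' @param keep_phi retain the pooled `Phi_FRET` sample for
#'   [phi_distribution()].
#' @param rate_cap transfer-rate cap in units of `k_d` (see
#'   [build_rate_system()]).
#' @return an `eta_estimate`: list with `eta` (mean efficiency), `sem`,
#'   `n_replicates`, `n_donors`, run metadata, and optionally `phi`.
#' @examples
#' estimate_eta(build_model("D4A"), 1.0, 0.5, case_spec("iv"),
#'              n_replicates = 200, seed = 1)
#' @export
estimate_eta <- function(geometry, mean_delta_da, mean_delta_dd = 1,
                         spec = case_spec("iv"), n_replicates = 100000,
                         seed = 1, params = photophysical_params(),
                         keep_phi = FALSE, rate_cap = 1e9) {
  stopifnot(inherits(geometry, "model_geometry"), inherits(spec, "case_spec"),
            n_replicates >= 1)
  if (mean_delta_da <= 0 || mean_delta_dd <= 0)
    stop("mean distances must be > 0", call. = FALSE)
  n <- geometry$n_donors
  pairs <- donor_pairs(geometry)
  pair_mean <- if (nrow(pairs) > 0)
    mean_delta_dd * geometry$pair_ratio[pairs] else numeric(0)
  deterministic <- spec$distance_mode == "single" &&
    spec$orientation_mode == "dynamic"
  if (deterministic) {
    cfg <- sample_configuration(geometry, mean_delta_da, mean_delta_dd, spec)
    phi1 <- absorption_probability(
      build_rate_system(cfg, params, rate_cap = rate_cap))
    phi <- if (keep_phi) rep(phi1, n_replicates) else phi1
    est <- list(eta = mean(phi1), sem = 0)
  } else {
    da_sd <- if (spec$distance_mode == "gaussian")
      rep(spec$relative_sd * mean_delta_da, n) else rep(0, n)
    pair_sd <- if (spec$distance_mode == "gaussian")
      spec$relative_sd * pair_mean else rep(0, length(pair_mean))
    phi <- local_seed(seed, mc_phi_sample(
      n, pairs, rep(mean_delta_da, n), da_sd, pair_mean, pair_sd,
      static_kappa = spec$orientation_mode == "static",
      kappa_scheme = spec$kappa_scheme, n_replicates = n_replicates,
      k_d = params$k_d, rate_cap = rate_cap))
    est <- list(eta = mean(phi), sem = sd(phi) / sqrt(length(phi)))
  }
  structure(c(est, list(
    n_replicates = n_replicates, n_donors = n, model = geometry$name,
    case = spec$case, mean_delta_da = mean_delta_da,
    mean_delta_dd = mean_delta_dd, seed = seed,
    phi = if (keep_phi) phi else NULL)), class = "eta_estimate")
}

#' @export
print.eta_estimate <- function(x, ...) {
  cat("<eta_estimate> ", x$model, " case (", x$case, "): eta_FRET = ",
      sprintf("%.4f", x$eta), " +- ", sprintf("%.2g", x$sem),
      " (", format(x$n_replicates, big.mark = ","), " replicates)\n",
      sep = "")
  invisible(x)
}

#' Efficiency enhancement over the single-donor reference
#'
#' `Delta eta_FRET = eta(DnA) - eta(D1A)` at matched mean donor-acceptor
#' distance, heterogeneity case and replicate count; SEMs combine in
#' quadrature.
#'
#' @param model_estimate,reference_d1a_estimate two [estimate_eta()]
#'   results; the reference must come from a single-donor geometry.
#' @return list with `delta_eta`, `sem`, and the two inputs' metadata.
#' @export
delta_eta <- function(model_estimate, reference_d1a_estimate) {
  stopifnot(inherits(model_estimate, "eta_estimate"),
            inherits(reference_d1a_estimate, "eta_estimate"))
  ref <- reference_d1a_estimate
  if (ref$n_donors != 1)
    stop("reference estimate must have a single donor", call. = FALSE)
  if (!isTRUE(all.equal(model_estimate$mean_delta_da, ref$mean_delta_da)) ||
      model_estimate$case != ref$case ||
      model_estimate$n_replicates != ref$n_replicates)
    stop("mismatched settings: delta_eta needs matched mean_delta_da, ",
         "case and n_replicates", call. = FALSE)
  list(delta_eta = model_estimate$eta - ref$eta,
       sem = sqrt(model_estimate$sem^2 + ref$sem^2),
       model = model_estimate$model, case = model_estimate$case,
       mean_delta_da = model_estimate$mean_delta_da)
}

#' Parameter sweep over mean distances, models and heterogeneity cases
#'
#' Runs [estimate_eta()] over a grid of mean normalized distances for each
#' model and case, and attaches the enhancement over the single-donor
#' reference computed at the same mean donor-acceptor distance and case.
#' Every grid cell (and every reference cell) draws from its own
#' counter-based sub-seed, so results are independent of evaluation order.
#'
#' @param models character vector of model names, or list of geometries.
#' @param cases character vector of case labels (e.g. `c("i", "iv")`) or
#'   list of [case_spec()]s.
#' @param delta_da_grid,delta_dd_grid numeric grids of mean normalized
#'   distances (defaults 0.1 to 2.5 in steps of 0.1).
#' @param n_replicates replicates per grid cell.
#' @param seed base seed.
#' @param params a [photophysical_params()].
#' @return a `sweep_result` data.frame with columns `model`, `case`,
#'   `delta_da`, `delta_dd`, `eta`, `sem`, `delta_eta`, `delta_eta_sem`.
#' @examples
#' sweep_eta("D4A", "i", delta_da_grid = c(0.5, 1), delta_dd_grid = 1,
#'           n_replicates = 1, seed = 1)
#' @export
sweep_eta <- function(models, cases = c("i", "ii", "iii", "iv"),
                      delta_da_grid = seq(0.1, 2.5, by = 0.1),
                      delta_dd_grid = seq(0.1, 2.5, by = 0.1),
                      n_replicates = 100000, seed = 1,
                      params = photophysical_params()) {
  if (is.character(models)) models <- lapply(models, build_model)
  if (!is.list(models) || !all(vapply(models, inherits, TRUE,
                                      "model_geometry")))
    models <- list(models)
  if (is.character(cases)) cases <- lapply(cases, function(cc) case_spec(cc))
  if (inherits(cases, "case_spec")) cases <- list(cases)
  d1a <- build_model("D1A")
  rows <- list()
  for (ci in seq_along(cases)) {
    spec <- cases[[ci]]
    # single-donor reference, one run per delta_da value
    ref <- lapply(seq_along(delta_da_grid), function(i) {
      estimate_eta(d1a, delta_da_grid[i], 1, spec, n_replicates,
                   seed = sub_seed(seed, 0, ci, i, 0), params = params)
    })
    for (mi in seq_along(models)) {
      g <- models[[mi]]
      for (i in seq_along(delta_da_grid)) {
        for (j in seq_along(delta_dd_grid)) {
          est <- estimate_eta(g, delta_da_grid[i], delta_dd_grid[j], spec,
                              n_replicates,
                              seed = sub_seed(seed, mi, ci, i, j),
                              params = params)
          de <- delta_eta(est, ref[[i]])
          rows[[length(rows) + 1L]] <- data.frame(
            model = g$name, case = spec$case,
            delta_da = delta_da_grid[i], delta_dd = delta_dd_grid[j],
            eta = est$eta, sem = est$sem, delta_eta = de$delta_eta,
            delta_eta_sem = de$sem)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Homo-FRET branching efficiency into a neighbour shell
#'
#' Ensemble-average probability that an excitation currently on a donor
#' makes its *next* hop to a donor of the given shell (nearest,
#' second-nearest, ...), rather than decaying or transferring elsewhere:
#' `sum_{j in shell} k_dd[i, j] / (k_d + k_da[i] + sum_j k_dd[i, j])`,
#' averaged over donors and replicates.
#'
#' @param geometry a `model_geometry`.
#' @param mean_delta_da,mean_delta_dd mean normalized distances.
#' @param spec a [case_spec()].
#' @param shell_index 1 = nearest shell, 2 = second-nearest, ...
#' @param n_replicates,seed Monte Carlo settings.
#' @param params a [photophysical_params()].
#' @param rate_cap transfer-rate cap in units of `k_d`.
#' @return branching probability in `[0, 1]`; 0 (with a warning) when the
#'   geometry has no such shell.
#' @export
homo_shell_efficiency <- function(geometry, mean_delta_da, mean_delta_dd,
                                  spec = case_spec("iv"), shell_index = 1,
                                  n_replicates = 10000, seed = 1,
                                  params = photophysical_params(),
                                  rate_cap = 1e9) {
  stopifnot(inherits(geometry, "model_geometry"), shell_index >= 1)
  n <- geometry$n_donors
  n_shells <- max(c(0L, lengths(geometry$shells)))
  if (shell_index > n_shells) {
    warning("geometry ", geometry$name, " has only ", n_shells,
            " shell(s); returning 0")
    return(0)
  }
  pairs <- donor_pairs(geometry)
  np <- nrow(pairs)
  pair_mean <- mean_delta_dd * geometry$pair_ratio[pairs]
  # donor x pair incidence (1 if the pair touches the donor) and the
  # donor x pair mask restricted to the requested shell of that donor
  inc <- matrix(0, n, np)
  shell_mask <- matrix(0, n, np)
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    inc[i, p] <- inc[j, p] <- 1
    if (shell_index <= length(geometry$shells[[i]]) &&
        j %in% geometry$shells[[i]][[shell_index]]) shell_mask[i, p] <- 1
    if (shell_index <= length(geometry$shells[[j]]) &&
        i %in% geometry$shells[[j]][[shell_index]]) shell_mask[j, p] <- 1
  }
  cap <- rate_cap * params$k_d
  static_kappa <- spec$orientation_mode == "static"
  gaussian <- spec$distance_mode == "gaussian"
  local_seed(seed, {
    total <- 0
    count <- 0
    done <- 0L
    while (done < n_replicates) {
      m <- min(5000L, n_replicates - done)
      draw <- function(mean_vec, rows) {
        if (!gaussian) return(matrix(mean_vec, rows, m))
        sd_vec <- spec$relative_sd * mean_vec
        x <- matrix(rnorm(rows * m, mean_vec, sd_vec), rows, m)
        bad <- which(x <= 0)
        while (length(bad) > 0) {
          x[bad] <- rnorm(length(bad), matrix(mean_vec, rows, m)[bad],
                          matrix(sd_vec, rows, m)[bad])
          bad <- bad[x[bad] <= 0]
        }
        x
      }
      kap <- function(rows) {
        if (!static_kappa) return(matrix(2 / 3, rows, m))
        if (spec$kappa_scheme == "solid_angle") {
          ct <- runif(rows * m, -1, 1); co <- runif(rows * m, -1, 1)
        } else {
          ct <- cos(runif(rows * m, 0, 2 * pi))
          co <- cos(runif(rows * m, 0, 2 * pi))
        }
        matrix((1 + 3 * ct^2) * co^2, rows, m)
      }
      kda <- pmin(1.5 * params$k_d * kap(n) / draw(rep(mean_delta_da, n), n)^6,
                  cap)
      kdd <- pmin(1.5 * params$k_d * kap(np) / draw(pair_mean, np)^6, cap)
      p_shell <- (shell_mask %*% kdd) /
        (params$k_d + kda + inc %*% kdd)
      total <- total + sum(p_shell)
      count <- count + length(p_shell)
      done <- done + m
    }
    total / count
  })
}

#' Summarize the per-donor efficiency distribution
#'
#' The width of the `Phi_FRET` distribution is the footprint of structural
#' heterogeneity: in case (i) it collapses to a point, and it broadens as
#' distance/orientation disorder grows.
#'
#' @param estimate an [estimate_eta()] result created with
#'   `keep_phi = TRUE`.
#' @param probs quantiles to report.
#' @param breaks passed to [hist()] (computed without plotting).
#' @return list with `mean`, `sd`, `quantiles`, `histogram`.
#' @export
phi_distribution <- function(estimate, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                             breaks = 50) {
  stopifnot(inherits(estimate, "eta_estimate"))
  if (is.null(estimate$phi))
    stop("no retained Phi samples; rerun estimate_eta with keep_phi = TRUE",
         call. = FALSE)
  phi <- estimate$phi
  list(mean = mean(phi), sd = sd(phi),
       quantiles = quantile(phi, probs = probs),
       histogram = graphics::hist(phi, breaks = breaks, plot = FALSE))
}
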