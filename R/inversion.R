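#' Recover the per-cell oxygen consumption rate from a central sensor reading
#'
#' Inverts the forward model: finds the `Q_m` at which the predicted oxygen
#' level at the construct's geometric centre equals an observed sensor
#' reading. Because the predicted central oxygen is strictly decreasing in
#' `Q_m`, the root is unique and a bracketed search (bisection with secant
#' acceleration, warm-started forward solves) is globally robust. Iteration
#' stops when the predicted and observed values agree to `tol_o2c` (% O2).
#'
#' Readings above the zero-consumption prediction are infeasible and raise an
#' error; if the initial bracket does not span the observation it is expanded
#' (doubling the upper end) up to `max_expand` times before failing.
#'
#' @param observed_o2c Observed central oxygen level (% O2), positive.
#' @param grid An [build_domain()] grid (its geometry locates the sensor).
#' @param params A [model_parameters()] object.
#' @param density_map A [cell_density_map()].
#' @param bracket Initial `Q_m` search interval (amol/cell/s).
#' @param tol_o2c Residual tolerance on the central oxygen match (% O2).
#' @param max_expand Maximum number of bracket doublings.
#'
#' @return An object of class `"qm_estimate"`: `Q_m` (amol/cell/s),
#'   `is_lower_bound`, `achieved_o2c` and `residual` (% O2), the final
#'   `bracket`, the number of forward `evaluations`, and for lower-bound
#'   estimates the depletion threshold `epsilon`.
#' @examples
#' \donttest{
#' grid <- build_domain(construct_geometry(), resolution = 0.25)
#' est <- fit_qm(4.6, grid, model_parameters(), cell_density_map(20e6))
#' est$Q_m
#' }
#' @export
fit_qm <- function(observed_o2c, grid, params, density_map,
                   bracket = c(0, 200), tol_o2c = 0.01, max_expand = 6L) {
  stopifnot(inherits(grid, "axi_grid"))
  if (is.null(grid$geometry))
    stop("fit_qm needs a grid built from a construct_geometry (sensor position)")
  if (!is.numeric(observed_o2c) || length(observed_o2c) != 1L ||
      observed_o2c <= 0)
    stop("observed_o2c must be a single positive oxygen level (% O2)")
  ctx <- fv_context(grid, params, density_map)
  qm_root(ctx, observed_o2c, bracket, tol_o2c, max_expand,
          is_lower_bound = FALSE, epsilon = NA_real_)
}

#' Minimum consumption rate that depletes the construct centre
#'
#' For sensor readings printed as 0.0% the inversion target is below the
#' model's reach at any finite `Q_m`; the reported estimate is then the
#' smallest `Q_m` whose predicted central oxygen falls to the depletion
#' threshold `epsilon`, flagged as a lower bound on the true consumption rate.
#'
#' @inheritParams fit_qm
#' @param epsilon Depletion threshold (% O2); the default 0.05 is half the
#'   last printed digit of the sensor readout.
#' @return A `"qm_estimate"` with `is_lower_bound = TRUE` and the `epsilon`
#'   used recorded.
#' @export
min_qm_for_depletion <- function(grid, params, density_map, epsilon = 0.05,
                                 bracket = c(0, 200), tol_o2c = 0.01,
                                 max_expand = 6L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive oxygen level (% O2)")
  ctx <- fv_context(grid, params, density_map)
  qm_root(ctx, epsilon, bracket, tol_o2c, max_expand,
          is_lower_bound = TRUE, epsilon = epsilon)
}

# Shared monotone root finder on f(Q_m) = predicted central O2 - target.
qm_root <- function(ctx, target, bracket, tol_o2c, max_expand,
                    is_lower_bound, epsilon) {
  grid <- ctx$grid
  sens <- sensor_position(grid$geometry)
  state <- new.env(parent = emptyenv())
  state$init <- NULL
  state$evals <- 0L
  predict_o2c <- function(Q_m) {
    sol <- fv_solve(ctx, Q_m, init = state$init)
    if (!sol$converged)
      stop("forward solve did not converge during inversion (Q_m = ", Q_m, ")")
    ctx$chol <<- sol$ctx$chol
    state$init <- sol$conc
    state$evals <- state$evals + 1L
    fld <- new_concentration_field(grid, ctx$params, ctx$density_map, Q_m, sol)
    unname(sample_at(fld, sens["r"], sens["z"])["percent"])
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  if (!(is.numeric(bracket) && length(bracket) == 2L && lo >= 0 && hi > lo))
    stop("bracket must be an increasing non-negative Q_m interval")
  f_lo <- predict_o2c(lo) - target
  if (f_lo < -tol_o2c) {
    if (lo == 0)
      stop(sprintf(paste0("observed central O2 (%.3g%%) exceeds the ",
                          "zero-consumption prediction (%.3g%%): infeasible"),
                   target, f_lo + target))
    stop("bracket lower end already predicts below the observation")
  }
  if (abs(f_lo) <= tol_o2c)
    return(new_qm_estimate(lo, is_lower_bound, f_lo + target, f_lo,
                           c(lo, hi), state$evals, epsilon))
  f_hi <- predict_o2c(hi) - target
  expand <- 0L
  while (f_hi > 0 && expand < max_expand) {
    lo <- hi; f_lo <- f_hi
    hi <- hi * 2
    f_hi <- predict_o2c(hi) - target
    expand <- expand + 1L
  }
  if (f_hi > 0)
    stop(sprintf(paste0("target central O2 %.3g%% not reachable within the ",
                        "expanded bracket [0, %.3g] amol/cell/s"), target, hi))
  # Illinois-damped regula falsi inside a maintained bracket
  mid <- NA_real_; f_mid <- NA_real_
  side <- 0L
  for (k in seq_len(200L)) {
    mid <- (lo * f_hi - hi * f_lo) / (f_hi - f_lo)
    if (!is.finite(mid) || mid <= lo || mid >= hi) mid <- (lo + hi) / 2
    f_mid <- predict_o2c(mid) - target
    if (abs(f_mid) <= tol_o2c || (hi - lo) < 1e-6) break
    if (f_mid > 0) {
      lo <- mid; f_lo <- f_mid
      if (side == 1L) f_hi <- f_hi / 2
      side <- 1L
    } else {
      hi <- mid; f_hi <- f_mid
      if (side == -1L) f_lo <- f_lo / 2
      side <- -1L
    }
  }
  new_qm_estimate(mid, is_lower_bound, f_mid + target, f_mid,
                  c(lo, hi), state$evals, epsilon)
}

new_qm_estimate <- function(Q_m, is_lower_bound, achieved, residual,
                            bracket, evaluations, epsilon) {
  structure(list(Q_m = Q_m, is_lower_bound = is_lower_bound,
                 achieved_o2c = achieved, residual = residual,
                 bracket = bracket, evaluations = evaluations,
                 epsilon = epsilon),
            class = "qm_estimate")
}

#' @export
print.qm_estimate <- function(x, ...) {
  cat(sprintf("Q_m %s %.4g amol/cell/s (central O2 %.3f%%, residual %.2e%%)\n",
              if (x$is_lower_bound) ">=" else "=", x$Q_m,
              x$achieved_o2c, x$residual))
  if (x$is_lower_bound)
    cat(sprintf("  lower bound: depletion threshold epsilon = %.3g%% O2\n",
                x$epsilon))
  invisible(x)
}

#' Batch inversion of a table of sensor readings
#'
#' Fits one `Q_m` per reading against a shared scenario (grid, parameters,
#' density map), routing depleted readings (at or below `epsilon`) through
#' [min_qm_for_depletion()]. Infeasible readings are flagged per row and the
#' batch continues. Per-condition mean and standard deviation of the
#' estimates are attached as the `"summary"` attribute.
#'
#' @param readings Data frame with columns `sample_id`, `day`, `condition`,
#'   `o2c_percent` (see [read_sensor_readings()]).
#' @inheritParams fit_qm
#' @param epsilon Depletion threshold (% O2) below which a reading is treated
#'   as fully depleted.
#' @return A data frame with one row per reading (`qm_amol_cell_s`,
#'   `is_lower_bound`, `residual_percent`, `epsilon_percent`, `error`), with
#'   attribute `"summary"` holding per-(condition, day) `n`, `mean_qm`,
#'   `sd_qm`.
#' @export
fit_qm_batch <- function(readings, grid, params, density_map,
                         bracket = c(0, 200), tol_o2c = 0.01,
                         epsilon = 0.05, max_expand = 6L) {
  req <- c("sample_id", "day", "condition", "o2c_percent")
  if (!is.data.frame(readings) || !all(req %in% names(readings)))
    stop("readings must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(readings) == 0L) stop("empty readings table")
  ctx <- fv_context(grid, params, density_map)
  fit_one <- function(o2c) {
    if (o2c <= epsilon)
      qm_root(ctx, epsilon, bracket, tol_o2c, max_expand,
              is_lower_bound = TRUE, epsilon = epsilon)
    else
      qm_root(ctx, o2c, bracket, tol_o2c, max_expand,
              is_lower_bound = FALSE, epsilon = NA_real_)
  }
  out <- readings[req]
  out$qm_amol_cell_s <- NA_real_
  out$is_lower_bound <- NA
  out$residual_percent <- NA_real_
  out$epsilon_percent <- NA_real_
  out$error <- NA_character_
  for (k in seq_len(nrow(readings))) {
    est <- tryCatch(fit_one(readings$o2c_percent[k]), error = identity)
    if (inherits(est, "error")) {
      out$error[k] <- conditionMessage(est)
    } else {
      out$qm_amol_cell_s[k] <- est$Q_m
      out$is_lower_bound[k] <- est$is_lower_bound
      out$residual_percent[k] <- est$residual
      out$epsilon_percent[k] <- est$epsilon
    }
  }
  ok <- is.na(out$error)
  grp <- interaction(out$condition, out$day, drop = TRUE)
  summ <- do.call(rbind, lapply(split(out[ok, ], droplevels(grp[ok])), function(d) {
    data.frame(condition = d$condition[1L], day = d$day[1L],
               n = nrow(d), mean_qm = mean(d$qm_amol_cell_s),
               sd_qm = stats::sd(d$qm_amol_cell_s))
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}
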