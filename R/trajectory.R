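#' @title Cumulative emission trajectories and equivalence points
#' @description Pool-exhaustion trajectories for degrading peat carbon
#'   (constant per-class emission rate until the class's stock is gone),
#'   the saturating mineral-soil sequestration curve, equivalence points
#'   between the two, and the Michaelis-Menten area-expansion scenario.
#' @name trajectory_simulator
NULL

#' Build the per-class emission pool table from a budget table
#'
#' Converts per-climate degrading C stocks and annual CO2-eq emission
#' ranges into the pool/rate form the trajectory simulator consumes. Rates
#' are converted to carbon-equivalents (x 12/44): the all-GHG C-eq flux
#' draws down the C pool.
#'
#' @param fixture Per-climate table in the shape of [global_peat_aggregates()].
#' @return Data frame with columns `class`, `pool_gt` (Gt C) and
#'   `rate_min/mean/max` (Gt CO2-C-eq per year).
#' @export
emission_pools <- function(fixture = global_peat_aggregates()) {
  data.frame(
    class = fixture$climate,
    pool_gt = fixture$degrading_c_gt,
    rate_min = co2eq_to_ceq(fixture$emission_min_gt),
    rate_mean = co2eq_to_ceq(fixture$emission_mean_gt),
    rate_max = co2eq_to_ceq(fixture$emission_max_gt),
    stringsAsFactors = FALSE
  )
}

#' Cumulative peat emission trajectory with pool exhaustion
#'
#' Each class emits at its constant rate until its degrading carbon pool is
#' exhausted (cumulative emission capped at the pool), then stops. Classes
#' are summed per uncertainty layer. The end points are therefore the
#' theoretical maximum emittable from the degrading stocks.
#'
#' @param pools Data frame with columns `class`, `pool_gt`,
#'   `rate_min`, `rate_mean`, `rate_max` (see [emission_pools()]).
#' @param horizon Simulation horizon (years).
#' @param dt Time step (years), > 0.
#' @return Data frame with columns `time` and cumulative `min`, `mean`,
#'   `max` (Gt CO2-C-eq).
#' @export
peat_trajectory <- function(pools, horizon = 1500, dt = 0.5) {
  stopifnot(dt > 0, horizon > 0)
  if (any(pools$pool_gt < 0) ||
      any(pools[c("rate_min", "rate_mean", "rate_max")] < 0)) {
    stop("pools and emission rates must be non-negative")
  }
  times <- seq(0, horizon, by = dt)
  out <- data.frame(time = times)
  for (layer in c("min", "mean", "max")) {
    rate <- pools[[paste0("rate_", layer)]]
    cum <- vapply(times, function(t) {
      sum(pmin(rate * t, pools$pool_gt))
    }, numeric(1))
    out[[layer]] <- cum
  }
  out
}

#' Cumulative mineral-soil sequestration curve
#'
#' A saturating sink: zero at t = 0, nondecreasing, reaching its maximum
#' additional storage `s_max` at `t_seq` years and flat afterwards. The
#' default form is exponential saturation normalized to hit `s_max`
#' exactly at `t_seq` (the raw exponential is within `eps` of saturation
#' there); any other nondecreasing shape on \[0, 1\] can be plugged in via
#' `shape`, so a differently calibrated saturation equation can be dropped
#' in unchanged.
#'
#' @param s_max Named or unnamed numeric of saturation levels per layer,
#'   default `c(min = 24, mean = 44, max = 64)` Gt C.
#' @param t_seq Years to reach saturation (default 63).
#' @param horizon,dt Time axis (years).
#' @param eps Residual unsaturated fraction of the raw exponential at
#'   `t_seq` (default 0.01).
#' @param shape Optional function mapping `t / t_seq` in \[0, 1\] to a
#'   fraction of `s_max` in \[0, 1\] with shape(0) = 0, shape(1) = 1.
#' @return Data frame with columns `time` and one cumulative column per
#'   layer (`min`, `mean`, `max` for the default `s_max`), in Gt C.
#' @export
mineral_sink <- function(s_max = c(min = 24, mean = 44, max = 64),
                         t_seq = 63, horizon = 1500, dt = 0.5,
                         eps = 0.01, shape = NULL) {
  stopifnot(t_seq > 0, dt > 0, all(s_max >= 0), eps > 0, eps < 1)
  times <- seq(0, horizon, by = dt)
  u <- pmin(times / t_seq, 1)
  frac <- if (is.null(shape)) {
    k <- -log(eps)
    (1 - exp(-k * u)) / (1 - exp(-k))
  } else {
    shape(u)
  }
  if (any(diff(frac) < -1e-12) || abs(frac[1]) > 1e-12) {
    stop("sink shape must be nondecreasing and start at 0")
  }
  out <- data.frame(time = times)
  nms <- names(s_max)
  if (is.null(nms)) nms <- paste0("layer", seq_along(s_max))
  for (i in seq_along(s_max)) out[[nms[i]]] <- s_max[i] * frac
  out
}

#' Equivalence point between cumulative emission and sink series
#'
#' First time at which the cumulative peat emission catches up with (>=)
#' the cumulative mineral sink, linearly interpolated between steps. If the
#' emission series never falls below the sink (e.g. identical series or a
#' zero sink) the equivalence point is 0; if it never catches up within the
#' horizon, `Inf` is returned.
#'
#' @param peat,sink Numeric vectors of cumulative values on a shared time
#'   axis.
#' @param time Numeric time axis (years), same length.
#' @return Equivalence year (possibly 0 or `Inf`).
#' @export
equivalence_point <- function(peat, sink, time) {
  if (length(peat) != length(sink) || length(peat) != length(time)) {
    stop("series and time axis lengths differ")
  }
  d <- peat - sink
  if (all(d >= 0)) return(0)
  behind <- which(d < 0)
  i <- behind[length(behind)] # last index where peat < sink
  if (i == length(d)) return(Inf)
  # crossing between i and i + 1
  t0 <- time[i]; t1 <- time[i + 1]
  d0 <- d[i]; d1 <- d[i + 1]
  t0 + (t1 - t0) * (-d0) / (d1 - d0)
}

#' Michaelis-Menten degraded-area expansion multiplier
#'
#' Multiplier on the current degraded area at time `t`:
#' `1 + (m - 1) * t / (t + K)`, rising from 1 at t = 0 toward the
#' asymptote `m` with half of the added area in place at `t = K`.
#'
#' @param t Years since present, >= 0 (vectorized).
#' @param m Asymptotic multiplier (default 2: a doubling of the current
#'   degraded area).
#' @param K Half-saturation time (years, default 60).
#' @return Area multiplier(s) in \[1, m).
#' @export
mm_multiplier <- function(t, m = 2, K = 60) {
  stopifnot(K > 0, m >= 1)
  if (any(t < 0)) stop("time must be non-negative")
  1 + (m - 1) * t / (t + K)
}

#' Expansion-scenario cumulative emission trajectory
#'
#' Newly degraded area enters on the Michaelis-Menten schedule as scaled
#' copies (vintages) of the baseline class mix: a vintage entering at time
#' `s` with weight `w` contributes `w * baseline(t - s)` — its own pools
#' depleting from its own start. The trajectory therefore dominates the
#' baseline everywhere and approaches `m` times the baseline total pool.
#'
#' @param pools Pool table (see [emission_pools()]).
#' @param horizon,dt Time axis (years). A warning is issued if `dt > K/10`
#'   (too coarse to resolve the expansion schedule).
#' @param m,K Michaelis-Menten parameters (see [mm_multiplier()]).
#' @return Data frame with columns `time`, `min`, `mean`, `max`
#'   (Gt CO2-C-eq).
#' @export
scenario_trajectory <- function(pools, horizon = 1500, dt = 0.5,
                                m = 2, K = 60) {
  if (dt > K / 10) {
    warning("dt = ", dt, " y is too coarse to resolve the expansion ",
            "schedule (K = ", K, " y); use dt <= K/10")
  }
  base <- peat_trajectory(pools, horizon, dt)
  mult <- mm_multiplier(base$time, m, K)
  dm <- diff(mult)
  n <- nrow(base)
  out <- base
  for (layer in c("min", "mean", "max")) {
    b <- base[[layer]]
    add <- numeric(n)
    for (j in seq_along(dm)) {
      if (dm[j] == 0) next
      # vintage entering at step j + 1 has aged i - (j + 1) steps at step i
      span <- (j + 1):n
      add[span] <- add[span] + dm[j] * b[seq_len(length(span))]
    }
    out[[layer]] <- b + add
  }
  out
}

#' Asymptotic cumulative release of the expansion scenario
#'
#' In the limit, every unit of (current and added) degraded area emits its
#' entire pool, so the cumulative release is the asymptotic area multiplier
#' times the total baseline stock.
#'
#' @param total_stock_gt Total degrading stock (Gt C for carbon, Gt N for
#'   nitrogen), vectorized.
#' @param m Asymptotic area multiplier.
#' @return Asymptotic cumulative release, same units as `total_stock_gt`.
#' @export
#' @examples
#' scenario_asymptote(80.8)       # ~161.6 Gt C
#' scenario_asymptote(2.3)        # ~4.6 Gt N
scenario_asymptote <- function(total_stock_gt, m = 2) {
  stopifnot(m >= 1, all(total_stock_gt >= 0))
  m * total_stock_gt
}

#' Full equivalence analysis between peat emissions and the mineral sink
#'
#' Runs the baseline (and optionally the expansion-scenario) cumulative
#' peat trajectory against the mineral sink and locates the equivalence
#' point per uncertainty layer. With `pairing = "envelope"` (default) the
#' reported minimum year pairs the fastest emissions with the smallest
#' sink and the maximum year the slowest emissions with the largest sink,
#' so the range brackets the earliest and latest possible crossing; with
#' `pairing = "matched"` each layer is compared with its own counterpart.
#'
#' @param pools Pool table (see [emission_pools()]).
#' @param sink_s_max Saturation levels per layer (Gt C).
#' @param horizon,dt Time axis (years).
#' @param scenario Logical: also run the expansion scenario.
#' @param m,K Expansion parameters.
#' @param pairing How uncertainty layers are paired across the two curves.
#' @return List with `trajectory` (tidy data frame: time, series, layer,
#'   value) and `equivalence` (data frame: case, layer, year).
#' @export
equivalence_analysis <- function(pools = emission_pools(),
                                 sink_s_max = c(min = 24, mean = 44,
                                                max = 64),
                                 horizon = 1500, dt = 0.5,
                                 scenario = TRUE, m = 2, K = 60,
                                 pairing = c("envelope", "matched")) {
  pairing <- match.arg(pairing)
  peat <- peat_trajectory(pools, horizon, dt)
  sink <- mineral_sink(sink_s_max, horizon = horizon, dt = dt)
  layers <- c("min", "mean", "max")
  # the sink layer always matches the reported layer; under envelope
  # pairing the peat side flips, bracketing the earliest/latest crossing
  sink_layer <- c(min = "min", mean = "mean", max = "max")
  peat_layer <- if (pairing == "envelope") {
    c(min = "max", mean = "mean", max = "min")
  } else {
    c(min = "min", mean = "mean", max = "max")
  }
  eq_years <- function(df) {
    vapply(layers, function(l) {
      equivalence_point(df[[peat_layer[[l]]]], sink[[sink_layer[[l]]]],
                        df$time)
    }, numeric(1))
  }
  eq <- data.frame(case = "baseline", layer = layers,
                   year = eq_years(peat), stringsAsFactors = FALSE)
  tidy <- function(df, series) {
    do.call(rbind, lapply(layers, function(l) {
      data.frame(time = df$time, series = series, layer = l,
                 value = df[[l]], stringsAsFactors = FALSE)
    }))
  }
  traj <- rbind(tidy(peat, "peat_baseline"), tidy(sink, "mineral_sink"))
  if (scenario) {
    sc <- scenario_trajectory(pools, horizon, dt, m, K)
    eq_sc <- data.frame(case = "scenario", layer = layers,
                        year = eq_years(sc), stringsAsFactors = FALSE)
    eq <- rbind(eq, eq_sc)
    traj <- rbind(traj, tidy(sc, "peat_scenario"))
  }
  list(trajectory = traj, equivalence = eq)
}
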