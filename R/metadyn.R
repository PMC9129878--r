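# Metadynamics bias bookkeeping: hill records, boundary-image deposition on a
# 2-D lattice over (zetaA, zetaB), height schedules, walker merging, and the
# time-averaged effective bias used for reweighting.

#' Create an empty 2-D bias lattice over (zetaA, zetaB)
#'
#' The default spacing of 0.05 Angstrom gives five lattice points per hill
#' width (0.25 Angstrom); the lower bound -2 Angstrom covers the full range
#' of the soft-minimum variable, which is bounded below by -C.
#'
#' @param lo,hi lattice bounds, Angstrom (both CV dimensions).
#' @param spacing lattice spacing, Angstrom.
#' @return list of class `bias_grid` with the axis vector `zeta` and a
#'   square matrix `values` (kcal/mol), rows indexing zetaA.
#' @export
bias_grid <- function(lo = -2, hi = 45, spacing = 0.05) {
  stopifnot(spacing > 0, hi > lo)
  n <- floor((hi - lo) / spacing) + 1L
  structure(
    list(lo = lo, spacing = spacing, n = n,
         zeta = lo + spacing * (seq_len(n) - 1L),
         values = matrix(0, n, n)),
    class = "bias_grid"
  )
}

#' @export
print.bias_grid <- function(x, ...) {
  cat(sprintf("bias_grid: %d x %d over [%g, %g] A, spacing %g A, max %g kcal/mol\n",
              x$n, x$n, x$lo, max(x$zeta), x$spacing, max(x$values)))
  invisible(x)
}

#' Hill records
#'
#' A plain data.frame describing deposited Gaussians, one row per hill, with
#' columns `time` (ps), `zeta_a`, `zeta_b` (centre, Angstrom), `sigma_a`,
#' `sigma_b` (widths, Angstrom), `height` (kcal/mol) and `walker` (integer).
#'
#' @param time,zeta_a,zeta_b,sigma_a,sigma_b,height,walker vectors, recycled
#'   to a common length.
#' @return data.frame of hill records.
#' @export
hill_records <- function(time, zeta_a, zeta_b, sigma_a = 0.25,
                         sigma_b = 0.25, height, walker = 0L) {
  df <- data.frame(time = time, zeta_a = zeta_a, zeta_b = zeta_b,
                   sigma_a = sigma_a, sigma_b = sigma_b, height = height,
                   walker = as.integer(walker))
  if (any(df$sigma_a <= 0) || any(df$sigma_b <= 0))
    stop("hill widths must be positive")
  if (any(df$height < 0)) stop("hill heights must be non-negative")
  df
}

#' Deposit hills onto a bias grid, with boundary images
#'
#' Each hill adds its 2-D Gaussian plus a mirror image reflected across
#' zeta = 0 in each CV dimension (and the double mirror), so the bias
#' gradient normal to the zeta = 0 boundary vanishes. Deposition is additive
#' and order-independent.
#'
#' @param grid a [bias_grid()].
#' @param hills a [hill_records()] data.frame.
#' @return a new `bias_grid` with the hills added.
#' @export
deposit_hills <- function(grid, hills) {
  stopifnot(inherits(grid, "bias_grid"))
  if (any(hills$sigma_a <= 0) || any(hills$sigma_b <= 0))
    stop("hill widths must be positive")
  if (any(!is.finite(hills$zeta_a)) || any(!is.finite(hills$zeta_b)))
    stop("hill centres must be finite")
  v <- grid$values + 0  # force a copy; C++ writes in place
  cpp_deposit_hills(v, grid$lo, grid$spacing,
                    as.matrix(hills[, c("zeta_a", "zeta_b", "sigma_a",
                                        "sigma_b", "height")]))
  grid$values <- v
  grid
}

#' Hill-height schedule
#'
#' Piecewise-linear schedule: the height rises from `h0` to `h_peak` over
#' `[0, t_rise_end]`, holds, then returns linearly to `h0` at `t_decay_end`
#' and stays there. Times in ns.
#'
#' @param h0 baseline height, kcal/mol (default 0.0035).
#' @param h_peak peak height, kcal/mol (default 0.007).
#' @param t_rise_end end of the rise, ns (default 30, the K+ protocol).
#' @param t_decay_end end of the decay, ns (default 100).
#' @return list of class `height_schedule`.
#' @export
height_schedule <- function(h0 = 0.0035, h_peak = 0.007,
                            t_rise_end = 30, t_decay_end = 100) {
  stopifnot(h0 <= h_peak, t_rise_end <= t_decay_end, h0 >= 0)
  structure(list(h0 = h0, h_peak = h_peak, t_rise_end = t_rise_end,
                 t_decay_end = t_decay_end),
            class = "height_schedule")
}

#' Evaluate a hill-height schedule
#'
#' @param t_ns time, ns (vectorised, must be >= 0).
#' @param schedule a [height_schedule()].
#' @return hill height(s), kcal/mol.
#' @export
#' @examples
#' schedule_height(c(0, 30, 200), height_schedule())  # 0.0035 0.007 0.0035
schedule_height <- function(t_ns, schedule = height_schedule()) {
  stopifnot(inherits(schedule, "height_schedule"), all(t_ns >= 0))
  with(schedule, {
    h <- rep(h0, length(t_ns))
    rise <- t_ns < t_rise_end
    h[rise] <- h0 + (h_peak - h0) * t_ns[rise] / t_rise_end
    hold <- !rise & t_ns <= t_rise_end  # t == t_rise_end
    h[hold] <- h_peak
    dec <- t_ns > t_rise_end & t_ns < t_decay_end
    h[dec] <- h_peak - (h_peak - h0) * (t_ns[dec] - t_rise_end) /
      (t_decay_end - t_rise_end)
    h
  })
}

#' Merge per-walker hill streams into one time-ordered stream
#'
#' Stable merge by deposition time; ties are broken by walker id ascending.
#' Because hill deposition is additive, the merged order reproduces the
#' shared bias exactly.
#'
#' @param streams list of [hill_records()] data.frames, each time-sorted.
#' @return one merged hill data.frame.
#' @export
merge_walker_hills <- function(streams) {
  stopifnot(is.list(streams), length(streams) >= 1)
  for (s in streams) {
    if (is.unsorted(s$time)) stop("each walker stream must be time-sorted")
  }
  all <- do.call(rbind, streams)
  all[order(all$time, all$walker), , drop = FALSE]
}

#' Time-averaged effective bias from bias snapshots
#'
#' Pointwise arithmetic mean of instantaneous bias grids whose times fall in
#' the averaging window. Used once the metadynamics bias has become
#' approximately stationary over the CV range of interest.
#'
#' @param grids list of [bias_grid()] objects (identical lattices).
#' @param times snapshot times, ps, parallel to `grids`.
#' @param window numeric `c(t_start, t_end)` in ps, `t_start < t_end`.
#' @return list of class `effective_bias`: the averaged `grid` plus `window`.
#' @export
time_average_bias <- function(grids, times, window) {
  stopifnot(length(grids) == length(times), length(window) == 2,
            window[1] < window[2])
  keep <- which(times >= window[1] & times <= window[2])
  if (length(keep) == 0L) stop("no bias snapshots inside the window")
  g <- grids[[keep[1]]]
  acc <- matrix(0, g$n, g$n)
  for (i in keep) {
    gi <- grids[[i]]
    if (gi$n != g$n || gi$lo != g$lo || gi$spacing != g$spacing)
      stop("bias grids must share one lattice")
    acc <- acc + gi$values
  }
  g$values <- acc / length(keep)
  structure(list(grid = g, window = window), class = "effective_bias")
}

#' Time-averaged effective bias reconstructed from a hill log
#'
#' Rebuilds the instantaneous bias (sum of hills with time <= t, with
#' boundary images) at `n_samples` times spread uniformly over the window
#' and averages them. This is the production route from a multiple-walker
#' hills file to the effective bias used in reweighting.
#'
#' @param hills merged [hill_records()] (time-sorted).
#' @param grid a [bias_grid()] defining the lattice.
#' @param window averaging window `c(t_start, t_end)`, ps.
#' @param n_samples number of bias snapshots averaged (default 25).
#' @return an `effective_bias` object.
#' @export
effective_bias_from_hills <- function(hills, grid, window, n_samples = 25) {
  stopifnot(inherits(grid, "bias_grid"), length(window) == 2,
            window[1] < window[2], n_samples >= 1)
  if (is.unsorted(hills$time)) stop("hills must be time-sorted")
  ts <- seq(window[1], window[2], length.out = n_samples)
  hm <- as.matrix(hills[, c("time", "zeta_a", "zeta_b", "sigma_a",
                            "sigma_b", "height")])
  g <- grid
  g$values <- cpp_bias_time_average(grid$n, grid$lo, grid$spacing, hm, ts)
  structure(list(grid = g, window = window), class = "effective_bias")
}

#' @export
print.effective_bias <- function(x, ...) {
  cat(sprintf("effective_bias: window [%g, %g] ps, max %g kcal/mol\n",
              x$window[1], x$window[2], max(x$grid$values)))
  invisible(x)
}

#' Stationarity diagnostic for an averaging window
#'
#' Maximum pointwise drift of the bias between the two halves of the window,
#' restricted to lattice cells the trajectory actually visited (optional).
#' Large drift indicates the bias was still growing unevenly and the window
#' should start later.
#'
#' @param hills merged hill records.
#' @param grid a [bias_grid()].
#' @param window averaging window, ps.
#' @param n_samples snapshots per half (default 12).
#' @return max |V1 - V2 - median offset| in kcal/mol, where V1 and V2 are the
#'   half-window averages (a uniform offset does not affect reweighting).
#' @export
bias_stationarity <- function(hills, grid, window, n_samples = 12) {
  mid <- mean(window)
  e1 <- effective_bias_from_hills(hills, grid, c(window[1], mid), n_samples)
  e2 <- effective_bias_from_hills(hills, grid, c(mid, window[2]), n_samples)
  d <- e2$grid$values - e1$grid$values
  max(abs(d - stats::median(d)))
}

#' Write hills to the whitespace-separated hills dialect
#'
#' Columns: `time_ps zetaA zetaB sigmaA sigmaB height_kcal walker_id`;
#' `#` introduces comment lines. Ten significant digits, so a read/write
#' round trip is bit-stable at that precision.
#'
#' @param hills a [hill_records()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_ps zetaA zetaB sigmaA sigmaB height_kcal walker_id", con)
  writeLines(sprintf("%.10g %.10g %.10g %.10g %.10g %.10g %d",
                     hills$time, hills$zeta_a, hills$zeta_b, hills$sigma_a,
                     hills$sigma_b, hills$height, as.integer(hills$walker)),
             con)
  invisible(path)
}

#' Read a hills file written by [write_hills()] (or the same dialect)
#' @param path file path.
#' @return a [hill_records()] data.frame.
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  tab <- read.table(text = lines, header = FALSE,
                    col.names = c("time", "zeta_a", "zeta_b", "sigma_a",
                                  "sigma_b", "height", "walker"))
  tab$walker <- as.integer(tab$walker)
  tab
}
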