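# Tracking-based loosening validation. For each screw the implant-vertebra
# relative movement series is summarized by its centered mean absolute
# value (the mean absolute deviation of the distance series), and the
# loose/fixed ratio of that summary is the loosening criterion: a screw is
# declared loose when the ratio strictly exceeds 2, i.e. the relative
# movement has more than doubled after loosening.

#' Tracked trajectory of a rigid-body reference point
#'
#' @param timestamps strictly increasing numeric vector, seconds.
#' @param positions numeric matrix with 3 columns (x, y, z), millimetres.
#' @param body label, one of `"L2"`, `"rod1"`, `"rod2"` (free-form labels
#'   are allowed for other rigs).
#' @return an object of class `tracked_trajectory`.
#' @export
tracked_trajectory <- function(timestamps, positions, body = "L2") {
  positions <- as.matrix(positions)
  if (length(timestamps) < 2)
    vs_stop("a trajectory needs at least 2 samples",
            "vibroscrew_input_error")
  if (any(diff(timestamps) <= 0))
    vs_stop("timestamps must be strictly increasing",
            "vibroscrew_input_error")
  if (ncol(positions) != 3 || nrow(positions) != length(timestamps))
    vs_stop("positions must be an n x 3 matrix matching timestamps",
            "vibroscrew_input_error")
  if (any(!is.finite(positions)))
    vs_stop("positions must be finite", "vibroscrew_input_error")
  structure(list(timestamps = as.numeric(timestamps),
                 positions = unname(positions), body = body),
            class = "tracked_trajectory")
}

#' Read / write a trajectory CSV
#'
#' Format: header `t,x,y,z`, time in seconds, coordinates in millimetres.
#'
#' @param path CSV file path.
#' @param traj a [tracked_trajectory()].
#' @param body body label attached on read.
#' @export
read_trajectory <- function(path, body = "L2") {
  df <- read.csv(path, comment.char = "#")
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(df)))
    vs_stop(sprintf("trajectory CSV %s must have columns t,x,y,z", path),
            "vibroscrew_format_error")
  tracked_trajectory(df$t, as.matrix(df[, c("x", "y", "z")]), body)
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(t = traj$timestamps, x = traj$positions[, 1],
                   y = traj$positions[, 2], z = traj$positions[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Synchronize two trajectories onto a common time grid
#'
#' Both trajectories are linearly interpolated onto the overlap of their
#' time ranges, sampled at the coarser of the two rates.
#'
#' @param trajA,trajB [tracked_trajectory()] objects with overlapping time
#'   ranges.
#' @return list with `timestamps`, `posA`, `posB` (equal-length matrices).
#' @export
synchronize <- function(trajA, trajB) {
  t0 <- max(min(trajA$timestamps), min(trajB$timestamps))
  t1 <- min(max(trajA$timestamps), max(trajB$timestamps))
  if (t0 >= t1)
    vs_stop("trajectories have no temporal overlap",
            "vibroscrew_input_error")
  step <- max(stats::median(diff(trajA$timestamps)),
              stats::median(diff(trajB$timestamps)))
  grid <- seq(t0, t1, by = step)
  interp <- function(traj) {
    vapply(1:3, function(j)
      approx(traj$timestamps, traj$positions[, j], xout = grid)$y,
      numeric(length(grid)))
  }
  list(timestamps = grid, posA = interp(trajA), posB = interp(trajB))
}

#' Relative movement series between vertebra and rod
#'
#' `dx_i = || x_L2(t_i) - x_rod(t_i) ||`, the Euclidean distance between
#' the two reference points at each synchronized time index, in mm.
#'
#' @param traj_L2,traj_rod [tracked_trajectory()] objects; they are
#'   synchronized internally with [synchronize()].
#' @return numeric vector of nonnegative distances (class
#'   `relative_movement`).
#' @export
relative_movement <- function(traj_L2, traj_rod) {
  sync <- synchronize(traj_L2, traj_rod)
  d <- sync$posA - sync$posB
  structure(sqrt(rowSums(d^2)), class = "relative_movement",
            timestamps = sync$timestamps)
}

#' Centered mean absolute movement
#'
#' The scalar movement summary: the mean absolute deviation of the
#' relative-movement series, `x_hat = (1/n) sum_i |dx_i - mean(dx)|` (mm).
#' Invariant to constant offsets in the series and linear in its scale.
#'
#' @param series numeric relative-movement series, length >= 2.
#' @return `x_hat` in mm.
#' @export
centered_mean_abs <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2)
    vs_stop("need at least 2 synchronized measurements",
            "vibroscrew_input_error")
  mean(abs(series - mean(series)))
}

#' Loosening ratio and decision
#'
#' `R_lf = x_hat_loose / x_hat_fixed`; the screw is considered loose when
#' the ratio strictly exceeds the threshold (default 2, i.e. a more than
#' doubled relative movement).
#'
#' @param x_hat_loose,x_hat_fixed centered mean absolute movements (mm);
#'   `x_hat_fixed` must be positive.
#' @param threshold decision threshold on the ratio.
#' @param screw_id optional identifier carried into the result.
#' @return an object of class `loosening_assessment`: list with
#'   `x_hat_fixed`, `x_hat_loose`, `ratio`, `threshold`, `is_loose`.
#' @export
loosening_ratio <- function(x_hat_loose, x_hat_fixed, threshold = 2,
                            screw_id = NA_integer_) {
  if (!is.finite(x_hat_fixed) || x_hat_fixed <= 0)
    vs_stop("x_hat_fixed must be positive: ratio undefined",
            "vibroscrew_domain_error")
  if (!is.finite(x_hat_loose) || x_hat_loose < 0)
    vs_stop("x_hat_loose must be nonnegative", "vibroscrew_domain_error")
  ratio <- x_hat_loose / x_hat_fixed
  structure(list(screw_id = screw_id, x_hat_fixed = x_hat_fixed,
                 x_hat_loose = x_hat_loose, ratio = ratio,
                 threshold = threshold, is_loose = ratio > threshold),
            class = "loosening_assessment")
}

#' @export
print.loosening_assessment <- function(x, ...) {
  cat(sprintf(
    "<loosening_assessment> screw %s: x_hat fixed %.4f mm, loose %.4f mm, R_lf %.4f -> %s\n",
    x$screw_id, x$x_hat_fixed, x$x_hat_loose, x$ratio,
    if (x$is_loose) "LOOSE" else "not loose"))
  invisible(x)
}

#' Assess all screws from fixed and loose trajectory sets
#'
#' Runs the full validation pipeline per screw: synchronize the vertebra
#' and rod trajectories, compute the relative-movement series and its
#' centered mean absolute value per condition, and form the loose/fixed
#' ratio.
#'
#' @param fixed,loose named lists with elements `L2` and `rod1`, `rod2`,
#'   ... (one rod per screw), as produced by [simulate_trajectories()].
#' @param threshold decision threshold on the ratio.
#' @return a `data.frame` with columns
#'   `screw_id, x_hat_fixed, x_hat_loose, ratio, is_loose`.
#' @export
assess_screws <- function(fixed, loose, threshold = 2) {
  rod_names <- sort(grep("^rod", names(fixed), value = TRUE))
  if (length(rod_names) == 0)
    vs_stop("no rod trajectories found in the fixed set",
            "vibroscrew_input_error")
  rows <- lapply(seq_along(rod_names), function(i) {
    rn <- rod_names[i]
    for (cond in c("fixed", "loose")) {
      set <- if (cond == "fixed") fixed else loose
      if (is.null(set[[rn]]) || is.null(set$L2))
        vs_stop(sprintf("missing %s trajectories for screw %d (%s)",
                        cond, i, rn), "vibroscrew_input_error")
    }
    xf <- centered_mean_abs(relative_movement(fixed$L2, fixed[[rn]]))
    xl <- centered_mean_abs(relative_movement(loose$L2, loose[[rn]]))
    a <- loosening_ratio(xl, xf, threshold, screw_id = i)
    data.frame(screw_id = i, x_hat_fixed = a$x_hat_fixed,
               x_hat_loose = a$x_hat_loose, ratio = a$ratio,
               is_loose = a$is_loose)
  })
  do.call(rbind, rows)
}
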