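#' Reconstruct the achieved trajectory from tracking data
#'
#' Embeds the rotation-only tracker-to-robot calibration and composes per
#' timepoint: `A_R_T_H^j = [R_OT | 0] . OT_T_HS^j . HS_T_H`, giving the
#' achieved humerus pose in the robot frame (up to the superfluous common
#' translation, which the first-waypoint normalization removes).
#'
#' @param tracked `pose_trajectory` of the tracked rigid body (HS) in the
#'   optical-tracker frame.
#' @param R_OT 3x3 rotation, tracker frame in robot frame.
#' @param HS_T_H [rt()] hemisphere-to-humerus transform.
#' @return `pose_trajectory` of the humerus in the robot frame.
#' @export
achieved_from_tracking <- function(tracked, R_OT, HS_T_H) {
  emb <- rt(R_OT, c(0, 0, 0))
  tracked$poses <- lapply(tracked$poses, function(p)
    rt_compose(rt_compose(emb, p, validate = FALSE), HS_T_H, validate = FALSE))
  tracked$source_frame <- "R"
  tracked$body_frame <- "H"
  tracked
}

traj_channels <- function(traj) {
  cbind(pt_translations(traj), pt_rotvecs(traj, unwrap = TRUE))
}

#' Temporal alignment by cross-correlation
#'
#' Finds the integer sample offset maximizing the summed normalized
#' cross-correlation over the 3 position and 3 rotation-vector channels
#' simultaneously. Channels are z-scored before summation so meters and
#' radians contribute comparably; zero-variance channels are dropped; ties
#' break toward the smallest `|offset|`. Offsets are searched while the
#' overlap remains at least 50% of the shorter signal.
#'
#' @param desired,achieved `pose_trajectory` objects at the same rate.
#' @return integer offset: `achieved` lags `desired` by `offset` samples
#'   (positive when the achieved signal is delayed).
#' @export
temporal_align <- function(desired, achieved) {
  D <- traj_channels(desired)
  A <- traj_channels(achieved)
  keep <- apply(D, 2, stats::sd) > 1e-12 & apply(A, 2, stats::sd) > 1e-12
  if (!any(keep)) stop("alignment undefined: all channels have zero variance")
  D <- D[, keep, drop = FALSE]; A <- A[, keep, drop = FALSE]
  nmin <- min(nrow(D), nrow(A))
  max_off <- floor(nmin / 2)
  offsets <- -max_off:max_off
  score <- vapply(offsets, function(off) {
    iD <- seq_len(nrow(D)); iA <- iD + off
    ok <- iA >= 1 & iA <= nrow(A)
    if (sum(ok) < nmin / 2) return(-Inf)
    s <- 0
    for (c in seq_len(ncol(D))) {
      d <- D[ok, c]; a <- A[iA[ok], c]
      if (stats::sd(d) < 1e-12 || stats::sd(a) < 1e-12) next
      s <- s + stats::cor(d, a)
    }
    s
  }, numeric(1))
  best <- max(score)
  cand <- offsets[score >= best - 1e-12]
  cand[which.min(abs(cand))]
}

shift_overlap <- function(nd, na, offset) {
  iD <- seq_len(nd); iA <- iD + offset
  ok <- iA >= 1 & iA <= na
  list(d = iD[ok], a = iA[ok])
}

nmae_series <- function(desired, achieved, span_floor = 1e-12) {
  span <- diff(range(desired))
  if (span <= span_floor) return(c(nmae = NA_real_, span = span))
  c(nmae = mean(abs(achieved - desired)) / span * 100, span = span)
}

#' Span-normalized mean absolute error report
#'
#' Expresses desired and achieved kinematics along the anatomical axes of
#' the thorax in the initial frame of the trial (ML = thorax Z, AP = thorax
#' X, IS = thorax Y under the ISB thorax convention), then reports, per
#' kinematic variable and axis, the mean absolute error divided by the span
#' (max - min) of the desired signal, in percent. The magnitude row of each
#' variable uses the Euclidean-norm time series and the span of that
#' magnitude signal. Zero-span axes (possible for secondary axes of
#' near-planar motions) are reported as `NA` rather than divided by a
#' floor. No mean-centering is applied: only span normalization.
#'
#' @param desired,achieved `pose_trajectory` objects at the same rate,
#'   already temporally aligned (see [temporal_align()]) or alignable via
#'   `align = TRUE`.
#' @param thorax_pose [rt()] pose of the thorax in the trial's initial
#'   frame; its axes define ML/AP/IS.
#' @param cutoff Butterworth cutoff (Hz) for the differentiation of the
#'   achieved trajectory (default 8); `NULL` to skip filtering.
#' @param align run [temporal_align()] first (default TRUE)?
#' @param variables which variables to report.
#' @return object of class `comparison_report`: data frame with columns
#'   `variable`, `axis` (`ML`, `AP`, `IS`, `magnitude`), `nmae_pct`,
#'   `span`; attribute `offset` (samples).
#' @export
normalized_mae <- function(desired, achieved, thorax_pose,
                           cutoff = 8, align = TRUE,
                           variables = c("position", "orientation",
                                         "linear_velocity", "angular_velocity",
                                         "linear_acceleration",
                                         "angular_acceleration")) {
  offset <- if (align) temporal_align(desired, achieved) else 0L
  ov <- shift_overlap(length(desired$poses), length(achieved$poses), offset)
  desired <- pt_subset(desired, ov$d)
  achieved <- pt_subset(achieved, ov$a)
  desired <- normalize_to_first_waypoint(desired)
  achieved <- normalize_to_first_waypoint(achieved)
  dd <- derive_kinematics(desired, cutoff = cutoff)
  da <- derive_kinematics(achieved, cutoff = cutoff)
  Rth <- thorax_pose$R
  axes <- c("ML", "AP", "IS")
  axis_cols <- c(3, 1, 2)  # ISB thorax: X anterior, Y superior, Z lateral
  get_var <- function(k, which_var) {
    m <- switch(which_var, position = k$position, orientation = k$rotvec,
                linear_velocity = k$linear_velocity,
                angular_velocity = k$angular_velocity,
                linear_acceleration = k$linear_acceleration,
                angular_acceleration = k$angular_acceleration)
    m %*% Rth  # components along thorax axes
  }
  rows <- list()
  for (v in variables) {
    Dm <- get_var(dd, v); Am <- get_var(da, v)
    for (i in seq_along(axes)) {
      r <- nmae_series(Dm[, axis_cols[i]], Am[, axis_cols[i]])
      rows[[length(rows) + 1]] <- data.frame(variable = v, axis = axes[i],
                                             nmae_pct = r[["nmae"]],
                                             span = r[["span"]])
    }
    r <- nmae_series(sqrt(rowSums(Dm^2)), sqrt(rowSums(Am^2)))
    rows[[length(rows) + 1]] <- data.frame(variable = v, axis = "magnitude",
                                           nmae_pct = r[["nmae"]],
                                           span = r[["span"]])
  }
  rep <- do.call(rbind, rows)
  attr(rep, "offset") <- offset
  class(rep) <- c("comparison_report", "data.frame")
  rep
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison report: temporal offset %d samples>\n",
              attr(x, "offset")))
  print.data.frame(cbind(x[, c("variable", "axis")],
                         nmae_pct = round(x$nmae_pct, 2),
                         span = signif(x$span, 4)), row.names = FALSE)
  invisible(x)
}

#' Normalized error-at-peak
#'
#' `|desired(t*) - achieved(t*)| / span(desired) * 100` with `t*` the
#' timepoint of maximum `|desired|`: the load replication error at the
#' instant the maximum desired load occurs. Only span normalization is
#' applied (no mean-centering), so a common additive offset does change
#' the result.
#'
#' @param desired,achieved aligned equal-length numeric load series.
#' @return percent error at peak (NA when the desired span is zero).
#' @export
error_at_peak <- function(desired, achieved) {
  if (length(desired) != length(achieved)) stop("series must have equal length")
  span <- diff(range(desired))
  if (span <= 1e-12) return(NA_real_)
  k <- which.max(abs(desired))
  abs(desired[k] - achieved[k]) / span * 100
}
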