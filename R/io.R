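#' Read a labeled landmark CSV
#'
#' Schema: header `label,x_m,y_m,z_m`; one point per row. Rows whose label
#' starts with `head_` form the humeral-head surface cloud; rows labeled
#' `medial_epicondyle` and `lateral_epicondyle` are the elbow landmarks.
#'
#' @param file CSV path.
#' @return list with `head_surface_points` (matrix), `medial_epicondyle`,
#'   `lateral_epicondyle` (3-vectors), and `all` (the full data frame).
#' @export
read_landmarks <- function(file) {
  d <- utils::read.csv(file)
  need <- c("label", "x_m", "y_m", "z_m")
  if (!all(need %in% names(d))) stop("landmark file needs columns label,x_m,y_m,z_m")
  pick <- function(lab) {
    r <- d[d$label == lab, , drop = FALSE]
    if (nrow(r) != 1L) stop("expected exactly one row labeled ", lab)
    as.numeric(r[1, c("x_m", "y_m", "z_m")])
  }
  list(head_surface_points = as.matrix(d[grepl("^head_", d$label),
                                         c("x_m", "y_m", "z_m")]),
       medial_epicondyle = pick("medial_epicondyle"),
       lateral_epicondyle = pick("lateral_epicondyle"),
       all = d)
}

#' Read/write paired calibration transforms CSV
#'
#' Schema: header `kind,index,r11..r33,tx_m,ty_m,tz_m` with `kind` in
#' `robot` (controller end-effector pose) or `tracked` (tracker rigid-body
#' pose); rows with equal `index` are simultaneous.
#'
#' @param file CSV path.
#' @return [calibration_set()].
#' @export
read_calibration_csv <- function(file) {
  d <- utils::read.csv(file)
  rt_of_row <- function(r) {
    R <- matrix(as.numeric(r[c("r11", "r12", "r13", "r21", "r22", "r23",
                               "r31", "r32", "r33")]), 3, 3, byrow = TRUE)
    rt(orthonormalize(R, tol = 1e-6),
       as.numeric(r[c("tx_m", "ty_m", "tz_m")]), validate = FALSE)
  }
  idx <- sort(unique(d$index))
  rb <- lapply(idx, function(i) rt_of_row(d[d$kind == "robot" & d$index == i, ][1, ]))
  tk <- lapply(idx, function(i) rt_of_row(d[d$kind == "tracked" & d$index == i, ][1, ]))
  calibration_set(rb, tk)
}

#' @rdname read_calibration_csv
#' @param calib a [calibration_set()] to write.
#' @export
write_calibration_csv <- function(calib, file) {
  row_of <- function(kind, i, p)
    data.frame(kind = kind, index = i, t(as.numeric(t(p$R))), t(p$t))
  rows <- c(lapply(seq_along(calib$robot_poses), function(i)
              row_of("robot", i, calib$robot_poses[[i]])),
            lapply(seq_along(calib$tracked_poses), function(i)
              row_of("tracked", i, calib$tracked_poses[[i]])))
  d <- do.call(rbind, rows)
  names(d) <- c("kind", "index", "r11", "r12", "r13", "r21", "r22", "r23",
                "r31", "r32", "r33", "tx_m", "ty_m", "tz_m")
  utils::write.csv(format(d, digits = 15, trim = TRUE), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}
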