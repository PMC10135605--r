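# Frame-to-frame linking of localizations into trajectories, and
# conversion of trajectories into uniform-lag step-length traces.

#' Link localizations into trajectories
#'
#' Frame-by-frame assignment between open tracks and detections: all
#' candidate pairs within `search_range_um` are sorted by distance (ties
#' broken by lowest track id, then lowest detection index) and linked
#' greedily so that the closest compatible pairs are joined first.  Tracks
#' unseen for at most `memory` frames may resume their id; older tracks are
#' closed.  Unmatched detections open new tracks.
#'
#' @param localizations `data.frame` with `frame` (0-based integer), `x_um`,
#'   `y_um` (other columns are carried through).
#' @param search_range_um Maximum link displacement (um); default 0.8
#'   (5 pixels at 0.160 um).
#' @param memory Maximum number of consecutive missed frames (default 1).
#' @return Trajectory `data.frame`: `particle_id`, `frame`, `x_um`, `y_um`
#'   plus any extra input columns, sorted by particle then frame.
#' @export
link_trajectories <- function(localizations, search_range_um = 0.8,
                              memory = 1L) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(localizations)))
  loc <- localizations[order(localizations$frame, localizations$x_um,
                             localizations$y_um), , drop = FALSE]
  if (nrow(loc) == 0) {
    loc$particle_id <- integer(0)
    return(loc)
  }
  loc$particle_id <- NA_integer_
  frames <- sort(unique(loc$frame))
  # open track registry
  tr_id <- integer(0); tr_x <- numeric(0); tr_y <- numeric(0)
  tr_last <- integer(0)
  next_id <- 1L
  for (f in frames) {
    idx <- which(loc$frame == f)
    dx <- loc$x_um[idx]; dy <- loc$y_um[idx]
    open <- which(f - tr_last <= memory + 1L)
    assigned_det <- rep(FALSE, length(idx))
    assigned_tr <- rep(FALSE, length(open))
    if (length(open) && length(idx)) {
      dist <- sqrt(outer(tr_x[open], dx, "-")^2 +
                   outer(tr_y[open], dy, "-")^2)
      cand <- which(dist <= search_range_um, arr.ind = TRUE)
      if (nrow(cand)) {
        d <- dist[cand]
        ord <- order(d, tr_id[open][cand[, 1]], cand[, 2])
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (assigned_tr[i] || assigned_det[j]) next
          assigned_tr[i] <- TRUE; assigned_det[j] <- TRUE
          loc$particle_id[idx[j]] <- tr_id[open[i]]
          ti <- open[i]
          tr_x[ti] <- dx[j]; tr_y[ti] <- dy[j]; tr_last[ti] <- f
        }
      }
    }
    new_det <- which(!assigned_det)
    if (length(new_det)) {
      ids <- next_id + seq_along(new_det) - 1L
      loc$particle_id[idx[new_det]] <- ids
      tr_id <- c(tr_id, ids)
      tr_x <- c(tr_x, dx[new_det]); tr_y <- c(tr_y, dy[new_det])
      tr_last <- c(tr_last, rep(f, length(new_det)))
      next_id <- next_id + length(new_det)
    }
    # drop expired tracks from the registry to keep the scan small
    live <- f - tr_last <= memory
    tr_id <- tr_id[live]; tr_x <- tr_x[live]; tr_y <- tr_y[live]
    tr_last <- tr_last[live]
  }
  out <- loc[order(loc$particle_id, loc$frame), , drop = FALSE]
  rownames(out) <- NULL
  front <- c("particle_id", "frame", "x_um", "y_um")
  out[, c(front, setdiff(names(out), front)), drop = FALSE]
}

#' Keep trajectories with at least a minimum number of steps
#'
#' @param trajectories Trajectory `data.frame`.
#' @param min_steps Minimum number of steps (positions minus one); default 10.
#' @return Filtered `data.frame`; warns when nothing survives.
#' @export
filter_tracks <- function(trajectories, min_steps = 10L) {
  n <- table(trajectories$particle_id)
  keep <- names(n)[n >= min_steps + 1L]
  out <- trajectories[as.character(trajectories$particle_id) %in% keep, ,
                      drop = FALSE]
  if (nrow(out) == 0 && nrow(trajectories) > 0)
    warning("no trajectories with >= ", min_steps, " steps")
  message(length(keep), " of ", length(n), " trajectories kept (min_steps = ",
          min_steps, ")")
  rownames(out) <- NULL
  out
}

#' Convert trajectories to uniform-lag step-length traces
#'
#' Step lengths are Euclidean displacements between consecutive frames;
#' displacements spanning a gap (missed frames bridged by linking memory)
#' are excluded rather than rescaled, so every step has the same lag.
#'
#' @param trajectories Trajectory `data.frame` (one or many particles).
#' @param frame_interval Lag time t between frames (s).
#' @return List of step traces, each a list with `particle_id`, `r` (um),
#'   `t` (s) and `n_gaps` (number of excluded gap steps).  Single-point
#'   tracks yield an empty `r` and are flagged with `degenerate = TRUE`.
#' @export
to_steps <- function(trajectories, frame_interval = 0.081) {
  split_idx <- split(seq_len(nrow(trajectories)), trajectories$particle_id)
  traces <- lapply(split_idx, function(ii) {
    d <- trajectories[ii, , drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    if (nrow(d) < 2)
      return(list(particle_id = d$particle_id[1], r = numeric(0),
                  t = frame_interval, n_gaps = 0L, degenerate = TRUE))
    df <- diff(d$frame)
    r <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    list(particle_id = d$particle_id[1], r = r[df == 1L],
         t = frame_interval, n_gaps = sum(df != 1L), degenerate = FALSE)
  })
  names(traces) <- NULL
  traces
}
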