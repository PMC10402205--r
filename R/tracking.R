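#' Optimal bipartite assignment (Hungarian algorithm)
#'
#' Minimum-total-cost assignment of rows to columns of a rectangular cost
#' matrix, used to link microbubble detections between frames. O(n^3)
#' shortest-augmenting-path implementation with dual potentials.
#'
#' @param cost Numeric matrix (rows <= assigned one column each when
#'   rows <= cols; otherwise the transpose is solved).
#' @return Integer vector of length `nrow(cost)`: the column assigned to
#'   each row (NA if the matrix has fewer columns than rows and the row is
#'   left out).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); transposed <- TRUE; tmp <- n; n <- m; m <- tmp }
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)   # row assigned to column j
  way <- integer(m + 1) # predecessor column on the alternating path
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else if (j >= 1) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    while (j0 != 0L) {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
    }
  }
  ans <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  if (transposed) {
    out <- rep(NA_integer_, m)  # original rows = m
    for (r in seq_len(m)) {
      hit <- which(ans == r)
      out[r] <- if (length(hit)) hit else NA_integer_
    }
    return(out)
  }
  ans
}

#' Link microbubble localizations into tracks
#'
#' Frame-to-frame linking by optimal bipartite assignment on Euclidean
#' distance: active track heads are matched to the next frame's detections,
#' links longer than `max_link` (scaled by the gap length when closing gaps)
#' are forbidden, unmatched detections open new tracks, tracks unmatched for
#' more than `max_gap` frames are closed, and tracks shorter than
#' `min_length` frames are discarded. Per-step velocity is displacement
#' times the frame rate (divided by the frame gap when a gap was closed).
#'
#' @param localizations A localization tibble (columns `x`, `y`, `z`,
#'   `frame`, `intensity`, optionally `direction_channel`) or a list of
#'   per-frame tibbles (frames numbered by list position).
#' @param frame_rate Volumetric frame rate, Hz.
#' @param max_link Maximum link distance per frame step, mm (> 0).
#' @param max_gap Maximum number of missed frames bridged by gap closing.
#' @param min_length Minimum track length in frames.
#' @return A `track_set`: tibble of class `track_set` with columns
#'   `track_id`, `frame`, `x`, `y`, `z`, `intensity`, `vx`, `vy`, `vz`,
#'   `speed` (mm/s; NA on each track's first point), and attribute
#'   `frame_rate`.
#' @export
track_bubbles <- function(localizations, frame_rate, max_link = 0.1,
                          max_gap = 2, min_length = 5) {
  if (max_link <= 0) stop("max_link must be > 0", call. = FALSE)
  stopifnot(frame_rate > 0, max_gap >= 0, min_length >= 1)
  if (is.data.frame(localizations)) {
    loc <- localizations
  } else {
    loc <- dplyr::bind_rows(lapply(seq_along(localizations), function(i) {
      li <- localizations[[i]]
      if (nrow(li)) li$frame <- i
      li
    }))
  }
  if (!nrow(loc)) return(empty_track_set(frame_rate))
  stopifnot(all(c("x", "y", "z", "frame") %in% names(loc)))
  if (!"intensity" %in% names(loc)) loc$intensity <- NA_real_
  frames <- sort(unique(loc$frame))

  # active tracks: list of (points matrix rows: frame,x,y,z,intensity)
  active <- list()
  done <- list()
  for (fr in frames) {
    det <- loc[loc$frame == fr, , drop = FALSE]
    np <- nrow(det)
    # retire stale tracks
    if (length(active)) {
      stale <- vapply(active, function(tr)
        fr - tr$last_frame > max_gap + 1, logical(1))
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    na <- length(active)
    assigned_det <- rep(FALSE, np)
    if (na > 0 && np > 0) {
      heads <- t(vapply(active, function(tr) tr$last_pos, numeric(3)))
      gaps <- vapply(active, function(tr) fr - tr$last_frame, numeric(1))
      D <- outer(seq_len(na), seq_len(np), Vectorize(function(a, d)
        sqrt(sum((heads[a, ] - c(det$x[d], det$y[d], det$z[d]))^2))))
      lim <- max_link * gaps
      BIG <- 1e6
      C <- D
      C[D > matrix(lim, na, np)] <- BIG
      asg <- solve_assignment(C)
      for (a in seq_len(na)) {
        j <- asg[a]
        if (!is.na(j) && C[a, j] < BIG) {
          active[[a]]$points <- rbind(active[[a]]$points,
                                      c(fr, det$x[j], det$y[j], det$z[j],
                                        det$intensity[j]))
          active[[a]]$last_pos <- c(det$x[j], det$y[j], det$z[j])
          active[[a]]$last_frame <- fr
          assigned_det[j] <- TRUE
        }
      }
    }
    for (j in which(!assigned_det)) {
      active[[length(active) + 1L]] <- list(
        points = matrix(c(fr, det$x[j], det$y[j], det$z[j],
                          det$intensity[j]), 1, 5),
        last_pos = c(det$x[j], det$y[j], det$z[j]), last_frame = fr)
    }
  }
  done <- c(done, active)
  done <- Filter(function(tr) nrow(tr$points) >= min_length, done)
  if (!length(done)) return(empty_track_set(frame_rate))
  rows <- dplyr::bind_rows(lapply(seq_along(done), function(k) {
    pts <- done[[k]]$points
    dfr <- diff(pts[, 1])
    v <- apply(pts[, 2:4, drop = FALSE], 2, diff) /
      (dfr / frame_rate)
    if (nrow(pts) == 2) v <- matrix(v, 1, 3)
    tibble::tibble(track_id = k, frame = as.integer(pts[, 1]),
                   x = pts[, 2], y = pts[, 3], z = pts[, 4],
                   intensity = pts[, 5],
                   vx = c(NA, v[, 1]), vy = c(NA, v[, 2]),
                   vz = c(NA, v[, 3]),
                   speed = c(NA, sqrt(rowSums(v^2))))
  }))
  as_track_set(rows, frame_rate)
}

as_track_set <- function(tb, frame_rate) {
  attr(tb, "frame_rate") <- frame_rate
  class(tb) <- c("track_set", class(tb))
  tb
}

empty_track_set <- function(frame_rate) {
  as_track_set(tibble::tibble(track_id = integer(0), frame = integer(0),
                              x = numeric(0), y = numeric(0), z = numeric(0),
                              intensity = numeric(0), vx = numeric(0),
                              vy = numeric(0), vz = numeric(0),
                              speed = numeric(0)), frame_rate)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d points @ %.1f Hz\n",
              dplyr::n_distinct(x$track_id), nrow(x),
              attr(x, "frame_rate")))
  NextMethod()
}

#' Summarise tracks
#'
#' @param x A `track_set`.
#' @param ... Unused.
#' @return `tidy()`: one row per track with length, duration and mean speed.
#'   `glance()`: one row with track count, point count and overall mean
#'   speed.
#' @export
tidy.track_set <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$track_id),
                   n_points = dplyr::n(),
                   first_frame = min(.data$frame),
                   last_frame = max(.data$frame),
                   path_length_mm = sum(sqrt(diff(.data$x)^2 +
                                               diff(.data$y)^2 +
                                               diff(.data$z)^2)),
                   mean_speed_mms = mean(.data$speed, na.rm = TRUE),
                   .groups = "drop")
}

#' @rdname tidy.track_set
#' @export
glance.track_set <- function(x, ...) {
  tibble::tibble(n_tracks = dplyr::n_distinct(x$track_id),
                 n_points = nrow(x),
                 mean_speed_mms = mean(x$speed, na.rm = TRUE),
                 frame_rate = attr(x, "frame_rate"))
}

#' Render super-resolved density and velocity maps
#'
#' Accumulates track points, interpolated along each track's polyline at
#' sub-voxel steps, onto a grid refined `upsample`-fold relative to the
#' beamforming grid. Density counts track samples per super-voxel; velocity
#' is the density-weighted mean speed, NA where no track passes.
#'
#' @param tracks A `track_set`.
#' @param grid The beamforming `voxel_grid`.
#' @param upsample Integer refinement factor (>= 1; default 4).
#' @param speed_source `"step"` paints each polyline segment with its own
#'   instantaneous speed; `"track"` paints a whole track with its
#'   end-to-end displacement over duration, which suppresses the upward
#'   bias that localization jitter adds to step speeds.
#' @return List with `density` and `velocity`, both `ulm_volume`s on the
#'   refined grid.
#' @export
render_maps <- function(tracks, grid, upsample = 4,
                        speed_source = c("step", "track")) {
  speed_source <- match.arg(speed_source)
  stopifnot(inherits(grid, "voxel_grid"), upsample >= 1,
            upsample == round(upsample))
  fine_sp <- grid$spacing / upsample
  fine <- voxel_grid(grid$shape * as.integer(upsample), fine_sp,
                     origin = grid$origin - grid$spacing / 2 + fine_sp / 2)
  dens <- array(0, dim = fine$shape)
  vel <- array(0, dim = fine$shape)
  if (nrow(tracks)) {
    step <- min(fine_sp) / 2
    for (id in unique(tracks$track_id)) {
      tr <- tracks[tracks$track_id == id, , drop = FALSE]
      tr <- tr[order(tr$frame), , drop = FALSE]
      pts <- cbind(tr$x, tr$y, tr$z)
      spd <- tr$speed
      if (speed_source == "track" && nrow(pts) >= 2) {
        fr <- attr(tracks, "frame_rate")
        dur <- (tr$frame[nrow(tr)] - tr$frame[1]) / fr
        spd <- rep(sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)) / dur,
                   nrow(pts))
      }
      if (nrow(pts) == 1) {
        samp <- pts
        svals <- spd
      } else {
        samp_l <- list(); sv_l <- list()
        for (k in seq_len(nrow(pts) - 1)) {
          seg <- pts[k + 1, ] - pts[k, ]
          L <- sqrt(sum(seg^2))
          nsub <- max(1L, ceiling(L / step))
          tpar <- (seq_len(nsub) - 1) / nsub
          samp_l[[k]] <- cbind(pts[k, 1] + tpar * seg[1],
                               pts[k, 2] + tpar * seg[2],
                               pts[k, 3] + tpar * seg[3])
          sv_l[[k]] <- rep(spd[k + 1], nsub)  # speed of the step ending at k+1
        }
        samp <- rbind(do.call(rbind, samp_l), pts[nrow(pts), , drop = FALSE])
        svals <- c(unlist(sv_l), spd[nrow(pts)])
      }
      iv <- cbind(round((samp[, 1] - fine$origin[1]) / fine_sp[1]) + 1,
                  round((samp[, 2] - fine$origin[2]) / fine_sp[2]) + 1,
                  round((samp[, 3] - fine$origin[3]) / fine_sp[3]) + 1)
      ok <- iv[, 1] >= 1 & iv[, 1] <= fine$shape[1] &
        iv[, 2] >= 1 & iv[, 2] <= fine$shape[2] &
        iv[, 3] >= 1 & iv[, 3] <= fine$shape[3]
      iv <- iv[ok, , drop = FALSE]
      svals <- svals[ok]
      if (!nrow(iv)) next
      lin <- iv[, 1] + (iv[, 2] - 1) * fine$shape[1] +
        (iv[, 3] - 1) * fine$shape[1] * fine$shape[2]
      # deduplicate within-voxel repeats along the interpolated polyline
      first <- !duplicated(lin)
      lin <- lin[first]; svals <- svals[first]
      dens[lin] <- dens[lin] + 1
      sv <- svals; sv[is.na(sv)] <- 0
      vel[lin] <- vel[lin] + sv
    }
  }
  velocity <- vel / pmax(dens, 1)
  velocity[dens == 0] <- NA_real_
  list(density = ulm_volume(dens, fine, kind = "DENSITY"),
       velocity = ulm_volume(velocity, fine, kind = "VELOCITY"))
}
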