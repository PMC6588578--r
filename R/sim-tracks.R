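#' Configuration for the Brownian track simulator
#'
#' Bundles and validates all parameters of [simulate_tracks()]. Defaults match
#' the single-molecule tracking conditions of the S-layer experiments this
#' package targets: camera cadence 20 frames/s (50 ms frame interval), full
#' 50 ms exposure, per-axis 3D localization errors of 93/93/91 nm, and an
#' apparent surface diffusion coefficient of 0.077 um^2/s.
#'
#' @param diffusion_coefficient Diffusion coefficient D in um^2/s (>= 0).
#' @param frame_interval Camera frame interval in s.
#' @param exposure_time Exposure time tau_E in s; must be <= `frame_interval`.
#'   The reported position of each frame is the average molecule position over
#'   the exposure (motion blur).
#' @param n_substeps_per_exposure Number of Brownian sub-steps used to average
#'   the position within one exposure (>= 1); 10 sub-steps approximate
#'   continuous-exposure averaging closely.
#' @param localization_error_xyz Per-axis localization error (s1, s2, s3) in
#'   nm; recycled to the dimensionality.
#' @param n_tracks,n_frames_per_track Number of trajectories and frames each.
#' @param dimensionality 2 (in-plane tracking) or 3.
#' @param binding Optional list describing capture at nucleation seeds:
#'   `seed_positions` (matrix, nm, one row per seed), `capture_radius` (nm),
#'   `on_rate` (1/s; `Inf` for deterministic capture on contact), `off_rate`
#'   (1/s; 0 for irreversible binding). `NULL` disables binding.
#' @param start_positions Optional matrix (`n_tracks` x dimensionality, nm) of
#'   initial positions; by default tracks start uniformly in a box of
#'   half-width `start_halfwidth` around the origin.
#' @param start_halfwidth Half-width (nm) of the default start box.
#' @param rng_seed Integer seed; fixing it makes the simulation reproducible.
#'
#' @return A validated list of class `"track_sim_config"`.
#' @examples
#' cfg <- track_sim_config(n_tracks = 2, n_frames_per_track = 50)
#' @export
track_sim_config <- function(diffusion_coefficient = 0.077,
                             frame_interval = 0.05,
                             exposure_time = 0.05,
                             n_substeps_per_exposure = 10L,
                             localization_error_xyz = c(93, 93, 91),
                             n_tracks = 30L,
                             n_frames_per_track = 500L,
                             dimensionality = 3L,
                             binding = NULL,
                             start_positions = NULL,
                             start_halfwidth = 1000,
                             rng_seed = NULL) {
  check_scalar(diffusion_coefficient, "diffusion_coefficient", min = 0)
  check_scalar(frame_interval, "frame_interval", min = .Machine$double.eps)
  check_scalar(exposure_time, "exposure_time", min = 0)
  if (exposure_time > frame_interval) {
    stop("`exposure_time` must not exceed `frame_interval`", call. = FALSE)
  }
  check_scalar(n_substeps_per_exposure, "n_substeps_per_exposure", min = 1)
  check_scalar(n_tracks, "n_tracks", min = 1)
  check_scalar(n_frames_per_track, "n_frames_per_track", min = 1)
  if (!dimensionality %in% c(2L, 3L)) {
    stop("`dimensionality` must be 2 or 3", call. = FALSE)
  }
  if (any(!is.finite(localization_error_xyz)) ||
      any(localization_error_xyz < 0)) {
    stop("`localization_error_xyz` must be finite and >= 0", call. = FALSE)
  }
  loc_err <- rep_len(localization_error_xyz, dimensionality)
  if (!is.null(binding)) {
    if (is.null(binding$seed_positions) ||
        nrow(as.matrix(binding$seed_positions)) < 1L) {
      stop("`binding$seed_positions` must contain at least one seed",
           call. = FALSE)
    }
    binding$seed_positions <- as.matrix(binding$seed_positions)
    if (ncol(binding$seed_positions) != dimensionality) {
      stop("`binding$seed_positions` must have one column per dimension",
           call. = FALSE)
    }
    check_scalar(binding$capture_radius, "binding$capture_radius", min = 0)
    check_scalar(binding$on_rate, "binding$on_rate", min = 0, allow_inf = TRUE)
    check_scalar(binding$off_rate, "binding$off_rate", min = 0)
  }
  if (!is.null(start_positions)) {
    start_positions <- as.matrix(start_positions)
    if (nrow(start_positions) != n_tracks ||
        ncol(start_positions) != dimensionality) {
      stop("`start_positions` must be n_tracks x dimensionality", call. = FALSE)
    }
  }
  check_scalar(start_halfwidth, "start_halfwidth", min = 0)
  structure(
    list(
      diffusion_coefficient = diffusion_coefficient,
      frame_interval = frame_interval,
      exposure_time = exposure_time,
      n_substeps_per_exposure = as.integer(n_substeps_per_exposure),
      localization_error_xyz = loc_err,
      n_tracks = as.integer(n_tracks),
      n_frames_per_track = as.integer(n_frames_per_track),
      dimensionality = as.integer(dimensionality),
      binding = binding,
      start_positions = start_positions,
      start_halfwidth = start_halfwidth,
      rng_seed = rng_seed
    ),
    class = "track_sim_config"
  )
}

#' Simulate Brownian single-molecule tracks with binding, blur and noise
#'
#' Generates trajectories of molecules diffusing with coefficient D, optionally
#' captured at nucleation seeds (first-order binding within a capture radius;
#' bound molecules are immobile until release). The reported position of each
#' frame is the mean of `n_substeps_per_exposure` intra-exposure true positions
#' (camera motion blur) plus independent Gaussian localization error per axis.
#'
#' @param config A [track_sim_config()].
#'
#' @return A data.frame of class `"slk_tracks"` with columns `track_id`,
#'   `frame`, `t_s`, observed positions `x_nm`, `y_nm` (and `z_nm` in 3D),
#'   per-axis uncertainties `sx_nm`, `sy_nm` (`sz_nm`), ground-truth blur-free
#'   mean positions `true_x_nm`, ... and `true_state` (`"bound"`/`"free"`,
#'   the molecule's majority state within the exposure). The generating config
#'   is attached as attribute `"config"`.
#' @examples
#' trk <- simulate_tracks(track_sim_config(
#'   n_tracks = 2, n_frames_per_track = 20, rng_seed = 1))
#' head(trk)
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "track_sim_config"))
  with_seed(config$rng_seed, simulate_tracks_impl(config))
}

simulate_tracks_impl <- function(config) {
  d <- config$dimensionality
  nf <- config$n_frames_per_track
  nsub <- config$n_substeps_per_exposure
  D_nm2 <- config$diffusion_coefficient * 1e6 # um^2/s -> nm^2/s
  dt_exp <- if (config$exposure_time > 0) config$exposure_time / nsub else 0
  dt_dead <- config$frame_interval - config$exposure_time
  sd_exp <- sqrt(2 * D_nm2 * dt_exp)
  sd_dead <- sqrt(2 * D_nm2 * dt_dead)
  bind <- config$binding
  out <- vector("list", config$n_tracks)
  axis_names <- c("x", "y", "z")[seq_len(d)]

  for (tr in seq_len(config$n_tracks)) {
    pos <- if (!is.null(config$start_positions)) {
      config$start_positions[tr, ]
    } else {
      runif(d, -config$start_halfwidth, config$start_halfwidth)
    }
    if (is.null(bind)) {
      # free diffusion: build the whole sub-step chain at once
      sd_steps <- rep(c(rep(sd_exp, nsub), sd_dead), nf)
      n_steps <- length(sd_steps)
      inc <- matrix(rnorm(n_steps * d), n_steps, d) * sd_steps
      path <- matrix(pos, n_steps, d, byrow = TRUE) + apply(inc, 2, cumsum)
      # recorded sub-positions of frame f are steps (f-1)*(nsub+1) + 1..nsub
      sub_idx <- rep(seq_len(nf), each = nsub) # frame of each exposure step
      expo <- path[rep(seq(0, nf - 1L) * (nsub + 1L), each = nsub) +
                     seq_len(nsub), , drop = FALSE]
      mean_pos <- rowsum(expo, sub_idx, reorder = TRUE) / nsub
      state_frac <- numeric(nf)
      err <- matrix(rnorm(nf * d), nf, d) %*%
        diag(config$localization_error_xyz, d)
      obs <- mean_pos + err
      df <- data.frame(
        track_id = tr,
        frame = seq_len(nf),
        t_s = (seq_len(nf) - 1L) * config$frame_interval
      )
      for (i in seq_len(d)) df[[paste0(axis_names[i], "_nm")]] <- obs[, i]
      for (i in seq_len(d)) {
        df[[paste0("s", axis_names[i], "_nm")]] <-
          config$localization_error_xyz[i]
      }
      for (i in seq_len(d)) {
        df[[paste0("true_", axis_names[i], "_nm")]] <- mean_pos[, i]
      }
      df$true_state <- "free"
      out[[tr]] <- df
      next
    }
    bound <- FALSE
    mean_pos <- matrix(NA_real_, nf, d)
    state_frac <- numeric(nf)
    for (f in seq_len(nf)) {
      sub <- matrix(NA_real_, nsub, d)
      n_bound_sub <- 0L
      for (s in seq_len(nsub)) {
        step <- update_binding_state(pos, bound, bind, dt_exp)
        bound <- step$bound
        if (!bound && sd_exp > 0) pos <- pos + rnorm(d, 0, sd_exp)
        sub[s, ] <- pos
        if (bound) n_bound_sub <- n_bound_sub + 1L
      }
      mean_pos[f, ] <- colMeans(sub)
      state_frac[f] <- n_bound_sub / nsub
      if (dt_dead > 0) {
        step <- update_binding_state(pos, bound, bind, dt_dead)
        bound <- step$bound
        if (!bound && sd_dead > 0) pos <- pos + rnorm(d, 0, sd_dead)
      }
    }
    err <- matrix(rnorm(nf * d), nf, d) %*% diag(config$localization_error_xyz, d)
    obs <- mean_pos + err
    df <- data.frame(
      track_id = tr,
      frame = seq_len(nf),
      t_s = (seq_len(nf) - 1L) * config$frame_interval
    )
    for (i in seq_len(d)) df[[paste0(axis_names[i], "_nm")]] <- obs[, i]
    for (i in seq_len(d)) {
      df[[paste0("s", axis_names[i], "_nm")]] <- config$localization_error_xyz[i]
    }
    for (i in seq_len(d)) df[[paste0("true_", axis_names[i], "_nm")]] <- mean_pos[, i]
    df$true_state <- ifelse(state_frac >= 0.5, "bound", "free")
    out[[tr]] <- df
  }
  res <- do.call(rbind, out)
  attr(res, "config") <- config
  class(res) <- c("slk_tracks", "data.frame")
  res
}

# One binding-kinetics update over an interval dt: an unbound molecule within
# capture_radius of any seed binds with P = 1 - exp(-on_rate * dt) (P = 1 for
# on_rate = Inf); a bound molecule releases with P = 1 - exp(-off_rate * dt).
update_binding_state <- function(pos, bound, bind, dt) {
  if (is.null(bind)) return(list(bound = FALSE))
  if (bound) {
    p_off <- if (bind$off_rate == 0) 0 else 1 - exp(-bind$off_rate * dt)
    if (p_off > 0 && runif(1) < p_off) bound <- FALSE
  } else {
    d2 <- colSums((t(bind$seed_positions) - pos)^2)
    if (min(d2) <= bind$capture_radius^2) {
      p_on <- if (is.infinite(bind$on_rate)) 1 else 1 - exp(-bind$on_rate * dt)
      if (p_on >= 1 || runif(1) < p_on) bound <- TRUE
    }
  }
  list(bound = bound)
}

#' Split a track table into a list of single-track data.frames
#'
#' @param tracks A data.frame with a `track_id` column (e.g. from
#'   [simulate_tracks()] or [read_tracks_csv()]).
#' @return A named list of data.frames, one per track, in order of first
#'   appearance.
#' @export
split_tracks <- function(tracks) {
  stopifnot(is.data.frame(tracks), "track_id" %in% names(tracks))
  split(as.data.frame(tracks), factor(tracks$track_id,
                                      levels = unique(tracks$track_id)))
}
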