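#' Construct a single-cell intensity track
#'
#' An intensity track holds one cell's time-stamped two-channel fluorescence
#' readout: the JAK-STAT reporter dome-MESO-GFP (green, \eqn{G_t}) and the
#' differentiation reporter eater-dsRed (red, \eqn{R_t}), plus optional 3D
#' positions. Times are minutes from track start, computed from the frame
#' index and the acquisition interval (default 15 s per frame).
#'
#' @param cell_id identifier for the cell (coerced to character).
#' @param frames integer frame indices, strictly increasing; frame 0 is the
#'   first acquired frame.
#' @param green,red per-frame mean intensities (arbitrary units, >= 0).
#' @param frame_interval_s seconds between frames (default 15).
#' @param positions optional numeric matrix with columns x, y, z (micrometres),
#'   one row per frame, or NULL.
#' @param label optional ground-truth tag (used by the synthetic generator).
#' @return An object of class \code{"intensity_track"}: a list with fields
#'   \code{cell_id}, \code{frames}, \code{times_min}, \code{green},
#'   \code{red}, \code{positions}, \code{label}.
#' @export
intensity_track <- function(cell_id, frames, green, red,
                            frame_interval_s = 15,
                            positions = NULL, label = NULL) {
  frames <- as.integer(frames)
  green <- as.numeric(green)
  red <- as.numeric(red)
  tr <- structure(list(
    cell_id = as.character(cell_id)[1],
    frames = frames,
    times_min = frames * frame_interval_s / 60,
    green = green,
    red = red,
    positions = positions,
    label = if (is.null(label)) NULL else as.character(label)[1]
  ), class = "intensity_track")
  validate_track(tr)
  tr
}

#' Validate an intensity track's invariants
#'
#' Checks strictly increasing times, equal series lengths (>= 2), and
#' non-negative finite intensities. Called by the constructor and by readers.
#'
#' @param tr an \code{intensity_track}.
#' @return \code{tr}, invisibly. Errors on violation.
#' @export
validate_track <- function(tr) {
  n <- length(tr$times_min)
  if (n < 2L)
    stop("track '", tr$cell_id, "': needs at least 2 frames, got ", n)
  if (length(tr$green) != n || length(tr$red) != n || length(tr$frames) != n)
    stop("track '", tr$cell_id, "': frames/times/green/red lengths differ")
  if (any(diff(tr$times_min) <= 0))
    stop("track '", tr$cell_id, "': times must be strictly increasing")
  if (any(!is.finite(tr$green)) || any(!is.finite(tr$red)))
    stop("track '", tr$cell_id, "': intensities must be finite")
  if (any(tr$green < 0) || any(tr$red < 0))
    stop("track '", tr$cell_id, "': intensities must be >= 0")
  if (!is.null(tr$positions)) {
    if (!is.matrix(tr$positions) || nrow(tr$positions) != n ||
        ncol(tr$positions) != 3L)
      stop("track '", tr$cell_id, "': positions must be an n x 3 matrix")
  }
  invisible(tr)
}

#' @export
print.intensity_track <- function(x, ...) {
  cat("<intensity_track> cell", x$cell_id, "-", length(x$frames), "frames,",
      sprintf("%.1f", max(x$times_min)), "min",
      if (!is.null(x$label)) paste0("[", x$label, "]") else "", "\n")
  invisible(x)
}

# column sets for the two supported CSV dialects
.generic_cols <- c("cell_id", "frame", "green", "red")
.spot_cols <- c("TRACK_ID", "FRAME", "MEAN_INTENSITY_CH1", "MEAN_INTENSITY_CH2")

#' Read single-cell tracks from CSV
#'
#' Two dialects are supported: \code{"generic"} (columns \code{cell_id},
#' \code{frame}, \code{green}, \code{red}, optional \code{x_um}, \code{y_um},
#' \code{z_um}, \code{label}) and \code{"spotexport"}, the tracking-software
#' spot-export table (\code{TRACK_ID}, \code{FRAME}, \code{POSITION_X/Y/Z},
#' \code{MEAN_INTENSITY_CH1} mapped to green, \code{CH2} to red). Rows may
#' arrive in any order; frames are sorted per track and times recomputed as
#' \code{frame * frame_interval_s / 60}.
#'
#' @param path CSV file path.
#' @param dialect \code{"generic"} or \code{"spotexport"}.
#' @param frame_interval_s seconds between frames (default 15).
#' @return list of \code{intensity_track}, ordered by first appearance of the
#'   track id; empty list for a header-only file.
#' @export
read_tracks <- function(path, dialect = c("generic", "spotexport"),
                        frame_interval_s = 15) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- if (dialect == "generic") .generic_cols else .spot_cols
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " for dialect '", dialect, "'")
  if (nrow(df) == 0L) return(list())
  if (dialect == "spotexport") {
    df2 <- data.frame(
      cell_id = df$TRACK_ID, frame = df$FRAME,
      green = df$MEAN_INTENSITY_CH1, red = df$MEAN_INTENSITY_CH2,
      stringsAsFactors = FALSE)
    for (p in c("X", "Y", "Z")) {
      col <- paste0("POSITION_", p)
      if (col %in% names(df)) df2[[tolower(paste0(p, "_um"))]] <- df[[col]]
    }
    df <- df2
  }
  ids <- unique(as.character(df$cell_id))
  lapply(ids, function(id) {
    rows <- df[as.character(df$cell_id) == id, , drop = FALSE]
    ord <- order(rows$frame)
    rows <- rows[ord, , drop = FALSE]
    if (anyDuplicated(rows$frame))
      stop("data error: duplicate frames in track '", id, "'")
    pos <- NULL
    if (all(c("x_um", "y_um", "z_um") %in% names(rows)) &&
        !all(is.na(rows$x_um))) {
      pos <- cbind(x = rows$x_um, y = rows$y_um, z = rows$z_um)
    }
    lab <- if ("label" %in% names(rows) && !is.na(rows$label[1]) &&
               nzchar(rows$label[1])) rows$label[1] else NULL
    intensity_track(id, rows$frame, rows$green, rows$red,
                    frame_interval_s = frame_interval_s,
                    positions = pos, label = lab)
  })
}

#' Write tracks to a generic-dialect CSV
#'
#' The output is parseable by \code{read_tracks(dialect = "generic")} and
#' round-trips all fields. Columns: cell_id, frame, time_min, x_um, y_um,
#' z_um, green, red, label.
#'
#' @param tracks list of \code{intensity_track}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  header <- c("cell_id", "frame", "time_min", "x_um", "y_um", "z_um",
              "green", "red", "label")
  rows <- lapply(tracks, function(tr) {
    validate_track(tr)
    n <- length(tr$frames)
    pos <- if (is.null(tr$positions)) matrix(NA_real_, n, 3) else tr$positions
    data.frame(cell_id = tr$cell_id, frame = tr$frames,
               time_min = tr$times_min,
               x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
               green = tr$green, red = tr$red,
               label = if (is.null(tr$label)) "" else tr$label,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), length(header)), header))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a lymph-gland geometry
#'
#' The geometry anchors the cylindrical organ frame: a point and unit
#' direction for the heart-tube axis, the posterior end of the gland on the
#' tube (where the PSC, the niche, sits), the dorsal-ventral unit axis
#' (z), and the primary-lobe boundary as a closed planar polygon.
#'
#' @param tube_point numeric length-3 point on the heart-tube axis (um).
#' @param tube_dir numeric length-3 direction of the heart-tube axis
#'   (normalized internally).
#' @param posterior_end numeric length-3 position of the posterior end (um).
#' @param z_dir numeric length-3 dorsal-ventral direction (normalized).
#' @param lobe_boundary numeric matrix (>= 3 rows, 2 cols) of polygon
#'   vertices (um), simple (non-self-intersecting).
#' @return object of class \code{"lg_geometry"}.
#' @export
lg_geometry <- function(tube_point, tube_dir, posterior_end, z_dir,
                        lobe_boundary) {
  unit <- function(v, what) {
    v <- as.numeric(v)
    if (length(v) != 3L) stop(what, " must have length 3")
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop(what, " must be non-zero")
    v / nv
  }
  lobe_boundary <- as.matrix(lobe_boundary)
  if (nrow(lobe_boundary) < 3L || ncol(lobe_boundary) != 2L)
    stop("lobe_boundary must be an n x 2 matrix with n >= 3")
  geom <- structure(list(
    tube_point = as.numeric(tube_point),
    tube_dir = unit(tube_dir, "tube_dir"),
    posterior_end = as.numeric(posterior_end),
    z_dir = unit(z_dir, "z_dir"),
    lobe_boundary = lobe_boundary
  ), class = "lg_geometry")
  geom
}

#' Read geometry from flat JSON
#' @param path JSON file with fields tube_point, tube_dir, posterior_end,
#'   z_dir, lobe_boundary (list of [x, y] pairs).
#' @return \code{lg_geometry}
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lg_geometry(j$tube_point, j$tube_dir, j$posterior_end, j$z_dir,
              matrix(unlist(j$lobe_boundary), ncol = 2, byrow = !is.matrix(j$lobe_boundary)))
}

#' Write geometry to flat JSON
#' @param geom \code{lg_geometry}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_geometry <- function(geom, path) {
  jsonlite::write_json(list(
    tube_point = geom$tube_point, tube_dir = geom$tube_dir,
    posterior_end = geom$posterior_end, z_dir = geom$z_dir,
    lobe_boundary = unname(apply(geom$lobe_boundary, 1, function(r) r,
                                 simplify = FALSE))
  ), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

# defaults mirror the study's stated values: 15 s frames, 40-frame mitosis
# onset offset, 5x5 heat-map grid, 45 deg rho/z cone, TrackMate-style blob
# diameter 13 px; the quality threshold is on this package's unit-normalized
# LoG scale (matched ideal blob of unit peak scores 1), not TrackMate's.
.config_defaults <- list(
  frame_interval_s = 15,
  onset_offset_frames = 40,
  grid_n = 5,
  rho_z_angle_threshold_deg = 45,
  aicc_margin = 2,
  fast_phase_quantiles = c(0.1, 0.9),
  ratio_floor = 0.01,
  smoothing_window = 0,
  blob_diameter_px = 13,
  blob_quality_threshold = 0.2,
  histo_sample_size = 2500,
  g_threshold = NA_real_,
  r_threshold = NA_real_,
  noise_cv = 0.1,
  seed = 0
)

#' Build a run configuration
#'
#' Unspecified settings take documented defaults (e.g. 15 s frame interval,
#' 40-frame mitosis onset offset, 5x5 grid, 45 degree rho/z threshold).
#' \code{g_threshold}/\code{r_threshold} default to NA, meaning Otsu
#' thresholds are derived from the data at gating time.
#'
#' @param ... named settings overriding the defaults.
#' @return object of class \code{"lg_config"} (a named list).
#' @export
lg_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.config_defaults))
  if (length(unknown))
    stop("config error: unknown key(s) ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.config_defaults, over)
  chk_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || any(!is.na(v) & v <= 0))
      stop("config error: '", key, "' must be positive")
  }
  for (key in c("frame_interval_s", "grid_n", "rho_z_angle_threshold_deg",
                "aicc_margin", "ratio_floor", "blob_diameter_px",
                "blob_quality_threshold", "histo_sample_size"))
    chk_pos(key)
  if (cfg$onset_offset_frames < 0)
    stop("config error: 'onset_offset_frames' must be >= 0")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed) ||
      cfg$seed < 0 || cfg$seed != floor(cfg$seed))
    stop("config error: 'seed' must be a non-negative integer")
  q <- cfg$fast_phase_quantiles
  if (length(q) != 2 || any(q <= 0) || any(q >= 1) || q[1] >= q[2])
    stop("config error: 'fast_phase_quantiles' must be 0 < q1 < q2 < 1")
  structure(cfg, class = "lg_config")
}

#' Load a run configuration from a YAML/JSON key-value file
#'
#' Unspecified keys take the defaults of \code{\link{lg_config}}; unknown
#' keys and out-of-range values raise a config error naming the key.
#'
#' @param path file path (YAML; JSON is valid YAML).
#' @return \code{lg_config}
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  do.call(lg_config, doc)
}
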