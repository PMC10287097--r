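.ply_type_info <- function(type) {
  switch(type,
         float = , float32 = list(what = "numeric", size = 4L),
         double = , float64 = list(what = "numeric", size = 8L),
         int = , int32 = list(what = "integer", size = 4L),
         uint = , uint32 = list(what = "integer", size = 4L),
         short = , int16 = list(what = "integer", size = 2L),
         ushort = , uint16 = list(what = "integer", size = 2L),
         char = , int8 = list(what = "integer", size = 1L),
         uchar = , uint8 = list(what = "integer", size = 1L),
         stop("read_ply: unsupported property type '", type, "'"))
}

#' Read a PLY point cloud
#'
#' Supports ASCII and binary little-endian PLY with float/double vertex
#' properties `x`, `y`, `z` (mm) and an optional integer `grid_index`
#' property carrying the depth-image raster ordering. Other vertex
#' properties are skipped.
#'
#' @param path file path.
#' @return A [point_cloud()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  offset <- 0L
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      stop(sprintf("read_ply: unexpected end of header at byte offset %d",
                   offset))
    offset <- offset + nchar(line, type = "bytes") + 1L
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 1000)
      stop(sprintf("read_ply: runaway header at byte offset %d", offset))
  }
  if (header[1] != "ply")
    stop("read_ply: malformed header at byte offset 0 (missing 'ply' magic)")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1)
    stop(sprintf("read_ply: missing format line (header ends at byte %d)",
                 offset))
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("read_ply: unsupported format '", fmt, "'")
  # vertex element and its properties (assumed first/only element we need)
  el <- grep("^element ", header)
  vx <- el[grepl("^element vertex ", header[el])]
  if (length(vx) != 1)
    stop(sprintf("read_ply: no vertex element (header ends at byte %d)",
                 offset))
  nvert <- as.integer(strsplit(header[vx], "\\s+")[[1]][3])
  stop_at <- c(el[el > vx], length(header))[1]
  props <- header[(vx + 1):(stop_at - 1)]
  props <- props[grepl("^property ", props)]
  parts <- strsplit(props, "\\s+")
  ptype <- vapply(parts, `[`, "", 2)
  pname <- vapply(parts, `[`, "", 3)
  for (axis in c("x", "y", "z"))
    if (!axis %in% pname)
      stop("read_ply: missing vertex property '", axis, "'")
  if (fmt == "ascii") {
    body <- readLines(con, n = nvert)
    if (length(body) < nvert)
      stop(sprintf("read_ply: truncated body at byte offset %d", offset))
    tab <- read.table(text = body, col.names = pname,
                      colClasses = "numeric")
    pts <- as.matrix(tab[, c("x", "y", "z")])
    gi <- if ("grid_index" %in% pname) as.integer(tab$grid_index) else NULL
  } else {
    info <- lapply(ptype, .ply_type_info)
    sizes <- vapply(info, function(i) i$size, integer(1))
    rowsize <- sum(sizes)
    raw <- readBin(con, "raw", n = rowsize * nvert)
    if (length(raw) < rowsize * nvert)
      stop(sprintf("read_ply: truncated body at byte offset %d",
                   offset + length(raw)))
    bytes <- matrix(raw, nrow = rowsize)
    starts <- cumsum(c(0L, sizes))
    read_prop <- function(j) {
      sel <- (starts[j] + 1L):starts[j + 1L]
      readBin(as.vector(bytes[sel, , drop = FALSE]), info[[j]]$what,
              n = nvert, size = sizes[j], endian = "little",
              signed = !(ptype[j] %in% c("uchar", "uint8", "ushort",
                                         "uint16")))
    }
    cols <- lapply(seq_along(pname), read_prop)
    names(cols) <- pname
    pts <- cbind(x = as.numeric(cols$x), y = as.numeric(cols$y),
                 z = as.numeric(cols$z))
    gi <- if ("grid_index" %in% pname) as.integer(cols$grid_index) else NULL
  }
  point_cloud(pts, grid_index = gi)
}

#' Write a PLY point cloud
#'
#' @param cloud A [point_cloud()].
#' @param path output path.
#' @param format `"binary_little_endian"` (default, lossless float32) or
#'   `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path,
                      format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  has_gi <- !is.null(cloud$grid_index)
  n <- nrow(cloud$points)
  header <- c("ply", paste("format", format, "1.0"),
              paste("element vertex", n),
              "property float x", "property float y", "property float z",
              if (has_gi) "property int grid_index",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    d <- cbind(format(cloud$points[, 1], digits = 9),
               format(cloud$points[, 2], digits = 9),
               format(cloud$points[, 3], digits = 9))
    if (has_gi) d <- cbind(d, cloud$grid_index)
    writeLines(apply(d, 1, paste, collapse = " "), con, sep = "\n")
  } else {
    fraw <- writeBin(as.numeric(t(cloud$points)), raw(), size = 4,
                     endian = "little")
    if (has_gi) {
      iraw <- writeBin(as.integer(cloud$grid_index), raw(), size = 4,
                       endian = "little")
      rows <- rbind(matrix(fraw, nrow = 12L), matrix(iraw, nrow = 4L))
      writeBin(as.vector(rows), con)
    } else {
      writeBin(fraw, con)
    }
  }
  invisible(path)
}

#' Read/write whitespace XYZ point clouds
#'
#' @param path file path.
#' @return `read_xyz` returns a [point_cloud()].
#' @export
read_xyz <- function(path) {
  tab <- read.table(path, col.names = c("x", "y", "z"))
  point_cloud(as.matrix(tab))
}

#' @rdname read_xyz
#' @param cloud A [point_cloud()].
#' @export
write_xyz <- function(cloud, path) {
  write.table(cloud$points, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write motion-trace CSV
#'
#' Comma-separated with header
#' `timestamp_s,tx_mm,ty_mm,tz_mm,qw,qx,qy,qz,valid`, quaternions scalar
#' first, one row per sample; `#` comment lines carry the space label and
#' reference note. Invalid samples have `valid = 0` and empty pose fields.
#'
#' @param path file path.
#' @return `read_trace` returns a [motion_trace()].
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  com <- lines[startsWith(lines, "#")]
  space <- sub("^# space:\\s*", "", grep("^# space:", com, value = TRUE))
  note <- sub("^# note:\\s*", "", grep("^# note:", com, value = TRUE))
  tab <- read.csv(text = lines[!startsWith(lines, "#")])
  valid <- tab$valid == 1
  motion_trace(tab$timestamp_s,
               as.matrix(tab[, c("tx_mm", "ty_mm", "tz_mm")]),
               as.matrix(tab[, c("qw", "qx", "qy", "qz")]),
               valid = valid,
               space = if (length(space)) space else "camera",
               note = if (length(note)) note else "")
}

#' @rdname read_trace
#' @param trace A [motion_trace()].
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# space: ", trace$space),
               paste0("# note: ", trace$note),
               "timestamp_s,tx_mm,ty_mm,tz_mm,qw,qx,qy,qz,valid"), con)
  d <- cbind(trace$time, trace$translation, trace$quaternion,
             as.integer(trace$valid))
  rows <- apply(d, 1, function(r)
    paste(c(format(r[1:8], digits = 17), r[9]), collapse = ","))
  writeLines(gsub(" ", "", rows), con)
  invisible(path)
}

# Euler decomposition for the .par dialect: R = Rx(rx) Ry(ry) Rz(rz)
.euler_xyz_from_rotation <- function(R) {
  ry <- asin(min(1, max(-1, R[1, 3])))
  rx <- atan2(-R[2, 3], R[3, 3])
  rz <- atan2(-R[1, 2], R[1, 1])
  c(rx, ry, rz)
}

.rotation_from_euler_xyz <- function(a) {
  rt_compose(rt_rotate(a[1], c(1, 0, 0)),
             rt_compose(rt_rotate(a[2], c(0, 1, 0)),
                        rt_rotate(a[3], c(0, 0, 1))))$rotation
}

#' Read/write fMRI realignment parameter files
#'
#' Six whitespace-separated columns per frame — three rotations in radians
#' (about x, y, z; composed as `Rx Ry Rz`) followed by three translations
#' in mm — the dialect written by common fMRI realignment tools. Frame
#' timestamps are placed at frame midpoints:
#' `t0 + (frame - 1/2) * frame_duration`.
#'
#' @param path file path.
#' @param frame_duration frame length in seconds (default 0.53).
#' @param t0 start time of the first frame (s).
#' @return `read_par` returns a [motion_trace()].
#' @export
read_par <- function(path, frame_duration = 0.53, t0 = 0) {
  tab <- as.matrix(read.table(path))
  if (ncol(tab) != 6) stop("read_par: expected 6 columns")
  n <- nrow(tab)
  q <- t(apply(tab[, 1:3, drop = FALSE], 1,
               function(a) quat_from_rotation(.rotation_from_euler_xyz(a))))
  motion_trace(t0 + (seq_len(n) - 0.5) * frame_duration,
               tab[, 4:6, drop = FALSE], q,
               valid = TRUE, space = "fmri", note = basename(path))
}

#' @rdname read_par
#' @param trace A [motion_trace()] (all samples must be valid).
#' @export
write_par <- function(trace, path) {
  stopifnot(all(trace$valid))
  ang <- t(vapply(seq_along(trace$time), function(i)
    .euler_xyz_from_rotation(rotation_from_quat(trace$quaternion[i, ])),
    numeric(3)))
  write.table(format(cbind(ang, trace$translation), digits = 17),
              path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write respiration CSV
#'
#' Either two columns `timestamp_s,value`, or the constant-rate variant
#' with a `# rate_hz: <r>` comment followed by a single `value` column
#' (timestamps then start at 0).
#'
#' @param path file path.
#' @return `read_respiration` returns a [respiration_signal()].
#' @export
read_respiration <- function(path) {
  lines <- readLines(path)
  rate_line <- grep("^# rate_hz:", lines, value = TRUE)
  tab <- read.csv(text = lines[!startsWith(lines, "#")])
  if (length(rate_line)) {
    rate <- as.numeric(sub("^# rate_hz:\\s*", "", rate_line[1]))
    respiration_signal((seq_len(nrow(tab)) - 1) / rate, tab$value)
  } else {
    respiration_signal(tab$timestamp_s, tab$value)
  }
}

#' @rdname read_respiration
#' @param resp A [respiration_signal()].
#' @export
write_respiration <- function(resp, path) {
  d <- data.frame(timestamp_s = resp$time, value = resp$values)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write sequence-interval CSV
#'
#' Columns `sequence,start_s,end_s`.
#'
#' @param path file path.
#' @return `read_sequence_table` returns a [sequence_table()].
#' @export
read_sequence_table <- function(path) {
  tab <- read.csv(path)
  sequence_table(tab$sequence, tab$start_s, tab$end_s)
}

#' @rdname read_sequence_table
#' @param table A [sequence_table()].
#' @export
write_sequence_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a scenario configuration as JSON
#'
#' @param path file path.
#' @return `read_scenario` returns a [scenario_config()].
#' @export
read_scenario <- function(path) {
  do.call(scenario_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_scenario
#' @param config A [scenario_config()].
#' @export
write_scenario <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a complete synthetic fixture set
#'
#' Generates and writes everything the pipeline consumes: the reference
#' cloud (`reference.ply`), per-frame clouds (`frames/frame_NNNN.ply`) with
#' a sidecar `timestamps.txt`, the ground-truth trace (`truth_trace.csv`),
#' the respiration channel (`respiration.csv`), an fMRI-like comparison
#' trace (`fmri.par`), and the scenario itself (`scenario.json`).
#'
#' @param config A [scenario_config()].
#' @param dir output directory (created if needed).
#' @param ascii_ply write ASCII instead of binary PLY.
#' @return Named list of the generated objects, invisibly.
#' @export
simulate_scenario <- function(config, dir, ascii_ply = FALSE) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  fmt <- if (ascii_ply) "ascii" else "binary_little_endian"
  ref <- make_face_cloud(config)
  truth <- make_truth_trace(config)
  frames <- render_frames(ref, truth, config)
  resp <- make_respiration(truth, config)
  fmri <- make_fmri_like_trace(truth)
  write_ply(ref, file.path(dir, "reference.ply"), format = fmt)
  for (k in seq_along(frames))
    write_ply(frames[[k]],
              file.path(dir, "frames", sprintf("frame_%04d.ply", k)),
              format = fmt)
  writeLines(format(truth$times, digits = 17),
             file.path(dir, "frames", "timestamps.txt"))
  write_trace(truth$trace, file.path(dir, "truth_trace.csv"))
  write_respiration(resp, file.path(dir, "respiration.csv"))
  write_par(fmri, file.path(dir, "fmri.par"))
  write_scenario(config, file.path(dir, "scenario.json"))
  invisible(list(reference = ref, truth = truth, frames = frames,
                 respiration = resp, fmri = fmri))
}

#' Load a frames directory written by [simulate_scenario()]
#'
#' @param dir directory containing `frame_NNNN.ply` files and
#'   `timestamps.txt`.
#' @return List of [point_cloud()] frames with timestamps attached.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_.*\\.ply$",
                           full.names = TRUE))
  times <- as.numeric(readLines(file.path(dir, "timestamps.txt")))
  if (length(files) != length(times))
    stop("read_frames: frame/timestamp count mismatch")
  lapply(seq_along(files), function(k) {
    f <- read_ply(files[k]); f$timestamp <- times[k]; f
  })
}
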