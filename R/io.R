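# Trajectory and report output: extended XYZ, LAMMPS text dumps, CSV/JSON
# reports, run manifests.

.species_names <- function(codes) names(.SPECIES)[codes]

#' Write frames as extended XYZ
#'
#' One block per frame: particle count, a comment line with the step and box,
#' then rows `species x y z nx ny nz`.
#'
#' @param frames a `particle_system`, or a list of frames from
#'   [run_dynamics()]
#' @param path output file
#' @param species species codes (taken from the system when `frames` is one)
#' @return invisibly, the path
#' @export
write_xyz <- function(frames, path, species = NULL) {
  if (inherits(frames, "particle_system")) {
    species <- frames$species
    frames <- list(.system_frame(frames))
  }
  if (!length(frames)) stop("write_xyz: no frames", call. = FALSE)
  if (is.null(species)) stop("write_xyz: species required", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$pos)
    writeLines(as.character(n), con)
    writeLines(sprintf("step=%g box=%.8g,%.8g", fr$step, fr$box[1],
                       fr$box[2]), con)
    rows <- sprintf("%s %.8g %.8g %.8g %.8g %.8g %.8g",
                    .species_names(species), fr$pos[, 1], fr$pos[, 2],
                    fr$pos[, 3], fr$ornt[, 1], fr$ornt[, 2], fr$ornt[, 3])
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' @param path file written by [write_xyz()]
#' @return list of frames, each with `step`, `box`, `pos`, `ornt`,
#'   `species`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    step <- as.numeric(sub(".*step=([-0-9.e+]+).*", "\\1", hdr))
    box <- as.numeric(strsplit(sub(".*box=", "", hdr), ",")[[1]])
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(body, " +")
    species <- vapply(parts, `[[`, character(1), 1L)
    num <- t(vapply(parts, function(x) as.numeric(x[2:7]), numeric(6)))
    frames[[length(frames) + 1L]] <-
      list(step = step, box = box, pos = num[, 1:3, drop = FALSE],
           ornt = num[, 4:6, drop = FALSE],
           species = unname(.SPECIES[species]))
    i <- i + 2L + n
  }
  frames
}

#' Write frames as a LAMMPS text dump
#'
#' Standard `ITEM: TIMESTEP / NUMBER OF ATOMS / BOX BOUNDS / ATOMS id type
#' x y z` layout readable by common visualisers.
#'
#' @inheritParams write_xyz
#' @param z_bounds open-direction bounds written to the dump
#' @return invisibly, the path
#' @export
write_lammps_dump <- function(frames, path, species = NULL,
                              z_bounds = c(-50, 50)) {
  if (inherits(frames, "particle_system")) {
    species <- frames$species
    frames <- list(.system_frame(frames))
  }
  if (!length(frames)) stop("write_lammps_dump: no frames", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$pos)
    writeLines(c("ITEM: TIMESTEP", sprintf("%d", as.integer(fr$step)),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp ff",
                 sprintf("0 %.8g", fr$box[1]),
                 sprintf("0 %.8g", fr$box[2]),
                 sprintf("%.8g %.8g", z_bounds[1], z_bounds[2]),
                 "ITEM: ATOMS id type x y z"), con)
    writeLines(sprintf("%d %d %.8g %.8g %.8g", seq_len(n), species,
                       fr$pos[, 1], fr$pos[, 2], fr$pos[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS text dump written by [write_lammps_dump()]
#'
#' @param path dump file
#' @return list of frames with `step`, `box`, `pos`, `species`
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    stopifnot(lines[i] == "ITEM: TIMESTEP")
    step <- as.numeric(lines[i + 1L])
    n <- as.integer(lines[i + 3L])
    bx <- as.numeric(strsplit(lines[i + 5L], " ")[[1]])
    by <- as.numeric(strsplit(lines[i + 6L], " ")[[1]])
    body <- lines[(i + 9L):(i + 8L + n)]
    num <- t(vapply(strsplit(body, " +"), as.numeric, numeric(5)))
    ord <- order(num[, 1])
    frames[[length(frames) + 1L]] <-
      list(step = step, box = c(bx[2] - bx[1], by[2] - by[1]),
           pos = num[ord, 3:5, drop = FALSE],
           species = as.integer(num[ord, 2]))
    i <- i + 9L + n
  }
  frames
}

#' Write a JSON deformation/run report
#'
#' @param report a `deformation_report` or plain list
#' @param path output path
#' @return invisibly, the path
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write an observable series as CSV
#'
#' @param series a data.frame (one row per recorded frame or run)
#' @param path output path
#' @return invisibly, the path
#' @export
write_series <- function(series, path) {
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Write the run manifest
#'
#' A self-describing record of a finished run: configuration snapshot,
#' package version, seed, step range and the output file inventory with
#' checksums. Written atomically (temp file + rename).
#'
#' @param dir run directory
#' @param params the validated `sim_params`
#' @param seed seed used
#' @param start_step,end_step step range covered
#' @return invisibly, the manifest path
#' @export
write_manifest <- function(dir, params, seed, start_step = 0, end_step = NA) {
  files <- setdiff(list.files(dir), "manifest.json")
  paths <- file.path(dir, files)
  inv <- data.frame(file = files,
                    md5 = unname(tools::md5sum(paths)),
                    bytes = unname(file.size(paths)))
  manifest <- list(
    package = "escrtsim",
    version = as.character(utils::packageVersion("escrtsim")),
    seed = seed, start_step = start_step, end_step = end_step,
    config = unclass(params), files = inv)
  tmp <- file.path(dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  file.rename(tmp, file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}
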