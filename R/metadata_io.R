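# STAR particle tables (rln-prefixed label dialect) and MRC2014
# volumes/stacks. Both readers preserve everything the pipeline does
# not touch: unknown STAR labels round-trip as extra columns, and MRC
# voxel data is stored as 32-bit reals (mode 2) exactly as read.

star_label_map <- c(
  micrograph_id      = "rlnMicrographName",
  rot                = "rlnAngleRot",
  tilt               = "rlnAngleTilt",
  psi                = "rlnAnglePsi",
  origin_x           = "rlnOriginX",
  origin_y           = "rlnOriginY",
  defocus_u          = "rlnDefocusU",
  defocus_v          = "rlnDefocusV",
  astig_angle        = "rlnDefocusAngle",
  voltage            = "rlnVoltage",
  cs                 = "rlnSphericalAberration",
  amplitude_contrast = "rlnAmplitudeContrast",
  phase_shift        = "rlnPhaseShift",
  pixel_size         = "rlnImagePixelSize")

#' Read a STAR particle table
#'
#' Parses the first `loop_` data block of a STAR file with rln-prefixed
#' labels into a [particle_table()]. `rlnImageName` entries of the form
#' `000001@stack.mrcs` populate `image_index` (and a `stack_file`
#' column). Origins are accepted in pixels (`rlnOriginX/Y`, the legacy
#' dialect) or in Angstrom (`rlnOriginXAngst/YAngst`) behind the
#' `origins_in` flag, and are always stored internally in pixels.
#' Labels the package does not know are kept verbatim as extra columns
#' and round-trip unchanged through [write_star()].
#'
#' @param path STAR file.
#' @param origins_in `"pixel"` or `"angstrom"`: dialect of the origin
#'   labels to expect.
#' @return A [particle_table()] data frame.
#' @export
read_star <- function(path, origins_in = c("pixel", "angstrom")) {
  origins_in <- match.arg(origins_in)
  lines <- trimws(readLines(path, warn = FALSE))
  if (!length(grep("^_", lines)))
    stop("format error: no loop_ labels found")
  # contiguous label block after the first loop_
  iloop <- grep("^loop_", lines)
  if (!length(iloop)) stop("format error: no loop_ block")
  start <- iloop[1] + 1
  labs <- character()
  i <- start
  while (i <= length(lines) && grepl("^_", lines[i])) {
    labs <- c(labs, sub("^_(\\S+).*$", "\\1", lines[i]))
    i <- i + 1
  }
  rows <- character()
  while (i <= length(lines) && !grepl("^(data_|loop_)", lines[i])) {
    if (nzchar(lines[i])) rows <- c(rows, lines[i])
    i <- i + 1
  }
  fields <- strsplit(rows, "\\s+")
  if (length(fields) && any(lengths(fields) != length(labs)))
    stop("format error: row width does not match label count")
  raw <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  if (!nrow(raw)) raw <- as.data.frame(matrix(character(), 0,
                                              length(labs)))
  names(raw) <- labs

  if (origins_in == "angstrom") {
    ox_lab <- "rlnOriginXAngst"; oy_lab <- "rlnOriginYAngst"
  } else {
    ox_lab <- "rlnOriginX"; oy_lab <- "rlnOriginY"
  }
  mandatory <- c("rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
                 ox_lab, oy_lab, "rlnDefocusU", "rlnDefocusV")
  for (lab in mandatory)
    if (!lab %in% labs) stop("format error: missing mandatory label _",
                             lab)

  num <- function(lab, what = "value") {
    x <- suppressWarnings(as.numeric(raw[[lab]]))
    if (nrow(raw) && anyNA(x))
      stop("parse error: non-numeric ", what, " in _", lab)
    x
  }
  tab <- data.frame(
    rot = num("rlnAngleRot", "angle"),
    tilt = num("rlnAngleTilt", "angle"),
    psi = num("rlnAnglePsi", "angle"))
  tab$origin_x <- num(ox_lab)
  tab$origin_y <- num(oy_lab)
  tab$defocus_u <- num("rlnDefocusU")
  tab$defocus_v <- num("rlnDefocusV")
  opt <- function(lab, default)
    if (lab %in% labs) num(lab) else rep(default, nrow(raw))
  tab$astig_angle <- opt("rlnDefocusAngle", 0)
  tab$voltage <- opt("rlnVoltage", 300)
  tab$cs <- opt("rlnSphericalAberration", 2.0)
  tab$amplitude_contrast <- opt("rlnAmplitudeContrast", 0.07)
  tab$phase_shift <- opt("rlnPhaseShift", 0)
  tab$pixel_size <- opt("rlnImagePixelSize", 1)
  if (origins_in == "angstrom") {
    tab$origin_x <- tab$origin_x / tab$pixel_size
    tab$origin_y <- tab$origin_y / tab$pixel_size
  }
  if ("rlnImageName" %in% labs && nrow(raw)) {
    parts <- strsplit(raw$rlnImageName, "@", fixed = TRUE)
    tab$image_index <- as.integer(vapply(parts, `[`, "", 1))
    tab$stack_file <- vapply(parts, function(p) p[min(2, length(p))], "")
  } else {
    tab$image_index <- seq_len(nrow(tab))
  }
  tab$micrograph_id <- if ("rlnMicrographName" %in% labs && nrow(raw))
    raw$rlnMicrographName else rep("mic_1", nrow(tab))
  known <- c(unname(star_label_map), "rlnImageName",
             "rlnOriginXAngst", "rlnOriginYAngst")
  for (lab in setdiff(labs, known)) {
    x <- suppressWarnings(as.numeric(raw[[lab]]))
    tab[[lab]] <- if (nrow(raw) && !anyNA(x)) x else raw[[lab]]
  }
  validate_particles(tab)
}

#' Write a STAR particle table
#'
#' Inverse of [read_star()]: emits one `data_particles` loop block with
#' rln labels, preserving record order and any extra columns under
#' their own labels. Numeric fields are written with enough digits to
#' round-trip to at least 1e-6 relative precision.
#'
#' @param table a [particle_table()].
#' @param path output file.
#' @param origins_in write origins in `"pixel"` or `"angstrom"` units.
#' @return Invisibly, `path`.
#' @export
write_star <- function(table, path, origins_in = c("pixel", "angstrom")) {
  origins_in <- match.arg(origins_in)
  table <- validate_particles(table)
  fmt <- function(x) {
    if (is.numeric(x)) sprintf("%.8g", x) else as.character(x)
  }
  cols <- list(rlnImageName = sprintf("%06d@%s", table$image_index,
    if (!is.null(table$stack_file)) table$stack_file else "particles.mrcs"))
  cols$rlnMicrographName <- table$micrograph_id
  for (nm in c("rot", "tilt", "psi")) cols[[star_label_map[nm]]] <-
      fmt(table[[nm]])
  if (origins_in == "angstrom") {
    cols$rlnOriginXAngst <- fmt(table$origin_x * table$pixel_size)
    cols$rlnOriginYAngst <- fmt(table$origin_y * table$pixel_size)
  } else {
    cols$rlnOriginX <- fmt(table$origin_x)
    cols$rlnOriginY <- fmt(table$origin_y)
  }
  for (nm in c("defocus_u", "defocus_v", "astig_angle", "voltage", "cs",
               "amplitude_contrast", "phase_shift", "pixel_size"))
    cols[[star_label_map[nm]]] <- fmt(table[[nm]])
  extra <- setdiff(names(table), c(particle_columns, "stack_file"))
  for (nm in extra) cols[[nm]] <- fmt(table[[nm]])

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "data_particles", "", "loop_",
               sprintf("_%s #%d", names(cols), seq_along(cols))), con)
  if (nrow(table)) {
    mat <- do.call(cbind, cols)
    writeLines(apply(mat, 1, paste, collapse = "  "), con)
  }
  invisible(path)
}

mrc_header <- function(nx, ny, nz, pixel_size, is_stack) {
  list(nx = nx, ny = ny, nz = nz, mode = 2L,
       nstart = c(0L, 0L, 0L), m = c(nx, ny, if (is_stack) 1L else nz),
       cella = c(nx, ny, if (is_stack) 1 else nz) * pixel_size,
       ispg = if (is_stack) 0L else 1L)
}

write_mrc_raw <- function(data, path, pixel_size, is_stack) {
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  h <- mrc_header(d[1], d[2], d[3], pixel_size, is_stack)
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(c(h$nx, h$ny, h$nz, h$mode))
  wi(h$nstart); wi(h$m)
  wf(h$cella); wf(c(90, 90, 90))
  wi(c(1L, 2L, 3L))
  wf(c(min(data), max(data), mean(data)))
  wi(c(h$ispg, 0L))                     # ispg, nsymbt
  wi(rep(0L, 25))                       # extra words 26-50 (incl exttyp)
  wf(c(0, 0, 0))                        # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(as.numeric(data)))
  wi(1L)                                # nlabl
  lab <- sprintf("%-80s", "Created by flexalign")
  writeChar(substr(lab, 1, 80), con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 720), collapse = ""), con, nchars = 720,
            eos = NULL)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

read_mrc_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4,
                            endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4,
                            endian = "little")
  nx <- ri(1); ny <- ri(1); nz <- ri(1); mode <- ri(1)
  if (mode != 2)
    stop("format error: only MRC mode 2 (32-bit real) is supported")
  ri(3)                                  # nstart
  m <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3)                    # cellb, axis map, dmin/max/mean
  ispg <- ri(1); nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  data <- rf(nx * ny * nz)
  dim(data) <- c(nx, ny, nz)
  px <- if (m[1] > 0) cella[1] / m[1] else 0
  if (px <= 0) {
    warning("missing pixel size in MRC header; defaulting to 1.0")
    px <- 1
  }
  list(data = data, pixel_size = px, ispg = ispg)
}

#' Read / write MRC2014 volumes and MRCS stacks
#'
#' Mode-2 (32-bit real) files with z as the slowest (section) axis.
#' Volumes must be cubic; the pixel size is taken from `cella/mx` and
#' defaults to 1.0 with a warning when the header leaves it unset.
#' Stack slice `k` (1-based) corresponds to `image_index == k`.
#'
#' @param path file path.
#' @param vol an [fx_volume()]; `stack` an [fx_stack()].
#' @param stack an [fx_stack()].
#' @return `read_volume()` an [fx_volume()]; `read_stack()` an
#'   [fx_stack()]; the writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  r <- read_mrc_raw(path)
  d <- dim(r$data)
  if (length(unique(d)) != 1)
    stop("shape error: volume is not cubic (", paste(d, collapse = "x"),
         ")")
  fx_volume(r$data, r$pixel_size)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "fx_volume"))
  write_mrc_raw(vol$grid, path, vol$pixel_size, is_stack = FALSE)
}

#' @rdname read_volume
#' @export
read_stack <- function(path) {
  r <- read_mrc_raw(path)
  fx_stack(r$data, r$pixel_size)
}

#' @rdname read_volume
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fx_stack"))
  write_mrc_raw(stack$data, path, stack$pixel_size, is_stack = TRUE)
}
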