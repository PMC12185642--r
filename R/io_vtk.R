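# Legacy-ASCII VTK I/O. Only the subset this toolkit needs is supported:
# DATASET UNSTRUCTURED_GRID with tetrahedra (cell type 10) or triangles
# (type 5), DATASET POLYDATA with POLYGONS triangles; POINT_DATA/CELL_DATA
# with SCALARS (1 component), VECTORS and NORMALS. Node indices are 0-based
# in the files and 1-based in memory. The sample time is stamped in the
# title line as "time= <seconds>".

#' Write a mesh with attached fields as a legacy-ASCII VTK file
#'
#' @param mesh a [volume_mesh()] or [surface_mesh()].
#' @param path output file.
#' @param point_data named list of per-node data: numeric vectors (SCALARS)
#'   or n x 3 matrices (VECTORS).
#' @param cell_data named list of per-cell data (same convention).
#' @param time optional sample time (s), stamped in the header.
#' @param as_polydata write surfaces as POLYDATA (default) instead of
#'   UNSTRUCTURED_GRID.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list(),
                      time = NULL, as_polydata = inherits(mesh, "surface_mesh")) {
  is_surf <- inherits(mesh, "surface_mesh")
  if (!is_surf && !inherits(mesh, "volume_mesh")) {
    stop("mesh must be a volume_mesh or surface_mesh")
  }
  conn <- if (is_surf) mesh$triangles else mesh$cells
  npts <- nrow(mesh$nodes); ncl <- nrow(conn); k <- ncol(conn)
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               if (is.null(time)) "avgflow" else paste0("avgflow time= ", num(time)),
               "ASCII"), con)
  pts <- apply(mesh$nodes, 1, function(r) paste(num(r), collapse = " "))
  cells_txt <- apply(conn - 1L, 1, function(r) paste(c(k, r), collapse = " "))
  if (is_surf && as_polydata) {
    writeLines(c("DATASET POLYDATA", paste("POINTS", npts, "double")), con)
    writeLines(pts, con)
    writeLines(paste("POLYGONS", ncl, ncl * (k + 1L)), con)
    writeLines(cells_txt, con)
  } else {
    writeLines(c("DATASET UNSTRUCTURED_GRID",
                 paste("POINTS", npts, "double")), con)
    writeLines(pts, con)
    writeLines(paste("CELLS", ncl, ncl * (k + 1L)), con)
    writeLines(cells_txt, con)
    writeLines(paste("CELL_TYPES", ncl), con)
    writeLines(as.character(rep(if (k == 4L) 10L else 5L, ncl)), con)
  }
  if (is_surf) {
    point_data <- c(list(.normals = mesh$normals), point_data)
  }
  write_attr_block <- function(label, n, data) {
    if (!length(data)) return(invisible())
    writeLines(paste(label, n), con)
    for (nm in names(data)) {
      x <- data[[nm]]
      if (nm == ".normals") {
        writeLines("NORMALS normals double", con)
        writeLines(apply(x, 1, function(r) paste(num(r), collapse = " ")), con)
      } else if (is.matrix(x)) {
        if (ncol(x) != 3L || nrow(x) != n) stop("vector field '", nm, "' must be n x 3")
        writeLines(paste("VECTORS", nm, "double"), con)
        writeLines(apply(x, 1, function(r) paste(num(r), collapse = " ")), con)
      } else {
        if (length(x) != n) stop("scalar field '", nm, "' has wrong length")
        writeLines(c(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default"), con)
        writeLines(num(as.numeric(x)), con)
      }
    }
  }
  write_attr_block("POINT_DATA", npts, point_data)
  write_attr_block("CELL_DATA", ncl, cell_data)
  invisible(path)
}

#' Read a legacy-ASCII VTK file written by this toolkit (or compatible)
#'
#' @param path file path.
#' @return list: `nodes`, `cells` (tetrahedra or triangles, 1-based),
#'   `cell_kind` ("tetra" or "triangle"), `point_data`, `cell_data`,
#'   `normals` (if present), `time` (NA if unstamped).
#' @export
read_vtk <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || !grepl("^# vtk DataFile", lines[1])) {
    stop("not a legacy VTK file: ", path)
  }
  time <- NA_real_
  tm <- regmatches(lines[2], regexec("time=\\s*([-+0-9.eE]+)", lines[2]))[[1]]
  if (length(tm) == 2L) time <- as.numeric(tm[2])
  if (toupper(trimws(lines[3])) != "ASCII") stop("only ASCII VTK supported")
  # tokenise everything after the dataset line lazily
  i <- 4L
  dataset <- toupper(sub("^DATASET\\s+", "", trimws(lines[i])))
  i <- i + 1L
  toks <- strsplit(paste(lines[i:length(lines)], collapse = "\n"), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  p <- 1L
  need <- function(word) {
    if (toupper(toks[p]) != word) stop("expected ", word, " at token ", p)
    p <<- p + 1L
  }
  take_num <- function(n) {
    out <- as.numeric(toks[p:(p + n - 1L)])
    if (any(is.na(out))) stop("non-numeric data where numbers expected")
    p <<- p + n
    out
  }
  need("POINTS")
  npts <- as.integer(toks[p]); p <- p + 2L        # skip dtype
  nodes <- matrix(take_num(3L * npts), ncol = 3L, byrow = TRUE)
  if (dataset == "POLYDATA") {
    need("POLYGONS")
    ncl <- as.integer(toks[p]); ntot <- as.integer(toks[p + 1L]); p <- p + 2L
    raw <- as.integer(take_num(ntot))
  } else if (dataset == "UNSTRUCTURED_GRID") {
    need("CELLS")
    ncl <- as.integer(toks[p]); ntot <- as.integer(toks[p + 1L]); p <- p + 2L
    raw <- as.integer(take_num(ntot))
    need("CELL_TYPES")
    nt <- as.integer(toks[p]); p <- p + 1L
    invisible(take_num(nt))
  } else stop("unsupported DATASET: ", dataset)
  k <- raw[1]
  if (!k %in% c(3L, 4L)) stop("only triangle/tetra cells supported")
  cm <- matrix(raw, ncol = k + 1L, byrow = TRUE)
  if (any(cm[, 1] != k)) stop("mixed cell sizes are not supported")
  cells <- cm[, -1L, drop = FALSE] + 1L
  point_data <- list(); cell_data <- list(); normals <- NULL
  section <- NULL; nsec <- 0L
  while (p <= length(toks)) {
    word <- toupper(toks[p])
    if (word %in% c("POINT_DATA", "CELL_DATA")) {
      section <- word; nsec <- as.integer(toks[p + 1L]); p <- p + 2L
    } else if (word == "NORMALS") {
      nm <- toks[p + 1L]; p <- p + 3L
      normals <- matrix(take_num(3L * nsec), ncol = 3L, byrow = TRUE)
    } else if (word == "VECTORS") {
      nm <- toks[p + 1L]; p <- p + 3L
      val <- matrix(take_num(3L * nsec), ncol = 3L, byrow = TRUE)
      if (section == "POINT_DATA") point_data[[nm]] <- val else cell_data[[nm]] <- val
    } else if (word == "SCALARS") {
      nm <- toks[p + 1L]; p <- p + 3L          # SCALARS name type
      if (grepl("^[0-9]+$", toks[p])) p <- p + 1L   # optional numComp
      if (toupper(toks[p]) == "LOOKUP_TABLE") p <- p + 2L
      val <- take_num(nsec)
      if (section == "POINT_DATA") point_data[[nm]] <- val else cell_data[[nm]] <- val
    } else if (toupper(toks[p]) == "LOOKUP_TABLE") {
      p <- p + 2L
    } else {
      stop("unsupported VTK attribute: ", toks[p])
    }
  }
  list(nodes = nodes, cells = cells,
       cell_kind = if (k == 4L) "tetra" else "triangle",
       point_data = point_data, cell_data = cell_data, normals = normals,
       time = time)
}

#' Write a field time series as one VTK file per sample plus a JSON manifest
#'
#' @param series a [volume_series()] or [wss_series()].
#' @param dir output directory (created).
#' @param basename file stem; files are `<basename>_NNN.vtk`.
#' @param field_name VTK field name, default "velocity"/"wss" by series kind.
#' @return path of the manifest JSON, invisibly.
#' @export
write_timeseries_mesh <- function(series, dir, basename = "sample",
                                  field_name = NULL) {
  is_vol <- inherits(series, "volume_series")
  if (!is_vol && !inherits(series, "wss_series")) stop("unsupported series type")
  if (is.null(field_name)) field_name <- if (is_vol) "velocity" else "wss"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- if (is_vol) series$velocity else series$wss
  files <- character(length(series$times))
  for (k in seq_along(series$times)) {
    f <- sprintf("%s_%03d.vtk", basename, k)
    pd <- stats::setNames(list(arr[, , k]), field_name)
    write_vtk(series$mesh, file.path(dir, f), point_data = pd,
              time = series$times[k])
    files[k] <- f
  }
  manifest <- file.path(dir, paste0(basename, "_series.json"))
  jsonlite::write_json(list(kind = if (is_vol) "volume" else "surface",
                            field = field_name, period = series$period,
                            files = data.frame(name = files,
                                               time = series$times)),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a mesh time series from VTK files
#'
#' Accepts either a JSON series manifest (as written by
#' [write_timeseries_mesh()]) or a character vector of VTK files whose header
#' carries a `time=` stamp. All files must share identical topology; samples
#' are sorted by time.
#'
#' @param paths manifest path or vector of VTK file paths.
#' @param kind "volume" or "surface" (inferred from the manifest when given).
#' @param period cycle period (s); taken from the manifest when available.
#' @param field_name name of the vector field (default "velocity"/"wss").
#' @return a [volume_series()] or [wss_series()].
#' @export
read_timeseries_mesh <- function(paths, kind = c("volume", "surface"),
                                 period = NULL, field_name = NULL) {
  times <- NULL
  if (length(paths) == 1L && grepl("\\.json$", paths)) {
    if (!file.exists(paths)) stop("series manifest not found: ", paths)
    man <- jsonlite::read_json(paths, simplifyVector = TRUE)
    kind <- man$kind
    period <- period %||% man$period
    field_name <- field_name %||% man$field
    times <- man$files$time
    paths <- file.path(dirname(paths), man$files$name)
  } else {
    kind <- match.arg(kind)
  }
  if (is.null(period)) stop("period must be supplied (no manifest)")
  if (is.null(field_name)) {
    field_name <- if (kind == "volume") "velocity" else "wss"
  }
  objs <- lapply(paths, read_vtk)
  if (is.null(times)) {
    times <- vapply(objs, function(o) o$time, 0)
    if (any(is.na(times))) stop("file(s) missing the time stamp")
  }
  if (anyDuplicated(times)) stop("duplicate sample times")
  o <- order(times)
  objs <- objs[o]; times <- times[o]
  ref <- objs[[1]]
  for (ob in objs[-1]) {
    if (!isTRUE(all.equal(dim(ob$nodes), dim(ref$nodes))) ||
        !identical(ob$cells, ref$cells) ||
        max(abs(ob$nodes - ref$nodes)) > 0) {
      stop("topology mismatch across series files")
    }
  }
  arr <- array(0, c(nrow(ref$nodes), 3, length(objs)))
  for (k in seq_along(objs)) {
    f <- objs[[k]]$point_data[[field_name]]
    if (is.null(f)) stop("field '", field_name, "' missing in series file ", k)
    arr[, , k] <- f
  }
  if (kind == "volume") {
    if (ref$cell_kind != "tetra") stop("volume series requires tetrahedral cells")
    volume_series(volume_mesh(ref$nodes, ref$cells), times, arr, period)
  } else {
    if (ref$cell_kind != "triangle") stop("surface series requires triangles")
    mesh <- surface_mesh(ref$nodes, ref$cells, normals = ref$normals)
    wss_series(mesh, times, arr, period)
  }
}

#' Read a waveform from a two-column CSV
#'
#' Columns `time_s,value` (header optional). Non-numeric rows and duplicate
#' times are errors.
#'
#' @param path CSV file.
#' @param period cycle period T (s).
#' @param units units tag, default "m3/s".
#' @param periodic logical, default TRUE.
#' @return a [waveform()].
#' @export
read_waveform_csv <- function(path, period, units = "m3/s", periodic = TRUE) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  df <- utils::read.csv(path, header = has_header,
                        colClasses = c("character", "character"))
  tt <- suppressWarnings(as.numeric(df[[1]]))
  vv <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(tt)) || any(is.na(vv))) stop("non-numeric row in waveform CSV")
  if (anyDuplicated(tt)) stop("duplicate time values in waveform CSV")
  o <- order(tt)
  waveform(tt[o], vv[o], period, units = units, periodic = periodic)
}

#' Write a waveform as CSV (`time_s,value`)
#'
#' @param w a [waveform()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  df <- data.frame(time_s = format(w$times, digits = 17, trim = TRUE),
                   value = format(w$values, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
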