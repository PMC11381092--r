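#' @include AllClasses.R
NULL

FIX_COLUMNS <- c("bird_id", "t", "lon", "lat", "depth", "wingbeat_hz",
                 "pitch")

parseUtc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS"))
  out
}

#' Read biologger deployments from CSV
#'
#' Reads per-fix biologger records from one CSV file (or every
#' \code{*.csv} in a directory) and assembles one
#' \linkS4class{MurreDeployment} per bird. Mandatory columns are
#' \code{bird_id, t, lon, lat, depth}; \code{wingbeat_hz} and
#' \code{pitch} are optional (filled with NA). Timestamps are ISO-8601,
#' read as UTC. Distance from the colony is computed by great-circle
#' distance from the configured colony. Rows that break timestamp
#' monotonicity within a bird are dropped with a warning.
#'
#' @param path a CSV file or a directory of CSV files.
#' @param config a \linkS4class{PipelineConfig} (supplies the colony).
#' @param metadata optional data.frame keyed by \code{bird_id} with any
#'   of \code{sex}, \code{stage}, \code{chick_age_d}, \code{mass_pre_g},
#'   \code{mass_post_g}, \code{time_at_colony_h}.
#' @return list of \linkS4class{MurreDeployment}, sorted by bird id and
#'   start time.
#' @export
readDeployments <- function(path, config = pipelineConfig(),
                            metadata = NULL) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else path
  if (!length(files)) stop("no CSV files found at ", path)
  raw <- do.call(rbind, lapply(files, utils::read.csv,
                               stringsAsFactors = FALSE))
  mandatory <- c("bird_id", "t", "lon", "lat", "depth")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(raw$wingbeat_hz)) raw$wingbeat_hz <- NA_real_
  if (is.null(raw$pitch)) raw$pitch <- NA_real_
  if (nrow(raw) == 0L) stop("empty deployment: file contains zero fixes")
  raw$t <- parseUtc(raw$t)

  deps <- lapply(split(raw, raw$bird_id), function(df) {
    df <- df[order(df$t), , drop = FALSE]
    keep <- c(TRUE, diff(as.numeric(df$t)) > 0)
    if (any(!keep)) {
      warning(sprintf("%s: dropped %d fix(es) with non-monotone timestamps",
                      df$bird_id[1], sum(!keep)))
      df <- df[keep, , drop = FALSE]
    }
    if (nrow(df) == 0L)
      stop("empty deployment after timestamp filtering: ", df$bird_id[1])
    md <- list(sex = "UNKNOWN", stage = "CHICK_REARING",
               chick_age_d = NA_real_, mass_pre_g = NA_real_,
               mass_post_g = NA_real_, time_at_colony_h = NA_real_)
    if (!is.null(metadata)) {
      row <- metadata[metadata$bird_id == df$bird_id[1], , drop = FALSE]
      if (nrow(row) == 1L)
        for (f in intersect(names(md), names(row))) md[[f]] <- row[[f]]
    }
    if (identical(md$stage, "CHICK_REARING") && is.na(md$chick_age_d))
      md$chick_age_d <- 0
    fx <- data.frame(
      t = df$t, lon = df$lon, lat = df$lat, depth = df$depth,
      wingbeatHz = df$wingbeat_hz, pitch = df$pitch,
      distColonyKm = haversineKm(config@colonyLonLat[1],
                                 config@colonyLonLat[2],
                                 df$lon, df$lat))
    new("MurreDeployment",
        birdId = as.character(df$bird_id[1]),
        sex = md$sex, stage = md$stage,
        chickAgeD = if (identical(md$stage, "INCUBATION")) NA_real_
                    else as.numeric(md$chick_age_d),
        startT = fx$t[1], endT = fx$t[nrow(fx)],
        fixes = fx,
        dives = emptyDiveTable(),
        massPreG = as.numeric(md$mass_pre_g),
        massPostG = as.numeric(md$mass_post_g),
        timeAtColonyH = as.numeric(md$time_at_colony_h))
  })
  ord <- order(vapply(deps, function(d) d@birdId, character(1)),
               vapply(deps, function(d) as.numeric(d@startT), numeric(1)))
  unname(deps[ord])
}

emptyDiveTable <- function() {
  data.frame(startT = as.POSIXct(numeric(0), origin = "1970-01-01",
                                 tz = "UTC"),
             endT = as.POSIXct(numeric(0), origin = "1970-01-01",
                               tz = "UTC"),
             maxDepthM = numeric(0))
}

#' Deployments as one long fix table
#'
#' @param deployments list of \linkS4class{MurreDeployment}.
#' @return data.frame in the on-disk schema (bird_id, t, lon, lat,
#'   depth, wingbeat_hz, pitch).
#' @export
fixTable <- function(deployments) {
  do.call(rbind, lapply(deployments, function(d) {
    fx <- d@fixes
    data.frame(bird_id = d@birdId,
               t = format(fx$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               lon = fx$lon, lat = fx$lat, depth = fx$depth,
               wingbeat_hz = fx$wingbeatHz, pitch = fx$pitch)
  }))
}

#' Write a summary table to CSV
#'
#' Writes any homogeneous table with full numeric precision (up to 15
#' significant digits) so that \code{read(write(x))} round-trips finite
#' values.
#'
#' @param rows data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTable <- function(rows, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open ", path, " for writing: ", conditionMessage(e)))
  on.exit(close(con))
  fmt <- rows
  for (j in seq_along(fmt)) {
    if (inherits(fmt[[j]], "POSIXct"))
      fmt[[j]] <- format(fmt[[j]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    else if (is.numeric(fmt[[j]]))
      fmt[[j]] <- formatC(fmt[[j]], digits = 15, format = "g")
  }
  utils::write.csv(fmt, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a summary table written by writeTable
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a utilization distribution as an ASCII grid
#'
#' Plain-text ESRI-style ASCII grid (\code{ncols/nrows/xllcorner/...}
#' header, rows from north to south).
#'
#' @param ud a \linkS4class{UtilizationDistribution}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAsciiGrid <- function(ud, path) {
  nx <- length(ud@x); ny <- length(ud@y)
  hdr <- c(
    sprintf("ncols %d", nx),
    sprintf("nrows %d", ny),
    sprintf("xllcorner %.6f", min(ud@x) - ud@cellM / 2),
    sprintf("yllcorner %.6f", min(ud@y) - ud@cellM / 2),
    sprintf("cellsize %.6f", ud@cellM),
    "NODATA_value -9999")
  ## rows north to south: y descending
  lines <- vapply(rev(seq_len(ny)), function(j)
    paste(formatC(ud@density[, j], digits = 10, format = "g"),
          collapse = " "), character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ASCII grid written by writeAsciiGrid
#'
#' @param path ASCII grid path.
#' @param crsNote projection descriptor to attach.
#' @return a \linkS4class{UtilizationDistribution}.
#' @export
readAsciiGrid <- function(path, crsNote = "aeqd (unspecified centre)") {
  ln <- readLines(path)
  hdr <- strsplit(ln[1:6], " +")
  val <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(val) <- vapply(hdr, `[`, character(1), 1)
  nx <- val[["ncols"]]; ny <- val[["nrows"]]; cell <- val[["cellsize"]]
  rows <- lapply(ln[7:(6 + ny)], function(s)
    as.numeric(strsplit(trimws(s), " +")[[1]]))
  dens <- matrix(0, nx, ny)
  for (j in seq_len(ny)) dens[, ny - j + 1] <- rows[[j]]
  x <- val[["xllcorner"]] + cell / 2 + (seq_len(nx) - 1) * cell
  y <- val[["yllcorner"]] + cell / 2 + (seq_len(ny) - 1) * cell
  new("UtilizationDistribution", x = x, y = y, density = dens,
      cellM = cell, crsNote = crsNote)
}
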