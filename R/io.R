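# CSV schemas
#   grid:       cell_id, x, y, mask, v1..vp   (v* excludes the intercept)
#   traps:      trap_id, x, y, T, w1..wp      (optional deploy_start, ISO 8601)
#   detections: individual_id, trap_id, time  (trap-relative, time units)
#               or individual_id, trap_id, timestamp (ISO 8601; requires
#               deploy_start in the trap file)
#   schedule:   trap_id, seg_start, seg_end, z1..zq
#   sun table:  date, sunrise, sunset         (YYYY-MM-DD, HH:MM[:SS])

#' Read a grid file into a domain
#'
#' @param path CSV with columns cell_id, x, y, mask, v1..vp. Cells must form
#'   a regular grid of identical square cells; the intercept regressor is
#'   prepended automatically.
#' @return an \code{scr_domain}.
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "x", "y", "mask")
  if (!all(need %in% names(df)))
    stop("grid file must have columns cell_id, x, y, mask")
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  res <- if (length(xs) > 1L) min(diff(xs)) else if (length(ys) > 1L) min(diff(ys)) else
    stop("cannot infer resolution from a single-cell grid")
  bounds <- c(min(xs) - res / 2, max(xs) + res / 2,
              min(ys) - res / 2, max(ys) + res / 2)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  # order rows to the canonical row-major layout of build_grid
  dom <- build_grid(bounds, res)
  key <- paste(round(df$x / res, 6), round(df$y / res, 6))
  ckey <- paste(round(dom$centers[, 1] / res, 6), round(dom$centers[, 2] / res, 6))
  m <- match(ckey, key)
  if (anyNA(m)) stop("grid file does not tile its bounding rectangle")
  dom$mask <- as.logical(df$mask[m])
  if (!any(dom$mask)) stop("domain-empty: grid file masks every cell")
  V <- matrix(1, nrow(dom$centers), 1L)
  if (length(vcols))
    V <- cbind(1, as.matrix(df[m, vcols, drop = FALSE]))
  dimnames(V) <- list(NULL, paste0("v", seq_len(ncol(V)) - 1L))
  dom$V <- V
  dom
}

#' Write a domain to a grid file
#' @param domain an \code{scr_domain}.
#' @param path output CSV path.
#' @export
write_grid <- function(domain, path) {
  V <- domain$V[, -1L, drop = FALSE]
  df <- data.frame(cell_id = seq_len(nrow(domain$centers)),
                   x = domain$centers[, 1], y = domain$centers[, 2],
                   mask = as.integer(domain$mask))
  if (ncol(V)) {
    colnames(V) <- paste0("v", seq_len(ncol(V)))
    df <- cbind(df, V)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trap file
#' @param path CSV with columns trap_id, x, y, T, optional w1..wp and
#'   deploy_start.
#' @return an \code{scr_traps}; deployment starts, if present, are kept in
#'   field \code{deploy_start} (POSIXct, UTC).
#' @export
read_traps <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trap_id", "x", "y", "T")
  if (!all(need %in% names(df)))
    stop("trap file must have columns trap_id, x, y, T")
  wcols <- grep("^w[0-9]+$", names(df), value = TRUE)
  tr <- scr_traps(cbind(df$x, df$y), df$T,
                  covariates = if (length(wcols)) as.matrix(df[, wcols, drop = FALSE]) else NULL,
                  id = df$trap_id)
  if ("deploy_start" %in% names(df))
    tr$deploy_start <- as.POSIXct(sub("T", " ", df$deploy_start, fixed = TRUE),
                                  tz = "UTC")
  tr
}

#' Write a trap file
#' @param traps an \code{scr_traps}.
#' @param path output CSV path.
#' @export
write_traps <- function(traps, path) {
  W <- traps$W[, -1L, drop = FALSE]
  df <- data.frame(trap_id = traps$id, x = traps$xy[, 1], y = traps$xy[, 2],
                   T = traps$T)
  if (ncol(W)) {
    colnames(W) <- paste0("w", seq_len(ncol(W)))
    df <- cbind(df, W)
  }
  if (!is.null(traps$deploy_start))
    df$deploy_start <- format(traps$deploy_start, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write detections in long format
#' @param survey an \code{scr_survey}.
#' @param path output CSV path (columns individual_id, trap_id, time).
#' @export
write_detections <- function(survey, path) {
  rows <- list()
  for (i in seq_len(survey$n)) for (k in seq_len(survey$traps$K)) {
    tt <- survey$times[[i]][[k]]
    if (length(tt))
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = survey$id[i], trap_id = survey$traps$id[k], time = tt)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual_id = character(0), trap_id = character(0),
               time = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a schedule file
#' @param schedule an \code{scr_schedule}.
#' @param traps matching \code{scr_traps} (for trap ids).
#' @param path output CSV path.
#' @export
write_schedule <- function(schedule, traps, path) {
  rows <- lapply(seq_len(schedule$K), function(k) {
    s <- schedule$segments[[k]]
    Z <- s$Z
    colnames(Z) <- paste0("z", seq_len(ncol(Z)))
    cbind(data.frame(trap_id = traps$id[k], seg_start = s$start,
                     seg_end = s$end), Z)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a schedule file
#' @param path CSV with columns trap_id, seg_start, seg_end, z1..zq.
#' @param traps the \code{scr_traps} the schedule belongs to.
#' @return an \code{scr_schedule}.
#' @export
read_schedule <- function(path, traps) {
  df <- utils::read.csv(path)
  need <- c("trap_id", "seg_start", "seg_end")
  if (!all(need %in% names(df)))
    stop("schedule file must have columns trap_id, seg_start, seg_end, z*")
  zcols <- grep("^z[0-9]*$", names(df), value = TRUE)
  if (!length(zcols)) stop("schedule file has no covariate columns z*")
  segs <- lapply(seq_len(traps$K), function(k) {
    sub <- df[df$trap_id == traps$id[k], , drop = FALSE]
    if (!nrow(sub)) stop(sprintf("schedule missing trap '%s'", traps$id[k]))
    out <- data.frame(start = sub$seg_start, end = sub$seg_end)
    cbind(out, sub[, zcols, drop = FALSE])
  })
  scr_schedule(segs, traps)
}

#' Parse a survey from its component files
#'
#' Reads the grid, trap, detection and (optionally) schedule files, builds
#' the n x K count matrix and detection-time sequences from the long-format
#' detection file (individuals ordered by first appearance), and validates
#' every detection against its trap's operating window.
#'
#' @param trap_path,detection_path,grid_path required file paths.
#' @param schedule_path optional schedule file path.
#' @return list(domain, traps, survey, schedule).
#' @export
parse_survey <- function(trap_path, detection_path, schedule_path = NULL,
                         grid_path) {
  domain <- read_grid(grid_path)
  traps <- read_traps(trap_path)
  det <- utils::read.csv(detection_path)
  if (!all(c("individual_id", "trap_id") %in% names(det)))
    stop("detection file must have columns individual_id, trap_id, time|timestamp")
  if (!"time" %in% names(det)) {
    if (!"timestamp" %in% names(det))
      stop("detection file must have a 'time' or 'timestamp' column")
    if (is.null(traps$deploy_start))
      stop("timestamp detections require deploy_start in the trap file")
    km <- match(det$trap_id, traps$id)
    if (anyNA(km))
      stop(sprintf("detection row %d: unknown trap_id '%s'",
                   which(is.na(km))[1], det$trap_id[which(is.na(km))[1]]))
    ts <- as.POSIXct(sub("T", " ", det$timestamp, fixed = TRUE), tz = "UTC")
    det$time <- as.numeric(difftime(ts, traps$deploy_start[km], units = "days"))
  }
  km <- match(det$trap_id, traps$id)
  if (anyNA(km))
    stop(sprintf("detection row %d: unknown trap_id '%s'",
                 which(is.na(km))[1], det$trap_id[which(is.na(km))[1]]))
  bad <- which(det$time <= 0 | det$time > traps$T[km] + 1e-9)
  if (length(bad))
    stop(sprintf("detection row %d: time %g outside (0, T=%g] of trap '%s'",
                 bad[1], det$time[bad[1]], traps$T[km[bad[1]]],
                 det$trap_id[bad[1]]))
  ids <- unique(det$individual_id)          # first-appearance order
  n <- length(ids)
  y <- matrix(0L, n, traps$K)
  times <- lapply(seq_len(n), function(i) rep(list(numeric(0)), traps$K))
  im <- match(det$individual_id, ids)
  for (r in seq_len(nrow(det))) {
    i <- im[r]; k <- km[r]
    y[i, k] <- y[i, k] + 1L
    times[[i]][[k]] <- c(times[[i]][[k]], det$time[r])
  }
  for (i in seq_len(n)) for (k in seq_len(traps$K))
    times[[i]][[k]] <- sort(times[[i]][[k]])
  survey <- scr_survey(traps, y, times, id = ids)
  schedule <- if (!is.null(schedule_path)) read_schedule(schedule_path, traps)
  list(domain = domain, traps = traps, survey = survey, schedule = schedule)
}

#' Build a day/night schedule from sunrise/sunset tables
#'
#' Converts per-date sunrise and sunset times into each trap's alternating
#' day (z = 1) / night (z = 0) segments on the trap's own clock, in days.
#' The sun table must cover every date each trap operates.
#'
#' @param sun_table data frame (or CSV path) with columns date (YYYY-MM-DD),
#'   sunrise, sunset (HH:MM or HH:MM:SS, local clock assumed consistent with
#'   deployments).
#' @param traps an \code{scr_traps} with \code{deploy_start} (POSIXct);
#'   durations T are in days.
#' @return an \code{scr_schedule} with one binary column z.
#' @export
build_day_night_schedule <- function(sun_table, traps) {
  if (is.character(sun_table)) sun_table <- utils::read.csv(sun_table)
  if (!all(c("date", "sunrise", "sunset") %in% names(sun_table)))
    stop("sun table must have columns date, sunrise, sunset")
  if (is.null(traps$deploy_start))
    stop("traps need deploy_start timestamps to build a day/night schedule")
  sun_table$date <- as.Date(sun_table$date)
  rise <- as.POSIXct(paste(sun_table$date, sun_table$sunrise), tz = "UTC")
  sets <- as.POSIXct(paste(sun_table$date, sun_table$sunset), tz = "UTC")
  segs <- lapply(seq_len(traps$K), function(k) {
    s0 <- traps$deploy_start[k]
    e0 <- s0 + traps$T[k] * 86400
    days <- seq(as.Date(s0, tz = "UTC"), as.Date(e0, tz = "UTC"), by = "day")
    mi <- match(days, sun_table$date)
    if (anyNA(mi))
      stop(sprintf("sun table does not cover date %s needed by trap '%s'",
                   days[which(is.na(mi))[1]], traps$id[k]))
    # breakpoints at every sunrise/sunset inside the window
    brk <- sort(unique(c(rise[mi], sets[mi])))
    brk <- brk[brk > s0 & brk < e0]
    edges <- c(s0, brk, e0)
    mids <- edges[-length(edges)] + diff(as.numeric(edges)) / 2
    dmid <- as.Date(mids, tz = "UTC")
    mmi <- match(dmid, sun_table$date)
    z <- as.integer(mids >= rise[mmi] & mids < sets[mmi])
    st <- as.numeric(difftime(edges[-length(edges)], s0, units = "days"))
    en <- as.numeric(difftime(edges[-1], s0, units = "days"))
    # merge runs of equal z
    keep <- c(TRUE, z[-1] != z[-length(z)])
    grp <- cumsum(keep)
    data.frame(start = tapply(st, grp, min), end = tapply(en, grp, max),
               z = tapply(z, grp, function(v) v[1]))
  })
  scr_schedule(segs, traps)
}

#' Export a chain as tidy CSV plus centers
#'
#' Writes draws in long format (iteration, parameter, value) to
#' \code{<stem>_chain.csv} and retained activity centers to
#' \code{<stem>_centers.csv} (iteration, individual, x, y).
#'
#' @param chain an \code{scr_chain}.
#' @param stem output path stem.
#' @return invisibly, the chain file path.
#' @export
write_chain <- function(chain, stem) {
  d <- chain$draws
  long <- data.frame(
    iteration = rep(seq_len(nrow(d)), times = ncol(d)),
    parameter = rep(names(d), each = nrow(d)),
    value = unlist(d, use.names = FALSE))
  utils::write.csv(long, paste0(stem, "_chain.csv"), row.names = FALSE)
  if (chain$n > 0) {
    cen <- data.frame(
      iteration = rep(seq_len(dim(chain$centers)[3]), each = chain$n),
      individual = rep(seq_len(chain$n), times = dim(chain$centers)[3]),
      x = as.vector(chain$centers[, 1, ]),
      y = as.vector(chain$centers[, 2, ]))
    utils::write.csv(cen, paste0(stem, "_centers.csv"), row.names = FALSE)
  }
  invisible(paste0(stem, "_chain.csv"))
}

#' Read a chain written by \code{write_chain}
#' @param stem the path stem used when writing.
#' @return an \code{scr_chain}-like object sufficient for summaries and maps.
#' @export
read_chain <- function(stem) {
  long <- utils::read.csv(paste0(stem, "_chain.csv"))
  pn <- unique(long$parameter)
  d <- as.data.frame(lapply(pn, function(p) long$value[long$parameter == p]))
  names(d) <- pn
  cpath <- paste0(stem, "_centers.csv")
  centers <- NULL; n <- 0L
  if (file.exists(cpath)) {
    cen <- utils::read.csv(cpath)
    n <- max(cen$individual)
    m <- max(cen$iteration)
    centers <- array(NA_real_, c(n, 2L, m))
    centers[, 1, ] <- matrix(cen$x, n, m)
    centers[, 2, ] <- matrix(cen$y, n, m)
  }
  model <- if (any(startsWith(pn, "xi"))) "full" else "restricted"
  structure(list(draws = d, centers = centers, n = n, model = model,
                 par_names = setdiff(pn, "n0")),
            class = "scr_chain")
}

#' Write an abundance map raster CSV
#' @param map an \code{scr_abundance_map}.
#' @param path output CSV (cell_id, x, y, mean, lo, hi).
#' @export
write_abundance_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

# minimal JSON writer used when jsonlite is unavailable
json_scalar <- function(x) {
  if (is.character(x)) paste0('"', gsub('"', '\\\\"', x), '"')
  else if (is.logical(x)) tolower(as.character(x))
  else format(x, digits = 15)
}
json_obj <- function(x) {
  items <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    val <- if (is.list(v)) json_obj(v)
    else if (length(v) == 1L) json_scalar(v)
    else paste0("[", paste(vapply(v, json_scalar, ""), collapse = ","), "]")
    paste0('"', nm, '":', val)
  }, "")
  paste0("{", paste(items, collapse = ","), "}")
}

#' Write a JSON run manifest
#' @param manifest named list (seed, config, priors, acceptance rates, ...).
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  } else {
    writeLines(json_obj(manifest), path)
  }
  invisible(path)
}

#' Read a flat key=value configuration file
#' @param path text file of key=value lines; '#' starts a comment.
#' @param allowed optional character vector of permitted keys (schema check).
#' @return named list of strings.
#' @export
read_run_config <- function(path, allowed = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, 0L) < 2L)
  if (length(bad)) stop(sprintf("config line %d is not key=value", bad[1]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  if (!is.null(allowed)) {
    unk <- setdiff(keys, allowed)
    if (length(unk)) stop("unknown config key(s): ", paste(unk, collapse = ", "))
  }
  stats::setNames(as.list(vals), keys)
}
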