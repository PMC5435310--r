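#' Temporal covariate schedule for a trap array
#'
#' A schedule records, for each trap, a piecewise-constant temporal covariate
#' path z(t) over the trap's operating window (0, T_k]: an ordered set of
#' half-open segments (start, end] that exactly tile the window, each carrying
#' a covariate vector (for the day/night model a single binary daytime
#' indicator, z = 1 by day and 0 by night).
#'
#' @param segments a list of length K; element k is a data frame with columns
#'   \code{start}, \code{end} and one or more covariate columns (any other
#'   names). Segments must be disjoint, ordered and exactly cover (0, T_k].
#' @param traps the \code{scr_traps} the schedule belongs to (for T_k checks).
#' @return An object of class \code{scr_schedule}: list with \code{segments}
#'   (per trap: list(start, end, Z matrix)), \code{q} covariate dimension,
#'   and stacked fields used internally.
#' @export
scr_schedule <- function(segments, traps) {
  K <- traps$K
  if (length(segments) != K) stop("need one segment table per trap")
  seglist <- vector("list", K)
  for (k in seq_len(K)) {
    df <- as.data.frame(segments[[k]])
    if (!all(c("start", "end") %in% names(df)))
      stop("segment tables need 'start' and 'end' columns")
    o <- order(df$start)
    df <- df[o, , drop = FALSE]
    zc <- setdiff(names(df), c("start", "end"))
    if (length(zc) == 0L) stop("segment tables need at least one covariate column")
    st <- as.numeric(df$start); en <- as.numeric(df$end)
    if (any(en <= st)) stop(sprintf("trap %d: empty or reversed segment", k))
    if (abs(st[1]) > 1e-9)
      stop(sprintf("trap %d: schedule must start at time 0", k))
    if (length(st) > 1L && any(abs(st[-1] - en[-length(en)]) > 1e-9))
      stop(sprintf("trap %d: schedule has a gap or overlap", k))
    if (abs(en[length(en)] - traps$T[k]) > 1e-9)
      stop(sprintf("trap %d: schedule must end at T_k = %g", k, traps$T[k]))
    Z <- as.matrix(df[, zc, drop = FALSE])
    storage.mode(Z) <- "double"
    dimnames(Z) <- list(NULL, paste0("z", seq_len(ncol(Z))))
    seglist[[k]] <- list(start = st, end = en, Z = Z)
  }
  q <- ncol(seglist[[1]]$Z)
  if (any(vapply(seglist, function(s) ncol(s$Z), 0L) != q))
    stop("temporal covariate dimension must be constant across traps")
  # stacked representation for vectorized Gamma_k(xi) evaluation
  lens <- unlist(lapply(seglist, function(s) s$end - s$start))
  Zall <- do.call(rbind, lapply(seglist, `[[`, "Z"))
  tidx <- rep(seq_len(K), vapply(seglist, function(s) length(s$start), 0L))
  structure(list(segments = seglist, q = q, K = K,
                 stack = list(len = lens, Z = Zall, trap = tidx)),
            class = "scr_schedule")
}

#' @export
print.scr_schedule <- function(x, ...) {
  cat(sprintf("scr_schedule: %d traps, %d temporal covariate(s), %d segments total\n",
              x$K, x$q, length(x$stack$len)))
  invisible(x)
}

#' Equal day/night schedule
#'
#' Builds the alternating day/night schedule used in simulation: each unit of
#' time is split into a daytime half (z = 1) followed by a nighttime half
#' (z = 0), so day and night occupy equal total durations.
#'
#' @param traps an \code{scr_traps}; each T_k should be a whole number of
#'   time units (a trailing partial unit is split in the same proportion).
#' @param day_fraction fraction of each unit that is daytime (default 0.5).
#' @return an \code{scr_schedule} with one binary covariate column \code{z}.
#' @export
equal_split_schedule <- function(traps, day_fraction = 0.5) {
  stopifnot(day_fraction >= 0, day_fraction <= 1)
  segs <- lapply(seq_len(traps$K), function(k) {
    Tk <- traps$T[k]
    nfull <- floor(Tk + 1e-9)
    st <- numeric(0); en <- numeric(0); z <- numeric(0)
    for (j in seq_len(nfull)) {
      if (day_fraction > 0) {
        st <- c(st, j - 1); en <- c(en, j - 1 + day_fraction); z <- c(z, 1)
      }
      if (day_fraction < 1) {
        st <- c(st, j - 1 + day_fraction); en <- c(en, j); z <- c(z, 0)
      }
    }
    rem <- Tk - nfull
    if (rem > 1e-9) {
      if (day_fraction > 0) {
        st <- c(st, nfull); en <- c(en, nfull + rem * day_fraction); z <- c(z, 1)
      }
      if (day_fraction < 1) {
        st <- c(st, nfull + rem * day_fraction); en <- c(en, Tk); z <- c(z, 0)
      }
    }
    data.frame(start = st, end = en, z = z)
  })
  scr_schedule(segs, traps)
}

#' Per-trap time-integrated temporal effect
#'
#' For piecewise-constant z(t), the integral of gamma(t) = exp(xi' z(t)) over
#' (0, T_k] has the closed form sum over segments of exp(xi' z_seg) times the
#' segment length. With an empty xi (restricted model) it reduces to T_k.
#'
#' @param schedule an \code{scr_schedule}, or NULL for a constant-gamma model.
#' @param xi temporal-effect coefficients (length q), or NULL/empty.
#' @param traps needed when \code{schedule} is NULL, to return T_k.
#' @return numeric vector of length K.
#' @export
schedule_gamma_integral <- function(schedule, xi, traps = NULL) {
  if (is.null(schedule) || is.null(xi) || length(xi) == 0L) {
    if (!is.null(schedule)) {
      s <- schedule$stack
      return(as.numeric(rowsum(s$len, s$trap)))  # = T_k
    }
    if (is.null(traps)) stop("need traps to evaluate a constant-gamma integral")
    return(traps$T)
  }
  if (length(xi) != schedule$q) stop("xi dimension does not match schedule covariates")
  s <- schedule$stack
  as.numeric(rowsum(s$len * exp(drop(s$Z %*% xi)), s$trap))
}

#' Evaluate the temporal covariate path at given times
#'
#' @param schedule an \code{scr_schedule}.
#' @param trap trap index.
#' @param times numeric vector of times in (0, T_k].
#' @return matrix (length(times) x q) of covariate values. Times are matched
#'   to half-open segments (start, end].
#' @export
schedule_z_at <- function(schedule, trap, times) {
  seg <- schedule$segments[[trap]]
  # (start, end] matching: findInterval on starts with left-open convention
  idx <- findInterval(times - 1e-12, seg$start)
  if (any(idx < 1L) || any(times > seg$end[length(seg$end)] + 1e-9))
    stop("time outside the trap's operating window")
  out <- seg$Z[idx, , drop = FALSE]
  dimnames(out) <- NULL
  out
}
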