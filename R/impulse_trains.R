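#' Build an excitation impulse train from a rate trajectory
#'
#' Converts one MU's firing-rate trajectory `r(t)` (piecewise constant over
#' grid steps) into an ordered list of firing times on the grid. The first
#' impulse fires at the first grid time with `r > 0`; each subsequent
#' impulse fires at the earliest grid time `t` satisfying
#' `t >= phi_prev + 1/r(t) - C_prev`, where the carried correction `C`
#' estimates, by linear interpolation between adjacent grid steps, when the
#' impulse would have fired in continuous time, cancelling the systematic
#' interval lengthening that pure grid rounding would cause. While `r = 0`
#' the pending interval requirement is re-evaluated each step from the last
#' firing time and no impulse fires.
#'
#' @param rates Numeric vector of rates \[Hz\] on a uniform grid, `>= 0`.
#' @param dt Grid step \[s\].
#' @param mu_index Optional MU index carried in the result.
#' @return An object of class `impulse_train`: list with `phi` (firing
#'   times \[s\]), `n` (impulse count), `dt`, `T_end`, `mu_index`.
#' @examples
#' tr <- build_impulse_train(rep(10, 501), dt = 0.002)
#' diff(tr$phi)[1:3]  # 0.1 s intervals
#' @export
build_impulse_train <- function(rates, dt, mu_index = 1L) {
  rates <- as.numeric(rates)
  if (anyNA(rates) || any(rates < 0)) stop("rates must be nonnegative and finite")
  stopifnot(dt > 0)
  phi <- build_train_cpp(rates, dt)
  structure(list(phi = phi, n = length(phi), dt = dt,
                 T_end = (length(rates) - 1) * dt,
                 mu_index = as.integer(mu_index)),
            class = "impulse_train")
}

#' @export
print.impulse_train <- function(x, ...) {
  cat(sprintf("<impulse_train MU %d> %d impulses over %.3f s (dt=%g s)\n",
              x$mu_index, x$n, x$T_end, x$dt))
  invisible(x)
}

#' Instantaneous firing frequency of an impulse train
#'
#' The raw frequency at impulse `j >= 2` is the reciprocal of the preceding
#' inter-impulse interval, `1 / (phi_j - phi_{j-1})`; the series is smoothed
#' with a centered moving average (default 5 samples) whose window shrinks
#' symmetrically at the edges.
#'
#' @param train An [build_impulse_train()] object.
#' @param window Odd window length `>= 1` (samples).
#' @return Data frame with columns `t` (time of impulse `j`), `raw` and
#'   `smoothed` frequencies \[Hz\]; zero rows for trains with fewer than two
#'   impulses.
#' @export
instantaneous_frequency <- function(train, window = 5L) {
  stopifnot(inherits(train, "impulse_train"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be an odd integer >= 1")
  if (train$n < 2L)
    return(data.frame(t = numeric(0), raw = numeric(0), smoothed = numeric(0)))
  raw <- 1 / diff(train$phi)
  m <- length(raw)
  half <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(m), function(j) {
    h <- min(half, j - 1L, m - j)
    mean(raw[(j - h):(j + h)])
  }, numeric(1))
  data.frame(t = train$phi[-1], raw = raw, smoothed = sm)
}

#' Write impulse trains as a delimited event list
#'
#' @param trains A list of `impulse_train` objects (or a single one).
#' @param file Output path; tab-separated columns `mu_index`, `time_s`.
#' @export
write_event_list <- function(trains, file) {
  if (inherits(trains, "impulse_train")) trains <- list(trains)
  rows <- do.call(rbind, lapply(trains, function(tr)
    if (tr$n > 0) data.frame(mu_index = tr$mu_index, time_s = tr$phi) else NULL))
  if (is.null(rows)) rows <- data.frame(mu_index = integer(0), time_s = numeric(0))
  write.table(rows, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read an event list written by [write_event_list()]
#'
#' @param file Path to the event list.
#' @param dt Grid step \[s\] of the originating simulation.
#' @param T_end Horizon \[s\]; defaults to the last event time.
#' @return Named list of `impulse_train` objects, one per MU present.
#' @export
read_event_list <- function(file, dt, T_end = NULL) {
  d <- read.table(file, header = TRUE, sep = "\t")
  if (is.null(T_end)) T_end <- if (nrow(d)) max(d$time_s) else 0
  out <- lapply(split(d$time_s, d$mu_index), function(phi)
    structure(list(phi = sort(phi), n = length(phi), dt = dt, T_end = T_end,
                   mu_index = NA_integer_), class = "impulse_train"))
  for (nm in names(out)) out[[nm]]$mu_index <- as.integer(nm)
  out
}
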