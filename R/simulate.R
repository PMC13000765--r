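#' Simulate decay times of a constant-activity source
#'
#' Homogeneous Poisson process: the number of decays in the acquisition is
#' Poisson with mean `activity_bq * duration_ps * 1e-12` and decay times are
#' independent and uniform over the acquisition. Activity is treated as
#' constant over the (short) acquisition; radioactive decay of the source
#' itself is not modelled.
#'
#' @param activity_bq source activity in becquerel (> 0).
#' @param duration_ps acquisition length in integer picoseconds (> 0).
#' @param seed optional integer seed for reproducibility.
#' @return Sorted numeric vector of integer-valued decay times in
#'   picoseconds.
#' @export
simulate_decays <- function(activity_bq, duration_ps, seed = NULL) {
  if (!is.numeric(activity_bq) || length(activity_bq) != 1L || activity_bq <= 0)
    stop("activity_bq must be a positive number")
  if (!is.numeric(duration_ps) || length(duration_ps) != 1L || duration_ps <= 0)
    stop("duration_ps must be a positive number")
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, activity_bq * duration_ps * 1e-12)
  sort(floor(stats::runif(n, 0, duration_ps)))
}

#' Emit detected singles from a list of decays
#'
#' For each decay, independently: with probability `eps2` both annihilation
#' photons are detected, with probability `eps1` exactly one, otherwise
#' none; independently, for a beta+-gamma emitter, the prompt gamma is
#' detected with probability `eps_gamma`. Every detected photon is stamped
#' with the decay time plus Gaussian timing jitter (per-photon sigma
#' `ctr_fwhm_ps / (2.3548 * sqrt(2))`), rounded to the integer picosecond
#' grid, and assigned a detector block. The prompt gamma is emitted
#' simultaneously with the decay and receives the same jitter.
#'
#' @param decay_times sorted numeric vector of decay times (ps).
#' @param isotope an [isotope_model].
#' @param detector a [detector_model].
#' @param seed optional integer seed.
#' @param activity_bq,duration_ps bookkeeping fields stored on the stream
#'   (used as rate denominators downstream).
#' @return A `singles_stream`: list with element `events`, a data.frame
#'   sorted by `time_ps` (ties broken by generation order) with columns
#'   `time_ps`, `decay_id` (1-based index into `decay_times`), `kind`
#'   (0 = annihilation, 1 = prompt gamma), `block_id` (0-based) and
#'   `energy_kev` (0 when energy simulation is off), plus acquisition
#'   metadata.
#' @export
emit_singles <- function(decay_times, isotope, detector, seed = NULL,
                         activity_bq = NA_real_, duration_ps = NA_real_) {
  stopifnot(inherits(isotope, "isotope_model"),
            inherits(detector, "detector_model"))
  if (is.unsorted(decay_times)) stop("decay_times must be sorted")
  if (!is.null(seed)) set.seed(seed)
  n <- length(decay_times)

  u <- stats::runif(n)
  n_annih <- (u < isotope$eps2) + (u < isotope$eps2 + isotope$eps1)
  has_gamma <- if (isotope$emits_prompt_gamma)
    stats::runif(n) < isotope$eps_gamma else rep(FALSE, n)

  first  <- which(n_annih >= 1)    # decays contributing >= 1 annihilation photon
  second <- which(n_annih == 2)
  gam    <- which(has_gamma)

  dec_id <- c(first, second, gam)
  t0     <- decay_times[dec_id]
  kind   <- c(rep(0L, length(first) + length(second)), rep(1L, length(gam)))

  sigma <- detector$ctr_fwhm_ps / (2 * sqrt(2 * log(2)) * sqrt(2))
  tt <- pmax(0, round(t0 + stats::rnorm(length(t0), 0, sigma)))

  nb <- detector$n_blocks
  block <- sample.int(nb, length(t0), replace = TRUE) - 1L
  if (detector$pair_block_mode == "opposed" && length(second)) {
    # second photon of a pair lands on the opposite block +/- 1
    i2 <- length(first) + seq_along(second)
    b1 <- block[match(second, first)]
    block[i2] <- (b1 + nb %/% 2L +
                    sample(c(-1L, 0L, 1L), length(second), replace = TRUE)) %% nb
  }

  energy <- rep(0, length(t0))
  if (!is.na(detector$energy_resolution_frac)) {
    fr <- detector$energy_resolution_frac
    e0 <- ifelse(kind == 0L, 511, 1274)
    # fractional FWHM scales as 1/sqrt(E) from its 511 keV reference
    fwhm <- e0 * fr * sqrt(511 / e0)
    energy <- round(pmax(0, stats::rnorm(length(t0), e0, fwhm / 2.3548)))
  }

  ord <- order(tt, method = "radix")  # stable: ties keep generation order
  events <- data.frame(
    time_ps = tt[ord],
    decay_id = dec_id[ord],
    kind = kind[ord],
    block_id = block[ord],
    energy_kev = energy[ord]
  )
  new_singles_stream(events,
                     duration_ps = duration_ps,
                     activity_bq = activity_bq,
                     isotope = isotope, detector = detector, seed = seed)
}

new_singles_stream <- function(events, duration_ps, activity_bq, isotope,
                               detector, seed = NULL) {
  s <- structure(list(
    events = events,
    duration_ps = duration_ps,
    activity_bq = activity_bq,
    isotope = isotope,
    detector = detector,
    seed = if (is.null(seed)) NA_integer_ else seed
  ), class = "singles_stream")
  validate_singles_stream(s)
  s
}

validate_singles_stream <- function(s) {
  ev <- s$events
  need <- c("time_ps", "decay_id", "kind", "block_id", "energy_kev")
  if (!all(need %in% names(ev))) stop("singles_stream events lack required columns")
  if (nrow(ev) && is.unsorted(ev$time_ps)) stop("singles_stream events must be time-sorted")
  if (nrow(ev) && any(ev$time_ps < 0)) stop("negative timestamps in singles_stream")
  invisible(s)
}

#' @export
print.singles_stream <- function(x, ...) {
  cat(sprintf("<singles_stream> %d singles over %.3g s (activity %.3g Bq, seed %s)\n",
              nrow(x$events),
              x$duration_ps * 1e-12, x$activity_bq,
              ifelse(is.na(x$seed), "-", as.character(x$seed))))
  if (!is.null(x$isotope)) cat("  isotope:", x$isotope$name, "\n")
  invisible(x)
}

#' Number of singles in a stream
#' @param stream a `singles_stream`.
#' @return Integer count of singles.
#' @export
n_singles <- function(stream) nrow(stream$events)

#' Simulate a complete singles stream
#'
#' Convenience wrapper chaining [simulate_decays()], [emit_singles()] and,
#' if the detector has a positive dead time, [apply_dead_time()].
#'
#' @param activity_bq source activity in Bq.
#' @param duration_s acquisition length in seconds.
#' @param isotope an [isotope_model].
#' @param detector a [detector_model].
#' @param seed optional integer seed.
#' @return A `singles_stream`.
#' @examples
#' iso <- isotope_model("demo", eps1 = 0.4, eps2 = 0.14)
#' s <- simulate_stream(1e6, 1e-3, iso, detector_model(), seed = 1)
#' n_singles(s)
#' @export
simulate_stream <- function(activity_bq, duration_s, isotope, detector,
                            seed = NULL) {
  duration_ps <- duration_s * 1e12
  dt <- simulate_decays(activity_bq, duration_ps, seed = seed)
  s <- emit_singles(dt, isotope, detector, seed = NULL,
                    activity_bq = activity_bq, duration_ps = duration_ps)
  s$seed <- if (is.null(seed)) NA_integer_ else seed
  if (detector$dead_time_ps > 0) s <- apply_dead_time(s, detector$dead_time_ps)
  s
}

#' Apply non-paralyzable per-block dead time
#'
#' A single is removed if it occurs within `dead_time_ps` after the last
#' accepted single on the same block (non-paralyzable model: rejected
#' singles do not extend the dead period). Ordering is preserved.
#'
#' @param stream a `singles_stream`.
#' @param dead_time_ps dead time in picoseconds (>= 0).
#' @return The filtered `singles_stream`.
#' @export
apply_dead_time <- function(stream, dead_time_ps) {
  stopifnot(inherits(stream, "singles_stream"))
  if (!is.numeric(dead_time_ps) || dead_time_ps < 0)
    stop("dead_time_ps must be >= 0")
  if (dead_time_ps == 0 || nrow(stream$events) == 0L) return(stream)
  ev <- stream$events
  keep <- rep(TRUE, nrow(ev))
  for (b in unique(ev$block_id)) {
    sel <- which(ev$block_id == b)
    keep[sel] <- .dead_time_keep(ev$time_ps[sel], dead_time_ps)
  }
  stream$events <- ev[keep, , drop = FALSE]
  rownames(stream$events) <- NULL
  stream
}

# Iterative vectorized non-paralyzable scan: in each pass, drop the first
# event of every run of too-small gaps, then recompute against the new
# predecessors. Converges because each pass fixes at least one event.
.dead_time_keep <- function(t, d) {
  keep <- rep(TRUE, length(t))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) break
    gaps <- diff(t[idx])
    bad <- gaps < d
    if (!any(bad)) break
    # only the first bad gap of each consecutive run is decidable this pass
    first_of_run <- bad & !c(FALSE, bad[-length(bad)])
    keep[idx[which(first_of_run) + 1L]] <- FALSE
  }
  keep
}
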