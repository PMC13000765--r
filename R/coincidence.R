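#' Coincidence window configuration
#'
#' The multiple-window method is used throughout: every single opens a
#' coincidence time window of length `tau_ps`, and a partner j qualifies
#' iff `0 < t_j - t_i <= tau_ps`. A veto scheme additionally requires
#' stated intervals to be free of other singles:
#'
#' * `vno` - no vetoes; all in-window combinations are formed (three
#'   double combinations from three singles in a window).
#' * `vbetween` - only neighbouring singles are combined (two doubles from
#'   three singles in a window).
#' * `vinner` - adjacent pair (i, i+1) accepted iff `t[i+2] - t[i] > tau`
#'   and `t[i+1] - t[i-1] > tau`.
#' * `vouter` - adjacent pair accepted iff `t[i] - t[i-1] > tau` and
#'   `t[i+2] - t[i+1] > tau` (neither member in coincidence with any other
#'   single).
#'
#' Missing neighbours at the stream edges are treated as infinitely far
#' away, so the guards pass. All veto inequalities are strict, and
#' timestamps live on an integer-picosecond grid, making every comparison
#' exact.
#'
#' @param tau_ps coincidence time window in picoseconds (> 0).
#' @param scheme one of `"vno"`, `"vbetween"`, `"vinner"`, `"vouter"`.
#' @param max_order highest multiple order to consider (>= 2).
#' @return An object of class `window_config`.
#' @export
window_config <- function(tau_ps, scheme = c("vouter", "vinner", "vbetween", "vno"),
                          max_order = 2L) {
  scheme <- match.arg(scheme)
  if (!is.numeric(tau_ps) || tau_ps <= 0) stop("tau_ps must be > 0")
  if (max_order < 2) stop("max_order must be >= 2")
  structure(list(tau_ps = tau_ps, scheme = scheme,
                 max_order = as.integer(max_order)),
            class = "window_config")
}

.stream_times <- function(stream) {
  if (inherits(stream, "singles_stream")) {
    # streams are validated at construction / read time
    stream$events$time_ps
  } else if (is.numeric(stream)) {
    if (is.unsorted(stream)) stop("times must be sorted")
    stream
  } else stop("expected a singles_stream or a sorted numeric time vector")
}

# count of events with a <= t <= b for each (a, b); exact on the
# integer-ps grid including fractional interval endpoints
.n_in <- function(t, a, b) .count_in_closed(a, b, t)

#' Identify prompt double coincidences
#'
#' Scans a time-sorted singles stream for double coincidences under the
#' configured veto scheme (see [window_config()] for the acceptance rules).
#'
#' @param stream a `singles_stream` (or a sorted numeric vector of
#'   timestamps in ps).
#' @param cfg a [window_config()].
#' @return A data.frame with one row per accepted double: member indices
#'   `i`, `j` (time order) and `dt_ps = t[j] - t[i]`; the scheme and
#'   `tau_ps` are attached as attributes.
#' @examples
#' cfg <- window_config(2600, "vno")
#' find_prompt_doubles(c(0, 1000, 2000), cfg)   # 3 combinations
#' @export
find_prompt_doubles <- function(stream, cfg) {
  stopifnot(inherits(cfg, "window_config"))
  t <- .stream_times(stream)
  tau <- cfg$tau_ps
  n <- length(t)
  if (n < 2L) {
    out <- data.frame(i = integer(), j = integer(), dt_ps = numeric())
  } else if (cfg$scheme == "vno") {
    lo <- .fi_sorted(t, t)                   # last index with time <= t[i]
    cnt <- .fi_sorted(t + tau, t) - lo
    i <- rep.int(seq_len(n), cnt)
    j <- sequence(cnt, from = lo + 1L)
    out <- data.frame(i = i, j = j, dt_ps = t[j] - t[i])
  } else {
    g <- t[-1L] - t[-n]
    cand <- which(g > 0 & g <= tau)
    if (length(cand) && cfg$scheme != "vbetween") {
      t_im1 <- ifelse(cand > 1L, t[pmax(cand - 1L, 1L)], -Inf)
      t_ip2 <- ifelse(cand + 2L <= n, t[pmin(cand + 2L, n)], Inf)
      keep <- if (cfg$scheme == "vinner")
        (t_ip2 - t[cand] > tau) & (t[cand + 1L] - t_im1 > tau)
      else  # vouter
        (t[cand] - t_im1 > tau) & (t_ip2 - t[cand + 1L] > tau)
      cand <- cand[keep]
    }
    out <- data.frame(i = cand, j = cand + 1L, dt_ps = t[cand + 1L] - t[cand])
  }
  attr(out, "scheme") <- cfg$scheme
  attr(out, "tau_ps") <- tau
  out
}

# doubles for several schemes in one pass over the gap vector
.prompt_doubles_all <- function(t, tau, schemes) {
  n <- length(t)
  out <- list()
  adj <- intersect(schemes, c("vbetween", "vinner", "vouter"))
  if (length(adj) && n >= 2L) {
    g <- t[-1L] - t[-n]
    cand0 <- which(g > 0 & g <= tau)
    t_im1 <- ifelse(cand0 > 1L, t[pmax(cand0 - 1L, 1L)], -Inf)
    t_ip2 <- ifelse(cand0 + 2L <= n, t[pmin(cand0 + 2L, n)], Inf)
    for (sc in adj) {
      cand <- switch(sc,
        vbetween = cand0,
        vinner = cand0[(t_ip2 - t[cand0] > tau) &
                         (t[cand0 + 1L] - t_im1 > tau)],
        vouter = cand0[(t[cand0] - t_im1 > tau) &
                         (t_ip2 - t[cand0 + 1L] > tau)])
      out[[sc]] <- data.frame(i = cand, j = cand + 1L,
                              dt_ps = t[cand + 1L] - t[cand])
    }
  } else {
    for (sc in adj)
      out[[sc]] <- data.frame(i = integer(), j = integer(), dt_ps = numeric())
  }
  if ("vno" %in% schemes)
    out$vno <- find_prompt_doubles(t, window_config(tau, "vno"))
  out
}

#' Identify prompt multiples of a given order
#'
#' A group of `m` consecutive singles `i..i+m-1` is an order-m candidate
#' iff its total span `t[i+m-1] - t[i]` is within one coincidence window
#' (`<= tau`). The veto windows are initiated at the timestamps of the
#' first and last single of the group: `vouter` requires
#' `t[i] - t[i-1] > tau` and `t[i+m] - t[i+m-1] > tau`; `vinner` requires
#' `t[i+m] - t[i] > tau` and `t[i+m-1] - t[i-1] > tau`; `vbetween` reports
#' every consecutive m-tuple with span `<= tau`; `vno` reports all
#' m-subsets with span `<= tau` (combinations, counted once).
#'
#' For beta+-gamma triple selection set
#' `composition = "two_annih_one_gamma"` to keep only triples whose members
#' are two annihilation-window photons and one prompt-gamma-window photon.
#'
#' @param stream a `singles_stream` (kind information is required for the
#'   composition filter) or sorted numeric times.
#' @param cfg a [window_config()].
#' @param order multiple order m (>= 3).
#' @param composition `"any"` or `"two_annih_one_gamma"` (order 3 only).
#' @return A list of class `prompt_multiples`: `members` (integer matrix,
#'   one row per accepted multiple, m columns of event indices in time
#'   order), `span_ps`, `order`, `scheme`, `tau_ps`.
#' @export
find_prompt_multiples <- function(stream, cfg, order = 3L,
                                  composition = c("any", "two_annih_one_gamma")) {
  stopifnot(inherits(cfg, "window_config"))
  composition <- match.arg(composition)
  m <- as.integer(order)
  if (m < 3L) stop("order must be >= 3; use find_prompt_doubles() for doubles")
  t <- .stream_times(stream)
  tau <- cfg$tau_ps
  n <- length(t)

  members <- if (n < m) {
    matrix(integer(), 0L, m)
  } else if (cfg$scheme == "vno") {
    .enum_vno_subsets(t, tau, m)
  } else {
    i <- seq_len(n - m + 1L)
    span_ok <- t[i + m - 1L] - t[i] <= tau & t[i + m - 1L] - t[i] > 0
    i <- i[span_ok]
    if (length(i) && cfg$scheme != "vbetween") {
      t_im1 <- ifelse(i > 1L, t[pmax(i - 1L, 1L)], -Inf)
      t_ipm <- ifelse(i + m <= n, t[pmin(i + m, n)], Inf)
      keep <- if (cfg$scheme == "vinner")
        (t_ipm - t[i] > tau) & (t[i + m - 1L] - t_im1 > tau)
      else  # vouter
        (t[i] - t_im1 > tau) & (t_ipm - t[i + m - 1L] > tau)
      i <- i[keep]
    }
    outer(i, 0L:(m - 1L), `+`)
  }

  if (composition == "two_annih_one_gamma") {
    if (m != 3L) stop("composition filter applies to triples only")
    if (!inherits(stream, "singles_stream"))
      stop("composition filter needs photon kinds; pass a singles_stream")
    k <- stream$events$kind
    keep <- (matrix(k[members], nrow(members), 3L) |> rowSums()) == 1L
    members <- members[keep, , drop = FALSE]
  }

  structure(list(
    members = members,
    span_ps = if (nrow(members)) t[members[, m]] - t[members[, 1L]] else numeric(),
    order = m, scheme = cfg$scheme, tau_ps = tau
  ), class = "prompt_multiples")
}

# all m-subsets with 0 < span <= tau, anchored at their lowest-index
# member; later members are any of the in-window singles after the anchor
# in sort order (internal timestamp ties allowed, all-tie groups are not)
.enum_vno_subsets <- function(t, tau, m) {
  n <- length(t)
  cnt <- .fi_sorted(t + tau, t) - seq_len(n)     # in-window singles after i
  anchors <- which(cnt >= m - 1L)
  if (!length(anchors)) return(matrix(integer(), 0L, m))
  members <- if (m == 3L) {
    # pairs (r < s) of offsets among the k in-window singles after each
    # anchor, by two-level expansion: r runs 1..k-1, s over r+1..k
    k <- cnt[anchors]
    a_r <- rep.int(anchors, k - 1L)
    r <- sequence(k - 1L)
    c_r <- rep.int(k, k - 1L) - r          # partners s available per r
    a <- rep.int(a_r, c_r)
    cbind(a, a + rep.int(r, c_r), a + sequence(c_r, from = r + 1L))
  } else {
    out <- lapply(anchors, function(i) {
      cmb <- utils::combn(i + seq_len(cnt[i]), m - 1L)
      cbind(i, t(cmb))
    })
    do.call(rbind, out)
  }
  members[t[members[, m]] - t[members[, 1L]] > 0, , drop = FALSE]
}

#' Classify coincidences against decay-ID ground truth
#'
#' @param members integer matrix of event indices (one coincidence per
#'   row, members in time order), or the data.frame returned by
#'   [find_prompt_doubles()], or a `prompt_multiples` object.
#' @param stream the `singles_stream` the indices refer to; ground-truth
#'   decay IDs must be present (non-negative).
#' @return A data.frame with `n_decays` (distinct decay IDs among the
#'   members), `is_true` (all members share one decay), and - for
#'   two-decay triples - `odd_position`: `"I"`, `"II"` or `"III"` as the
#'   single from the lone decay precedes, sits between, or follows the
#'   pair from the other decay (`NA` otherwise).
#' @export
classify_coincidences <- function(members, stream) {
  if (inherits(members, "prompt_multiples")) members <- members$members
  if (is.data.frame(members)) members <- cbind(members$i, members$j)
  stopifnot(inherits(stream, "singles_stream"))
  ids <- stream$events$decay_id
  if (any(ids < 0)) stop("ground truth unavailable: stream has decay_id < 0")
  m <- ncol(members)
  if (nrow(members) == 0L)
    return(data.frame(n_decays = integer(), is_true = logical(),
                      odd_position = character()))
  if (m == 2L) {
    same <- ids[members[, 1L]] == ids[members[, 2L]]
    return(data.frame(n_decays = ifelse(same, 1L, 2L), is_true = same,
                      odd_position = NA_character_))
  }
  if (m == 3L) {
    a <- ids[members[, 1L]]; b <- ids[members[, 2L]]; c_ <- ids[members[, 3L]]
    ab <- a == b; ac <- a == c_; bc <- b == c_
    n_dec <- ifelse(ab & bc, 1L, ifelse(ab | ac | bc, 2L, 3L))
    odd <- rep(NA_character_, length(a))
    odd[n_dec == 2L & bc] <- "I"     # lone decay first
    odd[n_dec == 2L & ac] <- "II"    # lone decay in the middle
    odd[n_dec == 2L & ab] <- "III"   # lone decay last
    return(data.frame(n_decays = n_dec, is_true = n_dec == 1L,
                      odd_position = odd))
  }
  idm <- matrix(ids[members], nrow(members), m)
  n_dec <- apply(idm, 1L, function(r) length(unique(r)))
  data.frame(n_decays = n_dec, is_true = n_dec == 1L,
             odd_position = NA_character_)
}

#' Flag paired and unpaired singles
#'
#' An annihilation single is *paired* iff the other annihilation photon of
#' its decay is also present in the stream, and *unpaired* otherwise.
#' Prompt-gamma singles are flagged separately (they are never "paired" in
#' the annihilation sense).
#'
#' @param stream a `singles_stream` with ground-truth decay IDs.
#' @return Character vector (`"paired"`, `"unpaired"`, `"gamma"`), one
#'   entry per single.
#' @export
flag_paired_singles <- function(stream) {
  stopifnot(inherits(stream, "singles_stream"))
  ev <- stream$events
  if (nrow(ev) == 0L) return(character())
  if (any(ev$decay_id < 0)) stop("ground truth unavailable: decay_id < 0 present")
  out <- rep("unpaired", nrow(ev))
  out[ev$kind == 1L] <- "gamma"
  an <- which(ev$kind == 0L)
  ids <- ev$decay_id[an]
  dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
  out[an[dup]] <- "paired"
  out
}

#' Histogram of prompt multiples by order
#'
#' Counts accepted order-m multiples for each requested order under one
#' veto scheme. For `vno` the count is the closed-form number of
#' m-subsets with span within the window; for the other schemes it is the
#' number of accepted consecutive groups.
#'
#' @param stream a `singles_stream` or sorted times.
#' @param cfg a [window_config()].
#' @param orders integer vector of orders (>= 2).
#' @return data.frame with columns `order`, `count`, `duration_ps`, `rate`.
#' @export
multiples_histogram <- function(stream, cfg, orders = 2:6) {
  stopifnot(inherits(cfg, "window_config"))
  t <- .stream_times(stream)
  dur <- if (inherits(stream, "singles_stream")) stream$duration_ps else NA_real_
  counts <- vapply(as.integer(orders), function(m) {
    if (m == 2L) {
      nrow(find_prompt_doubles(t, cfg))
    } else if (cfg$scheme == "vno") {
      hi_cnt <- .fi_sorted(t + cfg$tau_ps, t) - seq_along(t)
      tie_cnt <- .fi_sorted(t, t) - seq_along(t)
      # subtract the all-tie (zero-span) subsets
      sum(choose(hi_cnt, m - 1L)) - sum(choose(tie_cnt, m - 1L))
    } else {
      n <- length(t)
      if (n < m) return(0)
      i <- seq_len(n - m + 1L)
      span_ok <- t[i + m - 1L] - t[i] <= cfg$tau_ps & t[i + m - 1L] - t[i] > 0
      i <- i[span_ok]
      if (length(i) && cfg$scheme != "vbetween") {
        t_im1 <- ifelse(i > 1L, t[pmax(i - 1L, 1L)], -Inf)
        t_ipm <- ifelse(i + m <= n, t[pmin(i + m, n)], Inf)
        keep <- if (cfg$scheme == "vinner")
          (t_ipm - t[i] > cfg$tau_ps) & (t[i + m - 1L] - t_im1 > cfg$tau_ps)
        else if (cfg$scheme == "vouter")
          (t[i] - t_im1 > cfg$tau_ps) & (t_ipm - t[i + m - 1L] > cfg$tau_ps)
        else rep(TRUE, length(i))
        i <- i[keep]
      }
      length(i)
    }
  }, numeric(1L))
  data.frame(order = as.integer(orders), count = counts,
             duration_ps = dur, rate = counts / (dur * 1e-12))
}
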