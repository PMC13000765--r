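#' Delayed-window counting scheme specification
#'
#' Describes one delayed coincidence counting scheme. For doubles the
#' variants `d1`, `d2`, `d3` mirror a veto family's prompt geometry around
#' the opener and/or delayed partner (d1: vetoes around both singles; d2:
#' around one; d3: around one but with doubled interval). For triples the
#' variants are `t_1delay` (real double plus one delayed single),
#' `t_2delays` (both the pair gap and the third single delayed),
#' `t_1delay_dveto` / `t_2delays_dveto` (additionally vetoing around every
#' member, used for beta+-gamma emitters), and `t_scale1` / `t_scale2` /
#' `t_scale3` (two delayed windows of size tau with per-single veto
#' intervals of total length L, 2L, 3L, where `L = 2*tau + span`).
#'
#' @param family veto family mirrored: `"vouter"`, `"vinner"`,
#'   `"vbetween"` or `"vno"`.
#' @param variant scheme variant, see Details.
#' @param delta_ps primary delay (must greatly exceed tau; >= 100 tau is
#'   enforced with a warning below, an error at `delta <= tau`).
#' @param delta2_ps secondary delay for two-delay variants (defaults to
#'   `delta_ps`; the third single's window is then anchored at
#'   `delta_ps + delta2_ps`, keeping all windows disjoint).
#' @return An object of class `delayed_scheme`.
#' @export
delayed_scheme <- function(family = c("vouter", "vinner", "vbetween", "vno"),
                           variant = c("d1", "d2", "d3",
                                       "t_1delay", "t_2delays",
                                       "t_1delay_dveto", "t_2delays_dveto",
                                       "t_scale1", "t_scale2", "t_scale3"),
                           delta_ps = 5e6, delta2_ps = delta_ps) {
  family <- match.arg(family)
  variant <- match.arg(variant)
  if (delta_ps <= 0 || delta2_ps <= 0) stop("delays must be positive")
  structure(list(family = family, variant = variant,
                 delta_ps = delta_ps, delta2_ps = delta2_ps),
            class = "delayed_scheme")
}

.check_delta <- function(delta_ps, tau_ps) {
  if (delta_ps <= tau_ps)
    stop("delay must exceed the coincidence window (delta > tau)")
  if (delta_ps < 100 * tau_ps)
    warning("delay below 100*tau; prompt and delayed windows may correlate")
}

.new_delayed_counts <- function(count, duration_ps, spec) {
  structure(list(count = count, duration_ps = duration_ps,
                 rate = count / (duration_ps * 1e-12), spec = spec),
            class = "delayed_counts")
}

#' @export
print.delayed_counts <- function(x, ...) {
  cat(sprintf("<delayed_counts> %s/%s: %d counts, %.4g /s\n",
              x$spec$family, x$spec$variant, x$count, x$rate))
  invisible(x)
}

# pairs (i, j) with t[j] - t[i] - offset in (0, tau]
.enum_pairs_offset <- function(t, tau, offset = 0) {
  n <- length(t)
  lo <- .fi_sorted(t + offset, t)
  cnt <- .fi_sorted(t + offset + tau, t) - lo
  i <- rep.int(seq_len(n), cnt)
  j <- sequence(cnt, from = lo + 1L)
  list(i = i, j = j, u = t[j] - t[i] - offset)
}

#' Count delayed double coincidences
#'
#' For each opener i, every partner k with
#' `u = t[k] - (t[i] + delta)` in `(0, tau]` is examined; the pair is
#' counted iff the scheme's veto intervals contain no single other than
#' the pair members themselves. The veto geometries mirror the prompt veto
#' schemes:
#'
#' * `vouter` d1: intervals of length `2*tau + u` around both the opener
#'   (`[t_i - tau, t_i + u + tau]`) and the partner
#'   (`[t_k - u - tau, t_k + tau]`); d2: only the opener interval; d3:
#'   only the opener interval, doubled (`[t_i - 2*tau, t_i + 2*(u+tau)]`).
#' * `vinner` d1: intervals of length `2*tau - u`
#'   (`[t_i - (tau-u), t_i + tau]` and `[t_k - tau, t_k + (tau-u)]`);
#'   d2/d3 analogously with a single / doubled opener interval.
#' * `vbetween` d1: both gap intervals `[t_i, t_i + u]` and
#'   `[t_i + delta, t_k]` empty; d2: only the partner-side gap; d3: the
#'   partner-side gap doubled (`[t_i + delta - u, t_k]`).
#' * `vno`: no vetoes.
#'
#' @param stream a `singles_stream`.
#' @param tau_ps coincidence window in ps.
#' @param spec a [delayed_scheme()] with a doubles variant (`d1`-`d3`;
#'   ignored for family `vno`).
#' @return A `delayed_counts` object (count, duration, rate).
#' @export
count_delayed_doubles <- function(stream, tau_ps, spec) {
  stopifnot(inherits(stream, "singles_stream"), inherits(spec, "delayed_scheme"))
  .check_delta(spec$delta_ps, tau_ps)
  t <- stream$events$time_ps
  p <- .enum_pairs_offset(t, tau_ps, spec$delta_ps)
  acc <- .delayed_double_accept(t, p, tau_ps, spec$delta_ps,
                                spec$family, spec$variant)
  .new_delayed_counts(sum(acc), stream$duration_ps, spec)
}

.delayed_double_accept <- function(t, p, tau, delta, family, variant) {
  if (!length(p$i)) return(logical(0))
  ti <- t[p$i]; tk <- t[p$j]; u <- p$u
  ok1 <- function(a, b) .n_in(t, a, b) == 1L
  switch(family,
    vno = rep(TRUE, length(ti)),
    vouter = switch(variant,
      d1 = ok1(ti - tau, ti + u + tau) & ok1(tk - u - tau, tk + tau),
      d2 = ok1(ti - tau, ti + u + tau),
      d3 = ok1(ti - 2 * tau, ti + 2 * (u + tau))),
    vinner = switch(variant,
      d1 = ok1(ti - (tau - u), ti + tau) & ok1(tk - tau, tk + (tau - u)),
      d2 = ok1(ti - (tau - u), ti + tau),
      d3 = ok1(ti - 2 * (tau - u), ti + 2 * tau)),
    vbetween = switch(variant,
      d1 = ok1(ti, ti + u) & ok1(ti + delta, tk),
      d2 = ok1(ti + delta, tk),
      d3 = ok1(ti + delta - u, tk))
  )
}

#' All delayed-doubles window schemes in one pass
#'
#' Convenience wrapper enumerating the delayed pairs once and evaluating
#' the `d1`, `d2`, `d3` vetoes (or the single veto-free count for family
#' `vno`) for one or several veto families on the same enumeration.
#'
#' @inheritParams count_delayed_doubles
#' @param family veto family, or a character vector of families.
#' @param delta_ps delay in ps.
#' @return For a single family, a named list of `delayed_counts` (`d1`,
#'   `d2`, `d3`, or `dno`); for several families, a named list of such
#'   lists.
#' @export
delayed_doubles_suite <- function(stream, tau_ps, family, delta_ps = 5e6) {
  stopifnot(inherits(stream, "singles_stream"))
  .check_delta(delta_ps, tau_ps)
  t <- stream$events$time_ps
  p <- .enum_pairs_offset(t, tau_ps, delta_ps)
  one <- function(fam) {
    if (fam == "vno") {
      spec <- delayed_scheme("vno", "d1", delta_ps)
      return(list(dno = .new_delayed_counts(length(p$i), stream$duration_ps,
                                            spec)))
    }
    out <- lapply(c("d1", "d2", "d3"), function(v) {
      acc <- .delayed_double_accept(t, p, tau_ps, delta_ps, fam, v)
      .new_delayed_counts(sum(acc), stream$duration_ps,
                          delayed_scheme(fam, v, delta_ps))
    })
    names(out) <- c("d1", "d2", "d3")
    out
  }
  if (length(family) == 1L) return(one(family))
  out <- lapply(family, one)
  names(out) <- family
  out
}

#' Estimate the random double rate from delayed window schemes
#'
#' Ratio combination of the three delayed window schemes:
#' `R_hat = D_d1 * D_d2 / D_d3` (rates), which cancels the mismatch
#' between the prompt and delayed veto interval sizes exactly under
#' homogeneous-Poisson singles. For family `vno`, `R_hat = D_no`.
#'
#' @param d1,d2,d3 `delayed_counts` for the three window schemes; for
#'   family `vno` pass only `d1` (the veto-free count).
#' @return A `random_estimate`: list with `estimate_rate`, `target`,
#'   `components`.
#' @examples
#' # rates 100, 300, 300 counts/s combine to 100/s
#' @export
estimate_randoms_doubles <- function(d1, d2 = NULL, d3 = NULL) {
  fam <- d1$spec$family
  if (fam == "vno") {
    est <- d1$rate
    comp <- list(dno = d1)
  } else {
    stopifnot(!is.null(d2), !is.null(d3))
    if (d3$count == 0)
      stop("undefined estimate: delayed window scheme 3 has zero counts")
    est <- d1$rate * d2$rate / d3$rate
    comp <- list(d1 = d1, d2 = d2, d3 = d3)
  }
  structure(list(target = paste0("doubles_", fam), estimate_rate = est,
                 components = comp), class = "random_estimate")
}

#' @export
print.random_estimate <- function(x, ...) {
  cat(sprintf("<random_estimate> %s: %.6g /s\n", x$target, x$estimate_rate))
  invisible(x)
}

# ---- delayed triples ------------------------------------------------------

# Enumerate (double {i,j}, single k) configurations and their virtual
# geometry. mode "1delay": real pair (gap u in (0,tau]) plus a delayed
# single k with t_k - delta in [t_i - (tau-u), t_i + tau] (the union of
# the before/between/after intervals, total length 2*tau - u).
# mode "2delays": the pair gap is itself delayed (u = t_j - t_i - delta2)
# and the k window is anchored at delta + delta2, keeping all windows
# disjoint. Virtual member positions are {0, u, w}; w = (t_k - shift) -
# t_i reconstructs the prompt-equivalent position of the odd single.
.enum_triple_configs <- function(t, tau, delta, delta2, mode) {
  pair_off <- if (mode == "1delay") 0 else delta2
  kshift <- if (mode == "1delay") delta else delta + delta2
  p <- .enum_pairs_offset(t, tau, pair_off)
  if (!length(p$i))
    return(list(i = integer(), j = integer(), k = integer(),
                u = numeric(), w = numeric()))
  ti <- t[p$i]; u <- p$u
  a <- ti + kshift - (tau - u)   # k-window lower edge (closed)
  b <- ti + kshift + tau
  klo <- .fi_sorted(ceiling(a) - 1, t)
  kcnt <- .count_in_closed(a, b, t)
  sel <- rep.int(seq_along(p$i), kcnt)
  k <- sequence(kcnt, from = klo + 1L)
  i <- p$i[sel]; j <- p$j[sel]
  w <- t[k] - kshift - t[i]
  list(i = i, j = j, k = k, u = p$u[sel], w = w)
}

# two delayed windows of size tau: j in (delta, delta+tau] and k in
# (delta+delta2, delta+delta2+tau] after the opener; virtual {0, u, w}
.enum_scale_configs <- function(t, tau, delta, delta2) {
  p <- .enum_pairs_offset(t, tau, delta)
  if (!length(p$i))
    return(list(i = integer(), j = integer(), k = integer(),
                u = numeric(), w = numeric()))
  ti <- t[p$i]
  off <- delta + delta2
  klo <- .fi_sorted(ti + off, t)
  kcnt <- .fi_sorted(ti + off + tau, t) - klo
  sel <- rep.int(seq_along(p$i), kcnt)
  k <- sequence(kcnt, from = klo + 1L)
  i <- p$i[sel]; j <- p$j[sel]
  list(i = i, j = j, k = k, u = p$u[sel], w = t[k] - t[i] - off)
}

.composition_keep <- function(stream, cf, composition) {
  if (composition == "any") return(rep(TRUE, length(cf$i)))
  kd <- stream$events$kind
  kd[cf$i] + kd[cf$j] + kd[cf$k] == 1L
}

# veto interval around a member at real time x and virtual position p,
# scaled by f: [x - f*((p - vmin) + tau), x + f*((vmax - p) + tau)]
.member_veto_ok <- function(t, x, p, vmin, vmax, tau, f = 1, expect = 1L) {
  .n_in(t, x - f * ((p - vmin) + tau), x + f * ((vmax - p) + tau)) == expect
}

#' Count delayed triple configurations
#'
#' Implements the delayed window schemes for random triple estimation.
#' A configuration is a double `{i, j}` plus a single `k` whose (delayed)
#' position falls in the union of the before/between/after intervals of
#' total length `2*tau - dt_ij`; the *virtual* member positions
#' `{0, u, w}` reconstruct the prompt-equivalent triple, whose span sets
#' the matched veto interval size `L = 2*tau + span`.
#'
#' Variants (see [delayed_scheme()]): `t_1delay` and `t_2delays` veto (for
#' family `"vouter"`) an interval of length `L` around the delayed single
#' only, or nothing for family `"vno"`; `t_1delay_dveto` additionally
#' vetoes around the included double; `t_2delays_dveto` vetoes around all
#' three singles; the `t_scaleN` variants use two delayed windows of size
#' tau and per-single intervals totalling `N * L / 3` each.
#'
#' @param stream a `singles_stream`.
#' @param tau_ps coincidence window (ps).
#' @param spec a [delayed_scheme()] with a triples variant.
#' @param composition `"any"`, or `"two_annih_one_gamma"` to keep only
#'   configurations of two annihilation photons and one prompt gamma
#'   (beta+-gamma mode).
#' @return A `delayed_counts` object.
#' @export
count_delayed_triples <- function(stream, tau_ps, spec,
                                  composition = c("any", "two_annih_one_gamma")) {
  stopifnot(inherits(stream, "singles_stream"), inherits(spec, "delayed_scheme"))
  composition <- match.arg(composition)
  .check_delta(spec$delta_ps, tau_ps)
  t <- stream$events$time_ps
  v <- spec$variant
  cf <- if (v %in% c("t_scale1", "t_scale2", "t_scale3"))
    .enum_scale_configs(t, tau_ps, spec$delta_ps, spec$delta2_ps)
  else
    .enum_triple_configs(t, tau_ps, spec$delta_ps, spec$delta2_ps,
                         mode = if (v %in% c("t_1delay", "t_1delay_dveto"))
                           "1delay" else "2delays")
  keep <- .composition_keep(stream, cf, composition)
  acc <- .delayed_triple_accept(t, cf, tau_ps, spec$family, v)
  .new_delayed_counts(sum(keep & acc), stream$duration_ps, spec)
}

.delayed_triple_accept <- function(t, cf, tau, family, variant) {
  if (!length(cf$i)) return(logical(0))
  ti <- t[cf$i]; tj <- t[cf$j]; tk <- t[cf$k]
  u <- cf$u; w <- cf$w
  if (variant %in% c("t_scale1", "t_scale2", "t_scale3")) {
    vmin <- 0; vmax <- pmax(u, w)
    f <- c(t_scale1 = 1, t_scale2 = 2, t_scale3 = 3)[[variant]] / 3
    return(.member_veto_ok(t, ti, 0, vmin, vmax, tau, f) &
           .member_veto_ok(t, tj, u, vmin, vmax, tau, f) &
           .member_veto_ok(t, tk, w, vmin, vmax, tau, f))
  }
  vmin <- pmin(0, w); vmax <- pmax(u, w)
  if (family == "vno" && variant %in% c("t_1delay", "t_2delays"))
    return(rep(TRUE, length(ti)))
  single_ok <- .member_veto_ok(t, tk, w, vmin, vmax, tau)
  switch(variant,
    t_1delay = ,
    t_2delays = single_ok,
    t_1delay_dveto =
      single_ok & .n_in(t, ti + vmin - tau, ti + vmax + tau) == 2L,
    t_2delays_dveto =
      single_ok &
      .member_veto_ok(t, ti, 0, vmin, vmax, tau) &
      .member_veto_ok(t, tj, u, vmin, vmax, tau)
  )
}

#' Delayed triple counting suites
#'
#' Enumerates each delayed-triple geometry once and evaluates all counts
#' needed by the triple random estimators. `mode = "beta"` returns the
#' one-delay and two-delay counts with the outer veto around the delayed
#' single plus the three scale-scheme counts; `mode = "betagamma_vouter"`
#' the double-vetoed one-/two-delay counts and energy-filtered scale
#' counts; `mode = "betagamma_vno"` the veto-free energy-filtered
#' one-/two-delay counts. Several modes can be requested at once; the
#' underlying configuration enumerations and veto evaluations are then
#' shared.
#'
#' @param stream a `singles_stream`.
#' @param tau_ps coincidence window (ps).
#' @param delta_ps primary delay; the secondary delay equals it.
#' @param mode which estimator family the counts feed (may be a vector).
#' @return For one mode, a named list of `delayed_counts`; for several, a
#'   named list of such lists.
#' @export
delayed_triples_suite <- function(stream, tau_ps, delta_ps = 5e6,
                                  mode = c("beta", "betagamma_vouter",
                                           "betagamma_vno")) {
  mode <- match.arg(mode, several.ok = TRUE)
  stopifnot(inherits(stream, "singles_stream"))
  .check_delta(delta_ps, tau_ps)
  t <- stream$events$time_ps
  dur <- stream$duration_ps
  kd <- stream$events$kind
  mk <- function(count, fam, variant)
    .new_delayed_counts(count, dur,
                        delayed_scheme(fam, variant, delta_ps))

  need_cfs <- any(mode %in% c("beta", "betagamma_vouter"))
  cf1 <- .enum_triple_configs(t, tau_ps, delta_ps, delta_ps, "1delay")
  cf2 <- .enum_triple_configs(t, tau_ps, delta_ps, delta_ps, "2delays")
  cfs <- if (need_cfs) .enum_scale_configs(t, tau_ps, delta_ps, delta_ps)

  keep1 <- keep2 <- keeps <- NULL
  if (any(mode != "beta")) {
    filt <- function(cf) if (length(cf$i))
      kd[cf$i] + kd[cf$j] + kd[cf$k] == 1L else logical(0)
    keep1 <- filt(cf1); keep2 <- filt(cf2)
    if (need_cfs) keeps <- filt(cfs)
  }

  # veto evaluations shared across modes
  k_ok1 <- .triple_single_ok(t, cf1, tau_ps)
  k_ok2 <- .triple_single_ok(t, cf2, tau_ps)
  acc_s <- if (need_cfs) lapply(c("t_scale1", "t_scale2", "t_scale3"),
                                function(v) .delayed_triple_accept(
                                  t, cfs, tau_ps, "vouter", v))

  one <- function(m) {
    if (m == "beta") {
      out <- list(one_delay = mk(sum(k_ok1), "vouter", "t_1delay"),
                  two_delays = mk(sum(k_ok2), "vouter", "t_2delays"))
    } else if (m == "betagamma_vouter") {
      dbl_ok1 <- .triple_double_ok(t, cf1, tau_ps)
      ij_ok2 <- .triple_ij_ok(t, cf2, tau_ps)
      out <- list(
        one_delay = mk(sum(k_ok1 & dbl_ok1 & keep1), "vouter", "t_1delay_dveto"),
        two_delays = mk(sum(k_ok2 & ij_ok2 & keep2), "vouter", "t_2delays_dveto"))
    } else {
      out <- list(one_delay = mk(sum(keep1), "vno", "t_1delay"),
                  two_delays = mk(sum(keep2), "vno", "t_2delays"))
    }
    if (m != "betagamma_vno") {
      kp <- if (m == "beta") TRUE else keeps
      sc <- lapply(acc_s, function(a) sum(a & kp))
      out$scale1 <- mk(sc[[1L]], "vouter", "t_scale1")
      out$scale2 <- mk(sc[[2L]], "vouter", "t_scale2")
      out$scale3 <- mk(sc[[3L]], "vouter", "t_scale3")
    }
    out
  }
  if (length(mode) == 1L) return(one(mode))
  out <- lapply(mode, one)
  names(out) <- mode
  out
}

.triple_single_ok <- function(t, cf, tau) {
  if (!length(cf$i)) return(logical(0))
  vmin <- pmin(0, cf$w); vmax <- pmax(cf$u, cf$w)
  .member_veto_ok(t, t[cf$k], cf$w, vmin, vmax, tau)
}

.triple_double_ok <- function(t, cf, tau) {
  if (!length(cf$i)) return(logical(0))
  vmin <- pmin(0, cf$w); vmax <- pmax(cf$u, cf$w)
  .n_in(t, t[cf$i] + vmin - tau, t[cf$i] + vmax + tau) == 2L
}

.triple_ij_ok <- function(t, cf, tau) {
  if (!length(cf$i)) return(logical(0))
  vmin <- pmin(0, cf$w); vmax <- pmax(cf$u, cf$w)
  .member_veto_ok(t, t[cf$i], 0, vmin, vmax, tau) &
    .member_veto_ok(t, t[cf$j], cf$u, vmin, vmax, tau)
}

#' Estimate the two-decay random triple rate of a beta+ emitter
#'
#' One-delay minus two-delay subtraction: the one-delay count contains
#' both the sought (correlated double + uncorrelated single)
#' configurations and fully uncorrelated triples; the two-delay count
#' reproduces only the latter, so
#' `R_hat = D_1delay - D_2delays`.
#'
#' @param one_delay,two_delays `delayed_counts` with matching vetoes.
#' @return A `random_estimate`. A negative subtraction is clipped to zero
#'   with a warning.
#' @export
estimate_two_decay_triples_beta <- function(one_delay, two_delays) {
  est <- one_delay$rate - two_delays$rate
  if (est < 0) {
    warning("negative two-decay triple estimate clipped to 0")
    est <- 0
  }
  structure(list(target = "triples_2decay", estimate_rate = est,
                 components = list(one_delay = one_delay,
                                   two_delays = two_delays)),
            class = "random_estimate")
}

#' Estimate the three-decay random triple rate
#'
#' Counts from two delayed windows of size tau are halved (finding one
#' single in each of two windows is twice as probable as finding two in
#' one window) and corrected for the veto interval size with the scale
#' schemes. The default combination
#' `R_hat = 0.5 * D_scale3 * (D_scale1 / D_scale3)` cancels the excess
#' veto exponential exactly under homogeneous-Poisson singles (the scale-1
#' total veto length equals the prompt veto length `2*tau + span`);
#' `combination = "ratio_sq"` gives the alternative reading
#' `0.5 * D_scale1^2 / D_scale3`, retained for comparison, which
#' over-corrects by one veto factor and overestimates at high activity.
#'
#' @param scale1,scale3 `delayed_counts` from the scale schemes.
#' @param combination `"scaled"` (default) or `"ratio_sq"`.
#' @return A `random_estimate`.
#' @export
estimate_three_decay_triples <- function(scale1, scale3,
                                         combination = c("scaled", "ratio_sq")) {
  combination <- match.arg(combination)
  if (scale3$count == 0)
    stop("undefined estimate: scale-3 scheme has zero counts")
  est <- if (combination == "scaled")
    0.5 * scale3$rate * (scale1$rate / scale3$rate)
  else
    0.5 * scale1$rate^2 / scale3$rate
  structure(list(target = "triples_3decay", estimate_rate = est,
                 components = list(scale1 = scale1, scale3 = scale3),
                 combination = combination),
            class = "random_estimate")
}

#' Estimate the two-decay random triple rate of a beta+-gamma emitter
#'
#' Veto windows are applied around both the included double and the
#' delayed single, doubling the total veto interval; the scale schemes
#' supply the correction factors:
#' `R_hat = (D_1delay/D_scale2 - D_2delays/D_scale3) * D_scale1`,
#' where the one-delay count carries a doubled veto (corrected by the
#' scale-2 ratio) and the two-delay count a tripled veto (corrected by the
#' scale-3 ratio); multiplying by the scale-1 count restores the
#' prompt-matched veto factor.
#'
#' @param one_delay `delayed_counts`, variant `t_1delay_dveto`.
#' @param two_delays `delayed_counts`, variant `t_2delays_dveto`.
#' @param scale1,scale2,scale3 scale-scheme `delayed_counts`.
#' @return A `random_estimate`. A negative bracket is clipped to zero with
#'   a warning.
#' @export
estimate_two_decay_triples_betagamma <- function(one_delay, two_delays,
                                                 scale1, scale2, scale3) {
  if (scale2$count == 0 || scale3$count == 0)
    stop("undefined estimate: zero scale-scheme denominator")
  est <- (one_delay$rate / scale2$rate -
            two_delays$rate / scale3$rate) * scale1$rate
  if (est < 0) {
    warning("negative two-decay triple estimate clipped to 0")
    est <- 0
  }
  structure(list(target = "triples_2decay_betagamma", estimate_rate = est,
                 components = list(one_delay = one_delay,
                                   two_delays = two_delays,
                                   scale1 = scale1, scale2 = scale2,
                                   scale3 = scale3)),
            class = "random_estimate")
}

#' Ground-truth random rate from decay-ID labels
#'
#' Counts prompt coincidences of the requested class under the given veto
#' scheme, using the simulator's decay IDs: random doubles are accepted
#' doubles whose members stem from different decays; two-/three-decay
#' triples are accepted order-3 multiples with exactly two / three
#' distinct decays among their members.
#'
#' @param stream a `singles_stream` with ground truth.
#' @param cfg a [window_config()].
#' @param target `"doubles"`, `"triples_2decay"` or `"triples_3decay"`.
#' @param composition passed to [find_prompt_multiples()] for triples.
#' @return A list (class `rate_record`) with `count`, `duration_ps`,
#'   `rate`, `scheme`, `target`.
#' @export
ground_truth_randoms <- function(stream, cfg,
                                 target = c("doubles", "triples_2decay",
                                            "triples_3decay"),
                                 composition = "any") {
  target <- match.arg(target)
  if (target == "doubles") {
    d <- find_prompt_doubles(stream, cfg)
    lab <- classify_coincidences(d, stream)
    count <- sum(!lab$is_true)
  } else {
    tr <- find_prompt_multiples(stream, cfg, 3L, composition = composition)
    lab <- classify_coincidences(tr, stream)
    count <- sum(lab$n_decays == if (target == "triples_2decay") 2L else 3L)
  }
  structure(list(count = count, duration_ps = stream$duration_ps,
                 rate = count / (stream$duration_ps * 1e-12),
                 scheme = cfg$scheme, target = target),
            class = "rate_record")
}
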