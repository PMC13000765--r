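#' Experiment configuration
#'
#' Describes a simulation study: an activity sweep with repetitions at
#' fixed acquisition length, the coincidence window(s) and delay, the veto
#' schemes and the estimation targets to evaluate. The defaults mirror the
#' package's reference study design: activities 10-100 MBq in 10 MBq
#' steps, 0.1 s acquisitions repeated five times, tau = 2.6 ns,
#' delta = 5 us.
#'
#' @param isotope an [isotope_model].
#' @param detector a [detector_model].
#' @param activities_mbq activity grid in MBq (strictly increasing).
#' @param duration_s acquisition length per point, seconds.
#' @param repetitions repetitions per grid point (>= 1).
#' @param tau_ps coincidence window(s) in ps; several values are evaluated
#'   on the same simulated streams.
#' @param delta_ps delayed-window delay in ps.
#' @param schemes veto schemes to evaluate for doubles.
#' @param targets subset of `"doubles"`, `"triples_beta"`,
#'   `"triples_betagamma"`, `"multiples"`.
#' @param seed master seed; per-point seeds are derived deterministically.
#' @param output_dir optional directory for CSV/JSON reports.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(isotope, detector = detector_model(),
                              activities_mbq = seq(10, 100, by = 10),
                              duration_s = 0.1, repetitions = 5L,
                              tau_ps = 2600, delta_ps = 5e6,
                              schemes = c("vouter", "vinner", "vbetween", "vno"),
                              targets = "doubles",
                              seed = 1L, output_dir = NULL) {
  stopifnot(inherits(isotope, "isotope_model"),
            inherits(detector, "detector_model"))
  if (!length(activities_mbq) || is.unsorted(activities_mbq, strictly = TRUE))
    stop("activities_mbq must be a non-empty strictly increasing grid")
  if (repetitions < 1) stop("repetitions must be >= 1")
  bad <- setdiff(schemes, c("vouter", "vinner", "vbetween", "vno"))
  if (length(bad)) stop("unknown veto scheme(s): ", paste(bad, collapse = ", "))
  badt <- setdiff(targets, c("doubles", "triples_prompt", "triples_beta",
                             "triples_betagamma", "multiples"))
  if (length(badt)) stop("unknown target(s): ", paste(badt, collapse = ", "))
  if (any(delta_ps <= max(tau_ps)))
    stop("delta_ps must exceed every tau_ps")
  if ("triples_betagamma" %in% targets && !isotope$emits_prompt_gamma)
    stop("triples_betagamma requires a beta+-gamma isotope")
  structure(list(isotope = isotope, detector = detector,
                 activities_mbq = activities_mbq, duration_s = duration_s,
                 repetitions = as.integer(repetitions), tau_ps = tau_ps,
                 delta_ps = delta_ps, schemes = schemes, targets = targets,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

# deterministic per-point seed below 2^31
derive_seed <- function(master, index) {
  ((as.numeric(master) %% 1000003) * 8191 + index * 127 + 1) %% 2147483629
}

.analyze_doubles <- function(stream, tau_ps, delta_ps, schemes) {
  dd_all <- delayed_doubles_suite(stream, tau_ps, schemes, delta_ps)
  if (length(schemes) == 1L) dd_all <- stats::setNames(list(dd_all), schemes)
  unpaired <- flag_paired_singles(stream) == "unpaired"
  d_all <- .prompt_doubles_all(stream$events$time_ps, tau_ps, schemes)
  rows <- lapply(schemes, function(sc) {
    d <- d_all[[sc]]
    lab <- classify_coincidences(d, stream)
    rnd <- !lab$is_true
    # the model parameter <dt> describes randoms of unpaired singles;
    # randoms containing a paired single have a different gap distribution
    rnd_u <- rnd & unpaired[d$i] & unpaired[d$j]
    dd <- dd_all[[sc]]
    data.frame(scheme = sc,
               prompt = nrow(d),
               trues = sum(lab$is_true),
               randoms = sum(rnd),
               n_rnd_unp = sum(rnd_u),
               sum_dt_rnd = sum(d$dt_ps[rnd_u]),
               d1 = dd[[1L]]$count,
               d2 = if (sc == "vno") NA_real_ else dd$d2$count,
               d3 = if (sc == "vno") NA_real_ else dd$d3$count)
  })
  do.call(rbind, rows)
}

.analyze_triples_prompt <- function(stream, tau_ps) {
  cfg <- window_config(tau_ps, "vouter", max_order = 3L)
  tr <- find_prompt_multiples(stream, cfg, 3L)
  lab <- classify_coincidences(tr, stream)
  data.frame(doubles_prompt = nrow(find_prompt_doubles(stream, cfg)),
             truth_2decay = sum(lab$n_decays == 2L),
             truth_3decay = sum(lab$n_decays == 3L))
}

.analyze_triples_beta <- function(stream, tau_ps, delta_ps,
                                  doubles_prompt = NULL) {
  cfg <- window_config(tau_ps, "vouter", max_order = 3L)
  tr <- find_prompt_multiples(stream, cfg, 3L)
  lab <- classify_coincidences(tr, stream)
  dts <- delayed_triples_suite(stream, tau_ps, delta_ps, "beta")
  if (is.null(doubles_prompt))
    doubles_prompt <- nrow(find_prompt_doubles(stream, cfg))
  data.frame(doubles_prompt = doubles_prompt,
             truth_2decay = sum(lab$n_decays == 2L),
             truth_3decay = sum(lab$n_decays == 3L),
             one_delay = dts$one_delay$count,
             two_delays = dts$two_delays$count,
             scale1 = dts$scale1$count,
             scale2 = dts$scale2$count,
             scale3 = dts$scale3$count)
}

.analyze_triples_betagamma <- function(stream, tau_ps, delta_ps) {
  cfg_o <- window_config(tau_ps, "vouter", max_order = 3L)
  cfg_n <- window_config(tau_ps, "vno", max_order = 3L)
  lab_o <- classify_coincidences(
    find_prompt_multiples(stream, cfg_o, 3L, "two_annih_one_gamma"), stream)
  lab_n <- classify_coincidences(
    find_prompt_multiples(stream, cfg_n, 3L, "two_annih_one_gamma"), stream)
  both <- delayed_triples_suite(stream, tau_ps, delta_ps,
                                c("betagamma_vouter", "betagamma_vno"))
  sv <- both$betagamma_vouter
  sn <- both$betagamma_vno
  data.frame(truth_vouter = sum(lab_o$n_decays == 2L),
             truth_vno = sum(lab_n$n_decays == 2L),
             od_vouter = sv$one_delay$count,
             td_vouter = sv$two_delays$count,
             scale1 = sv$scale1$count,
             scale2 = sv$scale2$count,
             scale3 = sv$scale3$count,
             od_vno = sn$one_delay$count,
             td_vno = sn$two_delays$count)
}

#' Run a simulation experiment
#'
#' For every grid point and repetition: simulate a stream, identify prompt
#' coincidences, count the delayed window schemes and classify against
#' ground truth; then aggregate counts over repetitions into rates, apply
#' the random estimators, and tabulate deviations. Fully deterministic
#' given the master seed (per-point seeds are derived by fixed hashing of
#' the point index).
#'
#' @param config an [experiment_config()].
#' @param verbose logical; log each grid point to stderr.
#' @return A list of data.frames: `$doubles` (per tau/activity/scheme:
#'   prompt, truth and estimated random rates, mean random gap, relative
#'   deviation), `$triples_beta`, `$triples_betagamma` (per tau/activity:
#'   estimator components, estimates, truths, deviations), `$multiples`
#'   (order histogram), plus `$deviations`, a [deviation_report()] over
#'   every estimator in the run.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  acts <- config$activities_mbq
  reps <- config$repetitions
  taus <- config$tau_ps
  dur_ps <- config$duration_s * 1e12

  per_rep <- list()
  idx <- 0L
  for (ai in seq_along(acts)) {
    for (r in seq_len(reps)) {
      idx <- idx + 1L
      sd <- derive_seed(config$seed, idx)
      stream <- simulate_stream(acts[ai] * 1e6, config$duration_s,
                                config$isotope, config$detector, seed = sd)
      if (verbose)
        message(sprintf("[petrand] %g MBq rep %d: %d singles (seed %.0f)",
                        acts[ai], r, n_singles(stream), sd))
      for (tau in taus) {
        key <- length(per_rep) + 1L
        res <- list(activity_mbq = acts[ai], rep = r, tau_ps = tau)
        if ("doubles" %in% config$targets)
          res$doubles <- .analyze_doubles(stream, tau, config$delta_ps,
                                          config$schemes)
        if ("triples_prompt" %in% config$targets)
          res$triples_prompt <- .analyze_triples_prompt(stream, tau)
        if ("triples_beta" %in% config$targets) {
          dp <- if (!is.null(res$doubles) && "vouter" %in% config$schemes)
            res$doubles$prompt[res$doubles$scheme == "vouter"] else NULL
          res$triples_beta <- .analyze_triples_beta(stream, tau,
                                                    config$delta_ps, dp)
        }
        if ("triples_betagamma" %in% config$targets)
          res$triples_betagamma <- .analyze_triples_betagamma(stream, tau,
                                                              config$delta_ps)
        if ("multiples" %in% config$targets)
          res$multiples <- multiples_histogram(stream,
                                               window_config(tau, "vouter"))
        per_rep[[key]] <- res
      }
      rm(stream)
    }
  }

  out <- .aggregate_experiment(per_rep, config, dur_ps)
  if (!is.null(config$output_dir)) write_experiment_report(out, config$output_dir)
  out
}

.rate <- function(count, dur_s) count / dur_s

.aggregate_experiment <- function(per_rep, config, dur_ps) {
  reps <- config$repetitions
  tot_s <- reps * dur_ps * 1e-12
  rep_s <- dur_ps * 1e-12
  grid <- unique(do.call(rbind, lapply(per_rep, function(x)
    data.frame(activity_mbq = x$activity_mbq, tau_ps = x$tau_ps))))
  out <- list()

  pick <- function(a, tau) Filter(function(x)
    x$activity_mbq == a && x$tau_ps == tau, per_rep)

  if ("doubles" %in% config$targets) {
    rows <- list()
    for (g in seq_len(nrow(grid))) {
      reps_here <- pick(grid$activity_mbq[g], grid$tau_ps[g])
      for (sc in config$schemes) {
        m <- do.call(rbind, lapply(reps_here, function(x)
          x$doubles[x$doubles$scheme == sc, -1L]))
        est_rep <- if (sc == "vno") m$d1 / rep_s
          else ifelse(m$d3 > 0, (m$d1 / rep_s) * (m$d2 / rep_s) / (m$d3 / rep_s),
                      NA_real_)
        est <- if (sc == "vno") .rate(sum(m$d1), tot_s)
          else .rate(sum(m$d1), tot_s) * .rate(sum(m$d2), tot_s) /
               .rate(sum(m$d3), tot_s)
        truth_rep <- m$randoms / rep_s
        rows[[length(rows) + 1L]] <- data.frame(
          tau_ps = grid$tau_ps[g], activity_mbq = grid$activity_mbq[g],
          scheme = sc,
          prompt_rate = .rate(sum(m$prompt), tot_s),
          trues_rate = .rate(sum(m$trues), tot_s),
          truth_rate = .rate(sum(m$randoms), tot_s),
          se_truth = stats::sd(truth_rep) / sqrt(reps),
          estimate_rate = est,
          se_estimate = stats::sd(est_rep) / sqrt(reps),
          mean_dt_ps = sum(m$sum_dt_rnd) / sum(m$n_rnd_unp),
          rel_dev = est / .rate(sum(m$randoms), tot_s) - 1,
          d1_rate = .rate(sum(m$d1), tot_s),
          se_d1 = stats::sd(m$d1 / rep_s) / sqrt(reps),
          d2_rate = .rate(sum(m$d2), tot_s),
          se_d2 = stats::sd(m$d2 / rep_s) / sqrt(reps),
          d3_rate = .rate(sum(m$d3), tot_s),
          se_d3 = stats::sd(m$d3 / rep_s) / sqrt(reps))
      }
    }
    out$doubles <- do.call(rbind, rows)
  }

  if ("triples_prompt" %in% config$targets) {
    rows <- list()
    for (g in seq_len(nrow(grid))) {
      m <- do.call(rbind, lapply(pick(grid$activity_mbq[g], grid$tau_ps[g]),
                                 function(x) x[["triples_prompt"]]))
      rows[[length(rows) + 1L]] <- data.frame(
        tau_ps = grid$tau_ps[g], activity_mbq = grid$activity_mbq[g],
        doubles_rate = .rate(sum(m$doubles_prompt), tot_s),
        rate_2decay = .rate(sum(m$truth_2decay), tot_s),
        rate_3decay = .rate(sum(m$truth_3decay), tot_s),
        triples_to_doubles = sum(m$truth_2decay) / sum(m$doubles_prompt))
    }
    out$triples_prompt <- do.call(rbind, rows)
  }

  if ("triples_beta" %in% config$targets) {
    rows <- list()
    for (g in seq_len(nrow(grid))) {
      m <- do.call(rbind, lapply(pick(grid$activity_mbq[g], grid$tau_ps[g]),
                                 function(x) x[["triples_beta"]]))
      est2 <- .rate(sum(m$one_delay) - sum(m$two_delays), tot_s)
      est3 <- 0.5 * .rate(sum(m$scale1), tot_s)
      est2_rep <- (m$one_delay - m$two_delays) / rep_s
      rows[[length(rows) + 1L]] <- data.frame(
        tau_ps = grid$tau_ps[g], activity_mbq = grid$activity_mbq[g],
        doubles_rate = .rate(sum(m$doubles_prompt), tot_s),
        truth_2decay = .rate(sum(m$truth_2decay), tot_s),
        se_truth_2decay = stats::sd(m$truth_2decay / rep_s) / sqrt(reps),
        estimate_2decay = max(0, est2),
        se_estimate_2decay = stats::sd(est2_rep) / sqrt(reps),
        rel_dev_2decay = est2 / .rate(sum(m$truth_2decay), tot_s) - 1,
        truth_3decay = .rate(sum(m$truth_3decay), tot_s),
        estimate_3decay = est3,
        rel_dev_3decay = est3 / .rate(sum(m$truth_3decay), tot_s) - 1,
        triples_to_doubles = sum(m$truth_2decay) / sum(m$doubles_prompt))
    }
    out$triples_beta <- do.call(rbind, rows)
  }

  if ("triples_betagamma" %in% config$targets) {
    rows <- list()
    for (g in seq_len(nrow(grid))) {
      m <- do.call(rbind, lapply(pick(grid$activity_mbq[g], grid$tau_ps[g]),
                                 function(x) x[["triples_betagamma"]]))
      r <- function(v) .rate(sum(v), tot_s)
      est_o <- (r(m$od_vouter) / r(m$scale2) -
                  r(m$td_vouter) / r(m$scale3)) * r(m$scale1)
      est_n <- r(m$od_vno) - r(m$td_vno)
      rows[[length(rows) + 1L]] <- data.frame(
        tau_ps = grid$tau_ps[g], activity_mbq = grid$activity_mbq[g],
        truth_vouter = r(m$truth_vouter),
        estimate_vouter = max(0, est_o),
        rel_dev_vouter = est_o / r(m$truth_vouter) - 1,
        truth_vno = r(m$truth_vno),
        estimate_vno = max(0, est_n),
        rel_dev_vno = est_n / r(m$truth_vno) - 1)
    }
    out$triples_betagamma <- do.call(rbind, rows)
  }

  if ("multiples" %in% config$targets) {
    rows <- list()
    for (g in seq_len(nrow(grid))) {
      ms <- lapply(pick(grid$activity_mbq[g], grid$tau_ps[g]),
                   function(x) x$multiples)
      cnt <- Reduce(`+`, lapply(ms, function(h) h$count))
      rows[[length(rows) + 1L]] <- data.frame(
        tau_ps = grid$tau_ps[g], activity_mbq = grid$activity_mbq[g],
        order = ms[[1L]]$order, count = cnt, rate = .rate(cnt, tot_s))
    }
    out$multiples <- do.call(rbind, rows)
  }

  out$deviations <- .collect_deviations(out)
  out
}

.collect_deviations <- function(out) {
  frames <- list()
  if (!is.null(out[["doubles"]]))
    frames$doubles <- data.frame(
      target = paste0("doubles_", out$doubles$scheme),
      activity_mbq = out$doubles$activity_mbq,
      estimate_rate = out$doubles$estimate_rate,
      truth_rate = out$doubles$truth_rate,
      se_estimate = out$doubles$se_estimate,
      se_truth = out$doubles$se_truth)
  tb2 <- out[["triples_beta"]]
  if (!is.null(tb2))
    frames$t2 <- data.frame(
      target = "triples_2decay_beta",
      activity_mbq = tb2$activity_mbq,
      estimate_rate = tb2$estimate_2decay,
      truth_rate = tb2$truth_2decay,
      se_estimate = tb2$se_estimate_2decay,
      se_truth = tb2$se_truth_2decay)
  if (!is.null(out[["triples_betagamma"]])) {
    tb <- out[["triples_betagamma"]]
    frames$bg <- data.frame(
      target = rep(c("triples_2decay_betagamma_vouter",
                     "triples_2decay_betagamma_vno"), each = nrow(tb)),
      activity_mbq = c(tb$activity_mbq, tb$activity_mbq),
      estimate_rate = c(tb$estimate_vouter, tb$estimate_vno),
      truth_rate = c(tb$truth_vouter, tb$truth_vno),
      se_estimate = NA_real_, se_truth = NA_real_)
  }
  if (!length(frames)) return(NULL)
  deviation_report(do.call(rbind, frames))
}

#' Write experiment tables to disk
#'
#' CSV per result table plus a JSON deviation summary, the on-disk report
#' format of [run_experiment()].
#'
#' @param results list returned by [run_experiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in setdiff(names(results), "deviations")) {
    utils::write.csv(results[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(results$deviations))
    jsonlite::write_json(results$deviations,
                         file.path(dir, "deviations.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()]; the isotope is
#' given inline as `isotope: {name:, eps1:, eps2:, eps_gamma:}` and the
#' detector (optional) as `detector: {n_blocks:, ctr_fwhm_ps:,
#' dead_time_ps:}`. The round trip through [write_experiment_config()]
#' reproduces the identical run plan.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  iso <- do.call(isotope_model, y$isotope)
  det <- if (is.null(y$detector)) detector_model()
         else do.call(detector_model, y$detector)
  args <- y[setdiff(names(y), c("isotope", "detector"))]
  do.call(experiment_config, c(list(isotope = iso, detector = det), args))
}

#' Write an experiment configuration to a YAML file
#'
#' @param config an [experiment_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  y <- list(
    isotope = list(name = config$isotope$name, eps1 = config$isotope$eps1,
                   eps2 = config$isotope$eps2,
                   eps_gamma = config$isotope$eps_gamma),
    detector = list(n_blocks = config$detector$n_blocks,
                    ctr_fwhm_ps = config$detector$ctr_fwhm_ps,
                    dead_time_ps = config$detector$dead_time_ps),
    activities_mbq = config$activities_mbq,
    duration_s = config$duration_s,
    repetitions = config$repetitions,
    tau_ps = config$tau_ps,
    delta_ps = config$delta_ps,
    schemes = config$schemes,
    targets = config$targets,
    seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}
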