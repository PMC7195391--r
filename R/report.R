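#' Analyze one replicate end to end
#'
#' Runs the descriptor, state-classification and permeation stages on one
#' trajectory and returns the per-replicate summary row used by the
#' ensemble report: bent-state fraction, current, gate distances, membrane
#' thickness.
#'
#' @param topology a [topology]
#' @param frames a [frame_series]
#' @param replicate id recorded in the summary
#' @param t_low,t_high classifier thresholds (nm), see [classify_state()]
#' @param margin filter slab margin (nm), see [filter_bounds()]
#' @param config a [channel_config()]
#' @return list of class `replicate_analysis`: `summary` (one-row
#'   data.frame), `d_vg`, `states`, `events`, and the event counts
#' @export
analyze_replicate <- function(topology, frames, replicate = 1L,
                              t_low = 0.27, t_high = 0.45, margin = 0.1,
                              config = channel_config()) {
  nf <- n_frames(frames)
  dt <- if (nf > 1L) frames$times[2L] - frames$times[1L] else 1
  t_total <- nf * dt
  d_vg <- hbond_distance(frames, topology,
                         acceptor_resid = config$kink_pairs$VG[1],
                         donor_resid = config$kink_pairs$VG[2],
                         config = config)
  states <- classify_state(d_vg, t_low = t_low, t_high = t_high)
  d_ogog <- cross_subunit_distance(frames, topology,
    sprintf("resid %d and name OG1", config$thr59), config = config)
  d_pro19 <- cross_subunit_distance(frames, topology,
    sprintf("resid %d and name CA", config$pro19), config = config)
  d_cof <- phe87_cof_distance(frames, topology, res = config$phe87,
                              config = config)
  d_i84 <- sidechain_com_distance(frames, topology, res_a = config$ile84,
                                  res_b = config$thr59, config = config)
  thick <- tryCatch(
    membrane_thickness(frames, topology,
                       sprintf("name %s", config$phosphate_name),
                       config = config)$thickness,
    error = function(e) NA_real_)
  ion_sel <- suppressWarnings(
    select(topology, sprintf("resname %s", config$ion_resname)))
  events <- data.frame()
  current <- NA_real_
  n_plus <- NA_integer_; n_minus <- NA_integer_
  if (length(ion_sel$indices) > 0L) {
    bounds <- filter_bounds(frames, topology, margin = margin, config = config)
    zmat <- sapply(ion_sel$indices, function(i)
      unwrap_z(frames$coords[i + 1L, 3L, ], frames$box[, 3L]))
    events <- detect_permeation_events(matrix(zmat, ncol = length(ion_sel$indices)),
                                       bounds)
    n_plus <- sum(events$direction == 1L)
    n_minus <- sum(events$direction == -1L)
    current <- current_from_events(n_plus, n_minus, t_total)
  }
  summary <- data.frame(replicate = replicate, f_bent = states$f_bent,
                        I_pA = current, n_plus = n_plus, n_minus = n_minus,
                        d_ogog = mean(d_ogog), d_pro19 = mean(d_pro19),
                        d_cof = mean(d_cof),
                        d_i84t59 = mean(attr(d_i84, "system")),
                        thickness = thick, t_ns = t_total, n_frames = nf)
  structure(list(summary = summary, d_vg = d_vg, states = states,
                 events = events), class = "replicate_analysis")
}

#' Join per-replicate analyses into a summary table
#'
#' @param analyses list of `replicate_analysis` objects (or one-row
#'   summary data.frames)
#' @return data.frame with one row per replicate and the system mean/SEM
#'   attached as attribute `"system"` (a two-row data.frame)
#' @export
summarize_replicates <- function(analyses) {
  rows <- lapply(analyses, function(a)
    if (inherits(a, "replicate_analysis")) a$summary else a)
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, logical(1)) & names(tab) != "replicate"
  sys <- data.frame(stat = c("mean", "sem"))
  for (cl in names(tab)[num]) {
    v <- tab[[cl]]
    sys[[cl]] <- c(mean(v[is.finite(v)]), sem(v))
  }
  attr(tab, "system") <- sys
  tab
}

#' Split replicates by the prevalence of the bent state
#'
#' Threshold rule (default): replicates with `f_bent >= cutoff` form gp1
#' (the default cutoff, 0.125, is half a subunit's worth of bent
#' occupancy). Median rule: gp1 is strictly above the median, ties go to
#' gp2. Per-group mean and SEM of the bent fraction and current are
#' reported.
#'
#' @param summaries data.frame from [summarize_replicates()]
#' @param rule "threshold" or "median"
#' @param cutoff f_bent cutoff for the threshold rule
#' @return list of class `group_split`: `gp1`, `gp2` (replicate ids),
#'   `stats` (per-group mean/sem of f_bent and I_pA), `rule`, `cutoff`
#' @export
split_replicates <- function(summaries, rule = c("threshold", "median"),
                             cutoff = 0.125) {
  rule <- match.arg(rule)
  if (nrow(summaries) < 2L) stop("need at least 2 replicates to split")
  f <- summaries$f_bent
  cut_used <- if (rule == "median") median(f) else cutoff
  in_gp1 <- if (rule == "median") f > cut_used else f >= cut_used
  if (all(in_gp1) || !any(in_gp1))
    warning("degenerate split: all replicates in one group")
  grp_stats <- function(idx) data.frame(
    n = sum(idx),
    f_bent_mean = mean(f[idx]), f_bent_sem = sem(f[idx]),
    I_mean = mean(summaries$I_pA[idx]), I_sem = sem(summaries$I_pA[idx]))
  stats <- rbind(gp1 = grp_stats(in_gp1), gp2 = grp_stats(!in_gp1))
  structure(list(gp1 = summaries$replicate[in_gp1],
                 gp2 = summaries$replicate[!in_gp1],
                 stats = stats, rule = rule, cutoff = cut_used),
            class = "group_split")
}

#' Pearson correlation with a seeded bootstrap confidence interval
#'
#' @param x,y paired values (at least 3 finite pairs)
#' @param n_boot bootstrap resamples
#' @param seed RNG seed (the CI is reproducible given the seed)
#' @param conf confidence level of the percentile interval
#' @return list: `r`, `ci` (length 2), `n`, `n_boot`
#' @export
correlate <- function(x, y, n_boot = 10000L, seed = 1L, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  bs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[i]) == 0 || stats::var(y[i]) == 0) return(NA_real_)
      stats::cor(x[i], y[i])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  list(r = r, ci = unname(quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE)),
       n = n, n_boot = n_boot)
}

#' Configuration-resolved conductance
#'
#' Attributes every detected permeation event to the tetramer configuration
#' (number of bent subunits, 0..4) at its entry frame and normalizes by the
#' configuration residence time, yielding the crossing rate while the
#' channel sits in each configuration -- the numeric backbone of the
#' two-gate crosstalk picture (nonconductive all-kinked, conductive
#' asymmetric, suppressed all-bent).
#'
#' @param states a `state_trace` from [classify_state()]
#' @param events event data.frame from [detect_permeation_events()]
#' @param dt frame spacing (ns)
#' @return data.frame: `n_bent`, `n_frames`, `residence_fraction`,
#'   `n_events`, `rate_per_us` (NA where residence is zero)
#' @export
config_resolved_conductance <- function(states, events, dt) {
  stopifnot(inherits(states, "state_trace"))
  if (nrow(events) > 0 &&
      (max(events$entry_frame) > states$n_frames || min(events$entry_frame) < 1))
    stop("event frames do not align with the state trace")
  out <- data.frame(n_bent = 0:4)
  out$n_frames <- vapply(0:4, function(k) sum(states$n_bent == k), integer(1))
  out$residence_fraction <- out$n_frames / states$n_frames
  out$n_events <- vapply(0:4, function(k) {
    if (nrow(events) == 0L) return(0L)
    sum(states$n_bent[events$entry_frame] == k)
  }, integer(1))
  out$rate_per_us <- ifelse(out$n_frames > 0,
                            out$n_events / (out$n_frames * dt * 1e-3), NA_real_)
  out
}
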