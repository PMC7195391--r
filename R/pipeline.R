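#' Generate and analyze a synthetic ensemble
#'
#' Convenience driver: for each replicate, generates a trajectory from the
#' spec (with seed `base_seed + replicate`), runs [analyze_replicate()],
#' and aggregates the summaries.
#'
#' @param spec a [synthetic_spec()], e.g. from [preset_conduction_group()]
#' @param n_replicates number of replicates
#' @param base_seed seeds are `base_seed + 1 .. base_seed + n_replicates`
#' @param keep_analyses keep the full per-replicate analyses (memory)
#' @param config a [channel_config()]
#' @return list of class `ensemble`: `summaries` (from
#'   [summarize_replicates()]), `current` (a `current_estimate`), `f_bent`
#'   (mean over replicates), and optionally `analyses` and `truths`
#' @export
run_ensemble <- function(spec, n_replicates = 8L, base_seed = 0L,
                         keep_analyses = FALSE, config = channel_config()) {
  analyses <- vector("list", n_replicates)
  truths <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    gen <- generate_trajectory(spec, seed = base_seed + r)
    analyses[[r]] <- analyze_replicate(gen$topology, gen$frames,
                                       replicate = r, config = config)
    truths[[r]] <- gen$truth[c("f_bent", "events")]
  }
  summaries <- summarize_replicates(analyses)
  structure(list(summaries = summaries,
                 current = aggregate_current(summaries$I_pA),
                 f_bent = mean(summaries$f_bent),
                 analyses = if (keep_analyses) analyses,
                 truths = truths),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d replicates: f_bent = %.3f, I = %.2f +/- %.2f pA\n",
              nrow(x$summaries), x$f_bent, x$current$mean, x$current$sem))
  invisible(x)
}

#' Write the standard report tables for a set of ensembles
#'
#' Emits the numeric backbone of the ensemble comparison as plain text:
#' a per-replicate CSV, a per-system CSV, and a JSON summary including the
#' current-vs-bent-fraction correlation. Output is deterministic given the
#' input.
#'
#' @param ensembles named list of `ensemble` objects
#' @param out_dir output directory (created if needed)
#' @param boot_seed seed for the correlation bootstrap
#' @return named vector of files written, invisibly
#' @export
write_report <- function(ensembles, out_dir, boot_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_rep <- do.call(rbind, lapply(names(ensembles), function(nm) {
    s <- ensembles[[nm]]$summaries
    cbind(system = nm, s)
  }))
  per_sys <- do.call(rbind, lapply(names(ensembles), function(nm) {
    e <- ensembles[[nm]]
    data.frame(system = nm, f_bent = e$f_bent, I_mean = e$current$mean,
               I_sem = e$current$sem, n = e$current$n)
  }))
  f_rep <- file.path(out_dir, "replicates.csv")
  f_sys <- file.path(out_dir, "systems.csv")
  f_json <- file.path(out_dir, "summary.json")
  write.csv(per_rep, f_rep, row.names = FALSE)
  write.csv(per_sys, f_sys, row.names = FALSE)
  summary <- list(systems = per_sys, boot_seed = boot_seed)
  if (nrow(per_sys) >= 3L) {
    ct <- correlate(per_sys$f_bent, per_sys$I_mean, n_boot = 2000L,
                    seed = boot_seed)
    summary$r_fbent_current <- ct$r
    summary$r_ci <- ct$ci
  }
  jsonlite::write_json(summary, f_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(replicates = f_rep, systems = f_sys, summary = f_json))
}
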