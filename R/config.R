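## YAML pipeline configuration: a `simulation` block of sim_config()
## arguments plus a `thresholds` block of run_pipeline() knobs.

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with optional top-level \code{seed}, a
#'   \code{simulation} block ([sim_config()] arguments) and a
#'   \code{thresholds} block (fc, fdr, score, merge_distance,
#'   max_placements, rpm_filter, high_rpm).
#' @return list with \code{sim} (a \code{sim_config}) and
#'   \code{thresholds}.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(y$seed)) sim_args$seed <- y$seed
  if (!is.null(sim_args$n_samples_per_stage)) {
    sim_args$n_samples_per_stage <- unlist(sim_args$n_samples_per_stage)
  }
  if (!is.null(sim_args$read_length_range)) {
    sim_args$read_length_range <- unlist(sim_args$read_length_range)
  }
  if (!is.null(sim_args$planted_site_mismatches)) {
    sim_args$planted_site_mismatches <-
      unlist(sim_args$planted_site_mismatches)
  }
  th <- y$thresholds %||% list()
  list(sim = do.call(sim_config, sim_args),
       thresholds = list(
         fc = th$fc %||% 1.5,
         fdr = th$fdr %||% 0.05,
         score = th$score %||% 0.5,
         merge_distance = th$merge_distance %||% 0L,
         max_placements = th$max_placements %||% 30L,
         rpm_filter = th$rpm_filter %||% 1,
         high_rpm = th$high_rpm %||% 5000))
}

#' Run the pipeline from a YAML configuration
#'
#' @param config_path YAML configuration (see [load_config()]).
#' @param out_dir output directory.
#' @param upto final stage to run (default \code{"cluster"}: all).
#' @param seed optional seed override.
#' @return invisibly, the \code{pi_pipeline} result.
#' @export
run_pipeline_yaml <- function(config_path, out_dir, upto = "cluster",
                              seed = NULL) {
  cfg <- load_config(config_path)
  if (!is.null(seed)) {
    cfg$sim$seed <- as.integer(seed)
  }
  th <- cfg$thresholds
  run_pipeline(cfg$sim, out_dir = out_dir, upto = upto,
               fc_threshold = th$fc, fdr_threshold = th$fdr,
               score_threshold = th$score,
               merge_distance = th$merge_distance,
               max_placements = th$max_placements,
               rpm_filter_threshold = th$rpm_filter,
               high_rpm_cutoff = th$high_rpm)
}
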