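# End-to-end pipeline: extract -> predict (or geometric scores) -> select
# -> toy dose -> metrics, with re-loadable intermediates and stage timings.

#' Pipeline run configuration
#'
#' @param case a [patient_case()], or a path to an internal container
#'   directory ([write_case_dir()]), or a [phantom_config()] to generate.
#' @param out_dir directory for artifacts (NULL: no artifacts written).
#' @param weights a trained `baods_net`, or a path to one saved with
#'   [save_net()]; NULL (default) scores angles with the geometric
#'   surrogate [geometric_sbeam()] instead of the network.
#' @param angle_step collector angle step in degrees (default 2).
#' @param n_bins collector bins per ray (default 4000).
#' @param sigma reference-score Gaussian width, degrees (default 5).
#' @param k beams to select (default 3).
#' @param min_sep minimum angular separation, degrees (default 30).
#' @param ci_variant conformity-index variant (default "ratio").
#' @param seed RNG seed propagated to every stochastic stage (default 1).
#' @return object of class `run_config`.
#' @export
run_config <- function(case, out_dir = NULL, weights = NULL, angle_step = 2,
                       n_bins = 4000, sigma = 5, k = 3, min_sep = 30,
                       ci_variant = "ratio", seed = 1) {
  structure(list(case = case, out_dir = out_dir, weights = weights,
                 angle_step = angle_step, n_bins = n_bins, sigma = sigma,
                 k = k, min_sep = min_sep, ci_variant = ci_variant,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_stage <- function(log, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  entry <- list(stage = name, seconds = proc.time()[["elapsed"]] - t0)
  if (!is.null(log))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = 4), "\n",
        file = log, append = TRUE)
  res
}

#' Run the plan-creation pipeline on one case
#'
#' Executes the five-step procedure: extract the geometric features,
#' predict the beam-angle ranking score (with the trained network when
#' weights are supplied, otherwise with the geometric surrogate), select
#' the three beams under the separation rule, compute the unit-weight toy
#' dose, and evaluate plan metrics. Intermediates are written under
#' `out_dir` when given (ranking score as text, beams and metrics as JSON,
#' dose as DICOM RTDOSE) and every stage is timed into `log.jsonl`.
#'
#' @param config a [run_config()].
#' @return list with `sbeam`, `beams`, `dose` ([dose_grid()]), `metrics`
#'   (from [plan_metrics()]), and `case`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  out <- config$out_dir
  log <- NULL
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    log <- file.path(out, "log.jsonl")
    if (file.exists(log)) unlink(log)
  }
  case <- pipeline_stage(log, "load_case", {
    if (inherits(config$case, "patient_case")) config$case
    else if (inherits(config$case, "phantom_config"))
      generate_case(config$case)
    else read_case_dir(config$case)
  })
  net <- config$weights
  if (is.character(net)) net <- load_net(net)
  sbeam <- if (!is.null(net)) {
    ft <- pipeline_stage(log, "extract", build_feature_tensor(
      case, angle_step = config$angle_step, n_bins = config$n_bins))
    pipeline_stage(log, "predict", predict_sbeam(net, ft))
  } else {
    pipeline_stage(log, "geometric_scores", geometric_sbeam(case))
  }
  beams <- pipeline_stage(log, "select",
                          select_angles(sbeam, k = config$k,
                                        min_sep = config$min_sep))
  dose <- pipeline_stage(log, "dose", toy_dose(case, beams))
  metrics <- pipeline_stage(log, "evaluate",
                            plan_metrics(case, dose,
                                         ci_variant = config$ci_variant))
  if (!is.null(out)) {
    write_sbeam(sbeam, file.path(out, "sbeam.txt"))
    jsonlite::write_json(list(beams = beams), file.path(out, "beams.json"),
                         auto_unbox = FALSE, digits = NA)
    jsonlite::write_json(
      list(conformity_index = metrics$conformity_index,
           v_tlv = as.list(metrics$v_tlv),
           dose_stats = as.data.frame(metrics$dose_stats)),
      file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)
    write_dose(dose, file.path(out, "rtdose.dcm"))
  }
  list(sbeam = sbeam, beams = beams, dose = dose, metrics = metrics,
       case = case)
}
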