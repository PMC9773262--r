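#' Process one region of motion through features, classifier and events
#'
#' The per-ROM stage of the pipeline: feature extraction, stride probability,
#' 0.5 decision rule, and (for accepted ROMs) gait-event detection. Any error
#' raised while processing the ROM is captured and reported in the result
#' instead of propagating, so a corrupt region can never disturb its
#' neighbours.
#'
#' @param rom A `rom`.
#' @param template A `stride_template`.
#' @param model A `stepper_net`.
#' @return List with `prob`, `class` (`"stride"`, `"non-stride"` or
#'   `"error"`), `events` (a `gait_events` or `NULL`) and `error` (message or
#'   `NULL`).
#' @export
process_rom <- function(rom, template, model) {
  out <- tryCatch({
    fs <- suppressWarnings(build_feature_set(rom, template))
    prob <- stepper_forward(model$params, fs, model$cfg)
    cls <- classify_stride(prob)
    ev <- if (cls == "stride") detect_events(rom) else NULL
    list(prob = prob, class = cls, events = ev, error = NULL)
  }, error = function(e) {
    list(prob = NA_real_, class = "error", events = NULL,
         error = conditionMessage(e))
  })
  out
}

#' Run the full stride-detection pipeline on a recording
#'
#' Segments the recording into regions of motion, extracts features for each,
#' classifies them with the trained network, and detects HO/TO/HS/FF inside
#' every accepted stride. Each ROM is processed in isolation
#' ([process_rom()]), so a failure on one candidate only affects that
#' candidate. Output order follows the temporal order of the ROMs.
#'
#' @param rec An [imu_recording].
#' @param template A `stride_template`.
#' @param model A trained `stepper_net`.
#' @param cfg A [rom_config()].
#' @param roms Optional list of precomputed `rom` objects; when supplied,
#'   segmentation is skipped.
#' @return List with `strides` (per accepted stride: `rom_id`, `prob`,
#'   `events`), `rejected` (`data.frame` of rejected/failed ROMs with reason)
#'   and `roms` (the ROM table).
#' @export
run_pipeline <- function(rec, template, model, cfg = rom_config(),
                         roms = NULL) {
  stopifnot(inherits(template, "stride_template"),
            inherits(model, "stepper_net"))
  if (is.null(roms)) roms <- segment_roms(rec, cfg)
  results <- lapply(roms, process_rom, template = template, model = model)
  strides <- list()
  rejected <- data.frame(rom_id = integer(0), prob = numeric(0),
                         reason = character(0))
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (identical(r$class, "stride")) {
      strides[[length(strides) + 1L]] <-
        list(rom_id = i, prob = r$prob, events = r$events)
    } else {
      reason <- if (identical(r$class, "error")) r$error else
        sprintf("stride probability %.3f <= 0.5", r$prob)
      rejected <- rbind(rejected, data.frame(rom_id = i, prob = r$prob,
                                             reason = reason))
    }
  }
  list(strides = strides, rejected = rejected,
       roms = if (length(roms)) rom_table(roms) else NULL)
}

#' Detected events of a pipeline run as an annotation table
#'
#' @param run Result of [run_pipeline()].
#' @param side Side attributed to the events (default `"left"`).
#' @return Annotation `data.frame` (`event`, `side`, `t`, `source =
#'   "detector"`), valid strides only, ordered in time.
#' @export
pipeline_annotations <- function(run, side = "left") {
  rows <- lapply(run$strides, function(s) {
    if (is.null(s$events) || !s$events$valid) return(NULL)
    data.frame(event = c("HO", "TO", "HS", "FF"), side = side,
               t = c(s$events$ho, s$events$to, s$events$hs, s$events$ff),
               source = "detector")
  })
  out <- do.call(rbind, c(list(data.frame(event = character(0),
                                          side = character(0), t = numeric(0),
                                          source = character(0))), rows))
  out[order(out$t), , drop = FALSE]
}
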