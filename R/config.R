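# Run configuration: every tunable of the pipeline in one flat list whose
# defaults reproduce the printed constants (640 px input side, reg_max 16,
# 0.8/0.2 loss weights, 5 MP / 2.5% / 25% / 50% QA thresholds, mAP
# thresholds 0.50-0.95).

#' Default run configuration
#'
#' @return A named list of class `periocrop_config`:
#' \describe{
#'   \item{input_side}{network input side in pixels (640).}
#'   \item{reg_max}{DFL bin count parameter (16).}
#'   \item{loss_weight_prob, loss_weight_dfl}{total-loss weights (0.8, 0.2).}
#'   \item{qa_min_megapixels}{minimum upload resolution (5).}
#'   \item{qa_area_min, qa_area_max}{eye-region area-fraction window
#'     (0.025, 0.25) proxying shooting distance.}
#'   \item{qa_min_confidence}{reliability threshold on detection confidence
#'     (0.5).}
#'   \item{map_thresholds}{IOU thresholds for the AP sweep (0.50-0.95 by
#'     0.05).}
#'   \item{margin_factor}{crop margin per side (0).}
#'   \item{letterbox_fill}{pad grey level (114/255).}
#'   \item{seed}{default RNG seed (1).}
#' }
#' @export
default_config <- function() {
  structure(list(
    input_side = 640L,
    reg_max = 16L,
    loss_weight_prob = 0.8,
    loss_weight_dfl = 0.2,
    qa_min_megapixels = 5,
    qa_area_min = 0.025,
    qa_area_max = 0.25,
    qa_min_confidence = 0.5,
    map_thresholds = seq(0.5, 0.95, by = 0.05),
    margin_factor = 0,
    letterbox_fill = 114 / 255,
    seed = 1L
  ), class = "periocrop_config")
}

#' Read a configuration file
#'
#' Accepts YAML or a flat `key: value` / `key = value` text file; keys mirror
#' the fields of [default_config()] one-to-one and unknown keys are an error.
#' Missing keys keep their defaults.
#'
#' @param path Configuration file path.
#' @return A validated `periocrop_config` list.
#' @export
read_config <- function(path) {
  parsed <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (is.null(parsed) || !is.list(parsed)) {
    # flat key = value fallback
    lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
    parsed <- list()
    for (ln in lines) {
      kv <- strsplit(ln, "[:=]", fixed = FALSE)[[1]]
      if (length(kv) < 2) stop(sprintf("cannot parse config line: '%s'", ln))
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      num <- suppressWarnings(as.numeric(strsplit(val, "[, ]+")[[1]]))
      parsed[[key]] <- if (all(!is.na(num))) num else val
    }
  }
  cfg <- default_config()
  unknown <- setdiff(names(parsed), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in names(parsed)) cfg[[key]] <- parsed[[key]]
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$input_side >= 32,
    cfg$reg_max >= 1,
    cfg$loss_weight_prob >= 0, cfg$loss_weight_dfl >= 0,
    cfg$qa_min_megapixels > 0,
    cfg$qa_area_min >= 0, cfg$qa_area_max <= 1,
    cfg$qa_area_min < cfg$qa_area_max,
    cfg$qa_min_confidence >= 0, cfg$qa_min_confidence <= 1,
    all(cfg$map_thresholds > 0), all(cfg$map_thresholds <= 1),
    cfg$margin_factor >= 0,
    cfg$letterbox_fill >= 0, cfg$letterbox_fill <= 1
  )
  cfg$input_side <- as.integer(cfg$input_side)
  cfg$reg_max <- as.integer(cfg$reg_max)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "periocrop_config")
}

#' @export
print.periocrop_config <- function(x, ...) {
  cat("<periocrop_config>\n")
  for (key in names(x)) {
    cat(sprintf("  %s: %s\n", key, paste(format(x[[key]]), collapse = " ")))
  }
  invisible(x)
}
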