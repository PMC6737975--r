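#' Load and validate a pipeline run configuration
#'
#' A run configuration names the input stacks per sample, pairs the two
#' probe channels by explicit label (never by file order), and carries the
#' detection and matching parameters. Accepted as a YAML file path or an
#' equivalent nested list with fields:
#' \describe{
#'   \item{samples}{list of `{id, stack_a, stack_b, stack_nuclei?}`.}
#'   \item{channels}{`{a, b, counterstain?}` channel labels; `a` and `b`
#'     must differ.}
#'   \item{detection}{arguments for [detection_config()], optionally with
#'     per-channel override blocks `a:` / `b:`.}
#'   \item{d_max}{matching cutoff in voxels, default 3.}
#'   \item{roi_table}{optional CSV path, see [read_roi_table()]; without
#'     it each sample is analysed as one full-stack ROI.}
#'   \item{normalization}{optional `{target, reference}` (`"a"`/`"b"`) for
#'     per-ROI normalized expression.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config path to a YAML file, or a list.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$samples) || !length(config$samples))
    stop("config needs at least one sample")
  config$channels <- utils::modifyList(
    list(a = "A", b = "B", counterstain = "nuclei"),
    config$channels %||% list())
  if (identical(config$channels$a, config$channels$b))
    stop("channel labels a and b must be distinct")
  config$d_max <- config$d_max %||% 3
  config$out_dir <- config$out_dir %||% "smfish3d_out"
  for (s in config$samples) {
    if (is.null(s$id)) stop("every sample needs an id")
    for (f in c("stack_a", "stack_b"))
      if (is.null(s[[f]]) || !file.exists(s[[f]]))
        stop("sample ", s$id, ": missing or unreadable ", f,
             " ('", s[[f]], "')")
    if (!is.null(s$stack_nuclei) && !file.exists(s$stack_nuclei))
      stop("sample ", s$id, ": unreadable stack_nuclei")
  }
  if (!is.null(config$roi_table) && !file.exists(config$roi_table))
    stop("roi_table file not found: ", config$roi_table)
  class(config) <- c("run_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

channel_detection_config <- function(config, which) {
  det <- config$detection %||% list()
  shared <- det[setdiff(names(det), c("a", "b"))]
  over <- det[[which]] %||% list()
  do.call(detection_config, utils::modifyList(shared, over))
}

#' Run the full detection / co-localization / quantification pipeline
#'
#' For every sample and ROI: reads both channel stacks, extracts the ROI,
#' detects spots per channel (recording the selected threshold), matches
#' the two channels one-to-one under `d_max`, and derives quantifications
#' (spot counts, mRNA per cell when a nucleus count is available,
#' optional normalized expression). Manual nucleus counts from the ROI
#' table always take precedence; automatic counts from the counterstain
#' are flagged `"automatic"`. A failing ROI is recorded and the batch
#' continues.
#'
#' Outputs in `out_dir`: `spots.csv`, `pairs.csv`, `unmatched.csv`,
#' `quant.csv`, `thresholds.csv`, `summary.json`, `config.json`. Outputs
#' are deterministic: rerunning on identical inputs reproduces them
#' byte-identically.
#'
#' @param config a [run_config()], YAML path, or list.
#' @return Invisibly, the summary list (also written as JSON); element
#'   `failures` lists ROIs that errored.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  roi_tab <- if (!is.null(config$roi_table))
    read_roi_table(config$roi_table) else NULL
  norm <- config$normalization

  spots_rows <- list(); pair_rows <- list(); unmatched_rows <- list()
  quant_rows <- list(); thr_rows <- list()
  results <- list(); failures <- list()

  for (s in config$samples) {
    rois <- if (!is.null(roi_tab) && any(roi_tab$sample == s$id)) {
      roi_tab[roi_tab$sample == s$id, , drop = FALSE]
    } else {
      data.frame(sample = s$id, roi = "full", origin_z = 1, origin_y = 1,
                 origin_x = 1, size_z = NA, size_y = NA, size_x = NA,
                 nucleus_count = NA)
    }
    for (ri in seq_len(nrow(rois))) {
      row <- rois[ri, ]
      key <- paste(s$id, row$roi, sep = "/")
      res <- tryCatch(
        analyse_roi(s, row, config),
        error = function(e) structure(conditionMessage(e), class = "fail"))
      if (inherits(res, "fail")) {
        failures[[key]] <- as.character(res)
        next
      }
      spots_rows[[key]] <- res$spots
      pair_rows[[key]] <- res$pairs
      unmatched_rows[[key]] <- res$unmatched
      quant_rows[[key]] <- res$quant
      thr_rows[[key]] <- res$thresholds
      results[[key]] <- res$summary
    }
  }

  bind <- function(lst) if (length(lst)) do.call(rbind, unname(lst)) else NULL
  outs <- list(spots = bind(spots_rows), pairs = bind(pair_rows),
               unmatched = bind(unmatched_rows), quant = bind(quant_rows),
               thresholds = bind(thr_rows))
  for (nm in names(outs)) {
    if (is.null(outs[[nm]])) next
    write.csv(outs[[nm]], file.path(config$out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }

  cfg_json <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA)
  summary <- list(
    package_version = as.character(packageVersion("smfish3d")),
    config_md5 = unname(tools::md5sum(cfg_json)),
    d_max = config$d_max,
    rois = results,
    failures = failures)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}

analyse_roi <- function(s, row, config) {
  r <- roi_from_row(row)
  a <- extract_roi(read_stack(s$stack_a, config$channels$a), r)
  b <- extract_roi(read_stack(s$stack_b, config$channels$b), r)
  det_a <- detect_spots(a, channel_detection_config(config, "a"))
  det_b <- detect_spots(b, channel_detection_config(config, "b"))
  m <- match_spots(det_a, det_b, d_max = config$d_max)

  note <- ""
  nuc <- row$nucleus_count
  if (is.na(nuc) && !is.null(s$stack_nuclei)) {
    hoechst <- extract_roi(
      read_stack(s$stack_nuclei, config$channels$counterstain), r)
    nuc <- count_nuclei(hoechst)
    note <- "automatic"
  }
  counts <- c(a = nrow(det_a$spots), b = nrow(det_b$spots))
  quant <- data.frame(
    sample = s$id, roi = row$roi,
    channel = c(config$channels$a, config$channels$b),
    spot_count = as.integer(counts),
    nucleus_count = rep(if (is.na(nuc)) NA_integer_ else as.integer(nuc), 2),
    mrna_per_cell = if (!is.na(nuc) && nuc > 0) counts / nuc
                    else rep(NA_real_, 2),
    notes = rep(note, 2))
  norm_val <- NA_real_
  if (!is.null(config$normalization)) {
    tgt <- counts[[config$normalization$target]]
    ref <- counts[[config$normalization$reference]]
    if (ref >= 1) norm_val <- normalized_expression(tgt, ref, row$roi)
  }
  quant$normalized_expression <- c(norm_val, NA_real_)

  tag <- function(d) cbind(sample = rep(s$id, nrow(d)),
                           roi = rep(row$roi, nrow(d)), d)
  sp <- rbind(
    cbind(channel = rep(det_a$channel_label, nrow(det_a$spots)),
          det_a$spots),
    cbind(channel = rep(det_b$channel_label, nrow(det_b$spots)),
          det_b$spots))
  un <- rbind(
    data.frame(channel = rep(det_a$channel_label,
                             length(m$unmatched_a)), id = m$unmatched_a),
    data.frame(channel = rep(det_b$channel_label,
                             length(m$unmatched_b)), id = m$unmatched_b))
  thr <- data.frame(
    channel = c(det_a$channel_label, det_b$channel_label),
    threshold = c(det_a$threshold_used, det_b$threshold_used),
    flat_curve = c(isTRUE(det_a$curve$flat), isTRUE(det_b$curve$flat)))

  list(spots = tag(sp), pairs = tag(m$pairs), unmatched = tag(un),
       quant = quant, thresholds = tag(thr),
       summary = list(
         n_a = m$n_a, n_b = m$n_b, n_pairs = nrow(m$pairs),
         ratio_a_in_b = m$ratio_a_in_b, ratio_b_in_a = m$ratio_b_in_a,
         threshold_a = det_a$threshold_used,
         threshold_b = det_b$threshold_used,
         nucleus_count = if (is.na(nuc)) NULL else as.integer(nuc),
         nucleus_count_source = if (note == "automatic") "automatic"
                                else if (!is.na(nuc)) "manual" else NULL))
}
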