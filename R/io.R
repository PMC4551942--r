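# Readers/writers for the package's on-disk formats: multi-page 16-bit
# grayscale TIFF stacks, long-format trace CSVs with JSON truth sidecars,
# and YAML run configurations.

#' Write / read an image stack as multi-page 16-bit grayscale TIFF
#'
#' Counts are stored as 16-bit integers; values above 65535 are clipped (a
#' warning is raised, mirroring camera saturation).
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `write_stack`: the path, invisibly. `read_stack`: an
#'   [image_stack()] with integer count frames.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- lapply(stack$frames, function(f) {
    if (any(f > 65535)) {
      warning("counts above 65535 clipped to the 16-bit range")
      f[f > 65535] <- 65535
    }
    f[f < 0] <- 0
    round(f) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @param pixel_size,exposure metadata to attach on read (TIFF pages carry
#'   none).
#' @export
read_stack <- function(path, pixel_size = NA_real_, exposure = NA_real_) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) round(f * 65535))
  image_stack(frames, pixel_size = pixel_size, exposure = exposure)
}

#' Write / read intensity traces as long-format CSV
#'
#' Columns: `trace_id`, `frame` (1-based), `time_s`, `intensity`.
#'
#' @param traces a `trace_set`, a list of `pife_trace`, or one `pife_trace`.
#' @param path CSV file path.
#' @return `write_traces`: the path, invisibly. `read_traces`: a list of
#'   `pife_trace` objects.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  if (inherits(traces, "pife_trace")) traces <- list(traces)
  tabs <- lapply(traces, function(tr) data.frame(
    trace_id = tr$trace_id, frame = seq_along(tr$intensity),
    time_s = tr$time, intensity = tr$intensity))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "frame", "time_s", "intensity")
  if (!all(need %in% names(tab)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  lapply(split(tab, tab$trace_id), function(d) {
    d <- d[order(d$frame), ]
    dt <- if (nrow(d) > 1) stats::median(diff(d$time_s)) else NA_real_
    if (nrow(d) > 1 && any(abs(diff(d$time_s) - dt) > 1e-9))
      stop("trace ", d$trace_id[1], " has a non-uniform time grid")
    structure(list(time = d$time_s, intensity = d$intensity,
                   trace_id = as.character(d$trace_id[1]), exposure = dt),
              class = "pife_trace")
  })
}

#' Write / read a trace-set ground-truth sidecar (JSON)
#'
#' @param truth the `truth` element of a `trace_set` (list of `trace_truth`),
#'   or a whole `trace_set`.
#' @param path JSON file path.
#' @return `write_truth`: the path, invisibly. `read_truth`: a list of
#'   `trace_truth` objects.
#' @export
write_truth <- function(truth, path) {
  if (inherits(truth, "trace_set")) truth <- truth$truth
  plain <- lapply(truth, function(tt) {
    tt <- unclass(tt)
    tt$bleach_times <- unname(tt$bleach_times)
    lapply(tt, function(v) ifelse(is.infinite(v), "Inf", v))
  })
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(tt) {
    res <- list(kind = as.character(tt$kind))
    for (f in c("state_path", "bleach_times", "true_peak_times", "slide_end")) {
      v <- unlist(tt[[f]], use.names = FALSE)
      if (is.null(v)) v <- if (f == "slide_end") NA_real_ else numeric(0)
      v[v == "Inf"] <- Inf
      res[[f]] <- as.numeric(v)
    }
    structure(res, class = "trace_truth")
  })
}

#' Read a run configuration file (YAML)
#'
#' @param path YAML file; must contain a top-level integer `seed`.
#' @return a named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run config must set a top-level 'seed'")
  cfg
}
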