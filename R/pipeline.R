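# Pipeline orchestration: simulate -> count -> traces -> models, with one
# root seed, per-stage derived seeds, and a JSON report.

#' Default run configuration
#'
#' @param seed integer root seed.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "count", "traces", "models"),
    fov = list(n_fields = 2L, fov_shape = c(256L, 256L), psf_sigma = 1.3,
               background_mean = 100, spot_amplitude = 800,
               n_protein_spots = 150L, bound_fraction_true = 0.85,
               min_separation = 6),
    count = list(snr_threshold = 5, radius_px = 2, offset = c(0, 0)),
    kinetics = list(duplex_length = 40L, hop_rate = 40, enhancement = 2.25,
                    baseline_intensity = 500, bleach_lifetime = 30,
                    noise_sd = 50, acquisition = 60),
    traces = list(n_traces = 200L, mixture = c(sliding = 0.7, static = 0.3)),
    models = list(kd_list = c(113e-9, 220e-9), standard_state = 1e-3,
                  experimental_kd = 250e-12)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the simulate / count / traces / models pipeline
#'
#' Executes the requested stages on synthetic data and produces one
#' reproducible report: per-field and pooled binding summaries, the sliding
#' fraction and dwell-time summaries of the trace population, and the
#' binding-model outputs. Every stochastic stage derives its seed
#' deterministically from the root seed and the stage name, so a rerun with
#' the same configuration gives an identical report.
#'
#' @param config a configuration list (see [default_run_config()] for the
#'   schema; missing entries take defaults), or a path to a YAML file with
#'   the same structure. `seed` is mandatory.
#' @param out_dir optional directory; when given, image stacks, trace CSVs,
#'   the truth sidecar and `report.json` are written there.
#' @return the report, a list of class `pipeline_report`.
#' @examples
#' \donttest{
#' cfg <- default_run_config(seed = 7)
#' cfg$fov$n_protein_spots <- 40L
#' cfg$traces$n_traces <- 20L
#' rep <- run_pipeline(cfg)
#' rep$binding$bound_fraction
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop("config must set a root 'seed'")
  cfg <- merge_config(default_run_config(config$seed), config)
  stages <- cfg$stages
  known <- c("simulate", "count", "traces", "models")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(config = cfg)
  sim <- NULL; pop <- NULL

  if ("simulate" %in% stages) {
    fov_args <- cfg$fov[setdiff(names(cfg$fov), "n_fields")]
    sim <- lapply(seq_len(cfg$fov$n_fields), function(f) {
      generate_fov(do.call(sim_config, c(
        list(seed = derive_seed(cfg$seed, paste0("fov", f))), fov_args)))
    })
    kin <- do.call(slide_kinetics, cfg$kinetics)
    pop <- generate_trace_population(unlist(cfg$traces$mixture),
                                     cfg$traces$n_traces, kin,
                                     seed = derive_seed(cfg$seed, "traces"))
    report$simulate <- list(
      n_fields = length(sim),
      true_bound_fraction = cfg$fov$bound_fraction_true,
      n_traces = length(pop$traces),
      true_mixture = as.list(unlist(cfg$traces$mixture)))
    if (!is.null(out_dir)) {
      for (f in seq_along(sim)) {
        write_stack(sim[[f]]$protein,
                    file.path(out_dir, sprintf("field%02d_protein.tif", f)))
        write_stack(sim[[f]]$rna,
                    file.path(out_dir, sprintf("field%02d_rna.tif", f)))
        utils::write.csv(sim[[f]]$truth,
                         file.path(out_dir, sprintf("field%02d_truth.csv", f)),
                         row.names = FALSE)
      }
      write_traces(pop, file.path(out_dir, "traces.csv"))
      write_truth(pop, file.path(out_dir, "traces_truth.json"))
    }
  }

  if ("count" %in% stages) {
    if (is.null(sim)) stop("stage 'count' needs stage 'simulate' outputs")
    per <- lapply(sim, function(fv) {
      sa <- detect_spots(fv$protein, psf_sigma = cfg$fov$psf_sigma,
                         snr_threshold = cfg$count$snr_threshold)
      sb <- detect_spots(fv$rna, psf_sigma = cfg$fov$psf_sigma,
                         snr_threshold = cfg$count$snr_threshold)
      cl <- colocalize(sa, sb, radius_px = cfg$count$radius_px,
                       offset = cfg$count$offset)
      c(n_protein = nrow(sa), n_rna = nrow(sb), n_matched = cl$n_matched)
    })
    per <- do.call(rbind, per)
    bs <- bound_fraction(per[, "n_matched"], per[, "n_protein"])
    report$binding <- list(
      per_field = as.data.frame(per),
      n_protein = bs$n_protein, n_rna_bound = bs$n_rna_bound,
      bound_fraction = bs$bound_fraction,
      ci95 = unname(bs$ci95), mean_per_field = bs$mean_per_field)
  }

  if ("traces" %in% stages) {
    if (is.null(pop)) stop("stage 'traces' needs stage 'simulate' outputs")
    verdicts <- lapply(pop$traces, analyze_trace)
    labels <- vapply(verdicts, `[[`, character(1), "label")
    n_slide <- sum(labels == "sliding"); n_static <- sum(labels == "static")
    dts <- unlist(lapply(verdicts, `[[`, "dwell_intervals"))
    dur <- tryCatch(sliding_durations(verdicts,
                                      restrict = cfg$kinetics$acquisition),
                    error = function(e) NULL, warning = function(w) NULL)
    report$traces <- list(
      n_analyzed = length(labels),
      n_sliding = n_slide, n_static = n_static,
      n_rejected = sum(labels == "rejected"),
      sliding_fraction = if (n_slide + n_static > 0)
        n_slide / (n_slide + n_static) else NA_real_,
      mean_dwell_s = if (length(dts)) mean(dts) else NA_real_,
      n_dwell_intervals = length(dts),
      mean_sliding_duration_s = if (!is.null(dur)) dur$naive_mean else NA_real_,
      km_sliding_duration_s = if (!is.null(dur)) dur$km_restricted_mean
                              else NA_real_)
    if (!is.null(out_dir)) {
      vt <- data.frame(
        trace_id = vapply(pop$traces, `[[`, character(1), "trace_id"),
        label = labels,
        bleach_steps = vapply(verdicts, `[[`, integer(1), "bleach_steps"),
        n_dwell = vapply(verdicts, function(v) length(v$dwell_intervals),
                         integer(1)))
      utils::write.csv(vt, file.path(out_dir, "verdicts.csv"),
                       row.names = FALSE)
    }
  }

  if ("models" %in% stages) {
    m <- list()
    if (!is.null(cfg$models$kd_list)) {
      bnd <- avidity_lower_bound(cfg$models$kd_list,
                                 standard_state = cfg$models$standard_state)
      m$avidity_lower_bound_M <- as.numeric(bnd)
      if (!is.null(cfg$models$experimental_kd))
        m$independence_gap <-
          independence_gap(cfg$models$experimental_kd, bnd)$factor
    }
    if (!is.null(cfg$models$structured) && !is.null(cfg$models$nonstructured)) {
      ar <- affinity_ratio(cfg$models$structured, cfg$models$nonstructured,
                           seed = derive_seed(cfg$seed, "affinity_boot"))
      m$affinity_ratio <- ar$ratio
      m$affinity_ratio_ci <- unname(ar$ci)
    }
    report$models <- m
  }

  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass_report(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  report
}

unclass_report <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_report) else x
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report (seed", x$config$seed, ")\n")
  if (!is.null(x$binding))
    cat(sprintf("  bound fraction %.3f (CI %.3f-%.3f) from %d protein spots\n",
                x$binding$bound_fraction, x$binding$ci95[1],
                x$binding$ci95[2], x$binding$n_protein))
  if (!is.null(x$traces))
    cat(sprintf("  sliding fraction %.3f (%d sliding / %d static / %d rejected)\n",
                x$traces$sliding_fraction, x$traces$n_sliding,
                x$traces$n_static, x$traces$n_rejected))
  if (!is.null(x$models) && !is.null(x$models$avidity_lower_bound_M))
    cat(sprintf("  avidity lower bound %.3g M\n",
                x$models$avidity_lower_bound_M))
  invisible(x)
}

#' Write a small fixture dataset
#'
#' Generates a compact, fully synthetic dataset used by the test suite and
#' as a demo input: two 2-channel fields (TIFF), a 200-trace population
#' (CSV + JSON truth), a two-chain synthetic toy PDB, and a YAML run config.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed integer seed.
#' @param n_traces trace-population size.
#' @return invisibly, the vector of written file paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L, n_traces = 200L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (f in 1:2) {
    cfg <- sim_config(seed = derive_seed(seed, paste0("fixture_fov", f)),
                      fov_shape = c(128L, 128L), n_protein_spots = 40L,
                      min_separation = 6)
    fov <- generate_fov(cfg)
    p1 <- file.path(out_dir, sprintf("field%02d_protein.tif", f))
    p2 <- file.path(out_dir, sprintf("field%02d_rna.tif", f))
    write_stack(fov$protein, p1); write_stack(fov$rna, p2)
    paths <- c(paths, p1, p2)
  }
  kin <- slide_kinetics(acquisition = 30)
  pop <- generate_trace_population(c(sliding = 0.6, static = 0.3,
                                     multimer = 0.1),
                                   n_traces, kin,
                                   seed = derive_seed(seed, "fixture_traces"))
  pt <- file.path(out_dir, "traces.csv")
  pj <- file.path(out_dir, "traces_truth.json")
  write_traces(pop, pt); write_truth(pop, pj)
  pp <- file.path(out_dir, "toy_synthetic.pdb")
  write_toy_pdb(pp)
  pc <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(list(seed = as.integer(seed),
                        fov = list(n_fields = 2L, fov_shape = c(128L, 128L),
                                   n_protein_spots = 40L, min_separation = 6),
                        traces = list(n_traces = as.integer(n_traces))), pc)
  invisible(c(paths, pt, pj, pp, pc))
}

# Two-chain synthetic toy complex: a short strand of pseudo-backbone atoms
# (chain A) facing a smaller chain B across a realistic contact distance.
write_toy_pdb <- function(path) {
  za <- seq(0, 16.5, by = 1.5)
  a <- cbind(x = rep(0, length(za)), y = rep(0, length(za)), z = za)
  zb <- seq(2, 14, by = 2)
  b <- cbind(x = rep(4.2, length(zb)), y = rep(0.5, length(zb)), z = zb)
  xyz <- rbind(a, b)
  ele <- c(rep(c("C", "N", "O"), length.out = nrow(a)),
           rep(c("C", "P"), length.out = nrow(b)))
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", nrow(xyz)),
                   resno = seq_len(nrow(xyz)),
                   resid = rep("TOY", nrow(xyz)),
                   eleno = seq_len(nrow(xyz)),
                   elety = ele,
                   chain = c(rep("A", nrow(a)), rep("B", nrow(b))),
                   elesy = ele)
  invisible(path)
}
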