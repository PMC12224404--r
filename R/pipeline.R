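# End-to-end orchestration: phase series + mask -> respiratory regressor.

#' Pipeline configuration
#'
#' Defaults follow the reference protocol: SVD rank 5, solid harmonics to
#' third order, SHARP kernel of 4 voxels with Tikhonov weight 1e-2. The
#' solid-harmonic fit is performed on the selected rank-1 respiratory field
#' by default (`fit_source = "component"`); `"raw"` fits the full harmonic
#' field series instead.
#'
#' @param rank SVD truncation rank.
#' @param harmonic_order maximum solid-harmonic order (0-3).
#' @param sharp optional [sharp_config()]; built from the series' voxel size
#'   when omitted.
#' @param fit_source "component" or "raw".
#' @param keep_fields retain the 4D total/local/harmonic field series in the
#'   result (memory-heavy).
#' @param verbose print stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(rank = 5L, harmonic_order = 3L, sharp = NULL,
                            fit_source = c("component", "raw"),
                            keep_fields = FALSE, verbose = FALSE) {
  structure(list(rank = as.integer(rank),
                 harmonic_order = as.integer(harmonic_order),
                 sharp = sharp, fit_source = match.arg(fit_source),
                 keep_fields = keep_fields, verbose = verbose),
            class = "pipeline_config")
}

#' Run the respiratory field-extraction pipeline
#'
#' Per volume: Laplacian unwrapping of the masked phase, conversion to a
#' field offset in ppb, regularized SHARP, and harmonic background by
#' subtraction. Across volumes: measurement-matrix construction on the eroded
#' mask, truncated SVD, respiratory-component selection by maximal
#' instantaneous variation, solid-harmonic projection of the rank-1
#' respiratory field, and extraction of the zeroth-order coefficient as the
#' regressor.
#'
#' A warning is emitted when the regressor's dominant frequency reaches 90%
#' of the volume-rate Nyquist frequency (1 / (2 TR)): respiration is only
#' recoverable when the TR is shorter than half the breath period, and a
#' dominant frequency near Nyquist is the observable symptom of breathing at
#' or beyond that limit. Breathing far above Nyquist folds deep into the
#' sampled band and cannot be distinguished from genuine slow breathing.
#'
#' @param phase [epi_phase_series()].
#' @param mask [brain_mask()] on the same spatial grid.
#' @param config [pipeline_config()].
#' @return list of class `respfield_result`: `regressor`
#'   ([resp_regressor()]), `coefficients` (`sh_series`), `component`
#'   (`resp_component`), `model` (`lowrank_model`), `component_map` (3D
#'   array), `eroded_mask`, `diagnostics` (singular-value spectrum,
#'   L1-derivative scores, selected index, eroded-mask size, captured
#'   variance fraction of the rank-r model, dominant frequency, Nyquist
#'   frequency, aliasing flag, per-stage timings), and optionally the field
#'   series when `keep_fields = TRUE`.
#' @export
run_pipeline <- function(phase, mask, config = pipeline_config()) {
  stopifnot(inherits(phase, "epi_phase_series"))
  if (!identical(dim(phase$values)[1:3], dim(mask)))
    stop("phase and mask grids differ")
  cfg <- config
  sharp <- cfg$sharp
  if (is.null(sharp)) sharp <- sharp_config(phase$voxel_mm)
  d3 <- dim(phase$values)[1:3]
  nt <- dim(phase$values)[4]
  timing <- c()
  tick <- function() proc.time()[["elapsed"]]
  note <- function(stage, t0) timing[[stage]] <<- round(tick() - t0, 3)
  say <- function(...) if (cfg$verbose) message(sprintf(...))

  say("stage 1/6: unwrap + SHARP over %d volumes", nt)
  t0 <- tick()
  eroded <- tryCatch(erode_mask(mask, sharp$erosion_voxels),
                     error = function(e)
    stop(sprintf(paste0("stage erode: %s; reduce the SHARP kernel radius ",
                        "or the erosion depth"), conditionMessage(e))))
  M <- sum(eroded)
  total <- array(0, c(d3, nt))
  local <- array(0, c(d3, nt))
  eig <- .lap_eigenvalues(d3)
  for (t in seq_len(nt)) {
    ph <- phase$values[, , , t]
    ph[!mask] <- 0                       # discard meaningless exterior phase
    uw <- tryCatch(unwrap_laplacian(ph), error = function(e)
      stop(sprintf("stage unwrap (volume %d): %s", t, conditionMessage(e))))
    tf <- phase_to_field_ppb(uw, phase$te_s, phase$b0_t)
    sh <- tryCatch(remove_background_sharp(tf, mask, sharp),
                   error = function(e)
      stop(sprintf("stage sharp (volume %d): %s", t, conditionMessage(e))))
    total[, , , t] <- tf
    local[, , , t] <- sh$local
  }
  note("fieldmap", t0)

  say("stage 2/6: harmonic field + measurement matrix (M = %d)", M)
  t0 <- tick()
  harm <- harmonic_field(total, local, eroded)
  P <- build_measurement_matrix(harm, eroded, phase$tr_s)
  note("matrix", t0)

  say("stage 3/6: truncated SVD, rank %d", cfg$rank)
  t0 <- tick()
  model <- truncated_svd(P, rank = cfg$rank)
  note("svd", t0)

  t0 <- tick()
  comp <- select_respiratory_component(model)
  comp_series <- component_field_series(model, comp, eroded)
  note("select", t0)

  say("stage 4/6: solid-harmonic fit (order %d, source %s)",
      cfg$harmonic_order, cfg$fit_source)
  t0 <- tick()
  basis <- solid_harmonic_basis(P$voxel_index - 1L, phase$voxel_mm,
                                order = cfg$harmonic_order)
  fit_input <- if (cfg$fit_source == "component") comp_series else harm
  coef_series <- fit_series(fit_input, basis, eroded, tr_s = phase$tr_s)
  note("fit", t0)

  regressor <- regressor_from_coefficients(coef_series)

  sv2 <- model$sv_full^2
  varfrac <- if (sum(sv2) > 0) sum(sv2[seq_len(cfg$rank)]) / sum(sv2) else NA_real_

  freq <- .dominant_frequency_hz(regressor$values, phase$tr_s)
  nyq <- 1 / (2 * phase$tr_s)
  aliasing <- isTRUE(freq >= 0.9 * nyq)
  if (aliasing)
    warning(sprintf(paste0("possible respiratory aliasing: dominant ",
                           "regressor frequency %.3f Hz is within 10%% of ",
                           "the Nyquist frequency %.3f Hz"), freq, nyq))

  diagnostics <- list(
    singular_values = model$sv_full,
    l1_derivative_scores = comp$scores,
    selected_index = comp$index,
    eroded_mask_voxels = M,
    variance_captured = varfrac,
    dominant_freq_hz = freq,
    nyquist_hz = nyq,
    aliasing = aliasing,
    basis_condition = basis$condition,
    timing_s = timing,
    config = list(rank = cfg$rank, harmonic_order = cfg$harmonic_order,
                  fit_source = cfg$fit_source,
                  sharp_kernel_radius_mm = sharp$kernel_radius_mm,
                  sharp_reg_lambda = sharp$reg_lambda,
                  sharp_erosion_voxels = sharp$erosion_voxels))

  comp_map <- array(0, d3)
  comp_map[which(eroded)] <- comp$spatial_map

  out <- list(regressor = regressor, coefficients = coef_series,
              component = comp, model = model, component_map = comp_map,
              eroded_mask = eroded, diagnostics = diagnostics)
  if (cfg$keep_fields) {
    out$total <- field_volume_series(total, mask, "total")
    out$local <- field_volume_series(local, eroded, "local")
    out$harmonic <- harm
  }
  structure(out, class = "respfield_result")
}

# Dominant frequency of a uniformly sampled trace from the periodogram
# argmax (DC excluded); NA for an all-zero or too-short trace.
.dominant_frequency_hz <- function(x, dt) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  x <- x - mean(x)
  if (all(x == 0)) return(NA_real_)
  p <- Mod(fft(x))^2
  half <- 2:(floor(n / 2) + 1L)
  freqs <- (half - 1) / (n * dt)
  freqs[which.max(p[half])]
}

#' @export
print.respfield_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<respfield_result> regressor: %d samples at TR %.3f s\n",
              length(x$regressor$values), x$regressor$tr_s))
  cat(sprintf("  selected component %d of %d; rank-%d model captures %.1f%% of variance\n",
              d$selected_index, length(d$l1_derivative_scores),
              d$config$rank, 100 * d$variance_captured))
  cat(sprintf("  eroded mask: %d voxels; dominant frequency %.3f Hz (Nyquist %.3f Hz)%s\n",
              d$eroded_mask_voxels, d$dominant_freq_hz, d$nyquist_hz,
              if (d$aliasing) " [ALIASING?]" else ""))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Writes `regressor.tsv`, `coefficients.tsv`, `component_map.nii.gz`,
#' `diagnostics.json` and `run_config.yaml`; with `save_fields = TRUE` (and a
#' result run with `keep_fields = TRUE`) also `harmonic_field.nii.gz`.
#'
#' @param result [run_pipeline()] output.
#' @param dir output directory (created if needed).
#' @param voxel_mm voxel size recorded in volume headers.
#' @param save_fields write the 4D harmonic field too.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir, voxel_mm = 1,
                                   save_fields = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_regressor(result$regressor, file.path(dir, "regressor.tsv"))
  write_coefficients(result$coefficients, file.path(dir, "coefficients.tsv"))
  write_volume(result$component_map, file.path(dir, "component_map.nii.gz"),
               voxel_mm = voxel_mm)
  jsonlite::write_json(result$diagnostics,
                       file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(result$diagnostics$config,
                   file.path(dir, "run_config.yaml"))
  if (save_fields && !is.null(result$harmonic))
    write_volume(result$harmonic$values, file.path(dir, "harmonic_field.nii.gz"),
                 voxel_mm = voxel_mm, tr_s = result$regressor$tr_s)
  invisible(dir)
}
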