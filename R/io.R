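# CSV ingestion and the full analysis pipeline.

#' Read per-arm blood-loss samples from a CSV file
#'
#' Expects comma-delimited UTF-8 text with a header containing the arm and
#' volume columns. Rows with missing or nonpositive volumes are dropped and
#' counted (reported via message and the `dropped` attribute). One sample is
#' returned per distinct arm label, in order of first appearance.
#'
#' @param path path to the CSV file.
#' @param arm_col,volume_col column names (defaults `"arm"`, `"volume"`).
#' @param unit measurement unit recorded on the samples.
#' @return Named list of [blood_loss_sample()]s with attribute `dropped`.
#' @export
read_samples <- function(path, arm_col = "arm", volume_col = "volume",
                         unit = "mL") {
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(arm_col, volume_col), names(df))
  if (length(missing_cols))
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  vol <- suppressWarnings(as.numeric(df[[volume_col]]))
  keep <- is.finite(vol) & vol > 0
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(sprintf("dropped %d row(s) with missing or nonpositive volume",
                    dropped))
  df <- df[keep, , drop = FALSE]
  vol <- vol[keep]
  if (!nrow(df)) stop("no usable rows after filtering", call. = FALSE)
  labels <- unique(as.character(df[[arm_col]]))
  out <- lapply(labels, function(lab)
    blood_loss_sample(vol[df[[arm_col]] == lab], lab, unit))
  names(out) <- labels
  attr(out, "dropped") <- dropped
  out
}

#' Write per-arm samples to CSV
#'
#' Columns `arm`, `volume`, `unit`; the inverse of [read_samples()].
#'
#' @param samples named list of [blood_loss_sample()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  df <- do.call(rbind, lapply(samples, function(s)
    data.frame(arm = s$arm_label, volume = s$volumes, unit = s$unit)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Configuration for the full analysis pipeline
#'
#' @param input path to the CSV of measurements.
#' @param arm_col,volume_col input column names.
#' @param unit measurement unit.
#' @param cutoffs event cutoffs in mL, positive and sorted (default 500 and
#'   1000: PPH and severe PPH).
#' @param n_boot bootstrap replicates for the relative-risk CI (>= 100).
#' @param seed integer seed.
#' @param output_dir directory for the report bundle (created if absent).
#' @param verbose print progress messages.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(input, arm_col = "arm", volume_col = "volume",
                            unit = "mL", cutoffs = c(500, 1000),
                            n_boot = 1000L, seed = 1L,
                            output_dir = tempfile("pphloss_"),
                            verbose = FALSE) {
  if (any(cutoffs <= 0) || is.unsorted(cutoffs, strictly = TRUE))
    stop("`cutoffs` must be positive and strictly increasing", call. = FALSE)
  if (n_boot < 100L) stop("`n_boot` must be at least 100", call. = FALSE)
  structure(list(input = input, arm_col = arm_col, volume_col = volume_col,
                 unit = unit, cutoffs = cutoffs, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), output_dir = output_dir,
                 verbose = isTRUE(verbose)),
            class = "analysis_config")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  path
}

fit_summary <- function(fit) {
  out <- list(model = fit$model, method = fit$method, n = fit$n,
              converged = fit$converged, degenerate = fit$degenerate,
              params = list(m = fit$params$m, s = fit$params$s,
                            t = fit$params$t),
              loglik = fit$loglik, aic = fit$aic, bic = fit$bic)
  if (!is.null(fit$se)) out$se <- as.list(fit$se)
  if (!is.null(fit$ci95)) {
    disp <- cbind(estimate = c(fit$params$m, fit$params$s,
                               fit$params$t)[seq_len(fit$k)],
                  se = fit$se, fit$ci95)
    rownames(disp) <- c("m", "s", "t")[seq_len(fit$k)]
    out$display <- as.data.frame(round(disp, 4))
  }
  out
}

#' Run the full blood-loss analysis pipeline
#'
#' In order: measurement diagnostics (digit preference, LOD assessment),
#' two- and three-parameter lognormal fits with an AIC/BIC comparison,
#' per-cutoff tail estimates by both approaches with width ratios, and —
#' when exactly two arms are present — relative risks by both approaches.
#' Reports (JSON + CSV) and plot data (CSV) are written to the configured
#' output directory together with a manifest listing every file with its
#' MD5 hash; outputs produced before a failed stage are retained.
#'
#' @param config an [analysis_config()].
#' @return The report bundle, invisibly: a list with `samples`, `diagnostics`,
#'   `fits`, `tails`, `rr` (two-arm runs only), `manifest`, and `ok` (FALSE
#'   when any fit failed to converge).
#' @export
run_full_analysis <- function(config) {
  if (!inherits(config, "analysis_config"))
    stop("`config` must be an analysis_config", call. = FALSE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  out_path <- function(f) file.path(config$output_dir, f)
  written <- character(0)

  samples <- read_samples(config$input, config$arm_col, config$volume_col,
                          config$unit)
  if (length(samples) > 2L)
    stop(sprintf(
      "found %d arms; pairwise comparison supports at most 2 (split the input)",
      length(samples)), call. = FALSE)

  say("diagnostics on %d arm(s)", length(samples))
  diagnostics <- lapply(samples, function(s)
    list(digit_preference = digit_preference(s), lod = lod_assess(s)))
  written <- c(written, write_json_report(diagnostics, out_path("diagnostics.json")))

  say("fitting 2p and 3p lognormal per arm")
  fits <- list()
  ok <- TRUE
  for (arm in names(samples)) {
    f2 <- fit_mle_2p(samples[[arm]])
    f3 <- suppressWarnings(fit_mle_3p(samples[[arm]]))
    cmp <- tryCatch(compare_fits(f2, f3), error = function(e) NULL)
    ok <- ok && f3$converged
    fits[[arm]] <- list(lognormal2p = f2, lognormal3p = f3, comparison = cmp)
  }
  written <- c(written, write_json_report(
    lapply(fits, function(f) list(lognormal2p = fit_summary(f$lognormal2p),
                                  lognormal3p = fit_summary(f$lognormal3p),
                                  comparison = f$comparison)),
    out_path("fits.json")))

  say("tail estimates at cutoffs %s", paste(config$cutoffs, collapse = ", "))
  best_fits <- lapply(fits, function(f)
    if (f$lognormal3p$converged) f$lognormal3p else f$lognormal2p)
  tails <- tail_table(samples, best_fits, config$cutoffs)
  utils::write.csv(tails, out_path("tail_estimates.csv"), row.names = FALSE)
  written <- c(written, out_path("tail_estimates.csv"))

  for (arm in names(samples)) {
    pd <- probability_plot_data(samples[[arm]], best_fits[[arm]])
    ov <- cdf_overlay_data(samples[[arm]], best_fits[[arm]])
    f1 <- out_path(sprintf("probability_plot_%s.csv", arm))
    f2 <- out_path(sprintf("cdf_overlay_%s.csv", arm))
    utils::write.csv(pd$points, f1, row.names = FALSE)
    utils::write.csv(ov$points, f2, row.names = FALSE)
    written <- c(written, f1, f2)
  }

  rr <- NULL
  if (length(samples) == 2L) {
    say("relative risks (matched-row bootstrap, n_boot = %d)", config$n_boot)
    rr <- rr_report(samples[[1]], samples[[2]], config$cutoffs,
                    n_boot = config$n_boot, seed = config$seed)
    utils::write.csv(rr, out_path("relative_risks.csv"), row.names = FALSE)
    written <- c(written, out_path("relative_risks.csv"))
  } else say("single arm: comparison stage skipped")

  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)))
  if (length(samples) < 2L)
    attr(manifest, "note") <- "single-arm input: comparison stage skipped"
  write_json_report(list(files = manifest,
                         note = attr(manifest, "note"),
                         seed = config$seed, ok = ok),
                    out_path("manifest.json"))

  invisible(list(samples = samples, diagnostics = diagnostics, fits = fits,
                 tails = tails, rr = rr, manifest = manifest, ok = ok))
}
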