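# Plain-text run artefacts: rasters and traces as delimited text, arrays
# as MatrixMarket + TSV, metrics/manifests as key=value text.

#' Write / read a spike raster as two-column delimited text
#'
#' @param raster data.frame with `time_ms`, `neuron`.
#' @param file path.
#' @return (read) the raster data.frame.
#' @export
write_raster <- function(raster, file) {
  write.table(raster[, c("time_ms", "neuron")], file, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_raster
#' @export
read_raster <- function(file) {
  read.table(file, header = TRUE, sep = "\t")
}

#' Write a sampled trace (t, x1..xm) as delimited text
#'
#' @param t_ms sample times (ms).
#' @param x `m x length(t_ms)` matrix.
#' @param file path.
#' @export
write_traces <- function(t_ms, x, file) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  df <- data.frame(t_ms = t_ms, t(x))
  names(df) <- c("t_ms", paste0("x", seq_len(nrow(x))))
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

.write_kv <- function(x, file) {
  vals <- vapply(x, function(v) paste(format(v, digits = 10), collapse = ","),
                 character(1))
  writeLines(paste0(names(x), "=", vals), file)
  invisible(file)
}

.read_kv <- function(file) {
  ln <- readLines(file)
  ln <- ln[nzchar(ln)]
  kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)
  setNames(lapply(kv, `[`, 2), vapply(kv, `[`, character(1), 1))
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[!vapply(cfg, is.function, logical(1))]), f)
  unname(tools::md5sum(f))
}

.write_run <- function(res, cfg, seed, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(preset = cfg$preset, kind = cfg$kind, seed = seed,
                   package_version = as.character(utils::packageVersion("spikeforce")),
                   config_hash = .config_hash(cfg),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  .write_kv(manifest, file.path(out, "manifest.txt"))
  if (inherits(res, "force_fit")) {
    write_raster(res$raster, file.path(out, "raster.tsv"))
    write_traces(res$t_rec_ms, res$xhat, file.path(out, "xhat.tsv"))
    kx <- seq_len(min(ncol(res$x), length(res$t_rec_ms)))
    write_traces(res$t_rec_ms[kx], res$x[, kx, drop = FALSE],
                 file.path(out, "x.tsv"))
    s <- summary(res)
    met <- c(as.list(setNames(res$metrics$l2, paste0("l2_", names(res$metrics$l2)))),
             as.list(setNames(res$metrics$mean_rate_hz,
                              paste0("rate_hz_", names(res$metrics$mean_rate_hz)))),
             list(test_correlation = s$test_correlation,
                  n_spikes = s$n_spikes))
    if (!is.null(res$metrics$unit_rate))
      met$max_unit_rate_hz <- max(res$metrics$unit_rate$mean)
    .write_kv(met, file.path(out, "metrics.txt"))
  } else if (!is.null(res$curve)) {
    write.table(res$curve, file.path(out, "sweep.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    .write_kv(list(onset_G = res$onset_G), file.path(out, "metrics.txt"))
  } else if (!is.null(res$table)) {
    write.table(res$table, file.path(out, "errors.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    .write_kv(list(slope = res$slope, ci_lo = res$ci[1], ci_hi = res$ci[2]),
              file.path(out, "metrics.txt"))
  }
  invisible(out)
}

#' Serialise a weight configuration to portable text files
#'
#' The static matrix goes to MatrixMarket (`omega0.mtx`), the encoders to
#' TSV (`eta.tsv`), and the scalar metadata (N, p, G, Q, model, seed) to
#' `weights_meta.txt`.
#'
#' @param weights a [weight_config()].
#' @param dir directory to create/use.
#' @return the directory, invisibly.
#' @export
save_weights <- function(weights, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(weights$omega0, "dgTMatrix"),
                  file.path(dir, "omega0.mtx"))
  write.table(weights$eta, file.path(dir, "eta.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  .write_kv(list(N = weights$N, p = weights$p, G = weights$G, Q = weights$Q,
                 m = weights$m, model = weights$model,
                 sigma_omega = weights$sigma_omega,
                 seed = if (is.null(weights$seed)) NA else weights$seed),
            file.path(dir, "weights_meta.txt"))
  invisible(dir)
}

#' @rdname save_weights
#' @export
load_weights <- function(dir) {
  meta <- .read_kv(file.path(dir, "weights_meta.txt"))
  omega0 <- methods::as(Matrix::readMM(file.path(dir, "omega0.mtx")),
                        "dgCMatrix")
  eta <- as.matrix(read.table(file.path(dir, "eta.tsv"), sep = "\t"))
  dimnames(eta) <- NULL
  structure(list(N = as.integer(meta$N), p = as.numeric(meta$p),
                 G = as.numeric(meta$G), Q = as.numeric(meta$Q),
                 m = as.integer(meta$m), model = meta$model,
                 omega0 = omega0, eta = eta,
                 sigma_omega = as.numeric(meta$sigma_omega),
                 seed = suppressWarnings(as.integer(meta$seed))),
            class = "weight_config")
}

#' Generate small deterministic fixture files for tests and examples
#'
#' @param kind one of `"supervisor_trace"` (a sampled 5 Hz sinusoid),
#'   `"toy_raster"` (a periodic 10 Hz neuron), `"weight_set"` (a tiny
#'   serialised [weight_config()]), `"synthetic_movie"` (sampled
#'   moving-blob pixel supervisor).
#' @param params named list of kind-specific settings.
#' @param seed integer seed.
#' @param dir output directory.
#' @return character vector of file paths written.
#' @export
make_fixture <- function(kind = c("supervisor_trace", "toy_raster",
                                  "weight_set", "synthetic_movie"),
                         params = list(), seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  switch(kind,
    supervisor_trace = {
      p <- modifyList(list(freq_hz = 5, t_max_s = 1, dt_ms = 1), params)
      tt <- seq(0, p$t_max_s, by = p$dt_ms / 1000)
      f <- file.path(dir, "supervisor_trace.tsv")
      write_traces(tt * 1000, sample_supervisor(sup_sinusoid(p$freq_hz), tt), f)
      f
    },
    toy_raster = {
      p <- modifyList(list(rate_hz = 10, t_max_s = 1), params)
      times <- seq(1000 / p$rate_hz, p$t_max_s * 1000, by = 1000 / p$rate_hz)
      f <- file.path(dir, "toy_raster.tsv")
      write_raster(data.frame(time_ms = times, neuron = 1L), f)
      f
    },
    weight_set = {
      p <- modifyList(list(N = 20, p = 0.3, G = 1, Q = 1, m = 1,
                           model = "lif"), params)
      w <- weight_config(p$N, p$p, p$G, p$Q, p$m, p$model, seed = seed)
      d <- file.path(dir, "weight_set")
      save_weights(w, d)
      list.files(d, full.names = TRUE)
    },
    synthetic_movie = {
      p <- modifyList(list(side = 16, frames = 64, T_s = 2), params)
      sup <- sup_moving_blob(p$T_s, p$side)
      tt <- seq(0, p$T_s, length.out = p$frames + 1)[-(p$frames + 1)]
      f <- file.path(dir, "synthetic_movie.tsv")
      write_traces(tt * 1000, sample_supervisor(sup, tt), f)
      f
    })
}

#' Summarise a completed preset run directory
#'
#' Reads the manifest and metrics written by [run_preset()] and renders a
#' plain-text report (`report.txt`) alongside them.
#'
#' @param run_dir directory containing `manifest.txt`.
#' @return invisibly, a list with `manifest` and `metrics`.
#' @export
report <- function(run_dir) {
  mf <- file.path(run_dir, "manifest.txt")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  manifest <- .read_kv(mf)
  metrics <- if (file.exists(file.path(run_dir, "metrics.txt")))
    .read_kv(file.path(run_dir, "metrics.txt")) else list()
  lines <- c(sprintf("Run report: %s", manifest$preset),
             sprintf("  kind: %s | seed: %s | package %s | config %s",
                     manifest$kind, manifest$seed, manifest$package_version,
                     manifest$config_hash),
             "  metrics:",
             sprintf("    %s = %s", names(metrics), unlist(metrics)))
  writeLines(lines, file.path(run_dir, "report.txt"))
  cat(lines, sep = "\n")
  invisible(list(manifest = manifest, metrics = metrics))
}
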