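## End-to-end orchestration: read -> denoise -> features -> embed ->
## adaptive clustering -> evaluation, with every intermediate persisted as
## CSV so any stage can be re-run in isolation.

#' Pipeline configuration
#'
#' @param input path to an input file or dataset directory, or a
#'   `labeled_dataset` object to run in-memory.
#' @param format `"csv"` (per-segment CSVs with a manifest, as written by
#'   [write_dataset_csv()], or a single multi-row CSV) or `"edf"`.
#' @param fs sampling rate for headerless formats.
#' @param out_dir directory for stage artifacts.
#' @param seed root seed; each stochastic stage derives its own stream.
#' @param denoise list: `method` one of `"joint"`, `"ceemdan"`, `"wavelet"`,
#'   `"none"`; `ensemble_size`, `noise_ratio`, `threshold`, `wavelet`
#'   (a [wavelet_spec()]).
#' @param embed list: `d`, `perplexity`, `iters`.
#' @param ssa an [ssa_params()] (its seed is overridden by a derived one).
#' @param bounds optional [search_bounds()]; `NULL` = data-driven.
#' @param log_level one of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, format = "csv", fs = 200,
                            out_dir = tempfile("eegrun"), seed = 0L,
                            denoise = list(), embed = list(), ssa = NULL,
                            bounds = NULL, log_level = "info") {
  denoise <- utils::modifyList(
    list(method = "joint", ensemble_size = 50L, noise_ratio = 0.2,
         threshold = 0.3, wavelet = wavelet_spec()), denoise)
  embed <- utils::modifyList(list(d = 2L, perplexity = 30, iters = 1000L),
                             embed)
  if (is.null(ssa)) ssa <- ssa_params()
  log_level <- match.arg(log_level, c("debug", "info", "warning", "error"))
  structure(list(input = input, format = format, fs = fs, out_dir = out_dir,
                 seed = as.integer(seed), denoise = denoise, embed = embed,
                 ssa = ssa, bounds = bounds, log_level = log_level),
            class = "pipeline_config")
}

.log_levels <- c(debug = 1, info = 2, warning = 3, error = 4)

pipe_log <- function(cfg, level, fmt, ...) {
  if (.log_levels[level] >= .log_levels[cfg$log_level])
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), sprintf(fmt, ...)))
}

#' Read signal segments from a file
#'
#' Supported formats: `"csv"` (either a dataset directory with a manifest,
#' or a single CSV whose columns are segments / whose single column is one
#' segment) and `"edf"`. The sampling rate comes from the EDF header or the
#' `fs` argument for CSV.
#'
#' @param path input file or directory.
#' @param format `"csv"` or `"edf"`; `"mat"` is recognized but unsupported
#'   (no MAT reader available) and raises an informative error.
#' @param fs sampling rate in Hz for CSV input.
#' @return list of [signal_segment()].
#' @export
read_signals <- function(path, format = c("csv", "edf", "mat"), fs = 200) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input path does not exist: ", path, call. = FALSE)
  switch(format,
    edf = read_edf(path),
    mat = stop("MAT input is not supported by this build; convert to CSV or EDF",
               call. = FALSE),
    csv = {
      if (dir.exists(path)) return(read_dataset_csv(path)$segments)
      df <- utils::read.csv(path)
      lapply(seq_along(df), function(j)
        signal_segment(df[[j]], fs, id = names(df)[j]))
    })
}

#' Run the full adaptive clustering pipeline
#'
#' Executes denoise, feature extraction, embedding, SSA-DBSCAN clustering
#' and index evaluation in sequence, persisting each stage's output under
#' `cfg$out_dir` (denoised signals, feature matrix, embedding, labels, and a
#' JSON run summary). Fully deterministic given `cfg$seed`: the denoiser,
#' the embedding and the optimizer each receive a derived sub-seed, which is
#' logged.
#'
#' @param cfg a [pipeline_config()].
#' @return a `pipeline_run`: list with `labels`, `cluster` (the
#'   `cluster_result`), `embedding`, `features`, `indices` (SC/CH/DBI over
#'   non-noise points), `summary_path`, `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config"))
    stop("cfg must be a pipeline_config", call. = FALSE)
  segments <- if (inherits(cfg$input, "labeled_dataset")) {
    cfg$input$segments
  } else {
    read_signals(cfg$input, cfg$format, cfg$fs)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(segments)
  pipe_log(cfg, "info", "pipeline start: %d segments -> %s", n, cfg$out_dir)

  ## stage 1: denoise ---------------------------------------------------
  den_seed <- derive_seed(cfg$seed, 1L)
  pipe_log(cfg, "debug", "denoise stage seed = %d", den_seed)
  dn <- cfg$denoise
  denoised <- vector("list", n)
  for (i in seq_len(n)) {
    seg <- segments[[i]]
    y <- switch(dn$method,
      none = seg$samples,
      wavelet = wavelet_threshold_denoise(seg, dn$wavelet),
      ceemdan = {
        dec <- ceemdan(seg, dn$ensemble_size, dn$noise_ratio,
                       derive_seed(den_seed, i))
        rho <- imf_correlations(dec, seg)
        sel <- suppressWarnings(select_imfs(rho, dn$threshold))
        if (length(sel) == 0) sel <- which.max(rho)
        partial_reconstruct(dec, sel)
      },
      joint = joint_denoise(seg, dn$ensemble_size, dn$noise_ratio,
                            derive_seed(den_seed, i),
                            threshold = dn$threshold, spec = dn$wavelet),
      stop("unknown denoise method: ", dn$method, call. = FALSE))
    denoised[[i]] <- signal_segment(y, seg$fs, seg$id, seg$stage_label)
  }
  den_ds <- structure(list(segments = denoised,
                           labels = vapply(denoised, function(s)
                             if (is.null(s$stage_label)) -1L else s$stage_label,
                             integer(1)),
                           config = NULL),
                      class = "labeled_dataset")
  write_dataset_csv(den_ds, file.path(cfg$out_dir, "denoised"))
  pipe_log(cfg, "info", "denoise done (method=%s)", dn$method)

  ## stage 2: features ---------------------------------------------------
  fm <- extract_feature_matrix(denoised)
  write_feature_csv(fm, file.path(cfg$out_dir, "features.csv"))
  pipe_log(cfg, "info", "features done: %d x %d", nrow(fm$values),
           ncol(fm$values))

  ## stage 3: embed ------------------------------------------------------
  emb_seed <- derive_seed(cfg$seed, 2L)
  pipe_log(cfg, "debug", "embedding stage seed = %d", emb_seed)
  emb <- tsne_embed(fm, d = cfg$embed$d, perplexity = cfg$embed$perplexity,
                    iters = cfg$embed$iters, seed = emb_seed)
  write_embedding_csv(emb, file.path(cfg$out_dir, "embedding.csv"),
                      ids = fm$segment_ids)
  pipe_log(cfg, "info", "embedding done: final KL %.4f",
           emb$kl_trace[length(emb$kl_trace)])

  ## stage 4: cluster ----------------------------------------------------
  ssa <- cfg$ssa
  ssa$seed <- derive_seed(cfg$seed, 3L)
  pipe_log(cfg, "debug", "clustering stage seed = %d", ssa$seed)
  cl <- ssa_dbscan(emb$coords, bounds = cfg$bounds, params = ssa)
  write_labels_csv(cl, file.path(cfg$out_dir, "labels.csv"),
                   ids = fm$segment_ids)
  pipe_log(cfg, "info", "clustering done: %d clusters, silhouette %.4f",
           cl$n_clusters, cl$fitness)

  ## stage 5: evaluate ---------------------------------------------------
  keep <- cl$labels >= 0
  indices <- if (cl$n_clusters >= 2 && sum(keep) >= 3) {
    pts <- emb$coords[keep, , drop = FALSE]
    labs <- cl$labels[keep]
    c(SC = silhouette_coefficient(pts, labs),
      CH = calinski_harabasz(pts, labs),
      DBI = davies_bouldin(pts, labs))
  } else {
    c(SC = NA_real_, CH = NA_real_, DBI = NA_real_)
  }
  summary <- list(n_segments = n, seed = cfg$seed,
                  stage_seeds = list(denoise = den_seed, embed = emb_seed,
                                     cluster = ssa$seed),
                  denoise_method = dn$method,
                  eps = cl$eps, min_pts = cl$min_pts,
                  n_clusters = cl$n_clusters, n_noise = sum(cl$labels == -1),
                  fitness = cl$fitness, indices = as.list(indices))
  summary_path <- file.path(cfg$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(c(sprintf("segments: %d", n),
               sprintf("clusters: %d (noise %d)", cl$n_clusters,
                       sum(cl$labels == -1)),
               sprintf("eps: %.6g  minPts: %d", cl$eps, cl$min_pts),
               sprintf("silhouette: %.5f", cl$fitness)),
             file.path(cfg$out_dir, "summary.txt"))
  pipe_log(cfg, "info", "pipeline finished")
  structure(list(labels = cl$labels, cluster = cl, embedding = emb,
                 features = fm, indices = indices,
                 summary = summary, summary_path = summary_path,
                 out_dir = cfg$out_dir),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d segments -> %d clusters (noise %d)\n",
              x$summary$n_segments, x$summary$n_clusters, x$summary$n_noise))
  cat(sprintf("  eps=%.4g minPts=%d silhouette=%.4f\n",
              x$summary$eps, x$summary$min_pts, x$summary$fitness))
  if (!anyNA(x$indices))
    cat(sprintf("  SC=%.4f CH=%.2f DBI=%.4f\n",
                x$indices["SC"], x$indices["CH"], x$indices["DBI"]))
  cat("  artifacts:", x$out_dir, "\n")
  invisible(x)
}

#' @export
summary.pipeline_run <- function(object, ...) {
  print(object)
  invisible(object$summary)
}
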