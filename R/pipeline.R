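#' Convert a 3-column Hi-C dump to 7-column paired-loci text
#'
#' Expands each `start1 start2 value` row at a fixed resolution to
#' `chrom start1 end1 chrom start2 end2 value` (end = start + resolution),
#' the format paired-loci intersection tools consume. Line count is
#' preserved.
#'
#' @param path_in 3-column dump. @param resolution bin width bp.
#' @param path_out output path. @param chrom chromosome name for columns 1
#'   and 4.
#' @return `path_out`, invisibly.
#' @export
hic_text_to_pgl <- function(path_in, resolution, path_out, chrom = "chr") {
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path_in, header = FALSE,
                        col.names = c("s1", "s2", "value"))),
    error = function(e) stopf("cannot parse %s: %s", path_in,
                              conditionMessage(e)))
  if (nrow(dt) && (!is.numeric(dt$s1) || !is.numeric(dt$s2)))
    stopf("malformed dump %s: non-numeric start column", path_in)
  out <- if (nrow(dt))
    sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s", chrom, as.integer(dt$s1),
            as.integer(dt$s1 + resolution), chrom, as.integer(dt$s2),
            as.integer(dt$s2 + resolution),
            sprintf("%.15g", dt$value))
  else character(0)
  writeLines(out, path_out)
  invisible(path_out)
}

#' Assemble a validated pipeline configuration
#'
#' All numeric fields are checked here, once, so [run_pipeline()] can assume
#' a valid config. The config is serialized as JSON into the output
#' directory for reproducibility, and its hash is stamped into every output
#' header.
#'
#' @param counts path to the peak count matrix (TSV or .mtx).
#' @param chrom_sizes path to a chrom.sizes file.
#' @param outdir output directory.
#' @param peaks_bed optional BED of peak coordinates (required for .mtx).
#' @param cells optional cell-id list for .mtx input.
#' @param peaks_as "columns" or "rows" orientation of the dense matrix.
#' @param hic character vector of Hi-C dump paths (averaged into the prior);
#'   NULL for constant-penalty mode.
#' @param constant_rho scalar penalty used when `hic` is NULL (default 0.01).
#' @param bin_size,delta,eps model parameters (defaults 25000, 1, 1).
#' @param log_scale_h use log1p of the Hi-C enrichment in the penalty.
#' @param impute run MM matrix completion before covariance estimation
#'   (default TRUE).
#' @param rank,mm_iters,mm_tol,mask completion settings; `mask` is "none"
#'   (all entries observed) or "zeros" (exact zeros treated as missing).
#' @param tol,max_iter graphical-lasso settings.
#' @param min_abs_score,sign_mode,max_distance call filters.
#' @param seed integer seed recorded for provenance (the pipeline itself is
#'   deterministic).
#' @param force overwrite an existing output directory.
#' @return list of class `run_config`.
#' @export
make_config <- function(counts, chrom_sizes, outdir,
                        peaks_bed = NULL, cells = NULL,
                        peaks_as = "columns",
                        hic = NULL, constant_rho = 0.01,
                        bin_size = 25000L, delta = 1, eps = 1,
                        log_scale_h = FALSE,
                        impute = TRUE, rank = NULL, mm_iters = 200L,
                        mm_tol = 1e-5, mask = c("none", "zeros"),
                        tol = 1e-4, max_iter = 100L,
                        min_abs_score = 0, sign_mode = "positive",
                        max_distance = Inf,
                        seed = 1L, force = FALSE) {
  mask <- match.arg(mask)
  stopifnot(bin_size > 0, delta > 0, eps > 0, constant_rho >= 0,
            mm_iters > 0, mm_tol > 0, tol > 0, max_iter > 0,
            min_abs_score >= 0, max_distance > 0)
  cfg <- list(counts = counts, chrom_sizes = chrom_sizes, outdir = outdir,
              peaks_bed = peaks_bed, cells = cells, peaks_as = peaks_as,
              hic = hic, constant_rho = constant_rho,
              bin_size = as.integer(bin_size), delta = delta, eps = eps,
              log_scale_h = log_scale_h, impute = impute, rank = rank,
              mm_iters = as.integer(mm_iters), mm_tol = mm_tol, mask = mask,
              tol = tol, max_iter = as.integer(max_iter),
              min_abs_score = min_abs_score, sign_mode = sign_mode,
              max_distance = max_distance, seed = as.integer(seed),
              force = force)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  ser <- cfg[setdiff(names(cfg), "force")]
  ser$max_distance <- as.character(ser$max_distance)  # Inf-safe
  json <- jsonlite::toJSON(ser, auto_unbox = TRUE, null = "null")
  # small stable polynomial hash; avoids an external digest dependency
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full interaction-prediction pipeline
#'
#' Per chromosome: bin and log-transform the peak matrix, optionally denoise
#' by MM matrix completion, estimate the covariance, build the penalty
#' (Hi-C prior averaged over the supplied maps, or the constant baseline),
#' fit the elementwise-penalty graphical lasso, and emit interaction calls.
#' Outputs: per-chromosome and merged BEDPE, a UCSC interact track and a
#' JSON run report (dimensions, edge counts, objective traces, timings).
#' Deterministic given config; re-running over an existing output directory
#' requires `force = TRUE`.
#'
#' @param config a `run_config` from [make_config()].
#' @return list: `calls` (merged `interaction_calls`), `fits` (per
#'   chromosome `precision_fit`), `report`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  if (dir.exists(cfg$outdir) &&
      length(list.files(cfg$outdir)) && !isTRUE(cfg$force))
    stopf("output directory %s is non-empty; use force = TRUE", cfg$outdir)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  set.seed(cfg$seed)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    list(value = out, seconds = proc.time()[["elapsed"]] - t0)
  }

  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  bins <- bin_genome(sizes, cfg$bin_size)
  pm <- stage("read_counts", read_peak_matrix(cfg$counts, cfg$peaks_bed,
                                              cfg$cells, cfg$peaks_as))$value

  chroms <- intersect(names(sizes), unique(pm$peaks$chrom))
  fits <- list(); all_calls <- list(); report_chrom <- list()
  for (ch in chroms) {
    st_pre <- stage("preprocess",
                    preprocess_chromosome(pm$counts, pm$peaks, bins, ch))
    bm <- st_pre$value
    X <- bm$values
    mm_info <- NULL
    if (isTRUE(cfg$impute) && min(dim(X)) >= 4L) {
      A <- if (cfg$mask == "zeros") (X != 0) * 1 else NULL
      st_mm <- stage("impute",
                     mm_factorize(X, A = A, r = cfg$rank, max_iter = cfg$mm_iters,
                                  tol = cfg$mm_tol))
      X <- st_mm$value$X
      mm_info <- list(iterations = st_mm$value$iterations,
                      converged = st_mm$value$converged,
                      final_cost = tail(st_mm$value$cost, 1),
                      seconds = st_mm$seconds)
    }
    st_cov <- stage("covariance", empirical_covariance(X))
    rho <- if (is.null(cfg$hic)) {
      constant_penalty(bm$bins, cfg$constant_rho)
    } else {
      maps <- lapply(cfg$hic, load_contact_text,
                     resolution = cfg$bin_size, chrom = ch)
      build_penalty(average_contacts(maps), bm$bins,
                    delta = cfg$delta, eps = cfg$eps,
                    log_scale_h = cfg$log_scale_h)
    }
    st_fit <- stage("glasso", fit_glasso(st_cov$value, rho, tol = cfg$tol,
                                         max_iter = cfg$max_iter))
    fit <- st_fit$value
    calls <- call_interactions(fit, bm$bins, cfg$min_abs_score,
                               cfg$sign_mode, cfg$max_distance)
    fits[[ch]] <- fit
    all_calls[[ch]] <- calls
    report_chrom[[ch]] <- list(
      cells = nrow(bm$values), occupied_bins = ncol(bm$values),
      impute = mm_info, penalty_mode = rho$mode,
      edges = fit$n_edges, calls = nrow(calls),
      converged = fit$converged,
      objective_final = tail(fit$objective_trace, 1),
      seconds = list(preprocess = st_pre$seconds,
                     covariance = st_cov$seconds, glasso = st_fit$seconds))
  }

  merged <- do.call(rbind, all_calls)
  merged <- merged[order(merged$chrom, merged$start_a, merged$start_b), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  class(merged) <- c("interaction_calls", "data.frame")

  p_bedpe <- file.path(cfg$outdir, "interactions.bedpe")
  p_track <- file.path(cfg$outdir, "interactions.interact")
  p_report <- file.path(cfg$outdir, "report.json")
  p_config <- file.path(cfg$outdir, "config.json")
  meta <- sprintf("config=%s", hash)
  write_bedpe(merged, p_bedpe, metadata = meta)
  write_ucsc_track(merged, p_track,
                   track_name = sprintf("chromglasso_%s", hash))
  ser_cfg <- cfg[setdiff(names(cfg), "force")]
  ser_cfg$max_distance <- as.character(ser_cfg$max_distance)
  jsonlite::write_json(ser_cfg, p_config, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  report <- list(tool = "chromglasso",
                 version = as.character(utils::packageVersion("chromglasso")),
                 config_hash = hash, chromosomes = report_chrom,
                 total_calls = nrow(merged))
  jsonlite::write_json(report, p_report, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(calls = merged, fits = fits, report = report,
       paths = list(bedpe = p_bedpe, track = p_track, report = p_report,
                    config = p_config))
}
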