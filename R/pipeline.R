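#' Run the analysis pipeline end to end
#'
#' Orchestrates simulate -> behavior -> rates -> pca -> kinet -> cs ->
#' decode -> lds -> rrr -> overlap on a simulated or loaded session, writing
#' one or more CSV outputs per stage plus a JSON manifest recording inputs,
#' parameters, per-stage seeds and output file hashes. Identical config and
#' seed reproduce byte-identical numeric outputs.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{out_dir}{output directory (created).}
#'     \item{seed}{global integer seed; per-stage seeds are derived from it
#'       with fixed per-stage offsets so adding a stage does not shift the
#'       draws of the others.}
#'     \item{stages}{character vector of stage names (default: all).}
#'     \item{simulation}{list of [sim_config()] arguments, or `NULL` with
#'       `bundle_path` set.}
#'     \item{bundle_path}{optional session bundle to load instead of
#'       simulating.}
#'     \item{decode}{optional list: `window`, `bin_ms`, `n_shuffles`,
#'       `n_units`.}
#'     \item{lds}{optional list: `dims`, `epoch`.}
#'   }
#' @return the manifest (invisibly), also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config) {
  all_stages <- c("simulate", "behavior", "rates", "pca", "kinet", "cs",
                  "decode", "lds", "rrr", "overlap")
  stages <- config$stages
  if (is.null(stages)) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) {
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(name) {
    (config$seed * 97L + match(name, all_stages) * 1009L) %%
      .Machine$integer.max
  }
  outputs <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  state <- new.env(parent = emptyenv())
  if (!is.null(config$bundle_path)) {
    state$session <- read_session(config$bundle_path)
  }

  for (st in intersect(all_stages, stages)) {
    switch(st,
      simulate = run_stage(st, function() {
        args <- config$simulation
        if (is.null(args)) args <- list()
        args$seed <- stage_seed("simulate")
        state$session <- do.call(sim_config, args) |> simulate_session()
        sidecar <- args
        sidecar$hypothesis <- state$session$session_id
        jsonlite::write_json(sidecar,
                             file.path(out_dir, "simulation_config.json"),
                             auto_unbox = TRUE)
        outputs <<- c(outputs, file.path(out_dir, "simulation_config.json"))
      }),
      behavior = run_stage(st, function() {
        tr <- state$session$trials
        coh <- sort(unique(abs(tr$signed_coherence)))
        p <- vapply(coh, function(c)
          mean(tr$correct[abs(tr$signed_coherence) == c]), numeric(1))
        fit <- fit_weibull(coh, p)
        put(data.frame(alpha = fit$alpha, gamma_slope = fit$gamma_slope,
                       r2 = fit$r2,
                       rt_coherence_r2 = rt_coherence_r2(
                         tr$rt_ms, abs(tr$signed_coherence))),
            "psychometric_fit.csv")
        seq_stats <- post_outcome_rt_comparison(tr)
        put(data.frame(median_ec = seq_stats$median_ec,
                       median_cc = seq_stats$median_cc,
                       n_ec = seq_stats$n_ec, n_cc = seq_stats$n_cc,
                       p_value = seq_stats$p_value),
            "outcome_sequences.csv")
      }),
      rates = run_stage(st, function() {
        state$tensor_rt <- condition_average(state$session,
                                             grouping = "rt_bins")
        put(state$tensor_rt$cells, "rate_tensor_cells.csv")
      }),
      pca = run_stage(st, function() {
        state$stack <- soft_normalize_stack(state$tensor_rt)
        state$pc <- fit_pca(state$stack)
        put(data.frame(component = seq_along(state$pc$eigenvalues),
                       eigenvalue = state$pc$eigenvalues,
                       explained_var = state$pc$explained_var),
            "explained_variance.csv")
      }),
      kinet = run_stage(st, function() {
        state$trajset <- project(state$tensor_rt, state$pc,
                                 n_dims = min(6L,
                                              ncol(state$pc$loadings)))
        kr <- kinet_analyze(state$trajset)
        tidy <- do.call(rbind, lapply(seq_along(kr$levels), function(i)
          data.frame(level = kr$levels[i], ref_time_ms = kr$ref_time_ms,
                     t_ref_ms = kr$t_ref[i, ],
                     distance = kr$signed_distance[i, ])))
        put(tidy, "kinet.csv")
        sp <- scalar_speed(state$trajset)
        put(data.frame(level = sp$levels, prestim_speed = sp$prestim_mean),
            "speed.csv")
      }),
      cs = run_stage(st, function() {
        levels <- sort(unique(state$trajset$cells$level_index))
        rows <- lapply(levels, function(l) {
          cur <- cs_from_trajset(state$trajset, l)
          fit <- fit_piecewise_cs(cur, window = c(-100,
                                                  max(cur$time_ms)))
          data.frame(level = l, b = fit$b, m = fit$m,
                     t_latency_ms = fit$t_latency, flat = fit$flat)
        })
        put(do.call(rbind, rows), "cs_fits.csv")
      }),
      decode = run_stage(st, function() {
        dc <- config$decode
        if (is.null(dc)) dc <- list()
        window <- dc$window %||% c(-400, 0)
        bin_ms <- dc$bin_ms %||% (window[2L] - window[1L])
        n_shuffles <- dc$n_shuffles %||% 100L
        set.seed(stage_seed("decode"))
        units <- if (!is.null(dc$n_units))
          sort(sample.int(nrow(state$session$units), dc$n_units)) else NULL
        rtd <- rt_decoder(state$session, bin_ms = bin_ms, window = window,
                          n_shuffles = n_shuffles, units = units,
                          seed = stage_seed("decode"))
        put(cbind(rtd$bins,
                  r2_coherence_only = rtd$r2_coherence_only),
            "rt_decoder.csv")
        chd <- choice_decoder(state$session, bin_ms = bin_ms,
                              window = window, n_shuffles = n_shuffles,
                              units = units, seed = stage_seed("decode"))
        put(chd$bins, "choice_decoder.csv")
      }),
      lds = run_stage(st, function() {
        lc <- config$lds
        if (is.null(lc)) lc <- list()
        dims <- lc$dims %||% c(2L, 4L, 6L)
        epoch <- lc$epoch %||% "prestimulus"
        rows <- lapply(dims, function(d) {
          lat <- lds_latents(state$session, epoch = epoch, latent_dim = d)
          fit <- fit_lds(lat$latents)
          data.frame(dim = d, epoch = epoch, cv_r2 = fit$cv_r2)
        })
        put(do.call(rbind, rows), "lds_fit.csv")
      }),
      rrr = run_stage(st, function() {
        ses <- state$session
        pre <- count_tensor(ses, bin_ms = 400, window = c(-400, 0))
        post <- count_tensor(ses, bin_ms = 250, window = c(150, 400))
        pre_counts <- pre$counts[, , 1L]
        pre_counts <- pre_counts[, apply(pre_counts, 2L, stats::sd) > 0,
                                 drop = FALSE]   # drop prestimulus-silent units
        X <- cbind(pre_counts,
                   choice = as.numeric(ses$trials$choice == "left"),
                   coherence = abs(ses$trials$signed_coherence))
        Y <- post$counts[, , 1L]
        fit <- fit_rrr(X, Y, ranks = seq_len(min(8L, ncol(X), ncol(Y))),
                       seed = stage_seed("rrr"))
        put(data.frame(rank = fit$ranks, val_mse = fit$val_mse,
                       chosen = fit$ranks == fit$rank,
                       cv_r2 = ifelse(fit$ranks == fit$rank, fit$cv_r2, NA)),
            "rrr_fit.csv")
      }),
      overlap = run_stage(st, function() {
        tensor_out <- condition_average(state$session, grouping = "outcome")
        ai <- alignment_between(state$tensor_rt, tensor_out,
                                n_dims = min(6L,
                                             nrow(state$session$units)))
        put(data.frame(A = ai$A, n_dims = ai$n_dims_numerator,
                       captured = ai$captured_variance,
                       total = ai$total_variance),
            "alignment.csv")
      })
    )
  }
  manifest <- list(
    seed = config$seed,
    stages = stages,
    parameters = config[setdiff(names(config), c("out_dir"))],
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
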