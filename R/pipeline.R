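#' Default analysis settings for the pipeline drivers
#'
#' @param n_neighbors kNN graph neighbourhood (capped at n-2 for small
#'   populations).
#' @param resolutions resolution-scan grid.
#' @param n_repeats,subsample_frac stability-scan settings.
#' @param rate_threshold,width_threshold putative-inhibitory rule: clusters
#'   with median firing rate above `rate_threshold` (Hz) and median AP
#'   width below `width_threshold` (ms) are labeled "I".
#' @param r2_threshold GLIF subthreshold variance-explained filter.
#' @param sta_window STA window (ms).
#' @param d shared MCFA dimension; `NULL` selects the pooled eigenvalue
#'   count (at least 1).
#' @param seed analysis seed.
#' @return named list of settings.
#' @export
pipeline_config <- function(n_neighbors = 20L,
                            resolutions = seq(0, 5, by = 0.5),
                            n_repeats = 25L, subsample_frac = 0.9,
                            rate_threshold = 10, width_threshold = 0.5,
                            r2_threshold = 0.7, sta_window = 100,
                            d = NULL, seed = 1L) {
  list(n_neighbors = n_neighbors, resolutions = resolutions,
       n_repeats = n_repeats, subsample_frac = subsample_frac,
       rate_threshold = rate_threshold, width_threshold = width_threshold,
       r2_threshold = r2_threshold, sta_window = sta_window, d = d,
       seed = seed)
}

# preprocess + graph + resolution scan + final Louvain for one feature matrix
cluster_attribute <- function(X, cfg, seed_offset = 0L) {
  Xp <- preprocess_features(X)
  k <- min(cfg$n_neighbors, nrow(Xp) - 2L)
  g <- build_knn_graph(Xp, n_neighbors = k)
  sel <- select_resolution(g, resolutions = cfg$resolutions,
                           n_repeats = cfg$n_repeats,
                           subsample_frac = cfg$subsample_frac,
                           seed = cfg$seed + seed_offset)
  list(X = Xp, graph = g, gamma_star = sel$gamma_star,
       stability = sel$stability, result = sel$result,
       labels = sel$result$labels)
}

# mean waveform matrix over neurons for one protocol; returns NULL rows for
# neurons without usable spikes
mean_waveform_matrix <- function(recs, window_pre, window_post, sh = FALSE) {
  rows <- lapply(recs, function(r) {
    if (sh) {
      W <- do.call(rbind, lapply(r, function(sw) {
        spk <- detect_spikes(sw$V, sw$dt)
        ws <- extract_waveforms(sw$V, sw$dt, spk, window_pre, window_post)
        ws$waveforms
      }))
      if (is.null(W) || nrow(W) == 0L) NULL else colMeans(W)
    } else {
      spk <- detect_spikes(r$V, r$dt)
      ws <- extract_waveforms(r$V, r$dt, spk, window_pre, window_post)
      if (nrow(ws$waveforms) == 0L) NULL else ws$mean_waveform
    }
  })
  ok <- !vapply(rows, is.null, TRUE)
  list(X = do.call(rbind, rows[ok]), ok = ok)
}

#' Cross-protocol classification comparison
#'
#' Runs the first headline analysis on a paired FN/SH dataset: extracts
#' 5-ms mean spike waveforms and the 22 action-potential attributes per
#' protocol, clusters each with the graph pipeline, and quantifies
#' cross-protocol correspondence with the cluster-likelihood matrix,
#' ARI/AMI, cross-protocol cosine-similarity summaries, and an
#' ensemble-clustering (ECG) consistency check on the waveform graphs.
#' Neurons lacking usable spikes in either protocol are dropped and listed.
#'
#' @param dataset a `recording_set` with both `fn` and `sh`.
#' @param cfg a [pipeline_config()].
#' @return report list with elements `waveform` and `ap` (each carrying
#'   per-protocol cluster results, `likelihood`, `ari`, `ami`,
#'   `cosine_cross`), `ecg` (ECG vs Louvain AMI per protocol), and
#'   `dropped` (cell ids excluded).
#' @export
run_protocol_comparison <- function(dataset, cfg = pipeline_config()) {
  stopifnot(inherits(dataset, "recording_set"),
            !is.null(dataset$fn), !is.null(dataset$sh))
  ids <- dataset$truth$table$cell_id

  wf_fn <- mean_waveform_matrix(dataset$fn, 2, 3)
  wf_sh <- mean_waveform_matrix(dataset$sh, 2, 3, sh = TRUE)
  ap_fn <- t(vapply(dataset$fn, ap_feature_vector, numeric(22L)))
  ap_sh <- t(vapply(dataset$sh, ap_feature_vector, numeric(22L),
                    protocol = "SH"))

  keep_wf <- wf_fn$ok & wf_sh$ok
  keep_ap <- stats::complete.cases(ap_fn) & stats::complete.cases(ap_sh)

  analyse_pair <- function(X_fn, X_sh, off) {
    c_fn <- cluster_attribute(X_fn, cfg, seed_offset = off)
    c_sh <- cluster_attribute(X_sh, cfg, seed_offset = off + 1L)
    cmp <- compare_labelings(c_sh$labels, c_fn$labels)
    list(fn = c_fn, sh = c_sh,
         likelihood = cluster_likelihood(c_sh$labels, c_fn$labels),
         ari = cmp$ari, ami = cmp$ami,
         cosine_cross = cosine_summary(c_sh$X, c_sh$labels,
                                       c_fn$labels, X_b = c_fn$X))
  }
  wf_idx_fn <- keep_wf[wf_fn$ok]  # rows of wf matrices to keep
  wf_idx_sh <- keep_wf[wf_sh$ok]
  waveform <- analyse_pair(wf_fn$X[wf_idx_fn, , drop = FALSE],
                           wf_sh$X[wf_idx_sh, , drop = FALSE], 0L)
  ap <- analyse_pair(ap_fn[keep_ap, , drop = FALSE],
                     ap_sh[keep_ap, , drop = FALSE], 2L)

  ecg_check <- lapply(list(fn = waveform$fn, sh = waveform$sh), function(cl) {
    e <- ecg_cluster(cl$graph, resolution = cl$gamma_star, seed = cfg$seed)
    list(result = e,
         ami_vs_louvain = adjusted_mutual_information(e$labels, cl$labels))
  })

  list(waveform = waveform, ap = ap, ecg = ecg_check,
       dropped = list(waveform = ids[!keep_wf], ap = ids[!keep_ap]),
       cfg = cfg)
}

#' Attribute-set comparison under the frozen-noise protocol
#'
#' Runs the second headline analysis: splits the population into putative
#' excitatory/inhibitory groups by clustering 10-ms mean FN waveforms
#' (clusters with high median firing rate and narrow median AP width are
#' labeled "I"), then, per class, builds the four attribute sets — the 22
#' AP attributes, the six passive GLIF parameters (variance-explained
#' filtered), the adaptation-current kernel and the spike-triggered
#' average — clusters each, quantifies cross-attribute agreement, and fits
#' the MCFA shared/private variance decomposition over the four sets.
#'
#' @param dataset a `recording_set` with `fn` recordings.
#' @param cfg a [pipeline_config()].
#' @param fits optional precomputed list of `glif_fit` (one per neuron).
#' @return report list: `ei` (waveform clustering and E/I assignment),
#'   and per class a list with `sets` (the four matrices), `clusters`,
#'   `agreement` (pairwise ARI/AMI), `mcfa` (model, `variance`,
#'   `importance`), `n`.
#' @export
run_attribute_comparison <- function(dataset, cfg = pipeline_config(),
                                     fits = NULL) {
  stopifnot(inherits(dataset, "recording_set"), !is.null(dataset$fn))
  recs <- dataset$fn
  n <- length(recs)

  # --- putative E/I split from 10-ms waveforms + firing statistics
  wf <- mean_waveform_matrix(recs, 5, 5)
  ap <- t(vapply(recs, ap_feature_vector, numeric(22L)))
  keep <- wf$ok
  wcl <- cluster_attribute(wf$X, cfg, seed_offset = 100L)
  rate <- ap[keep, "firing_rate"]
  width <- ap[keep, "width_median"]
  is_inh_cluster <- vapply(sort(unique(wcl$labels)), function(cl) {
    m <- wcl$labels == cl
    stats::median(rate[m], na.rm = TRUE) > cfg$rate_threshold &&
      stats::median(width[m], na.rm = TRUE) < cfg$width_threshold
  }, TRUE)
  ei <- ifelse(is_inh_cluster[wcl$labels], "I", "E")

  # --- GLIF fits for passive + adaptation sets
  if (is.null(fits))
    fits <- lapply(recs, function(r)
      tryCatch(fit_glif(r, r2_threshold = cfg$r2_threshold),
               error = function(e) NULL))

  analyse_class <- function(cls) {
    idx <- which(keep)[ei == cls]
    if (length(idx) < 8L)
      stop("class ", cls, " has too few neurons after filtering")
    ok_fit <- vapply(idx, function(i) !is.null(fits[[i]]) &&
                       !fits[[i]]$excluded, TRUE)
    if (!any(ok_fit))
      stop("variance-explained filter removed class ", cls, " entirely")
    idx <- idx[ok_fit]
    ap_ok <- stats::complete.cases(ap[idx, , drop = FALSE])
    idx <- idx[ap_ok]
    sets <- list(
      AP = attribute_set(ap[idx, , drop = FALSE], "AP"),
      passive = attribute_set(
        t(vapply(fits[idx], function(f) f$passive, numeric(6L))), "passive"),
      eta = attribute_set(
        t(vapply(fits[idx], function(f) f$eta,
                 numeric(length(fits[[idx[1L]]]$eta)))), "eta"),
      STA = attribute_set(
        t(vapply(idx, function(i) {
          compute_sta(recs[[i]]$I,
                      detect_spikes(recs[[i]]$V, recs[[i]]$dt),
                      window = cfg$sta_window)$values
        }, numeric(round(cfg$sta_window / recs[[idx[1L]]]$dt)))), "STA"))
    clusters <- lapply(seq_along(sets), function(j)
      cluster_attribute(sets[[j]], cfg, seed_offset = 200L + j))
    names(clusters) <- names(sets)
    pairs <- utils::combn(names(sets), 2L)
    agreement <- apply(pairs, 2L, function(pr) {
      cmp <- compare_labelings(clusters[[pr[1L]]]$labels,
                               clusters[[pr[2L]]]$labels)
      data.frame(a = pr[1L], b = pr[2L], ari = cmp$ari, ami = cmp$ami)
    })
    agreement <- do.call(rbind, agreement)
    d <- cfg$d %||% max(1L, select_shared_dim(sets)$pooled)
    model <- fit_mcfa(sets, d = d, seed = cfg$seed)
    list(n = length(idx), cell_ids = dataset$truth$table$cell_id[idx],
         sets = sets, clusters = clusters, agreement = agreement,
         mcfa = list(model = model, variance = variance_report(model),
                     importance = feature_importance(model)))
  }

  classes <- intersect(c("E", "I"), unique(ei))
  out <- list(ei = list(clusters = wcl, labels = ei,
                        cell_ids = dataset$truth$table$cell_id[keep]),
              cfg = cfg)
  for (cls in classes)
    out[[cls]] <- tryCatch(analyse_class(cls), error = function(e) {
      warning("class ", cls, " skipped: ", conditionMessage(e))
      NULL
    })
  out
}

#' Write feature and label tables to CSV
#'
#' @param report a report from [run_protocol_comparison()] or
#'   [run_attribute_comparison()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_report_csv <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(obj), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$waveform)) {
    wr(data.frame(fn = report$waveform$fn$labels,
                  sh = report$waveform$sh$labels), "waveform_labels")
    wr(report$waveform$likelihood, "waveform_likelihood")
    wr(report$waveform$fn$stability, "waveform_fn_stability")
  }
  if (!is.null(report$ei))
    wr(data.frame(cell_id = report$ei$cell_ids, class = report$ei$labels),
       "ei_labels")
  for (cls in intersect(c("E", "I"), names(report))) {
    if (is.null(report[[cls]])) next
    wr(report[[cls]]$mcfa$variance$summary,
       paste0("mcfa_variance_", cls))
    wr(report[[cls]]$agreement, paste0("agreement_", cls))
  }
  invisible(paths)
}
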