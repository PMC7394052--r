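#' Default pipeline configuration
#'
#' Every stage parameter with its default: factorization cutoffs 80%/1.5%
#' (envelopes) and 55%/4% (coherence spectra), 200 ms Hamming taper with
#' ~50% overlap on a 256 Hz grid, 100 phase-randomized surrogates at
#' alpha = 0.05, N = 200 samples per normalized stride, corrected waveform
#' alpha 1/300, metric ANOVA alphas 0.05 / 0.005, and mode-classifier
#' thresholds delta = 0.15, v = 0.2.
#'
#' @param seed master seed
#' @param n_subjects,speeds,n_strides synthetic-study shape
#' @return named list of parameters understood by [run_study()]
#' @export
default_config <- function(seed = 1L, n_subjects = 2,
                           speeds = c(1.0, 2.5, 4.0), n_strides = 16) {
  list(seed = as.integer(seed), n_subjects = n_subjects, speeds = speeds,
       n_strides = n_strides,
       N = 200, lambda_cutoff = 80, delta_cutoff = 1.5,
       coh_lambda_cutoff = 55, coh_delta_cutoff = 4,
       target_fs = 256, taper_s = 0.2, band = c(4, 60),
       n_surrogates = 100, coh_alpha = 0.05,
       classifier_delta = 0.15, classifier_v = 0.2,
       spm_alpha = bonferroni_alpha(), spm_n_perm = 1000,
       anova_alpha = 0.05, posthoc_alpha = 0.005,
       max_rank = 8, coh_max_rank = 6, n_restarts = 5,
       remove_heartbeat = FALSE,
       stages = c("modes", "synergy", "coherence", "stats"))
}

#' Run the full study pipeline on a synthetic (or loaded) study
#'
#' Stages, in order: generate/ingest recordings; classify the arm-leg
#' coordination mode of every trial; preprocess EMG to the concatenated
#' envelope matrix; extract synergies with rank selection and build the
#' synergy multiplex; compute corrected intermuscular coherence for all
#' pairs, decompose into frequency components and build the coherence
#' multiplex (thresholded, with communities and layer metrics); compare
#' synergy waveforms between modes and network metrics between conditions.
#'
#' @param config list from [default_config()]
#' @param study optional pre-built `gait_study` (otherwise generated from
#'   the config)
#' @param out_dir optional directory for the JSON/TSV report bundle
#' @return report list (class `gait_report`) with per-stage results and the
#'   parameter snapshot
#' @export
run_study <- function(config = default_config(), study = NULL,
                      out_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(study)) {
    study <- generate_study(n_subjects = cfg$n_subjects, speeds = cfg$speeds,
                            n_strides = cfg$n_strides,
                            gt = default_ground_truth(seed = cfg$seed),
                            seed = cfg$seed)
  }
  report <- list(config = cfg, synthetic = !is.null(study$ground_truth))
  recs <- study$recordings

  if ("modes" %in% cfg$stages) {
    report$modes <- do.call(rbind, lapply(recs, function(rec) {
      ev <- classify_mode(rec$kin$arm, rec$kin$leg, rec$fs_kin,
                          delta = cfg$classifier_delta, v = cfg$classifier_v)
      data.frame(subject = rec$subject, speed_kmh = rec$speed_kmh,
                 planted_mode = rec$mode, label = ev$label,
                 overlap_21 = ev$overlap_21, overlap_11 = ev$overlap_11,
                 circvar_21 = ev$circvar_21, circvar_11 = ev$circvar_11)
    }))
  }

  # preprocessing shared by the synergy and coherence stages
  prep <- lapply(recs, function(rec) {
    emg <- rec$emg
    if (cfg$remove_heartbeat)
      emg <- remove_heartbeat(emg, rec$fs_emg)
    rect <- highpass_rectify(emg, rec$fs_emg)
    ev <- detect_heel_strikes(rec$kin$grf, rec$fs_kin)
    # heel strikes are at the kinematic rate; reuse on the EMG clock
    env <- emg_envelope(rect, rec$fs_emg)
    strides <- time_normalize(env, ev, rec$fs_emg, N = cfg$N)
    list(subject = rec$subject, speed_kmh = rec$speed_kmh, mode = rec$mode,
         strides = strides, rect = rect, fs = rec$fs_emg)
  })

  if ("synergy" %in% cfg$stages) {
    em <- amplitude_normalize_average_concat(prep,
                                             fastest_speed = max(cfg$speeds))
    sel <- select_rank(em$X, lambda_cutoff = cfg$lambda_cutoff,
                       delta_cutoff = cfg$delta_cutoff,
                       max_rank = cfg$max_rank,
                       n_restarts = cfg$n_restarts, seed = cfg$seed)
    model <- order_synergies(sel$models[[sel$m]], N = cfg$N)
    syn_net <- synergy_layers(model, N = cfg$N, blocks = em$blocks)
    syn_part <- communities_multiplex(syn_net, seed = cfg$seed)
    report$synergy <- list(m = sel$m, lambda_profile = sel$lambda_profile,
                           model = model, envelope_matrix = em,
                           network = syn_net, partition = syn_part)
  }

  if ("coherence" %in% cfg$stages) {
    sc_groups <- split(prep, vapply(prep, function(p)
      sprintf("%s|%s", p$subject, p$mode), character(1)))
    prepared <- lapply(sc_groups, function(g) {
      imc_prepare(lapply(g, `[[`, "rect"), fs = g[[1]]$fs,
                  target_fs = cfg$target_fs)
    })
    cs <- build_coherence_set(prepared, fs = cfg$target_fs, band = cfg$band,
                              taper_s = cfg$taper_s,
                              n_surrogates = cfg$n_surrogates,
                              alpha = cfg$coh_alpha, seed = cfg$seed)
    comps <- nmf_frequency_components(cs,
                                      lambda_cutoff = cfg$coh_lambda_cutoff,
                                      delta_cutoff = cfg$coh_delta_cutoff,
                                      max_rank = cfg$coh_max_rank,
                                      n_restarts = cfg$n_restarts,
                                      seed = cfg$seed)
    coh_net <- coherence_layers(comps, cs$sc)
    mc <- minimally_connect(coh_net)
    part <- communities_multiplex(mc$net, seed = cfg$seed)
    metrics <- do.call(rbind, lapply(seq_along(mc$net$layers), function(l) {
      lm <- layer_metrics(mc$net$layers[[l]])
      data.frame(layer = mc$net$layer_labels[l],
                 global_efficiency = lm$global_efficiency,
                 transitivity = lm$transitivity,
                 average_strength = lm$average_strength)
    }))
    report$coherence <- list(set = cs, components = comps,
                             network = coh_net, minimally_connected = mc,
                             partition = part, layer_metrics = metrics)
  }

  if ("stats" %in% cfg$stages && !is.null(report$synergy)) {
    report$stats <- waveform_mode_stats(report$synergy, cfg)
  }

  class(report) <- "gait_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# paired SPM between coordination modes for each synergy waveform
waveform_mode_stats <- function(syn, cfg) {
  em <- syn$envelope_matrix
  model <- syn$model
  N <- cfg$N
  modes <- unique(em$blocks$mode)
  out <- list()
  for (a in seq_along(modes)) {
    for (b in seq_along(modes)) {
      if (b <= a) next
      subs <- intersect(em$blocks$subject[em$blocks$mode == modes[a]],
                        em$blocks$subject[em$blocks$mode == modes[b]])
      if (length(subs) < 3) next
      for (s in seq_len(model$m)) {
        wav <- function(md) t(vapply(subs, function(su) {
          blk <- which(em$blocks$subject == su & em$blocks$mode == md)
          model$A[s, ((blk - 1) * N + 1):(blk * N)]
        }, numeric(N)))
        cmp <- spm_paired(wav(modes[a]), wav(modes[b]),
                          alpha = cfg$spm_alpha, n_perm = cfg$spm_n_perm,
                          seed = cfg$seed)
        out[[sprintf("S%d:%s-vs-%s", s, modes[a], modes[b])]] <- cmp
      }
    }
  }
  out
}

#' Score a synthetic run against its planted ground truth
#'
#' @param report `gait_report` from a synthetic [run_study()]
#' @param gt the study's `gait_ground_truth`
#' @return scorecard list: `mode_accuracy`, `rank_recovered`,
#'   `weight_cosines` (per matched synergy), `band_jaccard` (per coherence
#'   component), `partition_ari` (coherence partition vs planted muscle
#'   groups), each NA when the stage did not run
#' @export
validate_against_ground_truth <- function(report, gt) {
  if (!isTRUE(report$synthetic))
    stop("validate_against_ground_truth: not a synthetic run")
  score <- list(mode_accuracy = NA_real_, rank_recovered = NA,
                weight_cosines = NA, band_jaccard = NA,
                partition_ari = NA_real_)
  if (!is.null(report$modes))
    score$mode_accuracy <- mean(report$modes$label == report$modes$planted_mode)
  if (!is.null(report$synergy)) {
    score$rank_recovered <- report$synergy$m == gt$m_true
    if (report$synergy$m == gt$m_true)
      score$weight_cosines <-
        match_columns(report$synergy$model$W, gt$weights)$cosines
  }
  if (!is.null(report$coherence)) {
    planted <- lapply(gt$common_input_bands, function(b) c(b$f_lo, b$f_hi))
    score$band_jaccard <- vapply(report$coherence$components$dominant_bands,
                                 function(b) {
                                   max(vapply(planted, band_jaccard, numeric(1),
                                              b2 = b))
                                 }, numeric(1))
    # reference communities: the planted common-input muscle groups
    grp <- rep(0L, 26)
    for (b in seq_along(gt$common_input_bands))
      grp[gt$common_input_bands[[b]]$muscles] <- b
    score$partition_ari <-
      compare_partitions(report$coherence$partition$membership, grp,
                         n_perm = 0)$adjusted_rand
  }
  score
}

#' Jaccard overlap of two frequency bands
#' @param b1,b2 bands as `c(f_lo, f_hi)`
#' @return |intersection| / |union| of the intervals
#' @export
band_jaccard <- function(b1, b2) {
  inter <- max(0, min(b1[2], b2[2]) - max(b1[1], b2[1]))
  uni <- max(b1[2], b2[2]) - min(b1[1], b2[1])
  if (uni <= 0) return(0)
  inter / uni
}

# JSON/TSV report bundle
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$modes))
    utils::write.table(report$modes, file.path(dir, "modes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$synergy)) {
    jsonlite::write_json(list(m = report$synergy$m,
                              lambda_profile = report$synergy$lambda_profile,
                              W = report$synergy$model$W,
                              peak_location = report$synergy$model$peak_location,
                              membership = report$synergy$partition$membership),
                         file.path(dir, "synergy.json"), digits = NA)
    write_network_edgelist(report$synergy$network,
                           file.path(dir, "synergy_network.tsv"))
  }
  if (!is.null(report$coherence)) {
    jsonlite::write_json(list(m = report$coherence$components$m,
                              lambda_profile = report$coherence$components$lambda_profile,
                              dominant_bands = report$coherence$components$dominant_bands,
                              tau = report$coherence$minimally_connected$tau,
                              k = report$coherence$minimally_connected$k,
                              membership = report$coherence$partition$membership,
                              modularity_per_layer = report$coherence$partition$modularity_per_layer),
                         file.path(dir, "coherence.json"), digits = NA)
    utils::write.table(report$coherence$layer_metrics,
                       file.path(dir, "layer_metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_network_edgelist(report$coherence$minimally_connected$net,
                           file.path(dir, "coherence_network.tsv"))
  }
  jsonlite::write_json(report$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>\n")
  if (!is.null(x$modes))
    cat(sprintf("  modes: %d trials, %.0f%% match planted labels\n",
                nrow(x$modes),
                100 * mean(x$modes$label == x$modes$planted_mode)))
  if (!is.null(x$synergy))
    cat(sprintf("  synergies: m = %d (lambda %.1f%%)\n", x$synergy$m,
                x$synergy$lambda_profile[x$synergy$m]))
  if (!is.null(x$coherence))
    cat(sprintf("  coherence components: m = %d; tau = %.4f, k = %d\n",
                x$coherence$components$m,
                x$coherence$minimally_connected$tau,
                x$coherence$minimally_connected$k))
  invisible(x)
}
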