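#' Write one recording as long-format delimited text
#'
#' Tab-separated columns `time_s`, `channel`, `value`. EMG channels carry
#' the muscle labels; kinematic/force channels are `arm`, `leg`, `grf`
#' (sampled at the kinematic rate). A JSON sidecar (`<stem>.json`) stores
#' rates, subject, speed, mode and ground-truth heel strikes.
#'
#' @param rec `gait_recording`
#' @param path output file path (`.tsv`); the sidecar replaces the extension
#' @export
write_recording <- function(rec, path) {
  t_emg <- (seq_len(nrow(rec$emg)) - 1) / rec$fs_emg
  emg_long <- data.frame(
    time_s = rep(t_emg, ncol(rec$emg)),
    channel = rep(colnames(rec$emg), each = nrow(rec$emg)),
    value = as.vector(rec$emg))
  kin_long <- do.call(rbind, lapply(c("arm", "leg", "grf"), function(ch) {
    data.frame(time_s = rec$kin$time, channel = ch, value = rec$kin[[ch]])
  }))
  utils::write.table(rbind(emg_long, kin_long), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(subject = rec$subject, speed_kmh = rec$speed_kmh,
               mode = rec$mode, stride_period = rec$stride_period,
               fs_emg = rec$fs_emg, fs_kin = rec$fs_kin,
               heel_strikes = rec$heel_strikes)
  jsonlite::write_json(meta, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#' @param path `.tsv` path
#' @return `gait_recording`
#' @export
read_recording <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sub("\\.[^.]+$", ".json", path),
                              simplifyVector = TRUE)
  kin_ch <- c("arm", "leg", "grf")
  emg_long <- long[!long$channel %in% kin_ch, ]
  muscles <- unique(emg_long$channel)
  emg <- sapply(muscles, function(ch) emg_long$value[emg_long$channel == ch])
  attr(emg, "fs") <- meta$fs_emg
  kin <- lapply(kin_ch, function(ch) long$value[long$channel == ch])
  names(kin) <- kin_ch
  kin$time <- unique(long$time_s[long$channel == "arm"])
  kin$fs <- meta$fs_kin
  kin$mode <- meta$mode
  kin$heel_strikes <- meta$heel_strikes
  class(kin) <- "gait_kinematics"
  rec <- list(subject = meta$subject, speed_kmh = meta$speed_kmh,
              mode = meta$mode, stride_period = meta$stride_period,
              emg = emg, fs_emg = meta$fs_emg, kin = kin,
              fs_kin = meta$fs_kin, heel_strikes = meta$heel_strikes)
  class(rec) <- "gait_recording"
  rec
}

#' Write a synthetic study to a directory
#'
#' One `trial_<subject>_<speed>.tsv` (+ JSON sidecar) per recording plus
#' `ground_truth.json` and a `manifest.json`.
#'
#' @param study `gait_study`
#' @param dir output directory (created if missing)
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(study$recordings, function(rec) {
    f <- file.path(dir, sprintf("trial_s%02d_v%03.0f.tsv",
                                rec$subject, rec$speed_kmh * 10))
    write_recording(rec, f)
    basename(f)
  }, character(1))
  gt <- study$ground_truth
  jsonlite::write_json(
    list(m_true = gt$m_true, weights = gt$weights,
         activation_centers = gt$activation_centers,
         activation_width = gt$activation_width,
         common_input_bands = gt$common_input_bands,
         heartbeat = gt$heartbeat, seed = gt$seed),
    file.path(dir, "ground_truth.json"), digits = NA)
  jsonlite::write_json(list(files = files, seed = study$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#' @param dir study directory
#' @return `gait_study`
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  recs <- lapply(file.path(dir, manifest$files), read_recording)
  gtj <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                             simplifyVector = TRUE)
  gt <- list(m_true = gtj$m_true, weights = as.matrix(gtj$weights),
             activation_centers = gtj$activation_centers,
             activation_width = gtj$activation_width,
             common_input_bands = lapply(seq_len(nrow(gtj$common_input_bands)),
                                         function(i) {
                                           r <- gtj$common_input_bands[i, ]
                                           list(f_lo = as.numeric(r$f_lo),
                                                f_hi = as.numeric(r$f_hi),
                                                muscles = as.integer(unlist(r$muscles)),
                                                gain = as.numeric(r$gain))
                                         }),
             heartbeat = as.list(gtj$heartbeat), seed = gtj$seed)
  class(gt) <- "gait_ground_truth"
  study <- list(recordings = recs, ground_truth = gt,
                seed = manifest$seed)
  class(study) <- "gait_study"
  study
}

#' Write an envelope matrix as TSV plus JSON header
#' @param em `envelope_matrix`
#' @param path `.tsv` path; header JSON replaces the extension
#' @export
write_envelope_matrix <- function(em, path) {
  utils::write.table(em$X, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(N = em$N, muscles = em$muscles,
                            blocks = em$blocks),
                       sub("\\.[^.]+$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' Write a multiplex network as an edge list (TSV)
#'
#' Columns `node_i`, `node_j`, `layer`, `weight`; only nonzero edges with
#' `i < j` are written.
#'
#' @param net `multiplex_network`
#' @param path output path
#' @export
write_network_edgelist <- function(net, path) {
  rows <- list()
  for (l in seq_along(net$layers)) {
    L <- net$layers[[l]]
    idx <- which(upper.tri(L) & L > 0, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    rows[[l]] <- data.frame(node_i = net$nodes[idx[, 1]],
                            node_j = net$nodes[idx[, 2]],
                            layer = net$layer_labels[l],
                            weight = L[idx])
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
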