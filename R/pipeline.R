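# Subtractive per-function dependent variables (those defined for a single
# I/O function; offsets are intrinsically paired and handled separately).
feature_values <- function(io, phase, criterion, law) {
  thr <- detect_threshold(io, criterion, law)
  ma <- max_amplitude(io)
  vals <- c(
    "threshold|nC" = thr$charge_nc,
    "threshold|dB re 1 nC" = thr$charge_db,
    "max_amplitude|uV" = ma$uv,
    "max_amplitude|dB re 1 uV" = ma$db)
  for (lab in c("S1", "S2", "S3")) {
    sio <- suppressWarnings(transform_io(io, scale_spec(lab), phase, law))
    unit <- scale_spec(lab)$slope_unit
    vals[paste0("overall_slope|", unit)] <-
      as.numeric(overall_linear_slope(sio, thr$level, io$c_level))
    vals[paste0("max_slope|", unit)] <- as.numeric(max_slope_window(sio))
  }
  vals
}

#' Compute all IPG-effect records for one electrode
#'
#' The IPG effect of each dependent variable (DV) is
#' `DV_IPG42 - DV_IPG7`. Records cover the eCAP threshold (nC, dB re 1 nC),
#' maximum amplitude (uV, dB re 1 uV), overall linear slope and
#' window-method maximum slope (each on the three analysis scales), plus
#' the three stimulation-level-offset records. Offsets are intrinsically
#' paired quantities: their `dv_ipg7` / `dv_ipg42` fields stay `NA` and the
#' offset itself is the effect. A missing DV yields a record with a missing
#' effect and a reason code rather than an error.
#'
#' @param io7,io42 paired [io_function()]s at IPG 7 and 42 us.
#' @param phase phase duration in us.
#' @param criterion threshold criterion in uV.
#' @param law a [device_law()].
#' @return data.frame: subject, electrode, parameter, scale, dv_ipg7,
#'   dv_ipg42, effect, reason.
#' @export
compute_ipg_effects <- function(io7, io42, phase = io7$phase_duration,
                                criterion = 5, law = device_law()) {
  v7 <- feature_values(io7, phase, criterion, law)
  v42 <- feature_values(io42, phase, criterion, law)
  stopifnot(identical(names(v7), names(v42)))
  parts <- do.call(rbind, strsplit(names(v7), "|", fixed = TRUE))
  sub <- data.frame(subject = io7$subject, electrode = io7$electrode,
                    parameter = parts[, 1], scale = parts[, 2],
                    dv_ipg7 = unname(v7), dv_ipg42 = unname(v42),
                    effect = unname(v42 - v7),
                    reason = ifelse(is.na(v7) | is.na(v42),
                                    "missing DV at one or both IPGs",
                                    NA_character_),
                    stringsAsFactors = FALSE)
  offs <- offset_all_scales(io7, io42, phase, law)
  off <- data.frame(subject = io7$subject, electrode = io7$electrode,
                    parameter = "offset",
                    scale = vapply(offs, function(o) o$scale, character(1)),
                    dv_ipg7 = NA_real_, dv_ipg42 = NA_real_,
                    effect = vapply(offs, function(o) o$offset, numeric(1)),
                    reason = vapply(offs, function(o) o$reason, character(1)),
                    stringsAsFactors = FALSE)
  out <- rbind(sub, off)
  rownames(out) <- NULL
  out
}

#' Study configuration for the end-to-end simulated pipeline
#'
#' Defines a three-group simulated cohort (CND / NSCN / GJB2 scenarios from
#' [scenario_presets()]) measured at three electrode positions, with
#' group-specific sweep-level synchrony structure: the CND scenario uses
#' larger trial-to-trial latency jitter and smaller single-sweep amplitudes,
#' so simulated CND ears have lower PLVs as well as larger offsets.
#'
#' @param n_per_group subjects per group.
#' @param groups scenario labels.
#' @param electrodes electrode positions measured per subject.
#' @param phase_duration pulse phase duration in us.
#' @param io_noise_sd I/O amplitude noise in uV.
#' @param n_sweeps sweeps per PLV measurement.
#' @param sweep_noise_sd additive sweep noise in uV.
#' @param latency_jitter_sd named per-group latency jitter SD in us.
#' @param n1_amplitude named per-group N1 trough amplitude in uV.
#' @param criterion eCAP threshold criterion in uV.
#' @param sensitivity_threshold standardized-contrast threshold used to
#'   classify DV sensitivity tiers in the report.
#' @param seed top-level seed; per-ear substreams are derived from it.
#' @export
study_config <- function(n_per_group = 10,
                         groups = c("CND", "NSCN", "GJB2"),
                         electrodes = c("basal", "middle", "apical"),
                         phase_duration = 25, io_noise_sd = 3,
                         n_sweeps = 400, sweep_noise_sd = 5,
                         latency_jitter_sd = c(CND = 40, NSCN = 15, GJB2 = 10),
                         n1_amplitude = c(CND = -40, NSCN = -120, GJB2 = -150),
                         criterion = 5, sensitivity_threshold = 0.8,
                         seed = 1) {
  if (n_per_group < 1) stop_config("`n_per_group` must be >= 1")
  groups <- match.arg(groups, c("CND", "NSCN", "GJB2"), several.ok = TRUE)
  if (!all(groups %in% names(latency_jitter_sd)) ||
      !all(groups %in% names(n1_amplitude)))
    stop_config("per-group sweep parameters must cover every group")
  structure(as.list(environment()), class = "study_config")
}

#' Run the full simulated study pipeline
#'
#' simulate -> PLV -> growth-function features -> offsets -> IPG effects ->
#' descriptive statistics. Per-ear failures are isolated: the run completes
#' and reports them in the manifest. Identical config and seed reproduce the
#' study bit-identically.
#'
#' @param config a [study_config()].
#' @return An `ipg_study`: list with data.frames `plv`, `effects`,
#'   `offsets`, `features`, a `stats` list (`correlations`, `shape_tests`,
#'   `sensitivity`), and `manifest`.
#' @export
run_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) stop_config("`config` must be a study_config")
  roster <- expand.grid(subject_idx = seq_len(config$n_per_group),
                        group = config$groups,
                        electrode = config$electrodes,
                        stringsAsFactors = FALSE)
  roster$subject <- sprintf("%s%02d", roster$group, roster$subject_idx)
  roster <- roster[order(roster$subject, roster$electrode), ]
  plv_rows <- list(); eff_rows <- list(); off_rows <- list()
  feat_rows <- list(); failures <- list()
  for (i in seq_len(nrow(roster))) {
    ear <- roster[i, ]
    res <- tryCatch({
      sw_cfg <- sweep_sim_config(
        n_sweeps = config$n_sweeps,
        n1_amplitude = config$n1_amplitude[[ear$group]],
        p2_amplitude = -0.5 * config$n1_amplitude[[ear$group]],
        latency_jitter_sd = config$latency_jitter_sd[[ear$group]],
        amplitude_jitter_cv = 0.1, noise_sd = config$sweep_noise_sd,
        seed = substream_seed(config$seed, 2L * i))
      grid <- plv(simulate_sweeps(sw_cfg))
      io_cfg <- io_sim_config(scenario = ear$group,
                              electrode_position = ear$electrode,
                              phase_duration = config$phase_duration,
                              noise_sd = config$io_noise_sd,
                              subject = ear$subject, electrode = ear$electrode,
                              seed = substream_seed(config$seed, 2L * i + 1L))
      pair <- simulate_io_pair(io_cfg)
      eff <- compute_ipg_effects(pair[["7"]], pair[["42"]],
                                 criterion = config$criterion)
      eff$group <- ear$group
      offs <- offset_all_scales(pair[["7"]], pair[["42"]])
      off <- data.frame(subject = ear$subject, electrode = ear$electrode,
                        group = ear$group,
                        scale = vapply(offs, `[[`, character(1), "scale"),
                        offset = vapply(offs, `[[`, numeric(1), "offset"),
                        normalizer_uv = vapply(offs, `[[`, numeric(1), "normalizer"),
                        reason = vapply(offs, `[[`, character(1), "reason"),
                        stringsAsFactors = FALSE)
      feat <- rbind(io_features(pair[["7"]], criterion = config$criterion),
                    io_features(pair[["42"]], criterion = config$criterion))
      feat$group <- ear$group
      list(plv = data.frame(subject = ear$subject, electrode = ear$electrode,
                            group = ear$group, plv = grid$aggregate,
                            n_sweeps = grid$n_trials,
                            stringsAsFactors = FALSE),
           eff = eff, off = off, feat = feat)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(subject = ear$subject, electrode = ear$electrode,
             message = conditionMessage(res))
    } else {
      plv_rows[[i]] <- res$plv; eff_rows[[i]] <- res$eff
      off_rows[[i]] <- res$off; feat_rows[[i]] <- res$feat
    }
  }
  plv_tab <- do.call(rbind, plv_rows)
  eff_tab <- do.call(rbind, eff_rows)
  off_tab <- do.call(rbind, off_rows)
  feat_tab <- do.call(rbind, feat_rows)
  rownames(eff_tab) <- rownames(off_tab) <- rownames(feat_tab) <- NULL
  stats <- study_stats(plv_tab, off_tab, feat_tab, eff_tab,
                       config$sensitivity_threshold)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("ecapipg")),
                   n_ears = nrow(roster), n_failures = length(failures),
                   failures = failures,
                   config_hash = hash_config(config),
                   excluded = list(
                     effects_missing = sum(is.na(eff_tab$effect)),
                     offsets_missing = sum(is.na(off_tab$offset))))
  structure(list(plv = plv_tab, effects = eff_tab, offsets = off_tab,
                 features = feat_tab, stats = stats, manifest = manifest,
                 config = config),
            class = "ipg_study")
}

hash_config <- function(config) {
  cfg <- config
  js <- jsonlite::toJSON(cfg[setdiff(names(cfg), "law")], auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

# Descriptive/nonparametric statistics of a simulated study: PLV-offset
# Spearman correlations (Bonferroni across the three offset scales),
# Mann-Whitney comparisons of max amplitude / dynamic range between
# shape-transitioned and shape-preserved functions (BH-adjusted), and the
# three-tier sensitivity classification of each DV x scale.
study_stats <- function(plv_tab, off_tab, feat_tab, eff_tab, sens_threshold) {
  scales <- unique(off_tab$scale)
  cors <- lapply(scales, function(sc) {
    o <- off_tab[off_tab$scale == sc, ]
    key <- paste(o$subject, o$electrode)
    p <- plv_tab[match(key, paste(plv_tab$subject, plv_tab$electrode)), ]
    ct <- spearman_bonferroni(p$plv, o$offset, m = length(scales))
    data.frame(analysis = "spearman_plv_offset", measure = "offset",
               term = sc, estimate = ct$rho, p = ct$p,
               p_adjusted = ct$p_adjusted, n = ct$n,
               stringsAsFactors = FALSE)
  })
  cors <- do.call(rbind, cors)

  f42 <- feat_tab[feat_tab$ipg_us == 42, ]
  trans <- f42$shape_s3 == "exponential-transitioned"
  kept <- f42$shape_s3 %in% c("exponential-transitioned", "unchanged")
  shape <- NULL
  if (sum(trans & kept) > 0 && sum(!trans & kept) > 0) {
    rows <- lapply(c("max_amplitude_uv", "dynamic_range"), function(v) {
      mw <- mann_whitney(f42[[v]][trans & kept], f42[[v]][!trans & kept])
      data.frame(analysis = "mann_whitney_shape", measure = v,
                 term = "transitioned_vs_unchanged", estimate = mw$U,
                 p = mw$p, p_adjusted = NA_real_, n = mw$n_a + mw$n_b,
                 stringsAsFactors = FALSE)
    })
    shape <- do.call(rbind, rows)
    shape$p_adjusted <- benjamini_hochberg(shape$p)
  }

  sens <- sensitivity_tiers(eff_tab, sens_threshold)
  list(correlations = cors, shape_tests = shape, sensitivity = sens,
       shape_counts = as.data.frame(table(ipg_us = feat_tab$ipg_us,
                                          group = feat_tab$group,
                                          shape = feat_tab$shape_s3)))
}

# Standardized-contrast mirror of the three-way sensitivity structure:
# "group_and_location" when a DV separates CND from the other groups AND
# apical from basal within CND, "group_only" when only the former holds,
# "insensitive" otherwise. A simulation-based classification, not a
# clinical claim.
sensitivity_tiers <- function(eff_tab, threshold) {
  keys <- unique(eff_tab[, c("parameter", "scale")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- eff_tab[eff_tab$parameter == keys$parameter[i] &
                   eff_tab$scale == keys$scale[i] & !is.na(eff_tab$effect), ]
    g_con <- l_con <- NA_real_
    if (length(unique(d$group)) > 1 && "CND" %in% d$group) {
      a <- d$effect[d$group == "CND"]; b <- d$effect[d$group != "CND"]
      s <- stats::sd(d$effect)
      if (isTRUE(s > 0)) g_con <- abs(mean(a) - mean(b)) / s
    }
    cnd <- d[d$group == "CND", ]
    if (all(c("apical", "basal") %in% cnd$electrode)) {
      s <- stats::sd(cnd$effect)
      if (isTRUE(s > 0))
        l_con <- abs(mean(cnd$effect[cnd$electrode == "apical"]) -
                       mean(cnd$effect[cnd$electrode == "basal"])) / s
    }
    tier <- if (isTRUE(g_con > threshold) && isTRUE(l_con > threshold))
      "group_and_location"
    else if (isTRUE(g_con > threshold)) "group_only" else "insensitive"
    data.frame(parameter = keys$parameter[i], scale = keys$scale[i],
               group_contrast = g_con, location_contrast = l_con,
               tier = tier, n = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.ipg_study <- function(x, ...) {
  cat(sprintf("Simulated IPG-effect study: %d ears (%d failures), seed %s\n",
              x$manifest$n_ears, x$manifest$n_failures,
              format(x$manifest$seed)))
  cat("\nMean aggregate PLV by group:\n")
  print(round(tapply(x$plv$plv, x$plv$group, mean), 3))
  o1 <- x$offsets[x$offsets$scale == "nC", ]
  cat("\nMean stimulation level offset (nC) by group:\n")
  print(round(tapply(o1$offset, o1$group, mean, na.rm = TRUE), 3))
  cat("\nLog/log shape-transition counts (IPG 42 us):\n")
  sc <- x$stats$shape_counts
  print(sc[sc$ipg_us == 42 & sc$Freq > 0, ])
  cat("\nDV sensitivity tiers:\n")
  print(x$stats$sensitivity[, c("parameter", "scale", "tier")])
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Writes `effects.csv`, `plv.csv`, `offsets.csv`, `features.csv`,
#' `stats.csv`, `sensitivity.csv` and `manifest.json`.
#'
#' @param study an `ipg_study` from [run_study()].
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "ipg_study")) stop_config("`study` must be an ipg_study")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$effects, file.path(dir, "effects.csv"), row.names = FALSE)
  utils::write.csv(study$plv, file.path(dir, "plv.csv"), row.names = FALSE)
  utils::write.csv(study$offsets, file.path(dir, "offsets.csv"), row.names = FALSE)
  utils::write.csv(study$features, file.path(dir, "features.csv"), row.names = FALSE)
  stat_tab <- rbind(study$stats$correlations, study$stats$shape_tests)
  utils::write.csv(stat_tab, file.path(dir, "stats.csv"), row.names = FALSE)
  utils::write.csv(study$stats$sensitivity, file.path(dir, "sensitivity.csv"),
                   row.names = FALSE)
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
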