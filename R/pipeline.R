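#' Analyze one recording end to end
#'
#' Normalization, syllable detection, chirp grouping and feature
#' summarization in one call.
#'
#' @param x An [audio_recording()] or a path to a WAV file.
#' @param cfg A [detection_config()].
#' @param chirp_cap,band_hz Passed to [summarize_recording()].
#' @return A list of class `song_analysis`: `syllables`, `chirps`, `summary`,
#'   `config`, `source_id`.
#' @export
analyze_recording <- function(x, cfg = detection_config(), chirp_cap = 3500,
                              band_hz = c(1000, 10000)) {
  rec <- if (inherits(x, "audio_recording")) x else read_song_wav(x)
  rec <- normalize_audio(rec)
  syl <- detect_syllables(rec, cfg)
  chirps <- group_chirps(syl, cfg)
  summ <- summarize_recording(rec, chirps, chirp_cap = chirp_cap,
                              band_hz = band_hz)
  structure(
    list(syllables = syl, chirps = chirps, summary = summ, config = cfg,
         source_id = rec$source_id),
    class = "song_analysis"
  )
}

#' @export
print.song_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<song_analysis '%s'>\n", x$source_id))
  cat(sprintf("  %d syllables in %d chirps\n", s$n_syllables, s$n_chirps))
  if (s$n_chirps > 0) {
    cat(sprintf("  mean chirp duration %.1f ms, inter-chirp interval %.1f ms\n",
                s$mean_chirp_duration_ms, s$mean_inter_chirp_interval_ms))
    cat(sprintf("  mean syllable %.2f ms, inter-syllable interval %.2f ms\n",
                s$mean_syllable_duration_ms, s$mean_inter_syllable_interval_ms))
    cat(sprintf("  dominant frequency %s Hz; 3-syl %.1f%%, 4-syl %.1f%%\n",
                format(s$dominant_frequency_hz),
                100 * s$prop_3syl, 100 * s$prop_4syl))
  }
  invisible(x)
}

#' Flatten chirps to an exportable table
#'
#' @param chirps Data frame from [group_chirps()].
#' @param source_id Recording identifier for the `source_id` column.
#' @return A plain data frame, one row per chirp, with the list-columns
#'   reduced to within-chirp means.
#' @export
chirp_table <- function(chirps, source_id = "recording") {
  data.frame(
    source_id = rep(source_id, nrow(chirps)),
    chirp_id = chirps$chirp_id,
    onset_s = chirps$onset_s,
    duration_ms = chirps$duration_ms,
    n_syllables = chirps$n_syllables,
    mean_syllable_duration_ms =
      vapply(chirps$syllable_durations_ms, mean, numeric(1)),
    mean_inter_syllable_interval_ms =
      vapply(chirps$inter_syllable_intervals_ms,
             function(v) if (length(v)) mean(v) else NA_real_, numeric(1)),
    following_inter_chirp_interval_ms =
      chirps$following_inter_chirp_interval_ms,
    stringsAsFactors = FALSE
  )
}

#' Batch detection over WAV files
#'
#' For each input writes an Audacity label track (`<stem>.labels.txt`,
#' syllables labeled `syl`, chirps `chirp`) and a per-chirp CSV
#' (`<stem>.chirps.csv`) into `out_dir`, and collects the per-recording
#' summaries into `summary.csv`. Unreadable files are reported and skipped;
#' the call fails only if every input fails.
#'
#' @param paths Character vector of WAV paths.
#' @param out_dir Output directory (created if missing).
#' @param cfg A [detection_config()].
#' @param chirp_cap Passed to [summarize_recording()].
#' @return Invisibly, the combined summary data frame.
#' @export
run_detect <- function(paths, out_dir = ".", cfg = detection_config(),
                       chirp_cap = 3500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- list()
  n_failed <- 0L
  for (p in paths) {
    res <- tryCatch(analyze_recording(p, cfg, chirp_cap = chirp_cap),
                    error = function(e) e)
    if (inherits(res, "error")) {
      message("cricketsong: failed on '", p, "': ", conditionMessage(res))
      n_failed <- n_failed + 1L
      next
    }
    stem <- tools::file_path_sans_ext(basename(p))
    labels <- rbind(
      data.frame(start_s = res$syllables$onset_s,
                 end_s = res$syllables$offset_s,
                 label = rep("syl", nrow(res$syllables))),
      data.frame(start_s = res$chirps$onset_s,
                 end_s = res$chirps$offset_s,
                 label = rep("chirp", nrow(res$chirps)))
    )
    export_audacity_labels(labels, file.path(out_dir,
                                             paste0(stem, ".labels.txt")))
    utils::write.csv(chirp_table(res$chirps, stem),
                     file.path(out_dir, paste0(stem, ".chirps.csv")),
                     row.names = FALSE)
    message("cricketsong: '", p, "': ", res$summary$n_syllables,
            " syllables, ", res$summary$n_chirps, " chirps")
    summaries[[stem]] <- res$summary
  }
  if (n_failed == length(paths)) stop("All ", n_failed, " input files failed")
  out <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  utils::write.csv(out, file.path(out_dir, "summary.csv"), row.names = FALSE)
  invisible(out)
}

#' Compare detected events with ground truth
#'
#' Matches detected syllables to ground-truth syllables by temporal overlap
#' and reports recall, precision, boundary errors and whether the per-chirp
#' syllable-count annotation is fully correct.
#'
#' @param truth The `truth` element of a [synthesize_song()] result.
#' @param syllables Detected syllable events ([detect_syllables()]).
#' @param chirps Optional detected chirps ([group_chirps()]) for the
#'   annotation check.
#' @return A list: `recall`, `precision`, `n_truth`, `n_detected`,
#'   `onset_error_ms`, `offset_error_ms` (per matched pair),
#'   `max_boundary_error_ms`, and `counts_correct` (`NA` if `chirps` is
#'   `NULL`).
#' @export
evaluate_detection <- function(truth, syllables, chirps = NULL) {
  tr <- truth$syllables
  nt <- nrow(tr)
  nd <- nrow(syllables)
  if (nt == 0L || nd == 0L) {
    return(list(recall = as.numeric(nt == 0L), precision = as.numeric(nd == 0L),
                n_truth = nt, n_detected = nd,
                onset_error_ms = numeric(), offset_error_ms = numeric(),
                max_boundary_error_ms = if (nt == 0L && nd == 0L) 0 else Inf,
                counts_correct = NA))
  }
  overlap_len <- function(i, j) {
    pmax(0, pmin(tr$offset_s[i], syllables$offset_s[j]) -
           pmax(tr$onset_s[i], syllables$onset_s[j]))
  }
  # events are sorted and non-overlapping on both sides: locate by midpoint
  mid <- (tr$onset_s + tr$offset_s) / 2
  j0 <- findInterval(mid, syllables$onset_s)
  match_of <- integer(nt)
  for (i in seq_len(nt)) {
    best <- 0; best_j <- 0L
    for (j in unique(pmax(1L, pmin(nd, c(j0[i], j0[i] + 1L))))) {
      ov <- overlap_len(i, j)
      if (ov > best) { best <- ov; best_j <- j }
    }
    match_of[i] <- best_j
  }
  matched <- match_of > 0L
  dup <- duplicated(match_of[matched])
  n_matched <- sum(matched) - sum(dup)
  onset_err <- abs(tr$onset_s[matched] -
                     syllables$onset_s[match_of[matched]]) * 1000
  offset_err <- abs(tr$offset_s[matched] -
                      syllables$offset_s[match_of[matched]]) * 1000
  counts_correct <- NA
  if (!is.null(chirps)) {
    counts_correct <- nrow(chirps) == nrow(truth$chirps) &&
      all(chirps$n_syllables == truth$chirps$n_syllables)
  }
  list(recall = n_matched / nt,
       precision = n_matched / nd,
       n_truth = nt, n_detected = nd,
       onset_error_ms = onset_err, offset_error_ms = offset_err,
       max_boundary_error_ms = if (length(onset_err)) {
         max(onset_err, offset_err)
       } else Inf,
       counts_correct = counts_correct)
}

#' Compare two treatment groups of recording summaries
#'
#' For each feature: a normality check with the transform ladder on the
#' pooled values (the chosen transform is applied to both groups), followed
#' by a nested t-test on individual means (or a Welch t-test when
#' `nested = FALSE`). In addition, syllable-count proportions are compared
#' within each group against a uniform distribution over the observed
#' classes and the 3- vs 4-syllable split against 50:50, via the chi-square
#' goodness of fit.
#'
#' @param g1,g2 Data frames of per-recording summaries (rows =
#'   recordings) as produced by [summarize_recording()] /
#'   [run_detect()], with an `individual` column when `nested = TRUE`.
#' @param features Character vector of summary columns to compare.
#' @param nested Use the nested t-test on individual means (default); the
#'   `individual` column is required.
#' @param labels Group labels for the report.
#' @param out_json Optional path; when given the report is written as JSON.
#' @return A list of class `song_comparison`: per-feature test results
#'   (`features`), per-group chi-square blocks (`proportions`), labels.
#' @export
run_compare <- function(g1, g2,
                        features = "mean_inter_syllable_interval_ms",
                        nested = TRUE, labels = c("group1", "group2"),
                        out_json = NULL) {
  stopifnot(is.data.frame(g1), is.data.frame(g2))
  if (nested && (!"individual" %in% names(g1) ||
                 !"individual" %in% names(g2))) {
    stop("Nested comparison requires an 'individual' column in both groups")
  }
  feat_res <- list()
  for (f in features) {
    if (!f %in% names(g1) || !f %in% names(g2)) {
      stop("Summary column not found: ", f)
    }
    v1 <- g1[[f]]; v2 <- g2[[f]]
    ok1 <- is.finite(v1); ok2 <- is.finite(v2)
    nt <- check_normality_and_transform(c(v1[ok1], v2[ok2]))
    tv1 <- apply_song_transform(v1[ok1], nt$transform)
    tv2 <- apply_song_transform(v2[ok2], nt$transform)
    res <- if (nested) {
      nested_t_test(data.frame(value = tv1, individual = g1$individual[ok1]),
                    data.frame(value = tv2, individual = g2$individual[ok2]))
    } else {
      welch_t_test(tv1, tv2)
    }
    res$transform_applied <- nt$transform
    feat_res[[f]] <- res
  }
  prop_res <- list()
  for (g in list(list(labels[1L], g1), list(labels[2L], g2))) {
    df <- g[[2L]]
    counts <- vapply(1:5, function(k) {
      col <- paste0("prop_", k, "syl")
      if (col %in% names(df)) sum(df[[col]] * df$n_chirps) else 0
    }, numeric(1))
    observed_classes <- counts > 0
    prop_res[[g[[1L]]]] <- list(
      class_counts = stats::setNames(counts, paste0(1:5, "syl")),
      vs_uniform = chisq_gof(counts[observed_classes]),
      split_3v4_vs_5050 = chisq_gof(counts[c(3L, 4L)], c(0.5, 0.5))
    )
  }
  out <- structure(list(labels = labels, features = feat_res,
                        proportions = prop_res),
                   class = "song_comparison")
  if (!is.null(out_json)) {
    jsonlite::write_json(comparison_to_list(out), out_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

comparison_to_list <- function(x) {
  strip <- function(r) {
    r <- unclass(r)
    r[!vapply(r, is.null, logical(1))]
  }
  list(
    labels = x$labels,
    features = lapply(x$features, strip),
    proportions = lapply(x$proportions, function(p) list(
      class_counts = as.list(p$class_counts),
      vs_uniform = strip(p$vs_uniform),
      split_3v4_vs_5050 = strip(p$split_3v4_vs_5050)
    ))
  )
}

#' @export
print.song_comparison <- function(x, ...) {
  cat(sprintf("<song_comparison: %s vs %s>\n", x$labels[1L], x$labels[2L]))
  for (f in names(x$features)) {
    r <- x$features[[f]]
    cat(sprintf("  %s: %s stat=%.4g p=%.4g (transform: %s)\n",
                f, r$method_name, r$statistic, r$p_value,
                r$transform_applied))
  }
  for (g in names(x$proportions)) {
    p <- x$proportions[[g]]
    cat(sprintf("  %s 3v4 vs 50:50: X2=%.4g p=%.4g\n",
                g, p$split_3v4_vs_5050$statistic,
                p$split_3v4_vs_5050$p_value))
  }
  invisible(x)
}
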