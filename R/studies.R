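# Experiment runners: spectral-channel contrast study and angle-step study.

new_study_table <- function(df, kind) {
  structure(df, kind = kind, class = c("study_table", "data.frame"))
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table: %s>\n", attr(x, "kind")))
  print.data.frame(x)
  invisible(x)
}

#' Matched-keypoint counts per spectral channel
#'
#' Runs the matching front end of the pipeline once per channel (red,
#' green, blue, grayscale, ExG) under identical downstream parameters and
#' reports the number of matched keypoints each channel yields for the
#' view pair.
#'
#' @param view_a,view_b [spectral_frames()] bundles.
#' @param config A [recon_config()].
#' @param channels Channels to evaluate.
#' @param verbose Log per-channel counts.
#' @return A `study_table` data frame: `channel`, `matched`.
#' @export
channel_study <- function(view_a, view_b, config = recon_config(),
                          channels = c("red", "green", "blue", "gray", "exg"),
                          verbose = FALSE) {
  counts <- vapply(channels, function(ch) {
    mp <- match_pair(view_a, view_b, config, channel = ch, verbose = verbose)
    nrow(mp$matches)
  }, integer(1))
  new_study_table(data.frame(channel = channels, matched = unname(counts)),
                  "matched keypoints per spectral channel")
}

#' Matched-keypoint counts versus turntable angle step
#'
#' For each requested step size, matches every consecutive view pair of the
#' sequence separated by that step and reports the per-step mean matched
#' count.  Larger steps change the appearance more (foreshortening,
#' occlusion), so the matched count decreases with step size.
#'
#' @param views List of [spectral_frames()] (with `view_angle` set) or
#'   `rendered_view` objects.
#' @param steps Angle steps in degrees to evaluate.
#' @param config A [recon_config()].
#' @param verbose Log per-pair counts.
#' @return A `study_table` data frame: `step_deg`, `n_pairs`,
#'   `mean_matched`.
#' @export
angle_step_study <- function(views, steps, config = recon_config(),
                             verbose = FALSE) {
  views <- lapply(views, function(v)
    if (inherits(v, "rendered_view")) v$frames else check_frames(v))
  angles <- vapply(views, function(v) v$view_angle, numeric(1))
  ord <- order(angles)
  views <- views[ord]; angles <- angles[ord]
  rows <- lapply(steps, function(s) {
    idx_a <- integer(0); idx_b <- integer(0)
    for (i in seq_along(angles)) {
      j <- which(abs(angles - (angles[i] + s)) < 1e-6)
      if (length(j)) { idx_a <- c(idx_a, i); idx_b <- c(idx_b, j[1]) }
    }
    if (!length(idx_a))
      stop("step of ", s, " degrees is not representable by the view sequence")
    counts <- mapply(function(i, j) {
      n <- nrow(match_pair(views[[i]], views[[j]], config)$matches)
      log_stage(verbose, "step %g deg: views %g -> %g give %d matches",
                s, angles[i], angles[j], n)
      n
    }, idx_a, idx_b)
    data.frame(step_deg = s, n_pairs = length(counts),
               mean_matched = mean(counts))
  })
  new_study_table(do.call(rbind, rows),
                  "mean matched keypoints per angle step")
}
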