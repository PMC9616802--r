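#' Behavioural accuracy and reaction-time summaries
#'
#' Per participant x task: fraction of correct responses out of all trials
#' and mean reaction time (correct trials only by default).
#'
#' @param table data.frame with columns participant, task, correct
#'   (logical), rt (s).
#' @param rt_correct_only use only correct trials for the RT mean.
#' @return data.frame: participant, task, n_trials, accuracy, mean_rt.
#' @export
accuracySummary <- function(table, rt_correct_only = TRUE) {
  stopifnot(all(c("participant", "task", "correct") %in% names(table)))
  cells <- split(table, list(table$participant, table$task), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(df) {
    rtSel <- if (rt_correct_only) df$correct else rep(TRUE, nrow(df))
    data.frame(participant = df$participant[1L], task = df$task[1L],
               n_trials = nrow(df), accuracy = mean(df$correct),
               mean_rt = if ("rt" %in% names(df) && any(rtSel))
                 mean(df$rt[rtSel]) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$task, out$participant), ]
}

#' Participant exclusion by composite behavioural accuracy
#'
#' The composite score is the mean accuracy across the tasks; participants
#' more than 1.5 inter-quartile ranges below the lower quartile (or above
#' the upper) of the composite are flagged via [iqrOutliers()].
#'
#' @param summary data.frame from [accuracySummary()] (or any frame with
#'   participant, task, accuracy).
#' @return list(mask = named logical per participant, composite = named
#'   numeric, n_flagged).
#' @export
exclusionScreen <- function(summary) {
  byP <- split(summary$accuracy, summary$participant)
  composite <- vapply(byP, mean, numeric(1))
  if (length(composite) < 4L) stop("need at least 4 participants")
  mask <- iqrOutliers(composite)
  names(mask) <- names(composite)
  list(mask = mask, composite = composite, n_flagged = sum(mask))
}
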