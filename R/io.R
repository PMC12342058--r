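# Plain-text serialization of the package's tabular objects.

#' Hypnogram CSV round trip
#'
#' Writes/reads the standard hypnogram dialect: columns `epoch_index`,
#' `zt_start_s`, `state`.
#'
#' @param hyp A [hypnogram()].
#' @param path File path.
#' @return `readHypnogramCsv` returns a [hypnogram()];
#'   `writeHypnogramCsv` returns `path` invisibly.
#' @export
writeHypnogramCsv <- function(hyp, path) {
  df <- data.frame(epoch_index = seq_len(nEpochs(hyp)),
                   zt_start_s = hyp@ztStartS +
                     (seq_len(nEpochs(hyp)) - 1) * hyp@epochS,
                   state = states(hyp))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHypnogramCsv
#' @export
readHypnogramCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "zt_start_s", "state")
  if (!all(need %in% names(df)))
    stop("hypnogram CSV must have columns: ", paste(need, collapse = ", "))
  epochS <- if (nrow(df) > 1) df$zt_start_s[2] - df$zt_start_s[1] else 10
  hypnogram(df$state, epochS = epochS, ztStartS = df$zt_start_s[1])
}

#' Trajectory CSV round trip
#'
#' Columns `t_s`, `x_cm`, `y_cm`, `trial` (`empty`/`target`).
#'
#' @param trials List with `empty` and `target` trajectory data.frames.
#' @param path File path.
#' @return `readTrajectoryCsv` returns the trial list; the writer returns
#'   `path` invisibly.
#' @export
writeTrajectoryCsv <- function(trials, path) {
  df <- do.call(rbind, lapply(c("empty", "target"), function(tr) {
    data.frame(t_s = trials[[tr]]$t, x_cm = trials[[tr]]$x,
               y_cm = trials[[tr]]$y, trial = tr)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCsv
#' @export
readTrajectoryCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "x_cm", "y_cm", "trial")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  lapply(stats::setNames(c("empty", "target"), c("empty", "target")),
         function(tr) {
           d <- df[df$trial == tr, ]
           data.frame(t = d$t_s, x = d$x_cm, y = d$y_cm)
         })
}

#' Write a spectral table as TSV
#'
#' @param tab A table from [spectralTable()].
#' @param path File path.
#' @return `path` invisibly.
#' @export
writeSpectralTsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
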