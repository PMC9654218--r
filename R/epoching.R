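#' Cut a continuous recording into fixed-length labelled epochs
#'
#' Tiles the recording with windows of `windowS` seconds starting at t = 0,
#' advancing by `strideS` seconds (non-overlapping by default).  A trailing
#' partial window is discarded.  Every epoch inherits `label` and the
#' recording's subject id.
#'
#' @param rec an [EEGRecording-class].
#' @param windowS window length, seconds (default 2 s, the canonical
#'   emotion-classification window: 400 samples at 200 Hz).
#' @param strideS hop between window starts, seconds; defaults to
#'   `windowS` (non-overlapping).
#' @param label class label assigned to every epoch.
#' @return an [EEGEpochSet-class] with
#'   `floor((samples - window) / stride) + 1` epochs.
#' @examples
#' rec <- eegRecording(matrix(rnorm(2 * 2000), 2), fs = 200)
#' nEpochs(epochRecording(rec, windowS = 2, label = "neutral"))  # 5
#' @export
epochRecording <- function(rec, windowS = 2, strideS = windowS,
                           label = "unlabelled") {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  w <- as.integer(round(windowS * fs))
  s <- as.integer(round(strideS * fs))
  if (w < 1L) stop("windowS x fs must be at least one sample")
  if (s < 1L) stop("strideS must be positive")
  total <- ncol(rec@signal)
  if (total < w)
    stop("recording is shorter than one window; no epochs can be formed")
  n <- (total - w) %/% s + 1L
  starts <- (seq_len(n) - 1L) * s
  ep <- array(0, dim = c(n, nrow(rec@signal), w))
  for (i in seq_len(n))
    ep[i, , ] <- rec@signal[, (starts[i] + 1L):(starts[i] + w), drop = FALSE]
  eegEpochSet(ep, labels = rep(label, n),
              subjectIds = rep(rec@subjectId, n), fs = fs,
              windowS = w / fs, channelNames = rec@channelNames)
}

#' Combine epoch sets
#'
#' Concatenates epoch sets that share sampling rate, window length and
#' channel layout; the union of label levels is kept.
#'
#' @param ... [EEGEpochSet-class] objects.
#' @return an [EEGEpochSet-class].
#' @export
bindEpochSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "EEGEpochSet"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1L]]
  for (s in sets[-1L]) {
    if (!isTRUE(all.equal(s@fs, ref@fs)) || nSamples(s) != nSamples(ref) ||
        nChannels(s) != nChannels(ref))
      stop("epoch sets differ in sampling rate, window or channel layout")
  }
  lv <- unique(unlist(lapply(sets, function(s) levels(s@labels))))
  ep <- do.call(abind3, lapply(sets, epochArray))
  eegEpochSet(ep,
              labels = unlist(lapply(sets, function(s) as.character(s@labels))),
              subjectIds = unlist(lapply(sets, subjectIds)),
              fs = ref@fs, windowS = ref@windowS,
              channelNames = ref@channelNames, labelLevels = lv)
}

# bind 3-D arrays along the first (epoch) axis
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n <- sum(vapply(arrs, function(a) dim(a)[1L], integer(1)))
  out <- array(0, dim = c(n, d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1L]
    if (k) out[(at + 1L):(at + k), , ] <- a
    at <- at + k
  }
  out
}

#' Binarise a 1-9 affective rating
#'
#' Valence/arousal self-ratings on the 1-9 scale are mapped to two classes:
#' ratings below 5 are negative, ratings of 5 and above are positive.
#' Non-integer ratings are allowed and follow the same "< 5 is negative"
#' rule.
#'
#' @param rating numeric vector of ratings in \[1, 9\].
#' @return factor with levels `negative`, `positive`.
#' @examples
#' binarizeRating(c(3, 5, 4.5))  # negative positive negative
#' @export
binarizeRating <- function(rating) {
  if (any(!is.finite(rating)) || any(rating < 1) || any(rating > 9))
    stop("ratings must lie in [1, 9]")
  factor(ifelse(rating < 5, "negative", "positive"),
         levels = c("negative", "positive"))
}

#' Drop neutral epochs
#'
#' Removes every epoch labelled `neutral`, keeping the remaining epochs in
#' their original order.  Turning a balanced three-class set into the
#' positive/negative two-class task keeps two-thirds of the epochs.
#'
#' @param es an [EEGEpochSet-class] whose label set contains `neutral`.
#' @param neutralLabel the label treated as neutral.
#' @return an [EEGEpochSet-class] without neutral epochs (possibly empty);
#'   the `neutral` level is dropped from the label set.
#' @export
dropNeutral <- function(es, neutralLabel = "neutral") {
  stopifnot(is(es, "EEGEpochSet"))
  keep <- as.character(es@labels) != neutralLabel
  out <- es[keep]
  out@labels <- factor(as.character(out@labels),
                       levels = setdiff(levels(es@labels), neutralLabel))
  out
}
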