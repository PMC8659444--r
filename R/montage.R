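#' EEG channel montages
#'
#' A `channel_montage` is an ordered set of bipolar derivations. Identity of a
#' channel is the pair (index, label): labels need not be unique (the standard
#' 23-channel longitudinal bipolar montage used by the CHB-MIT scalp EEG
#' database lists T8-P8 twice, at positions 15 and 23).
#'
#' @param labels Character vector of channel labels, in montage order.
#' @return An object of class `channel_montage`: a data.frame with columns
#'   `index` (1-based) and `label`.
#' @examples
#' m <- channel_montage(c("FP1-F7", "F7-T7"))
#' nrow(m)
#' @export
channel_montage <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("a montage needs at least one channel")
  if (anyNA(labels) || any(!nzchar(trimws(labels))))
    stop("montage labels must be non-empty strings")
  out <- data.frame(index = seq_along(labels), label = labels,
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_montage", "data.frame")
  out
}

#' @describeIn channel_montage The default 23-channel CHB-MIT bipolar montage
#'   (256 Hz scalp recordings; T8-P8 appears at both index 15 and 23).
#' @export
chbmit_montage <- function() {
  channel_montage(c(
    "FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2", "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ", "P7-T7", "T7-FT9", "FT9-FT10", "FT10-T8", "T8-P8"
  ))
}

#' @export
print.channel_montage <- function(x, ...) {
  cat(sprintf("<channel_montage: %d channels>\n", nrow(x)))
  cat(paste(sprintf("%d:%s", x$index, x$label), collapse = " "), "\n")
  invisible(x)
}

# Canonical form used when matching file labels to montage labels:
# case- and whitespace-insensitive.
normalize_label <- function(x) toupper(gsub("[[:space:]]+", "", x))
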