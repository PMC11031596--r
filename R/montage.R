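#' Standard 64-channel 10-10 montage
#'
#' Returns the package's default 64-channel electrode set: labels from the
#' extended international 10-10 system together with schematic 2-D scalp
#' positions (head seen from above, nose up; unit-radius disc, `x` positive
#' to the right, `y` positive to the front). Only labels and flat positions
#' are needed for spatial weighting of the synthetic generator; no 3-D
#' digitization or head model is involved.
#'
#' @return A data.frame with columns `label`, `x`, `y` (64 rows).
#' @export
#' @examples
#' m <- std_montage()
#' subset(m, label %in% c("C3", "C4"))
std_montage <- function() {
  row <- function(labels, y, halfwidth) {
    k <- length(labels)
    x <- if (k == 1) 0 else seq(-halfwidth, halfwidth, length.out = k)
    data.frame(label = labels, x = x, y = y, stringsAsFactors = FALSE)
  }
  m <- rbind(
    row(c("Fp1", "Fpz", "Fp2"), 0.95, 0.35),
    row(c("AF7", "AF3", "AFz", "AF4", "AF8"), 0.75, 0.55),
    row(c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), 0.55, 0.75),
    row(c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"), 0.28, 0.85),
    row(c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"), 0.00, 1.00),
    row(c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"), -0.28, 0.85),
    row(c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"), -0.55, 0.75),
    row(c("PO7", "PO3", "POz", "PO4", "PO8"), -0.75, 0.55),
    row(c("O1", "Oz", "O2"), -0.95, 0.35),
    row(c("TP9", "TP10"), -0.40, 1.15),
    row("Iz", -1.10, 0)
  )
  rownames(m) <- NULL
  m
}

#' Look up 2-D positions for a set of montage labels
#'
#' @param labels character vector of channel labels; must be a subset of
#'   [std_montage()] labels.
#' @return data.frame `label`, `x`, `y` in the order of `labels`.
#' @export
channel_positions <- function(labels) {
  m <- std_montage()
  miss <- setdiff(labels, m$label)
  if (length(miss)) {
    stop("unknown montage channel(s): ", paste(miss, collapse = ", "))
  }
  m[match(labels, m$label), , drop = FALSE]
}

#' Mirror channel labels across the midline
#'
#' Maps left-hemisphere labels to their right-hemisphere homologues and vice
#' versa (odd channel numbers are left, even are right; `z` midline labels are
#' unchanged). Used to re-center the evoked topography when the right motor
#' cortex is stimulated.
#'
#' @param labels character vector of 10-10 labels.
#' @return character vector of mirrored labels.
#' @export
#' @examples
#' mirror_channels(c("C3", "FC3", "Cz", "C4"))
mirror_channels <- function(labels) {
  vapply(labels, function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+)([0-9]+)$", lab))[[1]]
    if (length(m) == 0) return(lab)        # midline (z) labels
    n <- as.integer(m[3])
    n2 <- if (n %% 2 == 1) n + 1L else n - 1L
    paste0(m[2], n2)
  }, character(1), USE.NAMES = FALSE)
}

# Euclidean distance of every montage position to a center label.
channel_distances <- function(labels, center) {
  pos <- channel_positions(labels)
  c0 <- channel_positions(center)
  sqrt((pos$x - c0$x)^2 + (pos$y - c0$y)^2)
}
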