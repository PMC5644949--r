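#' Vigilance-state vocabularies
#'
#' Mouse recordings are scored in 4-s epochs as WAKE/NREM/REM; human
#' polysomnography in 20-s epochs as W/N1/N2/N3/REM.
#'
#' @param species `"mouse"` or `"human"`.
#' @return Character vector of admissible state labels.
#' @export
state_vocabulary <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  switch(species,
    mouse = c("WAKE", "NREM", "REM"),
    human = c("W", "N1", "N2", "N3", "REM")
  )
}

# Default scoring epoch length in seconds.
default_epoch_s <- function(species) {
  switch(species, mouse = 4, human = 20)
}

# Human sleep stages (everything but wake).
human_sleep_stages <- function() c("N1", "N2", "N3", "REM")

#' Construct a hypnogram
#'
#' A hypnogram is a tibble of consecutive scoring epochs with columns
#' `epoch` (0-based index), `zt` (zeitgeber time in hours, ZT0 = light
#' onset), `state`, and `artifact`. Epoch indices are contiguous and the
#' zeitgeber time of epoch i is `start_zt + i * epoch_s / 3600`; epochs
#' cover the half-open interval `[zt, zt + epoch_s/3600)`.
#'
#' @param state Character vector of epoch states, drawn from
#'   [state_vocabulary()] for `species`.
#' @param species `"mouse"` (4-s epochs) or `"human"` (20-s epochs).
#' @param artifact Logical vector of artifact flags (recycled if length 1).
#' @param epoch_s Epoch length in seconds; defaults to the species
#'   convention.
#' @param start_zt Zeitgeber time of the first epoch, hours.
#' @return A tibble of class `"hypnogram"` with attributes `epoch_s` and
#'   `species`.
#' @export
#' @examples
#' hypnogram(c("WAKE", "NREM", "NREM"))
hypnogram <- function(state, species = c("mouse", "human"),
                      artifact = FALSE,
                      epoch_s = NULL, start_zt = 0) {
  species <- match.arg(species)
  if (is.null(epoch_s)) epoch_s <- default_epoch_s(species)
  n <- length(state)
  artifact <- rep_len(as.logical(artifact), n)
  out <- tibble(
    epoch = seq_len(n) - 1L,
    zt = start_zt + (seq_len(n) - 1L) * epoch_s / 3600,
    state = as.character(state),
    artifact = artifact
  )
  out <- structure(out,
    class = c("hypnogram", class(tibble())),
    epoch_s = epoch_s, species = species
  )
  validate_hypnogram(out)
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf(
    "<hypnogram> %s, %d epochs of %gs (%.2f h)\n",
    attr(x, "species"), nrow(x), attr(x, "epoch_s"),
    nrow(x) * attr(x, "epoch_s") / 3600
  ))
  NextMethod()
}

# Validate structure and state vocabulary; errors name the offence.
validate_hypnogram <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  species <- attr(hyp, "species")
  epoch_s <- attr(hyp, "epoch_s")
  if (nrow(hyp) == 0L) stop("hypnogram has no epochs", call. = FALSE)
  if (any(diff(hyp$epoch) != 1L)) {
    stop("epoch indices must be contiguous and strictly increasing",
      call. = FALSE
    )
  }
  expected_zt <- hyp$zt[1] + (hyp$epoch - hyp$epoch[1]) * epoch_s / 3600
  if (max(abs(hyp$zt - expected_zt)) > 1e-6) {
    stop(sprintf(
      "zt column inconsistent with %g-s epoch length", epoch_s
    ), call. = FALSE)
  }
  vocab <- state_vocabulary(species)
  bad <- setdiff(unique(hyp$state), vocab)
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown vigilance state label(s) for %s: %s",
      species, paste(dQuote(bad, FALSE), collapse = ", ")
    ), call. = FALSE)
  }
  if (!is.logical(hyp$artifact) || anyNA(hyp$artifact)) {
    stop("artifact flags must be non-missing logicals", call. = FALSE)
  }
  hyp
}

# Epoch length (s) of a hypnogram, with a safe default.
epoch_length_s <- function(hyp) {
  es <- attr(hyp, "epoch_s")
  if (is.null(es)) stop("hypnogram lacks an epoch_s attribute", call. = FALSE)
  es
}

#' Mark epochs flanked by the same vigilance state
#'
#' Spectral analyses of state-specific EEG power only use epochs that are
#' both preceded and followed by an epoch of the identical vigilance
#' state, so that state-transition epochs with mixed EEG content are
#' excluded. This returns that mask: `TRUE` marks a stable (usable)
#' epoch, `FALSE` a transition or boundary epoch. The first and last
#' epochs are always `FALSE`.
#'
#' @param hyp A [hypnogram()].
#' @return Logical vector, one element per epoch.
#' @export
#' @examples
#' mark_transition_epochs(hypnogram(c("WAKE", "WAKE", "WAKE")))
mark_transition_epochs <- function(hyp) {
  s <- hyp$state
  n <- length(s)
  if (n < 3L) stop("need at least 3 epochs", call. = FALSE)
  stable <- c(
    FALSE,
    s[2:(n - 1)] == s[1:(n - 2)] & s[2:(n - 1)] == s[3:n],
    FALSE
  )
  stable
}

# Epochs usable for state-specific spectral statistics.
clean_epoch_mask <- function(hyp) {
  !hyp$artifact & mark_transition_epochs(hyp)
}
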