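#' Read a hypnogram from a tab-separated file
#'
#' The file must have header columns `epoch`, `zt`, `state`, `artifact`.
#' Epoch indices must be contiguous, `zt` must be consistent with the
#' declared epoch length (4 s mouse, 20 s human), and state labels must
#' come from [state_vocabulary()].
#'
#' @param path Path to a TSV file.
#' @param species `"mouse"` or `"human"`.
#' @param epoch_s Epoch length override in seconds (defaults to the
#'   species convention).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, species = c("mouse", "human"),
                           epoch_s = NULL) {
  species <- match.arg(species)
  if (is.null(epoch_s)) epoch_s <- default_epoch_s(species)
  raw <- readr::read_tsv(path,
    col_types = readr::cols(
      epoch = readr::col_integer(),
      zt = readr::col_double(),
      state = readr::col_character(),
      artifact = readr::col_logical()
    ),
    progress = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop(sprintf(
      "malformed hypnogram row at line %d of %s", prob$row[1] + 1L, path
    ), call. = FALSE)
  }
  need <- c("epoch", "zt", "state", "artifact")
  if (!all(need %in% names(raw))) {
    stop("hypnogram file must have columns epoch, zt, state, artifact",
      call. = FALSE
    )
  }
  out <- structure(
    as_tibble(raw[need]),
    class = c("hypnogram", class(tibble())),
    epoch_s = epoch_s, species = species
  )
  validate_hypnogram(out)
}

#' Write a hypnogram to a tab-separated file
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  validate_hypnogram(hyp)
  readr::write_tsv(as_tibble(hyp), path, progress = FALSE)
  invisible(path)
}

#' Read per-epoch power spectra from CSV
#'
#' The header row is the frequency axis (bin centers in Hz at 0.25 Hz
#' spacing); each subsequent row is one epoch, row-aligned with the
#' matching hypnogram.
#'
#' @param path Path to a CSV file.
#' @return A [spectra()] object.
#' @export
read_spectra <- function(path) {
  header <- readLines(path, n = 1L)
  freq <- suppressWarnings(as.numeric(strsplit(header, ",")[[1]]))
  if (anyNA(freq) || length(freq) == 0) {
    stop("spectra header must be the numeric frequency axis", call. = FALSE)
  }
  # scan() parses doubles with correctly rounded strtod, so values
  # written at full precision round-trip exactly
  vals <- scan(path,
    what = numeric(), sep = ",", skip = 1L, quiet = TRUE
  )
  if (length(vals) %% length(freq) != 0) {
    stop("spectra rows do not match the frequency axis length", call. = FALSE)
  }
  spectra(
    matrix(vals, ncol = length(freq), byrow = TRUE),
    freq
  )
}

#' Write per-epoch power spectra to CSV
#'
#' Values are written at full precision so a write/read round trip is
#' lossless.
#'
#' @param x A [spectra()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  validate_spectra(x)
  df <- as.data.frame(x$psd)
  names(df) <- format(x$freq, trim = TRUE)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a PET region-of-interest uptake table
#'
#' Expected CSV columns: `subject`, `condition` (`baseline` or
#' `sleep_deprivation`), `region`, `hemisphere`, `c_t` (regional activity
#' concentration) and `c_cb` (cerebellar reference concentration).
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_roi_table <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      subject = readr::col_character(),
      condition = readr::col_character(),
      region = readr::col_character(),
      hemisphere = readr::col_character(),
      c_t = readr::col_double(),
      c_cb = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(raw$c_t <= 0) || any(raw$c_cb <= 0)) {
    stop("activity concentrations must be positive", call. = FALSE)
  }
  as_tibble(raw)
}

#' @rdname read_roi_table
#' @param tbl Table to write.
#' @export
write_roi_table <- function(tbl, path) {
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read an MRS metabolite table
#'
#' Expected CSV columns: `subject`, `condition`, `metabolite`,
#' `concentration` (arbitrary units) and `crlb_pct` (Cramer-Rao lower
#' bound of the fit, percent).
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_metabolite_table <- function(path) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      subject = readr::col_character(),
      condition = readr::col_character(),
      metabolite = readr::col_character(),
      concentration = readr::col_double(),
      crlb_pct = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(raw$crlb_pct < 0)) stop("crlb_pct must be >= 0", call. = FALSE)
  as_tibble(raw)
}

#' Read Y-maze arm-entry sequences
#'
#' Expected TSV columns: `subject`, `run`, `condition`, `sequence`
#' (comma-separated arm labels, e.g. `"A,B,C,A"`). An entry requires the
#' animal to leave its current arm, so consecutive duplicate arms cannot
#' occur; repeated labels in the raw record are collapsed to single
#' entries with a warning.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a list-column `entries` of character vectors.
#' @export
read_entries <- function(path) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(
      subject = readr::col_character(),
      run = readr::col_integer(),
      condition = readr::col_character(),
      sequence = readr::col_character()
    ),
    progress = FALSE
  )
  entries <- lapply(strsplit(raw$sequence, ","), function(e) {
    e <- trimws(e)
    bad <- setdiff(unique(e), c("A", "B", "C"))
    if (length(bad) > 0) {
      stop(sprintf(
        "unknown Y-maze arm label(s): %s", paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
    collapsed <- rle(e)$values
    if (length(collapsed) < length(e)) {
      warning("collapsed repeated same-arm records to single entries")
    }
    collapsed
  })
  out <- as_tibble(raw[c("subject", "run", "condition")])
  out$entries <- entries
  out
}

#' @rdname read_entries
#' @param tbl Table with `subject`, `run`, `condition` and an `entries`
#'   list-column, as produced by [read_entries()] or
#'   [simulate_ymaze_runs()].
#' @export
write_entries <- function(tbl, path) {
  out <- tibble(
    subject = tbl$subject, run = tbl$run, condition = tbl$condition,
    sequence = vapply(tbl$entries, paste, character(1), collapse = ",")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Analysis configuration defaults
#'
#' Central place for the tunable analysis constants: epoch lengths,
#' spectral bands, the mouse protocol windows, the equal-NREM-epoch
#' interval scheme, and the quality-control thresholds.
#'
#' @return A named list.
#' @export
somnostat_config <- function() {
  list(
    mouse_epoch_s = 4,
    human_epoch_s = 20,
    bands = list(
      delta_mouse = c(0.75, 4),
      swa_human = c(0.5, 4.5),
      slow_oscillation = c(0.25, 1.0)
    ),
    psd_area_band = c(0.75, 49),
    reference_zt = c(8, 12),
    protocol = list(baseline_h = 48, sd_start_zt = 48, sd_h = 6, recovery_h = 18),
    intervals = c(light = 12, dark = 6, recovery_light = 8),
    crlb_threshold_pct = 20,
    outlier_k_sd = 2,
    first_nrem_min_duration_min = 15,
    first_nrem_rem_break_min = 5
  )
}

# Flatten nested config values into "a.b: v1 v2" DCF fields and back.
flatten_config <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    v <- x[[nm]]
    if (is.list(v)) {
      out <- c(out, flatten_config(v, key))
    } else {
      out[[key]] <- paste(v, collapse = " ")
    }
  }
  out
}

#' Write or read a flat key-value configuration file
#'
#' Uses Debian-control (DCF) `key: value` lines; nested list names are
#' joined with dots and numeric vectors are space-separated.
#'
#' @param config A configuration list such as [somnostat_config()].
#' @param path File path.
#' @return For `write_config`, `path` invisibly; for `read_config`, a
#'   named list of character/numeric values (flat keys).
#' @export
write_config <- function(config, path) {
  flat <- flatten_config(config)
  write.dcf(as.data.frame(flat, check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  m <- read.dcf(path)
  vals <- lapply(seq_len(ncol(m)), function(j) {
    parts <- strsplit(m[1, j], "[ \t]+")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) parts else num
  })
  setNames(vals, colnames(m))
}
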