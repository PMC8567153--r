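# Frequency-domain feature extraction: per-channel FFT spectrum, the five
# dominant harmonics (amplitude, phase, peak frequency) and the canonical
# 270-dimensional feature vector (2 sensors x 9 channels x 5 harmonics x
# {A, P, F}).

#' One-sided amplitude spectrum of a channel
#'
#' Discrete Fourier transform of the mean-removed channel with one-sided
#' amplitude normalisation, so a pure sinusoid of amplitude `a` produces a
#' spectral peak of amplitude `a`. No taper window is applied. The fundamental
#' frequency is `f0 = 1 / t_total`, the reciprocal of the record length; the
#' frequency grid is `k * f0` for `k = 0 .. floor(N/2)`.
#'
#' @param series channel time series (length >= 16).
#' @param fs sampling rate, Hz.
#' @return An object of class `spectrum_1s`: list with `freqs` (Hz),
#'   `amplitude`, `phase` (radians, from the complex coefficients), `coeffs`
#'   (complex), `f0` (Hz) and `t_total` (seconds).
#' @export
channel_spectrum <- function(series, fs) {
  n <- length(series)
  if (n < 16L) stop("series too short for spectral analysis (need >= 16 samples)",
                    call. = FALSE)
  t_total <- n / fs
  x <- series - mean(series)
  co <- stats::fft(x)
  half <- floor(n / 2)
  idx <- 1:(half + 1L) # DC .. Nyquist
  scale <- c(1, rep(2, half - 1L), if (n %% 2 == 0) 1 else 2) / n
  co <- co[idx]
  structure(list(freqs = (idx - 1L) / t_total,
                 amplitude = abs(co) * scale,
                 phase = Arg(co),
                 coeffs = co,
                 f0 = 1 / t_total,
                 t_total = t_total),
            class = "spectrum_1s")
}

#' Extract the dominant harmonics of a spectrum
#'
#' Selects the `k` largest-amplitude non-DC spectral bins ("first `k`
#' harmonics" in decreasing order of energy), ties broken in favour of the
#' lower frequency, and records their amplitudes `A`, phase shifts `P`
#' (radians in (-pi, pi]) and peak frequencies `F` (Hz). The alternative
#' reading — the bins at exact multiples `1..k` of the fundamental — is
#' available with `mode = "fundamental"` (under which `F` is degenerate by
#' construction).
#'
#' @param spec a [channel_spectrum()] result.
#' @param k number of harmonics (default 5).
#' @param mode `"dominant"` (default) or `"fundamental"`.
#' @return An object of class `harmonic_set`: list of numeric vectors `A`,
#'   `P`, `F`, each of length `k`.
#' @export
extract_harmonics <- function(spec, k = 5L, mode = c("dominant", "fundamental")) {
  mode <- match.arg(mode)
  amp <- spec$amplitude[-1L] # drop DC
  frq <- spec$freqs[-1L]
  phs <- spec$phase[-1L]
  if (length(amp) < k)
    stop(sprintf("spectrum has %d non-DC bins, need at least %d", length(amp), k),
         call. = FALSE)
  sel <- if (mode == "dominant") {
    order(-amp, frq)[seq_len(k)] # ties -> lower frequency
  } else {
    seq_len(k)
  }
  structure(list(A = amp[sel], P = phs[sel], F = frq[sel]),
            class = "harmonic_set")
}

#' Canonical feature-vector index map
#'
#' The 270 features are laid out block-major: amplitudes at positions 1-90,
#' phases at 91-180, peak frequencies at 181-270. Within each block the
#' channels run hand ax..mz (1-9) then forearm ax..mz (10-18), and within
#' each channel the harmonics run 1-5. So
#' `index = (block - 1) * 90 + (channel - 1) * 5 + harmonic`.
#'
#' @param block `"A"`, `"P"` or `"F"`.
#' @param sensor `"hand"` or `"forearm"`.
#' @param channel one of `ax, ay, az, gx, gy, gz, mx, my, mz`.
#' @param harmonic harmonic rank 1-5 (1 = largest amplitude).
#' @return The 1-based position of that feature in the vector.
#' @examples
#' feature_index("P", "hand", "ax", 1) # 91
#' @export
feature_index <- function(block, sensor, channel, harmonic) {
  b <- match(block, c("A", "P", "F"))
  s <- match(sensor, c("hand", "forearm"))
  ch <- match(channel, CHANNELS)
  if (anyNA(c(b, s, ch)) || harmonic < 1 || harmonic > 5)
    stop("invalid feature coordinates", call. = FALSE)
  (b - 1L) * 90L + ((s - 1L) * 9L + (ch - 1L)) * 5L + as.integer(harmonic)
}

#' Names of the 270 canonical features
#' @return Character vector of length 270, e.g. `"A_hand_ax_h1"`.
#' @export
feature_names <- function() {
  nm <- character(270)
  for (b in c("A", "P", "F"))
    for (s in c("hand", "forearm"))
      for (ch in CHANNELS)
        for (h in 1:5)
          nm[feature_index(b, s, ch, h)] <- sprintf("%s_%s_%s_h%d", b, s, ch, h)
  nm
}

#' Build the 270-dimensional feature vector of a trial
#'
#' Computes the one-sided spectrum of each of the 18 sensor channels (hand
#' then forearm; accelerometer, gyroscope, magnetometer x/y/z), extracts the
#' five dominant harmonics per channel, and assembles amplitudes, phases and
#' peak frequencies into the canonical 270-vector (see [feature_index()]).
#'
#' @param trial a (trimmed) `raw_trial`.
#' @param mode harmonic selection mode, see [extract_harmonics()].
#' @return An object of class `feature_vector`: numeric vector of length 270
#'   with names from [feature_names()], attribute `label` copied from the
#'   trial (may be `NULL`).
#' @export
build_feature_vector <- function(trial, mode = "dominant") {
  stopifnot(inherits(trial, "raw_trial"))
  v <- numeric(270)
  for (s in c("hand", "forearm")) {
    for (ch in CHANNELS) {
      spec <- channel_spectrum(trial[[s]][[ch]], trial$fs)
      hs <- extract_harmonics(spec, 5L, mode = mode)
      for (h in 1:5) {
        v[feature_index("A", s, ch, h)] <- hs$A[h]
        v[feature_index("P", s, ch, h)] <- hs$P[h]
        v[feature_index("F", s, ch, h)] <- hs$F[h]
      }
    }
  }
  names(v) <- feature_names()
  structure(v, label = trial$label, class = c("feature_vector", "numeric"))
}

#' Build a labelled dataset from a list of trials
#'
#' One canonical feature vector per trial, order preserved. Every trial must
#' carry a 0/1 label.
#'
#' @param trials list of labelled `raw_trial` objects.
#' @param mode harmonic selection mode, see [extract_harmonics()].
#' @return An object of class `labeled_dataset`: list with `X` (n x 270
#'   matrix), `y` (integer labels) and `class_names`
#'   (`c("0" = "typical", "1" = "CP")`).
#' @export
build_dataset <- function(trials, mode = "dominant") {
  n <- length(trials)
  X <- matrix(NA_real_, nrow = n, ncol = 270,
              dimnames = list(NULL, feature_names()))
  y <- integer(n)
  for (i in seq_len(n)) {
    tr <- trials[[i]]
    if (is.null(tr$label))
      stop(sprintf("trial %d has no label; all trials must be labelled", i),
           call. = FALSE)
    X[i, ] <- as.numeric(build_feature_vector(tr, mode = mode))
    y[i] <- tr$label
  }
  labeled_dataset(X, y)
}

#' Construct a labelled dataset from a feature matrix
#' @param X numeric feature matrix (rows = instances).
#' @param y integer 0/1 labels, one per row.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("X rows and y length differ", call. = FALSE)
  if (length(y) && !all(y %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  structure(list(X = X, y = y,
                 class_names = c("0" = "typical", "1" = "CP")),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d instances x %d features  (label 1: %d, label 0: %d)\n",
              nrow(x$X), ncol(x$X), sum(x$y == 1), sum(x$y == 0)))
  invisible(x)
}

#' Write a labelled dataset as CSV (features + label column)
#' @param data a `labeled_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  df <- as.data.frame(data$X)
  df$label <- data$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a labelled dataset from CSV written by [write_dataset_csv()]
#' @param path input path.
#' @return A `labeled_dataset`.
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("CSV has no 'label' column", call. = FALSE)
  labeled_dataset(as.matrix(df[setdiff(names(df), "label")]), df$label)
}

#' Write a labelled dataset in ARFF (attribute-relation file format)
#'
#' Plain-text ARFF with numeric attributes and a nominal `class {0,1}`
#' attribute, for interoperability with Java-based workbench tools.
#'
#' @param data a `labeled_dataset`.
#' @param path output path.
#' @param relation relation name.
#' @return `path`, invisibly.
#' @export
write_dataset_arff <- function(data, path, relation = "imuwrist_features") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("@relation %s", relation), con)
  cn <- colnames(data$X)
  if (is.null(cn)) cn <- sprintf("f%03d", seq_len(ncol(data$X)))
  for (nm in cn) writeLines(sprintf("@attribute %s numeric", nm), con)
  writeLines("@attribute class {0,1}", con)
  writeLines("@data", con)
  rows <- apply(data$X, 1L, function(r) paste(sprintf("%.10g", r), collapse = ","))
  writeLines(paste(rows, data$y, sep = ","), con)
  invisible(path)
}
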