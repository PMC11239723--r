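#' Abnormality class vocabulary
#'
#' The eight-class vocabulary used throughout the package, and the
#' four-class subset shared between the training corpus and the external
#' generalization corpus.
#'
#' @return character vector of class acronyms.
#' @export
classVocabulary <- function() {
  c("1dAVb", "AF", "LBBB", "RBBB", "PAC", "PVC", "STD", "STE")
}

#' @rdname classVocabulary
#' @export
overlapSubset <- function() c("1dAVb", "AF", "LBBB", "RBBB")

#' Standard 12-lead names
#' @export
standardLeads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Construct an ECG record
#'
#' @param signal numeric matrix, leads x samples, millivolts.
#' @param samplingRate sampling rate in Hz.
#' @param leadNames one name per row; defaults to the standard 12 leads
#'   when there are 12 rows.
#' @param labels character vector of class acronyms carried by the record,
#'   or a named 0/1 vector over a vocabulary.
#' @param recordId identifier string.
#' @param age,sex optional demographics.
#' @param vocab class vocabulary used to encode `labels`.
#' @return an [ECGRecord-class].
#' @export
ecgRecord <- function(signal, samplingRate = 500, leadNames = NULL,
                      labels = character(), recordId = "record",
                      age = NA_real_, sex = NA_character_,
                      vocab = classVocabulary()) {
  signal <- as.matrix(signal)
  if (is.null(leadNames)) {
    leadNames <- if (nrow(signal) == 12L) standardLeads()
                 else sprintf("S%d", seq_len(nrow(signal)))
  }
  lab <- if (is.character(labels)) encodeLabels(labels, vocab)
         else {
           stopifnot(!is.null(names(labels)))
           stats::setNames(as.integer(labels), names(labels))
         }
  rec <- new("ECGRecord", signal = signal, samplingRate = samplingRate,
             leadNames = leadNames, labels = lab, recordId = recordId,
             age = age, sex = sex,
             excluded = ncol(signal) == 0L || all(signal == 0),
             padded = FALSE)
  validObject(rec)
  rec
}

#' Encode class names as a multi-hot vector
#'
#' @param names character vector of class acronyms (possibly empty; a
#'   record may carry several simultaneous abnormalities).
#' @param vocab ordered class vocabulary.
#' @return named integer 0/1 vector over `vocab`.
#' @examples
#' encodeLabels(c("AF", "RBBB"))
#' @export
encodeLabels <- function(names, vocab = classVocabulary()) {
  names <- as.character(names)
  unknown <- setdiff(names, vocab)
  assertFlag(length(unknown) == 0, "unknown class acronym(s): %s",
             paste(unknown, collapse = ", "))
  stats::setNames(as.integer(vocab %in% names), vocab)
}

# ---- readers ---------------------------------------------------------------

readDelimitedRecord <- function(path, samplingRate, vocab) {
  dt <- data.table::fread(path, header = "auto")
  m <- as.matrix(dt)
  hasNames <- !is.null(colnames(m)) && ncol(m) > 0 &&
    all(colnames(m) %in% c(standardLeads(), tolower(standardLeads())))
  if (!is.numeric(m)) stop("non-numeric entries in delimited file: ", path)
  leadNames <- NULL
  if (hasNames) {           # columns are leads, rows are time
    leadNames <- colnames(m)
    m <- t(m)
  } else if (nrow(m) > ncol(m)) {
    m <- t(m)               # longer axis is time
  }
  dimnames(m) <- NULL
  unknown <- setdiff(leadNames, standardLeads())
  assertFlag(is.null(leadNames) || length(unknown) == 0,
             "unknown lead name(s): %s", paste(unknown, collapse = ", "))
  rec <- ecgRecord(m, samplingRate = samplingRate, leadNames = leadNames,
                   recordId = sub("\\.[^.]+$", "", basename(path)),
                   vocab = vocab)
  reorderStandard(rec)
}

parseWfdbHeader <- function(heaPath) {
  lines <- readLines(heaPath, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 2) stop("malformed header line 1 in ", heaPath)
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(strsplit(top[3], "/")[[1]][1]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sigs <- lapply(lines[1 + seq_len(nsig)], function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 2) stop("malformed signal line in ", heaPath, ": ", ln)
    fmt <- tok[2]
    gainTok <- if (length(tok) >= 3) tok[3] else "200"
    gainNum <- sub("/.*$", "", gainTok)
    baseline <- 0
    if (grepl("\\(", gainNum)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gainNum))
      gainNum <- sub("\\(.*$", "", gainNum)
    }
    list(file = tok[1], format = fmt,
         gain = as.numeric(gainNum), baseline = baseline,
         lead = tok[length(tok)])
  })
  list(record = top[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sigs)
}

readWfdbRecord <- function(path, vocab) {
  heaPath <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  assertFlag(file.exists(heaPath), "header file not found: %s", heaPath)
  hd <- parseWfdbHeader(heaPath)
  fmts <- unique(vapply(hd$signals, `[[`, character(1), "format"))
  assertFlag(identical(fmts, "16"),
             "unsupported WFDB signal format(s): %s (only format 16)",
             paste(fmts, collapse = ", "))
  datFile <- file.path(dirname(heaPath), hd$signals[[1]]$file)
  assertFlag(file.exists(datFile), "signal file not found: %s", datFile)
  nBytes <- file.info(datFile)$size
  raw <- readBin(datFile, "integer", n = nBytes / 2, size = 2,
                 signed = TRUE, endian = "little")
  nsig <- hd$nsig
  nsamp <- length(raw) %/% nsig
  m <- matrix(raw[seq_len(nsig * nsamp)], nrow = nsig)  # frame-interleaved
  for (i in seq_len(nsig)) {
    si <- hd$signals[[i]]
    m[i, ] <- (m[i, ] - si$baseline) / si$gain
  }
  leads <- vapply(hd$signals, `[[`, character(1), "lead")
  unknown <- setdiff(leads, standardLeads())
  assertFlag(length(unknown) == 0, "unknown lead name(s): %s",
             paste(unknown, collapse = ", "))
  rec <- ecgRecord(m, samplingRate = hd$fs, leadNames = leads,
                   recordId = hd$record, vocab = vocab)
  reorderStandard(rec)
}

reorderStandard <- function(rec) {
  std <- standardLeads()
  if (setequal(rec@leadNames, std) && !identical(rec@leadNames, std)) {
    ord <- match(std, rec@leadNames)
    rec@signal <- rec@signal[ord, , drop = FALSE]
    rec@leadNames <- std
  }
  rec
}

#' Read an ECG record from disk
#'
#' Supported on-disk forms: WFDB-style header + format-16 binary signal
#' pairs (`.hea`/`.dat`), delimited numeric matrices (CSV/TSV; orientation
#' auto-detected, the longer axis is time), and the package's single-file
#' array container (see [writeRecord()]). Leads are reordered to the
#' standard 12-lead order when names are available. Records whose signal is
#' entirely empty are flagged `excluded`.
#'
#' @param path file path (for WFDB, the `.hea` file or the record stem).
#' @param format one of `"auto"`, `"wfdb"`, `"delimited"`, `"container"`.
#' @param samplingRate assumed rate for delimited input (no metadata).
#' @param vocab class vocabulary.
#' @return an [ECGRecord-class].
#' @export
readRecord <- function(path, format = c("auto", "wfdb", "delimited",
                                        "container"),
                       samplingRate = 500, vocab = classVocabulary()) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub("^.*\\.", "", path))
    format <- switch(ext,
                     hea = , dat = "wfdb",
                     csv = , tsv = , txt = "delimited",
                     rds = "container",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  switch(format,
         wfdb = readWfdbRecord(path, vocab),
         delimited = readDelimitedRecord(path, samplingRate, vocab),
         container = readContainerRecord(path))
}

readContainerRecord <- function(path) {
  obj <- readRDS(path)
  need <- c("signal", "labels", "lead_names", "fs")
  assertFlag(all(need %in% names(obj)),
             "container missing field(s): %s",
             paste(setdiff(need, names(obj)), collapse = ", "))
  rec <- new("ECGRecord", signal = obj$signal, samplingRate = obj$fs,
             leadNames = obj$lead_names,
             labels = obj$labels,
             recordId = if (!is.null(obj$record_id)) obj$record_id else "record",
             age = if (!is.null(obj$age)) obj$age else NA_real_,
             sex = if (!is.null(obj$sex)) obj$sex else NA_character_,
             excluded = ncol(obj$signal) == 0L || all(obj$signal == 0),
             padded = isTRUE(obj$padded))
  validObject(rec)
  rec
}

#' Write an ECG record
#'
#' `format = "container"` writes the single-file array container (fields
#' `signal`, `labels`, `lead_names`, `fs`, plus id/demographics);
#' `"delimited"` writes a samples x leads CSV with lead-name header;
#' `"wfdb"` writes a `.hea`/`.dat` pair in format 16 with gain 1000.
#'
#' @param record an [ECGRecord-class].
#' @param path output path (for WFDB, the record stem).
#' @param format output format.
#' @return the path, invisibly.
#' @export
writeRecord <- function(record, path,
                        format = c("container", "delimited", "wfdb")) {
  format <- match.arg(format)
  if (format == "container") {
    saveRDS(list(signal = record@signal, labels = record@labels,
                 lead_names = record@leadNames, fs = record@samplingRate,
                 record_id = record@recordId, age = record@age,
                 sex = record@sex, padded = record@padded), path)
  } else if (format == "delimited") {
    m <- t(record@signal)
    colnames(m) <- record@leadNames
    data.table::fwrite(data.table::as.data.table(m), path)
  } else {
    stem <- sub("\\.hea$", "", path)
    gain <- 1000
    raw <- round(record@signal * gain)
    raw <- pmin(pmax(raw, -32768), 32767)
    hea <- c(sprintf("%s %d %g %d", basename(stem), nrow(raw),
                     record@samplingRate, ncol(raw)),
             sprintf("%s.dat 16 %d 16 0 0 0 0 %s", basename(stem), gain,
                     record@leadNames))
    writeLines(hea, paste0(stem, ".hea"))
    con <- file(paste0(stem, ".dat"), "wb")
    writeBin(as.integer(raw), con, size = 2, endian = "little")
    close(con)
  }
  invisible(path)
}

# ---- shaping ---------------------------------------------------------------

# Fourier resampling of one series to m samples (spectrum truncation /
# zero-padding with Nyquist-bin splitting).
resampleFourier <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = m)
  kp <- min(ceiling(n / 2), ceiling(m / 2))   # positive-frequency bins kept
  Y[seq_len(kp)] <- X[seq_len(kp)]
  kn <- min(floor((n - 1) / 2), floor((m - 1) / 2))  # negative-frequency bins
  if (kn > 0)
    Y[m - seq_len(kn) + 1] <- X[n - seq_len(kn) + 1]
  if (m < n && m %% 2 == 0)                    # fold both halves of old spectrum
    Y[m / 2 + 1] <- X[m / 2 + 1] + X[n - m / 2 + 1]
  if (m > n && n %% 2 == 0) {                  # split old Nyquist bin
    Y[n / 2 + 1] <- X[n / 2 + 1] / 2
    Y[m - n / 2 + 1] <- X[n / 2 + 1] / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

#' Resample a record to a target rate
#'
#' Fourier-domain resampling per lead. The new length is
#' `round(n * targetRate / samplingRate)`, preserving duration to within
#' one sample period. Resampling to the current rate is the identity.
#'
#' @param record an [ECGRecord-class].
#' @param targetRate target sampling rate in Hz (> 0).
#' @return the resampled [ECGRecord-class].
#' @export
resampleTo <- function(record, targetRate) {
  assertFlag(is.numeric(targetRate) && targetRate > 0,
             "targetRate must be > 0")
  if (targetRate == record@samplingRate) return(record)
  n <- ncol(record@signal)
  m <- round(n * targetRate / record@samplingRate)
  sig <- t(apply(record@signal, 1L, resampleFourier, m = m))
  if (m == 1L) sig <- matrix(sig, nrow = nrow(record@signal))
  record@signal <- sig
  record@samplingRate <- targetRate
  record
}

#' Standardize a record to a fixed length
#'
#' Longer records keep their first `targetLength` samples ("extras are
#' omitted"); shorter records are zero-padded at the end and flagged
#' `padded` (set `pad = FALSE` to flag short records `excluded` instead).
#'
#' @param record an [ECGRecord-class].
#' @param targetLength target sample count (default 4096).
#' @param pad pad short records (default) rather than excluding them.
#' @return the standardized [ECGRecord-class].
#' @export
standardizeLength <- function(record, targetLength = 4096L, pad = TRUE) {
  assertFlag(targetLength >= 1, "targetLength must be >= 1")
  n <- ncol(record@signal)
  L <- as.integer(targetLength)
  if (n > L) {
    record@signal <- record@signal[, seq_len(L), drop = FALSE]
  } else if (n < L) {
    if (pad) {
      record@signal <- cbind(record@signal,
                             matrix(0, nrow(record@signal), L - n))
      record@padded <- TRUE
    } else record@excluded <- TRUE
  }
  record
}

#' Select a subset of leads
#'
#' @param record an [ECGRecord-class].
#' @param names leads to keep, in the requested order.
#' @return the sub-record.
#' @examples
#' \dontrun{selectLeads(rec, "II")}
#' @export
selectLeads <- function(record, names) {
  missing <- setdiff(names, record@leadNames)
  assertFlag(length(missing) == 0, "lead(s) not present: %s",
             paste(missing, collapse = ", "))
  idx <- match(names, record@leadNames)
  record@signal <- record@signal[idx, , drop = FALSE]
  record@leadNames <- record@leadNames[idx]
  record
}

# ---- manifests & cohorts ---------------------------------------------------

#' Read / write a label manifest
#'
#' The manifest is a CSV with columns `record_id`, `labels`
#' (semicolon-joined class acronyms; empty for normal records), `age`,
#' `sex`.
#'
#' @param records list of [ECGRecord-class] objects (for writing).
#' @param path CSV path.
#' @return `readManifest` returns a data.frame.
#' @export
writeManifest <- function(records, path) {
  df <- data.frame(
    record_id = vapply(records, recordId, character(1)),
    labels = vapply(records, function(r) {
      lb <- recordLabels(r)
      paste(names(lb)[lb == 1L], collapse = ";")
    }, character(1)),
    age = vapply(records, function(r) r@age, numeric(1)),
    sex = vapply(records, function(r) r@sex, character(1)),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  df <- as.data.frame(data.table::fread(path,
                                        colClasses = list(character = "labels")))
  if (!"labels" %in% names(df)) df$labels <- ""
  df$labels <- as.character(df$labels)
  df$labels[is.na(df$labels)] <- ""
  df
}

#' Convert records to dense cohort arrays
#'
#' @param records list of [ECGRecord-class] objects with identical shapes.
#' @param classes class names defining the label rows.
#' @return list with `x` (leads x samples x records array), `y`
#'   (classes x records 0/1 matrix) and `ids`.
#' @export
cohortArrays <- function(records, classes = classVocabulary()) {
  assertFlag(length(records) > 0, "empty record list")
  sigs <- lapply(records, ecgSignal)
  d1 <- dim(sigs[[1]])
  x <- array(unlist(sigs), c(d1, length(records)))
  y <- vapply(records, function(r) {
    lb <- recordLabels(r)
    as.integer(classes %in% names(lb)[lb == 1L])
  }, integer(length(classes)))
  y <- matrix(y, nrow = length(classes))
  rownames(y) <- classes
  list(x = x, y = y, ids = vapply(records, recordId, character(1)))
}

#' Write / read a cohort container
#'
#' Single-file container bundling all records' signals (leads x samples x
#' records), the label matrix, lead names, sampling rate and the manifest
#' fields.
#'
#' @param records list of [ECGRecord-class] objects.
#' @param path output path (`.rds`).
#' @param vocab class vocabulary used for the label matrix.
#' @return `readCohort` returns the list of records.
#' @export
writeCohort <- function(records, path, vocab = classVocabulary()) {
  arr <- cohortArrays(records, vocab)
  saveRDS(list(signal = arr$x, labels = arr$y, lead_names = leadNames(records[[1]]),
               fs = samplingRate(records[[1]]), record_id = arr$ids,
               age = vapply(records, function(r) r@age, numeric(1)),
               sex = vapply(records, function(r) r@sex, character(1))),
          path)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  obj <- readRDS(path)
  vocab <- rownames(obj$labels)
  lapply(seq_len(dim(obj$signal)[3]), function(i) {
    new("ECGRecord", signal = obj$signal[, , i],
        samplingRate = obj$fs, leadNames = obj$lead_names,
        labels = stats::setNames(as.integer(obj$labels[, i]), vocab),
        recordId = obj$record_id[i], age = obj$age[i], sex = obj$sex[i],
        excluded = FALSE, padded = FALSE)
  })
}

# ---- accessors & show ------------------------------------------------------

#' @rdname accessors
setMethod("ecgSignal", "ECGRecord", function(object) object@signal)
#' @rdname accessors
setMethod("samplingRate", "ECGRecord", function(object) object@samplingRate)
#' @rdname accessors
setMethod("leadNames", "ECGRecord", function(object) object@leadNames)
#' @rdname accessors
setMethod("recordId", "ECGRecord", function(object) object@recordId)
#' @rdname accessors
setMethod("recordLabels", "ECGRecord", function(object) object@labels)

setMethod("show", "ECGRecord", function(object) {
  lb <- object@labels
  pos <- names(lb)[lb == 1L]
  cat(sprintf("ECGRecord '%s': %d lead(s) x %d samples @ %g Hz\n",
              object@recordId, nrow(object@signal), ncol(object@signal),
              object@samplingRate))
  cat(sprintf("  labels: %s%s%s\n",
              if (length(pos)) paste(pos, collapse = ", ") else "(none)",
              if (object@excluded) " [excluded]" else "",
              if (object@padded) " [padded]" else ""))
})
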