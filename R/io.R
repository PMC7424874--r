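#' Write epochs (and their trial table) to a portable container
#'
#' Epochs are stored as a pair of files sharing a stem: `<stem>.json`, a
#' header holding the sampling rate, sensor ids, array dimensions and
#' provenance (seed, config hash when supplied); and `<stem>.dat`, the time
#' axis followed by the data array, both as little-endian float64 (data in
#' trials-fastest order). The trial table goes to `<stem>.trials.tsv`. The
#' round trip is bit-exact.
#'
#' @param ep an [epochs()] object.
#' @param stem file path without extension.
#' @param trials optional aligned trial table, written as TSV.
#' @param seed,config_hash optional provenance recorded in the header.
#' @return `stem`, invisibly.
#' @export
write_epochs <- function(ep, stem, trials = NULL, seed = NULL,
                         config_hash = NULL) {
  stopifnot(inherits(ep, "epochs"))
  hdr <- list(format = "iemdecode-epochs-v1",
              dim = dim(ep$data),
              sampling_rate = ep$sampling_rate,
              sensor_ids = ep$sensor_ids)
  if (!is.null(seed)) hdr$seed <- seed
  if (!is.null(config_hash)) hdr$config_hash <- config_hash
  jsonlite::write_json(hdr, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  # time axis precedes the data so both round-trip at full precision
  writeBin(ep$times, con, size = 8, endian = "little")
  writeBin(as.vector(ep$data), con, size = 8, endian = "little")
  if (!is.null(trials)) write_trial_table(trials, paste0(stem, ".trials.tsv"))
  invisible(stem)
}

#' Read epochs written by [write_epochs()]
#'
#' @param stem file path without extension.
#' @param with_trials also read `<stem>.trials.tsv` (default TRUE when the
#'   file exists).
#' @return list with `epochs` and `trials` (NULL when absent).
#' @export
read_epochs <- function(stem,
                        with_trials = file.exists(paste0(stem,
                                                         ".trials.tsv"))) {
  hpath <- paste0(stem, ".json")
  if (!file.exists(hpath)) stop("missing epochs header: ", hpath)
  hdr <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  for (f in c("dim", "sampling_rate", "sensor_ids"))
    if (is.null(hdr[[f]]))
      stop("epochs header is missing required field \"", f, "\"")
  dpath <- paste0(stem, ".dat")
  if (!file.exists(dpath)) stop("missing epochs payload: ", dpath)
  n <- prod(hdr$dim)
  con <- file(dpath, "rb")
  on.exit(close(con))
  times <- readBin(con, what = "double", n = hdr$dim[3], size = 8,
                   endian = "little")
  x <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  if (length(x) != n)
    stop("epochs payload truncated: expected ", n, " values, read ",
         length(x))
  # built directly (not via the constructor): window-averaged epochs have a
  # time axis stepped at the window step, not the raw sample interval
  ep <- structure(list(data = array(x, hdr$dim), times = times,
                       sampling_rate = hdr$sampling_rate,
                       sensor_ids = as.character(hdr$sensor_ids)),
                  class = "epochs")
  trials <- NULL
  if (with_trials) {
    trials <- read_trial_table(paste0(stem, ".trials.tsv"))
    if (nrow(trials) != hdr$dim[1])
      stop("trial table (", nrow(trials), " rows) does not match epochs (",
           hdr$dim[1], " trials)")
  }
  list(epochs = ep, trials = trials)
}

#' @rdname write_epochs
#' @param x trial table data.frame.
#' @param path TSV path.
#' @export
write_trial_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_epochs
#' @param path TSV path.
#' @export
read_trial_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

# 32-bit polynomial rolling hash of a config list rendered to canonical
# JSON; used to stamp output files with the configuration that produced
# them. Double arithmetic keeps every intermediate below 2^53.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
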