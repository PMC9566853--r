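## Session-bundle I/O and shared binning.
##
## A session bundle is a directory with:
##   session.json   metadata (duration, group, sampling rates, unit table,
##                  free metadata keys)
##   spikes.tsv     two columns: unit_id, time_s
##   waveforms.tsv  long table: unit_id, channel, sample, amplitude
##   lfp.tsv        one column per channel (values), fs in session.json
##   laser.tsv      optional: onset_s, duration_s
## All tables are plain TSV so bundles stay inspectable with command-line
## tools; times are seconds (float64), intervals half-open [a, b).

#' Write a session bundle
#'
#' @param session a [Session-class].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @seealso [readSession()]
#' @export
writeSession <- function(session, path) {
  validObject(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  unitTab <- lapply(session@units, function(u) {
    list(unit_id = u@spikeTrain@unitId, label = u@label,
         waveform_fs = u@waveformFs, peak_channel = u@peakChannel,
         channel_positions = if (nrow(u@channelPositions))
           unname(apply(u@channelPositions, 1, as.list, simplify = FALSE))
         else list())
  })
  meta <- list(duration = session@duration, group = session@group,
               lfp_fs = vapply(session@lfp, function(ch) ch@fs, numeric(1)),
               lfp_channel_ids = vapply(session@lfp, function(ch) ch@channelId,
                                        character(1)),
               units = unitTab, metadata = session@metadata)
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  sp <- data.table::rbindlist(lapply(session@units, function(u)
    data.table::data.table(unit_id = u@spikeTrain@unitId,
                           time_s = u@spikeTrain@times)))
  if (!nrow(sp)) sp <- data.table::data.table(unit_id = character(),
                                              time_s = numeric())
  data.table::fwrite(sp, file.path(path, "spikes.tsv"), sep = "\t")

  wf <- data.table::rbindlist(lapply(session@units, function(u) {
    m <- u@meanWaveform
    if (!length(m)) return(NULL)
    data.table::data.table(unit_id = u@spikeTrain@unitId,
                           channel = rep(seq_len(nrow(m)), ncol(m)),
                           sample = rep(seq_len(ncol(m)), each = nrow(m)),
                           amplitude = as.vector(m))
  }))
  if (is.null(wf) || !nrow(wf))
    wf <- data.table::data.table(unit_id = character(), channel = integer(),
                                 sample = integer(), amplitude = numeric())
  data.table::fwrite(wf, file.path(path, "waveforms.tsv"), sep = "\t")

  if (length(session@lfp)) {
    lf <- data.table::as.data.table(
      lapply(session@lfp, function(ch) ch@samples))
    data.table::setnames(lf, vapply(session@lfp, function(ch) ch@channelId,
                                    character(1)))
    data.table::fwrite(lf, file.path(path, "lfp.tsv"), sep = "\t")
  }
  if (nrow(session@laserPulses)) {
    data.table::fwrite(data.table::data.table(
      onset_s = session@laserPulses[, 1],
      duration_s = session@laserPulses[, 2]),
      file.path(path, "laser.tsv"), sep = "\t")
  }
  invisible(path)
}

#' Read a session bundle
#'
#' Validates all session invariants on load; non-monotone or duplicated spike
#' times raise an error naming the unit rather than being silently fixed.
#'
#' @param path bundle directory written by [writeSession()].
#' @return a [Session-class].
#' @export
readSession <- function(path) {
  metaPath <- file.path(path, "session.json")
  spikesPath <- file.path(path, "spikes.tsv")
  for (p in c(metaPath, spikesPath))
    if (!file.exists(p))
      stop("session bundle is missing required file: ", basename(p))
  meta <- jsonlite::read_json(metaPath, simplifyVector = FALSE)

  sp <- data.table::fread(spikesPath, sep = "\t",
                          colClasses = list(character = "unit_id"))
  wfPath <- file.path(path, "waveforms.tsv")
  wf <- if (file.exists(wfPath)) data.table::fread(wfPath, sep = "\t",
          colClasses = list(character = "unit_id")) else NULL

  units <- lapply(meta$units, function(um) {
    uid <- um$unit_id
    times <- sp$time_s[sp$unit_id == uid]
    m <- matrix(numeric(), 0, 0)
    if (!is.null(wf) && nrow(wf)) {
      w <- wf[wf$unit_id == uid, ]
      if (nrow(w))
        m <- matrix(w$amplitude[order(w$sample, w$channel)],
                    nrow = max(w$channel))
    }
    pos <- if (length(um$channel_positions))
      do.call(rbind, lapply(um$channel_positions, unlist))
    else matrix(numeric(), 0, 2)
    tr <- new("SpikeTrain", unitId = uid, times = as.numeric(times))
    v <- validObject(tr, test = TRUE)
    if (!isTRUE(v)) stop("invalid spike train: ", paste(v, collapse = "; "))
    Unit(tr, meanWaveform = m, waveformFs = um$waveform_fs,
         peakChannel = as.integer(um$peak_channel),
         channelPositions = pos, label = um$label)
  })

  lfp <- list()
  lfpPath <- file.path(path, "lfp.tsv")
  if (file.exists(lfpPath)) {
    lf <- data.table::fread(lfpPath, sep = "\t")
    fsList <- unlist(meta$lfp_fs)
    ids <- unlist(meta$lfp_channel_ids)
    lfp <- lapply(seq_along(ids), function(i)
      LFPChannel(lf[[ids[i]]], fs = fsList[i], channelId = ids[i]))
  }

  laser <- NULL
  laserPath <- file.path(path, "laser.tsv")
  if (file.exists(laserPath)) {
    lt <- data.table::fread(laserPath, sep = "\t")
    laser <- cbind(lt$onset_s, lt$duration_s)
  }

  Session(units = units, lfp = lfp, laserPulses = laser,
          duration = meta$duration, group = meta$group,
          metadata = meta$metadata)
}

#' Write an analysis result table
#'
#' Results are written as a TSV with one row per record; an empty result list
#' yields a header-only table. Writing is bit-stable for fixed inputs.
#'
#' @param results a data.frame (or object coercible to one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
  df <- as.data.frame(results)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read back a result table written by [writeResults()]
#' @param path file path.
#' @return data.frame.
#' @export
readResults <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Bin spike trains into counts
#'
#' Half-open bins `[t, t + binWidth)`; a spike exactly on a bin edge belongs
#' to the later bin. The number of bins is `floor((tEnd - tStart)/binWidth)`,
#' so spikes beyond the last full bin are not counted.
#'
#' @param trains a single spike-time vector / [SpikeTrain-class] / [Unit-class],
#'   or a list of them (one row per train).
#' @param binWidth bin width, seconds (default 0.025, the coactivation
#'   timescale used for assembly detection).
#' @param tStart,tEnd time range in seconds.
#' @return a [BinnedCounts-class] object.
#' @export
binSpikeCounts <- function(trains, binWidth = 0.025, tStart = 0, tEnd) {
  stopifnot(binWidth > 0, tEnd > tStart)
  if (!is.list(trains)) trains <- list(trains)
  nBins <- floor((tEnd - tStart) / binWidth + 1e-9)
  counts <- t(vapply(trains, function(tr) {
    t <- spikeTimes(tr)
    t <- t[t >= tStart & t < tStart + nBins * binWidth]
    tabulate(floor((t - tStart) / binWidth) + 1L, nbins = nBins)
  }, integer(nBins)))
  new("BinnedCounts", counts = counts, binWidth = binWidth,
      tStart = tStart, tEnd = tEnd)
}
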