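## S4 data model for a recording session: spike trains, units with mean
## waveforms and probe geometry, LFP channels, optional laser pulses.

#' @import methods
NULL

#' SpikeTrain: spike times of one unit
#'
#' Spike times are in seconds from session start, strictly increasing.
#'
#' @slot unitId character scalar identifier.
#' @slot times numeric vector of spike times (s), strictly increasing, >= 0.
#' @exportClass SpikeTrain
setClass("SpikeTrain",
         representation(unitId = "character", times = "numeric"),
         validity = function(object) {
           msg <- character()
           if (length(object@unitId) != 1L)
             msg <- c(msg, "unitId must be a single string")
           t <- object@times
           if (length(t) && any(t < 0))
             msg <- c(msg, sprintf("unit %s: negative spike times",
                                   object@unitId))
           if (length(t) > 1L && any(diff(t) <= 0))
             msg <- c(msg, sprintf(
               "unit %s: spike times not strictly increasing (duplicates or unsorted)",
               object@unitId))
           if (length(msg)) msg else TRUE
         })

#' Construct a SpikeTrain
#'
#' @param unitId unit identifier.
#' @param times numeric vector of spike times in seconds, strictly increasing.
#' @return a [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(unitId, times) {
  new("SpikeTrain", unitId = as.character(unitId), times = as.numeric(times))
}

#' Unit: spike train plus waveform and geometry
#'
#' @slot spikeTrain a [SpikeTrain-class].
#' @slot meanWaveform numeric matrix, channels x samples, arbitrary units
#'   (negative trough convention).
#' @slot waveformFs waveform sampling rate, Hz.
#' @slot peakChannel index of the channel with the largest negative
#'   deflection; the unit's estimated soma location.
#' @slot channelPositions numeric matrix, channels x 2, micrometres (may have
#'   zero rows when geometry is unknown).
#' @slot label one of "unclassified", "PYR", "INT", "PVI".
#' @exportClass Unit
setClass("Unit",
         representation(spikeTrain = "SpikeTrain", meanWaveform = "matrix",
                        waveformFs = "numeric", peakChannel = "integer",
                        channelPositions = "matrix", label = "character"),
         validity = function(object) {
           msg <- character()
           if (!object@label %in% c("unclassified", "PYR", "INT", "PVI"))
             msg <- c(msg, "label must be unclassified/PYR/INT/PVI")
           wf <- object@meanWaveform
           if (nrow(wf) > 0) {
             if (object@peakChannel < 1L || object@peakChannel > nrow(wf))
               msg <- c(msg, "peakChannel out of range")
             else if (which.min(apply(wf, 1, min)) != object@peakChannel)
               msg <- c(msg, "peakChannel is not the channel with the largest negative deflection")
           }
           if (nrow(object@channelPositions) > 0 &&
               nrow(object@channelPositions) != nrow(wf))
             msg <- c(msg, "channelPositions rows must match waveform channels")
           if (length(msg)) msg else TRUE
         })

#' Construct a Unit
#'
#' @param spikeTrain a [SpikeTrain-class] (or numeric spike-time vector).
#' @param meanWaveform channels x samples numeric matrix.
#' @param waveformFs waveform sampling rate in Hz.
#' @param peakChannel channel with largest negative deflection; computed from
#'   the waveform when missing.
#' @param channelPositions channels x 2 matrix of electrode coordinates (um).
#' @param label unit class label.
#' @param unitId identifier used when `spikeTrain` is a bare numeric vector.
#' @return a [Unit-class] object.
#' @export
Unit <- function(spikeTrain, meanWaveform = matrix(numeric(), 0, 0),
                 waveformFs = 30000, peakChannel = NA_integer_,
                 channelPositions = matrix(numeric(), 0, 2),
                 label = "unclassified", unitId = "u") {
  if (!is(spikeTrain, "SpikeTrain"))
    spikeTrain <- SpikeTrain(unitId, spikeTrain)
  meanWaveform <- as.matrix(meanWaveform)
  if (is.na(peakChannel))
    peakChannel <- if (nrow(meanWaveform)) which.min(apply(meanWaveform, 1, min)) else 1L
  new("Unit", spikeTrain = spikeTrain, meanWaveform = meanWaveform,
      waveformFs = as.numeric(waveformFs), peakChannel = as.integer(peakChannel),
      channelPositions = as.matrix(channelPositions), label = label)
}

#' LFPChannel: one local field potential trace
#'
#' @slot samples numeric vector, arbitrary units.
#' @slot fs sampling rate, Hz.
#' @slot channelId channel identifier.
#' @exportClass LFPChannel
setClass("LFPChannel",
         representation(samples = "numeric", fs = "numeric",
                        channelId = "character"),
         validity = function(object) {
           if (length(object@fs) != 1L || object@fs <= 0)
             "fs must be a positive scalar" else TRUE
         })

#' Construct an LFPChannel
#' @param samples numeric vector of field-potential samples.
#' @param fs sampling rate, Hz.
#' @param channelId identifier.
#' @export
LFPChannel <- function(samples, fs, channelId = "lfp1") {
  new("LFPChannel", samples = as.numeric(samples), fs = as.numeric(fs),
      channelId = as.character(channelId))
}

#' Session: container for one recording
#'
#' @slot units list of [Unit-class].
#' @slot lfp list of [LFPChannel-class] (possibly empty).
#' @slot laserPulses two-column matrix (onset s, duration s) or zero rows.
#' @slot duration session duration, seconds.
#' @slot group free-text group label (e.g. genotype).
#' @slot metadata named list of additional keys, preserved on I/O.
#' @exportClass Session
setClass("Session",
         representation(units = "list", lfp = "list", laserPulses = "matrix",
                        duration = "numeric", group = "character",
                        metadata = "list"),
         validity = function(object) {
           msg <- character()
           if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
           for (u in object@units) {
             if (!is(u, "Unit")) { msg <- c(msg, "units must be Unit objects"); break }
             t <- u@spikeTrain@times
             if (length(t) && (t[1] < 0 || t[length(t)] > object@duration))
               msg <- c(msg, sprintf("unit %s: spike times outside [0, duration]",
                                     u@spikeTrain@unitId))
           }
           for (ch in object@lfp)
             if (!is(ch, "LFPChannel")) { msg <- c(msg, "lfp must be LFPChannel objects"); break }
           if (nrow(object@laserPulses) && ncol(object@laserPulses) != 2L)
             msg <- c(msg, "laserPulses must have two columns (onset, duration)")
           if (length(msg)) msg else TRUE
         })

#' Construct a Session
#'
#' @param units list of [Unit-class] objects.
#' @param lfp list of [LFPChannel-class] objects.
#' @param laserPulses matrix with columns onset (s) and duration (s), or NULL.
#' @param duration session duration in seconds.
#' @param group group label (e.g. "control" / "mutant").
#' @param metadata named list, preserved verbatim by session I/O.
#' @return a [Session-class] object.
#' @export
Session <- function(units, lfp = list(), laserPulses = NULL, duration,
                    group = "unspecified", metadata = list()) {
  if (is.null(laserPulses)) laserPulses <- matrix(numeric(), 0, 2)
  laserPulses <- as.matrix(laserPulses)
  if (nrow(laserPulses)) colnames(laserPulses) <- c("onset", "duration")
  new("Session", units = units, lfp = lfp, laserPulses = laserPulses,
      duration = as.numeric(duration), group = as.character(group),
      metadata = metadata)
}

#' BinnedCounts: spike-count matrix
#'
#' Half-open bins [t, t + binWidth) covering [tStart, tStart + nBins*binWidth).
#'
#' @slot counts integer matrix, neurons x bins.
#' @slot binWidth bin width, seconds.
#' @slot tStart,tEnd requested range, seconds.
#' @exportClass BinnedCounts
setClass("BinnedCounts",
         representation(counts = "matrix", binWidth = "numeric",
                        tStart = "numeric", tEnd = "numeric"),
         validity = function(object) {
           msg <- character()
           if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
           nb <- floor((object@tEnd - object@tStart) / object@binWidth + 1e-9)
           if (ncol(object@counts) != nb)
             msg <- c(msg, "number of bins must be floor((tEnd - tStart)/binWidth)")
           if (length(msg)) msg else TRUE
         })

## --- accessors ------------------------------------------------------------

#' @describeIn Session-class list of units
#' @param session a Session.
#' @export
sessionUnits <- function(session) session@units

#' @describeIn Session-class list of LFP channels
#' @export
lfpChannels <- function(session) session@lfp

#' @describeIn Session-class laser pulse matrix (onset, duration)
#' @export
laserPulses <- function(session) session@laserPulses

#' @describeIn Session-class session duration (s)
#' @export
sessionDuration <- function(session) session@duration

#' @describeIn Session-class group label
#' @export
groupLabel <- function(session) session@group

#' Spike times of a SpikeTrain or Unit
#' @param x a SpikeTrain or Unit.
#' @return numeric vector of spike times (s).
#' @export
spikeTimes <- function(x) {
  if (is(x, "Unit")) x@spikeTrain@times
  else if (is(x, "SpikeTrain")) x@times
  else as.numeric(x)
}

#' Unit identifier
#' @param x a SpikeTrain or Unit.
#' @export
unitId <- function(x) {
  if (is(x, "Unit")) x@spikeTrain@unitId else x@unitId
}

#' Unit class labels of a session
#' @param session a Session.
#' @return character vector of labels, one per unit.
#' @export
unitLabels <- function(session) {
  vapply(session@units, function(u) u@label, character(1))
}

#' Replace unit labels
#' @param session a Session.
#' @param value character vector of labels, one per unit.
#' @export
`unitLabels<-` <- function(session, value) {
  stopifnot(length(value) == length(session@units))
  for (i in seq_along(session@units)) session@units[[i]]@label <- value[i]
  validObject(session)
  session
}

#' Count matrix of a BinnedCounts object
#' @param x a BinnedCounts.
#' @export
binnedMatrix <- function(x) x@counts

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain '%s': %d spikes", object@unitId,
              length(object@times)))
  if (length(object@times))
    cat(sprintf(" in [%.3f, %.3f] s", object@times[1],
                object@times[length(object@times)]))
  cat("\n")
})

setMethod("show", "Unit", function(object) {
  cat(sprintf("Unit '%s' [%s]: %d spikes, waveform %d ch x %d samples\n",
              object@spikeTrain@unitId, object@label,
              length(object@spikeTrain@times), nrow(object@meanWaveform),
              ncol(object@meanWaveform)))
})

setMethod("show", "Session", function(object) {
  labs <- table(factor(unitLabels(object),
                       levels = c("PYR", "INT", "PVI", "unclassified")))
  cat(sprintf("Session [%s]: %d units (%s), %d LFP channel(s), %d laser pulse(s), %.1f s\n",
              object@group, length(object@units),
              paste(sprintf("%s=%d", names(labs), labs), collapse = ", "),
              length(object@lfp), nrow(object@laserPulses), object@duration))
})

setMethod("show", "BinnedCounts", function(object) {
  cat(sprintf("BinnedCounts: %d neuron(s) x %d bins of %.3f s over [%g, %g)\n",
              nrow(object@counts), ncol(object@counts), object@binWidth,
              object@tStart, object@tEnd))
})
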