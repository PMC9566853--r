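## Group-level statistics (test-selection logic, circular permutation test,
## firing-rate tertiles) and end-to-end pipeline orchestration.

#' Two-group comparison with automatic test selection
#'
#' With more than 30 observations in each group a two-sided Welch's t-test
#' is used. For smaller groups, when both samples pass the Shapiro-Wilk
#' normality test (alpha = 0.05), Student's t-test is used for comparable
#' standard deviations (SD ratio <= 1.5) and Welch's otherwise; when either
#' sample fails normality, a two-sided Mann-Whitney U-test is used.
#'
#' @param a,b numeric sample vectors (each n >= 3).
#' @param sdRatioMax SD-comparability bound for Student vs Welch
#'   (default 1.5).
#' @return list with `testName`, `statistic`, `pValue`, `nA`, `nB`.
#' @export
chooseTest <- function(a, b, sdRatioMax = 1.5) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("each sample must have n >= 3")
  pick <- function() {
    if (length(a) > 30 && length(b) > 30) return("welch")
    swA <- stats::shapiro.test(a)$p.value
    swB <- stats::shapiro.test(b)$p.value
    if (swA > 0.05 && swB > 0.05) {
      r <- max(stats::sd(a), stats::sd(b)) /
        max(min(stats::sd(a), stats::sd(b)), .Machine$double.eps)
      if (r <= sdRatioMax) "student" else "welch"
    } else "mannwhitney"
  }
  kind <- pick()
  res <- switch(kind,
    welch = stats::t.test(a, b, var.equal = FALSE),
    student = stats::t.test(a, b, var.equal = TRUE),
    mannwhitney = suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)))
  list(testName = switch(kind, welch = "Welch's t-test",
                         student = "Student's t-test",
                         mannwhitney = "Mann-Whitney U-test"),
       statistic = unname(res$statistic), pValue = res$p.value,
       nA = length(a), nB = length(b))
}

#' Circular permutation test for a difference in preferred phase
#'
#' The statistic is the circular distance between the circular means of the
#' two groups; its null distribution is built by re-splitting the pooled
#' phases into groups of the original sizes. The conventional estimator
#' p = (1 + #(permuted >= observed)) / (nIter + 1) is the default;
#' `literal = TRUE` instead counts how often the observed distance exceeds
#' the permuted one (a significance-inverted quantity retained for
#' comparability).
#'
#' @param phasesA,phasesB phase samples, radians (each n >= 2).
#' @param nIter permutation iterations (default 10000).
#' @param seed RNG seed.
#' @param literal use the inverted counting direction (default FALSE).
#' @return list with `observed` (radians), `pValue`, `nIter`.
#' @export
circularPermutationTest <- function(phasesA, phasesB, nIter = 10000,
                                    seed = NULL, literal = FALSE) {
  stopifnot(length(phasesA) >= 2, length(phasesB) >= 2)
  if (!is.null(seed)) set.seed(seed)
  obs <- circDist(circMean(phasesA), circMean(phasesB))
  pool <- c(phasesA, phasesB)
  nA <- length(phasesA)
  if (max(circDist(pool, pool[1])) < .Machine$double.eps * 10)
    return(list(observed = 0, pValue = 1, nIter = nIter))
  perm <- vapply(seq_len(nIter), function(i) {
    idx <- sample.int(length(pool), nA)
    circDist(circMean(pool[idx]), circMean(pool[-idx]))
  }, numeric(1))
  p <- if (literal) sum(obs > perm) / nIter
       else (1 + sum(perm >= obs)) / (nIter + 1)
  list(observed = obs, pValue = p, nIter = nIter)
}

#' Firing-rate tertile subset
#'
#' Indices of the lowest or highest third (floor(n/3) units) of a rate
#' distribution, by rank with stable tie-breaking.
#'
#' @param rates numeric vector (n >= 3).
#' @param which "lowest" or "highest".
#' @return integer index vector of length floor(n/3).
#' @export
rateTertileSubset <- function(rates, which = c("lowest", "highest")) {
  which <- match.arg(which)
  n <- length(rates)
  stopifnot(n >= 3)
  k <- floor(n / 3)
  ord <- order(rates) # stable for ties
  if (which == "lowest") sort(ord[seq_len(k)]) else sort(ord[n - k + seq_len(k)])
}

#' Run the full analysis pipeline over sessions
#'
#' Per session: unit classification, optional optogenetic tagging, LFP band
#' power, spike-gamma coupling of INTs, monosynaptic connection detection,
#' INT-INT synchrony, and assembly detection. Sessions are aggregated one
#' value per session (mouse averages) and the two groups compared per
#' endpoint with [chooseTest()].
#'
#' @param sessions list of [Session-class] objects (each with a group label).
#' @param bands named list of frequency bands, Hz.
#' @param couplingBand band used for spike-gamma coupling (default high
#'   gamma).
#' @param nShuffles shuffle count for the coupling test.
#' @param seed RNG seed.
#' @param outDir optional directory: per-cell tables and a JSON summary are
#'   written there.
#' @return list with `perSession` (data.frame of session-level endpoints),
#'   `groupTests` (data.frame), `connections` (per-pair table), and
#'   `failures` (named list of stage errors, if any).
#' @export
runPipeline <- function(sessions,
                        bands = list(theta = c(6, 12), lowGamma = c(20, 40),
                                     highGamma = c(60, 90)),
                        couplingBand = c(60, 90), nShuffles = 200,
                        seed = 1L, outDir = NULL) {
  if (!length(sessions)) stop("empty session list")
  set.seed(seed)
  failures <- list()
  perSession <- list()
  connTables <- list()

  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    row <- list(session = si, group = groupLabel(s))
    res <- tryCatch({
      trains <- lapply(sessionUnits(s), spikeTimes)
      feats <- do.call(rbind, lapply(sessionUnits(s), function(u)
        as.data.frame(waveformFeatures(u))))
      labs <- classifyUnits(feats, seed = seed)
      ## keep pre-existing PVI labels if present
      pvi <- unitLabels(s) == "PVI"
      labs[pvi] <- "PVI"
      unitLabels(s) <- labs
      isInt <- labs %in% c("INT", "PVI")
      rates <- vapply(trains, length, numeric(1)) / sessionDuration(s)
      row$meanRatePyr <- mean(rates[!isInt])
      row$meanRateInt <- mean(rates[isInt])

      ab <- NULL
      if (length(lfpChannels(s))) {
        lfp <- preprocessLFP(lfpChannels(s)[[1]])
        psd <- powerSpectralDensity(lfp)
        for (bn in names(bands))
          row[[paste0("power_", bn)]] <- bandPower(psd, bands[[bn]])
        ab <- bandpassHilbert(lfp, couplingBand)
      }
      if (!is.null(ab)) {
        sigInt <- vapply(which(isInt), function(i) {
          if (length(trains[[i]]) < 2) return(NA)
          couplingSignificance(trains[[i]], ab,
                               nShuffles = nShuffles)$significant
        }, logical(1))
        row$propIntCoupled <- mean(sigInt, na.rm = TRUE)
      }

      conns <- detectConnections(s)
      connTables[[si]] <- cbind(session = si, group = groupLabel(s), conns)
      conn <- conns[which(conns$connected), , drop = FALSE]
      row$nConnections <- nrow(conn)
      row$nPairsTested <- sum(conns$tested)
      row$meanTransmission <- if (nrow(conn)) mean(conn$transmissionProb)
                              else NA_real_

      intIdx <- which(isInt)
      if (length(intIdx) >= 2) {
        prs <- utils::combn(intIdx, 2)
        sync <- vapply(seq_len(ncol(prs)), function(j)
          intIntSynchrony(trains[[prs[1, j]]], trains[[prs[2, j]]]),
          numeric(1))
        row$intSynchrony <- mean(sync)
      }

      pyrIdx <- which(!isInt)
      if (length(pyrIdx) >= 10) {
        bc <- binSpikeCounts(trains[pyrIdx], binWidth = 0.025,
                             tEnd = sessionDuration(s))
        pats <- detectPatterns(bc, seed = seed)
        row$nAssemblies <- ncol(pats$weights)
        if (ncol(pats$weights) > 0) {
          tr <- activationStrength(pats, trains[pyrIdx],
                                   duration = sessionDuration(s))
          ev <- lapply(tr, activationEvents)
          row$assemblyEventRate <- mean(vapply(ev, `[[`, numeric(1),
                                               "eventRate"))
          row$assemblyStrength <- mean(vapply(ev, function(e)
            e$meanEventStrength, numeric(1)), na.rm = TRUE)
        }
      }
      row
    }, error = function(e) {
      failures[[as.character(si)]] <<- conditionMessage(e)
      row
    })
    perSession[[si]] <- res
  }

  perSession <- data.table::rbindlist(lapply(perSession, as.data.frame),
                                      fill = TRUE)
  perSession <- as.data.frame(perSession)

  groups <- unique(perSession$group)
  groupTests <- NULL
  if (length(groups) == 2) {
    endpoints <- setdiff(names(perSession), c("session", "group"))
    groupTests <- do.call(rbind, lapply(endpoints, function(ep) {
      a <- perSession[[ep]][perSession$group == groups[1]]
      b <- perSession[[ep]][perSession$group == groups[2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 3 || length(b) < 3) return(NULL)
      ct <- tryCatch(chooseTest(a, b), error = function(e) NULL)
      if (is.null(ct)) return(NULL)
      data.frame(endpoint = ep, groupA = groups[1], groupB = groups[2],
                 meanA = mean(a), meanB = mean(b), test = ct$testName,
                 statistic = ct$statistic, pValue = ct$pValue)
    }))
  }

  connections <- if (length(connTables))
    do.call(rbind, connTables) else NULL

  out <- list(perSession = perSession, groupTests = groupTests,
              connections = connections, failures = failures)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeResults(perSession, file.path(outDir, "per_session.tsv"))
    if (!is.null(groupTests))
      writeResults(groupTests, file.path(outDir, "group_tests.tsv"))
    if (!is.null(connections))
      writeResults(connections, file.path(outDir, "connections.tsv"))
    jsonlite::write_json(
      list(nSessions = length(sessions),
           groups = as.list(table(perSession$group)),
           failures = failures),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
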