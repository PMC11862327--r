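#' Simulate an R-R interval series with known autonomic structure
#'
#' Generates a beat sequence whose instantaneous R-R interval is
#' `meanRR + lfAmp*sin(2*pi*lfFreq*t) + hfAmp*sin(2*pi*respFreq*t) + noise`,
#' realized beat by beat: each modulator is sampled at the onset of the beat
#' it lengthens or shortens. The low-frequency term emulates baroreflex
#' (Mayer-wave) modulation near 0.1 Hz, the high-frequency term respiratory
#' sinus arrhythmia at the respiration frequency, and the broadband term
#' unstructured beat-to-beat jitter.
#'
#' The generative amplitudes are stored in `meta(x)$truth` so downstream
#' estimators can be checked against ground truth: a sinusoidal modulation of
#' amplitude A contributes A^2/2 ms^2 of band power and A^2/2 to the R-R
#' variance.
#'
#' @param duration recording length in seconds.
#' @param meanRR mean R-R interval in ms; must exceed `2*(lfAmp+hfAmp)` so
#'   intervals stay positive.
#' @param lfAmp low-frequency modulation amplitude (ms).
#' @param lfFreq low-frequency modulation rate (Hz), default 0.1.
#' @param hfAmp respiratory modulation amplitude (ms).
#' @param respFreq respiration frequency (Hz), within \[0.15, 0.4\].
#' @param broadbandSD white beat-to-beat jitter SD (ms).
#' @param seed optional integer seed; the same seed reproduces the series
#'   exactly.
#' @return an [RRSeries] whose onsets start at 0 s.
#' @examples
#' rr <- simulateRRSeries(300, meanRR = 1000, hfAmp = 20, seed = 1)
#' sdrr(rejectArtifacts(rr))
#' @export
simulateRRSeries <- function(duration = 1800, meanRR = 850, lfAmp = 30,
                             lfFreq = 0.1, hfAmp = 25, respFreq = 0.25,
                             broadbandSD = 15, seed = NULL) {
  stopIfNot(duration > 0, "duration must be positive")
  stopIfNot(meanRR > 2 * (lfAmp + hfAmp),
            "meanRR must exceed 2*(lfAmp + hfAmp) to keep intervals positive")
  stopIfNot(respFreq >= 0.15 && respFreq <= 0.4,
            "respFreq must lie in [0.15, 0.4] Hz")
  stopIfNot(lfAmp >= 0 && hfAmp >= 0 && broadbandSD >= 0,
            "amplitudes must be non-negative")
  withSeed(seed, {
    nMax <- ceiling(duration / (meanRR / 1000) * 1.5) + 10L
    onsets <- numeric(nMax)
    rr <- numeric(nMax)
    t <- 0
    i <- 0L
    while (t < duration) {
      i <- i + 1L
      x <- meanRR + lfAmp * sin(2 * pi * lfFreq * t) +
        hfAmp * sin(2 * pi * respFreq * t)
      if (broadbandSD > 0) x <- x + rnorm(1L, 0, broadbandSD)
      if (x <= 0) stop("configuration produced a non-positive R-R interval",
                       call. = FALSE)
      onsets[i] <- t
      rr[i] <- x
      t <- t + x / 1000
    }
    RRSeries(onsets[seq_len(i)], rr[seq_len(i)],
             meta = list(truth = list(
               meanRR = meanRR, lfAmp = lfAmp, lfFreq = lfFreq,
               hfAmp = hfAmp, respFreq = respFreq,
               broadbandSD = broadbandSD, duration = duration)))
  })
}

#' Analytic SDRR and RMSSD of the R-R generator
#'
#' Closed-form population values of the time-domain indices implied by the
#' generator's sinusoid-plus-noise model. A sinusoid of amplitude A
#' contributes A^2/2 to the interval variance; its successive-difference
#' contribution is `2 A^2 sin^2(pi f tau)` where `tau = meanRR/1000` is the
#' mean beat spacing in seconds.
#'
#' @param meanRR,lfAmp,lfFreq,hfAmp,respFreq,broadbandSD generator
#'   parameters, see [simulateRRSeries()].
#' @return population SDRR (resp. RMSSD) in ms.
#' @export
analyticSDRR <- function(meanRR = 850, lfAmp = 30, lfFreq = 0.1, hfAmp = 25,
                         respFreq = 0.25, broadbandSD = 15) {
  sqrt(lfAmp^2 / 2 + hfAmp^2 / 2 + broadbandSD^2)
}

#' @rdname analyticSDRR
#' @export
analyticRMSSD <- function(meanRR = 850, lfAmp = 30, lfFreq = 0.1, hfAmp = 25,
                          respFreq = 0.25, broadbandSD = 15) {
  tau <- meanRR / 1000
  sqrt(2 * broadbandSD^2 +
       2 * lfAmp^2 * sin(pi * lfFreq * tau)^2 +
       2 * hfAmp^2 * sin(pi * respFreq * tau)^2)
}

# Ricker (Mexican-hat) QRS template: positive central peak, zero mean.
rickerTemplate <- function(samplingRate, width = 0.08, amplitude = 1000) {
  sigma <- width / 6
  tt <- seq(-3 * sigma, 3 * sigma, by = 1 / samplingRate)
  amplitude * (1 - (tt / sigma)^2) * exp(-tt^2 / (2 * sigma^2))
}

#' Synthesize a single-lead ECG from an R-R series
#'
#' Places one QRS-like template (a Ricker wavelet of ~80 ms width, positive
#' R peak at its centre) per beat at the cumulative beat times, then adds 50
#' Hz powerline interference, slow baseline wander (< 0.5 Hz) and sparse
#' movement artifacts modelled as 1-3 s saturating square pulses that replace
#' the signal. The exact beat times are returned as ground truth.
#'
#' @param rr an [RRSeries] (e.g. from [simulateRRSeries()]).
#' @param samplingRate output rate in Hz, at least 250.
#' @param qrsAmplitude R-peak amplitude (µV).
#' @param qrsWidth QRS template width (s).
#' @param powerlineAmp 50 Hz interference amplitude (µV).
#' @param powerlineFreq mains frequency (Hz).
#' @param baselineWanderAmp slow wander amplitude (µV), spread over a few
#'   sub-0.5 Hz sinusoids.
#' @param artifactRate movement artifacts per minute.
#' @param artifactAmp artifact saturation level (µV).
#' @param seed optional integer seed.
#' @return a list with elements `recording` ([EcgRecording]) and `truePeaks`
#'   (numeric, seconds).
#' @examples
#' rr <- simulateRRSeries(20, seed = 1)
#' sim <- simulateEcg(rr, samplingRate = 500, seed = 1)
#' sim$recording
#' @export
simulateEcg <- function(rr, samplingRate = 5000, qrsAmplitude = 1000,
                        qrsWidth = 0.08, powerlineAmp = 50,
                        powerlineFreq = 50, baselineWanderAmp = 200,
                        artifactRate = 0, artifactAmp = 2000, seed = NULL) {
  stopIfNot(is(rr, "RRSeries"), "rr must be an RRSeries")
  stopIfNot(length(rr) > 0L, "rr contains zero beats; nothing to synthesize")
  stopIfNot(samplingRate >= 250,
            "samplingRate below 250 Hz cannot resolve the QRS complex")
  stopIfNot(qrsAmplitude >= 0 && powerlineAmp >= 0 &&
            baselineWanderAmp >= 0 && artifactAmp >= 0 && artifactRate >= 0,
            "amplitudes and rates must be non-negative")
  onsets <- rrOnsets(rr)
  ints <- rrIntervals(rr)
  # 0.3 s lead-in/out so the first and last QRS are fully rendered
  peaks <- 0.3 + c(onsets, onsets[length(onsets)] + ints[length(ints)] / 1000)
  total <- peaks[length(peaks)] + 0.3
  n <- ceiling(total * samplingRate)
  withSeed(seed, {
    x <- numeric(n)
    tpl <- rickerTemplate(samplingRate, qrsWidth, qrsAmplitude)
    half <- (length(tpl) - 1L) %/% 2L
    idx <- round(peaks * samplingRate) + 1L
    for (i in idx) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      x[lo:hi] <- x[lo:hi] + tpl[(lo - i + half + 1L):(hi - i + half + 1L)]
    }
    tt <- (seq_len(n) - 1L) / samplingRate
    if (powerlineAmp > 0) {
      x <- x + powerlineAmp * sin(2 * pi * powerlineFreq * tt + runif(1, 0, 2 * pi))
    }
    if (baselineWanderAmp > 0) {
      wf <- c(0.06, 0.15, 0.31)
      wa <- baselineWanderAmp * c(0.6, 0.3, 0.1)
      for (k in seq_along(wf)) {
        x <- x + wa[k] * sin(2 * pi * wf[k] * tt + runif(1, 0, 2 * pi))
      }
    }
    if (artifactRate > 0 && artifactAmp > 0) {
      nArt <- rpois(1L, artifactRate * total / 60)
      for (a in seq_len(nArt)) {
        start <- runif(1, 0, max(total - 3, 0.1))
        len <- runif(1, 1, 3)
        lo <- max(1L, round(start * samplingRate))
        hi <- min(n, round((start + len) * samplingRate))
        x[lo:hi] <- sample(c(-1, 1), 1L) * artifactAmp
      }
    }
    meta <- rr@meta
    meta$truth$truePeaks <- peaks
    list(recording = EcgRecording(x, samplingRate, t0 = 0, meta = meta),
         truePeaks = peaks)
  })
}

#' Define a randomized crossover study design
#'
#' Lays out the 2 (stimulation: taVNS/sham) x 2 (side: left/right) x 3
#' (phase: baseline/stimulation/caloric_load) within-subject design: every
#' subject completes 4 sessions (all condition-by-side combinations) and the
#' stimulation side is held fixed across sessions 1-2 and switched for
#' sessions 3-4, with condition order randomized within each side pair.
#'
#' `effects` is a data frame with columns `index` ("hr", "rmssd" or "sdrr"),
#' `condition` ("taVNS", "sham" or "both") and `phase` ("stimulation",
#' "caloric_load" or "both"), and `delta` — the additive ground-truth shift
#' of that index (bpm for hr, ms otherwise) in the matching phases relative
#' to baseline. The default table mirrors a stimulation-induced heart-rate
#' drop of about -0.8 bpm, a caloric-load rise of about +3.3 bpm, and a
#' taVNS-specific RMSSD reduction of about -4.5 ms.
#'
#' @param nSubjects number of participants (default 36).
#' @param effects ground-truth effect table (see Details); `NULL` for none.
#' @param phaseDuration duration of each phase in seconds (default 1800).
#' @param seed integer seed driving the side/order randomization.
#' @return a list of class `StudyDesign`: `sessions` (one row per
#'   subject x session x phase) plus the arguments.
#' @export
studyDesign <- function(nSubjects = 36, effects = defaultEffectTable(),
                        phaseDuration = 1800, seed = NULL) {
  stopIfNot(nSubjects >= 1, "need at least one subject")
  stopIfNot(phaseDuration > 0, "phaseDuration must be positive")
  if (!is.null(effects)) {
    stopIfNot(all(c("index", "condition", "phase", "delta") %in%
                  names(effects)), "malformed effect table")
    stopIfNot(all(effects$index %in% c("hr", "rmssd", "sdrr")),
              "effect indices must be hr, rmssd or sdrr")
  }
  phases <- c("baseline", "stimulation", "caloric_load")
  withSeed(seed, {
    rows <- lapply(seq_len(nSubjects), function(s) {
      firstSide <- sample(c("left", "right"), 1L)
      sides <- c(firstSide, firstSide, setdiff(c("left", "right"), firstSide)[c(1, 1)])
      conds <- c(sample(c("taVNS", "sham")), sample(c("taVNS", "sham")))
      data.frame(subject = s, session = rep(1:4, each = 3L),
                 condition = rep(conds, each = 3L),
                 side = rep(sides, each = 3L),
                 phase = rep(phases, times = 4L),
                 stringsAsFactors = FALSE)
    })
    structure(list(sessions = do.call(rbind, rows), nSubjects = nSubjects,
                   effects = effects, phaseDuration = phaseDuration,
                   seed = seed),
              class = "StudyDesign")
  })
}

#' @rdname studyDesign
#' @export
defaultEffectTable <- function() {
  data.frame(
    index = c("hr", "hr", "rmssd", "rmssd"),
    condition = c("both", "both", "taVNS", "taVNS"),
    phase = c("stimulation", "caloric_load", "stimulation", "caloric_load"),
    delta = c(-0.82, 3.28, -4.5, -4.5),
    stringsAsFactors = FALSE
  )
}

# Shift generator parameters so the analytic value of each targeted index
# moves by exactly `delta` in this phase. HR shifts remap meanRR; RMSSD and
# SDRR shifts are realized through the respiratory amplitude (vagal
# withdrawal), falling back to the broadband term when hfAmp alone cannot
# absorb the shift.
applyPhaseEffects <- function(params, effects, condition, phase) {
  if (is.null(effects) || phase == "baseline") return(params)
  sel <- effects[(effects$condition %in% c(condition, "both")) &
                 (effects$phase %in% c(phase, "both")), , drop = FALSE]
  for (k in seq_len(nrow(sel))) {
    idx <- sel$index[k]
    delta <- sel$delta[k]
    if (idx == "hr") {
      hr <- 60000 / params$meanRR + delta
      stopIfNot(hr > 0, "heart-rate effect produced a non-positive rate")
      params$meanRR <- 60000 / hr
    } else if (idx == "rmssd") {
      cur <- analyticRMSSD(params$meanRR, params$lfAmp, params$lfFreq,
                           params$hfAmp, params$respFreq, params$broadbandSD)
      target <- cur + delta
      stopIfNot(target > 0, "RMSSD effect produced a non-positive target")
      tau <- params$meanRR / 1000
      lfTerm <- 2 * params$lfAmp^2 * sin(pi * params$lfFreq * tau)^2
      hfScale <- 2 * sin(pi * params$respFreq * tau)^2
      rest <- target^2 - 2 * params$broadbandSD^2 - lfTerm
      if (rest >= 0) {
        params$hfAmp <- sqrt(rest / hfScale)
      } else {
        params$hfAmp <- 0
        rest2 <- target^2 - lfTerm
        stopIfNot(rest2 >= 0,
                  "RMSSD effect not realizable with these base parameters")
        params$broadbandSD <- sqrt(rest2 / 2)
      }
    } else if (idx == "sdrr") {
      cur <- analyticSDRR(params$meanRR, params$lfAmp, params$lfFreq,
                          params$hfAmp, params$respFreq, params$broadbandSD)
      target <- cur + delta
      stopIfNot(target > 0, "SDRR effect produced a non-positive target")
      sc <- target / cur
      params$lfAmp <- params$lfAmp * sc
      params$hfAmp <- params$hfAmp * sc
      params$broadbandSD <- params$broadbandSD * sc
    }
  }
  stopIfNot(params$meanRR > 2 * (params$lfAmp + params$hfAmp),
            "effect table drove R-R intervals non-positive")
  params
}

#' Generate a full synthetic crossover study
#'
#' Draws per-subject physiology (mean heart rate uniform in 60-80 bpm,
#' respiration frequency uniform in 0.18-0.33 Hz, log-normal variation of
#' the modulation amplitudes), adds session- and phase-level variability,
#' applies the design's ground-truth effect table to the generative
#' parameters of the stimulation and caloric-load phases, and simulates one
#' R-R series — optionally rendered to a raw ECG — per
#' subject x session x phase.
#'
#' @param design a [studyDesign()] object.
#' @param signal `"rr"` to return R-R series directly (fast; ground-truth
#'   beat sequence) or `"ecg"` to synthesize raw ECG waveforms.
#' @param samplingRate,powerlineAmp,baselineWanderAmp,artifactRate ECG
#'   rendering parameters, passed to [simulateEcg()] when `signal = "ecg"`.
#' @param seed integer root seed; subject/session draws are derived from it.
#' @param dir optional directory: when given (with `signal = "ecg"`), each
#'   phase is written as a WFDB record plus a `manifest.csv` and a
#'   `ground_truth.json`.
#' @param format on-disk format, `"wfdb"` or `"edf"`.
#' @return a list of class `StudySimulation`: `sessions` manifest (one row
#'   per phase, with a `key` into `series`), `series` (named list of
#'   [RRSeries] or [EcgRecording]), `truth` (effect table and per-phase
#'   generative parameters).
#' @examples
#' des <- studyDesign(nSubjects = 2, phaseDuration = 400, seed = 1)
#' sim <- simulateStudy(des, seed = 1)
#' head(sim$sessions)
#' @export
simulateStudy <- function(design, signal = c("rr", "ecg"),
                          samplingRate = 5000, powerlineAmp = 50,
                          baselineWanderAmp = 200, artifactRate = 0,
                          seed = NULL, dir = NULL, format = c("wfdb", "edf")) {
  stopIfNot(inherits(design, "StudyDesign"), "design must be a StudyDesign")
  signal <- match.arg(signal)
  format <- match.arg(format)
  sess <- design$sessions
  sess$key <- sprintf("s%02d_se%d_%s", sess$subject, sess$session, sess$phase)
  sess$file <- NA_character_
  seeds <- deriveSeeds(seed, c("subjects", sess$key))
  nS <- design$nSubjects
  subjectBase <- withSeed(seeds[["subjects"]], {
    lapply(seq_len(nS), function(s) list(
      meanRR = 60000 / runif(1, 60, 80),
      lfAmp = 30 * exp(rnorm(1, 0, 0.15)),
      lfFreq = 0.1,
      hfAmp = 25 * exp(rnorm(1, 0, 0.15)),
      respFreq = runif(1, 0.18, 0.33),
      broadbandSD = 15 * exp(rnorm(1, 0, 0.15))
    ))
  })
  series <- vector("list", nrow(sess))
  names(series) <- sess$key
  truthParams <- vector("list", nrow(sess))
  names(truthParams) <- sess$key
  for (i in seq_len(nrow(sess))) {
    key <- sess$key[i]
    sub <- deriveSeeds(seeds[[key]], c("jitter", "rr", "ecg"))
    p <- subjectBase[[sess$subject[i]]]
    p <- withSeed(sub[["jitter"]], {
      # phase-level physiological drift, identical in law across conditions
      p$meanRR <- p$meanRR + rnorm(1, 0, 15)
      p$hfAmp <- p$hfAmp * exp(rnorm(1, 0, 0.10))
      p$lfAmp <- p$lfAmp * exp(rnorm(1, 0, 0.10))
      p$broadbandSD <- p$broadbandSD * exp(rnorm(1, 0, 0.10))
      p
    })
    p <- applyPhaseEffects(p, design$effects, sess$condition[i], sess$phase[i])
    rr <- simulateRRSeries(design$phaseDuration, meanRR = p$meanRR,
                           lfAmp = p$lfAmp, lfFreq = p$lfFreq,
                           hfAmp = p$hfAmp, respFreq = p$respFreq,
                           broadbandSD = p$broadbandSD,
                           seed = sub[["rr"]])
    rr@meta <- c(rr@meta, sess[i, c("subject", "session", "condition",
                                    "side", "phase")])
    truthParams[[key]] <- p
    if (signal == "ecg") {
      sim <- simulateEcg(rr, samplingRate = samplingRate,
                         powerlineAmp = powerlineAmp,
                         baselineWanderAmp = baselineWanderAmp,
                         artifactRate = artifactRate, seed = sub[["ecg"]])
      series[[key]] <- sim$recording
    } else {
      series[[key]] <- rr
    }
  }
  out <- structure(list(sessions = sess, series = series,
                        truth = list(effects = design$effects,
                                     params = truthParams),
                        signal = signal, seed = seed),
                   class = "StudySimulation")
  if (!is.null(dir)) {
    stopIfNot(signal == "ecg", "on-disk export requires signal = 'ecg'")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(sess))) {
      f <- file.path(dir, paste0(sess$key[i], if (format == "wfdb") ".hea"
                                 else ".edf"))
      writeEcg(series[[sess$key[i]]], f, format = format)
      out$sessions$file[i] <- basename(f)
    }
    write.csv(out$sessions, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(effects = design$effects,
           params = truthParams,
           seed = seed),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
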