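# Shared fixtures: everything is generated in code at test time.

stdConfig <- function() defaultConfig()
stdAcq <- function() defaultConfig()$acquisition
stdGeom <- function() VoxelGeometry(40, 12, 28)

# noiseless single-resonance FID at the default acquisition
lorentzFid <- function(ppm = 8.0, conc = 5, fwhm = 12, amplitude = 1,
                       noiseSd = 0, seed = NULL, lineshape = "lorentzian") {
  simulateFID(list(PeakSpec(ppm, amplitude, fwhm, lineshape)), conc,
              stdGeom(), stdAcq(), noiseSd = noiseSd, seed = seed)
}

# a small, fully valid cohort table written to a temp CSV
writeTempCohort <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

smallCohortDf <- function() {
  data.frame(
    subject_id = c("a1", "a2", "a3", "a4"),
    sex = c("male", "male", "female", "male"),
    group = c("control", "elite", "control", "elite"),
    category = c("control", "explosive", "control", "endurance"),
    discipline = c("untrained", "sprint", "untrained", "marathon"),
    best_distance_m = c(NA, 100, NA, 42195),
    carnosine_left_mM = c(4.2, 6.5, 3.1, 3.4),
    carnosine_right_mM = c(NA, 6.9, NA, 3.8),
    stringsAsFactors = FALSE)
}
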