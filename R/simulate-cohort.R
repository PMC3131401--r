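#' Simulate a study cohort with known fiber-type ground truth
#'
#' Draws one subject table with the study's statistical structure. Per
#' configured cell (sex x group x category) each subject receives a true
#' percent fast-twitch (type-II) fiber area from a scaled Beta distribution,
#' a true carnosine concentration that is affine in that area (FT fibers
#' carry `ft_st_ratio` times the carnosine of ST fibers), rescaled so the
#' cell mean and SD of the *reported* concentration match the configured
#' values in expectation, and one or two leg measurements equal to the truth
#' times lognormal measurement noise with coefficient of variation
#' `measurement_cv` (mean-one, so measurements are unbiased and positive).
#'
#' Controls are measured in one leg, athletes bilaterally; the bilateral
#' mean halves measurement variance, which the rescaling accounts for.
#'
#' @param config configuration list with a `cohort` block (see
#'   [defaultConfig()]).
#' @param seed integer seed; identical config + seed give an identical
#'   cohort.
#' @return a data.frame with columns `subject_id`, `sex`, `group`,
#'   `category`, `discipline`, `best_distance_m`, `carnosine_left_mM`,
#'   `carnosine_right_mM`, `carnosine_mean_mM`, plus the ground-truth
#'   columns `ft_area_true_pct` and `carnosine_true_mM`.
#' @examples
#' coh <- simulateCohort(defaultConfig(), seed = 1)
#' nrow(coh)  # 163 with the default cells
#' @export
simulateCohort <- function(config = defaultConfig(), seed = NULL) {
  cc <- config$cohort
  if (is.null(cc) || is.null(cc$cells) || !length(cc$cells))
    stop("empty cohort config: no cells defined")
  ratio <- cc$ft_st_ratio
  if (is.null(ratio) || ratio <= 1) stop("'ft_st_ratio' must be > 1")
  cv <- cc$measurement_cv
  if (is.null(cv) || cv < 0) stop("'measurement_cv' must be >= 0")
  k <- cc$ft_area_beta_concentration

  withSeed(seed, {
    rows <- lapply(cc$cells, function(cell) {
      n <- as.integer(cell$n)
      if (is.na(n) || n < 0) stop("cell 'n' must be >= 0")
      if (n == 0L) return(NULL)
      if (is.null(cell$sd_mm) || cell$sd_mm <= 0)
        stop("cell 'sd_mm' must be > 0")
      mu <- cc$ft_center[[cell$category]]
      if (is.null(mu)) stop("no ft_center configured for category ",
                            cell$category)
      f <- stats::rbeta(n, mu * k, (1 - mu) * k)
      raw <- 1 + (ratio - 1) * f
      rawMean <- 1 + (ratio - 1) * mu
      rawSd <- (ratio - 1) * sqrt(mu * (1 - mu) / (k + 1))
      # target the *reported* SD: remove the measurement-noise share
      # (halved for bilateral means) from the between-subject spread
      legFactor <- if (isTRUE(cell$both_legs)) 0.5 else 1
      measVar <- (cell$mean_mm * cv)^2 * legFactor
      trueSd <- sqrt(max(cell$sd_mm^2 - measVar, (0.25 * cell$sd_mm)^2))
      truth <- cell$mean_mm + (raw - rawMean) * trueSd / rawSd
      truth <- pmax(truth, 0.05 * cell$mean_mm)
      legNoise <- function() {
        if (cv == 0) return(rep(1, n))
        s <- sqrt(log(1 + cv^2))
        stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
      }
      left <- truth * legNoise()
      right <- if (isTRUE(cell$both_legs)) truth * legNoise() else
        rep(NA_real_, n)
      data.frame(sex = cell$sex, group = cell$group,
                 category = cell$category,
                 discipline = if (is.null(cell$discipline)) NA_character_
                              else cell$discipline,
                 best_distance_m = NA_real_,
                 carnosine_left_mM = left, carnosine_right_mM = right,
                 ft_area_true_pct = 100 * f, carnosine_true_mM = truth,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    out$carnosine_mean_mM <- rowMeans(
      cbind(out$carnosine_left_mM, out$carnosine_right_mM), na.rm = TRUE)
    out
  })
}

#' Simulate a biopsy calibration set
#'
#' Percent type-II fiber areas drawn from the control Beta distribution and
#' carnosine generated from the configured linear calibration truth plus
#' Gaussian residual noise; with the default residual SD an n = 12 set shows
#' a Pearson correlation around 0.714.
#'
#' @param config configuration list with a `calibration` block.
#' @param n number of biopsy subjects; `NULL` takes the configured value
#'   (12).
#' @param seed integer seed.
#' @return data.frame with `subject_id`, `ft_area_pct`, `carnosine_mM`.
#' @export
simulateCalibrationSet <- function(config = defaultConfig(), n = NULL,
                                   seed = NULL) {
  cal <- config$calibration
  if (is.null(cal)) stop("config missing calibration block")
  if (is.null(n)) n <- cal$n_subjects
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("'n' must be >= 3")
  mu <- config$cohort$ft_center$control
  k <- cal$ft_area_beta_concentration
  withSeed(seed, {
    x <- 100 * stats::rbeta(n, mu * k, (1 - mu) * k)
    y <- cal$intercept_mm + cal$slope_mm_per_pct * x +
      stats::rnorm(n, 0, cal$residual_sd_mm)
    data.frame(subject_id = sprintf("B%02d", seq_len(n)),
               ft_area_pct = x, carnosine_mM = pmax(y, 0.1),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a panel of elite runners ranked by best distance
#'
#' Z-scores are generated from the configured ground-truth sigmoid evaluated
#' at each runner's best distance plus Gaussian noise, and carnosine is
#' back-computed from the Z-score through the sex-matched reference mean and
#' SD.
#'
#' @param config configuration list with `sigmoid` and `cohort$reference`
#'   blocks.
#' @param distances best running distances in m (> 0); default: four runners
#'   at each configured event distance.
#' @param sexes `"male"`/`"female"` per runner (recycled; default all male).
#' @param seed integer seed.
#' @param zNoiseSd Z-score noise SD; `NULL` takes the configured value, 0
#'   gives exact sigmoid evaluations.
#' @return data.frame shaped like [simulateCohort()] output plus `z_score`.
#' @export
simulateRunnerPanel <- function(config = defaultConfig(), distances = NULL,
                                sexes = "male", seed = NULL,
                                zNoiseSd = NULL) {
  sg <- config$sigmoid
  if (is.null(sg)) stop("config missing sigmoid block")
  if (is.null(distances))
    distances <- rep(unlist(sg$distances_m), each = 4L)
  if (any(is.na(distances)) || any(distances <= 0))
    stop("all distances must be > 0")
  if (is.null(zNoiseSd)) zNoiseSd <- sg$z_noise_sd
  truth <- SigmoidModel(sg$top, sg$bottom, sg$d50_m, sg$hill)
  n <- length(distances)
  sexes <- rep_len(sexes, n)
  refs <- config$cohort$reference
  withSeed(seed, {
    z <- predictZ(truth, distances)
    if (zNoiseSd > 0) z <- z + stats::rnorm(n, 0, zNoiseSd)
    refMean <- vapply(sexes, function(s) refs[[s]]$mean_mm, numeric(1))
    refSd <- vapply(sexes, function(s) refs[[s]]$sd_mm, numeric(1))
    carn <- pmax(refMean + z * refSd, 0.1)
    category <- ifelse(distances <= 400, "explosive",
                       ifelse(distances >= 3000, "endurance", "mixed"))
    data.frame(subject_id = sprintf("R%03d", seq_len(n)), sex = sexes,
               group = "elite", category = category,
               discipline = sprintf("%gm", distances),
               best_distance_m = as.numeric(distances),
               carnosine_left_mM = carn, carnosine_right_mM = NA_real_,
               carnosine_mean_mM = carn, z_score = z,
               stringsAsFactors = FALSE)
  })
}
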