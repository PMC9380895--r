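## Synthetic gait cohorts: trait-driven sinusoidal limb kinematics plus
## BFI-44-range subscale scores, so the full pipeline can be exercised and
## validated without access to recorded videos.

.KINEMATIC_PARAMS <- c("arm_swing", "stride", "cadence", "torso_sway", "head_bob")

#' Rest pose of the synthetic walker
#'
#' A plausible front-view standing pose in pixel coordinates (image y grows
#' downwards), roughly a 420-pixel-tall person centred in a 1920 x 1080
#' frame -- the scale of a camera viewing a ~6 m walkway. Absolute scale and
#' position are irrelevant after MidHip translation.
#'
#' @return Numeric 25 x 2 matrix (columns x, y), rows in BODY_25 order.
#' @export
gaitBasePose <- function() {
  pose <- matrix(NA_real_, 25L, 2L, dimnames = list(.BODY25_LABELS, c("x", "y")))
  cx <- 960
  pose["Nose", ] <- c(cx, 320)
  pose["Neck", ] <- c(cx, 360)
  pose["RShoulder", ] <- c(cx + 40, 365)
  pose["RElbow", ] <- c(cx + 55, 420)
  pose["RWrist", ] <- c(cx + 60, 475)
  pose["LShoulder", ] <- c(cx - 40, 365)
  pose["LElbow", ] <- c(cx - 55, 420)
  pose["LWrist", ] <- c(cx - 60, 475)
  pose["MidHip", ] <- c(cx, 540)
  pose["RHip", ] <- c(cx + 25, 540)
  pose["RKnee", ] <- c(cx + 28, 640)
  pose["RAnkle", ] <- c(cx + 30, 740)
  pose["LHip", ] <- c(cx - 25, 540)
  pose["LKnee", ] <- c(cx - 28, 640)
  pose["LAnkle", ] <- c(cx - 30, 740)
  pose["REye", ] <- c(cx + 12, 310)
  pose["LEye", ] <- c(cx - 12, 310)
  pose["REar", ] <- c(cx + 22, 318)
  pose["LEar", ] <- c(cx - 22, 318)
  pose["LBigToe", ] <- c(cx - 34, 765)
  pose["LSmallToe", ] <- c(cx - 40, 763)
  pose["LHeel", ] <- c(cx - 28, 768)
  pose["RBigToe", ] <- c(cx + 34, 765)
  pose["RSmallToe", ] <- c(cx + 40, 763)
  pose["RHeel", ] <- c(cx + 28, 768)
  pose
}

#' Default trait-to-kinematics effect matrix
#'
#' Each trait modulates one kinematic parameter, following the qualitative
#' gait-personality literature: extraversion drives arm-swing amplitude,
#' agreeableness torso sway, conscientiousness stride amplitude, neuroticism
#' (negatively) cadence, openness head bob. Units are the parameter's units
#' per standard deviation of the latent trait; magnitudes are chosen so the
#' standardised trait-to-amplitude effect is strong (~0.8 of the base
#' value's half), giving a cohort in which trait signal is genuinely present
#' in the kinematics.
#'
#' @return Numeric 5 x 5 matrix, rows = traits, columns = kinematic
#'   parameters.
#' @export
defaultEffectMatrix <- function() {
  B <- matrix(0, 5L, 5L, dimnames = list(.BIG5, .KINEMATIC_PARAMS))
  B["extraversion", "arm_swing"] <- 6
  B["agreeableness", "torso_sway"] <- 3
  B["conscientiousness", "stride"] <- 10
  B["neuroticism", "cadence"] <- -0.12
  B["openness", "head_bob"] <- 2.5
  B
}

#' Default inter-trait correlation matrix
#'
#' The qualitative Big Five pattern reported for BFI-44 subscales:
#' extraversion, agreeableness, conscientiousness and openness mutually
#' positively correlated, all negatively correlated with neuroticism.
#'
#' @param rho Magnitude of the off-diagonal correlations (default 0.3).
#' @return Positive-definite 5 x 5 correlation matrix.
#' @export
defaultTraitCorrelation <- function(rho = 0.3) {
  s <- c(1, 1, 1, -1, 1) # neuroticism flipped
  R <- rho * tcrossprod(s) + (1 - rho) * diag(5L)
  dimnames(R) <- list(.BIG5, .BIG5)
  R
}

#' Configuration of a synthetic gait cohort
#'
#' @param nSubjects Number of subjects (default 150, the scale of a typical
#'   gait-personality cohort).
#' @param nFrames Frames per sequence (default 75; must be >= 75 for the
#'   full pipeline).
#' @param gaitPeriod Frames per gait cycle at cadence 1 (default 25, i.e.
#'   three cycles per 75-frame window).
#' @param basePose 25 x 2 rest pose, see [gaitBasePose()].
#' @param effectMatrix 5 x 5 trait-by-parameter coefficient matrix, see
#'   [defaultEffectMatrix()].
#' @param traitCorrelation 5 x 5 latent trait correlation, see
#'   [defaultTraitCorrelation()].
#' @param noiseSd Additive pixel noise SD on every coordinate (default 1,
#'   the jitter scale of pose estimation on clean video).
#' @param scoreNoiseSd Score-point noise SD on the subscale sums
#'   (default 2).
#' @param baseParams Baseline kinematic parameters (pixels;
#'   cadence unitless).
#' @param seed Integer seed; the cohort is a pure function of the
#'   configuration.
#' @return A `SyntheticConfig` list.
#' @export
syntheticConfig <- function(nSubjects = 150L, nFrames = 75L, gaitPeriod = 25,
                            basePose = gaitBasePose(),
                            effectMatrix = defaultEffectMatrix(),
                            traitCorrelation = defaultTraitCorrelation(),
                            noiseSd = 1, scoreNoiseSd = 2,
                            baseParams = c(
                              arm_swing = 12, stride = 25, cadence = 1,
                              torso_sway = 6, head_bob = 5
                            ),
                            seed = 1L) {
  stopifnot(
    nSubjects >= 1L, nFrames >= 1L, gaitPeriod > 0,
    all(dim(basePose) == c(25L, 2L)),
    all(dim(effectMatrix) == c(5L, 5L)),
    all(dim(traitCorrelation) == c(5L, 5L)),
    noiseSd >= 0, scoreNoiseSd >= 0,
    length(baseParams) == 5L
  )
  ev <- eigen(traitCorrelation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("traitCorrelation must be positive definite")
  }
  structure(
    list(
      nSubjects = as.integer(nSubjects), nFrames = as.integer(nFrames),
      gaitPeriod = gaitPeriod, basePose = basePose,
      effectMatrix = effectMatrix, traitCorrelation = traitCorrelation,
      noiseSd = noiseSd, scoreNoiseSd = scoreNoiseSd,
      baseParams = stats::setNames(
        as.numeric(baseParams), .KINEMATIC_PARAMS
      ),
      seed = as.integer(seed)
    ),
    class = "SyntheticConfig"
  )
}

#' Generate one synthetic gait sequence
#'
#' Keypoints follow the rest pose plus sinusoidal oscillation at the gait
#' period: wrists/elbows swing antiphase left-right (arm_swing amplitude,
#' elbows at half), ankles/knees/toes likewise (stride amplitude), the upper
#' body sways laterally (torso_sway), the head bobs vertically at twice the
#' step frequency (head_bob), and cadence scales the gait frequency.
#' Additive Gaussian pixel noise is drawn from the caller's RNG stream.
#'
#' @param params Named numeric vector of kinematic parameters
#'   (`arm_swing`, `stride`, `cadence`, `torso_sway`, `head_bob`).
#' @param config A `SyntheticConfig`.
#' @param subjectIdentifier Subject id for the sequence.
#' @return A [GaitSequence-class] with `config$nFrames` frames.
#' @export
generateGaitSequence <- function(params, config,
                                 subjectIdentifier = "synthetic") {
  stopifnot(inherits(config, "SyntheticConfig"))
  params <- params[.KINEMATIC_PARAMS]
  n <- config$nFrames
  phase <- 2 * pi * params[["cadence"]] * seq_len(n) / config$gaitPeriod
  s <- sin(phase)
  s2 <- sin(2 * phase)
  coords <- array(rep(t(config$basePose), each = n), c(n, 25L, 2L))
  kp <- function(label) match(label, .BODY25_LABELS)
  addX <- function(labels, amp, sgn = 1) {
    for (l in labels) {
      coords[, kp(l), 1L] <<- coords[, kp(l), 1L] + sgn * amp * s
    }
  }
  addX("RWrist", params[["arm_swing"]])
  addX("LWrist", params[["arm_swing"]], -1)
  addX("RElbow", params[["arm_swing"]] / 2)
  addX("LElbow", params[["arm_swing"]] / 2, -1)
  addX(c("RAnkle", "RBigToe", "RSmallToe", "RHeel"), params[["stride"]] / 2)
  addX(c("LAnkle", "LBigToe", "LSmallToe", "LHeel"), params[["stride"]] / 2, -1)
  addX("RKnee", params[["stride"]] / 4)
  addX("LKnee", params[["stride"]] / 4, -1)
  addX(
    c("Nose", "Neck", "RShoulder", "LShoulder", "REye", "LEye", "REar", "LEar"),
    params[["torso_sway"]]
  )
  for (l in c("Nose", "REye", "LEye", "REar", "LEar")) {
    coords[, kp(l), 2L] <- coords[, kp(l), 2L] + params[["head_bob"]] * s2
  }
  coords[, kp("Neck"), 2L] <- coords[, kp("Neck"), 2L] +
    params[["head_bob"]] / 2 * s2
  if (config$noiseSd > 0) {
    coords <- coords + stats::rnorm(length(coords), sd = config$noiseSd)
  }
  GaitSequence(subjectIdentifier, coords)
}

#' Generate a synthetic gait cohort with trait-driven kinematics
#'
#' Per subject: a latent Big Five trait vector is drawn from a multivariate
#' normal with the configured correlation structure; BFI-44 subscale scores
#' are the subscale midpoint plus a subscale-SD multiple of the latent trait
#' plus rounding noise, clipped to the legal subscale range; kinematic
#' parameters are the baseline plus `effectMatrix` times the latent traits
#' (amplitudes clipped at 0, cadence at 0.2); and a gait sequence is
#' generated from those parameters. Deterministic given `config$seed`.
#'
#' @param config A `SyntheticConfig` from [syntheticConfig()].
#' @return List with `sequences` (list of [GaitSequence-class]), `scores`
#'   (data frame: `subject_id` plus the five subscale columns), and `truth`
#'   (list with the latent trait matrix and the kinematic parameter matrix).
#' @export
generateCohort <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  n <- config$nSubjects
  traits <- bigFiveTraits()
  scoreMean <- (traits$min + traits$max) / 2
  scoreSd <- c(5, 5.5, 5.5, 5, 6)
  localSeed(config$seed, {
    z <- matrix(stats::rnorm(n * 5L), n, 5L) %*% chol(config$traitCorrelation)
    colnames(z) <- .BIG5
    raw <- sweep(sweep(z, 2L, scoreSd, "*"), 2L, scoreMean, "+") +
      matrix(stats::rnorm(n * 5L, sd = config$scoreNoiseSd), n, 5L)
    scores <- round(raw)
    for (j in seq_len(5L)) {
      scores[, j] <- pmin(pmax(scores[, j], traits$min[j]), traits$max[j])
    }
    params <- sweep(z %*% config$effectMatrix, 2L, config$baseParams, "+")
    amps <- setdiff(.KINEMATIC_PARAMS, "cadence")
    params[, amps] <- pmax(params[, amps], 0)
    params[, "cadence"] <- pmax(params[, "cadence"], 0.2)
    ids <- sprintf("S%03d", seq_len(n))
    sequences <- lapply(seq_len(n), function(i) {
      generateGaitSequence(params[i, ], config, subjectIdentifier = ids[i])
    })
    list(
      sequences = sequences,
      scores = data.frame(
        subject_id = ids, as.data.frame(scores),
        stringsAsFactors = FALSE
      ),
      truth = list(latent = z, params = params)
    )
  })
}
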