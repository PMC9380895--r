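# Fixtures are built in code: small GaitSequence objects, OpenPose JSON
# directories, and an independent greedy-selection oracle.

# Random walking-ish sequence: base pose plus smooth noise, all confidences 1.
makeSequence <- function(frames = 75L, seed = 1L, id = "fix") {
  set.seed(seed)
  base <- gaitBasePose()
  coords <- array(0, c(frames, 25L, 2L))
  for (k in 1:25) {
    for (ax in 1:2) {
      coords[, k, ax] <- base[k, ax] +
        5 * sin(2 * pi * seq_len(frames) / 25 + k + ax) +
        rnorm(frames, sd = 0.5)
    }
  }
  GaitSequence(id, coords)
}

# TranslatedSequence with fully controlled coordinates: supply a function
# f(frame, keypointIndex) -> c(x, y); MidHip is pinned at the origin.
makeTranslated <- function(frames, f) {
  coords <- array(0, c(frames, 25L, 2L))
  for (t in seq_len(frames)) {
    for (k in 0:24) {
      if (k == 8L) next
      coords[t, k + 1L, ] <- f(t, k)
    }
  }
  translateToMidHip(GaitSequence("ctrl", coords))
}

# Write an OpenPose BODY_25 JSON frame file. `people` is a list of
# 25x3 matrices (x, y, confidence).
writeOpenPoseFrame <- function(path, people) {
  payload <- list(
    version = 1.3,
    people = lapply(people, function(m) {
      list(pose_keypoints_2d = as.vector(t(m)))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
}

makeOpenPoseDir <- function(frames = 3L, seed = 1L) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  set.seed(seed)
  for (i in seq_len(frames)) {
    m <- cbind(matrix(runif(50, 100, 900), 25L, 2L), runif(25, 0.5, 1))
    writeOpenPoseFrame(file.path(dir, sprintf("frame_%03d.json", i)), list(m))
  }
  dir
}

# Independent brute-force greedy selection oracle: at each stage refit an
# OLS model per candidate subset with lm.fit and score mean negative RMSE
# over the same inner folds the package uses.
greedyOracleLr <- function(Z, y, k, cvFolds = 5L, seed = 1L) {
  foldId <- gaitfive:::foldAssignment(
    nrow(Z), cvFolds, gaitfive:::deriveSeed(seed, 7L)
  )
  sel <- integer(0)
  for (stage in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(Z)), sel)
    scores <- vapply(cand, function(j) {
      tot <- 0
      for (f in seq_len(cvFolds)) {
        tr <- foldId != f
        A <- cbind(1, Z[tr, c(sel, j), drop = FALSE])
        cf <- stats::lm.fit(A, y[tr])$coefficients
        cf[is.na(cf)] <- 0
        p <- cbind(1, Z[!tr, c(sel, j), drop = FALSE]) %*% cf
        tot <- tot + sqrt(mean((p - y[!tr])^2))
      }
      -tot / cvFolds
    }, numeric(1))
    sel <- c(sel, cand[which.max(scores)])
  }
  sel
}

# Minimal PredictionSet stand-in for evaluation-side tests.
fakePredictionSet <- function(all, odd = all, even = all, trait = "t") {
  structure(
    list(
      aggregated = cbind(all = all, odd = odd, even = even),
      perRepetition = NULL, trait = trait, algorithm = "lr",
      repeats = 1L, folds = 1L, seed = 1L
    ),
    class = "PredictionSet"
  )
}
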