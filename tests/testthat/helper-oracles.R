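# Independent brute-force oracles used to cross-check the pipeline.

# Enumerate every merged compliant interval of an alpha series and pick the
# longest (earliest on ties). Independent of the sequential merge in
# partition_micro_events: compliant runs are grouped by exhaustive
# enumeration of run index pairs (i, j) whose intervening gaps are all below
# the merge threshold, then non-maximal groups are discarded.
oracle_sip_interval <- function(alpha, alpha_diff_max = 8, merge_gap = 2L) {
  compliant <- c(TRUE, abs(diff(alpha)) <= alpha_diff_max)
  if (!any(compliant)) return(NULL)
  r <- rle(compliant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values] + 1L)
  nr <- nrow(runs)
  candidates <- list()
  for (i in seq_len(nr)) {
    for (j in i:nr) {
      gaps_ok <- TRUE
      if (j > i) {
        for (k in i:(j - 1)) {
          if (runs$start[k + 1] - runs$end[k] >= merge_gap) gaps_ok <- FALSE
        }
      }
      if (gaps_ok) {
        candidates[[length(candidates) + 1]] <-
          c(start = runs$start[i], end = runs$end[j], i = i, j = j)
      }
    }
  }
  cand <- do.call(rbind, candidates)
  # maximal groups only: not extendable left or right
  maximal <- logical(nrow(cand))
  for (m in seq_len(nrow(cand))) {
    i <- cand[m, "i"]; j <- cand[m, "j"]
    left_ok <- i == 1 || runs$start[i] - runs$end[i - 1] >= merge_gap
    right_ok <- j == nr || runs$start[j + 1] - runs$end[j] >= merge_gap
    maximal[m] <- left_ok && right_ok
  }
  cand <- cand[maximal, , drop = FALSE]
  lens <- cand[, "end"] - cand[, "start"]
  best <- which(lens == max(lens))[1]  # earliest by construction order
  cand[best, c("start", "end")]
}

# Closed-form normal equations for simple linear regression.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Trapezoidal quadrature written out longhand.
oracle_trapz <- function(y, dt) {
  if (length(y) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2 * dt)
}

sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

# A synthetic conditioned recording built directly on the uniform grid, for
# segmentation tests that need exact control over the motion indicator.
make_conditioned <- function(ax, ay, az, rate = 20, trial_id = "T1") {
  n <- length(ax)
  structure(tibble::tibble(t = (seq_len(n) - 1) / rate,
                           ax = ax, ay = ay, az = az),
            trial_id = trial_id, subject_id = "S1", rate = rate,
            class = c("sip_conditioned", class(tibble::tibble())))
}

# Cache the default synthetic cohort and its features across test files.
cohort_cache <- new.env(parent = emptyenv())
default_cohort_data <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(cohort_cache[[key]])) {
    cohort <- simulate_cohort(sim_config(seed = seed))
    feats <- suppressWarnings(featurize_cohort(cohort$recordings))
    data <- suppressWarnings(join_labels(feats, cohort$labels))
    cohort_cache[[key]] <- list(cohort = cohort, data = data)
  }
  cohort_cache[[key]]
}
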